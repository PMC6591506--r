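0
SECTION
2
ENTITIES
0
LINE
8
0
10
0.0
20
0.0
11
3.0
21
0.0
0
LINE
8
0
10
3.0
20
0.0
11
3.0
21
3.0
0
LINE
8
0
10
3.0
20
3.0
11
0.0
21
3.0
0
LINE
8
0
10
0.0
20
3.0
11
0.0
21
0.0
0
LWPOLYLINE
8
0
90
4
70
1
10
1.0
20
1.0
10
2.0
20
1.0
10
2.0
20
2.0
10
1.0
20
2.0
0
ENDSEC
0
EOF
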