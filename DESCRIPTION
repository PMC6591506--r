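Package: mfda
Title: Component-Connection Design Automation for Continuous-Flow
    Microfluidic Devices
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A headless design-automation library for continuous-flow
    microfluidic (lab-on-chip) devices. Devices are modelled as a
    component-connection netlist on paired flow/control functional layers,
    with procedurally generated parametric component geometry (ports,
    serpentine mixers, multiplexer trees, membrane valves, pumps,
    chambers), membrane-valve-to-channel mapping, design-for-manufacturing
    classification and 2.5D manufacturing-layer generation, DXF import of
    custom component geometry, serialization to a ParchMINT-superset JSON
    interchange format, import of a minimal MINT-style netlist language
    with automatic grid placement, SVG and DXF export, a quantitative
    design-effort model measured in user actions, and an
    electrical-equivalent hydraulic resistance network solver for steady
    pressures and flow rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    polyclip,
    Matrix,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    xml2
Config/testthat/edition: 3
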