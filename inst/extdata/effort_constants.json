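{
  "comment": "Design-effort constants, in user actions. CAD mode models drawing each geometry manually in a conventional CAD tool: E_Design = C_Base * f_Procedural(X), E_Parameterization = C_Identification + N_Params * (C_Constraint + C_Value). The MIXER row uses the published calibration (C_Base=6, C_Identification=20, C_Value=4, identity f at X = numberOfBends); its (N_Params=5, C_Constraint=0) completes the 88-action worked example and matches the mixer's five parameters. All other rows are library calibration choices, overridable via effort_constants(path). TOOL mode models placement in the design environment: 1 placement action plus C_Value per explicitly set parameter.",
  "include_connections": true,
  "modes": {
    "CAD": {
      "PORT":    {"c_base": 6, "c_identification": 10, "c_constraint": 0, "c_value": 4, "n_params": 2, "f": {"class": "constant"}},
      "MIXER":   {"c_base": 6, "c_identification": 20, "c_constraint": 0, "c_value": 4, "n_params": 5, "f": {"class": "linear", "coef": 1}, "size_param": "numberOfBends"},
      "MUX":     {"c_base": 6, "c_identification": 20, "c_constraint": 0, "c_value": 4, "n_params": 5, "f": {"class": "polynomial", "coef": 1, "degree": 2}, "size_param": "outputs"},
      "VALVE":   {"c_base": 6, "c_identification": 12, "c_constraint": 0, "c_value": 4, "n_params": 3, "f": {"class": "constant"}},
      "VALVE3D": {"c_base": 12, "c_identification": 16, "c_constraint": 0, "c_value": 4, "n_params": 4, "f": {"class": "constant"}},
      "PUMP":    {"c_base": 18, "c_identification": 16, "c_constraint": 0, "c_value": 4, "n_params": 4, "f": {"class": "constant"}},
      "CHAMBER": {"c_base": 6, "c_identification": 12, "c_constraint": 0, "c_value": 4, "n_params": 3, "f": {"class": "constant"}},
      "CHANNEL": {"c_base": 2, "c_identification": 4, "c_constraint": 0, "c_value": 2, "n_params": 2, "f": {"class": "linear", "coef": 1}, "size_param": "elements"},
      "CUSTOM":  {"c_base": 30, "c_identification": 10, "c_constraint": 0, "c_value": 4, "n_params": 2, "f": {"class": "constant"}}
    },
    "TOOL": {
      "default": {"c_base": 1, "c_identification": 0, "c_constraint": 0, "c_value": 1, "f": {"class": "constant"}}
    }
  }
}
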