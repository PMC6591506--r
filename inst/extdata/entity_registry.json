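{
  "comment": "Shipped defaults and bounds for the built-in parametric entities. Lengths in micrometres; counts dimensionless. Override by calling load_entity_registry() with a file of the same shape.",
  "circle_resolution": 32,
  "entities": {
    "PORT": {
      "dfm_class": "Z",
      "procedural_order": "constant",
      "functional_role": "ANY",
      "params": [
        {"name": "portRadius", "units": "um", "kind": "length", "default": 700, "min": 10, "max": 5000},
        {"name": "height", "units": "um", "kind": "length", "default": 100, "min": 1, "max": 2000}
      ]
    },
    "MIXER": {
      "dfm_class": "XY",
      "procedural_order": "linear",
      "functional_role": "FLOW",
      "size_param": "numberOfBends",
      "params": [
        {"name": "numberOfBends", "units": "count", "kind": "count", "default": 8, "min": 1, "max": 50},
        {"name": "bendLength", "units": "um", "kind": "length", "default": 2000, "min": 100, "max": 20000},
        {"name": "bendSpacing", "units": "um", "kind": "length", "default": 400, "min": 10, "max": 5000},
        {"name": "channelWidth", "units": "um", "kind": "length", "default": 400, "min": 10, "max": 2000},
        {"name": "height", "units": "um", "kind": "length", "default": 100, "min": 1, "max": 2000}
      ]
    },
    "MUX": {
      "dfm_class": "XY",
      "procedural_order": "polynomial",
      "functional_role": "FLOW",
      "size_param": "outputs",
      "params": [
        {"name": "outputs", "units": "count", "kind": "count", "default": 4, "min": 2, "max": 32},
        {"name": "channelWidth", "units": "um", "kind": "length", "default": 400, "min": 10, "max": 2000},
        {"name": "spacing", "units": "um", "kind": "length", "default": 2000, "min": 100, "max": 20000},
        {"name": "stageHeight", "units": "um", "kind": "length", "default": 2000, "min": 100, "max": 20000},
        {"name": "height", "units": "um", "kind": "length", "default": 100, "min": 1, "max": 2000}
      ]
    },
    "VALVE": {
      "dfm_class": "XY",
      "procedural_order": "constant",
      "functional_role": "CONTROL",
      "params": [
        {"name": "length", "units": "um", "kind": "length", "default": 1200, "min": 100, "max": 10000},
        {"name": "width", "units": "um", "kind": "length", "default": 400, "min": 50, "max": 5000},
        {"name": "height", "units": "um", "kind": "length", "default": 50, "min": 1, "max": 2000}
      ]
    },
    "VALVE3D": {
      "dfm_class": "XYZ",
      "procedural_order": "constant",
      "functional_role": "BOTH",
      "params": [
        {"name": "valveRadius", "units": "um", "kind": "length", "default": 700, "min": 100, "max": 5000},
        {"name": "channelWidth", "units": "um", "kind": "length", "default": 400, "min": 10, "max": 2000},
        {"name": "gap", "units": "um", "kind": "length", "default": 600, "min": 10, "max": 5000},
        {"name": "height", "units": "um", "kind": "length", "default": 100, "min": 1, "max": 2000}
      ]
    },
    "PUMP": {
      "dfm_class": "XY",
      "procedural_order": "constant",
      "functional_role": "CONTROL",
      "params": [
        {"name": "length", "units": "um", "kind": "length", "default": 1200, "min": 100, "max": 10000},
        {"name": "width", "units": "um", "kind": "length", "default": 400, "min": 50, "max": 5000},
        {"name": "spacing", "units": "um", "kind": "length", "default": 1000, "min": 50, "max": 10000},
        {"name": "height", "units": "um", "kind": "length", "default": 50, "min": 1, "max": 2000}
      ]
    },
    "CHAMBER": {
      "dfm_class": "XY",
      "procedural_order": "constant",
      "functional_role": "FLOW",
      "params": [
        {"name": "width", "units": "um", "kind": "length", "default": 2000, "min": 100, "max": 50000},
        {"name": "length", "units": "um", "kind": "length", "default": 4000, "min": 100, "max": 50000},
        {"name": "height", "units": "um", "kind": "length", "default": 400, "min": 1, "max": 2000}
      ]
    }
  }
}
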