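[
  {"id": "fa2low_1", "fa": "FA2_LOW", "shape": "rectangle", "length_mm": 300, "width_mm": 70},
  {"id": "fa2low_2", "fa": "FA2_LOW", "shape": "rectangle", "length_mm": 300, "width_mm": 70},
  {"id": "fa2low_3", "fa": "FA2_LOW", "shape": "rectangle", "length_mm": 300, "width_mm": 70},
  {"id": "fa2high_1", "fa": "FA2_HIGH", "shape": "rectangle", "length_mm": 300, "width_mm": 70},
  {"id": "fa2high_2", "fa": "FA2_HIGH", "shape": "rectangle", "length_mm": 300, "width_mm": 70},
  {"id": "fa2high_3", "fa": "FA2_HIGH", "shape": "rectangle", "length_mm": 300, "width_mm": 70},
  {"id": "fa3_1", "fa": "FA3", "shape": "rectangle", "length_mm": 300, "width_mm": 70},
  {"id": "fa3_2", "fa": "FA3", "shape": "rectangle", "length_mm": 300, "width_mm": 70},
  {"id": "fa3_3", "fa": "FA3", "shape": "rectangle", "length_mm": 300, "width_mm": 70},
  {"id": "fa3_4", "fa": "FA3", "shape": "rectangle", "length_mm": 300, "width_mm": 70},
  {"id": "fa3_5", "fa": "FA3", "shape": "rectangle", "length_mm": 300, "width_mm": 70},
  {"id": "roof_1", "fa": "FA1", "shape": "rectangle", "length_mm": 30, "width_mm": 30},
  {"id": "roof_2", "fa": "FA1", "shape": "rectangle", "length_mm": 30, "width_mm": 30},
  {"id": "roof_3", "fa": "FA1", "shape": "rectangle", "length_mm": 30, "width_mm": 30}
]
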