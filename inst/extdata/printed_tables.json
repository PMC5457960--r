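{
  "table3": [
    {"lv": "LV_10", "mv": "B_s_10", "weight": 0.6438, "std_weight": 0.991, "communality": 0.9819, "redundancy": 0},
    {"lv": "LV_10", "mv": "Me_s_10", "weight": 0.3723, "std_weight": 0.973, "communality": 0.9458, "redundancy": 0},
    {"lv": "LV_overall", "mv": "VD_10", "weight": -0.0165, "std_weight": -0.522, "communality": 0.2729, "redundancy": 0.2679},
    {"lv": "LV_overall", "mv": "B_s_10", "weight": 0.5436, "std_weight": 0.982, "communality": 0.9639, "redundancy": 0.9463},
    {"lv": "LV_overall", "mv": "Me_s_10", "weight": 0.4298, "std_weight": 0.964, "communality": 0.9287, "redundancy": 0.9117},
    {"lv": "LV_overall", "mv": "A_s_1", "weight": 0.1177, "std_weight": 0.176, "communality": 0.0308, "redundancy": 0.055},
    {"lv": "LV_overall", "mv": "Cp_f_1", "weight": 0.774, "std_weight": -0.703, "communality": 0.4944, "redundancy": 0},
    {"lv": "LV_1", "mv": "A_s_1", "weight": -0.7146, "std_weight": 0.638, "communality": 0.4068, "redundancy": 0},
    {"lv": "LV_1", "mv": "Cp_f_1", "weight": 0.774, "std_weight": -0.703, "communality": 0.4944, "redundancy": 0}
  ],
  "table4": {
    "lv_names": ["LV_10", "LV_overall", "LV_1", "LV_setback"],
    "values": [
      [1.000, 0.991, 0.182, 0.898],
      [0.991, 1.000, 0.309, 0.925],
      [0.182, 0.309, 1.000, 0.409],
      [0.898, 0.925, 0.409, 1.000]
    ]
  },
  "table5": {
    "gof": 0.7236,
    "LV_overall": {"r2": 0.9818, "paths": {"LV_10": 0.9908}},
    "LV_setback": {"r2": 0.8731,
                   "paths": {"LV_10": -0.9914, "LV_overall": 1.9065, "LV_1": 0.0013}}
  }
}
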