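{
  "scheme": "NSC",
  "levels": ["R0", "R1", "R2", "R3"],
  "level_names": {
    "R0": "no retinopathy",
    "R1": "background retinopathy",
    "R2": "pre-proliferative retinopathy",
    "R3": "proliferative retinopathy"
  },
  "rules": [
    {
      "level": "R3",
      "name": "proliferative",
      "any": [
        {"kind": "present",
         "types": ["NVD", "NVE", "PRERETINAL_HAEMORRHAGE", "FIBROSIS"]}
      ]
    },
    {
      "level": "R2",
      "name": "pre-proliferative",
      "any": [
        {"kind": "present",
         "types": ["VENOUS_BEADING", "VENOUS_LOOP", "VENOUS_REDUPLICATION",
                   "IRMA"]},
        {"kind": "count_ge", "types": ["BLOT_HAEMORRHAGE"], "count": 5}
      ]
    },
    {
      "level": "R1",
      "name": "background",
      "any": [
        {"kind": "present",
         "types": ["MA", "HAEMORRHAGE", "BLOT_HAEMORRHAGE", "EXUDATE", "CWS"]}
      ]
    }
  ],
  "default_level": "R0",
  "maculopathy": {"types": ["EXUDATE"], "radius_dd": 1.0},
  "referable": {"min_level": "R2", "or_maculopathy": true}
}
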