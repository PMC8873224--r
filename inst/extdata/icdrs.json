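{
  "scheme": "ICDRS",
  "levels": ["0", "1", "2", "3", "4"],
  "level_names": {
    "0": "no apparent retinopathy",
    "1": "mild NPDR",
    "2": "moderate NPDR",
    "3": "severe NPDR",
    "4": "PDR"
  },
  "rules": [
    {
      "level": "4",
      "name": "proliferative",
      "any": [
        {"kind": "present",
         "types": ["NVD", "NVE", "PRERETINAL_HAEMORRHAGE", "FIBROSIS"]}
      ]
    },
    {
      "level": "3",
      "name": "severe-4-2-1",
      "any": [
        {"kind": "per_quadrant_count_ge",
         "types": ["HAEMORRHAGE", "BLOT_HAEMORRHAGE"],
         "count": 20, "quadrants": 4},
        {"kind": "quadrants_present_ge",
         "types": ["VENOUS_BEADING"], "quadrants": 2},
        {"kind": "quadrants_present_ge",
         "types": ["IRMA"], "quadrants": 1}
      ]
    },
    {
      "level": "2",
      "name": "moderate",
      "any": [
        {"kind": "present",
         "types": ["HAEMORRHAGE", "BLOT_HAEMORRHAGE", "EXUDATE", "CWS",
                   "VENOUS_LOOP", "VENOUS_REDUPLICATION", "VENOUS_BEADING"]}
      ]
    },
    {
      "level": "1",
      "name": "mild-MAs-only",
      "any": [
        {"kind": "present", "types": ["MA"]}
      ]
    }
  ],
  "default_level": "0",
  "ma_mild_ceiling": null,
  "maculopathy": {"types": ["EXUDATE"], "radius_dd": 1.0},
  "referable": {"min_level": "2", "or_maculopathy": true}
}
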