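{
  "mask": "plausibility_mask.json",
  "aggregation": "aggregation_rules.json",
  "tier_width": 1,
  "labels": {
    "A": "Primary forests",
    "B": "Newly untouched forest",
    "C": "Specially managed forest under closer-to-nature forestry",
    "D": "Exploited natural forest under closer-to-nature or combined objective forestry",
    "E": "Plantation-like natural forest under intensive even-aged forestry",
    "F": "Partly natural forest under passive to medium intensity forest management",
    "G": "Native plantation under intensive even-aged or short-rotation forestry",
    "H": "Exotic plantation under intensive even-aged or short-rotation forestry",
    "I": "Exotic self-sown forest under intensive even-aged or short-rotation forestry"
  }
}
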