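[
  {
    "merged_codes": ["n7", "n6", "n5"],
    "target_archetype_id": "A"
  }
]
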