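{
  "rows": ["n7", "n6", "n5", "n4", "n3", "n2", "n1", "p4", "p3", "p2", "p1"],
  "cols": ["passive", "low", "medium", "high", "intensive"],
  "allowed": {
    "n7": ["passive"],
    "n6": ["passive"],
    "n5": ["passive", "low"],
    "n4": ["passive", "low"],
    "n3": ["low", "medium"],
    "n2": ["low", "medium"],
    "n1": ["medium", "high"],
    "p4": ["passive", "low", "medium"],
    "p3": ["high", "intensive"],
    "p2": ["high", "intensive"],
    "p1": ["high", "intensive"]
  }
}
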