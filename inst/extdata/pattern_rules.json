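[
  {
    "label": "U-shaped (short and long harmful)",
    "when": {"lowest_sig_neg": true, "highest_sig_pos": true, "linear_sig": false}
  },
  {
    "label": "inverted-U (mid-range harmful)",
    "when": {"lowest_sig_pos": true, "highest_sig_neg": true, "linear_sig": false}
  },
  {
    "label": "reverse-J (short harmful)",
    "when": {"lowest_sig_neg": true, "highest_sig_pos": false, "highest_sig_neg": false}
  },
  {
    "label": "J (long harmful)",
    "when": {"highest_sig_pos": true, "lowest_sig_neg": false, "lowest_sig_pos": false}
  },
  {
    "label": "linear-positive",
    "when": {"lowest_sig_pos": true, "highest_sig_pos": true}
  },
  {
    "label": "linear-negative",
    "when": {"lowest_sig_neg": true, "highest_sig_neg": true}
  },
  {
    "label": "linear-positive",
    "when": {"linear_sig_pos": true, "any_stratum_sig": false}
  },
  {
    "label": "linear-negative",
    "when": {"linear_sig_neg": true, "any_stratum_sig": false}
  },
  {
    "label": "null",
    "when": {"any_stratum_sig": false, "linear_sig": false}
  }
]
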