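[
  {
    "name": "gnomad_eas",
    "case_label": "HCM cohort",
    "control_label": "gnomAD v4.0 East Asian",
    "case_carriers": 36, "case_n": 2366,
    "control_carriers": 16, "control_n": 22448
  },
  {
    "name": "koges_kova2",
    "case_label": "HCM cohort",
    "control_label": "KoGES + KOVA2",
    "case_carriers": 36, "case_n": 2366,
    "control_carriers": 15, "control_n": 10305
  },
  {
    "name": "internal_exomes",
    "case_label": "HCM cohort",
    "control_label": "Internal exomes (non-HCM)",
    "case_carriers": 36, "case_n": 2366,
    "control_carriers": 8, "control_n": 5996
  },
  {
    "name": "combined",
    "case_label": "HCM cohort",
    "control_label": "Combined controls",
    "case_carriers": 36, "case_n": 2366,
    "control_carriers": 39, "control_n": 38749
  }
]
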