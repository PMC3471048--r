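[
  {
    "name": "pe-best",
    "note": "Pulmonary embolism, best case: anticoagulation benefit vastly exceeds bleeding harm. The published benefit/harm ratio is printed as 60.8; the components as printed (22.5/0.037) give 608, an arithmetic inconsistency in the source. The ratio 60.8 (components 22.5/0.37) is used here because it is the one the published 1.6% threshold follows from.",
    "profile": { "b2": "22.5%", "h2": "0.37%" },
    "parameters": { "gamma": 0, "k": 1, "m_I": 1 },
    "expected": {
      "p_eut": 0.016,
      "provenance": "published worked example (EUT threshold 1.6%)"
    }
  },
  {
    "name": "pe-worst",
    "note": "Pulmonary embolism, worst case: benefit/harm ratio 3.5 (17.5%/5%); system I, primed by a recent bleed, feels harm exceeding benefit by 10 percentage points. Only the difference b1 - h1 enters the threshold; the pair (0.175, 0.275) realizes it.",
    "profile": { "b2": "17.5%", "h2": "5%", "b1": 0.175, "h1": 0.275 },
    "parameters": { "gamma": 0.77, "k": 1, "m_I": 1 },
    "sweep": {
      "gamma_grid": [0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6, 0.7, 0.77, 0.78, 0.9, 0.99]
    },
    "expected": {
      "p_eut": 0.222,
      "p_dual_raw": 0.966,
      "provenance": "published worked example (EUT 22.2%, dual threshold 96.6% at gamma 0.77; threshold reaches 1 by gamma 0.78)"
    }
  },
  {
    "name": "pe-worst-synthetic-outcomes",
    "note": "Synthetic outcome quadruple constructed to realize the pe-worst benefit/harm profile at m_I = 0.5 (b2 = 0.175, h2 = 0.05, b1 - h1 = -0.10). Not published utilities; included so the bisection oracle can be exercised on the worked example.",
    "outcomes": { "x1": 0.855625, "x2": 0.000625, "x3": 0.680625, "x4": 0.050625 },
    "parameters": { "gamma": 0.77, "k": 1, "m_I": 0.5 },
    "expected": {
      "p_dual_raw": 0.966,
      "provenance": "published dual threshold realized through a synthetic quadruple"
    }
  },
  {
    "name": "aml-pessimistic",
    "note": "Acute myeloid leukemia, allogeneic transplant vs chemotherapy: leukemia-free-survival benefit 12%, treatment-related-mortality harm 16%. System I doubles the perceived harm (h1 = 0.32), as after a recent on-transplant death.",
    "profile": { "b2": "12%", "h2": "16%", "b1": 0.12, "h1": 0.32 },
    "parameters": { "gamma": 0.5, "k": 1, "m_I": 1 },
    "expected": {
      "p_eut": 0.571,
      "critical_gamma_never_treat": 0.55,
      "provenance": "published worked example (EUT 57.1%; threshold exceeds 1 for gamma above 55%)"
    }
  },
  {
    "name": "aml-optimistic",
    "note": "Same transplant dilemma with system I halving the perceived harm (h1 = 0.08): the threshold drops to zero for sufficiently intuition-driven decisions.",
    "profile": { "b2": "12%", "h2": "16%", "b1": 0.12, "h1": 0.08 },
    "parameters": { "gamma": 0.5, "k": 1, "m_I": 1 },
    "expected": {
      "p_eut": 0.571,
      "critical_gamma_always_treat": 0.89,
      "provenance": "published worked example (threshold drops to 0 for gamma above 89%)"
    }
  }
]
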