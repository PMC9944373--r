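{
  "schizophrenia": [
    {
      "value": 0.3,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    },
    {
      "value": 0.25,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    }
  ],
  "bipolar_disorder": [
    {
      "value": 0.18,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    },
    {
      "value": 0.22,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    }
  ],
  "psychiatric_comorbidity": [
    {
      "value": 0.15,
      "provenance": "expert",
      "citation_label": "synthetic-expert"
    }
  ],
  "alzheimers": [
    {
      "value": 0.08,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    }
  ],
  "lewy_body_dementia": [
    {
      "value": 0.05,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    }
  ],
  "personality_disorder": [
    {
      "value": 0.1,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    },
    {
      "value": 0.14,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    }
  ],
  "getting_out_of_bed": [
    {
      "value": 0.3,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    },
    {
      "value": 0.38,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    },
    {
      "value": 0.25,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    }
  ],
  "seated_to_standing": [
    {
      "value": 0.28,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    },
    {
      "value": 0.35,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    }
  ],
  "getting_to_bed": [
    {
      "value": 0.18,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    }
  ],
  "slipping": [
    {
      "value": 0.12,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    },
    {
      "value": 0.08,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    }
  ],
  "tripping": [
    {
      "value": 0.1,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    }
  ],
  "stumbling": [
    {
      "value": 0.08,
      "provenance": "expert",
      "citation_label": "synthetic-expert"
    }
  ],
  "aggression": [
    {
      "value": 0.2,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    }
  ],
  "anxious_behavior": [
    {
      "value": 0.15,
      "provenance": "expert",
      "citation_label": "synthetic-expert"
    }
  ],
  "agitation": [
    {
      "value": 0.22,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    },
    {
      "value": 0.18,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    }
  ],
  "narrow_base_of_support": [
    {
      "value": 0.12,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    }
  ],
  "obesity": [
    {
      "value": 0.25,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    },
    {
      "value": 0.31,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    }
  ],
  "gait_abnormality": [
    {
      "value": 0.2,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    },
    {
      "value": 0.16,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    },
    {
      "value": 0.24,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    }
  ],
  "dizziness": [
    {
      "value": 0.15,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    },
    {
      "value": 0.11,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    }
  ],
  "muscle_weakness": [
    {
      "value": 0.14,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    }
  ],
  "arrhythmia": [
    {
      "value": 0.06,
      "provenance": "literature",
      "citation_label": "synthetic-literature"
    }
  ],
  "fall_risk_not_screened": [
    {
      "value": 0.4,
      "provenance": "expert",
      "citation_label": "synthetic-expert"
    },
    {
      "value": 0.5,
      "provenance": "expert",
      "citation_label": "synthetic-expert"
    }
  ],
  "risk_assessment_not_updated": [
    {
      "value": 0.35,
      "provenance": "expert",
      "citation_label": "synthetic-expert"
    }
  ],
  "no_prevention_intervention": [
    {
      "value": 0.55,
      "provenance": "expert",
      "citation_label": "synthetic-expert"
    },
    {
      "value": 0.45,
      "provenance": "expert",
      "citation_label": "synthetic-expert"
    }
  ],
  "environmental_hazards_present": [
    {
      "value": 0.3,
      "provenance": "expert",
      "citation_label": "synthetic-expert"
    }
  ]
}
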