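{
  "name": "seclusion-falls-reconstruction",
  "top": "TOP",
  "gates": [
    {
      "id": "TOP",
      "kind": "AND",
      "inputs": [
        "DISORDER_OR",
        "MECHANISM_OR",
        "REASON_OR",
        "PREVENTION_AND"
      ]
    },
    {
      "id": "PREVENTION_AND",
      "kind": "AND",
      "inputs": [
        "ASSESSMENT_OR",
        "INTERVENTION_OR"
      ]
    },
    {
      "id": "DISORDER_OR",
      "kind": "OR",
      "inputs": [
        "schizophrenia",
        "bipolar_disorder",
        "psychiatric_comorbidity",
        "alzheimers",
        "lewy_body_dementia",
        "personality_disorder"
      ]
    },
    {
      "id": "MECHANISM_OR",
      "kind": "OR",
      "inputs": [
        "getting_out_of_bed",
        "seated_to_standing",
        "getting_to_bed",
        "slipping",
        "tripping",
        "stumbling"
      ]
    },
    {
      "id": "REASON_OR",
      "kind": "OR",
      "inputs": [
        "PSYCH_REASON_OR",
        "PHYS_REASON_OR"
      ]
    },
    {
      "id": "PSYCH_REASON_OR",
      "kind": "OR",
      "inputs": [
        "aggression",
        "anxious_behavior",
        "agitation"
      ]
    },
    {
      "id": "PHYS_REASON_OR",
      "kind": "OR",
      "inputs": [
        "narrow_base_of_support",
        "obesity",
        "gait_abnormality",
        "SIDE_EFFECT_OR"
      ]
    },
    {
      "id": "SIDE_EFFECT_OR",
      "kind": "OR",
      "inputs": [
        "dizziness",
        "muscle_weakness",
        "arrhythmia"
      ]
    },
    {
      "id": "ASSESSMENT_OR",
      "kind": "OR",
      "inputs": [
        "fall_risk_not_screened",
        "risk_assessment_not_updated"
      ]
    },
    {
      "id": "INTERVENTION_OR",
      "kind": "OR",
      "inputs": [
        "no_prevention_intervention",
        "environmental_hazards_present"
      ]
    }
  ],
  "events": [
    {
      "id": "schizophrenia",
      "label": "Diagnosis of schizophrenia",
      "theme": "other",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "bipolar_disorder",
      "label": "Diagnosis of bipolar disorder",
      "theme": "other",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "psychiatric_comorbidity",
      "label": "Psychiatric comorbidity",
      "theme": "other",
      "underdeveloped": true,
      "sources": []
    },
    {
      "id": "alzheimers",
      "label": "Alzheimer's disease",
      "theme": "other",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "lewy_body_dementia",
      "label": "Lewy body dementia",
      "theme": "other",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "personality_disorder",
      "label": "Personality disorder",
      "theme": "other",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "getting_out_of_bed",
      "label": "Getting out of bed",
      "theme": "patient_behavior",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "seated_to_standing",
      "label": "From seated to standing position",
      "theme": "patient_behavior",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "getting_to_bed",
      "label": "Getting to bed",
      "theme": "patient_behavior",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "slipping",
      "label": "Slipping",
      "theme": "environment",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "tripping",
      "label": "Tripping",
      "theme": "environment",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "stumbling",
      "label": "Stumbling",
      "theme": "environment",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "aggression",
      "label": "Aggressive behavior",
      "theme": "patient_behavior",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "anxious_behavior",
      "label": "Anxious behavior",
      "theme": "patient_behavior",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "agitation",
      "label": "Agitation",
      "theme": "patient_behavior",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "narrow_base_of_support",
      "label": "Narrow base of support",
      "theme": "physical_condition",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "obesity",
      "label": "Obesity",
      "theme": "physical_condition",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "gait_abnormality",
      "label": "Gait abnormality",
      "theme": "physical_condition",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "dizziness",
      "label": "Medication side effect: dizziness",
      "theme": "medication",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "muscle_weakness",
      "label": "Medication side effect: muscle weakness",
      "theme": "medication",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "arrhythmia",
      "label": "Medication side effect: arrhythmia",
      "theme": "medication",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "fall_risk_not_screened",
      "label": "Fall risk not screened",
      "theme": "prevention",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "risk_assessment_not_updated",
      "label": "Fall risk assessment not updated during seclusion",
      "theme": "prevention",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "no_prevention_intervention",
      "label": "No fall prevention intervention in place",
      "theme": "prevention",
      "underdeveloped": false,
      "sources": []
    },
    {
      "id": "environmental_hazards_present",
      "label": "Environmental hazards not removed from seclusion room",
      "theme": "environment",
      "underdeveloped": true,
      "sources": []
    }
  ],
  "metadata": {
    "illustrative": true
  }
}
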