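[
  {
    "rule_id": "R1",
    "treatment": "ARB",
    "trigger_type": "condition",
    "trigger_code": "PREGNANCY",
    "level": "absolute",
    "description": "Angiotensin receptor blockers must not be used in pregnancy",
    "source_type": "clinical_guideline",
    "source_name": "synthetic demo source",
    "source_date": "2020-01-01"
  },
  {
    "rule_id": "R2",
    "treatment": "ACE_INHIBITOR",
    "trigger_type": "comorbidity",
    "trigger_code": "ANGIOEDEMA_HISTORY",
    "level": "absolute",
    "description": "History of angioedema under ACE inhibition",
    "source_type": "professional_information",
    "source_name": "synthetic demo source",
    "source_date": "2020-01-01"
  },
  {
    "rule_id": "R3",
    "treatment": "ACE_INHIBITOR",
    "trigger_type": "condition",
    "trigger_code": "PREGNANCY",
    "level": "absolute",
    "description": "ACE inhibitors must not be used in pregnancy",
    "source_type": "clinical_guideline",
    "source_name": "synthetic demo source",
    "source_date": "2020-01-01"
  },
  {
    "rule_id": "R4",
    "treatment": "BETA_BLOCKER",
    "trigger_type": "comorbidity",
    "trigger_code": "ASTHMA",
    "level": "relative",
    "description": "Beta blockade may aggravate bronchial obstruction",
    "source_type": "professional_information",
    "source_name": "synthetic demo source",
    "source_date": "2020-01-01"
  },
  {
    "rule_id": "R5",
    "treatment": "DIURETIC",
    "trigger_type": "comorbidity",
    "trigger_code": "GOUT",
    "level": "relative",
    "description": "Thiazide diuretics may precipitate gout attacks",
    "source_type": "professional_information",
    "source_name": "synthetic demo source",
    "source_date": "2020-01-01"
  },
  {
    "rule_id": "R6",
    "treatment": "BETA_BLOCKER",
    "trigger_type": "comedication",
    "trigger_code": "VERAPAMIL",
    "level": "absolute",
    "description": "Combined beta blockade and verapamil risks AV block",
    "source_type": "professional_information",
    "source_name": "synthetic demo source",
    "source_date": "2020-01-01"
  }
]
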