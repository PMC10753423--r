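{
  "meta": {
    "schema": "cord-kb/1",
    "version": "1.0",
    "created": "2023-01-01T00:00:00Z"
  },
  "variables": [
    {
      "var_id": "body_weight",
      "kind": "timeseries",
      "units": "kg",
      "data_source": "self_report",
      "definition": "Self-reported body weight over time"
    },
    {
      "var_id": "cigarettes_per_day",
      "kind": "numeric",
      "units": "cigarettes/day",
      "data_source": "self_report",
      "definition": "Current number of cigarettes smoked per day"
    },
    {
      "var_id": "fev1_pct_predicted",
      "kind": "numeric",
      "units": "%",
      "data_source": "sensor",
      "definition": "Forced expiratory volume in 1 second, percent of predicted"
    },
    {
      "var_id": "hads_anxiety",
      "kind": "numeric",
      "units": "points",
      "data_source": "self_report",
      "definition": "Anxiety subscale of the Hospital Anxiety and Depression Scale (0-21 points)"
    },
    {
      "var_id": "hospitalizations_past_year",
      "kind": "boolean",
      "data_source": "self_report",
      "definition": "Any hospitalization or emergency department visit in the previous year"
    },
    {
      "var_id": "ics_dose",
      "kind": "categorical",
      "allowed_values": ["low", "medium", "high"],
      "data_source": "self_report",
      "definition": "Inhaled corticosteroid dose category"
    },
    {
      "var_id": "indoor_allergen_sensitization",
      "kind": "boolean",
      "data_source": "self_report",
      "definition": "Sensitization to at least one indoor allergen (skin prick test)"
    },
    {
      "var_id": "prescribed_medication",
      "kind": "boolean",
      "data_source": "self_report",
      "definition": "Has currently prescribed respiratory medication"
    },
    {
      "var_id": "secondhand_smoke_exposure",
      "kind": "boolean",
      "data_source": "self_report",
      "definition": "Regular exposure to secondhand tobacco smoke"
    },
    {
      "var_id": "self_reported_asthma",
      "kind": "boolean",
      "data_source": "self_report",
      "definition": "Self-reported physician-diagnosed asthma"
    },
    {
      "var_id": "significant_weight_loss_6mo",
      "kind": "boolean",
      "data_source": "derived",
      "definition": "Lost at least 10% of body weight within the last 6 months (derived from the body-weight series)",
      "derived": {
        "type": "change",
        "series_var": "body_weight",
        "mode": "relative_percent",
        "direction": "decrease",
        "threshold": 10,
        "window_months": 6
      }
    }
  ],
  "recommendations": [
    {
      "rec_id": "rec_smoking",
      "source_doc_type": "international_guideline",
      "original_text": "Encourage smoking cessation by patient/family; provide advice and resources",
      "page": "50",
      "source_ref": "GINA 2018",
      "original_loe": "A",
      "hle": "A",
      "domain": "exposure_to_external_agents",
      "subdomain": "smoking_habits",
      "target_group": "asthma",
      "source_priority": 1
    },
    {
      "rec_id": "rec_stress",
      "source_doc_type": "international_guideline",
      "original_text": "There is insufficient evidence to support one stress-reduction strategy over another, but relaxation strategies and breathing exercises may be helpful",
      "page": "92",
      "source_ref": "GINA 2018",
      "domain": "others",
      "subdomain": "anxiety_depression_stress",
      "target_group": "asthma",
      "source_priority": 2
    },
    {
      "rec_id": "rec_weight",
      "source_doc_type": "other",
      "original_text": "Synthetic demo recommendation: significant unintentional weight loss warrants nutritional assessment and clinical review.",
      "page": "1",
      "source_ref": "demo-synthetic",
      "domain": "others",
      "subdomain": "nutrition",
      "target_group": "all",
      "source_priority": 2
    }
  ],
  "personalized": [
    {
      "pr_id": "pr_smoking",
      "rec_id": "rec_smoking",
      "plain_text": "Smoking cessation is advised",
      "delivery_formats": [
        "text",
        "image",
        "video",
        "link"
      ],
      "priority": 1
    },
    {
      "pr_id": "pr_stress",
      "rec_id": "rec_stress",
      "plain_text": "Relaxation strategies and breathing exercises may help you manage stress and anxiety.",
      "delivery_formats": [
        "text"
      ],
      "priority": 2
    },
    {
      "pr_id": "pr_weight",
      "rec_id": "rec_weight",
      "plain_text": "You appear to have lost a significant amount of weight recently. Please discuss this with your health professional.",
      "delivery_formats": [
        "text"
      ],
      "priority": 2
    }
  ],
  "rules": [
    {
      "rule_id": "rule_smoking",
      "pr_id": "pr_smoking",
      "target_group": "asthma",
      "condition": "(\"self_reported_asthma\" = TRUE AND \"cigarettes_per_day\" >= 1)"
    },
    {
      "rule_id": "rule_stress",
      "pr_id": "pr_stress",
      "target_group": "asthma",
      "condition": "(\"self_reported_asthma\" = TRUE AND \"hads_anxiety\" >= 8)"
    },
    {
      "rule_id": "rule_weight",
      "pr_id": "pr_weight",
      "target_group": "all",
      "condition": "\"significant_weight_loss_6mo\" = TRUE"
    }
  ],
  "hle_map": []
}
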