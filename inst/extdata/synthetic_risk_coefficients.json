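{
  "schema_version": "walkdiab-risk-1",
  "label": "SYNTHETIC example coefficients for demonstration and testing. These are not the published coefficients of any validated risk algorithm; users supply real coefficient sets (with their centering constants) as configuration in this schema.",
  "sexes": {
    "male": {
      "weibull_shape": 1.15,
      "intercept": -5.10,
      "terms": [
        {"predictor": "age_years", "coefficient": 0.045, "center": 41.5},
        {"predictor": "bmi", "coefficient": 0.095, "center": 26.4},
        {"predictor": "hypertension", "coefficient": 0.55, "center": 0.15},
        {"predictor": "heart_disease", "coefficient": 0.35, "center": 0.03},
        {"predictor": "immigrant", "coefficient": 0.18, "center": 0.47},
        {"predictor": "smoking", "category": "current", "coefficient": 0.30, "center": 0.20},
        {"predictor": "ethnicity", "category": "south_asian", "coefficient": 0.60, "center": 0.16},
        {"predictor": "ethnicity", "category": "black", "coefficient": 0.35, "center": 0.08},
        {"predictor": "education", "category": "less_than_secondary", "coefficient": 0.25, "center": 0.09},
        {"predictor": "income_quintile", "category": "Q1", "coefficient": 0.20, "center": 0.193}
      ]
    },
    "female": {
      "weibull_shape": 1.10,
      "intercept": -5.30,
      "terms": [
        {"predictor": "age_years", "coefficient": 0.042, "center": 41.5},
        {"predictor": "bmi", "coefficient": 0.105, "center": 25.8},
        {"predictor": "hypertension", "coefficient": 0.60, "center": 0.15},
        {"predictor": "heart_disease", "coefficient": 0.30, "center": 0.03},
        {"predictor": "immigrant", "coefficient": 0.22, "center": 0.47},
        {"predictor": "smoking", "category": "current", "coefficient": 0.25, "center": 0.20},
        {"predictor": "ethnicity", "category": "south_asian", "coefficient": 0.65, "center": 0.16},
        {"predictor": "ethnicity", "category": "black", "coefficient": 0.40, "center": 0.08},
        {"predictor": "education", "category": "less_than_secondary", "coefficient": 0.30, "center": 0.09},
        {"predictor": "income_quintile", "category": "Q1", "coefficient": 0.25, "center": 0.193}
      ]
    }
  }
}
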