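{
  "schema_version": "walkdiab-costs-1",
  "label": "SYNTHETIC example cost schedule for demonstration and testing. Values mimic the qualitative shape of per-patient excess diabetes costs (expensive diagnosis year, a dip, then rising with duration) but are not estimates from any administrative-data study; real schedules are supplied as configuration.",
  "currency_label": "2012 CAD (synthetic)",
  "sexes": {
    "male": {
      "excess_cost_by_followup_year": [2200, 1450, 1500, 1580, 1680, 1800, 1950, 2120],
      "mortality_by_followup_year": [0.010, 0.011, 0.012, 0.013, 0.015, 0.016, 0.018, 0.020, 0.022, 0.024]
    },
    "female": {
      "excess_cost_by_followup_year": [2050, 1350, 1400, 1470, 1560, 1670, 1810, 1960],
      "mortality_by_followup_year": [0.007, 0.008, 0.009, 0.010, 0.011, 0.012, 0.014, 0.015, 0.017, 0.019]
    }
  }
}
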