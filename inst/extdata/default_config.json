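{
  "n_tracts": 598,
  "factor_loading": 0.759687435726036,
  "tract_sigma": 0.3,
  "seed": 1,
  "adi_log_or_per_10": 0.0676586484738149,
  "coefficients": {
    "race_aa": 0.0769610411361284,
    "sex_male": 0.343589704390077,
    "age": 0.0295588022415444,
    "bmi": 0.0295588022415444,
    "family_history_fdr": 0.524728528934982,
    "smoking_years": 0.00995033085316809,
    "diabetes": 0.398776119957368,
    "calcium_use": -0.527632742082372
  },
  "race_blocks": {
    "EA": {
      "n_subjects": 1457,
      "age_mean": 57.8,
      "age_sd": 7,
      "bmi_mean": 28.3,
      "bmi_sd": 5.9,
      "smoking_mean": 9.3,
      "smoking_sd": 13.6,
      "red_meat_mean": 2.9,
      "red_meat_sd": 2.8,
      "alcohol_mean": 3,
      "alcohol_sd": 5.6,
      "p_female": 0.567,
      "p_family_history_fdr": 0.107,
      "p_diabetes": 0.091,
      "p_calcium_use": 0.258,
      "target_prevalence": 0.063,
      "adi_target_mean": 28.1,
      "adi_target_sd": 11.5,
      "coefficients": {
        "sex_male": 0.357674444271816,
        "age": 0.0295588022415444,
        "bmi": 0.0392207131532813,
        "family_history_fdr": 0.60431596685333,
        "smoking_years": 0.00995033085316809,
        "calcium_use": -0.82098055206983
      },
      "adi_log_or_per_10": 0.215111379616945
    },
    "AA": {
      "n_subjects": 936,
      "age_mean": 57.9,
      "age_sd": 7.4,
      "bmi_mean": 31.8,
      "bmi_sd": 7.9,
      "smoking_mean": 17.4,
      "smoking_sd": 16.8,
      "red_meat_mean": 3.3,
      "red_meat_sd": 3.8,
      "alcohol_mean": 3,
      "alcohol_sd": 12.9,
      "p_female": 0.676,
      "p_family_history_fdr": 0.112,
      "p_diabetes": 0.25,
      "p_calcium_use": 0.111,
      "target_prevalence": 0.084,
      "adi_target_mean": 53.1,
      "adi_target_sd": 15.3,
      "coefficients": {
        "age": 0.0295588022415444,
        "smoking_years": 0.00995033085316809,
        "diabetes": 0.56531380905006,
        "red_meat_per_week": 0.0392207131532813
      },
      "adi_log_or_per_10": 0.0676586484738149
    }
  }
}
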