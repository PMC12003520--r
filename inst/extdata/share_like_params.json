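{
  "covariates": ["wealth_q2", "wealth_q3", "wealth_q4", "wealth_q5", "edu_secondary", "edu_tertiary", "has_partner", "has_children", "age_c", "age2_c", "female", "means_testing", "cash_for_care", "ltc_beds_c", "replacement_rate_c", "cpi_personal_care_c", "gdp_per_capita_c", "female_lfp_c"],
  "beta_need": {
    "(Intercept)": -1.26063837834295,
    "wealth_q2": -0.2,
    "wealth_q3": -0.45,
    "wealth_q4": -0.5,
    "wealth_q5": -0.7,
    "edu_secondary": -0.4,
    "edu_tertiary": -0.75,
    "has_partner": -0.05,
    "has_children": -0.25,
    "age_c": 0.05,
    "age2_c": 0.002,
    "female": 0.35,
    "means_testing": -0.1,
    "cash_for_care": 0,
    "ltc_beds_c": 0.008,
    "replacement_rate_c": 0.002,
    "cpi_personal_care_c": 0.05,
    "gdp_per_capita_c": -0.008,
    "female_lfp_c": -0.01
  },
  "beta_use": {
    "informal": {
      "(Intercept)": -2.30158791142615,
      "wealth_q2": -0.15,
      "wealth_q3": -0.2,
      "wealth_q4": -0.35,
      "wealth_q5": -0.35,
      "edu_secondary": 0.05,
      "edu_tertiary": 0,
      "has_partner": 0.9,
      "has_children": 0.25,
      "age_c": 0.02,
      "age2_c": 0.0008,
      "female": -0.25,
      "means_testing": 0.05,
      "cash_for_care": 0.1,
      "ltc_beds_c": -0.005,
      "replacement_rate_c": 0.01,
      "cpi_personal_care_c": 0.05,
      "gdp_per_capita_c": -0.02,
      "female_lfp_c": -0.01
    },
    "formal": {
      "(Intercept)": -1.46202443403781,
      "wealth_q2": -0.1,
      "wealth_q3": -0.15,
      "wealth_q4": -0.3,
      "wealth_q5": -0.55,
      "edu_secondary": 0,
      "edu_tertiary": 0.05,
      "has_partner": -1.1,
      "has_children": -0.45,
      "age_c": 0.05,
      "age2_c": 0.001,
      "female": 0.35,
      "means_testing": -0.45,
      "cash_for_care": 0.15,
      "ltc_beds_c": 0.02,
      "replacement_rate_c": 0.015,
      "cpi_personal_care_c": -0.08,
      "gdp_per_capita_c": 0.01,
      "female_lfp_c": -0.03
    },
    "mixed": {
      "(Intercept)": -3.99114336064488,
      "wealth_q2": -0.05,
      "wealth_q3": 0,
      "wealth_q4": -0.35,
      "wealth_q5": -0.25,
      "edu_secondary": 0,
      "edu_tertiary": 0.2,
      "has_partner": 0.45,
      "has_children": 0.1,
      "age_c": 0.045,
      "age2_c": 0.001,
      "female": 0.1,
      "means_testing": -0.2,
      "cash_for_care": 0.55,
      "ltc_beds_c": 0,
      "replacement_rate_c": 0.012,
      "cpi_personal_care_c": -0.05,
      "gdp_per_capita_c": 0,
      "female_lfp_c": 0.01
    }
  },
  "sigma_need": 0.3,
  "sigma_use": {
    "informal": 0.45,
    "formal": 0.55,
    "mixed": 0.5
  },
  "seed": 1
}
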