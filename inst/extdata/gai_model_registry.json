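{
  "NIR_RE": {
    "family": "ratio_linear",
    "predictors": ["nir_re"],
    "coef": {"(Intercept)": -5.498, "nir_re": 4.64}
  },
  "NIR_Red": {
    "family": "ratio_linear",
    "predictors": ["nir_red"],
    "coef": {"(Intercept)": -0.2066, "nir_red": 0.1984}
  },
  "NIR_Green": {
    "family": "ratio_linear",
    "predictors": ["nir_green"],
    "coef": {"(Intercept)": -1.023, "nir_green": 0.499}
  },
  "VIQUO": {
    "family": "ratio_linear",
    "predictors": ["nir_re", "nir_red", "nir_green"],
    "coef": {
      "(Intercept)": -2.829243,
      "nir_re": 1.814068,
      "nir_red": -0.004532,
      "nir_green": 0.321576
    }
  },
  "VIQUO_interaction": {
    "family": "ratio_linear_interaction",
    "predictors": ["nir_re", "nir_red", "nir_green"],
    "coef": {
      "(Intercept)": 0.23558,
      "nir_re": -0.72441,
      "nir_red": 0.11783,
      "nir_green": -0.02023,
      "nir_red*nir_green": 0.01313,
      "nir_red*nir_re": 0.10864,
      "nir_re*nir_green": 0.28252,
      "nir_re*nir_green*nir_red": -0.01195
    }
  },
  "NDVI_exp": {
    "family": "ndvi_exponential",
    "predictors": ["ndvi"],
    "a": 0.00197,
    "b": 8.42847
  }
}
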