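{
  "seed": 1,
  "group_sizes": {
    "Mexican American": 60,
    "NH White": 80,
    "NH Black": 60
  },
  "sex_fraction_male": 0.5076860841423948,
  "age_range": [50, 84],
  "n_topcoded": 6,
  "predictors": ["hannum", "cystatin_c", "monocytes"],
  "target_correlation": {
    "hannum": {
      "Mexican American": 0.81999999999999995,
      "NH White": 0.81999999999999995,
      "NH Black": 0.81999999999999995
    },
    "cystatin_c": {
      "Mexican American": 0.42999999999999999,
      "NH White": 0.42999999999999999,
      "NH Black": 0.42999999999999999
    },
    "monocytes": {
      "Mexican American": 0.75,
      "NH White": 0.75,
      "NH Black": 0.75
    }
  },
  "prediction_bias": {
    "hannum": {
      "Mexican American": 0,
      "NH White": 0,
      "NH Black": 0
    },
    "cystatin_c": {
      "Mexican American": 0,
      "NH White": 0,
      "NH Black": 0
    },
    "monocytes": {
      "Mexican American": 0,
      "NH White": 0,
      "NH Black": 0
    }
  },
  "phenotype_distributions": {
    "b2m": {
      "type": "lognormal",
      "meanlog": 0.64185388617239469,
      "sdlog": 0.29999999999999999,
      "trunc": 2.6000000000000001
    },
    "cystatin_c": {
      "type": "lognormal",
      "meanlog": -0.051293294387550578,
      "sdlog": 0.25,
      "trunc": 2.6000000000000001
    },
    "crp": {
      "type": "lognormal",
      "meanlog": 0.69314718055994529,
      "sdlog": 1,
      "trunc": 2.6000000000000001
    },
    "hba1c": {
      "type": "lognormal",
      "meanlog": 1.7047480922384253,
      "sdlog": 0.12,
      "trunc": 2.6000000000000001
    },
    "telomere": {
      "type": "lognormal",
      "meanlog": 0,
      "sdlog": 0.17999999999999999,
      "trunc": 2.6000000000000001
    },
    "cells": {
      "type": "dirichlet",
      "alpha": [21, 5.6000000000000005, 40.599999999999994, 2.8000000000000003]
    }
  },
  "prediction_scales": {
    "dnamtl": {
      "meanlog": 0,
      "sdlog": 0.17999999999999999
    },
    "b2m": {
      "meanlog": 0.64185388617239469,
      "sdlog": 0.29999999999999999
    },
    "crp": {
      "meanlog": 0.69314718055994529,
      "sdlog": 1
    },
    "cystatin_c": {
      "meanlog": -0.051293294387550578,
      "sdlog": 0.25
    },
    "hba1c": {
      "meanlog": 1.7047480922384253,
      "sdlog": 0.12
    },
    "lymphocytes": {
      "mean": 0.29999999999999999,
      "sd": 0.055
    },
    "monocytes": {
      "mean": 0.080000000000000002,
      "sd": 0.02
    },
    "neutrophils": {
      "mean": 0.57999999999999996,
      "sd": 0.059999999999999998
    },
    "nk": {
      "meanlog": -3.1010927892118172,
      "sdlog": 0.25
    },
    "lymphocyte_split": [40, 110.00000000000001, 50]
  },
  "n_outliers": {
    "cystatin_c": 2,
    "monocytes": 2
  },
  "n_sex_mismatch": 4,
  "missingness": {
    "cystatin_c": 3,
    "cells": 2
  }
}
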