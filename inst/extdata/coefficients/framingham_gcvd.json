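{
  "model_id": "framingham_gcvd",
  "label": "Framingham general cardiovascular disease risk score (2008)",
  "source": "D'Agostino RB Sr, Vasan RS, Pencina MJ, et al. General cardiovascular risk profile for use in primary care: the Framingham Heart Study. Circulation. 2008;117(6):743-53.",
  "provenance": "transcribed",
  "link": "cox_10yr",
  "strata_by": [
    "sex"
  ],
  "strata_levels": {
    "sex": [
      "female",
      "male"
    ]
  },
  "units": {
    "age": "years",
    "sbp": "mmHg",
    "tc": "mg/dL",
    "hdl": "mg/dL"
  },
  "valid_ranges": {
    "age": [
      30,
      74
    ],
    "sbp": [
      60,
      300
    ],
    "tc": [
      80,
      550
    ],
    "hdl": [
      5,
      200
    ]
  },
  "strata": {
    "female": {
      "baseline": {
        "s0_10yr": 0.95012,
        "mean_lp": 26.1931
      },
      "terms": [
        {
          "variable": "age",
          "transform": "natural_log",
          "coef": 2.32888
        },
        {
          "variable": "tc",
          "transform": "natural_log",
          "coef": 1.20904
        },
        {
          "variable": "hdl",
          "transform": "natural_log",
          "coef": -0.70833
        },
        {
          "variable": "sbp",
          "transform": "natural_log",
          "coef": 2.76157,
          "condition": {
            "on_antihypertensive": false
          }
        },
        {
          "variable": "sbp",
          "transform": "natural_log",
          "coef": 2.82263,
          "condition": {
            "on_antihypertensive": true
          }
        },
        {
          "variable": "smoker",
          "transform": "identity",
          "coef": 0.52873
        },
        {
          "variable": "diabetes",
          "transform": "identity",
          "coef": 0.69154
        }
      ]
    },
    "male": {
      "baseline": {
        "s0_10yr": 0.88936,
        "mean_lp": 23.9802
      },
      "terms": [
        {
          "variable": "age",
          "transform": "natural_log",
          "coef": 3.06117
        },
        {
          "variable": "tc",
          "transform": "natural_log",
          "coef": 1.1237
        },
        {
          "variable": "hdl",
          "transform": "natural_log",
          "coef": -0.93263
        },
        {
          "variable": "sbp",
          "transform": "natural_log",
          "coef": 1.93303,
          "condition": {
            "on_antihypertensive": false
          }
        },
        {
          "variable": "sbp",
          "transform": "natural_log",
          "coef": 1.99881,
          "condition": {
            "on_antihypertensive": true
          }
        },
        {
          "variable": "smoker",
          "transform": "identity",
          "coef": 0.65451
        },
        {
          "variable": "diabetes",
          "transform": "identity",
          "coef": 0.57367
        }
      ]
    }
  },
  "checksum": "611282fcd2be88077086b5965f05564c"
}
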