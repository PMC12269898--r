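{
  "model_id": "pce2018",
  "label": "Pooled Cohort Equations, 2018 logistic revision (synthetic stand-in)",
  "source": "Modeled on: Yadlowsky S, Hayward RA, Sussman JB, et al. Clinical implications of revised pooled cohort equations for estimating atherosclerotic cardiovascular disease risk. Ann Intern Med. 2018;169(1):20-9. Coefficient values are a reconstruction of the published sex-specific logistic equations, not a verified transcription; re-transcribe from the source before real-data use.",
  "provenance": "synthetic",
  "link": "logistic",
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
      40,
      79
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
      "terms": [
        {
          "variable": "intercept",
          "transform": "identity",
          "coef": -12.82311
        },
        {
          "variable": "age",
          "transform": "identity",
          "coef": 0.106501
        },
        {
          "variable": "black",
          "transform": "identity",
          "coef": 0.43244
        },
        {
          "variable": "sbp",
          "transform": "identity",
          "coef": 0.017666
        },
        {
          "variable": "on_antihypertensive",
          "transform": "identity",
          "coef": 0.731678
        },
        {
          "variable": "sbp",
          "transform": "identity",
          "coef": -0.003647,
          "condition": {
            "on_antihypertensive": true
          }
        },
        {
          "variable": "diabetes",
          "transform": "identity",
          "coef": 0.94397
        },
        {
          "variable": "smoker",
          "transform": "identity",
          "coef": 1.00979
        },
        {
          "variable": "tc_hdl_ratio",
          "transform": "identity",
          "coef": 0.151318
        },
        {
          "variable": "age",
          "transform": "identity",
          "coef": -0.00858,
          "condition": {
            "black": true
          }
        },
        {
          "variable": "sbp",
          "transform": "identity",
          "coef": 0.006208,
          "condition": {
            "black": true
          }
        },
        {
          "variable": "on_antihypertensive",
          "transform": "identity",
          "coef": 0.152968,
          "condition": {
            "black": true
          }
        },
        {
          "variable": "sbp",
          "transform": "identity",
          "coef": -0.000173,
          "condition": {
            "black": true,
            "on_antihypertensive": true
          }
        },
        {
          "variable": "diabetes",
          "transform": "identity",
          "coef": 0.115232,
          "condition": {
            "black": true
          }
        },
        {
          "variable": "smoker",
          "transform": "identity",
          "coef": -0.092231,
          "condition": {
            "black": true
          }
        },
        {
          "variable": "tc_hdl_ratio",
          "transform": "identity",
          "coef": 0.070498,
          "condition": {
            "black": true
          }
        }
      ]
    },
    "male": {
      "terms": [
        {
          "variable": "intercept",
          "transform": "identity",
          "coef": -11.67998
        },
        {
          "variable": "age",
          "transform": "identity",
          "coef": 0.0642
        },
        {
          "variable": "black",
          "transform": "identity",
          "coef": 0.482835
        },
        {
          "variable": "sbp",
          "transform": "identity",
          "coef": 0.03895
        },
        {
          "variable": "sbp",
          "transform": "identity",
          "coef": -6.1e-05,
          "interact": "sbp"
        },
        {
          "variable": "on_antihypertensive",
          "transform": "identity",
          "coef": 2.055533
        },
        {
          "variable": "sbp",
          "transform": "identity",
          "coef": -0.014207,
          "condition": {
            "on_antihypertensive": true
          }
        },
        {
          "variable": "diabetes",
          "transform": "identity",
          "coef": 0.842209
        },
        {
          "variable": "smoker",
          "transform": "identity",
          "coef": 0.895589
        },
        {
          "variable": "tc_hdl_ratio",
          "transform": "identity",
          "coef": 0.193307
        },
        {
          "variable": "age",
          "transform": "identity",
          "coef": 2.5e-05,
          "interact": "sbp"
        },
        {
          "variable": "sbp",
          "transform": "identity",
          "coef": 0.011609,
          "condition": {
            "black": true
          }
        },
        {
          "variable": "on_antihypertensive",
          "transform": "identity",
          "coef": -0.119621,
          "condition": {
            "black": true
          }
        },
        {
          "variable": "sbp",
          "transform": "identity",
          "coef": 0.00419,
          "condition": {
            "black": true,
            "on_antihypertensive": true
          }
        },
        {
          "variable": "age",
          "transform": "identity",
          "coef": -0.000199,
          "interact": "sbp",
          "condition": {
            "black": true
          }
        }
      ]
    }
  },
  "checksum": "022cb8c9f730f0a53921e6c0b0e2f1d6"
}
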