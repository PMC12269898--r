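{
  "model_id": "globorisk_lac",
  "label": "Country-recalibrated laboratory cardiovascular risk equation, Globorisk form (synthetic stand-in)",
  "source": "Modeled on the laboratory-based, country-recalibrated Globorisk methodology (fatal plus non-fatal events) for Latin America and the Caribbean. Coefficients, baseline rates and mean risk-factor levels are synthetic stand-ins, not transcriptions; obtain the published supplementary recalibration inputs before real-data use.",
  "provenance": "synthetic",
  "link": "globorisk_recalibrated",
  "version": "laboratory",
  "outcome": "fatal_plus_nonfatal_cvd",
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
    "tc": "mmol/L"
  },
  "valid_ranges": {
    "age": [
      40,
      74
    ],
    "sbp": [
      60,
      300
    ],
    "tc": [
      2.07,
      14.22
    ]
  },
  "strata": {
    "female": {
      "terms": []
    },
    "male": {
      "terms": []
    }
  },
  "risk_factors": [
    {
      "variable": "sbp",
      "coef_at_60": 0.0235,
      "age_slope": -0.0002
    },
    {
      "variable": "tc",
      "coef_at_60": 0.1817,
      "age_slope": -0.0012
    },
    {
      "variable": "diabetes",
      "coef_at_60": 0.615,
      "age_slope": -0.01
    },
    {
      "variable": "smoker",
      "coef_at_60": 0.5,
      "age_slope": -0.008
    }
  ],
  "calibration": {
    "country": "BRA",
    "age_bands": [
      [
        40,
        44
      ],
      [
        45,
        49
      ],
      [
        50,
        54
      ],
      [
        55,
        59
      ],
      [
        60,
        64
      ],
      [
        65,
        69
      ],
      [
        70,
        74
      ],
      [
        75,
        79
      ],
      [
        80,
        84
      ]
    ],
    "female": {
      "baseline_annual_rate": [
        0.001,
        0.0015,
        0.0023,
        0.0035,
        0.0053,
        0.008,
        0.012,
        0.018,
        0.027
      ],
      "mean_sbp": [
        122,
        125,
        129,
        133,
        137,
        141,
        144,
        147,
        149
      ],
      "mean_tc": [
        4.99,
        5.12,
        5.25,
        5.35,
        5.4,
        5.4,
        5.35,
        5.28,
        5.17
      ],
      "prev_smoker": [
        0.18,
        0.17,
        0.16,
        0.14,
        0.12,
        0.1,
        0.08,
        0.07,
        0.06
      ],
      "prev_diabetes": [
        0.06,
        0.08,
        0.1,
        0.13,
        0.16,
        0.19,
        0.21,
        0.23,
        0.24
      ]
    },
    "male": {
      "baseline_annual_rate": [
        0.002,
        0.003,
        0.0044,
        0.0065,
        0.0095,
        0.0138,
        0.02,
        0.029,
        0.042
      ],
      "mean_sbp": [
        126,
        128,
        131,
        134,
        137,
        140,
        143,
        146,
        148
      ],
      "mean_tc": [
        5.04,
        5.12,
        5.17,
        5.2,
        5.17,
        5.12,
        5.07,
        4.99,
        4.91
      ],
      "prev_smoker": [
        0.25,
        0.23,
        0.21,
        0.19,
        0.17,
        0.15,
        0.13,
        0.11,
        0.09
      ],
      "prev_diabetes": [
        0.07,
        0.09,
        0.11,
        0.14,
        0.17,
        0.2,
        0.22,
        0.24,
        0.25
      ]
    }
  },
  "checksum": "13bc60db2420e9eba7bd5412100b5446"
}
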