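{
  "schema": "dtascea-parameters-v1",
  "outcome90d": {
    "DTAS": {
      "MRS01": 0.2838,
      "MRS23": 0.29620000000000002,
      "MRS4": 0.17000000000000001,
      "MRS5": 0.089999999999999997,
      "DEAD": 0.16
    },
    "ITER": {
      "MRS01": 0.17999999999999999,
      "MRS23": 0.27000000000000002,
      "MRS4": 0.20000000000000001,
      "MRS5": 0.12,
      "DEAD": 0.23000000000000001
    }
  },
  "t90": {
    "MRS01": {
      "MRS01": 0.88,
      "MRS23": 0.080000000000000002,
      "MRS4": 0.01,
      "MRS5": 0,
      "DEAD": 0.029999999999999999
    },
    "MRS23": {
      "MRS01": 0.14999999999999999,
      "MRS23": 0.69999999999999996,
      "MRS4": 0.070000000000000007,
      "MRS5": 0.02,
      "DEAD": 0.059999999999999998
    },
    "MRS4": {
      "MRS01": 0.02,
      "MRS23": 0.14999999999999999,
      "MRS4": 0.63,
      "MRS5": 0.080000000000000002,
      "DEAD": 0.12
    },
    "MRS5": {
      "MRS01": 0,
      "MRS23": 0.029999999999999999,
      "MRS4": 0.10000000000000001,
      "MRS5": 0.56999999999999995,
      "DEAD": 0.29999999999999999
    },
    "DEAD": {
      "MRS01": 0,
      "MRS23": 0,
      "MRS4": 0,
      "MRS5": 0,
      "DEAD": 1
    }
  },
  "t_annual": {
    "MRS01": {
      "MRS01": 0.93999999999999995,
      "MRS23": 0.050000000000000003,
      "MRS4": 0.01,
      "MRS5": 0,
      "DEAD": 0
    },
    "MRS23": {
      "MRS01": 0.040000000000000001,
      "MRS23": 0.90000000000000002,
      "MRS4": 0.050000000000000003,
      "MRS5": 0.01,
      "DEAD": 0
    },
    "MRS4": {
      "MRS01": 0.01,
      "MRS23": 0.050000000000000003,
      "MRS4": 0.88,
      "MRS5": 0.059999999999999998,
      "DEAD": 0
    },
    "MRS5": {
      "MRS01": 0,
      "MRS23": 0.01,
      "MRS4": 0.059999999999999998,
      "MRS5": 0.93000000000000005,
      "DEAD": 0
    },
    "DEAD": {
      "MRS01": 0,
      "MRS23": 0,
      "MRS4": 0,
      "MRS5": 0,
      "DEAD": 1
    }
  },
  "mortality": {
    "age": [74, 75, 76, 77, 78, 79, 80, 81, 82, 83, 84, 85],
    "q0": [0.026200000000000001, 0.029100000000000001, 0.032300000000000002, 0.035999999999999997, 0.040099999999999997, 0.0448, 0.050000000000000003, 0.055899999999999998, 0.0625, 0.069900000000000004, 0.078200000000000006, 0.087499999999999994],
    "hr": {
      "MRS01": 1.5,
      "MRS23": 2.1000000000000001,
      "MRS4": 3.2999999999999998,
      "MRS5": 4.9000000000000004
    }
  },
  "utilities": {
    "MRS01": 0.84999999999999998,
    "MRS23": 0.62,
    "MRS4": 0.32000000000000001,
    "MRS5": 0.050000000000000003
  },
  "costs": {
    "acute_lvo": {
      "DTAS": 34000,
      "ITER": 31500
    },
    "diag_non_lvo": {
      "DTAS": 2600,
      "ITER": 1100
    },
    "annual_care": {
      "MRS01": 2800,
      "MRS23": 7900,
      "MRS4": 26000,
      "MRS5": 44000
    },
    "currency": "EUR",
    "eur_to_usd": 1.1827000000000001
  },
  "triage": {
    "p_lvo": 0.84482758620689657
  },
  "econ": {
    "discount_cost": 0.040000000000000001,
    "discount_qaly": 0.014999999999999999,
    "markov_years": 9,
    "entry_age": 74,
    "thresholds": [50000, 80000],
    "cohort_size": 10000
  },
  "options": {
    "accrual": "end",
    "half_cycle": false,
    "include_non_lvo_outcomes": false,
    "utility_order_check": true
  },
  "owsa_ranges": {
    "outcome90d.DTAS.MRS01": [0.22700000000000001, 0.34060000000000001],
    "outcome90d.DTAS.MRS4": [0.13600000000000001, 0.20400000000000001],
    "outcome90d.ITER.DEAD": [0.18400000000000002, 0.27600000000000002],
    "costs.acute_lvo.DTAS": [27200, 40800],
    "costs.acute_lvo.ITER": [25200, 37800],
    "costs.annual_care.MRS5": [35200, 52800],
    "utilities.MRS01": [0.68000000000000005, 1],
    "mortality.hr.MRS5": [3.9200000000000004, 5.8799999999999999],
    "triage.p_lvo": [0.67586206896551726, 1]
  },
  "psa_spec": {
    "outcome90d.DTAS": {
      "family": "dirichlet",
      "alpha": [21.001200000000001, 21.918800000000001, 12.58, 6.6600000000000001, 11.84]
    },
    "outcome90d.ITER": {
      "family": "dirichlet",
      "alpha": [13.139999999999999, 19.710000000000001, 14.600000000000001, 8.7599999999999998, 16.789999999999999]
    },
    "triage.p_lvo": {
      "family": "beta",
      "shape1": 147,
      "shape2": 27
    },
    "t90.MRS01": {
      "family": "dirichlet",
      "alpha": [264, 24, 3, 0, 9]
    },
    "t90.MRS23": {
      "family": "dirichlet",
      "alpha": [45, 210, 21.000000000000004, 6, 18]
    },
    "t90.MRS4": {
      "family": "dirichlet",
      "alpha": [6, 45, 189, 24, 36]
    },
    "t90.MRS5": {
      "family": "dirichlet",
      "alpha": [0, 9, 30, 170.99999999999997, 90]
    },
    "utilities.MRS01": {
      "family": "beta",
      "shape1": 2.8999999999999995,
      "shape2": 0.5117647058823529
    },
    "utilities.MRS23": {
      "family": "beta",
      "shape1": 8.8800000000000008,
      "shape2": 5.442580645161291
    },
    "utilities.MRS4": {
      "family": "beta",
      "shape1": 16.68,
      "shape2": 35.445
    },
    "utilities.MRS5": {
      "family": "beta",
      "shape1": 23.699999999999989,
      "shape2": 450.29999999999978
    },
    "costs.acute_lvo.DTAS": {
      "family": "gamma",
      "shape": 25,
      "rate": 0.00073529411764705881
    },
    "costs.acute_lvo.ITER": {
      "family": "gamma",
      "shape": 25,
      "rate": 0.00079365079365079365
    },
    "costs.diag_non_lvo.DTAS": {
      "family": "gamma",
      "shape": 25,
      "rate": 0.0096153846153846159
    },
    "costs.diag_non_lvo.ITER": {
      "family": "gamma",
      "shape": 25,
      "rate": 0.022727272727272728
    },
    "costs.annual_care.MRS01": {
      "family": "gamma",
      "shape": 25,
      "rate": 0.0089285714285714281
    },
    "costs.annual_care.MRS23": {
      "family": "gamma",
      "shape": 25,
      "rate": 0.0031645569620253164
    },
    "costs.annual_care.MRS4": {
      "family": "gamma",
      "shape": 25,
      "rate": 0.00096153846153846159
    },
    "costs.annual_care.MRS5": {
      "family": "gamma",
      "shape": 25,
      "rate": 0.00056818181818181815
    },
    "mortality.hr.MRS01": {
      "family": "gamma",
      "shape": 24.999999999999993,
      "rate": 16.666666666666661
    },
    "mortality.hr.MRS23": {
      "family": "gamma",
      "shape": 25,
      "rate": 11.904761904761905
    },
    "mortality.hr.MRS4": {
      "family": "gamma",
      "shape": 24.999999999999993,
      "rate": 7.5757575757575744
    },
    "mortality.hr.MRS5": {
      "family": "gamma",
      "shape": 25,
      "rate": 5.1020408163265305
    }
  },
  "sources": {
    "note": "SYNTHETIC BASE PARAMETER SET. Entries marked 'published' are publicly stated quantities of the Dutch DTAS-vs-ITER triage comparison; entries marked 'synthetic' are placeholders chosen for clinical plausibility only and carry no evidential weight.",
    "published": {
      "triage.p_lvo": "147/174 LVO confirmation rate (ANGIOCAT)",
      "outcome90d.DTAS.MRS01": "0.2838, midpoint of published 22.70-34.06% range",
      "econ": "age 74; discounting 4%/1.5%; thresholds EUR 50k/80k; 9y Markov",
      "costs.eur_to_usd": "1.1827 (2021)",
      "scenarios": "p_lvo 0.42 (RACE>4 PPV), 0.12 (FAST-only), 4y horizon"
    },
    "synthetic": ["outcome90d (all other entries)", "t90", "t_annual", "mortality (life table and hazard multipliers)", "utilities", "costs (all)", "owsa_ranges except outcome90d.DTAS.MRS01", "psa_spec hyperparameters"]
  }
}
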