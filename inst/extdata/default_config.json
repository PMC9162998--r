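{
  "constants": {
    "P0_L": 2.0299999999999998,
    "k_L": 0.80000000000000004,
    "P0_R": 2.1299999999999999,
    "k_R": 1.8999999999999999,
    "W": 0.129,
    "G_L": 0.22,
    "G_R": 0.64000000000000001
  },
  "patient": {
    "baseline": {
      "AP": 87,
      "P_LA": 17,
      "P_RA": 9.0999999999999996,
      "CO": 118,
      "HR": 129
    },
    "pk": {
      "k_e": 0.17328679513998632,
      "Vd": 300
    },
    "pd": {
      "Emax_SL": 0.40000000000000002,
      "EC50_SL": 1.5,
      "Emax_HR": 0.5,
      "EC50_HR": 0.80000000000000004
    },
    "dextran_fraction": 1,
    "furo": {
      "gain": 0.29999999999999999,
      "onset": 0.34999999999999998
    },
    "noise_sd": {
      "AP": 1,
      "P_LA": 0.5,
      "P_RA": 0.5,
      "CO": 3,
      "HR": 1
    },
    "ensemble_cv": 0.050000000000000003
  },
  "controller": {
    "pi": {
      "Kp": 4,
      "Ki": 1.3999999999999999,
      "u_max": 100
    },
    "volume": {
      "dead_band": 0.80000000000000004,
      "dead_band_deficit": 0.10000000000000001,
      "dextran_gain": 0.29999999999999999,
      "dextran_max": 1,
      "furosemide_bolus": 5,
      "furosemide_lockout": 6,
      "bolus_effect": 1.5,
      "effect_onset": 0.34999999999999998
    }
  },
  "protocol": {
    "duration": 60,
    "dt": 0.16666666666666666,
    "smoothing_window": 1,
    "baseline_window": 10,
    "ap_drop": 10,
    "ap_floor": 70,
    "pla_cap": 18,
    "recompute_targets": false
  }
}
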