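{
  "model": {
    "gka_distal": 70,
    "gka_low": 10,
    "gna": 4,
    "gkdr": 0.1,
    "gca": 1e-07,
    "cm": 1,
    "ra": 150,
    "g_leak": 0.25,
    "e_leak": -70
  },
  "synapse": {
    "g_max": 2,
    "tau_rise": 5,
    "tau_decay": 74,
    "reversal": -70
  },
  "protocol": {
    "ipsp_lead": 15,
    "train_gap": 20,
    "train_n": 5,
    "train_freqs": [50, 100],
    "pulse_width": 0.5,
    "dt": 0.005
  },
  "sweep": {
    "g_values": [10, 20, 30, 40, 50, 60, 70]
  },
  "imaging": {
    "kd": 2.3,
    "ca_rest": 0.05,
    "ca_scale": 5e+15,
    "ca_tau": 50,
    "g0": 50,
    "g_sat": 600,
    "red": 300,
    "noise_sd": 10,
    "line_rate": 500,
    "trials_per_condition": 10,
    "artifact_amp": 40,
    "artifact_duration": 10,
    "cell_cv": 0.2
  },
  "population": {
    "n_cells": 10
  },
  "seed": 1
}
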