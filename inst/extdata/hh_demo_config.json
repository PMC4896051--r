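{
  "mode": "hh_demo",
  "optimiser": {
    "offspring_size": 100,
    "max_ngen": 10,
    "kappa": 0.05,
    "eta": 10,
    "cx_prob": 0.7,
    "seed": 1,
    "hof_size": 10
  },
  "evaluator": {
    "name": "hh_demo",
    "model": {
      "gnabar": 0.12,
      "gkbar": 0.036,
      "gl": 0.0003,
      "cm": 1,
      "ena": 50,
      "ek": -77,
      "el": -54.3,
      "v_init": -65,
      "celsius": 6.3,
      "area_cm2": 3.14159265358979e-06
    },
    "parameters": [
      {
        "name": "cm",
        "lower_bound": 1,
        "upper_bound": 1,
        "frozen": true,
        "value": 1
      },
      {
        "name": "gnabar",
        "lower_bound": 0.05,
        "upper_bound": 0.125,
        "frozen": false,
        "value": null
      },
      {
        "name": "gkbar",
        "lower_bound": 0.01,
        "upper_bound": 0.075,
        "frozen": false,
        "value": null
      }
    ],
    "protocols": {
      "step1": {
        "amplitude": 0.01,
        "delay": 100,
        "duration": 50,
        "total_duration": 200,
        "holding": 0
      },
      "step2": {
        "amplitude": 0.05,
        "delay": 100,
        "duration": 50,
        "total_duration": 200,
        "holding": 0
      }
    },
    "targets": [
      {
        "protocol": "step1",
        "feature": "Spikecount",
        "exp_mean": 1,
        "exp_std": 0.05,
        "recording": "soma.v"
      },
      {
        "protocol": "step2",
        "feature": "Spikecount",
        "exp_mean": 5,
        "exp_std": 0.25,
        "recording": "soma.v"
      }
    ],
    "dt": 0.025,
    "threshold": -20,
    "penalty": 250
  }
}
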