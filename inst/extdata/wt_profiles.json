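{
  "comment": "Wild-type Kv4.1 biophysical profiles per channel configuration. The TERNARY parameter set carries the reference wild-type values (decay time constants, fast fraction, recovery time constant, Boltzmann midpoints, peak current at +40 mV). Slope factors k_act/k_inact, the activation rise time constant tau_act, the reversal potential e_rev and all beta-subunit effect magnitudes are SYNTHETIC defaults chosen for realism (directions of the beta effects follow the characteristic KChIP/DPP modulation of Kv4 channels). ALONE/KCHIP/DPP profiles derive from the base homotetramer profile by applying the beta_effects components; applying both subunit effect sets to ALONE reproduces TERNARY exactly.",
  "profiles": {
    "ALONE": {
      "tau1": 30.7,
      "tau2": 171.6,
      "rel_a1": 0.83,
      "tau_rec": 44.8,
      "v_half_act": 3.55,
      "k_act": 15.0,
      "v_half_inact": -57.9,
      "k_inact": 5.0,
      "tau_act": 1.5,
      "e_rev": -98.0,
      "peak_uA": 9.6
    },
    "KCHIP": {
      "tau1": 61.4,
      "tau2": 85.8,
      "rel_a1": 0.83,
      "tau_rec": 22.4,
      "v_half_act": 3.55,
      "k_act": 15.0,
      "v_half_inact": -47.9,
      "k_inact": 5.0,
      "tau_act": 1.5,
      "e_rev": -98.0,
      "peak_uA": 19.2
    },
    "DPP": {
      "tau1": 15.35,
      "tau2": 171.6,
      "rel_a1": 0.83,
      "tau_rec": 22.4,
      "v_half_act": -6.45,
      "k_act": 15.0,
      "v_half_inact": -67.9,
      "k_inact": 5.0,
      "tau_act": 1.5,
      "e_rev": -98.0,
      "peak_uA": 9.6
    },
    "TERNARY": {
      "tau1": 30.7,
      "tau2": 85.8,
      "rel_a1": 0.83,
      "tau_rec": 11.2,
      "v_half_act": -6.45,
      "k_act": 15.0,
      "v_half_inact": -57.9,
      "k_inact": 5.0,
      "tau_act": 1.5,
      "e_rev": -98.0,
      "peak_uA": 19.2
    }
  },
  "beta_effects": {
    "comment": "Each component names the profile field it acts on, a multiplicative factor or additive shift, and the configurations containing the subunit. Magnitudes are synthetic.",
    "components": {
      "kchip_tau1_slowed": {
        "field": "tau1",
        "mult": 2.0,
        "configurations": [
          "KCHIP",
          "TERNARY"
        ]
      },
      "kchip_tau2_accelerated": {
        "field": "tau2",
        "mult": 0.5,
        "configurations": [
          "KCHIP",
          "TERNARY"
        ]
      },
      "kchip_recovery_accelerated": {
        "field": "tau_rec",
        "mult": 0.5,
        "configurations": [
          "KCHIP",
          "TERNARY"
        ]
      },
      "kchip_ssi_positive_shift": {
        "field": "v_half_inact",
        "shift": 10.0,
        "configurations": [
          "KCHIP",
          "TERNARY"
        ]
      },
      "kchip_amplitude_increase": {
        "field": "g_max",
        "mult": 2.0,
        "configurations": [
          "KCHIP",
          "TERNARY"
        ]
      },
      "dpp_tau1_accelerated": {
        "field": "tau1",
        "mult": 0.5,
        "configurations": [
          "DPP",
          "TERNARY"
        ]
      },
      "dpp_recovery_accelerated": {
        "field": "tau_rec",
        "mult": 0.5,
        "configurations": [
          "DPP",
          "TERNARY"
        ]
      },
      "dpp_activation_negative_shift": {
        "field": "v_half_act",
        "shift": -10.0,
        "configurations": [
          "DPP",
          "TERNARY"
        ]
      },
      "dpp_ssi_negative_shift": {
        "field": "v_half_inact",
        "shift": -10.0,
        "configurations": [
          "DPP",
          "TERNARY"
        ]
      }
    }
  }
}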