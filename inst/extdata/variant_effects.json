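{
  "comment": "SYNTHETIC variant-effect magnitudes for the trace generator. Directions follow the qualitative per-variant findings (reduced amplitudes, accelerated or slowed inactivation, slowed recovery, voltage-dependence shifts, lost beta-subunit modulation); the magnitudes themselves are package defaults (x/0.5-1.5 on time constants and conductance, +/-10 mV midpoint shifts, +/-4 mV slope-factor shifts, ~100x recovery slowing for p.His308Tyr) and are NOT measured values. The demo.* entries are constructed controls with no biological counterpart.",
  "variants": {
    "p.Arg92Cys": {
      "effects": {
        "TERNARY": {"g_max_mult": 0.5, "tau1_mult": 1.5, "tau2_mult": 1.5, "k_act_shift": -4},
        "ALONE":   {"g_max_mult": 0.5, "v_half_act_shift": 10, "v_half_inact_shift": 10},
        "KCHIP":   {"g_max_mult": 0.5},
        "DPP":     {"g_max_mult": 0.5}
      },
      "beta_modulation_retained": {}
    },
    "p.Asp115Asn": {
      "effects": {
        "TERNARY": {"g_max_mult": 0.5, "tau1_mult": 0.6666666666666666, "tau2_mult": 0.6666666666666666, "v_half_inact_shift": -10},
        "ALONE":   {"v_half_act_shift": -10, "v_half_inact_shift": -10},
        "KCHIP":   {},
        "DPP":     {}
      },
      "beta_modulation_retained": {}
    },
    "p.Lys450Ter": {
      "effects": {
        "TERNARY": {"g_max_mult": 0.5, "tau1_mult": 1.5, "tau2_mult": 1.5, "rel_a1_delta": -0.15, "tau_rec_mult": 1.5, "v_half_inact_shift": -10},
        "ALONE":   {"g_max_mult": 0.5, "tau1_mult": 1.5, "tau2_mult": 1.5},
        "KCHIP":   {"g_max_mult": 0.5},
        "DPP":     {"g_max_mult": 0.5}
      },
      "beta_modulation_retained": {"kchip_recovery_accelerated": false}
    },
    "p.His308Tyr": {
      "effects": {
        "TERNARY": {"g_max_mult": 0.5, "tau1_mult": 1.5, "tau2_mult": 1.5, "tau_rec_mult": 100, "v_half_act_shift": -10, "v_half_inact_shift": -10, "k_act_shift": 4},
        "ALONE":   {"g_max_mult": 0.5, "tau_rec_mult": 100, "v_half_act_shift": -10, "v_half_inact_shift": -10},
        "KCHIP":   {"g_max_mult": 0.5, "tau_rec_mult": 100},
        "DPP":     {"g_max_mult": 0.5, "tau_rec_mult": 100}
      },
      "beta_modulation_retained": {"kchip_recovery_accelerated": false, "dpp_recovery_accelerated": false}
    },
    "demo.SingleParamAllConfigs": {
      "effects": {
        "TERNARY": {"tau_rec_mult": 2},
        "ALONE":   {"tau_rec_mult": 2},
        "KCHIP":   {"tau_rec_mult": 2},
        "DPP":     {"tau_rec_mult": 2}
      },
      "beta_modulation_retained": {}
    },
    "demo.Null": {
      "effects": {"TERNARY": {}, "ALONE": {}, "KCHIP": {}, "DPP": {}},
      "beta_modulation_retained": {}
    }
  }
}
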