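# Synthetic per-oocyte feature tables drawn directly from the profile
# parameters (lognormal conductance/peak, Gaussian elsewhere, same spread
# defaults as the trace generator). Used by the statistics and assessment
# tests, where re-simulating and re-fitting full trace sets would be
# needlessly slow; the trace -> fit path itself is validated by the
# round-trip tests in test-trace-features.R.

feature_means <- function(configuration, effect = NULL) {
  prof <- wt_profile(configuration)
  if (!is.null(effect)) prof <- apply_variant_effect(prof, effect, configuration)
  wt <- wt_profile(configuration)
  peak <- wt$peak_uA * prof$g_max / wt$g_max
  c(peak_amp = peak, tau1 = prof$tau1, tau2 = prof$tau2,
    rel_a1 = prof$rel_a1, tau_rec = prof$tau_rec,
    v_half_act = prof$v_half_act, k_act = prof$k_act,
    v_half_inact = prof$v_half_inact, k_inact = prof$k_inact)
}

synth_features <- function(variant, configuration, n, effect = NULL,
                           variability = default_variability()) {
  mu <- feature_means(configuration, effect)
  cv <- variability$g_max_cv
  sdlog <- sqrt(log(1 + cv^2))
  sds <- c(tau1 = variability$tau1_sd, tau2 = variability$tau2_sd,
           rel_a1 = variability$rel_a1_sd, tau_rec = variability$tau_rec_sd,
           v_half_act = variability$v_half_act_sd,
           v_half_inact = variability$v_half_inact_sd,
           k_act = variability$k_act_sd, k_inact = variability$k_inact_sd)
  df <- data.frame(
    configuration = configuration, variant = variant, oocyte = seq_len(n),
    peak_amp = mu[["peak_amp"]] *
      (if (cv > 0) stats::rlnorm(n, -sdlog^2 / 2, sdlog) else 1))
  for (fld in names(sds))
    df[[fld]] <- mu[[fld]] + stats::rnorm(n, 0, sds[[fld]])
  df$rel_a1 <- pmin(1, pmax(0, df$rel_a1))
  df$tau_rec <- pmax(df$tau_rec, 0.1)
  df
}

# combined table for a cohort: WT plus named variant effects, all configs
synth_cohort <- function(effects = list(), n = 16,
                         configurations = c("ALONE", "KCHIP", "DPP",
                                            "TERNARY"),
                         variability = default_variability()) {
  out <- list()
  for (cf in configurations) {
    out[[length(out) + 1L]] <- synth_features("WT", cf, n, NULL, variability)
    for (v in names(effects))
      out[[length(out) + 1L]] <-
        synth_features(v, cf, n, effects[[v]], variability)
  }
  do.call(rbind, out)
}

ternary_decay_trace <- function(dt = 0.5, noise_sd = 0, seed = NULL) {
  simulate_trace(wt_profile("TERNARY"),
                 build_protocol("DECAY", list(sample_interval = dt)),
                 noise_sd = noise_sd, seed = seed)
}
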