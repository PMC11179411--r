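test_that("measure_peak handles trivial and offset cases", {
  p <- wt_profile("TERNARY")
  proto <- build_protocol("DECAY", list(sample_interval = 1))
  p0 <- p; p0$g_max <- 0
  tr0 <- simulate_trace(p0, proto)
  expect_equal(measure_peak(tr0, role = "test"), 0)
  tr <- simulate_trace(p, proto)
  pk <- measure_peak(tr, role = "test", leak_subtract = TRUE)
  shifted <- tr; shifted$current <- tr$current + 1
  expect_equal(measure_peak(shifted, role = "test", leak_subtract = TRUE),
               pk, tolerance = 1e-12)
  expect_error(measure_peak(tr, window = c(-50, 10)), "outside")
  expect_error(measure_peak(tr, role = "interpulse"), "no epoch")
  # explicit window agrees with the role-based selection
  expect_equal(measure_peak(tr, window = c(50, 2549)),
               measure_peak(tr, role = "test"))
})

test_that("fit_decay recovers two-exponential parameters", {
  # pure single exponential: degenerate two-component case
  p1 <- wt_profile("TERNARY"); p1$rel_a1 <- 1  # only tau1 = 30.7 acts
  d1 <- fit_decay(simulate_trace(p1, build_protocol("DECAY")))
  expect_true(d1$converged)
  expect_equal(d1$tau1, 30.7, tolerance = 0.01)
  expect_gte(d1$rel_a1, 0.99)
  # the reference two-exponential: parameters back within 2%
  d2 <- fit_decay(ternary_decay_trace())
  expect_true(d2$converged)
  expect_equal(d2$tau1, 30.7, tolerance = 0.02)
  expect_equal(d2$tau2, 85.8, tolerance = 0.02)
  expect_equal(d2$rel_a1, 0.83, tolerance = 0.02)
  expect_lt(d2$tau1, d2$tau2)
})

test_that("fit_decay is robust under recording noise", {
  # scaled-down Monte-Carlo recovery study (50 replicates, 2% peak noise)
  base <- ternary_decay_trace(dt = 1)
  set.seed(123)
  errs <- replicate(50, {
    tr <- base
    tr$current <- tr$current + rnorm(length(tr$current), 0, 0.02 * 19.2)
    abs(fit_decay(tr)$tau1 - 30.7) / 30.7
  })
  expect_lt(median(errs), 0.10)
})

test_that("fit_decay agrees with an exhaustive grid search on toy traces", {
  # 200-sample toy trace, exact two-exponential decay from the peak
  dt <- 1
  t_test <- seq(0, 199)
  y <- 12 * (0.8 * exp(-t_test / 20) + 0.2 * exp(-t_test / 60))
  proto <- voltage_protocol(list(protocol_epoch(-100, 10, "holding"),
                                 protocol_epoch(40, 200, "test")),
                            dt, "DECAY")
  trace <- structure(list(time = seq(0, 209), voltage = c(rep(-100, 10), rep(40, 200)),
                          current = c(rep(0, 10), y), protocol = proto,
                          meta = list()), class = "current_trace")
  fit <- fit_decay(trace, skip_ms = 0)
  # independent oracle: coarse grid over (tau1, tau2, rel_a1), amplitude
  # total fixed at the peak sample, no offset
  grid1 <- seq(10, 30, 2); grid2 <- seq(40, 80, 4); grida <- seq(0, 1, 0.05)
  best <- c(Inf, NA, NA, NA)
  for (tau1 in grid1) for (tau2 in grid2) for (ra in grida) {
    pred <- 12 * (ra * exp(-t_test / tau1) + (1 - ra) * exp(-t_test / tau2))
    rss <- sum((y - pred)^2)
    if (rss < best[1]) best <- c(rss, tau1, tau2, ra)
  }
  expect_lte(abs(fit$tau1 - best[2]), 2)
  expect_lte(abs(fit$tau2 - best[3]), 4)
  expect_lte(abs(fit$rel_a1 - best[4]), 0.05)
})

test_that("fit_recovery recovers tau_rec across time scales", {
  grid <- 10 ^ seq(0, log10(3000), length.out = 12)
  pts <- data.frame(dt = grid, ratio = 1 - exp(-grid / 11.2))
  rf <- fit_recovery(pts)
  expect_true(rf$converged)
  expect_equal(rf$tau_rec, 11.2, tolerance = 0.01)
  # 100-fold slower process on a 100-fold extended grid
  pts2 <- data.frame(dt = grid * 100, ratio = 1 - exp(-grid * 100 / 1120))
  rf2 <- fit_recovery(pts2)
  expect_equal(rf2$tau_rec, 1120, tolerance = 0.02)
  # fully recovered input: nothing to fit
  flat <- data.frame(dt = grid, ratio = rep(1, length(grid)))
  expect_false(fit_recovery(flat)$converged)
  expect_error(fit_recovery(data.frame(dt = 1:3, ratio = c(.2, .5, .9))),
               "at least 4")
  expect_error(fit_recovery(data.frame(dt = c(1, 2, 3, 4),
                                       ratio = c(.2, .4, .5, .6))),
               "decade")
})

test_that("compute_conductance and fit_boltzmann close the loop", {
  p <- wt_profile("TERNARY")
  iv <- lapply(build_protocol("IV_FAMILY"), simulate_trace, profile = p)
  # ohmic input: constant normalized conductance
  ohm <- lapply(iv, function(tr) {
    tr$current <- 0.5 * (tr$voltage - p$e_rev); tr
  })
  gv <- compute_conductance(ohm, e_rev = p$e_rev)
  expect_true(all(abs(gv$g - 1) < 1e-12))
  # round trip: G-V midpoint within 1 mV of the seeded activation midpoint
  gv <- compute_conductance(iv, e_rev = p$e_rev)
  bf <- fit_boltzmann(data.frame(v = gv$v, y = gv$g), "activation")
  expect_true(bf$converged)
  expect_lt(abs(bf$v_half - p$v_half_act), 1)
  expect_false(bf$residual_warning)
  # misdeclared reversal potential: residual diagnostics flag the distortion
  expect_warning(gv2 <- compute_conductance(iv, e_rev = p$e_rev + 20),
                 "reversal potential")
  bf2 <- fit_boltzmann(data.frame(v = gv2$v, y = gv2$g), "activation")
  expect_true(bf2$residual_warning)
  expect_error(compute_conductance(iv, e_rev = -80), "undefined")
})

test_that("fit_boltzmann recovers exact curves and flags degenerate input", {
  v <- seq(-80, 60, 10)
  y <- 1 / (1 + exp((-6.45 - v) / 15))
  bf <- fit_boltzmann(data.frame(v = v, y = y), "activation")
  expect_equal(bf$v_half, -6.45, tolerance = 0.1 / 6.45)
  expect_equal(bf$k, 15, tolerance = 1e-4)
  vi <- seq(-100, 0, 10)
  yi <- 1 / (1 + exp((vi + 57.9) / 5))
  bi <- fit_boltzmann(data.frame(v = vi, y = yi), "inactivation")
  expect_equal(bi$v_half, -57.9, tolerance = 1e-4)
  expect_gt(bi$k, 0)
  flat <- data.frame(v = v, y = rep(0.5, length(v)))
  expect_false(fit_boltzmann(flat, "activation")$converged)
  expect_error(fit_boltzmann(data.frame(v = v[1:4], y = y[1:4]),
                             "activation"), "at least 6")
  expect_error(fit_boltzmann(data.frame(v = v, y = y + 0.2), "activation"),
               "1.05")
})

test_that("fit_boltzmann estimates are nearly unbiased under noise", {
  vi <- seq(-100, 0, 10)
  yi <- 1 / (1 + exp((vi + 57.9) / 5))
  set.seed(77)
  vh <- replicate(200, {
    pts <- data.frame(v = vi, y = pmin(pmax(yi + rnorm(11, 0, 0.02), 0), 1.05))
    fit_boltzmann(pts, "inactivation")$v_half
  })
  expect_lt(abs(mean(vh) + 57.9), 0.5)
})

test_that("Boltzmann fits are translation- and scale-equivariant", {
  v <- seq(-80, 60, 10)
  curve <- function(vh, k) 1 / (1 + exp((vh - v) / k))
  b0 <- fit_boltzmann(data.frame(v = v, y = curve(-10, 12)), "activation")
  b1 <- fit_boltzmann(data.frame(v = v + 15, y = curve(-10, 12)),
                      "activation")
  expect_equal(b1$v_half - b0$v_half, 15, tolerance = 1e-3)
  b2 <- fit_boltzmann(data.frame(v = -10 + 2 * (v + 10), y = curve(-10, 12)),
                      "activation")
  expect_equal(b2$k / b0$k, 2, tolerance = 1e-3)
})

test_that("round trip: noiseless generator output returns seeded parameters", {
  p <- wt_profile("TERNARY")
  set <- simulate_experiment(p, NULL, NULL, n_oocytes = 1,
                             variability = zero_variability(), seed = 1,
                             meta = list(variant = "WT",
                                         configuration = "TERNARY"))
  fs <- extract_features(set)
  expect_equal(fs$peak_amp, 19.2, tolerance = 0.02)
  expect_equal(fs$tau1, 30.7, tolerance = 0.02)
  expect_equal(fs$tau2, 85.8, tolerance = 0.02)
  expect_equal(fs$rel_a1, 0.83, tolerance = 0.02)
  expect_equal(fs$tau_rec, 11.2, tolerance = 0.02)
  expect_lt(abs(fs$v_half_act - (-6.45)), 1)
  expect_lt(abs(fs$v_half_inact - (-57.9)), 1)
  expect_equal(fs$k_inact, 5, tolerance = 0.02)
  # k_act carries a ~2.2% readout distortion from the activation /
  # inactivation overlap at the G-V foot (see the methods vignette)
  expect_equal(fs$k_act, 15, tolerance = 0.03)
})

test_that("extract_features flags identical oocytes and missing protocols", {
  p <- wt_profile("TERNARY")
  protos <- list(DECAY = build_protocol("DECAY", list(sample_interval = 1)),
                 IV_FAMILY = build_protocol("IV_FAMILY",
                                            list(sample_interval = 1)))
  set <- simulate_experiment(p, NULL, protos, n_oocytes = 3,
                             variability = zero_variability(), seed = 9,
                             meta = list(variant = "WT",
                                         configuration = "TERNARY"))
  expect_warning(fs <- extract_features(set), "RECOVERY")
  expect_false("tau_rec" %in% names(fs))
  expect_equal(nrow(fs), 3L)
  for (col in c("peak_amp", "tau1", "v_half_act"))
    expect_true(all(fs[[col]] == fs[[col]][1]))
})
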