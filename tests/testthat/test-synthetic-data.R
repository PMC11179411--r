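test_that("build_protocol produces the four stimulation paradigms", {
  iv <- build_protocol("IV_FAMILY")
  expect_length(iv, 15L)
  expect_equal(vapply(iv, function(p) p$sweep_value, numeric(1)),
               seq(-80, 60, 10))
  dec <- build_protocol("DECAY")
  expect_s3_class(dec, "voltage_protocol")
  expect_equal(dec$epochs[[2]]$duration, 2500)
  expect_equal(dec$epochs[[2]]$voltage, 40)
  ssi <- build_protocol("SSI")
  expect_length(ssi, 11L)
  expect_equal(vapply(ssi, function(p) p$sweep_value, numeric(1)),
               seq(-100, 0, 10))
  cond <- vapply(ssi, function(p) p$epochs[[3]]$duration, numeric(1))
  expect_true(all(cond == 10000))
  rec1 <- build_protocol("RECOVERY", list(dt_grid_ms = 1))
  expect_length(rec1, 1L)
  expect_equal(rec1[[1]]$epochs[[3]]$duration, 1)
  expect_equal(rec1[[1]]$epochs[[3]]$role, "interpulse")
})

test_that("protocol constructors enforce their invariants", {
  expect_error(protocol_epoch(40, 0), "positive")
  expect_error(protocol_epoch(100, 10), "-120")
  expect_error(build_protocol("NOPE"), "arg")
  expect_error(build_protocol("RECOVERY", list(dt_grid_ms = -5)), "positive")
  expect_error(voltage_protocol(list(protocol_epoch(-100, 10)), 0.5,
                                "DECAY"),
               "at least 2 epochs")
  # sample grid must divide epoch durations
  expect_error(voltage_protocol(list(protocol_epoch(-100, 10),
                                     protocol_epoch(40, 10.3)),
                                0.5, "DECAY"),
               "integer multiple")
  # recovery topology: two test-voltage epochs around one interpulse
  expect_error(voltage_protocol(list(protocol_epoch(-100, 10, "holding"),
                                     protocol_epoch(40, 10, "control"),
                                     protocol_epoch(40, 10, "test")),
                                0.5, "RECOVERY"),
               "interpulse")
})

test_that("wild-type ternary profile carries the reference parameters", {
  p <- wt_profile("TERNARY")
  expect_equal(p$tau1, 30.7)
  expect_equal(p$tau2, 85.8)
  expect_equal(p$rel_a1, 0.83)
  expect_equal(p$tau_rec, 11.2)
  expect_equal(p$v_half_act, -6.45)
  expect_equal(p$v_half_inact, -57.9)
  expect_equal(p$peak_uA, 19.2)
})

test_that("beta-subunit effects act in the documented directions", {
  a <- wt_profile("ALONE"); k <- wt_profile("KCHIP"); d <- wt_profile("DPP")
  expect_gt(k$tau1, a$tau1)          # KChIP slows the initial phase
  expect_lt(k$tau2, a$tau2)          # and accelerates the late phase
  expect_lt(k$tau_rec, a$tau_rec)    # accelerates recovery
  expect_gt(k$v_half_inact, a$v_half_inact)  # positive SSI shift
  expect_gt(k$g_max, a$g_max)        # larger currents
  expect_lt(d$tau1, a$tau1)          # DPP accelerates initial inactivation
  expect_lt(d$tau_rec, a$tau_rec)
  expect_lt(d$v_half_act, a$v_half_act)
  expect_lt(d$v_half_inact, a$v_half_inact)
})

test_that("applying both beta effect sets to the base profile gives ternary", {
  tab <- load_fixture("wt_profiles")
  pr <- tab$profiles$ALONE
  for (nm in names(tab$beta_effects$components)) {
    cp <- tab$beta_effects$components[[nm]]
    if (!"TERNARY" %in% unlist(cp$configurations)) next
    if (cp$field == "g_max") next  # conductance is peak-parameterized
    if (!is.null(cp$mult)) pr[[cp$field]] <- pr[[cp$field]] * cp$mult
    if (!is.null(cp$shift)) pr[[cp$field]] <- pr[[cp$field]] + cp$shift
  }
  tern <- tab$profiles$TERNARY
  for (f in c("tau1", "tau2", "tau_rec", "v_half_act", "v_half_inact"))
    expect_equal(pr[[f]], tern[[f]], tolerance = 1e-12)
})

test_that("profile invariants are enforced", {
  expect_error(biophysical_profile(1, 50, 30, 0.8, 10, -6, 15, -58, 5),
               "tau1 must be smaller")
  expect_error(biophysical_profile(1, 30, 86, 1.2, 10, -6, 15, -58, 5),
               "rel_a1")
  expect_error(biophysical_profile(1, 30, 86, 0.8, -1, -6, 15, -58, 5),
               "positive")
})

test_that("simulate_trace honours trivial contracts", {
  p <- wt_profile("TERNARY")
  proto <- build_protocol("DECAY")
  p0 <- p; p0$g_max <- 0
  tr0 <- simulate_trace(p0, proto)
  expect_true(all(tr0$current == 0))
  # determinism: same seed, same noise
  t1 <- simulate_trace(p, proto, noise_sd = 0.2, seed = 11)
  t2 <- simulate_trace(p, proto, noise_sd = 0.2, seed = 11)
  expect_identical(t1$current, t2$current)
  t3 <- simulate_trace(p, proto, noise_sd = 0.2, seed = 12)
  expect_false(identical(t1$current, t3$current))
  # noiseless calls leave the caller's RNG stream untouched
  set.seed(5); before <- rnorm(1)
  set.seed(5); invisible(simulate_trace(p, proto, noise_sd = 0.2, seed = 3))
  expect_identical(rnorm(1), before)
})

test_that("noiseless peak matches the dense-grid analytic oracle", {
  p <- wt_profile("TERNARY")
  tr <- simulate_trace(p, build_protocol("DECAY", list(sample_interval = 0.5)))
  analytic <- p$g_max * peak_open_fraction(p) * (40 - p$e_rev)
  expect_equal(measure_peak(tr, role = "test"), analytic, tolerance = 0.01)
})

test_that("availability obeys the closed-form recovery law across epochs", {
  p <- wt_profile("TERNARY")
  h_depleted <- function(t_dep) {
    hi <- h_inf(p, 40); h0 <- h_inf(p, -100)
    hi + (h0 - hi) * (p$rel_a1 * exp(-t_dep / p$tau1) +
                      (1 - p$rel_a1) * exp(-t_dep / p$tau2))
  }
  for (dt_ip in c(5, 20, 80)) {
    proto <- build_protocol("RECOVERY", list(dt_grid_ms = dt_ip))[[1]]
    tr <- simulate_trace(p, proto)
    # current at the first sample of the test pulse reflects h after the
    # interpulse; compare with the closed form h recovery
    idx <- kv4class:::epoch_sample_range(tr, "test")
    h1 <- h_depleted(500)                      # after the control pulse
    h_pred <- h_inf(p, -100) + (h1 - h_inf(p, -100)) * exp(-dt_ip / p$tau_rec)
    m_ctl_end <- m_inf(p, 40)
    m_start <- m_inf(p, -100) +
      (m_ctl_end - m_inf(p, -100)) * exp(-dt_ip / p$tau_act)
    i_pred <- p$g_max * m_start * h_pred * (40 - p$e_rev)
    expect_equal(tr$current[idx[1]], i_pred, tolerance = 1e-10)
  }
  # continuity within epochs: sample-to-sample steps bounded by the
  # fastest gating rate (the tau_act rise) at the sampling interval
  dt <- 0.1
  tr <- simulate_trace(p, build_protocol("DECAY", list(sample_interval = dt)))
  bound <- p$peak_uA * (1 - exp(-dt / p$tau_act)) * 1.2
  expect_lt(max(abs(diff(tr$current[kv4class:::epoch_sample_range(tr, "test")]))),
            bound)
})

test_that("peak current is linear in g_max and v_half_act is translation-equivariant", {
  p <- wt_profile("TERNARY")
  proto <- build_protocol("DECAY", list(sample_interval = 0.5))
  pk1 <- measure_peak(simulate_trace(p, proto), role = "test")
  p2 <- p; p2$g_max <- 2.5 * p$g_max
  expect_equal(measure_peak(simulate_trace(p2, proto), role = "test"),
               2.5 * pk1, tolerance = 1e-12)
  fit_vhalf <- function(prof) {
    iv <- lapply(build_protocol("IV_FAMILY"), simulate_trace, profile = prof)
    gv <- compute_conductance(iv, e_rev = prof$e_rev)
    fit_boltzmann(data.frame(v = gv$v, y = gv$g), "activation")$v_half
  }
  v0 <- fit_vhalf(p)
  p3 <- p; p3$v_half_act <- p$v_half_act + 7
  expect_equal(fit_vhalf(p3) - v0, 7, tolerance = 0.25)
})

test_that("simulate_experiment reproduces, spreads, and scales", {
  p <- wt_profile("TERNARY")
  protos <- list(DECAY = build_protocol("DECAY", list(sample_interval = 1)))
  # degenerate spread: every oocyte identical to the single-profile trace
  set <- simulate_experiment(p, NULL, protos, n_oocytes = 3,
                             variability = zero_variability(), seed = 2)
  ref <- simulate_trace(p, protos$DECAY)
  for (tr in set$traces) expect_identical(tr$current, ref$current)
  # seed reproducibility
  s1 <- simulate_experiment(p, NULL, protos, n_oocytes = 4, noise_sd = 0.1,
                            seed = 31)
  s2 <- simulate_experiment(p, NULL, protos, n_oocytes = 4, noise_sd = 0.1,
                            seed = 31)
  expect_identical(lapply(s1$traces, `[[`, "current"),
                   lapply(s2$traces, `[[`, "current"))
  # Monte-Carlo spread consistency: SD of per-oocyte peaks near configured
  set.seed(8)
  big <- simulate_experiment(p, NULL, protos, n_oocytes = 200, seed = 17)
  peaks <- vapply(big$traces, measure_peak, numeric(1), role = "test")
  expect_equal(sd(peaks) / 9.52, 1, tolerance = 0.2)
  # halved conductance halves the mean peak; with a shared seed the
  # per-oocyte perturbations pair up, so linearity in g_max is exact
  eff <- list(effects = list(TERNARY = list(g_max_mult = 0.5)))
  half <- simulate_experiment(p, eff, protos, n_oocytes = 50, seed = 5)
  full <- simulate_experiment(p, NULL, protos, n_oocytes = 50, seed = 5)
  r <- mean(vapply(half$traces, measure_peak, numeric(1), role = "test")) /
    mean(vapply(full$traces, measure_peak, numeric(1), role = "test"))
  expect_equal(r, 0.5, tolerance = 1e-9)
})

test_that("packaged fixtures validate and expose the printed values", {
  t1 <- load_fixture("table1_variants")
  expect_equal(nrow(t1), 17L)
  expect_equal(variant_record("p.Ala202Thr", t1)$v4_n_hemizygotes, 35)
  expect_equal(variant_record("p.Gly80Arg", t1)$v4_allele_count, 0)
  expect_equal(variant_record("p.Thr57Met", t1)$v4_allele_count, 12)
  t3 <- load_fixture("table3_criteria")
  expect_equal(nrow(t3), 12L)
  expect_equal(t3$criteria[t3$protein == "p.Arg107Gln"], "PS3")
  expect_error(variant_record("p.Nonexistent", t1), "not found")
  # schema violations are rejected
  bad <- t1; bad$v4_n_hemizygotes[1] <- bad$v4_allele_count[1] + 1
  expect_error(kv4class:::validate_table1(bad), "exceeds")
  bad2 <- t1[-1, ]
  expect_error(kv4class:::validate_table1(bad2), "17 rows")
})

test_that("trace CSV + sidecar serialization round-trips", {
  p <- wt_profile("TERNARY")
  protos <- list(RECOVERY = build_protocol("RECOVERY",
                                           list(dt_grid_ms = c(1, 10, 100),
                                                sample_interval = 1)))
  set <- simulate_experiment(p, NULL, protos, n_oocytes = 2, noise_sd = 0.05,
                             seed = 4, meta = list(variant = "WT",
                                                   configuration = "TERNARY"))
  dir <- withr::local_tempdir()
  write_traces(set, dir)
  back <- read_traces(dir)
  expect_length(back$traces, length(set$traces))
  for (i in seq_along(set$traces)) {
    expect_equal(back$traces[[i]]$current, set$traces[[i]]$current,
                 tolerance = 1e-12)
    expect_equal(back$traces[[i]]$protocol$label,
                 set$traces[[i]]$protocol$label)
  }
  expect_equal(back$meta$configuration, "TERNARY")
})
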