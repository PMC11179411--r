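#' Biophysical feature extraction
#'
#' Fitting routines for the five biophysical parameters: peak current
#' amplitude, double-exponential macroscopic inactivation, single
#' exponential recovery from inactivation, and Boltzmann voltage
#' dependences of activation and steady-state inactivation.
#'
#' All exponential fits use variable projection (linear amplitudes solved
#' exactly for each candidate set of time constants) with multi-start
#' nonlinear optimization of the time constants, which makes them robust
#' to the initialization sensitivity typical of sums of exponentials.
#'
#' @name trace_features
NULL

epoch_sample_range <- function(trace, role, occurrence = 1L) {
  epochs <- trace$protocol$epochs
  dt <- trace$protocol$sample_interval
  ns <- vapply(epochs, function(e) as.integer(round(e$duration / dt)),
               integer(1))
  ends <- cumsum(ns)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  idx <- which(vapply(epochs, `[[`, character(1), "role") == role)
  if (length(idx) < occurrence)
    stop("trace has no epoch #", occurrence, " with role '", role, "'")
  i <- idx[occurrence]
  starts[i]:ends[i]
}

leak_baseline <- function(trace) {
  hold <- tryCatch(epoch_sample_range(trace, "holding"),
                   error = function(e) NULL)
  if (is.null(hold)) return(0)
  tail_part <- hold[hold >= stats::quantile(hold, 0.5)]
  stats::median(trace$current[tail_part])
}

#' Peak current amplitude
#'
#' Maximum of the (optionally leak-subtracted) current within a window.
#' The leak estimate is the median current over the late half of the
#' holding epoch, so a constant offset leaves the reported peak unchanged.
#'
#' @param trace A `current_trace`.
#' @param window Numeric `c(t0, t1)` (ms) or `NULL` to use the epoch
#'   selected by `role`/`occurrence`.
#' @param role,occurrence Epoch selector used when `window` is `NULL`.
#' @param leak_subtract Subtract the holding-epoch baseline first.
#' @return Peak amplitude (uA).
#' @export
measure_peak <- function(trace, window = NULL, role = "test",
                         occurrence = 1L, leak_subtract = FALSE) {
  if (is.null(window)) {
    idx <- epoch_sample_range(trace, role, occurrence)
  } else {
    if (window[1] < min(trace$time) - 1e-9 ||
        window[2] > max(trace$time) + 1e-9)
      stop("window [", window[1], ", ", window[2], "] lies outside the trace")
    idx <- which(trace$time >= window[1] & trace$time <= window[2])
    if (!length(idx)) stop("window contains no samples")
  }
  cur <- trace$current[idx]
  if (leak_subtract) cur <- cur - leak_baseline(trace)
  max(cur)
}

## variable projection residual for y ~ sum_j exp(-t/tau_j) (+ offset)
varpro_exp <- function(t, y, taus, offset = c("free", "none"),
                       offset_bound = NULL) {
  offset <- match.arg(offset)
  X <- vapply(taus, function(tau) exp(-t / tau), numeric(length(t)))
  if (offset == "free") X <- cbind(X, 1)
  fit <- stats::lm.fit(X, y)
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0
  if (offset == "free" && !is.null(offset_bound)) {
    C <- coefs[length(coefs)]
    if (abs(C) > offset_bound) {
      C <- sign(C) * offset_bound
      Xa <- X[, -ncol(X), drop = FALSE]
      fa <- stats::lm.fit(Xa, y - C)
      coefs <- c(fa$coefficients, C)
      coefs[is.na(coefs)] <- 0
      resid <- y - Xa %*% coefs[-length(coefs)] - C
      return(list(amplitudes = coefs[-length(coefs)], offset = C,
                  rss = sum(resid^2)))
    }
  }
  amps <- if (offset == "free") coefs[-length(coefs)] else coefs
  off <- if (offset == "free") coefs[length(coefs)] else 0
  list(amplitudes = amps, offset = off, rss = sum(fit$residuals^2))
}

decay_time_to <- function(t, y, frac) {
  target <- y[1] * frac
  below <- which(y <= target)
  if (!length(below)) return(max(t) - t[1])
  t[below[1]] - t[1]
}

#' Double-exponential fit of macroscopic inactivation
#'
#' Fits `I(t) = A1 exp(-(t - t_peak)/tau1) + A2 exp(-(t - t_peak)/tau2) + C`
#' from the sample of peak current to the end of the depolarized epoch.
#' Components are relabeled so that `tau1 < tau2`;
#' `rel_a1 = A1 / (A1 + A2)`. The offset is bounded to +/-5% of the peak.
#' Initial time constants are seeded from the 20%/80% decay times and
#' refined from multiple perturbed starts.
#'
#' @param trace A `current_trace` containing a depolarized epoch with an
#'   identifiable peak (role `"test"` by default).
#' @param role Epoch role holding the decay phase.
#' @param n_starts Number of multi-start perturbations (>= 5 recommended).
#' @param skip_ms Dead time between the peak sample and the start of the
#'   fit window (ms). The default, 10 ms, excludes the short stretch where
#'   the activation gate is still settling, which would otherwise bias the
#'   fast time constant upward; `skip_ms = 0` fits literally from the
#'   peak.
#' @return A `decay_fit`: list with `tau1`, `tau2`, `rel_a1`, `offset`,
#'   `a1`, `a2`, `rss`, `converged`, `t_peak`.
#' @export
fit_decay <- function(trace, role = "test", n_starts = 7L, skip_ms = 10) {
  idx <- epoch_sample_range(trace, role)
  t <- trace$time[idx]
  y <- trace$current[idx]
  ip <- which.max(y)
  peak <- y[ip]
  t_peak <- t[ip]
  ip <- ip + match(TRUE, t[ip:length(t)] >= t_peak + skip_ms) - 1L
  if (is.na(ip) || ip >= length(y) - 10L)
    stop("no identifiable decay phase after the peak")
  t <- t[ip:length(y)] - t_peak
  y <- y[ip:length(y)]
  t80 <- decay_time_to(t, y, 0.8)
  t20 <- decay_time_to(t, y, 0.2)
  tf0 <- max(t80 / 0.223, min(diff(t)))      # -log(0.8) = 0.223
  ts0 <- max(t20 / 1.609, tf0 * 2)           # -log(0.2) = 1.609
  base_starts <- list(c(tf0, ts0), c(tf0 / 2, ts0), c(tf0, ts0 * 3),
                      c(tf0 / 3, ts0 / 3), c(tf0 * 2, ts0 * 4))
  extra <- max(0L, n_starts - length(base_starts))
  if (extra > 0) {
    fac <- exp(seq(-1, 1, length.out = extra))
    base_starts <- c(base_starts,
                     lapply(fac, function(f) c(tf0 * f, ts0 * f * 2.5)))
  }
  obj <- function(theta) {
    tau1 <- exp(theta[1]); tau2 <- tau1 + exp(theta[2])
    varpro_exp(t, y, c(tau1, tau2), "free", 0.05 * abs(peak))$rss
  }
  best <- NULL
  for (st in base_starts) {
    th0 <- c(log(st[1]), log(max(st[2] - st[1], st[1] * 0.1)))
    res <- tryCatch(stats::optim(th0, obj, method = "Nelder-Mead",
                                 control = list(maxit = 800,
                                                reltol = 1e-12)),
                    error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    return(structure(list(tau1 = NA_real_, tau2 = NA_real_,
                          rel_a1 = NA_real_, offset = NA_real_,
                          a1 = NA_real_, a2 = NA_real_, rss = NA_real_,
                          converged = FALSE, t_peak = t_peak),
                     class = "decay_fit"))
  tau1 <- exp(best$par[1]); tau2 <- tau1 + exp(best$par[2])
  vp <- varpro_exp(t, y, c(tau1, tau2), "free", 0.05 * abs(peak))
  a <- vp$amplitudes
  if (tau1 > tau2) { tau <- c(tau2, tau1); a <- rev(a) } else tau <- c(tau1, tau2)
  denom <- a[1] + a[2]
  ## effectively single-exponential input: keep the mass-carrying
  ## component as tau1 and report an empty slow component
  if (abs(denom) > .Machine$double.eps &&
      abs(a[1]) / abs(denom) < 1e-3) {
    tau <- c(tau[2], Inf)
    a <- c(a[2], 0)
  }
  rel_a1 <- if (abs(denom) < .Machine$double.eps) NA_real_ else a[1] / denom
  structure(list(tau1 = tau[1], tau2 = tau[2],
                 rel_a1 = min(1, max(0, rel_a1)),
                 offset = vp$offset, a1 = a[1], a2 = a[2], rss = vp$rss,
                 converged = best$convergence == 0 && is.finite(vp$rss),
                 t_peak = t_peak),
            class = "decay_fit")
}

#' Single-exponential fit of recovery from inactivation
#'
#' Fits `R(dt) = 1 - a exp(-dt/tau_rec)` to normalized test/control
#' amplitude ratios from a double-pulse paradigm. The asymptote is fixed
#' at 1 and the amplitude `a` is free.
#'
#' @param points data.frame (or list) with `dt` (interpulse duration, ms)
#'   and `ratio` (I_test / I_control); at least 4 points spanning at least
#'   one decade of `dt`.
#' @return A `recovery_fit`: list with `tau_rec`, `amplitude`, `rss`,
#'   `converged`.
#' @export
fit_recovery <- function(points) {
  dt <- points$dt
  r <- points$ratio
  if (length(dt) < 4L) stop("need at least 4 recovery points")
  if (max(dt) / min(dt) < 10) stop("recovery grid must span >= 1 decade")
  if (max(abs(1 - r)) < 0.02)
    return(structure(list(tau_rec = NA_real_, amplitude = NA_real_,
                          rss = NA_real_, converged = FALSE),
                     class = "recovery_fit"))
  y <- 1 - r
  obj <- function(ltau) {
    x <- exp(-dt / exp(ltau))
    a <- sum(x * y) / sum(x * x)
    sum((y - a * x)^2)
  }
  opt <- stats::optimize(obj, c(log(min(dt) / 100), log(max(dt) * 100)),
                         tol = 1e-10)
  tau <- exp(opt$minimum)
  x <- exp(-dt / tau)
  a <- sum(x * y) / sum(x * x)
  edge <- opt$minimum < log(min(dt) / 100) + 0.01 ||
    opt$minimum > log(max(dt) * 100) - 0.01
  structure(list(tau_rec = tau, amplitude = a, rss = opt$objective,
                 converged = !edge && is.finite(opt$objective)),
            class = "recovery_fit")
}

#' Normalized conductance-voltage relation from an IV family
#'
#' `G(V) = I_peak(V) / (V - e_rev)`, normalized to the maximum over the
#' family.
#'
#' @param iv_sweeps List of `current_trace` objects (one per test voltage)
#'   or a `trace_set` restricted to one oocyte's IV family.
#' @param e_rev Reversal potential used for the driving-force correction
#'   (mV).
#' @param leak_subtract Passed to [measure_peak()].
#' @return data.frame with `v` (mV), `g` (normalized), `g_raw` (uS).
#' @export
compute_conductance <- function(iv_sweeps, e_rev = -98,
                                leak_subtract = FALSE) {
  if (inherits(iv_sweeps, "trace_set")) iv_sweeps <- iv_sweeps$traces
  v <- vapply(iv_sweeps, function(tr) tr$protocol$sweep_value, numeric(1))
  if (any(abs(v - e_rev) < 1e-9))
    stop("test voltage equals the reversal potential; conductance undefined")
  if (any(v < e_rev)) {
    warning(sum(v < e_rev), " test voltage(s) at or below the declared ",
            "reversal potential excluded from the conductance transform")
    keep <- v > e_rev
    iv_sweeps <- iv_sweeps[keep]
    v <- v[keep]
  }
  ip <- vapply(iv_sweeps, measure_peak, numeric(1), role = "test",
               leak_subtract = leak_subtract)
  g_raw <- ip / (v - e_rev)
  ord <- order(v)
  data.frame(v = v[ord], g = (g_raw / max(g_raw))[ord], g_raw = g_raw[ord])
}

#' Boltzmann fit of a voltage dependence
#'
#' Activation: `y = [1 / (1 + exp((v_half - V)/k))]^power` (default
#' `power = 1`; a fourth-power variant is available but off by default).
#' Inactivation: `y = pedestal + (1 - pedestal) / (1 + exp((V - v_half)/k))`.
#' The slope factor is reported positive in both conventions.
#'
#' @param points data.frame with `v` (mV) and `y` (normalized, in
#'   \[0, 1.05\]); at least 6 voltages.
#' @param direction `"activation"` or `"inactivation"`.
#' @param pedestal Residual availability at depolarized potentials
#'   (inactivation only); fixed, default 0.
#' @param power Activation exponent (1 or 4).
#' @return A `boltzmann_fit`: list with `v_half`, `k`, `direction`,
#'   `pedestal`, `rss`, `converged`, `residual_warning` (TRUE when the RMS
#'   residual exceeds 1% of the normalized scale, e.g. with a misdeclared
#'   reversal potential).
#' @export
fit_boltzmann <- function(points, direction = c("activation", "inactivation"),
                          pedestal = 0, power = 1) {
  direction <- match.arg(direction)
  v <- points$v
  y <- points$y
  if (length(v) < 6L) stop("need at least 6 voltage points")
  if (any(y < -1e-9 | y > 1.05 + 1e-9))
    stop("normalized values must lie in [0, 1.05]")
  if (diff(range(y)) < 0.2)
    return(structure(list(v_half = NA_real_, k = NA_real_,
                          direction = direction, pedestal = pedestal,
                          rss = NA_real_, converged = FALSE,
                          residual_warning = TRUE),
                     class = "boltzmann_fit"))
  model <- function(par, v) {
    vh <- par[1]; k <- exp(par[2])
    if (direction == "activation")
      (1 / (1 + exp((vh - v) / k)))^power
    else
      pedestal + (1 - pedestal) / (1 + exp((v - vh) / k))
  }
  obj <- function(par) sum((y - model(par, v))^2)
  ## seed v_half at the half-crossing
  ord <- order(v)
  yo <- y[ord]; vo <- v[ord]
  cross <- if (direction == "activation") which(yo >= 0.5)[1] else
    utils::tail(which(yo >= 0.5), 1)
  vh0 <- if (is.na(cross)) stats::median(vo) else vo[cross]
  best <- NULL
  for (st in list(c(vh0, log(10)), c(vh0 - 10, log(5)), c(vh0 + 10, log(5)),
                  c(vh0, log(20)), c(vh0 - 5, log(15)))) {
    res <- tryCatch(stats::optim(st, obj, method = "Nelder-Mead",
                                 control = list(maxit = 500,
                                                reltol = 1e-12)),
                    error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best))
    return(structure(list(v_half = NA_real_, k = NA_real_,
                          direction = direction, pedestal = pedestal,
                          rss = NA_real_, converged = FALSE,
                          residual_warning = TRUE),
                     class = "boltzmann_fit"))
  structure(list(v_half = best$par[1], k = exp(best$par[2]),
                 direction = direction, pedestal = pedestal,
                 rss = best$value,
                 converged = best$convergence == 0,
                 residual_warning = sqrt(best$value / length(v)) > 0.01),
            class = "boltzmann_fit")
}

#' Recovery points from a set of double-pulse sweeps
#'
#' @param sweeps List of RECOVERY `current_trace` objects.
#' @param leak_subtract Passed to [measure_peak()].
#' @return data.frame with `dt` and `ratio`.
#' @export
recovery_points <- function(sweeps, leak_subtract = FALSE) {
  if (inherits(sweeps, "trace_set")) sweeps <- sweeps$traces
  dt <- vapply(sweeps, function(tr) tr$protocol$sweep_value, numeric(1))
  ratio <- vapply(sweeps, function(tr) {
    measure_peak(tr, role = "test", leak_subtract = leak_subtract) /
      measure_peak(tr, role = "control", leak_subtract = leak_subtract)
  }, numeric(1))
  ord <- order(dt)
  data.frame(dt = dt[ord], ratio = ratio[ord])
}

#' Steady-state inactivation points from SSI sweeps
#'
#' @param sweeps List of SSI `current_trace` objects.
#' @param leak_subtract Passed to [measure_peak()].
#' @return data.frame with `v` (conditioning voltage) and `y`
#'   (I_test / I_control, clipped to 1.05).
#' @export
ssi_points <- function(sweeps, leak_subtract = FALSE) {
  if (inherits(sweeps, "trace_set")) sweeps <- sweeps$traces
  v <- vapply(sweeps, function(tr) tr$protocol$sweep_value, numeric(1))
  y <- vapply(sweeps, function(tr) {
    measure_peak(tr, role = "test", leak_subtract = leak_subtract) /
      measure_peak(tr, role = "control", leak_subtract = leak_subtract)
  }, numeric(1))
  ord <- order(v)
  data.frame(v = v[ord], y = pmin(y[ord], 1.05))
}

#' Extract the per-oocyte feature table from a trace set
#'
#' Runs the peak measurement and all four fits for every oocyte and
#' returns one row per oocyte. Protocols absent from the trace set yield
#' absent columns (with a warning), not zeros; failed fits yield `NA`
#' with their `converged` flag set to `FALSE`.
#'
#' @param traceset A `trace_set` from [simulate_experiment()].
#' @param e_rev Reversal potential for the conductance transform (mV).
#' @param leak_subtract Apply holding-epoch baseline subtraction.
#' @return A `feature_set` data.frame with columns `configuration`,
#'   `variant`, `oocyte` and, per available protocol, `peak_amp`, `tau1`,
#'   `tau2`, `rel_a1`, `tau_rec`, `v_half_act`, `k_act`, `v_half_inact`,
#'   `k_inact` plus convergence flags.
#' @export
extract_features <- function(traceset, e_rev = -98, leak_subtract = FALSE) {
  labels <- unique(vapply(traceset$traces, function(tr) tr$protocol$label,
                          character(1)))
  absent <- setdiff(PROTOCOL_LABELS, labels)
  if (length(absent))
    warning("trace set lacks protocol(s) ", paste(absent, collapse = ", "),
            "; the corresponding feature columns are absent")
  rows <- lapply(ts_oocytes(traceset), function(oo) {
    row <- list(configuration = traceset$meta$configuration %||% NA_character_,
                variant = traceset$meta$variant %||% "WT",
                oocyte = oo)
    if ("DECAY" %in% labels) {
      dec <- ts_traces(traceset, "DECAY", oo)[[1L]]
      row$peak_amp <- measure_peak(dec, role = "test",
                                   leak_subtract = leak_subtract)
      df <- fit_decay(dec)
      row$tau1 <- df$tau1; row$tau2 <- df$tau2; row$rel_a1 <- df$rel_a1
      row$decay_converged <- df$converged
    }
    if ("RECOVERY" %in% labels) {
      rf <- fit_recovery(recovery_points(ts_traces(traceset, "RECOVERY", oo),
                                         leak_subtract = leak_subtract))
      row$tau_rec <- rf$tau_rec
      row$recovery_converged <- rf$converged
    }
    if ("IV_FAMILY" %in% labels) {
      gv <- compute_conductance(ts_traces(traceset, "IV_FAMILY", oo),
                                e_rev = e_rev,
                                leak_subtract = leak_subtract)
      bf <- fit_boltzmann(data.frame(v = gv$v, y = gv$g), "activation")
      row$v_half_act <- bf$v_half; row$k_act <- bf$k
      row$activation_converged <- bf$converged
    }
    if ("SSI" %in% labels) {
      sp <- ssi_points(ts_traces(traceset, "SSI", oo),
                       leak_subtract = leak_subtract)
      bf <- fit_boltzmann(sp, "inactivation")
      row$v_half_inact <- bf$v_half; row$k_inact <- bf$k
      row$inactivation_converged <- bf$converged
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("feature_set", class(out))
  out
}
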