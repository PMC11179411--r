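#' Phenomenological two-electrode voltage-clamp trace simulator
#'
#' Current is computed per sample as
#' `I = g_max * m(t, V) * h(t, V) * (V - e_rev)` (outward positive, uA).
#' The activation gate `m` relaxes mono-exponentially (time constant
#' `tau_act`) toward its Boltzmann steady state; the availability gate `h`
#' relaxes toward its steady state double-exponentially
#' (`tau1`/`tau2`/`rel_a1`) at depolarized potentials and
#' mono-exponentially (`tau_rec`) at potentials at or below the recovery
#' threshold (-80 mV). Gate state carries over across epochs, so double
#' pulse paradigms obey the closed-form recovery law exactly.
#'
#' @name simulate
NULL

RECOVERY_THRESHOLD_MV <- -80

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  } else {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate one current trace
#'
#' @param profile A `biophysical_profile`.
#' @param protocol A `voltage_protocol` (one sweep).
#' @param noise_sd Standard deviation of additive Gaussian current noise
#'   (uA); 0 gives a bit-reproducible noiseless trace.
#' @param seed Optional integer seed for the noise; the caller's RNG state
#'   is restored afterwards. With `seed = NULL` the current RNG stream is
#'   used.
#' @param meta Named list merged into the trace metadata (e.g.
#'   `configuration`, `variant`, `oocyte`).
#' @return A `current_trace`: list with `time` (ms), `current` (uA),
#'   `voltage` (mV command per sample), `protocol`, `meta`.
#' @export
simulate_trace <- function(profile, protocol, noise_sd = 0, seed = NULL,
                           meta = list()) {
  validate_profile(profile)
  if (!inherits(protocol, "voltage_protocol")) stop("protocol must be a voltage_protocol")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  dt <- protocol$sample_interval
  epochs <- protocol$epochs
  v0 <- epochs[[1L]]$voltage
  m_state <- m_inf(profile, v0)
  h_state <- h_inf(profile, v0)
  time <- numeric(0); current <- numeric(0); vcmd <- numeric(0)
  t_off <- 0
  for (ep in epochs) {
    v <- ep$voltage
    n <- as.integer(round(ep$duration / dt))
    tl <- seq(0, by = dt, length.out = n)
    mi <- m_inf(profile, v)
    hi <- h_inf(profile, v)
    m <- mi + (m_state - mi) * exp(-tl / profile$tau_act)
    if (v <= RECOVERY_THRESHOLD_MV) {
      relax <- exp(-tl / profile$tau_rec)
      relax_end <- exp(-ep$duration / profile$tau_rec)
    } else {
      relax <- profile$rel_a1 * exp(-tl / profile$tau1) +
        (1 - profile$rel_a1) * exp(-tl / profile$tau2)
      relax_end <- profile$rel_a1 * exp(-ep$duration / profile$tau1) +
        (1 - profile$rel_a1) * exp(-ep$duration / profile$tau2)
    }
    h <- hi + (h_state - hi) * relax
    current <- c(current, profile$g_max * m * h * (v - profile$e_rev))
    time <- c(time, t_off + tl)
    vcmd <- c(vcmd, rep(v, n))
    m_state <- mi + (m_state - mi) * exp(-ep$duration / profile$tau_act)
    h_state <- hi + (h_state - hi) * relax_end
    t_off <- t_off + ep$duration
  }
  if (noise_sd > 0)
    current <- current + with_seed(seed, stats::rnorm(length(current), 0, noise_sd))
  structure(list(time = time, current = current, voltage = vcmd,
                 protocol = protocol,
                 meta = utils::modifyList(list(seed = seed,
                                               noise_sd = noise_sd), meta)),
            class = "current_trace")
}

#' Default per-oocyte parameter spread
#'
#' Defaults match the wild-type ternary between-oocyte standard deviations
#' (peak 19.2 +/- 9.52 uA, i.e. conductance CV ~ 0.496; tau1 4.72 ms,
#' tau2 56.8 ms, fast fraction 0.11, tau_rec 2.02 ms, activation midpoint
#' 5.42 mV, inactivation midpoint 4.30 mV); slope-factor spreads are
#' synthetic.
#'
#' @return Named list of spread settings.
#' @export
default_variability <- function() {
  list(g_max_cv = 9.52 / 19.2, tau1_sd = 4.72, tau2_sd = 56.8,
       rel_a1_sd = 0.11, tau_rec_sd = 2.02, v_half_act_sd = 5.42,
       v_half_inact_sd = 4.30, k_act_sd = 1.5, k_inact_sd = 0.8)
}

#' Zero per-oocyte spread (identical oocytes)
#' @return Spread settings with every component set to 0.
#' @export
zero_variability <- function() {
  v <- default_variability()
  v[] <- 0
  v
}

perturb_profile <- function(profile, variability, max_tries = 200L) {
  for (i in seq_len(max_tries)) {
    prof <- unclass(profile)
    cv <- variability$g_max_cv %||% 0
    if (cv > 0) {
      sdlog <- sqrt(log(1 + cv^2))
      prof$g_max <- prof$g_max * stats::rlnorm(1, -sdlog^2 / 2, sdlog)
    }
    gaus <- c(tau1 = "tau1_sd", tau2 = "tau2_sd", rel_a1 = "rel_a1_sd",
              tau_rec = "tau_rec_sd", v_half_act = "v_half_act_sd",
              v_half_inact = "v_half_inact_sd", k_act = "k_act_sd",
              k_inact = "k_inact_sd")
    for (fld in names(gaus)) {
      sd <- variability[[gaus[[fld]]]] %||% 0
      if (sd > 0) prof[[fld]] <- prof[[fld]] + stats::rnorm(1, 0, sd)
    }
    prof$rel_a1 <- min(1, max(0, prof$rel_a1))
    ok <- tryCatch({ validate_profile(prof); TRUE }, error = function(e) FALSE)
    if (ok) return(structure(prof, class = "biophysical_profile"))
  }
  stop("could not draw a valid perturbed profile within ", max_tries,
       " attempts; reduce the variability settings")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a multi-oocyte experiment
#'
#' Each simulated oocyte draws its own profile perturbation (lognormal on
#' conductance, Gaussian on the remaining parameters, truncated to the
#' profile invariants) and then produces every sweep of every requested
#' protocol.
#'
#' @param profile Wild-type `biophysical_profile` for the configuration.
#' @param variant_effect Optional variant-effect record (see
#'   [apply_variant_effect()]); applied before per-oocyte perturbation.
#' @param protocol_set Named list of protocols; each entry is a
#'   `voltage_protocol` or a list of sweeps, as produced by
#'   [build_protocol()]. Default: all four standard protocols.
#' @param n_oocytes Number of simulated oocytes (>= 1).
#' @param variability Spread settings, see [default_variability()];
#'   use [zero_variability()] for identical oocytes.
#' @param noise_sd Additive Gaussian current noise per sample (uA).
#' @param seed Integer seed; the full experiment is reproducible under it.
#' @param meta Extra metadata fields (e.g. `variant`, `configuration`).
#' @return A `trace_set`: list of `current_trace` objects with an
#'   `oocyte` index in each trace's metadata.
#' @export
simulate_experiment <- function(profile, variant_effect = NULL,
                                protocol_set = NULL, n_oocytes = 1L,
                                variability = default_variability(),
                                noise_sd = 0, seed = 1L, meta = list()) {
  if (n_oocytes < 1L) stop("n_oocytes must be >= 1")
  if (is.null(protocol_set))
    protocol_set <- list(IV_FAMILY = build_protocol("IV_FAMILY"),
                         DECAY = build_protocol("DECAY"),
                         RECOVERY = build_protocol("RECOVERY"),
                         SSI = build_protocol("SSI"))
  if (!is.null(variant_effect))
    profile <- apply_variant_effect(profile, variant_effect,
                                    profile$configuration)
  traces <- with_seed(seed, {
    out <- list()
    for (oo in seq_len(n_oocytes)) {
      prof <- perturb_profile(profile, variability)
      for (lab in names(protocol_set)) {
        sweeps <- protocol_set[[lab]]
        if (inherits(sweeps, "voltage_protocol")) sweeps <- list(sweeps)
        for (sw in sweeps) {
          out[[length(out) + 1L]] <- simulate_trace(
            prof, sw, noise_sd = noise_sd, seed = NULL,
            meta = utils::modifyList(meta, list(oocyte = oo)))
        }
      }
    }
    out
  })
  structure(list(traces = traces,
                 meta = utils::modifyList(meta, list(
                   n_oocytes = n_oocytes, seed = seed,
                   noise_sd = noise_sd,
                   configuration = profile$configuration))),
            class = "trace_set")
}

#' Subset a trace set
#'
#' @param set A `trace_set`.
#' @param label Optional protocol label filter.
#' @param oocyte Optional oocyte index filter.
#' @return List of `current_trace` objects.
#' @export
ts_traces <- function(set, label = NULL, oocyte = NULL) {
  keep <- vapply(set$traces, function(tr) {
    (is.null(label) || tr$protocol$label == label) &&
      (is.null(oocyte) || identical(tr$meta$oocyte, oocyte))
  }, logical(1))
  set$traces[keep]
}

#' Oocyte indices present in a trace set
#' @param set A `trace_set`.
#' @return Sorted integer vector.
#' @export
ts_oocytes <- function(set) {
  sort(unique(vapply(set$traces, function(tr) as.integer(tr$meta$oocyte %||% 1L),
                     integer(1))))
}

#' Write / read traces as CSV plus JSON sidecar
#'
#' One CSV per sweep (`time_ms`, `current_uA`, `voltage_mV`) and one JSON
#' sidecar holding the protocol and metadata; diffable and language
#' neutral.
#'
#' @param set A `trace_set`.
#' @param dir Output directory (created if needed).
#' @return `write_traces` returns the directory invisibly; `read_traces`
#'   returns a `trace_set`.
#' @export
write_traces <- function(set, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(set$traces)) {
    tr <- set$traces[[i]]
    stem <- sprintf("sweep_%04d", i)
    utils::write.csv(
      data.frame(time_ms = tr$time, current_uA = tr$current,
                 voltage_mV = tr$voltage),
      file.path(dir, paste0(stem, ".csv")), row.names = FALSE)
    side <- list(
      label = tr$protocol$label,
      sample_interval = tr$protocol$sample_interval,
      sweep_value = tr$protocol$sweep_value,
      epochs = lapply(tr$protocol$epochs, function(e)
        list(voltage = e$voltage, duration = e$duration, role = e$role)),
      meta = tr$meta)
    jsonlite::write_json(side, file.path(dir, paste0(stem, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  jsonlite::write_json(set$meta, file.path(dir, "traceset.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_traces
#' @export
read_traces <- function(dir) {
  sides <- sort(list.files(dir, pattern = "^sweep_\\d+\\.json$",
                           full.names = TRUE))
  traces <- lapply(sides, function(sp) {
    side <- jsonlite::read_json(sp, simplifyVector = TRUE)
    df <- utils::read.csv(sub("\\.json$", ".csv", sp))
    epochs <- lapply(seq_len(nrow(side$epochs)), function(i)
      protocol_epoch(side$epochs$voltage[i], side$epochs$duration[i],
                     side$epochs$role[i]))
    proto <- voltage_protocol(epochs, side$sample_interval, side$label,
                              side$sweep_value %||% NA_real_)
    structure(list(time = df$time_ms, current = df$current_uA,
                   voltage = df$voltage_mV, protocol = proto,
                   meta = as.list(side$meta)),
              class = "current_trace")
  })
  meta_path <- file.path(dir, "traceset.json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  structure(list(traces = traces, meta = as.list(meta)), class = "trace_set")
}
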