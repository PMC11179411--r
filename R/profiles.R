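#' Biophysical channel profiles
#'
#' A `biophysical_profile` is the 9+2 parameter phenomenological description
#' of one channel configuration: maximal conductance, double-exponential
#' macroscopic inactivation (tau1 < tau2, fractional fast amplitude),
#' single-exponential recovery from inactivation, and Boltzmann voltage
#' dependences of activation and steady-state inactivation, plus the
#' activation rise time constant and the reversal potential.
#'
#' @name profiles
NULL

CONFIGURATIONS <- c("ALONE", "KCHIP", "DPP", "TERNARY")

#' Construct and validate a biophysical profile
#'
#' @param g_max Maximal conductance (uS), >= 0.
#' @param tau1,tau2 Fast and slow macroscopic inactivation time constants
#'   (ms); `tau1 < tau2`.
#' @param rel_a1 Fractional amplitude of the fast decay component, in
#'   \[0, 1\].
#' @param tau_rec Recovery-from-inactivation time constant (ms), > 0.
#' @param v_half_act,k_act Activation Boltzmann midpoint (mV) and slope
#'   factor (mV, > 0).
#' @param v_half_inact,k_inact Steady-state inactivation Boltzmann midpoint
#'   (mV) and slope factor (mV, > 0).
#' @param tau_act Activation rise time constant (ms), > 0.
#' @param e_rev Reversal potential (mV). The default, -98 mV, is the
#'   potassium Nernst potential for a 2 mM external / 100 mM internal
#'   K+ gradient at 21 degrees C.
#' @param configuration Optional configuration label
#'   (`ALONE`, `KCHIP`, `DPP`, `TERNARY`).
#' @return A `biophysical_profile` object (a named list).
#' @export
biophysical_profile <- function(g_max, tau1, tau2, rel_a1, tau_rec,
                                v_half_act, k_act, v_half_inact, k_inact,
                                tau_act = 1.5, e_rev = -98,
                                configuration = NA_character_) {
  prof <- list(g_max = g_max, tau1 = tau1, tau2 = tau2, rel_a1 = rel_a1,
               tau_rec = tau_rec, v_half_act = v_half_act, k_act = k_act,
               v_half_inact = v_half_inact, k_inact = k_inact,
               tau_act = tau_act, e_rev = e_rev,
               configuration = configuration)
  validate_profile(prof)
  structure(prof, class = "biophysical_profile")
}

validate_profile <- function(prof) {
  num <- c("g_max", "tau1", "tau2", "rel_a1", "tau_rec", "v_half_act",
           "k_act", "v_half_inact", "k_inact", "tau_act", "e_rev")
  vals <- unlist(prof[num])
  if (!all(is.finite(vals))) stop("profile parameters must be finite")
  if (prof$g_max < 0) stop("g_max must be non-negative")
  if (prof$tau1 >= prof$tau2)
    stop("tau1 must be smaller than tau2 (got ", prof$tau1, " >= ",
         prof$tau2, ")")
  if (prof$tau1 <= 0) stop("tau1 must be positive")
  if (prof$rel_a1 < 0 || prof$rel_a1 > 1) stop("rel_a1 must lie in [0, 1]")
  pos <- c("tau_rec", "k_act", "k_inact", "tau_act")
  bad <- pos[unlist(prof[pos]) <= 0]
  if (length(bad)) stop(paste(bad, collapse = ", "), " must be positive")
  invisible(prof)
}

#' Steady-state activation / inactivation
#'
#' Boltzmann steady states: activation
#' `m_inf(V) = 1 / (1 + exp((v_half_act - V)/k_act))`, inactivation
#' `h_inf(V) = 1 / (1 + exp((V - v_half_inact)/k_inact))` (no pedestal, so
#' availability vanishes at strongly depolarized potentials).
#'
#' @param profile A `biophysical_profile`.
#' @param v Voltage(s), mV.
#' @return Steady-state value(s) in \[0, 1\].
#' @export
m_inf <- function(profile, v) 1 / (1 + exp((profile$v_half_act - v) / profile$k_act))

#' @rdname m_inf
#' @export
h_inf <- function(profile, v) 1 / (1 + exp((v - profile$v_half_inact) / profile$k_inact))

#' Analytic peak open-probability factor for a depolarizing step
#'
#' Maximum over time of `m(t) * h(t)` for a step from `v_hold` (assumed
#' equilibrated) to `v_test`, evaluated in closed form on a dense time grid.
#' Used to convert between maximal conductance and the target peak current,
#' and as an independent oracle for peak measurements on sampled traces.
#'
#' @param profile A `biophysical_profile`.
#' @param v_test,v_hold Step and holding potentials (mV).
#' @param dt Grid spacing (ms).
#' @param t_max Grid extent (ms).
#' @return Peak of `m * h` (dimensionless).
#' @export
peak_open_fraction <- function(profile, v_test = 40, v_hold = -100,
                               dt = 0.01, t_max = 400) {
  t <- seq(0, t_max, by = dt)
  m0 <- m_inf(profile, v_hold)
  h0 <- h_inf(profile, v_hold)
  mi <- m_inf(profile, v_test)
  hi <- h_inf(profile, v_test)
  m <- mi + (m0 - mi) * exp(-t / profile$tau_act)
  h <- hi + (h0 - hi) * (profile$rel_a1 * exp(-t / profile$tau1) +
                         (1 - profile$rel_a1) * exp(-t / profile$tau2))
  max(m * h)
}

#' Conductance that yields a target peak current
#'
#' @param profile A `biophysical_profile` (its `g_max` is ignored).
#' @param peak_uA Target peak current (uA) at `v_test`.
#' @inheritParams peak_open_fraction
#' @return Conductance (uS).
#' @export
g_max_for_peak <- function(profile, peak_uA, v_test = 40, v_hold = -100) {
  drive <- v_test - profile$e_rev
  if (drive <= 0) stop("test potential must lie above the reversal potential")
  peak_uA / (drive * peak_open_fraction(profile, v_test, v_hold))
}

wt_profile_table <- function() {
  path <- system.file("extdata", "wt_profiles.json", package = "kv4class")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Wild-type channel profile per configuration
#'
#' The ternary (Kv4.1 + KChIP + DPP) profile carries the reference
#' wild-type parameter set (tau1 30.7 ms, tau2 85.8 ms, fast fraction 0.83,
#' tau_rec 11.2 ms, activation midpoint -6.45 mV, inactivation midpoint
#' -57.9 mV, peak 19.2 uA at +40 mV). The other configurations are derived
#' from a base homotetramer profile by the characteristic beta-subunit
#' effects (KChIP: slowed fast / accelerated slow inactivation, faster
#' recovery, depolarized steady-state inactivation, larger currents;
#' DPP: faster fast inactivation and recovery, hyperpolarized activation
#' and inactivation); effect magnitudes are synthetic defaults documented
#' in the packaged `wt_profiles.json` fixture.
#'
#' Conductance is parameterized through the target peak current at +40 mV
#' and converted with [g_max_for_peak()], so a noiseless decay-protocol
#' simulation reproduces the stated peak amplitude.
#'
#' @param configuration One of `ALONE`, `KCHIP`, `DPP`, `TERNARY`.
#' @return A `biophysical_profile`.
#' @export
wt_profile <- function(configuration = "TERNARY") {
  configuration <- match.arg(configuration, CONFIGURATIONS)
  tab <- wt_profile_table()$profiles[[configuration]]
  prof <- biophysical_profile(
    g_max = 1, tau1 = tab$tau1, tau2 = tab$tau2, rel_a1 = tab$rel_a1,
    tau_rec = tab$tau_rec, v_half_act = tab$v_half_act, k_act = tab$k_act,
    v_half_inact = tab$v_half_inact, k_inact = tab$k_inact,
    tau_act = tab$tau_act, e_rev = tab$e_rev, configuration = configuration)
  prof$g_max <- g_max_for_peak(prof, tab$peak_uA)
  prof$peak_uA <- tab$peak_uA
  prof
}

#' Variant perturbation of a channel profile
#'
#' Applies a variant-effect description to a wild-type profile:
#' multiplicative factors on `g_max`, `tau1`, `tau2`, `tau_rec`; additive
#' shifts (mV) on `v_half_act`, `v_half_inact`, `k_act`, `k_inact`; an
#' additive change on `rel_a1` (clamped to \[0, 1\]). If a
#' `beta_modulation_retained` flag is `FALSE`, the corresponding
#' beta-subunit effect component is cancelled (its inverse is applied) in
#' the configurations containing that subunit, emulating a variant that no
#' longer responds to the auxiliary subunit.
#'
#' @param profile Wild-type `biophysical_profile` for one configuration.
#' @param effect A variant-effect record: list with per-configuration
#'   `effects` (named modifier lists) and optional
#'   `beta_modulation_retained` flags; see the packaged
#'   `variant_effects.json` fixture for the schema.
#' @param configuration Configuration the profile belongs to.
#' @return Modified `biophysical_profile` (still validated).
#' @export
apply_variant_effect <- function(profile, effect,
                                 configuration = profile$configuration) {
  configuration <- match.arg(configuration, CONFIGURATIONS)
  mods <- effect$effects[[configuration]]
  prof <- unclass(profile)
  if (!is.null(mods)) {
    for (fld in c("g_max", "tau1", "tau2", "tau_rec")) {
      m <- mods[[paste0(fld, "_mult")]]
      if (!is.null(m)) prof[[fld]] <- prof[[fld]] * m
    }
    for (fld in c("v_half_act", "v_half_inact", "k_act", "k_inact")) {
      s <- mods[[paste0(fld, "_shift")]]
      if (!is.null(s)) prof[[fld]] <- prof[[fld]] + s
    }
    if (!is.null(mods$rel_a1_delta))
      prof$rel_a1 <- min(1, max(0, prof$rel_a1 + mods$rel_a1_delta))
  }
  retained <- effect$beta_modulation_retained
  if (!is.null(retained)) {
    beta <- wt_profile_table()$beta_effects
    for (flag in names(retained)) {
      if (isTRUE(retained[[flag]])) next
      comp <- beta$components[[flag]]
      if (is.null(comp))
        stop("unknown beta-modulation flag: ", flag)
      applies <- configuration %in% unlist(comp$configurations)
      if (!applies) next
      if (!is.null(comp$mult)) prof[[comp$field]] <- prof[[comp$field]] / comp$mult
      if (!is.null(comp$shift)) prof[[comp$field]] <- prof[[comp$field]] - comp$shift
    }
  }
  validate_profile(prof)
  structure(prof, class = "biophysical_profile")
}
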