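#' Voltage-clamp stimulation protocols
#'
#' A `VoltageProtocol` is an ordered sequence of constant-voltage epochs
#' sampled at a fixed interval. Four protocol kinds cover the standard
#' characterization of A-type currents:
#'
#' * `IV_FAMILY` - depolarizing test pulses from a hyperpolarized holding
#'   potential, one sweep per test voltage, for conductance-voltage analysis.
#' * `DECAY` - a single prolonged depolarizing step (default 2.5 s at
#'   +40 mV) for macroscopic inactivation kinetics.
#' * `RECOVERY` - a double-pulse paradigm: a long control pulse and a brief
#'   test pulse to the same voltage separated by a variable-duration
#'   interpulse at a hyperpolarized potential.
#' * `SSI` - brief control and test pulses separated by a long conditioning
#'   epoch at graded voltages, for steady-state inactivation.
#'
#' @name protocols
NULL

PROTOCOL_LABELS <- c("IV_FAMILY", "DECAY", "RECOVERY", "SSI")

#' Create one protocol epoch
#'
#' @param voltage Command potential (mV), within \[-120, +80\].
#' @param duration Epoch duration (ms), > 0. Epochs are half-open
#'   `[start, end)` on the time axis.
#' @param role Free-text role tag used by downstream feature extraction:
#'   one of `"holding"`, `"control"`, `"test"`, `"interpulse"`,
#'   `"conditioning"`.
#' @return A `protocol_epoch` object.
#' @export
protocol_epoch <- function(voltage, duration, role = "test") {
  stopifnot(is.numeric(voltage), length(voltage) == 1L,
            is.numeric(duration), length(duration) == 1L)
  if (!is.finite(duration) || duration <= 0)
    stop("epoch duration must be positive, got ", duration)
  if (voltage < -120 || voltage > 80)
    stop("epoch voltage must lie in [-120, +80] mV, got ", voltage)
  structure(list(voltage = voltage, duration = duration, role = role),
            class = "protocol_epoch")
}

#' Assemble a voltage protocol from epochs
#'
#' @param epochs List of [protocol_epoch()] objects (at least 2).
#' @param sample_interval Sampling interval (ms); every epoch duration must
#'   be an integer multiple of it.
#' @param label Protocol kind, one of `IV_FAMILY`, `DECAY`, `RECOVERY`, `SSI`.
#' @param sweep_value Scalar annotation identifying the sweep within a
#'   family (test voltage for IV, conditioning voltage for SSI, interpulse
#'   duration for RECOVERY).
#' @return A `voltage_protocol` object.
#' @export
voltage_protocol <- function(epochs, sample_interval, label,
                             sweep_value = NA_real_) {
  label <- match.arg(label, PROTOCOL_LABELS)
  if (length(epochs) < 2L) stop("a protocol needs at least 2 epochs")
  stopifnot(all(vapply(epochs, inherits, logical(1), "protocol_epoch")))
  if (sample_interval <= 0) stop("sample_interval must be positive")
  durs <- vapply(epochs, `[[`, numeric(1), "duration")
  n_per <- durs / sample_interval
  if (any(abs(n_per - round(n_per)) > 1e-8))
    stop("every epoch duration must be an integer multiple of sample_interval")
  if (label == "RECOVERY") {
    roles <- vapply(epochs, `[[`, character(1), "role")
    volts <- vapply(epochs, `[[`, numeric(1), "voltage")
    ctl <- which(roles == "control")
    tst <- which(roles == "test")
    itp <- which(roles == "interpulse")
    if (length(ctl) != 1L || length(tst) != 1L || length(itp) != 1L ||
        itp != ctl + 1L || tst != itp + 1L ||
        abs(volts[ctl] - volts[tst]) > 1e-9)
      stop("RECOVERY protocols need control and test epochs at the same ",
           "voltage separated by exactly one interpulse epoch")
  }
  structure(list(epochs = epochs, sample_interval = sample_interval,
                 label = label, sweep_value = sweep_value),
            class = "voltage_protocol")
}

#' Total duration and sample count of a protocol
#' @param protocol A `voltage_protocol`.
#' @return Duration in ms / number of samples.
#' @export
protocol_duration <- function(protocol) {
  sum(vapply(protocol$epochs, `[[`, numeric(1), "duration"))
}

#' @rdname protocol_duration
#' @export
protocol_n_samples <- function(protocol) {
  as.integer(round(protocol_duration(protocol) / protocol$sample_interval))
}

#' Build the standard stimulation protocols
#'
#' Constructs the sweep (or sweep family) for one of the four protocol
#' kinds with the defaults used throughout the package:
#'
#' * `IV_FAMILY`: 15 test pulses, -80 to +60 mV in 10 mV increments,
#'   500 ms long, from a -100 mV holding epoch.
#' * `DECAY`: one 2.5 s step to +40 mV from -100 mV.
#' * `RECOVERY`: a 500 ms control pulse and a 25 ms test pulse to +40 mV
#'   separated by a -100 mV interpulse whose duration sweeps a
#'   log-spaced grid (default 1-3000 ms, 12 points; durations are rounded
#'   to the sample grid).
#' * `SSI`: 25 ms control and test pulses to +40 mV separated by a 10 s
#'   conditioning epoch, 11 sweeps with conditioning voltages -100 to 0 mV
#'   in 10 mV increments.
#'
#' @param label Protocol kind.
#' @param params Optional overrides: `holding_mV`, `test_mV`, `v_from`,
#'   `v_to`, `v_step` (IV/SSI voltage grids), `test_ms`, `control_ms`,
#'   `conditioning_ms`, `holding_ms`, `decay_ms`, `dt_grid_ms` (RECOVERY
#'   interpulse durations), `interpulse_mV`, `sample_interval`.
#' @return A single `voltage_protocol` for `DECAY`; a list of sweeps for
#'   the family protocols.
#' @export
build_protocol <- function(label, params = list()) {
  label <- match.arg(label, PROTOCOL_LABELS)
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  holding <- p("holding_mV", -100)
  holding_ms <- p("holding_ms", 50)
  switch(label,
    IV_FAMILY = {
      dt <- p("sample_interval", 0.5)
      volts <- seq(p("v_from", -80), p("v_to", 60), by = p("v_step", 10))
      test_ms <- p("test_ms", 500)
      lapply(volts, function(v)
        voltage_protocol(list(protocol_epoch(holding, holding_ms, "holding"),
                              protocol_epoch(v, test_ms, "test")),
                         dt, "IV_FAMILY", sweep_value = v))
    },
    DECAY = {
      dt <- p("sample_interval", 0.5)
      voltage_protocol(list(protocol_epoch(holding, holding_ms, "holding"),
                            protocol_epoch(p("test_mV", 40),
                                           p("decay_ms", 2500), "test")),
                       dt, "DECAY", sweep_value = p("test_mV", 40))
    },
    RECOVERY = {
      dt <- p("sample_interval", 0.5)
      grid <- p("dt_grid_ms",
                10 ^ seq(log10(1), log10(3000), length.out = 12))
      if (any(grid <= 0)) stop("interpulse durations must be positive")
      grid <- pmax(round(grid / dt), 1) * dt
      test_mV <- p("test_mV", 40)
      lapply(grid, function(d)
        voltage_protocol(list(protocol_epoch(holding, holding_ms, "holding"),
                              protocol_epoch(test_mV, p("control_ms", 500),
                                             "control"),
                              protocol_epoch(p("interpulse_mV", -100), d,
                                             "interpulse"),
                              protocol_epoch(test_mV, p("test_ms", 25),
                                             "test")),
                         dt, "RECOVERY", sweep_value = d))
    },
    SSI = {
      dt <- p("sample_interval", 0.5)
      volts <- seq(p("v_from", -100), p("v_to", 0), by = p("v_step", 10))
      lapply(volts, function(v)
        voltage_protocol(list(protocol_epoch(holding, holding_ms, "holding"),
                              protocol_epoch(p("test_mV", 40),
                                             p("control_ms", 25), "control"),
                              protocol_epoch(v, p("conditioning_ms", 10000),
                                             "conditioning"),
                              protocol_epoch(p("test_mV", 40),
                                             p("test_ms", 25), "test")),
                         dt, "SSI", sweep_value = v))
    })
}

#' Voltage command as a function of time
#'
#' @param protocol A `voltage_protocol`.
#' @return data.frame with `time_ms` (sample times, epoch-aligned, starting
#'   at 0) and `voltage_mV`.
#' @export
protocol_command <- function(protocol) {
  durs <- vapply(protocol$epochs, `[[`, numeric(1), "duration")
  volts <- vapply(protocol$epochs, `[[`, numeric(1), "voltage")
  n_per <- as.integer(round(durs / protocol$sample_interval))
  data.frame(
    time_ms = seq(0, by = protocol$sample_interval, length.out = sum(n_per)),
    voltage_mV = rep(volts, times = n_per))
}
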