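#' Uniformly sampled waveform
#'
#' Container for a uniformly sampled coil voltage or coil current trace.
#' Time is measured in microseconds throughout the package; voltages in
#' volts and currents in amperes.
#'
#' @param samples Numeric vector of amplitude values (at least 64, all
#'   finite). A current waveform must start at 0 A.
#' @param dt Sampling step in microseconds (strictly positive).
#' @param kind Either `"voltage"` or `"current"`.
#' @param label Free-text description carried along for plots and file
#'   headers.
#'
#' @return An object of class `sampled_waveform`: a list with fields
#'   `samples`, `dt`, `kind`, `label`.
#' @export
sampled_waveform <- function(samples, dt, kind = c("voltage", "current"),
                             label = "") {
  kind <- match.arg(kind)
  samples <- as.numeric(samples)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("`dt` must be a single positive number (microseconds)")
  if (length(samples) < 64L)
    stop("a sampled_waveform needs at least 64 samples")
  if (!all(is.finite(samples)))
    stop("all samples must be finite")
  if (kind == "current" && abs(samples[1L]) > 1e-12)
    stop("a current waveform must start at 0 A")
  structure(list(samples = samples, dt = dt, kind = kind,
                 label = as.character(label)[1L]),
            class = "sampled_waveform")
}

#' @export
print.sampled_waveform <- function(x, ...) {
  cat(sprintf("<sampled_waveform: %s, %d samples, dt = %g us, span %g us>\n",
              x$kind, length(x$samples), x$dt,
              (length(x$samples) - 1L) * x$dt))
  if (nzchar(x$label)) cat(" label:", x$label, "\n")
  cat(sprintf(" range: [%.4g, %.4g] %s\n", min(x$samples), max(x$samples),
              if (x$kind == "voltage") "V" else "A"))
  invisible(x)
}

#' Time axis of a waveform
#'
#' @param wave A [sampled_waveform()].
#' @return Numeric vector of sample times in microseconds, starting at 0.
#' @export
waveform_time <- function(wave) {
  stopifnot(inherits(wave, "sampled_waveform"))
  (seq_along(wave$samples) - 1) * wave$dt
}

#' Stimulator circuit configuration
#'
#' Circuit constants of the capacitor-discharge monophasic stimulator.
#' The discharge loop is a series RLC circuit (storage capacitor, coil
#' inductance and coil resistance); once the capacitor voltage reaches
#' zero the coil current freewheels through a clamp path whose *total*
#' loop resistance (coil resistance included) is `freewheel_resistance`,
#' so the tail decay time constant is exactly L / R_fw.
#'
#' Defaults correspond to a Magstim 200^2-class device; the capacitance
#' is set so the dominant spectral component of the full-output pulse
#' falls near 2.46 kHz (see the methods vignette).
#'
#' @param capacitance Storage capacitance in microfarads.
#' @param inductance Coil inductance in microhenries.
#' @param coil_resistance Series loop resistance in ohms.
#' @param initial_voltage Capacitor charge voltage in volts (<= 2800).
#' @param freewheel_resistance Total resistance of the freewheel decay
#'   loop in ohms.
#' @return A `device_config` list.
#' @export
device_config <- function(capacitance = 150,
                          inductance = 16.35,
                          coil_resistance = 0.08,
                          initial_voltage = 2800,
                          freewheel_resistance = 16.35 / 110) {
  cfg <- list(capacitance = capacitance, inductance = inductance,
              coil_resistance = coil_resistance,
              initial_voltage = initial_voltage,
              freewheel_resistance = freewheel_resistance)
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("device_config field `%s` must be a single positive number", nm))
  }
  if (initial_voltage > 2800)
    stop("initial_voltage exceeds the 2800 V device bound")
  class(cfg) <- "device_config"
  cfg
}

#' Five-level PWM modulator configuration
#'
#' Two cascaded H-bridge cells, each with DC-link voltage V, give the
#' output level alphabet \{-2V, -V, 0, +V, +2V\}. The default switching
#' frequency of 32 kHz is 13 times the ~2.46 kHz dominant component of
#' the monophasic target pulse.
#'
#' @param n_levels Number of output levels; must be 5 (2 cells).
#' @param dc_link_voltage Per-cell DC-link voltage in volts
#'   (2 * dc_link_voltage <= 1600).
#' @param switching_frequency Switching frequency in kilohertz.
#' @param pulse_duration Nominal modulated pulse duration in microseconds
#'   (the modulator extends it to a whole number of switching periods).
#' @param placement Pulse placement within each switching period:
#'   `"centered"` (default, symmetric double-edge modulation) or
#'   `"leading-edge"`.
#' @return A `pwm_config` list.
#' @export
pwm_config <- function(n_levels = 5,
                       dc_link_voltage = 800,
                       switching_frequency = 32,
                       pulse_duration = 1200,
                       placement = c("centered", "leading-edge")) {
  placement <- match.arg(placement)
  if (n_levels != 5L)
    stop("only the five-level (two-cell) topology is supported")
  if (2 * dc_link_voltage > 1600)
    stop("2 * dc_link_voltage exceeds the 1600 V device maximum")
  if (dc_link_voltage <= 0 || switching_frequency <= 0 || pulse_duration <= 0)
    stop("pwm_config values must be positive")
  structure(list(n_levels = 5L, dc_link_voltage = dc_link_voltage,
                 switching_frequency = switching_frequency,
                 pulse_duration = pulse_duration, placement = placement),
            class = "pwm_config")
}

#' Synthesize the conventional monophasic coil pulse
#'
#' Analytic two-phase solution of the capacitor-discharge circuit. Phase
#' one is the underdamped series-RLC discharge, which runs until the
#' capacitor (= coil terminal) voltage first crosses zero, just after the
#' coil current peak. Phase two is the exponential freewheel decay of the
#' coil current with time constant L / R_fw; during it the coil terminal
#' voltage equals (R - R_fw) * i(t), the shallow negative tail seen on
#' monophasic stimulators.
#'
#' @param config A [device_config()].
#' @param dt Sampling step in microseconds (<= 1; must resolve the rise).
#' @param lead_in Zero-padding before the pulse onset, microseconds.
#' @param n_decay_tau Tail length in freewheel time constants (>= 5).
#' @return List with elements `voltage` and `current`, both
#'   [sampled_waveform()]s on the same time grid.
#' @export
synth_magstim_monophasic <- function(config = device_config(), dt = 0.125,
                                     lead_in = 50, n_decay_tau = 6) {
  stopifnot(inherits(config, "device_config"))
  if (dt > 1) stop("dt must be <= 1 microsecond")
  if (n_decay_tau < 5) stop("tail must cover at least 5 decay time constants")
  L <- config$inductance; C <- config$capacitance
  R <- config$coil_resistance; V0 <- config$initial_voltage
  if (R^2 >= 4 * L / C)
    stop(sprintf(paste0("overdamped circuit: R^2 = %.4g >= 4L/C = %.4g; ",
                        "the monophasic model requires an underdamped discharge"),
                 R^2, 4 * L / C))
  alpha <- R / (2 * L)                 # 1/us
  omega <- sqrt(1 / (L * C) - alpha^2) # rad/us
  # end of phase 1: first zero of the capacitor voltage
  t_switch <- (pi - atan(omega / alpha)) / omega
  if (t_switch / dt < 50)
    stop("dt too coarse to resolve the discharge rise; decrease dt")
  tau_fw <- L / config$freewheel_resistance
  dur <- t_switch + n_decay_tau * tau_fw
  n_lead <- round(lead_in / dt)
  t <- seq(0, dur, by = dt)
  i1 <- V0 / (omega * L) * exp(-alpha * t) * sin(omega * t)
  v1 <- V0 * exp(-alpha * t) * (cos(omega * t) + alpha / omega * sin(omega * t))
  ph2 <- t > t_switch
  i_sw <- V0 / (omega * L) * exp(-alpha * t_switch) * sin(omega * t_switch)
  i <- ifelse(ph2, i_sw * exp(-(t - t_switch) / tau_fw), i1)
  v <- ifelse(ph2, (R - config$freewheel_resistance) * i, v1)
  pad <- numeric(n_lead)
  list(
    voltage = sampled_waveform(c(pad, v), dt, "voltage",
                               label = "monophasic coil voltage"),
    current = sampled_waveform(c(pad, i), dt, "current",
                               label = "monophasic coil current")
  )
}

pwm_levels <- function(pwm) pwm$dc_link_voltage * (-2:2)

#' Approximate a voltage target with five-level PWM
#'
#' Regular-sampled modulation: each switching period gets the pair of
#' adjacent levels that brackets the period-averaged target, with the
#' duty cycle chosen so the plan's volt-second integral over the period
#' equals the target's exactly (for targets within the level range).
#' Targets beyond the extreme levels saturate with a warning.
#'
#' The switching plan stores the exact (continuous) duty cycles; the
#' returned sampled waveform renders the plan on the target's time grid
#' with edges snapped to the nearest sample, so it takes only the five
#' permitted levels.
#'
#' @param target A voltage [sampled_waveform()] to approximate.
#' @param pwm A [pwm_config()]. The switching period must be an integer
#'   multiple of the target's `dt`.
#' @return List with `plan` (data frame: one row per switching period
#'   with `t_start`, `t_end`, `level_lo`, `level_hi`, `duty`,
#'   `target_avg`), `voltage` (the rendered five-level waveform) and
#'   `saturated_periods` (count).
#' @export
synth_pwm_pulse <- function(target, pwm = pwm_config()) {
  stopifnot(inherits(target, "sampled_waveform"), inherits(pwm, "pwm_config"))
  if (target$kind != "voltage") stop("PWM target must be a voltage waveform")
  period <- 1000 / pwm$switching_frequency   # us
  npp <- period / target$dt
  if (abs(npp - round(npp)) > 1e-9)
    stop("switching period must be an integer multiple of the waveform dt")
  npp <- as.integer(round(npp))
  x <- target$samples
  n_per <- ceiling(length(x) / npp)
  x <- c(x, numeric(n_per * npp - length(x)))
  avg <- colMeans(matrix(x, nrow = npp))
  lv <- pwm_levels(pwm)
  vmax <- lv[5L]
  sat <- sum(avg > vmax | avg < -vmax)
  if (sat > 0) {
    warning(sprintf("%d switching period(s) saturated at the extreme level", sat))
    avg <- pmin(pmax(avg, -vmax), vmax)
  }
  # positive targets that hit a level exactly report duty 1 on that
  # level; zero and negative ones report duty 0 on theirs
  idx <- ifelse(avg > 0,
                findInterval(avg, lv, left.open = TRUE),
                findInterval(avg, lv, rightmost.closed = TRUE))
  idx <- pmin(pmax(idx, 1L), 4L)
  lo <- lv[idx]; hi <- lv[idx + 1L]
  duty <- (avg - lo) / (hi - lo)
  out <- numeric(length(x))
  n_hi <- round(duty * npp)
  lead <- if (pwm$placement == "centered") floor((npp - n_hi) / 2)
          else integer(n_per)
  for (k in seq_len(n_per)) {
    seg <- rep(lo[k], npp)
    if (n_hi[k] > 0) seg[seq.int(lead[k] + 1L, lead[k] + n_hi[k])] <- hi[k]
    out[((k - 1L) * npp + 1L):(k * npp)] <- seg
  }
  plan <- data.frame(
    period = seq_len(n_per),
    t_start = (seq_len(n_per) - 1) * period,
    t_end = seq_len(n_per) * period,
    level_lo = lo, level_hi = hi, duty = duty, target_avg = avg
  )
  list(plan = plan,
       voltage = sampled_waveform(out, target$dt, "voltage",
                                  label = "five-level PWM coil voltage"),
       saturated_periods = sat)
}

#' Volt-second integral of each switching period of a plan
#'
#' Analytic integral of the piecewise-constant planned waveform; used by
#' the volt-second conservation checks.
#'
#' @param plan The `plan` data frame from [synth_pwm_pulse()].
#' @return Numeric vector, one V*us value per switching period.
#' @export
plan_volt_seconds <- function(plan) {
  (plan$duty * plan$level_hi + (1 - plan$duty) * plan$level_lo) *
    (plan$t_end - plan$t_start)
}

#' Derive coil current from coil voltage
#'
#' Fixed-step trapezoidal integration of di/dt = (v - R i) / L at the
#' waveform's own sampling step, with i(0) = 0.
#'
#' @param voltage A voltage [sampled_waveform()].
#' @param config A [device_config()] supplying L and R.
#' @return A current [sampled_waveform()] on the same grid.
#' @export
coil_current_from_voltage <- function(voltage, config = device_config()) {
  stopifnot(inherits(voltage, "sampled_waveform"))
  if (voltage$kind != "voltage") stop("input must be a voltage waveform")
  L <- config$inductance; R <- config$coil_resistance
  dt <- voltage$dt; v <- voltage$samples
  g <- dt * R / (2 * L)
  u <- dt * (v[-length(v)] + v[-1L]) / (2 * L) / (1 + g)
  a <- (1 - g) / (1 + g)
  i <- c(0, as.numeric(stats::filter(u, a, method = "recursive")))
  sampled_waveform(i, dt, "current",
                   label = paste("current from", voltage$label))
}

#' Intensity calibration ratio between two devices
#'
#' Devices are matched on the positive peak coil voltage; the ratio
#' expresses one device's output on the other's percent-of-maximum
#' intensity scale.
#'
#' @param wave_a,wave_b Voltage [sampled_waveform()]s.
#' @return `max(wave_a) / max(wave_b)` over the positive phase.
#' @export
calibrate_intensity_scale <- function(wave_a, wave_b) {
  stopifnot(inherits(wave_a, "sampled_waveform"),
            inherits(wave_b, "sampled_waveform"))
  if (wave_a$kind != "voltage" || wave_b$kind != "voltage")
    stop("both inputs must be voltage waveforms")
  pa <- max(wave_a$samples); pb <- max(wave_b$samples)
  if (pa <= 0 || pb <= 0) stop("both waveforms need a positive voltage peak")
  pa / pb
}

#' Scale a waveform by a constant factor
#'
#' @param wave A [sampled_waveform()].
#' @param k Scale factor.
#' @return The scaled waveform.
#' @export
scale_waveform <- function(wave, k) {
  stopifnot(inherits(wave, "sampled_waveform"))
  sampled_waveform(wave$samples * k, wave$dt, wave$kind, wave$label)
}

#' Write a waveform to a two-column CSV file
#'
#' The file carries a one-line comment header naming kind, units and dt,
#' then `time_us,value` rows printed with 17 significant digits so the
#' round trip through [read_waveform_csv()] is bit exact.
#'
#' @param wave A [sampled_waveform()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_waveform_csv <- function(wave, path) {
  stopifnot(inherits(wave, "sampled_waveform"))
  units <- if (wave$kind == "voltage") "V" else "A"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s units=%s dt_us=%.17g label=%s",
                     wave$kind, units, wave$dt, wave$label), con)
  writeLines("time_us,value", con)
  writeLines(sprintf("%.17g,%.17g", waveform_time(wave), wave$samples), con)
  invisible(path)
}

#' Read a waveform written by [write_waveform_csv()]
#'
#' @param path File path.
#' @return A [sampled_waveform()].
#' @export
read_waveform_csv <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "# kind="))
    stop("not a waveform CSV: missing '# kind=' header line")
  kind <- sub("^# kind=(\\S+).*$", "\\1", hdr)
  dt <- as.numeric(sub("^.*dt_us=(\\S+).*$", "\\1", hdr))
  label <- sub("^.*label=", "", hdr)
  d <- utils::read.csv(path, skip = 1L)
  sampled_waveform(d$value, dt, kind, label)
}
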