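#' Configuration of the synthetic two-device MEP study
#'
#' Generative parameters of a within-subject cohort measured with a
#' conventional monophasic stimulator ("magstim" condition) and its PWM
#' approximation ("ptms" condition). Defaults are calibrated to the
#' reported group statistics of the 12-participant comparison study:
#' conventional-device resting motor threshold (RMT) 41.34 +/- 6.07
#' percent of maximum stimulator output (%MSO), PWM condition about
#' 3 %MSO lower in every participant, device-independent MEP latencies
#' near 22 ms, and input-output (IO) curves whose midpoint slope is
#' identical across devices by construction.
#'
#' `anchor_kappa` is the calibration constant that anchors the response
#' probability: the participant's IO curve evaluated at the true RMT
#' equals `log10(50) - anchor_kappa`, which makes the probability that
#' the *measured* peak-to-peak amplitude reaches the 50 uV criterion
#' equal to one half at the true RMT under the default noise model, so
#' the 5-of-10 staircase estimator is unbiased by design.
#'
#' @param n_participants Cohort size.
#' @param rmt_mean,rmt_sd Conventional-device RMT distribution, %MSO;
#'   truncated to (20, 80).
#' @param rmt_diff_mean,rmt_diff_sd Within-participant RMT difference
#'   (conventional minus PWM), %MSO; truncated to be positive.
#' @param io_floor,io_ceiling Lower/upper asymptotes of the IO sigmoid
#'   on the log10 microvolt scale (shared across devices).
#' @param io_width_mean,io_width_sd Participant IO width parameter
#'   (%MSO); truncated below at 2.
#' @param latency_mean,latency_sd Participant MEP onset latency (ms),
#'   identical across devices.
#' @param latency_trial_sd Trial-to-trial latency jitter (ms).
#' @param trial_log_sd Trial-to-trial MEP variability, SD of log10
#'   amplitude.
#' @param emg_noise_sd Baseline EMG noise SD in microvolts.
#' @param sampling_rate EMG sampling rate in hertz.
#' @param anchor_kappa RMT anchoring constant on the log10 uV scale.
#' @param seed Integer seed making the cohort and all of its sessions
#'   reproducible.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 12,
                          rmt_mean = 41.34, rmt_sd = 6.07,
                          rmt_diff_mean = 3.34, rmt_diff_sd = 1.5,
                          io_floor = 0.7, io_ceiling = 3.3,
                          io_width_mean = 5, io_width_sd = 1,
                          latency_mean = 22, latency_sd = 1.5,
                          latency_trial_sd = 0.5,
                          trial_log_sd = 0.25,
                          emg_noise_sd = 5,
                          sampling_rate = 5000,
                          anchor_kappa = 0.132,
                          seed = 1L) {
  cfg <- as.list(environment())
  sds <- c("rmt_sd", "rmt_diff_sd", "io_width_sd", "latency_sd",
           "latency_trial_sd", "trial_log_sd", "emg_noise_sd")
  if (any(unlist(cfg[sds]) < 0)) stop("standard deviations must be >= 0")
  if (io_ceiling <= io_floor) stop("io_ceiling must exceed io_floor")
  if (n_participants < 1) stop("need at least one participant")
  structure(cfg, class = "cohort_config")
}

rtruncnorm1 <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    if (mean <= lower || mean >= upper)
      stop("degenerate truncation: mean outside the truncation bounds")
    return(rep(mean, n))
  }
  lo <- stats::pnorm(lower, mean, sd); hi <- stats::pnorm(upper, mean, sd)
  if (hi - lo < 1e-12) stop("impossible truncation bounds")
  stats::qnorm(lo + (hi - lo) * stats::runif(n), mean, sd)
}

#' Generate a synthetic participant cohort
#'
#' Draws per-participant true RMTs for both devices (the PWM RMT is the
#' conventional RMT minus a strictly positive difference draw), IO
#' curve parameters with a device-independent midpoint slope, and a
#' device-independent latency. The IO midpoint for each device is
#' placed so that the curve passes through `log10(50) - anchor_kappa`
#' at that device's true RMT; with the default asymptotes this puts the
#' midpoint above the RMT.
#'
#' @param config A [cohort_config()]. Uses `config$seed` unless the
#'   caller has already seeded the session stream (`seed = NULL` in the
#'   config is not supported; pass a seed).
#' @return A `cohort` data frame with one row per participant and the
#'   config attached as attribute `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_participants
  rmt_m <- rtruncnorm1(n, config$rmt_mean, config$rmt_sd, 20, 80)
  diff <- rtruncnorm1(n, config$rmt_diff_mean, config$rmt_diff_sd, 0, Inf)
  rmt_p <- rmt_m - diff
  width <- rtruncnorm1(n, config$io_width_mean, config$io_width_sd, 2, Inf)
  lat <- stats::rnorm(n, config$latency_mean, config$latency_sd)
  frac <- (log10(50) - config$anchor_kappa - config$io_floor) /
    (config$io_ceiling - config$io_floor)
  if (frac <= 0 || frac >= 0.5)
    stop("anchoring requires io_floor < log10(50) - kappa < midpoint level")
  offset <- -stats::qnorm(frac) * width   # midpoint sits above the RMT
  cohort <- data.frame(
    id = seq_len(n),
    rmt_magstim = rmt_m, rmt_ptms = rmt_p,
    io_floor = config$io_floor, io_ceiling = config$io_ceiling,
    io_width = width,
    io_mid_magstim = rmt_m + offset, io_mid_ptms = rmt_p + offset,
    latency = lat
  )
  attr(cohort, "config") <- config
  class(cohort) <- c("cohort", "data.frame")
  cohort
}

#' Evaluate a participant's generating IO curve
#'
#' @param participant One row of a cohort data frame.
#' @param device `"magstim"` or `"ptms"`.
#' @param intensity Intensity in %MSO (Magstim-equivalent scale).
#' @return Median log10 MEP amplitude (uV) at that intensity.
#' @export
io_curve_value <- function(participant, device, intensity) {
  mid <- if (device == "magstim") participant$io_mid_magstim
         else participant$io_mid_ptms
  participant$io_floor +
    (participant$io_ceiling - participant$io_floor) *
    stats::pnorm((intensity - mid) / participant$io_width)
}

#' Simulate a block of stimulation trials
#'
#' Each trial draws a log-normal MEP amplitude from the participant's
#' IO curve plus trial noise, then builds the EMG trace: Gaussian
#' baseline noise over the full window (100 ms pre-stimulus plus the
#' post-stimulus span) with a biphasic wavelet -- two opposed half-sine
#' lobes, 8 ms total width, peak-to-peak equal to the drawn amplitude --
#' inserted at the participant's (jittered) latency.
#'
#' Randomness comes from the current RNG stream; seed upstream for
#' reproducibility.
#'
#' @param participant One cohort row.
#' @param device `"magstim"` or `"ptms"`.
#' @param intensity Stimulation intensity, %MSO in (0, 100].
#' @param n_trials Number of trials.
#' @param config The [cohort_config()] (for noise and sampling
#'   parameters).
#' @param post_ms Post-stimulus window length in ms (default 100).
#' @return A `mep_session` list: `trials` data frame (participant,
#'   device, intensity, interval, true amplitude and latency per trial)
#'   and `traces` matrix (one row per trial, microvolts), with
#'   `sampling_rate` and `pre_ms` fields.
#' @export
simulate_trials <- function(participant, device, intensity, n_trials,
                            config, post_ms = 100) {
  if (intensity <= 0 || intensity > 100)
    stop("intensity must lie in (0, 100] %MSO")
  fs <- config$sampling_rate
  n_pre <- round(0.1 * fs)            # exactly 100 ms pre-stimulus
  n_post <- round(post_ms / 1000 * fs)
  ns <- n_pre + n_post
  y <- io_curve_value(participant, device, intensity) +
    stats::rnorm(n_trials, 0, config$trial_log_sd)
  amp <- 10^y
  lat <- participant$latency +
    stats::rnorm(n_trials, 0, config$latency_trial_sd)
  lat <- pmax(lat, 5)
  traces <- matrix(stats::rnorm(n_trials * ns, 0, config$emg_noise_sd),
                   nrow = n_trials)
  w_n <- round(0.008 * fs)            # 8 ms wavelet support
  shape <- sin(2 * pi * seq_len(w_n) / w_n)
  for (j in seq_len(n_trials)) {
    i0 <- n_pre + round(lat[j] / 1000 * fs)
    idx <- i0 + seq_len(w_n)
    idx <- idx[idx <= ns]
    traces[j, idx] <- traces[j, idx] + amp[j] / 2 * shape[seq_along(idx)]
  }
  trials <- data.frame(
    participant = participant$id, device = device, intensity = intensity,
    interval = stats::runif(n_trials, 4.25, 6),
    true_amplitude = amp, true_latency = lat
  )
  structure(list(trials = trials, traces = traces,
                 sampling_rate = fs, pre_ms = 100),
            class = "mep_session")
}

bind_sessions <- function(sessions) {
  stopifnot(length(sessions) > 0)
  out <- sessions[[1L]]
  if (length(sessions) > 1L) {
    out$trials <- do.call(rbind, lapply(sessions, `[[`, "trials"))
    out$traces <- do.call(rbind, lapply(sessions, `[[`, "traces"))
  }
  rownames(out$trials) <- NULL
  out
}

#' Simulate a resting-motor-threshold session
#'
#' Applies the shared 5-of-10 staircase protocol (see
#' [determine_rmt()]): blocks of 10 pulses per intensity, stepping down
#' after a block with at least 5 measured responses of >= 50 uV
#' peak-to-peak and up otherwise, terminating at the lowest intensity
#' with >= 5/10 whose next-lower visited intensity scored < 5/10.
#' Responses are scored with [measure_peak_to_peak()], exactly as the
#' analysis side does.
#'
#' @param participant One cohort row.
#' @param device `"magstim"` or `"ptms"`.
#' @param config The [cohort_config()].
#' @param start Starting intensity; default is the participant's true
#'   RMT rounded to the nearest %MSO plus 5 (a hotspot-phase estimate).
#' @param step Staircase step, %MSO (default 1).
#' @param max_blocks Abort with an error beyond this many blocks.
#' @return A `mep_session` with an extra `blocks` data frame
#'   (block, intensity, successes) and the protocol's `rmt`.
#' @export
generate_rmt_session <- function(participant, device, config,
                                 start = NULL, step = 1, max_blocks = 30) {
  if (is.null(start)) {
    true_rmt <- if (device == "magstim") participant$rmt_magstim
                else participant$rmt_ptms
    start <- round(true_rmt) + 5
  }
  sessions <- list()
  respond <- function(intensity) {
    s <- simulate_trials(participant, device, intensity, 10, config)
    sessions[[length(sessions) + 1L]] <<- s
    m <- measure_session(s, latency = FALSE)
    sum(m$p2p >= 50)
  }
  st <- rmt_staircase(start, respond, step = step, max_blocks = max_blocks)
  out <- bind_sessions(sessions)
  out$trials$block <- rep(seq_len(nrow(st$blocks)), each = 10)
  out$blocks <- st$blocks
  out$rmt <- st$rmt
  out
}

#' Simulate an input-output curve session
#'
#' Fifteen MEPs at each intensity, intensities ascending in fixed steps
#' of 3 %MSO from `start` up to `max_intensity` (the highest
#' Magstim-equivalent intensity the PWM device reaches).
#'
#' @param participant One cohort row.
#' @param device `"magstim"` or `"ptms"`.
#' @param config The [cohort_config()].
#' @param start First intensity, %MSO.
#' @param step Intensity step, %MSO (default 3).
#' @param max_intensity Last intensity not exceeded, %MSO (default 57,
#'   the 1600 V PWM ceiling on the 2800 V conventional scale).
#' @param n_per_intensity Trials per intensity (default 15).
#' @return A `mep_session`.
#' @export
generate_io_session <- function(participant, device, config,
                                start = 32, step = 3, max_intensity = 57,
                                n_per_intensity = 15) {
  intens <- seq(start, max_intensity, by = step)
  if (length(intens) < 4) stop("IO session needs at least 4 intensities")
  bind_sessions(lapply(intens, function(x)
    simulate_trials(participant, device, x, n_per_intensity, config)))
}

#' Write a session to a pair of CSV files
#'
#' `path_trials` gets one row per trial (participant, device,
#' intensity, interval); `path_traces` gets the long-format traces
#' (trial id, time_ms relative to the stimulus, amplitude_uv).
#'
#' @param session A `mep_session`.
#' @param path_trials,path_traces Output paths.
#' @return Invisibly, the two paths.
#' @export
write_session_csv <- function(session, path_trials, path_traces) {
  tr <- session$trials
  tr$trial <- seq_len(nrow(tr))
  utils::write.csv(tr[, c("trial", "participant", "device", "intensity",
                          "interval")],
                   path_trials, row.names = FALSE)
  ns <- ncol(session$traces)
  t_ms <- (seq_len(ns) - 1) * 1000 / session$sampling_rate - session$pre_ms
  long <- data.frame(
    trial = rep(seq_len(nrow(session$traces)), each = ns),
    time_ms = rep(t_ms, nrow(session$traces)),
    amplitude_uv = as.vector(t(session$traces))
  )
  utils::write.csv(long, path_traces, row.names = FALSE)
  invisible(c(path_trials, path_traces))
}

#' Read a session written by [write_session_csv()]
#'
#' @param path_trials,path_traces Paths of the trial table and trace
#'   table.
#' @param sampling_rate,pre_ms Sampling rate (Hz) and pre-stimulus span
#'   (ms) of the stored traces.
#' @return A `mep_session`.
#' @export
read_session_csv <- function(path_trials, path_traces,
                             sampling_rate = 5000, pre_ms = 100) {
  trials <- utils::read.csv(path_trials)
  long <- utils::read.csv(path_traces)
  ids <- unique(long$trial)
  traces <- t(vapply(ids, function(i) long$amplitude_uv[long$trial == i],
                     numeric(sum(long$trial == ids[1L]))))
  structure(list(trials = trials[order(trials$trial), ], traces = traces,
                 sampling_rate = sampling_rate, pre_ms = pre_ms),
            class = "mep_session")
}
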