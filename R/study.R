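#' Run one synthetic two-device MEP study end to end
#'
#' Generates the cohort, simulates the staircase threshold session and
#' (optionally) the IO session for every participant under both
#' devices, runs the analysis pipeline (threshold re-derivation, IO
#' sigmoid fits, latency binning), and computes the study-level
#' repeated-measures statistics. Everything is driven by
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @param include_io Simulate and analyse IO sessions as well as the
#'   threshold sessions (default TRUE).
#' @param keep_sessions Keep the raw simulated sessions in the result
#'   (default FALSE; they are large).
#' @return A `study_result`: list with `cohort`, `participants` (per
#'   participant and device: estimated RMT, true RMT, IO fit
#'   parameters), `latency_bins`, and `stats` (see
#'   [study_statistics()]).
#' @export
run_study <- function(config = cohort_config(), include_io = TRUE,
                      keep_sessions = FALSE) {
  cohort <- generate_cohort(config)   # seeds the stream
  devices <- c("magstim", "ptms")
  rows <- list(); meas_io <- list(); sessions <- list()
  for (i in seq_len(nrow(cohort))) {
    p <- cohort[i, ]
    for (dev in devices) {
      rmt_sess <- generate_rmt_session(p, dev, config)
      est <- determine_rmt(rmt_sess)
      row <- data.frame(participant = p$id, device = dev,
                        rmt_true = if (dev == "magstim") p$rmt_magstim
                                   else p$rmt_ptms,
                        rmt_est = est$rmt,
                        n_blocks = nrow(est$blocks))
      if (include_io) {
        io_sess <- generate_io_session(p, dev, config)
        m <- measure_session(io_sess)
        fit <- fit_io_curve(m$intensity, log10(m$p2p_floored))
        row$io_floor <- fit$floor; row$io_ceiling <- fit$ceiling
        row$io_midpoint <- fit$midpoint; row$io_width <- fit$width
        row$io_slope <- fit$midpoint_slope
        row$io_converged <- fit$converged
        meas_io[[paste(p$id, dev)]] <- m
        if (keep_sessions) sessions[[paste(p$id, dev, "io")]] <- io_sess
      }
      if (keep_sessions) sessions[[paste(p$id, dev, "rmt")]] <- rmt_sess
      rows[[paste(p$id, dev)]] <- row
    }
  }
  participants <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  latency_bins <- if (include_io)
    latency_by_amplitude(do.call(rbind, meas_io)) else NULL
  res <- structure(list(cohort = cohort, participants = participants,
                        latency_bins = latency_bins,
                        config = config,
                        sessions = if (keep_sessions) sessions else NULL),
                   class = "study_result")
  res$stats <- study_statistics(res)
  res
}

#' Study-level repeated-measures statistics
#'
#' The reported outcomes: the device effect on the estimated RMT
#' (two-level within-subject ANOVA plus Cohen's d in both variants),
#' the device effect on the fitted IO midpoint slopes, and the device
#' effect on mean MEP latency in each amplitude bin.
#'
#' @param res A `study_result` (the `stats` field is ignored).
#' @return List with `rmt` (F, df, p, d_pooled, d_difference, group
#'   means/SDs), `io_slope` (F, df, p or NULL) and `latency` (list per
#'   amplitude target).
#' @export
study_statistics <- function(res) {
  d <- res$participants
  w <- stats::reshape(d[, c("participant", "device", "rmt_est")],
                      idvar = "participant", timevar = "device",
                      direction = "wide")
  an <- rm_anova_two_level(d$rmt_est, d$device, d$participant)
  rmt <- c(an, list(
    d_pooled = cohens_d(w$rmt_est.magstim, w$rmt_est.ptms, "pooled"),
    d_difference = cohens_d(w$rmt_est.magstim, w$rmt_est.ptms, "difference"),
    mean_magstim = mean(w$rmt_est.magstim), sd_magstim = stats::sd(w$rmt_est.magstim),
    mean_ptms = mean(w$rmt_est.ptms), sd_ptms = stats::sd(w$rmt_est.ptms),
    mean_difference = mean(w$rmt_est.magstim - w$rmt_est.ptms)))
  io <- NULL
  if (!is.null(d$io_slope)) {
    ok <- d$io_converged
    dd <- d[ok, ]
    io <- rm_anova_two_level(dd$io_slope, dd$device, dd$participant)
  }
  lat <- NULL
  if (!is.null(res$latency_bins)) {
    lat <- lapply(split(res$latency_bins, res$latency_bins$target),
                  function(b) tryCatch(
                    rm_anova_two_level(b$mean_latency, b$device, b$participant),
                    error = function(e) NULL))
  }
  list(rmt = rmt, io_slope = io, latency = lat)
}

#' @export
print.study_result <- function(x, ...) {
  s <- x$stats
  cat("<study_result>\n")
  cat(sprintf(" RMT: magstim %.2f +/- %.2f, ptms %.2f +/- %.2f %%MSO\n",
              s$rmt$mean_magstim, s$rmt$sd_magstim,
              s$rmt$mean_ptms, s$rmt$sd_ptms))
  cat(sprintf(" device effect on RMT: F(%d,%d) = %.2f, p = %.2g, d = %.2f\n",
              s$rmt$df1, s$rmt$df2, s$rmt$F, s$rmt$p, s$rmt$d_pooled))
  if (!is.null(s$io_slope))
    cat(sprintf(" IO midpoint slope: F(%d,%d) = %.2f, p = %.2f\n",
                s$io_slope$df1, s$io_slope$df2, s$io_slope$F, s$io_slope$p))
  for (tg in names(s$latency))
    if (!is.null(s$latency[[tg]]))
      cat(sprintf(" latency @ %s uV: F(%d,%d) = %.2f, p = %.2f\n", tg,
                  s$latency[[tg]]$df1, s$latency[[tg]]$df2,
                  s$latency[[tg]]$F, s$latency[[tg]]$p))
  invisible(x)
}

#' Replicate the synthetic study across seeds
#'
#' Runs [run_study()] once per seed and aggregates the quantities the
#' study design is judged on: grand-mean estimated RMTs per device,
#' the mean within-participant RMT difference, and the fraction of
#' replications in which each ANOVA reaches (or avoids) significance.
#'
#' @param n_replications Number of seeded replications (default 20).
#' @param base_seed Seeds are `base_seed * 1000 + 1:n_replications`.
#' @param config Template [cohort_config()]; its seed is overridden.
#' @param include_io Include the IO/latency pipeline (default TRUE).
#' @return A `study_replicates` list: `per_rep` data frame and grand
#'   summaries.
#' @export
replicate_study <- function(n_replications = 20, base_seed = 1,
                            config = cohort_config(), include_io = TRUE) {
  reps <- lapply(seq_len(n_replications), function(r) {
    cfg <- config
    cfg$seed <- base_seed * 1000 + r
    res <- run_study(cfg, include_io = include_io)
    s <- res$stats
    data.frame(
      seed = cfg$seed,
      mean_rmt_magstim = s$rmt$mean_magstim,
      mean_rmt_ptms = s$rmt$mean_ptms,
      mean_diff = s$rmt$mean_difference,
      rmt_p = s$rmt$p,
      d_pooled = s$rmt$d_pooled,
      io_slope_p = if (!is.null(s$io_slope)) s$io_slope$p else NA_real_,
      lat50_p = stat_or_na(s$latency, "50"),
      lat500_p = stat_or_na(s$latency, "500"),
      lat1000_p = stat_or_na(s$latency, "1000"),
      all_lower_true = all(res$cohort$rmt_ptms < res$cohort$rmt_magstim)
    )
  })
  per_rep <- do.call(rbind, reps)
  structure(list(
    per_rep = per_rep,
    grand_mean_rmt_magstim = mean(per_rep$mean_rmt_magstim),
    grand_mean_rmt_ptms = mean(per_rep$mean_rmt_ptms),
    grand_mean_diff = mean(per_rep$mean_diff),
    frac_rmt_significant = mean(per_rep$rmt_p < 0.01),
    frac_io_nonsig = mean(per_rep$io_slope_p > 0.05, na.rm = TRUE),
    frac_lat_nonsig = c(`50` = mean(per_rep$lat50_p > 0.05, na.rm = TRUE),
                        `500` = mean(per_rep$lat500_p > 0.05, na.rm = TRUE),
                        `1000` = mean(per_rep$lat1000_p > 0.05, na.rm = TRUE))),
    class = "study_replicates")
}

stat_or_na <- function(lat, key) {
  if (!is.null(lat) && !is.null(lat[[key]])) lat[[key]]$p else NA_real_
}

#' @export
print.study_replicates <- function(x, ...) {
  cat(sprintf(paste0("<study_replicates: %d runs>\n",
                     " grand-mean RMT: magstim %.2f, ptms %.2f, diff %.2f %%MSO\n",
                     " RMT ANOVA p<0.01 in %.0f%%; IO slope p>0.05 in %.0f%%\n",
                     " latency p>0.05 in %.0f/%.0f/%.0f%% (50/500/1000 uV)\n"),
              nrow(x$per_rep), x$grand_mean_rmt_magstim,
              x$grand_mean_rmt_ptms, x$grand_mean_diff,
              100 * x$frac_rmt_significant, 100 * x$frac_io_nonsig,
              100 * x$frac_lat_nonsig[1], 100 * x$frac_lat_nonsig[2],
              100 * x$frac_lat_nonsig[3]))
  invisible(x)
}

#' Default calibrated waveform pair for the threshold comparison
#'
#' Synthesizes the conventional monophasic pulse, scales it to the PWM
#' device's 1600 V positive peak via [calibrate_intensity_scale()],
#' modulates it with the default five-level PWM configuration and
#' derives both coil currents.
#'
#' @param config A [device_config()].
#' @param pwm A [pwm_config()].
#' @param dt Sampling step, microseconds.
#' @return List with `magstim` (voltage, current), `ptms` (plan,
#'   voltage, current), and the intensity `ratio`.
#' @export
default_waveform_pair <- function(config = device_config(),
                                  pwm = pwm_config(), dt = 0.125) {
  wf <- synth_magstim_monophasic(config, dt = dt)
  ratio <- (2 * pwm$dc_link_voltage) / max(wf$voltage$samples)
  v_m <- scale_waveform(wf$voltage, ratio)
  i_m <- scale_waveform(wf$current, ratio)
  pw <- synth_pwm_pulse(v_m, pwm)
  i_p <- coil_current_from_voltage(pw$voltage, config)
  list(magstim = list(voltage = v_m, current = i_m),
       ptms = list(plan = pw$plan, voltage = pw$voltage, current = i_p,
                   saturated_periods = pw$saturated_periods),
       ratio = ratio)
}
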