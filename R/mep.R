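#' Peak-to-peak MEP amplitude of one trace
#'
#' Maximum minus minimum of the EMG trace within a post-stimulus
#' window. Values below 20 uV are floored at 20 uV (the smallest
#' amplitude distinguishable from EMG noise) with a flag; the floor is
#' what the IO fitting consumes.
#'
#' @param trace Numeric EMG vector in microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param pre_ms Pre-stimulus span of the trace in ms.
#' @param window Post-stimulus measurement window in ms (default
#'   c(15, 45)).
#' @param floor_uv Amplitude floor (default 20).
#' @return List with `p2p` (raw, uV), `p2p_floored` and `floored`.
#' @export
measure_peak_to_peak <- function(trace, sampling_rate, pre_ms = 100,
                                 window = c(15, 45), floor_uv = 20) {
  n <- length(trace)
  i0 <- round(pre_ms / 1000 * sampling_rate)
  idx <- (i0 + floor(window[1] / 1000 * sampling_rate) + 1L):
         (i0 + ceiling(window[2] / 1000 * sampling_rate))
  if (idx[1] < 1L || idx[length(idx)] > n)
    stop("measurement window lies outside the trace")
  p2p <- max(trace[idx]) - min(trace[idx])
  list(p2p = p2p, p2p_floored = max(p2p, floor_uv), floored = p2p < floor_uv)
}

#' MEP onset latency of one trace
#'
#' The detection threshold is the mean plus two standard deviations of
#' the rectified 100 ms pre-stimulus segment. The latency is the first
#' post-stimulus time at which the rectified EMG exceeds the threshold
#' continuously for at least `persist_ms` (default 1 ms; set
#' `method = "first"` for the bare first crossing). The detector never
#' reports a latency inside the pre-stimulus window; a trace that never
#' crosses is reported as undetected.
#'
#' @param trace Numeric EMG vector in microvolts.
#' @param sampling_rate Sampling rate in Hz.
#' @param pre_ms Pre-stimulus span in ms (must be >= 100).
#' @param persist_ms Required supra-threshold run length in ms.
#' @param method `"persistent"` (default) or `"first"`.
#' @return List with `latency` (ms after the stimulus, `NA` if
#'   undetected), `detected` and `threshold` (uV).
#' @export
detect_latency <- function(trace, sampling_rate, pre_ms = 100,
                           persist_ms = 1, method = c("persistent", "first")) {
  method <- match.arg(method)
  if (pre_ms < 100) stop("need the full 100 ms pre-stimulus segment")
  n_pre <- round(pre_ms / 1000 * sampling_rate)
  r <- abs(trace)
  base <- r[seq_len(n_pre)]
  thr <- mean(base) + 2 * stats::sd(base)
  post <- r[(n_pre + 1L):length(r)]
  above <- post > thr
  need <- if (method == "first") 1L
          else max(1L, round(persist_ms / 1000 * sampling_rate))
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  hit <- which(runs$values & runs$lengths >= need)
  if (length(hit) == 0L)
    return(list(latency = NA_real_, detected = FALSE, threshold = thr))
  list(latency = (starts[hit[1L]] - 1L) * 1000 / sampling_rate,
       detected = TRUE, threshold = thr)
}

#' Measure every trial of a session
#'
#' @param session A `mep_session`.
#' @param window Post-stimulus measurement window, ms.
#' @param latency Also run the onset latency detector on every trial
#'   (default TRUE; threshold sessions skip it).
#' @return Data frame: one row per trial with participant, device,
#'   intensity, `p2p`, `p2p_floored`, `floored`, and (when requested)
#'   `latency`, `latency_detected`.
#' @export
measure_session <- function(session, window = c(15, 45), latency = TRUE) {
  fs <- session$sampling_rate
  i0 <- round(session$pre_ms / 1000 * fs)
  idx <- (i0 + floor(window[1] / 1000 * fs) + 1L):
         (i0 + ceiling(window[2] / 1000 * fs))
  if (idx[1] < 1L || idx[length(idx)] > ncol(session$traces))
    stop("measurement window lies outside the trace")
  win <- session$traces[, idx, drop = FALSE]
  p2p <- apply(win, 1L, max) - apply(win, 1L, min)
  out <- cbind(session$trials[, c("participant", "device", "intensity")],
               data.frame(p2p = p2p, p2p_floored = pmax(p2p, 20),
                          floored = p2p < 20))
  if (latency) {
    n <- nrow(session$traces)
    lat <- numeric(n); det <- logical(n)
    for (j in seq_len(n)) {
      l <- detect_latency(session$traces[j, ], fs, session$pre_ms)
      lat[j] <- l$latency; det[j] <- l$detected
    }
    out$latency <- lat; out$latency_detected <- det
  }
  out
}

#' 5-of-10 staircase protocol
#'
#' Shared protocol core used both when simulating a threshold session
#' and when re-deriving the threshold from recorded trials. Blocks of
#' 10 pulses are delivered at one intensity; with >= 5 responses the
#' intensity steps down, otherwise up. The protocol terminates at the
#' lowest intensity scoring >= 5/10 whose next-lower visited intensity
#' scored < 5/10 (latest block at each intensity counts; revisits are
#' allowed).
#'
#' @param start Starting intensity, %MSO.
#' @param respond Function of one argument (intensity) returning the
#'   number of successes in a 10-pulse block.
#' @param step Step size, %MSO.
#' @param max_blocks Error out beyond this many blocks.
#' @return List with `rmt` and a `blocks` data frame (block, intensity,
#'   successes).
#' @export
rmt_staircase <- function(start, respond, step = 1, max_blocks = 30) {
  outcome <- list()   # latest successes keyed by intensity
  blocks <- data.frame(block = integer(), intensity = numeric(),
                       successes = integer())
  key <- function(x) sprintf("%.6g", x)
  cur <- start
  for (b in seq_len(max_blocks)) {
    if (cur <= 0 || cur > 100)
      stop("staircase left the (0, 100] %MSO intensity range")
    s <- respond(cur)
    outcome[[key(cur)]] <- s
    blocks <- rbind(blocks,
                    data.frame(block = b, intensity = cur, successes = s))
    vis <- as.numeric(names(outcome))
    succ <- unlist(outcome) >= 5
    cand <- vis[succ & vapply(vis, function(v) {
      j <- match(key(v - step), names(outcome))
      !is.na(j) && unlist(outcome)[j] < 5
    }, logical(1))]
    if (length(cand) > 0)
      return(list(rmt = min(cand), blocks = blocks))
    cur <- if (s >= 5) cur - step else cur + step
  }
  stop("staircase failed to terminate within ", max_blocks, " blocks")
}

#' Re-derive the resting motor threshold from a recorded session
#'
#' Replays the recorded 10-pulse blocks through the staircase
#' termination rule, scoring each trial with [measure_peak_to_peak()]
#' (success: measured peak-to-peak >= 50 uV).
#'
#' @param session A `mep_session` from [generate_rmt_session()] (or any
#'   session whose trials come in consecutive 10-trial blocks of
#'   constant intensity).
#' @param step Staircase step used during acquisition, %MSO.
#' @param window Measurement window, ms.
#' @return An `rmt_estimate`: list with `rmt`, `blocks` (data frame
#'   with per-block intensity and successes) and `intensities`
#'   (visited, with final success counts).
#' @export
determine_rmt <- function(session, step = 1, window = c(15, 45)) {
  m <- measure_session(session, window, latency = FALSE)
  n <- nrow(m)
  if (n %% 10 != 0) stop("trials do not form complete 10-pulse blocks")
  blk <- rep(seq_len(n / 10), each = 10)
  intens <- tapply(m$intensity, blk, function(x) {
    if (length(unique(x)) != 1) stop("intensity varies inside a block")
    x[1]
  })
  succ <- tapply(m$p2p >= 50, blk, sum)
  i <- 0L
  feed <- function(x) { i <<- i + 1L
    if (abs(intens[i] - x) > 1e-9)
      stop("recorded block order is inconsistent with the staircase")
    succ[i] }
  st <- rmt_staircase(intens[1L], feed, step = step,
                      max_blocks = length(intens))
  final <- tapply(succ, intens, function(s) s[length(s)])
  structure(list(rmt = st$rmt, blocks = st$blocks,
                 intensities = data.frame(
                   intensity = as.numeric(names(final)),
                   successes = as.integer(final))),
            class = "rmt_estimate")
}

#' Fit the four-parameter sigmoid IO curve
#'
#' Least-squares fit of y(x) = floor + (ceiling - floor) *
#' Phi((x - midpoint) / width) to log10 peak-to-peak amplitude, with
#' Phi the standard normal CDF (a cumulative-Gaussian sigmoid). The
#' midpoint slope is the derivative of the fitted curve at the
#' midpoint, (ceiling - floor) / (width * sqrt(2 pi)). Fitting uses
#' Levenberg-Marquardt with a small multi-start over width and
#' midpoint initializations.
#'
#' @param intensity Stimulation intensities, %MSO (one entry per
#'   measurement).
#' @param log10_amplitude log10 of the floored peak-to-peak amplitudes
#'   (uV).
#' @return An `io_curve_fit`: list with `floor`, `ceiling`, `midpoint`,
#'   `width`, `midpoint_slope`, `rss`, `converged`.
#' @export
fit_io_curve <- function(intensity, log10_amplitude) {
  x <- as.numeric(intensity); y <- as.numeric(log10_amplitude)
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 4)
    stop("IO fit needs measurements at >= 4 distinct intensities")
  if (stats::sd(y) < 1e-9)
    return(structure(list(floor = NA, ceiling = NA, midpoint = NA,
                          width = NA, midpoint_slope = NA, rss = NA,
                          converged = FALSE,
                          reason = "degenerate data (no amplitude spread)"),
                     class = "io_curve_fit"))
  span <- diff(range(x))
  starts <- expand.grid(mid = stats::quantile(x, c(0.35, 0.5, 0.65),
                                              names = FALSE),
                        wid = span * c(0.15, 0.3, 0.6))
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    fit <- tryCatch(minpack.lm::nlsLM(
      y ~ lo + (hi - lo) * pnorm((x - mid) / wid),
      start = list(lo = min(y), hi = max(y),
                   mid = starts$mid[k], wid = starts$wid[k]),
      lower = c(-Inf, -Inf, min(x) - 10, 1e-3),
      upper = c(Inf, Inf, max(x) + 10, 10 * span),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss)
        best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    return(structure(list(floor = NA, ceiling = NA, midpoint = NA,
                          width = NA, midpoint_slope = NA, rss = NA,
                          converged = FALSE, reason = "no start converged"),
                     class = "io_curve_fit"))
  p <- stats::coef(best$fit)
  if (p["hi"] < p["lo"]) {   # reflect the mirrored solution
    tmp <- p["lo"]; p["lo"] <- p["hi"]; p["hi"] <- tmp
  }
  structure(list(floor = unname(p["lo"]), ceiling = unname(p["hi"]),
                 midpoint = unname(p["mid"]), width = unname(p["wid"]),
                 midpoint_slope =
                   unname((p["hi"] - p["lo"]) / (p["wid"] * sqrt(2 * pi))),
                 rss = best$rss, converged = TRUE),
            class = "io_curve_fit")
}

#' @export
print.io_curve_fit <- function(x, ...) {
  if (!x$converged) { cat("<io_curve_fit: not converged>\n"); return(invisible(x)) }
  cat(sprintf(paste0("<io_curve_fit: floor %.3f, ceiling %.3f, midpoint ",
                     "%.2f %%MSO, width %.2f, slope %.4f log10(uV)/%%MSO>\n"),
              x$floor, x$ceiling, x$midpoint, x$width, x$midpoint_slope))
  invisible(x)
}

#' Two-level repeated-measures ANOVA
#'
#' Within-subject ANOVA for a two-level factor (one value per
#' participant and condition), fitted with `aov` and an error stratum
#' per participant. For two levels the F statistic with (1, n - 1)
#' degrees of freedom equals the square of the paired t statistic.
#'
#' @param value Numeric outcome.
#' @param condition Two-level factor (e.g. device).
#' @param participant Participant identifier; every participant must
#'   appear once per condition.
#' @return List with `F`, `df1`, `df2`, `p`, `n`, `capped` (TRUE when
#'   the difference variance is zero and F is reported as Inf).
#' @export
rm_anova_two_level <- function(value, condition, participant) {
  condition <- factor(condition); participant <- factor(participant)
  if (nlevels(condition) != 2) stop("condition must have exactly two levels")
  tab <- table(participant, condition)
  keep <- rownames(tab)[rowSums(tab == 1) == 2]
  ok <- participant %in% keep
  value <- value[ok]; condition <- droplevels(condition[ok])
  participant <- droplevels(participant[ok])
  n <- nlevels(participant)
  if (n < 3) stop("need complete pairs from at least 3 participants")
  d <- value[order(condition, participant)]
  diffs <- d[1:n] - d[(n + 1):(2 * n)]
  if (stats::sd(diffs) < 1e-12) {
    if (mean(diffs) == 0)
      return(list(F = 0, df1 = 1, df2 = n - 1, p = 1, n = n, capped = FALSE))
    return(list(F = Inf, df1 = 1, df2 = n - 1, p = 0, n = n, capped = TRUE))
  }
  fit <- stats::aov(value ~ condition + Error(participant))
  s <- summary(fit)[["Error: Within"]][[1L]]
  Fv <- s[["F value"]][1L]
  list(F = Fv, df1 = s[["Df"]][1L], df2 = s[["Df"]][2L],
       p = s[["Pr(>F)"]][1L], n = n, capped = FALSE)
}

#' Cohen's d for paired condition means
#'
#' `"pooled"` (default) standardizes the mean difference by
#' sqrt((s1^2 + s2^2) / 2); `"difference"` standardizes by the SD of
#' the within-participant differences.
#'
#' @param a,b Paired numeric vectors (same participants, two
#'   conditions).
#' @param variant `"pooled"` or `"difference"`.
#' @return The effect size.
#' @export
cohens_d <- function(a, b, variant = c("pooled", "difference")) {
  variant <- match.arg(variant)
  stopifnot(length(a) == length(b))
  s <- if (variant == "pooled") sqrt((stats::var(a) + stats::var(b)) / 2)
       else stats::sd(a - b)
  if (!is.finite(s) || s == 0) stop("zero variance: effect size undefined")
  (mean(a) - mean(b)) / s
}

#' Mean MEP latencies in target amplitude bins
#'
#' Trials are binned by measured peak-to-peak amplitude around the
#' 50 uV, 500 uV and 1 mV targets using multiplicative bands
#' (target / band, target * band); per participant, device and bin the
#' mean detected latency is returned for the device comparisons.
#'
#' @param measurements Data frame from [measure_session()] (rows may
#'   pool several sessions).
#' @param targets Amplitude targets in uV.
#' @param band Multiplicative half-band (default 1.5).
#' @return Data frame with participant, device, target, `n` and
#'   `mean_latency`.
#' @export
latency_by_amplitude <- function(measurements, targets = c(50, 500, 1000),
                                 band = 1.5) {
  out <- list()
  m <- measurements[measurements$latency_detected %in% TRUE, , drop = FALSE]
  for (tg in targets) {
    sel <- m[m$p2p >= tg / band & m$p2p <= tg * band, , drop = FALSE]
    if (nrow(sel) == 0) next
    agg <- stats::aggregate(latency ~ participant + device, sel, mean)
    cnt <- stats::aggregate(latency ~ participant + device, sel, length)
    agg$n <- cnt$latency
    agg$target <- tg
    names(agg)[names(agg) == "latency"] <- "mean_latency"
    out[[as.character(tg)]] <- agg
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
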