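test_that("peak-to-peak measurement and the 20 uV floor behave as specified", {
  fs <- 5000
  t <- seq(0, 0.2 - 1 / fs, by = 1 / fs) * 1000   # ms, 100 pre + 100 post
  tone <- ifelse(t >= 100, 40 * sin(2 * pi * (t - 100) / 8), 0)
  m <- measure_peak_to_peak(tone, fs)
  expect_equal(m$p2p, 80, tolerance = 1e-6)
  expect_false(m$floored)

  flat <- numeric(length(t))
  mf <- measure_peak_to_peak(flat, fs)
  expect_equal(mf$p2p_floored, 20)
  expect_true(mf$floored)

  expect_error(measure_peak_to_peak(flat, fs, window = c(90, 120)),
               "outside the trace")
})

test_that("a noiseless generated MEP measures back at its drawn amplitude", {
  cfg <- cohort_config(n_participants = 1, rmt_sd = 0, rmt_diff_sd = 0,
                       io_width_sd = 0, latency_sd = 0, latency_trial_sd = 0,
                       trial_log_sd = 0, emg_noise_sd = 0, seed = 2)
  p <- generate_cohort(cfg)[1, ]
  x <- 53   # noiseless amplitude ~ several hundred uV
  set.seed(1)
  s <- simulate_trials(p, "magstim", x, 1, cfg)
  target <- 10^io_curve_value(p, "magstim", x)
  m <- measure_peak_to_peak(s$traces[1, ], cfg$sampling_rate)
  expect_equal(m$p2p, target, tolerance = 1 / target)  # within 1 uV
})

test_that("latency detection finds a clean onset at the right sample", {
  fs <- 5000
  n <- 0.2 * fs
  tr <- numeric(n)
  tr[(0.1 * fs + 0.022 * fs + 1):n] <- 100   # step 22 ms post-stimulus
  l <- detect_latency(tr, fs)
  expect_true(l$detected)
  expect_equal(l$latency, 22, tolerance = 1 / (fs / 1000) / 22)
})

test_that("latency detection is reliable on realistic MEPs and quiet on noise", {
  fs <- 5000; n <- 0.2 * fs
  set.seed(31)
  hits <- misses <- 0
  w_n <- round(0.008 * fs)
  shape <- 500 * sin(2 * pi * seq_len(w_n) / w_n)   # 1 mV p2p wavelet
  for (k in 1:1000) {
    tr <- rnorm(n, 0, 5)
    i0 <- 0.1 * fs + round(0.020 * fs)
    tr[i0 + seq_len(w_n)] <- tr[i0 + seq_len(w_n)] + shape
    l <- detect_latency(tr, fs)
    if (l$detected && abs(l$latency - 20) <= 1) hits <- hits + 1
  }
  expect_gte(hits / 1000, 0.95)

  for (k in 1:1000) {
    l <- detect_latency(rnorm(n, 0, 5), fs)
    if (!l$detected) misses <- misses + 1
  }
  expect_gte(misses / 1000, 0.95)
})

test_that("the detector never reports a latency inside the pre-stimulus window", {
  fs <- 5000; n <- 0.2 * fs
  w_n <- round(0.008 * fs)
  shape <- 500 * sin(2 * pi * seq_len(w_n) / w_n)
  set.seed(8)
  lat <- replicate(50, {
    # large pre-stimulus artifact plus a clear MEP at 25 ms
    tr <- rnorm(n, 0, 5) + c(rep(30, 40), numeric(n - 40))
    i0 <- 0.1 * fs + round(0.025 * fs)
    tr[i0 + seq_len(w_n)] <- tr[i0 + seq_len(w_n)] + shape
    detect_latency(tr, fs)$latency
  })
  expect_true(all(is.na(lat) | lat >= 0))
  expect_gt(mean(!is.na(lat)), 0.9)
})

test_that("a hard-threshold participant staircases to the exact threshold", {
  respond <- function(x) if (x >= 40) 10L else 0L
  st <- rmt_staircase(45, respond)
  expect_equal(st$rmt, 40)
  # descending visits 45..40, then the failure at 39 terminates
  expect_equal(st$blocks$intensity, 45:39)
})

test_that("staircase outcomes match exact binomial enumeration", {
  p_success <- c(`39` = 0, `40` = 0, `41` = 0.5, `42` = 1, `43` = 1,
                 `44` = 1, `45` = 1)
  exact <- enumerate_staircase(p_success, start = 45)
  expect_equal(sum(exact), 1, tolerance = 1e-9)
  expect_equal(unname(exact["41"]), sum(dbinom(5:10, 10, 0.5)),
               tolerance = 1e-9)

  set.seed(55)
  est <- replicate(500, {
    respond <- function(x) rbinom(1, 10, p_success[[as.character(x)]])
    rmt_staircase(45, respond)$rmt
  })
  expect_true(all(est %in% as.numeric(names(exact))))
  modal <- as.numeric(names(which.max(table(est))))
  exact_modal <- as.numeric(names(which.max(exact)))
  expect_equal(modal, exact_modal)
  expect_equal(mean(est == 41), unname(exact["41"]), tolerance = 0.15)
})

test_that("determine_rmt replays a recorded session to the protocol result", {
  fix <- deterministic_participant(seed = 17)
  set.seed(17)
  s <- generate_rmt_session(fix$participant, "magstim", fix$config)
  est <- determine_rmt(s)
  expect_s3_class(est, "rmt_estimate")
  expect_equal(est$rmt, s$rmt)
  # protocol invariants on the final success counts
  final <- est$intensities
  at <- final$successes[final$intensity == est$rmt]
  below <- final$successes[final$intensity == est$rmt - 1]
  expect_gte(at, 5)
  if (length(below) == 1) expect_lt(below, 5)
})

test_that("noise-free IO data identify the four sigmoid parameters", {
  x <- rep(seq(30, 57, by = 3), each = 15)
  truth <- list(lo = 1.31, hi = 3.12, mid = 44.5, wid = 4.2)
  y <- truth$lo + (truth$hi - truth$lo) * pnorm((x - truth$mid) / truth$wid)
  fit <- fit_io_curve(x, y)
  expect_true(fit$converged)
  expect_equal(fit$floor, truth$lo, tolerance = 1e-4)
  expect_equal(fit$ceiling, truth$hi, tolerance = 1e-4)
  expect_equal(fit$midpoint, truth$mid, tolerance = 1e-4)
  expect_equal(fit$width, truth$wid, tolerance = 1e-4)

  # midpoint slope equals the numerical derivative at the midpoint
  curve <- function(z) fit$floor + (fit$ceiling - fit$floor) *
    pnorm((z - fit$midpoint) / fit$width)
  h <- 1e-4
  num <- (curve(fit$midpoint + h) - curve(fit$midpoint - h)) / (2 * h)
  expect_equal(fit$midpoint_slope, num, tolerance = 1e-6)
})

test_that("the IO fit is equivariant under amplitude shifts", {
  set.seed(42)
  x <- rep(seq(32, 57, by = 3), each = 15)
  y <- 1.3 + 1.8 * pnorm((x - 45) / 5) + rnorm(length(x), 0, 0.1)
  f0 <- fit_io_curve(x, y)
  f1 <- fit_io_curve(x, y + 0.7)
  expect_equal(f1$floor, f0$floor + 0.7, tolerance = 1e-5)
  expect_equal(f1$ceiling, f0$ceiling + 0.7, tolerance = 1e-5)
  expect_equal(f1$midpoint, f0$midpoint, tolerance = 1e-5)
  expect_equal(f1$width, f0$width, tolerance = 1e-5)
  expect_equal(f1$midpoint_slope, f0$midpoint_slope, tolerance = 1e-5)
})

test_that("degenerate IO data are flagged instead of fitted", {
  x <- rep(seq(32, 44, by = 3), each = 15)
  y <- rep(log10(20), length(x))          # everything floored
  fit <- fit_io_curve(x, y)
  expect_false(fit$converged)
  expect_error(fit_io_curve(c(30, 33, 36), c(1, 2, 3)), "4 distinct")
})

test_that("the two-level repeated-measures F equals the squared paired t", {
  set.seed(13)
  for (k in 1:5) {
    n <- sample(6:14, 1)
    a <- rnorm(n, 50, 8); b <- a + rnorm(n, 2, 3)
    an <- rm_anova_two_level(c(a, b), rep(c("x", "y"), each = n),
                             rep(seq_len(n), 2))
    tt <- t.test(a, b, paired = TRUE)
    expect_equal(an$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(an$p, tt$p.value, tolerance = 1e-10)
    expect_equal(an$df1, 1); expect_equal(an$df2, n - 1)
  }
})

test_that("ANOVA edge cases: identical conditions and zero-variance shifts", {
  a <- c(40, 42, 45, 39)
  an0 <- rm_anova_two_level(c(a, a), rep(c("x", "y"), each = 4),
                            rep(1:4, 2))
  expect_equal(an0$F, 0); expect_equal(an0$p, 1)

  an1 <- rm_anova_two_level(c(a, a + 2), rep(c("x", "y"), each = 4),
                            rep(1:4, 2))
  expect_true(an1$capped)
  expect_equal(an1$F, Inf)
})

test_that("Cohen's d variants match their closed forms", {
  set.seed(2)
  std <- function(v) (v - mean(v)) / stats::sd(v)
  # vectors constructed to carry the printed group summaries exactly
  a <- 41.34 + 6.07 * std(rnorm(12))
  b <- 38.00 + 5.91 * std(rnorm(12))
  expect_equal(cohens_d(a, b, "pooled"),
               3.34 / sqrt((6.07^2 + 5.91^2) / 2), tolerance = 1e-9)

  x <- 40 + 5 * std(rnorm(12))
  y <- x - 3.34 - 6.30 * std(rnorm(12))  # difference: mean 3.34, SD 6.30
  expect_equal(cohens_d(x, y, "difference"), 3.34 / 6.30, tolerance = 1e-9)

  expect_equal(cohens_d(a, a), 0)
  expect_error(cohens_d(rep(1, 5), rep(1, 5)), "zero variance")
})

test_that("latency binning pools trials around the three amplitude targets", {
  m <- data.frame(participant = rep(1:2, each = 6),
                  device = rep(c("magstim", "ptms"), 6),
                  intensity = 40,
                  p2p = rep(c(50, 500, 1000), 4),
                  p2p_floored = rep(c(50, 500, 1000), 4),
                  floored = FALSE,
                  latency = 22, latency_detected = TRUE)
  bins <- latency_by_amplitude(m)
  expect_equal(sort(unique(bins$target)), c(50, 500, 1000))
  expect_true(all(bins$mean_latency == 22))

  one <- latency_by_amplitude(m[m$p2p == 500, ])
  expect_equal(unique(one$target), 500)
})
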