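test_that("induced drive is the central-difference dI/dt", {
  flat <- sampled_waveform(numeric(100), 1, "current")
  expect_true(all(induced_drive(flat)$samples == 0))

  ramp <- sampled_waveform(0.25 * (0:99), 1, "current")
  d <- induced_drive(ramp)$samples
  expect_true(all(abs(d - 0.25) < 1e-12))
})

test_that("drive peak is stable under halving the synthesis step", {
  i1 <- synth_magstim_monophasic(dt = 0.125)$current
  i2 <- synth_magstim_monophasic(dt = 0.0625)$current
  p1 <- max(abs(induced_drive(i1)$samples))
  p2 <- max(abs(induced_drive(i2)$samples))
  expect_lt(abs(p1 - p2) / p2, 0.01)
  # and the peak occurs during the initial rise
  d <- induced_drive(i1)
  t_peak <- (which.max(d$samples) - 1) * d$dt
  t_imax <- (which.max(i1$samples) - 1) * i1$dt
  expect_lt(t_peak, t_imax)
})

test_that("membrane response matches the Lapicque charging formula", {
  nr <- neuron_model("n", "L4", 1, tau = 200, 1, 1, 1)
  zero <- structure(list(samples = numeric(1000), dt = 0.5), class = "drive_waveform")
  expect_equal(membrane_response(zero, nr), 0)

  for (dur in c(50, 150, 400)) {
    A <- 3
    rect <- structure(list(samples = c(rep(A, dur / 0.5), numeric(2000)),
                           dt = 0.5), class = "drive_waveform")
    expect_equal(membrane_response(rect, nr), A * (1 - exp(-dur / 200)),
                 tolerance = 1e-3)
  }
})

test_that("a 32 kHz drive is attenuated like a first-order low-pass", {
  nr <- neuron_model("n", "L4", 1, tau = 200, 1, 1, 1)
  dt <- 0.125
  t <- seq(0, 2000, by = dt)
  sine <- structure(list(samples = sin(2 * pi * 32 * t / 1000), dt = dt),
                    class = "drive_waveform")
  gain <- 1 / sqrt(1 + (2 * pi * 0.032 * 200)^2)
  expect_equal(membrane_response(sine, nr), gain, tolerance = 0.2)
})

test_that("membrane attenuation of the switching frequency grows with tau", {
  dt <- 0.125
  t <- seq(0, 2000, by = dt)
  sine <- structure(list(samples = sin(2 * pi * 32 * t / 1000), dt = dt),
                    class = "drive_waveform")
  resp <- vapply(c(60, 100, 150, 250, 400, 600), function(tau)
    membrane_response(sine, neuron_model("n", "L4", 1, tau, 1, 1, 1)),
    numeric(1))
  expect_true(all(diff(resp) < 0))
})

test_that("PWM switching ripple barely moves the membrane for tau >= 150 us", {
  pair <- fixture_pair()
  drv <- induced_drive(pair$ptms$current)
  npp <- round((1000 / 32) / drv$dt)
  diffs <- vapply(c(150, 250, 400, 600), function(tau) {
    nr <- neuron_model("n", "L4", 1, tau, 1, 0.3, 1)
    raw <- membrane_response(drv, nr)
    # same drive with the membrane's input (after the polarity map)
    # averaged over one switching period: the 32 kHz content removed
    g <- pmax(drv$samples, 0) + 0.3 * pmin(drv$samples, 0)
    gs <- as.numeric(stats::filter(g, rep(1 / npp, npp), sides = 2))
    gs[is.na(gs)] <- 0
    lam <- exp(-drv$dt / tau)
    sm <- max(0, max(stats::filter((1 - lam) * gs[-length(gs)], lam,
                                   method = "recursive")))
    abs(raw - sm) / sm
  }, numeric(1))
  expect_true(all(diffs < 0.05))
})

test_that("bisection equals the closed-form threshold for the homogeneous model", {
  pair <- fixture_pair()
  drv <- induced_drive(pair$magstim$current)
  peak_drive <- max(abs(drv$samples))
  bank <- default_neuron_bank()
  for (nr in bank) {
    res <- find_threshold(pair$magstim$current, nr, tol = 1e-4)
    closed <- nr$base_threshold / membrane_response(drv, nr) * peak_drive
    expect_true(res$converged)
    expect_equal(res$threshold, closed, tolerance = 2e-4)
  }
})

test_that("threshold scaling laws hold", {
  pair <- fixture_pair()
  nr <- neuron_model("n", "L4", 1, 160, 1, 0.3, 2)
  r1 <- find_threshold(pair$magstim$current, nr)
  r2 <- find_threshold(scale_waveform(pair$magstim$current, 2), nr)
  expect_equal(r2$scale, r1$scale / 2, tolerance = 3e-4)

  nr2 <- neuron_model("n", "L4", 1, 160, 1, 0.3, 4)
  r3 <- find_threshold(pair$magstim$current, nr2)
  expect_equal(r3$threshold, 2 * r1$threshold, tolerance = 3e-4)
})

test_that("an unreachable threshold reports non-convergence", {
  pair <- fixture_pair()
  nr <- neuron_model("n", "L4", 1, 160, 1, 0.3, 1e9)
  res <- find_threshold(pair$magstim$current, nr, max_scale = 1e4)
  expect_false(res$converged)
  expect_true(is.na(res$threshold))
})

test_that("the default bank is deterministic and structured 6 x 5", {
  b1 <- default_neuron_bank()
  b2 <- default_neuron_bank()
  expect_identical(b1, b2)
  expect_length(b1, 30)
  layers <- vapply(b1, `[[`, "", "layer")
  expect_equal(sort(unique(layers)), sort(attr(b1, "layers")))
  expect_true(all(table(layers) == 5))
  b3 <- default_neuron_bank(seed = 1)
  expect_false(identical(b1, b3))
  taus <- vapply(b1, `[[`, 0, "tau")
  expect_true(all(taus >= 50 & taus <= 600))
})

test_that("identical pulses give slope 1, r^2 1 and zero reductions", {
  pair <- fixture_pair()
  bank <- default_neuron_bank()
  # lm warns about the (expected) essentially perfect fit
  cmp <- suppressWarnings(
    population_thresholds(bank, pair$magstim$current, pair$magstim$current))
  expect_equal(cmp$slope, 1, tolerance = 1e-3)
  expect_equal(cmp$r_squared, 1, tolerance = 1e-6)
  expect_lt(max(abs(cmp$per_neuron$percent_reduction)), 0.05)
})

test_that("the PWM pulse activates every default neuron at a lower threshold", {
  pair <- fixture_pair()
  cmp <- population_thresholds(default_neuron_bank(),
                               pair$magstim$current, pair$ptms$current)
  expect_true(all(cmp$per_neuron$threshold_ptms <
                    cmp$per_neuron$threshold_magstim))
  expect_equal(cmp$n_excluded, 0)
})

test_that("the threshold comparison is reproducible from the seed", {
  pair <- fixture_pair()
  c1 <- population_thresholds(default_neuron_bank(seed = 99),
                              pair$magstim$current, pair$ptms$current)
  c2 <- population_thresholds(default_neuron_bank(seed = 99),
                              pair$magstim$current, pair$ptms$current)
  expect_identical(c1$per_neuron, c2$per_neuron)
})

test_that("tukey fences mark only extreme values and keep the bulk", {
  x <- c(rnorm(50), 100)
  g <- rep("a", 51)
  keep <- tukey_keep(x, g)
  expect_false(keep[51])
  expect_gt(mean(keep), 0.9)
})

test_that("a neuron bank survives the TOML round trip", {
  bank <- default_neuron_bank()
  path <- withr::local_tempfile(fileext = ".toml")
  write_neuron_bank_toml(bank, path)
  back <- read_neuron_bank_toml(path)
  expect_length(back, 30)
  for (k in c(1, 17, 30)) {
    expect_identical(back[[k]]$tau, bank[[k]]$tau)
    expect_identical(back[[k]]$base_threshold, bank[[k]]$base_threshold)
    expect_identical(back[[k]]$layer, bank[[k]]$layer)
  }
})
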