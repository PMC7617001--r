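# Shared fixtures, computed once per test run.

# Default calibrated waveform pair (conventional monophasic scaled to the
# 1600 V PWM peak, plus its five-level PWM approximation and currents).
fixture_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- default_waveform_pair()
    cache
  }
})

# Spectra of the two voltage waveforms on a shared grid.
fixture_spectra <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      pair <- fixture_pair()
      cache <<- list(magstim = compute_spectrum(pair$magstim$voltage),
                     ptms = compute_spectrum(pair$ptms$voltage))
    }
    cache
  }
})

# A sampled sinusoidal voltage with integer periods, zero at both ends.
make_sine_wave <- function(freq_khz, amp = 1, dur_ms = 40, dt = 0.125) {
  t <- seq(0, dur_ms * 1000, by = dt)
  n_per <- floor(freq_khz * dur_ms)         # whole periods in the window
  t_end <- n_per / freq_khz * 1000          # us
  x <- ifelse(t <= t_end, amp * sin(2 * pi * freq_khz * t / 1000), 0)
  sampled_waveform(x, dt, "voltage", label = sprintf("%g kHz tone", freq_khz))
}

# A single-participant cohort with every SD forced to zero.
deterministic_participant <- function(rmt = 41, width = 5, seed = 1) {
  cfg <- cohort_config(n_participants = 1, rmt_mean = rmt, rmt_sd = 0,
                       rmt_diff_sd = 0, io_width_mean = width,
                       io_width_sd = 0, latency_sd = 0, seed = seed)
  list(config = cfg, participant = generate_cohort(cfg)[1, ])
}

# Independent enumeration of the 5-of-10 staircase outcome distribution
# for a participant with known per-intensity response probabilities.
# Follows the protocol text directly (latest block outcome per intensity;
# terminate at the lowest intensity with >= 5/10 whose next-lower visited
# intensity scored < 5/10); kept separate from rmt_staircase() on purpose.
enumerate_staircase <- function(p_success, start, step = 1,
                                max_blocks = 30) {
  p_block <- vapply(p_success, function(p)
    sum(stats::dbinom(5:10, 10, p)), numeric(1))  # P(>= 5 successes)
  names(p_block) <- names(p_success)
  dist <- new.env()
  add <- function(rmt, pr) {
    k <- as.character(rmt)
    assign(k, pr + mget(k, dist, ifnotfound = 0)[[1]], dist)
  }
  recurse <- function(cur, outcome, pr, depth) {
    if (depth > max_blocks || pr < 1e-12) return()
    pb <- p_block[[as.character(cur)]]
    for (succ in c(TRUE, FALSE)) {
      pr2 <- pr * if (succ) pb else (1 - pb)
      if (pr2 < 1e-12) next
      out2 <- outcome
      out2[[as.character(cur)]] <- succ
      vis <- as.numeric(names(out2))
      ok <- vis[vapply(vis, function(v) {
        lower <- as.character(v - step)
        isTRUE(out2[[as.character(v)]]) && !is.null(out2[[lower]]) &&
          !out2[[lower]]
      }, logical(1))]
      if (length(ok) > 0) add(min(ok), pr2)
      else recurse(cur + if (succ) -step else step, out2, pr2, depth + 1)
    }
  }
  recurse(start, list(), 1, 1)
  out <- unlist(as.list(dist))
  out[order(as.numeric(names(out)))]
}
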