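#' Magnitude spectrum of a pulse waveform
#'
#' Discrete Fourier magnitude of the zero-padded waveform, reported as a
#' percentage of the fundamental. The pulse has compact support, so a
#' rectangular window is used and the waveform is required to have
#' decayed at both ends (no leakage from truncation). The "fundamental"
#' of a transient pulse is taken as the global magnitude maximum over
#' f > 0.
#'
#' @param wave A [sampled_waveform()], fully containing the pulse.
#' @param min_span_ms Minimum zero-padded length in milliseconds; the
#'   default 10 ms gives a grid resolution of at most 0.1 kHz. Padding is
#'   extended to the next power of two.
#' @return Object of class `pulse_spectrum`: list with `frequency`
#'   (kHz, uniform grid from the first positive bin to Nyquist),
#'   `magnitude` (percent of fundamental), `fundamental_frequency`
#'   (kHz), `fundamental_magnitude` (absolute, V*s for a voltage input)
#'   and `resolution` (kHz).
#' @export
compute_spectrum <- function(wave, min_span_ms = 10) {
  stopifnot(inherits(wave, "sampled_waveform"))
  x <- wave$samples
  peak <- max(abs(x))
  if (peak == 0) stop("all-zero waveform has no spectrum")
  if (abs(x[1L]) > 0.01 * peak || abs(x[length(x)]) > 0.01 * peak)
    stop(paste("waveform has not decayed at its boundaries",
               "(end samples exceed 1% of the peak); pad the synthesis window"))
  n_min <- max(2L * length(x), ceiling(min_span_ms * 1000 / wave$dt))
  n <- 2L^ceiling(log2(n_min))
  X <- stats::fft(c(x, numeric(n - length(x))))
  half <- seq_len(n %/% 2L + 1L)           # f = 0 .. Nyquist
  mag <- Mod(X[half]) * wave$dt * 1e-6     # |V(f)| in V*s
  freq <- (half - 1L) / (n * wave$dt * 1e-3)  # kHz
  m <- mag[-1L]; f <- freq[-1L]            # exclude the DC bin
  i0 <- which.max(m)
  structure(list(frequency = f,
                 magnitude = 100 * m / m[i0],
                 fundamental_frequency = f[i0],
                 fundamental_magnitude = m[i0],
                 resolution = f[2L] - f[1L],
                 time_energy = sum(x^2) * wave$dt * 1e-6,
                 spectral_energy = sum(Mod(X)^2) * wave$dt * 1e-6 / n),
            class = "pulse_spectrum")
}

#' @export
print.pulse_spectrum <- function(x, ...) {
  cat(sprintf(paste0("<pulse_spectrum: fundamental %.3f kHz ",
                     "(|V| = %.4g V*s), resolution %.4f kHz>\n"),
              x$fundamental_frequency, x$fundamental_magnitude, x$resolution))
  invisible(x)
}

#' Largest above-fundamental harmonic and cross-device comparison
#'
#' Finds the largest local magnitude maximum of `spec` above
#' `search_floor` (excluding the fundamental's low-frequency lobe) and
#' probes a second spectrum at that frequency. Local maxima below
#' `min_magnitude` percent of the fundamental do not count; if none
#' qualifies the summary reports the harmonic as absent together with
#' the largest bin above the floor.
#'
#' @param spec A `pulse_spectrum` (from [compute_spectrum()]).
#' @param other A second `pulse_spectrum` on the same frequency grid.
#' @param search_floor Lower search bound in kHz (default 10, well above
#'   the ~2.5 kHz fundamental of the monophasic pulse).
#' @param min_magnitude Minimum percent-of-fundamental for a local
#'   maximum to qualify as a harmonic (default 1).
#' @return List with `largest_harmonic_frequency` (kHz),
#'   `largest_harmonic_magnitude` (percent of `spec`'s fundamental),
#'   `comparison_magnitude_at_frequency` (percent of `other`'s own
#'   fundamental at the same grid frequency) and `harmonic_present`.
#' @export
harmonic_summary <- function(spec, other = spec, search_floor = 10,
                             min_magnitude = 1) {
  stopifnot(inherits(spec, "pulse_spectrum"), inherits(other, "pulse_spectrum"))
  if (length(spec$frequency) != length(other$frequency) ||
      any(abs(spec$frequency - other$frequency) > 1e-9))
    stop("the two spectra must share a frequency grid")
  if (search_floor <= spec$fundamental_frequency)
    stop("search_floor must lie above the fundamental")
  m <- spec$magnitude; f <- spec$frequency
  n <- length(m)
  is_max <- c(FALSE, m[2:(n - 1)] > m[1:(n - 2)] & m[2:(n - 1)] >= m[3:n], FALSE)
  cand <- which(is_max & f >= search_floor & m >= min_magnitude)
  if (length(cand) == 0L) {
    above <- which(f >= search_floor)
    i <- above[which.max(m[above])]
    return(list(largest_harmonic_frequency = f[i],
                largest_harmonic_magnitude = m[i],
                comparison_magnitude_at_frequency = other$magnitude[i],
                harmonic_present = FALSE))
  }
  i <- cand[which.max(m[cand])]
  list(largest_harmonic_frequency = f[i],
       largest_harmonic_magnitude = m[i],
       comparison_magnitude_at_frequency = other$magnitude[i],
       harmonic_present = TRUE)
}
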