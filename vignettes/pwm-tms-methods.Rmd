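---
title: "Modelling PWM-based TMS: waveforms, surrogate thresholds and the MEP pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling PWM-based TMS: waveforms, surrogate thresholds and the MEP pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pwmtms)
```

Most transcranial magnetic stimulators deliver a fixed pulse shape: a
capacitor discharges through the coil and the circuit's resonance
dictates the waveform. A pulse-width-modulated (PWM) stimulator
replaces the resonant discharge with cascaded H-bridge cells that
switch among a small set of voltage levels, so that an arbitrary
target waveform can be approximated by a staircase whose *average*
tracks the target. The price is switching harmonics; the physiological
question is whether neural membranes, which integrate the induced
field over hundreds of microseconds, even notice them. `pwmtms`
implements the modelling and analysis chain needed to study that
question end to end: circuit-level waveform synthesis, harmonic
spectral comparison, a calibrated surrogate neuron bank for activation
thresholds, and a complete motor-evoked-potential (MEP) measurement
pipeline exercised on a synthetic within-subject cohort.

## The monophasic circuit model

The conventional pulse is the analytic two-phase solution of the
capacitor-discharge circuit. Phase one is the underdamped series RLC
discharge (capacitance $C$, coil inductance $L$, loop resistance $R$,
charge voltage $V_0$):

$$i(t) = \frac{V_0}{\omega L} e^{-\alpha t} \sin(\omega t), \qquad
  \alpha = \frac{R}{2L}, \quad
  \omega = \sqrt{\tfrac{1}{LC} - \alpha^2},$$

which runs until the capacitor voltage first crosses zero, just after
the coil-current peak. From there the current freewheels through a
clamp path with total loop resistance $R_{fw}$, decaying exponentially
with $\tau_{fw} = L/R_{fw}$, while the coil terminal voltage is the
shallow negative tail $(R - R_{fw})\,i(t)$. The model is linear, so
scaling $V_0$ scales every waveform exactly — this is also why the
intensity calibration between devices reduces to the positive-peak
voltage ratio (`calibrate_intensity_scale()`), 1600/2800 for the
default pair.

The published description of the modelled device does not include its
circuit constants, so they are calibrated here against the device's
*spectral* signature: the dominant component of the pulse must sit
near 2.46 kHz (one thirteenth of the 32 kHz switching frequency), the
largest PWM harmonic at 32 kHz must reach about half the fundamental,
and the conventional pulse about 10% at the same frequency. With the
coil fixed at $L = 16.35\,\mu H$, $R = 0.08\,\Omega$, this pins
$C = 150\,\mu F$ and $\tau_{fw} = 110\,\mu s$ (the widely quoted
180 µs tail leaves too much low-frequency weight and drags the
spectral maximum down to ~1.5 kHz). All constants are configurable
(`device_config()`, TOML template in `inst/extdata/`).

```{r waveforms}
pair <- default_waveform_pair()
sp <- compute_spectrum(pair$ptms$voltage)
harmonic_summary(sp, compute_spectrum(pair$magstim$voltage))[1:3]
```

## Five-level modulation

Two cascaded cells with an 800 V DC link give the level alphabet
$\{-1600, -800, 0, 800, 1600\}$ V. Modulation is regular-sampled: each
31.25 µs switching period takes the period-average of the target,
selects the adjacent level pair that brackets it and the duty cycle
that makes the planned volt-seconds *exactly* equal to the target's.
The plan keeps continuous duty cycles; the rendered waveform snaps
edges to the sampling grid (0.125 µs, 250 samples per switching
period), so it takes only the five levels while the plan preserves
volt-seconds to floating-point precision. Pulses are centred in the
period by default (symmetric double-edge modulation); leading-edge
placement is available. Positive targets that exactly hit a level are
booked as duty 1 on that level, zero and negative ones as duty 0 —
an arbitrary but fixed tie-break.

Because the tail of the monophasic target is a shallow negative
voltage, its PWM approximation consists of brief $-800$ V slivers: the
modulated pulse has a sharper, higher-amplitude negative phase than
the conventional pulse, which matters below.

## Spectral analysis choices

A single pulse is a transient, not a periodic signal, so "fundamental"
is defined as the global magnitude maximum of the zero-padded FFT over
$f > 0$ and all magnitudes are reported relative to it. The waveform
has compact support, hence a rectangular window and a hard error if
the ends have not decayed below 1% of the peak (that would be
truncation leakage, not signal). Padding to at least 10 ms gives a
grid of at most 0.1 kHz. The harmonic search looks for local maxima
above 10 kHz — safely above the ~2.5 kHz fundamental lobe and below
nothing of interest — and ignores maxima under 1% of the fundamental
so that sinc sidelobes of the padding are not mistaken for harmonics.

## The surrogate neuron bank

The reference modelling work couples morphologically detailed cortical
neurons to induced electric fields; that is far beyond desk scale.
The package substitutes a *declared, calibrated surrogate*: 30 neurons
(6 layers × 5 clones), each a first-order membrane

$$\tau \frac{dm}{dt} = g(e(t)) - m, \qquad
  g(e) = \begin{cases} g_+ \, e & e > 0 \\ g_- \, e & e < 0 \end{cases}$$

driven by the coil-current rate of change $e = dI/dt$ (unit field
coupling), with activation when $m$ reaches the neuron's base
threshold. The polarity map keeps the sign of the drive; with
$g_- = g_+$ the membrane is fully linear, and with $g_- < g_+$ the
hyperpolarizing phase counts less — the directional sensitivity
characteristic of monophasic stimulation. The model is positively
homogeneous, so the bisection threshold search has an exact closed
form to test against, and thresholds scale linearly with the base
threshold.

Why does the PWM pulse activate at a lower threshold here? The
switching ripple makes the drive cross zero where the smooth target
would not, and the kink in $g$ at zero converts that sign-alternating
ripple into a net depolarizing shift whenever $g_- < g_+$. This is the
surrogate's counterpart of the sharper negative phase of the PWM pulse
being implicated in its lower motor thresholds. The layer time
constants (172–190 µs, shortest in L1, longest in L5) and the gain
ratio $g_-/g_+ = 0.3$ are calibrated constants, fixed so that the
per-layer median threshold reduction lands in the reported 5.6–6.2%
band with a cross-pulse regression slope near 0.939; clone jitter (2%
on $\tau$, 20% on the base threshold, seeded generator) provides the
within-layer spread. The calibration is a stated property of the
surrogate, not a prediction. Layer base thresholds are spread over
roughly a decade to mimic the layer profiles of morphological models;
only relative quantities (reductions, slope) are meaningful.

One published-style invariant needs care: "membrane dynamics attenuate
the switching harmonics" is checked by comparing the response to the
PWM drive against the response to the same *membrane input* (after the
polarity map) with its 32 kHz content averaged out over one switching
period; for $\tau \ge 150\,\mu s$ they differ by under 5%. Averaging
the signed drive *before* the polarity map instead would also remove
the rectified DC shift described above — i.e. it would remove the
effect under study, not just the ripple.

```{r thresholds}
cmp <- population_thresholds(default_neuron_bank(),
                             pair$magstim$current, pair$ptms$current)
cmp$layer_medians
c(slope = cmp$slope, r_squared = cmp$r_squared)
```

## The synthetic cohort

The deposited human data are deliberately not consumed; instead the
generator emulates a 12-participant within-subject study with the
reported statistical structure, so the analysis pipeline can be tested
against known ground truth:

* Conventional-device resting motor thresholds (RMTs) are drawn from a
  normal distribution with mean 41.34 and SD 6.07 %MSO, truncated to
  (20, 80); the PWM-condition RMT is lower by a strictly positive
  truncated-normal draw (mean 3.34, SD 1.5 %MSO), so *every*
  participant's PWM threshold is lower by construction.
* Each participant has one set of input–output (IO) curve parameters —
  a four-parameter cumulative-Gaussian sigmoid on log10 amplitude —
  shared across devices except for the midpoint, which shifts with the
  device RMT. Midpoint slopes and MEP latencies (22 ± 1.5 ms) are
  device-independent by construction, matching the reported null
  effects.
* A trial draws a log-normal MEP amplitude from the IO curve (trial SD
  0.25 on log10 amplitude, a typical MEP variability) and embeds a
  biphasic wavelet — two opposed half-sine lobes, 8 ms wide,
  peak-to-peak equal to the drawn amplitude — in Gaussian baseline
  noise (SD 5 µV, 5 kHz sampling, 100 ms pre-stimulus window). The
  sampling rate and wavelet shape are conventions; only peak-to-peak
  amplitude and onset matter downstream.

The one calibrated constant is the response anchor: the IO curve at
the true RMT equals $\log_{10}(50) - \kappa$ with $\kappa = 0.132$,
fixed once by Monte Carlo so that the probability that the *measured*
peak-to-peak amplitude reaches the 50 µV criterion is one half at the
true RMT (baseline noise inflates the measured max-minus-min, so the
raw wavelet median must sit slightly below 50 µV). This makes the
5-of-10 staircase estimator unbiased by design, which is what lets the
pipeline-recovery checks compare estimated group means directly
against the generating ones.

What the generator does **not** model: coil-positioning drift,
hysteresis and order effects, amplifier filtering, heteroscedastic or
correlated EMG noise, and participant-level deviations from the
sigmoid IO form. Passing recovery tests therefore demonstrate that the
*pipeline* is unbiased under the stated generative model — not that
real EMG data are this clean.

## The measurement pipeline

* **Peak-to-peak**: max minus min in a 15–45 ms post-stimulus window;
  values under 20 µV are floored at 20 µV (flagged) before IO fitting.
* **RMT staircase**: blocks of 10 pulses per intensity; at least 5
  measured responses ≥ 50 µV steps the intensity down by 1 %MSO,
  fewer steps it up; the protocol stops at the lowest intensity
  scoring ≥ 5/10 whose next-lower *visited* intensity scored < 5/10
  (latest block per intensity counts, revisits allowed, hard cap of
  30 blocks). The same code drives both the simulated experimenter and
  the offline re-derivation, so recorded sessions replay to identical
  estimates. Sessions start 5 %MSO above the (rounded) true RMT — the
  hotspot phase of a real session provides exactly this kind of
  suprathreshold starting guess.
* **Latency**: threshold at mean + 2 SD of the rectified 100 ms
  pre-stimulus segment; onset is the first post-stimulus crossing
  sustained for ≥ 1 ms. The persistence requirement suppresses
  isolated noise crossings (a bare first-crossing mode exists); with
  5 µV noise the detector finds 1 mV MEPs within 1 ms of their true
  onset in over 95% of trials and stays quiet on noise-only traces.
* **IO fit**: least squares of
  $y = \mathrm{floor} + (\mathrm{ceiling}-\mathrm{floor})\,
  \Phi((x - \mathrm{midpoint})/\mathrm{width})$ on log10 amplitude via
  Levenberg–Marquardt with a 9-point multi-start over midpoint and
  width; the midpoint slope is
  $(\mathrm{ceiling}-\mathrm{floor})/(\mathrm{width}\sqrt{2\pi})$.
  The cumulative-Gaussian form is one reading of a "Gaussian-type"
  four-parameter regression; it is the one that makes the midpoint
  slope analytic. All-floored data return a non-convergence flag
  rather than a fit.
* **Statistics**: the two-level repeated-measures ANOVA is fitted with
  an error stratum per participant and equals the squared paired t
  test by construction — an identity the tests assert rather than
  assume. Cohen's d ships in both the pooled-SD and difference-SD
  variants: the printed group summaries reproduce ≈ 0.557 under the
  pooled formula, and the reported 0.53 corresponds to a difference-SD
  of ≈ 6.3, so neither variant is asserted against the printed value.
  Latency comparisons bin trials at 50/500/1000 µV with ×/÷1.5
  multiplicative bands (bin widths are not specified anywhere, so a
  symmetric band on the log scale is used), and no multiple-testing
  correction is applied, mirroring the reported analysis.

## Problem sizes and numerical choices

Waveforms are synthesized at 0.125 µs steps (250 samples per switching
period, an exact tiling; ~8,800 samples per pulse) and padded to
65,536 bins for spectra. Membrane integration uses the exact
exponential zero-order-hold update; coil currents use fixed-step
trapezoidal integration of $di/dt = (v - Ri)/L$. Threshold bisection
runs to a relative tolerance of $10^{-4}$ after bracket doubling
(giving up beyond $10^6\times$). The replication study uses 20 seeded
cohorts of 12 participants — enough for grand means with standard
errors well under the 1 %MSO comparisons of interest while keeping a
full run in tens of seconds. With 20 replications the
fraction-significant summaries have a sampling SD of about 5
percentage points, which is worth remembering when reading the
90%-style thresholds.

## Known limitations

The surrogate neuron bank is calibrated, not predictive: it reproduces
the direction and size of the PWM threshold advantage by construction
and cannot substitute for morphological modelling on new pulse shapes
far from this pair. The circuit model omits semiconductor details
(dead time, finite switching edges, snubbers), coil geometry and any
spatial field structure. The cohort generator treats the reported
group SDs as pure between-participant variability. The staircase
formalizes what was a manual adjustment procedure; real experimenter
behaviour is looser.
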