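---
title: "Delineating impedance cardiograms with empirical mode decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delineating impedance cardiograms with empirical mode decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icgemd)
```

## The problem

Impedance cardiography (ICG) records the rate of change of thoracic
impedance, dZ/dt. Three landmarks of each cardiac cycle carry the
clinically relevant timing: **B** (aortic valve opening, the onset of the
systolic upstroke), **C** (the waveform maximum, i.e. the largest rate of
impedance change) and **X** (aortic valve closing, the post-systolic
trough). From them one derives the left-ventricular ejection time
(LVET, the B-to-X interval), dZ/dt~max~ (the amplitude at C), the Kubicek
stroke volume

$$\mathrm{SV} = \rho \frac{L^2}{Z_0^2}\, \frac{dZ}{dt}\Big|_{\max} \cdot \mathrm{LVET},$$

heart rate (from the C-to-C intervals) and cardiac output
(SV x HR / 1000). Here $\rho$ is the specific resistance of blood
(Ohm cm), $L$ the inter-electrode thoracic length (cm) and $Z_0$ the base
impedance (Ohm); the units work out to millilitres.

Automatic delineation is hard because the waveform morphology varies from
beat to beat and the B and X notches are small features sitting next to a
large C wave. This package implements a delineator built entirely on
empirical mode decomposition (EMD), which needs no simultaneous ECG.

## The decomposition machinery

**EMD** splits a series into intrinsic mode functions (IMFs) plus a
residual, $x(t) = \sum_i C_i(t) + r(t)$, by iterative *sifting*: locate
the extrema, interpolate upper and lower natural cubic-spline envelopes
through them, and subtract the envelope mean until the candidate mode has
(i) extrema and zero-crossing counts differing by at most one and (ii) an
envelope mean of (approximately) zero. Decomposition stops when the
residual is monotone, constant, or has fewer than two maxima or two
minima.

Numerical choices the literature leaves open, and what this package does:

* **Sifting stop.** A mode is accepted when it passes the strict IMF test
  (`is_imf()`), or when the Cauchy criterion
  $\sum (h_{k-1}-h_k)^2 / \sum h_{k-1}^2 < 0.2$ is met — the standard
  rule since the original EMD literature — or after 100 iterations. The
  per-mode stopping reason is recorded in the `sift_log` attribute. Note
  that a Cauchy-stopped mode is generally *not* within the strict
  pointwise envelope-mean tolerance of `is_imf()` (5% of the mode RMS):
  the two tolerances differ by an order of magnitude, and sifting every
  mode to the strict tolerance takes roughly ten times as many iterations
  while materially over-smoothing the modes. The log makes the
  distinction explicit instead of hiding it.
* **Envelope-mean tolerance.** `is_imf()` accepts an envelope mean whose
  largest absolute value is at most 5% of the candidate's RMS.
* **Boundary policy.** The two extrema nearest each record edge are
  mirrored about the edge before spline fitting. This suppresses the
  end swings that would otherwise distort mode amplitudes — and hence
  fiducial timing — near the record boundaries.
* **Plateaus and exact zeros.** A plateau contributes one extremum at its
  midpoint; an exact zero adopts the sign of the following sample when
  zero crossings are counted.

**EEMD** (ensemble EMD) mitigates mode mixing: white noise with standard
deviation 0.2 x sd(x) is added, the noisy copy is decomposed, and the
modes are averaged order-by-order over 100 realizations (both
configurable). Realizations yielding fewer modes contribute zeros for the
missing high orders, which keeps the mode-wise mean well defined. Each
realization draws its noise from a substream derived from the master seed
and the realization index, so results are reproducible and independent of
evaluation order. Averaged modes are *not* required to pass `is_imf()` —
averaging breaks that property by construction — but the averaged modes
plus averaged residual still reproduce the ensemble mean of the noisy
inputs exactly.

## The delineator

The pipeline expects a preprocessed signal: integer-factor zero-phase
downsampling to 250 Hz where needed (`resample_signal()`), then
Savitzky-Golay smoothing of order 3 with a 15-sample (60 ms) window
(`savgol_smooth()`). The order-3 filter preserves the cubic curvature of
the systolic upstroke; the window is fixed rather than adaptive — what an
"adaptive" Savitzky-Golay window should track is not well defined, so
both parameters are simply exposed.

**C point.** From the plain EMD, the detection function
$\mathrm{cf1} = |(\mathrm{IMF}_1+\mathrm{IMF}_2+\mathrm{IMF}_3+\mathrm{IMF}_4)
\cdot \mathrm{IMF}_1 \mathrm{IMF}_2 \mathrm{IMF}_3|$
concentrates amplitude where all fast modes are simultaneously large,
i.e. at the C wave. Its local maxima are scanned with a two-level
adaptive threshold in the Pan-Tompkins style: running peak and noise
levels are exponential moving averages (weight 0.125) of accepted peaks
and rejected candidates, and the threshold sits a fixed fraction of the
way from noise to peak. Three details matter in practice:

* The running fraction is 0.25 (the classic two-level detector constant),
  not 0.5: cf1 is a *product* of three modes, so its per-beat peak value
  spans more than an order of magnitude even for modest amplitude jitter,
  and a 0.5 fraction demonstrably drops low-amplitude beats. The initial
  threshold is still half of the maximum over the first 3 s.
* A search-back stage re-examines the gap whenever no beat has been
  accepted for 1.66 times the running mean beat interval and accepts the
  best candidate above half the threshold — the standard recovery from a
  threshold excursion.
* Within 360 ms after an acceptance, a candidate is accepted only if it
  exceeds half the previous peak. This rejects the diastolic (O-wave)
  lobe of cf1, the analogue of T-wave discrimination in QRS detection.

Within the 200 ms refractory period after an acceptance no further
candidate is accepted; the first supra-threshold lobe of a beat wins.
A tie-break that instead keeps the largest lobe within the window was
evaluated and rejected: the relative size of the cf1 lobes of one beat
complex is noise-modulated, and the largest lobe occasionally sits tens
of samples past C, beyond repair by the snap step below.

Because the C point is defined on the waveform itself (the cycle
maximum), each accepted index is finally *snapped* to the dZ/dt maximum
within +/-40 ms (`snap_c_to_signal()`; disable with `snap = FALSE` to
keep the raw cf1 peaks).

**B point.** From the EEMD, B is the local maximum of the first
derivative of mode 4 nearest before each C, searched up to 300 ms before
C (a generous bound on pre-ejection timing; the search is also clipped at
the previous beat's C).

**X point.** From the EEMD, the function
$\mathrm{cf2} = \mathrm{IMF}_3 + 2\,\mathrm{IMF}_4 + 4\,\mathrm{IMF}_5$
is searched in the interval $[C,\; C + 0.15\,\overline{CC}]$, where
$\overline{CC}$ is the mean C-to-C interval: X is the first local minimum
strictly inside the interval, or the interval's global minimum (excluding
C itself) when the function is monotone there — the fallback reconciles
"first minimum after C" with the bounded search window. The upper bound
uses round-half-up; an EEMD with fewer than five modes is zero-padded
with a warning. B and X may be absent near record edges; beats without a
C are never emitted.

All sample indices are 1-based, in the API and in the annotation files
(CSV/JSON, long format `beat,point,sample_index`).

## The synthetic generator

`synth_signal()` produces dZ/dt-like records with analytic ground truth,
so the whole detector is testable without any recording. Each beat is a
sum of four Gaussian lobes (A, C, X, O). Defaults, chosen once for
physiological plausibility:

| lobe | amplitude | centre vs C | FWHM |
|------|-----------|-------------|------|
| A (atrial, negative) | 0.25 | -70 ms | 30 ms |
| C (systolic) | 1.5 | 0 | 50 ms |
| X (trough, negative) | 0.5 | +110 ms | 45 ms |
| O (diastolic) | 0.25 | +220 ms | 60 ms |

Ground truth is read off the noiseless template: C at the maximum, B at
the local minimum nearest before C (the notch between the A wave and the
upstroke; the B-to-C interval of ~70 ms sits in the resting physiological
range), X at the first local minimum after C (C-to-X ~110 ms, LVET
~190 ms). Beats are placed at intervals of $60/\mathcal N(75, 3)$ s
(truncated at 0.3 s), each scaled by a lognormal-free multiplicative
jitter $\mathcal N(1, 0.07)$; a 0.3 Hz, 0.1-amplitude sine emulates
respiratory baseline wander, and white Gaussian noise is added last —
annotations are fixed before noise, so noise never moves the truth.
`snr_db` sets the noise level relative to the RMS of the clean beat
train (20 dB is the default study condition).

What the generator does *not* emulate: morphology drift within a record,
arrhythmic beats, low-amplitude or double-notch B variants, motion
artifacts, respiration-gated amplitude modulation. Passing the synthetic
suite therefore shows the algorithm recovers landmarks under noise,
wander and beat-to-beat jitter — not that it handles pathological
morphologies.

## Evaluation

`match_points()` pairs detected and reference annotations greedily in
ascending reference order, nearest detected candidate first, each point
used at most once, within a tolerance of 7 samples (28 ms at 250 Hz,
inside the conventional 30 ms agreement window). On beat-separated
trains (spacing > 2 x tolerance) the greedy matching equals the optimal
bipartite matching. Accuracy is reported as
100 x matched / reference, rounded to two decimals (ties up).
`median_difference()` compares medians of derived parameters between two
annotation sources.

## Problem sizes and determinism

The bundled tests and the acceptance script run the full pipeline on
120 s records at 250 Hz (~150 beats) with the default 100-realization
ensemble; a complete run takes well under a minute on one core. Every
stochastic step (generator, ensemble noise) is seeded explicitly, and
identical seeds give bitwise-identical results.

## Known limitations

* The delineator needs at least 4 EMD modes (~a few hundred samples of
  oscillatory signal); short or flat records fail with a clear error.
* Mode indices (1-4 for C, 4 for B, 3-5 for X) presuppose the 250 Hz
  analysis rate; at other rates the beat energy lands in different
  modes, so resample first.
* The Heather index definition ("C/(C-Q)") is ambiguous in the
  literature; it is implemented explicitly as amplitude-at-C divided by
  the Q-to-C time and requires externally supplied ECG Q indices, as
  does PEP.
* X detection inherits the bounded search window: an X trough later than
  15% of the mean beat interval after C is attributed to the window
  bound, not recovered.
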