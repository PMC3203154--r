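---
title: "Methods: single- and multichannel detrended fluctuation analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single- and multichannel detrended fluctuation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdfa)
```

## The problem

Spontaneous field potentials recorded from the dorsal surface of the spinal
cord (cord dorsum potentials, CDPs) are noise-like signals punctuated by
discrete biphasic events of roughly 100–300 ms that appear synchronously
across recording sites over neighbouring lumbar segments.  Two questions
arise for such multichannel records: does each channel carry persistent
long-range temporal correlations, and how strongly is the *ensemble* of
channels synchronized — in particular, how does that synchronization change
when the pathways connecting segments are partially interrupted?

Detrended fluctuation analysis (DFA) answers the first question per
channel.  This package also implements a multichannel generalization
(mDFA) that summarizes an aligned ensemble of channels with a single
scaling exponent, together with the surrounding workflow: shuffle
surrogates as a randomization control, magnitude-squared coherence as the
classical pairwise cross-check, paired statistical comparison of
fluctuation curves across conditions, and a synthetic generator of
CDP-like coupled ensembles whose ground-truth coupling can be "lesioned".

## Single-channel DFA

For a series $x(i)$, $i = 1..N$, the profile is the integrated,
mean-removed series

$$y(k) = \sum_{i=1}^{k} \left( x(i) - \langle x \rangle \right),$$

which telescopes to $y(N) = 0$.  The profile is cut into
$\lfloor N/n \rfloor$ contiguous non-overlapping boxes of length $n$; in
every box a least-squares polynomial of degree $m$ (the *local trend*,
$m = 1$ for classical DFA, general $m$ for "DFA$m$") is removed, and the
residuals are pooled:

$$F(n) = \sqrt{ \frac{1}{N'} \sum_{k} \left[ y(k) - y_n(k) \right]^2 },$$

where $N' = n \lfloor N/n \rfloor$ counts only the samples covered by
complete boxes.  For self-similar signals $F(n) \propto n^{\alpha}$, and
the scaling exponent $\alpha$ is estimated as the ordinary least-squares
slope of $\log_{10} F(n)$ on $\log_{10} n$: $\alpha = 0.5$ for
uncorrelated noise, $\alpha > 0.5$ for persistent long-range correlation,
$\alpha \approx 1$ for 1/f noise, $\alpha < 0.5$ for anti-correlation.

Numerical choices:

* **Tail remainder.** Boxes are anchored at the first sample and the
  remainder `N %% n` is dropped (normalizing by $N'$, not $N$, so that a
  profile that is exactly polynomial inside every box yields exactly
  $F(n) = 0$).  The common variance-reduction variant that averages the
  forward partition with one anchored at the last sample is available as
  `two_sided = TRUE`.
* **Box schedule.** Default is log-spaced, about 4 sizes per octave, from
  $n_{\min} = \max(2(m+2), 4)$ to $n_{\max} = \lfloor N/4 \rfloor$,
  rounded to integers and deduplicated — roughly 45 sizes at
  $N = 2^{16}$.  Four sizes per octave keeps the schedule dense in log
  space while bounding the curve to a few dozen points, each backed by at
  least four boxes.
* **Fit range.** The default fit uses the whole schedule; `n_range`
  restricts it, because the physiologically interesting window range
  (e.g. windows spanning one CDP, 100–300 ms) depends on the sampling
  rate of the recording and is better chosen by the analyst.
* **Degenerate points.** $F(n) = 0$ has no logarithm; such points occur
  only for degenerate inputs (constant or box-wise polynomial series) and
  are dropped from the fit with a warning.  Fits require at least four
  usable points.
* **Conditioning.** Per-box polynomial trends are solved by QR on a
  design matrix with box abscissae rescaled to $[-1, 1]$; all boxes of a
  given size share one factorization, which is also why the
  implementation is fast enough to sweep million-sample records.
* Reported intercepts are base-10; $\alpha$ itself is base-invariant.

## Multichannel DFA

A $d$-channel recording is treated componentwise: each channel is
integrated into its own profile (no cross-channel mixing), every channel
is detrended per box with its own local trend on one shared box
partition (the channels are simultaneously sampled and aligned), and the
squared residuals are pooled over channels:

$$F(n) = \sqrt{ \frac{1}{N' d} \sum_{c=1}^{d} \sum_{k}
  \left[ y_c(k) - y_{c,n}(k) \right]^2 }.$$

One power-law fit of this pooled curve gives a single ensemble exponent.
The $1/(N'd)$ normalization is a deliberate design choice: it makes
$d = 1$ reduce *bitwise* to classical DFA, makes duplicating or permuting
channels a no-op, and gives the pooling identity
$F(n)^2 = \mathrm{mean}_c\, F_c(n)^2$.  Any other constant normalization
would change only the intercept of the log–log line, never $\alpha$.

Channels are pooled on their raw scale by default; `normalize = TRUE`
z-scores each channel first, which is advisable when electrode gains
differ, since raw pooling weights channels by variance.

Note a structural property that matters for interpretation: because
residuals are pooled *after* per-channel detrending, the pooled curve is
determined entirely by the marginal dynamics of the channels (the pooling
identity above).  mDFA "sees" inter-channel synchronization through the
marginal imprint the shared activity leaves on every channel — when a
shared long-range-correlated source is attenuated, each channel's
spectrum whitens and the ensemble exponent falls.  The pairwise coherence
module provides the complementary, explicitly cross-channel view.

## Surrogates

`shuffle_series()` permutes samples uniformly at random, preserving the
amplitude distribution exactly while destroying temporal ordering; any
series collapses to $\alpha \approx 0.5$ after shuffling.  For ensembles,
`shuffle_multichannel()` offers `independent` mode (each channel its own
permutation — the full null, also destroying cross-channel synchrony; the
default) and `joint` mode (one permutation applied to all channels,
preserving every zero-lag cross-channel relation — useful for ablating
only the temporal structure).  Seeded use is expected; unseeded calls
warn.

## Coherence

`msc()` implements Welch's magnitude-squared coherence: overlapping
segments (default 50 %), per-segment mean removal and Hann windowing,
averaged auto- and cross-spectra, and
$C_{xy}(f) = |S_{xy}|^2 / (S_{xx} S_{yy})$ clipped into $[0, 1]$.  The
default segment length is the power of two nearest two seconds of
samples, resolving the sub-10 Hz band where CDP-like events concentrate.
With $L$ averaged segments the coherence of independent signals is biased
upward by about $1/L$, so band summaries (`band_mean_coherence()`) should
use records long enough for several dozen segments.

## Comparing fluctuation curves

`compare_fluctuations()` performs a paired Student t-test of
$\log_{10} F(n)$ differences across the box sizes shared by two curves,
with a one-sided `reduction` tail for lesion-style hypotheses
("fluctuations are lower after the intervention").  Two caveats are
deliberate and documented rather than hidden:

* The test treats window sizes as independent paired observations, the
  way such fluctuation tables are classically compared.  Estimation
  errors of $\log F(n)$ are in fact correlated across $n$ within one
  recording, so under a *seed-level* null (two independent recordings of
  the same process) these p-values are anticonservative — in our own
  measurement, a nominal 5 % level rejects in roughly half of independent
  white-noise pairs.  Treat the p-value as a descriptive index of
  curve separation, or compare per-seed exponent replicates when a
  calibrated test is needed.
* Zero-variance difference vectors are resolved exactly: identical curves
  give $t = 0$, $p = 1$; a constant nonzero log-ratio is an exact
  rejection (p at the smallest positive double).

## The synthetic generator

The recordings this workflow was designed for are not publicly available,
so the generator emulates their geometry and the features the statistics
rely on; its defaults are the study conditions, not tuning knobs.

* **Record geometry.** 10-minute records of about $10^6$ samples per
  channel, i.e. a default sampling rate of $10^6/600 \approx 1666.67$
  samples/s.
* **Calibration noises.** Gaussian white noise; fractional Gaussian noise
  with prescribed Hurst parameter $H$ by exact Davies–Harte circulant
  embedding of the fGn autocovariance
  $\gamma(j) = \tfrac12(|j+1|^{2H} - 2|j|^{2H} + |j-1|^{2H})$ (the
  $k = 0$ and Nyquist eigenvalue lines are drawn as real Gaussians —
  treating them as complex halves the variance); and 1/f noise by
  random-phase spectral synthesis with amplitude $\propto f^{-1/2}$,
  unit-sd normalized.
* **CDP-like trains.** Poisson event onsets (default 1 event/s — the
  event rate and amplitude of real records are free parameters here),
  durations uniform in 0.1–0.3 s, each event one sine cycle under a Hann
  window (biphasic, smooth, exactly zero-mean so trains add no baseline
  drift), superposed on a Gaussian noise floor.  The acquisition
  band-pass of a real amplifier chain is not emulated.
* **Coupling model.** `gen_coupled_multichannel()` mixes one shared
  source with per-channel private white noise:
  $\mathrm{ch}_c = w_c s + \sqrt{1 - w_c^2}\, p_c (+ \text{noise floor})$.
  The weights are the rank-1 least-squares factorization of the
  off-diagonal coupling matrix ($C_{ij} \approx w_i w_j$, fixed-point
  iteration); a uniform coupling $\rho$ gives $w = \sqrt{\rho}$ and
  pairwise correlations of exactly $\rho$ in expectation.  We use this
  shared-source model for *all* coupling matrices rather than a symmetric
  matrix-square-root mixing of same-spectrum sources, because with
  square-root mixing every channel's marginal spectrum — and therefore
  the pooled mDFA exponent — would be independent of the mixing weights;
  the shared-source/white-private construction is the simplest model in
  which coupling strength moves the ensemble exponent in the direction
  the physiology predicts, with closed-form pairwise correlations for
  testing.
* **Lesions.** `apply_lesion()` multiplies chosen off-diagonal entries by
  $(1 - \text{attenuation})$, symmetrically; sequential lesions compose
  multiplicatively.  The ground truth travels with each generated
  ensemble as an attribute.

What passing tests on these inputs do and do not show: they validate the
estimators against known exponents, exact structural identities, and
ground-truth coupling orderings.  Real cord dorsum recordings are
nonstationary, band-limited, artifact-laden, and have event statistics
the generator only caricatures, so calibration here does not certify
accuracy on any particular physiological record.

## The lesion demo

`run_lesion_demo()` wires the modules together: a four-site ensemble
(L5L, L5R, L6L, L6R) with uniform baseline coupling (default 0.9) driven
by a 1/f shared source; a first simulated lesion attenuates (default
0.8) the edges from L5L across the segmental boundary, a second those
from L5R; each stage is an independently seeded recording of the lesioned
preparation.  Per stage the report holds per-channel DFA, all pairwise
and the 4-channel pooled mDFA (every exponent with its $R^2$ and fit
range), pairwise band-mean coherence (default 0.3–10 Hz), and a
reduction-tail comparison of the pooled curve against baseline.  The
expected signature — falling ensemble exponent and falling coherence of
lesioned pairs — is what the acceptance suite checks across seeds.

## Problem sizes and determinism

Calibration suites use $N = 10^5$ samples for white-noise nulls,
$N = 2^{17}$ for 1/f and fGn recovery, 10 seeds per condition, and
$N = 2^{16}$ per stage for the lesion demo; these sizes give
across-seed standard errors well inside the tolerances being checked
while keeping a full run at desk scale (a couple of minutes on one core).
All generators and surrogates are seeded, restore the caller's RNG
state, and are bit-reproducible; analysis functions are deterministic
given their inputs.

## Known limitations

* No multifractal spectra, wavelet estimators, sliding-window
  time-varying exponents, or cross-correlation (DCCA-style) variants.
* The mDFA pooled statistic is marginal-driven by construction (see
  above); it is a synchronization index only jointly with a generative
  assumption such as the shared-source model.
* Crossovers: a single power-law fit summarizes curves that on real
  signals may bend; inspect the curve and use `n_range` rather than
  trusting one global slope.
* `compare_fluctuations()` p-values are descriptive under seed-level
  nulls (anticonservative; see above).
* The reader supports delimited text only; binary acquisition formats
  are out of scope, though the reader is a small, replaceable surface.
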