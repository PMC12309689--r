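---
title: "Frequency-domain RSA for rhythm categorization: models, conventions, and validity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain RSA for rhythm categorization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmRSA)
```

## The problem

A two-interval rhythm repeats a pattern of two interonset intervals (IOIs)
and is summarized by the ratio $r = \mathrm{IOI}_1 / (\mathrm{IOI}_1 +
\mathrm{IOI}_2)$, so $r = 0.50$ is isochrony (1:1) and $r = 2/3$ a long–short
2:1 pattern. Listeners do not represent this continuum faithfully: both overt
synchronization (finger tapping) and neural activity warp it into a small
number of categories separated by a boundary, with responses attracted toward
category prototypes. The analytical challenge is that tapping onsets are
discrete events while EEG (and tapping force) are smooth continuous signals
with no extractable temporal markers. This package implements
frequency-domain representational similarity analysis (fRSA), which detects
categorical structure in *any* continuous periodic response, plus the
classical intertap-interval (ITI) pipeline and a prototype-similarity
analysis, with synthetic generators providing ground truth for every stage.

## The fRSA procedure

1. **Frequency tagging.** A stimulus sequence loops a pattern of duration
   $T$ (default 0.75 s) for $n$ cycles (default 30, hence 22.5 s). Any
   response component that repeats with the pattern lives entirely at the
   repetition rate $f_0 = 1/T$ (1.33 Hz) and harmonics $k f_0$. Because the
   analyzed epoch spans an integer number of cycles, these frequencies fall
   on exact DFT bins (`harmonicFrequencies()` asserts this) and there is no
   leakage; no windowing is used.
2. **Frequencies of interest.** Significance of the response at each
   harmonic is assessed on the grand-average magnitude spectrum with a local
   signal-to-noise z-score: the magnitude at the bin minus the mean of eight
   surrounding bins (four per side, skipping the immediately adjacent bin),
   divided by the SD of those bins. Harmonics with $z > 3.09$ (one-tailed
   $P < 0.001$) are retained, truncated to the unbroken run starting at the
   first harmonic (`consecutiveSignificant()`). In practice this keeps
   harmonics up to 8 Hz for EEG (alpha activity contaminates higher bins)
   and up to 16 Hz for tapping signals.
3. **Feature vectors.** Per condition, the real and imaginary Fourier
   coefficients at the frequencies of interest are concatenated across
   channels (layout: harmonic-major, real before imaginary, channels
   innermost), giving a complete low-dimensional description of the
   repeating response trajectory, including timing.
4. **Response RSM.** Feature vectors are Pearson-correlated across all
   condition pairs, yielding a symmetric condition-by-condition
   representational similarity matrix with unit diagonal.
5. **Model comparison.** The response RSM's strict lower triangle
   (column-major, 78 values for 13 conditions) is compared against each
   two-category model RSM (binary block matrices; boundaries leaving a
   category with fewer than 2 conditions are excluded, so 13 conditions
   give 10 models) by Spearman partial correlation, partialing out the
   acoustic RSM ($1 - |r_i - r_j|$) to remove stimulus-driven structure.
   The best model is the one with the highest partial rho; exact ties are
   broken toward the boundary nearest the continuum center (and logged).
6. **Inference.** Individual-level significance shuffles the triangle
   entries (5000 iterations by default), refits all models per shuffle, and
   stores the maximum rho; $p = (b + 1)/(n_{\mathrm{iter}} + 1)$ where $b$
   counts null values at or above the observed statistic, Bonferroni-
   corrected over the 10 models. The group statistic is the mean of
   per-participant best rhos; its null shuffles every participant's
   triangle independently (10000 iterations). Boundary consistency is
   summarized by the median boundary ratio (midpoint between the flanking
   condition ratios) with a percentile bootstrap CI over participants
   resampled with replacement.

### Validity of the permutation scheme

The triangle-shuffle scheme (the entries of the lower triangle are permuted,
not rows/columns of the matrix) is exact only when the response triangle is
exchangeable under the null. Three regimes matter and the test suite
characterizes each:

- **Exchangeable responses** (noise-dominated triangles): rejection rate at
  $\alpha = 0.05$ is calibrated (measured 0.02–0.08 over 200 simulations).
- **Stimulus-tracking continuous responses through fRSA** (acoustic
  structure plus noise): the acoustic covariate deflates the observed
  statistic but not the shuffled null, so the test is *conservative* —
  a significant result remains interpretable, absence of one is not
  evidence of absence.
- **Near-noiseless scalar summaries** (mean ITI ratios tracking the
  stimulus almost exactly): the response triangle is a deterministic
  tie-break of the acoustic covariate's many tied entries, exchangeability
  fails in the other direction, and p-values can be grossly anticonservative.
  Scalar-RSM permutation results should therefore only be trusted when
  between-participant variability is substantial relative to the condition
  grid spacing. This regime is demonstrated by a dedicated test and is why
  the null-dataset pipeline check asserts the fRSA route.

## The behavioral (ITI) pipeline

Tap cleaning removes onsets closer than 30 ms to the previously retained tap
(greedy left-to-right scan). The participant's mean tap–tone asynchrony,
computed across all trials and conditions after cleaning, is subtracted from
every onset; taps whose residual asynchrony to the nearest tone exceeds
80 ms (less than half the smallest stimulus IOI) are excluded. Per pattern
repetition, the cycle's two tones plus the first tone of the next repetition
are matched to their closest taps; $\mathrm{ITI}_1$ and $\mathrm{ITI}_2$
are the spans between the three matched taps and the produced ratio is
$\mathrm{ITI}_1 / (\mathrm{ITI}_1 + \mathrm{ITI}_2)$. Two conventions the
source procedure leaves open are fixed here: (i) when one tap is the nearest
neighbor of two tones, the pairing with the smaller asynchrony wins and the
losing tone's cycle is excluded; (ii) the loop boundary at $nT$ — the onset
the next pattern would have — serves as a matching target for the final
cycle, so all 30 repetitions per trial are scoreable.

Categorization in the produced ratios is quantified two ways. First, the
pooled condition means are fitted with a straight line and with a
4-parameter logistic $y = a + (b - a)/(1 + e^{-k(x - x_0)})$ (free
asymptotes, threshold $x_0$; least squares from five deterministic starts
via `minpack.lm`), compared by a Wilcoxon rank-sum test on
leave-one-participant-out cross-validated $R^2$. The rank-sum (rather than
signed-rank) form follows the source procedure's wording even though folds
are paired. Second, pooled per-cycle ratios are binned into 13 equal bins
over the stimulus range (out-of-range values clamp to the edge bins) and
tested against uniformity with a chi-square statistic on 12 degrees of
freedom.

## Spectral conventions

FFT coefficients are divided by the signal length (a unit-amplitude
exact-bin cosine has magnitude 0.5 per conjugate bin); any consistent
convention leaves correlations and z-scores unchanged, and tests assert this
one. The z-score baseline uses the sample SD ($n - 1$); the population-SD
variant is available via an argument and differs by the fixed factor
$\sqrt{8/7}$. Frequencies of interest are at least 30 bins from the spectrum
edge at the default 22.5-s epochs, so baselines never truncate.

For noiseless periodic signals containing only harmonics below Nyquist, the
time-domain RSM (Pearson correlation of demeaned average cycles) coincides
with the frequency-domain RSM on the full harmonic set by Plancherel's
theorem — exactly so when each feature vector is mean-zero, which is how the
equivalence oracle constructs its fixtures; for generic signals the two
differ by terms of the order of the feature-vector means (empirically
$\sim 10^{-3}$ in correlation units at 95 harmonics), which is one reason
the frequency-domain route is preferred.

Filtering is zero-phase (forward–backward Butterworth): the source
procedure does not state phase handling, and a causal filter's group delay
would rotate Fourier coefficients by frequency-dependent phases and distort
feature-vector correlations. Downsampling decimates without an extra
anti-alias stage, matching the "by a factor of 4" convention after a prior
low-pass; a warning fires if the processing log shows no low-pass stage.

## Prototype analysis

Templates are two-impulse-per-cycle unit impulse trains at 76 ratios equally
spaced over 0.50–0.84, realized on the sample grid (the stored
`realizedRatios` make the analytic magnitude $2|\cos(\pi k r)|$ per cycle an
exact oracle). Note the grid's stated upper endpoint (0.84) sits slightly
beyond the 127.5-ms shortest-interval rationale that would give 0.83; the
stated numbers are followed and the tension is recorded rather than
resolved. Response fingerprints are noise-corrected magnitudes at the
frequencies of interest (the same 8-bin local baseline, subtracted rather
than standardized; values may be negative and are not clipped). Template
fingerprints are noiseless and used raw.

The bootstrap resamples participants with replacement (one resample shared
by all conditions per iteration), averages fingerprints — valid because the
noise correction is linear, so averaging corrected fingerprints equals
correcting the resampled grand average — and stores the template ratio with
the highest Pearson correlation per condition (1000 iterations by default).
The on-stimulus test counts best-template ratios inside a window bounded by
the midpoints to the neighboring conditions versus outside, each count
divided by the ratio span it covers (in-width plus out-width equal the full
template range); the bootstrap is re-run 500 times and the response is
flagged off-stimulus when the index is negative in more than 95% of runs
(add-one proportion, Bonferroni-corrected by the number of conditions).

Category-pooled distributions (split at the median best boundary) are
smoothed with a Gaussian kernel using Silverman's rule-of-thumb bandwidth on
a fixed grid over the template range; peaks are local maxima above 10% of
the mean grid density. Each peak is tested with a window one condition-grid
step wide against directly flanking regions of half that width per side;
the peak's $p$ is the add-one proportion of outer bootstrap runs with index
$\le 0$, Bonferroni-corrected by the number of peaks tested. Read literally,
the source procedure's "proportion of times the index was larger than zero"
would give $p \approx 1$ for genuine peaks; the $\le 0$ direction is the
only one consistent with its use and is adopted deliberately.

## The synthetic generators

`simulationSpec()` fixes the study conditions: 13 conditions from 0.50 to
2/3 with a 750-ms pattern looped 30 times; 18 participants; 3 tapping and 6
EEG trials per condition; a category boundary after condition 5 (boundary
ratio 0.5625) with attractors at 0.53 and 0.63 — prototype ratios reported
for tapping, giving non-integer ground truth; attractor pull (warp) 0.8;
10-ms Gaussian tap jitter; 30-ms mean anticipation; 2% missed and 1%
spurious taps. Tapping trials place taps on the event grid of the produced
(warped) ratio plus a continuation tap at the loop boundary. EEG-like trials
convolve the produced-ratio impulse train (circularly, so the noiseless
response is exactly periodic) with a gamma-shaped kernel peaking at 100 ms,
scale it by a frontocentral-maximal topography over a 64-channel 10-20
montage, and add 1/f noise (exponent 1) plus 8–12-Hz band-limited noise per
trial and channel at 256 Hz. The default noise scale was fixed once so that
the grand-average harmonic z-scores at the full study scale are moderate:
the leading harmonics clear the 3.09 criterion comfortably while the 8-Hz
harmonic is marginal, so the consecutive-significance rule is genuinely
exercised, as in real recordings where alpha activity swamps high harmonics.

What the generators do *not* emulate: drifting tempo, serial dependence of
tap errors, non-stationary or spatially correlated EEG noise, volume
conduction, artifacts (blinks, muscle), or individual differences in
boundary position and kernel shape. Passing recovery tests therefore show
the estimators are correct under the stated model, not that real data meet
its assumptions.

## Numerical choices and problem sizes

Ratios are compared with tolerance $10^{-9}$; asymmetry beyond $10^{-9}$
rejects a matrix; rank residuals with norm below $10^{-10} n$ are treated
as undefined (reported `NA`, never $\pm\infty$); correlations of magnitude
1 are clipped at $1 - 10^{-12}$ before Fisher transforms, with a warning.
Every stochastic function takes a local seed and restores the caller's RNG
stream. Default iteration counts follow the study conventions (5000
individual / 10000 group permutations, 1000-iteration prototype bootstrap
with 500 outer repetitions, 10000 bootstrap medians). The test suite and
acceptance script run the same code at reduced sizes chosen to keep the
full suite around two minutes on one CPU — 200–2000 permutation iterations,
150–500 inner and 40–300 outer bootstrap repetitions, and EEG simulations
with 2–9 channels and 2 trials except for one full-scale tapping study of
18 participants — since every check scales in distribution, not in kind.

## Known limitations

- Permutation p-values assume triangle exchangeability (see above); the
  scalar-ITI route on nearly noiseless data is the failure mode to watch.
- Harmonic selection happens at the group level; individual RSMs reuse the
  group frequency set, so atypical individual spectra are not re-selected.
- The prototype grid inherits the 0.50–0.84 endpoints; responses genuinely
  attracted beyond 0.84 would alias onto the grid edge.
- EDF/BrainVision/WAV support covers the continuous, uncompressed variants
  the pipeline writes and reads; annotation channels and segmented files
  are out of scope, as are acquisition-side preprocessing steps (ICA,
  channel interpolation, re-referencing), which are assumed done upstream.
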