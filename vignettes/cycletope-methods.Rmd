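---
title: "Detecting cycling transcripts with cycletope: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cycling transcripts with cycletope: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Circadian profiling experiments measure gene expression every 1–4 hours over
1.5–4 days and ask which transcripts oscillate with a roughly 24-hour period.
Template-based detectors (cosinor fits, rank-correlation against reference
waveforms) miss rhythms that do not resemble the chosen templates, and their
permutation nulls — fully randomized time-series — allow expression jumps
faster than transcription and degradation permit, which biases significance.

cycletope takes a dynamical-systems view instead. A state variable that
cycles traces a closed loop in its state space; a scalar observation of that
system can reconstruct the state space (up to diffeomorphism) through a
time-delay embedding. Rhythmicity then becomes a *topological* property —
"is there a loop?" — measurable without committing to any waveform shape.

## The detection pipeline

For each gene the pipeline is:

1. **Replicate averaging.** Replicate time-points are averaged (missing
   entries ignored; a cell is missing only if missing in all replicates).
2. **Grid regularization and imputation.** Uneven grids are linearly
   resampled at the minimum observed interval; interior missing values are
   linearly interpolated and boundary gaps filled by nearest-value
   extension (linear extrapolation could manufacture drift that the
   embedding would read as signal).
3. **Standardization.** Each gene is mean-centered and scaled to unit
   (n−1) variance. This is what makes a *shared* null possible (below).
4. **Delay embedding.** The series \(x_t\) becomes points
   \((x_t, x_{t-\tau}, x_{t-2\tau})\) in \(\mathbb{R}^3\). Three
   coordinates, not two, so that a drifting oscillation — a helix in the
   embedding — keeps its circular component separable from the drift axis.
5. **Laplacian Eigenmaps.** The 3-D cloud is projected to 2-D using the
   eigenvectors of the symmetric normalized Laplacian of its heat-kernel
   weighted symmetric kNN graph (2nd and 3rd smallest eigenvalues). Local
   circular geometry survives; a dominant drift axis is discarded. If the
   drift dominates the local geometry, the projection keeps the drift
   instead and the gene scores low — the desired behaviour, since such a
   signal is not strictly periodic.
6. **Persistent homology.** Circularity of the 2-D cloud is the maximum
   persistence of an H1 class in the Vietoris–Rips filtration: points are
   connected when at most \(2\epsilon\) apart, a loop is born at
   \(\epsilon_b\) and filled at \(\epsilon_d\), and the score is
   \(\epsilon_d - \epsilon_b\) (radius scale). Z/2 coefficients; the
   filtration is capped at the cloud diameter, where all loops have died.
7. **Lag sweep.** No single delay \(\tau\) is optimal for short noisy
   series, so steps 4–6 run for every feasible lag in a small set
   (default \(\{2,3,4,5\}\) samples) and the per-lag maxima are averaged:
   a truly rhythmic signal should look circular *on average* across lags.

### Significance: the finite-difference permutation null

The null model permutes the *first differences* of a series and
re-accumulates them. The resulting random series has exactly the same
marginal distribution of expression changes as the data — it respects the
rates at which transcription and degradation can move a transcript — while
destroying the temporal ordering that creates a loop. Because every gene is
standardized first, one pool of permuted series serves all genes: each of
the `resamples` draws picks a source gene uniformly at random (from a
lexicographically ordered candidate list, so gene order cannot affect the
null), permutes its differences, re-standardizes, and scores it through
steps 4–7. The per-gene p-value is the add-one empirical tail
\(p = (1 + \#\{s_{null} \ge s_{obs}\})/(1 + n)\), so \(p = 0\) is never
reported and the resolution floor is \(1/(n+1)\). Genes are ranked by
Benjamini–Hochberg q-values.

The null is built *after* imputation, so the smoothness assumptions
introduced by interpolation are shared by the null model and do not inflate
significance. Whether to re-standardize after permuting differences is
ambiguous (the permutation preserves endpoints but not variance exactly);
cycletope re-standardizes so observed and null scores are on the same
scale.

### Rhythm parameters

Period, phase and amplitude come from a separate harmonic fit of the
replicate-averaged, imputed but **unscaled** series (so amplitude keeps its
expression units). The series is linearly detrended and smoothed with a
centered window-3 moving average *only to select frequencies*: the three
largest-magnitude positive DFT bins. The trend line and those harmonics are
then re-fit jointly by least squares to the raw series, and the fitted
harmonic curve yields period (dominant harmonic), phase (time of the first
fitted maximum within one period, in \([0, P)\)), and amplitude (half the
fitted peak-to-trough range). Fitting the *unsmoothed* series matters: a
window-3 moving average attenuates a 24-h harmonic sampled every 2 h by
\((1 + 2\cos(\pi/6))/3 \approx 0.91\), and the joint fit also avoids the
small bias from the non-orthogonality of a line and a bin-aligned sinusoid
on finite grids. On bin-aligned noiseless sinusoids recovery is exact to
machine precision. The dominant harmonic is searched within periods
\([P_0/2, 2 P_0]\) (default \(P_0 = 24\) h) to avoid trend leakage into the
lowest bins.

## Tunable parameters

| parameter | default | units | why |
|---|---|---|---|
| `lag_set` | 2–5 | samples | small lags keep clouds dense for short series; theory is lag-insensitive |
| `k_neighbors` | 6 | points | standard spectral-embedding practice; clamped to n−1 for tiny clouds |
| `heat_scale` | `"auto"` | distance | median pairwise distance; scale-free bandwidth |
| `resamples` | 10,000 | – | p-value floor 1/10,001; use 1,000 for exploration |
| `period_h` | 24 | hours | circadian prior; only bounds the dominant-harmonic search |
| `seed` | 1234 | – | the null is drawn once from this seed before scoring |

The eigenvector sign/rotation ambiguity of the eigenmap is irrelevant:
Rips persistence is invariant to rigid motions, and p-values depend only on
score ranks, so any consistent monotone rescaling of the persistence
measure leaves inference unchanged.

## The synthetic benchmark

`simulate_grid()` reproduces the published benchmark design: 144 datasets
crossing replicates (1–3), sampling interval (1, 2, 4 h), duration (36, 48,
72, 96 h) and Gaussian noise at 10–40% of each waveform's amplitude, with
11,000 genes per dataset — 1000 per waveform family, seven cyclic families
(sine, peak, sawtooth, linear trend, damped, amplified, contractile) and
four non-cyclic (flat, linear, sigmoid, exponential). The exact parameter
distributions of the original benchmark live in external code, so this
package declares its own: amplitude log-uniform over a 4-fold range [1, 4],
baseline U(5, 10), phase U(0, 24) h, peak sharpness κ ∈ U(2, 8), sawtooth
rising fraction U(0.1, 0.9), damped/amplified envelope half-life U(24, 96)
h, contractile period-shrink rate U(0.05, 0.12), trend slope
±U(0.5, 2)·amplitude/96 per hour, sigmoid steepness U(0.1, 0.5) with
midpoint U(12, 36) h, exponential rate ±U(0.005, 0.02) per hour. These were
fixed once as realistic values for circadian expression and are recorded
here for reproducibility. Replicates are i.i.d. noise draws around a shared
base curve. `degrade_missing()` masks a floor-rule fraction per gene (never
below 2 observed points); `inject_outliers()` replaces cells at a Bernoulli
rate with draws uniform on the two bands 3–4 standard deviations from the
gene's diurnal mean, side chosen evenly.

What a green benchmark test does **not** establish: the generator draws
i.i.d. Gaussian noise around smooth curves, with no count-noise
mean–variance coupling, no correlated technical noise across genes or
samples, no batch structure, and waveform parameterizations that are this
package's stand-ins rather than the original benchmark's. Synthetic AUCs
therefore validate the machinery, not field performance on any particular
platform.

## Numerical choices and degenerate inputs

- Zero-variance or all-missing genes (and genes with fewer than 3 usable
  points) cannot be standardized; they get persistence 0, p = 1 and
  undefined rhythm parameters, with a warning.
- Clouds whose points all coincide, or whose largest kNN-graph component
  has fewer than 3 points, are degenerate: persistence 0.
- Filtration ties (equal distances) are ordered by edge index; only the
  maximum persistence is consumed, so tie-breaking cannot change results.
- Feasibility: a lag τ needs N − 2τ ≥ 3 embedded points; infeasible lags
  are skipped with a warning, and a run errors only if no lag is feasible.
- Eigenmap of very small clouds clamps k to n − 1 (a complete graph).

## Known limitations

- Sharply peaked waveforms sampled coarsely (e.g. κ near 8 at 4-h
  sampling, and to a lesser degree 2-h) spend few samples on the peak; the
  embedded loop does not close and sensitivity for the "peak" family is
  poor at desk scale even at low noise. Aggregate discrimination remains
  at the published level.
- Strong drift (slope comparable to amplitude per period) dominates the
  local geometry and suppresses the cycle, so long records of trending
  oscillators are increasingly called non-cycling — by design, since such
  signals are not strictly periodic, but users wanting them flagged should
  detrend upstream.
- The shared null assumes all genes share a series length (guaranteed by
  the common grid) and trades gene-specific nulls for a pooled one; genes
  with idiosyncratic difference distributions are tested against the
  pooled behaviour.
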