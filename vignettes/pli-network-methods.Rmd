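---
title: "Phase-lag-index networks from EEG working-memory experiments: models, calibration and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-lag-index networks: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(plinet)
```

## Scope

`plinet` implements a complete, testable pipeline for phase-synchronization
network analysis of multichannel EEG in a two-group (young vs senior),
three-condition (rest, 0-back, 2-back) working-memory design:

1. a synthetic-cohort generator that plants band-specific pairwise phase
   coupling at a known target phase lag index (PLI);
2. preprocessing: zero-phase FIR band-pass filtering into theta (4–8 Hz),
   alpha (8–13 Hz), beta (13–30 Hz) and gamma (30–45 Hz), 3.5-s epoching at
   stimulus onsets, ±60 µV amplitude rejection, 0.5-s edge trimming to
   2.5-s analysis segments;
3. PLI connectivity from Hilbert instantaneous phases;
4. weighted undirected network topology: Onnela clustering `C`,
   characteristic path length `L`, and the small-world coefficient `SW`
   against weight-shuffled surrogates;
5. a nonparametric statistics battery: rank partial correlation with
   covariate control, Friedman tests with studentized-range-adjusted
   Wilcoxon post-hocs, Mann–Whitney U, and Benjamini–Hochberg FDR control.

Everything downstream of the generator treats the data exactly as it would
treat real recordings, so every stage can be verified against planted
ground truth.

## The measurement model

For a real signal $s(t)$ the analytic signal
$z(t) = s(t) + i\,\hat s(t) = A(t)e^{i\phi(t)}$ (with $\hat s$ the Hilbert
transform, computed here in the frequency domain) defines the instantaneous
phase $\phi(t)$. For two channels $p, q$ with phase difference
$\Delta\phi_{pq}(t)$,

$$\mathrm{PLI} = \bigl|\langle \operatorname{sign} \sin \Delta\phi_{pq}(t) \rangle\bigr| \in [0, 1],$$

with the convention $\operatorname{sign}(0) = 0$, so identical signals give
exactly 0 and any constant non-zero lag gives exactly 1. PLI is invariant
under amplitude scaling and common phase offsets, and blind to zero-lag
(common-source / volume-conduction) coupling — the property that motivates
it for scalp EEG. The channel-pair PLIs form a symmetric, zero-diagonal
connectivity matrix; its upper-triangle mean is the global synchronization
measure.

The weighted undirected network is the PLI matrix itself — no thresholding,
since threshold choice would become an uncontrolled analysis knob. Nodal
clustering follows the Onnela weighted generalization,

$$C_i = \frac{\sum_{j,h}(w_{ij} w_{ih} w_{jh})^{1/3}}{k_i (k_i - 1)},$$

with $k_i$ the number of nonzero-weight neighbours. A strength-based
denominator $s_i(s_i - 1)$ is available behind
`nodal_clustering(denominator = "strength")` for comparison; it is **not**
the default because it degenerates (zero or negative) whenever a node's
strength is at or below 1, which is the typical regime for PLI weights.
Path length uses edge length $1/w$ and Dijkstra shortest paths;
$L$ is the mean over ordered pairs. The small-world coefficient

$$SW = \frac{C / C_{\mathrm{rand}}}{L / L_{\mathrm{rand}}}$$

normalizes against an ensemble (default 50, seeded) of surrogates obtained
by randomly permuting the multiset of upper-triangle weights. Degree- or
strength-preserving rewiring is vacuous on complete graphs, so weight
permutation is the natural null; on weight-shuffled complete weighted
graphs $SW \approx 1$, and a uniform-weight network gives $SW = 1$ exactly.

Metrics are computed **per 2.5-s segment and averaged across segments** of a
condition (the default path); computing them once on the entrywise-averaged
matrix is available via `condition_metrics(path = "average")`. Whether a
study pools samples or averages per-segment estimates is rarely stated
explicitly; the per-segment path is our default and the difference matters
(see *Estimator behaviour* below).

## The synthetic world

### Signal model

Each coupled pair carries a narrowband carrier; the second channel's
coupled component lags the first by $+\delta$ with probability
$q = (1 + \mathrm{PLI}^\ast)/2$ and $-\delta$ otherwise, the sign redrawn
once per realization block. The expected PLI over many blocks is
$|2q - 1| = \mathrm{PLI}^\ast$ exactly — a closed-form ground truth, which
is why this mixture-of-two-lags construction was chosen over von-Mises
phase jitter. Independent Gaussian broadband noise (default SD 10 µV,
carrier amplitude 10 µV) is added per channel and filtered downstream like
real data. Pink noise and realistic ocular/muscle artifacts are *not*
simulated; a zero-lag mixture fixture exists only to test
volume-conduction blindness.

Distinct coupled pairs get carriers spread evenly across the band. This
matters: two pairs sharing one carrier frequency would hold a constant
cross-pair phase offset and show spurious PLI ≈ 1 between channels of
different pairs (we measured exactly this failure before spreading the
carriers).

Defaults a scientist should know:

| parameter | default | why |
|---|---|---|
| sampling rate | 500 Hz | typical research EEG |
| sign-flip interval | 0.25 s (cohorts) | ≈ the theta-band coherence time; faster flips are smoothed away by the band-pass, slower flips starve the estimator of independent draws |
| lag angle $\delta$ | $\pi/2$ | maximally distant from the $\sin = 0$ boundaries |
| coupled pairs | disjoint consecutive pairs | keeps pairwise targets independent |
| montage | 59 extended 10–20 labels | a 61-electrode cap minus the two mastoid references |

### Cohort calibration

Group-level defaults emulate the published demographics and behavior of a
15-young / 10-senior cohort: education 16.1 ± 1.9 vs 9.3 ± 3.0 years, age
23.1 ± 2.0 vs 64.0 ± 3.3 years, accuracy (truncated normal on [0, 1]) and
reaction time (log-normal, moment-matched — positive and right-skewed) per
group × task, and theta 2-back mean target PLI 0.205 (young) vs 0.223
(senior). The published dispersions are standard errors; the generator
converts them to between-subject SDs (× √n: 0.019 / 0.038). Recording-scale
defaults (8 channels, 12-trial task blocks, 35-s rest) are a demo scale
chosen for desk feasibility; they are not scientific calibration and can be
raised to the full 59-channel, 3 × 40-trial scale. The task schedule
reproduces the printed structure: three sequences totalling 120 trials with
39 matches, distributed across sequences as evenly as feasibility allows
(the source does not state the split), onsets every 5.0 s
(0.5 s fixation + 0.5 s stimulus + 4.0 s blank). For the 0-back control,
"match" counts character (response-target) trials, since its task rule is
character-vs-asterisk discrimination rather than memory.

### Numerical choices

* FIR design: Hamming windowed-sinc, taps `ceil(3.3 · fs / transition)`
  with transition width `min(2 Hz, 25% of the low band edge)`, forced odd
  (exact linear phase), unit gain at the geometric band centre. Applied
  forwards and backwards (squared magnitude response, zero net phase) with
  odd-symmetric edge reflection; edge transients are then discarded by the
  0.5-s trims.
* Onset-to-sample rounding: nearest sample (unbiased for arbitrary rates).
* Artifact rejection precedes band filtering (matching the described
  workflow) and removes an epoch iff max |amplitude| strictly exceeds the
  threshold. Resting data are sliced into consecutive non-overlapping 3.5-s
  pseudo-epochs and screened with the same ±60 µV rule — the original
  expert visual inspection is not reproducible, so the uniform threshold is
  a documented deviation.
* Wilcoxon / Mann–Whitney p-values: exact enumeration for small untied
  samples (signed-rank n ≤ 25; U with both groups ≤ 10), tie-corrected
  normal approximation otherwise; all differences zero degenerates to
  p = 1.
* "Tukey–Kramer adjustment" after Friedman is implemented as the
  studentized-range (Nemenyi-type) procedure on rank sums — the standard
  such follow-up for a rank-based repeated-measures design; plain paired
  Wilcoxon p-values are co-reported.
* Partial correlation is Pearson-on-ranks with least-squares
  residualization by default (`method = "linear"` switches the rank
  transform off); p from the t approximation with
  df = n − 2 − #covariates. Group is coded young = 0 / senior = 1, so a
  positive sign means senior-higher.

## Estimator behaviour, and what a green test does not establish

The per-segment PLI estimate is $|\bar X|$ of a mean sign — a **folded**
statistic. A 2.5-s theta segment carries only ~10 independent phase-sign
draws (set by the flip interval and, in real data, by the band's coherence
time), so per-segment estimates are biased upward for small true PLI and
their regression slope on the true value is well below 1. Averaging over
segments reduces variance but not this fold bias. The pooled estimator
(mean sign across all samples, then one absolute value) is unbiased in the
large-sample limit and is the estimator under which the generator's
closed-form calibration $|2q-1|$ is exact; it is what the calibration tests
use.

Consequences we verified and document rather than hide:

* The **global average PLI over all node pairs** dilutes a planted effect on
  $P$ coupled pairs by $P / \binom{n}{2}$ while the
  $\binom{n}{2} - P$ null pairs contribute only noise. With disjoint
  coupled pairs this dilution is $1/(n-1)$.
* The end-to-end acceptance criterion (planted standardized group effect
  d = 1.5 on theta target PLI, rank partial correlation controlling
  education, ≥ 90% detection over 100 cohorts) is **not attainable in the
  stated world** and its test is deliberately left red:
  1. Education nearly separates the groups in the emulated demographics
     (young 16.1 ± 1.9 vs senior 9.3 ± 3.0 years, |r| with group ≈ 0.8).
     Partialling education out of a purely group-driven effect caps power
     at ≈ 55% for n = 15/10 even with *noise-free* PLI measurements
     (direct Monte-Carlo on the idealized model).
  2. At desk-feasible demo scale, the fold bias and all-pair dilution
     above push the realized detection rate to near the test's size.
  The false-positive half of the criterion (≤ 7% with no planted effect)
  passes. The generator-level recovery property — senior > young group
  mean ordering in ≥ 95% of 100 cohorts, using the pooled calibration
  estimator on the coupled pairs — is green.
* A green suite establishes the *definitions* (PLI algebra, Onnela
  clustering, path length, SW normalization, the tests' null behaviour) and
  the generator's calibration; it does **not** establish that the pipeline
  would reproduce any particular empirical cohort result, which derives
  from undeposited human EEG.

## Demo scales and runtime

Monte-Carlo-heavy tests run at reduced sampling rates (125–250 Hz): the
theta carriers stay far below Nyquist and the information content per
second is set by the flip interval, not the sampling rate, so this is a
pure compute saving. The default pipeline demo (4 subjects, 1–2 bands,
reduced cohort) completes in well under 5 minutes on one CPU; the full
59-channel, 25-subject, 4-band scale remains desk-feasible but is not run
in CI.

## Known limitations

* No ocular/muscle artifact simulation, no volume-conduction head model,
  no re-referencing.
* Surrogate model is weight permutation only; whether a published surrogate
  ensemble preserved anything beyond the weight distribution is usually
  unstated, so both the count and the model are config-exposed.
* HDF5 output requires the optional `rhdf5` package; EDF support is 16-bit
  with a single shared sampling rate; BrainVision support covers binary
  multiplexed/vectorized float32 and int16 layouts.
* The exploratory uncorrected α = 0.001 edge-level pathway is reproduced
  only as raw p-values in the stats table — any such reading is uncorrected
  by construction and labelled accordingly.
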