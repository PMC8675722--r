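---
title: "Topological analysis of EEG functional brain networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological analysis of EEG functional brain networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegtda)
```

## The analysis in one paragraph

Multichannel EEG evoked by a stimulus is treated as a point cloud of
channels. A channel-by-channel dissimilarity matrix is thresholded at an
increasing scale $\varepsilon$, producing a growing family of graphs whose
clique complexes form a Vietoris--Rips filtration. Two families of
topological summaries are tracked along the filtration and compared
between paired experimental conditions (e.g. a clear versus a degraded
visual stimulus), separately per frequency band:

* the **Euler characteristic**
  $\chi(\varepsilon) = \sum_{k=0}^{K} (-1)^k \mathrm{Cl}_k(\varepsilon)$,
  where $\mathrm{Cl}_k$ counts the $k$-simplices (nodes, edges, triangles,
  tetrahedra; $K = 3$ by default) of the clique complex, its trial average
  $\langle\chi\rangle$, the **Euler entropy**
  $S_\chi = \ln |\langle\chi\rangle|$, and the **topological phase
  transition**: the scale $\varepsilon^\ast$ at the negative peak of
  $S_\chi$, i.e. where $\langle\chi\rangle$ crosses zero;
* the **persistence barcode** of the filtration in homological dimensions
  0 and 1, summarised by the **persistent entropy**
  $H = -\sum_i p_i \ln p_i$, $p_i = (y_i - x_i)/L$,
  $L = \sum_i (y_i - x_i)$ over bars $[x_i, y_i]$, and its rescaled form
  $\hat H = H / \ln \ell_{\max}$ with $\ell_{\max}$ the longest bar.

Per-subject features (transition scale, entropies) are compared between
the two conditions with a two-sided paired t-test, one test per feature
and band.

## Distance matrices: the two branches

Two dissimilarities feed the two branches, and they are deliberately
different:

* **Phase-locking value (PLV)** for the Euler branch. Instantaneous
  phases $\phi^r(n)$ are obtained from the analytic signal of each
  band-filtered channel (quadrature component from the one-sided
  spectrum), and
  $\mathrm{PLV}(r,t) = \frac{1}{N}\left|\sum_n e^{j(\phi^r(n)-\phi^t(n))}\right|$.
  PLV is a similarity in $[0,1]$; the filtration needs a dissimilarity,
  and the edge rule "connect $r,t$ when their normalized correlation
  exceeds $1-\varepsilon$" is exactly the Rips rule on $1-\mathrm{PLV}$.
  `plv_distance_matrix()` therefore stores $1-\mathrm{PLV}$ and keeps the
  raw PLV retrievable from the `"similarity"` attribute.
* **Standardized Euclidean distance** for the persistence branch. Each
  channel is a point whose coordinates are its $N$ sample values;
  coordinate $k$ is divided by $v_k$, the sample standard deviation
  (denominator $n-1$) across all channels at sample position $k$:
  $d(r,t) = \sqrt{\sum_k \left((r_k - t_k)/v_k\right)^2}$. We compute
  $v_k$ across channels — the standard standardized-Euclidean convention —
  although the defining text for the quantity could also be read as a
  per-channel statistic; the conventional reading is the one that makes
  the denominator shared between $r$ and $t$. The metric is invariant to
  a global affine map $x \mapsto a x + b$ applied to all channels at
  once: the offset cancels in the differences and the scale cancels
  through $v_k$.

Standardized-Euclidean matrices are **not** rescaled to $[0,1]$ by
default. The rescaled entropy divides by $\ln \ell_{\max}$, which is
non-positive when every bar is shorter than 1: normalizing the matrix
would make $\hat H$ ill-defined, so `normalized_persistent_entropy()`
refuses rather than silently flipping sign, and a `unit_max`
normalization is available only as an explicit flag.

Trial handling is `per_trial` by default: each trial yields its own
matrix, the Euler characteristic is averaged over trials
($\langle\chi\rangle$), and entropies are averaged over trials per
subject. `mean_over_trials` is available where a single averaged network
is wanted.

## Filtration, Euler entropy, and the phase transition

`euler_entropy_curve()` evaluates clique counts by exact recursive
enumeration (compiled) on a grid of $\varepsilon$: 101 evenly spaced
points on $[0,1]$ for PLV dissimilarity, and on $[0, \max d]$ for
unnormalized metrics. The truncation at $K = 3$ is the definition of the
statistic, not an approximation we control: counts above $K$ are ignored
exactly as the truncated alternating sum prescribes.

$\ln|\langle\chi\rangle|$ at $\langle\chi\rangle = 0$ is stored as
$-\infty$, and `detect_phase_transition()` treats any such singularity as
the transition; when $\langle\chi\rangle$ never vanishes on the grid the
smallest $\varepsilon$ attaining the global minimum of $S_\chi$ is
returned (ties break to the smallest scale, matching the "first
transition" reading). A constant curve is flagged `degenerate` with a
warning rather than an error. On fixtures with a clean hole — the four
corners of the unit square are the worked example, with distance multiset
$\{1,1,1,1,\sqrt2,\sqrt2\}$, regimes $\chi = 4, 0, 1$ and a single H1 bar
$[1,\sqrt2]$ — the detected transition coincides, within one grid step,
with the crossing of the $\beta_0$ and $\beta_1$ curves.

## Persistence: algorithm and conventions

`rips_persistence()` computes dimensions 0 and 1 by boundary-matrix
reduction over the two-element field, written in compiled code inside the
package (no external TDA engine in the main path; a brute-force full
reduction lives in the test suite as an independent oracle):

* H0 by union-find over the weight-sorted edge list (elder rule);
* H1 by reducing triangle columns against edge rows. Any $\mathbb{Z}_2$
  sum of triangle boundaries is a 1-cycle, and the latest edge of a cycle
  is necessarily cycle-creating, so pivots land only on positive edges
  and the vertex/edge part of the matrix never needs to be materialised.

Conventions, each of which some tools choose differently:

* The surviving connected component's infinite bar is **capped** at
  `max_filtration` (the matrix maximum by default) and flagged in column
  `infinite`, so it contributes to entropy; dropping it would silently
  remove the largest bar from $\ell_{\max}$.
* Zero-persistence pairs — the bulk of any Rips reduction — are dropped
  from the barcode, as persistence software conventionally does; the
  entropy definition discards them anyway.
* Entropies pool dimensions 0 and 1 by default (`dimensions = c(0, 1)`),
  with per-dimension selection available; natural logarithms are used
  throughout, for consistency with the Euler entropy.

## The synthetic generator

No public recordings accompany the analysis this package implements, so
the generator is a first-class module: it is the only way every
downstream stage can be validated quantitatively.

Each channel $c$ in module $m$ receives
$$x_c(t) = \sum_b a_b \cos\!\big(2\pi f_b t + \psi_m(t) + \theta_c(t)\big) + \eta_c(t),$$
with one carrier per band ($f$ = 2, 6, 10, 22 Hz, unit amplitude),
$\psi_m$ a Gaussian random-walk module phase (increment SD 0.05
rad/sample) optionally locked across modules through a von Mises term
with concentration $\kappa_{\mathrm{cross}}$, $\theta_c$ i.i.d. von Mises
jitter with the condition's within-module concentration
$\kappa_{\mathrm{within}}$, and $\eta_c$ white Gaussian noise.

Two modelling choices deserve emphasis:

* **Jitter is redrawn every sample.** With constant-within-trial jitter
  the within-trial PLV of two same-module channels would be exactly 1
  whatever $\kappa$; per-sample jitter instead gives the closed form
  $\mathrm{PLV} \to (I_1(\kappa)/I_0(\kappa))^2$ (`expected_plv()`),
  which is what makes the generator falsifiable — the empirical PLV at
  $\kappa = 2$ must land on $0.6978^2 \approx 0.487$ within 0.02 at
  $10^4$ samples, and the test suite checks exactly that.
* **One jitter process per channel**, applied to every carrier, rather
  than independent jitter per band: the per-band closed form is
  unchanged and the generator stays cheap at 64 channels.

Defaults mirror the study conditions the pipeline is meant for: 64
channels (four modules of 16, a coarse stand-in for lobe-scale
organisation), 250 Hz, 2-s epochs, 20 subjects, 40 trials per condition —
the per-class trial count of an 80-image session — with noise SD 0.5
against unit carriers, a moderate signal-to-noise choice fixed once. The
condition effect is a difference in $\kappa_{\mathrm{within}}$ (defaults
2 vs 4): stronger within-module locking for the harder stimulus, the
direction suggested by the observation that degraded images recruit more
coordinated activity. The generator makes no claim about the mechanism
linking stimulus quality to coupling; it plants a known effect so that
recovery can be tested. Per-subject/condition seeds are derived
arithmetically from the master seed, so studies are reproducible and
subjects independent.

What the generator does **not** emulate: realistic EEG spectra (1/f
background), artifacts (blinks, EMG), volume conduction, or electrode
geometry. Passing tests therefore demonstrate that the pipeline recovers
planted phase-coupling structure through the full preprocessing and TDA
chain — not that any specific neurophysiological claim holds on real
recordings.

## Preprocessing choices

The filter family is unspecified in the analysis this package follows;
we use zero-phase forward-backward Butterworth filters (4th order per
pass) for their flat passband, applied with reflection padding, and
document them as swappable. Band-pass gain is validated against the
closed-form response: an in-band tone is retained within 5%, a tone one
octave outside the band is attenuated by at least 20 dB. Decimation
(e.g. 1000 Hz to 250 Hz) low-passes at 0.4 times the target rate (a
standard guard band) before keeping every $q$-th sample; only integer
factors are supported. Epochs default to the 2 s after stimulus onset.
Filtering is applied after epoching with edge padding; with the
recommended epoch lengths the two orders differ only in edge transients.

## Worked example

A small synthetic study, end to end (sizes chosen to run in seconds):

```{r example, eval = FALSE}
library(eegtda)

rc <- run_config(
  spec = coupling_spec(n_channels = 16, n_modules = 4,
                       within_module_concentration = c(clear = 2, unclear = 4)),
  config = simulation_config(n_subjects = 6, n_trials_per_condition = 8,
                             sampling_rate = 250, epoch_duration = 1,
                             seed = 1),
  bands = c("alpha", "beta")
)
res <- run_pipeline(rc, output_dir = "eegtda-demo")
res$tests
```

The result table has one row per feature, band and condition pair:
`transition_epsilon` (the Euler-entropy phase transition of the
trial-averaged PLV network), and `persistent_entropy` /
`normalized_persistent_entropy` (trial means from the standardized
Euclidean barcodes), each tested with the paired t-test across subjects
(raw p-values primary, Holm-adjusted column as a conservative extra).

## Numerical and degenerate-input policy

* Distance matrices must be symmetric with zero diagonal (enforced at
  construction; asymmetry beyond $10^{-8}$ is an error, not repaired).
* A constant channel has no phase: `instantaneous_phase()` errors naming
  the channel. A zero-variance sample position makes $v_k$ degenerate:
  `std_euclidean_matrix()` errors listing the offending positions.
* `paired_ttest()` on identical vectors returns $t = 0$, $p = 1$ (a
  well-defined degenerate case); zero-variance differences with nonzero
  mean are refused.
* Argmin ties in transition detection go to the smallest $\varepsilon$;
  grid resolution is the analyst's choice (101 points by default) and the
  reported transition is exact only to one grid step.
* Perturbing a matrix by $\delta$ in sup-norm moves every finite
  birth/death by at most $\delta$ (Rips stability); the suite smoke-tests
  this at $\delta = 0.01$.

## Problem sizes used in the validation suite

The test suite exercises the exact combinatorial cores at full fidelity
(brute-force oracles on graphs with up to 10 vertices and metrics with up
to 8 points, where enumeration is exact and fast) and the stochastic
claims at reduced but sufficient scale, chosen once: the null calibration
of the paired test uses 200 replicate studies of 10 subjects with 12
channels, 2 trials per condition and 0.5-s epochs; the planted-effect
recovery check uses 10 subjects at the full 64-channel geometry with 16
trials per condition. The acceptance script runs the planted-effect
analysis at full study scale (20 subjects, 64 channels, 40 trials per
condition, 2-s epochs at 250 Hz).

## Known limitations

* Homology stops at dimension 1 (components and holes); no H2 or higher,
  matching the truncated Euler sum at $K = 3$.
* Only the two distance constructions above are provided — no coherence,
  imaginary PLV or wPLI.
* The EDF reader handles plain continuous EDF (one shared sampling rate,
  annotations skipped), not the full EDF+ event model.
* Rational-factor resampling is not implemented; choose a target rate
  that divides the acquisition rate.
* The paired design assumes exactly two conditions per subject; more
  complex designs (sessions, distortion types) are accommodated by the
  `distortion_type` stratum of the result table, not by a mixed model.
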