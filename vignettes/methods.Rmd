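---
title: "Directed brain networks, middleman power, and progressive decline: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Directed brain networks, middleman power, and progressive decline: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpgcnet)
```

## The problem

Resting-state fMRI gives, per subject, a T x q matrix of BOLD time series —
one column per region of interest (ROI). Undirected "functional
connectivity" (Pearson correlation between columns) says which regions
fluctuate together, but not who drives whom. This package estimates
*directed* networks via Granger causality — region X causes region Y if X's
past improves prediction of Y's future beyond Y's own past — and then asks
which nodes occupy critical broker positions in those networks, and whether
those nodal roles decline across four ordered clinical groups (normal
controls NC, early and late mild cognitive impairment EMCI/LMCI, and
Alzheimer's disease AD).

Two methodological obstacles shape the design:

1. **Hemodynamics.** The BOLD signal is the latent neural signal convolved
   with a hemodynamic response function (HRF) that varies across regions
   and subjects. Regional differences in HRF latency masquerade as
   temporal precedence, confounding lag-based causality. We therefore
   blindly deconvolve each ROI series before model fitting.
2. **Instantaneous correlation.** At a TR of ~3 s much genuine neural
   interaction collapses into zero-lag covariance. If the autoregressive
   model omits contemporaneous terms, that covariance leaks into the lagged
   coefficients. We therefore fit a zero-lag-augmented model and read
   causality only from the lagged terms ("correlation-purged" Granger
   causality, CPGC).

## Model and pipeline

### Blind deconvolution

Resting-state activity is treated as spontaneous event-related activity.
Per ROI:

- **Pseudo-events** are local maxima of the standardized (linearly
  detrended, zero-mean, unit-variance) series exceeding `threshold_sd`
  (default 1) standard deviations. Detection is invariant to affine
  rescaling.
- The **HRF** is fit by least squares with a three-function basis: the
  canonical double-gamma response, its temporal derivative (latency) and its
  dispersion derivative (width), with event onsets placed on a small grid
  of lags (0-2 samples) before each detected peak; the lag minimizing the
  residual variance wins. Because the data are sampled at the TR and the
  latent activity is modeled as sustained within a TR, all kernels are
  block-averaged over one TR (the basis is convolved with a TR-long boxcar
  before sampling). Point-sampled kernels would carry a systematic ~TR/2
  group delay.
- The **latent series** is recovered by Wiener inversion: latent spectrum
  `conj(H) * S / (|H|^2 + nsr)`, computed on a zero-padded grid so the
  inverse acts on the linear convolution. `nsr` (default 0.1, or a crude
  data-driven estimate) trades noise amplification against temporal
  smearing; columns with fewer than three events fall back — loudly — to
  the canonical HRF.

### Correlation-purged Granger causality

For each region i, its (demeaned) series is regressed on the
contemporaneous values of all other regions and on every region at lags
1..p (default p = 1: at a 3-second TR a first-order model captures the
relevant causal delays). The contemporaneous block has a zero diagonal and
is *not* interpreted — it exists only to absorb instantaneous covariance.
The causal strength from j to i is the sum over lags of the squared lagged
coefficients. When the per-equation design approaches saturation
(predictors >= 0.8 x samples, as happens at q = 200 with T = 140), the
equation switches to ridge regression with a GCV-chosen penalty and says
so; at the package's default simulation scale ordinary least squares is
used.

### Surrogate thresholding

Each connection's strength is referred to a null distribution obtained by
phase-randomizing every column independently (preserving each series'
magnitude spectrum, hence mean, power and autocovariance, while destroying
all cross-structure) and refitting. With R surrogates the p-value is
`(1 + #(null >= observed)) / (1 + R)`; Benjamini-Hochberg is applied across
the q(q-1) connections within subject and connections with adjusted p below
alpha (strictly, matching the "p < 0.05, FDR corrected" convention) form
the subject's binary directed network.

**Surrogate resolution matters.** The counting p-value cannot go below
`1/(R+1)`. For BH at level alpha over m = q(q-1) connections, *no*
connection can survive unless at least `m / ((R+1) * alpha)` connections
sit at that floor simultaneously. At q = 16 and R = 200 that is 24
connections — more than a sparse stable network can reliably deliver — so
the package defaults to R = 1000, for which the crossing is ~5. When
choosing R for other problem sizes, keep `1/(R+1)` well below
`alpha * k_expected / m`, where `k_expected` is the plausible edge count.

### Nodal graph measures

On each binary directed network:

- **Betweenness centrality (BC)**: for every ordered pair (s, t) the
  fraction of shortest directed paths through node i, summed; unreachable
  pairs contribute zero; ties share weight. Un-normalized by default.
- **Brokerage**: total successor counts in D minus successor counts in the
  node-deleted graph D - i minus i's own successor and predecessor counts,
  where "successor" means reachable by a directed path. This equals the
  number of ordered pairs (s, t) whose connection is destroyed by deleting
  i — an identity the test suite verifies exhaustively on all 4-node
  digraphs and on 10^4 random digraphs.
- **Middleman power (MP)**: brokerage normalized by the network's maximal
  potential brokerage (the total count of *indirect* successor relations),
  floored at 1. The center of a reciprocal star scores exactly 1; nodes
  whose removal disconnects nothing score 0.

BC counts traffic on geodesics and can exaggerate the importance of nodes
that merely sit on many long shortest paths; MP isolates the nodes whose
removal actually severs communication. The packaged 8-node example
(`toy_middleman_network()`) makes the contrast concrete: the three
middlemen score BC 4 / brokerage 4 while two non-middleman hubs score the
*higher* BC 6 with brokerage 0.

### Group inference

Per nodal measure, six one-sided comparisons (NC>EMCI, NC>LMCI, NC>AD,
EMCI>LMCI, EMCI>AD, LMCI>AD) are run as linear regressions of the nodal
value on a group indicator plus age and sex (pooled-variance t on the
indicator, one-sided p). BH is applied across nodes within each comparison,
and the six significant sets are intersected: a node qualifies only if it
declines significantly at every disease stage. Pearson correlations link
nodal measures to clinical scores (NPI-Q, MMSE, FAQ, CDR). A control arm
repeats the analysis with undirected FDR-binarized correlation networks and
their BC (MP is undefined for undirected graphs).

## The synthetic cohort

Real multi-site clinical imaging data cannot be redistributed, so the
package generates cohorts with known answers.

- **Ground truth.** A sparse directed lag-1 network on q nodes with
  `n_middlemen` designated middlemen. Each middleman receives the single
  outgoing edge of a dedicated feeder node, which guarantees the middleman
  property by construction (and is verified against the brute-force
  oracle). Background edges among non-feeder nodes appear with probability
  `density`. Coefficients have magnitude ~`coeff_scale` with random signs
  (30% negative) and the matrix is rescaled to spectral radius <= 0.9.
- **Dynamics.** Neural states follow a stable VAR(1) at the TR timescale —
  the causal lag equals one TR, the resolution at which the network model
  operates — and are held constant within each TR on a 0.5 s grid
  (sustained activity). Innovations are unit-variance Gaussian.
- **Observation.** Each region's activity is convolved with its own
  double-gamma HRF — peak time jittered in 5-7 s, undershoot time in
  14-18 s, dispersion in 0.8-1.2 s, per region and subject — sampled every
  TR = 3 s for T = 140 volumes, plus white observation noise (sd 1 against
  a BOLD-scale sd of roughly 3-6). A 45 s lead-in absorbs the convolution
  ramp.
- **Groups.** Four groups with non-decreasing `pruning_fractions`
  (default 0, 0.3, 0.6, 0.9): each subject's network is the ground truth
  with that fraction of middleman-incident edges deleted at random, so
  middleman power at the planted nodes declines progressively in
  expectation. Ages come from one N(73, 7) distribution truncated to
  55-90 (groups age-matched by construction), sex from a fair coin.
  Behavioral scores are linear in the subject's pruning fraction with
  anchors taken from typical clinical values (MMSE 28.8 falling by ~8
  points at full pruning; NPI-Q, FAQ and CDR rising), plus Gaussian noise.

Default simulation scale is q = 16 regions, 3 middlemen, 10 subjects per
group, `density` 0.15 and `coeff_scale` 0.65 — sparse, strong coupling of
the kind effective-connectivity simulations typically assume, chosen so
that individual edges are detectable at T = 140. A full default run takes
a couple of minutes on one core; the acquisition-scale configuration
(q = 200, groups 35/34/32/29) is accepted and flagged as long-running.

### What the generator does and does not emulate

It reproduces the features the method is sensitive to: hemodynamic
variability, TR-limited sampling, instantaneous correlation induced by
smoothing, ordered group structure, covariates and behavioral coupling. It
does *not* simulate volumetric images, atlas geometry, physiological
(cardiac/respiratory) noise, motion, scanner drift beyond a linear trend,
or nonstationary dynamics. Passing recovery tests here demonstrates
internal consistency of the pipeline, not performance on real scanner data.

## Numerical choices

- Reachability uses dense boolean closure by repeated squaring (simple to
  verify; adequate to a few hundred nodes). The middleman oracle uses
  independent breadth-first searches so the two routes cross-check.
- Shortest-path ties share weight equally; unreachable pairs are skipped.
- Surrogate p-values use the plus-one correction and are never exactly 0.
- The Wiener gain is zeroed where `|H|^2 + nsr` underflows; an all-zero
  HRF is an error.
- All randomness flows from one master seed through deterministic
  sub-seed streams (per subject, per stage); reruns are byte-identical.
- Degenerate nodal values (zero variance within a comparison) yield NA
  p-values and are reported untestable rather than aborting the cohort.

## Known limitations

- **Single-subject network identifiability at short T.** With T = 140 and
  TR = 3 s, edge-level sensitivity after blind deconvolution is roughly
  50-70% even for strong couplings; subject-level binary networks are
  accordingly noisy. Group *mean* middleman power at planted nodes declines
  cleanly and monotonically across groups, but the intersection of six
  FDR-corrected one-sided tests demands per-step effect sizes (d > ~1.2 at
  n = 10 per group) that this noise level does not produce. With the
  default desk-scale cohort the progressive-intersection analysis therefore
  has low power; larger groups, longer acquisitions, or weaker correction
  would be needed for reliable recovery of every planted node.
- The zero-lag purge deliberately sacrifices any true instantaneous
  interaction; only lagged structure is interpreted.
- Deconvolution quality depends on event-like structure in the data; very
  smooth series with few suprathreshold events fall back to the canonical
  HRF, which reintroduces latency confounds for those regions.
- The identity "brokerage = destroyed ordered pairs" relies on reading
  "successor" as directed-path reachability; direct-neighbor readings do
  not reproduce the toy-network or star values.
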