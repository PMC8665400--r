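---
title: "Spatio-spectral cluster inference for MEG power change: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-spectral cluster inference for MEG power change: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The scientific problem

In a two-arm pre/post trial with resting-state MEG, the question is whether a
change in a behavioural measure — here the CPT-III commission score, an index
of inhibitory control where higher is worse — is accompanied by a change in
source-space oscillatory power, and where in the brain and the spectrum that
coupling lives. Both quantities are expressed as post/pre ratios per
participant: a commission ratio below 1 means improved inhibitory control,
and a power ratio above 1 means a power increase. The package implements the
full inferential chain from those ratios to familywise-error-controlled
spatio-spectral clusters, together with the trial-level analytics that
surround it, and a synthetic cohort generator that makes every stage testable
without access to raw recordings.

## The cluster statistic

At every (node, frequency-step) cell of the participants × nodes × steps
ratio tensor we compute an age-partialed Spearman correlation with the
behavioural ratio: all three variables are rank-transformed (midranks for
ties), the ranks of the power ratio and of the behavioural ratio are
residualized on `[1, rank(age)]` by least squares, and the residuals are
correlated. The two-sided p-value uses a t reference with `n - 3` degrees of
freedom. Because the statistic is rank-based, it is invariant under strictly
increasing transforms of either variable, so working on ratios versus
log-ratios makes no difference.

Cells with `p < alpha_node` (default 0.05) are candidate members. Three
structural filters follow:

1. **Persistence.** A node contributes only cells lying inside runs of at
   least `min_consecutive_steps` consecutive significant steps of the same
   sign (default 4 steps; on the default 1/3-Hz axis this is a 1-Hz
   interval). This reading attaches the persistence requirement to nodes,
   which is the stricter and more conservative of the two plausible readings;
   a cluster-level span requirement is implied by it.
2. **Connectivity.** Connected components are taken on the node × frequency
   lattice, where two cells are neighbours if they share a step and their
   nodes are spatially adjacent, or share a node and sit on consecutive
   steps. All members of a component carry the same correlation sign by
   construction of the masks.
3. **Extent.** Within a cluster's frequency span, every step must involve at
   least `ceiling(min_extent_fraction × n_nodes)` nodes (default 1%, i.e. 12
   nodes on the default 1200-node grid). By default thin steps are *trimmed*
   — their cells are removed and components re-extracted until stable —
   rather than the whole cluster being discarded. The discard variant
   (`extent_rule = "discard"`) is available, but under it a single
   chance one-node tail at a band edge, which joins a cluster through one
   node's long significance run, would sink an otherwise solid 40-node
   cluster; trimming matches the behaviour implied by an extent profile that
   tapers at the band edges while remaining above threshold.

The cluster **mass** is the sum of member correlation coefficients. Inference
is by permutation: the behavioural ratio is shuffled across participants
(power and age stay with their participant, since the covariate belongs to
the brain data side of the correspondence being broken; joint shuffling is
available via `shuffle_age = TRUE`), the entire map-to-cluster pipeline is
re-run, and the maximum absolute surrogate mass is recorded per permutation —
zero when nothing survives, the conservative standard convention. A cluster's
p-value is `(count of null maxima >= |mass| + 1) / (B + 1)`; the +1
estimator avoids exact zeros. Observed clusters are formed once from the
unshuffled data, so increasing `B` refines p-values without changing which
clusters are reported. The default `B = 5000`; a minimum of 100 is enforced.

Internally the permutation loop thresholds `|rho|` against the critical value
equivalent to `p < alpha_node` (the two are monotonically equivalent), and
the whole map for one shuffle is a single matrix product against a
precomputed residualized, column-standardized rank matrix, which is what
makes thousands of permutations on a 1200 × 130 lattice practical.

Post hoc, the per-participant mean ratio over a significant cluster's members
is the cluster's marker; its age-partialed Spearman correlation with the
behavioural ratio is reported for the whole sample and per arm, along with
the extent profile and peak-extent frequency. ROI occupancy tables report,
per labelled region, how many of its sources the cluster captured.

## Spatial scaffold

The spatial adjacency rule is a Euclidean distance threshold of 1.05 × the
grid spacing, i.e. 6-connectivity on a regular grid, with k-nearest
neighbours as an alternative; the analysis never needs more than the edge
list. The synthetic source space places the innermost `n_nodes` points of a
regular grid inside an ellipsoid (semi-axis aspect 1 : 1.2 : 1, slightly
elongated anterior-posterior), ties broken lexicographically, so the
construction is deterministic. The default 1200 nodes at 10 mm spacing make
the 1% extent rule exactly 12 nodes and are consistent with a whole-head
source grid at that resolution. Node indices are 1-based everywhere, in
memory and on disk.

## The synthetic generator

The generator emulates the study conditions: 15 + 14 participants aged 8-11,
baseline commission T scores Normal(53.87, 8.37) and Normal(48.79, 7.53) per
arm, mean post-pre shifts of -6.07 and +0.85, and a participant-level
post-pre residual SD of 5 (a plausible short-interval test-retest noise for a
T-scored measure; the source conditions do not pin it). Baseline spectra are
1/f trends with a Gaussian alpha bump (centre 10.5 Hz, width 1.5 Hz) whose
amplitude grows toward posterior nodes, times log-normal noise.

The planted effect lives on the log power ratio of a spatially compact node
set (a 25 mm ball around the most posterior node, about 65 nodes on the
default grid) over the 11.67-13.33 Hz band: `a + s·b·z + eta + eps`, with
`z` the z-scored behavioural ratio, `s = sign(target_rho)`, `eta` a
participant-level shared "physiological" change (SD 0.25 on the log scale)
and `eps` per-cell measurement noise (SD 0.10). Linearity in `z` is an
implementation convenience — the rank statistic only needs monotonicity. The
slope `b` is calibrated from the noise budget so the age-partialed Spearman
correlation between the cluster-mean ratio and the behavioural ratio
approximates `target_rho` (default -0.56), using the bivariate-normal
Spearman-to-Pearson conversion `r = 2 sin(pi * rho / 6)`. With all noise at
zero the coupling is perfectly monotone, the realized correlation is ±1, and
the generator warns that the target is unreachable. Under `target_rho = 0`
no effect term is injected at all, so in- and out-of-cluster cells are
identically distributed — the null used for error-rate checks.

Per-cell noise is smoothed by one neighbour-averaging pass over the source
graph (`noise_spatial_smoothing = TRUE`). Source-reconstructed power is
strongly spatially correlated (leakage), and cluster-based inference presumes
that coherence; with independent cell noise the significance maps fragment
into scatter that no contiguous-cluster procedure could or should stitch
together. The smoothing is applied to the noise field only, before the
effect term, so the planted boundary stays crisp for recovery checks.

What the generator does *not* emulate: raw time series, sensor noise, head
movement, realistic anatomy or atlases (the bundled partition is explicitly
synthetic), frequency-dependent noise structure, or distance-dependent
leakage profiles. Passing tests therefore demonstrate the statistical
machinery's operating characteristics under an idealized but
structurally matched data-generating process, not performance on real
recordings. Whether node power should be absolute or per-node relative
(normalized across frequencies) is left as a switch (`normalize`), defaulting
to absolute.

## Trial-level analytics

Baseline comparisons use the pooled-variance Student t (Welch available) and
the Pearson chi-square without continuity correction. The primary model is a
random-intercept linear mixed model on scores standardized by the
whole-sample baseline mean/SD, REML-estimated, with the condition × period
interaction as the treatment effect (Satterthwaite degrees of freedom) and a
likelihood-ratio chi-square between ML fits for the interaction's
contribution; age enters stepwise when it lowers the ML AIC. Plain REML is
used: the "robust" variant referred to in the source material is uncited, and
all conclusions drawn from the model in this package rest on simulation
calibration rather than on matching a printed coefficient. Hedges g uses the
averaged pre/post SD denominator with the `J = 1 - 3/(4(n-1)-1)` small-sample
correction — the formula that reproduces the printed control-arm value;
no single standard formula reproduces the printed experimental-arm value
from the published moments, and the package does not chase it. Respondent
analysis counts inclusive improvements of at least 0.64 reference SDs
(improvement = score decrease). Simulation-based power for the interaction
uses cohorts with intraclass correlation 0.5 — the variance split is not
stated in the source conditions, and 0.5 is the neutral choice — and the
positive predictive value follows Button-style prestudy odds:
`PPV = power·R / (power·R + alpha)`.

## Numerical choices and degenerate inputs

* Midranks for ties everywhere; significance is strict (`p < alpha`).
* Cells constant across participants have undefined correlations, are
  returned as `NA` and never enter clusters; an all-constant map is flagged
  invalid. A permuted behavioural vector that becomes rank-collinear with
  the covariate yields an all-`NA` surrogate map contributing 0 to the null.
* The respondent threshold comparison carries a 1e-9 tolerance so exact
  boundary cases are inclusive despite float rounding.
* Degenerate mixed-model data (zero residual variance) trip the default
  optimizer; fits are retried with bobyqa and flagged via `isSingular`.
* Text round trips write floats with 17 significant digits, so datasets
  reload bit-for-bit.
* All randomness is locally seeded (`with_seed`) and restores the caller's
  RNG state; identical spec + seed gives byte-identical datasets and
  reports.

## Problem sizes used by the validation suite

The suite checks operating characteristics at sizes chosen to be
representative yet tractable: familywise error under the null generator on a
300-node grid over an 8-16 Hz slab, 200 replicate cohorts of 29 at 500
permutations each, against the one-sided binomial bound (a max-statistic
test is conservative by construction, so its rejection rate under the null
sits below the nominal level rather than at it); planted-effect recovery on
the full 1200-node grid and 2-45 Hz axis across 20 seeds at 500
permutations; mixed-model size and recovery over 200 simulations each; and
exhaustive-enumeration agreement for the permutation p at n = 6. Exact
arithmetic (chi-square, PPV, Hedges g, partial Spearman) is checked against
independent brute-force oracles and printed-table values.

## Limitations

Sensor-level statistics, connectivity/network-based statistics on
connectivity matrices, event-related designs, reading native MEG formats,
head modelling and source reconstruction are all out of scope. The
permutation test inherits the usual caveats of cluster inference: evidence
is at cluster level, not cell level, and cluster boundaries are not
confidence regions. The generator's calibration targets a correlation, not
effect-size units in physical power; realized correlations fluctuate with
sampling variability of order 0.12 at n = 29.
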