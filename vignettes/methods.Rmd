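---
title: "Models and methods in pharmaconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in pharmaconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`pharmaconn` analyses multi-subject, multi-condition resting-state BOLD
cohorts at the grayordinate level and ships a generative model of such
cohorts so that every stage of the pipeline can be validated against
ground truth. This vignette explains the models, the parameters that
matter, and the design choices that were genuinely open.

## The data model

A *grayordinate space* is a geometry-free brain: per-grayordinate
structure labels (left/right cortex, thalamus, amygdala, other subcortex,
ventricle and white-matter proxies in fixed proportions), seven functional
network labels on cortex, a parcellation mirrored across hemispheres, and
a neighbourhood graph (ring by default, optionally a 2-D lattice) that
gives cluster statistics a well-defined topology. Gray matter — the mask
over which the global signal is averaged — is cortex plus labelled
subcortex, explicitly excluding the ventricle/white-matter proxies.
Grayordinate indices are 0-based in every file format; loaders verify the
index column and refuse to reorder silently. The native container is a
single serialized file with space/design/runs/truth groups; maps and
spaces additionally export to plain TSV, and a thin NIfTI adapter is
available when RNifti is present.

## The generative cohort model

Each run (subject × condition × session) is

    bold_k(t) = baseline + a · w_k(cond) · g(t)
                + Σ_c L_kc · η_c(t) + spikes + ε_k(t)

* `g(t)` — a global fluctuation: AR(1) (φ = 0.4) band-limited below
  0.1 Hz and standardized; a respiratory-like slow artifact. Its spatial
  weights `w_k` average one over gray matter; under the drug the weight
  topography shifts (amount `gs_shift`, default 0.4) upward in associative
  cortex and subcortex and downward in sensory cortex, with the shift
  mean-centred so total GS variance is condition-invariant — only the
  *topography* moves.
* `η_c(t)` — one latent signal per network, with the same slow spectrum
  as `g`. Baseline loadings are graded (visual 0.55 … default-mode 1.2,
  ±15 % ramp within each network block), giving the cortex a stable
  baseline connectivity topography; without such a gradient,
  rank-based analyses (top/bottom deciles) would be decided by sampling
  noise and conjunctions across processing variants would be empty.
* `ε_k(t)` — private noise whose baseline sd follows
  `sqrt(1.69 − L²)` per network, keeping total non-global variance
  approximately flat across networks so that correlation- and
  covariance-based connectivity rank areas identically — the premise of
  the conjunction analysis.
* spikes — with per-frame probability 0.02, a single-frame 0.8 mm motion
  excursion co-occurs with an intensity burst, exercising both scrubbing
  criteria.

**The drug effect is a coherence change, not an amplitude change.** The
per-network `loading_delta` (default +0.3 in sensory/somatomotor, −0.3 in
associative networks, relative to the baseline loading) is applied to the
*private-noise gain*: positive deltas shrink private noise (the area
becomes more coherent with its distributed network), negative deltas
inflate it. The shared amplitude — and hence each network's contribution
to the global mean — is untouched. This choice is deliberate: global
signal regression exactly removes the gray-matter mean from every
residual, so the residual's covariance with that mean is zero by
construction. Any "drug effect" implemented as a change in a network's
shared amplitude changes the network's share of the global mean, and the
bookkeeping of removing that share dominates the post-GSR GBC contrast
with the opposite sign to the intended effect (we verified this both by
simulation and exactly on population covariance matrices). A coherence
change encodes the same hyper/hypo phenomenon — increased or decreased
participation of an area in large-scale activity — while leaving the
global mean invariant, and the pipeline then recovers its sign and
topography. The thalamus, a small fraction of gray matter, keeps
amplitude-type deltas (its bookkeeping leak is negligible).

A corollary worth knowing: after GSR, *covariance*-GBC is pinned near
zero by the same orthogonality identity, so its contrast direction is not
meaningful; correlation-GBC and seed-based maps carry the recoverable
pattern.

Subject-level effect sizes for the sensory (hyper) and associative (hypo)
sides are drawn from a bivariate normal with mean 1, sd `effect_sd`
(0.3), and correlation chosen so that the *signed* effect sizes correlate
at `rho_hh` (default −0.9): participants with the strongest
hyper-coupling show the strongest de-coupling. A small per-subject,
per-network jitter (`network_jitter_sd`, default 0.1) gives each network
a subject-specific component; raising it (e.g. 0.6) with `rho_hh = 0`
creates the network-selectivity regime used to test behavioural
correlations. Behavioural scores (percent of scale maximum, three
assessment times with a decaying profile) are
`behav_coupling × (somatomotor subject effect)` plus noise in the drug
condition and near zero otherwise — the blocked condition
(`ket_fraction = 0`) retains none of the drug effects, encoding full
antagonist blockade.

## Denoising

Fixed order: DCT high-pass → scrub-mask computation on raw intensities →
nuisance GLM on all frames → frame deletion of the residuals
(`censor_before_regression` flips the last two). The high-pass removes
the mean and all DCT components below 0.008 Hz; a projection onto an
orthogonal basis, exactly linear and free of IIR edge transients. The
design matrix is intercept, ventricle, white matter, six motion
parameters, optionally the GS, and the first backward difference of every
non-intercept column (first element 0); zero-variance columns are dropped
with a warning, rank deficiency is an error naming the collinear columns.
The GS is computed after filtering by default (a flag provides the
alternative, which the underlying acquisition description leaves open).

Scrubbing flags frames where (1) the sum of absolute frame-to-frame
displacements across the six rigid-body parameters — rotations converted
to arc length on a 50 mm sphere — exceeds 0.5 mm, or (2) the RMS
frame-difference intensity divided by mean intensity exceeds 1.6 × the
run's median, computed on raw intensities; flags dilate one frame back
and two forward, and subjects with more than half their frames flagged
are excluded. Under generator defaults, censoring rates run ~15–30 %:
the DVARS criterion responds to fast excursions of the band-limited
global fluctuation in addition to spikes, which is faithful to how that
criterion behaves on structured artifacts.

## Connectivity and inference

GBC is computed in column blocks so the G × G correlation matrix is never
materialized (the blocked result equals the dense one to 1e-10);
correlations are clipped at 1 − 1e-7 before `atanh` because synthetic
data can contain exact duplicates; self-correlations are excluded and the
mean divides by the number of valid other grayordinates (zero-variance
grayordinates are masked NaN and dropped pairwise). Covariance-GBC uses
the unbiased T′−1 denominator — "non-normalized" meaning
not variance-normalized, i.e. not a correlation.

Group inference converts a one-sample t on within-subject difference maps
to z (tail-stable), enhances with TFCE, and corrects FWE by the maximum
of |TFCE| over random sign flips (two-sided); the condition main effect
uses the repeated-measures F with within-subject label permutation. TFCE
integrates `extent^E · height^H · dh` over thresholds `h = dh, 2dh, …`
with H = 2, E = 0.5, `dh = max/100` (the conventional volume defaults;
the threshold grid is computed multiplicatively to avoid floating-point
drift, and the permutation engines run in compiled code with a recorded
seed, so inference is bit-reproducible). FWE p-values use the
(1 + count)/(n_perm + 1) estimator, slightly conservative by design.

The conjunction analysis takes the four placebo group-mean thalamic-seed
maps ({r, cov} × {GSR, no-GSR}), extracts the top and bottom decile of
eligible (cortical) grayordinates with ties broken deterministically by
lower index, and intersects across the four variants; the mask is then
applied to seed and GBC contrasts. In degenerate fully-tied inputs a
grayordinate could qualify for both sets; such grayordinates are dropped
from both with a warning so the sets stay disjoint.

## Transcriptomic matching

Matching is performed at parcel level — contrast maps are averaged over
each parcel's left-hemisphere cortical grayordinates — because
parcel-level expression profiles are the only construction the underlying
atlas supports. Per-gene Pearson correlations (masked parcels dropped
pairwise) yield a percentile rank for named target genes:
`100 · #{genes with r < r_target} / (n_genes − 1)`. Significance is
reported with naive parcel-count degrees of freedom; spatial
autocorrelation makes these optimistic, a known caveat. Comparing a
gene's correlation with two contrast maps (e.g. with vs without GSR) uses
Steiger's Z̄* for dependent correlations sharing one variable, with the
pooled-r covariance term and a positive-semi-definiteness check on the
correlation triple; a Bonferroni helper covers gene sets of interest. The
expression simulator builds the first gene at a target correlation to a
reference map by a scaled mixture, the second at an anti-correlation, the
rest spatially random; every row is z-scored across parcels.

## Problem sizes and what the tests show

The validation suite runs cohorts of 12–100 subjects at 200–1000
grayordinates and T = 240 frames (TR 2.5 s), with 150–1000 permutations
— sizes chosen so the full suite completes in minutes while keeping
estimation noise well below the tested effects; the acceptance script
states each problem size next to each reported quantity. Calibration
checks use 200 null datasets at 500 permutations.

Passing tests demonstrate that the pipeline recovers known generative
structure: GS-beta maps recover the injected weight topography
(RMSE < 0.1); post-GSR GBC contrasts track the true coupling-change map
(r > 0.8) while pre-GSR contrasts track the GS-topography shift
(r > 0.6), with GS-beta contrasts correlating negatively with the former
and positively with the latter; subject-level hyper/hypo change scores
recover ρ = −0.9 within sampling error; FWE is calibrated within the
binomial band; conjunction deciles move in the predicted directions; and
constructed target genes rank at the top of the gene set. They do *not*
show that the generator reproduces real BOLD physiology — hemodynamic
response variation, neurovascular coupling changes, scanner noise
spectra, and spatial autocorrelation within networks are all absent —
so conclusions about real pharmacological data rest on the pipeline's
correctness, not on the generator's realism.

## Known limitations

* Covariance-GBC after GSR is structurally near zero (see above); its
  contrasts are computed and reported but should not be interpreted
  directionally.
* The generator's drug effects are block-wise by network; real effects
  are spatially graded and overlapping.
* Gene-map significance ignores spatial autocorrelation (an optional
  parcel-permutation p-value is provided but off by default).
* Exact feature parity with full permutation-inference suites
  (exchangeability blocks beyond within-subject relabeling, variance
  smoothing) is out of scope.
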