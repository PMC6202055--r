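# pharmaconn

Pharmacological resting-state fMRI connectivity analysis at the
grayordinate level, with a synthetic-cohort generator that provides ground
truth for every stage.

## The problem

Pharmacological resting-state studies ask how a drug reshapes the brain's
functional architecture. A data-driven answer is **global brain
connectivity (GBC)**: for grayordinate *k* with time series *x_k*,

> GBC(k) = mean over j ≠ k of atanh( r(x_k, x_j) )

— the average Fisher-z-transformed correlation of an area with every other
area. GBC is exquisitely sensitive to the **global signal (GS)**, the
spatial mean of gray-matter BOLD, which mixes neural signal with
respiratory and scanner artifacts. Whether the GS is regressed out (GSR)
can change not just the magnitude but the *direction* of an inferred drug
effect, because a drug may shift which areas contribute most to the GS
(the **GS-beta topography**, the per-grayordinate regression weight
b_GS of BOLD on the GS) independently of any coupling change.

`pharmaconn` implements the full analysis battery needed to disentangle
these possibilities:

* post-HCP denoising: DCT high-pass filtering (> 0.008 Hz), nuisance
  regression (ventricle, white matter, 6 motion parameters, optionally the
  GS, plus first derivatives), and motion scrubbing (0.5 mm framewise
  displacement on a 50 mm sphere, 1.6 × median normalized DVARS, −1/+2
  frame dilation, > 50 % exclusion rule);
* per-run maps: GBC (correlation or non-normalized covariance), thalamic
  seed FC, GS-beta, and variance summaries;
* group inference: paired and repeated-measures contrasts with
  threshold-free cluster enhancement (TFCE, H = 2, E = 0.5) and
  max-statistic permutation FWE correction (sign flips / within-subject
  relabeling), in compiled code;
* rank conjunctions of the top/bottom 10 % of connections across
  {correlation, covariance} × {GSR, no-GSR} variants;
* network summaries, behavioural (symptom) correlations with Bonferroni
  correction, and spatial matching of contrast maps against parcel-level
  cortical gene-expression profiles (percentile ranks and Steiger's test
  for dependent correlations).

Because raw pharmacological fMRI data are rarely shareable, the package
ships a **generative cohort model** (`simulate_cohort()`): latent slow
network signals with a graded baseline topography, a band-limited global
fluctuation whose spatial weights shift under the drug, drug-induced
coherence changes (hyper in sensory/somatomotor, hypo in associative
networks) with correlated subject-level effect sizes, motion/intensity
spikes, and behavioural scores coupled to the somatomotor effect. Every
analysis can therefore be validated against known ground truth.

## Worked example

```r
library(pharmaconn)

space  <- make_space(n_gray = 600, n_networks = 7, n_parcels = 20)
config <- generator_config(n_subjects = 12, n_gray = 600, T = 240,
                           n_parcels = 20, seed = 1)
cohort <- simulate_cohort(space, config)
cohort
#> <cohort> 72 runs, 12 subjects, G=600

pp  <- preprocess_run(cohort$runs[["sub001_LSD_s1"]], space, gsr = TRUE)
gbc <- gbc_map(pp$residual)
round(network_means(gbc, space), 3)
#>            visual       somatomotor  dorsal-attention ventral-attention
#>             0.013             0.012            -0.007            -0.008
#>            limbic    frontoparietal           default
#>            -0.008             0.004             0.027
```

After GSR the GBC map is mean-centred; what remains is the relative
topography. A group contrast recovers the simulated drug effect:

```r
subj <- sort(unique(cohort$design$subject))
maps <- function(cond) t(vapply(subj, function(s) {
  ids <- cohort$design$run_id[cohort$design$subject == s &
                              cohort$design$condition == cond]
  rowMeans(vapply(ids, function(id)
    gbc_map(preprocess_run(cohort$runs[[id]], space, gsr = TRUE)$residual),
    numeric(600)))
}, numeric(600)))

contrast <- paired_contrast(maps("LSD"), maps("Pla"), space,
                            n_perm = 1000, seed = 2)
contrast
#> <contrast_result> 600 grayordinates, 1000 permutations (seed 2)
#>   significant at alpha=0.05: 144 positive, 360 negative

spatial_correlation(contrast$z, cohort$truth$coupling_change)
#> [1] 0.99
```

The 144 FWE-significant positive grayordinates are the sensory/somatomotor
hyper-connectivity, the 360 negative ones the associative
hypo-connectivity, and the unthresholded z map matches the generator's
signed coupling-change map at r = 0.99.

`run_study(study_config(...), "report/")` executes the whole battery —
both GSR variants, all drug and session contrasts, GS-beta topography,
hyper/hypo change-score coupling, the 4-way thalamic rank conjunction,
network/behaviour correlations, and gene-map matching — and writes a
reproducible TSV + JSON report bundle.

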