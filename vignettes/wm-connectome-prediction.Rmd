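---
title: "Predicting fluid intelligence from white-matter functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting fluid intelligence from white-matter functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmcpm)
```

## The model

Connectome-based predictive modeling (CPM) asks whether inter-individual
variation in a behavioral trait — here general fluid intelligence (Gf),
measured as a psychometric total score — can be predicted from resting-state
functional connectivity. `wmcpm` implements the white-matter (WM) flavor of
this procedure: BOLD signals restricted to a rigorously thresholded WM mask,
parcellated into K = 128 roughly equal-size nodes, summarized as a K × K
Pearson correlation matrix between node-averaged time series, Fisher
r-to-z transformed, and never thresholded or binarized.

Within each cross-validation training fold:

1. Edges whose correlation with mean framewise displacement (FD) is
   significant at `alpha_motion` (default 0.05, two-tailed) are excluded —
   motion-coupled connectivity must not carry the prediction.
2. Each remaining edge is correlated with Gf across training participants;
   edges with two-tailed p < 0.01 (Student-t transform at df = n − 2) form
   the feature mask, split by the sign of r into a *positive* and a
   *negative network*.
3. Each participant's Fisher-z values are summed over the two sets into two
   network strengths, S⁺ and S⁻.
4. An ordinary least-squares model Gf ~ 1 + S⁺ + S⁻ (the "glm" variant;
   single-strength "positive"/"negative" variants exist for exploration) is
   fitted on the training participants and evaluated on the held-out data.

Prediction quality is the Pearson correlation between observed and predicted
scores across held-out participants. Because feature selection inside the CV
makes parametric degrees of freedom unreliable, significance is assessed by a
permutation test: scores are shuffled B = 5000 times, the *entire* LOOCV is
re-run per shuffle, and p = #{null r ≥ observed r}/B. *Consensus features* —
edges selected in every fold — define a single model refitted on the full
training cohort, the object that generalizes to retest sessions and external
cohorts scored on a different instrument (correlation is invariant to the
affine rescaling between instruments).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| initial discard | 7 | frames | pre-steady-state volumes (242 acquired → 235 used) |
| TR | 2.0 | s | acquisition repetition time; fixes the 0.25 Hz Nyquist |
| band-pass | 0.01–0.10 | Hz | low-frequency BOLD band, drift and respiration removed |
| FD threshold | 0.5 | mm | scrub trigger; window {i−2, i−1, i, i+1} censored |
| retention floor | 0.80 | fraction | participants keeping <80% of frames are excluded |
| motion limits | 2 / 2 / 0.15 | mm / ° / mm | max translation / rotation / mean FD |
| Gf outlier cutoff | 2 | SD | screening on the full-sample mean and SD, no iteration |
| WM probability | 0.90 | — | individual mask threshold (inclusive) |
| group coverage | 0.80 | — | voxel kept if in ≥ ⌈0.8·n⌉ individual masks |
| subcortical removal | 0.25 | — | probability-atlas threshold (inclusive) |
| K | 128 | nodes | equal-size WM parcels; 8128 edges |
| selection p | 0.01 | — | two-tailed edgewise threshold |
| k-fold | 20 × 50 | folds × repeats | fold sizes differ by ≤ 1 (326 → six folds of 17) |
| permutations | 5000 | shuffles | full-LOOCV nulls |

## The synthetic world

Real cohort data are not redistributable, so every stage is exercised on a
generator whose defaults state the emulated design: n = 326 training
participants, K = 128 nodes, 20 planted positive and 20 planted negative
edges, integer Gf scores at mean 65, SD 7 (a Raven's-type total on a
72-item test for college students; the source study does not print its score
distribution, so this is the package's one-time realistic choice), retest
reliability 0.7, an external cohort of 53 scored as 15·latent + 100 (an
IQ-like scale), and a 2% per-frame FD-spike rate.

Each planted edge is `sign · ρ · latent + sqrt(1 − ρ²) · noise` with
standard-normal latent trait and noise, so its population correlation with
the latent Gf is exactly the target `effect_r`; the spec of the study gives
no per-edge effect size, so planted magnitudes (0.3–0.5 in tests) are
artifact choices, not claims about the data. Retest sessions mix session-1
edges with fresh noise at weight ρ, making the edgewise retest correlation
equal `reliability` analytically and attenuating edge–behavior correlations
to ρ·effect_r, which is what produces the observed ordering r(time 1) >
r(time 2) ≥ r(time 3).

What the generator does *not* emulate: spatial autocorrelation between
edges, non-Gaussian BOLD spectra, heteroscedastic motion–signal coupling, or
site effects. A green test therefore establishes that the *procedure* is
correct and calibrated, not that any particular real-data correlation is
reproducible.

## Numerical choices

- **Edge order.** Row-major upper triangle, (1,2), (1,3), …, (K−1,K);
  `edge_nodes()` is the single source of truth and all masks and ground
  truth use it.
- **FD.** Power-style sum of absolute backward differences, rotations
  converted to arc length on a 50 mm sphere; the source pipeline cites this
  convention without printing a formula. Rotation units are declared at
  construction (radians default, degrees converted).
- **Band-pass.** Realized as the squared 4th-order Butterworth magnitude
  response applied in the frequency domain after linear detrending — exactly
  zero-phase, with DC gain 0. No IIR filtering library is guaranteed in the
  target environment, and the tests pin the response contract (in-band
  variance retained ≥ 80%, 0.2 Hz attenuated below 5%), not a filter brand.
- **Thresholds** on probability maps and coverage are inclusive (≥); the
  sources say "90% threshold" without strictness, and boundary tests pin
  the choice.
- **Scrub window** "{two previous, the point, one forward}" is clipped at
  series boundaries and overlapping windows are unioned; censored frames are
  dropped, never interpolated.
- **Stage order** discard → nuisance regression → band-pass → scrub is a
  design decision; the source lists the stages in this order without stating
  whether scrubbing preceded filtering.
- **Parcellation** is size-aware k-means on voxel coordinates with
  contiguity repair and a boundary-voxel balance pass — the cited group-wise
  algorithm is not described in the source text, and the only stated
  property is "roughly equal sizes" (enforced: max/min ≤ 2, CV ≤ 0.35 on
  connected masks). Deterministic given the seed.
- **Empty-mask folds** predict the training-mean score, keeping n
  predictions aligned; this is logged loudly. A fold whose negative set is
  empty makes the glm variant reduce *exactly* to the positive variant
  (the zero column is dropped rather than pseudo-inverted).
- **Permutation p** is #{null ≥ observed}/B. The source's sentence inverts
  numerator and denominator syntactically; its worked value (0.004 at
  B = 5000, i.e. 20/5000) fixes the reading. A +1-smoothed variant is
  available by flag.
- **Consensus ambiguity.** Whether the externally applied model was refit on
  all training participants at the consensus features or averaged across
  folds is ambiguous in the source; refit-on-all is implemented.
- **Steiger's z** is the single-shared-variable case (the observed score is
  common to both predictions), with the asymptotic variance evaluated at the
  mean of the two correlations — the case the study's comparisons require.
- **Sex** enters partial correlations as a binary covariate.

## Known limitations

- Under the null, the cross-validated r does **not** concentrate at the
  1/√n parametric scale: feature selection gives it an O(1) spread with a
  negative median (measured sd ≈ 0.2 at n = 150–300). Parametric p-values
  for LOOCV r are therefore anti-conservative in general; the permutation
  test is the supported inference and its type-I calibration is verified in
  the acceptance suite (rejection rate at p < 0.05 inside the exact binomial
  95% interval; KS distance of the null p distribution from uniform < 0.1).
- Volumes are plain 3-D arrays with a text serialization; no NIfTI I/O is
  bundled because no NIfTI package exists in the supported environment.
  Grid geometry (voxel size, affine) is therefore the caller's
  responsibility.
- The parcellation is a generic equal-size spatial clustering, not a
  re-implementation of any published group-wise parcellation; nodes are
  contiguous and balanced but carry no anatomical identity.
- No regularized or nonlinear predictive models, no partial-correlation or
  dynamic connectomes, no effective-connectivity analyses.

## A worked run

```{r, eval = FALSE}
cfg <- run_config(n_participants = 120, n_nodes = 16, n_pos_edges = 6,
                  n_neg_edges = 6, effect_r = 0.4, kfold_repeats = 10,
                  n_permutations = 200, seed = 7)
bundle <- run_internal(cfg, out_dir = "wmcpm-out")
bundle$summary
```

The bundle's summary reports the LOOCV r at time 1, the attenuated r at
times 2 and 3, the consensus feature counts, the repeated k-fold mean ± SD,
and the permutation p — each of which the test suite recomputes on the same
stated world.
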