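---
title: "Coactivation-pattern analysis of transient brain network states: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coactivation-pattern analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Coactivation-pattern (CAP) analysis treats every fMRI frame as an
observation of a momentary whole-brain activation configuration. Given
per-subject parcellated BOLD matrices (frames x parcels), the package

1. z-scores each parcel's time course within subject (mean 0, sample sd 1),
2. concatenates all subjects' frames into one matrix,
3. clusters the frames with k-means, and
4. calls the cluster centers *transient network states* (TNSs).

With a 7-network parcellation the states typically organize into *mirror
pairs*: two states with strongly anticorrelated spatial patterns (e.g. a
DMN-activated and a DMN-deactivated state). Downstream, each state is
characterized spatially (how tightly frames concentrate around the
center, how reproducible the map is across scanning sites, how stably
individual parcels activate within subjects) and temporally (how much
time subjects spend in it and how they move between states).

### Distance and similarity conventions

Frames are compared with patterns by Pearson correlation across parcels;
the *distance to center* of a frame is `1 - r` with its cluster center,
in [0, 2]. Because k-means operates in Euclidean space, each frame is
additionally standardized across parcels (mean 0, sd 1 within the row)
before clustering, which makes squared Euclidean distance a monotone
function of `1 - r`: the clustering then groups frames by spatial
similarity, matching the distance definition used afterwards. Raw
Euclidean clustering (no row standardization) remains available via
`row_standardize = FALSE`. Whether per-parcel normalization should
instead be per-frame is genuinely open for this kind of analysis; the
per-parcel convention is the default because it is the standard CAP
preparation, and the row standardization applied at clustering time
covers the per-frame view.

### Z maps, thresholds, stable regions

Each state's *Z map* divides the center by the within-cluster standard
deviation per parcel (population convention, `sd_type = "population"`;
the sample convention is a switch). A parcel is *activated* when
`z > tau` and *deactivated* when `z < -tau`, with strict inequalities
(ties are neutral); `tau = 0.4` by default, and the supported working
range is roughly 0.3-0.5. *Individual-specific* state maps average one
subject's member frames and divide by the within-cluster sd; by default
the cohort-level ("global") sd, so that subjects stay on a common scale
(the subject-level sd is available via `sd_mode = "subject"`; which one
the field should prefer is unsettled). A parcel is a *stable region* of
a state when strictly more than half of the subjects with a defined
individual map exceed the threshold there. The *individual-level stable
activation rate* (iSAR) of a subject on a stable region is n/N: the
fraction of the subject's N member frames whose normalized intensity
(frame value over the same within-cluster sd) exceeds `tau` in absolute
value.

In the noiseless limit the within-cluster sd collapses to zero; the
group Z maps flag such parcels (z set to 0), while individual maps and
iSAR floor the sd at a tiny epsilon so that genuinely nonzero activation
stays suprathreshold. This keeps the degenerate case interpretable: a
noise-free cohort yields distance 0 and iSAR 1 on every planted
suprathreshold region.

### Temporal features

*Dwell time* is the fraction of a subject's frames assigned to each
state (summing to one). *Transition probabilities* count ordered changes
of state at consecutive frames, within subject only, divided by the
total number of changes; consecutive frames in the same state are not
transitions (the `include_self = TRUE` switch implements the alternative
denominator, since published definitions rarely say which was used).
Subjects with fewer than 10 between-state transitions are flagged
low-confidence. Transition mass is further split into within-pair
transitions and *internetwork* transitions between the DMN/ECN/SN pair
blocks, and the symmetrized transition matrix is correlated with the
spatial similarity matrix at both the group and subject level.

## Choosing k and the k-means engine

The state count is chosen by the elbow of the SSE curve over
`k in {2, 4, 6, 8, 10}`: the interior grid point maximizing the discrete
second difference. Two conditions must hold for the elbow to count: the
largest second difference must exceed 5% of the curve's total range, and
the SSE drop after the candidate must fall below half of the drop
entering it. The second condition is what separates a genuine kink from
the smooth, steadily decaying curve that unstructured data produces;
without it a structureless Gaussian cloud can pass the range test.
Curves failing either condition are flagged `no_elbow` and the smallest
grid k is returned with a warning, with the full curve exposed for
manual override.

k-means itself is implemented in the package as Lloyd iterations
expressed as BLAS cross-products with greedy k-means++ seeding (several
candidate seeds per step, keeping the one minimizing the potential) and
best-of-`n_init` replicates by SSE. At the default cohort scale
(~68,000 frames x 400 parcels) the replicate search runs on a fixed
random subsample of 20,000 frames and the best replicate is then
polished on all frames to the assignment fixpoint, so returned centers
are exact member means and the total SSE is exact. Elbow selection
evaluates its SSE curve on that same fixed subsample with `n_init = 5`
replicates per k; the final model uses `n_init = 20`. These sizes were
chosen once as the point where further replicates stopped changing the
selected k or the recovered states on planted-structure cohorts; the
pipeline reuses the elbow's best centers at the selected k as the
polish start. Empty clusters during iteration are re-seeded at the
point farthest from its center. Everything is deterministic given
`(seed, n_init)`.

State matching across runs or sites maximizes the total *absolute*
spatial correlation under a bijection (exact optimal assignment by
enumeration at these sizes), reporting signed correlations; matching on
the magnitude keeps sign-flipped recoveries of the same pattern matched
to each other. Mirror pairing minimizes the summed signed correlation
over perfect matchings; pairs with r > -0.5 are flagged as not
mirror-like.

## The statistical layer

Derived features (per-state dwell times, mean distances, pair sums) are
harmonized across scanning sites with parametric empirical-Bayes
location/scale harmonization (ComBat, via the sva package) before
statistics. Site is the only batch variable: TR and eye status are
constant within site in the cohorts this package targets, so one batch
factor absorbs all three. The group and age-group design is protected
during harmonization, except for design columns perfectly confounded
with site (an age-group factor nested in site cannot be protected; the
wrapper detects and drops such columns with a message, which also means
between-age-group mean differences are partially absorbed into site
effects — group contrasts within or across strata are unaffected).

The mixed-design ANOVA (state as the within-subject factor, group and
age group between subjects, full IQ and motion as covariates in the
between-subject stratum) uses Type-III sums of squares on a multivariate
linear model with univariate split-plot tests (via car). No sphericity
correction is applied by default; `gg = TRUE` switches the
within-subject p-values to Greenhouse-Geisser. Note that for dwell
times, which sum to one within subject, the between-subject main effects
are degenerate by construction (the subject average is constant); the
interpretable dwell effects are the within-subject ones. Post hoc group
contrasts are covariate-adjusted GLM t tests (`y ~ group + covariates`),
which reduce exactly to the classical pooled two-sample t test without
covariates. Multiple comparisons are corrected with Benjamini-Hochberg
FDR within each analysis family (e.g. the state-wise contrasts of one
feature and stratum form one family). Feature-symptom correlations
residualize age, full IQ and motion from the features and age, full IQ
and scale version from the SRS T scores, then report Pearson r with
two-sided p and family-wise FDR; covariates that are constant over the
analyzed subjects (scale version within one age group) are dropped.

Canonical correlation between the iSAR values of a state's stable
regions and the six SRS T scores is solved by QR decomposition of the
centered, unit-variance blocks and an SVD of the cross-product of their
orthonormal bases. Significance of the first canonical pair uses a
permutation test (default 10,000 permutations of the rows of the SRS
block, freely exchangeable) with a max-statistic family-wise correction
across canonical pairs and the add-one p-value convention
`(1 + #null >= observed) / (1 + n_perm)`. The permutation loop exploits
that row-permuting a block row-permutes its orthonormal basis, so each
permutation costs one small cross-product and SVD. Canonical loadings
are plain Pearson correlations of the original variables with their
block's first variate.

## The synthetic cohort generator

`simulate_cohort()` generates the validation cohort the tests and the
acceptance script run on: 264 subjects across 7 sites (four juvenile
sites, three adult sites) with the site-specific frame counts, TRs and
eye status of the multi-site resting-state cohort it emulates, 400
parcels partitioned into the 7 canonical networks, and 6 planted states
built as 3 exact mirror pairs from network-level signatures (DMN pair:
DMN up, limbic weakly up, SN and somatomotor down; ECN pair: ECN and
DAN up, DMN down; SN pair: SN up, visual down, DAN weakly down) plus a
small fixed parcel-level texture.

State sequences follow a reversible Markov chain built so that its
stationary distribution *equals* the cell's target dwell distribution:
off-diagonal rates are proportional to `affinity(i, j) * pi(j)` with a
symmetric pair-level affinity, scaled so the smallest self-transition
probability is the configured stick probability (0.55). Planted cell
effects, stated as pair-level dwell targets: controls sit near
DMN 0.37 / ECN 0.31 / SN 0.32; ASD cells move four points of dwell mass
out of the DMN pair, into the SN pair for juveniles and the ECN pair for
adults; adult controls get a slightly higher DMN share than juvenile
controls. The affinities (DMN-SN 1.20, DMN-ECN 1.15, SN-ECN 1.13,
within-pair 0.02) put the internetwork transition shares in the
DMN-SN > DMN-ECN > ECN-SN order with roughly 35/33/29 percent splits
and keep within-pair transitions below one percent.

Frames are `subject_gain x template[state] + white Gaussian noise`.
Noise sd is composed of a per-cell level (juveniles 1.2, adult controls
1.1, adult ASD 1.35 — the planted spatial-stability deficit), a fixed
per-site multiplier (0.95-1.08, what ComBat later removes), a lognormal
per-subject multiplier, and a per-pair state multiplier (DMN 0.9,
ECN 1.15, SN 1.0) that makes DMN states the most and ECN states the
least spatially stable, mirroring the stability ordering the method is
meant to detect. At these levels a frame correlates with its template at
roughly r = 0.4-0.6, a realistic single-frame SNR. Covariates are drawn
uniformly within per-site ranges; motion is weakly coupled to the
subject noise multiplier so covariate adjustment has real work to do.
SRS-like T scores are a group baseline shift (ASD +22 on a baseline of
50) plus linear couplings to the subject's realized SN-pair dwell and
log noise level, item noise, rounding, and clipping to [35, 120]; the
total is the item mean. All generation is deterministic given the master
seed, with per-subject seeds derived by a fixed counter scheme
(`(seed + 100003 * counter) mod 2^31 - 1`).

What the generator deliberately does *not* model: temporal
autocorrelation of BOLD beyond state persistence (CAP operates
frame-wise on band-passed data; white noise is the matching idealization
— `simulate_subject()` accepts per-frame noise so an AR(1) extension is
straightforward), hemodynamic convolution, scanner-specific artifacts,
motion-corrupted frames, and spatially correlated noise. Passing the
recovery tests therefore shows the pipeline's estimators are correct and
well calibrated under the planted model, not that real resting-state
data satisfies that model.

## Numerical choices and degenerate inputs

- Zero-variance parcels are zeroed and flagged during normalization,
  never dropped, keeping parcel indices aligned across subjects.
- Ties at the activation threshold are neutral (strict inequalities).
- Singleton clusters make Z maps an error (the sd is meaningless);
  clusters with identical members flag their parcels instead.
- A subject who never visits a state has missing (never zero) distance
  and dwell-derived cells; missingness propagates listwise into the
  ANOVA and correlation layers, with a logged count.
- Constant features pass through harmonization untouched and flagged;
  a single site is an identity transform.
- The permutation p-value can never be exactly zero (add-one rule).
- k-means ties between replicates resolve to the first-best SSE;
  `max.col` assignment ties resolve to the lowest state index.

## Problem sizes used in validation

The test suite and `scripts/acceptance.R` validate against the
generator at the full default scale (264 subjects, ~68,000 frames, 400
parcels) for state recovery, dwell/transition recovery and the planted
group contrasts (20 seeds), and at reduced scale (60-120 parcels, 4
sites, 24-64 subjects) for mechanics that do not depend on cohort size.
Calibration checks use 1,000-2,000 null replicates per test family and
500 permutations per CCA null dataset. These sizes were chosen as the
smallest at which the binomial uncertainty of an empirical rejection
rate is well inside the asserted bands.

## Known limitations

- The elbow rule is a heuristic; curves from real cohorts can be
  ambiguous, which is why the full SSE curve is always returned and the
  selected k is only a default.
- ComBat assumes exchangeable batch effects per feature; with age group
  nested in site, age effects and site effects are not separable, and
  the package resolves the confound in favor of removing site.
- The dwell ANOVA's between-subject stratum is degenerate (compositional
  features); interpret within-subject effects.
- Individual-level iSAR is undefined for subjects who never visit a
  state; cohorts with very short scans will produce many such cells.
- The CCA requires more subjects than variables per block; the pipeline
  caps the stable-region block at the 12 highest-consensus regions for
  that reason.
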