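---
title: "Modelling disease progression: continuous trajectories and event orderings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling disease progression: continuous trajectories and event orderings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(progmod)
library(dplyr)
```

## The problem

Neurodegenerative diseases unfold over decades, but longitudinal studies
observe each patient for only a few years. Two complementary strategies
reconstruct the long-term picture from such short windows:

* the **differential equation model (DEM)** treats each subject's
  short-term rate of change as a sample of the derivative of a common
  long-term trajectory, regresses rate on biomarker value, and integrates
  the fitted rate function to obtain biomarker value as a function of
  time;
* the **event-based model (EBM)** treats each biomarker's transition
  from its normal to its abnormal distribution as an *event* and infers
  the ordering of events directly from a cross-section of patients and
  controls, with no time axis at all.

`progmod` implements both, plus the preprocessing they require and the
rank-based statistics for comparing inferred orderings within and
between patient groups (for example, a posterior-cortical syndrome with
early occipital/parietal atrophy versus an amnestic syndrome with early
hippocampal/entorhinal atrophy). Because no suitable clinical data set is
publicly deposited, the package ships a synthetic-cohort generator with
complete ground truth; every claim made by the test suite is a claim
about recovery of that known truth.

## Preprocessing

Observed regional volumes are confounded by head size, age, gender,
scanner field strength and site. `adjust_covariates()` fits, per
biomarker, a linear model of value on these covariates (categorical ones
one-hot encoded, first level as reference) and subtracts the fitted
contribution centred on the reference sample, so the overall level is
retained. The model is fitted **on controls only** by default and applied
to everyone. The alternative — fitting on the full sample — risks
regressing out genuine disease effects that correlate with age; both
options are exposed (`reference = "all"`) because the choice is a real
degree of freedom in studies of this kind.

`aggregate_rois()` averages left/right hemisphere pairs first and then
takes the unweighted mean of constituent regions per composite region of
interest; the packaged default mapping (46 bilateral regions into whole
brain, hippocampal, occipital, frontal, entorhinal, temporal, parietal
and ventricular composites) is reconstructed from the Neuromorphometrics
atlas naming conventions and can be replaced by any `roi_mapping()`.
Unweighted averaging is the plainest reading of "averaged"; a
volume-weighted variant would change composite values by a few percent
but not the methodology.

`zscore_to_controls()` standardises each biomarker against baseline
control visits only — using all control visits would weight controls by
their visit count. `orient_abnormality()` flips biomarkers whose
abnormal direction is upwards (ventricular volume, timed tests) so that
"more abnormal" is always downwards internally; the flip is recorded and
reversible.

Cognitive testing uses a discontinuation rule: once a participant scores
at floor, the test is discontinued, the *next* visit is assigned the
floor score regardless of anything recorded, and all later visits are
missing. `apply_floor_rule()` reproduces this exactly
(`[12, 0, 7, 9] -> [12, 0, 0, NA]`), and never resurrects values that
were already missing.

## The differential equation model

1. **Subject slopes** (`fit_subject_slopes()`): an ordinary
   least-squares line of value against years since baseline per subject;
   the slope is the subject's rate of change and is paired with the mean
   of the subject's observed values (not the fitted midpoint — the mean
   of what was actually measured). Subjects with fewer than two usable
   visits are excluded and counted.
2. **Rate regression** (`fit_rate_model()`): a Gaussian process with a
   squared-exponential kernel plus an observation-noise term, regressing
   slope on mean value. Hyperparameters (length scale, signal SD, noise
   SD) maximise the log marginal likelihood from five seeded restarts;
   bounds keep the length scale between 1/50 and 10 times the data range.
   The posterior mean and a pointwise 95% band are evaluated on a uniform
   grid (default 100 points) over the observed value range.
3. **Integration** (`integrate_trajectory()`): solving `dt/du = 1/f(u)`
   by trapezoidal quadrature of `1/f` on a fine grid (default 2000
   points) from the starting integration limit — the upper value limit
   for a decreasing biomarker — and inverting to value on a uniform time
   grid (default step 0.1 y). Integration limits are where the posterior
   mean rate falls within a zero-tolerance of zero (`1e-3` of the peak
   rate) or the limits of the data. A rate that *genuinely* changes sign
   in the interior makes the trajectory non-monotone and is an error; in
   practice the fitted rate also wiggles slightly around zero at the
   healthy plateau, so only opposite-signed excursions exceeding half the
   peak rate count as genuine crossings — weaker wiggles truncate the
   integration instead. This tolerance is the one numerically delicate
   choice in the package; it is deliberately conservative, and bootstrap
   replicates that still fail to integrate are dropped and counted.
4. **Anchoring** (`anchor_t0()`): with no usable age-at-onset, the time
   origin is the biomarker value threshold that best separates controls
   from patients — raw classification accuracy over candidate thresholds
   at the midpoints of the sorted pooled values, ties resolved by the
   median maximiser (balanced accuracy would differ only under heavy
   class imbalance, which the anchoring samples do not have). The time
   axis shifts so `value(0)` equals the threshold, and the y-axis is
   re-expressed as a z-score against the control sample. Anchoring is a
   rigid shift: it cannot change the trajectory's shape.
5. **Staging** (`stage_subjects_dem()`): a subject's disease time is the
   grid time minimising the equally weighted sum of squared differences
   between the subject's observed z-scores and each biomarker's `z(t)`,
   over non-missing biomarkers. Values beyond a trajectory's support
   compare against its clamped end value, so extreme subjects stage at
   the boundary rather than failing.
6. **Uncertainty** (`bootstrap_trajectories()`): nonparametric
   subject-level resampling, stratified by group so the anchoring step
   always sees both samples, with a full refit per replicate (default
   100). `compare_trajectory_values()` then tests estimated values at
   fixed times from t0 (default −10, 0, +10 years): paired t-tests across
   replicates for biomarker pairs within a group, two-sample t-tests per
   biomarker between groups, with one Bonferroni threshold across all
   tests performed. Testing across bootstrap replicates is a choice —
   the replicate spread stands in for the estimator's sampling
   distribution.

## The event-based model

Each biomarker needs densities for its measurement under "event not yet
happened" (`p(x | ¬E)`) and "event happened" (`p(x | E)`):

* `fit_gaussian_mixture()` — volumes. A two-component Gaussian mixture
  fitted by EM on pooled controls and patients, with the normal
  component tethered to the control sample (mean within ±0.5 control SD,
  SD within 0.5–1.5 control SD) and the abnormal mean constrained to the
  abnormal side of the normal mean. Without these constraints EM happily
  bisects a null distribution into two half-normals. A fit whose
  abnormal mean lies within 1.5 control SDs of the control mean is
  flagged `uninformative` (it stays usable; its event simply carries
  little ordering information).
* `fit_kde_mixture()` — cognitive scores, which are bounded, floored and
  skewed. Both components are weighted Gaussian-kernel density estimates
  with Silverman bandwidths on the responsibility-weighted sample. The
  fit alternates between reassigning each point's abnormal
  responsibility from the relative component densities and refitting the
  weighted KDEs, starting from the control/patient labels, until hard
  assignments stabilise; controls keep at least half their weight on the
  normal component so the labels anchor the solution.

Given a sequence `S` over `N` events and a subject's data row, the
likelihood sums over the subject's unknown stage `k = 0..N` with a
uniform prior:

$$P(X \mid S) = \prod_j \frac{1}{N+1} \sum_{k=0}^{N}
  \prod_{i \le k} p(x_{S(i),j} \mid E)
  \prod_{i > k} p(x_{S(i),j} \mid \neg E)$$

Missing values contribute a factor of one (marginalised out), densities
are floored at `1e-12` to keep log-likelihoods finite, and the whole
computation runs in log space (`sequence_log_likelihood()`).

`find_ml_sequence()` maximises over permutations by greedy ascent over
pairwise swaps from random restarts, with exhaustive enumeration
available up to 7 events; `mcmc_sample()` draws a posterior over
sequences by Metropolis–Hastings with symmetric pairwise-swap proposals.
Adjacent samples are correlated, so rank-based testing uses
`thin_chain()` (1 in 100 by default). `positional_variance()` turns any
set of sequences — a thinned chain or `bootstrap_sequences()` replicates,
both are offered since either is a defensible uncertainty summary — into
the event-by-position probability matrix behind positional variance
diagrams. `stage_subjects_ebm()` returns each subject's full posterior
over stages `k = 0..N` (posterior mode reported, ties towards the
earlier stage).

## Comparing orderings

Positions are ranks, so the tests are nonparametric
(`within_group_order_test()`, `between_group_position_test()`): a
one-tailed Wilcoxon signed-rank on paired position samples asks whether
event *i* precedes event *j* within a group (small position = early;
zero differences discarded, the convention built into
`stats::wilcox.test`, with the exact distribution for small tie-free
samples), and a two-tailed Mann–Whitney U with tie correction compares
one biomarker's position between groups, reported with the rank-biserial
effect size. `bonferroni_control()` applies `p < alpha/m` with `m` the
number of tests actually performed in the family, and the table wrappers
report `m` explicitly.

## The synthetic cohort generator

`generate_cohort()` emulates the study design the models target: two
patient groups (defaults 117 and 106 subjects) and 138 controls, up to
six annual visits with independent per-visit dropout (default 0.15),
five covariates with additive linear effects, and per-biomarker logistic
transitions on a latent disease-time axis. The logistic scale is
`transition_duration/6`, so the named duration covers ~95% of the
transition. Patients' baseline latent times are uniform over
`latent_time_range` (default −12 to 15 years, wide enough that the
cross-section spans the full course including the latest default onset
at 10.5 y); controls sit fixed at the pre-onset lower end. Between-
subject spread of the healthy level (`healthy_sd`) and within-visit
noise (`noise_sd`) are separate, and scores with a declared floor are
clipped there. The default two-group configuration
(`default_cohort_config()`) places occipital/parietal onsets first in
group A and hippocampal/entorhinal onsets first in group B, 1.5 years
apart, with 5-SD total shifts — a strong but not trivial signal.

What the generator does **not** emulate: informative dropout, practice
effects on cognitive tests, scanner-by-region interactions, non-sigmoid
trajectory shapes, or correlated noise across biomarkers. Passing
recovery tests on these cohorts therefore demonstrates correctness of
the machinery under the models' own assumptions, not robustness to every
way real data violate them. The uniform distribution of baseline disease
stages is likewise a modelling convenience: the clinical literature
rarely reports the stage distribution, and a cross-section concentrated
at one stage would genuinely degrade both models.

## Problem sizes used in validation

The test suite and the acceptance script size their simulations to be
decisive yet quick: 20 replicate cohorts (200 patients, 5 events) for
the search-versus-enumeration check with 2,000 MCMC refinement
iterations (the sequence posterior at that separation mixes within a few
hundred swaps); 10 cohorts of 150 patients for eight-event ordering
recovery; 100 patients × 3 visits for trajectory recovery; 500 simulated
suites for the familywise-error calibration of the rank tests. The
`mcmc_sample()` default of 100,000 iterations with thinning 100 remains
the recommendation for real analyses.

## A small worked example

```{r example, message = FALSE, warning = FALSE}
coh <- generate_cohort(default_cohort_config(seed = 42))
bms <- coh$truth$biomarkers
dirs <- setNames(ifelse(bms == "ventricle", "increasing", "decreasing"), bms)

ref <- control_reference(coh$data, bms)
z <- orient_abnormality(zscore_to_controls(coh$data, ref), dirs)
base <- z |>
  group_by(subject_id) |>
  slice_min(visit_index, n = 1, with_ties = FALSE) |>
  ungroup() |>
  filter(group %in% c("groupA", "control"))

fits <- fit_mixtures(base, bms, "gaussian", baseline_only = FALSE)
ml <- find_ml_sequence(filter(base, group == "groupA"), fits, seed = 1)
ml
ground_truth_ordering(coh, "groupA")
```

## Known limitations

* The DEM assumes a single monotone trajectory per biomarker; rate
  functions that genuinely cross zero mid-range are rejected rather than
  modelled piecewise.
* The GP kernel is stationary; strongly stage-dependent smoothness of
  the rate function is averaged over.
* Biomarkers are modelled independently in both the DEM (no cross-
  biomarker covariance in the GP) and the EBM mixtures (conditional
  independence given the stage).
* EBM staging is cross-sectional; longitudinal consistency of a
  subject's stages across visits is not enforced.
* Mixture fits for very late events in a cohort observed early are
  intrinsically weak (few abnormal examples); the `uninformative` flag
  marks them but no prior information rescues them.
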