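---
title: "Static and dynamic functional network connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Static and dynamic functional network connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`dynfnc` analyses resting-state independent-component (IC) time courses: a
matrix of T time points by C components per subject, sampled at a fixed
repetition time (TR). Two complementary views are computed. *Static*
functional network connectivity (sFNC) is the whole-scan Pearson correlation
between IC time courses, Fisher z-transformed, at component level (C x C)
and aggregated to network level. *Dynamic* FNC (dFNC) re-estimates
connectivity inside a tapered sliding window, clusters the windowed matrices
into recurring connectivity states, and summarises each subject's state
sequence with temporal-property metrics. A per-component temporal
variability statistic and a group/clinical statistics layer complete the
pipeline. A synthetic cohort generator with planted ground truth backs every
stage's validation.

Network-level sFNC entries are means of the pairwise Fisher-z values over
the component pairs spanning the two networks (within-network entries
average unordered distinct pairs only); averaging on the z scale rather
than the r scale keeps the aggregate variance-stabilised and is the common
toolbox convention. Ten components populate five canonical networks —
somatomotor (2), dorsal attention (2), visual (2), default mode (3) and
ventral attention (1); a single-component network has no defined
within-network entry and is masked.

# The windowed connectivity model

## Taper

Windows use a rectangle of width `W` TRs convolved with a Gaussian kernel of
standard deviation `sigma` TRs, truncated to the central `W` samples and
renormalised to sum to one (defaults `W = 30`, `sigma = 3`). The taper
softens window edges so that entering/leaving time points are down-weighted,
reducing the jitter of consecutive window estimates. Window `i` covers TRs
`[i*step, i*step + W)` with `step = 1` by default, giving
`floor((T - W)/step) + 1` windows — exactly 170 windows at the default
`T = 199`.

## Regularised covariance

With `W = 30` samples and `C = 10` components, the per-window sample
covariance is noisy, so each window's precision matrix is estimated by the
graphical lasso: maximise `log det(Theta) - tr(S Theta)` minus an L1 penalty
`lambda` on the off-diagonal precision entries. The optimiser is a block
coordinate-descent (compiled in C++), with a lasso sub-problem per column.
Convergence is declared when the mean absolute change of the working
covariance over one full cycle falls below `tol` times the mean absolute
off-diagonal of `S` (`tol = 1e-7`); at `lambda = 0` the algorithm converges
to the plain matrix inverse, which the tests exploit as an oracle, together
with the 2-variable closed form (off-diagonal covariance soft-thresholded by
`lambda`, then inverted).

The estimated covariance (the inverse of the penalised precision) is
normalised to correlation and Fisher z-transformed (`atanh`), with the
diagonal masked as undefined rather than mapped to infinity. Values with
`|r| >= 1` anywhere are clipped to `1 - 1e-7` with a warning. Whether the
clustering should consume these full correlations or the partial
correlations read off the precision matrix is genuinely ambiguous in the
methodological literature; both are implemented (`fc = "correlation"` or
`"partial"`), full correlation being the default because it stays on the
same scale as sFNC.

## Penalty choice

`select_lambda()` follows the convention of repeated random splits: per
subject, 100 random half-splits of the windows into fit and evaluation
sets; each candidate penalty is scored by the mean held-out Gaussian
log-likelihood of the precision fitted on the pooled fit-half covariance.
On cohorts from the bundled generator this procedure selects the bottom of
the default grid (0.01); the pipeline therefore uses a fixed
`lambda = 0.01` default so that large simulation studies need not repeat
the selection per subject, and `lambda = "select"` switches the full
procedure on.

## Nuisance residualisation

Connectivity values are residualised against subject-level covariates (age,
gender by default) *after* the Fisher transform. Because the covariates are
constant within subject, one ordinary-least-squares fit per connectivity
pair on the subject-mean z-values suffices; the fitted subject effect
(minus its grand mean, so the overall intercept is retained) is subtracted
from all windows of that subject. Collinear covariate designs are rejected
rather than silently dropped.

# Connectivity states

All subjects' windowed matrices are vectorised over the upper triangle and
pooled; k-means with squared Euclidean distance (Hartigan-Wong, best of
`n_replicates = 100` random restarts under a fixed seed) yields `k`
centroids and a state label per window. States are relabelled in descending
order of total occurrence so reports are stable across runs. Per subject,
the label sequence gives:

* **fraction time** — windows in each state / total windows;
* **mean dwell time** — mean length of maximal runs of each state, 0 for
  unvisited states (so cohort medians of 0 are representable);
* **transition number** — count of label changes, plus per-state entry
  counts since the aggregate number alone does not say *into which* state
  transitions occur.

## Choosing k: the elbow

For candidate k's the cluster validity index is the ratio of within-cluster
to between-cluster dispersion. This curve is convex and decreasing for
essentially any data, and its raw second difference is therefore maximal at
the smallest interior candidate regardless of cluster structure — a
structureless `1/k` curve already behaves this way. The package instead
locates the elbow as the point of maximum distance between the normalised
index curve and the chord joining its endpoints (the "kneedle" construction):
the candidate where the curve bends away most from its overall decline.
Raw second differences are still returned in the curve for inspection. A
curve whose maximum normalised chord distance falls below `tol = 0.02` is
declared flat and the smallest candidate is returned with a warning.

# Temporal variability

For component k, each window contributes a profile: the k-th row of its
connectivity matrix with the self-entry removed (the self-correlation is
constant by construction and would otherwise be a degenerate coordinate).
The temporal variability is

`V_k = 1 - sum_{i != j} rho(F_i,k, F_j,k) / (n (n - 1))`,

one minus the mean Pearson correlation over all ordered window pairs. All
windows identical gives `V_k = 0`; unrelated profiles give `V_k` near 1.
Window pairs in which either profile is constant have no defined
correlation; they are dropped and the divisor reduced, with the dropped-pair
count reported per subject, which preserves the mean interpretation without
fabricating values. `V` is computed on the residualised Fisher-z matrices
for consistency with the rest of the pipeline; Pearson correlation of
profiles is only approximately invariant to the monotone z-map, so the raw
correlation alternative is available by running the stack un-transformed.

# Group and clinical statistics

Group contrasts use Student's equal-variance t-test by default (Welch
optional), or the Mann-Whitney U test with exact small-sample p-values
(pooled n at most 12, no ties) and a tie-corrected normal approximation
otherwise. Gender enters as a covariate through the linear model
`value ~ group + covariates` for t-type tests and through partial
correlation (residualise both variables, test on `n - 2 - q` degrees of
freedom) for correlations. Paired pre/post clinical contrasts use the
paired t-test with per-subject percent change, masked where the baseline is
zero. All tests are two-sided. Benjamini-Hochberg FDR correction is applied
within families — component-pair sFNC, network-level sFNC, state metrics,
variability — mirroring how such results are reported separately. A
Kolmogorov-Smirnov normality check is available as a diagnostic only: which
test runs is a configuration choice, never a silent automatic switch.

# The synthetic cohort generator

The generator emulates the *structure* of a two-group resting-state study —
33 patients vs 23 controls, ~199 TRs, 10 ICs in five canonical networks
(SMN, DAN, VN, DMN, VAN with 2/2/2/3/1 components), four recurring
connectivity states, male-skewed patients (26/33 vs 9/23), clinical scores
(MMSE, timed-up-and-go, three ordinal grading-scale subscores) — without
claiming to reproduce any patient-level values.

Hidden dynamics are first-order Markov at TR resolution: the simplest
process that yields well-defined fraction/dwell/transition ground truth.
Observations are zero-mean Gaussian draws with the active state's
covariance; no hemodynamic convolution is applied, because covariance-state
recovery from IC time courses is indifferent to a shared smoothing kernel
(an optional AR(1) flag exists for realism and is off by default).

Two generator design choices matter and are deliberate:

* **Dwell scale.** Two pressures pull in opposite directions. A state run
  of `d` TRs contains `d - W + 1` uncontaminated windows, so states lasting
  about one window length are invisible to windowed connectivity — dwell
  must span several windows. But a run must also fit well inside the
  `T = 199` TR scan, or observed run lengths are truncated at the scan ends
  and the planted group dwell contrast collapses into noise. The defaults
  sit between: baseline expected dwell two window lengths (60 TRs;
  self-transition `1 - 1/60`) and ~120 TRs for the patients' designated
  "abnormality" state (state 4), a two-fold contrast. The planted group
  effect is monotone in the bias parameter. Where a property specifically
  concerns window-label fidelity (label agreement with planted truth), the
  validation additionally uses a slow-switching variant (dwell 150/250 TRs)
  in which windows are nearly pure.
* **State separation.** The four regimes — sparse/weak; segregated
  (within-network coupling with mild between-network anticorrelation);
  globally integrated; a mixed pattern with anti-correlated DMN/attention
  blocks — differ from one another across many of the 45 component pairs,
  because Fisher-z estimation noise at `W = 30` is roughly constant per
  entry and separation concentrated in a few pairs would be swamped.
  Matrices are jittered per seed, projected to SPD correlation form, and
  the first state is kept near-diagonal.

Clinical scores follow a linear link on (group, planted dwell time in the
target state, planted switching rate) plus Gaussian noise, then rounding
and clipping into valid ranges; the ordinal grading subscores threshold a
latent continuous score. Patients receive a second, partially improved
postoperative record.

What passing tests on this generator do **not** show: robustness to
hemodynamic and motion confounds, to spatially overlapping IC estimation
error, to non-Gaussian heavy-tailed noise, or to dwell distributions far
from geometric. Conclusions about real cohorts require real data.

# Validation problem sizes

The test-suite experiments run at sizes chosen to exercise the full
pipeline while remaining routine on a laptop: elbow recovery uses 20 seeds
of ~20-subject cohorts (T = 199, 170 windows each, k-candidates 2..8, 100
k-means restarts); dwell-bias recovery uses 50 seeds at the full 33/23
cohort with k = 4 and 10 restarts; statistical calibration uses 5000 null
features and a 500-feature known mixture over 20 replicates. The
Monte-Carlo consistency checks of the generator use single subjects of
20000-30000 time points.

# Numerical conventions and degenerate inputs

* ICA sign indeterminacy is resolved by orienting each spatial map so its
  maximum-absolute voxel is positive; components are ordered by descending
  explained variance. Template labeling assigns by maximum absolute spatial
  correlation, stores the signed value, and flags components below
  `|r| = 0.2` as unassigned.
* `pearson_fc` refuses constant columns by name; windowed segments with
  taper-weighted variance below 1e-12 name the offending component.
* The sFNC diagonal is masked `NA`, never `atanh(1)`. Network-level
  aggregation averages unordered distinct within-network pairs; a
  single-component network (VAN) has an undefined within-network entry,
  masked.
* k-means label/centroid reproducibility is guaranteed by seeding the
  restart stream; identical configuration and seeds reproduce every
  deterministic output bit-identically (checksummed in the run report).
* Unvisited states contribute dwell 0 and fraction 0.
* Zero-variance nonzero-mean paired differences report the machine floor
  rather than erroring; zero preoperative scores mask percent change for
  that subject only.

# Limitations

Back-reconstruction is spatio-temporal regression through the stored PCA
operators; ICASSO-style stability resampling is out of scope. The elbow is
a heuristic: on data without genuine multi-state structure it returns the
smallest candidate with a warning rather than inventing an order. The
graphical-lasso penalty default reflects the bundled generator's regime;
other data scales warrant re-running `select_lambda()`. Transition-number
semantics (all changes vs entries into specific states) are reported both
ways because the convention is ambiguous in the field.
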