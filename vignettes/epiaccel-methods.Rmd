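---
title: "Models and methods behind epiaccel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind epiaccel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

epiaccel contrasts epigenetic ageing between two lifestyle groups — a
free-ranging ("wild") and a captive ("zoo") cohort of the same species —
from whole-genome CpG methylation counts, and complements that contrast
with an age-independent differential-methylation scan and a survival
analysis. This vignette explains the models, the tunable parameters, the
numerical choices, and what the synthetic cohorts used by the test suite
do and do not establish.

## The two-group epigenetic clock

### Why a grid approximation

An epigenetic clock regresses age on methylation. When the cohort mixes
two groups whose biological ageing may differ by an offset and/or a rate,
the age-acceleration signal is bimodal, which violates the residual
assumptions of a single penalised regression. `grid_fit()` therefore
linearises the zoo ages with a candidate transform

  t = 2^s * age + b        (zoo samples; wild ages are untouched)

and asks, for each candidate `(s, b, alpha)`, how well a leave-one-out
elastic net on the principal components of methylation predicts the
transformed ages. The score of a grid point is the squared Pearson
correlation between LOO-predicted and transformed age; the grid is then
re-centred on the incumbent with halved steps.

Two numerical guards matter here:

* **Positive orientation only.** With an intercept-only model, the
  leave-one-out prediction of sample *i* is the training mean of the other
  n−1 responses — an exact affine function of the held-out response with
  slope −1/(n−1). A near-constant predictor is therefore perfectly
  *anti*-correlated with the response, and a naive squared correlation
  would score it 1. `grid_fit()` scores a point 0 unless the correlation
  is positive: an age predictor anticorrelated with age is not a fit.
* **A one-standard-error-style parsimony rule.** The (s, b) surface has a
  structural trade-off ridge: compressing the zoo ages and compensating
  with the intercept changes the score by a few thousandths, far below
  the sampling error of a squared correlation at n = 64 (about 0.016).
  Points within half a standard error of the maximum are therefore
  treated as statistically tied, and among ties the smallest |s| wins,
  then the best score, then the smaller |b|. Without this rule the argmax
  wanders along the ridge and the intercept absorbs an arbitrary
  slope-compensation term.

### The penalised regression engine

Each grid point needs n outer leave-one-out fits, each with its penalty
chosen by leave-one-out cross-validation *inside* its n−1 training
samples, over a fixed 100-point log-spaced penalty path. Refit by brute
force this is ~10^9 model fits. The package instead uses the closed-form
leave-one-out identity of the active-set-restricted problem: for a fixed
active set the elastic-net estimator is affine in the response, so LOO
residuals are `(y - fitted) / (1 - H_ii)` with `H` the ridge-type hat
matrix on the active set. This is exact for ridge, and exact for the
elastic net whenever deleting one observation does not change the active
set; `loo_predict(..., inner_method = "exact")` provides the brute-force
reference, and the test suite checks the two agree.

Further numerical choices, each visible as an argument:

* **Centring without variance-scaling.** The predictors are PC scores,
  whose scale *is* the explained variance. Equal-variance standardisation
  (the glmnet default for raw predictors) would inflate the ~60 noise
  components to the size of the signal component and destroy the ridge
  end of the path; with centring only, ridge shrinkage acts per
  eigenvalue, as principal-component regression intends.
* **Penalty path.** 100 points, log-spaced from the smallest
  all-coefficients-zero penalty (scaled by 1/alpha, capped for ridge)
  down to `max|cov(x, y)| * lambda_min_ratio` (default ratio 0.01). The
  lower anchor is alpha-independent so the ridge path actually reaches
  the lightly penalised regime. Paths are derived per training set from
  the *untransformed* ages, so they are shared across grid points and
  never use the held-out sample's methylation.
* **Degrees-of-freedom guard** (`dfmax`, default 32 in `grid_config()`):
  path points whose active set exceeds `dfmax` components are excluded
  from penalty selection. With 63 predictors and 63 training samples
  those points are deep in the interpolation regime and are never a
  sensible CV choice, but evaluating their hat matrices dominates run
  time.
* **Grid schedule.** Round 1: s in [-1, 1] step 0.25, b in [-15, 15] years
  step 1.5, alpha in {0, 0.25, 0.5, 0.75, 1}; two refinement rounds, each
  spanning ± one previous step with halved steps; refinement stops when
  the intercept step would fall below 0.25 y.

### From predictions to the reported group effect

Epigenetic age acceleration is defined per sample as
`EAA = predicted age − calendar age`, with the predictions taken from the
leave-one-out fits at the best grid point (not from a final refit on all
samples; both views of the data are available from the returned object).
`group_effect()` then models predicted age on calendar age, group,
conversion efficiency and genome-wide mean methylation, with a random
intercept per individual when repeated samples exist, and reports the
marginal-mean group difference. Note that penalised LOO predictions are
shrunk toward the training mean, so this marginal difference is
attenuated relative to the grid intercept `b`; the grid intercept is the
calibrated estimator of the planted offset and is what the recovery
checks use.

Two independent checks guard against overfitting-induced group effects:

* `cross_group_validation()` trains the whole pipeline (site selection,
  PCA, penalty selection) on one group only, with untransformed ages, and
  predicts the other group.
* `adms_estimator()` forgoes regression entirely: the unweighted mean
  methylation over the sites most negatively correlated with age
  (squared correlation at least 0.2), scaled linearly to the observed age
  range with the orientation reversed (maximum methylation maps to the
  youngest observed age). Group labels enter no step of the estimator.
  The group effect is then a linear model of the scaled age on calendar
  age, group and the two technical covariates; calendar age (not log age)
  is the covariate, log age being used only for trajectory plots.

### The permutation null

`permute_and_refit()` randomises the wild/zoo labels among individuals
(samples of one individual move together; the number of individuals per
group is preserved) and re-runs the grid search, recording the best-fit
intercept. Because label permutation leaves site selection and the PCA
untouched, those are computed once. The default permutation grid is
deliberately coarse — slope step 0.5, intercept step 3 y, ridge only, no
refinement — keeping hundreds of permutations affordable; the full
round-1 grid is available via the `grid` argument. Critically, the
observed statistic is evaluated with the *same* coarse grid (a
permutation test is only valid if observed and null statistics are
computed identically); `empirical_p()` uses that value by default and
reports both a normal-fit p and a rank-based p. The grid statistic is
discrete, so the rank p is super-uniform (conservative); the test suite
checks conservativeness rather than exact uniformity.

## The DMR caller

`call_dmrs()` looks for regions whose methylation differs between groups
*independently* of age and of age acceleration:

1. **Covariate correction** (`beta_correct()`): per site, a beta
   regression (logit mean link, constant precision, maximum likelihood)
   of the shrunk levels `y' = (y(N-1) + 0.5)/N` on age, EAA, conversion
   efficiency and genome-wide mean methylation — group is deliberately
   excluded, because the group contrast is the signal being segmented.
   The corrected value is the fitted mean at covariate means plus the
   response-scale residual, clipped to (0, 1). The fitter is a dedicated
   Fisher-scoring implementation (~0.4 ms per site; the correction runs
   over tens of thousands of sites); non-convergence falls back to
   linear-model residualisation with a flag, and constant sites pass
   through unchanged.
2. **Candidate windows** (`build_windows()`): maximal runs of CpGs with
   pre-correction level standard deviation at least 0.1 and adjacent
   gaps of at most 500 bp; runs shorter than 10 CpGs are dropped.
3. **Segmentation** (`segment_window()`): on the per-CpG difference of
   group means of corrected levels, the contiguous sub-segment (length at
   least 10) maximising the absolute mean difference is emitted if that
   mean exceeds 0.1, and both flanks are segmented recursively. Ties
   within 1e-9 resolve to the longer, then the leftmost sub-segment, so
   a uniformly shifted window is returned whole. The test suite checks
   the recursion against an exhaustive scan of all sub-segments.
4. **Scoring** (`test_segment()` / `mwu_test()`): per-sample segment
   means are compared between groups with a two-sided Mann-Whitney U
   test — exact enumeration of assignments when both groups have at most
   8 samples (ties handled by mid-ranks), otherwise the normal
   approximation with tie and continuity correction.
5. **Multiplicity**: one Benjamini-Hochberg correction across all tested
   segments genome-wide; a region is significant if q <= 0.05, its
   absolute mean difference exceeds 0.1, and it has at least 10 CpGs.

Reported coordinates are 0-based, half-open, with the end at the last
member CpG + 2 (covering the dinucleotide). `annotate_dmrs()` assigns
DMRs to genes whose span — gene body plus a strand-aware promoter window
1500 bp upstream to 500 bp downstream of the TSS — lies within 5 kb,
classifying by overlap priority promoter > UTR > exon > intron > flank.

A consequence worth stating plainly: when the cohort carries a genuine
age acceleration, EAA correlates strongly with group, and the covariate
correction legitimately removes most of any group-mean difference. An
age-independent DMR then has to be large to survive. The DMR recovery
experiments in the test suite therefore plant group DMRs in cohorts
*without* a planted acceleration, so that the recall target is
well-defined; with a 6-year planted acceleration the same planted
differences are (correctly) attenuated below the reporting threshold.

## The survival contrast

Wild individuals contribute annual detection histories.
`return_probability()` estimates, among maximal undetected runs of at
least `gap` years that are observable to their end, the fraction followed
by a later detection — terminal silences count as non-returns.
`assign_fates()` then declares an individual dead at
`last detection age + 1` (detection is annual; the offset is an argument)
when it has been silent for at least 2 years and the estimated return
probability is below the cutoff (default 0.01); everyone else is censored
at their age in the final study year. This operational rule is a
deliberately simple surrogate for a full posterior over survival given
the detection history: the package exposes the two constants rather than
inventing an unstated prior structure. Zoo records carry explicit death
or censoring dates and pass through.

`fit_cox()` is a proportional-hazards fit (Efron ties) with group and —
when it varies — sex; it reports the zoo/wild hazard ratio with a 95%
Wald interval and per-stratum survival curves, from which
`survival_quantiles()` reads median and quartile ages at death. Left
truncation is not modelled: all individuals enter at age 0, matching
known-age monitoring from hatching.

## The synthetic cohort generator

`cohort_config()` + `simulate_cohort()` emulate the data structure the
analysis assumes: 34 wild and 30 zoo samples by default, ages uniform on
2–25 years, six individuals sampled twice at least a year apart, pooled
binomial counts at a mean depth of 30x (Poisson around a Gamma mean,
shape 8, so depth is overdispersed), per-sample conversion efficiencies
uniform on 0.97–0.999 applied as false-positive methylation
(`pi_obs = pi + (1 - pi)(1 - c)`), and three site classes:

* **Clock sites** decline with the logarithm of *effective age*
  `a + delta * zoo + eps`, where `delta` (default 6 y) is the planted
  acceleration and `eps ~ N(0, 1.5 y)` is a per-sample biological jitter
  shared across sites — this jitter, not the binomial noise, sets the
  clock's realistic residual error. Baselines and slopes are drawn wide
  (`m0` in 0.25–0.95, `beta` in −0.35..−0.04 per log-year) so that many
  trajectories saturate at the 0.01/0.99 bounds at site-specific ages.
  The saturation heterogeneity is essential, not cosmetic: if every site
  followed the same log shape, the methylome would be a rank-one function
  of log-age and no linear readout of principal components could
  represent effective age itself, leaving the grid's slope parameter
  biased. Real clocks likewise rely on CpGs with heterogeneous, bounded
  trajectories.
* **DMR sites** come in clusters (15 CpGs, in-cluster spacing 50–400 bp,
  clusters at least 600 bp apart) with a planted group offset (default
  0.2, sign drawn per region).
* **Inert sites** carry no group or age signal.

DMR and inert sites receive per-cell Gaussian level noise (sd 0.1,
clipped). Without it, a site whose true level is constant has
cross-sample standard deviation below the 0.1 window filter at 30x depth,
and every null site would vanish from the DMR pipeline, making null
calibration checks vacuous; the noise emulates ordinary inter-individual
variation. Clock sites sit on their own contig at ~1 kb spacing so they
never form DMR windows.

The per-sample noise on age trajectories has no quantitative analogue to
copy from data, so `noise_sd = 1.5` effective-age years is a judgement
call: it yields a clock residual error (a few years) and fit quality
comparable to what blood methylation clocks typically achieve.

What passing tests on these cohorts shows: that each stage recovers what
was planted, at the study's sample sizes, under binomial sampling noise,
overdispersed coverage, conversion-efficiency artefacts and repeated
sampling. What it does not show: robustness to genetic structure between
groups, batch effects correlated with group, non-logarithmic trajectory
shapes, or misspecified detection models in the survival data — real-data
features the generator deliberately does not attempt.

## Problem sizes used by the checks

The end-to-end checks run the clock on cohorts with 2,000 clock sites
(plus background), the DMR caller on 50,000 sites with 200 planted
regions, the permutation null with 100 relabellings, and the survival
recovery with 2,000 individuals per group over 100 replicate seeds;
multi-seed clock recovery properties use 20 replicate cohorts at reduced
site counts. These sizes keep every stage's statistical behaviour visible
(recall, false-discovery control, CI coverage) while completing in
minutes.

## Known limitations

* The marginal-mean group effect computed from penalised LOO predictions
  is attenuated by shrinkage; use the grid intercept for calibrated
  effect recovery, and the marginal model for inference about its
  significance.
* The hat-matrix inner LOO is approximate for the elastic net exactly at
  active-set changes; the brute-force mode exists for verification and
  small problems.
* With strong group-correlated EAA, age-independent DMRs are partially
  absorbed by the covariate correction (see above) — an identifiability
  limit of the correction design, not an implementation artefact.
* The fate-assignment rule is a surrogate for a full detection-model
  posterior and ignores heterogeneity in detection probability.
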