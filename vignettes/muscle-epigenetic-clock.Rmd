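---
title: "Building and evaluating a muscle epigenetic clock from heterogeneous methylation datasets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and evaluating a muscle epigenetic clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Chronological age leaves a reproducible imprint on DNA methylation. A tissue
cohort profiled on Illumina-style arrays yields a probes-by-samples matrix of
beta values (methylation fractions in [0, 1]), and a penalized regression of a
transformed age on those fractions — an *epigenetic clock* — predicts
chronological age from tissue alone. Skeletal muscle is poorly served by
pan-tissue clocks, and assembling a muscle-specific one means pooling many
small, heterogeneous cohorts: different array generations (HM27, HM450,
HMEPIC), different labs, paired designs (twins, pre/post interventions),
wildly different age ranges, and only a modest set of probes present on every
platform. `muscleclock` implements that whole pipeline: preprocessing and QC,
cross-dataset calibration to a gold standard, elastic-net clock training with
leave-one-dataset-out (LOOCV) evaluation, two age-acceleration statistics, and
the accompanying age EWAS with region calling and enrichment tests. A
synthetic multi-dataset simulator makes every stage testable without any
external downloads.

## The age transform and the clock

Ages are mapped to a scale on which methylation drift is approximately
linear: below the adult pivot `adult_age` (default 20 years) the transform is
logarithmic, `log((age + 1) / (adult_age + 1))`; above it, linear,
`(age - adult_age) / (adult_age + 1)`. The map is continuous, strictly
increasing and zero at the pivot; `inverse_transform_age()` undoes it
exactly. The clock is an elastic net on the transformed age,

$$\min_{b_0,\beta} \tfrac{1}{2n}\sum_i (y_i - b_0 - x_i^T\beta)^2 +
\lambda\left[\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\right],$$

with mixing weight `alpha = 0.5` and `lambda` chosen by 10-fold
cross-validation (fit via glmnet). Two choices were genuinely open and are
fixed as follows:

* **Fold assignment** is stratified by dataset, so no CV fold coincides with
  a single cohort — otherwise the fold error would re-create the
  dataset-confounding the LOOCV is designed to expose.
* **`lambda_rule`** defaults to the CV minimum (`"min"`); the one-standard-
  error rule is available but yields sparser, slightly less accurate clocks
  on the simulated compendium.

Only probes with nonzero weight are stored. At prediction time, model probes
missing from a dataset are imputed from the stored gold-standard mean profile
as long as at least 95% of model probes are present; predictions are clipped
at 0 years since the inverse transform can go negative for extreme inputs.

## Accuracy metrics

Dataset-level LOOCV holds out one whole cohort, trains on the rest and
predicts the held-out samples. Accuracy is summarized per held-out dataset
by:

* `AA_diff = predicted - actual` (years); its median absolute value measures
  calibration, its mean measures whether a cohort reads systematically young
  or old.
* `AA_resid`: residuals of an OLS regression of predicted on actual age
  *within* the evaluation group. By construction the residuals average zero
  and are exactly uncorrelated with age, so `AA_resid` is insensitive to a
  cohort's mean age. Groups with fewer than 3 samples get no `AA_resid`.
* Pearson r between predicted and actual age, reported only when the group
  has at least 4 samples and non-constant age (cohorts of a single
  intervention age, or of n = 3, are reported as "not computed").

`compare_clocks()` contrasts two clocks by a two-sided paired t-test on
per-sample absolute age acceleration, flagged at p < 0.005.

## Gold-standard calibration (three-state beta-mixture quantile matching)

Every sample is mapped onto the methylation distribution of a designated
gold-standard dataset. A three-component beta mixture (hypo-, hemi-,
hypermethylated states) is fitted by EM to the gold reference profile and to
each sample; hypo-state values move through beta-CDF quantile matching
between the hypo components and hyper-state values likewise; hemi-state
values map through the hemi components and are then rescaled affinely so the
hemi segment is anchored exactly at the images of the two state boundaries
under the hypo and hyper maps. The anchoring keeps the overall map continuous
and monotone even when the middle components of source and target disagree
(a straight-line hemi interpolation was tried first and left a systematic
mid-range residual about twice as large).

Numerical choices:

* The EM M-step maximizes each component's weighted beta log-likelihood
  through its three sufficient statistics, with a BFGS step started at the
  current parameters; a step is only accepted if it does not decrease the
  objective, so the observed-data log-likelihood is non-decreasing (a
  generalized EM).
* `max_iter = 100` deliberately caps warm-started per-sample fits short of
  full convergence: the capped fits stay mildly regularized toward the gold
  fit, which stabilizes the per-sample calibration maps. Raising the cap
  gives fully converged but noisier maps and slightly worse downstream
  age predictions.
* Initialization is deterministic, from cut points at beta = 0.2 and 0.75
  (falling back to tertiles for degenerate inputs), so repeated fits are
  bit-identical. Defaults: `max_iter = 100`, `tol = 1e-6` on the
  log-likelihood change, clipping at `eps = 1e-6`.
* The gold reference is the per-probe *mean* beta of the gold dataset.
  Calibrating against a mean profile rather than one reference sample halves
  the reference noise and is the natural population-level target.
* When calibrating a dataset, each sample's EM is warm-started at the gold
  fit, so the capped fits are anchored at a sensible common reference rather
  than at per-sample moment estimates.

The transform is monotone (hence rank-preserving within a sample), bounded
in [0, 1], and near-identity when a dataset already matches the gold
standard.

## Preprocessing

The filters use the conventional thresholds with their literal boundary
semantics: samples are dropped when *strictly more than* 10% of probes have
detection p > 0.01; probes are dropped for any missing beta, any detection
p > 0.01, bead count < 3 in *at least* 5% of samples, non-CpG target,
multi-mapping or SNP-associated probes, missing annotation, and (for
mixed-sex cohorts) sex-chromosome location. Beta values come from
intensities as `M / (U + M + 100)`; modelling happens on the M (logit2)
scale after clipping betas to `[1e-6, 1 - 1e-6]`. Dataset-level QC flags a
cohort whose mean inter-sample correlation is at or below 0.97 or whose
maximum beta is at or below 0.99 — a warning and a report flag, not a hard
stop, since this is an inclusion screen for external data.

Missing values are filled by k-nearest-neighbour imputation across samples
(k = 5, Euclidean distance on mutually observed probes); probes observed in
fewer than k samples are dropped with a warning.

Known-batch adjustment is a parametric empirical-Bayes location-scale model
on M values: per-probe standardization, per-batch mean/variance estimates
shrunk toward normal / inverse-gamma priors fitted across probes by moments,
then recentring and rescaling. Shrinkage deliberately leaves a probe's
*individual* batch deviation partially intact — only its systematic
component is removed — so per-probe batch means are equalized approximately,
not exactly. `method = "direct"` skips the shrinkage and equalizes exactly;
it is the right choice when batch effects are homogeneous or probes are few.
The adjustment preserves each probe's grand mean exactly (the output is
recentred), and a second technical factor (array position) is handled as a
sequential second pass.

## Age EWAS

`ewas_fit()` regresses methylation on age plus covariates (sex and dataset
id by default) per probe, all probes at once via a shared QR decomposition.
Paired designs are handled with a single consensus intra-block correlation:
the within-subject correlation of residuals is pooled over a probe
subsample, and the model is refitted by GLS under an exchangeable
within-block correlation (block-wise whitening). A fixed-subject-effects
fallback exists for longitudinal designs where age varies within subject.

Residual variances are moderated with a scaled inverse-chi-square prior
estimated by matching the mean and variance of `log s^2` (digamma/trigamma
inversion); the moderated variance is `(d0 s0^2 + d s^2) / (d0 + d)` and the
moderated t has `d0 + d` degrees of freedom. At `d0 = 0` this reduces to the
ordinary t, at `d0 = Inf` to a common variance; the estimates agree with
limma's to numerical precision, which the test suite checks as an
independent cross-check.

DMRs follow the direction-consistency definition: significant probes
(BH FDR < 0.005) sorted by position are merged while consecutive gaps are at
most 1,000 bp *and* the sign of the age slope is unchanged; clusters of at
least two probes are reported. This is a transparent, testable rule;
kernel-smoothing region callers are deliberately out of scope.

Enrichment of a probe panel over island contexts or the 15 chromatin states
uses a two-sided Fisher exact test per level with the sample odds ratio, BH
corrected within each category. Everything in the package uses the same
significance convention, FDR < 0.005 (p < 0.005 where a single test is
involved).

### The bias-aware gene-set test

Genes accumulate significant probes in proportion to how many probes they
carry, so a naive hypergeometric test over genes is anticonservative. The
package models the null number of significant genes in a set as a Wallenius
noncentral hypergeometric distribution whose odds parameter is the ratio of
mean gene weights inside versus outside the set. The weight of a gene with
`k` probes is its null probability of containing at least one significant
probe, `1 - (1 - p)^k`, where `p` is the fraction of background probes that
are significant: proportional to `k` when significance is sparse, and
correctly saturating when it is not (a 20-probe gene is *not* ten times as
likely to be hit as a 2-probe gene once hits are common). The Wallenius pmf
is evaluated by numerical integration after a substitution that turns the
integrand into a smooth, bounded expectation under a Beta kernel; at odds 1
the expression collapses analytically to the central hypergeometric, which
is also the package's reference point in tests.

The Monte-Carlo overlap null (`random_overlap_test()`) draws uniform panels
from the background and reports the null overlap distribution with a second
panel plus a (+1-corrected) tail probability — the standard way to ask
whether two clock CpG panels share more probes than chance.

## The synthetic compendium

`default_paper_like_config()` describes twelve datasets across the three
array platforms with a fixed per-dataset age-stratum quota matrix. At
`scale = 1` the pooled design has exactly 682 samples in strata
242 / 105 / 275 / 60 over ages 18–30 / 30–50 / 50–70 / 70–90 — a bimodal
pooled age distribution with a 30–50 trough — and reproduces the qualitative
cohort structure such heterogeneous compendia show: one broad-age-range
"gold" dataset (n = 48, young and old only), one large middle-aged/old
cohort (n = 282), two age-constant young cohorts, one n = 3 cohort, and
eight paired designs whose members share a subject effect and an age.

Generation is linear on the M scale: per-probe baselines drawn from a
three-component beta mixture, age effects at a configurable subset of core
probes, optional sex effects, per-subject random effects, Gaussian probe
noise, and an *affine* distortion of the whole logit-methylation
distribution: a fixed per-platform dilation (HM27 1.15, HM450 1.00, HMEPIC
0.92 — the all-Type-I HM27 runs wider and the Type-II-dominated HMEPIC more
compressed, mirroring the Infinium design-type effect) times a per-dataset
lab factor, plus a per-dataset shift. The affine distortion is the
kind of artifact that separates platforms and labs — compression or dilation
of the beta distribution is precisely what beta-mixture quantile calibration
exists to remove — whereas probe-level batch noise is what the
empirical-Bayes batch adjustment targets; the simulator implements the
former as its "batch" effect so that calibration demonstrably matters in
LOOCV.

Default magnitudes, chosen once from what muscle array studies report:
age slopes on the beta scale are N(0, 0.0015 per year) truncated to
[5e-4, 5e-3], so the strongest probes drift ~0.3% per year (~3% per decade);
probe noise is 0.15 on the M scale, which gives a top age probe an R² with
age of about 0.7 under the pooled age spread (note that no realistic level
of independent probe noise makes the *ensemble* clock inaccurate — a
300-probe elastic net averages it away, so the simulated clock is
considerably more accurate than clocks trained on real muscle cohorts,
whose errors are dominated by biological and protocol heterogeneity the
simulator does not model); batch shift sd 0.2 and lab log-scale sd 0.1;
subject effect sd 0.1 (within-pair correlation ~0.3).
Ages are integers, as real sample sheets carry them. Gene annotations give
genes long-tailed probe counts specifically so the gene-set bias correction
is exercised; positions sit on two synthetic chromosomes with island-like
clustered spacing.

What the simulator does *not* emulate: probe-specific cross-reactivity,
cell-type / fibre-type composition, circadian oscillations, raw two-channel
intensities, and spatial correlation of methylation beyond cluster spacing.
Passing tests on this compendium therefore demonstrate the statistical
machinery under the structural assumptions above — heterogeneous cohorts,
platform cores, distributional batch artifacts — not performance on any real
muscle dataset.

## Problem sizes used in the checks

The heavier end-to-end checks run the compendium at half scale
(~341 samples, 5,000 core probes, 300 age probes): full calibrated LOOCV,
the calibrated-versus-uncalibrated comparison under a strong batch artifact
(shift sd 0.5), 20-replicate null EWAS runs (5,000 probes x 100 samples)
for type-I error, and a 100,000-draw overlap null against its hypergeometric
moments. Oracle equivalences (Fisher vs exhaustive hypergeometric sums, BH
vs brute force, elastic net at vanishing penalty vs OLS, moderated t at
d0 = 0 vs ordinary t) run on small fixtures. The same computations are
reproduced by `scripts/acceptance.R`.

## Known limitations

* The BMIQ-style calibration corrects distribution-level (monotone)
  differences between datasets; probe-specific batch effects pass through it
  and must be handled by the EB batch adjustment, which in turn requires
  known batch labels.
* The consensus intra-block correlation is a single exchangeable value; a
  cohort mixing very different pairing strengths is summarized by their
  pooled average.
* The Wallenius gene-set p uses a two-group mean-weight approximation; sets
  with extreme internal weight heterogeneity are tested approximately.
* DMR calling is a clustering rule on significant probes; it does not model
  spatial autocorrelation and inherits the EWAS significance threshold.
* Predictions for cohorts far outside the training age range inherit the
  elastic net's shrinkage toward the training mean, the familiar
  young-predicted-older / old-predicted-younger compression.
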