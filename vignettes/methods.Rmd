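---
title: "Models and methods behind retromem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind retromem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retromem)
```

# The scientific problem

In a sensory-preconditioning paradigm, participants first learn neutral
face–object pairs; each face is later re-presented and paired with either an
aversive scream or a neutral voice. Memory for the *original* face–object
association is then tested. The core phenomenon is retroactive: aversive
emotional learning strengthens memory for associations formed *before* it.
Mechanistically this is attributed to trial-specific reactivation — the
multivoxel pattern evoked by a pair during initial learning is re-expressed
when its face is cued during emotional learning — together with changes in
hippocampal coupling with the amygdala and stimulus-sensitive cortex, online
and at post-learning rest.

retromem implements the analysis chain for this design: trial-level
pattern-similarity reinstatement measures, cross-validated brain–behaviour
prediction with a permutation null, gPPI and resting-state connectivity
contrasts, a serial two-mediator bootstrap mediation model, and the
behavioural statistics particular to the paradigm. Everything is exercised
on a synthetic generator so the whole chain is testable without imaging
data.

# The synthetic generator

## Design arithmetic

`generate_design()` reproduces the paradigm's timing exactly. An
initial-learning trial is 4 s of pair presentation plus 2 s of vividness
rating; inter-trial intervals are drawn from {2, 4, 6} s. An
emotional-learning trial is 2 s face cue + 2 s face–voice pairing + 2 s
rating with ITIs from {6, 8, 10} s. ITIs are *counterbalanced* — each jitter
value occurs equally often, in seeded shuffled order — rather than sampled
independently. This is a deliberate design choice: the realized mean ITI is
then exactly the nominal mean, so run durations are closed forms,
`n * (event seconds + mean ITI)`: 72 trials give 720 s (12 min) per initial
run and 1008 s (16.8 min) for the emotional run. Whether the original
jitters were counterbalanced or i.i.d. is not stated anywhere we could
check; counterbalancing makes the duration targets deterministic, which is
worth more to a simulator than distributional purism.

Condition sequences are drawn by seeded rejection sampling under the
constraint that no more than two same-condition trials occur in a row. When
a constraint is too tight for rejection to ever succeed (for example strict
alternation), a feasibility-preserving sequential sampler takes over; both
paths are deterministic given the seed, and every output is checked in the
tests against an independent run-length validator.

The generator uses 365 volumes for each initial run and 508 for the
emotional run at TR = 2 s — the printed scan lengths of the design it
emulates, a handful of volumes longer than the task itself — and 240-volume
(8-min) rest runs.

## Patterns

Each pair `p` has a unit-norm face component `f_p` and object component
`o_p`; each condition a shared unit-norm category component `g_c`:

* initial phase: `init(p) = f_p + o_p + gamma * g_c + noise`
* emotional phase: `emo(p) = f_p + rho_c * o_p + gamma * g_c + noise`

`rho_c` in [0, 1] is the reinstatement gain — how much of the initial object
trace is re-expressed when the face is cued — and is the generator's handle
on the phenomenon: defaults `rho_aversive = 0.8`, `rho_neutral = 0.2`
encode stronger trial-specific reinstatement under arousal. Components are
unit-norm so signal-to-noise is controlled purely by `sigma_noise`; with the
default 120 voxels and `sigma_noise = 0.25`, expected pair-specific
correlations sit around 0.15–0.25 (aversive) versus 0.10–0.15 (neutral),
the magnitude regime ROI reinstatement analyses typically report.

Two consequences of this model are worth knowing. First, because `f_p`
appears in both phases, pair-specific similarity has a positive floor even
at `rho_c = 0` — the cue itself is a shared trace. Reinstatement claims must
therefore rest on condition *contrasts*, which is exactly how the analyses
are framed; the null-calibration tests accordingly target the across-pair
and within-phase measures, which are mean-zero without signal. Second, the
category component `g_c` raises across-pair similarity within a condition,
letting the tests distinguish trial-specific from category-level effects.

## Time series, behaviour, subject tables

For the connectivity analyses, the seed's neural signal is the stimulus
boxcar plus *temporally smooth* Gaussian fluctuations (white noise filtered
with a 2-TR Gaussian kernel, unit SD). Smoothness matters: fluctuations
faster than the haemodynamic low-pass are unidentifiable after convolution,
and a generator built on white neural noise would make the gPPI ground
truth unrecoverable by any method. The target's neural signal is
`coupling_baseline * n(t)` plus `coupling_c * n(t)` restricted to
condition-`c` stimulus epochs; both series are convolved with the canonical
HRF and observed with white measurement noise (SD 0.3). Rest runs are
Gaussian pairs with population correlation `rest_r`; confounds are slow
sinusoidal drifts plus noise, labelled like a six-motion + CSF + WM set.

Behaviour follows `P(correct) = plogis(beta0 + beta1 * reinstatement)` per
pair; vividness and confidence ratings threshold latent standard normals
(correlated `latent_cor = 0.4` with standardized reinstatement) at the
equal-width cut points −1, 0, 1 into ratings 1–4 — simple, documented and
invertible. Subject-level tables for the prediction and mediation stages
follow the recursive system `M1 = a1 X + e`, `M2 = a2 X + d21 M1 + e`,
`Y = c' X + b1 M1 + b2 M2 + e`.

# First-level GLM

The canonical HRF is the SPM-style double gamma (response peak 6 s,
undershoot peak 16 s, unit dispersions, 6:1 peak:undershoot ratio, 32 s
support) normalized to unit peak. Boxcars are built at microtime resolution
(16 samples per TR), convolved, and sampled at volume onsets. Stimulus
events are modelled with 2 s from onset in both phases; face cues enter as
nuisance regressors (two in condition mode, one in trial mode, giving the
73 task regressors of the emotional-phase trial GLM). In trial mode, the two
presentations of a pair across the initial runs share a single regressor —
we read "collapsing across two repetitions" as one regressor spanning both
presentations rather than post-hoc beta averaging, with
`collapse_repetitions = FALSE` exposing the alternative. High-pass
filtering is a discrete-cosine drift basis with a 128-s cutoff. Estimation
is OLS with `df = n - rank(X)`; no AR(1) prewhitening is attempted, and
trial GLMs are fitted per run.

# Pattern similarity

Patterns are z-scored across voxels (removing mean-amplitude differences),
compared with Pearson correlation, and Fisher-transformed with correlations
clipped at `|r| = 1 - 1e-7` so identical synthetic patterns stay finite. At
trial level the package averages correlations on the r scale and transforms
the mean (`transform = "after_averaging"`), matching the order in which the
measures are described; since averaging order is genuinely ambiguous at
trial level, `transform = "before_averaging"` is a flag. The pair's own
initial pattern is excluded from every across-pair and within-phase
average, and `across_pair_combined` — the category-level measure — is the
mean over all other pairs, so it always lies between the within- and
between-condition versions.

The searchlight evaluates any trial-level measure over the in-mask voxels
of a 6-mm sphere around each voxel (membership by Euclidean distance
between voxel centers; no partial-volume weighting) and stores the
aversive − neutral contrast. Spheres with fewer than two usable voxels
yield NA and a single summary warning. A sphere that covers exactly an ROI
reproduces the ROI-based measure to numerical precision — the equivalence
the tests assert.

# Behavioural statistics

The memory test presents four faces and four objects per screen and
responses are made in order without replacement, so chance accuracy is
position dependent: `mean(1/(n-k+1))` over positions, 52% for four options.
Ratings 3–4 form the high bin and 1–2 the low bin for both confidence and
vividness; empty bins propagate as missing, never as zero accuracy. The
2×2 repeated-measures ANOVA is computed through within-subject contrasts,
where each effect's F is the squared paired t of its contrast — an identity
the tests verify against `aov()`'s sum-of-squares decomposition — with
partial eta squared `F / (F + df_error)`. With covariates, the contrast is
regressed on mean-centered covariates and the intercept tested, the
convention of mainstream statistics packages for repeated-measures ANCOVA.
Effect sizes for paired comparisons use `d_av`, the mean difference divided
by the average of the two conditions' SDs. The trial-level
vividness–confidence relation uses an lme4 random-intercept model with a
Wald 95% CI (the CI method was not derivable from any stated source; Wald
is the simplest defensible choice). Skin-conductance levels are means over
[onset, onset + 6 s) windows.

# Prediction and Steiger's test

"Balanced" fourfold cross-validation is interpreted as rank-stratification
on the outcome: subjects are ranked, consecutive blocks of four are dealt
one per fold in seeded random order, so fold outcome distributions are
comparable and sizes differ by at most one. Per fold a simple linear
regression is fitted on the training subjects and used to predict the
held-out ones; `r` is the Pearson correlation between pooled predictions
and observed outcomes. The permutation p is the proportion of label
shuffles whose statistic *strictly exceeds* the observed one (folds
re-balanced per shuffle); the minimum attainable p is therefore 0, and an
add-one variant is available. The default is one-sided in r, matching the
"greater than" formulation; a two-sided flag exists.

One caution established by simulation: under the null, r(predicted,
observed) is *negatively* biased (mean ≈ −0.08 at n = 28), a known property
of refit-per-fold prediction correlations. This does not affect inference —
the permutation null is built from the same statistic — but the raw r
should not be read as mean-zero under independence.

Steiger's Z for dependent non-overlapping correlations divides the
Fisher-z difference by a standard error built from the Pearson–Filon
covariance with the two compared correlations replaced by their pooled
mean; the caller supplies (or the data wrapper computes) the full 4×4
correlation matrix, which is checked for positive semidefiniteness. The
test is antisymmetric in its arguments and calibrated to nominal type-I in
multivariate-normal simulation.

# Connectivity

gPPI: the seed's neural activity is estimated by ridge-regularized
inversion of the HRF convolution operator at TR resolution (penalty chosen
by generalized cross-validation on the seed by default, or supplied);
per-cell interaction regressors are the estimated neural series times the
cell boxcar, re-convolved with the HRF, fitted alongside the HRF-convolved
psychological boxcars and the seed physiological series so the contrast
isolates condition-specific coupling. The memory-status variant uses four
cells (remembered-with-high-confidence / forgotten × aversive / neutral),
with low-confidence remembered trials omitted. Because the HRF starts at
zero and is low-pass, deconvolution is inherently regularized: the
deconvolve-then-convolve identity holds (to < 1% RMS at small penalty) for
series in the operator's range, i.e. actual haemodynamic signals.

Rest series are band-passed 0.008–0.10 Hz with a zero-phase
(forward–backward) Butterworth design; confounds are filtered with the same
band *before* regression so the regression cannot reintroduce out-of-band
energy. Seeded connectivity is clipped Fisher z; difference maps (Rest 2 −
Rest 1, Rest 3 − Rest 2) subtract in z space — computing differences on raw
r is the other defensible option, but z space keeps differences
variance-stabilized. The group model regresses each subject's difference
value on aversive- and neutral-condition memory accuracy and tests the
coefficient difference with `df = n - 3`. Group maps are reported
voxelwise-uncorrected; cluster-extent correction is out of scope.

# Mediation

The path model is the full serial topology X → M1 → M2 → Y with all
lower-order paths (b1 included — whether the original freely estimated it
is not fully explicit, so the full model is fitted), estimated by three OLS
equations on standardized variables. The decomposition
`c = c' + a1 b1 + a2 b2 + a1 d21 b2` holds exactly by OLS algebra and is
asserted to 1e−8. Inference uses the case-resampling bias-corrected (BC,
not accelerated) bootstrap: `z0 = qnorm(P(boot < estimate))`, interval
endpoints at the bootstrap quantiles `pnorm(2 z0 ± 1.96)`; degenerate
resamples are redrawn and counted.

Calibration facts established by simulation and encoded in the tests: BC
intervals for the *serial product* are strongly conservative at the
complete null (exclusion rate well under 1% at n = 28 — products of three
near-zero coefficients concentrate at zero), mildly liberal at the
least-favourable boundary null (two strong paths, one zero; ≈ 9%), and the
machinery itself shows the canonical mild BC liberality (≈ 8% for a sample
mean at n = 28, n_boot = 200). Power for a planted serial effect of 0.10 at
n = 200 exceeds 80%.

# Pipeline and reproducibility

`run_pipeline()` executes synth → firstlevel → similarity → behav →
predict → connectivity → mediation on a simulated cohort, with one RNG
stream per stage derived from the master seed, and writes tidy TSVs plus a
manifest of MD5 hashes; identical configurations give byte-identical
artifacts. Configurations round-trip through YAML. The demonstration
configuration is scaled (12 subjects, 24 pairs, 60 voxels, 100
permutations/bootstraps) so the full chain runs in seconds; the test-suite
and acceptance-script simulations use the study-scale design (72 pairs, 36
per condition, full-length runs) with 100–1000 replicates per property,
sizes chosen to keep Monte-Carlo error comfortably inside each asserted
band.

# Known limitations

* No realistic BOLD physiology: no spatial autocorrelation, physiological
  noise spectra, or SCR waveform shapes; passing tests demonstrate the
  statistical machinery, not robustness to real-data artifacts.
* OLS without prewhitening; temporally autocorrelated noise would make the
  GLM t values optimistic.
* The pair-specific measure's positive floor under shared cue traces (see
  above) means absolute reinstatement levels are generator-relative; only
  contrasts are interpretable.
* The permutation p can be exactly 0; use `add_one = TRUE` when a strictly
  positive p is required.
* Searchlights are computed in plain R loops — fine at fixture scale,
  pedestrian for whole-brain grids.
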