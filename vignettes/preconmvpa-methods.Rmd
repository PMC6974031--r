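---
title: "Models and methods behind preconmvpa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind preconmvpa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(preconmvpa)
```

This vignette is the package's own account of its science: the generative
model the synthetic data follow, what each analysis estimates, the
numerical choices, and what a green test does and does not establish. It
states no empirical result that the test suite and the acceptance script
do not themselves compute.

## The experimental design being modeled

A sensory preconditioning study with three scanned phases. During
*preconditioning* (4 analyzed runs), eight sets of cue pairs A→B and C→D
plus four E–E control pairs are shown (3 s per cue, 300 ms gap, jittered
3–11 s fixation; participants press a button when the second symbol
differs). During *conditioning* (5 runs), cues B and D appear alone
(1.5 s) followed by $1 and $0 feedback; each cue repeats twice per run
(10 repetitions total) and participants predict the outcome. At the
*probe test* (1 run) all 32 cues appear four times without feedback.
A post-session recognition test probes memory for the pairs (old vs
recombined), summarized as d′. TR is 2 s throughout. These design
constants are the generator defaults (`sim_config()`), including
`n_subjects = 24`.

## The generative model

### Cue patterns and their convergence

Each cue starts as an i.i.d. Gaussian voxel pattern (unit per-voxel RMS)
in each ROI. Pair convergence is modeled geometrically: with per-run angle
$\theta_r$, the run-$r$ state of cue A in set $i$ is

$$A_i(r) = \cos\theta_r\,p_{A_i} + \sin\theta_r\,u_i,$$

where $u_i$ is a pair-specific *association direction* shared by both
members. Because $\sin^2\theta_r = \tanh(s\,(r-1))$, the expected paired
correlation equals $\tanh(s(r-1))$, i.e. the paired-minus-unpaired
Fisher-z contrast grows linearly at the configured
`similarity_slope` $s$ (z-units/run) while unpaired cues, which share no
direction, stay uncorrelated. This makes slope recovery an exact,
closed-form property rather than a calibration knob. Default
$s = 0.05$ z/run: small against the measurement noise of single-run
t-maps, so group detection at $n = 24$ lands in the range typical for
this kind of contrast rather than being trivially saturated.

### The outcome-value axis

From conditioning onward, one fixed random unit vector $v$ per subject and
ROI acts as a shared value axis: reward-associated cues add
$+a\,v$ and nonreward cues $-a\,v$ (`value_amplitude` $a$, default 0.3, in
units of pattern SD), in the designated `value_roi` only (default
`medial_OFC`). A shared axis — rather than per-cue value coding — is what
makes *cross-cue-set* decoding possible, mirroring the logic of training
on seven cue sets and testing on the eighth. The default amplitude is
chosen to give a clearly detectable planted signal at desk-scale cohort
sizes; no attempt is made to match the absolute decoding accuracies of any
particular dataset, since the SNR of real data is not identifiable from
published statistics.

### Reactivation

The probe-phase pattern of cue A is anchored at the *association-neutral*
state $\mathrm{anchor} = \mathrm{norm}(A_i(1) + A_i(R))$, which by
symmetry correlates equally with the first- and last-run preconditioning
states. `reactivation_gain` $g$ pulls the probe pattern toward the
end-of-preconditioning state:

$$\text{probe}_{A_i} = \mathrm{norm}\big((1-g)\,\mathrm{anchor} + g\,A_i(R)\big).$$

This construction was chosen over a literal blend with the paired cue's
pattern because it makes the first/last reactivation contrast *exactly*
zero at $g = 0$ and strictly positive for any $g > 0$ once an association
exists ($\theta_R > 0$) — the property the recovery and null tests need.
Since $A_i(R)$ contains the shared direction $u_i$ (the associative trace
of B), pulling toward it is the same phenomenon the analysis interprets
as reactivation of the associate. Conditioning-phase B/D patterns use the
same construction with `conditioning_reactivation_gain`, default 0,
because the reference finding there is a null; a positive value turns the
generator into a power-analysis tool for that contrast.

### Connectivity

During the probe run, every voxel of the target ROI receives
$(b_0 + m\,x_{AC}(t))\,s(t)$, where $s(t)$ is the centered mean series of
the seed ROI, $x_{AC}$ the HRF-convolved preconditioned-cue regressor
(normalized to peak 1), $b_0$ = `coupling_base` (0.2) and $m$ =
`coupling_modulation` (0.5). The PPI interaction column is exactly the
generative term, so the fitted contrast recovers $m$'s sign and ordering.

### Noise and nuisance

Voxel noise is Gaussian AR(1) (`ar1` = 0.3, marginal SD `noise_sd` = 1) —
the simplest temporally autocorrelated BOLD surrogate; the generative
model is not specified by the reference description, so nothing more
elaborate is assumed. Each run also gets a slow, respiration-like nuisance
regressor (low-pass filtered noise, z-scored) which the GLMs accept as a
given column. An optional additive day-2 pattern (`day_effect_sd`,
default 0) contaminates all day-2 runs to exercise the scan-day control.

### Behavior

Conditioning predictions follow a saturating curve
$P(\text{predict reward}\mid \text{rep }k) = 0.5 + (A_c - 0.5)\,(1 - e^{-\lambda k})$
with `learning_rate` $\lambda = 0.6$ per repetition and asymptotes 0.97/0.03
(fast, near-deterministic learning of a deterministic contingency, with a
small lapse rate). Probe A/C responding is
$0.5 \pm (A_c - 0.5)\,\sigma(\beta_0 + \beta_1 d')$, a logistic link from
each subject's recognition d′ ($\beta_0 = -1.2$, $\beta_1 = 1.3$,
d′ ~ N(1.5, 0.8²)) — this is what produces the positive d′–inference
correlation across subjects. Recognition counts are binomial with
$P(\text{hit}) = \Phi(d'/2)$, $P(\text{FA}) = \Phi(-d'/2)$ (unbiased
observer). RTs decrease linearly across preconditioning runs
(intercept 0.95 s, slope −0.05 s/run, trial SD 0.15 s), carry an
inference cost of +0.15 s on probe A/C trials, and, in random-effects
mode, decrease with a subject's coupling modulation (0.2 s per unit),
linking connectivity to behavior. Non-responses occur at rate 0.02 and
are excluded from all percentage denominators, never coded as 0.

Where neither the design nor the reference reporting fixes a value
(all effect sizes, RT parameters, d′ distribution, lapse rate), the
defaults above are one-time choices justified here; tests never move them.

### Fixed versus random effects

Whether effect sizes vary across subjects is not identifiable from the
reference statistics, so both modes exist: `random_effects = FALSE`
(default) gives every subject the configured effect;
`random_effects = TRUE` draws per-subject effects with coefficient of
variation `effect_cv` (0.3). Ground truth always records what each
subject actually received.

## Analysis choices on genuinely open points

- **Per-set versus pooled GLMs.** The similarity trajectory uses per-set
  patterns (32 cue regressors; Fisher-z per set-pair, averaged over the 8
  sets), matching the build contract. The pooled 4-regressor scheme is
  implemented (`scheme = "precond"`) and used where templates are pooled
  (reactivation). Control pairs are modeled as separate regressors in the
  per-set scheme (E1–E4) and one pooled column otherwise; E patterns never
  enter any statistic.
- **Fisher-z before averaging**, for additivity of the paired/unpaired
  contrast; a regression test asserts the order.
- **Exemplar granularity.** All-set decoding trains on one B and one D
  t-map per conditioning run (last three runs, 6 exemplars) and tests on
  the 16 per-cue probe patterns; cross-set training uses per-set
  conditioning patterns (42 exemplars over 7 sets). The reference
  granularity is under-specified; this choice is configurable in code.
- **Feature ranking is per subject** (native voxel spaces are not
  comparable across subjects); the leave-one-subject-out step selects only
  the *count*, never the voxels, of the held-out subject.
- **Permutations shuffle test labels only**, never training labels, and
  empirical chance is the mean permuted accuracy per subject
  (default 10,000 permutations).
- **Tails.** Directed hypotheses (similarity increase, above-chance
  decoding, positive reactivation, positive PPI contrast, faster RT with
  stronger coupling) are tested one-tailed; undirected comparisons
  two-tailed.
- **PPI without deconvolution.** The interaction is the seed BOLD series
  times the convolved psychological regressor (BOLD-level gPPI). The
  neural-level deconvolution step of toolbox implementations is a
  deliberate simplification hook; with the BOLD-level generative coupling
  used here the two coincide. The group analysis uses the target ROI mean
  series; voxel-level maps plus max-statistic permutation are available in
  the searchlight machinery rather than random-field-theory correction,
  which is out of scope.
- **Scan-day control.** Day halves are runs {1,2} versus {3,4} of the
  analyzed preconditioning runs. The control subtracts the first/last
  contrast computed on unrelated pairs (A-template vs C patterns and vice
  versa). The subtraction removes an additive day component exactly only
  in the weak-correlation regime (atanh is nonlinear); the test asserts
  bulk removal, not exact invariance.
- **Exclusion rule.** "Not significantly above chance in the last
  conditioning run" is operationalized as a one-tailed binomial test
  against 0.5 at α = 0.05 on responded trials.

## Numerical choices

- HRF: difference of gammas (shape 6 and 16, rate 1), undershoot ratio 6,
  32 s support, peak-normalized; convolution on a 0.1 s microtime grid,
  sampled at volume midpoints $(k+0.5)\,\mathrm{TR}$ (onsets are not
  TR-aligned); values below 1e−10 are zeroed (FFT roundoff).
- OLS via QR; rank deficiency is an error naming the collinear columns;
  zero-variance voxels yield t = 0 rather than NaN in rankings and an
  error in correlations.
- Fisher z clamps |r| at 1 − 1e−12 and flags the clamp, so degenerate
  comparisons stay finite.
- The SVM dual is solved by SMO with second-order working-set selection
  to a KKT gap of 1e−10 — far tighter than production defaults, so small
  problems match an exact QP oracle; a decision value of exactly 0
  deterministically predicts the reward class. No feature standardization
  is applied (t-maps are already voxel-scale-normalized).
- Greenhouse–Geisser ε = tr(Σ)²/(q·tr(Σ²)) from the covariance of
  orthonormalized contrast scores, applied to both df; degenerate
  zero-variance effects are guarded against floating-point roundoff with
  a scale-relative tolerance (F = 0, p = 1).
- d′ always applies the log-linear correction (0.5/cell, 1/denominator),
  so perfect performance stays finite.
- All randomness derives from one master seed through a string-keyed
  32-bit hash; identical configs give byte-identical datasets, and
  subjects can be generated independently (streaming) with unchanged
  results.

## What the generator does not emulate

No anatomical geometry (ROIs are compact boxes with synthetic affines),
no spatial correlation between voxels or smoothness, no physiological
(cardiac/respiratory) noise structure beyond the slow nuisance regressor,
no motion, no susceptibility artifacts, no inter-regional signal leakage.
Consequently a green searchlight test establishes the correctness of the
sphere geometry and map mechanics, not realistic spatial inference; and
recovered accuracies/effect magnitudes validate the estimators, not the
SNR of any real dataset.

## Known limitations

- The reference study's raw data are not deposited; its printed
  statistics can only be recomputed from the S1 Data spreadsheet, which
  cannot be shipped with this package. The recomputation code paths exist
  and run against prepared CSVs when provided (`inst/extdata/s1_data/`);
  the corresponding acceptance test fails honestly in their absence.
- Desk-scale tests use reduced cohorts, voxel counts and permutation
  counts; the scaling is stated in each test and affects power, not the
  planted effect sizes.
- The SMO solver is pure R and sized for the tiny exemplar counts of this
  design (≤ ~50 training patterns); it is not a general-purpose SVM.
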