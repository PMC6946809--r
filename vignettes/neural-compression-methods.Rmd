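---
title: "Goal-directed neural compression: models, measures and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Goal-directed neural compression: models, measures and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocompress)
```

## The scientific problem

When people learn a new concept, they learn not only the category
assignments but also *which stimulus features matter*. A brain region that
builds goal-directed representations should therefore compress away
irrelevant feature dimensions: a rule that depends on one of three binary
features needs a lower-dimensional neural code than a rule that depends on
all three. `neurocompress` implements a complete analysis chain for testing
this idea with trial-wise fMRI activation patterns and a formal model of
attention during category learning, together with a synthetic-data generator
so that every stage can be exercised and validated without scanner data.

The experimental design it targets: eight stimuli formed by three binary
features, classified under three rules of increasing complexity —
unidimensional ("low"), two-feature XOR ("medium") and three-feature parity
("high") — each learned over four functional runs of 32 trials (every
stimulus four times per run, twice per 16-trial sub-block). The same eight
stimuli serve all three problems, so only the *goal* changes.

## Neural compression

For each learning block (one functional run, 32 trials) and each
searchlight sphere, the trial-by-voxel pattern matrix is mean-centered per
voxel and decomposed by SVD. With `k` the smallest number of principal
components whose cumulative explained-variance ratio reaches 90%,

$$\mathrm{compression} = 1 - k/n, \qquad n = 32 .$$

Larger values mean fewer dimensions suffice. `pca_k()` implements the
criterion; `searchlight_compression()` maps it over a volume with a
voxel-radius sphere (radius 4 by default, 257 lattice offsets; spheres are
truncated to the analysis mask and skipped below `min_sphere_voxels = 10`).
Two numerical conventions matter:

* Centering is per voxel across trials, with no variance scaling, matching
  standard SVD-based PCA of observations-by-features data. A consequence is
  that at most `n - 1` components carry variance, so `k = n` (compression
  exactly 0) is unattainable; the least compressible data reach
  `k = n - 1`.
* The cumulative-ratio comparison uses a `1e-12` tolerance so that
  noise-free exact-rank data give deterministic `k`.

The searchlight hot loop is compiled (RcppArmadillo), working from the
trial-space Gram matrix (32 x 32 eigendecomposition) rather than the full
SVD; the test suite verifies it voxel-for-voxel against a naive R loop over
`pca_k()`.

## Category discrimination in the compression solution

Compression alone does not show that the retained dimensions carry category
information. `pc_category_discrimination()` computes, for each retained PC,
the absolute difference between the mean trial loadings (projections of the
centered patterns onto the unit PC axis) of category A and category B
trials, weights it by that PC's explained-variance ratio, and sums over the
`k` retained PCs. Loadings are unnormalized projections, so the score
scales linearly with the data while the variance-ratio weights do not — a
convention the tests assert explicitly. `permutation_null()` calibrates the
score against label permutations that preserve class counts.

## Single-trial estimation

The pattern matrices come from an event-specific ("least-squares-separate")
GLM: per trial, one regressor holds that trial's 3.5 s boxcar convolved
with a canonical double-gamma HRF (peak near 5 s), one regressor holds all
other stimulus events combined, plus correct/incorrect feedback boxcars
(2 s), response impulses split by button, six motion parameters and an
intercept. `lss_estimate()` collects the target beta per trial.

Numerical notes:

* Convolution is done on a 0.1 s grid and read out at the volume times.
* All-zero motion columns (simulated data without head motion) are dropped;
  they would otherwise make every design rank-deficient.
* An optional 128 s high-pass + linear-detrend step projects a
  cosine/trend confound basis out of both data and regressors, which leaves
  estimates invariant to drift inside that basis. Genuinely rank-deficient
  designs fall back to a pseudo-inverse with a warning.
* LS-S is exactly unbiased only when trial bundles do not overlap and all
  non-target stimulus events are identical sampled translates (onsets
  commensurate with the TR). Feedback and response regressors shared across
  trials couple trials with heterogeneous amplitudes, producing the usual
  few-percent LS-S approximation; the tests quantify both regimes.

## The SUSTAIN learner

Behavior is modeled with the supervised SUSTAIN architecture: stimuli are
encoded one-hot per attribute; memory clusters hold attribute distributions
and per-category association weights; attention tunings $\lambda_i \ge 0$
act as receptive fields. Cluster activation uses the halved city-block
distance $\mu_{ij}$:

$$\mathrm{act}_j = \frac{\sum_i \lambda_i^{\gamma} e^{-\lambda_i \mu_{ij}}}
{\sum_i \lambda_i^{\gamma}},$$

the winning cluster's output is inhibited by
$\mathrm{act}^{\beta}/\sum_m \mathrm{act}_m^{\beta}$, category evidence is
the winner's weights times its output, and choices follow a softmax with
consistency $d$ (chance with no clusters or $d = 0$). Learning recruits a
new cluster at the stimulus when the winner predicts the wrong category or
its activation falls below the threshold $\tau_h$; otherwise the winner
moves toward the stimulus, its weights follow a humble-teacher ($\pm 1$)
delta rule, and each $\lambda_i$ takes the receptive-field gradient step
$\eta\, e^{-\lambda_i \mu_i}(1 - \lambda_i \mu_i)$, clamped at zero.

Design choices that were genuinely open:

* **Winner ties break to the most recently recruited cluster.** With binary
  one-hot stimuli and state carryover across problems, a stale cluster from
  the previous problem and a freshly recruited cluster can sit at exactly
  the same corner with activation exactly 1. Breaking ties toward the older
  cluster deadlocks learning at chance (the stale associations win forever
  and recruitment repeats); breaking toward the newest cluster lets
  relearning proceed and is equally deterministic.
* **Recruitment** uses misprediction OR sub-threshold activation; $\tau_h$
  is fitted like the other parameters.
* **Zero-cluster choice** is uniform, matching chance responding before any
  experience; a per-trial probability floor of `1e-6` keeps likelihoods
  finite.
* **Initial tunings** are 1 on all attributes; the scale is absorbed by
  $\gamma$.
* Attention tunings are recorded *after* each trial's update; the
  extraction point is not dictated by the fitting protocol and either
  convention shifts the trajectory by one trial.

A consequence of the cluster architecture worth knowing: runs that happen
to solve even the unidimensional problem by memorizing one cluster per
stimulus receive no attention gradient (every winner matches the stimulus
exactly, $\mu_i = 0$ on all attributes), so attention stays near-uniform.
At the default parameters this happens in roughly one run in six, which
caps how often trained attention concentrates past 1/2 on the relevant
attribute (~83% of runs; it exceeds the uniform share far more often).

Relatedly, the receptive-field gradient carries the factor
$e^{-\lambda_i \mu_i}$, so once every $\lambda_i$ has grown large — as
happens while memorizing the parity problem, where winners sit exactly on
the stimuli and all tunings grow in lockstep — subsequent differentiation
is glacial. A generative learner that carries state out of the parity
problem therefore shows near-zero attention compression in the later
problems, whereas a fresh-state learner on the unidimensional problem shows
the expected rise (roughly 0.03 to 0.30 across the four blocks at the
default parameters). Per-participant fitted parameters, not the group
means, are what give the attention index its between-subject dynamic range.

Fitting (`fit_sustain()`) maximizes the likelihood of the participant's
trial-by-trial responses — replayed in experienced order with model state
carried from problem to problem — by differential evolution
(`de_optimize()`, DE/rand/1/bin, population 15 x 5, up to 300 generations
with early stopping, box bounds $\gamma,\beta \in [0,20]$,
$\eta \in [0,1]$, $d \in [0,30]$, $\tau_h \in [0,1]$). The trial loop is
compiled; the pure-R reference implementation (`sustain_run_reference()`)
is part of the public surface and the tests require exact trace equality
between the two.

## Attention compression

Per trial, the tunings are normalized to a probability distribution
(`normalize_attention()`), their Shannon entropy (bits) is computed with
the $0 \log 0 = 0$ convention, and

$$\mathrm{attention\ compression} = 1 - \mathrm{entropy}/\log_2 3,$$

which is 0 for uniform attention and 1 for one-hot attention. The
denominator is the entropy maximum for three dimensions, $\log_2 3$; a
divisor of $\log_2(1/3)$ would be negative and could not produce the
documented 0-1 range, so the positive form is used. Per-trial values are
averaged within learning block and problem
(`blockwise_attention_compression()`) — averaging the index, not the
weights, because the tunings are extracted trial by trial.

## Group statistics

All group models are frequentist linear mixed-effects regressions (lme4
with Satterthwaite inference via lmerTest) with the structure: fixed
effects of learning block (1-4), problem complexity (coded numerically
1/2/3 so the interaction is a single coefficient), their interaction, and
covariates such as accuracy; participants enter as random intercepts.
Bayesian MCMC estimation is deliberately out of scope; the scientific
content here is the fixed/random structure and the coefficient signs.
`voxelwise_interaction_map()` fits the model per voxel and stores the
interaction t map; singular or failed fits are flagged and excluded.
`cluster_extract()` thresholds |t| two-sided and labels connected
components under second-nearest-neighbor (faces+edges) connectivity; the
extent threshold is a user parameter (the original cluster-extent
simulation machinery is replaced by this explicit parameter or a
permutation calibration of the user's choosing). Behavioral learning is
summarized by 16-trial accuracy curves and a mixed-effects logistic
regression of accuracy on stimulus repetition, complexity and learning
order, with likelihood-ratio tests per term. The link between brain and
behavior is `compression_attention_regression()`: attention compression
regressed on neural compression, block, complexity, order and accuracy
with participant intercepts, reporting the neural coefficient with a Wald
interval and partial residuals for plotting.

## The synthetic-data generator

`make_problem_bank()` reproduces the three class maps exactly;
`make_trial_schedule()` draws balanced pseudo-random orders (each stimulus
twice per 16-trial sub-block) and jittered timing. One timing convention
deserves a note: a 3.5 s stimulus, 0.5-4.5 s fixation, 2 s feedback and a
2-6 s inter-trial fixation (uniform on a 0.5 s grid) are the only jitter
windows that fit 32 trials into the 388 s run; a 4-8 s inter-trial window
would average 448 s and is therefore not usable with this run length.

`simulate_beta_series()` generates trial-wise patterns per (problem, run)
as a low-rank structured signal plus i.i.d. Gaussian noise. The score
directions are orthonormal and zero-mean with equal variance; the class
contrast (A vs B, i.e. the problem's relevant-attribute combination) is
centered, orthogonalized against the score directions and added to
component 1, so that

* with `noise_sd = 0` the numerical rank is exactly the planted
  `intrinsic_rank`, and the 90% criterion returns `k = rank` for ranks up
  to 8;
* category separation is controlled independently of rank.

Default generative conditions (chosen once for the whole package): planted
rank per problem and block is 8,6,4,2 (low), 8,7,6,5 (medium) and 8,8,8,8
(high) — dimensionality falls with learning fastest for the simplest goal,
giving a negative block-by-complexity interaction on compression; category
separation rises over blocks and falls with complexity (low 0.8-2.6,
medium 0.6-1.8, high 0.4-1.0 in units of noise SD). The per-voxel signal
amplitude is 3.5x the noise SD so that the 90% criterion tracks the
planted rank through the noise; this is considerably cleaner than real
single-trial fMRI estimates, which is the point — passing tests show the
pipeline recovers planted structure, not that real vmPFC data would behave
this way. Realistic fMRI noise (temporal autocorrelation, physiology,
motion) is intentionally absent.

`simulate_bold()` provides the optional forward model to the full-BOLD
path (boxcar-convolved patterns plus feedback/response contributions plus
noise) for validating the single-trial GLM; `write_dataset()` /
`read_dataset()` round-trip everything through NIfTI volumes and
BIDS-style events TSVs.

## Problem sizes used by the test suite

The packaged checks run at sizes chosen for a laptop-class machine: oracle
equivalence on 10^3 volumes; parameter recovery with 20 replicates of 384
trials; the group-level direction checks on 20 replicates of 23 simulated
participants in a 12^3 volume (ellipsoidal mask, ~550 voxels) with the
searchlight summarized by its in-mask mean and the discrimination score
computed on the whole-mask patterns. The full pipeline (`run_pipeline()`)
defaults to a 20^3 volume and 23 participants and scales linearly in
voxels and participants.

## Known limitations

* The generator plants the compression and discrimination structure
  directly; it validates the measurement chain, not the neuroscientific
  claim.
* SUSTAIN's equations follow the standard supervised formulation; variants
  differ in the recruitment rule and teacher signal, and fitted parameter
  values are comparable only within a fixed variant.
* The five SUSTAIN parameters are only weakly jointly identified from a
  single participant's 384 trials when responding is near-deterministic:
  the learning rate is sharply identified *conditional on* the other
  parameters, but the joint likelihood has compensation ridges and
  competing basins (e.g. a high-learning-rate, high-recruitment-threshold
  "memorize on first sight" regime that mimics a fast incremental
  learner), so maximum-likelihood point estimates of the learning rate
  scatter well beyond +/-50% in a substantial fraction of simulated
  recovery replicates. Group-level inferences should rely on quantities
  that are stable across these basins (choice probabilities, attention
  trajectories) rather than on raw per-participant parameter values.
* LS-S estimates are exactly unbiased only under the separation conditions
  described above — as with any single-trial GLM method.
* Cluster-extent inference uses a user-specified extent (or sign-flipping
  permutation calibration); no parametric smoothness model is provided.
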