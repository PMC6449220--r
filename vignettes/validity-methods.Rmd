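---
title: "Validating inferences from response-time models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating inferences from response-time models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Evidence-accumulation models translate choices and response times (RT) from
two-alternative forced-choice tasks into four psychologically meaningful
components: *ease of processing* (drift rate), *response caution* (boundary
separation), *response bias* (starting point), and *non-decision time*. The
package implements a complete, synthetic re-creation of a blinded validation
design for such inferences: a factorial experiment with known manipulations
of ease, caution and bias is simulated from a generative model; fourteen
two-condition "pseudo-experiments" are assembled from its cells; inference
procedures then try to recover which components were manipulated, and their
submissions are scored against the known truth under several scoring keys.

Because the data are synthetic, every inference can be checked against a
known ground truth — the package is a laboratory for asking *when do RT-model
inferences recover what was actually manipulated?*

# Generative models

## Drift-diffusion model

Evidence accumulates with drift $v$ and diffusion coefficient $s$ between
absorbing boundaries $0$ and $a$, starting at $z = z_r \cdot a$; the observed
RT adds a non-decision time $T_{er}$. The defective first-passage densities
at the two boundaries are computed from the classical series representation,
switching between its small-time and large-time forms with truncation chosen
for an absolute error of at most $10^{-7}$ on the standardized density
(`wiener_fpt_density()`). The full model adds trial-to-trial variability:
drift normal with SD `sv`, start uniform over range `szr`, non-decision time
uniform over range `st`; with all three at zero the simple model is recovered
exactly, and `simulate_diffusion()` covers both cases.

**Scale convention.** The diffusion coefficient is not identifiable; we fix
$s = 1$ throughout. The $s = 0.1$ convention found in parts of the literature
is an equivalent reparameterization, and `diffusion_rescale()` converts
parameter sets between conventions exactly.

**Simulation scheme.** Trials are integrated by Euler–Maruyama with a
Brownian-bridge correction for within-step boundary crossings: after each
step the probability that the bridge between consecutive states crossed a
boundary is evaluated and a crossing is drawn accordingly. This removes the
dominant $O(\sqrt{dt})$ boundary-miss bias of the plain scheme, and lets a
step of `dt = 5e-4` s (the default, configurable) reach a
Kolmogorov–Smirnov distance of about 0.003 from the exact density at
$n = 10^5$ trials — comfortably below the 0.01 bar used in the test suite,
and more accurate than plain Euler at a five-times-smaller step. Trials
still unabsorbed at the 3 s response deadline are recorded as timed out and
excluded by the fitting routines.

## Linear ballistic accumulator (LBA)

Two independent accumulators race to threshold $b$ from uniform start points
on $[0, A]$ with drifts drawn once per trial from
$\mathcal N(v_c, s_d)$ and $\mathcal N(v_e, s_d)$; accumulation is
noise-free within a trial. The defective winner densities use the standard
closed form in the normal pdf/cdf (`lba_defective_density()`), and the mass
of trials on which both sampled drifts are negative — the race never
finishes — is accounted for explicitly
(`lba_nonterminating_prob()`). In simulation such trials are resampled by
default (and counted), or optionally censored at the deadline. Response bias
is modeled as an additive threshold offset `start_bias`, which keeps the two
response sides exchangeable when zero. For fitting, $s_d = 1$ is the scaling
constraint.

# The synthetic experiment

The generator emulates a two-hour factorial session: 20 participants, 18
blocks of 156 trials (`block_schedule()`), speed/accuracy emphasis and a
stimulus base-rate bias (2/3 vs 1/3, favored side left or right) alternating
across blocks, and a 50/50 easy/hard mix within every block. Blocks 2–17
realize each emphasis-by-bias cell four times; blocks 1 and 18 add two extra
speed/no-bias blocks so the null pseudo-experiment can be split from one
cell. Practice blocks are not simulated — they never enter any analysis.

Manipulations act selectively by construction (`map_cell_to_params()`), on
the $s = 1$ scale:

| manipulation | parameter | levels |
|---|---|---|
| difficulty | drift $v$ | hard 1.0, easy 2.0 |
| emphasis | boundary $a$ | speed 1.0, accuracy 2.0 |
| base rate | start $z_r$ | $\pm 0.05$ toward the favored side |
| (never manipulated) | $T_{er}$ | 0.30 s |

These defaults place block-level behavior in the empirically typical range
for this design (speed blocks ≈ 0.81 accuracy, median RT ≈ 0.47 s; accuracy
blocks more accurate and substantially slower), and they give each
manipulation a clearly detectable but not overwhelming behavioral signature.
Participant heterogeneity is log-normal for $v$, $a$, $T_{er}$ (CV 0.15,
0.15, 0.10) and logit-normal for $z_r$ (SD 0.10 on the logit scale) —
moderate individual differences of the size routinely seen in simple
perceptual tasks. All spreads are configurable, and zero spread reproduces
the base parameters exactly.

**What the generator does *not* emulate:** practice and fatigue drift across
blocks (behavior is stationary by construction), sequential dependencies,
contaminant/guessing mixtures beyond the deadline censoring, and
condition-specific non-decision time. Passing tests therefore demonstrate
internal validity of the inference chain under a well-specified generative
model, not robustness to the many misspecifications real data can carry.

## Relabeling and construction of the 14 data sets

Before construction, left/right labels are recoded so the favored option
always reads "R" in biased blocks; in no-bias blocks the labels of both
stimulus and response are flipped for the even half of the trials, averaging
out any intrinsic side preference (`relabel_trials()`). Accuracy and RT are
invariant under both operations.

The fourteen truth patterns are the complete set of assignments of
$\{A, 0, B\}$ to (ease, caution, rightward bias), reduced by the global
A↔B label swap: $(3^3 + 1)/2 = 14$ equivalence classes
(`enumerate_patterns()`). Where several cell pairs could realize a pattern,
the pair with no bias and the most expected errors is used — hard over easy,
speed over accuracy — because most RT models need error responses to
constrain their parameters. Each condition draws 312 trials per participant
(pooled freely across the four qualifying blocks of 78 same-difficulty
trials each; the schedule makes more available for the null cell), the null
data set splits its 6-block pool into disjoint halves of 234, participant
ids are shuffled per data set with the pairing preserved, and the A/B labels
of a random half of the data sets are flipped with the stored truth swapped
alongside.

# Estimation

Every estimator first applies one documented outlier rule: drop timed-out
trials and RTs below 0.18 s.

- **EZ** (`ez_point_estimates()`): exact closed-form inversion of
  (proportion correct, mean and variance of correct RTs) for the unbiased
  simple diffusion model; the forward equations and the inversion round-trip
  to $10^{-8}$ and the forward map is itself verified against quadrature
  over the first-passage density. Edge cases are nudged by $1/(2n)$:
  perfect or zero accuracy toward the interior, and exact 0.5 toward the
  side suggested by the relative speed of correct vs. error responses.
- **EZ2** (`ez2_point_estimates()`): adds the starting point by inverting
  per-stimulus-side moments (proportion correct, mean and variance of all
  RTs on each side). Predicted moments come from Gauss–Legendre quadrature
  over the density (square-root time substitution, 160 nodes); the solver
  minimizes squared residuals (variances on the SD scale) by Nelder–Mead
  from EZ-based starts with a BFGS polish. Side-symmetric input recovers
  $z_r = 0.5$ to $10^{-6}$.
- **Maximum likelihood** (`fit_ml_simple_diffusion()`, `fit_ml_lba()`):
  sums of log defective densities, optimized on transformed scales (log for
  positive parameters, logit for $z_r$, non-decision time mapped into
  (0, min RT)) with five jittered starts from moment-based initial values.
  Full-diffusion ML (with trial-to-trial variabilities free) is deliberately
  not provided; variability parameters can be frozen at zero, which is the
  simple model.

VRT in EZ is computed over correct responses only (the standard
convention); whether contributed analyses in comparable studies used
all responses instead is left open, and the choice is isolated in
`compute_ez_moments()`.

# Inference and scoring

Two procedure families mirror the estimate-based and heuristic approaches:

- **Estimate-based** (`infer_pattern_estimate_based()`): per component, a
  paired two-sided t-test across participants on the mapped parameter
  ($v \to$ ease, $a \to$ caution, $z_r \to$ bias, $T_{er} \to$ ndt; for the
  LBA, `lba_component_map()`), $\alpha = 0.05$, no multiple-testing
  correction — the modal practice. The label is the sign of the mean
  difference when significant, else 0.
- **Heuristic** (`infer_pattern_heuristic()`): the published 5%-accuracy
  rule for ease; caution when the slower condition (0.9 RT quantile, 50 ms
  cutoff) is also the more accurate; bias from the signal-detection
  criterion $C = (z(H) + z(FA))/2$ (0.1 cutoff; the lower-criterion
  condition is the more rightward-biased); non-decision time from a common
  shift of the 0.1 RT quantile in both response classes. The non-printed
  cutoffs are package defaults, clearly labeled and configurable.

The criterion uses the normal *quantile* transform of the hit and
false-alarm rates; a CDF in that formula would not reproduce the published
values, so the quantile reading is implemented.

Scoring (`summarize_scores()`) classifies each of the 56 slots (14 data sets
× 4 components) as correct, miss, false alarm, or flip, and supports four
keys: the planned key (strict selective influence), two alternative keys
coupling caution manipulations to ease (with the three incoherent data sets
excluded) or to non-decision time, and the planned key without the ndt
column (42 slots). Proportions are kept at full precision and rounded half
up to two decimals only for display. `agreement_matrix()` gives the
pairwise proportion of shared inferences.

# Numerical and design choices

- Quadrature: Gauss–Legendre after $t = u^2$ substitution, with the
  integration horizon set from the density's slowest decay rate; 192 nodes
  for user-facing moments, 160 inside the EZ2 solver.
- The canonical pattern representative (which of the two swap-equivalent
  labelings a class is reported under) prefers more "B" entries, breaking
  ties toward "B" on the later component — reproducing the conventional
  table of the fourteen designs, against which the enumeration is verified.
- Deterministic hierarchical seeding: every participant-by-block cell and
  every data-set construction derives its own substream seed, so results
  are reproducible regardless of evaluation order; all substream seeds stay
  within the 32-bit integer range.
- Degenerate inputs: EZ refuses non-positive RT variance; EZ2 requires both
  stimulus sides; the estimate-based procedure requires at least three
  paired participants; construction errors name the short cell.

# Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run the full chain at the study's
conditions — 20 participants, 312 trials per condition, 14 (or the first 4)
data sets — with replicate counts chosen to keep the whole suite at a few
minutes on one core: 50 seeded replicates for the detection/calibration
checks in the test suite, 30 in the acceptance script, 10–30 replicates for
the estimator-consistency and recovery unit tests, and $10^5$-trial
simulations for the density cross-checks. Detection rates for the singly
manipulated components run well above the 80% mark at these sizes, and the
null data set's false-alarm rate stays within binomial bounds of the nominal
$\alpha$.

# Known limitations

- EZ2 estimation here inverts quadrature-predicted moments rather than the
  original closed-form moment equations; results agree by construction with
  the package's density, which the test suite cross-validates against
  simulation.
- The LBA start-point range $A$ is weakly identified at a few hundred
  trials per condition; its recovery is markedly noisier than the other
  LBA parameters, a well-known property of the model rather than a defect
  of the optimizer.
- Model-selection-based inference (information criteria, model-indicator
  parameters), hierarchical-Bayesian estimation, and full-diffusion ML
  fitting are out of scope.
- The agreement and accuracy figures produced by `run_validation_study()`
  describe synthetic data from this generator; they are not estimates of
  the corresponding published values for real teams analyzing real data.
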