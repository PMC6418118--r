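---
title: "Methods: adaptive slope estimation and voxelwise slope-diffusivity inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: adaptive slope estimation and voxelwise slope-diffusivity inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psivox)
```

psivox implements a two-stage analysis of "meta-volition" — the capacity to
let an external cue drive a choice automatically rather than deliberately.
Stage one estimates, by a Bayesian adaptive procedure, the slope of the
psychometric function relating the onset asynchrony of two saccade targets to
the probability of looking at the first one; a steep slope means choice is
governed by the asynchrony alone, a flat slope means delta-independent
("volitional") influences intrude. Stage two asks, over a cohort of subjects,
where in skeleton-masked white-matter diffusivity maps that slope is
correlated with the tissue measure, using a permutation GLM with
threshold-free cluster enhancement. No subject data ship with the package;
everything is exercised against synthetic observers and cohorts whose
generative structure is under test-time control.

## The psychometric model

The probability of foveating the first-onset target at asynchrony
$\delta \ge 0$ ms is

$$P(\delta) = \gamma + (1 - \gamma - \lambda)\,
  \sigma\!\left(10^{\beta}(\delta - \alpha)\right),$$

with $\sigma$ the standard logistic. The guess rate $\gamma$ is fixed at 0.5:
with two targets and no information, choice is a coin flip. The threshold
$\alpha \in [0, 300]$ ms locates the midpoint; the lapse
$\lambda \in [0, 0.1]$ shrinks the upper asymptote to $1 - \lambda$
(Wichmann–Hill convention, lapse applied to the upper tail only, which is the
standard form for a two-alternative task with a fixed guess rate). The slope
$\beta \in [-2, 2]$ is the base-10 logarithm of the logistic rate in 1/ms, so
the admissible range spans rates from 0.01 to 100 per ms. We read the slope
range as a log-scale spread because a linear rate range containing negative
values would make the function *decreasing* in $\delta$, contradicting the
task's construction; the original toolbox's exact parameterisation is not
recoverable, so printed per-subject slope values are not treated as ground
truth anywhere in the package.

## The adaptive engine

Estimation is grid-Bayesian (the psi-method family): the joint posterior over
$(\alpha, \beta, \lambda)$ lives on a regular grid spanning exactly the
admissible ranges, by default $31 \times 41 \times 11$ nodes. That default
balances resolution against per-trial cost: it resolves $\alpha$ at the task's
10 ms granularity and keeps each selection step below ~5 ms, and estimates are
grid-mean rather than grid-mode precisely so they are not quantised to node
spacing. Starting from a flat prior, each double-target outcome multiplies the
posterior by the per-node Bernoulli likelihood and renormalises; updates are
therefore order-invariant and sequential updating equals a single batch update
with the product likelihood (both properties are asserted in the tests).

The next asynchrony is chosen from 0–300 ms in 10 ms steps (31 candidates) to
minimise the expected Shannon entropy of the joint posterior,
$$\mathbb{E}[H \mid \delta] = \sum_{o \in \{0,1\}} P(o \mid \delta)\,
  H\!\big(\mathrm{post} \mid \delta, o\big),$$
with $P(o \mid \delta)$ the posterior predictive. Since the current entropy is
fixed at selection time, minimising expected posterior entropy is identical to
maximising expected information gain. The lapse axis stays inside the joint
posterior during selection (marginalising it out is a known efficiency
variant, not a correctness issue, and the simpler reading is kept). Ties break
to the smallest candidate so selection is deterministic. The implementation
reduces the two-outcome enumeration algebraically to four matrix–vector
products against a precomputed likelihood table; the tests keep the explicit
enumeration as an independent oracle and require agreement to 1e-10.

A session comprises 50 training trials followed by 400 main trials, the main
trials split exactly 200/200 between single- and double-target in seeded
random order (exact allocation rather than per-trial coin flips, so the
estimation-trial count is a design constant). The first main double-target
trial uses 300 ms; training trials are excluded from estimation — we reset to
the flat prior at the start of the main run, the most conservative reading of
"training not used in the analysis" — and training double-target asynchronies
are drawn uniformly from the candidate set since nothing about their schedule
is specified. Single-target trials never update the posterior: no model
parameter is informed by them; their role is to discourage anticipation.

## Simulated observers and what they do and do not emulate

A pure observer answers a double-target trial "first target" with probability
$P(\delta)$ at its true parameters. Volitional interference is modelled as a
delta-independent mixture: with probability `pi_vol` the response ignores
$\delta$ entirely and goes left with probability `bias`. This is the minimal
generative process that reproduces the mechanism of interest — mixing toward
a flat, stimulus-independent process flattens the *estimated* function — and
the interference sweep (weights 0, 0.25, 0.5, 50 seeded sessions each, median
estimated slope) operationalises it. The sweep's underlying observer is fixed
at $\alpha = 150$ ms, $\beta = -1$, $\lambda = 0.02$: mid-range threshold, a
rate of 0.1/ms (a comfortably measurable slope), and a small lapse typical of
practised observers.

Simulated observers are stationary and memoryless: no fatigue, learning,
sequential dependencies, anticipatory errors or reaction-time structure.
Passing tests therefore certify the estimator and the study's statistical
logic, not robustness to those human non-stationarities.

## Identifiability of the slope and the recovery study

Recovery studies draw truth uniformly over the central 90% of each range
($\alpha \in [30, 270]$, $\beta \in [-1.8, 1.8]$, $\lambda \in
[0.005, 0.095]$) — strictly interior to the grid, with no other shaping, and
this choice was fixed before any recovery run. One consequence is inherited
from the model itself: at the task's 10 ms stimulus granularity, any slope
above $\beta \approx -0.3$ (rate above ~0.5/ms) renders every candidate
asynchrony effectively all-or-none, so the likelihood is flat over the steep
half of the admissible range and the posterior mean saturates near +0.75
there. Threshold recovery is essentially perfect (truth–estimate $r \approx
0.996$), while the slope's truth–estimate correlation is capped near ~0.86 by
that saturation — a property of the parameterisation and stimulus set, not of
the estimator, and documented rather than patched (e.g. by restricting the
recovery draw to the identifiable region, which would overstate performance).
Slope credible intervals remain honest: 95% equal-tailed grid intervals cover
truth at near-nominal rates because the posterior is wide exactly where the
slope is unidentifiable.

## Synthetic cohorts

A cohort is a set of per-subject 3D scalar maps — an axial-diffusivity
surrogate in arbitrary units — confined to a common synthetic skeleton, plus
a covariates table (`subject_id, beta_slope, age, sex`). Defaults mirror the
study design: 13 subjects, ages uniform on 21–28, sexes 6:7. The skeleton is
built from smooth random-walk curves rasterised at 1–2 voxel width to a
target fraction (default 3%) of a $40 \times 48 \times 40$ volume of 2 mm
voxels; the first curve is confined to the low-x half and long enough to host
a 150-voxel contiguous "planted" region grown by breadth-first search along
the skeleton — a lateralised tract segment. Voxel values are
`baseline + nuisance + noise`, baseline 1.0 and subject noise SD 0.05
(arbitrary units: every downstream statistic is scale-invariant), with small
age and sex trends spread over the whole mask as nuisance realism. Inside the
planted region each subject is additionally shifted by
$-c\,z(\beta)$ with $c$ defaulting to 0.15 — three noise SDs per SD of slope
— so a steeper slope means lower diffusivity, the sign convention under test.
Setting $c = 0$ (or removing the region) gives exact global-null cohorts for
error-rate calibration. The generator does not emulate raw diffusion imaging:
no tensors, no registration, no skeleton projection — it stands in for the
*output* of that pipeline, which is where this package's analysis begins.

## Voxelwise inference

Each mask voxel's values across subjects are regressed on
`[intercept | slope | age | sex]`; the statistic is the t of the slope
coefficient. Because 13 subjects give only 9 residual degrees of freedom, the
residual-variance image may be Gaussian-smoothed within the mask before the
standard error is formed (default $\sigma = 5$ mm, renormalised over in-mask
neighbours so edge voxels are proper averages); this mirrors the variance
smoothing of the standard permutation imaging tools for small cohorts. A
voxel fitting exactly (zero residual variance at floating-point scale) gets a
capped, flagged t rather than an error — and a coefficient that is itself
rounding noise gets t = 0, so degenerate constant cohorts correctly report
nothing.

TFCE integrates $e(v,h)^{E} h^{H}\,\mathrm{d}h$ over 100 midpoint height
steps from 0 to the map maximum, where $e(v,h)$ is the extent of the
connected component containing $v$ at threshold $h$; defaults $E = 0.5$,
$H = 2$, 26-connectivity are the canonical ones for the method (none are
printed in the source analysis). Midpoint integration makes the
single-voxel case match $h^3/3$ to $O(n^{-2})$, which the tests exploit as an
analytic oracle. The integrator processes thresholds from high to low with an
incremental union-find in compiled code, since the permutation null needs
tens of thousands of TFCE evaluations.

Inference is Freedman–Lane: the data are residualised against the nuisance
submodel (intercept, age, sex), residual rows are permuted, the nuisance fit
is re-added, and the full-model t and its TFCE map are recomputed. The null
distribution is the mask-wide maximum TFCE per permutation, and
$p(v) = (1 + \#\{\text{perm max} \ge \mathrm{TFCE}(v)\})/(n_\mathrm{perm}+1)$,
the observed labelling always counting once, so the smallest attainable p is
$1/(n_\mathrm{perm}+1)$. The two correlation signs are tested as separate
one-sided analyses sharing one permutation stream derived from the seed,
which makes the sign-flip antisymmetry between directions exact. If the
requested permutation count reaches the number of distinct orderings (tiny
cohorts), all orderings are enumerated with a warning. Significant clusters
are connected components of $\{p < 0.05\}$ whose size strictly exceeds 100
voxels ("over 100 contiguous voxels" is read as a strict inequality), sorted
by size, with 0-based peak voxel indices; no atlas lookup is attempted.

One caution on an invariance sometimes claimed for this design: the corrected
p-map is invariant to *affine* rescaling of the regressor of interest (the t
statistic is), but not to general monotone transformations, which change a
linear-model t. The tests assert the affine version.

## Problem sizes and numerical choices

The validation studies use: 200 simulated observers for recovery, 100 matched
observers for the adaptive-versus-random comparison, 50 sessions per
interference weight; 200 null cohorts of 200 permutations each on a
$32^3$ grid at 1.2% mask fraction for the familywise-error calibration; and
20 seeded default cohorts at 500 permutations per direction for
planted-effect recovery. These sizes put Monte-Carlo error comfortably below
the margins being asserted (e.g. the FWER check uses the 95% binomial
interval around 0.05 at 200 draws) while keeping a full validation run in the
tens of minutes on one core. All randomness descends from explicit integer
seeds through tagged sub-streams (`derive_seed`), so every study, session and
cohort is bit-reproducible; posterior normalisation is asserted to 1e-10
throughout, and likelihood tables guard the $x\log x$ terms so saturating
asynchronies (probabilities rounding to 0 or 1) cannot poison entropy
computations.

## Known limitations

The behavioural stage models neither reaction times nor error/anticipation
trial rejection; the slope's upper half is unidentifiable at 10 ms stimulus
resolution (above); synthetic skeletons are geometrically, not anatomically,
realistic; and the imaging stage starts from already-skeletonised maps, so
nothing here validates tensor fitting, registration or skeletonisation. The
headline anatomical result of the motivating study (right-frontal clusters in
13 real participants) is not reproducible without the original data; what the
package establishes is that the *procedure* — adaptive slope estimation
feeding a variance-smoothed, TFCE-corrected permutation GLM with the stated
reporting rules — behaves correctly: it recovers planted effects of the
stated sign and geometry, reports nothing in the opposite direction, and
controls its familywise error at the null.
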