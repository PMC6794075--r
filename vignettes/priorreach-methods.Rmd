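---
title: "Methods: graded action priors and motor-goal encoding"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graded action priors and motor-goal encoding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The task and its data model

`priorreach` analyzes a rule-guided delayed center-out reach task. On
each trial a pre-cue appears at one of four cardinal locations and
defines two potential reach goals, 90 degrees clockwise (cw) and
counter-clockwise (ccw) of the pre-cue. The relative sizes of the
pre-cue's two arrowheads announce a likelihood ratio
$k:(6-k)$, $k \in \{0,\dots,6\}$, for which rotation rule will later be
instructed. Priors are constant within blocks of eight successful
trials, six instructed (reward 1 unit) and two free-choice (either goal
rewarded, 1.5 or 0.5 units with equal probability). The initial
expected value of a rule over a block is therefore

$$\mathrm{iEV}(k) = \tfrac{6}{8}\cdot\tfrac{k}{6} +
\tfrac{2}{8}\cdot\tfrac12 = \tfrac{k}{8} + \tfrac18,$$

and the *prior level* is the absolute normalized iEV difference,
$|\mathrm{iEV}_{hi}-\mathrm{iEV}_{lo}|/(\mathrm{iEV}_{hi}+\mathrm{iEV}_{lo})
\in \{0, 0.25, 0.5, 0.75\}$. We adopt degrees with 0° rightward and ccw
positive; the ccw rule maps a pre-cue at $\theta$ to the goal
$\theta+90°$, cw to $\theta-90°$. All times are in ms from trial start;
analysis windows are half-open $[t_0, t_1)$ so adjacent windows never
double-count a spike. Neither convention is observable in the task
description itself; both are declared here and fixed throughout.

A dataset is a `ReachSession`: three tables (units, trials, spikes)
with validity rules — resolvable keys, strictly increasing event times,
reaction time = movement onset − go ≤ 800 ms for completed trials, and
prior levels consistent with the ratio. Reaches executed toward the
higher-prior direction are *follow* trials, the others *against*; in
the zero-prior condition cw reaches are booked as follow purely by
convention.

# The synthetic generator

Every analysis stage is exercised on synthetic sessions with known
ground truth; the generator's defaults are the study conditions for all
tests, not free dials.

**Task structure.** Fixation 500–1000 ms (uniform), pre-cue 500 ms,
memory 500–1500 ms (uniform), rule-cue/go 250 ms, movement 300 ms. The
seven prior ratios are assigned to blocks in balanced shuffled order;
pre-cue locations are uniform per trial; instructed rules follow the
block's likelihood ratio.

**Behavior.** Free choices select the high-prior rule with probability
$\operatorname{logit}^{-1}(\beta\,\ell)$ at prior level $\ell$; the
default slope $\beta = 2.8$ puts the strongest-prior choice probability
at 89%, the qualitative operating point of trained subjects in this
task family. Reaction times are log-normal around 400 ms with a
congruency shift of ±40 ms per unit prior level (faster follow, slower
against) and log-sd 0.12, truncated at the task's 800 ms limit.
Instructed error probability is 3% at baseline, rising by 0.25 per unit
prior level against the prior and shrinking toward zero along it. Real
animals show idiosyncratic, partly non-linear bias patterns and
trial-history effects; the generator deliberately exposes only this
logistic/linear family, so passing tests show correct *recovery of the
configured laws*, not realism of any particular animal.

**Neural population.** Units belong to two areas (PMd, PRR) and three
classes: up-regulating (UR), down-regulating (DR), untuned (default
mixture 0.375/0.375/0.25). Baseline rates are log-normal (median 8 Hz,
log-sd 0.4), lobe gains log-normal (median 24 Hz, log-sd 0.3). Tuning
lobes are truncated von-Mises bumps
$\max\!\big(0,(e^{\kappa(\cos\Delta-1)}-e^{-\kappa})/(1-e^{-\kappa})\big)$
with $\kappa = 2$: peak 1 at the preferred direction (PD) and exactly
zero at and beyond ±90°, so goals orthogonal to a unit's PD axis evoke
no modulation by construction. Ground-truth PDs are drawn from the four
task directions. This is a stated idealization — real PDs are
continuous — chosen so that direction roles (PD/OD/orthogonal) are
exact and the no-orthogonal-modulation property of the planning code
holds identically rather than approximately; with off-axis PDs a
truncated-at-90° lobe would leak prior modulation into nominally
orthogonal goals.

During planning, a DR unit carries lobes at both potential goals with
the low-prior goal's lobe weighted $1 - s_{DR}\,\ell$; the default
$s_{DR} = 1.4$ makes the full-prior weight slightly negative
(−0.05), so the response to a fully disregarded goal dips just below
the orthogonal-goal level, with rates rectified at zero. A UR unit
carries a single lobe at the high-prior goal with weight
$s_{UR}\,\ell$ ($s_{UR} = 1$) and is untuned in the zero-prior
condition. After rule-cue onset plus the unit's *selection latency*
the activity switches to single-goal coding of the executed reach.
Default latencies are 80 (PMd-DR), 120 (PMd-UR), 130 (PRR-DR) and 180
ms (PRR-UR) with 10 ms between-unit jitter — an encoded ordering
(premotor down-regulation first) that the latency analysis must
recover, with magnitudes inside the physiological 70–260 ms range for
frontoparietal selection signals. Spikes are inhomogeneous Poisson,
sampled by thinning against a per-unit rate bound; a root seed spawns
named child streams (`units`, `trials`, `behavior`, `spikes`) so each
stage is independently reproducible.

An optional `commitment_gain` adds a planning-period lobe toward the
*to-be-chosen* goal on free-choice trials. The default 0 encodes a
population that co-plans both options without premature commitment;
tests use the positive variant as a contrast to show the
choice-predictive ROC would detect commitment if present.

# Analysis chain

**Epoch rates and selectivity.** Four windows: baseline [−300, 0) and
pre-cue [0, 300) around pre-cue onset, planning [−300, 0) before
rule-cue onset, movement [onset, offset). Direction selectivity uses
the directional tuning vector (rate-weighted sum of cardinal unit
vectors, computed from raw epoch means — whether to baseline-subtract
is not determined by any stated formula, so the raw choice is declared)
and a Kruskal–Wallis test across the four directions
(visual reference for baseline/pre-cue, reach-goal reference for
planning/movement). *Motor-goal neurons* must exceed 5 Hz mean rate in
some window and be planning-selective at $\alpha = 0.01$ in successful
full-prior instructed trials, where the pre-cue announces the goal
unambiguously. The discrete preferred direction PD\_max is the
direction of maximal mean planning response, ties broken toward the
continuous tuning-vector angle.

**Population tuning.** Planning rates as a function of the high-prior
goal direction, aligned per unit so PD\_max → 0° and normalized by the
unit's full-prior response at aligned 0°. Continuous curves are
reconstructed from the four samples by trigonometric (DFT) low-pass
interpolation — mean, first harmonic, and half-weight Nyquist cosine
(the Nyquist sine is unobservable at N = 4); the curve passes exactly
through the samples. Interpolation is presentation-only; every
statistic uses the four sampled directions.

**Prior modulation and classes.** Per unit, normalized planning rates
are regressed on prior level × prior direction (high prior toward
PD\_max vs toward OD; zero-prior trials are excluded from slope fits
since their prior direction is undefined). The modulation angle is
$\operatorname{atan2}(\max(b_{PD},0),\, \max(-b_{OD},0)) \in [0,\pi/2]$
— upregulation on the y axis, downregulation magnitude on the x axis,
so wrong-sign slopes land on an axis instead of outside the quadrant. A
unit with a significant PD slope and angle > π/4 is UR; a significant
OD slope with angle < π/4 is DR. The angle, not dual significance,
decides the class: the two angle conditions are mutually exclusive, so
a unit significant on both axes (flagged `both_significant`, the
scatter-plot's dual-modulation color) still falls on the side its
angle indicates. Per-slope $\alpha = 0.05$. Population-level tests fit
rate on prior × prior-direction with per-unit random slopes (lme4),
falling back to the documented two-stage route (per-unit OLS slopes,
one-sample t-tests across units) whenever the mixed fit fails or is
singular — with the fallback flagged in the report; orthogonal-role
slopes are always assessed two-stage. Successive prior levels are
compared with Bonferroni-corrected paired t-tests.

**Dip test.** Bimodality of the class structure is tested on the
angle distribution with Hartigans' dip — the minimal sup-norm distance
between the empirical CDF and any unimodal CDF (convex then concave,
an atom allowed at the mode). The implementation is exact: for every
modal split of the distinct values, the minimal feasible band
half-width follows from the largest chord violation of the
convex/concave hull geometry plus the half-mass of each off-mode atom,
and the dip is the minimum over splits (computed in C++ with
incremental hulls). Equal point masses at two values attain the
maximum 0.25; identical values give 0. P-values are Monte-Carlo
against a uniform null of matched size (default 10,000 draws, seeded);
the uniform is the classical least-favorable unimodal calibration, and
the test suite verifies both the exactness (against a brute-force
small-n oracle) and the 5% size empirically.

**Behavioral models.** Error rates (binomial) and RTs (identity link,
untransformed — the response family for RTs is a declared default) are
modeled as `prior + prior:congruency` with subject random slopes;
free-choice follow/against as `prior` (binomial) with subject random
slopes. Prior enters as the continuous level in {0, 0.25, 0.5, 0.75}.
With only two subjects the mixed fits are frequently singular; the
two-stage per-subject fallback with inverse-variance pooling is then
used and flagged.

**Neural distance and latencies.** For each unit, condition-averaged
spike densities (Gaussian kernel, σ = 50 ms, 1 ms grid) are computed
for trials reaching the two opposing goals, per pre-cue location,
normalized by the unit's full-prior PD\_max planning response, within
the unit's own session. The neural distance is the Euclidean norm of
the condition difference across units — no dimensionality reduction —
averaged over the four pre-cue locations. The selection-signal latency
is the maximal-velocity time (MVT) of the distance (centered finite
difference, earliest bin wins ties) in a [0, 600] ms post-rule-cue
search window (declared; reaction times are bounded by 800 ms). The
plateau time (PT) is the first bin after MVT with velocity below 0.3.
The 0.3 threshold is kept on the scale in which it is stated, i.e.
distance units per ms; on normalized distances, velocities are far
smaller, so PT binds almost immediately after MVT — the threshold is
configurable and PT is reported for completeness while MVT carries the
inferential weight. Variability comes from resampling *units* with
replacement (1000 draws, 90% percentile CIs; resampling trials instead
would be an equally defensible contract — units is ours). Between-area
latency differences are tested by permutation: units are randomly
reassigned to areas preserving sample sizes (default 10,000), and the
p-value is the fraction of permutations with an absolute latency
difference at least the observed one.

**Choice prediction and co-activation.** Free-choice trials are sorted
per unit into Prior-in/Prior-out/orthogonal (high prior at PD\_max, OD,
or neither) × Reach-in/Reach-out; Prior-in+Reach-in and
Prior-out+Reach-out are follow choices. Discriminability is rank-based
AUC (ties at ½), requiring at least 5 trials per class (a declared
floor; the trial counts per cell are small for free choices).
Within-condition ROC (Reach-in vs Reach-out inside a prior condition)
measures premature commitment; between-condition ROC (Prior-in vs
Prior-out) measures prior encoding. Pairwise signal correlations are
Pearson correlations of planning rates across all correct trials
within a prior level for simultaneously recorded gated pairs, binned
by PD\_max distance (270° folds to 90°), with a prior-trend model for
the opposite-PD bin. Pooling instructed and free-choice trials within
a level is our declared reading of "across all trials".

# Numerical choices

* The EPSP-like display kernel is
  $(1-e^{-t/\tau_g})e^{-t/\tau_d}$, $t \ge 0$, with $\tau_g = 2$ ms and
  $\tau_d = 50$ ms, rescaled to unit area on its sampled support (the
  shape is fully determined by the two constants; unit area makes the
  density integral estimate spike counts). The Gaussian kernel
  (σ = 50 ms) is used for all velocity/latency work: it is non-causal
  but much better conditioned for differentiation.
* Densities evaluate the kernel at every spike (no zero-padding):
  spikes outside a window still contribute within kernel support. The
  batched path bins spikes on the 1 ms grid and convolves once; the
  discretization error at these kernel widths is below 1%.
* Condition-averaged densities are computed as the density of the
  pooled spikes divided by the trial count (exact by linearity).
* Classification uses clipped-at-zero angle components so that
  wrong-sign slopes can never masquerade as the opposite class.
* Dip p-values, bootstrap draws and permutations all consume explicit
  seeds; every pipeline stage derives a named child seed from the root
  seed, recorded in the run manifest.

# Problem sizes

Defaults are desk-scale by design: 2 sessions (one per synthetic
subject, exercising the random-effect code paths), 20 units per area
per session, 84 blocks (672 trials) per session. The test suite uses
smaller sessions plus three focused experiments: a 200-unit UR/DR
population (70 blocks, ≥ 20 trials per prior × direction-role cell)
for class recovery, 100 units per area for latency-offset recovery
with 2000-permutation tests, and 2000 free-choice trials for the
choice-bias model. These sizes make every recovery property sharp
while keeping a full run in minutes on one core.

# Known limitations

* Poisson spiking with piecewise-constant rates ignores refractoriness,
  bursting and slow drifts; recovery results certify the analysis
  chain, not robustness to every noise structure of real recordings.
* Cardinal ground-truth PDs idealize away tuning misalignment; the
  tie-break and continuous-angle code paths are exercised by direct
  unit tests instead.
* The generator has no trial-history effects, no aborts or fixation
  breaks, and no bias-balancing pre-task.
* With two subjects, mixed-effect fits typically resolve to the
  two-stage fallback; conclusions at the subject level are
  correspondingly coarse.
* PT on normalized distances is threshold-degenerate (see above);
  comparisons should rely on MVT unless the threshold is rescaled.
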