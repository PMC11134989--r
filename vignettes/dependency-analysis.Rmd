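---
title: "Measuring stochastic dependency of event elements in episodic memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring stochastic dependency of event elements in episodic memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eventdep)
```

## The measurement problem

When people encode a multi-element event (an agent, a patient, an object,
an action), does retrieving one element raise the probability of retrieving
the others? That *stochastic dependency* of retrieval is the behavioural
signature of binding: the elements were stored as one integrated
representation rather than as separate associations. `eventdep` implements a
latent-trait analysis of this question for cued-recognition data: every test
trial probes one association of one event with a forced-choice test, and the
analysis asks whether trial outcomes belonging to the *same* event remain
correlated after overall memory ability is accounted for.

The data are binary outcomes $u_{ij}$ (person $i$, item $j$), where each item
belongs to exactly one event (by default 24 events with 3 association tests
each, i.e. 72 items), and each person belongs to one of at most two
between-subjects conditions.

## The measurement model

The baseline model is a three-parameter logistic IRT model with the
discrimination fixed to 1 (events are randomly assembled, so no item should
be systematically more discriminating) and the guessing parameter fixed to
the stochastic guessing probability of the forced-choice test, $c = 1/6$ for
six response alternatives:

$$P(u_{ij} = 1) \;=\; c + (1 - c)\,
  \frac{e^{\theta_i - \beta_j}}{1 + e^{\theta_i - \beta_j}},$$

with person trait $\theta_i \sim N(0, \sigma^2)$ and item difficulty
$\beta_j$. Only the difficulties and the trait variance are free; the trait
mean is fixed at 0 for identification. Crucially, the model assumes *local
independence*: given $\theta_i$, responses are independent. Binding predicts
a structured violation of this assumption — within events only.

`fit_unidimensional()` estimates the model by marginal maximum likelihood
(Bock–Aitkin EM): the E-step forms each person's posterior over a quadrature
grid, the M-step updates every difficulty by Fisher scoring (with a
golden-section fallback that guarantees ascent) and the variance by direct
maximisation of its expected-log-prior term.

### Quadrature

The latent trait is integrated over a *fixed, equally spaced* grid (61 points
over ±8 logits by default) with normalised normal prior weights re-evaluated
at the current variance. Two properties motivated this choice over adaptive
Gauss–Hermite nodes:

* the discretised model is constant across EM iterations, so the marginal
  log-likelihood is monotone by construction — an invariant the test suite
  asserts on every fit;
* trapezoid-type quadrature is spectrally accurate for the smooth,
  Gaussian-like posterior integrands here: on 2×2 toy problems the grid
  likelihood matches brute-force dense-grid summation to about $10^{-7}$,
  and EAP scores match a 20,001-node oracle to about $10^{-14}$.

For the bifactor model the general trait uses the same 61-point grid: with 72
items the general-trait posterior is narrower than a coarse grid spacing, and
a 21-point outer grid demonstrably broke the nesting inequality between the
bifactor and unidimensional likelihoods. The event-specific trait, whose
per-event posterior rests on only 3 items and is therefore wide, uses 21
points over ±6.

### Residual correlations and the dependency measure

After fitting, each person is scored by the expected a posteriori (EAP)
trait, and residuals are formed as
$e_{ij} = u_{ij} - P(\hat\theta_i^{EAP}, \hat\beta_j)$. Yen's $Q_3$
statistic is the Pearson correlation of two items' residual columns across
persons. The dependency measure contrasts same-event and different-event
pairs:

$$D \;=\; \frac{1}{K} \sum_{k > k'} Q_{3,kk'} \;-\;
          \frac{1}{L} \sum_{l > l'} Q_{3,ll'},$$

with $K$ same-event pairs ($24 \times \binom{3}{2} = 72$ in the default
design) and $L$ different-event pairs ($\binom{72}{2} - 72 = 2484$).
Subtracting the between-event mean removes baseline dependence (including
the small negative bias $Q_3$ carries under local independence) and makes
$D$ robust to model misspecification that affects all pairs alike.

The reported $Q_3$ matrix is additionally *bias-corrected* by centring on the
mean over all pairs. Any pair-constant correction provably cancels in $D$
(the suite asserts raw-vs-corrected agreement to $10^{-12}$), so this choice
affects reported correlations but never the dependency measure — whichever
pair-constant correction an analyst prefers, inference on $D$ is unchanged.
The residual scoring rule (EAP by default) is pluggable.

Residual columns with zero variance (e.g. an item everyone answered the same
way) cannot be correlated; their pairs become missing and $D$ averages over
the effective pair counts, which are reported alongside the nominal ones.

## Bootstrap inference

The sampling distribution of $Q_3$ — and hence of $D$ — is unknown, so
significance is assessed by parametric bootstrap.

**$D$ against zero** (`test_D()`): simulate $B$ datasets from the *fitted*
unidimensional model (which embodies local independence, hence $D = 0$ up to
sampling noise), re-run the full pipeline on each — refit, rescore, $Q_3$,
$D$ — and compare:
$p = \bigl(1 + \#\{|D^*_b| \ge |D_{obs}|\}\bigr) / (B + 1)$, two-tailed
around 0 because the null hypothesis is $D = 0$. The add-one smoothing
avoids $p = 0$ at finite $B$; the bootstrap SD is the reported SE. Refitting
each replicate is the canonical parametric bootstrap and the default; a
no-refit mode exists for exploration and is labelled non-canonical.

**Between-condition difference** (`test_D_difference()`): the null must allow
dependency while forbidding a *difference* in dependency. Each condition is
fitted with a bifactor model, $P(u_{ij} = 1) = c + (1-c)\,
\mathrm{logistic}(\theta_i + \eta_{ie} - \beta_j)$, with
$\theta_i \sim N(0, \sigma^2_g)$ and event traits
$\eta_{ie} \sim N(0, \sigma^2_s)$ sharing one variance across events (the
equality constraint is justified by events being randomly generated — no
event is special). The null generative model keeps each condition's own
difficulties and general variance but sets both specific variances to the
*smaller* of the two estimates, then $B$ dataset pairs are simulated and
pushed through the single-condition pipeline;
$p = (1 + \#\{D^*_{diff} \ge D_{obs,diff}\})/(B+1)$, one-tailed in the
hypothesised direction (which must be stated — the default is that the
first condition shows more binding).

Marginal likelihoods for the bifactor model use dimension reduction — an
outer quadrature over the general trait with independent inner quadratures
per event — never a joint 25-dimensional grid. Estimation is EM, with one
refinement: variance components approaching the boundary make EM crawl
sublinearly, so every tenth iteration (and once at the end) the specific
standard deviation is updated by direct golden-section maximisation of its
profile marginal likelihood at the current difficulties. This is coordinate
ascent on the true objective, so monotonicity is preserved, and null fits
($\sigma^2_s = 0$) converge in ~40 iterations instead of stalling.

**Extreme item parameters.** Sample fits occasionally pin a difficulty at the
box bound (±15 logits by default): an item everyone, or no one, answered
correctly. Simulating from such a parameter produces constant columns that
break the refit inside the bootstrap. Flagged difficulties are therefore
replaced by random draws from the empirical distribution of the unflagged
ones (inverse CDF with linear interpolation between order statistics) before
any simulation. The bound-hit flag is our operationalisation of "extreme";
both the bound and the flag rule are configurable.

**Reproducibility.** Every bootstrap derives one child seed per replicate
from the caller's seed up front, so results are bit-identical across runs
and independent of the parallel worker count.

## The synthetic-data generator

`simulate_dataset()` emulates the test phase of a two-condition
cued-recognition experiment: per condition, persons draw a general trait and
independent event traits, and answer `events × items_per_event` forced-choice
items (24 × 3 with 6 alternatives by default). The event-specific variance is
the *only* source of within-event dependency, which makes the generator the
calibration instrument for the whole pipeline: variance 0 is exact local
independence (expected $D = 0$), and mean $D$ rises strictly with it (the
suite checks variances 0, 1, 2, 4).

Defaults the generator treats as the study conditions:

| parameter | default | note |
|---|---|---|
| events per participant | 24 | per participant, between-subjects conditions |
| association tests per event | 3 | one per probed element pair |
| response alternatives | 6 | guessing $c = 1/6$ |
| difficulty distribution | $N(0, 1)$ | unspecified upstream; configurable |
| general trait variance | 1 | unspecified upstream; printed in every power report |
| baseline specific variance | 2 | power-analysis anchor |

Association labels (e.g. which element pair a test probes) are assigned
cyclically within events so each label occurs equally often; they are
metadata only and never affect generation.

What the generator does *not* emulate: serial-position and list-structure
effects, distractor similarity (guessing is a flat 1/6 regardless of the
response set's composition), person-varying guessing or engagement, and any
encoding-phase manipulation beyond what the variance parameters summarise.
Passing calibration tests on synthetic data therefore shows the *procedure*
is sound under the stated latent structure — not that real data satisfy that
structure.

## Power analysis

`estimate_power()` and `required_sample_size()` reproduce the simulation-based
a priori power logic for the difference test: simulate replicate experiment
pairs at baseline specific variance $v$ versus $v + \Delta$, analyse each
with the full bootstrap difference test at one-tailed $\alpha = .05$, and
report rejection proportions with exact binomial intervals. The design
anchors are a medium difference ($v = 2$, $\Delta = 1$, 100 per condition)
and a small-to-medium difference ($\Delta = 0.75$, 150 per condition), both
targeting 80% power. Sample-size selection smooths the Monte-Carlo power
curve by pool-adjacent-violators before thresholding, so a noisy dip cannot
leapfrog the selection past a smaller sufficient $n$.

Power runs default to $B = 199$ bootstrap samples and 250 replicates:
bootstrap-within-power cost is quadratic, and rejection decisions at
$\alpha = .05$ are stable from $B = 199$ on; the full $B = 1000$ remains
available.

## Numerical choices and degenerate inputs

* EM convergence: maximum absolute parameter change $< 10^{-4}$ or 500
  iterations (both configurable); non-convergence returns the fit with a
  warning rather than an error.
* Difficulty box bounds ±15 logits; bound-hits are flagged extreme.
* Specific-variance search range: SD in $[10^{-3}, 2.5]$ (variance up to
  6.25), wide enough for the design space; estimates at the lower edge are
  reported as effectively zero.
* Ties in the signed-rank test vs chance use average ranks; zero differences
  are dropped; the effect size is $r = |Z|/\sqrt{n}$ from the tie- and
  continuity-corrected normal approximation.
* A dataset whose residuals are all zero (a saturated fit) yields missing
  $Q_3$ entries and an explicit error from $D$, not NaN propagation.
* Bootstrap replicates whose refit fails are redrawn with a fresh derived
  seed up to a retry cap and counted in the result.

## Problem sizes used in the test suite

The suite exercises the full pipeline at sizes chosen to balance Monte-Carlo
resolution against runtime on a single CPU: type-I calibration with 100
replicate datasets (100 persons, 12 events, $B = 99$) in the suite and 200
in `scripts/acceptance.R`; the two power anchors at 80 replicates and
$B = 99$; parameter recovery at $n = 2000$ across 10 seeds; dose-response of
$D$ at $n = 500$ with 20 replicates per variance. Tolerances follow binomial
bands for rates and generous sampling bands for recovered parameters.

## Known limitations

* The bifactor fitter requires complete response matrices; missing data are
  supported in the unidimensional pipeline (pairwise-complete $Q_3$) only.
* The equality constraint estimates a single specific variance; designs where
  binding plausibly varies by event type need a richer model.
* $Q_3$'s small-sample bias is handled by mean-centring, which is exact for
  $D$ but means reported per-pair correlations are only centred, not
  debiased pair by pair.
* Guessing is a fixed constant; forced-choice tests with systematically
  attractive distractors violate this.
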