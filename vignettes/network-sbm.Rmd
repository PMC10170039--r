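---
title: "Network slack-based efficiency with weakly disposable undesirable outputs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network slack-based efficiency with weakly disposable undesirable outputs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netdea)
```

## The problem

Hospitals transform resources (beds, staff hours, operating costs) into
care (inpatients, outpatient visits, surgeries), and the care they deliver
comes with quality and access outcomes — some desirable (patients not
readmitted, timely hip-fracture surgery), some undesirable (pressure
ulcers, septicaemia, delayed appointments, waiting days).  Classical data
envelopment analysis (DEA) treats each unit as a black box and ignores
both the internal structure and the adverse outcomes.  `netdea`
implements a network slack-based measure (NSBM) in which each
decision-making unit (DMU) is split into divisions connected by
intermediate products, and undesirable outputs are *weakly disposable*:
a benchmark cannot discard adverse events for free, it can only scale a
peer's desirable and undesirable outputs down jointly.

## The model

A DMU $o$ consists of $K$ divisions.  Division $k$ consumes external
inputs $x_o^k \in \mathbb{R}^{m_k}$, emits desirable outputs
$v_o^k \in \mathbb{R}^{r_k}$ and undesirable outputs
$u_o^k \in \mathbb{R}^{w_k}$, and exchanges link variables
$z_o^{(k,h)}$ with other divisions (produced in $k$, consumed in $h$).
The benchmark for DMU $o$ is a convex combination of all observed DMUs
with intensity vector $\lambda^k \ge 0$ per division.  Weak disposability
attaches a per-peer abatement factor $\theta_j^k \in [0,1]$ that scales
peer $j$'s desirable and undesirable outputs jointly.  The product
$\theta^k \lambda^k$ makes the program nonlinear; the standard
linearisation splits the intensity vector into an abating and a producing
part,

$$\lambda^k = \mu^k + \varphi^k, \qquad
  \theta^k = \frac{\varphi^k}{\mu^k + \varphi^k},$$

with $\mu^k, \varphi^k \ge 0$.  Inputs and links are generated by the
full intensity $\mu^k + \varphi^k$; outputs only by the producing part
$\varphi^k$.  For each evaluated DMU the package solves one linear
program per division, always carrying the full coupled constraint set:

* $x_o^k = X^k(\mu^k + \varphi^k) + s^{k-}$ for every division $k$,
* $v_o^k = V^k\varphi^k - s^{k+}$ for every $k$,
* $u_o^k = U^k\varphi^k$ for every $k$ (kept as an equality: adverse
  events are neither freely disposable nor over-producible),
* $Z^{(k,h)}(\mu^h + \varphi^h) = Z^{(k,h)}(\mu^k + \varphi^k)$ for every
  link (the fixed-link convention; `free_links = TRUE` drops these rows),
* $\sum_j (\mu_j^k + \varphi_j^k) = 1$ for every $k$ under variable
  returns to scale (VRS); the constraint is removed under constant
  returns to scale (CRS),

with all slacks nonnegative.  The division objective follows the
slack-based convention: an input-oriented division maximises the mean
relative input slack $\frac{1}{m_k}\sum_i s_i^{k-}/x_{io}^k$ and scores
$1 - \text{optimum}$; an output-oriented division maximises the mean
relative shortfall $\frac{1}{r_k}\sum_r s_r^{k+}/v_{ro}^k$ and scores
$1/(1 + \text{optimum})$.  By default the first division is input
oriented (it is the resource-using part of the unit) and all others are
output oriented.  The overall score is the arithmetic mean of the $K$
divisional scores (configurable weights), so a DMU is fully efficient
only when every division is.

Two modelling questions are genuinely open in this family of models and
we fixed them as follows.  First, divisional scores could come from one
joint weighted program or from $K$ per-division programs; we solve $K$
separate programs, each focused on one division's slacks but constrained
by the whole network, and average.  This makes every divisional score a
well-defined optimum of its own program (scores are then unique even when
slacks and intensities are not) at the cost of $K$ small LPs per DMU.
Second, undesirable outputs never enter an objective denominator — they
constrain the benchmark but are not themselves averaged into the score.

### Returns to scale and scale efficiency

`netdea()` fits either regime; `scale_efficiency()` reports the per-DMU
ratio $\rho_{CRS}/\rho_{VRS}$, which isolates the share of inefficiency
attributable to operating away from the most productive scale.  Because
the CRS feasible set contains the VRS one, $\rho_{CRS} \le \rho_{VRS}$
and the ratio lies in $(0, 1]$ up to solver tolerance.

## Numerical choices

* **LP backend.**  The package ships its own dense two-phase revised
  simplex.  The frontier programs are small (tens of equality rows, a few
  hundred variables) but systematically degenerate — link rows have a
  zero right-hand side and the self-benchmark is always feasible — and a
  classical tableau accumulates roundoff over long degenerate pivot
  sequences.  The solver refactorises the basis from the original data at
  every iteration, prunes linearly dependent equality rows up front
  (re-checking them against the final solution), pivots by Dantzig's rule
  with largest-pivot tie-breaking, and restarts under Bland's rule — which
  guarantees termination under degeneracy — if a basis ever turns
  singular.
* **Column scaling.**  Divisional scores are unit invariant, so every
  variable column is internally divided by its mean before the LP is
  assembled.  Hospital data mix counts of order ten with costs of order
  $10^8$; without scaling the tableau mixes coefficients across nine
  orders of magnitude.  Reported slacks are mapped back to the original
  units.
* **Zero replacement.**  The slack objective divides by the evaluated
  DMU's own values, so exact zeros are degenerate.  At bind time each
  zero cell is replaced by $10^{-6}$ times its period column mean (an
  absolute $10^{-6}$ if the whole column is zero).  Strictly positive
  cells are never modified.
* **Frontier tolerance.**  A DMU is classified efficient when its score
  is within `tol = 1e-6` of 1; an LP optimum below $10^{-9}$ is treated
  as exactly zero so that frontier units score exactly 1.
* **Degenerate divisions.**  A division with no inputs under input
  orientation (or no desirable outputs under output orientation) has an
  empty objective; its score is defined as 1 with a warning.
* **Feasibility.**  For observed data the program is always feasible:
  $\mu^k = 0$, $\varphi^k = e_o$ reproduces the DMU itself with zero
  slacks.  An infeasible program therefore signals edited data (for
  example a user-modified undesirable column that no convex combination
  can reproduce) and raises an error rather than silently relaxing the
  equality.

## Variable screening and merging

Near-collinear variables inflate the number of spuriously efficient DMUs.
`pearson_matrix()` computes product-moment correlations over all pooled
(DMU, period) observations — pooling rather than per-period because the
screen is meant to identify stable redundancies across the panel, not
year-specific ones.  `find_clusters()` thresholds the correlations at
0.95 by default, but only within a (division, role) context: an input can
substitute for an input of the same division, never for an output or a
link.  Clusters are the connected components (size at least 2) of the
thresholded graph per context, so a variable may belong to clusters in
different contexts.  `merge_variables()` collapses a cluster into its
cellwise sum under a new name (e.g. doctors' plus nurses' hours into a
clinical-staff column); summation is the only merge offered because any
other combination silently mixes units.

## Scenario analysis

`impact_analysis()` asks what each quality/access variable contributes to
measured efficiency by replacing its column with a hypothetical best or
worst case and refitting.  The canonical construction for an undesirable
event count is: best case, essentially zero — the constant
$\varepsilon = 10^{-6}$, a constant because the counterfactual "no
pressure ulcers anywhere" has no cross-DMU variation to preserve — and
worst case, the bounding volume column (every inpatient develops one).
The default rule table extends this pattern: desirable counts are best at
their bounding volume and worst at $\varepsilon$; delayed appointments
are bounded by outpatient visits; waiting days, which have no natural
volume bound, default to twice the observed maximum.  Only the
undesirable-event construction is canonical; the other bounds are this
package's documented defaults, overridable per scenario.  The per-DMU
impact is the ratio of scenario to baseline cross-period mean overall
score, minus one; positive values mean the edit flatters the DMU.  Group
summaries average the absolute impact within each DMU group.  Scenarios
edit one variable at a time, which ignores the correlation between, say,
ulcers and infections; a joint scenario can be composed by applying
several `scenario_spec`s in sequence, but the defaults deliberately
follow the one-at-a-time design so each variable's contribution is
attributable.

## Sensitivity to variable choice

Because clustered variables are interchangeable, any of them could have
represented the cluster in the model.  `enumerate_variants()` builds the
Cartesian product of single-representative choices over all clusters that
intersect the model, and `compare_variants()` refits every variant and
reports each DMU's score spread — by default the maximum absolute
pairwise difference of cross-period mean overall scores, with a
designated-baseline mode behind the `baseline` argument.  DMUs whose
spread exceeds 0.05 (five percentage points, the conventional materiality
threshold for this check) are flagged.

## The synthetic panel generator

Real hospital panels of this kind are published by health ministries and
are not redistributable, so `generate_panel()` draws panels with the
structural features the model relies on: 27 DMUs over 4 periods by
default with 19 variables (E1–E9, Q1–Q7, A1–A3).  A latent size per DMU,
lognormally spread over one decade, drives beds (E1); staff hours (E2,
E3) are proportional to beds with idiosyncratic noise calibrated so their
pooled correlation hits a configurable target (0.99 by default,
reproducing the doctors/nurses collinearity that motivates the screening
step); costs (E4–E6) follow staff; patient volumes (E7–E9) follow size
divided by a per-DMU inefficiency factor $\ge 1$.  Event and outcome
counts are binomial draws at configured rates, bounded by construction by
their volume columns (ulcers and catheter infections by inpatients;
septic and embolic complications, timely hip-fracture surgeries and
outpatient-eligible surgeries by surgeries; delayed first appointments by
outpatient visits); inefficient DMUs also have proportionally inflated
adverse-event rates.  Waiting days are positive and scale with the
inefficiency factor.  All noise is multiplicative lognormal with
coefficient of variation 0.08, keeping values strictly positive without
truncation artefacts; group labels B–F cycle over the size ranking to
mimic a size-graded grouping.

What the generator does *not* emulate: real marginal distributions or
magnitudes of any national system, case-mix differences between groups,
serial correlation beyond a shared latent size, or correlated shocks
between quality variables.  Tests passing on synthetic panels therefore
validate the machinery (feasibility, orderings, invariances, exact
constructions), not any empirical claim about real hospitals.

```{r example, eval = FALSE}
panel <- generate_panel(synthetic_config(seed = 1))
fit_vrs <- netdea(panel, model = "A", rts = "vrs")
fit_crs <- netdea(panel, model = "A", rts = "crs")
summary(fit_vrs)
head(scale_efficiency(fit_vrs, fit_crs))

clusters <- find_clusters(pearson_matrix(panel), model_spec("A"))
impacts  <- impact_analysis(panel, model = "A", baseline = fit_vrs)
plot(impacts)
```

## Verification strategy and problem sizes

The solver is validated against an independent brute-force oracle: for a
single division without undesirable outputs, slacks are closed-form given
the intensity vector, so an exhaustive grid over the VRS simplex
(resolution $10^{-3}$, up to three DMUs) brackets the optimum; one
hundred random instances agree with the LP to machine precision.  The
weak-disposability, returns-to-scale and free-link variants are checked
through their ordering properties (abatement free $\le$ abatement off,
CRS $\le$ VRS, relaxed links never raise a score) on dozens of random
multi-division instances, and unit invariance under random column
rescalings to $10^{-6}$.  The default check sizes — 4–6 DMU random
networks, a 27$\times$4 synthetic panel for the end-to-end runs — keep the
whole suite under a minute while exercising every constraint type; all of
them are ordinary problem sizes for this class of model, where real
panels rarely exceed a few dozen comparable units.

## Known limitations

* Scores are point estimates; no bootstrap or statistical inference on
  efficiency is provided.
* No super-efficiency ranking of frontier DMUs, no Malmquist
  productivity change, no dynamic carry-overs between periods: each
  period is an independent frontier, and cross-period results are plain
  averages.
* The shipped hospital models A–D are documented reconstructions of a
  four- and three-division layout; users with a different production
  story should write their own YAML wiring.
* Scenario edits do not propagate to correlated columns, so the measured
  impact of a variable is a ceteris-paribus quantity.
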