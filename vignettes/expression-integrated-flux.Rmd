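---
title: "Expression-integrated flux prediction: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expression-integrated flux prediction: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxweaver)
```

## The model

A genome-scale metabolic model provides a stoichiometric matrix $S \in
\mathbb{R}^{m\times n}$, flux bounds, a biomass pseudo-reaction, and Boolean
gene–protein–reaction (GPR) rules. At steady state, feasible flux vectors
satisfy $Sv = 0$ with $L \le v \le U$. Flux balance analysis (FBA) picks the
feasible vector maximizing biomass; flux variability analysis (FVA) reports,
per reaction, the minimum $\alpha_{j,d}$ and maximum $\beta_{j,d}$ flux
attainable in condition $d$ while a fraction $p$ of the FBA optimum is
retained.

The integration MILP couples fluxes to transcriptomes measured across $D \ge
2$ conditions. All reactions are first made irreversible (reversible
reactions split into a forward/backward pair; at most one direction of a
pair may be active, enforced by binary variables $b$ with $b_f + b_b = 1$).
Relative expression $\tilde g_{i,d} \in [0,1]$ anchors a free gene-activity
variable $g_i \in [0,1]$ through deviation variables
($g_i - \tilde g_i = \delta_{i1} - \delta_{i2}$), GPR rules aggregate gene
activities into a reaction activity $\hat g_j$ (minimum over AND, maximum
over OR, encoded with binary selectors), and each rule-bearing reaction's
flux — rescaled to $[0,1]$ by the *cross-condition* FVA envelope
$[\min_d \alpha_{j,d},\ \max_d \beta_{j,d}]$ — is matched against $\hat g_j$
through a second pair of deviations $\varepsilon_{j1}, \varepsilon_{j2}$.
The objective

$$\min\; -\tilde c\, v_{\text{biomass}} \;+\; \textstyle\sum_i
(\delta_{i1}+\delta_{i2}) \;+\; \sum_j (\varepsilon_{j1}+\varepsilon_{j2})$$

trades growth against fidelity to the transcriptome. Because the envelope
and the expression normalization are shared across conditions while the MILP
is solved per condition, the resulting flux distributions are mutually
comparable — the property that single-condition integration methods lack.

Key assumptions: expression is a usable proxy for enzyme capacity on a
*relative* scale (not absolute $V_\max$); the cell operates near a growth
optimum softened by the deviation terms; the GPR min/max semantics describe
complex/isozyme kinetics adequately.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `ctilde` | `"B"` | Biomass weight. `B = (2k + 2n) / v_biomass_max` equates the largest possible biomass term with the largest possible deviation total ($2k + 2n$, since every $\delta,\varepsilon \in [0,1]$ pairwise sums to at most 2). The schedule `{1, B/1000, ..., 2B}` is accepted symbolically. Larger values push the solution toward the FBA optimum; the acceptance suite verifies biomass is non-decreasing along the schedule. |
| `transform` | `"mean_reference"` | Expression normalization (see below). |
| `p` | `1.0` | FVA retention fraction; the retained objective is an equality by default (`retention = "ge"` gives the inequality reading). |
| `U_default` | `1000` | Replacement for non-finite upper bounds, in flux units (mmol/gDW/h). |
| `exp_mode` / `exp_band` | `"equality"` / `0.01` | How measured uptake rates constrain their exchange reaction: a ±1% equality band by default; `"upper"` and `"lower"` apply the measured value as a one-sided bound. |
| `omega`, `omega_flux` | `0.001` | Denominator guards: rows (expression) or envelope ranges (flux) at or below the guard are treated as degenerate. |
| `retention_tol` | `1e-6` | Relative tolerance on the step-1 optimum in the L1/L2 second step. |

`compute_B()` resolves `B` against a condition's own FBA optimum. In
`run_multi_condition()` each condition therefore gets its own `B`: FBA is
run per condition anyway, and tying the weight to the condition's attainable
growth keeps the two objective parts balanced condition by condition.

## Expression normalization

Three row-wise schemes map raw non-negative expression $T_{i,d}$ into
$[0,1]$:

* **max-reference** $\tilde g = T / \max_d T$: the strongest condition maps
  to 1; invariant to positive row scaling.
* **min-max** $\tilde g = (T - \min_d T)/(\max_d T - \min_d T)$: spans the
  full unit interval.
* **mean-reference**: the row mean maps to 0.5; values above the mean are
  scaled between mean and max into $(0.5, 1]$, values below between min and
  mean into $[0, 0.5)$.

For the lower branch of the mean-reference scheme the package defaults to
the monotone form $(T - \min)/(2(\bar T - \min))$, under which the row
minimum maps to 0 and the transform is non-decreasing within a row. The
reflected alternative $(\bar T - T)/(2(\bar T - \min))$ — which maps the row
*minimum* to 0.5 and values just below the mean to 0, and is therefore
non-monotone — is available as `mean_low = "as_printed"` for comparison;
it contradicts the stated intent of a scheme whose lower half should span
$[0, 0.5)$, so it is not the default.

Degenerate rows (guard `omega` fails) get the scheme-neutral constant 0.5
(or 1 under max-reference when the row is a positive constant); this keeps
the anchoring constraint well-posed without dropping genes. Duplicated gene
rows are averaged; model genes absent from the table leave their $g_i$ free
in $[0,1]$ with no anchoring row.

## The mixed-integer GPR encoding

`min`/`max` are not linear, so each internal AST node with $k$ children gets
an auxiliary variable in $[0,1]$, $k$ binary selectors summing to $k-1$, and
$2k+1$ rows (e.g. for AND: $\hat g \le g_i$ and $\hat g \ge g_i - M y_i$).
With every participating variable in $[0,1]$, $M = 1$ is sufficient and the
tightest valid big-M; nothing is gained by a larger constant, and the box
$[0,1]$ is never loosened. Nested rules are encoded recursively, one
auxiliary per node. The package carries a direct recursive evaluator
(`evaluate_rule()`) as an independent oracle; the test suite checks
MILP-vs-evaluator equality on hundreds of random rule/value combinations.
OR can alternatively aggregate by summation (`or_mode = "sum"`, no binaries
needed); the default is the maximum.

## Scope of the flux-matching constraint

The scaled-flux row is emitted only for reactions that (a) carry a GPR rule
and (b) are non-degenerate in the envelope. Exchange, biomass, and rule-less
reactions have no $\hat g$ (there are no genes to define one); a degenerate
envelope range would make the scaling an undefined division. Binaries are
created only for split direction pairs — for all other reactions $b = 1$ is
a strict relaxation-free simplification, since $b$ appears in no objective
term and only enlarges the box.

## Measured uptake rates

The measured-flux constraint admits three readings; the package defaults to
a two-sided band $v \in v^{exp}(1 \pm 1\%)$, which pins uptake to the
measurement (the way measured uptake rates are used in practice) while
tolerating measurement noise, and offers `upper`/`lower` one-sided modes for
the two literal readings. Measured values refer to original reaction ids and
are applied to the forward direction on the irreversible model.

## Two-step variants

At the retained step-1 optimum $z^*$ (tolerance `retention_tol`,
relative), the **L1** step minimizes $\sum_j v_j$ — a parsimonious
refinement that collapses alternate optima and removes futile cycles — as a
second MILP. The **L2** step minimizes $\sum_j v_j^2$; mixed-integer
quadratics are outside the solver backend, so the binaries are fixed at
their step-1 values and the continuous quadratic program is solved with a
ridge of $10^{-6}$ on the non-flux variables to keep it strictly convex.
The QP path runs an active-set solver after a presolve that substitutes
pinned variables, folds singleton rows into bounds, and merges rows that are
scalar multiples of each other (fixed selector binaries otherwise leave
implicit equalities as opposing inequality pairs, which active-set methods
handle poorly); if the active-set solver still reports numerical
inconsistency, a trust-region solve warm-started from the feasible step-1
point takes over. Retention is imposed as a single equality pinned at the
step-1 value of the retention expression — exactly feasible by
construction — rather than as a tight two-sided band.

## Numerical choices

* LP/MILP backend: HiGHS through scipy, MIP relative gap $10^{-9}$.
* FVA bounds are rounded at $10^{-9}$ to suppress solver sign noise, and
  $\alpha \le \beta$ is enforced after rounding.
* Ties among alternate optima are real: tests assert objective values and
  envelope-level properties, not raw flux vectors, except after the L1 step.
* Infeasible FBA/FVA/MILP solves raise errors naming the stage; the pipeline
  records per-condition failures and completes the remaining conditions.

## The fixture generator

`make_network()` builds four deterministic motifs (≤ 30 reactions): a linear
chain (unique flux), parallel isozyme branches (routing degrees of freedom),
a branched network with a rule-less futile cycle (alternate optima for L1 to
remove), and a diamond with nested AND/OR rules. Every motif contains a
reversible reaction, so direction splitting is always exercised, and a
biomass sink. `make_condition_set()` designs per-condition ground-truth
routings: uptake `10 * (1 - 0.1 ((d-1) mod 5))` mmol/gDW/h — the scale of
measured glucose uptake in chemostat experiments — with 80% of flux through
a preferred branch cycling across conditions. `make_expression()` inverts
the model's own assumption: gene expression proportional to the
cross-condition *relative* magnitude of designed fluxes through the gene's
reactions (a gene participating in several reactions takes the largest
profile; genes of unused pathways sit at a constant baseline), scaled to a
platform-like magnitude of 100 and perturbed by multiplicative log-normal
noise.

What passing tests show — and what they do not: recovery of designed
routings from noiseless or mildly noisy expression demonstrates that the
optimization faithfully propagates relative expression into relative flux
*when the coupling assumption holds exactly*. Real transcriptomes violate
that assumption (post-transcriptional regulation, enzyme saturation,
condition-dependent $k_{cat}$), carry platform-specific noise far from
log-normal, and sit in networks orders of magnitude larger; desk-scale
fixtures say nothing about solve times at genome scale.

## Known limitations

* One MILP per condition with a shared envelope; a literal joint MILP over
  all conditions simultaneously is not provided (the per-condition
  formulation with shared scaling already yields cross-condition
  comparability).
* The L2 step is exact only given the step-1 binary assignment; a true
  mixed-integer quadratic could in principle choose different directions.
* No loopless-FVA or thermodynamic constraints; futile cycles are handled
  only by the L1 refinement.
* The FVA retention fraction used with published datasets is not
  identifiable from the outside; the default `p = 1` is a choice, and
  results at genome scale may be sensitive to it.
* Problem sizes in the test and acceptance suites are deliberately small
  (≤ 30 reactions, ≤ 12 binaries where exhaustive enumeration serves as the
  oracle, 2–8 conditions), chosen so that independent brute-force oracles
  remain computable exactly.
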