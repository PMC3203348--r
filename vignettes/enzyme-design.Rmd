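---
title: "Designing enzyme manipulations with resilience-aware fuzzy optimization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing enzyme manipulations with resilience-aware fuzzy optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The design problem

Given a kinetic model of a metabolic network — metabolite concentrations
$x \in \mathbb{R}^n$, enzyme activities $e \in \mathbb{R}^m$, rate laws
$v(x, e; \theta)$ and a stoichiometric matrix $S$ with dynamics
$\dot x = S\,v(x, e;\theta)$ — the package answers: *which enzymes should be
over-expressed or repressed, and by how much, to maximize the steady-state
synthesis rates of chosen target fluxes, while keeping the manipulated set
small and the strain viable?*

Two formulations are implemented.

**Crisp primal problem.** Maximize the flux ratios
$v_i / v_i^{\mathrm{basal}}$ for the targets $i \in \Sigma_O$, and minimize
the number of modulated enzymes $\sum_j y_j$, subject to:

* steady state, $S\,v(x, e) = 0$, for the dependent metabolites;
* enzyme intervals: a modulated enzyme ($y_j = 1$) moves within
  $[\gamma_e^{LB}, \gamma_e^{UB}]\, e_j^{\mathrm{basal}}$, an un-modulated
  one only within the narrower band
  $[\gamma_b^{LB}, \gamma_b^{UB}]\, e_j^{\mathrm{basal}}$;
* at least one modulation, $\sum_j y_j \ge 1$;
* metabolite boxes $[\gamma_x^{LB}, \gamma_x^{UB}]\, x_i^{\mathrm{basal}}$;
* crisp cell-viability caps on the totals,
  $\sum_i x_i \le \zeta_x \sum_i x_i^{\mathrm{basal}}$ and
  $\sum_j e_j \le \zeta_e \sum_j e_j^{\mathrm{basal}}$.

The enzyme-count objective becomes the budget constraint
$\sum_j y_j \le \varepsilon$; sweeping $\varepsilon$ traces the Pareto front
between productivity and intervention effort. Several simultaneous targets
are scalarized by the weighted infinite norm
$\max_i (f_i^{UB} - f_i)/(f_i^{UB} - f_i^{LB})$, whose upper anchors come
from single-objective bound runs over the same feasible set; with one
target this reduces to plain ratio maximization, independent of the
anchors.

**Fuzzy resilience problem.** Mutants tend to settle into a new steady
state close to the wild type. The crisp problem ignores this and therefore
over-estimates what a manipulation can deliver. The fuzzy formulation adds
*fuzzy-equal* goals pulling every metabolite (set $\Sigma_X$) and enzyme
(set $\Sigma_E$) toward its basal level, turns the target maximizations
into *fuzzy-max* goals, and softens the two viability caps into
*fuzzy-inequality* goals over an interval
$[\zeta^{LB}, \zeta^{UB}] \cdot \mathrm{total}^{\mathrm{basal}}$. Each goal
is graded by a membership function on $[0, 1]$ (linear by default;
exponential, hyperbolic, inverse and piecewise-linear shapes are available
but not calibrated against published results), and a compromise is found by
minimizing the augmented min–max goal attainment
$$\eta_D = \max_i\,(\bar\eta_i - \eta_i) \;+\; \delta \sum_i (\bar\eta_i - \eta_i),$$
with ideal grades $\bar\eta_i = 1$ and $\delta = 10^{-4}$, the midpoint of
the $10^{-3}$–$10^{-5}$ band in which the augmentation term merely breaks
ties. A viability membership of exactly zero marks the point non-viable and
the solution infeasible.

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `gamma_e` | fold-range of a modulated enzyme | (0.2, 5) | the studies also use (0.4, 2.5) and (0.8, 1.25) |
| `gamma_b` | drift band of un-modulated enzymes | (0.9, 1.1) | study configs pin to (1, 1); see below |
| `gamma_x` | metabolite box | (0.2, 5) | also anchors the fuzzy-equal metabolite goals |
| `zeta_x`, `zeta_e` | crisp viability caps | 2 | `Inf` disables; the yeast study disables them |
| `zeta_soft` | soft viability interval | (1.6, 2.0) | grade 1 below 1.6×, 0 above 2.0× |
| `delta` | min–max augmentation weight | 1e-4 | constrained to [1e-5, 1e-3] |
| `n_starts` | multistarts per pattern NLP | 25 | basal start always first |

All quantities are dimensionless ratios against the basal state, so rate
constants cancel; only kinetic orders, relative basal fluxes and basal
concentrations (as weights in the viability totals) shape the results.

## Solution machinery

The mixed-integer structure is handled exactly at the scale of the bundled
studies: all binary patterns with $\sum y_j \le \varepsilon$ (255 for the
yeast network at $\varepsilon \le 8$) are enumerated, and each pattern's
continuous problem is solved by multistart bound-constrained
quasi-Newton iteration (L-BFGS-B) over the log activity ratios of the free
enzymes. The steady state is imposed by an inner damped Newton solve on the
dependent balances in log-concentration space, which preserves positivity;
for power-law (GMA) models the balances, their Jacobian and the full
objective gradient (via the implicit function theorem) are evaluated
analytically, and the kinetic orders are extracted exactly at load time by
log-ratio probing. Metabolite boxes and viability caps enter as quadratic
penalties tightened in a second stage and re-verified on the reported
point at a $10^{-6}$ relative tolerance; min–max objectives get a final
derivative-free polish (Nelder–Mead) on the best multistart candidates.
Membership grades are clamped to $[0,1]$ for reporting, but the optimizer
sees a lower-unclamped extension so that zero-grade regions retain a
descent direction — the two coincide wherever any optimum can lie.

For larger enzyme sets the `incremental` engine grows the modulated set
greedily (the best single addition per step) followed by swap local
search, exploiting the empirically observed nesting of optimal sets across
budgets; an `evolutionary` mode (random-key differential-evolution-style
search over patterns) is available behind the same interface. Budget
sweeps solve each pattern once for single-target primal problems; fuzzy
sweeps re-solve per budget because the flux-membership anchors are
refreshed from the primal front at the same budget. In fuzzy sweeps only
exact-size patterns are enumerated: with the bundled configurations the
un-modulated band lies inside the modulated interval, so every smaller
pattern is dominated by a superset and nothing is lost.

Determinism: every source of randomness (multistart locations, jittered
Newton restarts, the toy generator) derives from the engine seed, and the
per-pattern stream is a deterministic function of the seed and the
pattern, so identical configurations reproduce results bit-identically.

## The bundled fixtures and what they can show

**Yeast anaerobic fermentation.** A generalized mass action model of
glucose fermentation to ethanol (glucose uptake HXT, hexokinase GLK,
phosphofructokinase PFK, glyceraldehyde-3-phosphate dehydrogenase TDH,
pyruvate kinase PYK, storage-carbohydrate branch TPS, glycerol branch GOL,
net ATP consumption ATPase; five dependent pools including ATP). The rate
laws follow the published kinetic model of anaerobic fermentation in
*S. cerevisiae*; the transcription is validated by a test asserting that
the recorded basal state is an exact steady state and that the ethanol
rate carries its documented kinetic orders (0.05, 0.533, −0.0822 with
respect to the fructose pool, PEP and ATP). One kinetic order — the
glycerol branch's order with respect to the fructose-bisphosphate pool —
is not available to us directly; it is set to 0.5, the value implied by
treating the triose pool as in aldolase equilibrium with the
bisphosphate pool (so DHAP $\propto$ FDP$^{1/2}$), which is also the value
under which the enumerated optimization results agree with the published
per-budget optima to a fraction of a percent.

When the allowed perturbation region is varied (the over-estimation
analysis runs it at 5-fold, 2.5-fold and 1.25-fold), the fuzzy-equal
enzyme goals keep their anchors at the reference 5-fold physiological
range (`enzyme_anchor_gamma`): the resilience scale describes the cell,
not the search box, and tying it to the shrinking region would harden the
goals exactly where the optimizer has least room, distorting the
comparison between regions.

Two further configuration choices were resolved against the published
per-budget tables rather than taken from the package defaults, and the bundled study
configs record them explicitly: (i) un-modulated enzymes are *fixed at
basal* (`gamma_b = c(1, 1)`) — allowing the ±10% drift band uniformly
inflates the low-budget optima by roughly the band width; (ii) the
fuzzy-equal enzyme goals cover *all* enzymes, modulated ones included,
with triangular anchors at the wide significant bounds — restricting them
to un-modulated enzymes leaves the large-budget compromises several
percent too optimistic. The crisp viability caps are disabled in the
yeast study (the primal runs are reported without viability constraints);
the library default keeps $\zeta = 2$.

**Synthetic E. coli central carbon metabolism.** A GMA *stand-in* with the
topology of the central carbon network (PTS uptake coupled to the
PEP/pyruvate pair, glycolysis, pentose-phosphate pathway, and the
amino-acid precursor drains DAHPS, SERS, PEPC among others; 18 dependent
metabolites, 30 reactions, 7 co-metabolites held constant). Its kinetic
orders are plausible — canonical substrate saturation, the known allosteric
signs (FDP activates PK and PEPC, PEP inhibits PFK, glucose-6-phosphate
inhibits uptake), chemostat-like glucose supply — but synthetic: they were
*not* fit to the published central-carbon model, whose full parameterization
is not redistributable here. Quantitative results on this fixture
characterize the method, not the organism, and the file and accessor are
named accordingly (`ecoli_ccm_synthetic.json`). The glucose supply step is
excluded from modulation in the study configuration: it is an operating
condition, not a genetic target. The co-metabolite conservation variant
(fixed adenylate energy charge and fixed reduced fractions of the NAD and
NADP pools, with the pool levels otherwise free) is available as a per-run
flag; it adds four degrees of freedom to each pattern NLP, parameterized so
the three conservation relations hold exactly by construction.

Because the generator and the synthetic fixture are clean GMA systems with
exact basal steady states, passing tests demonstrate correctness of the
formulation and machinery — steady-state solving, enumeration, membership
algebra, dominance of the primal over the resilience optimum — but they do
not validate kinetic assumptions against real data: saturable
(Michaelis–Menten) kinetics appear only in small test models, measurement
noise and model misfit are absent, and local stability of the selected
steady states is reported (`stability_diagnostic()`) but never enforced,
consistent with the steady-state-only formulation.

## Numerical choices and degenerate inputs

* Steady-state tolerance $10^{-9}$ (scaled by the largest basal flux),
  at most 200 damped Newton iterations, up to 5 jittered restarts;
  solutions drifting beyond $e^{50}$ in any log-concentration are treated
  as divergence.
* Penalty stages $\mu = 10^4$ then $10^6$; the reported point is always
  re-checked against the crisp constraints, so penalty softness cannot
  leak into reported feasibility.
* Ties among patterns (objectives equal within $10^{-6}$ relative) go to
  the pattern with fewer modulated enzymes, then the lexicographically
  smallest index set — tables are reproducible.
* Degenerate scalarization bounds ($f^{UB} \le f^{LB}$) and empty goal
  sets are rejected with errors; a fuzzy run without resolved upper
  anchors instructs the caller to run the primal problem first.
* Budgets larger than the candidate set are truncated to it; enumerations
  beyond `max_patterns` refuse with a pointer to the incremental mode.

## Problem sizes used in the bundled checks

The shipped tests and the acceptance script run the yeast study at full
width (255 patterns per sweep; 25 starts per pattern for the primal front,
15 for the fuzzy front) and the narrower perturbation regions at 5 starts;
the E. coli study is exercised at a budget of one (29 candidate patterns
plus three single-objective bound runs). These sizes were chosen so the
whole suite completes comfortably on a single core while keeping the
enumeration exhaustive and the multistart redundancy high enough that
repeated runs land on identical optima.

## Known limitations

* Global optimality of each pattern NLP is multistart-empirical, not
  certified; the enumeration is exact only over the discrete layer.
* The resilience formulation calibrates membership anchors from crisp
  bounds; other anchor policies change the compromise and only the default
  is validated against published values.
* The E. coli fixture is synthetic (see above), so organism-level
  conclusions require substituting a measured kinetic model through the
  documented JSON schema.
* Steady-state multiplicity is handled only implicitly: the Newton solve
  tracks the branch connected to the basal state from its warm start.
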