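---
title: "Constraint-based prediction of metabolic dynamics: models, discretization and solvers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based prediction of metabolic dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

dynfba predicts time-resolved metabolite concentrations and reaction
fluxes from the stoichiometry of a metabolic network alone, without
enzyme-kinetic rate laws.  This vignette explains the model family, the
discretization, the numerical choices and the limits of what the tests
can show.

## The problem and the model family

A metabolic network with stoichiometric matrix $S$ (metabolites in
rows, reactions in columns) obeys the mass balance
$$\frac{dX}{dt} = S\,v(t), \qquad v_{min} \le v \le v_{max}, \qquad
x_{min} \le X \le x_{max}, \qquad X(t_0) = X_0 .$$
At steady state ($dX/dt = 0$) flux balance analysis picks one flux
distribution by optimizing an objective.  To reach *transient* states,
the whole horizon $[t_0, t_f]$ is treated as a single optimization
problem (the dynamic optimization approach), with the mass balance as a
constraint at every time point.  What distinguishes the ten methods is
only the objective:

* **dfba** — classical dynamic FBA: maximize the integral of a sink
  (export) concentration, i.e. cumulative production.
* **mdfba / mdfba_flux / mdfba_cf** — MOMA-style smoothness: minimize
  $\sum_j \sum_i (x_{i,j} - x_{i,j-1})^2$, the same sum over fluxes, or
  both.  The premise is that metabolic profiles change smoothly.
* **rdfba\* (NLP and MINLP forms)** — ROOM-style on/off counting:
  minimize the *number* of significant changes between adjacent time
  points.  A binary indicator $y_{i,j}$ (and $z_{l,j}$ for fluxes) is
  forced to 1 only when the value leaves a tolerance band around its
  predecessor,
  $$w^u_{i,j} = x_{i,j-1}(1 + \gamma_x) + \epsilon_x, \qquad
    w^l_{i,j} = x_{i,j-1}(1 - \gamma_x) - \epsilon_x,$$
  through the big-M constraints
  $x_{i,j} - y_{i,j}(x_{max,i} - w^u_{i,j}) \le w^u_{i,j}$ and
  $x_{i,j} - y_{i,j}(x_{min,i} - w^l_{i,j}) \ge w^l_{i,j}$.  This
  permits a few large jumps while keeping the profile flat elsewhere —
  qualitatively different from the quadratic penalty, which spreads
  change over many small steps.  The relaxed variants box the
  indicators into $[0,1]$ and force $\gamma = \epsilon = 0$, giving a
  smooth NLP.

The combined (`_cf`) on/off objectives weight concentration and flux
indicators as $\sum 2\alpha\, y + \sum 2(1-\alpha)\, z$ with
$\alpha = 0.5$ by default, which reproduces the plain unweighted sum;
$\alpha$ is exposed because equal weighting is itself a modeling
choice.

## Orthogonal collocation on finite elements

The horizon is divided into $E$ uniform finite elements; inside each
element every state and flux is parameterized at the $R$ roots of the
shifted Legendre polynomial of order $R$ (`legendre_roots()`), giving
$M = E \cdot R$ global nodes and $(N + F)\,M$ node unknowns
(`count_variables()`).  The state inside an element is the polynomial
through the element-start value and the $R$ node values; the dynamics
are enforced exactly at the roots and the interpolated element end
value equals the next element's start (continuity).  Roots are
interior (Gauss points): the element start is an interpolation support
node, not a collocation node, which makes the initial condition natural
and is the convention the tests pin down.  Fluxes share the node grid
but carry no continuity constraints — only the state obeys an ODE.

"Adjacent" in all fluctuation objectives means adjacent in the single
global ordering of the $M$ nodes, crossing element boundaries; the
first concentration difference is taken against $X_0$.  Flux
differences and flux indicators start at the second node because a
flux has no prescribed initial value.  The Dirac comb in the
objective definitions reduces to a plain sum over nodes.

## How the programs are solved

Programs are stated declaratively over $x_{i,j}$, $v_{l,j}$ and the
indicators, then compiled for the solver in *reduced space*: because
the collocated dynamics are linear in $(x, v)$, the state is eliminated
exactly through the element-wise integral operator,
$x = X_0 + G\,(S v)$ (`integration_operator()`).  Consequently every
returned trajectory satisfies dynamics, continuity and the initial
condition to machine precision — the feasibility tests measure
residuals around $10^{-13}$ — and the decision space shrinks to the
fluxes and indicators.  Concentration bounds become linear inequalities
in $v$; rows that interval arithmetic over the flux box proves vacuous
are dropped.

Solver classes, in the spirit of a pluggable backend
(`solver_capability()`):

* **LP/QP** (dfba, mdfba family, on/off leaves): the dual active-set
  solver of quadprog.  Linear objectives receive a ridge of
  `1e-7 * max(1, |c|)` on the diagonal so the Hessian is positive
  definite; the perturbation moves vertex optima by less than the
  feasibility tolerance and makes degenerate flux directions unique,
  which is also what makes repeated runs byte-identical.
* **smooth NLP** (relaxed on/off variants; the threshold constraints
  are bilinear in $(x_{prev}, y)$): SLSQP through nloptr with analytic
  Jacobians, `xtol` $10^{-10}$, constraint tolerance $10^{-8}$, and
  deterministic multistarts drawn from a Lehmer generator seeded by the
  caller (the package never touches R's global RNG stream).  These
  problems are nonconvex; the contract is the best feasible point over
  the configured starts.
* **MINLP** (binary on/off variants): a best-first branch and bound
  written in the package, layered on the smooth backend.  Node
  relaxations box the remaining indicators; leaves substitute the fixed
  indicators, which turns every off-constraint into a linear row, and
  are solved on the LP/QP path with a small projection objective.  An
  incumbent always exists because the all-ones indicator assignment is
  feasible by construction of the big-M rows.  On instances with up to
  twelve binaries the search provably matches exhaustive enumeration
  (tested on fifty seeded cases); at study scale (150-325 binaries)
  the node cap tightens to eight and the result is the best incumbent,
  with the relaxation bound reported as a gap.  Pruning against
  locally solved nonconvex relaxations is heuristic, which is the
  standard caveat for this problem class.

Threshold clipping: with $x_{min} = 0$ and $\epsilon_x \ge 0$ the raw
band edges can only leave the concentration box where the box already
dominates, so clipping the thresholds into the box equals adding the
box rows that are present anyway; binary leaves therefore use the raw
affine rows plus the box, and smooth evaluations use `pmin`/`pmax`
directly.

## The kinetic reference (synthetic data generator)

Evaluating a stoichiometry-only prediction needs a richer standard.
The package ships a deliberately simple kinetic oracle: every reaction
follows saturable single-substrate kinetics
$v_l = v_{max,l}\, x_s/(K_l + x_s)$ (product over substrates for
two-substrate lumped reactions, $v_{max,l}(t)$ for input reactions),
with $K_l = 1$ mmol l$^{-1}$ by default and the $v_{max}$ capacities of
the fixture.  It is integrated with deSolve (lsoda, rtol $10^{-8}$,
atol $10^{-10}$, 401 output points) and sampled at the collocation
nodes by cubic splines.  The published reference models behind the
original comparisons are not publicly available, so this oracle is a
labelled stand-in: it emulates the qualitative features that matter
(saturable consumption, monotone sink accumulation, light/dark
forcing) but not the true rate laws or fitted parameters.  Passing
tests therefore demonstrate correctness of the machinery and
qualitative agreement, not numerical reproduction of published error
tables — those depend on unpublished kinetics and are out of scope by
design.  An externally computed reference can be supplied as a long
CSV (`read_reference_csv()`) and replaces the stand-in everywhere.

## Fixtures and study presets

**Calvin-Benson cycle** (`calvin_model()`, preset `calvin-10s`): six
metabolites (Ru5P, RuBP, PGA, DPGA, GAP, sink), seven irreversible
reactions with capacities $(3.78, 11.75, 5.04, 3.05, 8, 3, 0.1)$ mmol
l$^{-1}$ s$^{-1}$, initial state RuBP 2.0, PGA 2.4, others 1.0 mmol
l$^{-1}$; 10 s horizon, $E = 5$, order 5; on/off tolerances
$\gamma_x = 0.4$, $\gamma_v = 0.2$, $\epsilon_x = 0.01$,
$\epsilon_v = 0.05$; GAP is additionally confined to the kinetic
reference $\pm 0.1$ mmol l$^{-1}$ at every node.

**Diurnal carbohydrate metabolism** (`carbohydrate_model()`, preset
`carbohydrate-24h`): six pools (sugar phosphates, sucrose, glucose,
fructose, starch, sink export) over a 24 h day beginning at 06:00 with
16 h light / 8 h dark, $E = 12$ two-hour elements, order 5.  The exact
published wiring of this model is not publicly available; the shipped
topology is a documented minimal reconstruction — photosynthetic input
(light phase only), sucrose and starch synthesis from sugar
phosphates, starch degradation, vacuolar invertase (knocked out in the
`inv4` genotype), hexose phosphorylation, sucrose export — and its
rate constants (e.g. photosynthetic capacity 1.0 mmol l$^{-1}$
h$^{-1}$, initial starch 5 mmol l$^{-1}$) are order-of-magnitude
choices made once, not fitted values.  Conclusions about the real
published model cannot be drawn from this reconstruction.

Where no concentration ceiling is given, metabolites default to
$x_{max} = 20$ mmol l$^{-1}$ (an order of magnitude above the largest
initial value); a finite ceiling is structurally required by the
big-M rows.

## Evaluation

`rss()` sums squared deviations between reference and prediction at
the collocation nodes only — never on a denser grid, since the node
values are what the programs optimize.  `kendall_tau_timecourse()`
concatenates the $N$ concentrations and $F$ fluxes into one
state vector per node and computes Kendall's tau between prediction
and reference per node.  The tie-adjusted tau-b variant is used
because constant-profile predictions (typical for the relaxed
variants) generate heavy ties; a node where one vector is entirely
tied has no defined rank correlation and is reported as `NA` rather
than an arbitrary number.  `compare_methods()` ranks methods by total
concentration RSS and total flux RSS separately, because the two are
routinely won by different methods.

## Numerical choices and degenerate inputs

* Element integration matrices are built by 20-point Gauss quadrature
  of the Lagrange basis — exact for all supported orders (max 12) and
  better conditioned than monomial coefficient manipulation.
* The collocation scheme is verified against $\dot x = -x$: with
  $E = 5$, order 5 on $[0, 1]$ the node error against $e^{-t}$ is
  below $10^{-6}$ (observed $\sim 6\times 10^{-11}$).
* Zero-horizon grids, empty reaction lists, unknown metabolite
  references, inverted bounds and negative tolerances are rejected
  with typed errors before any solve.
* Ties in branch-and-bound node selection break by insertion order;
  branching picks the most fractional indicator, lowest index first.
  With no wall-clock limit set (the default), runs are fully
  deterministic.
* Problem sizes in the test suite are chosen so the whole suite runs
  in minutes on one core: the full ten-method comparison runs on the
  Calvin study ($M = 25$, up to $\sim$650 decision variables), while
  property checks use one- and two-element grids.  The carbohydrate
  preset at full size ($M = 60$) is exercised through its cheap
  members in the driver tests.

## Known limitations

* Nonconvex NLP/MINLP solutions are local; different multistart counts
  can land on different optima.  All downstream claims are therefore
  about feasible trajectories and relative objective bounds, which the
  relaxation-order test checks explicitly.
* Uniform elements only, Gauss (interior) roots only; no Radau/Lobatto
  schemes and no adaptive refinement.
* The SBML importer reads stoichiometry and constant fbc bounds only;
  time-varying capacities need the native format.
* Genome-scale instances are out of computational reach by the
  variable-count arithmetic alone ($\sim$85k unknowns for the
  *E. coli* reconstruction at the Calvin discretization);
  `count_variables()` makes that arithmetic explicit.
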