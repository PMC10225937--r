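---
title: "Designing gene circuits with prescribed saddle-node structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing gene circuits with prescribed saddle-node structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifdesign)
```

## The design problem

A small gene regulatory circuit driven by an inducer signal $S$ can present
qualitatively different steady-state landscapes as $S$ varies: a unique
equilibrium, a hysteretic bistable switch, a *mushroom* (two separate
bistable signal ranges whose intermediate "ON" branch is reachable only at
intermediate signal), or an *isola* (a closed branch of equilibria,
disconnected from the rest of the diagram, whose exit is irreversible).
These structures are delimited by saddle-node (fold) bifurcations, where a
stable and an unstable equilibrium collide. `bifdesign` turns the desired
diagram into an optimization target: the user prescribes how many folds the
diagram must have and rectangular regions of the $(S, \omega)$ plane where
they must sit, and the package searches over both circuit wiring (integer
edge signs) and kinetics (real parameters) for designs that realize them.

## Circuit model

The superstructure has $N$ genes (2 or 3 here). Protein concentrations
$\omega_i$ follow thermodynamic promoter-occupancy kinetics

$$\frac{d\omega_i}{dt} \;=\; p_i\,\frac{N_i}{D_i} \;-\; d_i\,\omega_i,
\qquad
N_i = l_i + q_i(S) + \sum_{j:\,y_{ij}=+1} k\,\omega_j^2,
\qquad
D_i = 1 + N_i + \sum_{j:\,y_{ij}=-1} k\,\omega_j^2,$$

where $p_i$ is the promoter strength (concentration/time), $l_i \ge 0$ the
dimensionless leakiness, $d_i$ the degradation rate (1/time), and the
integer matrix $y$ encodes the wiring ($y_{ij} = \pm 1$: gene $j$
activates/represses gene $i$). All active regulatory edges share a single
interaction strength $k$ (1/concentration$^2$) and regulators bind as
dimers (exponent 2); self-edges follow the same rule. Signal-receiving
genes (by default the first two, U and V) gain an activating input
$q_i(S) = R_i S^2 / (K_i^2 + S^2)$ with Hill cooperativity 2, total
transcription-factor concentration $R_i$ and dissociation constant $K_i$.
Two standing assumptions reduce the search dimension: the leakiness of V is
tied to that of U ($p_3 = p_1$ in the flat design-vector notation), and
time is measured in units of U's protein lifetime ($d_u = 1$). Both can be
overridden per problem.

## Fold detection

With $f(\omega, x, y, S)$ the right-hand side above, the extended Jacobian
$Q = [D_\omega f,\; D_S f]$ is $N \times (N+1)$ and its unit null vector
$\beta$ is tangent to the equilibrium branch in $(\omega, S)$ space. At a
saddle node the branch turns back in $S$, so the last component vanishes;
the scalar objective

$$J = \beta_{N+1}^2$$

is zero exactly at a fold. For a target with $n_f$ folds at coordinates
$(\omega_k, S_k)$ the design objective is $\Psi = \sum_k J_k$, minimized
subject to the equilibrium conditions $f(\omega_k, S_k) = 0$, box bounds on
the design vector, and the rectangular target boxes. The derivatives in
$Q$ are analytic (closed forms of the occupancy kinetics), and the null
vector is computed by SVD with a degeneracy gate on the smallest singular
value; `refine_fold()` polishes approximate folds by Newton iteration on
the system $\{f = 0, \det D_\omega f = 0\}$, with the determinant scaled by
the product of row norms so the gauge is dimensionless.

## Tracing and classifying diagrams

Continuation from a single starting point cannot find an isola, which is
disconnected from every other branch. `trace_diagram()` therefore sweeps a
(log-spaced) signal grid and solves for *all* equilibria at each grid point
by damped Newton iteration from a dense seed lattice covering
$[0, p_i/d_i]$ per coordinate (8 points per axis by default), reusing the
previous grid point's roots as extra seeds. Equilibria at adjacent grid
points are linked into branches by stability-aware nearest-neighbor
matching (relative distance below 0.4); every change in the equilibrium
count is bracketed by bisection on the survival of the merging pair and
polished by the fold Newton solver. Duplicate folds are merged at relative
distance $10^{-3}$.

Classification is structural, not threshold-based:

* **mushroom** — 4 folds, two disjoint bistable signal ranges, and an
  intermediate stable branch that terminates at folds on both sides;
  the `inverted_mushroom` label applies when that branch sits at lower
  expression of the reporting gene (gene U by default) than the outer
  locus. Searches for "mushroom" accept both orientations, since the ON
  state is defined by branch identity rather than expression level.
* **isola** — 2 folds bounding a closed component (every member branch
  terminates at folds; the component never touches the signal-window
  edge) that passes the curvature test (the inverse branch function
  $S(u)$ curves away from the folds into the interior: positive curvature
  at the lower fold, negative at the upper, estimated by a quadratic fit
  through the 5 branch points nearest each fold), coexisting with a
  fold-free open branch.
* **bistable_switch** — 2 folds with one bistable range on open branches.
* **incomplete_mushroom_left/right** — 2–3 folds with the head truncated
  by the signal window; "incomplete" is always relative to the configured
  window, which defaults to the problem's signal bounds.
* **monostable** — no folds, one equilibrium everywhere; anything
  ambiguous is **other**.

## The search strategy

The mixed-integer problem is solved by a seeded multistart, each start
fully deterministic given its derived seed:

1. **Sample** a topology uniformly within the superstructure's edge-sign
   bounds, then design vectors log-uniformly within their bounds (printed
   working values span roughly $10^{-2}$–$10^3$, so log-uniform sampling is
   the natural prior) until a candidate shows multiple equilibria somewhere
   on a 21-point probe grid (up to 60 draws).
2. **Morph** the candidate by stochastic hill climbing in log-parameter
   space on a diagram-shape merit: interior bistable windows (up to the
   number of prescribed fold pairs) are rewarded most, monostable window
   edges next, then raw multistability. Proposals perturb a random
   3-coordinate subset (4 for three genes) with step 0.6; when 60
   proposals in a row fail, the climber restarts from the incumbent with a
   0.5 jitter, and it abandons the start after 220 proposals without a new
   best.
3. **Place the folds** by bounded Levenberg–Marquardt on the stacked
   residual (scaled equilibrium residuals and $\beta_{N+1}$ at each
   prescribed fold) over the log design vector and log fold coordinates,
   the latter confined to their target boxes. The fold system has fewer
   equations than unknowns, so weak Tikhonov rows ($10^{-4}(z - z_0)$)
   keep the least-squares system well posed and select the solution
   nearest the morphed candidate; they are far below the acceptance gates.
4. **Verify**: trace the diagram, classify it, check that the label
   matches the target, that the polished folds sit inside their boxes and
   that $\Psi \le 10^{-6}$. Minimizing $\Psi$ alone can collapse folds
   onto a cusp, which verification rejects.

Stages 1–2 play the role of a global diversification phase and stage 3 of
a local intensification step. The two-stage design replaces monolithic
metaheuristics with components whose behavior is fully reproducible from
the seed chain (master seed → per-run seed → all draws within the run).

Default bounds (promoter strengths [10, 2000], leakiness [1, 500],
$k \in [10^{-3}, 1]$, $R \in [50, 500]$, $K \in [1, 300]$,
$d \in [0.1, 10]$) cover every bundled working value. The default target
boxes follow the two-paired-regions convention — folds are constrained
pairwise, the low-signal pair to $S \in [0.5, 60]$ and the high-signal
pair to $S \in [5, 1500]$ — with a stricter expression range on gene U
(up to 300) than on the others (up to 800) to break the U/V symmetry of
the superstructure. The box coordinates were fixed once from the geometry
of the bundled reference diagrams (their folds sit at $S \approx 3.7$,
$19.5$, $28.8$ and $85$, with expressions between 8 and 220) and are wide
enough not to prejudge particular designs.

Isola targets use two folds plus curvature-sign conditions (positive at
$S_1$, negative at $S_2$); accepting a solution additionally requires the
closed-component test. Flipping the curvature signs removes the closed
component requirement's satisfiable geometry and the same machinery
verifies open bistable switches instead.

## Reference circuits

`reference_circuit()` bundles a two-gene wiring — cross-repression between
U and V plus a self-repression on U, both genes signal-induced — at four
parameter regimes: a mushroom (`A1_mushroom`), its neck pinched into an
isola by raising the leakiness to 200 (`A1_isola`), a re-opened mushroom
at leakiness 20 used to reset the state onto the isola (`A1_reset`), and a
second parameterization (`A3_base`) whose diagram morphs between all four
regimes as $(d_v, k)$ vary. The wiring was identified by screening all 72
connected two-gene structures under the generalized kinetics for the one
whose reference parameter values reproduce the 1–3–1–3–1 equilibrium-count
pattern of a mushroom; it is the unique such structure, and the same
wiring reproduces the isola and phase-map regimes.

A note on the pinching direction: for both bundled parameterizations the
neck folds collide as $d_v$ *decreases* (e.g. the mushroom at
$d_v = 1.38$ becomes an isola near $d_v \approx 0.9$ and monostable below
$\approx 0.5$), so the pinching demonstrations sweep $d_v$ downward. The
direction is a property of the circuit, not of the method; what matters is
that varying the degradation rate alone carries the diagram through
mushroom → isola → monostable without touching the topology.

## Dynamics

`simulate_circuit()` integrates the ODEs with `deSolve`'s stiff-capable
`lsoda`. Signal programs cover constant inputs, Gaussian pulses
$S(t) = S_{\min} + (S_{\max} - S_{\min}) e^{-\frac12 ((t - 100)/\tau)^2}$
(center fixed at $t = 100$, horizon $[0, 250]$ by default), and Wiener
paths precomputed at $dt = 0.01$ with diffusion $\sigma = 1.5$ by default
and clamped at zero — the noise drives only the signal, never the state
equations, so a stored path keeps runs exactly reproducible. The Wiener
step and diffusion are package defaults chosen so that a path started
between the isola folds (about $S = 14$–$50$ for the bundled circuit)
typically crosses one of them within a few hundred time units; both are
recorded in the signal object.

ON/OFF assignment is by branch identity: the mushroom head (or the closed
isola branch) is ON, the outer locus OFF, with a relative matching
tolerance of 0.05. Activation maps rest the circuit on the OFF branch at
the pulse baseline before each pulse. The isola memory demonstration
initializes on the closed branch by computing the ON state of the
re-opened mushroom (leakiness override 20 applied to the tied pair) and
relaxing it under the isola parameters; an exit event is the first signal
crossing of either fold. Because falling off the branch takes a few
protein lifetimes, a grazing crossing does not instantly dislodge the
state; the irreversibility property asserted by the tests is therefore
monotone — once the state has left the closed branch it never rejoins it,
even when the signal returns between the folds.

## Robustness and trade-offs

For each successful topology the verified design vectors form a solution
set. After standardizing all sets against the pooled mean and standard
deviation (so scores are comparable across topologies), two spread scores
are computed: the natural-log determinant of the sample covariance (a
hypervolume measure, requiring at least $d + 1$ solutions; singular
covariances raise a dedicated error rather than returning $-\infty$, so
ranking code must handle missing scores explicitly) and the sum of
per-parameter interquartile ranges (linear-interpolation quantiles,
defined for any $n \ge 4$). `bootstrap_scores()` resamples rows with
replacement (1000 replicates by default, seeded) and reports medians and
quartiles; replicates with singular covariance contribute only to the IQR
score and are counted. `robustness_vs_complexity()` pairs either score
with the connection count and computes the Pareto front (maximize
robustness, minimize connections) via the generic `pareto_front()`.
Multi-objective design uses the $\varepsilon$-constraint scalarization:
one criterion is minimized while the others are bounded by a swept
$\varepsilon$, with the fold-placement condition kept as a hard
constraint through verification.

## Problem sizes and what the tests show

The bundled demonstrations run at desk scale: the two-gene screen smoke
uses 500 starts (the full screen in the thousands of starts is the same
code with a larger `n_runs`), the three-gene screen 240 starts, parameter
recovery 200 starts, phase maps an 18-cell grid, and the pulse map a
3 × 4 grid. At these scales the screens find a handful of the two-gene
mushroom topologies (always including a cross-repression core) rather
than the full family of seven, and the three-gene screen demonstrates
that distinct topologies accumulate with runs rather than exhausting the
several-hundred-strong family. The synthetic solution sets used in the
robustness tests are Gaussian/uniform clouds with known covariance —
they validate the scores' closed-form identities, not the distributional
shape of real search output, whose spread is bounded by the search boxes
and is neither Gaussian nor independent across parameters.

## Numerical choices and limitations

Equilibria are deduplicated at relative distance $10^{-4}$; Newton
polishing targets machine-level residuals (scaled $10^{-10}$); fold
bisection runs 12 steps before Newton polishing; stability uses
Routh–Hurwitz conditions for up to three genes and eigenvalues beyond.
Degenerate points (cusps, rank-deficient extended Jacobians) raise typed
conditions that the search converts into large finite penalties. Known
limitations: the tracer's grid resolution bounds the narrowest detectable
neck (about one grid spacing — the default 80–90 point log grids resolve
neck-width ratios down to roughly 1.2); the hill-climbing merit cannot
distinguish an isola from a bistable switch (verification does); and
intrinsic gene-expression noise is outside scope — the Wiener term
perturbs only the extrinsic signal.
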