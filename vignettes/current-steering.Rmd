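---
title: "Current steering by constrained field optimization: model, numerics, and design choices"
author: "steerfield"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Current steering by constrained field optimization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(steerfield)
```

## The model

A multi-contact stimulation system delivers a total stimulus current split
across `n` contacts by dimensionless fractions `α`. Under quasi-static
conditions the tissue responds linearly, so any excitation field at a set
of points `X` is a superposition of unit-current basis fields,
`F(X, α) = Σ_j α_j f_j(X)`. Two field kinds are supported, chosen per
region by what predicts excitation there:

* the **activating function** `d²V/dr²` (V/m²) along the fiber direction
  `r`, which predicts excitation of axons of passage, and
* the **directional electric field** `−dV/dr` (V/m), which predicts
  excitation at axon terminals of local cells.

The program maximizes the *largest* field value over the region of
interest: a cell is recruited wherever the field first exceeds threshold,
so the peak — not the mean — is the right objective. Physical
realizability imposes two constraints on the fractions: the anodic
fractions sum to +1 and the cathodic ones to −1, equivalently
`Σ α_j = 0` and `Σ |α_j| = 2`.

Both the maximum operator and the absolute value are non-differentiable,
which would rule out Lagrange-multiplier methods. They are replaced by
smooth surrogates:

* `max_S(v, β) = Σ v_k e^{β v_k} / Σ e^{β v_k}` — the Boltzmann operator.
  For `β > 0` it lies between the mean and the maximum and converges to
  the maximum as `β` grows; `β < 0` tracks the largest *negative* value.
* `abs_S(α, γ) = α tanh(γ α)` — even, everywhere differentiable, never
  exceeding `|α|`, and uniformly convergent to it as `γ` grows.

The single-objective problem then reads: maximize `max_S(F(X, α), β)`
subject to `h₁ = 2 − Σ α_j tanh(γ α_j) = 0` and `h₂ = Σ α_j = 0`. Setting
the gradient of the Lagrangian `L = max_S − λ₁h₁ − λ₂h₂` to zero yields a
system of `n + 2` equations whose roots are *all* the constrained critical
points — maxima, minima and saddles — classified afterwards by the
sign-sequence test on the bordered Hessian. This is the decisive advantage
over heuristic search: minima (configurations producing a near-zero field,
useful for avoidance) and the complete set of tied optima come out of the
same computation.

With several regions, one objective is kept and every other region enters
as an inequality cap `max_S(F_i, β_i) ≤ ε_i` (the ε-constraint method).
The generalized Lagrangian adds KKT multipliers `μ_i ≥ 0`; a solution is
accepted only if it passes all four KKT conditions — primal feasibility of
every cap, the equality constraints, dual feasibility, and complementary
slackness (`validate_kkt()`). Sweeping `ε` traces the Pareto front even
where it is nonconvex, which a weighted-sum scalarization cannot do.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `beta` | auto | 1 / field units | Smooth-max scale. Chosen so `β·|F| ≈ 10` at the expected optimum, using the largest row-wise spread of the basis values as the scale estimate (`auto_beta()`). |
| `gamma` | 50 | — | Smooth-abs scale. At 50, fractions above ~0.05 are counted at their full absolute value to better than 1%. |
| `n_starts` | 200 | — | Latin-hypercube multistart size; fractions drawn in [−1, 1], multipliers in [−10, 10] (on the rescaled system, below). |
| `residual_tol` | 1e−10 | — | Max-abs residual for Newton convergence. |
| `dedup_tol` | 1e−4 | — | L∞ distance on corrected fractions merging duplicate solutions. |
| `n_eps` | 25 | — | ε grid size per capped region, spanning the region's achievable objective range. |

## Numerical strategy

**Rescaling.** Analytic point-source fields at millimeter distances are of
order 10⁶–10⁹ V/m² per ampere. Each region's basis matrix is divided by
its best-bipole spread before solving, so fields, multipliers and `β` are
order one; objectives and multipliers are mapped back exactly afterwards
(the problem is scale-covariant: scaling all fields by `c` scales
objectives and `λ` by `c` and leaves `α` unchanged). The ±10 multiplier
start bounds refer to this rescaled system.

**Continuation in `γ`.** The tanh constraint at `γ = 50` is stiff: cold
Newton starts stall on its transition region. Each random start is driven
through a five-stage geometric ramp `γ: 5 → 50`, warm-starting each stage
from the previous one.

**Why `β` is not pushed higher.** The exact objective `max_i F(X_i, α)` is
a maximum of linear functions of `α` — convex. Its constrained maxima
therefore sit at *vertices* of the balanced-fraction set, which the smooth
constraint rounds off. At `β·F ≈ 10` the smoothed problem still has
interior maxima with workable basins; sharpening `β` much further turns
them into fold saddles flanked by needle-thin true maxima that no
practical multistart finds. The default is therefore a single solve at the
`β·F ≈ 10` scale (`beta_rounds = 1`), with optional ×4 continuation for
users who want it.

**Vertex seeding.** The per-coordinate stationarity factor
`q(y) = tanh y + y sech² y` (with `y = γ α_j`) rises to ~1.20 at `y ≈ 1.2`
and falls back toward 1: small-fraction coordinates admit two roots, and
constrained maxima live on the *rising* branch while random starts
overwhelmingly converge to falling-branch saddles. The multistart is
therefore augmented with one deterministic start per ordered contact pair:
an ideal bipole whose multipliers are solved from its two active contacts
and whose remaining fractions are placed on the rising branch by a short
fixed-point iteration. These structured starts skip the `γ` ramp (they are
already final-scale). For arrays with more than ~9 contacts the seeds are
pruned to the 36 best and 36 worst pairs by exact bipole objective.

**Newton with a Levenberg fallback.** The stationarity Jacobian is
singular exactly at the fold of `q`, which neighbours the solutions; when
the damped Newton step fails there, a few regularized Gauss–Newton steps
(`(JᵀJ + μI) δ = −Jᵀr`, escalating `μ`) restore progress. Starts that
still fail to converge are discarded and counted.

**Classification conventions.** The bordered-Hessian minor test is used
when all tested minors exceed 1e−10 in magnitude; otherwise the Hessian of
the Lagrangian is projected onto the constraint tangent space and its
eigenvalues decide, ignoring near-zero eigenvalues. Two degenerate cases
are reported as (weak) maxima by convention: a zero-dimensional feasible
set (two contacts, where the constraints pin `α` completely) and a wholly
flat projected Hessian. The latter arises systematically on
mirror-symmetric geometries — a midline axon sees both leads identically,
so the basis matrix has duplicated columns and the optimum is a continuum
of equivalent splits across the leads; every point of the continuum is a
weak maximum and ranking by objective value disambiguates. "Invalid" is
reserved for rank-deficient constraint gradients.

**Post-processing.** The smooth constraints leave solver output slightly
off the exact balance laws; `correct_fractions()` rescales by
`2/Σ|α*|`, after which `Σ|α| = 2` holds at machine precision. Rounding to
3 significant digits (`round_fractions()`) absorbs the rounding residuals
into the largest positive and negative fractions so the anodic and
cathodic sums are exactly ±1 at the reported precision — within a budget
of `n` half-units in the last place, else an error. Among tied optima the
canonical representative is simply the first in the objective-sorted
output; all ties are reported.

**ε sweeps as homotopy.** `pareto_sweep()` solves the loosest cap with the
full multistart, then continues each tighter cap from the previous front's
KKT-valid points (top 5) plus a light fresh multistart (a tenth of
`n_starts`, no vertex seeds). Complementary slackness is resolved exactly
by enumerating all `2^(Q−1)` active sets per cap — exact and cheap for the
two- and three-region problems this package targets. Per-region objectives
on the front can be normalized by the region's own largest achievable
objective, either signed (`"signed"`) or in magnitude (`"absolute"`); the
latter matters when the desired field value is a large negative one, e.g.
an E-field objective steered with `β < 0`.

## What the built-in fixtures emulate — and what they do not

`make_two_lead_16()` emulates two parallel 8-contact percutaneous leads:
point sources at the contact centers, two z-aligned columns 4 mm apart
with 4 mm center-to-center pitch (3 mm contacts with 1 mm gaps), in a
homogeneous anisotropic white-matter medium (0.6 S/m longitudinal,
0.083 S/m transverse). Axon-line regions (161 points, 0.5 mm spacing,
spanning the array ±20 mm margins) sit at a 3 mm dorsoventral offset — a
documented choice, since the actual electrode-to-cord geometry through the
CSF is not reproducible in a homogeneous model. `make_cube8()` places
eight sources at the corners of a 10 mm cube with nested inner regions of
dimension 0 to 3, useful for the subset rule: a region that contains
another can never have a smaller optimal objective.

These fixtures deliberately omit what a finite-element volume conductor
provides: tissue compartments (CSF, gray matter, bone, fat), electrode
encapsulation, finite contact geometry, and boundary conditions. Passing
tests on them demonstrates the *optimization machinery* — stationarity,
classification, constraint handling, Pareto structure — not field-model
realism. For real applications, export unit-current fields from a FEM
solver (already differentiated along the fiber direction; this package
never differentiates sampled data) and load them with
`import_basis_fields()`.

## Degenerate inputs and edge behavior

* Region points coinciding with a contact raise a singular-evaluation
  error; zero or negative conductivities are rejected.
* An all-zero solved configuration cannot be corrected (degenerate); a
  solution with `|Σα| > 1e−6` violates the correction precondition.
* With two contacts the feasible set is the two ideal bipoles; the solver
  returns both, classified as (trivial) maxima, ordered by objective.
* If no start converges, the solvers return an empty list with a warning
  rather than an error; the workbench propagates this as empty outputs and
  a zero exit.

## Problem sizes used by the tests and the acceptance script

Module tests run on 2- and 4-contact problems (exhaustive balanced-grid
oracles at step 0.05 are enumerated exactly for n ≤ 4) and the 8-source
cube; the end-to-end checks use the 16-contact two-lead fixture with
200 multistarts for single solves, 10 000 seeded random baselines, and a
25-point ε sweep at 60 first-cap multistarts. The full suite completes in
about two minutes on one CPU, the acceptance script in about one.

## Known limitations

* Point-source contacts ignore the finite 3 mm contact geometry; absolute
  field magnitudes on the fixtures are not FEM-grade.
* Activation thresholds are not computed: objectives are field surrogates
  for excitability, not membrane-model thresholds.
* Active-set enumeration scales as `2^(Q−1)`; practical for a handful of
  regions, not for dozens.
* The smoothed problem's optimum differs from the exact-constraint
  optimum by design; the reported exact objectives are evaluated at the
  smoothed solution after correction, and the grid-oracle tests bound this
  gap at 2% on the 4-contact problems.
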