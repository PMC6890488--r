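---
title: "Adaptive moving-mesh evolution of closed plane curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive moving-mesh evolution of closed plane curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(curveflow)
library(ggplot2)
```

## The problem

Many moving-boundary problems — cell-membrane motion in models of eukaryotic
cell migration, geodesic active contours in image analysis, grain-boundary
motion in materials — reduce to evolving a closed plane curve $\Gamma(t)$
with a normal velocity of forced curve-shortening type,

$$V = \dot{\mathbf x}\cdot\mathbf n = \alpha(\mathbf x, t)\,\kappa
      + \beta(\mathbf x, t),$$

where $\kappa$ is the signed curvature, $\alpha \ge 0$ weights the
curvature-driven smoothing and $\beta$ is an external forcing. Tracking the
curve with marker particles that move only normally fails in practice:
nodes pile up where normals converge and starve regions of high curvature,
degrading accuracy until the computation breaks down. `curveflow`
implements a sharp-interface polygon evolver that adds a *tangential* node
velocity derived from a moving-mesh PDE, so that the nodes continuously
redistribute themselves while the shape itself — which only depends on the
normal velocity — is untouched.

## Tangential velocity from mesh equidistribution

Let $M(\mathbf x, t) > 0$ be a monitor function expressing where resolution
is wanted. A parameterisation $\mathbf x(\xi, t)$, $\xi \in [0,1]$,
equidistributes $M$ when $M\,|\mathbf x_\xi|$ is constant along the curve,
i.e. equal amounts of the weighted arc-length $M\,ds$ sit between
consecutive nodes of a uniform $\xi$-grid. Relaxing the mesh towards this
state by a gradient flow of the equidistribution functional gives the
tangential velocity

$$\dot{\mathbf x}\cdot\mathbf t
  = \frac{P}{\tau\,(M |\mathbf x_\xi|)^2}\,(M|\mathbf x_\xi|)_\xi,$$

with two tunables:

* $\tau > 0$, the **mesh relaxation time** (dimensionless here, like all
  quantities): small $\tau$ re-equidistributes within a few steps, large
  $\tau$ lets the mesh lag. Too small a $\tau$ relative to $\Delta t$
  makes the nonlinear solver struggle or fail.
* $P$, a positive **spatial balancing operator**. `p_mode = "identity"`
  ($P = 1$) is plain steepest descent; `p_mode = "balanced"`
  ($P = M|\mathbf x_\xi|^2$) rescales the relaxation rate uniformly along
  the curve. Discretely we take
  $P_i = M_i\,(|\mathbf x_{i+1}-\mathbf x_{i-1}|/(2\Delta\xi))^2$ with the
  $\Delta\xi$ scaling retained, which keeps the meaning of $\tau$
  independent of the resolution $N$; the balanced form tolerates much
  larger $\tau$ and is the default.

## Monitor functions

`monitor_spec("uniform")` ($M = 1$) targets a uniform arc-length mesh.
`monitor_spec("curvature")` targets

$$M = \tfrac12\left(M_{\text{floor}} + |\kappa|^\gamma\right),
\qquad
M_{\text{floor}} = \frac{1}{|\Gamma|}\int_\Gamma |\kappa|^\gamma\,ds,$$

with $\gamma = 1/2$ by default: equidistributing $|\kappa|^{1/2}$
minimises (to leading order) the maximal distance between the smooth curve
and its polygonal interpolant, which is why a curvature-weighted mesh
yields visibly smaller area errors than a uniform arc-length mesh of the
same size. Exponents $1/3$ (enclosed-area discrepancy) and $2/3$ (length
discrepancy) are available through `exponent`. The floor — the curve
average of $|\kappa|^\gamma$, recomputed from the current polygon at every
evaluation so it adapts to the evolving length — keeps the density
positive on flat segments without any hand-chosen parameter. Monitor
values are smoothed by a periodic weighted average with weights
$(q/(q+1))^{|k|}$, $|k| \le p$ (defaults $p = 2$, $q = 3$, i.e. weights
$9/16, 3/4, 1, 3/4, 9/16$); smoothing is applied at every monitor
evaluation, inside both the time stepper and the initial-mesh generator,
and can be disabled for testing. For the uniform monitor smoothing is the
identity and is skipped.

## Discretisation

The polygon stores $N$ distinct nodes with periodic index arithmetic and
uniform parameter step $\Delta\xi = 1/N$. Per node, central differences
give the unit tangent $\mathbf t_i$ from the chord
$\mathbf x_{i+1}-\mathbf x_{i-1}$, the normal
$\mathbf n_i = (t_2, -t_1)$, and the curvature

$$\kappa_i = \frac{4\,(\mathbf x_{i-1} - 2\mathbf x_i + \mathbf x_{i+1})
             \cdot \mathbf n_i}{|\mathbf x_{i+1}-\mathbf x_{i-1}|^2}.$$

With counterclockwise node order this normal points outward and convex
curves have $\kappa < 0$, so $V = \kappa$ shrinks them — the sign
convention is fixed by the shrinking-circle exact solution and no flip is
applied anywhere.

Each time step solves a coupled $2N \times 2N$ system: per node, the
implicit normal equation (backward Euler, or Crank–Nicolson in the hybrid
`"cnbe"` scheme, which keeps backward Euler for the better-damped
tangential equation) and the implicit tangential equation, each a
three-node stencil projected on the lagged normal and tangent directions.
The Crank–Nicolson equation uses the *average* of the previous-level and
current-iterate normals, deliberately not re-normalised to unit length.
The nonlinearity (coefficients depend on the unknown geometry) is resolved
by Picard iteration: geometry is lagged one iterate, the linear system is
solved exactly, and the iteration stops when the maximal nodal
displacement between consecutive iterates drops below `picard_tol = 1e-6`
(initial guess: the previous level). Monitor and balancing values are
always taken from the previous time level, so mesh adaptivity never feeds
back within a step. The linear solve is a purpose-written $O(N)$ cyclic
block-tridiagonal direct elimination with $2\times 2$ blocks
(condensation on the last node plus a block Thomas sweep); the blocks are
built from a near-orthonormal tangent/normal pair, so unpivoted
elimination is well conditioned, and the solve is verified against a dense
reference factorisation in the test suite at residuals below $10^{-12}$.

If the Picard iteration exhausts its budget (200 iterations) the run
stops and reports status `"singularity"` with the failure time — for a
fully implicit scheme this is precisely what happens as the curve
approaches a geometric singularity, and the failure time is a useful
detector of it. Setting `picard_cap` (1 for BE, 2 for CNBE) instead
performs a fixed number of iterations per step regardless of convergence;
this semi-implicit mode can step *across* such a singularity.

## Initial meshes by de Boor equidistribution

A good initial mesh matters: starting from a badly distributed mesh forces
a burst of rapid tangential motion that costs accuracy and robustness.
`make_curve()` therefore samples its parametric generators through an
iterated de Boor algorithm: sample the curve on the current partition of
$u \in [0,1]$, evaluate the (smoothed) monitor on the sampled polygon,
form the per-cell density $\rho_j = M(u_{j+1/2})\,|\mathbf x_u|_{j+1/2}$
at cell midpoints (analytic derivative when the generator has one, else
central differences on a 10× refined local sample), and invert the
piecewise-linear cumulative integral of $\rho$ at uniform mass targets.
Iteration stops when the maximal partition update falls below
`tol = 1e-10` (default; `max_iter = 100`), values chosen so the partition
is converged to well below the spatial discretisation error at all sizes
used here; non-convergence is carried as a warning flag on the result
rather than an error since the iteration is convergent but can be slow.

One subtlety worth knowing: the de Boor fixed point equidistributes the
*cell integrals* of $M(u)|\mathbf x_u|$, while the
`equidistribution_ratio()` diagnostic weighs polygon *chords*. The two
quadratures agree only up to $O(1/N^2)$, so the diagnostic of a freshly
generated mesh sits at $1 + O(1/N^2)$, not at $1 + O(\text{tol})$ — the
test suite checks exactly this second-order shrinkage.

## Benchmark shapes and error measures

The built-in generators (`circle`, `ellipse` with axes 3 and 1,
`nonconvex` star-like lobes, the self-intersecting `selfintersect`, and
the rounded-square `lpball` with exponent $p = 10$) are the standard test
set for tangentially stabilised curve evolvers; all are sampled
counterclockwise on $[0,1)$. There are no external data: every input is
generated from these closed forms.

Accuracy is measured through the enclosed polygon area (shoelace formula),
because the exact area is known in closed form for *any* curve under
$V = \kappa$: it decreases at exactly $2\pi$ per unit time. The error
norms are the discrete $L^2([0,T])$ norm of the area error and the
absolute final-time error; convergence orders are least-squares slopes in
log–log coordinates. For forced flow ($\beta \ne 0$) no closed form
exists and the reference is a self-generated gold standard: same mesh,
CNBE, time step ten times smaller than the finest compared run.

## What the studies show

Problem sizes below are the defaults of the `study_*()` drivers, chosen to
match the benchmark configurations while keeping a full suite run in
minutes on one core.

* **Circle** ($N = 10^4$, $T = 0.25$, $N_T = 10\ldots160$; spatial sweep
  $N = 160\ldots2560$ at $N_T = 10^4$): BE converges at first order, CNBE
  at second order in time and space, with CNBE strictly more accurate at
  every resolution. Picard costs are small (2–6 iterations) and decrease
  with temporal refinement. Because the monitor is constant on a circle,
  the area trajectory is invariant to the monitor kind, $\tau$, and $P$ —
  a direct check that tangential motion does not alter the shape.
* **Ellipse** ($N = 160$, $N_T = 10^4$, $T = 1.4$, $\tau = 10$, balanced
  $P$): the curvature-based monitor gives a strictly smaller $L^2$ area
  error than the uniform arc-length monitor (measured here:
  $6.4\times10^{-4}$ vs $2.8\times10^{-3}$).
* **Self-intersecting curve** ($N = 10^3$, $\Delta t = 10^{-5}$,
  $\tau = 10^{-3}$, $M = 1$): the fully implicit CNBE run marches
  smoothly through $t = 0.0829$ and first fails Picard convergence at
  $t \approx 0.0859$, detecting the finite-time singularity; the
  `picard_cap = 2` run steps straight past $t = 0.086$.
* **Forced $l_p$-ball** ($V = \kappa + 10$, $N = 160$, $T = 0.05$,
  $N_T = 40\ldots160$, gold standard at $N_T = 1600$): BE slope
  $\approx 0.96$, CNBE slope $\approx 1.90$ against the gold standard.

```{r, eval = FALSE}
tab <- study_circle_temporal()
tab |>
  dplyr::group_by(scheme) |>
  dplyr::summarise(order = convergence_order(n_steps, l2_error))
```

## Numerical choices and edge cases

* Unknowns are interleaved $(x_1, y_1, \dots)$; this is internal.
* The Picard update norm is the maximum over nodes of the Euclidean
  displacement — the strictest common reading of an unnormed tolerance,
  and scale-free per node.
* A zero central chord ($\mathbf x_{i+1} = \mathbf x_{i-1}$) is reported
  as a degenerate-geometry failure naming the node; inside the time
  stepper it is treated like Picard non-convergence (singularity signal).
  Self-intersection as such is *not* detected — the self-intersecting
  benchmark is evolved as is.
* The iteration count reported per step is the number of linear solves
  performed; a step whose first solve already satisfies the tolerance
  counts 1 (this happens exactly at fixed points, e.g. zero velocity on a
  regular polygon).
* Discrete curvature of the printed central-difference formula suffers
  double-precision cancellation $\sim \varepsilon/\Delta\theta^2$; at
  $N \sim 10^3$ agreement with closed forms saturates around $10^{-10}$
  relative. This bounds what any implementation of the formula can
  achieve in doubles.
* Everything is deterministic: no randomness enters anywhere, and runs
  are bit-reproducible for a fixed linear-solver implementation.

## What the generators do not emulate

The benchmark shapes are smooth analytic curves; the package does not
model measurement noise on node positions, image-derived forcings, open
curves, topology changes through the singularity, or coupling of the
interface to bulk fields. Passing the studies here shows the geometric
solver and mesh adaptation behave as designed on clean closed curves — it
says nothing about segmentation-quality inputs, for which the CSV polygon
reader (`read_curve()`) is the entry point but no robustness machinery is
provided.

## Known limitations

* Fixed time step; Picard non-convergence could drive adaptive time
  stepping, but does not (the failure is reported instead).
* Monitor functions are geometric only; solution-field monitors (e.g.
  membrane-bound concentrations) are not implemented.
* One space dimension of mesh equidistribution; no surfaces.
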