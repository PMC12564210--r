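---
title: "Methods: lattice SCF modelling of comb and double-comb bottle-brushes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lattice SCF modelling of comb and double-comb bottle-brushes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brushscf)
```

## The physical model

`brushscf` models a cylindrical molecular bottle-brush: identical comb or
double-comb grafts tethered by the first segment of their main chain to a
straight backbone, at axial spacing `h` (grafting density
`sigma = a/h`, with `a` the monomer size, the length unit throughout;
energies are in units of `kBT`).  The model makes four structural
assumptions.

1. **Cylindrical symmetry.**  Excluded-volume repulsion between grafts
   stretches the backbone over scales much larger than the brush
   cross-section, so density varies only radially.  All fields live on
   cylindrical shells `z = 1, ..., zmax`.
2. **Phantom backbone.**  The backbone occupies the axis (`z = 0`) but
   has no excluded volume of its own; in a strongly overlapping brush its
   direct contribution is negligible.  Polymer steps directed into the
   axis are reflected back into shell 1.
3. **Freely jointed chains in a mean field.**  Graft conformations are
   random walks on a cubic lattice weighted by `exp(-u(z))` per segment;
   orientational correlations beyond one step are neglected.
4. **Incompressibility with a monomeric solvent.**  Polymer and solvent
   fill every site: `phi(z) + phi_s(z) = 1`, enforced by a Lagrange
   multiplier field `alpha(z)`.  In the athermal default (`chi = 0`)
   the segment potential is `u = alpha` and the solvent weight is
   `phi_s = exp(-u)`, normalised to 1 in the polymer-free far field.

A graft is described by six integers (`graft_architecture()`): `P1`
branch points spaced `m1` apart carrying side chains of length `n1`
(proximal domain), then `P2`, `m2`, `n2` (peripheral domain).  Total
monomers `N = P1 (n1 + m1) + P2 (n2 + m2)`; main-chain length
`Nb = P1 m1 + P2 m2`.  Side chains attach to the *last* rank of each
spacer, which makes the "root spacer" (the `m1` ranks between the
grafting point and the first branch point) well defined — its stretching
is the observable reported by `first_branch_distribution()`.

The branching strength of a comb enters the analytic theory through the
topological ratio `eta = sqrt(1 + n/m)`: the side-chain load per spacer
softens the effective Gaussian elasticity of the comb, and `eta = 1`
recovers the linear chain.

## Lattice geometry

The shell `z` spans radii `[z - 1/2, z + 1/2]`, giving the dimensionless
area `L(z) = 2 pi z`.  Step weights start from the cubic-lattice
fractions `(1/6, 4/6, 1/6)` and are modulated by interface-to-shell area
ratios, `lambda_±(z) = (1/6)(z ± 1/2)/z`, which leaves `lambda_0 = 2/3`
and satisfies detailed balance
`L(z) lambda_+(z) = L(z+1) lambda_-(z+1)` **exactly** — the property that
makes one averaging step conserve shell-weighted mass and makes the chain
partition function identical whether propagated from the grafted or the
free end.  Both boundaries reflect (their outward weights are folded into
`lambda_0`).

This radii convention is the simplest one with cylindrical growth; others
(e.g. shells `[z-1, z]`, `L = pi(2z - 1)`) shift profiles by at most half
a layer.  The choice is a convention, not a fitted quantity.

`zmax = "auto"` sizes the box to 1.6 times the analytic dead-zone outer
edge `z0 + H` (plus a 5-shell margin), capped by the maximal radial reach
`Nb + 2` of the graft; a converged fit warns if `phi(zmax) > 1e-6`.

## Propagators for branched grafts

Per-shell, per-site statistical weights are built by the recursion
`q(t, z) = G(z) B_t(z) <q(t-1)>(z)` with `G = exp(-u)` and `<.>` the
step-weight average.  At a branch rank, the side-chain factor
`B_t = <qs_n>` (the averaged free-end side-chain propagator) enters
exactly once; identical side chains within a domain are propagated once
and reused.  Rank densities compose as
`phi_t = sigma * q_fwd q_bwd / (G B_t)` normalised per rank, which
enforces `sum_z phi L = N sigma` to machine precision and doubles as the
under/overflow guard (each rank is max-renormalised, with the logs
accumulated into `ln Q`).

The composition rule for branches is not uniquely dictated by the mean
field equations alone, so it is locked by two independent test families:
exhaustive enumeration of all lattice walks for chains of up to 4
segments (linear and branched, in random fields, agreement to `1e-12`)
and the end-symmetry identity `ln Q_fwd = ln Q_bwd` for random branched
architectures.

## Self-consistent iteration

The Lagrange field is initialised to zero and iterated against the
incompressibility residual `g = phi + phi_s - 1` until
`max|g| <= 1e-8` (default `tol`).  Two updaters are provided:

* `mixing = "picard"`: `alpha <- alpha + h_mix * g` with
  `h_mix = 0.2 < 1/2`, the classical relaxation.  Robust but slow — on
  the dense preset brushes it needs on the order of `1e4`–`1e5`
  iterations.
* `mixing = "anderson"` (default): Anderson mixing with a depth-5
  difference history, damping `h_mix`, three plain warm-up steps, and a
  restart-from-best guard if the residual grows by two orders of
  magnitude.  It reaches `1e-8` in 20–50 iterations on every preset in
  the package and converges to the same fixed point as Picard (asserted
  in the tests to `1e-6`).

Both are fully deterministic; there is no randomness anywhere in the
solver.  The field is clamped to `|alpha| <= 8`, far above any physical
value here (`u` of order 1 at most) but low enough that the within-row
dynamic range of a 75-segment side-chain propagator stays representable
in double precision.  Non-convergence raises an error carrying the last
residual unless `must_converge = FALSE`; `free_energy()` refuses
unconverged fits.

The per-graft free energy is evaluated as
`F = -ln Q - (1/sigma) sum_z u(z) phi(z) L(z)` on the converged fields —
the negative log partition function minus the work done by the field,
zero for an isolated ideal graft.

## Dead-zone theory

In a convex brush the parabolic potential cannot support free ends near
the axis.  The analytic model pieces together an inner zone
`phi = (3 A sigma^2 eta^2 / (16 nu pi^2 z^2))^(1/3)` on `(0, z0]` — only
the comb main chain stretches there, side chains relax — and an outer
parabola `phi = K (H^2 - (z - z0)^2)` carrying the fraction `X` of the
monomers, with three matching conditions: continuity at `z0` and the two
zone mass normalizations (`(1-X) N sigma` inner, `X N sigma` outer).

`dead_zone_solve()` eliminates `z0(X)` and `H(X)` through the first two
conditions and root-finds `X` in `(0, 1)` on the residual of the third.
Reducing the system by hand gives the closed form (kept as an independent
cross-check, `solve = "closed_form"`): with `c = 2 pi / (3 sqrt(A))` and
`t = (1 - X)/X`,

    t = 3 / (9 c^2 - 8 c),      z0 / H = c t,

so the partition depends on `A` only.  At `A = 1.45` this yields
`X = 0.8161` and `z0/H = 0.3920` — about 82% of the mass peripheral, 18%
in the dead zone.  No partition exists for `A >= (3 pi / 4)^2 ~ 5.55`
(`c <= 8/9`), which the function reports as a domain error.  Both zone
widths scale as `N^(3/4) sigma^(1/4) eta^(-1/2)`.

The scaling factor `A` is a box-model calibration constant, not derived
from first principles.  `fit_amplitude_A()` estimates it from simulated
profiles by least squares on `log phi` in the window
`z in [2, 0.8 z0]` (per-profile `z0` from the end distribution), jointly
across profiles: the model is log-linear in `log A` with fixed slope
`-2/3`, so the joint estimator reduces to a closed-form mean.  The first
shell is excluded because the lattice discretisation of the `z^(-2/3)`
singularity is least faithful there; the window rule and its sensitivity
are part of the fit report.

## Observables and estimator conventions

* **Moments** (`mean_H`, `mean_He`): first radial moments with the
  cylindrical weight, discretised on shell centres (midpoint rule,
  `O(1/H^2)` accurate; the exact-parabola check reproduces `8H/15` to
  0.1% at `H = 150`).
* **Numeric dead-zone width** (`dead_zone_width`): radius below which
  the cumulative end fraction is under 1%, linearly interpolated on
  shell edges.  The analytic boundary draws the conventional `z0`; a
  numeric estimator needs a threshold, and because the cumulative
  fraction rises steeply at the zone edge the estimate moves by well
  under a shell between thresholds of 0.5% and 2%.
* **Axial force** (`axial_force`): `f = -dF/dh` by finite differences
  over an integer `h` grid.  The default estimator uses two-point
  differences reported at interval midpoints: for an exact
  `F ~ h^(-1/2)` law its log-log slope bias on the unit grid is below
  0.03, whereas the three-point central stencil at integer `h` biases
  the slope by about `-0.11` at `h = 2` (the `±1` stencil is too coarse
  where the power law is steep).  The central variant is retained as
  `method = "central"` for comparison.
* **Induced persistence length** (`persistence_length`):
  `lp = F H^2 / h` with `H = (15/8) mean_H` (the parabolic relation
  inverted on the measured mass moment) and unit prefactor.  This is a
  convention: only scaling exponents and relative comparisons are
  meaningful, which is how the packaged analyses use it.  The printed
  closed form `persistence_length_analytic()` (`0.046 N / h^2`) absorbs
  a bending-expansion constant and has a different `N` scaling than the
  `F H^2 / h` route; it is provided as the literature formula, again for
  scalings only.

## Preset experiments and problem sizes

The presets are the package's study conditions, fixed once:

* `comb_quartet`: graft main chain 500, `m = 5`, `n = 0, 15, 40, 75`
  (`eta = 1..4`), `N sigma = 500`.  Grafts range from `N = 500` to
  `N = 8000`; lattices up to ~220 shells.
* `force_sweep`: comb `m = 3`, `n = 25`, 20 side chains (`N = 560`),
  `h = 1..9`; slopes read on `h in [2, 8]`.
* `moment_grid`: `sigma in {0.1, 0.5, 1, 2}` times
  `eta in {1, 1.5, 2, 2.5, 3}` realised as `n/m` with `m = 4`
  (`n = 0, 5, 12, 21, 32`), `P` chosen so `N` is within 1% of 1000
  (the exact `N` per run is reported; topology is never silently
  adjusted to force a round number — the same policy as for the
  double-comb family, where the explicit architecture `P1 = P2 = 10`,
  `m = 3`, `n1 + n2 = 50` gives `N = 560` per graft and is reported as
  such).
* `double_comb`: `n1 = 0, 13, 25, 37, 50` with `n1 + n2 = 50` at
  `sigma = 0.5` (integer side chains make exact quarter splits of 50
  impossible; the nearest integers are used).

With Anderson mixing every preset converges in well under a minute in
total; the full test suite, which reruns all of them, completes in tens
of seconds.

## What the model does and does not capture

The package emulates athermal, neutral, flexible brushes with annealed
(equilibrium) conformations.  Passing tests therefore demonstrate
internal consistency of the mean-field model and agreement with its
analytic limit — not quantitative accuracy for real aggrecan–hyaluronan
complexes, which additionally involve polyelectrolyte effects
(GAG chains are strongly charged; screening and counterion osmotics
dominate real swelling), finite chain stiffness, backbone excluded
volume, and possibly liquid-crystalline ordering at semidilute
concentrations.  Also out of scope: explicitly bent backbones (the
persistence length here comes from the straight-brush free energy
scaling, not from simulating curvature), the third-virial term in the
analytic profiles, and polydisperse or dendronized grafts.

Within scope, the known limitations are: lattice-convention dependence
of profiles at the half-layer level; the 1% threshold convention inside
`dead_zone_width()`; and mean-field neglect of correlations, which is
most severe at low grafting density where the cylindrical blob picture
would apply.
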