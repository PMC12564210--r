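# brushscf

Lattice self-consistent field (SF-SCF) modelling of cylindrical molecular
bottle-brushes whose grafts are **comb** or **double-comb (aggrecan-like)**
polymers, together with the matching analytical brush theory.

## The problem

Aggrecan–hyaluronan complexes in articular cartilage are natural
"bottle-brushes of brushes": comb-shaped proteoglycans (aggrecan monomers)
tethered along a hyaluronan backbone, each carrying two block-wise domains
of glycosaminoglycan side chains — shorter keratan-sulfate chains near the
junction, longer chondroitin-sulfate chains at the periphery.  Synthetic
double-comb (DC) bottle-brushes mimic this architecture.  `brushscf` is
for polymer physicists and biomimetic-materials researchers who want to
predict, from the graft topology alone, how such brushes organise radially
and how stiff the assembly becomes:

* radial volume-fraction profiles `phi(z)` and the **"dead" zone** — the
  end-free region around the backbone of any convex brush, where the
  density decays as `z^(-2/3)` instead of following the parabolic law;
* radial distributions of the graft main-chain **free ends** and of the
  **first branch point** (root-spacer stretching, a proxy for the normal
  force at the graft junction);
* brush thickness moments, the **axial tension** `f(h) ~ h^(-3/2)` the
  grafts impose on the backbone, and the **induced persistence length**
  `lp ~ h^(-2)`.

## The model

One graft is a comb: `P1` branch points spaced `m1` monomers apart carrying
side chains of length `n1` (proximal domain), followed by `P2`, `m2`, `n2`
(peripheral domain); total monomers `N = P1 (n1 + m1) + P2 (n2 + m2)`.
Grafts are tethered at spacing `h` (grafting density `sigma = a/h`) to a
straight phantom backbone, and the system is resolved on cylindrical
shells `z = 1, ..., zmax` of a cubic lattice with shell areas
`L(z) = 2 pi z`.  Chains are freely jointed in the self-consistent field
`u(z)`; propagators for the branched grafts are built by recursive
nearest-layer averaging (detailed-balance step weights), and the
incompressibility constraint `phi(z) + phi_s(z) = 1` is enforced by a
Lagrange multiplier field iterated to `max|phi + phi_s - 1| <= 1e-8`.
The per-graft free energy is `F = -ln Q - (1/sigma) sum_z u phi L`.

The companion analytical theory matches the inner power-law zone
`phi = (3 A sigma^2 eta^2 / (16 nu pi^2 z^2))^(1/3)` to an outer shifted
parabola through three conditions (continuity plus the two zone mass
normalizations), where `eta = sqrt(1 + n/m)` is the topological ratio of
the comb and `A` the dead-zone scaling factor.  Solving the system gives a
universal partition: at the best-fit `A = 1.45`, the peripheral zone holds
`X = 0.816` of the monomers and `z0/H = 0.39`, independent of `N`,
`sigma` and `eta`.

## Worked example

An aggrecan-like double comb: 20 secondary side chains on every third
main-chain unit, proximal-heavy split `n1 = 40`, `n2 = 10`, grafted at
`h = 2a`:

```r
library(brushscf)
arch <- double_comb_graft(P = 10, m = 3, n1 = 40, n2 = 10)
fit  <- scf_brush(arch, sigma = 0.5)
fit
#> Cylindrical SF-SCF brush fit
#> Graft architecture (double comb)
#>   proximal : P1 = 10, m1 = 3, n1 = 40
#>   peripheral: P2 = 10, m2 = 3, n2 = 10
#>   N = 560 monomers per graft, main-chain length Nb = 60
#>   sigma = 0.5 (h = 2 a), chi = 0, zmax = 62 shells
#>   converged after 32 iterations, residual 9.46e-09
#>   lnQ = -94.251745, free energy F = 26.538893 kBT per graft

round(coef(fit), 4)
#>          F        lnQ     mean_H    mean_He         z0         lp
#>    26.5389   -94.2517    17.2630    27.1164    15.9093 13902.4093
```

The graft pays `F = 26.5 kBT` relative to an isolated ideal chain; the
brush mass sits at a mean radius of `17.3 a` while the main-chain free
ends sit further out (`27.1 a`), excluded from the inner `z0 = 15.9 a`
(the numeric dead-zone width, 1% cumulative end fraction).  The matching
analytic partition:

```r
dead_zone_solve(A = 1.45, N = 560, sigma = 0.5, eta = topological_ratio(10, 3))
#> Dead-zone brush partition
#>   A = 1.45: X = 0.8161 (peripheral mass fraction), z0/H = 0.3920
#>   N = 560, sigma = 0.5, eta = 2.082, nu = 0.5:
#>   z0 = 12.160 a (dead zone), H = 31.023 a (peripheral zone)
```

`plot(fit)`, `plot(fit, "ends")` and `plot(fit, "potential")` draw the
density, end-distribution and `U(z)` vs `z^2` profiles;
`brush_sweep()` + `axial_force()` / `persistence_length()` produce the
scaling laws; `run_experiment("comb_quartet", out = "out/")` reruns a
whole preset family and writes provenance-tagged TSV/JSON output.

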