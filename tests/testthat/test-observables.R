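# Moment estimators, dead-zone width estimator, force and persistence
# length observables.

test_that("radial first moments are exact on delta and discrete profiles", {
  lat <- cylindrical_lattice(20)
  d7 <- numeric(20); d7[7] <- 2.3
  expect_equal(mean_H(d7, lat), 7)
  d10 <- numeric(20); d10[10] <- 1
  expect_equal(mean_He(d10, lat), 10)
  # two equal-volume-fraction deltas at 4 and 8: L weighting makes the
  # weights proportional to z, so the moment is (16 + 64) / (4 + 8)
  d2 <- numeric(20); d2[c(4, 8)] <- 1
  expect_equal(mean_H(d2, lat), 20 / 3)
  # uniform profile on 1..H: discrete moment is (2H + 1)/3 ~ (2/3) H
  H <- 60
  latH <- cylindrical_lattice(H)
  expect_equal(mean_H(rep(1, H), latH), (2 * H + 1) / 3)
  expect_lt(abs(mean_H(rep(1, H), latH) - 2 * H / 3), 1)
})

test_that("mass moment of an exact parabolic profile is 8H/15", {
  H <- 150
  lat <- cylindrical_lattice(H + 10)
  z <- seq_len(H + 10)
  phi <- pmax(H^2 - z^2, 0)
  expect_equal(mean_H(phi, lat), (8 / 15) * H, tolerance = 1e-3)
})

test_that("moment errors are explicit", {
  lat <- cylindrical_lattice(10)
  expect_error(mean_H(rep(0, 10), lat), "no mass")
  expect_error(mean_H(c(-1, rep(1, 9)), lat), "non-negative")
  expect_error(mean_H(rep(1, 5), lat), "mismatch")
})

test_that("dead-zone width estimator brackets a shifted support", {
  lat <- cylindrical_lattice(30)
  g <- numeric(30); g[12:20] <- 1
  z0 <- dead_zone_width(g, lat)
  expect_gt(z0, 11); expect_lt(z0, 12)
  expect_error(dead_zone_width(rep(0, 30), lat), "no mass")
  # monotone in the threshold
  ths <- c(0.005, 0.01, 0.05, 0.2)
  z0s <- sapply(ths, function(t) dead_zone_width(g, lat, threshold = t))
  expect_true(all(diff(z0s) >= 0))
})

test_that("axial-force estimators recover a known power law", {
  # synthetic sweep carrying an exact F = 10 h^(-1/2) free energy
  h <- 1:9
  sw <- structure(list(table = data.frame(h = h, F = 10 * h^(-0.5)),
                       arch = comb_graft(2, 2, 1)),
                  class = "brush_sweep")
  fo <- axial_force(sw)                     # midpoint differences
  expect_equal(nrow(fo), 8)
  expect_true(all(fo$f > 0))
  slope <- fit_powerlaw(fo$h, fo$f)$exponent
  expect_equal(slope, -1.5, tolerance = 0.05 / 1.5)
  # the central (integer-h, +/-1) stencil is biased steep on this grid
  foc <- axial_force(sw, method = "central")
  sel <- foc$h %in% c(2, 3, 4, 6, 8)
  slope_c <- fit_powerlaw(foc$h[sel], foc$f[sel])$exponent
  expect_lt(slope_c, -1.58)
  expect_error(axial_force(structure(list(
    table = data.frame(h = 1, F = 1)), class = "brush_sweep")), ">= 2")
})

test_that("ideal brushes exert (almost) no axial force", {
  # tiny graft at very sparse grafting: forces orders of magnitude below
  # the crowded-brush scale (kBT/a)
  fo <- axial_force(comb_graft(2, 2, 0), h = c(20, 30, 40), zmax = 12)
  expect_lt(max(abs(fo$f)), 1e-4)
})

test_that("persistence length follows the F H^2 / h convention", {
  fit <- scf_brush(comb_graft(10, 3, 5), sigma = 0.5, zmax = 30)
  lp <- persistence_length(fit)
  expect_gt(lp, 0)
  expect_equal(lp, fit$free_energy * ((15 / 8) * mean_H(fit))^2 * fit$sigma)
})

test_that("molecular potential is referenced to the far field", {
  fit <- scf_brush(comb_graft(10, 3, 5), sigma = 0.5, zmax = 40)
  mp <- molecular_potential(fit)
  expect_identical(mp$U[40], 0)
  expect_gt(mp$U[1], 0)
  expect_equal(mp$z2, mp$z^2)
})

test_that("monodisperse comb potential is parabolic in the peripheral zone", {
  fit <- scf_brush(comb_graft(20, 3, 25), sigma = 0.5)
  mp <- molecular_potential(fit)
  z0 <- dead_zone_width(fit)
  cum <- cumsum(fit$phi * fit$lattice$L) / sum(fit$phi * fit$lattice$L)
  z95 <- which(cum >= 0.95)[1]
  sel <- mp$z >= z0 & mp$z <= z95
  comb_fit <- fit_linear(mp$z2[sel], mp$U[sel])
  expect_gte(comb_fit$r_squared, 0.99)
  expect_lt(comb_fit$slope, 0)
  # a strongly proximal-heavy double comb deviates more from a single
  # straight line over its own end-containing region
  fitd <- scf_brush(double_comb_graft(10, 3, 45, 5), sigma = 0.5)
  mpd <- molecular_potential(fitd)
  z0d <- dead_zone_width(fitd)
  cumd <- cumsum(fitd$phi * fitd$lattice$L) / sum(fitd$phi * fitd$lattice$L)
  seld <- mpd$z >= z0d & mpd$z <= which(cumd >= 0.95)[1]
  r2_dc <- fit_linear(mpd$z2[seld], mpd$U[seld])$r_squared
  expect_lt(r2_dc, comb_fit$r_squared)
})

test_that("first-branch distribution is normalised and physically placed", {
  fit <- scf_brush(double_comb_graft(5, 3, 6, 2), sigma = 0.5, zmax = 30)
  fb <- first_branch_distribution(fit)
  expect_equal(sum(fb$g * fit$lattice$L), 0.5, tolerance = 1e-10)
  # unbranched graft: no branch distribution
  fit0 <- scf_brush(comb_graft(5, 3, 0), sigma = 0.5, zmax = 25)
  expect_error(first_branch_distribution(fit0), "no branch")
  # near-ideal graft with the first branch 2 ranks from the anchor:
  # support only on the shells reachable in one step
  fit1 <- scf_brush(graft_architecture(P1 = 1, m1 = 2, n1 = 1),
                    sigma = 1e-6, zmax = 10)
  fb1 <- first_branch_distribution(fit1)
  expect_true(all(fb1$g[3:10] < 1e-12))
  expect_true(all(fb1$g[1:2] > 0))
})

test_that("root-spacer stretching correlates with the axial force", {
  # the domain split that pulls harder on the backbone also stretches
  # the root spacer further out
  arch_hi <- double_comb_graft(10, 3, 40, 10)
  arch_lo <- double_comb_graft(10, 3, 10, 40)
  f_hi <- axial_force(arch_hi, h = 3:5, method = "central")
  f_lo <- axial_force(arch_lo, h = 3:5, method = "central")
  fit_hi <- scf_brush(arch_hi, sigma = 0.25)
  fit_lo <- scf_brush(arch_lo, sigma = 0.25)
  mean_fb <- function(fit) {
    fb <- first_branch_distribution(fit)
    sum(fb$z * fb$g * fit$lattice$L) / sum(fb$g * fit$lattice$L)
  }
  expect_gt(f_hi$f[f_hi$h == 4], f_lo$f[f_lo$h == 4])
  expect_gt(mean_fb(fit_hi), mean_fb(fit_lo))
})
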