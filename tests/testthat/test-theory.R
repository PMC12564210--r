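# Analytical dead-zone theory: matching conditions, closed-form
# cross-checks, scaling exponents and the printed constants.

test_that("dead-zone partition at A = 1.45 gives the known constants", {
  dz <- dead_zone_solve(A = 1.45)
  expect_equal(dz$X, 0.816, tolerance = 0.005 / 0.816)
  expect_equal(dz$ratio, 0.39, tolerance = 0.01 / 0.39)
  # ~82% / ~18% mass split between peripheral and dead zones
  expect_equal(100 * dz$X, 82, tolerance = 0.01)
  expect_equal(100 * (1 - dz$X), 18, tolerance = 0.05)
})

test_that("the three matching conditions are satisfied to 1e-10", {
  for (p in list(c(500, 1, 1), c(8000, 1 / 16, 4), c(1000, 0.5, 2))) {
    dz <- dead_zone_solve(A = 1.45, N = p[1], sigma = p[2], eta = p[3])
    # (1) continuity of phi at z0
    inner_at_z0 <- dz$C_in * dz$z0^(-2 / 3)
    outer_at_z0 <- dz$K_out * dz$H^2
    expect_equal(inner_at_z0, outer_at_z0, tolerance = 1e-10)
    expect_equal(dead_zone_profile(dz, dz$z0 - 1e-9),
                 dead_zone_profile(dz, dz$z0 + 1e-9), tolerance = 1e-7)
    # (2) inner mass = (1 - X) N sigma  (closed-form integral of z^(-2/3) 2 pi z)
    inner_mass <- (3 * pi / 2) * dz$C_in * dz$z0^(4 / 3)
    expect_equal(inner_mass, (1 - dz$X) * p[1] * p[2], tolerance = 1e-10)
    # (3) outer mass = X N sigma, by quadrature
    outer_mass <- integrate(function(z) dead_zone_profile(dz, z) * 2 * pi * z,
                            dz$z0, dz$z0 + dz$H, rel.tol = 1e-12)$value
    expect_equal(outer_mass, dz$X * p[1] * p[2], tolerance = 1e-9)
  }
})

test_that("X and z0/H depend on A only, and match the closed form", {
  ref <- dead_zone_solve(A = 1.45)
  for (N in c(200, 1000, 5000))
    for (sigma in c(0.1, 0.5, 2))
      for (eta in c(1, 2, 4)) {
        dz <- dead_zone_solve(A = 1.45, N = N, sigma = sigma, eta = eta)
        expect_equal(dz$X, ref$X, tolerance = 1e-10)
        expect_equal(dz$ratio, ref$ratio, tolerance = 1e-10)
      }
  for (A in c(0.5, 1, 1.45, 3)) {
    sys <- dead_zone_solve(A = A)
    cf <- dead_zone_solve(A = A, solve = "closed_form")
    expect_equal(sys$X, cf$X, tolerance = 1e-10)
    expect_equal(sys$ratio, cf$ratio, tolerance = 1e-10)
  }
})

test_that("X -> 1 collapses the dead zone", {
  # z0/H is proportional to (1-X)/X: as A decreases, X -> 1 and the
  # ratio vanishes
  dzs <- sapply(c(0.4, 0.2, 0.1, 0.05), function(A) {
    d <- dead_zone_solve(A = A)
    c(d$X, d$ratio)
  })
  expect_true(all(diff(dzs[1, ]) > 0))
  expect_true(all(diff(dzs[2, ]) < 0))
  expect_lt(abs(dzs[2, 4] / ((2 * pi / (3 * sqrt(0.05))) *
                             (1 - dzs[1, 4]) / dzs[1, 4]) - 1), 1e-8)
})

test_that("parabolic profile has the exact normalization and scalings", {
  pb <- parabolic_profile(500, 1, 1)
  expect_equal(pb$phi(pb$H), 0)
  expect_equal(pb$phi(pb$H + 5), 0)
  mass <- integrate(function(z) pb$phi(z) * 2 * pi * z, 0, pb$H,
                    rel.tol = 1e-12)$value
  expect_equal(mass, 500 * 1, tolerance = 1e-10)
  # eta doubling divides H by sqrt(2); N quadrupling scales H by 4^(3/4)
  expect_equal(parabolic_profile(500, 1, 2)$H, pb$H / sqrt(2))
  expect_equal(parabolic_profile(2000, 1, 1)$H, pb$H * 4^(3 / 4))
  expect_error(parabolic_profile(500, 1, 1, nu = -0.1), "solvent")
})

test_that("analytic mass moment is exactly 8/15 of the parabolic radius", {
  pb <- parabolic_profile(1000, 0.5, 2)
  num <- integrate(function(z) pb$phi(z) * 2 * pi * z^2, 0, pb$H,
                   rel.tol = 1e-12)$value
  den <- integrate(function(z) pb$phi(z) * 2 * pi * z, 0, pb$H,
                   rel.tol = 1e-12)$value
  expect_equal(num / den, (8 / 15) * pb$H, tolerance = 1e-10)
  expect_equal(mean_H_analytic(1000, 0.5, 2), (8 / 15) * pb$H)
  expect_equal(mean_H_analytic(4000, 0.5, 2),
               4^(3 / 4) * mean_H_analytic(1000, 0.5, 2))
})

test_that("dead-zone profile keeps the power law and total mass", {
  dz <- dead_zone_solve(A = 1.45, N = 2000, sigma = 0.5, eta = 2)
  z <- dz$z0 * c(0.1, 0.2, 0.35)
  expect_equal(dead_zone_profile(dz, 2 * z) / dead_zone_profile(dz, z),
               rep(2^(-2 / 3), 3), tolerance = 1e-12)
  mass <- integrate(function(z) dead_zone_profile(dz, z) * 2 * pi * z,
                    0, dz$z0 + dz$H, rel.tol = 1e-12)$value
  expect_equal(mass, 2000 * 0.5, tolerance = 1e-8)
  expect_identical(dead_zone_profile(dz, dz$z0 + dz$H + 1), 0)
})

test_that("widths carry the N^(3/4) sigma^(1/4) eta^(-1/2) scaling", {
  w1 <- z0_and_H_widths(1000, 0.5, eta = 1)
  expect_equal(z0_and_H_widths(1000, 0.5, eta = 4), w1 / 2,
               tolerance = 1e-10)
  expect_equal(z0_and_H_widths(16000, 0.5, eta = 1), w1 * 8,
               tolerance = 1e-10)
  expect_equal(z0_and_H_widths(1000, 0.5 * 16, eta = 1), w1 * 2,
               tolerance = 1e-10)
  # eta log-slope on a grid
  etas <- c(1, 1.5, 2, 3, 4)
  z0s <- sapply(etas, function(e) z0_and_H_widths(1000, 0.5, e)[["z0"]])
  expect_equal(fit_powerlaw(etas, z0s)$exponent, -0.5, tolerance = 1e-8)
  # ratio equals the partition constant
  expect_equal(w1[["z0"]] / w1[["H"]], dead_zone_solve(1.45)$ratio,
               tolerance = 1e-12)
})

test_that("analytic force obeys the power-law derivative identity", {
  h <- c(2, 3, 4, 6, 8)
  ff <- free_energy_and_force_analytic(560, eta = 2, h = h)
  expect_equal(ff$f * ff$h / ff$F, rep(1 / 2, 5), tolerance = 1e-12)
  ff2 <- free_energy_and_force_analytic(560, eta = 4, h = h)
  expect_equal(ff2$f, 2 * ff$f, tolerance = 1e-12)
  expect_equal(fit_powerlaw(h, ff$f)$exponent, -1.5, tolerance = 1e-10)
  expect_equal(fit_powerlaw(h, ff$F)$exponent, -0.5, tolerance = 1e-10)
})

test_that("printed persistence-length formula and its scalings", {
  expect_equal(persistence_length_analytic(1000, 2), 11.5)
  expect_equal(persistence_length_analytic(1000, 1),
               4 * persistence_length_analytic(1000, 2))
  expect_equal(fit_powerlaw(c(2, 4, 8), persistence_length_analytic(
    500, c(2, 4, 8)))$exponent, -2, tolerance = 1e-12)
})

test_that("degenerate theory inputs are refused", {
  expect_error(dead_zone_solve(A = -1), "positive")
  expect_error(dead_zone_solve(A = 10), "no dead-zone partition")
  expect_error(dead_zone_solve(A = 10, solve = "closed_form"),
               "no dead-zone partition")
  expect_error(mean_H_analytic(1000, 0.5, nu = 0), "solvent")
})
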