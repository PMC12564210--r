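# The propagator engine against exhaustive walk enumeration, and the
# internal consistency identities of the branched-chain composition.

test_that("rank-resolved densities equal exhaustive enumeration, linear chains", {
  lat <- cylindrical_lattice(6)
  set.seed(11)
  for (len in 1:4) {
    arch <- graft_architecture(P1 = len, m1 = 1, n1 = 0)
    for (rep in 1:3) {
      u <- runif(6, 0, 1.2)
      o <- enum_oracle(lat, segment_map(arch)$side_chain, u)
      d <- brush_density(arch, lat, u, detail = TRUE)
      expect_equal(d$lnQ, log(o$Q), tolerance = 1e-12)
      expect_lt(max(abs(engine_marginals(arch, lat, u) - o$marg)), 1e-12)
    }
  }
})

test_that("rank-resolved densities equal enumeration, one-branch chains", {
  lat <- cylindrical_lattice(8)
  set.seed(12)
  archs <- list(
    graft_architecture(P1 = 1, m1 = 1, n1 = 1),   # 2 segments
    graft_architecture(P1 = 1, m1 = 1, n1 = 2),   # 3 segments
    graft_architecture(P1 = 1, m1 = 2, n1 = 2),   # 4 segments
    graft_architecture(P1 = 1, m1 = 3, n1 = 1),   # 4 segments
    graft_architecture(P1 = 2, m1 = 1, n1 = 1))   # 4 segments, 2 branches
  for (arch in archs) {
    for (rep in 1:3) {
      u <- runif(8, 0, 1.5)
      o <- enum_oracle(lat, segment_map(arch)$side_chain, u)
      d <- brush_density(arch, lat, u, detail = TRUE)
      expect_equal(d$lnQ, log(o$Q), tolerance = 1e-12)
      expect_equal(d$lnQ_reverse, log(o$Q), tolerance = 1e-12)
      expect_lt(max(abs(engine_marginals(arch, lat, u) - o$marg)), 1e-12)
    }
  }
})

test_that("zero-field single-segment graft sits in shell 1 with lnQ = 0", {
  lat <- cylindrical_lattice(5)
  arch <- graft_architecture(P1 = 1, m1 = 1, n1 = 0)
  d <- brush_density(arch, lat, rep(0, 5), sigma = 0.7)
  expect_equal(d$lnQ, 0)
  expect_equal(d$phi[1] * lat$L[1], 0.7)
  expect_true(all(d$phi[-1] == 0))
})

test_that("zero-field three-segment chain matches enumeration shell by shell", {
  lat <- cylindrical_lattice(6)
  arch <- graft_architecture(P1 = 3, m1 = 1, n1 = 0)
  u0 <- rep(0, 6)
  o <- enum_oracle(lat, segment_map(arch)$side_chain, u0)
  expect_equal(log(o$Q), 0)   # step weights are probabilities
  expect_lt(max(abs(engine_marginals(arch, lat, u0) - o$marg)), 1e-13)
})

test_that("lnQ is identical from either chain end for random branched grafts", {
  lat <- cylindrical_lattice(15)
  set.seed(13)
  for (i in 1:100) {
    arch <- random_small_arch()
    u <- runif(15, -0.5, 1.5)
    d <- brush_density(arch, lat, u)
    expect_lt(abs(d$lnQ - d$lnQ_reverse),
              1e-10 * max(1, abs(d$lnQ)))
  }
})

test_that("branched graft in a linear field: end symmetry to 1e-12", {
  lat <- cylindrical_lattice(10)
  arch <- graft_architecture(P1 = 2, m1 = 1, n1 = 1)
  u <- 0.2 * (1:10)
  d <- brush_density(arch, lat, u)
  expect_equal(d$lnQ, d$lnQ_reverse, tolerance = 1e-12)
})

test_that("rank densities partition the total and conserve mass", {
  lat <- cylindrical_lattice(20)
  arch <- double_comb_graft(P = 3, m = 2, n1 = 4, n2 = 2)
  set.seed(14)
  u <- runif(20, 0, 1)
  d <- brush_density(arch, lat, u, sigma = 0.4, detail = TRUE)
  total_from_ranks <- colSums(d$rank_density) +
    Reduce(`+`, lapply(d$side_rank_density, colSums))
  expect_equal(total_from_ranks, as.numeric(d$phi), tolerance = 1e-12)
  expect_equal(d$phi_backbone + d$phi_side, d$phi, tolerance = 1e-14)
  expect_equal(sum(d$phi * lat$L), total_monomers(arch) * 0.4,
               tolerance = 1e-12)
  # each rank slice carries exactly sigma
  expect_equal(unname(rowSums(sweep(d$rank_density, 2, lat$L, "*"))),
               rep(0.4, backbone_length(arch)), tolerance = 1e-12)
})

test_that("non-finite fields are rejected", {
  lat <- cylindrical_lattice(5)
  arch <- graft_architecture(P1 = 1, m1 = 1, n1 = 0)
  expect_error(brush_density(arch, lat, c(0, NA, 0, 0, 0)), "finite")
  expect_error(brush_density(arch, lat, rep(0, 4)), "mismatch")
})
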