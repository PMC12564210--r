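# Exhaustive enumeration of all lattice walks of one (possibly branched)
# graft anchored at shell 1, in an arbitrary per-shell field u.  Entirely
# independent of the propagator engine: walks are enumerated segment by
# segment with the shell step weights, weights multiplied explicitly.
# Returns the partition function and per-segment marginal layer
# probabilities (backbone ranks first, then branch segments in main-chain
# order).  Feasible for chains of a handful of segments on small lattices.
enum_oracle <- function(lat, blen, u) {
  Z <- lat$zmax
  G <- exp(-u)
  Nb <- length(blen)
  ids <- list()
  nid <- Nb
  for (t in seq_len(Nb)) {
    if (blen[t] > 0) {
      ids[[t]] <- nid + seq_len(blen[t])
      nid <- nid + blen[t]
    }
  }
  marg <- matrix(0, nid, Z)
  Q <- 0
  steps <- function(z) {
    tt <- c(z - 1L, z, z + 1L)
    ww <- c(lat$lambda_minus[z], lat$lambda_0[z], lat$lambda_plus[z])
    k <- ww > 0
    list(t = tt[k], w = ww[k])
  }
  # walk plan: each entry is a segment id; parent[k] indexes the plan
  # entry the k-th segment steps from (0 = anchored at shell 1)
  plan <- integer(0)
  parent <- integer(0)
  prev_bb <- 0L
  for (t in seq_len(Nb)) {
    plan <- c(plan, t)
    parent <- c(parent, prev_bb)
    prev_bb <- length(plan)
    if (blen[t] > 0) {
      pb <- prev_bb
      for (j in seq_len(blen[t])) {
        plan <- c(plan, ids[[t]][j])
        parent <- c(parent, pb)
        pb <- length(plan)
      }
    }
  }
  pos <- integer(length(plan))
  rec <- function(k, wgt) {
    if (k > length(plan)) {
      Q <<- Q + wgt
      for (i in seq_along(plan))
        marg[plan[i], pos[i]] <<- marg[plan[i], pos[i]] + wgt
      return(invisible())
    }
    if (k == 1L) {
      pos[1L] <<- 1L
      rec(2L, wgt * G[1L])
      return(invisible())
    }
    s <- steps(pos[parent[k]])
    for (i in seq_along(s$t)) {
      pos[k] <<- s$t[i]
      rec(k + 1L, wgt * s$w[i] * G[s$t[i]])
    }
  }
  rec(1L, 1)
  list(Q = Q, marg = marg / Q)
}

# Stack the engine's rank-resolved densities in oracle segment order and
# convert per-site volume fractions into layer probabilities.
engine_marginals <- function(arch, lat, u, sigma = 1) {
  d <- brush_density(arch, lat, u, sigma = sigma, detail = TRUE)
  rows <- d$rank_density
  if (length(d$side_rank_density))
    rows <- rbind(rows, do.call(rbind, d$side_rank_density))
  sweep(rows, 2L, lat$L, "*") / sigma
}

random_small_arch <- function() {
  P1 <- sample(0:2, 1)
  P2 <- if (P1 == 0L) sample(1:2, 1) else sample(0:2, 1)
  graft_architecture(P1 = P1, m1 = sample(1:3, 1), n1 = sample(0:3, 1),
                     P2 = P2, m2 = sample(1:3, 1), n2 = sample(0:3, 1))
}
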