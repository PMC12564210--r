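#' Define the topology of one grafted (double-)comb chain
#'
#' A graft is a comb polymer: a main chain tethered by its first segment to
#' the bottle-brush backbone, carrying secondary side chains on regularly
#' spaced branch points.  The branch points are organised in two blocks: a
#' proximal domain (adjacent to the grafting point) with `P1` branch points,
#' spacer length `m1` and side-chain length `n1`, followed by a peripheral
#' domain with `P2`, `m2`, `n2`.  Monodisperse combs have `n1 == n2` and
#' `m1 == m2`; aggrecan-like double combs have two different side-chain
#' lengths arranged block-wise, mimicking the KS/CS domains of aggrecan.
#'
#' Side chains attach to the *last* rank of each spacer, so the first branch
#' point sits `m1` ranks from the grafting point and the first spacer is the
#' "root spacer" whose stretching reports the normal force at the junction.
#'
#' @param P1,P2 number of branch points in the proximal / peripheral domain
#'   (non-negative integers; `P1 + P2 >= 1`).
#' @param m1,m2 spacer contour lengths (monomer units) in each domain;
#'   required positive wherever the corresponding `P` is positive.
#' @param n1,n2 secondary side-chain contour lengths (monomer units,
#'   non-negative; 0 means the domain is an unbranched chain section).
#' @return An object of class `"graft_architecture"`: a list with the six
#'   topology fields plus the derived `N` (total monomers, one graft) and
#'   `Nb` (graft main-chain length).
#' @examples
#' double_comb_graft(P = 10, m = 3, n1 = 40, n2 = 10)
#' comb_graft(P = 100, m = 5, n = 40)
#' @export
graft_architecture <- function(P1, m1, n1, P2 = 0L, m2 = m1, n2 = 0L) {
  vals <- list(P1 = P1, m1 = m1, n1 = n1, P2 = P2, m2 = m2, n2 = n2)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (length(v) != 1L || !is.finite(v) || v < 0 || v != round(v))
      stop("'", nm, "' must be a single non-negative integer", call. = FALSE)
  }
  P1 <- as.integer(P1); P2 <- as.integer(P2)
  m1 <- as.integer(m1); m2 <- as.integer(m2)
  n1 <- as.integer(n1); n2 <- as.integer(n2)
  if (P1 + P2 < 1L)
    stop("architecture needs at least one spacer (P1 + P2 >= 1)", call. = FALSE)
  if (P1 > 0L && m1 < 1L)
    stop("m1 must be >= 1 when P1 > 0", call. = FALSE)
  if (P2 > 0L && m2 < 1L)
    stop("m2 must be >= 1 when P2 > 0", call. = FALSE)
  arch <- list(
    P1 = P1, m1 = m1, n1 = n1, P2 = P2, m2 = m2, n2 = n2,
    N  = P1 * (n1 + m1) + P2 * (n2 + m2),
    Nb = P1 * m1 + P2 * m2
  )
  class(arch) <- "graft_architecture"
  arch
}

#' @rdname graft_architecture
#' @param P,m,n single-domain shorthand for a monodisperse comb.
#' @export
comb_graft <- function(P, m, n) graft_architecture(P1 = P, m1 = m, n1 = n)

#' @rdname graft_architecture
#' @export
double_comb_graft <- function(P, m, n1, n2) {
  graft_architecture(P1 = P, m1 = m, n1 = n1, P2 = P, m2 = m, n2 = n2)
}

#' @export
print.graft_architecture <- function(x, ...) {
  cat("Graft architecture (", if (is_monodisperse(x)) "monodisperse comb"
      else "double comb", ")\n", sep = "")
  cat(sprintf("  proximal : P1 = %d, m1 = %d, n1 = %d\n", x$P1, x$m1, x$n1))
  cat(sprintf("  peripheral: P2 = %d, m2 = %d, n2 = %d\n", x$P2, x$m2, x$n2))
  cat(sprintf("  N = %d monomers per graft, main-chain length Nb = %d\n",
              x$N, x$Nb))
  invisible(x)
}

#' Total monomers and main-chain length of a graft
#'
#' `total_monomers()` returns `N = P1*(n1+m1) + P2*(n2+m2)`, the degree of
#' polymerization of one grafted comb; `backbone_length()` returns
#' `Nb = P1*m1 + P2*m2`, the contour length of the graft main chain.
#'
#' @param arch a [graft_architecture()].
#' @return A single integer.
#' @examples
#' total_monomers(double_comb_graft(P = 10, m = 3, n1 = 25, n2 = 25)) # 560
#' @export
total_monomers <- function(arch) {
  stopifnot(inherits(arch, "graft_architecture"))
  arch$N
}

#' @rdname total_monomers
#' @export
backbone_length <- function(arch) {
  stopifnot(inherits(arch, "graft_architecture"))
  arch$Nb
}

is_monodisperse <- function(arch) arch$P2 == 0L ||
  (arch$n1 == arch$n2 && arch$m1 == arch$m2)

#' Topological ratio of a comb chain
#'
#' The branching parameter `eta = sqrt(1 + n/m)` quantifies how side chains
#' of length `n` on spacers of length `m` soften the effective (Gaussian)
#' elasticity of a comb chain relative to a linear chain; `eta = 1` for an
#' unbranched chain and grows with the side-chain load per spacer.
#'
#' @param n secondary side-chain contour length (monomer units, `>= 0`).
#' @param m spacer contour length (monomer units, `>= 1`).
#' @return `sqrt(1 + n/m)`, a dimensionless value `>= 1`.
#' @examples
#' topological_ratio(15, 5)  # 2
#' topological_ratio(75, 5)  # 4
#' @export
topological_ratio <- function(n, m) {
  if (any(!is.finite(m)) || any(m < 1))
    stop("invalid architecture: spacer length m must be >= 1 ",
         "(a linear chain has no spacer ratio)", call. = FALSE)
  if (any(!is.finite(n)) || any(n < 0))
    stop("side-chain length n must be >= 0", call. = FALSE)
  sqrt(1 + n / m)
}

#' Per-rank segment map of a graft main chain
#'
#' Expands an architecture into the rank-by-rank description consumed by the
#' propagator engine: ranks `1..Nb` along the graft main chain, each
#' annotated with the length of the secondary side chain attached there
#' (0 for plain spacer ranks).  Branch points sit on the last rank of each
#' spacer, so rank `m1` hosts the first branch and ranks `1..m1` form the
#' root spacer.
#'
#' @param arch a [graft_architecture()].
#' @return A data frame with columns `rank` and `side_chain` (attached
#'   side-chain length, 0 if none), one row per main-chain rank, with
#'   attribute `"first_branch_rank"` (rank of the first branch point, or
#'   `NA` if the graft carries no side chains).
#' @export
segment_map <- function(arch) {
  stopifnot(inherits(arch, "graft_architecture"))
  side <- integer(arch$Nb)
  if (arch$P1 > 0L) side[arch$m1 * seq_len(arch$P1)] <- arch$n1
  if (arch$P2 > 0L) side[arch$P1 * arch$m1 + arch$m2 * seq_len(arch$P2)] <- arch$n2
  map <- data.frame(rank = seq_len(arch$Nb), side_chain = side)
  br <- which(side > 0L)
  attr(map, "first_branch_rank") <- if (length(br)) br[1L] else NA_integer_
  map
}

#' Solvent and grafting parameters of the brush
#'
#' Bundles the grafting density `sigma = a/h` (grafts per unit axial length,
#' in units of the monomer size `a`), the Flory-Huggins parameter `chi`
#' (0 for an athermal solvent) and the derived excluded-volume (second
#' virial) coefficient `nu = 1/2 - chi`.
#'
#' @param sigma grafting density, `0 < sigma <= 2`.
#' @param chi Flory-Huggins solvency parameter; good solvent requires
#'   `chi < 1/2`.
#' @return An object of class `"brush_parameters"`.
#' @export
brush_parameters <- function(sigma, chi = 0) {
  if (!is.finite(sigma) || sigma <= 0 || sigma > 2)
    stop("sigma must be in (0, 2]", call. = FALSE)
  if (!is.finite(chi) || chi >= 1/2)
    stop("good solvent requires chi < 1/2 (nu = 1/2 - chi > 0)", call. = FALSE)
  structure(list(sigma = sigma, h = 1 / sigma, chi = chi, nu = 1/2 - chi),
            class = "brush_parameters")
}

#' @export
print.brush_parameters <- function(x, ...) {
  cat(sprintf(
    "Brush parameters: sigma = %.4g (h = %.4g a), chi = %.3g, nu = %.3g\n",
    x$sigma, x$h, x$chi, x$nu))
  invisible(x)
}
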