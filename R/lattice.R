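#' Cylindrical shell lattice around the brush axis
#'
#' Builds the cubic-lattice shell geometry used by the propagator
#' recursion.  Shell `z` (`z >= 1`) spans radii `[z - 1/2, z + 1/2]`
#' around the backbone axis, so its dimensionless cross-sectional area is
#' `L(z) = 2*pi*z` per unit axial length.  Layer `z = 0` is the phantom
#' backbone: it carries no polymer or solvent, and steps directed into it
#' are reflected back into shell 1.  The outer boundary at `zmax` is
#' reflecting as well.
#'
#' Step weights start from the cubic-lattice fractions (1/6, 4/6, 1/6) and
#' are modulated by the ratio of the shared interface area to the shell
#' area: `lambda_plus(z) = (1/6)*(z + 1/2)/z` and
#' `lambda_minus(z) = (1/6)*(z - 1/2)/z`, leaving `lambda_0 = 2/3`
#' everywhere in the interior.  This construction satisfies detailed
#' balance `L(z)*lambda_plus(z) == L(z+1)*lambda_minus(z+1)` exactly, and
#' the weights of each shell sum to one (reflected boundary weights are
#' folded into `lambda_0`).
#'
#' @param zmax number of shells (`>= 3`), or the result of
#'   `"auto"`-sizing done by [scf_brush()].
#' @param offset radial offset added to every shell radius
#'   (`L(z) = 2*pi*(z + offset)`).  The default 0 is the cylindrical brush
#'   geometry; a large offset approaches the planar limit and exists for
#'   consistency testing.
#' @return An object of class `"cyl_lattice"`: list with `zmax`, `offset`,
#'   `L`, and the step-weight vectors `lambda_minus`, `lambda_0`,
#'   `lambda_plus` (boundary-folded).
#' @examples
#' lat <- cylindrical_lattice(50)
#' all.equal(lat$L[1:2], c(2 * pi, 4 * pi))
#' @export
cylindrical_lattice <- function(zmax, offset = 0) {
  if (!is.finite(zmax) || zmax < 3 || zmax != round(zmax))
    stop("zmax must be an integer >= 3", call. = FALSE)
  if (!is.finite(offset) || offset < 0)
    stop("offset must be >= 0", call. = FALSE)
  zmax <- as.integer(zmax)
  z <- seq_len(zmax) + offset
  L  <- 2 * pi * z
  lp <- (z + 0.5) / (6 * z)
  lm <- (z - 0.5) / (6 * z)
  l0 <- 1 - lp - lm                      # == 2/3 exactly
  # reflecting boundaries: fold the outward-directed weights back
  l0[1L]   <- l0[1L] + lm[1L];  lm[1L]   <- 0
  l0[zmax] <- l0[zmax] + lp[zmax]; lp[zmax] <- 0
  structure(list(zmax = zmax, offset = offset, L = L,
                 lambda_minus = lm, lambda_0 = l0, lambda_plus = lp),
            class = "cyl_lattice")
}

#' @export
print.cyl_lattice <- function(x, ...) {
  cat(sprintf("Cylindrical shell lattice: zmax = %d shells%s\n", x$zmax,
              if (x$offset > 0) sprintf(" (radial offset %g)", x$offset)
              else ""))
  cat(sprintf("  L(1) = %.4f, L(zmax) = %.4f; step weights lambda0 = 2/3\n",
              x$L[1L], x$L[x$zmax]))
  invisible(x)
}

#' Nearest-layer average of a per-shell quantity
#'
#' The angular-bracket operator of the propagator recursion:
#' `<f>(z) = lambda_minus(z) f(z-1) + lambda_0(z) f(z) +
#' lambda_plus(z) f(z+1)`, with reflecting boundaries at the phantom
#' backbone (z = 0) and at `zmax`.  A constant field is left unchanged,
#' and the shell-weighted mass `sum(L * f)` is conserved exactly (a
#' consequence of detailed balance).
#'
#' @param lattice a [cylindrical_lattice()].
#' @param f numeric vector of per-shell values, length `zmax`.
#' @return Numeric vector of the same length.
#' @export
layer_average <- function(lattice, f) {
  stopifnot(inherits(lattice, "cyl_lattice"))
  if (length(f) != lattice$zmax)
    stop("f must have one value per shell (length zmax)", call. = FALSE)
  Z <- lattice$zmax
  out <- lattice$lambda_0 * f
  out[-1L] <- out[-1L] + lattice$lambda_minus[-1L] * f[-Z]
  out[-Z]  <- out[-Z]  + lattice$lambda_plus[-Z]  * f[-1L]
  out
}

# Auto-size the lattice: 1.6x the analytic dead-zone outer edge (z0 + H),
# clamped to the maximal radial reach of the graft main chain (Nb + 2)
# and to a small floor.  eta is taken on the softer (smaller) domain so
# that the estimate errs on the generous side for double combs.
auto_zmax <- function(arch, sigma, nu = 0.5, A = 1.45) {
  eta_lo <- if (arch$P1 > 0L && arch$P2 > 0L)
    min(topological_ratio(arch$n1, arch$m1),
        topological_ratio(arch$n2, arch$m2))
  else if (arch$P1 > 0L) topological_ratio(arch$n1, arch$m1)
  else topological_ratio(arch$n2, arch$m2)
  dz <- dead_zone_solve(A = A, N = arch$N, sigma = sigma,
                        eta = eta_lo, nu = nu)
  zc <- ceiling(1.6 * (dz$z0 + dz$H)) + 5L
  max(10L, min(as.integer(zc), arch$Nb + 2L))
}
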