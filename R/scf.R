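#' Solve the self-consistent field of a cylindrical bottle-brush
#'
#' Converges the Scheutjens-Fleer lattice mean field for a brush of
#' identical comb or double-comb grafts tethered to a straight phantom
#' backbone with grafting density `sigma = a/h`.  The grafts are
#' freely-jointed chains in the effective field `u(z)`; polymer and
#' (monomeric) solvent satisfy the incompressibility constraint
#' `phi(z) + phi_s(z) = 1` via a Lagrange multiplier field `alpha(z)`
#' which, in the athermal model (`chi = 0`), is the potential itself.
#' Iteration stops when the maximum incompressibility violation drops
#' below `tol`.
#'
#' The default updater is Anderson mixing (difference history `depth`,
#' damping `h_mix`), with plain Picard relaxation
#' `alpha <- alpha + h_mix * (phi + phi_s - 1)` available as
#' `mixing = "picard"`.  Both are fully deterministic; the field is
#' initialised to zero.
#'
#' @param arch a [graft_architecture()].
#' @param sigma grafting density `a/h` (`0 < sigma <= 2`; larger values
#'   are refused unless `check_sigma = FALSE`, which exists for
#'   planar-limit test geometries).
#' @param chi Flory-Huggins parameter; default 0 (athermal).
#' @param zmax number of shells, or `"auto"` (1.6 times the analytic
#'   dead-zone outer edge `z0 + H`, capped by the graft contour length).
#' @param lattice optionally a pre-built [cylindrical_lattice()]
#'   (overrides `zmax`).
#' @param tol convergence tolerance on `max |phi + phi_s - 1|`.
#' @param maxit iteration cap.
#' @param h_mix mixing step (must be `< 1/2` for Picard stability).
#' @param mixing `"anderson"` (default) or `"picard"`.
#' @param depth Anderson difference-history depth.
#' @param check_sigma refuse `sigma > 2` (diagnostic guard)?
#' @param must_converge error on non-convergence (default)?  If `FALSE`
#'   an unconverged fit is returned with `converged = FALSE`.
#' @return An object of class `"scf_brush"`: the converged fields
#'   (`u`, `phi`, `phi_solvent`), component profiles (`phi_backbone`,
#'   `phi_side`, `phi_end`, `phi_first_branch`), `lnQ` (per graft, equal
#'   from either chain end), `free_energy` per graft (kB*T), solver
#'   diagnostics, and the inputs.
#' @examples
#' fit <- scf_brush(comb_graft(10, 3, 5), sigma = 0.5, zmax = 30)
#' fit
#' coef(fit)
#' @export
scf_brush <- function(arch, sigma, chi = 0, zmax = "auto", lattice = NULL,
                      tol = 1e-8, maxit = 200000L, h_mix = 0.2,
                      mixing = c("anderson", "picard"), depth = 5L,
                      check_sigma = TRUE, must_converge = TRUE) {
  stopifnot(inherits(arch, "graft_architecture"))
  mixing <- match.arg(mixing)
  if (!is.finite(sigma) || sigma <= 0)
    stop("sigma must be positive", call. = FALSE)
  if (check_sigma && sigma > 2)
    stop("sigma = ", sigma, " > 2: outside the dense-grafting range the ",
         "model is built for (set check_sigma = FALSE to override)",
         call. = FALSE)
  if (!is.finite(chi) || chi >= 1/2)
    stop("good solvent requires chi < 1/2", call. = FALSE)
  if (h_mix <= 0 || h_mix >= 1/2)
    stop("h_mix must be in (0, 1/2)", call. = FALSE)
  if (is.null(lattice)) {
    if (identical(zmax, "auto")) zmax <- auto_zmax(arch, sigma, nu = 1/2 - chi)
    lattice <- cylindrical_lattice(zmax)
  }
  stopifnot(inherits(lattice, "cyl_lattice"))

  blen <- segment_map(arch)$side_chain
  sol <- scf_core_solve(lattice$L, lattice$lambda_minus, lattice$lambda_0,
                        lattice$lambda_plus, as.integer(blen),
                        sigma, chi, tol, as.integer(maxit), h_mix,
                        as.integer(depth), mixing == "picard")
  if (!sol$converged && must_converge)
    stop(sprintf(
      "SCF iteration did not converge: residual %.3e after %d iterations",
      sol$residual, sol$iterations), call. = FALSE)

  u <- as.numeric(sol$u)
  phi <- as.numeric(sol$phi)
  fit <- list(
    arch = arch, sigma = sigma, h = 1 / sigma, chi = chi, nu = 1/2 - chi,
    lattice = lattice,
    u = u, alpha = as.numeric(sol$alpha),
    phi = phi, phi_solvent = as.numeric(sol$phi_solvent),
    phi_backbone = as.numeric(sol$phi_backbone),
    phi_side = as.numeric(sol$phi_side),
    phi_end = as.numeric(sol$phi_end),
    phi_first_branch = if (is.null(sol$phi_first_branch)) NULL
                       else as.numeric(sol$phi_first_branch),
    lnQ = sol$lnQ, lnQ_reverse = sol$lnQ_reverse,
    free_energy = -sol$lnQ - sum(u * phi * lattice$L) / sigma,
    iterations = sol$iterations, residual = sol$residual,
    converged = sol$converged,
    options = list(tol = tol, maxit = maxit, h_mix = h_mix,
                   mixing = mixing, depth = depth)
  )
  class(fit) <- "scf_brush"
  if (fit$converged && phi[lattice$zmax] > 1e-6)
    warning(sprintf(
      "phi(zmax) = %.2e > 1e-6: lattice may be too small (zmax = %d)",
      phi[lattice$zmax], lattice$zmax), call. = FALSE)
  fit
}

#' Rank-resolved densities and propagator diagnostics in a fixed field
#'
#' Evaluates the branched-chain propagators and segment densities for one
#' graft architecture in an externally imposed per-shell field `u(z)`,
#' without any self-consistency loop.  This is the single-field building
#' block of [scf_brush()], exposed for inspection and for validation
#' against exhaustive enumeration on small chains.
#'
#' @param arch a [graft_architecture()].
#' @param lattice a [cylindrical_lattice()].
#' @param u per-shell dimensionless potential (length `zmax`).
#' @param sigma grafting density used to normalise densities
#'   (`sum(phi * L) = N * sigma`).
#' @param detail return per-rank density matrices?
#' @return A list with `phi`, `phi_backbone`, `phi_side`, `phi_end`,
#'   `phi_first_branch`, `lnQ`, `lnQ_reverse` and, with `detail = TRUE`,
#'   `rank_density` (an `Nb x zmax` matrix of main-chain rank densities)
#'   plus `side_rank_density` (one `n x zmax` matrix per branch, in
#'   main-chain order; `side_rank_at` gives the hosting rank).
#' @export
brush_density <- function(arch, lattice, u, sigma = 1, detail = FALSE) {
  stopifnot(inherits(arch, "graft_architecture"),
            inherits(lattice, "cyl_lattice"))
  if (length(u) != lattice$zmax)
    stop("field/lattice size mismatch", call. = FALSE)
  if (any(!is.finite(u)))
    stop("numerical error: non-finite field", call. = FALSE)
  blen <- segment_map(arch)$side_chain
  d <- scf_core_density(lattice$L, lattice$lambda_minus, lattice$lambda_0,
                        lattice$lambda_plus, as.integer(blen),
                        as.numeric(u), sigma, detail)
  for (nm in c("phi", "phi_backbone", "phi_side", "phi_end",
               "phi_first_branch"))
    if (!is.null(d[[nm]])) d[[nm]] <- as.numeric(d[[nm]])
  d
}

#' Free energy per grafted chain
#'
#' Evaluates `F = -lnQ - (1/sigma) * sum_z u(z) phi(z) L(z)` (in kB*T) on
#' the converged fields: the negative log partition function of one graft
#' in the self-consistent field, minus the work done by the field.  The
#' ideal (field-free) reference is `F = 0`.
#'
#' @param fit a converged [scf_brush()] fit.
#' @return Free energy per grafted chain, in kB*T.
#' @export
free_energy <- function(fit) {
  stopifnot(inherits(fit, "scf_brush"))
  if (!fit$converged)
    stop("refusing to evaluate the free energy of an unconverged fit ",
         sprintf("(residual %.3e)", fit$residual), call. = FALSE)
  fit$free_energy
}

#' @export
print.scf_brush <- function(x, ...) {
  cat("Cylindrical SF-SCF brush fit\n")
  print(x$arch)
  cat(sprintf("  sigma = %.4g (h = %.4g a), chi = %.3g, zmax = %d shells\n",
              x$sigma, x$h, x$chi, x$lattice$zmax))
  cat(sprintf("  %s after %d iterations, residual %.2e\n",
              if (x$converged) "converged" else "NOT converged",
              x$iterations, x$residual))
  cat(sprintf("  lnQ = %.6f, free energy F = %.6f kBT per graft\n",
              x$lnQ, x$free_energy))
  invisible(x)
}

#' @export
summary.scf_brush <- function(object, ...) {
  m <- coef(object)
  cat("Cylindrical SF-SCF brush fit\n")
  print(object$arch)
  cat(sprintf("  sigma = %.4g, chi = %.3g, zmax = %d, residual %.2e (%d it.)\n",
              object$sigma, object$chi, object$lattice$zmax,
              object$residual, object$iterations))
  cat("Brush metrics:\n")
  for (nm in names(m)) cat(sprintf("  %-14s %.6g\n", nm, m[[nm]]))
  invisible(m)
}

#' Extract brush metrics from a fit
#'
#' @param object a converged [scf_brush()] fit.
#' @param ... unused.
#' @return Named numeric vector: free energy `F` (kB*T), `lnQ`, mass
#'   first moment `mean_H` (a), end first moment `mean_He` (a), numeric
#'   dead-zone width `z0` (a), and induced persistence length `lp` (a).
#' @export
coef.scf_brush <- function(object, ...) {
  c(F = object$free_energy, lnQ = object$lnQ,
    mean_H = mean_H(object), mean_He = mean_He(object),
    z0 = dead_zone_width(object), lp = persistence_length(object))
}

#' @export
residuals.scf_brush <- function(object, ...) {
  object$phi + object$phi_solvent - 1
}

#' Per-shell profiles of a brush fit
#'
#' @param fit an [scf_brush()] fit.
#' @return Data frame with one row per shell: `z`, `L`, `phi`,
#'   `phi_solvent`, `phi_backbone`, `phi_side`, `phi_end`,
#'   `phi_first_branch` (if any), and the potential `u`.
#' @export
profiles <- function(fit) {
  stopifnot(inherits(fit, "scf_brush"))
  d <- data.frame(z = seq_len(fit$lattice$zmax) + fit$lattice$offset,
                  L = fit$lattice$L, phi = fit$phi,
                  phi_solvent = fit$phi_solvent,
                  phi_backbone = fit$phi_backbone,
                  phi_side = fit$phi_side, phi_end = fit$phi_end,
                  u = fit$u)
  if (!is.null(fit$phi_first_branch))
    d$phi_first_branch <- fit$phi_first_branch
  d
}

#' @export
plot.scf_brush <- function(x, which = c("density", "ends", "potential"),
                           ...) {
  which <- match.arg(which)
  z <- seq_len(x$lattice$zmax) + x$lattice$offset
  if (which == "density") {
    graphics::plot(z, x$phi, type = "l", xlab = "z / a",
                   ylab = expression(phi(z)),
                   main = "Radial volume-fraction profile", ...)
    graphics::lines(z, x$phi_side, lty = 2)
    graphics::lines(z, x$phi_backbone, lty = 3)
    graphics::legend("topright", lty = 1:3, bty = "n",
                     legend = c("total", "side chains", "main chains"))
  } else if (which == "ends") {
    graphics::plot(z, x$phi_end, type = "l", xlab = "z / a",
                   ylab = "g(z)",
                   main = "Free ends of the graft main chains", ...)
    graphics::abline(v = dead_zone_width(x), lty = 2)
  } else {
    graphics::plot(z^2, x$u - x$u[length(x$u)], type = "l",
                   xlab = expression(z^2),
                   ylab = "U(z) / kBT",
                   main = "Molecular potential vs squared distance", ...)
  }
  invisible(x)
}
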