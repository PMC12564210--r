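#' Best-fit dead-zone amplitude A from simulated profiles
#'
#' Fits the single scaling factor `A` of the inner-zone power law
#' `phi(z) = (3 A sigma^2 eta^2 / (16 nu pi^2 z^2))^(1/3)` jointly to one
#' or more converged SF-SCF volume-fraction profiles, by least squares on
#' `log phi` restricted to the inner dead-zone window
#' `z in [window[1], window[2] * z0]` of each profile (`z0` estimated per
#' profile from its end distribution via [dead_zone_width()] unless
#' supplied).  Because the model is log-linear in `log A` with a fixed
#' `-2/3` slope, the joint least-squares solution is the closed-form mean
#' of `3 log phi + 2 log z - log(3 sigma^2 eta^2 / (16 nu pi^2))` over
#' all windowed points.
#'
#' @param fits a single [scf_brush()] fit or a list of them (monodisperse
#'   comb brushes with a detectable dead zone).
#' @param window two numbers `c(zmin, frac)`: shells from `zmin` up to
#'   `frac * z0` enter the fit.  Default `c(2, 0.8)`.
#' @param z0 optional vector of dead-zone widths (one per fit)
#'   overriding the per-profile estimate.
#' @return An object of class `"amplitude_fit"`: list with the estimate
#'   `A`, `log_residuals`, `n_points`, the window rule, and per-profile
#'   bookkeeping (`z0`, points used).
#' @examples
#' # self-consistency: data generated exactly from the model recover A
#' lat <- cylindrical_lattice(40)
#' z <- seq_len(40)
#' phi <- (2.0 * 3 * 0.5^2 / (16 * 0.5 * pi^2 * z^2))^(1/3)
#' fit <- list(phi = phi, lattice = lat, sigma = 0.5, eta = 1, nu = 0.5)
#' @export
fit_amplitude_A <- function(fits, window = c(2, 0.8), z0 = NULL) {
  if (inherits(fits, "scf_brush")) fits <- list(fits)
  stopifnot(is.list(fits), length(fits) >= 1L)
  if (length(window) != 2L || window[1] < 1 || window[2] <= 0 ||
      window[2] > 1)
    stop("window must be c(zmin >= 1, frac in (0, 1])", call. = FALSE)

  logA_pts <- list()
  info <- vector("list", length(fits))
  for (i in seq_along(fits)) {
    f <- fits[[i]]
    if (inherits(f, "scf_brush")) {
      eta <- graft_eta(f$arch)
      prof <- f$phi; lat <- f$lattice
      sig <- f$sigma; nu <- f$nu
      z0i <- if (is.null(z0)) dead_zone_width(f) else z0[i]
    } else {
      prof <- f$phi; lat <- f$lattice
      sig <- f$sigma; nu <- f$nu; eta <- f$eta
      z0i <- if (is.null(z0)) f$z0 else z0[i]
    }
    z <- seq_len(lat$zmax) + lat$offset
    sel <- z >= window[1] & z <= window[2] * z0i & prof > 0
    if (!any(sel))
      stop("empty fit window for profile ", i,
           sprintf(" (z0 estimate %.2f)", z0i), call. = FALSE)
    logA_pts[[i]] <- 3 * log(prof[sel]) + 2 * log(z[sel]) -
      log(3 * sig^2 * eta^2 / (16 * nu * pi^2))
    info[[i]] <- data.frame(profile = i, z0 = z0i, n = sum(sel))
  }
  pts <- unlist(logA_pts)
  A <- exp(mean(pts))
  structure(list(A = A,
                 log_residuals = (pts - mean(pts)) / 3,  # in log phi
                 n_points = length(pts),
                 window = window,
                 profiles = do.call(rbind, info)),
            class = "amplitude_fit")
}

graft_eta <- function(arch) {
  if (!is_monodisperse(arch))
    stop("amplitude fit expects monodisperse comb grafts", call. = FALSE)
  m <- if (arch$P1 > 0L) arch$m1 else arch$m2
  n <- if (arch$P1 > 0L) arch$n1 else arch$n2
  topological_ratio(n, m)
}

#' @export
print.amplitude_fit <- function(x, ...) {
  cat(sprintf(
    "Dead-zone amplitude fit: A = %.4f (%d points, window [%g, %g*z0])\n",
    x$A, x$n_points, x$window[1], x$window[2]))
  cat(sprintf("  rms log-phi residual: %.4f\n",
              sqrt(mean(x$log_residuals^2))))
  invisible(x)
}

#' Power-law fit in log-log coordinates
#'
#' Ordinary least squares of `log y` on `log x` over an optional index
#' window, returning the exponent, the log-prefactor and the goodness of
#' fit.  Used for the force-law and persistence-length scaling slopes.
#'
#' @param x,y positive numeric vectors of equal length (`>= 3` points in
#'   the window).
#' @param window optional integer index range `c(first, last)`.
#' @return An object of class `"powerlaw_fit"`: list with `exponent`,
#'   `log_prefactor` (natural log), `prefactor`, `r_squared`, `window`,
#'   and `n`.
#' @examples
#' fit_powerlaw(c(2, 4, 8, 16), 5 * c(2, 4, 8, 16)^-2)$exponent  # -2
#' @export
fit_powerlaw <- function(x, y, window = NULL) {
  stopifnot(length(x) == length(y))
  if (is.null(window)) window <- c(1L, length(x))
  idx <- seq.int(window[1], window[2])
  x <- x[idx]; y <- y[idx]
  if (length(x) < 3L)
    stop("power-law fit needs >= 3 points", call. = FALSE)
  if (any(!is.finite(x) | !is.finite(y) | x <= 0 | y <= 0))
    stop("power-law fit needs positive finite values in the window",
         call. = FALSE)
  fit <- lm(log(y) ~ log(x))
  structure(list(exponent = unname(coef(fit)[2L]),
                 log_prefactor = unname(coef(fit)[1L]),
                 prefactor = exp(unname(coef(fit)[1L])),
                 r_squared = r_squared(log(y), fitted(fit)),
                 window = window, n = length(x)),
            class = "powerlaw_fit")
}

#' @export
print.powerlaw_fit <- function(x, ...) {
  cat(sprintf(
    "Power-law fit: y = %.4g * x^(%.4f)  (R^2 = %.5f, n = %d)\n",
    x$prefactor, x$exponent, x$r_squared, x$n))
  invisible(x)
}

#' Ordinary least-squares straight line
#'
#' @param x,y numeric vectors of equal length (`>= 3`, `x` not all
#'   equal).
#' @return List with `slope`, `intercept` and `r_squared`.
#' @export
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("linear fit needs >= 3 points", call. = FALSE)
  if (any(!is.finite(x) | !is.finite(y)))
    stop("linear fit needs finite values", call. = FALSE)
  if (diff(range(x)) == 0)
    stop("degenerate x: no spread", call. = FALSE)
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       r_squared = r_squared(y, fitted(fit)))
}

r_squared <- function(y, yhat) {
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(1)
  1 - sum((y - yhat)^2) / sst
}
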