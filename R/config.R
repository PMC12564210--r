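# Config-file interface: a YAML mapping with an `architecture` block
# (P1, m1, n1, P2, m2, n2), `sigma`, `chi`, and an optional `solver`
# block (zmax, tol, maxit, h_mix, mixing, depth).

config_keys <- list(
  top = c("architecture", "sigma", "chi", "solver"),
  architecture = c("P1", "m1", "n1", "P2", "m2", "n2"),
  solver = c("zmax", "tol", "maxit", "h_mix", "mixing", "depth")
)

#' Read and validate a brush run configuration
#'
#' @param path path to a YAML config file, or a list with the same
#'   structure: an `architecture` block (`P1`, `m1`, `n1`, optional
#'   `P2`, `m2`, `n2`), `sigma`, optional `chi` (default 0) and an
#'   optional `solver` block (`zmax`, `tol`, `maxit`, `h_mix`,
#'   `mixing`, `depth`).
#' @return A validated list with elements `arch`
#'   (a [graft_architecture()]), `sigma`, `chi` and `solver`.
#' @export
read_brush_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(cfg)) stop("config must be a mapping", call. = FALSE)
  check_keys(cfg, config_keys$top, "")
  if (is.null(cfg$architecture))
    stop("config error at 'architecture': block is required", call. = FALSE)
  check_keys(cfg$architecture, config_keys$architecture, "architecture.")
  if (!is.null(cfg$solver))
    check_keys(cfg$solver, config_keys$solver, "solver.")
  if (is.null(cfg$sigma))
    stop("config error at 'sigma': value is required", call. = FALSE)
  a <- cfg$architecture
  arch <- graft_architecture(
    P1 = a$P1, m1 = a$m1, n1 = a$n1,
    P2 = if (is.null(a$P2)) 0L else a$P2,
    m2 = if (is.null(a$m2)) a$m1 else a$m2,
    n2 = if (is.null(a$n2)) 0L else a$n2)
  list(arch = arch, sigma = cfg$sigma,
       chi = if (is.null(cfg$chi)) 0 else cfg$chi,
       solver = if (is.null(cfg$solver)) list() else cfg$solver)
}

check_keys <- function(x, allowed, prefix) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("config error at '", prefix, bad[1L], "': unknown key",
         call. = FALSE)
  invisible(TRUE)
}

#' Write a brush run configuration
#'
#' Emits the YAML form of a configuration so that
#' `read_brush_config(write_brush_config(cfg, path))` round-trips.
#'
#' @param config a list as returned by [read_brush_config()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_brush_config <- function(config, path) {
  a <- config$arch
  out <- list(
    architecture = list(P1 = a$P1, m1 = a$m1, n1 = a$n1,
                        P2 = a$P2, m2 = a$m2, n2 = a$n2),
    sigma = config$sigma, chi = config$chi)
  if (length(config$solver)) out$solver <- config$solver
  yaml::write_yaml(out, path)
  invisible(path)
}
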