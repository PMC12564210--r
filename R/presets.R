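# Preset experiments: the standard parameter families of the study.
# All presets are deterministic; rerunning one reproduces identical
# numeric output.

#' Preset parameter sets
#'
#' Ready-made experiment definitions:
#'
#' * `preset_fig_comb_quartet()` — four monodisperse comb brushes with
#'   graft main-chain length 500, spacer `m = 5`, side-chain lengths
#'   `n = 0, 15, 40, 75` (`eta = 1, 2, 3, 4`) at fixed axial mass
#'   `N * sigma = 500`.  The family whose end distributions display the
#'   growth of the dead zone with branching and whose density profiles
#'   calibrate the dead-zone amplitude `A`.
#' * `preset_force_sweep()` — a monodisperse comb (`m = 3`, `n = 25`,
#'   20 side chains, `N = 560`) swept over grafting spacings
#'   `h = 1..9`, for the axial-force law (slope -3/2) and the induced
#'   persistence length (slope -2).
#' * `preset_moment_grid()` — monodisperse combs with graft
#'   polymerization degree close to 1000 on the grid
#'   `sigma = 0.1, 0.5, 1, 2` times `eta = 1, 1.5, 2, 2.5, 3`
#'   (realised as `n/m` with `m = 4`, `n = 0, 5, 12, 21, 32`), for the
#'   mass-moment vs end-moment proportionality.
#' * `preset_double_comb()` — aggrecan-like double combs at
#'   `sigma = 0.5`, 20 secondary side chains per graft on every third
#'   main-chain unit (`m = 3`), lengths split `n1 + n2 = 50` with
#'   `n1 = 0, 13, 25, 37, 50` (the computed `N = 560` per graft is
#'   reported in all output).
#'
#' @return A list of run definitions, each with elements `label`,
#'   `arch`, `sigma` and (sweeps) `h`.
#' @export
preset_fig_comb_quartet <- function() {
  lapply(c(0L, 15L, 40L, 75L), function(n) {
    arch <- comb_graft(P = 100L, m = 5L, n = n)
    list(label = sprintf("comb_m5_n%d", n), arch = arch,
         sigma = 500 / arch$N)
  })
}

#' @rdname preset_fig_comb_quartet
#' @export
preset_force_sweep <- function() {
  list(list(label = "comb_m3_n25_hsweep",
            arch = comb_graft(P = 20L, m = 3L, n = 25L),
            h = 1:9, report_h = c(2, 3, 4, 6, 8)))
}

#' @rdname preset_fig_comb_quartet
#' @export
preset_moment_grid <- function() {
  ns <- c(0L, 5L, 12L, 21L, 32L)           # eta = 1, 1.5, 2, 2.5, 3 at m = 4
  sigmas <- c(0.1, 0.5, 1, 2)
  runs <- list()
  for (n in ns) for (s in sigmas) {
    P <- as.integer(round(1000 / (n + 4L)))
    arch <- comb_graft(P = P, m = 4L, n = n)
    runs[[length(runs) + 1L]] <- list(
      label = sprintf("comb_m4_n%d_sigma%g", n, s),
      arch = arch, sigma = s,
      eta = topological_ratio(n, 4L))
  }
  runs
}

#' @rdname preset_fig_comb_quartet
#' @export
preset_double_comb <- function() {
  lapply(c(0L, 13L, 25L, 37L, 50L), function(n1) {
    arch <- double_comb_graft(P = 10L, m = 3L, n1 = n1, n2 = 50L - n1)
    list(label = sprintf("dc_n1_%d_n2_%d", n1, 50L - n1),
         arch = arch, sigma = 0.5)
  })
}

preset_registry <- function() {
  list(comb_quartet = preset_fig_comb_quartet,
       force_sweep = preset_force_sweep,
       moment_grid = preset_moment_grid,
       double_comb = preset_double_comb)
}

#' Run a preset experiment or a config file
#'
#' Executes the SCF runs of a named preset (see
#' [preset_fig_comb_quartet()]) or of a single-run YAML config (see
#' [read_brush_config()]), optionally writing per-run profile TSVs
#' (columns `z`, `phi`, `phi_solvent`, `phi_end`, `u`, with `#`-prefixed
#' provenance headers), a `metrics.tsv` table and a `metrics.json`
#' record to an output directory.  Rerunning a preset reproduces
#' byte-identical numeric columns.
#'
#' @param x preset name (`"comb_quartet"`, `"force_sweep"`,
#'   `"moment_grid"`, `"double_comb"`), a config file path, or a config
#'   list.
#' @param out optional output directory (created if needed).
#' @param ... passed to [scf_brush()] / [brush_sweep()].
#' @return Invisibly, a list with `fits` (or `sweep`), the `metrics`
#'   data frame, and for the quartet preset the amplitude-fit object.
#' @export
run_experiment <- function(x, out = NULL, ...) {
  if (is.character(x) && x %in% names(preset_registry())) {
    runs <- preset_registry()[[x]]()
    name <- x
  } else {
    cfg <- read_brush_config(x)
    runs <- list(list(label = "run1", arch = cfg$arch, sigma = cfg$sigma,
                      chi = cfg$chi, solver = cfg$solver))
    name <- "config"
  }
  if (!is.null(out) && !dir.exists(out))
    dir.create(out, recursive = TRUE)

  if (name == "force_sweep") {
    spec <- runs[[1L]]
    sweep <- brush_sweep(spec$arch, h = spec$h, ...)
    force <- axial_force(sweep)
    metrics <- sweep$table
    if (!is.null(out)) {
      write_run_table(metrics, file.path(out, "metrics.tsv"),
                      header = run_header(spec$arch, NA, sweep = TRUE))
      write_run_table(force, file.path(out, "force.tsv"),
                      header = run_header(spec$arch, NA, sweep = TRUE))
    }
    res <- list(sweep = sweep, force = force, metrics = metrics)
  } else {
    fits <- vector("list", length(runs))
    rows <- vector("list", length(runs))
    for (i in seq_along(runs)) {
      spec <- runs[[i]]
      args <- c(list(arch = spec$arch, sigma = spec$sigma,
                     chi = if (is.null(spec$chi)) 0 else spec$chi),
                if (!is.null(spec$solver)) spec$solver, list(...))
      fit <- do.call(scf_brush, args)
      fits[[i]] <- fit
      rows[[i]] <- cbind(data.frame(label = spec$label, N = spec$arch$N,
                                    sigma = spec$sigma),
                         as.data.frame(as.list(coef(fit))),
                         data.frame(iterations = fit$iterations,
                                    residual = fit$residual))
      if (!is.null(out)) {
        prof <- profiles(fit)[, c("z", "phi", "phi_solvent", "phi_end", "u")]
        write_run_table(prof,
                        file.path(out, paste0(spec$label, "_profile.tsv")),
                        header = run_header(spec$arch, spec$sigma, fit = fit))
      }
    }
    metrics <- do.call(rbind, rows)
    res <- list(fits = fits, metrics = metrics)
    if (name == "comb_quartet") {
      res$amplitude <- fit_amplitude_A(fits)
      if (!is.null(out))
        jsonlite::write_json(
          list(A = res$amplitude$A, window = res$amplitude$window,
               n_points = res$amplitude$n_points),
          file.path(out, "amplitude_fit.json"), auto_unbox = TRUE,
          digits = NA)
    }
    if (!is.null(out))
      write_run_table(metrics, file.path(out, "metrics.tsv"),
                      header = c(sprintf("# brushscf %s preset %s",
                                         pkg_version(), name)))
  }
  if (!is.null(out))
    jsonlite::write_json(res$metrics, file.path(out, "metrics.json"),
                         dataframe = "rows", digits = NA)
  invisible(res)
}

pkg_version <- function() {
  as.character(utils::packageVersion("brushscf"))
}

run_header <- function(arch, sigma, fit = NULL, sweep = FALSE) {
  hdr <- c(sprintf("# brushscf %s", pkg_version()),
           sprintf("# architecture: P1=%d m1=%d n1=%d P2=%d m2=%d n2=%d (N=%d, Nb=%d)",
                   arch$P1, arch$m1, arch$n1, arch$P2, arch$m2, arch$n2,
                   arch$N, arch$Nb))
  if (!is.null(fit))
    hdr <- c(hdr,
             sprintf("# sigma=%.10g chi=%.3g zmax=%d", fit$sigma, fit$chi,
                     fit$lattice$zmax),
             sprintf("# solver: mixing=%s tol=%.3g h_mix=%.3g; residual=%.3e iterations=%d",
                     fit$options$mixing, fit$options$tol, fit$options$h_mix,
                     fit$residual, fit$iterations))
  if (sweep) hdr <- c(hdr, "# sweep over grafting spacing h (sigma = 1/h)")
  hdr
}

write_run_table <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
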