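#' Reference run configuration
#'
#' The configuration of the package's reference experiment: kinetic
#' parameters `(d1, d2, a, b) = (0.01, 1, 3.5, 0.25)`, the interval
#' `[0, 10]` with spacing 0.2 (51 nodes), `t` in `[0, 100]` with
#' snapshots every 4 time units, sinusoidal drive/response initial
#' conditions, and control gain `K = 15`.
#'
#' @return A nested list (a run configuration) accepted by
#'   [run_simulation()], [run_synchronization()] and the CLI.
#' @export
reference_config <- function() {
  list(
    params = list(a = 3.5, b = 0.25, d1 = 0.01, d2 = 1),
    grid = list(ndim = 1, extent = 10, n_points = 51),
    time = list(t_end = 100, snapshot_interval = 4, dt = NULL,
                cfl_safety = 0.9),
    ic = list(drive = "reference", response = "reference",
              amplitude = 0.05, seed = 1),
    control = list(K = 15, margin = 1.2,
                   overrides = list(c11 = NULL, c12 = NULL, c22 = NULL)),
    output = list(dir = ".", format = "tsv", write_snapshots = FALSE,
                  convergence_threshold = 1e-6)
  )
}

#' Validate a run configuration
#'
#' Checks the nested structure and the individual fields, constructing
#' the corresponding package objects as it goes; errors name the
#' offending field.
#'
#' @param cfg a nested configuration list as produced by
#'   [reference_config()] or [read_run_config()].
#' @return `cfg`, invisibly, on success.
#' @export
validate_run_config <- function(cfg) {
  need <- function(ok, field) {
    if (!ok) stop("invalid run configuration field: ", field, call. = FALSE)
  }
  need(is.list(cfg$params), "params")
  p <- tryCatch(do.call(selkov_params, cfg$params[c("a", "b", "d1", "d2")]),
                error = function(e) stop("invalid run configuration field: params (",
                                         conditionMessage(e), ")", call. = FALSE))
  need(is.list(cfg$grid), "grid")
  g <- tryCatch(rd_grid(cfg$grid$ndim, cfg$grid$extent, cfg$grid$n_points),
                error = function(e) stop("invalid run configuration field: grid (",
                                         conditionMessage(e), ")", call. = FALSE))
  need(is.list(cfg$time), "time")
  tryCatch(time_config(cfg$time$t_end, cfg$time$snapshot_interval,
                       cfg$time$dt, cfg$time$cfl_safety %||% 0.9),
           error = function(e) stop("invalid run configuration field: time (",
                                    conditionMessage(e), ")", call. = FALSE))
  need(is.list(cfg$ic), "ic")
  known_ic <- c("reference", "perturbed_steady")
  need(cfg$ic$drive %in% known_ic, "ic$drive")
  need(cfg$ic$response %in% known_ic, "ic$response")
  need(is.list(cfg$control), "control")
  K <- cfg$control$K
  need(identical(K, "auto") || (is.numeric(K) && K > 0), "control$K")
  need(is.list(cfg$output), "output")
  need(is.character(cfg$output$format) &&
         cfg$output$format %in% c("tsv", "csv"), "output$format")
  invisible(cfg)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Read / write a run configuration (YAML)
#'
#' Configurations round-trip exactly: writing and re-reading a
#' configuration yields an equivalent validated configuration.
#'
#' @param path file path.
#' @return `read_run_config` returns the validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_run_config(cfg)
  cfg
}

#' @param cfg a run configuration list.
#' @rdname read_run_config
#' @return `write_run_config` returns `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  validate_run_config(cfg)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

cfg_objects <- function(cfg) {
  validate_run_config(cfg)
  params <- do.call(selkov_params, cfg$params[c("a", "b", "d1", "d2")])
  grid <- rd_grid(cfg$grid$ndim, cfg$grid$extent, cfg$grid$n_points)
  tcfg <- time_config(cfg$time$t_end, cfg$time$snapshot_interval,
                      cfg$time$dt, cfg$time$cfl_safety %||% 0.9)
  list(params = params, grid = grid, tcfg = tcfg)
}

cfg_ic <- function(cfg, which, params, grid) {
  kind <- cfg$ic[[which]]
  if (kind == "perturbed_steady") {
    ic_perturbed_steady(params, grid,
                        amplitude = cfg$ic$amplitude %||% 0.05,
                        seed = cfg$ic$seed %||% 1L)
  } else if (which == "drive") {
    ic_drive_reference(grid)
  } else {
    ic_response_reference(grid)
  }
}

#' Run a single (uncontrolled) simulation from a configuration
#'
#' @param cfg a run configuration list.
#' @param write if `TRUE`, snapshot tables and a boundedness summary are
#'   written to `cfg$output$dir`.
#' @return The `rd_run` object, invisibly.
#' @export
run_simulation <- function(cfg, write = isTRUE(cfg$output$write_snapshots)) {
  obj <- cfg_objects(cfg)
  init <- cfg_ic(cfg, "drive", obj$params, obj$grid)
  run <- rd_integrate(init, obj$params, obj$tcfg)
  if (write) write_snapshots(run, cfg$output$dir, cfg$output$format %||% "tsv")
  invisible(run)
}

#' Run a drive-response synchronization from a configuration
#'
#' Uses the configured gain `K`, or — when `control$K` is `"auto"` — the
#' two-stage pipeline of [auto_gains()] (uncontrolled rehearsal run,
#' sup-norm bounds, Lyapunov gain).  The diagnostics table is written to
#' the output directory.
#'
#' @param cfg a run configuration list.
#' @param write if `TRUE`, write the diagnostics table (and snapshots if
#'   configured).
#' @return The `selkov_sync` object, invisibly.
#' @export
run_synchronization <- function(cfg, write = TRUE) {
  obj <- cfg_objects(cfg)
  drive_ic <- cfg_ic(cfg, "drive", obj$params, obj$grid)
  resp_ic <- cfg_ic(cfg, "response", obj$params, obj$grid)
  ov <- cfg$control$overrides %||% list()
  if (identical(cfg$control$K, "auto")) {
    ag <- auto_gains(drive_ic, resp_ic, obj$params, obj$tcfg,
                     margin = cfg$control$margin %||% 1.2)
    gains <- control_gains(ag$K, obj$params, ov$c11, ov$c12, ov$c22)
  } else {
    gains <- control_gains(cfg$control$K, obj$params, ov$c11, ov$c12, ov$c22)
  }
  sync <- synchronize(drive_ic, resp_ic, obj$params, gains, obj$tcfg)
  if (write) {
    dir.create(cfg$output$dir, showWarnings = FALSE, recursive = TRUE)
    write_diagnostics(sync, file.path(cfg$output$dir, "diagnostics.tsv"))
    if (isTRUE(cfg$output$write_snapshots)) {
      write_snapshots(sync, cfg$output$dir, cfg$output$format %||% "tsv")
    }
  }
  invisible(sync)
}

#' Write run snapshots as delimited-text tables
#'
#' One file per snapshot (`snapshot_<index>_t<time>.tsv`), row-major
#' with node coordinates in the leading columns.  Single-system runs
#' write `u1`/`u2`; synchronization runs additionally write the response
#' fields and the error.
#'
#' @param run an `rd_run` or `selkov_sync` object.
#' @param dir output directory (created if needed).
#' @param format `"tsv"` or `"csv"`.
#' @return Character vector of file paths, invisibly.
#' @export
write_snapshots <- function(run, dir = ".", format = c("tsv", "csv")) {
  format <- match.arg(format)
  sep <- if (format == "tsv") "\t" else ","
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  grid <- run$grid
  coord_cols <- if (grid$ndim == 1L) {
    data.frame(x = grid$coords[[1L]])
  } else {
    expand.grid(x = grid$coords[[1L]], y = grid$coords[[2L]],
                KEEP.OUT.ATTRS = FALSE)
  }
  paths <- character(length(run$snapshots))
  for (k in seq_along(run$snapshots)) {
    s <- run$snapshots[[k]]
    tab <- if (inherits(s, "coupled_state")) {
      cbind(coord_cols,
            u1 = as.vector(s$drive$u1), u2 = as.vector(s$drive$u2),
            v1 = as.vector(s$response$u1), v2 = as.vector(s$response$u2),
            e1 = as.vector(s$e1), e2 = as.vector(s$e2))
    } else {
      cbind(coord_cols, u1 = as.vector(s$u1), u2 = as.vector(s$u2))
    }
    tab[] <- lapply(tab, signif, digits = 9)
    paths[k] <- file.path(dir, sprintf("snapshot_%03d_t%g.%s",
                                       k, s$time, format))
    utils::write.table(tab, paths[k], sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(paths)
}
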