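#' Spatial L2 norm of a two-component error field
#'
#' `sqrt( integral over the domain of (e1^2 + e2^2) )`, with the integral
#' evaluated by the trapezoidal rule on the vertex grid — the same
#' quadrature used everywhere in the package, so the Lyapunov functional
#' below is exactly half the square of this norm.
#'
#' @param e1,e2 numeric fields matching `grid`.
#' @param grid an [rd_grid()] object.
#' @return Scalar norm.
#' @examples
#' g <- rd_grid(1, 10, 51)
#' l2_norm(rep(1, 51), rep(0, 51), g)  # sqrt(10)
#' @export
l2_norm <- function(e1, e2, grid) {
  check_field(e1, grid, "e1")
  check_field(e2, grid, "e2")
  sqrt(sum(grid$w * (e1 * e1 + e2 * e2)))
}

#' Lyapunov functional of the synchronization error
#'
#' `V = 1/2 * integral of (e1^2 + e2^2)`, the energy functional whose
#' monotone decay along controlled trajectories certifies asymptotic
#' synchronization.  Identically `0.5 * l2_norm(...)^2`.
#'
#' @inheritParams l2_norm
#' @return Scalar `V >= 0`.
#' @export
lyapunov_v <- function(e1, e2, grid) {
  check_field(e1, grid, "e1")
  check_field(e2, grid, "e2")
  0.5 * sum(grid$w * (e1 * e1 + e2 * e2))
}

as_diagnostics <- function(x) {
  if (inherits(x, "selkov_sync")) return(x$diagnostics)
  if (is.data.frame(x)) return(x)
  stop("expected a 'selkov_sync' run or a diagnostics data frame",
       call. = FALSE)
}

#' Check monotone decrease of the Lyapunov series
#'
#' Verifies `V(t[k+1]) <= V(t[k]) * (1 + tol)` for all consecutive
#' snapshots.  The relative tolerance absorbs floating-point noise once
#' V is near zero.
#'
#' @param series a `selkov_sync` run or a diagnostics data frame with
#'   columns `time` and `lyapunov_v`.
#' @param tol relative tolerance (default `1e-8`).
#' @return List with `pass`, `first_violation` (snapshot index or `NA`),
#'   `first_violation_time`, and `max_increase` (largest relative
#'   one-step increase observed, `-Inf` if the series never increases).
#' @export
check_monotone_decrease <- function(series, tol = 1e-8) {
  d <- as_diagnostics(series)
  v <- d$lyapunov_v
  if (length(v) < 1L) stop("empty diagnostics series", call. = FALSE)
  if (length(v) == 1L) {
    return(list(pass = TRUE, first_violation = NA_integer_,
                first_violation_time = NA_real_, max_increase = -Inf))
  }
  prev <- v[-length(v)]
  nxt <- v[-1L]
  bad <- nxt > prev * (1 + tol)
  rel <- ifelse(prev > 0, nxt / prev - 1, ifelse(nxt > 0, Inf, 0))
  first <- if (any(bad)) which(bad)[1L] + 1L else NA_integer_
  list(pass = !any(bad),
       first_violation = first,
       first_violation_time = if (is.na(first)) NA_real_ else d$time[first],
       max_increase = suppressWarnings(max(rel, na.rm = TRUE)))
}

#' Earliest time at which the error has shrunk by a given factor
#'
#' @param series a `selkov_sync` run or diagnostics data frame with
#'   columns `time` and `l2_error`.
#' @param threshold_ratio fraction in (0, 1); the convergence time is the
#'   first snapshot at which `l2_error <= threshold_ratio * l2_error(0)`.
#' @return The convergence time, `0` when the initial error is already
#'   zero, or `NA` when the threshold is never reached.
#' @export
convergence_time <- function(series, threshold_ratio) {
  if (!is.numeric(threshold_ratio) || threshold_ratio <= 0 ||
      threshold_ratio >= 1) {
    stop("'threshold_ratio' must be in (0, 1)", call. = FALSE)
  }
  d <- as_diagnostics(series)
  e0 <- d$l2_error[1L]
  if (e0 == 0) return(0)
  hit <- which(d$l2_error <= threshold_ratio * e0)
  if (length(hit) == 0L) NA_real_ else d$time[hit[1L]]
}

#' Boundedness and positivity report over a run
#'
#' Global extrema of each field over all snapshots, plus flags for
#' negative and non-finite values.  The continuum solution is known to
#' stay nonnegative and uniformly bounded, so a negative value here
#' signals discretization error — it is reported, never clipped.
#'
#' @param snapshots an `rd_run`, a `selkov_sync` run (drive and response
#'   are reported separately), or a list of [rd_state()] objects.
#' @param M_cap optional upper bound to check against.
#' @return A list of per-field extrema plus logical flags `negative`,
#'   `nonfinite`, and (when `M_cap` is given) `cap_exceeded`.
#' @export
boundedness_report <- function(snapshots, M_cap = NULL) {
  states <- collect_states(snapshots)
  if (length(states) == 0L) stop("no snapshots given", call. = FALSE)
  u1 <- unlist(lapply(states, `[[`, "u1"), use.names = FALSE)
  u2 <- unlist(lapply(states, `[[`, "u2"), use.names = FALSE)
  nonfinite <- any(!is.finite(u1)) || any(!is.finite(u2))
  rng1 <- range(u1, na.rm = TRUE, finite = TRUE)
  rng2 <- range(u2, na.rm = TRUE, finite = TRUE)
  out <- list(min_u1 = rng1[1L], max_u1 = rng1[2L],
              min_u2 = rng2[1L], max_u2 = rng2[2L],
              negative = rng1[1L] < 0 || rng2[1L] < 0,
              nonfinite = nonfinite)
  if (!is.null(M_cap)) {
    out$M_cap <- M_cap
    out$cap_exceeded <- rng1[2L] > M_cap || rng2[2L] > M_cap
  }
  out
}

collect_states <- function(x) {
  if (inherits(x, "rd_run")) return(x$snapshots)
  if (inherits(x, "rd_state")) return(list(x))
  if (inherits(x, "selkov_sync")) {
    return(c(lapply(x$snapshots, `[[`, "drive"),
             lapply(x$snapshots, `[[`, "response")))
  }
  if (is.list(x)) {
    flat <- lapply(x, function(el) {
      if (inherits(el, "rd_state")) list(el) else collect_states(el)
    })
    return(unlist(flat, recursive = FALSE))
  }
  stop("cannot interpret 'snapshots'", call. = FALSE)
}

#' Write a diagnostics series to a delimited-text table
#'
#' One row per snapshot, tab-separated, 9 significant digits.
#'
#' @param series a `selkov_sync` run or diagnostics data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_diagnostics <- function(series, path) {
  d <- as_diagnostics(series)
  d[] <- lapply(d, function(col) if (is.numeric(col)) signif(col, 9) else col)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
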