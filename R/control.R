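#' Sup-norm bound estimates for the gain construction
#'
#' The Lyapunov gain construction needs uniform bounds `K1`, `K2`, `K3`
#' on the drive fields `u1`, `u2` and the (uncontrolled) response field
#' `v1`.  Boundedness of the solution is guaranteed analytically, but
#' the numeric values must be measured: this takes the sup over all
#' supplied snapshots and inflates it by a safety margin.  Bounds use
#' the supremum of the fields themselves, not of absolute values; any
#' negative value encountered (a discretization artifact) raises the
#' `positivity_violation` flag.
#'
#' @param drive an `rd_run`, list of [rd_state()] snapshots, or a single
#'   state, for the drive system.
#' @param response same, for the uncontrolled response system; `NULL`
#'   reuses the drive snapshots (bounds from a single system).
#' @param margin multiplicative safety margin >= 1 (default 1.2).
#' @return An object of class `"bound_estimates"`: list with `K1`, `K2`,
#'   `K3`, `M`, `margin`, `positivity_violation`.
#' @export
estimate_bounds <- function(drive, response = NULL, margin = 1.2) {
  if (!is.numeric(margin) || margin < 1) {
    stop("'margin' must be >= 1", call. = FALSE)
  }
  dstates <- collect_states(drive)
  rstates <- if (is.null(response)) dstates else collect_states(response)
  if (length(dstates) == 0L || length(rstates) == 0L) {
    stop("at least one snapshot is required", call. = FALSE)
  }
  u1 <- unlist(lapply(dstates, `[[`, "u1"), use.names = FALSE)
  u2 <- unlist(lapply(dstates, `[[`, "u2"), use.names = FALSE)
  v1 <- unlist(lapply(rstates, `[[`, "u1"), use.names = FALSE)
  v2 <- unlist(lapply(rstates, `[[`, "u2"), use.names = FALSE)
  K1 <- margin * max(u1)
  K2 <- margin * max(u2)
  K3 <- margin * max(v1)
  structure(list(K1 = K1, K2 = K2, K3 = K3, M = max(K1, K2, K3),
                 margin = margin,
                 positivity_violation = min(u1, u2, v1, v2) < 0),
            class = "bound_estimates")
}

#' @export
print.bound_estimates <- function(x, ...) {
  cat(sprintf("Field bounds (margin %.3g): K1 = %.6g, K2 = %.6g, K3 = %.6g, M = %.6g\n",
              x$margin, x$K1, x$K2, x$K3, x$M))
  if (x$positivity_violation) cat("  warning: negative field values were present\n")
  invisible(x)
}

#' Lyapunov gain from field bounds
#'
#' The smallest gain for which the cubic coupling term is dominated by
#' the linear error, `|v1^2 v2 - u1^2 u2| <= K (|e1| + |e2|)`:
#' `K = max(K3^2, K2 * (K1 + K3))`.
#'
#' @param bounds a [estimate_bounds()] result, or a list with fields
#'   `K1`, `K2`, `K3`.
#' @return The scalar gain `K`.
#' @examples
#' lemma2_gain(list(K1 = 1, K2 = 1, K3 = 1))  # 2
#' @export
lemma2_gain <- function(bounds) {
  k <- c(bounds$K1, bounds$K2, bounds$K3)
  if (length(k) != 3L || any(!is.finite(k)) || any(k < 0)) {
    stop("bounds K1, K2, K3 must be finite and nonnegative", call. = FALSE)
  }
  max(bounds$K3^2, bounds$K2 * (bounds$K1 + bounds$K3))
}

#' Linear feedback gains of the synchronization control law
#'
#' The control law is the unique linear full-state feedback that turns
#' the open-loop error dynamics
#' \deqn{\dot e_1 = d_1 \Delta e_1 + b e_2 - e_1 + (v_1^2 v_2 - u_1^2 u_2) + U_1}
#' \deqn{\dot e_2 = d_2 \Delta e_2 - b e_2 - (v_1^2 v_2 - u_1^2 u_2) + U_2}
#' into the closed loop with linear damping `-2K` on both components:
#' `U1 = -(2K - 1) e1 - b e2`, `U2 = -(2K - b) e2`.  The coefficients can
#' be overridden to reproduce alternative renderings of the law; any
#' override with damping at least `2K` preserves the Lyapunov decay
#' argument.
#'
#' @param K scalar gain > 0, typically from [lemma2_gain()].
#' @param params a [selkov_params()] object (supplies `b`).
#' @param c11,c12,c22 optional overrides of the feedback coefficients in
#'   `U1 = c11 e1 + c12 e2`, `U2 = c22 e2`.
#' @return An object of class `"control_gains"`.
#' @examples
#' control_gains(15, selkov_params())
#' @export
control_gains <- function(K, params, c11 = NULL, c12 = NULL, c22 = NULL) {
  if (!is.numeric(K) || length(K) != 1L || !is.finite(K) || K <= 0) {
    stop("'K' must be a single positive number", call. = FALSE)
  }
  params <- as_selkov_params(params)
  b <- params$b
  structure(list(K = K, b = b,
                 c11 = if (is.null(c11)) -(2 * K - 1) else c11,
                 c12 = if (is.null(c12)) -b else c12,
                 c22 = if (is.null(c22)) -(2 * K - b) else c22),
            class = "control_gains")
}

#' @export
print.control_gains <- function(x, ...) {
  cat(sprintf("Linear synchronization feedback: K = %g (b = %g)\n", x$K, x$b))
  cat(sprintf("  U1 = %g * e1 + %g * e2\n  U2 = %g * e2\n",
              x$c11, x$c12, x$c22))
  invisible(x)
}

#' Evaluate the linear control law on an error field
#'
#' @param e1,e2 error fields (response minus drive), equal shape.
#' @param gains a [control_gains()] object.
#' @return `list(U1 = , U2 = )`, fields of the same shape.
#' @export
control_law <- function(e1, e2, gains) {
  stopifnot(inherits(gains, "control_gains"))
  check_same_shape(e1, e2)
  list(U1 = gains$c11 * e1 + gains$c12 * e2,
       U2 = gains$c22 * e2)
}

#' Pair a drive and a response state
#'
#' @param drive,response [rd_state()] objects on the same grid at the
#'   same time.
#' @return An object of class `"coupled_state"` with fields `drive`,
#'   `response`, `e1`, `e2`, `time`.
#' @export
coupled_state <- function(drive, response) {
  stopifnot(inherits(drive, "rd_state"), inherits(response, "rd_state"))
  if (!identical(drive$grid$n, response$grid$n) ||
      !identical(drive$grid$extent, response$grid$extent)) {
    stop("drive and response must share the same grid", call. = FALSE)
  }
  if (abs(drive$time - response$time) > 1e-9 * max(1, abs(drive$time))) {
    stop("drive and response must share the same time", call. = FALSE)
  }
  structure(list(drive = drive, response = response,
                 e1 = response$u1 - drive$u1,
                 e2 = response$u2 - drive$u2,
                 time = drive$time),
            class = "coupled_state")
}

#' Open-loop (uncontrolled) error dynamics
#'
#' Right-hand side of the error system with `U = 0`:
#' `rhs1 = d1 Lap(e1) + b e2 - e1 + (v1^2 v2 - u1^2 u2)`,
#' `rhs2 = d2 Lap(e2) - b e2 - (v1^2 v2 - u1^2 u2)`.
#' Useful for verifying that directly integrated error dynamics match
#' the difference of separately integrated drive and response
#' trajectories.
#'
#' @param coupled a [coupled_state()].
#' @param params a [selkov_params()] object.
#' @return `list(rhs1 = , rhs2 = )`.
#' @export
open_loop_error_rhs <- function(coupled, params) {
  stopifnot(inherits(coupled, "coupled_state"))
  params <- as_selkov_params(params)
  grid <- coupled$drive$grid
  u <- coupled$drive; v <- coupled$response
  nl <- v$u1 * v$u1 * v$u2 - u$u1 * u$u1 * u$u2
  list(rhs1 = params$d1 * neumann_laplacian(coupled$e1, grid) +
         params$b * coupled$e2 - coupled$e1 + nl,
       rhs2 = params$d2 * neumann_laplacian(coupled$e2, grid) -
         params$b * coupled$e2 - nl)
}

#' Stable time step for the controlled coupled integration
#'
#' The control adds linear damping of rate `2K` to each error component
#' on top of the diffusive stiffness, so the explicit scheme must
#' resolve both.  The combined forward-Euler limit used here is
#' `dt = 2 * cfl_safety / (diffusion_rate + 4K)`, where
#' `diffusion_rate = 2 / stable_dt(..., cfl_safety = 1)`.  It reduces to
#' the diffusion CFL limit as `K -> 0`.
#'
#' @param params a [selkov_params()] object.
#' @param grid an [rd_grid()] object.
#' @param K control gain.
#' @param cfl_safety factor in (0, 1].
#' @return A time step (scalar).
#' @export
coupled_stable_dt <- function(params, grid, K, cfl_safety = 0.9) {
  params <- as_selkov_params(params)
  2 * cfl_safety / (diffusion_rate(params, grid) + 4 * K)
}

#' Co-integrate drive and response systems under linear feedback
#'
#' Integrates the autonomous drive system and the controlled response
#' system with a shared explicit time step; the control input is
#' evaluated from the current error at the beginning of every step (the
#' same time level as the kinetics).  Synchronization diagnostics — the
#' L2 error norm, the Lyapunov functional `V`, per-field sup-norms and
#' the field minimum — are recorded at every stored snapshot.
#'
#' When `tcfg$dt` is `NULL` the step is taken from [coupled_stable_dt()],
#' which accounts for the control damping `2K` as well as diffusion; the
#' diffusion-only CFL step is not sufficient for strong gains.
#'
#' @param drive_ic,response_ic initial [rd_state()]s on the same grid.
#' @param params a [selkov_params()] object.
#' @param gains a [control_gains()] object (use
#'   `control_gains(K, params, c11 = 0, c12 = 0, c22 = 0)` for an
#'   uncontrolled reference run).
#' @param tcfg a [time_config()].
#' @return An object of class `"selkov_sync"`: list with `snapshots`
#'   (list of [coupled_state()]), `diagnostics` (data frame with columns
#'   `time`, `l2_error`, `lyapunov_v`, `sup_u1`, `sup_u2`, `sup_v1`,
#'   `sup_v2`, `min_field`), `params`, `gains`, `grid`, `dt`,
#'   `initial_error`, `final_error`.
#' @examples
#' g <- rd_grid(1, 10, 26)
#' p <- selkov_params()
#' run <- synchronize(ic_drive_reference(g), ic_response_reference(g),
#'                    p, control_gains(15, p), time_config(t_end = 4))
#' run$final_error / run$initial_error
#' @export
synchronize <- function(drive_ic, response_ic, params, gains, tcfg) {
  stopifnot(inherits(drive_ic, "rd_state"), inherits(response_ic, "rd_state"),
            inherits(gains, "control_gains"), inherits(tcfg, "time_config"))
  params <- as_selkov_params(params)
  cs0 <- coupled_state(drive_ic, response_ic)  # validates shared grid/time
  grid <- drive_ic$grid

  dt <- tcfg$dt
  if (is.null(dt)) {
    dt <- coupled_stable_dt(params, grid, gains$K, tcfg$cfl_safety)
  }

  step_pair <- function(pair, h) {
    u <- pair$drive; v <- pair$response
    U <- control_law(v$u1 - u$u1, v$u2 - u$u2, gains)
    u_new <- tryCatch(step_explicit(u, params, h),
                      blowup_error = function(e) blowup_stop(e$time, "drive"))
    v_new <- tryCatch(step_explicit(v, params, h, U),
                      blowup_error = function(e) blowup_stop(e$time, "response"))
    list(drive = u_new, response = v_new, time = u_new$time)
  }

  st <- snapshot_times(tcfg$t_end, tcfg$snapshot_interval)
  pair <- list(drive = drive_ic, response = response_ic, time = drive_ic$time)
  pair$drive$time <- 0; pair$response$time <- 0; pair$time <- 0

  snapshots <- vector("list", length(st))
  diag_rows <- vector("list", length(st))
  record <- function(k, pair) {
    cs <- coupled_state(pair$drive, pair$response)
    snapshots[[k]] <<- cs
    l2 <- l2_norm(cs$e1, cs$e2, grid)
    diag_rows[[k]] <<- data.frame(
      time = cs$time, l2_error = l2,
      lyapunov_v = lyapunov_v(cs$e1, cs$e2, grid),
      sup_u1 = max(cs$drive$u1), sup_u2 = max(cs$drive$u2),
      sup_v1 = max(cs$response$u1), sup_v2 = max(cs$response$u2),
      min_field = min(cs$drive$u1, cs$drive$u2,
                      cs$response$u1, cs$response$u2))
  }
  record(1L, pair)
  if (length(st) > 1L) {
    for (k in seq.int(2L, length(st))) {
      pair <- march_to(pair, st[k], dt, step_pair)
      pair$drive$time <- st[k]; pair$response$time <- st[k]
      record(k, pair)
    }
  }
  diagnostics <- do.call(rbind, diag_rows)
  structure(list(snapshots = snapshots, diagnostics = diagnostics,
                 params = params, gains = gains, grid = grid, dt = dt,
                 initial_error = diagnostics$l2_error[1L],
                 final_error = diagnostics$l2_error[nrow(diagnostics)]),
            class = "selkov_sync")
}

#' @export
print.selkov_sync <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("Drive-response synchronization run: K = %g, t in [0, %g], dt = %.4g\n",
              x$gains$K, d$time[nrow(d)], x$dt))
  cat(sprintf("  L2 error: %.6g -> %.6g (ratio %.3g)\n",
              x$initial_error, x$final_error,
              if (x$initial_error > 0) x$final_error / x$initial_error else 0))
  invisible(x)
}

#' @export
summary.selkov_sync <- function(object, ...) {
  print(object)
  mono <- check_monotone_decrease(object)
  ct <- convergence_time(object, 1e-3)
  cat(sprintf("  V(t) monotone non-increasing: %s\n", mono$pass))
  cat(sprintf("  time to 1e-3 of initial error: %s\n",
              if (is.na(ct)) "not reached" else format(ct)))
  invisible(list(monotone = mono, convergence_time_1e3 = ct))
}

#' @export
plot.selkov_sync <- function(x, ...) {
  d <- x$diagnostics
  pos <- d$l2_error > 0
  graphics::plot(d$time[pos], d$l2_error[pos], type = "b", log = "y",
                 xlab = "t", ylab = expression("||e||"[L^2]),
                 main = "Synchronization error", ...)
  invisible(x)
}

#' Verify the gain-domination bound along a run
#'
#' Checks pointwise, at every node of every snapshot, that the cubic
#' coupling is dominated by the linear error:
#' `|v1^2 v2 - u1^2 u2| <= K * (|e1| + |e2|)`.  Violations are reported,
#' not raised.
#'
#' @param x a `selkov_sync` run, or a list of [coupled_state()]s.
#' @param K the gain to test against.
#' @return List with `holds`, `max_ratio` (sup of lhs/rhs over points
#'   with nonzero rhs), `n_violations`, and `first_violation`
#'   (`c(snapshot, node)` or `NULL`).
#' @export
verify_lemma2_bound <- function(x, K) {
  snaps <- if (inherits(x, "selkov_sync")) x$snapshots
           else if (inherits(x, "coupled_state")) list(x)
           else x
  if (length(snaps) == 0L) stop("no snapshots given", call. = FALSE)
  max_ratio <- 0
  n_viol <- 0L
  first <- NULL
  for (k in seq_along(snaps)) {
    cs <- snaps[[k]]
    stopifnot(inherits(cs, "coupled_state"))
    u <- cs$drive; v <- cs$response
    lhs <- abs(v$u1 * v$u1 * v$u2 - u$u1 * u$u1 * u$u2)
    rhs <- K * (abs(cs$e1) + abs(cs$e2))
    pos <- rhs > 0
    if (any(pos)) max_ratio <- max(max_ratio, lhs[pos] / rhs[pos])
    bad <- lhs > rhs & (pos | lhs > 0)
    if (any(bad)) {
      n_viol <- n_viol + sum(bad)
      if (is.null(first)) first <- c(snapshot = k, node = which(bad)[1L])
    }
  }
  list(holds = n_viol == 0L, max_ratio = max_ratio,
       n_violations = n_viol, first_violation = first)
}

#' Two-stage gain construction from an uncontrolled rehearsal run
#'
#' Runs the drive and the uncontrolled response over the configured
#' horizon, estimates the sup-norm bounds with [estimate_bounds()],
#' derives the gain with [lemma2_gain()] and packages it with
#' [control_gains()].  This is the default pipeline when no gain is
#' supplied explicitly.
#'
#' @param drive_ic,response_ic initial [rd_state()]s on one grid.
#' @param params a [selkov_params()] object.
#' @param tcfg a [time_config()] for the rehearsal integration.
#' @param margin bound-inflation margin passed to [estimate_bounds()].
#' @return List with `bounds`, `K`, and `gains`.
#' @export
auto_gains <- function(drive_ic, response_ic, params, tcfg, margin = 1.2) {
  drive_run <- rd_integrate(drive_ic, params, tcfg)
  resp_run <- rd_integrate(response_ic, params, tcfg)
  bounds <- estimate_bounds(drive_run, resp_run, margin = margin)
  K <- lemma2_gain(bounds)
  list(bounds = bounds, K = K, gains = control_gains(K, params))
}
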