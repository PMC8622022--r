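#' Diffusion-limited stable time step for the explicit scheme
#'
#' The forward-Euler stability limit of the diffusive part of the
#' scheme, scaled by a safety factor:
#' `cfl_safety * dx^2 / (2 * ndim * max(d1, d2))` on a grid with equal
#' spacing per axis (the general-anisotropic form is used when the
#' spacings differ).  The reaction terms add stiffness of their own, so
#' runs that approach this limit with strong kinetics or strong control
#' feedback need a smaller step; see [coupled_stable_dt()] for the
#' controlled (drive-response) limit.
#'
#' @param params a [selkov_params()] object.
#' @param grid an [rd_grid()] object.
#' @param cfl_safety factor in (0, 1].
#' @return A time step (scalar).
#' @examples
#' stable_dt(selkov_params(), rd_grid(1, 10, 51))  # 0.9 * 0.02
#' @export
stable_dt <- function(params, grid, cfl_safety = 0.9) {
  params <- as_selkov_params(params)
  stopifnot(inherits(grid, "rd_grid"))
  if (!is.numeric(cfl_safety) || cfl_safety <= 0 || cfl_safety > 1) {
    stop("'cfl_safety' must be in (0, 1]", call. = FALSE)
  }
  dmax <- max(params$d1, params$d2)
  cfl_safety / (2 * dmax * sum(1 / grid$dx^2))
}

# Explicit-Euler rate of the diffusion operator: the unsafe stability
# limit is 2 / diffusion_rate.
diffusion_rate <- function(params, grid) {
  4 * max(params$d1, params$d2) * sum(1 / grid$dx^2)
}

#' Time-stepping configuration
#'
#' @param t_end final time, >= 0.
#' @param snapshot_interval time between stored snapshots (the reference
#'   runs store every 4 time units); snapshots are always stored at t = 0
#'   and at `t_end`.
#' @param dt explicit time step, or `NULL` to derive it from the CFL rule
#'   at integration time.
#' @param cfl_safety safety factor used when `dt` is derived.
#' @return An object of class `"time_config"`.
#' @export
time_config <- function(t_end, snapshot_interval = 4, dt = NULL,
                        cfl_safety = 0.9) {
  if (!is.numeric(t_end) || t_end < 0) stop("'t_end' must be >= 0", call. = FALSE)
  if (!is.numeric(snapshot_interval) || snapshot_interval <= 0) {
    stop("'snapshot_interval' must be positive", call. = FALSE)
  }
  if (!is.null(dt)) {
    if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive", call. = FALSE)
    if (t_end > 0 && snapshot_interval < dt && snapshot_interval < t_end) {
      stop("'snapshot_interval' must be at least 'dt'", call. = FALSE)
    }
  }
  if (cfl_safety <= 0 || cfl_safety > 1) {
    stop("'cfl_safety' must be in (0, 1]", call. = FALSE)
  }
  structure(list(t_end = as.numeric(t_end),
                 snapshot_interval = as.numeric(snapshot_interval),
                 dt = dt, cfl_safety = cfl_safety),
            class = "time_config")
}

blowup_stop <- function(time, subsystem = NULL) {
  msg <- sprintf("solution blew up (non-finite fields) at t = %.6g%s",
                 time,
                 if (is.null(subsystem)) "" else paste0(" in the ", subsystem,
                                                       " system"))
  stop(structure(class = c("blowup_error", "error", "condition"),
                 list(message = msg, call = NULL,
                      time = time, subsystem = subsystem)))
}

#' One explicit forward-Euler step of the reaction-diffusion system
#'
#' Updates both fields by
#' `u_i <- u_i + dt * (d_i * Lap(u_i) + kinetics_i + forcing_i)` and
#' advances the time stamp.  `forcing` realizes additive control inputs;
#' `NULL` means none.
#'
#' @param state an [rd_state()].
#' @param params a [selkov_params()] object.
#' @param dt time step.
#' @param forcing optional `list(U1 = , U2 = )` of fields matching the
#'   grid.
#' @return The updated [rd_state()].  Raises a `blowup_error` naming the
#'   time reached if the update produces non-finite values.
#' @export
step_explicit <- function(state, params, dt, forcing = NULL) {
  stopifnot(inherits(state, "rd_state"))
  params <- as_selkov_params(params)
  grid <- state$grid
  kin <- selkov_rhs(state$u1, state$u2, params)
  r1 <- params$d1 * neumann_laplacian(state$u1, grid) + kin$f
  r2 <- params$d2 * neumann_laplacian(state$u2, grid) + kin$g
  if (!is.null(forcing)) {
    r1 <- r1 + forcing$U1
    r2 <- r2 + forcing$U2
  }
  u1 <- state$u1 + dt * r1
  u2 <- state$u2 + dt * r2
  t_new <- state$time + dt
  if (!all(is.finite(u1)) || !all(is.finite(u2))) blowup_stop(t_new)
  state$u1 <- u1
  state$u2 <- u2
  state$time <- t_new
  state
}

# Snapshot times: multiples of the interval, always including 0 and t_end.
snapshot_times <- function(t_end, interval) {
  if (t_end <= 0) return(0)
  st <- seq(0, t_end, by = interval)
  if (st[length(st)] < t_end - 1e-12 * max(1, t_end)) st <- c(st, t_end)
  else st[length(st)] <- t_end
  st
}

# March from one snapshot time to the next, landing exactly on 'target'.
# step_fn(state, h) must return the advanced state.
march_to <- function(state, target, dt, step_fn) {
  eps <- dt * 1e-9
  while (state$time < target - eps) {
    h <- min(dt, target - state$time)
    state <- step_fn(state, h)
  }
  state$time <- target
  state
}

#' Integrate a single reaction-diffusion system
#'
#' Repeated explicit forward-Euler steps from the initial state to
#' `tcfg$t_end`, storing snapshots at multiples of the snapshot interval
#' (always including t = 0 and the final time; the partial step before
#' each stored time is shortened so snapshots land exactly).  When
#' `tcfg$dt` is `NULL` the diffusion-limited CFL step from [stable_dt()]
#' is used.  Supplying a `dt` beyond the stability limit is allowed (a
#' warning is issued) and leads to a `blowup_error` once the fields lose
#' finiteness, rather than to silently returned NaNs.
#'
#' @param initial an [rd_state()].
#' @param params a [selkov_params()] object.
#' @param tcfg a [time_config()].
#' @param forcing_fn optional `function(state)` returning
#'   `list(U1 = , U2 = )`, evaluated at the beginning of each step.
#' @return An object of class `"rd_run"`: list with `snapshots` (list of
#'   [rd_state()]), `times`, `final`, `params`, `grid`, `dt`.
#' @examples
#' g <- rd_grid(1, 10, 26)
#' p <- selkov_params()
#' ss <- steady_state(p)
#' init <- rd_state(rep(ss[1], 26), rep(ss[2], 26), g)
#' run <- rd_integrate(init, p, time_config(t_end = 1))
#' @export
rd_integrate <- function(initial, params, tcfg, forcing_fn = NULL) {
  stopifnot(inherits(initial, "rd_state"), inherits(tcfg, "time_config"))
  params <- as_selkov_params(params)
  grid <- initial$grid
  dt <- tcfg$dt
  limit <- stable_dt(params, grid, 1)
  if (is.null(dt)) {
    dt <- tcfg$cfl_safety * limit
  } else if (dt > limit) {
    warning(sprintf("dt = %g exceeds the diffusion stability limit %g",
                    dt, limit), call. = FALSE)
  }
  step_fn <- if (is.null(forcing_fn)) {
    function(state, h) step_explicit(state, params, h)
  } else {
    function(state, h) step_explicit(state, params, h, forcing_fn(state))
  }
  st <- snapshot_times(tcfg$t_end, tcfg$snapshot_interval)
  state <- initial
  snapshots <- vector("list", length(st))
  snapshots[[1L]] <- state
  if (length(st) > 1L) {
    for (k in seq.int(2L, length(st))) {
      state <- march_to(state, st[k], dt, step_fn)
      snapshots[[k]] <- state
    }
  }
  structure(list(snapshots = snapshots, times = st, final = state,
                 params = params, grid = grid, dt = dt),
            class = "rd_run")
}

#' @export
print.rd_run <- function(x, ...) {
  cat(sprintf("Selkov reaction-diffusion run: t in [0, %g], dt = %.4g, %d snapshots\n",
              x$times[length(x$times)], x$dt, length(x$snapshots)))
  f <- x$final
  cat(sprintf("  final u1 in [%.6g, %.6g], u2 in [%.6g, %.6g]\n",
              min(f$u1), max(f$u1), min(f$u2), max(f$u2)))
  invisible(x)
}

#' @export
summary.rd_run <- function(object, ...) {
  rep_ <- boundedness_report(object)
  print(object)
  cat(sprintf("  global bounds: u1 in [%.6g, %.6g], u2 in [%.6g, %.6g]\n",
              rep_$min_u1, rep_$max_u1, rep_$min_u2, rep_$max_u2))
  if (rep_$negative) cat("  note: transient negative values occurred\n")
  invisible(rep_)
}

#' @export
plot.rd_run <- function(x, species = c("u1", "u2"), ...) {
  species <- match.arg(species)
  if (x$grid$ndim == 1L) {
    vals <- sapply(x$snapshots, function(s) s[[species]])
    graphics::matplot(x$grid$coords[[1L]], vals, type = "l", lty = 1,
                      xlab = "x", ylab = species,
                      main = sprintf("%s snapshots", species), ...)
  } else {
    f <- x$final
    graphics::image(x$grid$coords[[1L]], x$grid$coords[[2L]], f[[species]],
                    xlab = "x", ylab = "y",
                    main = sprintf("%s at t = %g", species, f$time), ...)
  }
  invisible(x)
}
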