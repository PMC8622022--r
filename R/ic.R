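#' Reference initial condition for the drive system
#'
#' The smooth sinusoidal perturbation of the homogeneous steady state
#' used by the reference experiments:
#' `u1(x, 0) = 3.5 + 0.1 sin(x)`, `u2(x, 0) = 0.28 + 0.1 sin(x)`.
#' The baseline `(3.5, 0.28)` is the steady state of the default
#' parameter set.  On a 2D grid the same expressions are evaluated in
#' `x` only by default (constant along `y`); `mode = "product"` uses the
#' separable variant `sin(x) * sin(y)` instead.
#'
#' @param grid an [rd_grid()] object.
#' @param mode 2D extension: `"x"` (default) or `"product"`.
#' @return An [rd_state()] at time 0.
#' @export
ic_drive_reference <- function(grid, mode = c("x", "product")) {
  ic_sine(grid, base1 = 3.5, base2 = 0.28, amp = 0.1, freq = 1,
          mode = match.arg(mode))
}

#' Reference initial condition for the response system
#'
#' `v1(x, 0) = 1 + 0.5 sin(0.2 x)`, `v2(x, 0) = 0.6 + 0.5 sin(0.2 x)` —
#' deliberately far from the drive state, so the synchronization error
#' starts at order one.  2D extension as in [ic_drive_reference()].
#'
#' @inheritParams ic_drive_reference
#' @return An [rd_state()] at time 0.
#' @export
ic_response_reference <- function(grid, mode = c("x", "product")) {
  ic_sine(grid, base1 = 1, base2 = 0.6, amp = 0.5, freq = 0.2,
          mode = match.arg(mode))
}

ic_sine <- function(grid, base1, base2, amp, freq, mode) {
  x <- grid$coords[[1L]]
  if (grid$ndim == 1L) {
    s <- sin(freq * x)
  } else {
    y <- grid$coords[[2L]]
    s <- if (mode == "product") outer(sin(freq * x), sin(freq * y))
         else matrix(sin(freq * x), nrow = grid$n[1L], ncol = grid$n[2L])
  }
  rd_state(base1 + amp * s, base2 + amp * s, grid)
}

#' Seeded random perturbation of the homogeneous steady state
#'
#' Multiplies each component of the steady state by
#' `1 + amplitude * U(-1, 1)` noise, node by node, reproducibly from the
#' seed.  This is the stock initial condition for pattern-formation
#' runs: the noise seeds every spatial mode, so the linearly unstable
#' (Turing) band can be selected by the dynamics.  The caller's RNG
#' state is left untouched.
#'
#' @param params a [selkov_params()] object.
#' @param grid an [rd_grid()] object.
#' @param amplitude relative perturbation amplitude, >= 0 (default 0.05).
#' @param seed integer seed.
#' @return An [rd_state()] at time 0.
#' @export
ic_perturbed_steady <- function(params, grid, amplitude = 0.05, seed = 1L) {
  params <- as_selkov_params(params)
  if (!is.numeric(amplitude) || amplitude < 0) {
    stop("'amplitude' must be nonnegative", call. = FALSE)
  }
  ss <- steady_state(params)
  npts <- prod(grid$n)
  noise <- with_local_seed(seed, stats::runif(2L * npts, -1, 1))
  shape <- function(z) if (grid$ndim == 1L) z else matrix(z, nrow = grid$n[1L])
  u1 <- ss[["u1"]] * (1 + amplitude * shape(noise[seq_len(npts)]))
  u2 <- ss[["u2"]] * (1 + amplitude * shape(noise[npts + seq_len(npts)]))
  rd_state(u1, u2, grid)
}

# Evaluate 'expr' under a fixed seed without disturbing the caller's RNG.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
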