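#' Selkov reaction kinetics
#'
#' Evaluates the reaction terms of the Selkov glycolysis model
#' elementwise on a pair of concentration fields:
#' \deqn{f(u_1, u_2) = b u_2 - u_1 + u_1^2 u_2,}
#' \deqn{g(u_1, u_2) = a - b u_2 - u_1^2 u_2.}
#' Species 1 is the autocatalytic product, species 2 the substrate; the
#' cubic term \eqn{u_1^2 u_2} is the autocatalytic step.  The kinetics are
#' autonomous (no explicit time dependence).  The two rates satisfy the
#' structural identity \eqn{f + g = a - u_1} exactly, which the
#' implementation preserves to machine precision by sharing the computed
#' product terms.
#'
#' @param u1,u2 numeric fields (vectors or matrices) of equal shape,
#'   finite.
#' @param params a [selkov_params()] object.
#' @return A list with fields `f` and `g`, each the same shape as `u1`.
#' @examples
#' p <- selkov_params(a = 3.5, b = 0.25)
#' selkov_rhs(3.5, 0.28, p)  # steady state: both rates vanish
#' @export
selkov_rhs <- function(u1, u2, params) {
  params <- as_selkov_params(params)
  check_same_shape(u1, u2)
  if (!all(is.finite(u1)) || !all(is.finite(u2))) {
    stop("non-finite values in concentration fields", call. = FALSE)
  }
  auto <- u1 * u1 * u2   # autocatalytic term, shared so that f + g = a - u1
  lin <- params$b * u2
  list(f = lin - u1 + auto, g = params$a - lin - auto)
}

#' Homogeneous steady state of the Selkov model
#'
#' The unique spatially uniform equilibrium.  Adding the two kinetic
#' rates gives \eqn{f + g = a - u_1}, so \eqn{u_1^* = a}; substituting
#' into \eqn{g = 0} then yields \eqn{u_2^* = a / (b + a^2)}.  The
#' denominator is always positive, so the steady state exists for every
#' admissible parameter set and both components are positive.
#'
#' @param params a [selkov_params()] object.
#' @return Named numeric vector `c(u1 = a, u2 = a / (b + a^2))`.
#' @examples
#' steady_state(selkov_params(a = 3.5, b = 0.25))  # (3.5, 0.28)
#' @export
steady_state <- function(params) {
  params <- as_selkov_params(params)
  c(u1 = params$a, u2 = params$a / (params$b + params$a^2))
}

#' Jacobian of the Selkov kinetics
#'
#' Linearization of the reaction terms at a given state
#' \eqn{(u_1, u_2)}:
#' \deqn{J = \begin{pmatrix} -1 + 2 u_1 u_2 & b + u_1^2 \\
#'                           -2 u_1 u_2     & -(b + u_1^2) \end{pmatrix}.}
#' The column sums are \eqn{(-1, 0)}, the derivative of the identity
#' \eqn{f + g = a - u_1}.
#'
#' @param params a [selkov_params()] object.
#' @param state length-2 numeric (the evaluation point); defaults to the
#'   homogeneous steady state.
#' @return A 2x2 numeric matrix.
#' @examples
#' selkov_jacobian(selkov_params())
#' @export
selkov_jacobian <- function(params, state = steady_state(params)) {
  params <- as_selkov_params(params)
  if (length(state) != 2L || !all(is.finite(state))) {
    stop("'state' must be two finite numbers", call. = FALSE)
  }
  u1 <- state[[1]]; u2 <- state[[2]]
  cross <- 2 * u1 * u2
  diag2 <- params$b + u1^2
  matrix(c(-1 + cross, -cross, diag2, -diag2), nrow = 2L)
}

#' Linear (Turing) stability analysis of the homogeneous steady state
#'
#' Computes the dispersion relation of the Selkov reaction-diffusion
#' model: for each squared wavenumber \eqn{k^2} the growth rate is the
#' largest real part of the eigenvalues of \eqn{J - \mathrm{diag}(d_1,
#' d_2)\, k^2}, where \eqn{J} is the kinetic Jacobian at the steady
#' state.  The steady state is *Turing unstable* when it is stable
#' without diffusion (trace of \eqn{J} negative, determinant positive)
#' but some mode with \eqn{k^2 > 0} has a positive growth rate; the
#' resulting diffusion-driven instability is what produces the spatial
#' patterns seen in simulations at the reference parameters.
#'
#' The default wavenumber grid samples the Neumann eigenmodes of an
#' interval of length `extent`, \eqn{k = m\pi/L} for \eqn{m = 0, \dots,}
#' `modes`, which are the admissible modes under zero-flux boundaries.
#'
#' @param params a [selkov_params()] object.
#' @param k2 optional numeric vector of squared wavenumbers, nonnegative
#'   and sorted increasing.  When `NULL`, the Neumann-mode default grid
#'   is used.
#' @param extent domain length used for the default mode grid.
#' @param modes highest mode index for the default grid.
#' @return An object of class `"turing_analysis"` with fields
#'   `steady_state`, `jacobian`, `trace`, `determinant`,
#'   `homogeneous_stable`, `turing_unstable`, `max_growth_rate`,
#'   `k2_max` (argmax of the growth rate) and `dispersion`
#'   (a data frame with columns `k2`, `growth_rate`).
#' @examples
#' ta <- turing_analysis(selkov_params())
#' ta$turing_unstable
#' @export
turing_analysis <- function(params, k2 = NULL, extent = 10, modes = 64) {
  params <- as_selkov_params(params)
  if (is.null(k2)) {
    k2 <- ((0:modes) * pi / extent)^2
  }
  if (length(k2) == 0L) stop("wavenumber grid must be nonempty", call. = FALSE)
  if (any(!is.finite(k2)) || any(k2 < 0)) {
    stop("wavenumber grid must be finite and nonnegative", call. = FALSE)
  }
  if (is.unsorted(k2)) stop("wavenumber grid must be sorted", call. = FALSE)

  ss <- steady_state(params)
  J <- selkov_jacobian(params, ss)
  growth <- vapply(k2, function(kk) {
    a11 <- J[1, 1] - params$d1 * kk
    a22 <- J[2, 2] - params$d2 * kk
    tr <- a11 + a22
    dt <- a11 * a22 - J[1, 2] * J[2, 1]
    disc <- tr^2 - 4 * dt
    if (disc >= 0) (tr + sqrt(disc)) / 2 else tr / 2
  }, numeric(1))

  tr0 <- J[1, 1] + J[2, 2]
  det0 <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  homog <- tr0 < 0 && det0 > 0
  pos <- k2 > 0
  max_pos <- if (any(pos)) max(growth[pos]) else -Inf
  structure(list(
    steady_state = ss,
    jacobian = J,
    trace = tr0,
    determinant = det0,
    homogeneous_stable = homog,
    turing_unstable = homog && max_pos > 0,
    max_growth_rate = max(growth),
    k2_max = k2[which.max(growth)],
    dispersion = data.frame(k2 = k2, growth_rate = growth)
  ), class = "turing_analysis")
}

#' @export
print.turing_analysis <- function(x, ...) {
  cat("Turing stability analysis of the Selkov steady state\n")
  cat(sprintf("  steady state      : (%.6g, %.6g)\n",
              x$steady_state[[1]], x$steady_state[[2]]))
  cat(sprintf("  trace, determinant: %.6g, %.6g\n", x$trace, x$determinant))
  cat(sprintf("  homogeneous stable: %s\n", x$homogeneous_stable))
  cat(sprintf("  Turing unstable   : %s\n", x$turing_unstable))
  cat(sprintf("  max growth rate   : %.6g at k^2 = %.6g  (%d modes sampled)\n",
              x$max_growth_rate, x$k2_max, nrow(x$dispersion)))
  invisible(x)
}

#' @export
as.data.frame.turing_analysis <- function(x, ...) x$dispersion

#' Write a dispersion relation to a delimited-text table
#'
#' @param x a [turing_analysis()] object.
#' @param path output file path; columns `k2` and `growth_rate`,
#'   tab-separated.
#' @return `path`, invisibly.
#' @export
write_dispersion <- function(x, path) {
  stopifnot(inherits(x, "turing_analysis"))
  d <- x$dispersion
  d[] <- lapply(d, signif, digits = 9)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
plot.turing_analysis <- function(x, ...) {
  graphics::plot(x$dispersion$k2, x$dispersion$growth_rate, type = "l",
                 xlab = expression(k^2), ylab = "growth rate",
                 main = "Dispersion relation", ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  invisible(x)
}

check_same_shape <- function(x, y) {
  if (length(x) != length(y) || !identical(dim(x), dim(y))) {
    stop("fields must have identical shape", call. = FALSE)
  }
  invisible(TRUE)
}
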