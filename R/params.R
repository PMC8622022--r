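#' Kinetic parameters of the Selkov reaction-diffusion model
#'
#' Bundles the four positive constants of the model: the substrate
#' injection rate `a`, the linear kinetic rate `b`, and the diffusion
#' coefficients `d1`, `d2` of the two species.  The defaults are the
#' reference parameter set used throughout the package's worked examples,
#' `(d1, d2, a, b) = (0.01, 1, 3.5, 0.25)`, which places the model in the
#' Turing (diffusion-driven) instability regime.
#'
#' @param a substrate injection rate (concentration/time), > 0.
#' @param b linear kinetic rate (1/time), > 0.
#' @param d1 diffusion coefficient of species 1 (length^2/time), > 0.
#' @param d2 diffusion coefficient of species 2 (length^2/time), > 0.
#'
#' @return An object of class `"selkov_params"`: a list with components
#'   `a`, `b`, `d1`, `d2`.
#' @examples
#' p <- selkov_params()
#' steady_state(p)
#' @export
selkov_params <- function(a = 3.5, b = 0.25, d1 = 0.01, d2 = 1) {
  vals <- c(a = a, b = b, d1 = d1, d2 = d2)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0) {
      stop("'", nm, "' must be a single finite positive number", call. = FALSE)
    }
  }
  structure(list(a = a, b = b, d1 = d1, d2 = d2), class = "selkov_params")
}

#' @export
print.selkov_params <- function(x, ...) {
  cat("Selkov kinetic parameters\n")
  cat(sprintf("  a = %g, b = %g, d1 = %g, d2 = %g\n", x$a, x$b, x$d1, x$d2))
  invisible(x)
}

as_selkov_params <- function(x) {
  if (inherits(x, "selkov_params")) return(x)
  if (is.list(x) && all(c("a", "b", "d1", "d2") %in% names(x))) {
    return(selkov_params(x$a, x$b, x$d1, x$d2))
  }
  stop("'params' must be a 'selkov_params' object", call. = FALSE)
}
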