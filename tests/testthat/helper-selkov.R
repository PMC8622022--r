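# Shared fixtures: the reference experiment (interval [0,10], 51 nodes,
# (d1,d2,a,b) = (0.01,1,3.5,0.25)) and memoized long runs reused across
# test files.

ref_params <- function() selkov_params(a = 3.5, b = 0.25, d1 = 0.01, d2 = 1)
ref_grid <- function(n = 51L) rd_grid(1, 10, n)

.run_cache <- new.env(parent = emptyenv())
cached <- function(name, expr) {
  if (is.null(.run_cache[[name]])) .run_cache[[name]] <- force(expr)
  .run_cache[[name]]
}

# Controlled reference run, K = 15, t in [0, 100].
ref_sync <- function() cached("ref_sync", {
  g <- ref_grid()
  p <- ref_params()
  synchronize(ic_drive_reference(g), ic_response_reference(g), p,
              control_gains(15, p), time_config(t_end = 100))
})

# Same run with the control switched off (zeroed feedback coefficients).
ref_uncontrolled <- function() cached("ref_uncontrolled", {
  g <- ref_grid()
  p <- ref_params()
  synchronize(ic_drive_reference(g), ic_response_reference(g), p,
              control_gains(15, p, c11 = 0, c12 = 0, c22 = 0),
              time_config(t_end = 100))
})

# Two-stage gain pipeline: uncontrolled rehearsal -> bounds -> K -> run.
ref_auto <- function() cached("ref_auto", {
  g <- ref_grid()
  p <- ref_params()
  tcfg <- time_config(t_end = 100)
  ag <- auto_gains(ic_drive_reference(g), ic_response_reference(g), p, tcfg)
  sync <- synchronize(ic_drive_reference(g), ic_response_reference(g), p,
                      ag$gains, tcfg)
  c(ag, list(sync = sync))
})

random_field <- function(grid, rng = c(-1, 1)) {
  v <- stats::runif(prod(grid$n), rng[1], rng[2])
  if (grid$ndim == 1L) v else matrix(v, nrow = grid$n[1L])
}
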