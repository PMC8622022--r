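test_that("Lyapunov gain formula max(K3^2, K2 (K1 + K3))", {
  expect_equal(lemma2_gain(list(K1 = 1, K2 = 1, K3 = 1)), 2)
  expect_equal(lemma2_gain(list(K1 = 0, K2 = 0, K3 = 0)), 0)
  expect_equal(lemma2_gain(list(K1 = 4, K2 = 1, K3 = 4)), 16)
  expect_error(lemma2_gain(list(K1 = -1, K2 = 1, K3 = 1)), "nonnegative")
})

test_that("bound estimation takes sup norms with a safety margin", {
  g <- rd_grid(1, 10, 11)
  drive <- rd_state(rep(3.5, 11), rep(0.28, 11), g)
  resp <- rd_state(rep(1, 11), rep(0.6, 11), g)
  b1 <- estimate_bounds(drive, resp, margin = 1)
  expect_equal(c(b1$K1, b1$K2, b1$K3), c(3.5, 0.28, 1))
  expect_false(b1$positivity_violation)
  b2 <- estimate_bounds(drive, resp, margin = 1.2)
  expect_equal(c(b2$K1, b2$K2, b2$K3), c(4.2, 0.336, 1.2))
  # sup of the fields themselves, not absolute values; negativity flagged
  neg <- rd_state(c(rep(2, 10), -0.5), rep(0.3, 11), g)
  b3 <- estimate_bounds(neg, resp, margin = 1)
  expect_equal(b3$K1, 2)
  expect_true(b3$positivity_violation)
  expect_error(estimate_bounds(list(), resp), "snapshot")
  expect_error(estimate_bounds(drive, resp, margin = 0.5), "margin")
})

test_that("control law is the unique feedback producing -2K damping", {
  p <- ref_params()
  # no control at synchrony
  gains <- control_gains(15, p)
  U <- control_law(rep(0, 5), rep(0, 5), gains)
  expect_equal(U$U1, rep(0, 5))
  expect_equal(U$U2, rep(0, 5))
  # hand value: K = 15, b = 0.25, e = (1, 0)
  U <- control_law(1, 0, gains)
  expect_equal(U$U1, -29)
  expect_equal(U$U2, 0)

  # closed-loop identity on random fields, several gains:
  #   b e2 - e1 + U1 = -2K e1   and   -b e2 + U2 = -2K e2
  set.seed(21)
  g <- ref_grid()
  for (K in c(0.2, 2, 15, 80)) {
    gn <- control_gains(K, p)
    for (i in 1:5) {
      e1 <- random_field(g, c(-3, 3))
      e2 <- random_field(g, c(-3, 3))
      U <- control_law(e1, e2, gn)
      lhs1 <- p$b * e2 - e1 + U$U1
      lhs2 <- -p$b * e2 + U$U2
      expect_lt(max(abs(lhs1 + 2 * K * e1)), 1e-12 * max(1, 2 * K * max(abs(e1))))
      expect_lt(max(abs(lhs2 + 2 * K * e2)), 1e-12 * max(1, 2 * K * max(abs(e2))))
    }
  }
  expect_error(control_law(1:3, 1:2, gains), "shape")
})

test_that("open-loop error dynamics match the difference of the subsystems", {
  p <- ref_params()
  g <- ref_grid()
  set.seed(31)
  u <- rd_state(3.5 + random_field(g, c(-0.3, 0.3)),
                0.28 + random_field(g, c(-0.05, 0.05)), g)
  v <- rd_state(1 + random_field(g, c(-0.3, 0.3)),
                0.6 + random_field(g, c(-0.05, 0.05)), g)
  cs <- coupled_state(u, v)
  # zero error has zero rhs
  z <- coupled_state(u, u)
  rhs0 <- open_loop_error_rhs(z, p)
  expect_equal(rhs0$rhs1, rep(0, 51))
  expect_equal(rhs0$rhs2, rep(0, 51))
  # hand value of the cubic coupling at u = (1,1), v = (2,1): 4 - 1 = 3
  g3 <- rd_grid(1, 1, 3)
  cs3 <- coupled_state(rd_state(rep(1, 3), rep(1, 3), g3),
                       rd_state(rep(2, 3), rep(1, 3), g3))
  rhs3 <- open_loop_error_rhs(cs3, selkov_params(a = 1, b = 1))
  # rhs1 = b e2 - e1 + nl = 0 - 1 + 3 on a uniform field
  expect_equal(rhs3$rhs1, rep(2, 3))
  expect_equal(rhs3$rhs2, rep(-3, 3))

  # one explicit-Euler step of the error system equals the difference of
  # separately stepped drive and response (linearity of the update)
  dt <- 0.004
  e1_new <- cs$e1 + dt * open_loop_error_rhs(cs, p)$rhs1
  e2_new <- cs$e2 + dt * open_loop_error_rhs(cs, p)$rhs2
  u1s <- step_explicit(u, p, dt)
  v1s <- step_explicit(v, p, dt)
  expect_equal(v1s$u1 - u1s$u1, e1_new, tolerance = 1e-12)
  expect_equal(v1s$u2 - u1s$u2, e2_new, tolerance = 1e-12)

  # antisymmetry: swapping drive and response negates the error dynamics,
  # and the linear feedback negates with the error
  sw <- coupled_state(v, u)
  rhs <- open_loop_error_rhs(cs, p)
  rhs_sw <- open_loop_error_rhs(sw, p)
  expect_equal(rhs_sw$rhs1, -rhs$rhs1, tolerance = 1e-12)
  expect_equal(rhs_sw$rhs2, -rhs$rhs2, tolerance = 1e-12)
  gn <- control_gains(5, p)
  U <- control_law(cs$e1, cs$e2, gn)
  U_sw <- control_law(sw$e1, sw$e2, gn)
  expect_equal(U_sw$U1, -U$U1)
  expect_equal(U_sw$U2, -U$U2)
})

test_that("identical initial conditions stay synchronized with zero control", {
  p <- ref_params()
  g <- ref_grid(26)
  ic <- ic_drive_reference(g)
  sync <- synchronize(ic, ic, p, control_gains(15, p),
                      time_config(t_end = 8, snapshot_interval = 2))
  expect_equal(sync$diagnostics$l2_error, rep(0, 5))
  expect_equal(sync$diagnostics$lyapunov_v, rep(0, 5))
})

test_that("diagnostics identity V = l2^2 / 2 holds along runs", {
  d <- ref_sync()$diagnostics
  expect_equal(d$lyapunov_v, d$l2_error^2 / 2, tolerance = 1e-12)
})

test_that("gain-domination bound: worked example and violation reporting", {
  g3 <- rd_grid(1, 1, 3)
  cs <- coupled_state(rd_state(rep(1, 3), rep(1, 3), g3),
                      rd_state(rep(2, 3), rep(1, 3), g3))
  # bounds K1=1, K2=1, K3=2 give K = max(4, 3) = 4; |nl| = 3 <= 4 * |e1|
  K <- lemma2_gain(list(K1 = 1, K2 = 1, K3 = 2))
  expect_equal(K, 4)
  rep_ok <- verify_lemma2_bound(list(cs), K)
  expect_true(rep_ok$holds)
  expect_equal(rep_ok$max_ratio, 0.75)
  rep_bad <- verify_lemma2_bound(list(cs), 1)
  expect_false(rep_bad$holds)
  expect_equal(rep_bad$max_ratio, 3)
  expect_equal(unname(rep_bad$first_violation["snapshot"]), 1)
  # at synchrony the bound holds trivially
  z <- coupled_state(cs$drive, cs$drive)
  expect_true(verify_lemma2_bound(list(z), 0.1)$holds)
})

test_that("auto-gain pipeline synchronizes across the kinetic parameter range", {
  g <- ref_grid()
  corners <- expand.grid(a = c(1, 4), b = c(0.1, 1))
  for (i in seq_len(nrow(corners))) {
    p <- selkov_params(a = corners$a[i], b = corners$b[i], d1 = 0.01, d2 = 1)
    drive_ic <- ic_perturbed_steady(p, g, amplitude = 0.1, seed = 100 + i)
    resp_ic <- ic_perturbed_steady(p, g, amplitude = 0.3, seed = 200 + i)
    tcfg <- time_config(t_end = 100, cfl_safety = 0.5)
    ag <- auto_gains(drive_ic, resp_ic, p, tcfg)
    expect_gt(ag$K, 0)
    sync <- synchronize(drive_ic, resp_ic, p, ag$gains, tcfg)
    ratio <- sync$final_error / sync$initial_error
    expect_lt(ratio, 1e-4)
    expect_true(check_monotone_decrease(sync)$pass)
    expect_true(verify_lemma2_bound(sync, ag$K)$holds)
  }
})

test_that("coupled time step accounts for the control damping", {
  p <- ref_params()
  g <- ref_grid()
  # reduces to the diffusion limit as K -> 0
  expect_equal(coupled_stable_dt(p, g, 1e-12, cfl_safety = 0.9),
               stable_dt(p, g, 0.9), tolerance = 1e-9)
  expect_lt(coupled_stable_dt(p, g, 15), stable_dt(p, g))
  # and the reference controlled run is stable at that step
  expect_s3_class(ref_sync(), "selkov_sync")
})
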