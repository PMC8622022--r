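test_that("reaction rates match hand-computed values", {
  p <- ref_params()
  # all product terms vanish at the origin
  r <- selkov_rhs(0, 0, p)
  expect_identical(r$f, 0)
  expect_identical(r$g, p$a)
  # steady state of the reference parameters
  r <- selkov_rhs(3.5, 0.28, p)
  expect_equal(r$f, 0, tolerance = 1e-12)
  expect_equal(r$g, 0, tolerance = 1e-12)
  # generic point, a = b = 1: f = 1 - 1 + 1, g = 1 - 1 - 1
  r <- selkov_rhs(1, 1, selkov_params(a = 1, b = 1))
  expect_equal(r$f, 1)
  expect_equal(r$g, -1)
  expect_error(selkov_rhs(c(1, NaN), c(1, 1), p), "non-finite")
  expect_error(selkov_rhs(1:3, 1:2, p), "shape")
})

test_that("f + g equals a - u1 to machine precision on random fields", {
  set.seed(42)
  for (i in 1:20) {
    p <- selkov_params(a = runif(1, 0.5, 5), b = runif(1, 0.1, 2))
    u1 <- runif(40, 0, 6)
    u2 <- runif(40, 0, 6)
    r <- selkov_rhs(u1, u2, p)
    expect_equal(r$f + r$g, p$a - u1, tolerance = 1e-14)
  }
})

test_that("homogeneous steady state has the closed form (a, a/(b+a^2))", {
  expect_equal(unname(steady_state(ref_params())), c(3.5, 0.28),
               tolerance = 1e-14)
  expect_equal(unname(steady_state(selkov_params(a = 1, b = 1))), c(1, 0.5),
               tolerance = 1e-14)
  # substituted back, both rates vanish
  set.seed(7)
  for (i in 1:20) {
    p <- selkov_params(a = runif(1, 0.1, 5), b = runif(1, 0.05, 3))
    ss <- steady_state(p)
    r <- selkov_rhs(ss[["u1"]], ss[["u2"]], p)
    expect_lt(abs(r$f), 1e-12)
    expect_lt(abs(r$g), 1e-12)
    expect_true(all(ss > 0))
  }
})

test_that("kinetic Jacobian matches closed form and finite differences", {
  p <- ref_params()
  expect_equal(selkov_jacobian(p, c(3.5, 0.28)),
               matrix(c(0.96, -1.96, 12.5, -12.5), 2), tolerance = 1e-12)
  expect_equal(selkov_jacobian(p, c(0, 0)),
               matrix(c(-1, 0, p$b, -p$b), 2))
  set.seed(11)
  for (i in 1:10) {
    pt <- runif(2, 0.2, 4)
    J <- selkov_jacobian(p, pt)
    # columns sum to the gradient of f + g = a - u1
    expect_equal(colSums(J), c(-1, 0), tolerance = 1e-12)
    # central finite-difference oracle
    h <- 1e-6
    num <- matrix(NA_real_, 2, 2)
    for (j in 1:2) {
      dp <- dm <- pt
      dp[j] <- pt[j] + h
      dm[j] <- pt[j] - h
      rp <- selkov_rhs(dp[1], dp[2], p)
      rm <- selkov_rhs(dm[1], dm[2], p)
      num[, j] <- c(rp$f - rm$f, rp$g - rm$g) / (2 * h)
    }
    expect_equal(J, num, tolerance = 1e-6)
  }
})

test_that("Turing analysis flags diffusion-driven instability", {
  p <- ref_params()
  ta <- turing_analysis(p)
  expect_true(ta$homogeneous_stable)
  expect_lt(ta$trace, 0)
  expect_gt(ta$determinant, 0)
  expect_true(ta$turing_unstable)
  expect_gt(ta$max_growth_rate, 0)
  expect_gt(ta$k2_max, 0)

  # equal diffusion cannot destabilize a kinetically stable state
  ta_eq <- turing_analysis(selkov_params(a = 3.5, b = 0.25, d1 = 1, d2 = 1))
  expect_true(ta_eq$homogeneous_stable)
  expect_false(ta_eq$turing_unstable)
  expect_lt(ta_eq$max_growth_rate, 0)

  # the k^2 = 0 growth rate is the leading kinetic eigenvalue
  ev <- eigen(selkov_jacobian(p), only.values = TRUE)$values
  expect_equal(ta$dispersion$growth_rate[ta$dispersion$k2 == 0],
               max(Re(ev)), tolerance = 1e-12)

  expect_error(turing_analysis(p, k2 = numeric(0)), "nonempty")
  expect_error(turing_analysis(p, k2 = c(-1, 0)), "nonnegative")
  expect_error(turing_analysis(p, k2 = c(2, 1)), "sorted")
})

test_that("dispersion table serializes to delimited text", {
  ta <- turing_analysis(ref_params(), modes = 8)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dispersion(ta, path)
  tab <- read.delim(path)
  expect_named(tab, c("k2", "growth_rate"))
  expect_equal(nrow(tab), 9)
  expect_equal(tab$growth_rate, ta$dispersion$growth_rate, tolerance = 1e-8)
})
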