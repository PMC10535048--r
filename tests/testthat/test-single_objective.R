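test_that("stationarity residual has the right shape and analytic roots", {
  params <- smoothing_params(beta = 1, gamma = 50)
  for (n in c(2L, 4L, 16L)) {
    b <- basis_from_matrix(matrix(seq_len(2L * n) / n, 2L, n))
    r <- residual_single(runif(n, -1, 1), c(0.3, -0.2), b, params)
    expect_length(r, n + 2L)
  }
  # two contacts, one region point: multipliers solved by hand make the
  # ideal bipole stationary
  f1 <- 3.2; f2 <- -1.7; gamma <- 50
  b <- basis_from_matrix(matrix(c(f1, f2), 1L))
  g1 <- tanh(gamma) + gamma / cosh(gamma)^2
  lam <- c((f2 - f1) / (2 * g1), (f1 + f2) / 2)
  r <- residual_single(c(1, -1), lam, b, smoothing_params(1, gamma))
  expect_lt(max(abs(r)), 1e-8)
})

test_that("analytic Jacobians match finite differences on random states", {
  set.seed(5)
  params <- smoothing_params(beta = 2, gamma = 12)
  for (i in 1:10) {
    b <- basis_from_matrix(matrix(rnorm(20), 5L, 4L))
    z <- c(runif(4, -1, 1), runif(2, -2, 2))
    jac <- jacobian_single(z[1:4], z[5:6], b, params)
    fd <- fd_jacobian(function(zz) residual_single(zz[1:4], zz[5:6], b, params),
                      z)
    expect_equal(jac, fd, tolerance = 1e-6 * max(abs(jac)),
                 ignore_attr = TRUE)
    # constraint rows are the balance-constraint gradients by construction
    bc <- balance_constraints(z[1:4], params$gamma, gradients = TRUE)
    expect_equal(unname(jac[5L, 1:4]), bc$grad_h1)
    expect_equal(unname(jac[6L, 1:4]), bc$grad_h2)
    # purity
    expect_identical(jac, jacobian_single(z[1:4], z[5:6], b, params))
  }
})

test_that("two-contact problems are forced to the ideal bipole", {
  b <- basis_from_matrix(matrix(c(5, 2), 1L))  # f1 > f2
  pts <- multistart_solve(b, settings = solver_settings(n_starts = 20, seed = 1))
  best <- global_optimum(pts)
  expect_equal(best$config$alpha, c(1, -1), tolerance = 1e-9)
  expect_equal(best$objective, 3, tolerance = 1e-9)
  b2 <- basis_from_matrix(matrix(c(-4, 1), 1L))  # f2 > f1
  best2 <- global_optimum(multistart_solve(
    b2, settings = solver_settings(n_starts = 20, seed = 1)))
  expect_equal(best2$config$alpha, c(-1, 1), tolerance = 1e-9)
  expect_equal(best2$objective, 5, tolerance = 1e-9)
})

test_that("multistart solving is deterministic and residuals re-verify", {
  basis <- test4_basis(c(0.5e-3, 1.5e-3, 0.5e-3))
  st <- solver_settings(n_starts = 40, seed = 9)
  p1 <- multistart_solve(basis, settings = st)
  p2 <- multistart_solve(basis, settings = st)
  expect_identical(lapply(p1, `[[`, "alpha"), lapply(p2, `[[`, "alpha"))
  expect_identical(vapply(p1, `[[`, "", "classification"),
                   vapply(p2, `[[`, "", "classification"))
  # every reported point satisfies the stationarity system from scratch
  params <- smoothing_params(beta = attr(p1, "beta_final"), gamma = 50)
  for (p in p1) {
    r <- residual_single(p$alpha, p$lambda, basis, params)
    expect_lt(max(abs(r)) / max(abs(basis$values)), 1e-9)
  }
})

test_that("mirrored steering finds the negated optimum", {
  basis <- test4_basis(c(0.5e-3, 1.5e-3, 0.5e-3))
  st <- solver_settings(n_starts = 60, seed = 13)
  best <- global_optimum(multistart_solve(basis, settings = st))
  neg <- multistart_solve(basis, settings = st, sense = "min")
  mins <- Filter(function(p) p$classification == "minimum", neg)
  worst <- mins[[which.min(vapply(mins, `[[`, 0, "objective"))]]
  expect_equal(worst$objective, -best$objective,
               tolerance = 1e-6 * abs(best$objective))
  expect_equal(worst$config$alpha, -best$config$alpha, tolerance = 1e-4)
})

test_that("uniform field rescaling rescales objectives and not fractions", {
  basis <- test4_basis(rbind(c(0, 1e-3, 0), c(0.5e-3, 1e-3, 1e-3)))
  st <- solver_settings(n_starts = 40, seed = 21)
  p1 <- global_optimum(multistart_solve(basis, settings = st))
  scaled <- basis
  scaled$values <- basis$values * 250
  p2 <- global_optimum(multistart_solve(scaled, settings = st))
  expect_equal(p2$objective, 250 * p1$objective, tolerance = 1e-9)
  expect_equal(p2$config$alpha, p1$config$alpha, tolerance = 1e-10)
})

test_that("bordered-Hessian classification agrees with projected eigenvalues", {
  # maximize -||x||^2 under two independent linear constraints: interior
  # stationary point is a maximum
  expect_identical(classify_critical(-2 * diag(3), rbind(c(1, 1, 1),
                                                         c(1, -1, 0))),
                   "maximum")
  expect_identical(classify_critical(2 * diag(3), rbind(c(1, 1, 1),
                                                        c(1, -1, 0))),
                   "minimum")
  # indefinite quadratic with one linear constraint leaving both signs
  expect_identical(classify_critical(diag(c(2, -2, 1)), rbind(c(0, 0, 1))),
                   "saddle")
  # negating the Hessian mirrors the classification
  set.seed(6)
  for (i in 1:10) {
    q <- qr.Q(qr(matrix(rnorm(16), 4L)))
    h <- q %*% diag(-c(1, 2, 3, 4)) %*% t(q)
    jg <- matrix(rnorm(4), 1L)
    cls <- classify_critical(h, jg)
    expect_identical(cls, "maximum")
    expect_identical(classify_critical(-h, jg), "minimum")
  }
  # rank-deficient constraint gradients are flagged invalid
  expect_identical(
    as.character(classify_critical(-diag(3), rbind(c(1, 1, 1), c(2, 2, 2)))),
    "invalid")
  # fully constrained (zero-dimensional) feasible sets default to maximum
  expect_identical(classify_critical(-diag(2), diag(2)), "maximum")
})

test_that("fraction correction restores the exact constraints", {
  expect_equal(correct_fractions(c(0.6, -0.6))$alpha, c(1, -1))
  cfg <- correct_fractions(c(0.5, 0.3, -0.8))
  expect_equal(cfg$alpha, c(0.625, 0.375, -1))
  expect_identical(cfg$status, "corrected")
  # idempotent on already-corrected input
  expect_equal(correct_fractions(cfg)$alpha, cfg$alpha)
  expect_error(correct_fractions(c(0, 0, 0)), "degenerate")
  expect_error(correct_fractions(c(0.5, -0.2)), "not balanced")
})

test_that("rounding to significant digits preserves exact sums", {
  r1 <- round_fractions(configuration(c(1, -1), "corrected"))
  expect_identical(r1$alpha, c(1, -1))
  r2 <- round_fractions(configuration(c(0.625, 0.375, -1), "corrected"))
  expect_identical(r2$alpha, c(0.625, 0.375, -1))
  # a full-precision 16-contact solution rounds to exactly balanced sums
  best <- global_optimum(left_axon_solution())
  r <- round_fractions(best$config)
  expect_identical(r$status, "rounded")
  expect_equal(sum(r$alpha[r$alpha > 0]), 1, tolerance = 1e-12)
  expect_equal(sum(r$alpha[r$alpha < 0]), -1, tolerance = 1e-12)
  expect_true(all(abs(r$alpha) <= 1 + 1e-9))
})
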