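roi_p <- function() test4_basis(c(0.5e-3, 1.5e-3, 0.5e-3), name = "p")
roa_q <- function() test4_basis(c(-0.5e-3, 1.5e-3, -2e-3), name = "q",
                                role = "roa")

test_that("generalized residual reduces to the single-objective system", {
  params <- smoothing_params(beta = 1, gamma = 30)
  bases <- list(roi_p(), roa_q())
  a <- c(0.4, -0.7, 0.5, -0.2)
  lam <- c(0.3, -0.1)
  r0 <- residual_multi(a, lam, numeric(0), bases, params,
                       c(q = 100), character(0))
  expect_equal(r0, residual_single(a, lam, bases[[1L]], params))
  r1 <- residual_multi(a, lam, 0.5, bases, params, c(q = 100), "q")
  expect_length(r1, 4L + 2L + 1L)
  expect_error(residual_multi(a, lam, 0.5, bases, params,
                              c(bogus = 1), "q"), "unknown region")
})

test_that("generalized Jacobian matches finite differences", {
  set.seed(8)
  params <- smoothing_params(beta = 2, gamma = 10)
  for (i in 1:8) {
    bases <- list(basis_from_matrix(matrix(rnorm(12), 3L, 4L), name = "p"),
                  basis_from_matrix(matrix(rnorm(8), 2L, 4L), name = "q"))
    z <- c(runif(4, -1, 1), runif(3, -2, 2))
    eps <- c(q = runif(1, -1, 1))
    jac <- jacobian_multi(z[1:4], z[5:6], z[7], bases, params, eps, "q")
    fd <- fd_jacobian(function(zz) {
      residual_multi(zz[1:4], zz[5:6], zz[7], bases, params, eps, "q")
    }, z)
    expect_equal(jac, fd, tolerance = 1e-6 * max(abs(jac)), ignore_attr = TRUE)
  }
})

test_that("KKT validation passes and fails for the textbook cases", {
  mk_point <- function(mu, obj_q, eps_q) {
    structure(list(alpha = c(1, -1), lambda = c(0, 0),
                   mu = if (is.null(mu)) numeric(0) else c(q = mu),
                   objectives_smooth = c(p = 1, q = obj_q),
                   epsilon = c(q = eps_q),
                   active_set = if (is.null(mu)) integer(0) else 2L),
              class = "critical_point")
  }
  # interior solution: constraint slack, mu = 0
  v1 <- validate_kkt(mk_point(NULL, obj_q = 0.5, eps_q = 2))
  expect_true(v1$valid)
  # negative multiplier violates dual feasibility
  v2 <- validate_kkt(mk_point(-0.5, obj_q = 2, eps_q = 2))
  expect_false(v2$valid)
  expect_false(v2$checks$pass[grepl("dual_feasibility", v2$checks$condition)])
  # slack constraint that is still "paid for" violates complementarity
  v3 <- validate_kkt(mk_point(0.3, obj_q = 1.8, eps_q = 2))
  expect_false(v3$valid)
  expect_false(
    v3$checks$pass[grepl("complementary_slackness", v3$checks$condition)])
  # infeasible point
  v4 <- validate_kkt(mk_point(NULL, obj_q = 3, eps_q = 2))
  expect_false(v4$valid)
})

test_that("a cap far above the optimum recovers the single-objective solution", {
  st <- solver_settings(n_starts = 40, seed = 17)
  single <- global_optimum(multistart_solve(roi_p(), settings = st))
  multi <- solve_epsilon(list(roi_p(), roa_q()),
                         c(q = 1e3 * abs(single$objective)), settings = st)
  best <- global_optimum(multi)
  expect_equal(best$objective, single$objective,
               tolerance = 1e-8 * abs(single$objective))
  expect_equal(best$config$alpha, single$config$alpha, tolerance = 1e-6)
  expect_true(validate_kkt(best)$valid)
})

test_that("capping a region at zero against itself forces a near-zero optimum", {
  b1 <- roi_p()
  b2 <- b1
  b2$region$name <- "q"
  b2$region$role <- "roa"
  st <- solver_settings(n_starts = 60, seed = 19)
  sols <- suppressWarnings(
    solve_epsilon(list(b1, b2), c(q = 0), settings = st))
  best <- global_optimum(sols)
  expect_false(is.null(best))
  scale <- max(abs(b1$values))
  expect_lt(abs(best$objective) / scale, 1e-4)
})

test_that("dominance filtering matches a quadratic-scan oracle", {
  pts <- rbind(c(1, 1), c(2, 2), c(3, 0))
  expect_equal(dominance_filter(pts, c("max", "max")),
               rbind(c(2, 2), c(3, 0)))
  expect_equal(dominance_filter(rbind(c(4, 2)), c("max", "min")),
               rbind(c(4, 2)))
  set.seed(10)
  m <- matrix(runif(200), 100L, 2L)
  flags <- pareto_nondominated(m, c("max", "min"))
  oracle <- vapply(seq_len(nrow(m)), function(i) {
    !any(vapply(seq_len(nrow(m)), function(j) {
      j != i && m[j, 1L] >= m[i, 1L] && m[j, 2L] <= m[i, 2L] &&
        (m[j, 1L] > m[i, 1L] || m[j, 2L] < m[i, 2L])
    }, logical(1L)))
  }, logical(1L))
  expect_identical(flags, oracle)
  expect_error(pareto_nondominated(m, "max"), "dimension")
})

test_that("epsilon sweeps produce monotone fronts anchored at the optimum", {
  st <- solver_settings(n_starts = 40, seed = 23)
  bases <- list(roi_p(), roa_q())
  single <- global_optimum(multistart_solve(bases[[1L]], settings = st))
  front <- pareto_sweep(bases, n_eps = 6, settings = st)
  expect_s3_class(front, "pareto_front")
  expect_gt(nrow(front), 2L)
  # loosest cap reproduces the unconstrained optimum
  expect_equal(front$obj_p[1L], single$objective,
               tolerance = 1e-6 * abs(single$objective))
  # primary objective non-increasing as the cap tightens
  expect_true(all(diff(front$obj_smooth_p) <=
                    1e-8 * max(abs(front$obj_smooth_p))))
  # all reported points re-validate
  for (p in attr(front, "points")) expect_true(validate_kkt(p)$valid)
})

test_that("epsilon schedules validate their shape", {
  expect_error(epsilon_schedule(), "named")
  expect_error(epsilon_schedule(q = c(1, 3, 2)), "monotone")
  s <- epsilon_schedule(q = c(3, 2, 1))
  expect_s3_class(s, "epsilon_schedule")
})
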