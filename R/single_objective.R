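#' Solver settings for multistart stationarity solving
#'
#' @param n_starts Number of Latin-hypercube initial guesses.
#' @param alpha_bounds Interval for initial current-fraction guesses.
#' @param multiplier_bounds Interval for initial Lagrange/KKT multiplier
#'   guesses (the multipliers of the internally rescaled problem, which is
#'   solved with fields normalized to order one).
#' @param seed RNG seed; multistart runs are deterministic given the seed.
#' @param residual_tol Convergence tolerance on the max-abs root residual.
#' @param imag_tol Magnitude below which imaginary parts would be treated
#'   as zero. The solver works in real arithmetic, where complex
#'   stationary points manifest as non-convergence, so this tolerance is
#'   recorded for the contract but the discard rule is residual-based.
#' @param dedup_tol L-infinity distance on corrected fractions below which
#'   two solutions are merged as duplicates.
#' @param rounding_digits Significant digits for reported fractions.
#' @param max_iter Maximum damped-Newton iterations per stage.
#' @param bipole_starts Append one deterministic start per ordered
#'   contact pair: an ideal bipole with multipliers seeded from the
#'   stationarity conditions of its two active contacts. The smoothed
#'   maxima sit near such vertices of the balanced-fraction set (the
#'   near-zero fractions on their small-magnitude tanh branch) and have
#'   narrow basins that uniform random starts reach unreliably.
#' @param gamma_schedule Continuation schedule for the smooth-abs scale;
#'   `NULL` means a five-stage geometric ramp from 5 up to the requested
#'   `gamma` (the stiff tanh at the final scale traps root solvers when
#'   started cold).
#' @param beta_rounds Smooth-max continuation rounds: the solve is
#'   repeated with `beta` multiplied by 4 between rounds, and solutions
#'   are re-verified at the final `beta`. The default is a single round
#'   at the `beta * max|F| ~ 10` scale: because the exact objective is a
#'   maximum of linear functions (convex in the fractions), sharpening
#'   `beta` much further turns interior smoothed maxima into saddles
#'   with needle-thin basins.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(n_starts = 200, alpha_bounds = c(-1, 1),
                            multiplier_bounds = c(-10, 10), seed = 1,
                            residual_tol = 1e-10, imag_tol = 1e-8,
                            dedup_tol = 1e-4, rounding_digits = 3,
                            max_iter = 200, gamma_schedule = NULL,
                            beta_rounds = 1, bipole_starts = TRUE) {
  stopifnot(n_starts >= 1, residual_tol > 0, dedup_tol > 0, max_iter >= 1,
            beta_rounds >= 1, length(alpha_bounds) == 2L,
            length(multiplier_bounds) == 2L)
  structure(list(n_starts = as.integer(n_starts),
                 alpha_bounds = as.numeric(alpha_bounds),
                 multiplier_bounds = as.numeric(multiplier_bounds),
                 seed = as.integer(seed), residual_tol = residual_tol,
                 imag_tol = imag_tol, dedup_tol = dedup_tol,
                 rounding_digits = as.integer(rounding_digits),
                 max_iter = as.integer(max_iter),
                 gamma_schedule = gamma_schedule,
                 beta_rounds = as.integer(beta_rounds),
                 bipole_starts = isTRUE(bipole_starts)),
            class = "solver_settings")
}

## Run code under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

## ---------------------------------------------------------------------------
## Generalized KKT residual and Jacobian, shared by the single- and
## multi-objective paths. `bvals` is a list of basis-value matrices (the
## primary region first), `betas` the per-region smooth-max scales,
## `epsilon`/`active` the inequality caps and active-set indices into the
## secondary regions (2..Q). Unknowns: z = (alpha, lambda1, lambda2,
## mu[active]).

kkt_residual_core <- function(z, bvals, betas, gamma, epsilon, active) {
  n <- ncol(bvals[[1L]])
  alpha <- z[seq_len(n)]
  lambda <- z[n + 1:2]
  mu <- if (length(active)) z[n + 2L + seq_along(active)] else numeric(0)
  bc <- balance_constraints(alpha, gamma, gradients = TRUE)
  f1 <- drop(bvals[[1L]] %*% alpha)
  sw1 <- softmax_weights(f1, betas[1L])
  grad <- drop(crossprod(bvals[[1L]], sw1$w * (1 + betas[1L] * (f1 - sw1$s)))) -
    lambda[1L] * bc$grad_h1 - lambda[2L] * bc$grad_h2
  gres <- numeric(length(active))
  for (j in seq_along(active)) {
    i <- active[j]
    fi <- drop(bvals[[i]] %*% alpha)
    swi <- softmax_weights(fi, betas[i])
    grad <- grad - mu[j] *
      drop(crossprod(bvals[[i]], swi$w * (1 + betas[i] * (fi - swi$s))))
    gres[j] <- swi$s - epsilon[i]
  }
  c(grad, bc$h1, bc$h2, gres)
}

kkt_jacobian_core <- function(z, bvals, betas, gamma, epsilon, active) {
  n <- ncol(bvals[[1L]])
  alpha <- z[seq_len(n)]
  lambda <- z[n + 1:2]
  mu <- if (length(active)) z[n + 2L + seq_along(active)] else numeric(0)
  bc <- balance_constraints(alpha, gamma, gradients = TRUE)
  h <- smooth_max_hess(bvals[[1L]], alpha, betas[1L])
  diag(h) <- diag(h) - lambda[1L] * balance_h1_hess_diag(alpha, gamma)
  nact <- length(active)
  m_grads <- matrix(0, nrow = n, ncol = nact)
  for (j in seq_along(active)) {
    i <- active[j]
    fi <- drop(bvals[[i]] %*% alpha)
    swi <- softmax_weights(fi, betas[i])
    m_grads[, j] <- drop(crossprod(bvals[[i]],
                                   swi$w * (1 + betas[i] * (fi - swi$s))))
    h <- h - mu[j] * smooth_max_hess(bvals[[i]], alpha, betas[i])
  }
  dim_tot <- n + 2L + nact
  jac <- matrix(0, dim_tot, dim_tot)
  jac[seq_len(n), seq_len(n)] <- h
  jac[seq_len(n), n + 1L] <- -bc$grad_h1
  jac[seq_len(n), n + 2L] <- -bc$grad_h2
  jac[n + 1L, seq_len(n)] <- bc$grad_h1
  jac[n + 2L, seq_len(n)] <- bc$grad_h2
  if (nact) {
    jac[seq_len(n), n + 2L + seq_len(nact)] <- -m_grads
    jac[n + 2L + seq_len(nact), seq_len(n)] <- t(m_grads)
  }
  jac
}

#' Stationarity residual of the single-objective Lagrangian
#'
#' The gradient of the Lagrangian `L = smooth_max(F(alpha), beta) -
#' lambda1 h1 - lambda2 h2` with respect to `(alpha, lambda)`: the first
#' `n` entries are the stationarity conditions in the fractions, the last
#' two are the balance-constraint residuals `h1` and `h2`. Roots of this
#' system are the constrained critical points.
#'
#' @param alpha Current fractions (length n).
#' @param lambda The two equality multipliers.
#' @param basis A `basis_field_set`.
#' @param params A [smoothing_params()]; a `NULL` `beta` is resolved with
#'   [auto_beta()].
#' @return Numeric vector of length `n + 2`.
#' @export
residual_single <- function(alpha, lambda, basis, params) {
  alpha <- as_alpha(alpha)
  if (length(alpha) != ncol(basis$values)) {
    stop("dimension error: fractions vs contacts", call. = FALSE)
  }
  beta <- if (is.null(params$beta)) auto_beta(basis) else params$beta
  kkt_residual_core(c(alpha, lambda), list(basis$values), beta,
                    params$gamma, numeric(0), integer(0))
}

#' Jacobian of the single-objective stationarity system
#'
#' Closed-form `(n+2) x (n+2)` Jacobian of [residual_single()]; its
#' fraction block is the Hessian of the Lagrangian and the constraint
#' rows are the balance-constraint gradients.
#'
#' @inheritParams residual_single
#' @return An `(n+2) x (n+2)` matrix.
#' @export
jacobian_single <- function(alpha, lambda, basis, params) {
  alpha <- as_alpha(alpha)
  if (length(alpha) != ncol(basis$values)) {
    stop("dimension error: fractions vs contacts", call. = FALSE)
  }
  beta <- if (is.null(params$beta)) auto_beta(basis) else params$beta
  kkt_jacobian_core(c(alpha, lambda), list(basis$values), beta,
                    params$gamma, numeric(0), integer(0))
}

## Damped Newton iteration with backtracking line search on the residual
## norm. Returns the final iterate whether or not it converged.
newton_solve <- function(z0, res_fn, jac_fn, tol, max_iter) {
  z <- z0
  r <- res_fn(z)
  nr <- max(abs(r))
  for (it in seq_len(max_iter)) {
    if (!is.finite(nr)) return(list(z = z, converged = FALSE, res_norm = nr))
    if (nr <= tol) return(list(z = z, converged = TRUE, res_norm = nr,
                               iterations = it - 1L))
    j <- jac_fn(z)
    step <- tryCatch(solve(j, -r), error = function(e) NULL)
    improved <- FALSE
    if (!is.null(step) && all(is.finite(step))) {
      t_ <- 1
      for (ls in 1:30) {
        z_new <- z + t_ * step
        r_new <- res_fn(z_new)
        nr_new <- max(abs(r_new))
        if (is.finite(nr_new) && nr_new < nr) {
          z <- z_new; r <- r_new; nr <- nr_new; improved <- TRUE
          break
        }
        t_ <- t_ / 2
      }
    }
    if (!improved) {
      ## Levenberg fallback for (near-)singular Jacobians: damped
      ## Gauss-Newton steps with escalating regularization.
      jtj <- crossprod(j)
      jtr <- crossprod(j, r)
      mu <- 1e-8 * max(diag(jtj), 1)
      for (lm in 1:8) {
        step <- tryCatch(
          solve(jtj + mu * diag(nrow(jtj)), -jtr),
          error = function(e) NULL)
        if (!is.null(step) && all(is.finite(step))) {
          z_new <- z + drop(step)
          r_new <- res_fn(z_new)
          nr_new <- max(abs(r_new))
          if (is.finite(nr_new) && nr_new < nr) {
            z <- z_new; r <- r_new; nr <- nr_new; improved <- TRUE
            break
          }
        }
        mu <- mu * 10
      }
    }
    if (!improved) return(list(z = z, converged = nr <= tol, res_norm = nr))
  }
  list(z = z, converged = nr <= tol, res_norm = nr, iterations = max_iter)
}

## Internal problem scaling: each region's basis is divided by its
## bipole-spread scale so fields, multipliers and beta are order one in
## the solved system. Multipliers map back as lambda = s1 * lambda_scaled,
## mu_i = s1 / s_i * mu_scaled.
region_scale <- function(values) {
  spread <- max(apply(values, 1L, max) - apply(values, 1L, min))
  if (spread <= 0) spread <- max(abs(values), 1e-300)
  spread
}

## The per-coordinate stationarity factor q(y) = tanh(y) + y sech^2(y)
## (minus the h1 gradient at y = gamma * alpha) rises from 0 to ~1.1997
## at y ~ 1.199 and then falls back toward 1. Small-fraction stationary
## coordinates have two roots; constrained maxima live on the rising
## branch (the falling branch gives fold saddles). Invert the rising
## branch by bisection, extended oddly, clamping beyond the fold.
g_inv_rising <- function(cval) {
  g_fun <- function(y) tanh(y) + y / cosh(y)^2
  y_fold <- 1.19
  vapply(cval, function(ci) {
    s <- sign(ci)
    ci <- abs(ci)
    if (ci < 1e-14) return(0)
    if (ci >= g_fun(y_fold)) return(s * y_fold)
    lo <- 0
    hi <- y_fold
    for (k in 1:60) {
      mid <- (lo + hi) / 2
      if (g_fun(mid) < ci) lo <- mid else hi <- mid
    }
    s * (lo + hi) / 2
  }, numeric(1L))
}

## Deterministic structured starts: every ordered (anode, cathode) pair
## as an ideal bipole, refined by a few fixed-point rounds - equality
## multipliers from the two active contacts' stationarity equations, the
## remaining fractions at the rising-branch root of their own
## stationarity condition - so that Newton enters the (narrow) basin of
## the vertex maximum rather than a fold saddle. Inequality multipliers
## are seeded at zero.
bipole_seed_starts <- function(bvals1, beta1, gamma_final, nact) {
  n <- ncol(bvals1)
  pairs <- expand.grid(a = seq_len(n), c_ = seq_len(n))
  pairs <- pairs[pairs$a != pairs$c_, , drop = FALSE]
  ## For larger arrays, seed only the most promising vertices in each
  ## steering direction (best maxima candidates and their mirrors, the
  ## minima); the Latin-hypercube starts still roam everywhere.
  if (nrow(pairs) > 72L) {
    score <- vapply(seq_len(nrow(pairs)), function(i) {
      d <- bvals1[, pairs$a[i]] - bvals1[, pairs$c_[i]]
      if (beta1 > 0) max(d) else -min(d)
    }, numeric(1L))
    keep <- union(order(score, decreasing = TRUE)[1:36],
                  order(score)[1:36])
    pairs <- pairs[keep, , drop = FALSE]
  }
  out <- matrix(0, nrow(pairs), n + 2L + nact)
  k <- 0L
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$a[i]
    c_ <- pairs$c_[i]
    {
      alpha <- numeric(n)
      alpha[a] <- 1
      alpha[c_] <- -1
      lam <- c(0, 0)
      others <- setdiff(seq_len(n), c(a, c_))
      for (round in 1:3) {
        f <- drop(bvals1 %*% alpha)
        sw <- softmax_weights(f, beta1)
        grad <- drop(crossprod(bvals1, sw$w * (1 + beta1 * (f - sw$s))))
        bc <- balance_constraints(alpha, gamma_final, gradients = TRUE)
        lam <- tryCatch(
          solve(rbind(c(bc$grad_h1[a], 1), c(bc$grad_h1[c_], 1)),
                c(grad[a], grad[c_])),
          error = function(e) c(0, 0))
        if (abs(lam[1L]) < 1e-12) break
        alpha[others] <- g_inv_rising((lam[2L] - grad[others]) / lam[1L]) /
          gamma_final
      }
      k <- k + 1L
      out[k, seq_len(n)] <- alpha
      out[k, n + 1:2] <- lam
    }
  }
  out
}

## One multistart sweep over a (possibly inequality-constrained) KKT
## system given *scaled* basis values. Continuation: gamma_schedule
## stages, then beta_rounds doublings-by-4 of beta. Returns converged raw
## iterates.
multistart_core <- function(bvals, betas, gamma, epsilon, active, settings,
                            warm_starts = NULL) {
  n <- ncol(bvals[[1L]])
  nact <- length(active)
  dim_tot <- n + 2L + nact
  starts <- with_seed(settings$seed, lhs::randomLHS(settings$n_starts, dim_tot))
  ab <- settings$alpha_bounds
  mb <- settings$multiplier_bounds
  starts[, seq_len(n)] <- ab[1L] + starts[, seq_len(n)] * (ab[2L] - ab[1L])
  starts[, n + seq_len(2L + nact)] <-
    mb[1L] + starts[, n + seq_len(2L + nact)] * (mb[2L] - mb[1L])
  ## Structured and warm starts are already near final-scale solutions:
  ## they skip the gamma continuation and solve at the final scales only.
  structured <- rep(FALSE, nrow(starts))
  if (!is.null(warm_starts) && length(warm_starts)) {
    starts <- rbind(starts, do.call(rbind, warm_starts))
    structured <- c(structured, rep(TRUE, length(warm_starts)))
  }
  gammas <- settings$gamma_schedule
  if (is.null(gammas)) {
    g0 <- min(5, gamma)
    gammas <- unique(g0 * (gamma / g0)^(seq(0, 1, length.out = 5L)))
  }
  if (isTRUE(settings$bipole_starts)) {
    bs <- bipole_seed_starts(bvals[[1L]], betas[1L], gamma, nact)
    starts <- rbind(starts, bs)
    structured <- c(structured, rep(TRUE, nrow(bs)))
  }
  beta_stages <- betas
  stages <- list()
  for (g in gammas) stages[[length(stages) + 1L]] <- list(betas = betas, gamma = g)
  if (settings$beta_rounds > 1L) {
    for (r in seq_len(settings$beta_rounds - 1L)) {
      beta_stages <- beta_stages * 4
      stages[[length(stages) + 1L]] <- list(betas = beta_stages, gamma = gamma)
    }
  }
  final <- stages[[length(stages)]]
  final_stages <- stages[seq(length(gammas), length(stages))]
  sols <- list()
  n_discarded <- 0L
  for (i in seq_len(nrow(starts))) {
    z <- starts[i, ]
    ok <- TRUE
    for (st in if (structured[i]) final_stages else stages) {
      fit <- newton_solve(
        z,
        function(zz) kkt_residual_core(zz, bvals, st$betas, st$gamma,
                                       epsilon, active),
        function(zz) kkt_jacobian_core(zz, bvals, st$betas, st$gamma,
                                       epsilon, active),
        settings$residual_tol, settings$max_iter)
      if (!fit$converged) { ok <- FALSE; break }
      z <- fit$z
    }
    if (!ok || any(abs(z[seq_len(n)]) > 1.5)) {
      n_discarded <- n_discarded + 1L
      next
    }
    sols[[length(sols) + 1L]] <- list(z = z, res_norm = fit$res_norm,
                                      start_index = i)
  }
  list(solutions = sols, n_discarded = n_discarded,
       betas_final = final$betas, gamma_final = final$gamma)
}

#' Multistart solve of the single-objective fraction optimization
#'
#' Draws Latin-hypercube initial guesses for `(alpha, lambda)`, runs a
#' damped Newton iteration with the analytic Jacobian on the stationarity
#' system (with continuation in the smoothing scales), discards starts
#' that fail to converge, merges duplicates, classifies every surviving
#' critical point with the bordered Hessian, and returns the points
#' sorted by objective value, best first. The run is deterministic for a
#' fixed seed. Internally the basis fields are rescaled to order one; all
#' reported objectives and multipliers are on the original field scale.
#'
#' @param basis A `basis_field_set`.
#' @param params A [smoothing_params()]; `beta = NULL` selects
#'   `auto_beta(basis, sense = sense)`.
#' @param settings A [solver_settings()].
#' @param sense `"max"` to steer toward the largest positive field,
#'   `"min"` toward the largest negative one (flips the sign of an
#'   automatic `beta`).
#' @return An object of class `critical_points`: a list of critical
#'   points, each with fractions (raw and corrected), multipliers,
#'   residual norm, classification, exact and smooth objectives, and the
#'   originating start index. Empty (with a warning) if no start
#'   converged.
#' @export
multistart_solve <- function(basis, params = smoothing_params(),
                             settings = solver_settings(),
                             sense = c("max", "min")) {
  sense <- match.arg(sense)
  stopifnot(inherits(basis, "basis_field_set"))
  s1 <- region_scale(basis$values)
  beta_raw <- if (is.null(params$beta)) auto_beta(basis, sense = sense) else
    params$beta
  bvals <- list(basis$values / s1)
  run <- multistart_core(bvals, beta_raw * s1, params$gamma, numeric(0),
                         integer(0), settings)
  pts <- finalize_points(run, bvals, list(basis), s1, numeric(0), integer(0),
                         params$gamma, settings)
  attr(pts, "beta") <- beta_raw
  attr(pts, "beta_final") <- run$betas_final[1L] / s1
  attr(pts, "gamma") <- run$gamma_final
  attr(pts, "n_discarded") <- run$n_discarded
  if (!length(pts)) warning("no converged stationary points; empty solution list")
  pts
}

## Shared post-processing: dedup, correction, classification, objectives,
## multiplier rescaling, sorting. `bvals` are scaled values, `bases` the
## raw basis_field_sets (primary first), `scales` per-region scales,
## `epsilon` the full Q-length cap vector in *raw* field units (entry 1
## unused), `active` indices into 2..Q.
finalize_points <- function(run, bvals, bases, scales, epsilon, active,
                            gamma, settings) {
  region_names <- vapply(bases, function(b) b$region$name, character(1L))
  n <- ncol(bvals[[1L]])
  pts <- list()
  seen <- list()
  for (sol in run$solutions) {
    alpha <- sol$z[seq_len(n)]
    if (abs(sum(alpha)) > 1e-6 || sum(abs(alpha)) < 1e-8) next
    corrected <- 2 * alpha / sum(abs(alpha))
    dup <- FALSE
    for (sv in seen) {
      if (max(abs(sv - corrected)) < settings$dedup_tol) { dup <- TRUE; break }
    }
    if (dup) next
    seen[[length(seen) + 1L]] <- corrected
    lambda_s <- sol$z[n + 1:2]
    mu_s <- if (length(active)) sol$z[n + 2L + seq_along(active)] else numeric(0)
    cls <- classify_state(sol$z, bvals, run$betas_final, gamma, active)
    objs <- vapply(seq_along(bases), function(i) {
      f <- drop(bases[[i]]$values %*% alpha)
      if (run$betas_final[i] > 0) max(f) else min(f)
    }, numeric(1L))
    objs_smooth <- vapply(seq_along(bases), function(i) {
      smooth_max(drop(bvals[[i]] %*% alpha), run$betas_final[i]) * scales[i]
    }, numeric(1L))
    names(objs) <- names(objs_smooth) <- region_names
    mu_raw <- if (length(active)) mu_s * scales[1L] / scales[active] else
      numeric(0)
    names(mu_raw) <- region_names[active]
    eps_out <- if (length(bases) > 1L) {
      stats::setNames(epsilon[-1L], region_names[-1L])
    } else numeric(0)
    pts[[length(pts) + 1L]] <- structure(
      list(alpha = alpha,
           config = configuration(corrected, "corrected"),
           lambda = lambda_s * scales[1L], mu = mu_raw,
           residual_norm = sol$res_norm, classification = cls,
           objective = unname(objs[1L]), objectives = objs,
           objectives_smooth = objs_smooth,
           epsilon = eps_out,
           active_set = active, start_index = sol$start_index),
      class = "critical_point")
  }
  if (length(pts)) {
    pts <- pts[order(vapply(pts, function(p) p$objective, numeric(1L)),
                     decreasing = TRUE)]
  }
  structure(pts, class = "critical_points")
}

## Hessian of the Lagrangian in alpha plus constraint Jacobian at a
## solved state, fed to the bordered-Hessian classifier.
classify_state <- function(z, bvals, betas, gamma, active) {
  n <- ncol(bvals[[1L]])
  alpha <- z[seq_len(n)]
  lambda <- z[n + 1:2]
  mu <- if (length(active)) z[n + 2L + seq_along(active)] else numeric(0)
  h <- smooth_max_hess(bvals[[1L]], alpha, betas[1L])
  diag(h) <- diag(h) - lambda[1L] * balance_h1_hess_diag(alpha, gamma)
  bc <- balance_constraints(alpha, gamma, gradients = TRUE)
  jg <- rbind(bc$grad_h1, bc$grad_h2)
  for (j in seq_along(active)) {
    i <- active[j]
    fi <- drop(bvals[[i]] %*% alpha)
    swi <- softmax_weights(fi, betas[i])
    h <- h - mu[j] * smooth_max_hess(bvals[[i]], alpha, betas[i])
    jg <- rbind(jg, drop(crossprod(bvals[[i]],
                                   swi$w * (1 + betas[i] * (fi - swi$s)))))
  }
  classify_critical(h, jg)
}

#' Classify a constrained critical point from its bordered Hessian
#'
#' Applies the standard sign-sequence test to the last `n - k` leading
#' principal minors of the bordered Hessian (the Lagrangian Hessian `H`
#' bordered by the `k` active-constraint gradients): alternating signs
#' ending in `(-1)^n` indicate a constrained maximum, constant sign
#' `(-1)^k` a minimum. When any tested minor is smaller than `minor_tol`
#' in magnitude the test is inconclusive and the eigenvalues of `H`
#' projected onto the constraint tangent space decide instead, with
#' near-zero eigenvalues ignored (weak classification, which also covers
#' tie continua of equivalent optima). A zero-dimensional feasible set
#' (`k = n`) and a wholly flat projected Hessian (the objective locally
#' constant on the feasible manifold) are both reported as maxima by
#' convention; ranking by objective value disambiguates.
#'
#' @param hessian `n x n` Hessian of the Lagrangian in the fractions.
#' @param cons_jac `k x n` Jacobian of the active constraints.
#' @param minor_tol Magnitude below which a minor triggers the
#'   eigenvalue fallback.
#' @return `"maximum"`, `"minimum"`, `"saddle"`, or `"invalid"` (with a
#'   `reason` attribute) when the constraint gradients are rank
#'   deficient or the projected Hessian is wholly degenerate.
#' @export
classify_critical <- function(hessian, cons_jac, minor_tol = 1e-10) {
  n <- ncol(hessian)
  k <- nrow(cons_jac)
  qr_g <- qr(t(cons_jac))
  if (qr_g$rank < k) {
    return(structure("invalid", reason = "rank-deficient constraint gradients"))
  }
  if (k >= n) return("maximum")
  bordered <- rbind(cbind(matrix(0, k, k), cons_jac),
                    cbind(t(cons_jac), hessian))
  minors <- vapply(seq_len(n - k), function(r) {
    det(bordered[seq_len(2L * k + r), seq_len(2L * k + r), drop = FALSE])
  }, numeric(1L))
  if (all(abs(minors) >= minor_tol)) {
    sgn <- sign(minors)
    is_max <- all(sgn == (-1)^(k + seq_len(n - k)))
    is_min <- all(sgn == (-1)^k)
    if (is_max) return("maximum")
    if (is_min) return("minimum")
    return("saddle")
  }
  ## Eigenvalue fallback on the constraint tangent space.
  qq <- qr.Q(qr_g, complete = TRUE)
  zbase <- qq[, (k + 1L):n, drop = FALSE]
  hp <- crossprod(zbase, hessian %*% zbase)
  ev <- eigen((hp + t(hp)) / 2, symmetric = TRUE, only.values = TRUE)$values
  tol_e <- 1e-7 * max(1, max(abs(ev)))
  pos <- ev > tol_e
  neg <- ev < -tol_e
  if (any(pos) && any(neg)) return("saddle")
  if (!any(pos) && !any(neg)) {
    ## Objective locally constant on the feasible manifold (a flat
    ## continuum of equivalent configurations): a weak maximum (and weak
    ## minimum); reported as maximum, ranking by objective disambiguates.
    return("maximum")
  }
  if (any(neg)) "maximum" else "minimum"
}

#' Classify a solved critical point
#'
#' Rebuilds the Lagrangian Hessian and active-constraint gradients at a
#' critical point and runs [classify_critical()].
#'
#' @param point A `critical_point`.
#' @param basis A `basis_field_set` or list of them (primary region
#'   first) matching the problem the point was solved on.
#' @param params The [smoothing_params()] used.
#' @return The classification string.
#' @export
classify <- function(point, basis, params) {
  bases <- if (inherits(basis, "basis_field_set")) list(basis) else basis
  scales <- vapply(bases, function(b) region_scale(b$values), numeric(1L))
  bvals <- lapply(seq_along(bases), function(i) bases[[i]]$values / scales[i])
  betas <- vapply(seq_along(bases), function(i) {
    b <- if (is.null(params$beta)) auto_beta(bases[[i]]) else params$beta
    b * scales[i]
  }, numeric(1L))
  active <- point$active_set
  mu_s <- if (length(active)) point$mu * scales[active] / scales[1L] else
    numeric(0)
  z <- c(point$alpha, point$lambda / scales[1L], mu_s)
  classify_state(z, bvals, betas, params$gamma, active)
}

#' @export
print.critical_points <- function(x, ...) {
  cat(sprintf("%d critical point(s)", length(x)))
  if (!is.null(attr(x, "n_discarded"))) {
    cat(sprintf(" (%d start(s) discarded as non-converged)",
                attr(x, "n_discarded")))
  }
  cat("\n")
  for (i in seq_along(x)) {
    p <- x[[i]]
    cat(sprintf("  [%d] %-8s objective %.6g  residual %.2e\n", i,
                p$classification, p$objective, p$residual_norm))
  }
  invisible(x)
}

#' @export
print.critical_point <- function(x, ...) {
  cat(sprintf("Critical point (%s): objective %.6g, residual %.2e\n",
              x$classification, x$objective, x$residual_norm))
  print(x$config)
  invisible(x)
}

#' Best classified maximum of a solution list
#'
#' @param points A `critical_points` list.
#' @param classification Which classification to select from.
#' @return The best (first, i.e. largest-objective) point with that
#'   classification, or `NULL` if none.
#' @export
global_optimum <- function(points, classification = "maximum") {
  for (p in points) if (p$classification == classification) return(p)
  NULL
}

#' Rescale solved fractions to satisfy the exact balance constraints
#'
#' Smooth surrogates leave solver output slightly off the exact
#' constraints; `2 * alpha / sum(abs(alpha))` restores
#' `sum(abs(alpha)) = 2` at machine precision while preserving the
#' direction of the solution.
#'
#' @param alpha_star Solved fractions (vector or [configuration()]);
#'   must already be balanced to `|sum(alpha)| <= 1e-6`.
#' @return A corrected [configuration()].
#' @export
correct_fractions <- function(alpha_star) {
  alpha <- as_alpha(alpha_star)
  s <- sum(abs(alpha))
  if (s == 0) stop("degenerate configuration: all fractions zero",
                   call. = FALSE)
  if (abs(sum(alpha)) > 1e-6) {
    stop("precondition violated: solution is not balanced (|sum(alpha)| > 1e-6)",
         call. = FALSE)
  }
  configuration(2 * alpha / s, "corrected")
}

#' Round fractions to reporting precision while keeping exact balance
#'
#' Rounds every fraction to `digits` significant digits (the precision a
#' clinical system can realize), then absorbs the rounding residuals into
#' the largest-magnitude positive and negative fractions so that the
#' positive fractions sum to exactly +1 and the negative ones to exactly
#' -1. The absorbed adjustment can be at most `n` half-units in the last
#' significant place of the largest fraction; anything larger raises an
#' error.
#'
#' @param config A corrected [configuration()].
#' @param digits Significant digits (default 3).
#' @return A rounded [configuration()].
#' @export
round_fractions <- function(config, digits = 3) {
  alpha <- as_alpha(config)
  rounded <- signif(alpha, digits)
  pos <- rounded > 0
  neg <- rounded < 0
  if (!any(pos) || !any(neg)) {
    stop("rounding failure: need at least one positive and one negative fraction",
         call. = FALSE)
  }
  ulp_half <- 0.5 * 10^(floor(log10(max(abs(rounded)))) - digits + 1L)
  budget <- length(alpha) * ulp_half * (1 + 1e-9)
  ip <- which(pos)[which.max(rounded[pos])]
  dp <- 1 - sum(rounded[pos])
  if (abs(dp) > budget) stop("rounding failure: unreconcilable positive residual",
                             call. = FALSE)
  rounded[ip] <- 1 - sum(rounded[setdiff(which(pos), ip)])
  im <- which(neg)[which.min(rounded[neg])]
  dm <- -1 - sum(rounded[neg])
  if (abs(dm) > budget) stop("rounding failure: unreconcilable negative residual",
                             call. = FALSE)
  rounded[im] <- -1 - sum(rounded[setdiff(which(neg), im)])
  configuration(rounded, "rounded")
}
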