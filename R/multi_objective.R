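## Resolve per-region smooth-max scales. `senses` gives the steering
## direction per region ("max" -> beta > 0, "min" -> beta < 0); defaults
## to "max" everywhere (a region-of-avoidance objective is the maximum of
## its field, capped from above).
resolve_betas <- function(bases, params, senses = NULL) {
  q <- length(bases)
  if (is.null(senses)) senses <- rep("max", q)
  if (length(senses) == 1L) senses <- rep(senses, q)
  if (is.null(params$beta)) {
    vapply(seq_len(q), function(i) auto_beta(bases[[i]], sense = senses[i]),
           numeric(1L))
  } else {
    rep_len(params$beta, q)
  }
}

## Normalize user epsilon input (named by secondary region, or positional
## over regions 2..Q) into a full Q-length vector with entry 1 unused.
full_epsilon <- function(epsilon, region_names) {
  q <- length(region_names)
  out <- rep(NA_real_, q)
  if (!is.null(names(epsilon)) && any(nzchar(names(epsilon)))) {
    idx <- match(names(epsilon), region_names)
    if (anyNA(idx)) {
      stop("unknown region name in epsilon: ",
           paste(names(epsilon)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    out[idx] <- as.numeric(epsilon)
  } else {
    if (length(epsilon) != q - 1L) {
      stop("epsilon must have one entry per secondary region", call. = FALSE)
    }
    out[-1L] <- as.numeric(epsilon)
  }
  if (anyNA(out[-1L])) stop("missing epsilon for a secondary region",
                            call. = FALSE)
  out
}

#' Stationarity residual of the generalized (KKT) Lagrangian
#'
#' Residual of the epsilon-constraint subproblem
#' `L = smooth_max_1 - sum(lambda * h) - sum(mu_i * (smooth_max_i - eps_i))`
#' for a chosen active set of secondary-region constraints: stationarity
#' in the fractions, the two balance constraints, and `g_i = 0` for each
#' active constraint. Inactive constraints contribute `mu_i = 0` and no
#' row. With an empty active set this reduces exactly to
#' [residual_single()].
#'
#' @param alpha Current fractions.
#' @param lambda The two equality multipliers.
#' @param mu Multipliers of the active inequality constraints (in
#'   active-set order).
#' @param basis_per_region List of `basis_field_set`s, primary first.
#' @param params A [smoothing_params()]; `beta` may be per-region.
#' @param epsilon Caps for the secondary regions (named by region or
#'   positional for regions `2..Q`), in that region's field units.
#' @param active_set Names (or indices into `2..Q`) of the secondary
#'   regions treated as active.
#' @param senses Optional per-region steering direction, see
#'   [solve_epsilon()].
#' @return Numeric vector of length `n + 2 + |active_set|`.
#' @export
residual_multi <- function(alpha, lambda, mu, basis_per_region, params,
                           epsilon, active_set, senses = NULL) {
  sysm <- multi_system(basis_per_region, params, epsilon, active_set, senses)
  kkt_residual_core(c(as_alpha(alpha), lambda, mu), sysm$bvals, sysm$betas,
                    params$gamma, sysm$eps, sysm$active)
}

#' Jacobian of the generalized stationarity system
#'
#' Closed-form Jacobian of [residual_multi()] with respect to
#' `(alpha, lambda, mu)`.
#'
#' @inheritParams residual_multi
#' @return A square matrix of side `n + 2 + |active_set|`.
#' @export
jacobian_multi <- function(alpha, lambda, mu, basis_per_region, params,
                           epsilon, active_set, senses = NULL) {
  sysm <- multi_system(basis_per_region, params, epsilon, active_set, senses)
  kkt_jacobian_core(c(as_alpha(alpha), lambda, mu), sysm$bvals, sysm$betas,
                    params$gamma, sysm$eps, sysm$active)
}

## Assemble the raw-unit system pieces shared by the public multi
## entry points (no internal rescaling here; the public residuals are in
## the caller's field units).
multi_system <- function(bases, params, epsilon, active_set, senses) {
  stopifnot(is.list(bases), length(bases) >= 2L)
  region_names <- vapply(bases, function(b) b$region$name, character(1L))
  eps <- full_epsilon(epsilon, region_names)
  active <- resolve_active(active_set, region_names)
  n <- ncol(bases[[1L]]$values)
  for (b in bases) {
    if (ncol(b$values) != n) stop("regions disagree on contact count",
                                  call. = FALSE)
  }
  list(bvals = lapply(bases, `[[`, "values"),
       betas = resolve_betas(bases, params, senses),
       eps = eps, active = active)
}

resolve_active <- function(active_set, region_names) {
  if (is.null(active_set) || !length(active_set)) return(integer(0))
  if (is.character(active_set)) {
    idx <- match(active_set, region_names)
    if (anyNA(idx) || any(idx == 1L)) {
      stop("active_set must name secondary regions", call. = FALSE)
    }
    sort(idx)
  } else {
    idx <- as.integer(active_set)
    if (any(idx < 2L | idx > length(region_names))) {
      stop("active_set indices must lie in 2..Q", call. = FALSE)
    }
    sort(idx)
  }
}

#' Validate the Karush-Kuhn-Tucker conditions at a critical point
#'
#' Checks, for a solved epsilon-constraint critical point: primal
#' feasibility of every inequality cap (`g_i <= tol`), the equality
#' (balance) residuals, dual feasibility (`mu >= -tol`), and
#' complementary slackness (`|mu_i * g_i| <= tol`). Tolerances scale
#' with the magnitude of the quantities involved. A point is only a
#' valid constrained optimum if all four hold.
#'
#' @param point A `critical_point` (from [solve_epsilon()] or
#'   [multistart_solve()]).
#' @param epsilon Caps for the secondary regions; defaults to the caps
#'   stored in the point.
#' @param basis_per_region Optional list of `basis_field_set`s to
#'   recompute the smooth objectives from scratch; if omitted the
#'   objectives stored in the point are used.
#' @param params [smoothing_params()] supplying `gamma` (and `beta` for
#'   recomputation).
#' @param senses Optional per-region steering direction.
#' @param feas_tol,comp_tol,mu_tol Relative tolerances for feasibility,
#'   complementary slackness and dual feasibility.
#' @return A list with `valid` (logical) and `checks`, a data.frame of
#'   per-condition results with reasons.
#' @export
validate_kkt <- function(point, epsilon = NULL, basis_per_region = NULL,
                         params = smoothing_params(), senses = NULL,
                         feas_tol = 1e-8, comp_tol = 1e-8, mu_tol = 1e-10) {
  if (is.null(epsilon)) epsilon <- point$epsilon
  sec_names <- names(epsilon)
  if (!is.null(basis_per_region)) {
    betas <- resolve_betas(basis_per_region, params, senses)
    objs <- vapply(seq_along(basis_per_region), function(i) {
      smooth_max(drop(basis_per_region[[i]]$values %*% point$alpha), betas[i])
    }, numeric(1L))
    names(objs) <- vapply(basis_per_region, function(b) b$region$name,
                          character(1L))
  } else {
    objs <- point$objectives_smooth
  }
  mu_full <- stats::setNames(rep(0, length(sec_names)), sec_names)
  if (length(point$mu)) mu_full[names(point$mu)] <- point$mu
  g <- objs[sec_names] - epsilon
  checks <- data.frame(condition = character(0), pass = logical(0),
                       detail = character(0), stringsAsFactors = FALSE)
  add <- function(cond, pass, detail) {
    rbind(checks, data.frame(condition = cond, pass = pass, detail = detail,
                             stringsAsFactors = FALSE))
  }
  for (nm in sec_names) {
    scale <- max(1, abs(epsilon[nm]), abs(objs[nm]))
    checks <- add(paste0("primal_feasibility:", nm),
                  g[nm] <= feas_tol * scale,
                  sprintf("g = %.6g (cap %.6g)", g[nm], epsilon[nm]))
  }
  bc <- balance_constraints(point$alpha, params$gamma)
  eq_tol <- 1e-6
  checks <- add("equality_feasibility",
                abs(bc$h1) <= eq_tol && abs(bc$h2) <= eq_tol,
                sprintf("h1 = %.3g, h2 = %.3g", bc$h1, bc$h2))
  for (nm in sec_names) {
    checks <- add(paste0("dual_feasibility:", nm),
                  mu_full[nm] >= -mu_tol * max(1, abs(mu_full[nm])),
                  sprintf("mu = %.6g", mu_full[nm]))
  }
  for (nm in sec_names) {
    scale <- max(1, abs(mu_full[nm])) * max(1, abs(epsilon[nm]), abs(objs[nm]))
    checks <- add(paste0("complementary_slackness:", nm),
                  abs(mu_full[nm] * g[nm]) <= comp_tol * scale,
                  sprintf("mu * g = %.6g", mu_full[nm] * g[nm]))
  }
  list(valid = all(checks$pass), checks = checks)
}

#' Solve one epsilon-constraint subproblem
#'
#' Maximizes the primary region's smooth objective subject to the
#' balance constraints and the caps `smooth_max_i <= eps_i` on every
#' secondary region. Complementary slackness is resolved exactly by
#' enumerating all `2^(Q-1)` active sets: each candidate set yields a
#' smooth square root system solved by the multistart Newton iteration;
#' solutions are kept only if they pass the full KKT validation,
#' classified with the active constraints included in the bordered
#' Hessian, deduplicated, and returned sorted by the primary objective.
#'
#' @param basis_per_region Named list of `basis_field_set`s, the primary
#'   region first.
#' @param epsilon Caps for the secondary regions (named or positional),
#'   in raw field units.
#' @param params A [smoothing_params()].
#' @param settings A [solver_settings()].
#' @param senses Per-region steering direction (`"max"`/`"min"`),
#'   default `"max"` for every region.
#' @param warm_starts Optional list of previously solved
#'   `critical_point`s appended as additional starts (their multipliers
#'   are reused where the active set matches, zero otherwise); used by
#'   [pareto_sweep()] to continue solutions along the epsilon path.
#' @return A `critical_points` list of KKT-valid points (classified
#'   maxima of the primary objective first by objective value); empty
#'   with a warning when nothing converged.
#' @export
solve_epsilon <- function(basis_per_region, epsilon,
                          params = smoothing_params(),
                          settings = solver_settings(), senses = NULL,
                          warm_starts = NULL) {
  stopifnot(is.list(basis_per_region), length(basis_per_region) >= 2L)
  bases <- basis_per_region
  q <- length(bases)
  region_names <- vapply(bases, function(b) b$region$name, character(1L))
  eps_raw <- full_epsilon(epsilon, region_names)
  scales <- vapply(bases, function(b) region_scale(b$values), numeric(1L))
  betas_raw <- resolve_betas(bases, params, senses)
  bvals <- lapply(seq_len(q), function(i) bases[[i]]$values / scales[i])
  betas_s <- betas_raw * scales
  eps_s <- eps_raw / scales
  n <- ncol(bvals[[1L]])
  all_pts <- list()
  total_discarded <- 0L
  for (mask in 0:(2^(q - 1L) - 1L)) {
    active <- (2:q)[bitwAnd(mask, 2^(seq_len(q - 1L) - 1L)) > 0]
    ws <- NULL
    if (!is.null(warm_starts) && length(warm_starts)) {
      ws <- lapply(warm_starts, function(p) {
        mu_s <- vapply(active, function(i) {
          nm <- region_names[i]
          if (!is.null(p$mu) && nm %in% names(p$mu)) {
            p$mu[[nm]] * scales[i] / scales[1L]
          } else 0
        }, numeric(1L))
        c(p$alpha, p$lambda / scales[1L], mu_s)
      })
    }
    run <- multistart_core(bvals, betas_s, params$gamma, eps_s, active,
                           settings, warm_starts = ws)
    total_discarded <- total_discarded + run$n_discarded
    pts <- finalize_points(run, bvals, bases, scales, eps_raw, active,
                           params$gamma, settings)
    for (p in pts) {
      kkt <- validate_kkt(p, params = params)
      if (kkt$valid) all_pts[[length(all_pts) + 1L]] <- p
    }
  }
  ## Deduplicate across active sets, preferring the better objective.
  keep <- list()
  for (p in all_pts) {
    dup <- FALSE
    for (kq in keep) {
      if (max(abs(kq$config$alpha - p$config$alpha)) < settings$dedup_tol) {
        dup <- TRUE; break
      }
    }
    if (!dup) keep[[length(keep) + 1L]] <- p
  }
  if (length(keep)) {
    keep <- keep[order(vapply(keep, function(p) p$objective, numeric(1L)),
                       decreasing = TRUE)]
  } else {
    warning("no KKT-valid stationary points for this epsilon")
  }
  structure(keep, class = "critical_points", n_discarded = total_discarded)
}

#' Epsilon schedule for a Pareto sweep
#'
#' @param ... Named arguments, one per constrained (secondary) region:
#'   a strictly monotone numeric vector of cap values in that region's
#'   field units.
#' @return An object of class `epsilon_schedule`.
#' @export
epsilon_schedule <- function(...) {
  sched <- list(...)
  if (!length(sched) || is.null(names(sched)) || any(!nzchar(names(sched)))) {
    stop("epsilon_schedule needs named per-region cap vectors", call. = FALSE)
  }
  for (nm in names(sched)) {
    v <- as.numeric(sched[[nm]])
    if (!length(v) || any(!is.finite(v))) {
      stop("schedule for ", nm, " must be finite and nonempty", call. = FALSE)
    }
    if (length(v) > 1L && !(all(diff(v) > 0) || all(diff(v) < 0))) {
      stop("schedule for ", nm, " must be strictly monotone", call. = FALSE)
    }
    sched[[nm]] <- v
  }
  structure(sched, class = "epsilon_schedule")
}

#' Achievable range of a region's smooth objective
#'
#' Runs an unconstrained multistart solve on one region and returns the
#' smallest and largest smooth-objective values among its classified
#' critical points - the natural endpoints for an epsilon sweep on that
#' region.
#'
#' @param basis The region's `basis_field_set`.
#' @param params,settings Smoothing and solver settings.
#' @param sense Steering direction for the region's own objective.
#' @return Numeric `c(min, max)` of the achievable smooth objective.
#' @export
objective_range <- function(basis, params = smoothing_params(),
                            settings = solver_settings(),
                            sense = "max") {
  pts <- multistart_solve(basis, params, settings, sense = sense)
  if (!length(pts)) stop("no critical points found for region '",
                         basis$region$name, "'", call. = FALSE)
  vals <- vapply(pts, function(p) p$objectives_smooth[1L], numeric(1L))
  range(vals)
}

#' Trace a Pareto front with the epsilon-constraint method
#'
#' Sweeps the caps on the secondary regions over a schedule, solving one
#' epsilon-constraint subproblem per grid point (warm-started from the
#' previous front point), keeping the best KKT-valid maximum of the
#' primary objective, re-evaluating all objectives at the final
#' smoothing scales, and flagging Pareto dominance. When no schedule is
#' given, each secondary region's caps span its achievable objective
#' range (from unconstrained solves of that region) on a uniform grid.
#'
#' @param basis_per_region Named list of `basis_field_set`s, primary
#'   first.
#' @param schedule An [epsilon_schedule()], or `NULL` for the automatic
#'   range-spanning grid.
#' @param n_eps Grid size per region for the automatic schedule.
#' @param params,settings Smoothing and solver settings.
#' @param senses Per-region steering direction; defaults to `"max"` for
#'   the primary and every capped region.
#' @param normalization `"signed"` divides each region's objectives by
#'   its largest achievable smooth objective; `"absolute"` divides by
#'   the largest achievable magnitude (relevant when the desired field
#'   is a large negative value).
#' @param dominance_senses Optional per-region `"max"`/`"min"` vector
#'   for the dominance flags; by default the primary is maximized and
#'   each secondary region is minimized when its role is `"roa"`,
#'   maximized otherwise.
#' @return A `pareto_front`: a data.frame with one row per swept cap
#'   (epsilon per region, raw/smooth/normalized objectives per region,
#'   fractions per contact, validity and nondominance flags), carrying
#'   the solved points and senses as attributes.
#' @export
pareto_sweep <- function(basis_per_region, schedule = NULL, n_eps = 25,
                         params = smoothing_params(),
                         settings = solver_settings(), senses = NULL,
                         normalization = c("signed", "absolute"),
                         dominance_senses = NULL) {
  normalization <- match.arg(normalization)
  bases <- basis_per_region
  q <- length(bases)
  stopifnot(q >= 2L)
  region_names <- vapply(bases, function(b) b$region$name, character(1L))
  sec_names <- region_names[-1L]
  ranges <- lapply(seq_len(q)[-1L], function(i) {
    objective_range(bases[[i]], params, settings,
                    sense = if (is.null(senses)) "max" else senses[i])
  })
  names(ranges) <- sec_names
  if (is.null(schedule)) {
    sched <- lapply(ranges, function(r) {
      seq(r[2L], r[1L], length.out = n_eps)  # loosest cap first
    })
    schedule <- do.call(epsilon_schedule, sched)
  }
  for (nm in names(schedule)) {
    if (!nm %in% sec_names) stop("schedule names an unknown region: ", nm,
                                 call. = FALSE)
  }
  grid <- expand.grid(schedule[sec_names], KEEP.OUT.ATTRS = FALSE)
  names(grid) <- sec_names
  points <- vector("list", nrow(grid))
  ## Homotopy along the epsilon path: the first (loosest) cap gets the
  ## full multistart; subsequent caps are dominated by continuation from
  ## the previous front's valid points plus a light fresh multistart.
  light <- settings
  light$n_starts <- max(8L, settings$n_starts %/% 10L)
  light$bipole_starts <- FALSE
  warm <- NULL
  for (r in seq_len(nrow(grid))) {
    eps <- stats::setNames(as.numeric(grid[r, ]), sec_names)
    sols <- withCallingHandlers(
      solve_epsilon(bases, eps, params,
                    if (is.null(warm)) settings else light,
                    senses, warm_starts = warm),
      warning = function(w) invokeRestart("muffleWarning"))
    best <- global_optimum(sols, "maximum")
    if (!is.null(best)) {
      points[[r]] <- best
      warm <- sols[seq_len(min(5L, length(sols)))]
    }
  }
  have <- !vapply(points, is.null, logical(1L))
  if (!any(have)) {
    warning("empty Pareto front: no epsilon was feasible")
  }
  ## Normalization factors: own largest achievable smooth objective,
  ## signed or in magnitude. The primary's factor comes from its own
  ## unconstrained solve.
  prim_range <- objective_range(bases[[1L]], params, settings,
                                sense = if (is.null(senses)) "max" else
                                  senses[1L])
  norm_fac <- numeric(q)
  for (i in seq_len(q)) {
    r <- if (i == 1L) prim_range else ranges[[region_names[i]]]
    norm_fac[i] <- if (normalization == "signed") r[2L] else max(abs(r))
    if (norm_fac[i] == 0) norm_fac[i] <- 1
  }
  labels <- colnames(bases[[1L]]$values)
  rows <- list()
  for (r in which(have)) {
    p <- points[[r]]
    row <- as.list(stats::setNames(as.numeric(grid[r, ]),
                                   paste0("epsilon_", sec_names)))
    for (i in seq_len(q)) {
      nm <- region_names[i]
      row[[paste0("obj_", nm)]] <- unname(p$objectives[nm])
      row[[paste0("obj_smooth_", nm)]] <- unname(p$objectives_smooth[nm])
      row[[paste0("norm_", nm)]] <- unname(p$objectives_smooth[nm]) /
        norm_fac[i]
    }
    for (j in seq_along(labels)) {
      row[[paste0("alpha_", labels[j])]] <- p$config$alpha[j]
    }
    row$valid <- TRUE
    rows[[length(rows) + 1L]] <- as.data.frame(row)
  }
  front <- if (length(rows)) do.call(rbind, rows) else data.frame()
  obj_sense <- if (!is.null(dominance_senses)) {
    rep_len(dominance_senses, q)
  } else {
    c("max", ifelse(
      vapply(bases[-1L], function(b) b$region$role, character(1L)) == "roa",
      "min", "max"))
  }
  if (nrow(front)) {
    objcols <- paste0("obj_smooth_", region_names)
    front$nondominated <- pareto_nondominated(front[objcols], obj_sense)
  }
  structure(front, class = c("pareto_front", "data.frame"),
            points = points[have], senses = obj_sense,
            regions = region_names, norm_factors = norm_fac)
}

#' Nondominance flags for a set of objective vectors
#'
#' @param points Matrix or data.frame, one row per point, one column per
#'   objective.
#' @param senses Character vector, `"max"` or `"min"` per objective.
#' @return Logical vector: `TRUE` where no other point is at least as
#'   good in every objective and strictly better in one.
#' @export
pareto_nondominated <- function(points, senses) {
  m <- as.matrix(points)
  if (length(senses) != ncol(m)) {
    stop("dimension error: one sense per objective column", call. = FALSE)
  }
  m <- sweep(m, 2L, ifelse(senses == "min", -1, 1), "*")
  np <- nrow(m)
  flags <- rep(TRUE, np)
  for (i in seq_len(np)) {
    for (j in seq_len(np)) {
      if (i == j) next
      if (all(m[j, ] >= m[i, ]) && any(m[j, ] > m[i, ])) {
        flags[i] <- FALSE
        break
      }
    }
  }
  flags
}

#' Filter a point set down to its nondominated subset
#'
#' @inheritParams pareto_nondominated
#' @return The nondominated rows, in their original (stable) order.
#' @export
dominance_filter <- function(points, senses) {
  flags <- pareto_nondominated(points, senses)
  if (is.data.frame(points) || is.matrix(points)) {
    points[flags, , drop = FALSE]
  } else {
    points[flags]
  }
}

#' @export
print.pareto_front <- function(x, ...) {
  cat(sprintf("Pareto front: %d point(s), %d nondominated\n", nrow(x),
              sum(x$nondominated)))
  NextMethod()
}
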