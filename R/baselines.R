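#' Draw a random balanced configuration
#'
#' Samples a configuration that satisfies the exact balance constraints:
#' every contact is assigned a random sign (redrawn until both signs are
#' present), then independent uniform weights are normalized within each
#' sign group so the positive fractions sum to +1 and the negative ones
#' to -1. With two contacts this always yields an ideal bipole.
#'
#' @param n Number of contacts (>= 2).
#' @param seed Optional seed; `NULL` uses the current RNG stream.
#' @return A corrected [configuration()].
#' @export
sample_random_configuration <- function(n, seed = NULL) {
  if (n < 2) stop("need at least 2 contacts", call. = FALSE)
  draw <- function() {
    repeat {
      s <- sample(c(-1, 1), n, replace = TRUE)
      if (any(s > 0) && any(s < 0)) break
    }
    u <- stats::runif(n)
    alpha <- numeric(n)
    alpha[s > 0] <- u[s > 0] / sum(u[s > 0])
    alpha[s < 0] <- -u[s < 0] / sum(u[s < 0])
    alpha
  }
  alpha <- if (is.null(seed)) draw() else with_seed(seed, draw())
  configuration(alpha, "corrected")
}

#' Enumerate every bipolar configuration
#'
#' All ordered (cathode, anode) contact pairs: -1 on the cathode, +1 on
#' the anode, zero elsewhere; `n * (n - 1)` configurations in total
#' (240 for a 16-contact system).
#'
#' @param n Number of contacts (>= 2).
#' @return A list of corrected [configuration()]s, each carrying a
#'   `cathode`/`anode` attribute (contact indices).
#' @export
enumerate_bipolar <- function(n) {
  if (n < 2) stop("need at least 2 contacts", call. = FALSE)
  out <- vector("list", n * (n - 1L))
  k <- 0L
  for (cat_ in seq_len(n)) {
    for (an in seq_len(n)) {
      if (an == cat_) next
      alpha <- numeric(n)
      alpha[cat_] <- -1
      alpha[an] <- 1
      k <- k + 1L
      cfg <- configuration(alpha, "corrected")
      attr(cfg, "cathode") <- cat_
      attr(cfg, "anode") <- an
      out[[k]] <- cfg
    }
  }
  out
}

## Exact (non-smooth) single-region objective of a configuration: the
## pointwise extremum of the superposed field. Baselines need no
## derivatives, so no smoothing enters here.
exact_objective <- function(basis, alpha, sense = "max") {
  f <- drop(basis$values %*% as_alpha(alpha))
  if (sense == "max") max(f) else min(f)
}

#' Baseline comparison of random and bipolar configurations
#'
#' Evaluates the exact single-region objective (pointwise maximum of the
#' superposed field) for a seeded set of random balanced configurations
#' and for every bipolar configuration, and summarizes how far the
#' random set falls short of a supplied optimum: the mean relative
#' deficit `1 - mean(random objectives) / optimum`.
#'
#' @param basis A `basis_field_set`.
#' @param optimum_objective The optimized objective to compare against
#'   (e.g. `global_optimum(multistart_solve(...))$objective`); the
#'   deficit is only reported when this is positive.
#' @param n_random Number of random configurations.
#' @param seed RNG seed for the random draws.
#' @return An object of class `baseline_report`: per-configuration
#'   objectives, summary statistics, the deficit, and the best bipolar
#'   contact pair.
#' @export
baseline_report <- function(basis, optimum_objective, n_random = 10000,
                            seed = 1) {
  stopifnot(inherits(basis, "basis_field_set"))
  n <- ncol(basis$values)
  random_obj <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      exact_objective(basis, sample_random_configuration(n))
    }, numeric(1L))
  })
  bipoles <- enumerate_bipolar(n)
  bipolar_obj <- vapply(bipoles, function(cfg) exact_objective(basis, cfg),
                        numeric(1L))
  best_b <- which.max(bipolar_obj)
  labels <- colnames(basis$values)
  deficit <- if (is.finite(optimum_objective) && optimum_objective > 0) {
    1 - mean(random_obj) / optimum_objective
  } else NA_real_
  structure(list(
    random_objectives = random_obj,
    bipolar_objectives = bipolar_obj,
    summary = c(mean = mean(random_obj),
                stats::quantile(random_obj, c(0.05, 0.25, 0.5, 0.75, 0.95))),
    optimum_objective = optimum_objective,
    deficit = deficit,
    best_bipolar = list(cathode = labels[attr(bipoles[[best_b]], "cathode")],
                        anode = labels[attr(bipoles[[best_b]], "anode")],
                        objective = bipolar_obj[best_b]),
    n_random = n_random, seed = seed),
    class = "baseline_report")
}

#' @export
print.baseline_report <- function(x, ...) {
  cat(sprintf("Baseline report: %d random + %d bipolar configurations\n",
              x$n_random, length(x$bipolar_objectives)))
  cat(sprintf("  mean random objective: %.6g\n", x$summary[["mean"]]))
  cat(sprintf("  best bipole: (-%s, +%s), objective %.6g\n",
              x$best_bipolar$cathode, x$best_bipolar$anode,
              x$best_bipolar$objective))
  if (is.finite(x$deficit)) {
    cat(sprintf("  mean random deficit vs optimum (%.6g): %.1f%%\n",
                x$optimum_objective, 100 * x$deficit))
  }
  invisible(x)
}
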