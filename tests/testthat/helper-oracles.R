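# Shared fixtures and independent oracles for the test suite. Expensive
# solves are cached so that several test files can reuse them within one
# test run.

.steer_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .steer_cache)) {
    assign(key, force(expr), envir = .steer_cache)
  }
  get(key, envir = .steer_cache)
}

white_matter <- function() anisotropic_medium(0.083, 0.083, 0.6)

# Deliberately asymmetric four-contact array: no two contacts are
# mirror-equivalent with respect to the test regions, so stationary
# points are isolated and classifications definite.
test4_contacts <- function() {
  contact_array(rbind(c(-2e-3, 0, -3e-3), c(2e-3, 0, -1e-3),
                      c(-2e-3, 0, 2e-3), c(2.5e-3, 0, 4e-3)))
}

test4_basis <- function(points, name = "p", kind = "activating_function",
                        role = "roi") {
  analytic_basis_fields(
    test4_contacts(),
    region_spec(matrix(points, ncol = 3L, byrow = TRUE), c(0, 0, 1), kind,
                role, name),
    white_matter())
}

# Build a basis_field_set directly from a value matrix (dummy distinct
# coordinates), via the imported-table path.
basis_from_matrix <- function(values, name = "m", role = "roi") {
  values <- as.matrix(values)
  df <- data.frame(x = seq_len(nrow(values)) * 1e-3, y = 0, z = 0)
  colnames(values) <- paste0("C", seq_len(ncol(values)))
  df <- cbind(df, as.data.frame(values))
  meta <- region_spec(matrix(0, 1L, 3L), c(0, 0, 1), "activating_function",
                      role, name)
  import_basis_fields(df, meta)
}

# Exhaustive enumeration of balanced fraction vectors on a grid:
# components are multiples of `step`, positives sum to +1 and negatives
# to -1 exactly (integer arithmetic). The independent optimum oracle.
enumerate_balanced_grid <- function(n, step = 0.05) {
  cached(sprintf("grid_%d_%g", n, step), {
    k <- round(1 / step)
    g <- as.matrix(expand.grid(rep(list(seq(-k, k)), n)))
    pos <- g * (g > 0)
    ok <- rowSums(pos) == k & rowSums(g) == 0L
    g[ok, , drop = FALSE] / k
  })
}

grid_best_objective <- function(basis, step = 0.05, feasible = NULL) {
  g <- enumerate_balanced_grid(ncol(basis$values), step)
  obj <- apply(g %*% t(basis$values), 1L, max)
  if (!is.null(feasible)) {
    keep <- feasible(g)
    obj <- obj[keep]
    g <- g[keep, , drop = FALSE]
  }
  i <- which.max(obj)
  list(objective = obj[i], alpha = g[i, ])
}

# Central finite differences of a vector-valued function.
fd_jacobian <- function(fn, z, h = 1e-6) {
  r0 <- fn(z)
  out <- matrix(0, length(r0), length(z))
  for (j in seq_along(z)) {
    zp <- z; zm <- z
    zp[j] <- zp[j] + h
    zm[j] <- zm[j] - h
    out[, j] <- (fn(zp) - fn(zm)) / (2 * h)
  }
  out
}

# Richardson-extrapolated second-order central stencils for directional
# derivatives of a scalar field along a unit direction.
fd_directional <- function(f, point, direction, order = 1L, h = 1e-4) {
  stencil <- function(hh) {
    if (order == 1L) {
      (f(point + hh * direction) - f(point - hh * direction)) / (2 * hh)
    } else {
      (f(point + hh * direction) - 2 * f(point) +
         f(point - hh * direction)) / hh^2
    }
  }
  d1 <- stencil(h)
  d2 <- stencil(h / 10)
  (100 * d2 - d1) / 99
}

two_lead <- function() cached("two_lead", make_two_lead_16())

left_axon_solution <- function() {
  cached("left_axon_solution", {
    multistart_solve(fixture_basis(two_lead(), "left_axon"),
                     settings = solver_settings(n_starts = 200, seed = 7,
                                                max_iter = 100))
  })
}

midline_solution <- function() {
  cached("midline_solution", {
    multistart_solve(fixture_basis(two_lead(), "midline_axon"),
                     settings = solver_settings(n_starts = 200, seed = 3,
                                                max_iter = 100))
  })
}
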