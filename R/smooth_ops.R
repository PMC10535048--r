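#' Contact current-fraction configuration
#'
#' A vector of dimensionless current fractions, one per contact. A
#' physically realizable (balanced) configuration has its positive
#' fractions summing to +1 and its negative fractions to -1, i.e.
#' `sum(alpha) = 0` and `sum(abs(alpha)) = 2`. Raw solver output need not
#' satisfy these exactly; [correct_fractions()] and [round_fractions()]
#' produce `corrected` and `rounded` configurations that do, and those
#' statuses are validated here.
#'
#' @param alpha Numeric vector of current fractions.
#' @param status Provenance tag: `"raw"`, `"corrected"` or `"rounded"`.
#' @return An object of class `configuration`.
#' @export
configuration <- function(alpha, status = c("raw", "corrected", "rounded")) {
  alpha <- as.numeric(alpha)
  status <- match.arg(status)
  if (!all(is.finite(alpha))) stop("fractions must be finite", call. = FALSE)
  if (status != "raw") {
    tol <- 1e-9
    if (abs(sum(alpha)) > tol) {
      stop("balanced configuration violates sum(alpha) = 0", call. = FALSE)
    }
    if (abs(sum(abs(alpha)) - 2) > tol) {
      stop("balanced configuration violates sum(|alpha|) = 2", call. = FALSE)
    }
    if (any(abs(alpha) > 1 + tol)) {
      stop("fractions must lie in [-1, 1]", call. = FALSE)
    }
  }
  structure(list(alpha = alpha, status = status), class = "configuration")
}

#' @export
print.configuration <- function(x, ...) {
  cat(sprintf("Configuration (%s, %d contacts):\n", x$status,
              length(x$alpha)))
  print(round(x$alpha, 4L))
  invisible(x)
}

as_alpha <- function(config) {
  if (inherits(config, "configuration")) config$alpha else as.numeric(config)
}

#' Smoothing parameters for the surrogate operators
#'
#' @param beta Smooth-maximum scale (reciprocal field units). `beta > 0`
#'   tracks the largest positive field value, `beta < 0` the largest
#'   negative one. `NULL` requests automatic selection via [auto_beta()]
#'   at solve time.
#' @param gamma Smooth-absolute-value scale (dimensionless, > 0).
#' @return An object of class `smoothing_params`.
#' @export
smoothing_params <- function(beta = NULL, gamma = 50) {
  if (!is.null(beta) && (!is.finite(beta) || beta == 0)) {
    stop("beta must be nonzero and finite (or NULL for automatic)",
         call. = FALSE)
  }
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  structure(list(beta = beta, gamma = gamma), class = "smoothing_params")
}

#' Automatic smooth-maximum scale for a basis field set
#'
#' Chooses `beta` so that `beta * F` is about `target` at the expected
#' optimum, using the best single-bipole field over the region (the
#' largest row-wise spread of the basis values) as the scale estimate.
#' The smooth maximum is a good surrogate once that product is around 10.
#'
#' @param basis A `basis_field_set`.
#' @param target Desired value of `beta * max|F|` (default 10).
#' @param sense `"max"` for the largest positive field (`beta > 0`),
#'   `"min"` for the largest negative one (`beta < 0`).
#' @return A scalar `beta`.
#' @export
auto_beta <- function(basis, target = 10, sense = c("max", "min")) {
  sense <- match.arg(sense)
  v <- basis$values
  spread <- max(apply(v, 1L, max) - apply(v, 1L, min))
  if (spread <= 0) spread <- max(abs(v), 1e-300)
  b <- target / spread
  if (sense == "min") -b else b
}

#' Smooth (Boltzmann) maximum
#'
#' Differentiable surrogate for the maximum of a vector,
#' \deqn{\mathrm{max}_S(v, \beta) = \frac{\sum_i v_i e^{\beta v_i}}
#'       {\sum_i e^{\beta v_i}},}
#' computed with overflow-safe shifting. For `beta > 0` it approaches
#' `max(v)` as `beta` grows (and lies between `mean(v)` and `max(v)`);
#' for `beta < 0` it approaches `min(v)`, the largest negative value of a
#' field.
#'
#' @param values Numeric vector (m >= 1) of field values.
#' @param beta Nonzero scale.
#' @return Scalar smooth maximum.
#' @export
smooth_max <- function(values, beta) {
  if (length(values) == 0L) stop("empty field vector", call. = FALSE)
  if (!is.finite(beta) || beta == 0) stop("beta must be nonzero", call. = FALSE)
  e <- beta * values
  w <- exp(e - max(e))
  sum(values * w) / sum(w)
}

## Boltzmann weights and the smooth maximum in one pass.
softmax_weights <- function(values, beta) {
  e <- beta * values
  w <- exp(e - max(e))
  w <- w / sum(w)
  list(w = w, s = sum(values * w))
}

#' Gradient of the smooth maximum of a superposed field
#'
#' Closed-form gradient of `smooth_max(superpose(basis, alpha), beta)`
#' with respect to the current fractions. With Boltzmann weights `w` and
#' smooth maximum `S`, the gradient is
#' `t(B) %*% (w * (1 + beta * (F - S)))` for basis matrix `B`.
#'
#' @param basis A `basis_field_set`.
#' @param config Current fractions (vector or [configuration()]).
#' @param beta Nonzero smooth-maximum scale.
#' @return Numeric vector of n partial derivatives.
#' @export
smooth_max_grad <- function(basis, config, beta) {
  alpha <- as_alpha(config)
  if (length(alpha) != ncol(basis$values)) {
    stop("dimension error: fractions vs contacts", call. = FALSE)
  }
  f <- drop(basis$values %*% alpha)
  sw <- softmax_weights(f, beta)
  unname(drop(crossprod(basis$values, sw$w * (1 + beta * (f - sw$s)))))
}

## Hessian of smooth_max(B alpha, beta) w.r.t. alpha. With a_k = 1 +
## beta (F_k - S), the field-space Hessian is
##   H_kl = beta [ delta_kl w_k (a_k + 1) - w_k w_l (a_k + a_l) ]
##        = beta [ diag(w (a + 1)) - (wa) w' - w (wa)' ],  wa = w * a,
## so the alpha-space Hessian t(B) H B needs only O(m n^2) work.
smooth_max_hess <- function(basis_values, alpha, beta) {
  f <- drop(basis_values %*% alpha)
  sw <- softmax_weights(f, beta)
  a <- 1 + beta * (f - sw$s)
  v1 <- drop(crossprod(basis_values, sw$w * a))
  v2 <- drop(crossprod(basis_values, sw$w))
  beta * (crossprod(basis_values, basis_values * (sw$w * (a + 1))) -
            tcrossprod(v1, v2) - tcrossprod(v2, v1))
}

#' Smooth absolute value
#'
#' Elementwise `alpha * tanh(gamma * alpha)`: an even, everywhere
#' differentiable surrogate for `|alpha|` that never exceeds it and
#' converges to it uniformly as `gamma` grows.
#'
#' @param alpha Numeric vector.
#' @param gamma Positive scale.
#' @return Numeric vector of the same length.
#' @export
smooth_abs <- function(alpha, gamma) {
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  alpha * tanh(gamma * alpha)
}

#' Current-balance constraint residuals
#'
#' The two equality constraints of the fraction-optimization problem:
#' \deqn{h_1 = 2 - \sum_i \alpha_i \tanh(\gamma \alpha_i), \qquad
#'       h_2 = \sum_i \alpha_i,}
#' i.e. the smooth surrogate of `sum(|alpha|) = 2` and exact current
#' balance. Optionally returns the constraint gradients
#' (`dh1/dalpha_j = -[tanh(g a) + g a sech^2(g a)]`, `dh2/dalpha_j = 1`).
#'
#' @param alpha Numeric vector of fractions (or [configuration()]).
#' @param gamma Positive smooth-abs scale.
#' @param gradients If `TRUE`, also return `grad_h1` and `grad_h2`.
#' @return List with `h1`, `h2` (and gradients on request).
#' @export
balance_constraints <- function(alpha, gamma, gradients = FALSE) {
  alpha <- as_alpha(alpha)
  if (!is.finite(gamma) || gamma <= 0) stop("gamma must be > 0", call. = FALSE)
  t_ <- tanh(gamma * alpha)
  out <- list(h1 = 2 - sum(alpha * t_), h2 = sum(alpha))
  if (gradients) {
    sech2 <- 1 - t_^2
    out$grad_h1 <- -(t_ + gamma * alpha * sech2)
    out$grad_h2 <- rep(1, length(alpha))
  }
  out
}

## Diagonal of the Hessian of h1 (h2 is linear):
## d2 h1 / d a_j^2 = -2 gamma sech^2(g a) (1 - g a tanh(g a)).
balance_h1_hess_diag <- function(alpha, gamma) {
  t_ <- tanh(gamma * alpha)
  sech2 <- 1 - t_^2
  -2 * gamma * sech2 * (1 - gamma * alpha * t_)
}
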