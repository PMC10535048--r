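#' Anisotropic volume-conductor medium
#'
#' Homogeneous anisotropic conductor described by its principal
#' conductivities along the coordinate axes. The default values are the
#' standard white-matter conductivities for spinal cord tissue with the
#' fiber (rostrocaudal) axis along z: 0.6 S/m longitudinal and 0.083 S/m
#' transverse.
#'
#' @param sigma_xx,sigma_yy,sigma_zz Principal conductivities (S/m);
#'   strictly positive and finite.
#' @return An object of class `anisotropic_medium`.
#' @examples
#' white_matter <- anisotropic_medium()
#' saline <- anisotropic_medium(1.76, 1.76, 1.76)
#' @export
anisotropic_medium <- function(sigma_xx = 0.083, sigma_yy = 0.083,
                               sigma_zz = 0.6) {
  sig <- c(sigma_xx = sigma_xx, sigma_yy = sigma_yy, sigma_zz = sigma_zz)
  if (!all(is.finite(sig)) || any(sig <= 0)) {
    stop("conductivities must be strictly positive and finite", call. = FALSE)
  }
  structure(as.list(sig), class = "anisotropic_medium")
}

#' @export
print.anisotropic_medium <- function(x, ...) {
  cat(sprintf("Anisotropic medium: sigma = (%g, %g, %g) S/m\n",
              x$sigma_xx, x$sigma_yy, x$sigma_zz))
  invisible(x)
}

#' Multi-contact electrode array
#'
#' @param positions Numeric matrix, one row per contact, columns x, y, z in
#'   meters. Rows must be pairwise distinct.
#' @param labels Character vector of unique contact labels; defaults to
#'   `C1..Cn`.
#' @return An object of class `contact_array`.
#' @export
contact_array <- function(positions, labels = NULL) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L || !all(is.finite(positions))) {
    stop("positions must be a finite n x 3 matrix (meters)", call. = FALSE)
  }
  n <- nrow(positions)
  if (n < 2L) stop("a contact array needs at least 2 contacts", call. = FALSE)
  if (anyDuplicated(positions)) {
    stop("contact positions must be pairwise distinct", call. = FALSE)
  }
  if (is.null(labels)) labels <- paste0("C", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels)) {
    stop("labels must be unique and match the number of contacts",
         call. = FALSE)
  }
  dimnames(positions) <- list(labels, c("x", "y", "z"))
  structure(list(n = n, positions = positions, labels = labels),
            class = "contact_array")
}

#' @export
print.contact_array <- function(x, ...) {
  cat(sprintf("Contact array: %d contacts (%s ... %s)\n",
              x$n, x$labels[1L], x$labels[x$n]))
  invisible(x)
}

#' Region of interest / avoidance specification
#'
#' A set of spatial points together with the local fiber direction and the
#' excitation field that predicts activation there: the directional
#' electric field `-dV/dr` (terminal excitation of local cells) or the
#' activating function `d2V/dr2` (excitation of passing axons).
#'
#' @param points Numeric matrix, one row per sample point (x, y, z meters).
#' @param direction Unit 3-vector parallel to the target neural structure.
#' @param field_kind `"activating_function"` (second directional derivative
#'   of the potential, V/m^2) or `"e_field"` (negative first directional
#'   derivative, V/m).
#' @param role `"roi"` (activation desired) or `"roa"` (activation avoided).
#' @param name Identifier used in reports.
#' @return An object of class `region_spec`.
#' @export
region_spec <- function(points, direction = c(0, 0, 1),
                        field_kind = c("activating_function", "e_field"),
                        role = c("roi", "roa"), name = "region") {
  points <- as.matrix(points)
  if (is.null(dim(points)) || ncol(points) != 3L) {
    stop("points must be an m x 3 matrix", call. = FALSE)
  }
  if (nrow(points) < 1L || !all(is.finite(points))) {
    stop("points must be finite and nonempty", call. = FALSE)
  }
  direction <- as.numeric(direction)
  if (length(direction) != 3L || abs(sqrt(sum(direction^2)) - 1) > 1e-12) {
    stop("direction must be a unit 3-vector (within 1e-12)", call. = FALSE)
  }
  structure(list(points = points, direction = direction,
                 field_kind = match.arg(field_kind), role = match.arg(role),
                 name = as.character(name)),
            class = "region_spec")
}

#' @export
print.region_spec <- function(x, ...) {
  cat(sprintf("Region '%s' [%s]: %d points, %s along (%g, %g, %g)\n",
              x$name, toupper(x$role), nrow(x$points), x$field_kind,
              x$direction[1L], x$direction[2L], x$direction[3L]))
  invisible(x)
}

#' Potential of a monopole current source in an anisotropic medium
#'
#' Closed-form quasi-static potential of a point current source in an
#' unbounded homogeneous anisotropic conductor,
#' \deqn{V = \frac{I}{4\pi\sqrt{\sigma_{xx}\sigma_{yy}\sigma_{zz}}}
#'   \left(\frac{\Delta x^2}{\sigma_{xx}} + \frac{\Delta y^2}{\sigma_{yy}} +
#'         \frac{\Delta z^2}{\sigma_{zz}}\right)^{-1/2}.}
#'
#' @param point Evaluation point(s): length-3 vector or m x 3 matrix (m).
#' @param source Source location, length-3 vector (m).
#' @param current Source current (A).
#' @param medium An [anisotropic_medium()].
#' @return Potential(s) in volts, one per evaluation point.
#' @export
monopole_potential <- function(point, source, current, medium) {
  stopifnot(inherits(medium, "anisotropic_medium"))
  point <- if (is.null(dim(point))) matrix(point, ncol = 3L) else as.matrix(point)
  source <- as.numeric(source)
  sig <- c(medium$sigma_xx, medium$sigma_yy, medium$sigma_zz)
  d <- sweep(point, 2L, source)
  q <- d[, 1L]^2 / sig[1L] + d[, 2L]^2 / sig[2L] + d[, 3L]^2 / sig[3L]
  if (any(q == 0)) {
    stop("singular evaluation: point coincides with the source", call. = FALSE)
  }
  current / (4 * pi * sqrt(prod(sig))) / sqrt(q)
}

## Directional derivatives of the monopole potential along a unit vector r.
## With q = sum(d_i^2 / sigma_i), p = sum(d_i r_i / sigma_i),
## c = sum(r_i^2 / sigma_i) and k the source prefactor:
##   dV/dr  = -k p q^(-3/2)
##   d2V/dr2 = k (3 p^2 q^(-5/2) - c q^(-3/2))
monopole_field <- function(point, source, medium, direction, field_kind) {
  point <- if (is.null(dim(point))) matrix(point, ncol = 3L) else as.matrix(point)
  sig <- c(medium$sigma_xx, medium$sigma_yy, medium$sigma_zz)
  k <- 1 / (4 * pi * sqrt(prod(sig)))
  d <- sweep(point, 2L, as.numeric(source))
  ds <- sweep(d, 2L, sig, "/")
  q <- rowSums(ds * d)
  if (any(q == 0)) {
    stop("singular evaluation: region point coincides with a contact",
         call. = FALSE)
  }
  p <- drop(ds %*% direction)
  if (field_kind == "e_field") {
    k * p * q^(-1.5)                      # -dV/dr
  } else {
    cc <- sum(direction^2 / sig)
    k * (3 * p^2 * q^(-2.5) - cc * q^(-1.5))  # d2V/dr2
  }
}

#' Unit-current basis fields from the analytic point-source model
#'
#' Evaluates, for every region point and every contact, the excitation
#' field produced by a +1 A current on that contact alone (all others at
#' 0 A). The directional derivatives of the monopole potential are taken
#' in closed form along the region's fiber direction.
#'
#' @param contacts A [contact_array()].
#' @param region A [region_spec()].
#' @param medium An [anisotropic_medium()].
#' @return A `basis_field_set`: list with the region, an m x n `values`
#'   matrix (columns named by contact label, units V/m or V/m^2 per
#'   ampere), and `provenance = "analytic"`.
#' @export
analytic_basis_fields <- function(contacts, region, medium) {
  stopifnot(inherits(contacts, "contact_array"),
            inherits(region, "region_spec"),
            inherits(medium, "anisotropic_medium"))
  values <- vapply(seq_len(contacts$n), function(j) {
    monopole_field(region$points, contacts$positions[j, ], medium,
                   region$direction, region$field_kind)
  }, numeric(nrow(region$points)))
  values <- matrix(values, nrow = nrow(region$points),
                   dimnames = list(NULL, contacts$labels))
  new_basis_field_set(region, values, "analytic")
}

new_basis_field_set <- function(region, values, provenance) {
  if (!all(is.finite(values))) {
    stop("basis field values must all be finite", call. = FALSE)
  }
  structure(list(region = region, values = values, provenance = provenance),
            class = "basis_field_set")
}

#' @export
print.basis_field_set <- function(x, ...) {
  cat(sprintf("Basis field set (%s): %d points x %d contacts, region '%s' (%s)\n",
              x$provenance, nrow(x$values), ncol(x$values),
              x$region$name, x$region$field_kind))
  invisible(x)
}

#' Number of contacts spanned by a basis field set
#' @param basis A `basis_field_set`.
#' @return Integer count of contacts (columns).
#' @export
n_contacts <- function(basis) ncol(basis$values)

#' Import precomputed basis fields from a delimited table
#'
#' Reads a CSV with columns `x`, `y`, `z` followed by one column of
#' already-differentiated field values per contact. Use this to bring in
#' fields exported from an external volume-conductor solver; this function
#' never differentiates sampled data.
#'
#' @param file Path to the CSV file (or a data.frame already read in).
#' @param region_meta A [region_spec()] supplying direction, field kind,
#'   role and name; its points are replaced by the table coordinates.
#' @return A `basis_field_set` with `provenance = "imported"`.
#' @export
import_basis_fields <- function(file, region_meta) {
  stopifnot(inherits(region_meta, "region_spec"))
  tab <- if (is.data.frame(file)) file else
    utils::read.csv(file, check.names = FALSE)
  need <- c("x", "y", "z")
  if (!all(need %in% names(tab))) {
    stop("basis table must have columns x, y, z then one per contact; missing: ",
         paste(setdiff(need, names(tab)), collapse = ", "), call. = FALSE)
  }
  contact_cols <- setdiff(names(tab), need)
  if (length(contact_cols) < 2L) {
    stop("basis table needs at least two contact columns", call. = FALSE)
  }
  for (cn in c(need, contact_cols)) {
    col <- tab[[cn]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(col)))))[1L]
      stop(sprintf("non-numeric cell in column '%s' (row %d)", cn,
                   if (is.na(bad)) 1L else bad), call. = FALSE)
    }
    if (anyNA(col) || any(!is.finite(col))) {
      stop(sprintf("NaN/Inf entry in column '%s' (row %d)", cn,
                   which(!is.finite(col))[1L]), call. = FALSE)
    }
  }
  region <- region_spec(as.matrix(tab[need]), region_meta$direction,
                        region_meta$field_kind, region_meta$role,
                        region_meta$name)
  values <- as.matrix(tab[contact_cols])
  new_basis_field_set(region, values, "imported")
}

#' Export basis fields to a delimited table
#'
#' Writes the CSV format read back by [import_basis_fields()]: columns
#' `x,y,z` then one column per contact, 17 significant digits so that a
#' round trip is bit-identical.
#'
#' @param basis A `basis_field_set`.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
export_basis_fields <- function(basis, file) {
  stopifnot(inherits(basis, "basis_field_set"))
  pts <- basis$region$points
  tab <- cbind(data.frame(x = pts[, 1L], y = pts[, 2L], z = pts[, 3L]),
               as.data.frame(basis$values))
  fmt <- vapply(tab, function(col) format(col, digits = 17, trim = TRUE,
                                          scientific = NA),
                character(nrow(tab)))
  fmt <- matrix(fmt, nrow = nrow(tab))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(names(tab), collapse = ","), con)
  writeLines(apply(fmt, 1L, paste, collapse = ","), con)
  invisible(file)
}

#' Superpose basis fields for a set of current fractions
#'
#' Field at every region point for contact currents `alpha` (in units of
#' the stimulus amplitude), by linear superposition of the unit-current
#' basis fields.
#'
#' @param basis A `basis_field_set`.
#' @param config A [configuration()] or bare numeric vector of length n.
#' @return Numeric vector of m field values.
#' @export
superpose <- function(basis, config) {
  alpha <- as_alpha(config)
  if (length(alpha) != ncol(basis$values)) {
    stop(sprintf("dimension error: %d fractions vs %d contacts",
                 length(alpha), ncol(basis$values)), call. = FALSE)
  }
  drop(basis$values %*% alpha)
}
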