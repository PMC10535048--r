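#' Eight-source cube fixture
#'
#' An idealized geometry for exercising the optimizer without any
#' external field data: eight point current sources at the corners of a
#' cube centered at the origin, in a white-matter-like anisotropic
#' medium (0.6 S/m along z, 0.083 S/m transversely). Regions of
#' increasing dimension - a single point, a line along z, a transverse
#' plane, and a box - all lie strictly inside the cube, use the
#' activating function along z, and nest so that the point belongs to
#' the plane and box point sets.
#'
#' @param edge_length Cube edge (m); default 10 mm.
#' @return A `fixture`: list with `name`, `contacts`
#'   ([contact_array()]), `medium` ([anisotropic_medium()]) and a named
#'   list of `regions` ([region_spec()]s: `point0d`, `line1d`,
#'   `plane2d`, `box3d`).
#' @export
make_cube8 <- function(edge_length = 0.01) {
  half <- edge_length / 2
  corners <- as.matrix(expand.grid(x = c(-half, half), y = c(-half, half),
                                   z = c(-half, half)))
  contacts <- contact_array(corners, paste0("S", 1:8))
  medium <- anisotropic_medium(0.083, 0.083, 0.6)
  s <- edge_length / 5   # inner region scale: strictly inside the cube
  point0d <- matrix(c(0, 0, s), ncol = 3L)
  line1d <- cbind(0, 0, seq(-2 * s, 2 * s, length.out = 17L))
  plane_xy <- as.matrix(expand.grid(x = c(-s, 0, s), y = c(-s, 0, s)))
  plane2d <- cbind(plane_xy, z = s)
  box3d <- as.matrix(expand.grid(x = c(-s, 0, s), y = c(-s, 0, s),
                                 z = c(-2 * s, -s, 0, s, 2 * s)))
  mk <- function(pts, name) {
    region_spec(pts, c(0, 0, 1), "activating_function", "roi", name)
  }
  structure(list(name = "cube8", contacts = contacts, medium = medium,
                 regions = list(point0d = mk(point0d, "point0d"),
                                line1d = mk(line1d, "line1d"),
                                plane2d = mk(plane2d, "plane2d"),
                                box3d = mk(box3d, "box3d"))),
            class = "fixture")
}

#' Two-lead sixteen-contact percutaneous array fixture
#'
#' Emulates two parallel eight-contact percutaneous leads: contacts are
#' approximated as point sources at the contact centers, two z-aligned
#' columns 4 mm apart with a 4 mm center-to-center contact pitch (3 mm
#' contacts, 1 mm edge-to-edge gaps), in the anisotropic white-matter
#' medium. Regions: a midline axon line and left/right off-midline axon
#' lines (activating function along z, 161 points at 0.5 mm spacing
#' spanning the array plus ~20 mm margins, at a documented dorsoventral
#' offset), plus two lateral boxes evaluated with the directional
#' electric field (terminal-excitation analogs).
#'
#' @param lead_separation Center-to-center lead distance (m).
#' @param contact_pitch Center-to-center contact spacing along z (m).
#' @param n_per_lead Contacts per lead.
#' @param axon_offset Dorsoventral (y) offset of the axon lines from the
#'   lead plane (m).
#' @return A `fixture` with contacts `C1..C8` (left lead, x < 0) and
#'   `C9..C16` (right lead), and regions `midline_axon`, `left_axon`,
#'   `right_axon`, `left_box`, `right_box`.
#' @export
make_two_lead_16 <- function(lead_separation = 0.004, contact_pitch = 0.004,
                             n_per_lead = 8, axon_offset = 0.003) {
  zc <- (seq_len(n_per_lead) - (n_per_lead + 1) / 2) * contact_pitch
  xl <- -lead_separation / 2
  xr <- +lead_separation / 2
  pos <- rbind(cbind(xl, 0, zc), cbind(xr, 0, zc))
  contacts <- contact_array(pos, paste0("C", seq_len(2L * n_per_lead)))
  medium <- anisotropic_medium(0.083, 0.083, 0.6)
  zline <- seq(-0.04, 0.04, length.out = 161L)
  axon <- function(x, name, role = "roi") {
    region_spec(cbind(x, axon_offset, zline), c(0, 0, 1),
                "activating_function", role, name)
  }
  box <- function(x0, name, role) {
    pts <- as.matrix(expand.grid(x = x0 + c(-0.001, 0, 0.001),
                                 y = c(0.002, 0.004),
                                 z = seq(-0.01, 0.01, length.out = 9L)))
    region_spec(pts, c(0, 0, 1), "e_field", role, name)
  }
  structure(list(name = "two_lead_16", contacts = contacts, medium = medium,
                 regions = list(
                   midline_axon = axon(0, "midline_axon"),
                   left_axon = axon(xl, "left_axon"),
                   right_axon = axon(xr, "right_axon", role = "roa"),
                   left_box = box(-0.006, "left_box", "roi"),
                   right_box = box(0.006, "right_box", "roa"))),
            class = "fixture")
}

#' @export
print.fixture <- function(x, ...) {
  cat(sprintf("Fixture '%s': %d contacts, regions: %s\n", x$name,
              x$contacts$n, paste(names(x$regions), collapse = ", ")))
  invisible(x)
}

#' Basis fields for a fixture region
#'
#' Convenience wrapper: analytic unit-current basis fields for one of a
#' fixture's named regions.
#'
#' @param fixture A `fixture` from [make_cube8()] or
#'   [make_two_lead_16()].
#' @param region Region name.
#' @return A `basis_field_set`.
#' @export
fixture_basis <- function(fixture, region) {
  stopifnot(inherits(fixture, "fixture"))
  if (!region %in% names(fixture$regions)) {
    stop("unknown region '", region, "'; fixture has: ",
         paste(names(fixture$regions), collapse = ", "), call. = FALSE)
  }
  analytic_basis_fields(fixture$contacts, fixture$regions[[region]],
                        fixture$medium)
}
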