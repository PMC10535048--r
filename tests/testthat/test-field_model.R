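test_that("monopole potential matches the closed form and its symmetries", {
  iso <- anisotropic_medium(1, 1, 1)
  # isotropic reduction: V = I / (4 pi sigma r)
  expect_equal(monopole_potential(c(1, 0, 0), c(0, 0, 0), 4 * pi, iso), 1)
  for (i in 1:100) {
    set.seed(i)
    p <- rnorm(3)
    s <- rnorm(3)
    sg <- runif(1, 0.05, 2)
    med <- anisotropic_medium(sg, sg, sg)
    r <- sqrt(sum((p - s)^2))
    expect_equal(monopole_potential(p, s, 1, med), 1 / (4 * pi * sg * r),
                 tolerance = 1e-12)
  }
  # transverse isotropy: sigma_xx = sigma_yy makes x- and y-displacements
  # equivalent
  wm <- white_matter()
  a <- 2.3e-3
  expect_identical(monopole_potential(c(a, 0, 0), c(0, 0, 0), 1, wm),
                   monopole_potential(c(0, a, 0), c(0, 0, 0), 1, wm))
  # frozen direct evaluation of the anisotropic formula at 1 mm
  k <- 1 / (4 * pi * sqrt(0.083 * 0.083 * 0.6))
  v_expect <- k / sqrt(1e-6 / 0.083)
  expect_equal(monopole_potential(c(1e-3, 0, 0), c(0, 0, 0), 1, wm), v_expect)
  expect_equal(v_expect, 356.5952, tolerance = 1e-6)
  # linear in current
  expect_equal(monopole_potential(c(1e-3, 0, 0), c(0, 0, 0), 3.7, wm),
               3.7 * v_expect)
  expect_error(monopole_potential(c(0, 0, 0), c(0, 0, 0), 1, wm), "singular")
  expect_error(anisotropic_medium(-1, 1, 1), "positive")
})

test_that("analytic basis fields agree with finite-difference oracles", {
  wm <- white_matter()
  contacts <- test4_contacts()
  pts <- rbind(c(0.5e-3, 1.5e-3, 0.5e-3), c(-1e-3, 2e-3, -2e-3))
  for (kind in c("e_field", "activating_function")) {
    reg <- region_spec(pts, c(0, 0, 1), kind, "roi", "fd")
    basis <- analytic_basis_fields(contacts, reg, wm)
    for (i in seq_len(nrow(pts))) {
      for (j in seq_len(contacts$n)) {
        f <- function(x) monopole_potential(x, contacts$positions[j, ], 1, wm)
        ref <- if (kind == "e_field") {
          -fd_directional(f, pts[i, ], c(0, 0, 1), order = 1L)
        } else {
          fd_directional(f, pts[i, ], c(0, 0, 1), order = 2L)
        }
        expect_equal(unname(basis$values[i, j]), ref, tolerance = 1e-6)
      }
    }
  }
})

test_that("basis fields respect conductivity scaling and odd symmetry", {
  contacts <- test4_contacts()
  pts <- matrix(c(0.5e-3, 1.5e-3, 0.5e-3), 1L)
  for (kind in c("e_field", "activating_function")) {
    reg <- region_spec(pts, c(0, 0, 1), kind, "roi", "s")
    b1 <- analytic_basis_fields(contacts, reg, white_matter())
    b2 <- analytic_basis_fields(contacts, reg,
                                anisotropic_medium(0.166, 0.166, 1.2))
    expect_equal(b2$values, b1$values / 2, tolerance = 1e-12)
  }
  # E-field along z vanishes in the source's transverse plane
  reg <- region_spec(matrix(c(1e-3, 2e-3, -3e-3), 1L), c(0, 0, 1),
                     "e_field", "roi", "t")
  src <- contact_array(rbind(c(0, 0, -3e-3), c(5e-3, 0, 0)))
  b <- analytic_basis_fields(src, reg, white_matter())
  expect_equal(unname(b$values[1L, 1L]), 0)
})

test_that("import/export round trip is bit-identical and validates input", {
  basis <- test4_basis(c(0.5e-3, 1.5e-3, 0.5e-3))
  tmp <- tempfile(fileext = ".csv")
  export_basis_fields(basis, tmp)
  back <- import_basis_fields(tmp, basis$region)
  expect_identical(back$values, basis$values)
  expect_identical(back$provenance, "imported")
  expect_equal(back$region$points, basis$region$points, ignore_attr = TRUE)

  df <- data.frame(x = 1:3, y = 0, z = 0, C1 = c(1, 2, 3), C2 = c(4, 5, 6))
  b32 <- import_basis_fields(df, basis$region)
  expect_equal(dim(b32$values), c(3L, 2L))
  df_bad <- df
  df_bad$C2[2L] <- NaN
  expect_error(import_basis_fields(df_bad, basis$region), "row 2")
  expect_error(import_basis_fields(df[, -1L], basis$region), "missing")
})

test_that("superposition is exactly linear in the fractions", {
  basis <- test4_basis(rbind(c(0, 1e-3, 0), c(1e-3, 1e-3, 2e-3)))
  n <- ncol(basis$values)
  for (j in seq_len(n)) {
    e <- numeric(n)
    e[j] <- 1
    expect_identical(superpose(basis, e), unname(basis$values[, j]))
  }
  expect_identical(superpose(basis, numeric(n)), c(0, 0))
  set.seed(42)
  for (i in 1:20) {
    a1 <- rnorm(n); a2 <- rnorm(n); w <- rnorm(2)
    expect_equal(superpose(basis, w[1] * a1 + w[2] * a2),
                 w[1] * superpose(basis, a1) + w[2] * superpose(basis, a2),
                 tolerance = 1e-13)
  }
  expect_error(superpose(basis, c(1, -1)), "dimension")
})
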