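test_that("run configurations validate their required fields", {
  expect_error(run_config("optimize"), "fixture or an imported")
  expect_error(run_config("optimize", fixture = "cube8"), "region")
  expect_error(run_config("pareto", fixture = "two_lead_16", roi = "left_axon"),
               "roi and roa")
  expect_error(run_config("evaluate", fixture = "cube8", region = "point0d"),
               "alpha")
  cfg <- run_config("optimize", fixture = "cube8", region = "point0d",
                    seed = 2, n_starts = 10, out = tempfile())
  expect_s3_class(cfg, "run_config")
})

test_that("evaluate reports the field extrema of a given configuration", {
  # bipolar fractions over an imported single-point basis: the dot product
  df <- data.frame(x = 0, y = 0, z = 0, C1 = 5, C2 = 2)
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(df, tmp, row.names = FALSE)
  cfg <- run_config("evaluate", basis = tmp, alpha = c(1, -1), out = ".")
  expect_message(wb_evaluate(cfg), "field max 3")
  out <- suppressMessages(wb_evaluate(cfg))
  expect_equal(out$max, 3)
  expect_equal(out$min, 3)
})

test_that("optimize runs write deterministic solution tables and manifests", {
  dir1 <- tempfile(); dir2 <- tempfile()
  cfg <- run_config("optimize", fixture = "cube8", region = "point0d",
                    n_starts = 20, seed = 12, out = dir1)
  pts <- suppressMessages(wb_optimize(cfg))
  expect_true(file.exists(file.path(dir1, "solutions.csv")))
  expect_true(file.exists(file.path(dir1, "manifest.json")))
  tab <- utils::read.csv(file.path(dir1, "solutions.csv"))
  expect_identical(nrow(tab), length(pts))
  expect_true(all(c("classification", "objective", "alpha_S1") %in% names(tab)))
  # byte-identical rerun
  cfg$out <- dir2
  suppressMessages(wb_optimize(cfg))
  expect_identical(readLines(file.path(dir1, "solutions.csv")),
                   readLines(file.path(dir2, "solutions.csv")))
})

test_that("a manifest reruns to identical outputs", {
  dir1 <- tempfile(); dir2 <- tempfile()
  cfg <- run_config("optimize", fixture = "cube8", region = "point0d",
                    n_starts = 15, seed = 33, out = dir1)
  suppressMessages(wb_optimize(cfg))
  suppressMessages(run_from_manifest(file.path(dir1, "manifest.json"),
                                     out = dir2))
  expect_identical(readLines(file.path(dir1, "solutions.csv")),
                   readLines(file.path(dir2, "solutions.csv")))
})

test_that("gen-fixture emits geometry and basis tables that re-import", {
  dir1 <- tempfile()
  cfg <- run_config("gen-fixture", fixture = "cube8", out = dir1)
  wb_gen_fixture(cfg)
  expect_true(file.exists(file.path(dir1, "contacts.csv")))
  expect_true(file.exists(file.path(dir1, "basis_point0d.csv")))
  fx <- make_cube8()
  back <- import_basis_fields(file.path(dir1, "basis_point0d.csv"),
                              fx$regions$point0d)
  direct <- fixture_basis(fx, "point0d")
  expect_identical(unname(back$values), unname(direct$values))
})

test_that("the CLI dispatches commands and reports bad input", {
  dir1 <- tempfile()
  status <- suppressMessages(steer_cli(c(
    "optimize", "--fixture", "cube8", "--region", "point0d",
    "--n-starts", "15", "--seed", "3", "--out", dir1)))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(dir1, "solutions.csv")))
  expect_identical(suppressMessages(steer_cli(c("optimize", "--fixture",
                                                "nosuch", "--region", "x"))),
                   1L)
  expect_identical(suppressMessages(steer_cli(character(0))), 1L)
  # YAML config files supply defaults for flags
  cfgfile <- tempfile(fileext = ".yaml")
  dir2 <- tempfile()
  writeLines(c("fixture: cube8", "region: point0d", "n_starts: 15",
               "seed: 3"), cfgfile)
  status2 <- suppressMessages(steer_cli(c("optimize", "--config", cfgfile,
                                          "--out", dir2)))
  expect_identical(status2, 0L)
  expect_identical(readLines(file.path(dir1, "solutions.csv")),
                   readLines(file.path(dir2, "solutions.csv")))
})

test_that("baseline command summarizes random and bipolar objectives", {
  dir1 <- tempfile()
  cfg <- run_config("baseline", fixture = "cube8", region = "point0d",
                    n_starts = 20, n_random = 100, seed = 14, out = dir1)
  rep_ <- suppressMessages(wb_baseline(cfg))
  expect_s3_class(rep_, "baseline_report")
  tab <- utils::read.csv(file.path(dir1, "baseline.csv"))
  expect_identical(sum(tab$type == "random"), 100L)
  expect_identical(sum(tab$type == "bipolar"), 56L)
  summ <- jsonlite::read_json(file.path(dir1, "baseline_summary.json"))
  # single-point objectives can be negative for random draws, so the
  # mean shortfall must simply be positive
  expect_true(summ$deficit > 0)
})
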