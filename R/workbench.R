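#' Assemble and validate a run configuration
#'
#' A run configuration drives the workbench commands ([wb_optimize()],
#' [wb_pareto()], [wb_baseline()], [wb_evaluate()]). Every stochastic
#' command requires a seed so that any run can be reproduced
#' bit-identically from its manifest.
#'
#' @param command One of `optimize`, `pareto`, `baseline`, `evaluate`,
#'   `gen-fixture`.
#' @param fixture Built-in fixture name (`cube8` or `two_lead_16`), or
#'   `NULL` when `basis` supplies an imported field table.
#' @param region Region name for single-region commands.
#' @param roi,roa Region names for `pareto` (primary and capped region).
#' @param basis Path to an imported basis-field CSV (alternative to a
#'   fixture; the region metadata defaults to an activating-function ROI
#'   along z).
#' @param alpha Numeric vector of fractions for `evaluate`.
#' @param beta,gamma Smoothing scales; `beta = NULL` means automatic.
#' @param n_starts,seed Solver multistart size and RNG seed.
#' @param n_eps Epsilon-grid size for `pareto`.
#' @param n_random Random-draw count for `baseline`.
#' @param out Output directory.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(command, fixture = NULL, region = NULL, roi = NULL,
                       roa = NULL, basis = NULL, alpha = NULL, beta = NULL,
                       gamma = 50, n_starts = 200, seed = 1, n_eps = 25,
                       n_random = 10000, out = ".") {
  command <- match.arg(command,
                       c("optimize", "pareto", "baseline", "evaluate",
                         "gen-fixture"))
  cfg <- list(command = command, fixture = fixture, region = region,
              roi = roi, roa = roa, basis = basis, alpha = alpha,
              beta = beta, gamma = gamma, n_starts = as.integer(n_starts),
              seed = as.integer(seed), n_eps = as.integer(n_eps),
              n_random = as.integer(n_random), out = out)
  if (is.null(cfg$fixture) && is.null(cfg$basis) && command != "evaluate") {
    stop("config needs a fixture or an imported basis table", call. = FALSE)
  }
  if (command %in% c("optimize", "baseline") && is.null(cfg$region) &&
      is.null(cfg$basis)) {
    stop("config needs a region name", call. = FALSE)
  }
  if (command == "pareto" && (is.null(cfg$roi) || is.null(cfg$roa))) {
    stop("pareto needs both roi and roa region names", call. = FALSE)
  }
  if (command == "evaluate" && is.null(cfg$alpha)) {
    stop("evaluate needs current fractions (alpha)", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

cfg_fixture <- function(cfg) {
  switch(cfg$fixture,
         cube8 = make_cube8(),
         two_lead_16 = make_two_lead_16(),
         stop("unknown fixture '", cfg$fixture, "'", call. = FALSE))
}

cfg_basis <- function(cfg, region = cfg$region) {
  if (!is.null(cfg$basis)) {
    meta <- region_spec(matrix(0, 1L, 3L), c(0, 0, 1), "activating_function",
                        "roi", if (is.null(region)) "imported" else region)
    import_basis_fields(cfg$basis, meta)
  } else {
    fixture_basis(cfg_fixture(cfg), region)
  }
}

cfg_params <- function(cfg) smoothing_params(beta = cfg$beta, gamma = cfg$gamma)

cfg_settings <- function(cfg) {
  solver_settings(n_starts = cfg$n_starts, seed = cfg$seed)
}

write_manifest <- function(cfg, path, extra = list()) {
  man <- c(unclass(cfg), extra,
           list(package_version = as.character(utils::packageVersion("steerfield"))))
  jsonlite::write_json(man, path, auto_unbox = TRUE, null = "null",
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Re-run a workbench command from its manifest
#'
#' Reads a manifest written by a previous run and re-dispatches the same
#' command with the same settings and seed, reproducing the output files
#' exactly.
#'
#' @param path Path to a `manifest.json`.
#' @param out Optional new output directory (defaults to the one in the
#'   manifest).
#' @return The command's return value, invisibly.
#' @export
run_from_manifest <- function(path, out = NULL) {
  man <- jsonlite::read_json(path, simplifyVector = TRUE)
  keep <- intersect(names(man), names(formals(run_config)))
  cfg <- do.call(run_config, man[keep])
  if (!is.null(out)) cfg$out <- out
  dispatch_command(cfg)
}

dispatch_command <- function(cfg) {
  switch(cfg$command,
         "gen-fixture" = wb_gen_fixture(cfg),
         "optimize" = wb_optimize(cfg),
         "pareto" = wb_pareto(cfg),
         "baseline" = wb_baseline(cfg),
         "evaluate" = wb_evaluate(cfg))
}

#' Write a fixture's geometry and basis fields to a directory
#'
#' Emits `contacts.csv` (label, x, y, z), one `region_<name>.csv` per
#' region (point coordinates), and one `basis_<name>.csv` per region in
#' the import/export format of [export_basis_fields()].
#'
#' @param cfg A [run_config()] with `command = "gen-fixture"`.
#' @return The output directory, invisibly.
#' @export
wb_gen_fixture <- function(cfg) {
  fx <- cfg_fixture(cfg)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  ct <- data.frame(label = fx$contacts$labels, fx$contacts$positions)
  utils::write.csv(ct, file.path(cfg$out, "contacts.csv"), row.names = FALSE)
  for (nm in names(fx$regions)) {
    reg <- fx$regions[[nm]]
    utils::write.csv(as.data.frame(reg$points),
                     file.path(cfg$out, paste0("region_", nm, ".csv")),
                     row.names = FALSE)
    basis <- analytic_basis_fields(fx$contacts, reg, fx$medium)
    export_basis_fields(basis, file.path(cfg$out, paste0("basis_", nm, ".csv")))
  }
  write_manifest(cfg, file.path(cfg$out, "manifest.json"),
                 list(regions = names(fx$regions)))
  invisible(cfg$out)
}

#' Write a solution table for a list of critical points
#'
#' One row per critical point: rank, classification, exact and smooth
#' objectives, residual norm, then the corrected fraction per contact.
#'
#' @param points A `critical_points` list.
#' @param file Output CSV path.
#' @param labels Contact labels for the fraction columns.
#' @return `file`, invisibly.
#' @export
write_solutions_csv <- function(points, file, labels = NULL) {
  if (!length(points)) {
    utils::write.csv(data.frame(), file, row.names = FALSE)
    return(invisible(file))
  }
  n <- length(points[[1L]]$config$alpha)
  if (is.null(labels)) labels <- paste0("C", seq_len(n))
  rows <- lapply(seq_along(points), function(i) {
    p <- points[[i]]
    row <- data.frame(rank = i, classification = p$classification,
                      objective = unname(p$objective),
                      objective_smooth = unname(p$objectives_smooth[1L]),
                      residual = p$residual_norm)
    for (j in seq_len(n)) row[[paste0("alpha_", labels[j])]] <-
      p$config$alpha[j]
    row
  })
  utils::write.csv(do.call(rbind, rows), file, row.names = FALSE)
  invisible(file)
}

#' Run a single-objective optimization from a configuration
#'
#' Builds the region's basis fields, runs [multistart_solve()], and
#' writes `solutions.csv` plus a `manifest.json` recording the settings
#' and the smoothing scales actually used.
#'
#' @param cfg A [run_config()] with `command = "optimize"`.
#' @return The `critical_points` list, invisibly.
#' @export
wb_optimize <- function(cfg) {
  basis <- cfg_basis(cfg)
  pts <- withCallingHandlers(
    multistart_solve(basis, cfg_params(cfg), cfg_settings(cfg)),
    warning = function(w) {
      message("warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  write_solutions_csv(pts, file.path(cfg$out, "solutions.csv"),
                      colnames(basis$values))
  write_manifest(cfg, file.path(cfg$out, "manifest.json"),
                 list(beta_used = attr(pts, "beta"),
                      beta_final = attr(pts, "beta_final"),
                      gamma_used = cfg$gamma,
                      n_solutions = length(pts),
                      n_discarded = attr(pts, "n_discarded")))
  message(sprintf("optimize: %d solution(s), %d start(s) discarded",
                  length(pts), attr(pts, "n_discarded")))
  invisible(pts)
}

#' Run an epsilon-constraint Pareto sweep from a configuration
#'
#' Uses the configured ROI as the primary region and the ROA as the
#' capped region, sweeps the automatic epsilon grid, and writes
#' `pareto.csv` (one row per front point: caps, raw and normalized
#' objectives, fractions, flags) plus a manifest.
#'
#' @param cfg A [run_config()] with `command = "pareto"`.
#' @return The `pareto_front`, invisibly.
#' @export
wb_pareto <- function(cfg) {
  fx <- cfg_fixture(cfg)
  bases <- list(fixture_basis(fx, cfg$roi), fixture_basis(fx, cfg$roa))
  front <- withCallingHandlers(
    pareto_sweep(bases, n_eps = cfg$n_eps, params = cfg_params(cfg),
                 settings = cfg_settings(cfg)),
    warning = function(w) {
      message("warning: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(front), file.path(cfg$out, "pareto.csv"),
                   row.names = FALSE)
  write_manifest(cfg, file.path(cfg$out, "manifest.json"),
                 list(n_front = nrow(front),
                      n_nondominated = sum(front$nondominated)))
  message(sprintf("pareto: %d front point(s), %d nondominated", nrow(front),
                  sum(front$nondominated)))
  invisible(front)
}

#' Run baseline comparisons from a configuration
#'
#' Optimizes the configured region, evaluates the seeded random and
#' bipolar baselines against the optimum, and writes `baseline.csv`
#' (configuration id, type, objective), `baseline_summary.json`, and a
#' manifest.
#'
#' @param cfg A [run_config()] with `command = "baseline"`.
#' @return The `baseline_report`, invisibly.
#' @export
wb_baseline <- function(cfg) {
  basis <- cfg_basis(cfg)
  pts <- multistart_solve(basis, cfg_params(cfg), cfg_settings(cfg))
  best <- global_optimum(pts)
  if (is.null(best)) stop("no optimized maximum found for the baseline run",
                          call. = FALSE)
  rep_ <- baseline_report(basis, best$objective, n_random = cfg$n_random,
                          seed = cfg$seed)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  tab <- rbind(
    data.frame(id = paste0("random_", seq_along(rep_$random_objectives)),
               type = "random", objective = rep_$random_objectives),
    data.frame(id = paste0("bipolar_", seq_along(rep_$bipolar_objectives)),
               type = "bipolar", objective = rep_$bipolar_objectives))
  utils::write.csv(tab, file.path(cfg$out, "baseline.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(mean_random = rep_$summary[["mean"]], deficit = rep_$deficit,
         optimum = rep_$optimum_objective, best_bipolar = rep_$best_bipolar),
    file.path(cfg$out, "baseline_summary.json"), auto_unbox = TRUE,
    digits = NA)
  write_manifest(cfg, file.path(cfg$out, "manifest.json"),
                 list(deficit = rep_$deficit))
  message(sprintf("baseline: mean random deficit %.1f%%", 100 * rep_$deficit))
  invisible(rep_)
}

#' Evaluate the objective of a given configuration
#'
#' Superposes the basis fields for the supplied fractions and prints the
#' pointwise maximum and minimum of the field over the region.
#'
#' @param cfg A [run_config()] with `command = "evaluate"`.
#' @return A list with `max`, `min` and the field values, invisibly.
#' @export
wb_evaluate <- function(cfg) {
  basis <- cfg_basis(cfg)
  f <- superpose(basis, cfg$alpha)
  out <- list(max = max(f), min = min(f), field = f)
  message(sprintf("evaluate: field max %.6g, min %.6g over %d point(s)",
                  out$max, out$min, length(f)))
  if (!is.null(cfg$out) && nzchar(cfg$out) && cfg$out != ".") {
    dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(list(max = out$max, min = out$min),
                         file.path(cfg$out, "evaluate.json"),
                         auto_unbox = TRUE, digits = NA)
    write_manifest(cfg, file.path(cfg$out, "manifest.json"))
  }
  invisible(out)
}

#' Command-line entry point
#'
#' Dispatches `steerfield <command> [--flag value ...]` where the
#' command is one of `gen-fixture`, `optimize`, `pareto`, `baseline`,
#' `evaluate`. Flags mirror the [run_config()] fields (`--fixture`,
#' `--region`, `--roi`, `--roa`, `--basis`, `--alpha` as a comma list,
#' `--beta`, `--gamma`, `--n-starts`, `--n-eps`, `--n-random`,
#' `--seed`, `--out`, `--config` for a YAML file with the same keys;
#' explicit flags override the file). Installed alongside the package as
#' `cli/steerfield.R`, runnable with `Rscript`.
#'
#' @param args Character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
steer_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) {
    message("usage: steerfield <gen-fixture|optimize|pareto|baseline|evaluate> [options]")
    return(invisible(1L))
  }
  command <- args[1L]
  opts <- parse_cli_flags(args[-1L])
  if (!is.null(opts$config)) {
    fromfile <- yaml::read_yaml(opts$config)
    for (nm in setdiff(names(fromfile), names(opts))) opts[[nm]] <- fromfile[[nm]]
    opts$config <- NULL
  }
  if (!is.null(opts$alpha) && is.character(opts$alpha)) {
    opts$alpha <- as.numeric(strsplit(opts$alpha, ",")[[1L]])
  }
  for (nm in c("beta", "gamma")) {
    if (!is.null(opts[[nm]])) opts[[nm]] <- as.numeric(opts[[nm]])
  }
  for (nm in c("n_starts", "n_eps", "n_random", "seed")) {
    if (!is.null(opts[[nm]])) opts[[nm]] <- as.integer(opts[[nm]])
  }
  status <- tryCatch({
    cfg <- do.call(run_config, c(list(command = command), opts))
    dispatch_command(cfg)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

parse_cli_flags <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) stop("unexpected argument: ", a, call. = FALSE)
    key <- gsub("-", "_", substring(a, 3L))
    if (i == length(args) || startsWith(args[i + 1L], "--")) {
      stop("flag ", a, " needs a value", call. = FALSE)
    }
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  opts
}
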