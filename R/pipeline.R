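#' Build a pipeline run configuration
#'
#' Collects every input path and stage option of the end-to-end analysis into
#' one validated list. Every stochastic stage carries an explicit seed so a
#' run is reproducible from its manifest alone.
#'
#' @param peak_csv raw peak table CSV (see [read_peak_table()]); may be
#'   `NULL` when `scenario` is given, in which case synthetic inputs are
#'   generated first.
#' @param env_csv covariate CSV (see [read_env_table()]); as above.
#' @param clones_fasta optional clone FASTA; when given, the digestion stage
#'   runs.
#' @param out_dir output directory for all stage outputs and the manifest.
#' @param scenario optional [trflp_scenario()] used to simulate the inputs.
#' @param min_bp,max_bp,tolerance_bp,noise_floor,renormalize preprocessing
#'   options.
#' @param exclude_before_day moving-window start-up exclusion (days;
#'   `NULL` keeps all pairs).
#' @param cca_scaling,cca_n_perm,cca_alpha,cca_seed ordination options
#'   (scaling mode, permutations for the global tests and forward selection,
#'   inclusion threshold, seed).
#' @param mantel_metric,mantel_n_perm,mantel_tail,mantel_seed Mantel options.
#' @param enzyme_site,digest_tolerance_bp digestion options.
#' @return an object of class `run_config`.
#' @export
run_config <- function(peak_csv = NULL, env_csv = NULL, clones_fasta = NULL,
                       out_dir, scenario = NULL,
                       min_bp = 50, max_bp = 500, tolerance_bp = 1.0,
                       noise_floor = 0.02, renormalize = TRUE,
                       exclude_before_day = NULL,
                       cca_scaling = "species", cca_n_perm = 499,
                       cca_alpha = 0.05, cca_seed = 1L,
                       mantel_metric = "bray-curtis", mantel_n_perm = 999,
                       mantel_tail = "greater", mantel_seed = 1L,
                       enzyme_site = "TCGA", digest_tolerance_bp = 3) {
  .check(!is.null(scenario) || (!is.null(peak_csv) && !is.null(env_csv)),
         "either a scenario or both peak_csv and env_csv must be given")
  structure(list(
    peak_csv = peak_csv, env_csv = env_csv, clones_fasta = clones_fasta,
    out_dir = out_dir, scenario = scenario,
    min_bp = min_bp, max_bp = max_bp, tolerance_bp = tolerance_bp,
    noise_floor = noise_floor, renormalize = renormalize,
    exclude_before_day = exclude_before_day,
    cca_scaling = cca_scaling, cca_n_perm = cca_n_perm,
    cca_alpha = cca_alpha, cca_seed = as.integer(cca_seed),
    mantel_metric = mantel_metric, mantel_n_perm = mantel_n_perm,
    mantel_tail = mantel_tail, mantel_seed = as.integer(mantel_seed),
    enzyme_site = enzyme_site, digest_tolerance_bp = digest_tolerance_bp
  ), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file holds [run_config()] arguments by name; a `scenario` entry is
#' passed through [trflp_scenario()] field handling as in [read_scenario()].
#'
#' @param path YAML or JSON configuration file.
#' @param out_dir optional override of the configured output directory.
#' @return a `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  .check(file.exists(path), "config file not found: %s", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (!is.null(raw$scenario)) {
    sc <- raw$scenario
    if (!is.null(sc$env_specs)) sc$env_specs <- .spec_df(sc$env_specs)
    if (!is.null(sc$response_specs)) sc$response_specs <- .spec_df(sc$response_specs)
    raw$scenario <- do.call(trflp_scenario, sc)
  }
  if (!is.null(out_dir)) raw$out_dir <- out_dir
  do.call(run_config, raw)
}

.stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    writeLines(sprintf("stage %s failed: %s", name, conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full fingerprint analysis pipeline
#'
#' Executes, in order: optional synthetic-input generation, preprocessing
#' (size window, binning, relative abundance, noise floor), moving-window
#' change analysis, CCA with global permutation tests and forward selection,
#' per-variable Mantel tests, and, when clone sequences are supplied,
#' in-silico digestion. All stage outputs are written under
#' `config$out_dir`, together with `manifest.json` recording the package
#' version, the full configuration, the seeds, and an md5 checksum per
#' output file. Reruns with the same configuration are byte-identical. A
#' failing stage aborts with the stage name and cause and leaves a `FAILED`
#' marker beside any partial outputs.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the manifest and the in-memory stage
#'   results (`series`, `env`, `change`, `cca`, `forward`, `mantel`,
#'   `digestion`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  .check(inherits(config, "run_config"), "config must be a run_config")
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(out, "FAILED"))
  say <- function(...) if (!quiet) message(sprintf(...))

  peak_csv <- config$peak_csv
  env_csv <- config$env_csv
  if (!is.null(config$scenario)) {
    say("stage simulate: generating synthetic study inputs")
    .stage("simulate", out, {
      peak_csv <- file.path(out, "peaks.csv")
      env_csv <- file.path(out, "env.csv")
      write_synthetic_study(config$scenario, peak_csv, env_csv)
    })
  }

  say("stage preprocess: %s", peak_csv)
  pre <- .stage("preprocess", out, {
    peaks <- read_peak_table(peak_csv)
    env <- read_env_table(env_csv)
    preprocess_peaks(peaks, env, config$min_bp, config$max_bp,
                     config$tolerance_bp, config$noise_floor,
                     config$renormalize)
  })
  write_profile_series(pre$series, file.path(out, "profiles.tsv"))

  say("stage dynamics: moving-window change analysis")
  change <- .stage("dynamics", out, {
    moving_window(pre$series, config$exclude_before_day)
  })
  write_change_series(change, file.path(out, "change_series.tsv"),
                      file.path(out, "change_summary.json"))

  say("stage ordination: CCA with %d permutations", config$cca_n_perm)
  env_vars <- setdiff(names(pre$env)[vapply(pre$env, is.numeric, logical(1))],
                      "time_days")
  X <- as.matrix(pre$env[, env_vars, drop = FALSE])
  ord <- .stage("ordination", out, {
    fit <- fit_cca(pre$series$matrix, X, scaling = config$cca_scaling,
                   n_perm = config$cca_n_perm, seed = config$cca_seed)
    fwd <- forward_select(pre$series$matrix, X, alpha = config$cca_alpha,
                          n_perm = config$cca_n_perm, seed = config$cca_seed)
    list(fit = fit, fwd = fwd)
  })
  write_cca_result(ord$fit, out)
  utils::write.table(ord$fwd$trace, file.path(out, "forward_selection.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  say("stage mantel: per-variable tests (%d permutations)", config$mantel_n_perm)
  mt <- .stage("mantel", out, {
    mantel_table(pre$series, pre$env, variables = env_vars,
                 metric = config$mantel_metric, n_perm = config$mantel_n_perm,
                 seed = config$mantel_seed, tail = config$mantel_tail)
  })
  utils::write.table(mt, file.path(out, "mantel.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  digestion <- NULL
  if (!is.null(config$clones_fasta)) {
    say("stage digestion: %s", config$clones_fasta)
    digestion <- .stage("digestion", out, {
      digest_clones(read_clones(config$clones_fasta), bins = pre$series$bins,
                    enzyme_site = config$enzyme_site,
                    tolerance_bp = config$digest_tolerance_bp)
    })
    utils::write.table(digestion, file.path(out, "digestion.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  outputs <- sort(setdiff(list.files(out), "manifest.json"))
  manifest <- list(
    package = "trflpdyn",
    version = as.character(utils::packageVersion("trflpdyn")),
    config = .config_for_manifest(config),
    seeds = list(scenario = if (!is.null(config$scenario)) config$scenario$seed,
                 cca = config$cca_seed, mantel = config$mantel_seed),
    outputs = as.list(stats::setNames(
      unname(tools::md5sum(file.path(out, outputs))), outputs))
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(list(manifest = manifest, series = pre$series, env = pre$env,
                 removed_mass = pre$removed_mass, change = change,
                 cca = ord$fit, forward = ord$fwd, mantel = mt,
                 digestion = digestion))
}

# configuration as plain JSON-serializable values (scenario flattened)
.config_for_manifest <- function(config) {
  cfg <- unclass(config)
  if (!is.null(cfg$scenario)) cfg$scenario <- unclass(cfg$scenario)
  cfg
}
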