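#' Pipeline configuration
#'
#' Builds a fully materialized configuration for the pipeline commands:
#' every default is resolved into the returned object, so the run
#' manifest records the complete set of seeds and thresholds actually
#' used. Values are taken, in increasing precedence, from the package
#' defaults, a JSON config file, and `...` overrides.
#'
#' @param path optional path to a JSON configuration file.
#' @param ... named overrides of individual fields.
#' @return An object of class `pipeline_config` (a named list). Fields:
#'   `input_dir` (cohort directory of adjacency CSVs + metadata.csv),
#'   `out_dir`, `seed`, `alpha`, `spins`, `gamma`, `module_method`,
#'   `n_perm`, `n_pcs`, `subsample`, `schemes`, `h_formula`,
#'   `clustering_isolates`, `impute_assortativity`, and `simulate`
#'   (parameters forwarded to [make_cohort()]).
#' @export
pipeline_config <- function(path = NULL, ...) {
  config <- list(
    input_dir = NULL,
    out_dir = "skullnet_results",
    seed = 42L,
    alpha = 0.05,
    spins = 25L,
    gamma = 1,
    module_method = "anchored",
    n_perm = 10000L,
    n_pcs = NULL,
    subsample = "all",
    schemes = "group",
    h_formula = "cv",
    clustering_isolates = "zero",
    impute_assortativity = TRUE,
    simulate = list(n_half = 19L, n_midline = 6L, p_extra = 0.25,
                    reach = 3L, bias = 4, mirror_prob = 0.9))
  if (!is.null(path)) {
    user <- jsonlite::read_json(path, simplifyVector = TRUE)
    config[names(user)] <- user
  }
  dots <- list(...)
  config[names(dots)] <- dots
  structure(config, class = "pipeline_config")
}

# Writes config.json + manifest.json (package version, R version, config
# hash) into out_dir. No timestamps: reruns are byte-comparable.
write_manifest <- function(config, out_dir, extra = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null")
  manifest <- c(list(
    package = "skullnet",
    package_version = as.character(utils::packageVersion("skullnet")),
    r_version = R.version.string,
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed), extra)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cfg_path)
}

load_input_cohort <- function(config) {
  if (is.null(config$input_dir))
    abort_skullnet("config$input_dir is required for this command",
                   "skullnet_bad_input")
  cohort <- read_cohort(config$input_dir)
  missing <- setdiff(names(cohort$networks), cohort$metadata$specimen_id)
  if (length(missing))
    abort_skullnet(sprintf("specimen(s) missing from metadata: %s",
                           paste(missing, collapse = ", ")),
                   "skullnet_metadata")
  cohort
}

detect_cohort_modules <- function(cohort, config) {
  nets <- cohort$networks
  lapply(seq_along(nets), function(i)
    detect_modules(nets[[i]], seed = config$seed + i,
                   alpha = config$alpha, spins = config$spins,
                   gamma = config$gamma, method = config$module_method))
}

#' Pipeline commands
#'
#' Thin orchestration over the package functions, mirroring the analysis
#' workflow: networks -> topological variables -> morphospace
#' (PCA + PERMANOVA) -> modules. Every command writes CSV outputs plus a
#' machine-readable run manifest (`config.json`, `manifest.json`) into
#' `config$out_dir`; given the same configuration the result CSVs are
#' byte-identical across reruns.
#'
#' * `cmd_simulate()` generates a synthetic cohort and writes it as a
#'   directory of adjacency CSVs plus `metadata.csv`.
#' * `cmd_metrics()` computes per-specimen topology profiles
#'   (`profiles.csv`).
#' * `cmd_modules()` writes the disjoint partition (`modules.csv`), the
#'   long-format overlap table (`modules_overlap.csv`) and per-specimen
#'   GraphML exports under `graphml/`.
#' * `cmd_morphospace()` writes PCA outputs (`pca_variance.csv`,
#'   `pca_scores.csv`, `pca_loadings.csv`) and the PERMANOVA table
#'   (`permanova.csv`).
#' * `cmd_run_all()` chains all of the above, detecting modules once.
#'
#' @param config a [pipeline_config()].
#' @return The main result of each command, invisibly (`cmd_run_all()`:
#'   list with profiles, module tables, morphospace and PERMANOVA table).
#' @name pipeline-commands
NULL

#' @rdname pipeline-commands
#' @export
cmd_simulate <- function(config) {
  sim <- config$simulate
  cohort <- make_cohort(
    groups = if (is.null(sim$groups)) default_cohort_groups() else sim$groups,
    n_half = sim$n_half, n_midline = sim$n_midline,
    p_extra = sim$p_extra, reach = sim$reach, bias = sim$bias,
    mirror_prob = sim$mirror_prob, seed = config$seed)
  out <- file.path(config$out_dir, "cohort")
  write_cohort(cohort, out, spec = c(sim, list(seed = config$seed)))
  write_manifest(config, config$out_dir,
                 extra = list(n_specimens = length(cohort$networks)))
  invisible(cohort)
}

#' @rdname pipeline-commands
#' @export
cmd_metrics <- function(config) {
  cohort <- load_input_cohort(config)
  mods <- detect_cohort_modules(cohort, config)
  profiles <- profiles_table(
    cohort$networks, module_sets = mods, seed = config$seed,
    impute_assortativity = config$impute_assortativity,
    clustering_isolates = config$clustering_isolates,
    h_formula = config$h_formula)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(profiles, file.path(config$out_dir, "profiles.csv"),
                   row.names = FALSE)
  write_manifest(config, config$out_dir)
  invisible(profiles)
}

#' @rdname pipeline-commands
#' @export
cmd_modules <- function(config) {
  cohort <- load_input_cohort(config)
  mods <- detect_cohort_modules(cohort, config)
  tabs <- module_tables(mods)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(tabs$partition, file.path(config$out_dir, "modules.csv"),
                   row.names = FALSE)
  utils::write.csv(tabs$overlap,
                   file.path(config$out_dir, "modules_overlap.csv"),
                   row.names = FALSE)
  gml_dir <- file.path(config$out_dir, "graphml")
  dir.create(gml_dir, showWarnings = FALSE)
  for (i in seq_along(cohort$networks)) {
    sid <- names(cohort$networks)[i]
    write_graphml(cohort$networks[[i]],
                  file.path(gml_dir, paste0(sid, ".graphml")),
                  partition = mods[[i]]$partition)
  }
  write_manifest(config, config$out_dir)
  invisible(mods)
}

#' @rdname pipeline-commands
#' @export
cmd_morphospace <- function(config) {
  cohort <- load_input_cohort(config)
  profiles_path <- file.path(config$out_dir, "profiles.csv")
  profiles <- if (file.exists(profiles_path))
    utils::read.csv(profiles_path, stringsAsFactors = FALSE)
  else cmd_metrics(config)
  morphospace_outputs(profiles, cohort$metadata, config)
}

morphospace_outputs <- function(profiles, metadata, config) {
  ms <- pca_profiles(profiles)
  res <- run_grouping_suite(profiles, metadata,
                            schemes = config$schemes,
                            subsamples = config$subsample,
                            n_perm = config$n_perm, seed = config$seed,
                            n_pcs = config$n_pcs)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(pc = seq_along(ms$variance_fraction),
                              variance_fraction = ms$variance_fraction),
                   file.path(out, "pca_variance.csv"), row.names = FALSE)
  utils::write.csv(data.frame(specimen_id = rownames(ms$scores),
                              ms$scores, check.names = FALSE),
                   file.path(out, "pca_scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(variable = rownames(ms$loadings),
                              ms$loadings, check.names = FALSE),
                   file.path(out, "pca_loadings.csv"), row.names = FALSE)
  utils::write.csv(res, file.path(out, "permanova.csv"), row.names = FALSE)
  write_manifest(config, out)
  invisible(list(morphospace = ms, permanova = res))
}

#' @rdname pipeline-commands
#' @export
cmd_run_all <- function(config) {
  cohort <- if (is.null(config$input_dir)) {
    ch <- cmd_simulate(config)
    config$input_dir <- file.path(config$out_dir, "cohort")
    ch
  } else load_input_cohort(config)
  mods <- detect_cohort_modules(cohort, config)
  profiles <- profiles_table(
    cohort$networks, module_sets = mods, seed = config$seed,
    impute_assortativity = config$impute_assortativity,
    clustering_isolates = config$clustering_isolates,
    h_formula = config$h_formula)
  tabs <- module_tables(mods)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(profiles, file.path(out, "profiles.csv"),
                   row.names = FALSE)
  utils::write.csv(tabs$partition, file.path(out, "modules.csv"),
                   row.names = FALSE)
  utils::write.csv(tabs$overlap, file.path(out, "modules_overlap.csv"),
                   row.names = FALSE)
  ms <- morphospace_outputs(profiles, cohort$metadata, config)
  invisible(list(profiles = profiles, modules = tabs,
                 morphospace = ms$morphospace, permanova = ms$permanova))
}
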