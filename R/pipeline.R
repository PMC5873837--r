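# End-to-end orchestration: scenes -> metrics -> simulated events ->
# filtered analysis table -> selected model -> report bundle.

#' Default study configuration
#'
#' @param n_scenes number of synthetic photographs.
#' @param image_size scene side in pixels.
#' @param cap_px granularity schedule cap (256 for the adult game, 128 for
#'   the egg game; smaller caps suit smaller synthetic targets).
#' @param n_sessions number of simulated sessions.
#' @param seed master seed.
#' @param scope `"near"`, `"whole"` or `"auto"` (pick by BIC on the maximal
#'   model).
#' @param behavior a [behavior_model()].
#' @param polynomial_slide include the quadratic slide term in the maximal
#'   model.
#' @return named list, class `study_config`.
#' @export
study_config <- function(n_scenes = 24, image_size = 192, cap_px = 64,
                         n_sessions = 200, seed = 1L,
                         scope = c("auto", "near", "whole"),
                         behavior = behavior_model(),
                         polynomial_slide = FALSE) {
  scope <- match.arg(scope)
  structure(list(n_scenes = n_scenes, image_size = image_size,
                 cap_px = cap_px, n_sessions = n_sessions,
                 seed = as.integer(seed), scope = scope,
                 behavior = behavior, polynomial_slide = polynomial_slide),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Top-level keys mirror [study_config()] arguments; a `behavior` mapping
#' overrides [behavior_model()] defaults.
#'
#' @param path .yaml config file.
#' @return a `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  beh <- do.call(behavior_model, as.list(y$behavior))
  args <- y[setdiff(names(y), "behavior")]
  args$behavior <- beh
  do.call(study_config, args)
}

log_stage <- function(verbose, stage, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full pipeline
#'
#' Generates the synthetic photo pool, measures camouflage metrics,
#' simulates the study, applies the exclusion rules, derives the analysis
#' table (choosing the background scope by BIC when `scope = "auto"`),
#' simplifies the maximal mixed model, and writes every stage's output under
#' `out_dir` together with a run manifest (JSON) holding the seed, a config
#' hash and per-file MD5 checksums. The same config and seed reproduce an
#' identical bundle.
#'
#' @param config a `study_config`.
#' @param out_dir output directory.
#' @param verbose log stage progress to stderr.
#' @return invisible list with the analysis table, scope decision,
#'   simplification result and report.
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  stopifnot(inherits(config, "study_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  log_stage(verbose, "scenes", "generating %d scenes of %d px",
            config$n_scenes, config$image_size)
  pool <- scene_pool(config$n_scenes, config$image_size, config$cap_px,
                     seed = config$seed)
  metrics_path <- file.path(out_dir, "metrics.csv")
  utils::write.csv(pool$metrics, metrics_path, row.names = FALSE)

  log_stage(verbose, "simulate", "simulating %d sessions", config$n_sessions)
  photos <- photo_covariates(pool$metrics, scope = "near",
                             image_width = config$image_size,
                             image_height = config$image_size)
  events <- simulate_study(config$n_sessions, photos, config$behavior,
                           seed = config$seed)
  events_path <- file.path(out_dir, "events.csv")
  utils::write.csv(events, events_path, row.names = FALSE)

  log_stage(verbose, "filter", "filtering %d events", nrow(events))
  filt <- filter_events(events)
  excl_path <- file.path(out_dir, "exclusions.json")
  write_exclusion_report(filt$report, excl_path)

  maximal <- maximal_spec(polynomial_slide = config$polynomial_slide)
  scope <- config$scope
  scope_info <- NULL
  if (scope == "auto") {
    log_stage(verbose, "scope", "choosing background scope by BIC")
    scope_info <- choose_background_scope(filt$retained, pool$metrics,
                                          maximal)
    scope <- scope_info$scope
  }
  log_stage(verbose, "table", "deriving covariates (scope: %s)", scope)
  table <- derive_covariates(filt$retained, pool$metrics, scope = scope)
  table_path <- file.path(out_dir, "analysis_table.csv")
  utils::write.csv(table, table_path, row.names = FALSE)

  log_stage(verbose, "model", "BIC simplification of the maximal model")
  sel <- simplify_model(table, maximal)
  report <- model_report(sel$fit, sel$trace)
  report_dir <- file.path(out_dir, "report")
  write_report(report, report_dir)

  cfg_json <- jsonlite::toJSON(config_digestable(config), auto_unbox = TRUE,
                               digits = NA)
  tmp <- tempfile(fileext = ".json")
  writeLines(cfg_json, tmp)
  outputs <- c(metrics_path, events_path, excl_path, table_path,
               list.files(report_dir, full.names = TRUE))
  manifest <- list(
    seed = config$seed,
    config_hash = unname(tools::md5sum(tmp)),
    scope = scope,
    scope_bic = scope_info[c("bic_near", "bic_whole")],
    final_terms = sel$spec$fixed,
    random_terms = sel$spec$random,
    checksums = as.list(tools::md5sum(outputs))
  )
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(table = table, scope = scope, scope_info = scope_info,
                 selection = sel, report = report, metrics = pool$metrics,
                 exclusions = filt$report))
}

config_digestable <- function(config) {
  c(config[setdiff(names(config), "behavior")],
    list(behavior = unclass(config$behavior)))
}
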