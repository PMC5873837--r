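# Parsing and cleaning of game-event tables: exclusion rules, covariate
# derivation, join with photograph metrics, and the near-vs-whole background
# scope decision.

event_required_cols <- c("session_id", "viewing", "age_class",
                         "played_before", "slide_number", "photo_id",
                         "outcome", "capture_time_s", "n_incorrect_clicks",
                         "edge_distance_px")

#' Apply the slide exclusion rules
#'
#' Two rules clean the raw event table: slides on which the participant made
#' more than 2 incorrect clicks are dropped (guarding against "scatter-gun"
#' clicking, which can yield fast captures without the target having been
#' identified), and timeout slides are dropped because a timeout cannot be
#' distinguished from the participant being distracted. A slide with exactly
#' 2 incorrect clicks and a capture is retained. Malformed rows (missing
#' fields, capture times outside (0, 30], negative click counts) are
#' collected in the report rather than silently dropped.
#'
#' @param events event data frame (schema of [simulate_study()]).
#' @return list with `retained` (data frame) and `report`: counts
#'   `n_input`, `n_retained`, `n_excluded_incorrect_clicks`,
#'   `n_excluded_timeout`, `n_malformed`, plus `malformed_rows` (indices
#'   into the input).
#' @export
filter_events <- function(events) {
  missing_cols <- setdiff(event_required_cols, names(events))
  if (length(missing_cols))
    stop("event table lacks columns: ", paste(missing_cols, collapse = ", "))
  n <- nrow(events)
  is_capture <- !is.na(events$outcome) & events$outcome == "capture"
  is_timeout <- !is.na(events$outcome) & events$outcome == "timeout"
  malformed <- !(is_capture | is_timeout) |
    is.na(events$n_incorrect_clicks) | events$n_incorrect_clicks < 0 |
    is.na(events$session_id) | is.na(events$photo_id) |
    is.na(events$slide_number) |
    is.na(events$edge_distance_px) | events$edge_distance_px <= 0 |
    (is_capture & (is.na(events$capture_time_s) |
                     events$capture_time_s <= 0 |
                     events$capture_time_s > 30))
  scatter <- !malformed & events$n_incorrect_clicks > 2
  timeout <- !malformed & !scatter & is_timeout
  keep <- !malformed & !scatter & !timeout
  list(
    retained = events[keep, , drop = FALSE],
    report = list(
      n_input = n,
      n_retained = sum(keep),
      n_excluded_incorrect_clicks = sum(scatter),
      n_excluded_timeout = sum(timeout),
      n_malformed = sum(malformed),
      malformed_rows = which(malformed)
    )
  )
}

age_levels <- c("<10", "10-15", "16-35", "36-50", ">50")

#' Derive the analysis table from filtered events and photograph metrics
#'
#' Joins retained capture events with the per-photograph camouflage metrics
#' (by `photo_id`, either the near-annulus or whole-background comparison)
#' and applies the model's transforms: natural-log capture time, natural-log
#' edge distance, natural-log pattern difference. The first slide is flagged
#' as categorically different (trial naivety) separately from the
#' participant-level played-before flag. Viewing condition and age class
#' become factors with trichromat and the youngest bracket as reference
#' levels.
#'
#' Pattern differences that are not strictly positive have no logarithm; the
#' pipeline stops with an error rather than imputing an offset.
#'
#' @param retained retained events from [filter_events()].
#' @param metrics data frame from [metrics_table()].
#' @param scope `"near"` or `"whole"` background comparison.
#' @return analysis data frame with columns `log_capture_time,
#'   log_edge_dist, slide_number, first_slide, played_before,
#'   viewing_condition, age_class, log_pattern_diff, lum_dist_diff,
#'   target_area, bg_lum_mean, bg_contrast, target_lum_mean,
#'   target_contrast, session_id, photo_id`.
#' @export
derive_covariates <- function(retained, metrics, scope = c("near", "whole")) {
  scope <- match.arg(scope)
  if (any(retained$outcome != "capture"))
    stop("derive_covariates expects only capture outcomes; run filter_events first")
  miss <- setdiff(unique(retained$photo_id), metrics$photo_id)
  if (length(miss))
    stop("no metrics for photo_id(s): ", paste(miss, collapse = ", "))
  i <- match(retained$photo_id, metrics$photo_id)
  pd <- metrics[[paste0("pattern_diff_", scope)]][i]
  if (any(pd <= 0))
    stop("pattern difference <= 0: log undefined for photo_id(s) ",
         paste(unique(retained$photo_id[pd <= 0]), collapse = ", "))
  data.frame(
    log_capture_time = log(retained$capture_time_s),
    log_edge_dist = log(retained$edge_distance_px),
    slide_number = retained$slide_number,
    first_slide = retained$slide_number == 1,
    played_before = retained$played_before,
    viewing_condition = factor(retained$viewing,
                               levels = c("trichromat", "dichromat")),
    age_class = factor(retained$age_class, levels = age_levels),
    log_pattern_diff = log(pd),
    lum_dist_diff = metrics[[paste0("lum_dist_diff_", scope)]][i],
    target_area = metrics$target_area[i],
    bg_lum_mean = metrics[[paste0("mean_lum_", scope)]][i],
    bg_contrast = metrics[[paste0("contrast_", scope)]][i],
    target_lum_mean = metrics$mean_lum_target[i],
    target_contrast = metrics$contrast_target[i],
    session_id = retained$session_id,
    photo_id = retained$photo_id,
    stringsAsFactors = FALSE
  )
}

#' Choose between near-annulus and whole-background covariates
#'
#' Fits the same maximal mixed model on the analysis table built with the
#' 500 px surround ("near") comparison and with the whole-image comparison,
#' and returns the scope whose maximal fit has the lower BIC. Exact ties
#' (BIC difference below 1e-6) resolve to "near". The fits are
#' order-invariant, so the decision is too.
#'
#' @param retained retained events from [filter_events()].
#' @param metrics photograph metrics table.
#' @param maximal a [model_spec()] for the maximal model.
#' @return list with `scope` ("near" or "whole"), `bic_near`, `bic_whole`.
#' @export
choose_background_scope <- function(retained, metrics, maximal) {
  fits <- lapply(c("near", "whole"), function(sc) {
    tab <- derive_covariates(retained, metrics, scope = sc)
    tryCatch(fit_lmm(tab, maximal),
             error = function(e) stop("maximal fit failed for scope '", sc,
                                      "': ", conditionMessage(e)))
  })
  bn <- fits[[1]]$bic; bw <- fits[[2]]$bic
  scope <- if (bw < bn - 1e-6) "whole" else "near"
  list(scope = scope, bic_near = bn, bic_whole = bw)
}

#' Write an exclusion report as JSON
#'
#' @param report the `report` element of [filter_events()].
#' @param path output .json path.
#' @export
write_exclusion_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
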