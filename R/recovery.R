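# Parameter-recovery harness: does the BIC selection procedure keep the
# interactions that generated the data and shed the ones that did not, and
# are the coefficient estimates calibrated?

#' Generative model for the interaction-recovery study
#'
#' A behaviour model in which exactly one viewing-condition interaction is
#' active: dichromats are slower overall and extra-sensitive to pattern
#' difference (`b_viewing_pattern`), while every other camouflage covariate
#' and interaction is zero, so target contrast serves as the null
#' interaction the selection procedure should drop. The active interaction
#' is set well above its sampling error at the default study size, as in the
#' source experiments where the retained interactions were estimated from
#' very large samples.
#'
#' @param b_viewing_pattern the single active interaction coefficient.
#' @return a [behavior_model()].
#' @export
recovery_behavior <- function(b_viewing_pattern = 0.3) {
  behavior_model(intercept = log(5), b_viewing = 0.15, b_pattern = 0.2,
                 b_lumdiff = 0, b_area = 0, b_bglum = 0,
                 b_slide = -0.03, b_first = 0, b_edge = 0,
                 b_viewing_pattern = b_viewing_pattern,
                 b_viewing_lumdiff = 0, b_viewing_area = 0,
                 b_viewing_bglum = 0, b_viewing_slide = 0)
}

#' Interaction recovery across replicate studies
#'
#' Simulates replicate studies from [recovery_behavior()] on a shared photo
#' pool, runs the exclusion rules and the full BIC simplification on each,
#' and records whether the true viewing x pattern-difference interaction was
#' retained, whether the null viewing x target-contrast interaction was
#' dropped, and whether the estimate of the true coefficient lies within 3
#' standard errors of the generating value.
#'
#' @param n_replicates number of replicate studies.
#' @param n_sessions sessions per study (20 slides each).
#' @param metrics photo metrics table (e.g. from [scene_pool()]).
#' @param seed master seed; replicate r uses `seed + 1000 * r`.
#' @param b_viewing_pattern generating value of the active interaction.
#' @return data frame with one row per replicate: `retained_true`,
#'   `dropped_null`, `estimate`, `se`, `within_3se`, `n_rows`.
#' @export
recovery_study <- function(n_replicates = 24, n_sessions = 250, metrics,
                           seed = 1L, b_viewing_pattern = 0.3) {
  beh <- recovery_behavior(b_viewing_pattern)
  photos <- photo_covariates(metrics, scope = "near")
  maximal <- model_spec(
    c("slide_number", "viewing_condition", "log_pattern_diff",
      "target_contrast", "viewing_condition:log_pattern_diff",
      "viewing_condition:target_contrast"),
    c("session_id", "photo_id"))
  true_term <- "viewing_condition:log_pattern_diff"
  null_term <- "viewing_condition:target_contrast"
  rows <- lapply(seq_len(n_replicates), function(r) {
    ev <- simulate_study(n_sessions, photos, beh,
                         seed = (seed + 1000 * r) %% .Machine$integer.max)
    tab <- derive_covariates(filter_events(ev)$retained, metrics, "near")
    sel <- simplify_model(tab, maximal)
    retained <- true_term %in% sel$spec$fixed
    est <- se <- NA_real_
    if (retained) {
      co <- sel$fit$coefficients
      i <- grep("dichromat:log_pattern_diff|log_pattern_diff:.*dichromat",
                co$term)
      est <- co$estimate[i]; se <- co$se[i]
    }
    data.frame(replicate = r, retained_true = retained,
               dropped_null = !(null_term %in% sel$spec$fixed),
               estimate = est, se = se,
               within_3se = retained &&
                 abs(est - b_viewing_pattern) <= 3 * se,
               n_rows = nrow(tab))
  })
  do.call(rbind, rows)
}

#' Qualitative sign recovery of the four viewing-condition interactions
#'
#' Simulates replicate studies from the default [behavior_model()], whose
#' interaction signs follow the pattern observed in the adult-target
#' experiment (positive viewing x pattern difference, positive viewing x
#' luminance-distribution difference, negative viewing x target area,
#' negative viewing x background luminance), fits the model containing all
#' four interactions, and reports whether each fitted sign matches its
#' generating sign.
#'
#' @param n_replicates number of replicate studies.
#' @param n_sessions sessions per study.
#' @param metrics photo metrics table.
#' @param seed master seed.
#' @return data frame with one row per replicate and one logical column per
#'   interaction (`pattern`, `lumdiff`, `area`, `bglum`), TRUE when the
#'   fitted sign matches the generating sign.
#' @export
sign_recovery_study <- function(n_replicates = 20, n_sessions = 250,
                                metrics, seed = 1L) {
  beh <- behavior_model()
  truth <- c(pattern = sign(beh$b_viewing_pattern),
             lumdiff = sign(beh$b_viewing_lumdiff),
             area = sign(beh$b_viewing_area),
             bglum = sign(beh$b_viewing_bglum))
  photos <- photo_covariates(metrics, scope = "near")
  spec <- model_spec(
    c("slide_number", "first_slide", "log_edge_dist", "viewing_condition",
      "log_pattern_diff", "lum_dist_diff", "target_area", "bg_lum_mean",
      "viewing_condition:log_pattern_diff",
      "viewing_condition:lum_dist_diff",
      "viewing_condition:target_area",
      "viewing_condition:bg_lum_mean"),
    c("session_id", "photo_id"))
  coef_of <- function(co, cov) {
    i <- grep(paste0("dichromat:", cov, "$"), co$term)
    co$estimate[i]
  }
  covs <- c(pattern = "log_pattern_diff", lumdiff = "lum_dist_diff",
            area = "target_area", bglum = "bg_lum_mean")
  rows <- lapply(seq_len(n_replicates), function(r) {
    ev <- simulate_study(n_sessions, photos, beh,
                         seed = (seed + 2000 * r) %% .Machine$integer.max)
    tab <- derive_covariates(filter_events(ev)$retained, metrics, "near")
    fit <- fit_lmm(tab, spec)
    match <- vapply(names(covs), function(k)
      sign(coef_of(fit$coefficients, covs[[k]])) == truth[[k]], TRUE)
    cbind(data.frame(replicate = r), as.data.frame(as.list(match)))
  })
  do.call(rbind, rows)
}
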