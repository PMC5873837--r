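# analysis table simulated straight from the generative model, shared
# across the blocks in this file
sim_table <- function(n_sessions, behavior, seed, scope = "near") {
  photos <- synth_photos(seed = seed)
  ev <- simulate_study(n_sessions, photos, behavior, seed = seed)
  metrics <- data.frame(photo_id = photos$photo_id,
                        pattern_diff_near = photos$pattern_diff,
                        pattern_diff_whole = photos$pattern_diff * 1.5,
                        lum_dist_diff_near = photos$lum_dist_diff,
                        lum_dist_diff_whole = photos$lum_dist_diff,
                        contrast_target = 0.2 + photos$lum_dist_diff / 4,
                        contrast_near = 0.25, contrast_whole = 0.25,
                        mean_lum_target = photos$bg_lum_mean,
                        mean_lum_near = photos$bg_lum_mean,
                        mean_lum_whole = photos$bg_lum_mean,
                        target_area = photos$target_area,
                        stringsAsFactors = FALSE)
  derive_covariates(filter_events(ev)$retained, metrics, scope)
}

test_that("model specs enforce marginality and the polynomial slide term", {
  expect_error(model_spec(c("viewing_condition:log_pattern_diff"),
                          "session_id"),
               "without both parents")
  sp <- model_spec(c("slide_number", "viewing_condition"), "session_id",
                   polynomial_slide = TRUE)
  expect_true("I(slide_number^2)" %in% sp$fixed)
  expect_error(model_spec("viewing_condition", "session_id",
                          polynomial_slide = TRUE),
               "requires slide_number")
})

test_that("BIC is recomputed exactly from logLik, parameter count and rows", {
  tab <- sim_table(30, behavior_model(), seed = 2)
  fit <- fit_lmm(tab, model_spec(c("viewing_condition", "slide_number"),
                                 c("session_id", "photo_id")))
  expect_true(fit$converged)
  expect_equal(fit$bic, -2 * fit$logLik + fit$npar * log(fit$n_obs))
  # lm path agrees with the same identity
  f0 <- fit_lmm(tab, model_spec("slide_number", character(0)))
  expect_equal(f0$bic, -2 * f0$logLik + f0$npar * log(f0$n_obs))
})

test_that("degenerate and ill-posed designs are handled explicitly", {
  tab <- sim_table(10, behavior_model(), seed = 3)
  # constant response, intercept-only, one random term: analytic fit
  tab$log_capture_time <- 1.25
  fit <- fit_lmm(tab, model_spec(character(0), "session_id"))
  expect_true(fit$converged)
  expect_equal(fit$coefficients$estimate, 1.25)
  expect_equal(fit$sigma, 0)

  tab2 <- sim_table(10, behavior_model(), seed = 3)
  tab2$dup <- tab2$slide_number
  expect_error(fit_lmm(tab2, model_spec(c("slide_number", "dup"),
                                        "session_id")),
               "rank-deficient.*dup")
  expect_error(fit_lmm(tab2, model_spec("slide_number", "nope")),
               "lacks columns")
  tab2$one_level <- "a"
  expect_error(fit_lmm(tab2, model_spec("slide_number", "one_level")),
               "fewer than 2 levels")
})

test_that("fixed-effect estimates recover the generating coefficients", {
  beh <- behavior_model(b_viewing = 0.2, sd_resid = 0.3,
                        b_viewing_pattern = 0, b_viewing_lumdiff = 0,
                        b_viewing_area = 0, b_viewing_bglum = 0,
                        b_first = 0, b_edge = 0)
  tab <- sim_table(250, beh, seed = 4)
  fit <- fit_lmm(tab, model_spec(
    c("viewing_condition", "log_pattern_diff", "lum_dist_diff",
      "target_area", "bg_lum_mean", "slide_number"),
    c("session_id", "photo_id")))
  co <- fit$coefficients
  est <- function(term) co[co$term == term, ]
  v <- est("viewing_conditiondichromat")
  expect_lt(abs(v$estimate - 0.2), 3 * v$se)
  p <- est("log_pattern_diff")
  expect_lt(abs(p$estimate - beh$b_pattern), 3 * p$se)
  s <- est("slide_number")
  expect_lt(abs(s$estimate - beh$b_slide), 3 * s$se)
})

test_that("consistency: coefficient RMSE shrinks as the study grows", {
  beh <- behavior_model(b_viewing = 0.2, b_first = 0, b_edge = 0,
                        b_viewing_pattern = 0, b_viewing_lumdiff = 0,
                        b_viewing_area = 0, b_viewing_bglum = 0)
  err <- vapply(c(25, 400), function(ns) {
    mean(vapply(31:33, function(seed) {
      tab <- sim_table(ns, beh, seed = seed)
      fit <- fit_lmm(tab, model_spec(c("viewing_condition", "slide_number"),
                                     c("session_id", "photo_id")))
      co <- fit$coefficients
      abs(co$estimate[co$term == "viewing_conditiondichromat"] - 0.2)
    }, numeric(1)))
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("BIC simplification keeps signal, sheds noise, and logs a replayable trace", {
  beh <- behavior_model(b_lumdiff = 0, b_area = 0, b_bglum = 0,
                        b_first = 0, b_edge = 0, b_viewing_pattern = 0.3,
                        b_viewing_lumdiff = 0, b_viewing_area = 0,
                        b_viewing_bglum = 0)
  tab <- sim_table(200, beh, seed = 13)
  maximal <- model_spec(
    c("slide_number", "viewing_condition", "log_pattern_diff",
      "target_contrast", "viewing_condition:log_pattern_diff",
      "viewing_condition:target_contrast"),
    c("session_id", "photo_id"))
  sel <- simplify_model(tab, maximal)
  max_fit <- fit_lmm(tab, maximal)

  expect_lte(sel$fit$bic, max_fit$bic)
  expect_true("viewing_condition:log_pattern_diff" %in% sel$spec$fixed)
  # marginality: parents of every retained interaction are retained
  for (t in sel$spec$fixed[grepl(":", sel$spec$fixed)])
    expect_true(all(strsplit(t, ":")[[1]] %in% sel$spec$fixed))
  # accepted steps never increase BIC
  acc <- sel$trace[sel$trace$accepted, ]
  expect_true(all(acc$bic_after <= acc$bic_before + 1e-6))
  # the session term is mandatory; with simulated session and photo
  # variance both > 0 the forward phase keeps both intercepts
  expect_equal(sel$spec$random[1], "session_id")
  expect_true("photo_id" %in% sel$spec$random)

  # selection is invariant to row permutation
  perm <- withr::with_seed(2, sample(nrow(tab)))
  sel2 <- simplify_model(tab[perm, ], maximal)
  expect_setequal(sel2$spec$fixed, sel$spec$fixed)
  expect_setequal(sel2$spec$random, sel$spec$random)
  expect_equal(sel2$fit$bic, sel$fit$bic, tolerance = 1e-6)
})

test_that("null data simplify toward the nuisance-only model", {
  beh <- null_behavior(b_slide = -0.03, sd_resid = 0.4, sd_session = 0.2)
  tab <- sim_table(150, beh, seed = 29)
  maximal <- model_spec(
    c("slide_number", "viewing_condition", "log_pattern_diff",
      "lum_dist_diff", "viewing_condition:log_pattern_diff",
      "viewing_condition:lum_dist_diff"),
    c("session_id", "photo_id"))
  sel <- simplify_model(tab, maximal)
  expect_true("slide_number" %in% sel$spec$fixed)
  expect_false(any(grepl(":", sel$spec$fixed)))
  expect_lte(length(sel$spec$fixed), 3)
})

test_that("reports order parents above interactions and regenerate identically", {
  tab <- sim_table(60, behavior_model(), seed = 8)
  spec <- model_spec(c("viewing_condition", "log_pattern_diff",
                       "slide_number", "viewing_condition:log_pattern_diff"),
                     c("session_id", "photo_id"))
  fit <- fit_lmm(tab, spec)
  rep1 <- model_report(fit)
  expect_equal(nrow(rep1$terms), 4)
  ipos <- which(rep1$terms$term == "viewing_condition:log_pattern_diff")
  expect_true(all(which(rep1$terms$term %in%
                          c("viewing_condition", "log_pattern_diff")) < ipos))
  expect_identical(capture.output(print(rep1)),
                   capture.output(print(model_report(fit))))

  d <- withr::local_tempdir()
  write_report(model_report(fit), d)
  expect_setequal(list.files(d),
                  c("terms.csv", "coefficients.csv", "summary.txt"))
})
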