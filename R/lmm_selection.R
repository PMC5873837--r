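# Linear mixed models of log capture time and BIC-based simplification:
# backward elimination of fixed effects under maximum likelihood, forward
# selection of random intercepts under REML, then re-backward elimination of
# the fixed effects with the chosen random structure.

#' Specify a capture-time mixed model
#'
#' Fixed terms are column names of the analysis table; interactions are
#' written `"a:b"`. With `polynomial_slide = TRUE`, a quadratic slide term
#' `I(slide_number^2)` is added so learning curves may tail off. The design
#' matrix uses treatment coding with trichromat and the youngest age bracket
#' as reference levels (set by [derive_covariates()]'s factor levels).
#'
#' @param fixed character vector of fixed-effect terms.
#' @param random character vector of random-intercept grouping factors
#'   (subset of session/photo/season identifiers).
#' @param response response column name (default `"log_capture_time"`).
#' @param polynomial_slide add a quadratic slide-number term.
#' @param estimation `"ML"` or `"REML"`.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(fixed, random, response = "log_capture_time",
                       polynomial_slide = FALSE,
                       estimation = c("ML", "REML")) {
  estimation <- match.arg(estimation)
  fixed <- unique(as.character(fixed))
  if (polynomial_slide && !"I(slide_number^2)" %in% fixed) {
    if (!"slide_number" %in% fixed)
      stop("polynomial_slide requires slide_number among the fixed terms")
    fixed <- c(fixed, "I(slide_number^2)")
  }
  bad <- violates_marginality(fixed)
  if (length(bad))
    stop("interaction term(s) without both parents present: ",
         paste(bad, collapse = ", "))
  structure(list(response = response, fixed = fixed,
                 random = unique(as.character(random)),
                 polynomial_slide = polynomial_slide,
                 estimation = estimation),
            class = "model_spec")
}

# components a term depends on: "a:b" -> a, b; "I(x^2)" -> x
term_components <- function(term) {
  if (grepl("^I\\(", term))
    return(sub("\\^.*$", "", sub("^I\\(", "", term)))
  strsplit(term, ":", fixed = TRUE)[[1]]
}

term_order <- function(term) length(term_components(term)) +
  as.integer(grepl("^I\\(", term))

violates_marginality <- function(fixed) {
  higher <- fixed[vapply(fixed, term_order, 1L) > 1]
  higher[!vapply(higher, function(t)
    all(term_components(t) %in% fixed), TRUE)]
}

# terms whose removal keeps the spec marginal: nothing retained may depend
# on them
droppable_terms <- function(fixed) {
  Filter(function(t) {
    others <- setdiff(fixed, t)
    deps <- unlist(lapply(others[vapply(others, term_order, 1L) > 1],
                          term_components))
    !(t %in% deps)
  }, fixed)
}

fixed_formula <- function(spec) {
  rhs <- if (length(spec$fixed)) paste(spec$fixed, collapse = " + ") else "1"
  stats::as.formula(paste(spec$response, "~", rhs))
}

full_formula <- function(spec) {
  rhs <- c(if (length(spec$fixed)) spec$fixed else "1",
           sprintf("(1 | %s)", spec$random))
  stats::as.formula(paste(spec$response, "~", paste(rhs, collapse = " + ")))
}

#' Fit a capture-time mixed model
#'
#' Fits the specified model with `lme4::lmer` (or ordinary least squares
#' when the random set is empty, with the matching ML/REML log-likelihood),
#' and returns the coefficient table, per-term Wald F statistics, the
#' log-likelihood and the BIC computed as `-2 logLik + k log(n)` with `k`
#' the number of estimated parameters and `n` the number of rows.
#'
#' Denominator degrees of freedom for the F statistics use the conservative
#' lower-bound convention: `n` minus the number of fixed-effect parameters
#' minus the number of random-effect grouping factors. Random-effect
#' variances estimated at zero (singular fits) are allowed and simply mean
#' the term is not helping.
#'
#' @param table analysis data frame from [derive_covariates()].
#' @param spec a [model_spec()].
#' @return object of class `camo_fit`: list with `spec`, `model`,
#'   `converged`, `logLik`, `npar`, `n_obs`, `bic`, `sigma`, `coefficients`
#'   (data frame: term, estimate, se, t) and `anova` (data frame: term, df1,
#'   df2, F, p).
#' @export
fit_lmm <- function(table, spec) {
  stopifnot(inherits(spec, "model_spec"))
  needed <- unique(c(spec$response,
                     unlist(lapply(spec$fixed, term_components)),
                     spec$random))
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols))
    stop("analysis table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  for (g in spec$random)
    if (length(unique(table[[g]])) < 2)
      stop("random term '", g, "' has fewer than 2 levels")
  y <- table[[spec$response]]
  n <- nrow(table)

  ffix <- fixed_formula(spec)
  mm <- stats::model.matrix(ffix, table)
  qrm <- qr(mm)
  if (qrm$rank < ncol(mm)) {
    aliased <- colnames(mm)[qrm$pivot[(qrm$rank + 1):ncol(mm)]]
    stop("rank-deficient design; aliased: ", paste(aliased, collapse = ", "))
  }

  # constant response: every variance component is zero, likelihood
  # degenerate; return the analytic fit instead of tripping the solver
  if (pop_sd(y) == 0) {
    coefs <- data.frame(term = "(Intercept)", estimate = y[1], se = 0,
                        t = NA_real_, stringsAsFactors = FALSE)
    return(structure(list(spec = spec, model = NULL, converged = TRUE,
                          degenerate = TRUE, logLik = Inf,
                          npar = ncol(mm) + 1L, n_obs = n, bic = -Inf,
                          sigma = 0, coefficients = coefs,
                          anova = data.frame()),
                     class = "camo_fit"))
  }

  reml <- spec$estimation == "REML"
  if (length(spec$random) == 0) {
    fit <- stats::lm(ffix, data = table)
    ll <- stats::logLik(fit, REML = reml)
    beta <- stats::coef(fit)
    vc <- stats::vcov(fit)
    converged <- TRUE
    sig <- stats::sigma(fit)
    npar <- length(beta) + 1L
    n_groups <- 0L
  } else {
    msgs <- character()
    fit <- withCallingHandlers(
      lme4::lmer(full_formula(spec), data = table, REML = reml,
                 control = lme4::lmerControl(calc.derivs = FALSE,
                                             check.conv.singular = "ignore")),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      },
      message = function(m) {
        msgs <<- c(msgs, conditionMessage(m))
        invokeRestart("muffleMessage")
      })
    converged <- fit@optinfo$conv$opt == 0 &&
      !any(grepl("failed to converge", msgs))
    ll <- stats::logLik(fit)
    beta <- lme4::fixef(fit)
    vc <- as.matrix(stats::vcov(fit))
    sig <- stats::sigma(fit)
    npar <- attr(ll, "df")
    n_groups <- length(spec$random)
  }
  p <- length(beta)
  bic <- -2 * as.numeric(ll) + npar * log(n)
  coefs <- data.frame(term = names(beta), estimate = as.numeric(beta),
                      se = sqrt(diag(vc)),
                      t = as.numeric(beta) / sqrt(diag(vc)),
                      stringsAsFactors = FALSE, row.names = NULL)

  # per-term Wald F with lower-bound denominator df
  asgn <- attr(mm, "assign")
  labels <- attr(stats::terms(ffix), "term.labels")
  df2 <- n - p - n_groups
  an <- do.call(rbind, lapply(seq_along(labels), function(j) {
    idx <- which(asgn == j)
    b <- as.numeric(beta[idx])
    Fv <- tryCatch(
      drop(crossprod(b, solve(vc[idx, idx, drop = FALSE], b))) / length(idx),
      error = function(e) NA_real_)
    data.frame(term = labels[j], df1 = length(idx), df2 = df2, F = Fv,
               p = stats::pf(Fv, length(idx), df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  structure(list(spec = spec, model = fit, converged = converged,
                 degenerate = FALSE, logLik = as.numeric(ll), npar = npar,
                 n_obs = n, bic = bic, sigma = sig,
                 coefficients = coefs, anova = an),
            class = "camo_fit")
}

#' @export
print.camo_fit <- function(x, ...) {
  cat(sprintf("<camo_fit %s | %d obs | logLik %.2f | BIC %.2f%s>\n",
              x$spec$estimation, x$n_obs, x$logLik, x$bic,
              if (x$converged) "" else " | NOT CONVERGED"))
  invisible(x)
}

respec <- function(spec, fixed = spec$fixed, random = spec$random,
                   estimation = spec$estimation) {
  structure(list(response = spec$response, fixed = fixed, random = random,
                 polynomial_slide = spec$polynomial_slide,
                 estimation = estimation),
            class = "model_spec")
}

safe_fit <- function(table, spec) {
  tryCatch(fit_lmm(table, spec), error = function(e) NULL)
}

trace_row <- function(step, phase, action, term, bic_before, bic_after,
                      accepted, note = "") {
  data.frame(step = step, phase = phase, action = action, term = term,
             bic_before = bic_before, bic_after = bic_after,
             accepted = accepted, note = note, stringsAsFactors = FALSE)
}

# one backward-elimination pass over the fixed effects under ML; returns the
# reduced fixed set, the current fit and the trace rows
backfit_fixed <- function(table, spec, phase, trace, step) {
  cur <- respec(spec, estimation = "ML")
  cur_fit <- fit_lmm(table, cur)
  tol <- 1e-6
  repeat {
    cands <- droppable_terms(cur$fixed)
    if (!length(cands)) break
    bics <- rep(NA_real_, length(cands))
    fits <- vector("list", length(cands))
    for (i in seq_along(cands)) {
      red <- respec(cur, fixed = setdiff(cur$fixed, cands[i]))
      f <- safe_fit(table, red)
      fits[[i]] <- f
      # a candidate that fails or does not converge is not an improvement
      if (!is.null(f) && f$converged) bics[i] <- f$bic
      trace <- rbind(trace, trace_row(
        step, phase, "drop-fixed", cands[i], cur_fit$bic,
        if (is.null(f)) NA_real_ else f$bic, FALSE,
        note = if (is.null(f)) "fit failed"
               else if (!f$converged) "not converged" else ""))
      step <- step + 1
    }
    if (all(is.na(bics))) break
    best <- which.min(bics)
    # ties resolve toward the smaller model: accept when not worse
    if (bics[best] <= cur_fit$bic + tol) {
      trace$accepted[nrow(trace) - length(cands) + best] <- TRUE
      cur <- fits[[best]]$spec
      cur_fit <- fits[[best]]
    } else break
  }
  list(spec = cur, fit = cur_fit, trace = trace, step = step)
}

#' Simplify a maximal mixed model by BIC
#'
#' Three-phase procedure. Phase 1: with the full allowed random structure,
#' repeatedly drop the single fixed term whose removal most decreases the
#' BIC of the maximum-likelihood fit, respecting marginality (interactions
#' and the quadratic slide term are removed before the main effects they
#' contain), until no removal decreases BIC. Phase 2: starting from the
#' first allowed random term (the session, the repeated-measures unit that a
#' final fit always retains), forward-select the remaining random intercepts
#' under REML, keeping additions that decrease BIC. Phase 3: repeat the
#' backward fixed-effect pass under ML with the selected random structure.
#' Candidate fits that fail or do not converge count as "not an
#' improvement" and are logged in the trace. BIC ties (difference below
#' 1e-6) resolve toward the smaller model.
#'
#' @param table analysis data frame.
#' @param maximal a [model_spec()] holding the maximal fixed terms and the
#'   full set of allowed random terms.
#' @return list with `spec` (final [model_spec()]), `fit` (final ML
#'   `camo_fit`) and `trace` (data frame: step, phase, action, term,
#'   bic_before, bic_after, accepted, note).
#' @export
simplify_model <- function(table, maximal) {
  stopifnot(inherits(maximal, "model_spec"))
  if (!length(maximal$random))
    stop("the maximal model needs at least one allowed random term")
  trace <- data.frame(step = integer(), phase = character(),
                      action = character(), term = character(),
                      bic_before = numeric(), bic_after = numeric(),
                      accepted = logical(), note = character(),
                      stringsAsFactors = FALSE)
  step <- 1L

  p1 <- backfit_fixed(table, maximal, "backward-fixed", trace, step)
  trace <- p1$trace; step <- p1$step

  # phase 2: forward random under REML, session term mandatory
  base_random <- maximal$random[1]
  cur_random <- base_random
  cur_fit <- fit_lmm(table, respec(p1$spec, random = cur_random,
                                   estimation = "REML"))
  tol <- 1e-6
  repeat {
    cands <- setdiff(maximal$random, cur_random)
    if (!length(cands)) break
    bics <- rep(NA_real_, length(cands))
    fits <- vector("list", length(cands))
    for (i in seq_along(cands)) {
      f <- safe_fit(table, respec(p1$spec, random = c(cur_random, cands[i]),
                                  estimation = "REML"))
      fits[[i]] <- f
      if (!is.null(f) && f$converged) bics[i] <- f$bic
      trace <- rbind(trace, trace_row(
        step, "forward-random", "add-random", cands[i], cur_fit$bic,
        if (is.null(f)) NA_real_ else f$bic, FALSE,
        note = if (is.null(f)) "fit failed"
               else if (!f$converged) "not converged" else ""))
      step <- step + 1
    }
    if (all(is.na(bics))) break
    best <- which.min(bics)
    if (bics[best] < cur_fit$bic - tol) {   # additions must strictly improve
      trace$accepted[nrow(trace) - length(cands) + best] <- TRUE
      cur_random <- fits[[best]]$spec$random
      cur_fit <- fits[[best]]
    } else break
  }

  p3 <- backfit_fixed(table, respec(p1$spec, random = cur_random),
                      "re-backward-fixed", trace, step)
  final_spec <- respec(p3$spec, estimation = "ML")
  list(spec = final_spec, fit = p3$fit, trace = p3$trace)
}

#' Tabulate a fitted model in the style of a results table
#'
#' Produces the term table (term, df, F, p) with main effects listed above
#' the interactions that contain them, the coefficient table, and the
#' selection trace. Regenerating the report from the same fit and trace is
#' byte-identical.
#'
#' @param fit a converged `camo_fit`.
#' @param trace selection trace from [simplify_model()] (optional).
#' @return object of class `camo_report`: list with `terms`,
#'   `coefficients`, `trace`, `bic`, `n_obs`.
#' @export
model_report <- function(fit, trace = NULL) {
  stopifnot(inherits(fit, "camo_fit"))
  if (!fit$converged) stop("cannot report a non-converged fit")
  an <- fit$anova
  ord <- order(vapply(an$term, term_order, 1L), seq_len(nrow(an)))
  structure(list(terms = an[ord, , drop = FALSE],
                 coefficients = fit$coefficients,
                 trace = trace, bic = fit$bic, n_obs = fit$n_obs),
            class = "camo_report")
}

#' @export
print.camo_report <- function(x, ...) {
  cat(sprintf("Capture-time model (n = %d, BIC = %.2f)\n", x$n_obs, x$bic))
  cat("Model Terms / DF / F / P\n")
  t <- x$terms
  for (i in seq_len(nrow(t)))
    cat(sprintf("  %-45s %d,%d  %8.2f  %s\n", t$term[i], t$df1[i], t$df2[i],
                t$F[i],
                if (is.na(t$p[i])) "NA"
                else if (t$p[i] < 0.001) "<0.001"
                else sprintf("%.3f", t$p[i])))
  invisible(x)
}

#' Write a model report to a directory
#'
#' Writes `terms.csv`, `coefficients.csv`, `trace.json` and a human-readable
#' `summary.txt`.
#'
#' @param report a `camo_report`.
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$terms, file.path(dir, "terms.csv"),
                   row.names = FALSE)
  utils::write.csv(report$coefficients, file.path(dir, "coefficients.csv"),
                   row.names = FALSE)
  if (!is.null(report$trace))
    jsonlite::write_json(report$trace, file.path(dir, "trace.json"),
                         auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "summary.txt"), "w")
  sink(con); print(report); sink()
  close(con)
  invisible(dir)
}

#' Maximal model specification for a study
#'
#' Builds the maximal fixed structure used before simplification: nuisance
#' terms (slide number, optionally quadratic; first-slide and played-before
#' naivety flags; log edge distance; age class), viewing condition, the
#' camouflage covariates, and all two-way interactions of each camouflage
#' covariate with viewing condition and with slide number, plus the viewing
#' x slide interaction.
#'
#' @param camo_covariates character vector of camouflage covariate columns.
#' @param random allowed random terms (first one is mandatory in final
#'   fits).
#' @param polynomial_slide include a quadratic slide term.
#' @return a [model_spec()].
#' @export
maximal_spec <- function(camo_covariates = c("log_pattern_diff",
                                             "lum_dist_diff", "target_area",
                                             "bg_lum_mean", "bg_contrast",
                                             "target_lum_mean",
                                             "target_contrast"),
                         random = c("session_id", "photo_id"),
                         polynomial_slide = FALSE) {
  fixed <- c("slide_number", "first_slide", "played_before",
             "log_edge_dist", "age_class", "viewing_condition",
             camo_covariates,
             paste0("viewing_condition:", camo_covariates),
             paste0("slide_number:", camo_covariates),
             "viewing_condition:slide_number")
  model_spec(fixed, random, polynomial_slide = polynomial_slide,
             estimation = "ML")
}
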