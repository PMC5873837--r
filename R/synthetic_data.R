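# Synthetic camouflage scenes with controllable target/background mismatch,
# and simulated search-game sessions with the generative structure the
# capture-time mixed model assumes. Together they make every downstream
# stage testable without any photograph deposit.

#' Specification of a synthetic camouflage scene
#'
#' The background is isotropic noise with a `1/f^beta` power spectrum
#' (a standard natural-texture surrogate) given a dominant spatial scale by
#' a log-Gaussian spectral weight centred on `texture_scale_px`; a pure
#' power law is scale-free, so the dominant scale is what makes a target
#' pattern-scale shift measurable. The elliptical target carries
#' background-like texture whose dominant scale is multiplied by
#' `target_pattern_scale_shift` and whose luminance is shifted by
#' `target_lum_offset`; both default to the perfect-camouflage control
#' (shift 1, offset 0).
#'
#' @param image_size side of the square image in pixels.
#' @param bg_spectral_slope exponent `beta` of the `1/f^beta` background
#'   power spectrum.
#' @param bg_mean_lum,bg_contrast background mean luminance in `[0, 1]` and
#'   contrast (SD/mean).
#' @param target_axes ellipse semi-axes `(a, b)` in pixels.
#' @param target_lum_offset additive luminance shift of the target.
#' @param target_pattern_scale_shift multiplicative shift of the target's
#'   dominant texture scale.
#' @param texture_scale_px dominant background texture scale in pixels.
#' @param chroma_sd amplitude of the red-green and blue chromatic noise laid
#'   over the luminance plane (purely chromatic: it cancels in `(R + G)/2`).
#' @param seed integer seed; scenes are bit-identical given the same spec.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(image_size = 256, bg_spectral_slope = 2,
                       bg_mean_lum = 0.5, bg_contrast = 0.2,
                       target_axes = c(24, 16), target_lum_offset = 0,
                       target_pattern_scale_shift = 1,
                       texture_scale_px = 16, chroma_sd = 0.08,
                       seed = 1L) {
  stopifnot(image_size >= 16, bg_mean_lum > 0, bg_mean_lum <= 1,
            bg_contrast >= 0, length(target_axes) == 2,
            target_pattern_scale_shift > 0)
  # the target must fit inside the central 60% placement box
  if (2 * max(target_axes) >= 0.6 * image_size)
    stop("target larger than the central 60% placement area")
  structure(list(image_size = as.integer(image_size),
                 bg_spectral_slope = bg_spectral_slope,
                 bg_mean_lum = bg_mean_lum, bg_contrast = bg_contrast,
                 target_axes = target_axes,
                 target_lum_offset = target_lum_offset,
                 target_pattern_scale_shift = target_pattern_scale_shift,
                 texture_scale_px = texture_scale_px,
                 chroma_sd = chroma_sd,
                 seed = as.integer(seed)),
            class = "scene_spec")
}

# Zero-mean unit-SD noise field with power spectrum f^(-beta) shaped by a
# log-Gaussian bump (sigma = 1 octave) around the dominant scale.
texture_field <- function(n, beta, scale_px, sigma_oct = 1) {
  f <- seq_len(n) - 1; f[f > n / 2] <- f[f > n / 2] - n
  r <- sqrt(outer((f / n)^2, (f / n)^2, `+`))
  wl <- ifelse(r > 0, 1 / r, Inf)
  amp <- ifelse(r > 0, r^(-beta / 2), 0) *
    exp(-(log2(wl / scale_px))^2 / (2 * sigma_oct^2))
  white <- stats::fft(matrix(stats::rnorm(n * n), n, n))
  x <- Re(stats::fft(white * amp, inverse = TRUE)) / (n * n)
  (x - mean(x)) / pop_sd(x)
}

#' Generate a synthetic camouflage scene
#'
#' Deterministic given the spec's seed. The target polygon (a 64-vertex
#' ellipse centred in the image) is rasterized to define the target patch
#' exactly; the target texture is alpha-blended over the background across a
#' 2 px feather at the ellipse edge. Chromatic noise is added symmetrically
#' to R and G (and independently to B) so that per-pixel luminance equals
#' the generated luminance plane exactly.
#'
#' @param spec a [scene_spec].
#' @return object of class `synthetic_scene`: list with `image`
#'   ([rgb_image]), `target_polygon` (vertex matrix), `target_mask` and
#'   `truth` (the spec).
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  n <- spec$image_size
  withr::with_seed(spec$seed, {
    zbg <- texture_field(n, spec$bg_spectral_slope, spec$texture_scale_px)
    ztg <- texture_field(n, spec$bg_spectral_slope,
                         spec$texture_scale_px * spec$target_pattern_scale_shift)
    sdlum <- spec$bg_contrast * spec$bg_mean_lum
    bg <- spec$bg_mean_lum + sdlum * zbg
    tg <- spec$bg_mean_lum + spec$target_lum_offset + sdlum * ztg
    cx <- (n - 1) / 2; cy <- (n - 1) / 2
    th <- seq(0, 2 * pi, length.out = 65)[-65]
    poly <- cbind(x = cx + spec$target_axes[1] * cos(th),
                  y = cy + spec$target_axes[2] * sin(th))
    mask <- rasterize_polygon(poly, n, n)
    dist_out <- EBImage::imageData(EBImage::distmap(1 - mask * 1))
    alpha <- pmax(0, 1 - dist_out / 2)   # 1 inside, 2 px feather outside
    lum <- pmin(pmax(alpha * tg + (1 - alpha) * bg, 0), 1)
    ch_rg <- spec$chroma_sd * texture_field(n, spec$bg_spectral_slope,
                                            spec$texture_scale_px)
    ch_b <- spec$chroma_sd * texture_field(n, spec$bg_spectral_slope,
                                           spec$texture_scale_px)
    margin <- pmin(lum, 1 - lum)         # keep R and G inside [0, 1]
    c_rg <- pmin(pmax(ch_rg, -margin), margin)
    px <- array(0, c(n, n, 3))
    px[, , 1] <- lum + c_rg
    px[, , 2] <- lum - c_rg
    px[, , 3] <- pmin(pmax(lum + ch_b, 0), 1)
    structure(list(image = rgb_image(px), target_polygon = poly,
                   target_mask = mask, truth = spec),
              class = "synthetic_scene")
  })
}

#' Generative behaviour model for simulated game sessions
#'
#' Coefficients act on log capture time (natural log of seconds). Viewing
#' condition is coded 0 = trichromat, 1 = simulated dichromat, so a positive
#' `b_viewing` means dichromats are slower overall, and the interaction
#' coefficients give the extra dichromat sensitivity to each camouflage
#' covariate. Defaults encode the qualitative structure of the study design:
#' a dichromat penalty of the order of a 15% slowdown, positive extra
#' dichromat sensitivity to pattern and luminance-distribution differences,
#' negative interactions with target area and background luminance, a
#' negative learning slope over the 20 slides, a first-slide surprise
#' effect, lognormal residual noise, session and photograph random
#' intercepts, a 30-second censoring timeout, and sporadic incorrect clicks.
#'
#' @param intercept log-seconds baseline.
#' @param b_viewing dichromat main effect.
#' @param b_pattern,b_lumdiff,b_area,b_bglum slopes on log pattern
#'   difference, luminance distribution difference, target area (px) and
#'   background mean luminance.
#' @param b_slide learning slope per slide; `b_first` first-slide effect;
#'   `b_edge` slope on log edge distance.
#' @param b_viewing_pattern,b_viewing_lumdiff,b_viewing_area,b_viewing_bglum,b_viewing_slide
#'   viewing-condition interactions.
#' @param sd_session,sd_photo random-intercept standard deviations.
#' @param sd_resid residual SD of log time.
#' @param timeout_s censoring time in seconds (default 30).
#' @param false_click_rate expected incorrect clicks per slide (Poisson).
#' @return object of class `behavior_model`.
#' @export
behavior_model <- function(intercept = log(5),
                           b_viewing = 0.15,
                           b_pattern = 0.2, b_lumdiff = 0.5,
                           b_area = -3e-4, b_bglum = -0.8,
                           b_slide = -0.03, b_first = 0.3, b_edge = -0.1,
                           b_viewing_pattern = 0.1,
                           b_viewing_lumdiff = 0.3,
                           b_viewing_area = -2e-4,
                           b_viewing_bglum = -0.4,
                           b_viewing_slide = 0,
                           sd_session = 0.25, sd_photo = 0.15,
                           sd_resid = 0.5,
                           timeout_s = 30, false_click_rate = 0.3) {
  stopifnot(sd_session >= 0, sd_photo >= 0, sd_resid >= 0, timeout_s > 0,
            false_click_rate >= 0)
  structure(as.list(environment()), class = "behavior_model")
}

linear_predictor <- function(cov, b) {
  v <- cov$viewing
  b$intercept + b$b_viewing * v +
    (b$b_pattern + b$b_viewing_pattern * v) * cov$log_pattern_diff +
    (b$b_lumdiff + b$b_viewing_lumdiff * v) * cov$lum_dist_diff +
    (b$b_area + b$b_viewing_area * v) * cov$target_area +
    (b$b_bglum + b$b_viewing_bglum * v) * cov$bg_lum_mean +
    (b$b_slide + b$b_viewing_slide * v) * cov$slide_number +
    b$b_first * cov$first_slide +
    b$b_edge * cov$log_edge_dist
}

#' Simulate one slide of a game session
#'
#' The latent log capture time is the linear predictor plus the session and
#' photograph random effects plus Normal(0, `sd_resid`) noise. Latent times
#' above the timeout become timeout records (no capture time recorded, as in
#' the game logs); otherwise the capture time is the exponentiated latent.
#' Incorrect-click counts are Poisson; their coordinates are uniform over
#' the image and the final correct click falls inside the target.
#'
#' @param cov list/row of covariates: `viewing` (0/1), `log_pattern_diff`,
#'   `lum_dist_diff`, `target_area`, `bg_lum_mean`, `slide_number`,
#'   `first_slide` (0/1), `log_edge_dist`, `session_effect`, `photo_effect`.
#' @param behavior a [behavior_model].
#' @return list with `outcome` ("capture" or "timeout"), `capture_time_s`
#'   (NA for timeouts) and `n_incorrect_clicks`. Uses the current RNG
#'   stream.
#' @export
simulate_slide <- function(cov, behavior) {
  stopifnot(inherits(behavior, "behavior_model"))
  eta <- linear_predictor(cov, behavior) +
    cov$session_effect + cov$photo_effect
  latent <- eta + stats::rnorm(1, 0, behavior$sd_resid)
  t <- exp(latent)
  n_bad <- stats::rpois(1, behavior$false_click_rate)
  if (t > behavior$timeout_s) {
    list(outcome = "timeout", capture_time_s = NA_real_,
         n_incorrect_clicks = n_bad)
  } else {
    list(outcome = "capture", capture_time_s = t,
         n_incorrect_clicks = n_bad)
  }
}

#' Simulate a whole citizen-science study
#'
#' Each session is assigned a viewing condition, an age bracket and a
#' played-before flag, then plays `n_slides` slides drawn from the photo
#' pool with replacement. On every slide the target is placed uniformly
#' within the central 60% of the image, which determines the edge distance
#' (target centre to nearest image edge). Slides are simulated in order so
#' the slide number carries the learning effect. Randomness flows from one
#' master seed with per-session substreams derived by counter, so studies
#' are reproducible regardless of session count.
#'
#' @param n_sessions number of sessions.
#' @param photos data frame of per-photograph covariates with columns
#'   `photo_id`, `pattern_diff`, `lum_dist_diff`, `target_area`,
#'   `bg_lum_mean`, `image_width`, `image_height` (see
#'   [photo_covariates()]).
#' @param behavior a [behavior_model].
#' @param seed master seed (integer).
#' @param dichromat_ratio fraction of sessions played in the dichromat
#'   condition.
#' @param n_slides slides per completed session (default 20).
#' @param played_before_rate fraction of sessions by repeat players.
#' @return event data frame with columns `session_id, viewing, age_class,
#'   played_before, slide_number, photo_id, outcome, capture_time_s,
#'   n_incorrect_clicks, target_cx, target_cy, edge_distance_px`.
#' @export
simulate_study <- function(n_sessions, photos, behavior, seed = 1L,
                           dichromat_ratio = 0.5, n_slides = 20,
                           played_before_rate = 0.3) {
  stopifnot(inherits(behavior, "behavior_model"), nrow(photos) >= 1)
  empty <- data.frame(session_id = character(), viewing = character(),
                      age_class = character(), played_before = logical(),
                      slide_number = integer(), photo_id = character(),
                      outcome = character(), capture_time_s = numeric(),
                      n_incorrect_clicks = integer(), target_cx = numeric(),
                      target_cy = numeric(), edge_distance_px = numeric(),
                      stringsAsFactors = FALSE)
  if (n_sessions == 0) return(empty)
  ages <- c("<10", "10-15", "16-35", "36-50", ">50")
  # per-photograph random intercepts: one draw per study
  photo_eff <- withr::with_seed((seed * 7L) %% .Machine$integer.max, {
    stats::setNames(stats::rnorm(nrow(photos), 0, behavior$sd_photo),
                    photos$photo_id)
  })
  sessions <- lapply(seq_len(n_sessions), function(s) {
    sub_seed <- (seed + 1000003 * s) %% .Machine$integer.max
    withr::with_seed(sub_seed, {
      viewing_chr <- if (stats::runif(1) < dichromat_ratio) "dichromat"
                     else "trichromat"
      v <- as.numeric(viewing_chr == "dichromat")
      age <- sample(ages, 1)
      played <- stats::runif(1) < played_before_rate
      sess_eff <- stats::rnorm(1, 0, behavior$sd_session)
      idx <- sample(nrow(photos), n_slides, replace = TRUE)
      outcome <- character(n_slides)
      time_s <- numeric(n_slides)
      n_bad <- integer(n_slides)
      cxs <- numeric(n_slides); cys <- numeric(n_slides)
      edges <- numeric(n_slides)
      for (k in seq_len(n_slides)) {
        ph <- photos[idx[k], ]
        w <- ph$image_width; h <- ph$image_height
        cx <- stats::runif(1, 0.2 * w, 0.8 * w)
        cy <- stats::runif(1, 0.2 * h, 0.8 * h)
        edge <- min(cx, w - 1 - cx, cy, h - 1 - cy)
        cov <- list(viewing = v,
                    log_pattern_diff = log(ph$pattern_diff),
                    lum_dist_diff = ph$lum_dist_diff,
                    target_area = ph$target_area,
                    bg_lum_mean = ph$bg_lum_mean,
                    slide_number = k,
                    first_slide = as.numeric(k == 1),
                    log_edge_dist = log(edge),
                    session_effect = sess_eff,
                    photo_effect = photo_eff[[ph$photo_id]])
        sl <- simulate_slide(cov, behavior)
        outcome[k] <- sl$outcome
        time_s[k] <- sl$capture_time_s
        n_bad[k] <- sl$n_incorrect_clicks
        cxs[k] <- cx; cys[k] <- cy; edges[k] <- edge
      }
      data.frame(session_id = sprintf("S%05d", s),
                 viewing = viewing_chr, age_class = age,
                 played_before = played,
                 slide_number = seq_len(n_slides),
                 photo_id = photos$photo_id[idx], outcome = outcome,
                 capture_time_s = time_s, n_incorrect_clicks = n_bad,
                 target_cx = cxs, target_cy = cys,
                 edge_distance_px = edges, stringsAsFactors = FALSE)
    })
  })
  out <- do.call(rbind, sessions)
  rownames(out) <- NULL
  out
}

#' Generative photo covariates from a metrics table
#'
#' Maps a [metrics_table()] to the covariate columns [simulate_study()]
#' feeds into the behaviour model, using either the near-annulus or the
#' whole-background comparison.
#'
#' @param metrics data frame from [metrics_table()].
#' @param scope `"near"` or `"whole"`.
#' @param image_width,image_height nominal image/screen size for target
#'   placement.
#' @return data frame suitable as the `photos` argument of
#'   [simulate_study()].
#' @export
photo_covariates <- function(metrics, scope = c("near", "whole"),
                             image_width = 800, image_height = 600) {
  scope <- match.arg(scope)
  data.frame(photo_id = metrics$photo_id,
             pattern_diff = metrics[[paste0("pattern_diff_", scope)]],
             lum_dist_diff = metrics[[paste0("lum_dist_diff_", scope)]],
             target_area = metrics$target_area,
             bg_lum_mean = metrics[[paste0("mean_lum_", scope)]],
             image_width = image_width, image_height = image_height,
             stringsAsFactors = FALSE)
}

#' Default synthetic photo pool
#'
#' Generates a set of synthetic scenes spanning ranges of target luminance
#' offset (-0.15 ... 0.15), pattern-scale shift (0.5 ... 2), target size,
#' background mean luminance (0.35 ... 0.65) and background contrast
#' (0.15 ... 0.25), measures each scene, and returns the scenes with their
#' metrics. The factors cycle with coprime periods so even a small pool
#' varies every covariate the capture-time model uses, the way a field
#' photograph set would.
#'
#' @param n_scenes number of scenes.
#' @param image_size scene side in pixels.
#' @param cap_px granularity cap for the measurement schedule.
#' @param seed integer seed.
#' @param inner_gap_px,outer_radius_px measurement-region radii. The
#'   defaults scale the field protocol (15 px spacer, 500 px annulus on
#'   full-size photographs) down to synthetic scene size so the "near"
#'   annulus remains a genuinely local surround rather than the whole
#'   background.
#' @return list with `scenes` (list of `synthetic_scene`), `metrics`
#'   (data frame) and `schedule`.
#' @export
scene_pool <- function(n_scenes = 24, image_size = 192, cap_px = 64,
                       seed = 1L, inner_gap_px = 8,
                       outer_radius_px = image_size / 4) {
  offsets <- seq(-0.15, 0.15, length.out = 5)
  shifts <- c(0.5, 0.75, 1, 1.5, 2)
  size_scales <- c(0.7, 1, 1.4)
  bg_lums <- c(0.35, 0.5, 0.65)
  bg_contrasts <- c(0.15, 0.2, 0.25)
  cyc <- function(v, i, phase) v[((i + phase) %% length(v)) + 1]
  sched <- band_schedule(cap_px)
  scenes <- vector("list", n_scenes)
  metrics <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    sp <- scene_spec(image_size = image_size,
                     bg_mean_lum = cyc(bg_lums, i, 1),
                     bg_contrast = cyc(bg_contrasts, i, 2),
                     target_axes = c(24, 16) * cyc(size_scales, i, 0),
                     target_lum_offset = cyc(offsets, i, seed %% 5),
                     target_pattern_scale_shift = cyc(shifts, i * 2, 0),
                     seed = (seed * 131L + i) %% .Machine$integer.max)
    sc <- generate_scene(sp)
    scenes[[i]] <- sc
    regions <- build_regions(sc$target_mask, inner_gap_px, outer_radius_px)
    metrics[[i]] <- measure_regions(to_luminance(sc$image), regions, sched)
  }
  names(metrics) <- sprintf("P%03d", seq_len(n_scenes))
  list(scenes = scenes, metrics = metrics_table(metrics), schedule = sched)
}
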