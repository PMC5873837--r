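# Shared fixtures and independent oracles, all built in code.

# random RGB image with values in [0, 1]
random_rgb <- function(h, w, seed) {
  withr::with_seed(seed, rgb_image(array(runif(h * w * 3), c(h, w, 3))))
}

# horizontal-wavelength grating: luminance varies along x with the given
# wavelength in pixels
grating <- function(n, wavelength, amplitude = 0.3, mean_lum = 0.5) {
  x <- matrix(rep(0:(n - 1), each = n), n, n)
  mean_lum + amplitude * sin(2 * pi * x / wavelength)
}

# independent point-in-polygon oracle: winding number via signed angles
# (equals the even-odd rule for simple polygons)
winding_mask <- function(vertices, width, height, eps = 1e-7) {
  v <- as.matrix(vertices)
  n <- nrow(v)
  out <- matrix(FALSE, height, width)
  for (yy in 0:(height - 1)) for (xx in 0:(width - 1)) {
    px <- xx + eps; py <- yy + eps
    total <- 0
    for (k in seq_len(n)) {
      a <- v[k, ]; b <- v[if (k == n) 1 else k + 1, ]
      a1 <- atan2(a[2] - py, a[1] - px)
      a2 <- atan2(b[2] - py, b[1] - px)
      d <- a2 - a1
      if (d > pi) d <- d - 2 * pi
      if (d < -pi) d <- d + 2 * pi
      total <- total + d
    }
    out[yy + 1, xx + 1] <- abs(total) > pi
  }
  out
}

# exhaustive Euclidean distance to the nearest target pixel
brute_distance <- function(target_mask) {
  tp <- which(target_mask, arr.ind = TRUE)
  h <- nrow(target_mask); w <- ncol(target_mask)
  d <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w))
    d[i, j] <- sqrt(min((tp[, 1] - i)^2 + (tp[, 2] - j)^2))
  d
}

# synthetic per-photograph covariate table for session simulations that do
# not need rendered scenes
synth_photos <- function(n_photos = 12, seed = 1) {
  withr::with_seed(seed, data.frame(
    photo_id = sprintf("P%03d", seq_len(n_photos)),
    pattern_diff = exp(rnorm(n_photos, -2, 0.5)),
    lum_dist_diff = runif(n_photos, 0.05, 0.6),
    target_area = runif(n_photos, 500, 2500),
    bg_lum_mean = runif(n_photos, 0.35, 0.65),
    image_width = 800, image_height = 600,
    stringsAsFactors = FALSE
  ))
}

# covariates for single-slide simulations
unit_covariates <- function(viewing = 0, slide = 1) {
  list(viewing = viewing, log_pattern_diff = 0, lum_dist_diff = 0,
       target_area = 0, bg_lum_mean = 0, slide_number = slide,
       first_slide = as.numeric(slide == 1), log_edge_dist = 0,
       session_effect = 0, photo_effect = 0)
}

# behaviour model with every coefficient and noise source zeroed, then
# selectively overridden
null_behavior <- function(...) {
  base <- list(intercept = log(2), b_viewing = 0, b_pattern = 0,
               b_lumdiff = 0, b_area = 0, b_bglum = 0, b_slide = 0,
               b_first = 0, b_edge = 0, b_viewing_pattern = 0,
               b_viewing_lumdiff = 0, b_viewing_area = 0,
               b_viewing_bglum = 0, b_viewing_slide = 0,
               sd_session = 0, sd_photo = 0, sd_resid = 0,
               false_click_rate = 0)
  do.call(behavior_model, utils::modifyList(base, list(...)))
}

# five-slide event fixture exercising both exclusion rules:
# 0/1/2/3 incorrect clicks with captures, plus one timeout
five_slide_fixture <- function() {
  data.frame(
    session_id = "S1", viewing = "trichromat", age_class = "16-35",
    played_before = FALSE, slide_number = 1:5,
    photo_id = paste0("P", 1:5),
    outcome = c("capture", "capture", "capture", "capture", "timeout"),
    capture_time_s = c(2.1, 3.5, 1.2, 0.8, NA),
    n_incorrect_clicks = c(0L, 1L, 2L, 3L, 1L),
    target_cx = 100, target_cy = 100, edge_distance_px = 50,
    stringsAsFactors = FALSE
  )
}
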