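# Per-photograph camouflage covariates: granularity spectra and pattern
# difference, luminance-distribution difference, patch contrast, mean
# luminance, target area.
#
# Numerical conventions, stated once and used everywhere:
#  * "energy" of a granularity band is the population standard deviation of
#    the band-pass-filtered luminance over the region's pixels;
#  * patch contrast is population SD / mean (coefficient of variation);
#  * luminance histograms use 100 fixed-width bins spanning the global
#    [0, 1] range, so differences are comparable across photographs.

pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

#' Granularity band schedule
#'
#' Spatial scales start at `start_px` and increment at multiples of the
#' square root of two up to `cap_px`. The cap is the size of the smallest
#' target in a game: 256 px for the adult-nightjar game (15 bands) and
#' 128 px for the egg game (13 bands). A relative tolerance of `1e-6` at the
#' cap guarantees that the nominal cap itself is always included despite
#' floating-point representation of the powers.
#'
#' @param cap_px largest band size in pixels.
#' @param start_px smallest band size in pixels (default 2).
#' @return numeric vector of band sizes, class `granularity_schedule`.
#' @export
band_schedule <- function(cap_px, start_px = 2) {
  if (cap_px < start_px) stop("cap_px must be >= start_px")
  k <- 0:ceiling(2 * log2(cap_px / start_px) + 2)
  sizes <- start_px * 2^(k / 2)   # exact powers of two at even k
  sizes <- sizes[sizes <= cap_px * (1 + 1e-6)]
  structure(sizes, class = "granularity_schedule")
}

# Annular Fourier pass-band masks for a schedule on an h x w raster.
# Band i passes wavelengths in [s_i / 2^(1/4), s_i * 2^(1/4)): boundaries at
# the geometric midpoints to the sqrt(2)-neighbouring schedule sizes, so the
# bands tile the spectrum without gap or overlap. DC is excluded from every
# band. Hard-edged (ideal) masks: a deliberate, swappable filter-bank choice
# kept behind this function.
band_masks <- function(h, w, sizes) {
  fy <- seq_len(h) - 1; fy[fy > h / 2] <- fy[fy > h / 2] - h
  fx <- seq_len(w) - 1; fx[fx > w / 2] <- fx[fx > w / 2] - w
  r <- sqrt(outer((fy / h)^2, (fx / w)^2, `+`))   # cycles per pixel
  wl <- ifelse(r > 0, 1 / r, Inf)                 # wavelength in pixels
  half <- 2^(1 / 4)
  lapply(sizes, function(s) wl >= s / half & wl < s * half)
}

#' Granularity spectrum of a region
#'
#' Decomposes the luminance image into band-pass spatial-scale bands with an
#' ideal annular filter in the Fourier domain and measures, for each band,
#' the population standard deviation of the filtered values over the
#' region's pixels ("band energy"). Pixels outside the region are filled
#' with the region's mean luminance before the transform, which keeps the DC
#' of the padded image at the region mean and suppresses mask-edge
#' artefacts.
#'
#' @param lum a [luminance_image] (or bare numeric matrix).
#' @param region logical matrix of region membership, nonempty.
#' @param schedule a [band_schedule].
#' @return object of class `granularity_spectrum`: list with `band_sizes`
#'   and nonnegative `energies`.
#' @export
granularity_spectrum <- function(lum, region, schedule) {
  x <- if (inherits(lum, "luminance_image")) lum$values else as.matrix(lum)
  region <- as.matrix(region) > 0
  if (!any(region)) stop("empty region")
  sizes <- as.numeric(schedule)
  if (min(dim(x)) < max(sizes))
    stop("image smaller than the largest band size")
  mu <- mean(x[region])
  x[!region] <- mu
  h <- nrow(x); w <- ncol(x)
  fw <- stats::fft(x)
  masks <- band_masks(h, w, sizes)
  energies <- vapply(masks, function(m) {
    filt <- Re(stats::fft(fw * m, inverse = TRUE)) / (h * w)
    pop_sd(filt[region])
  }, numeric(1))
  structure(list(band_sizes = sizes, energies = energies),
            class = "granularity_spectrum")
}

#' Pattern difference between two granularity spectra
#'
#' The sum of absolute band-energy differences between the target's and the
#' background's spectra, a scale-by-scale distance between the two texture
#' profiles. Zero means perfect pattern matching.
#'
#' @param target_spec,bg_spec [granularity_spectrum] objects computed on the
#'   same schedule.
#' @return nonnegative scalar.
#' @export
pattern_difference <- function(target_spec, bg_spec) {
  if (length(target_spec$band_sizes) != length(bg_spec$band_sizes) ||
      any(abs(target_spec$band_sizes - bg_spec$band_sizes) >
          1e-9 * target_spec$band_sizes))
    stop("granularity schedules do not match")
  sum(abs(target_spec$energies - bg_spec$energies))
}

#' Luminance distribution difference
#'
#' Nonparametric distance between the target's and the background's
#' luminance histograms, accommodating the non-normal luminance
#' distributions common in animal patterning. Both pixel sets are binned
#' into `n_bins` equal-width bins over the fixed range `[0, 1]`, each
#' histogram normalized to unit mass, and the statistic is half the sum of
#' absolute bin differences (total-variation distance): 0 for identical
#' distributions, 1 for disjoint ones.
#'
#' @param target_px,bg_px numeric vectors of luminances in `[0, 1]`,
#'   nonempty.
#' @param n_bins number of histogram bins (default 100).
#' @return scalar in `[0, 1]`.
#' @export
luminance_distribution_difference <- function(target_px, bg_px, n_bins = 100) {
  if (length(target_px) == 0 || length(bg_px) == 0)
    stop("empty pixel set")
  binned <- function(v) {
    idx <- pmin(floor(v * n_bins) + 1L, n_bins)  # value 1 joins the top bin
    tabulate(idx, nbins = n_bins) / length(v)
  }
  sum(abs(binned(target_px) - binned(bg_px))) / 2
}

#' Patch contrast
#'
#' Standard deviation of luminance within a patch divided by its mean
#' (population SD). Scale-free: multiplying all luminances by a positive
#' constant leaves it unchanged.
#'
#' @param px numeric vector of luminances, nonempty with positive mean.
#' @return nonnegative scalar.
#' @export
patch_contrast <- function(px) {
  if (length(px) == 0) stop("empty pixel set")
  m <- mean(px)
  if (m <= 0) stop("undefined contrast: mean luminance is zero")
  pop_sd(px) / m
}

#' Measure every camouflage covariate for one photograph
#'
#' Builds the luminance channel and the three measurement regions, then
#' computes the pattern difference and luminance-distribution difference of
#' the target against both the near annulus and the whole background, the
#' contrast and mean luminance of all three patches, and the target area.
#' All metrics are functions of luminance only, so they are identical
#' whether measured on the trichromatic or the dichromat-rendered image.
#'
#' @param img an [rgb_image].
#' @param poly target polygon vertices (see [rasterize_polygon]).
#' @param schedule a [band_schedule].
#' @param inner_gap_px,outer_radius_px region parameters, see
#'   [build_regions].
#' @param n_bins histogram bins for the luminance distribution difference.
#' @return object of class `camouflage_metrics`: named list of scalars.
#' @export
measure_photo <- function(img, poly, schedule,
                          inner_gap_px = 15, outer_radius_px = 500,
                          n_bins = 100) {
  lum <- to_luminance(img)
  target <- rasterize_polygon(poly, img$width, img$height)
  regions <- build_regions(target, inner_gap_px, outer_radius_px)
  measure_regions(lum, regions, schedule, n_bins = n_bins)
}

#' Measure camouflage covariates from a prepared luminance image and regions
#'
#' Same output as [measure_photo] for callers that already hold the
#' luminance channel and the region masks (e.g. the synthetic scene
#' generator, whose target mask is known exactly).
#'
#' @param lum a [luminance_image].
#' @param regions a `region_set` from [build_regions].
#' @inheritParams measure_photo
#' @return object of class `camouflage_metrics`.
#' @export
measure_regions <- function(lum, regions, schedule, n_bins = 100) {
  stopifnot(inherits(regions, "region_set"))
  vals <- if (inherits(lum, "luminance_image")) lum$values else as.matrix(lum)
  tpx <- vals[regions$target_mask]
  npx <- vals[regions$annulus_mask]
  wpx <- vals[regions$whole_bg_mask]
  spec_t <- granularity_spectrum(vals, regions$target_mask, schedule)
  spec_n <- granularity_spectrum(vals, regions$annulus_mask, schedule)
  spec_w <- granularity_spectrum(vals, regions$whole_bg_mask, schedule)
  structure(list(
    pattern_diff_near  = pattern_difference(spec_t, spec_n),
    pattern_diff_whole = pattern_difference(spec_t, spec_w),
    lum_dist_diff_near  = luminance_distribution_difference(tpx, npx, n_bins),
    lum_dist_diff_whole = luminance_distribution_difference(tpx, wpx, n_bins),
    contrast_target = patch_contrast(tpx),
    contrast_near   = patch_contrast(npx),
    contrast_whole  = patch_contrast(wpx),
    mean_lum_target = mean(tpx),
    mean_lum_near   = mean(npx),
    mean_lum_whole  = mean(wpx),
    target_area = sum(regions$target_mask)
  ), class = "camouflage_metrics")
}

#' Collect camouflage metrics into a table
#'
#' @param metrics_list named list of `camouflage_metrics` (names are photo
#'   ids).
#' @return data frame with one row per photograph, a `photo_id` column and
#'   one column per metric.
#' @export
metrics_table <- function(metrics_list) {
  rows <- lapply(names(metrics_list), function(id) {
    m <- metrics_list[[id]]
    cbind(data.frame(photo_id = id, stringsAsFactors = FALSE),
          as.data.frame(unclass(m)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
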