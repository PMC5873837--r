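# Image containers, dichromat rendering, and measurement-region construction.
#
# Conventions used throughout the package:
#  * pixel values are floating point in [0, 1]; 8/16-bit files are linearly
#    rescaled on read (no gamma handling: images are assumed linearized
#    upstream, e.g. white-balanced against a grey standard);
#  * coordinates are 0-based with the pixel-centre convention: pixel (x, y)
#    has its centre at (x, y), x increasing rightward, y downward;
#  * rasters are stored as base matrices/arrays indexed [row = y + 1,
#    col = x + 1].

#' Construct an RGB image
#'
#' @param pixels numeric array of dimension `height x width x 3` with values
#'   in `[0, 1]` (R, G, B planes).
#' @return an object of class `rgb_image`.
#' @export
rgb_image <- function(pixels) {
  pixels <- as.array(pixels)
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be a height x width x 3 array")
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 1))
    stop("pixel values must be finite and in [0, 1]")
  if (any(dim(pixels)[1:2] < 1L)) stop("image must be at least 1 x 1")
  structure(list(pixels = pixels,
                 width = dim(pixels)[2], height = dim(pixels)[1]),
            class = "rgb_image")
}

#' @export
print.rgb_image <- function(x, ...) {
  cat(sprintf("<rgb_image %d x %d px>\n", x$width, x$height))
  invisible(x)
}

#' Construct a luminance image
#'
#' @param values numeric matrix (`height x width`) of luminances in `[0, 1]`.
#' @return an object of class `luminance_image`.
#' @export
luminance_image <- function(values) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("luminance values must be finite and in [0, 1]")
  structure(list(values = values,
                 width = ncol(values), height = nrow(values)),
            class = "luminance_image")
}

#' Extract the luminance channel
#'
#' Luminance is the average of the red and green channels, the achromatic
#' signal carried by the summed long- and medium-wavelength cone responses
#' that drives human pattern processing. The blue channel does not
#' contribute.
#'
#' @param img an [rgb_image].
#' @return a [luminance_image] with `L = (R + G) / 2` per pixel.
#' @export
to_luminance <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  luminance_image((img$pixels[, , 1] + img$pixels[, , 2]) / 2)
}

#' Render an image as seen by a simulated red-green dichromat
#'
#' Collapses the red and green channels onto their average
#' `Y = (R + G) / 2`, producing a blue-yellow image with the red-green
#' opponent channel removed. The blue channel is untouched. Because
#' luminance is itself `(R + G) / 2`, the transform preserves the luminance
#' channel exactly, so every luminance-based camouflage metric is identical
#' in the trichromatic and dichromatic renderings of a photograph.
#'
#' @param img an [rgb_image].
#' @return an [rgb_image] with pixels `(Y, Y, B)`.
#' @export
simulate_dichromat <- function(img) {
  stopifnot(inherits(img, "rgb_image"))
  y <- (img$pixels[, , 1] + img$pixels[, , 2]) / 2
  out <- img$pixels
  out[, , 1] <- y
  out[, , 2] <- y
  rgb_image(out)
}

#' Rasterize a target polygon
#'
#' A pixel belongs to the mask when its centre falls inside the polygon
#' under the even-odd (crossing-number) fill rule. Containment is half-open:
#' centres exactly on a lower/left boundary are inside, on an upper/right
#' boundary outside, so an axis-aligned `[0, k) x [0, k)` box covers exactly
#' `k^2` pixels.
#'
#' @param vertices two-column matrix or data frame of `(x, y)` vertex
#'   coordinates in pixel units (0-based, pixel-centre convention), at least
#'   three rows, describing a simple (non-self-intersecting) polygon.
#' @param width,height raster dimensions in pixels.
#' @return logical `height x width` matrix.
#' @export
rasterize_polygon <- function(vertices, width, height) {
  v <- as.matrix(vertices)
  if (ncol(v) < 2L) stop("`vertices` needs x and y columns")
  v <- v[, 1:2, drop = FALSE]
  storage.mode(v) <- "double"
  n <- nrow(v)
  if (n < 3L) stop("a polygon needs at least 3 vertices")
  # shoelace area; zero means degenerate (e.g. collinear vertices)
  xs <- v[, 1]; ys <- v[, 2]
  area <- abs(sum(xs * ys[c(2:n, 1)] - xs[c(2:n, 1)] * ys)) / 2
  if (area < .Machine$double.eps * max(1, max(abs(v))))
    stop("degenerate polygon: zero area")
  # epsilon-shifted pixel centres implement the half-open containment rule
  eps <- 1e-7
  px <- matrix(rep(seq_len(width) - 1, each = height), height, width) + eps
  py <- matrix(rep(seq_len(height) - 1, times = width), height, width) + eps
  crossings <- matrix(0L, height, width)
  for (k in seq_len(n)) {
    a <- v[k, ]
    b <- v[if (k == n) 1L else k + 1L, ]
    straddles <- (a[2] > py) != (b[2] > py)
    if (!any(straddles)) next
    xint <- a[1] + (py - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
    crossings <- crossings + (straddles & px < xint)
  }
  crossings %% 2L == 1L
}

#' Build the measurement regions around a target
#'
#' Constructs the three regions in which camouflage is measured for one
#' photograph: the target itself, a surrounding "doughnut" annulus whose
#' edge distance from the target lies in `(inner_gap_px, outer_radius_px]`,
#' and the whole background (everything farther than `inner_gap_px` from the
#' target). The spacer within `inner_gap_px` of the target is excluded from
#' both backgrounds so that out-of-focus pixels straddling the target edge
#' are never measured. Distance is exact Euclidean distance to the nearest
#' target pixel; regions running off-frame are clipped at the image bounds
#' without compensation.
#'
#' @param target_mask logical/0-1 matrix marking target pixels; must be
#'   nonempty.
#' @param inner_gap_px spacer radius in pixels (default 15).
#' @param outer_radius_px outer annulus radius in pixels (default 500).
#' @return an object of class `region_set`: list with logical matrices
#'   `target_mask`, `annulus_mask`, `whole_bg_mask` and the numeric distance
#'   map `distance`.
#' @export
build_regions <- function(target_mask, inner_gap_px = 15, outer_radius_px = 500) {
  m <- target_mask
  if (is.logical(m)) m <- m * 1
  m <- as.matrix(m)
  if (!any(m > 0)) stop("empty target mask")
  if (outer_radius_px <= inner_gap_px)
    stop("outer_radius_px must exceed inner_gap_px")
  d <- EBImage::imageData(EBImage::distmap(1 - m))
  target <- m > 0
  whole_bg <- d > inner_gap_px
  if (!any(whole_bg))
    stop("no background remains: target plus spacer fills the image")
  annulus <- whole_bg & d <= outer_radius_px
  structure(list(target_mask = target,
                 annulus_mask = annulus,
                 whole_bg_mask = whole_bg,
                 distance = d),
            class = "region_set")
}

#' Read an RGB image from PNG or TIFF
#'
#' 8- and 16-bit integer files are rescaled linearly to `[0, 1]`; greyscale
#' files are replicated across channels; an alpha channel, if present, is
#' dropped.
#'
#' @param path file path ending in .png, .tif or .tiff.
#' @return an [rgb_image].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: ", ext)
  )
  if (length(dim(a)) == 2L) a <- array(rep(a, 3), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  if (dim(a)[3] == 1L) a <- array(rep(a, 3), c(dim(a)[1:2], 3L))
  rgb_image(pmin(pmax(a, 0), 1))
}

#' Write an RGB image to PNG or TIFF
#'
#' @param img an [rgb_image].
#' @param path output path ending in .png, .tif or .tiff.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "rgb_image"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(img$pixels, path),
    tif = ,
    tiff = tiff::writeTIFF(img$pixels, path, bits.per.sample = 16L),
    stop("unsupported image format: ", ext)
  )
  invisible(path)
}

#' Write a binary mask as a single-channel PNG
#'
#' @param mask logical matrix.
#' @param path output .png path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Read polygon annotations
#'
#' CSV annotations have columns `photo_id, vertex_index, x, y`; JSON
#' annotations are a list of objects with `photo_id` and a `vertices` array
#' of `[x, y]` pairs.
#'
#' @param path .csv or .json annotation file.
#' @return named list of two-column vertex matrices, one per `photo_id`.
#' @export
read_polygons <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
    stopifnot(all(c("photo_id", "vertex_index", "x", "y") %in% names(d)))
    d <- d[order(d$photo_id, d$vertex_index), ]
    lapply(split(d, d$photo_id),
           function(g) cbind(x = g$x, y = g$y))
  } else if (ext == "json") {
    items <- jsonlite::read_json(path, simplifyVector = TRUE,
                                 simplifyDataFrame = FALSE)
    out <- lapply(items, function(it) {
      v <- it$vertices
      if (is.list(v)) v <- do.call(rbind, lapply(v, unlist))
      v <- matrix(as.numeric(v), ncol = 2)
      colnames(v) <- c("x", "y")
      v
    })
    names(out) <- vapply(items, function(it) as.character(it$photo_id), "")
    out
  } else stop("unsupported annotation format: ", ext)
}
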