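# Rendering: a pick's localizations are binned into a square oversampled
# 2D histogram, the grayscale image the classifier consumes. Augmentation
# rotates the localization coordinates (not the image) before binning, which
# is exact and interpolation-free.

#' Rendering configuration
#'
#' @param oversampling Subpixels per camera pixel (integer >= 1). The default
#'   of 13 puts one subpixel at ~10 nm for a 130-nm camera pixel, about twice
#'   the default simulated localization precision.
#' @param image_size Side length of the square image in subpixels; must be
#'   even. Use [image_size_for_pick()] to derive it from a pick diameter.
#' @param centering `"center_of_mass"` (default; robust to imperfect pick
#'   placement) or `"pick_center"`.
#' @param normalization `"max_to_one"` (default; localization counts vary per
#'   structure so classifier inputs should be scale-free) or `"none"`.
#' @return A `render_config` list.
#' @export
render_config <- function(oversampling = 13L, image_size = 20L,
                          centering = c("center_of_mass", "pick_center"),
                          normalization = c("max_to_one", "none")) {
  centering <- match.arg(centering)
  normalization <- match.arg(normalization)
  stopifnot(oversampling >= 1, oversampling == floor(oversampling),
            image_size >= 2, image_size %% 2 == 0)
  structure(list(oversampling = as.integer(oversampling),
                 image_size = as.integer(image_size),
                 centering = centering, normalization = normalization),
            class = "render_config")
}

#' Image size covering a pick at a given oversampling
#'
#' `ceil(diameter * oversampling)`, rounded up to the next even integer so the
#' pick center can sit on the image midpoint.
#'
#' @param pick_diameter Pick diameter in camera px.
#' @param oversampling Subpixels per camera px.
#' @return Even integer side length in subpixels.
#' @export
image_size_for_pick <- function(pick_diameter, oversampling) {
  s <- ceiling(pick_diameter * oversampling)
  as.integer(s + s %% 2)
}

render_center <- function(locs, pick, cfg) {
  if (cfg$centering == "center_of_mass" && nrow(locs) > 0)
    c(mean(locs$x), mean(locs$y))
  else
    c(pick$center_x, pick$center_y)
}

#' Render a pick into an oversampled 2D-histogram image
#'
#' Each localization falls into subpixel bin
#' `(floor((x - x0) * o), floor((y - y0) * o))` with `o = oversampling` and
#' `(x0, y0)` chosen so the configured center sits at the image midpoint.
#' Bins are half-open; localizations outside the image are dropped and
#' counted. With normalization `"none"` the pixel sum equals the number of
#' in-bounds localizations exactly.
#'
#' @param locs Localization subset (may be empty).
#' @param pick Pick row (used for `pick_center` centering and bookkeeping);
#'   may be `NULL` with `center_of_mass` centering.
#' @param cfg A [render_config()].
#' @param center Optional explicit center `(x, y)` overriding `cfg$centering`
#'   (used by augmentation so all rotations share one center).
#' @return A `rendered_image` list: `pixels` (image_size x image_size matrix,
#'   row = y bin, column = x bin), `config`, `source_pick`, `n_locs` (input
#'   count) and `n_dropped` (out-of-image count).
#' @export
render_pick <- function(locs, pick = NULL, cfg = render_config(), center = NULL) {
  s <- cfg$image_size
  o <- cfg$oversampling
  if (is.null(center)) {
    if (is.null(pick) && cfg$centering == "pick_center")
      stop("pick_center centering requires a pick")
    center <- render_center(locs, pick, cfg)
  }
  n <- nrow(locs)
  if (n > 0) {
    x0 <- center[1] - s / (2 * o)
    y0 <- center[2] - s / (2 * o)
    ix <- floor((locs$x - x0) * o)
    iy <- floor((locs$y - y0) * o)
    keep <- ix >= 0 & ix < s & iy >= 0 & iy < s
    counts <- tabulate(iy[keep] * s + ix[keep] + 1, nbins = s * s)
    pixels <- matrix(as.numeric(counts), nrow = s, ncol = s, byrow = TRUE)
    n_dropped <- sum(!keep)
  } else {
    pixels <- matrix(0, s, s)
    n_dropped <- 0L
  }
  if (cfg$normalization == "max_to_one") {
    m <- max(pixels)
    if (m > 0) pixels <- pixels / m
  }
  structure(list(pixels = pixels, config = cfg,
                 source_pick = if (is.null(pick)) NA_integer_ else pick$pick_id,
                 n_locs = n, n_dropped = as.integer(n_dropped)),
            class = "rendered_image")
}

#' Rigidly rotate localization coordinates about a center
#'
#' Rotates `(x, y)` by `angle` radians about `center`; all other fields and
#' the record order are untouched. The rotation matrix is the mathematical
#' one in the `(x, y)` plane; because image y points downward, a positive
#' angle appears clockwise on screen.
#'
#' @param locs Localization data.frame.
#' @param center Numeric `(x, y)` rotation center in camera px.
#' @param angle Rotation angle in radians.
#' @return The rotated data.frame.
#' @export
rotate_locs <- function(locs, center, angle) {
  ca <- cos(angle); sa <- sin(angle)
  dx <- locs$x - center[1]
  dy <- locs$y - center[2]
  locs$x <- center[1] + ca * dx - sa * dy
  locs$y <- center[2] + sa * dx + ca * dy
  locs
}

#' Render picksets with rotation augmentation
#'
#' Each pickset is rendered at `n_angles` rotations `2*pi*k / n_angles`,
#' `k = 0 ... n_angles - 1`, about its configured center (the `k = 0` image is
#' bin-identical to the unaugmented render). Labels are replicated per angle.
#'
#' @param picksets List of localization data.frames, one per structure.
#' @param labels Vector of class labels, one per pickset.
#' @param cfg A [render_config()].
#' @param n_angles Number of rotation steps (>= 1); 1 disables augmentation.
#' @param picks Optional `pick_set` aligned with `picksets` (needed for
#'   `pick_center` centering).
#' @return A list with `images` (list of `rendered_image`, length
#'   `n_angles * length(picksets)`), `labels` (replicated), and
#'   `structure_id` (index of the source pickset for every image, so that
#'   rotated copies of one structure can be traced).
#' @export
augment_set <- function(picksets, labels, cfg = render_config(), n_angles = 1L,
                        picks = NULL) {
  stopifnot(n_angles >= 1, length(picksets) == length(labels))
  n_angles <- as.integer(n_angles)
  angles <- 2 * pi * (seq_len(n_angles) - 1L) / n_angles
  images <- vector("list", length(picksets) * n_angles)
  out_labels <- rep(labels, each = n_angles)
  structure_id <- rep(seq_along(picksets), each = n_angles)
  k <- 1L
  for (i in seq_along(picksets)) {
    locs <- picksets[[i]]
    pick <- if (is.null(picks)) NULL else picks[i, , drop = FALSE]
    center <- render_center(locs, pick, cfg)
    for (a in angles) {
      rotated <- if (a == 0) locs else rotate_locs(locs, center, a)
      images[[k]] <- render_pick(rotated, pick, cfg, center = center)
      k <- k + 1L
    }
  }
  list(images = images, labels = out_labels, structure_id = structure_id)
}

#' Flatten rendered images into a sample-by-pixel matrix
#'
#' Row-major flattening (y bin outer, x bin inner), one image per row — the
#' input layout the multilayer perceptron expects.
#'
#' @param images List of `rendered_image` objects with a common image size.
#' @return Numeric matrix, `length(images)` rows, `image_size^2` columns.
#' @export
flatten_images <- function(images) {
  if (length(images) == 0) return(matrix(0, 0, 0))
  s <- images[[1]]$config$image_size
  t(vapply(images, function(im) as.numeric(t(im$pixels)), numeric(s * s)))
}

#' Write a rendered image to PNG for visual inspection
#'
#' @param image A `rendered_image`.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
export_image_png <- function(image, path) {
  px <- image$pixels
  m <- max(px)
  if (m > 0) px <- px / m
  grDevices::png(path, width = ncol(px), height = nrow(px))
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::image(t(px)[, nrow(px):1, drop = FALSE], axes = FALSE,
                  col = grDevices::gray.colors(256, start = 0, end = 1),
                  useRaster = TRUE)
  invisible(path)
}
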