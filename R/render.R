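#' Rendering parameters for synthetic slices
#'
#' Controls how curves and distractors are rasterized into an 8-bit-scale
#' grayscale slice. The defaults (background 30, foreground 220, noise sd
#' 10) keep twice the Otsu threshold well below the foreground level, so
#' factor-2 Otsu thresholding retains rendered strokes intact: with a
#' background-dominated histogram the Otsu value settles just above the
#' background noise tail rather than midway between the classes.
#'
#' @param image_shape Integer `(height, width)` in pixels.
#' @param stroke_thickness Stroke diameter in pixels (>= 1).
#' @param foreground_level,background_level Intensities on a 0-255 scale;
#'   foreground must exceed background.
#' @param noise_sd Standard deviation of additive Gaussian noise (>= 0).
#' @param distractors List of [distractor_spec()] objects.
#' @param seed Integer seed for the noise, or `NULL` to draw from the
#'   current RNG stream (so callers can manage seeding themselves).
#' @return An object of class `render_spec`.
#' @export
render_spec <- function(image_shape = c(512L, 512L), stroke_thickness = 3,
                        foreground_level = 220, background_level = 30,
                        noise_sd = 10, distractors = list(), seed = NULL) {
  if (foreground_level <= background_level)
    stop("foreground_level must exceed background_level")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (stroke_thickness < 1) stop("stroke_thickness must be >= 1")
  structure(list(image_shape = as.integer(image_shape),
                 stroke_thickness = stroke_thickness,
                 foreground_level = foreground_level,
                 background_level = background_level,
                 noise_sd = noise_sd, distractors = distractors,
                 seed = seed),
            class = "render_spec")
}

#' Distractor object specification
#'
#' Each distractor kind is constructed to be rejected by exactly one
#' fragment filter:
#' * `speck` — a small disc of area below 100 px (rejected by the area
#'   rule);
#' * `dense_texture` — a connected raster of parallel lines with
#'   bounding-box occupancy above 0.15 but solidity below 0.36, mimicking
#'   superimposed lamellae (rejected by the occupancy rule);
#' * `solid_blob` — a solid diagonal band with solidity above 0.9 but,
#'   thanks to its oblique orientation, bounding-box occupancy below 0.15,
#'   mimicking compact adventitia-like tissue (rejected by the solidity
#'   rule).
#'
#' @param kind One of `"speck"`, `"solid_blob"`, `"dense_texture"`.
#' @param size Characteristic size in pixels (disc diameter, band length,
#'   or texture box side).
#' @param location Numeric `(x, y)` center, in pixels.
#' @return An object of class `distractor_spec`.
#' @export
distractor_spec <- function(kind = c("speck", "solid_blob", "dense_texture"),
                            size = NULL, location = c(0, 0)) {
  kind <- match.arg(kind)
  if (is.null(size))
    size <- switch(kind, speck = 7, solid_blob = 100, dense_texture = 40)
  structure(list(kind = kind, size = size, location = as.numeric(location)),
            class = "distractor_spec")
}

# pixel (row, col) indices covered by a disc-stamped stroke along the
# continuous points (x, y); radius = thickness / 2
stamp_stroke <- function(pts, thickness, shape) {
  rad <- thickness / 2
  k <- ceiling(rad)
  offs <- expand.grid(dr = -k:k, dc = -k:k)
  n <- nrow(pts)
  cr <- round(pts[, 2]); cc <- round(pts[, 1]) # y -> row, x -> col
  rows <- rep(cr, each = nrow(offs)) + rep(offs$dr, n)
  cols <- rep(cc, each = nrow(offs)) + rep(offs$dc, n)
  xs <- rep(pts[, 1], each = nrow(offs))
  ys <- rep(pts[, 2], each = nrow(offs))
  keep <- (cols - xs)^2 + (rows - ys)^2 <= rad^2 &
    rows >= 1 & rows <= shape[1] & cols >= 1 & cols <= shape[2]
  unique(cbind(rows[keep], cols[keep]))
}

# rasterize one distractor into (row, col) pixel indices
stamp_distractor <- function(d, shape) {
  x0 <- d$location[1]; y0 <- d$location[2]
  if (d$kind == "speck") {
    rad <- d$size / 2
    k <- ceiling(rad)
    g <- expand.grid(r = round(y0) + (-k:k), c = round(x0) + (-k:k))
    keep <- (g$c - x0)^2 + (g$r - y0)^2 <= rad^2
    px <- cbind(g$r[keep], g$c[keep])
  } else if (d$kind == "solid_blob") {
    # solid band of thickness 6 at 45 degrees
    half <- d$size / 2
    t <- seq(-half, half, by = 0.25)
    pts <- cbind(x = x0 + t / sqrt(2), y = y0 + t / sqrt(2))
    px <- stamp_stroke(pts, 6, shape)
  } else { # dense_texture
    half <- floor(d$size / 2)
    r0 <- round(y0) - half; c0 <- round(x0) - half
    rows <- seq(r0, r0 + 2L * half, by = 4L)
    px <- cbind(rep(rows, each = 2L * half + 1L),
                rep(c0:(c0 + 2L * half), length(rows)))
    diag_px <- cbind(r0:(r0 + 2L * half), c0:(c0 + 2L * half))
    px <- unique(rbind(px, diag_px))
  }
  px[px[, 1] >= 1 & px[, 1] <= shape[1] &
     px[, 2] >= 1 & px[, 2] <= shape[2], , drop = FALSE]
}

#' Render curves and distractors into one grayscale slice
#'
#' Draws each curve as a connected stroke of the configured thickness
#' (a disc of diameter `stroke_thickness` stamped along a dense sampling
#' of the curve, which guarantees 8-connectivity), adds distractors, and
#' applies additive Gaussian noise clamped to \[0, 255\]. Curves must fit
#' inside the frame with a margin of one stroke thickness; partial
#' lamellae would bias length measurement downstream.
#'
#' @param curves List of [curve_spec()] objects. Pixel centers sit at
#'   integer coordinates with `x = column`, `y = row` (1-based).
#' @param render A [render_spec()].
#' @return A list with `image` (numeric matrix) and `truth` (data frame
#'   of per-curve [curve_truth()] values, aligned by curve index).
#' @export
render_slice <- function(curves, render = render_spec()) {
  shape <- render$image_shape
  draw <- function() {
    img <- matrix(render$background_level, shape[1], shape[2])
    truth <- vector("list", length(curves))
    for (i in seq_along(curves)) {
      spec <- curves[[i]]
      arc <- curve_arc_length(spec)
      pts <- curve_points(spec, max(50L, as.integer(ceiling(4 * arc))))
      m <- render$stroke_thickness
      if (min(pts[, 1]) < 1 + m || max(pts[, 1]) > shape[2] - m ||
          min(pts[, 2]) < 1 + m || max(pts[, 2]) > shape[1] - m)
        stop(sprintf("curve %d exits the frame (margin %g px required)", i, m))
      px <- stamp_stroke(pts, render$stroke_thickness, shape)
      img[px] <- render$foreground_level
      tr <- curve_truth(spec)
      truth[[i]] <- data.frame(curve = i, arc_length = tr$arc_length,
                               chord_length = tr$chord_length,
                               true_rec_step = tr$true_rec_step,
                               true_rec_chord = tr$true_rec_chord)
    }
    for (d in render$distractors) {
      img[stamp_distractor(d, shape)] <- render$foreground_level
    }
    if (render$noise_sd > 0) {
      img <- img + matrix(stats::rnorm(length(img), 0, render$noise_sd),
                          shape[1], shape[2])
      img[img < 0] <- 0
      img[img > 255] <- 255
    }
    list(image = img,
         truth = if (length(curves)) do.call(rbind, truth) else
           data.frame(curve = integer(0), arc_length = numeric(0),
                      chord_length = numeric(0), true_rec_step = numeric(0),
                      true_rec_chord = numeric(0)))
  }
  if (!is.null(render$seed)) withr::with_seed(render$seed, draw()) else draw()
}
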