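#' Fragment extraction parameters
#'
#' Threshold and filter settings for turning a grayscale slice into
#' retained lamella-fragment regions: global threshold at `otsu_factor`
#' times the Otsu value, then three region filters — minimum area,
#' maximum bounding-box occupancy (removes patches of superimposed
#' lamellae), and maximum solidity (removes unstructured blob-like zones
#' such as adventitia).
#'
#' @param otsu_factor Multiplier applied to the Otsu threshold (default 2).
#' @param min_area Minimum region area in pixels; regions with
#'   `area >= min_area` pass (default 100).
#' @param max_bbox_occupancy Regions pass only if
#'   `area / bbox_area < max_bbox_occupancy` (default 0.15).
#' @param max_solidity Regions pass only if
#'   `area / convex_hull_area < max_solidity` (default 0.36).
#' @param connectivity Pixel connectivity for region labeling, 4 or 8
#'   (default 8; thin curves at arbitrary angles fragment under 4).
#' @return An object of class `extraction_params`.
#' @export
extraction_params <- function(otsu_factor = 2.0, min_area = 100L,
                              max_bbox_occupancy = 0.15,
                              max_solidity = 0.36, connectivity = 8L) {
  if (otsu_factor <= 0) stop("otsu_factor must be > 0")
  if (min_area < 1) stop("min_area must be >= 1")
  if (max_bbox_occupancy <= 0 || max_bbox_occupancy > 1)
    stop("max_bbox_occupancy must be in (0, 1]")
  if (max_solidity <= 0 || max_solidity > 1)
    stop("max_solidity must be in (0, 1]")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  structure(list(otsu_factor = otsu_factor, min_area = as.integer(min_area),
                 max_bbox_occupancy = max_bbox_occupancy,
                 max_solidity = max_solidity,
                 connectivity = as.integer(connectivity)),
            class = "extraction_params")
}

#' Otsu threshold of a grayscale image
#'
#' Exhaustive between-class-variance maximization over a 256-bin histogram
#' of the image after min-max rescaling to \[0, 255\]; the selected bin is
#' mapped back to the original intensity scale. The first bin attaining
#' the maximum is chosen.
#'
#' @param image Numeric matrix with at least two distinct values.
#' @return Threshold on the original intensity scale, with attribute
#'   `bin` (the selected histogram bin, 0-255).
#' @export
otsu_threshold <- function(image) {
  r <- range(image)
  if (!all(is.finite(r))) stop("image contains non-finite values")
  if (r[1] == r[2]) stop("Otsu threshold undefined for a constant image")
  x <- as.integer(pmin(floor((image - r[1]) / (r[2] - r[1]) * 256), 255))
  h <- tabulate(x + 1L, 256L)
  p <- h / sum(h)
  bins <- 0:255
  w0 <- cumsum(p)
  mu <- cumsum(p * bins)
  muT <- mu[256L]
  sb <- (muT * w0 - mu)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  t_bin <- bins[which.max(sb)]
  structure(r[1] + t_bin / 255 * (r[2] - r[1]), bin = t_bin)
}

#' Threshold a slice at a multiple of the Otsu value
#'
#' A pixel is foreground iff its intensity strictly exceeds
#' `otsu_factor * otsu_threshold(image)`. Bright lamella cross-sections
#' sit far above the bulk of the wall signal, so a factor around 2
#' isolates them even when the single Otsu value would not.
#'
#' @param image Numeric matrix, one grayscale slice.
#' @param params [extraction_params()].
#' @return Logical matrix; warns (and returns all-`FALSE`) if the scaled
#'   threshold exceeds the image maximum.
#' @export
threshold_slice <- function(image, params = extraction_params()) {
  t <- params$otsu_factor * as.numeric(otsu_threshold(image))
  if (t >= max(image))
    warning(sprintf("threshold %.2f is at or above the image maximum %.2f; empty mask",
                    t, max(image)))
  image > t
}

# connected-component membership of foreground pixels; pixels is a
# lexicographically ordered (row, col) matrix
label_components <- function(pixels, connectivity = 8L) {
  n <- nrow(pixels)
  key <- pixels[, 1] * 1e6 + pixels[, 2]
  offs <- rbind(c(0, 1), c(1, 0))
  if (connectivity == 8L) offs <- rbind(offs, c(1, 1), c(1, -1))
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- match(key + offs[k, 1] * 1e6 + offs[k, 2], key)
    hit <- !is.na(nb)
    from <- c(from, which(hit)); to <- c(to, nb[hit])
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to))
  igraph::components(g)$membership
}

# count of pixels whose centers lie inside or on the convex hull of the
# region's pixel centers
hull_pixel_count <- function(pixels) {
  ur <- unique(pixels[, 1]); uc <- unique(pixels[, 2])
  hull <- grDevices::chull(pixels[, 2], pixels[, 1])
  if (length(hull) < 3 || length(ur) == 1 || length(uc) == 1)
    return(nrow(pixels)) # degenerate (collinear) hull: the region itself
  hx <- pixels[hull, 2]; hy <- pixels[hull, 1]
  grid <- expand.grid(row = min(ur):max(ur), col = min(uc):max(uc))
  inside <- pracma::inpolygon(grid$col, grid$row, hx, hy, boundary = TRUE)
  sum(inside)
}

#' Label connected bright regions of a binary slice
#'
#' One `fragment_region` per connected component, carrying the area,
#' bounding box, bounding-box occupancy (extent) and solidity descriptors
#' used by [filter_fragments()]. Convex-hull area is counted as pixels
#' whose centers lie inside or on the hull of the region's pixel centers.
#'
#' @param binary Logical (or 0/1) matrix.
#' @param params [extraction_params()] (supplies the connectivity).
#' @param slice_index Slice index recorded in each region.
#' @return List of `fragment_region` objects (empty for an empty mask).
#' @export
label_fragments <- function(binary, params = extraction_params(),
                            slice_index = 1L) {
  pixels <- which(binary != 0, arr.ind = TRUE)
  if (nrow(pixels) == 0) return(list())
  ord <- order(pixels[, 1], pixels[, 2])
  pixels <- pixels[ord, , drop = FALSE]
  memb <- label_components(pixels, params$connectivity)
  lapply(seq_len(max(memb)), function(id) {
    px <- pixels[memb == id, , drop = FALSE]
    area <- nrow(px)
    rmin <- min(px[, 1]); rmax <- max(px[, 1])
    cmin <- min(px[, 2]); cmax <- max(px[, 2])
    h <- rmax - rmin + 1L; w <- cmax - cmin + 1L
    structure(list(slice_index = slice_index, region_id = id,
                   pixel_coords = px, area = area,
                   bbox = c(min_row = rmin, min_col = cmin,
                            height = h, width = w),
                   bbox_occupancy = area / (h * w),
                   solidity = area / hull_pixel_count(px)),
              class = "fragment_region")
  })
}

# binary mask of one region cropped to its bounding box (plus padding)
region_mask <- function(region, pad = 0L) {
  b <- region$bbox
  m <- matrix(FALSE, b["height"] + 2L * pad, b["width"] + 2L * pad)
  m[cbind(region$pixel_coords[, 1] - b["min_row"] + 1L + pad,
          region$pixel_coords[, 2] - b["min_col"] + 1L + pad)] <- TRUE
  m
}

#' Filter fragment regions by area, occupancy and solidity
#'
#' Keeps a region iff `area >= min_area` (rule 1, drops small specks) and
#' `bbox_occupancy < max_bbox_occupancy` (rule 2, drops dense patches of
#' superimposed lamellae) and `solidity < max_solidity` (rule 3, drops
#' blob-like unstructured zones). Order is preserved. Idempotent.
#'
#' @param regions List of `fragment_region` from [label_fragments()].
#' @param params [extraction_params()].
#' @return The kept sublist, with attributes `rejections` (named counts
#'   of regions rejected per rule, each region counted once under the
#'   first rule it fails, in the order area, bbox_occupancy, solidity)
#'   and `rejected` (data frame of `region_id`, `rule`).
#' @export
filter_fragments <- function(regions, params = extraction_params()) {
  rules <- vapply(regions, function(r) {
    if (r$area < params$min_area) return("area")
    if (r$bbox_occupancy >= params$max_bbox_occupancy) return("bbox_occupancy")
    if (r$solidity >= params$max_solidity) return("solidity")
    "kept"
  }, character(1))
  kept <- regions[rules == "kept"]
  rej <- rules[rules != "kept"]
  structure(kept,
            rejections = c(area = sum(rej == "area"),
                           bbox_occupancy = sum(rej == "bbox_occupancy"),
                           solidity = sum(rej == "solidity")),
            rejected = data.frame(
              region_id = vapply(regions[rules != "kept"],
                                 function(r) r$region_id, integer(1)),
              rule = unname(rej)))
}
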