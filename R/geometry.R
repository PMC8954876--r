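#' Curvilinear (geodesic-like) length of a polyline
#'
#' Sum of Euclidean distances between consecutive vertices.
#'
#' @param vertices Numeric matrix with two columns (vertex coordinates),
#'   at least two rows.
#' @return Length in pixels.
#' @export
geodesic_like_length <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2) stop("need at least 2 vertices")
  d <- diff(vertices)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

# cumulative geodesic positions of the vertices (first vertex at 0)
cum_geodesic <- function(vertices) {
  d <- diff(vertices)
  c(0, cumsum(sqrt(d[, 1]^2 + d[, 2]^2)))
}

# point on the polyline at geodesic position p (linear interpolation)
point_at_geodesic <- function(vertices, cum, p) {
  n <- nrow(vertices)
  if (p <= 0) return(vertices[1, ])
  if (p >= cum[n]) return(vertices[n, ])
  i <- findInterval(p, cum, rightmost.closed = TRUE)
  # skip zero-length segments
  while (i < n - 1 && cum[i + 1] <= cum[i]) i <- i + 1
  f <- (p - cum[i]) / (cum[i + 1] - cum[i])
  vertices[i, ] + f * (vertices[i + 1, ] - vertices[i, ])
}

#' End-to-end (Euclidean-like) length of a polyline
#'
#' Sums chords between points marked every `step` units of geodesic-like
#' length along the polyline, the final vertex always included as a mark.
#' Short polylines fall back to a single first-to-last chord (total length
#' below `step`) or to two chords through the vertex nearest to half the
#' geodesic length (total length below `2 * step`; ties resolved to the
#' earlier vertex).
#'
#' @inheritParams geodesic_like_length
#' @param step Geodesic step between marks, in pixels (default 100).
#' @return Length in pixels; never exceeds the geodesic-like length.
#' @export
euclid_like_length <- function(vertices, step = 100) {
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 2) stop("need at least 2 vertices")
  if (step <= 0) stop("step must be > 0")
  cum <- cum_geodesic(vertices)
  L <- cum[length(cum)]
  n <- nrow(vertices)
  chord <- function(a, b) sqrt(sum((b - a)^2))
  if (L < step) {
    return(chord(vertices[1, ], vertices[n, ]))
  }
  if (L < 2 * step) {
    mid <- which.min(abs(cum - L / 2)) # ties -> earlier vertex
    return(chord(vertices[1, ], vertices[mid, ]) +
           chord(vertices[mid, ], vertices[n, ]))
  }
  pos <- seq(0, L, by = step)
  if (pos[length(pos)] < L) pos <- c(pos, L)
  marks <- t(vapply(pos, function(p) point_at_geodesic(vertices, cum, p),
                    numeric(2)))
  d <- diff(marks)
  sum(sqrt(d[, 1]^2 + d[, 2]^2))
}

#' Subsample then oversample a skeleton path
#'
#' Selects every `s`-th pixel of the path (always retaining the final
#' pixel), then linearly interpolates vertices back into each gap so the
#' polyline has exactly as many vertices as the original path. Full gaps
#' receive `s - 1` interpolated vertices; a trailing partial gap of `r`
#' pixels receives `r - 1`. With `s = 1` the path is returned unchanged.
#' Subsampling followed by interpolation smooths the 8-connected staircase
#' discretization so polyline length approaches the underlying curve's.
#'
#' @param path Numeric matrix of ordered path coordinates (two columns),
#'   consecutive rows 8-adjacent pixels.
#' @param s Sampling factor, a positive integer (default 3).
#' @return Numeric matrix of polyline vertices (possibly subpixel), same
#'   number of rows as `path`, with attribute `s` recording the factor
#'   actually used.
#' @export
subsample_oversample <- function(path, s = 3L) {
  path <- as.matrix(path)
  n <- nrow(path)
  if (n < 2) stop("path must have at least 2 pixels")
  s <- as.integer(s)
  if (s < 1) stop("s must be >= 1")
  if (n < s + 1) s <- 1L # too short to subsample; keep pixels as-is
  if (s == 1L) return(structure(path, s = 1L))
  sel <- unique(c(seq(1L, n, by = s), n))
  out <- matrix(NA_real_, n, 2)
  pos <- 1L
  for (i in seq_len(length(sel) - 1L)) {
    a <- path[sel[i], ]; b <- path[sel[i + 1L], ]
    g <- sel[i + 1L] - sel[i] # gap in original pixels
    f <- seq(0, 1, length.out = g + 1L)[-(g + 1L)]
    out[pos:(pos + g - 1L), ] <- cbind(a[1] + f * (b[1] - a[1]),
                                       a[2] + f * (b[2] - a[2]))
    pos <- pos + g
  }
  out[n, ] <- path[n, ]
  structure(out, s = s)
}

# matrix shift by (dr, dc) with zero fill, for thinning neighborhoods
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 - dr):min(nr, nr - dr)
  cs <- max(1, 1 - dc):min(nc, nc - dc)
  out[rs, cs] <- m[rs + dr, cs + dc]
  out
}

#' Skeletonize a binary region
#'
#' Iterative two-subiteration thinning (Guo-Hall) to a one-pixel-wide,
#' 8-connected, topology-preserving centerline. Guo-Hall thinning is used
#' rather than Zhang-Suen because the latter progressively erodes the
#' open ends of oblique strokes, truncating lamella fragments. Deterministic
#' for fixed input.
#'
#' @param mask Logical or 0/1 matrix; `TRUE`/1 is foreground.
#' @return Logical matrix of the same shape containing the skeleton.
#' @export
skeletonize <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    changed <- FALSE
    for (sub in 0:1) {
      # neighbors: p2 = N, then clockwise p3..p9
      p2 <- shift_mat(m, -1L,  0L); p3 <- shift_mat(m, -1L,  1L)
      p4 <- shift_mat(m,  0L,  1L); p5 <- shift_mat(m,  1L,  1L)
      p6 <- shift_mat(m,  1L,  0L); p7 <- shift_mat(m,  1L, -1L)
      p8 <- shift_mat(m,  0L, -1L); p9 <- shift_mat(m, -1L, -1L)
      C <- (1L - p2) * pmax(p3, p4) + (1L - p4) * pmax(p5, p6) +
           (1L - p6) * pmax(p7, p8) + (1L - p8) * pmax(p9, p2)
      N1 <- pmax(p9, p2) + pmax(p3, p4) + pmax(p5, p6) + pmax(p7, p8)
      N2 <- pmax(p2, p3) + pmax(p4, p5) + pmax(p6, p7) + pmax(p8, p9)
      N <- pmin(N1, N2)
      O <- if (sub == 0L) pmax(p6, p7, 1L - p9) * p8 else
        pmax(p2, p3, 1L - p5) * p4
      del <- m == 1L & C == 1L & N >= 2L & N <= 3L & O == 0L
      if (any(del)) {
        m[del] <- 0L
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  m == 1L
}

# --- skeleton pixel graph helpers ------------------------------------------

# adjacency (edge list) of skeleton pixels under 8-connectivity;
# pixels is a 2-column (row, col) matrix ordered lexicographically
skeleton_edges <- function(pixels) {
  key <- pixels[, 1] * 1e6 + pixels[, 2]
  idx <- seq_len(nrow(pixels))
  offs <- rbind(c(0, 1), c(1, -1), c(1, 0), c(1, 1)) # forward half-plane
  from <- integer(0); to <- integer(0)
  for (k in seq_len(nrow(offs))) {
    nb <- match(key + offs[k, 1] * 1e6 + offs[k, 2], key)
    hit <- !is.na(nb)
    from <- c(from, idx[hit]); to <- c(to, nb[hit])
  }
  cbind(from, to)
}

# exact longest simple path by DFS over all start vertices; adj is a list
# of integer neighbor vectors (lexicographically ordered). Returns vertex
# index sequence of the first maximal path found scanning starts in order.
exact_longest_path <- function(adj) {
  n <- length(adj)
  best <- integer(0)
  visited <- logical(n)
  path <- integer(n)
  dfs <- function(v, depth) {
    path[depth] <<- v
    visited[v] <<- TRUE
    extended <- FALSE
    for (w in adj[[v]]) {
      if (!visited[w]) {
        extended <- TRUE
        dfs(w, depth + 1L)
      }
    }
    if (!extended && depth > length(best)) best <<- path[seq_len(depth)]
    visited[v] <<- FALSE
  }
  for (v in seq_len(n)) dfs(v, 1L)
  best
}

# farthest vertex from src by BFS (unweighted); ties -> smallest index
bfs_farthest <- function(g, src) {
  d <- as.vector(igraph::distances(g, v = src))
  which.max(d) # first max = smallest index
}

#' Longest path of a skeleton
#'
#' Extracts the maximum-length simple path (in vertex count) from the
#' pixel-adjacency graph of a skeleton, discarding side branches. Exact by
#' exhaustive search on small graphs; on larger graphs, trees (the typical
#' case for thinned curvilinear strokes) are solved exactly by a
#' double-sweep farthest-pair search, and cyclic skeletons are opened at
#' the lexicographically smallest pixel first. Ties are broken toward the
#' lexicographically smallest start pixel.
#'
#' @param skeleton Logical matrix from [skeletonize()], or a 2-column
#'   (row, col) matrix of skeleton pixel coordinates.
#' @param exact_limit Maximum pixel count for exhaustive search on
#'   non-tree graphs.
#' @return A 2-column (row, col) matrix of ordered path pixels, class
#'   `skeleton_path`; consecutive rows are 8-neighbors.
#' @export
longest_path <- function(skeleton, exact_limit = 40L) {
  if (is.logical(skeleton) || (is.matrix(skeleton) && ncol(skeleton) > 2)) {
    pixels <- which(skeleton != 0, arr.ind = TRUE)
  } else {
    pixels <- as.matrix(skeleton)
  }
  if (nrow(pixels) < 2) stop("skeleton must contain at least 2 pixels")
  ord <- order(pixels[, 1], pixels[, 2])
  pixels <- pixels[ord, , drop = FALSE]
  n <- nrow(pixels)
  el <- skeleton_edges(pixels)
  if (nrow(el) == 0) stop("skeleton pixels are not connected")
  is_tree <- nrow(el) == n - 1L
  if (!is_tree && n <= exact_limit) {
    adj <- lapply(seq_len(n), function(i) {
      nb <- sort(c(el[el[, 1] == i, 2], el[el[, 2] == i, 1]))
      nb
    })
    path_idx <- exact_longest_path(adj)
  } else {
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (!is_tree) {
      deg <- igraph::degree(g)
      if (all(deg >= 2)) {
        # pure cycle (or cycle with chords): open at the lexicographically
        # smallest pixel by removing its edge to its smallest neighbor
        nb1 <- min(c(el[el[, 1] == 1L, 2], el[el[, 2] == 1L, 1]))
        g <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(1L, nb1)))
      }
    }
    u <- bfs_farthest(g, 1L)
    v <- bfs_farthest(g, u)
    sp <- igraph::shortest_paths(g, from = u, to = v)$vpath[[1]]
    path_idx <- as.integer(sp)
  }
  # orient so the start pixel is lexicographically smallest of the two ends
  a <- path_idx[1]; b <- path_idx[length(path_idx)]
  if (b < a) path_idx <- rev(path_idx)
  structure(pixels[path_idx, , drop = FALSE], class = "skeleton_path")
}

#' Measure one fragment's waviness
#'
#' Skeletonizes the fragment, keeps the longest skeleton path, applies the
#' subsample/oversample scheme, and computes the geodesic-like length,
#' the Euclidean-like length, and their ratio r_ec. A perfectly straight
#' fragment yields r_ec = 1; waviness pushes r_ec below 1.
#'
#' @param region A `fragment_region` from [label_fragments()].
#' @param s Sampling factor for [subsample_oversample()] (default 3).
#' @param step Geodesic step for [euclid_like_length()] (default 100).
#' @return A one-row data frame with `slice_index`, `region_id`, `area`,
#'   `geodesic_like`, `euclid_like`, `r_ec`, `s`, or `NULL` if the
#'   fragment degenerates (skeleton under 2 pixels or zero length).
#' @export
measure_fragment <- function(region, s = 3L, step = 100) {
  stopifnot(inherits(region, "fragment_region"))
  mask <- region_mask(region, pad = 1L)
  skel <- skeletonize(mask)
  if (sum(skel) < 2) {
    message(sprintf("region %d on slice %d: skeleton degenerate, skipped",
                    region$region_id, region$slice_index))
    return(NULL)
  }
  path <- longest_path(skel)
  if (nrow(path) < 2) return(NULL)
  poly <- subsample_oversample(unclass(path), s)
  geo <- geodesic_like_length(poly)
  if (geo <= 0) {
    message(sprintf("region %d on slice %d: zero-length path, skipped",
                    region$region_id, region$slice_index))
    return(NULL)
  }
  euc <- euclid_like_length(poly, step = step)
  data.frame(slice_index = region$slice_index, region_id = region$region_id,
             area = region$area, geodesic_like = geo, euclid_like = euc,
             r_ec = euc / geo, s = attr(poly, "s"))
}

#' Measure all retained fragments of one slice
#'
#' Runs threshold, labeling, filtering (optional) and fragment measurement
#' on one grayscale slice.
#'
#' @param image Numeric matrix, one grayscale slice.
#' @param params [extraction_params()].
#' @param s,step See [measure_fragment()].
#' @param slice_index Index recorded in the output rows.
#' @param apply_filters If `FALSE`, all labeled regions of at least
#'   `params$min_area` pixels are measured without the occupancy and
#'   solidity filters (useful for geometry validation on clean renders).
#' @param binary_input If `TRUE`, `image` is treated as an already
#'   segmented binary mask and thresholding is skipped.
#' @return A data frame of fragment records (possibly 0 rows) with a
#'   `rejections` attribute (per-rule counts from [filter_fragments()]).
#' @export
measure_slice <- function(image, params = extraction_params(), s = 3L,
                          step = 100, slice_index = 1L,
                          apply_filters = TRUE, binary_input = FALSE) {
  binary <- if (binary_input) image != 0 else threshold_slice(image, params)
  regions <- label_fragments(binary, params, slice_index = slice_index)
  if (apply_filters) {
    regions <- filter_fragments(regions, params)
    rej <- attr(regions, "rejections")
  } else {
    regions <- Filter(function(r) r$area >= params$min_area, regions)
    rej <- c(area = 0L, bbox_occupancy = 0L, solidity = 0L)
  }
  rows <- lapply(regions, measure_fragment, s = s, step = step)
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(slice_index = integer(0), region_id = integer(0),
                      area = numeric(0), geodesic_like = numeric(0),
                      euclid_like = numeric(0), r_ec = numeric(0),
                      s = integer(0))
  }
  attr(out, "rejections") <- rej
  out
}
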