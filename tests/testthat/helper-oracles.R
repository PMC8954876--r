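# Independent brute-force oracles used to cross-check the implementation.

# connected-component count by queue-based flood fill
oracle_flood_fill_count <- function(binary, connectivity = 8L) {
  nr <- nrow(binary); nc <- ncol(binary)
  seen <- matrix(FALSE, nr, nc)
  offs <- rbind(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))
  if (connectivity == 8L)
    offs <- rbind(offs, c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  count <- 0L
  for (r0 in seq_len(nr)) for (c0 in seq_len(nc)) {
    if (binary[r0, c0] && !seen[r0, c0]) {
      count <- count + 1L
      queue <- list(c(r0, c0)); seen[r0, c0] <- TRUE
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (k in seq_len(nrow(offs))) {
          r <- p[1] + offs[k, 1]; c <- p[2] + offs[k, 2]
          if (r >= 1 && r <= nr && c >= 1 && c <= nc &&
              binary[r, c] && !seen[r, c]) {
            seen[r, c] <- TRUE
            queue[[length(queue) + 1L]] <- c(r, c)
          }
        }
      }
    }
  }
  count
}

# Otsu bin by explicit scan over all 256 candidate thresholds, recomputing
# class weights and means from scratch at each candidate
oracle_otsu_bin <- function(image) {
  r <- range(image)
  x <- as.integer(pmin(floor((image - r[1]) / (r[2] - r[1]) * 256), 255))
  h <- tabulate(x + 1L, 256L)
  best <- -Inf; best_t <- 0L
  for (t in 0:255) {
    c0 <- h[seq_len(t + 1L)]; c1 <- h[-seq_len(t + 1L)]
    w0 <- sum(c0); w1 <- sum(c1)
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(c0 * (0:t)) / w0
    mu1 <- sum(c1 * ((t + 1L):255)) / w1
    sb <- (w0 / sum(h)) * (w1 / sum(h)) * (mu0 - mu1)^2
    if (sb > best) { best <- sb; best_t <- t }
  }
  best_t
}

# length (vertex count) of the longest simple path by full recursive
# enumeration over the 8-adjacency graph of the given pixel set
oracle_longest_path_len <- function(pixels) {
  n <- nrow(pixels)
  adj <- lapply(seq_len(n), function(i) {
    d <- abs(sweep(pixels, 2, pixels[i, ]))
    which(pmax(d[, 1], d[, 2]) == 1L)
  })
  best <- 0L
  recurse <- function(v, visited, len) {
    if (len > best) best <<- len
    for (w in adj[[v]]) if (!visited[w]) {
      visited[w] <- TRUE
      recurse(w, visited, len + 1L)
      visited[w] <- FALSE
    }
  }
  for (v in seq_len(n)) {
    visited <- rep(FALSE, n); visited[v] <- TRUE
    recurse(v, visited, 1L)
  }
  best
}

# sinusoid arc length by midpoint Riemann sum (independent of integrate())
oracle_sinusoid_arc <- function(amplitude, wavelength, baseline, phase = 0,
                                n = 2e5) {
  k <- 2 * pi / wavelength
  u <- (seq_len(n) - 0.5) * baseline / n
  sum(sqrt(1 + (amplitude * k * cos(k * u + phase))^2)) * baseline / n
}

# random connected pixel mask of npix pixels grown inside an nr x nc grid
random_connected_mask <- function(npix, nr = 6L, nc = 6L) {
  px <- matrix(c(sample(nr, 1), sample(nc, 1)), 1)
  while (nrow(px) < npix) {
    base <- px[sample(nrow(px), 1), ]
    cand <- base + c(sample(-1:1, 1), sample(-1:1, 1))
    if (cand[1] < 1 || cand[1] > nr || cand[2] < 1 || cand[2] > nc) next
    if (!any(px[, 1] == cand[1] & px[, 2] == cand[2]))
      px <- rbind(px, cand)
  }
  px[order(px[, 1], px[, 2]), , drop = FALSE]
}

# all connected pixel subsets of a small grid (for exhaustive oracle runs)
all_connected_subsets <- function(nr = 3L, nc = 3L, min_size = 2L) {
  cells <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  n <- nrow(cells)
  out <- list()
  for (code in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(code, 2^(seq_len(n) - 1)) > 0)
    if (length(idx) < min_size) next
    px <- as.matrix(cells[idx, , drop = FALSE])
    bin <- matrix(FALSE, nr, nc)
    bin[px] <- TRUE
    if (oracle_flood_fill_count(bin, 8L) == 1L)
      out[[length(out) + 1L]] <- px
  }
  out
}
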