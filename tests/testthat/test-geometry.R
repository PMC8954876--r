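test_that("geodesic-like length sums consecutive chords", {
  expect_equal(geodesic_like_length(rbind(c(0, 0), c(3, 4))), 5)
  # duplicate consecutive vertices contribute nothing
  expect_equal(geodesic_like_length(rbind(c(0, 0), c(3, 4), c(3, 4))), 5)
  # dense semicircle sampling approaches pi R
  th <- seq(0, pi, length.out = 1000)
  semi <- cbind(100 * cos(th), 100 * sin(th))
  expect_lt(abs(geodesic_like_length(semi) - pi * 100) / (pi * 100), 1e-4)
  expect_error(geodesic_like_length(rbind(c(0, 0))), "2 vertices")
})

test_that("euclid-like length follows the step-chord rule with fallbacks", {
  # collinear vertices: chords along a line always sum to the span
  line <- cbind(seq(0, 300, by = 0.5), 0)
  for (st in c(40, 100, 500)) {
    expect_equal(euclid_like_length(line, step = st), 300, tolerance = 1e-9)
  }

  # semicircle R = 100, L = pi R: marks at arc 0, 100, 200, 300, L;
  # closed-form chord between marks a, b is 2 R sin((b - a) / (2 R))
  th <- seq(0, pi, length.out = 20000)
  semi <- cbind(100 * cos(th), 100 * sin(th))
  marks <- c(0, 100, 200, 300, pi * 100)
  oracle <- sum(2 * 100 * sin(diff(marks) / 200))
  expect_equal(euclid_like_length(semi, step = 100), oracle, tolerance = 1e-4)

  # short line: single first-to-last chord
  short <- cbind(seq(0, 60, by = 0.5), sin(seq(0, 60, by = 0.5) / 5) * 10)
  cum <- c(0, cumsum(sqrt(rowSums(diff(short)^2))))
  expect_lt(cum[length(cum)], 100)
  expect_equal(euclid_like_length(short, step = 100),
               sqrt(sum((short[nrow(short), ] - short[1, ])^2)))

  # mid-length polyline: two chords through the half-geodesic vertex
  u <- seq(0, 140, by = 0.25)
  poly <- cbind(u, 15 * sin(2 * pi * u / 70))
  cum <- c(0, cumsum(sqrt(rowSums(diff(poly)^2))))
  L <- cum[length(cum)]
  expect_true(L >= 100 && L < 200)
  mid <- which.min(abs(cum - L / 2))
  oracle2 <- sqrt(sum((poly[mid, ] - poly[1, ])^2)) +
    sqrt(sum((poly[nrow(poly), ] - poly[mid, ])^2))
  expect_equal(euclid_like_length(poly, step = 100), oracle2)

  # the chord sum can never exceed the geodesic length
  expect_lte(euclid_like_length(poly, step = 100),
             geodesic_like_length(poly) + 1e-9)
})

test_that("subsample/oversample preserves vertex count and smooths staircases", {
  line <- cbind(1:10, 5)
  out <- subsample_oversample(line, 3)
  expect_equal(nrow(out), 10)
  expect_true(all(out[, 2] == 5))
  expect_equal(out[, 1], as.numeric(1:10), tolerance = 1e-12)

  expect_identical(subsample_oversample(line, 1), structure(line, s = 1L))

  # 20-pixel staircase: subsampling shortens the measured length
  stair <- cbind(cumsum(rep(c(1, 0), 10)), cumsum(rep(c(0, 1), 10)))
  raw <- geodesic_like_length(stair)
  smoothed <- geodesic_like_length(subsample_oversample(stair, 3))
  expect_lt(smoothed, raw)

  # vertex count invariant across trailing-gap configurations
  for (n in c(7, 10, 11, 23)) for (s in 1:4) {
    p <- cbind(seq_len(n), seq_len(n) %% 3)
    expect_equal(nrow(subsample_oversample(p, s)), n)
  }

  # path shorter than s + 1 falls back to s = 1
  tiny <- cbind(1:3, 1)
  expect_identical(attr(subsample_oversample(tiny, 5), "s"), 1L)
})

test_that("skeletonization thins bars to centerlines and keeps arc length", {
  bar <- matrix(FALSE, 9, 104)
  bar[4:6, 3:102] <- TRUE
  sk <- skeletonize(bar)
  px <- which(sk, arr.ind = TRUE)
  expect_true(all(px[, 1] == 5))
  expect_lte(abs(min(px[, 2]) - 3), 2)
  expect_lte(abs(max(px[, 2]) - 102), 2)

  # rotationally symmetric blob collapses to a near-point skeleton
  disc <- matrix(FALSE, 25, 25)
  ctr <- expand.grid(r = 1:25, c = 1:25)
  disc[as.matrix(ctr[(ctr$r - 13)^2 + (ctr$c - 13)^2 <= 100, ])] <- TRUE
  expect_lte(sum(skeletonize(disc)), 10)

  # rendered sinusoid stroke: s-smoothed skeleton length tracks true arc
  sp <- curve_spec("sinusoid", amplitude = 15, wavelength = 120,
                   baseline_length = 300, origin = c(20, 60))
  sl <- render_slice(list(sp), render_spec(image_shape = c(120L, 340L),
                                           noise_sd = 0))
  reg <- label_fragments(threshold_slice(sl$image))[[1]]
  path <- longest_path(skeletonize(region_mask(reg, pad = 1L)))
  geo <- geodesic_like_length(subsample_oversample(unclass(path), 3))
  expect_lt(abs(geo - sl$truth$arc_length) / sl$truth$arc_length, 0.02)
})

test_that("longest_path extracts the diameter of branched skeletons", {
  # straight path graph: the line itself
  line_px <- cbind(5, 1:50)
  p <- longest_path(line_px)
  expect_equal(nrow(p), 50)
  expect_equal(p[1, 2], 1)

  # Y: arms of 40, 30, 20 pixels from one junction -> 71-vertex path
  junction <- c(50, 50)
  arm <- function(dr, dc, len)
    cbind(junction[1] + dr * seq_len(len), junction[2] + dc * seq_len(len))
  y_px <- rbind(junction, arm(-1, 0, 40), arm(1, -1, 30), arm(1, 1, 20))
  p2 <- longest_path(y_px)
  expect_equal(nrow(p2), 71)
  expect_equal(nrow(p2), oracle_longest_path_len(y_px))

  # equal-armed T: deterministic result, stable across calls
  t_px <- rbind(c(10, 10), cbind(10, 11:20), cbind(10, 1:9),
                cbind(11:20, 10))
  r1 <- longest_path(t_px)
  r2 <- longest_path(t_px)
  expect_identical(r1, r2)

  # a cycle is opened rather than an error raised
  ring <- rbind(cbind(1, 1:5), cbind(2:5, 5), cbind(5, 4:1), cbind(4:2, 1))
  p3 <- longest_path(ring)
  expect_gte(nrow(p3), nrow(ring) - 2)

  expect_error(longest_path(cbind(1, 1)), "2 pixels")
})

test_that("longest_path matches exhaustive enumeration on small skeletons", {
  # every connected subset of a 3x3 grid
  for (px in all_connected_subsets(3L, 3L)) {
    expect_equal(nrow(longest_path(px)), oracle_longest_path_len(px))
  }
  # random connected masks up to 15 pixels in larger grids
  set.seed(17)
  for (i in 1:60) {
    px <- random_connected_mask(sample(3:15, 1), 6L, 6L)
    expect_equal(nrow(longest_path(px)), oracle_longest_path_len(px))
  }
})

test_that("measured fragments keep r_ec in (0, 1] and rotation-stable", {
  rs <- render_spec(image_shape = c(420L, 420L), noise_sd = 0)
  recs <- vapply(c(0, pi / 6, pi / 4), function(ori) {
    sp <- curve_spec("sinusoid", amplitude = 15, wavelength = 120,
                     baseline_length = 260, orientation = ori,
                     origin = c(40, 60))
    sl <- render_slice(list(sp), rs)
    m <- measure_slice(sl$image, apply_filters = FALSE)
    expect_equal(nrow(m), 1)
    m$r_ec
  }, numeric(1))
  expect_true(all(recs > 0 & recs <= 1 + 1e-9))
  expect_lt(max(recs) - min(recs), 0.02)

  # randomized noisy slices keep the ratio bound
  set.seed(23)
  for (i in 1:5) {
    sp <- curve_spec("sinusoid", amplitude = runif(1, 5, 20),
                     wavelength = runif(1, 80, 150),
                     baseline_length = 300, phase = runif(1, 0, 2 * pi),
                     origin = c(30, 60))
    sl <- render_slice(list(sp), render_spec(image_shape = c(120L, 380L),
                                             noise_sd = 10, seed = 100 + i))
    m <- measure_slice(sl$image, apply_filters = FALSE)
    expect_true(all(m$r_ec > 0 & m$r_ec <= 1 + 1e-9))
    expect_true(all(m$euclid_like <= m$geodesic_like + 1e-9))
  }
})
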