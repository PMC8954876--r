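test_that("thresholding separates a clean bimodal image", {
  img <- matrix(50, 40, 40)
  img[15:25, 5:35] <- 200
  p1 <- extraction_params(otsu_factor = 1)
  bin <- threshold_slice(img, p1)
  expect_identical(bin, img == 200)
})

test_that("otsu_threshold agrees with a 256-candidate brute-force scan", {
  set.seed(11)
  for (i in 1:30) {
    img <- switch(1 + i %% 3,
      matrix(rnorm(1024, 50, 10), 32) + (runif(1024) < 0.2) * rnorm(1024, 150, 20),
      matrix(runif(1024, 0, 255), 32),
      matrix(rgamma(1024, shape = 2, scale = 30), 32))
    expect_identical(attr(otsu_threshold(img), "bin"), oracle_otsu_bin(img))
  }
})

test_that("degenerate threshold inputs are handled", {
  expect_error(otsu_threshold(matrix(7, 5, 5)), "constant")
  # bright class too close to the bulk: scaled threshold exceeds the max
  img <- matrix(rnorm(10000, 100, 2), 100)
  expect_warning(bin <- threshold_slice(img, extraction_params(otsu_factor = 3)),
                 "maximum")
  expect_false(any(bin))
})

test_that("labeling resolves components under the configured connectivity", {
  bin <- matrix(FALSE, 12, 12)
  bin[2:4, 2:4] <- TRUE
  bin[8:10, 8:10] <- TRUE
  regs <- label_fragments(bin)
  expect_length(regs, 2)
  for (r in regs) {
    expect_equal(r$area, 9)
    expect_equal(r$bbox_occupancy, 1.0)
    expect_equal(r$solidity, 1.0)
  }

  diag_mask <- matrix(FALSE, 6, 6)
  diag_mask[cbind(1:5, 1:5)] <- TRUE
  expect_length(label_fragments(diag_mask, extraction_params(connectivity = 8)), 1)
  expect_length(label_fragments(diag_mask, extraction_params(connectivity = 4)), 5)

  expect_length(label_fragments(matrix(FALSE, 4, 4)), 0)
})

test_that("labeling matches flood-fill component counts on random binaries", {
  set.seed(99)
  for (i in 1:12) {
    bin <- matrix(runif(64 * 64) < runif(1, 0.2, 0.6), 64)
    for (conn in c(4L, 8L)) {
      n <- length(label_fragments(bin, extraction_params(connectivity = conn)))
      expect_identical(n, oracle_flood_fill_count(bin, conn))
    }
  }
})

test_that("solidity counts hull pixels inclusively of the boundary", {
  # L-shape: hull is the right triangle; (2,2) lies on the hypotenuse
  bin <- matrix(FALSE, 4, 4)
  bin[cbind(c(1, 2, 3, 3, 3), c(1, 1, 1, 2, 3))] <- TRUE
  r <- label_fragments(bin)[[1]]
  expect_equal(r$area, 5)
  expect_equal(r$solidity, 5 / 6)
})

test_that("filter rules apply the stated inequalities and precedence", {
  mk <- function(bin) label_fragments(bin)

  square <- matrix(FALSE, 30, 30); square[5:24, 5:24] <- TRUE
  out <- filter_fragments(mk(square))
  expect_length(out, 0)
  expect_identical(attr(out, "rejected")$rule, "bbox_occupancy")

  speck <- matrix(FALSE, 30, 30); speck[10:14, 10:19] <- TRUE # 50 px
  out2 <- filter_fragments(mk(speck))
  expect_identical(attr(out2, "rejected")$rule, "area")

  # thin wavy stroke: all descriptors verified by direct counting
  stroke <- matrix(FALSE, 60, 130)
  cols <- 5:125
  rows <- round(30 + 20 * sin(2 * pi * (cols - 5) / 80))
  for (dr in 0:2) stroke[cbind(rows + dr, cols)] <- TRUE
  r <- mk(stroke)[[1]]
  expect_equal(r$area, sum(stroke))
  expect_equal(r$bbox_occupancy,
               sum(stroke) / (diff(range(rows)) + 3) / (diff(range(cols)) + 1))
  out3 <- filter_fragments(mk(stroke))
  expect_length(out3, 1)

  # exact boundary: area equal to min_area passes rule 1 ("above or
  # equal"); a perfectly straight diagonal then fails only the strict
  # solidity rule
  bar <- matrix(FALSE, 105, 105); bar[cbind(3:102, 3:102)] <- TRUE
  r_bar <- mk(bar)[[1]]
  expect_equal(r_bar$area, 100)
  expect_lt(r_bar$bbox_occupancy, 0.15)
  kept <- filter_fragments(list(r_bar))
  expect_length(kept, 0)
  expect_identical(attr(kept, "rejected")$rule, "solidity")
})

test_that("filtering is idempotent and kept regions satisfy all predicates", {
  set.seed(3)
  params <- extraction_params()
  for (i in 1:5) {
    bin <- matrix(runif(96 * 96) < 0.35, 96)
    regs <- label_fragments(bin, params)
    kept <- filter_fragments(regs, params)
    again <- filter_fragments(kept, params)
    expect_identical(`attributes<-`(again, NULL), `attributes<-`(kept, NULL))
    expect_identical(sum(attr(again, "rejections")), 0L)
    for (r in kept) {
      expect_gte(r$area, params$min_area)
      expect_lt(r$bbox_occupancy, params$max_bbox_occupancy)
      expect_lt(r$solidity, params$max_solidity)
    }
  }
})
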