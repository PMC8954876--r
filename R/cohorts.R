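#' Cohort specification for synthetic stacks
#'
#' Describes one group of synthetic image stacks. The cohort effect is
#' injected through the amplitude distribution only: wavier (higher
#' amplitude) lamellae give lower r_ec. Wavelength is held common across
#' groups by default, the simplest mechanism for a "smoother vs wavier"
#' contrast.
#'
#' @param group_label `"control"` or `"diabetic"`.
#' @param n_stacks Number of stacks in the group.
#' @param slices_per_stack,curves_per_slice Counts per stack / per slice.
#' @param amplitude_distribution `(mean, sd)` of curve amplitudes, pixels.
#' @param wavelength_distribution `(mean, sd)` of wavelengths, pixels.
#' @param region_label Anatomical region per stack (`"arch"`,
#'   `"thoracic"`, `"abdominal"`); a single value or vector recycled to
#'   `n_stacks`. Default cycles through the three regions.
#' @param seed Integer cohort seed; per-stack seeds derive from it
#'   deterministically.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_label = c("control", "diabetic"),
                        n_stacks = 10L, slices_per_stack = 2L,
                        curves_per_slice = 5L,
                        amplitude_distribution = c(18, 2),
                        wavelength_distribution = c(90, 0),
                        region_label = c("arch", "thoracic", "abdominal"),
                        seed = 1L) {
  group_label <- match.arg(group_label)
  if (any(c(n_stacks, slices_per_stack, curves_per_slice) < 1))
    stop("all counts must be >= 1")
  if (amplitude_distribution[2] < 0 || wavelength_distribution[2] < 0)
    stop("distribution sds must be >= 0")
  structure(list(group_label = group_label, n_stacks = as.integer(n_stacks),
                 slices_per_stack = as.integer(slices_per_stack),
                 curves_per_slice = as.integer(curves_per_slice),
                 amplitude_distribution = amplitude_distribution,
                 wavelength_distribution = wavelength_distribution,
                 region_label = rep(region_label, length.out = n_stacks),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Construct an image stack
#'
#' @param slices List of numeric matrices sharing one shape.
#' @param pixel_size Pixel size in micrometres per pixel.
#' @param stack_id Identifier string.
#' @param group_label,region_label Optional cohort metadata.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(slices, pixel_size = 0.65, stack_id = "stack",
                        group_label = NA_character_,
                        region_label = NA_character_) {
  if (!length(slices)) stop("a stack needs at least one slice")
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("all slices must share one shape")
  if (pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(slices = slices, pixel_size = pixel_size,
                 stack_id = stack_id, group_label = group_label,
                 region_label = region_label),
            class = "image_stack")
}

# draw the curve layout of one slice: horizontal bands, one curve each,
# with truncated-normal amplitude/wavelength and random phase
draw_slice_curves <- function(cohort, shape, thickness) {
  n <- cohort$curves_per_slice
  margin <- ceiling(thickness) + 2
  band_h <- (shape[1] - 2 * margin) / n
  lapply(seq_len(n), function(i) {
    amp_max <- band_h / 2 - thickness - 1
    amp <- min(max(stats::rnorm(1, cohort$amplitude_distribution[1],
                                cohort$amplitude_distribution[2]), 0), amp_max)
    wl <- max(stats::rnorm(1, cohort$wavelength_distribution[1],
                           cohort$wavelength_distribution[2]), 20)
    phase <- stats::runif(1, 0, 2 * pi)
    baseline <- shape[2] - 2 * margin - 2
    y0 <- margin + (i - 0.5) * band_h + stats::runif(1, -1, 1)
    curve_spec(kind = if (amp == 0) "straight" else "sinusoid",
               amplitude = amp, wavelength = wl, phase = phase,
               baseline_length = baseline, orientation = 0,
               origin = c(margin + 1, y0))
  })
}

#' Generate two synthetic cohorts with ground truth
#'
#' Builds seeded image stacks for a control and a diabetic cohort plus a
#' per-curve ground-truth table. Per-stack seeds are derived
#' deterministically from each cohort seed, so identical specs give
#' byte-identical output. If `out_dir` is given, each stack is written as
#' a multi-page TIFF and the truth table as `truth.csv`.
#'
#' @param control,diabetic [cohort_spec()] objects.
#' @param render A [render_spec()]; its `seed` field is ignored (seeding
#'   is driven by the cohort seeds).
#' @param out_dir Optional output directory.
#' @param compute_truth If `FALSE`, skip the (comparatively costly)
#'   analytic truth table; `truth` is then `NULL`.
#' @return A list with `stacks` (list of [image_stack()]) and `truth`
#'   (data frame keyed by group, stack, slice, curve).
#' @export
generate_cohorts <- function(control, diabetic, render = render_spec(),
                             out_dir = NULL, compute_truth = TRUE) {
  stopifnot(inherits(control, "cohort_spec"), inherits(diabetic, "cohort_spec"))
  stacks <- list()
  truth <- list()
  for (cohort in list(control, diabetic)) {
    for (k in seq_len(cohort$n_stacks)) {
      stack_seed <- (cohort$seed + 99991L * k) %% .Machine$integer.max
      stack_id <- sprintf("%s_%02d", cohort$group_label, k)
      slices <- vector("list", cohort$slices_per_stack)
      for (j in seq_len(cohort$slices_per_stack)) {
        sl <- withr::with_seed(stack_seed + j, {
          curves <- draw_slice_curves(cohort, render$image_shape,
                                      render$stroke_thickness)
          r <- render
          r$seed <- NULL
          out <- tryCatch(render_slice(curves, r), error = function(e)
            stop(sprintf("stack %s slice %d: %s", stack_id, j,
                         conditionMessage(e)), call. = FALSE))
          if (!compute_truth) out$truth <- out$truth[0, ]
          out
        })
        slices[[j]] <- sl$image
        if (compute_truth && nrow(sl$truth)) {
          sl$truth$group <- cohort$group_label
          sl$truth$stack_id <- stack_id
          sl$truth$slice <- j
          truth[[length(truth) + 1L]] <- sl$truth
        }
      }
      stacks[[stack_id]] <- image_stack(slices, stack_id = stack_id,
                                        group_label = cohort$group_label,
                                        region_label = cohort$region_label[k])
    }
  }
  truth_df <- if (compute_truth && length(truth)) {
    df <- do.call(rbind, truth)
    df[, c("group", "stack_id", "slice", "curve", "arc_length",
           "chord_length", "true_rec_step", "true_rec_chord")]
  } else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (st in stacks)
      write_stack(st, file.path(out_dir, paste0(st$stack_id, ".tif")))
    if (!is.null(truth_df))
      utils::write.csv(truth_df, file.path(out_dir, "truth.csv"),
                       row.names = FALSE)
    meta <- data.frame(
      stack_id = vapply(stacks, `[[`, "", "stack_id"),
      group_label = vapply(stacks, `[[`, "", "group_label"),
      region_label = vapply(stacks, `[[`, "", "region_label"))
    utils::write.csv(meta, file.path(out_dir, "stacks.csv"),
                     row.names = FALSE)
  }
  list(stacks = stacks, truth = truth_df)
}

#' Write an image stack as a multi-page 8-bit grayscale TIFF
#'
#' @param stack An [image_stack()]; intensities on a 0-255 scale.
#' @param path Output file path.
#' @export
write_stack <- function(stack, path) {
  pages <- lapply(stack$slices, function(m) {
    m[m < 0] <- 0; m[m > 255] <- 255
    m / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Read a multi-page grayscale TIFF as an image stack
#'
#' Intensities are rescaled to the 0-255 working range; multi-channel
#' pages are averaged to one channel.
#'
#' @param path TIFF file path.
#' @inheritParams image_stack
#' @return An [image_stack()].
#' @export
read_stack <- function(path, pixel_size = 0.65,
                       stack_id = tools::file_path_sans_ext(basename(path)),
                       group_label = NA_character_,
                       region_label = NA_character_) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  slices <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- apply(p, c(1, 2), mean)
    p * 255
  })
  image_stack(slices, pixel_size = pixel_size, stack_id = stack_id,
              group_label = group_label, region_label = region_label)
}
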