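#' Measure all fragments of one stack
#'
#' Runs extraction and waviness measurement over the slices of a stack.
#'
#' @param stack An [image_stack()].
#' @param params [extraction_params()].
#' @param s,step See [measure_fragment()].
#' @param slice_range Optional integer vector `(start, end)` or
#'   `(start, end, stride)` of 1-based slice indices to process.
#' @param apply_filters,binary_input Passed to [measure_slice()].
#' @param verbose Log progress every 100 slices.
#' @return Data frame of fragment records with a `stack_id` column and a
#'   `rejections` attribute (summed per-rule counts).
#' @export
measure_stack <- function(stack, params = extraction_params(), s = 3L,
                          step = 100, slice_range = NULL,
                          apply_filters = TRUE, binary_input = FALSE,
                          verbose = FALSE) {
  stopifnot(inherits(stack, "image_stack"))
  idx <- seq_along(stack$slices)
  if (!is.null(slice_range)) {
    stride <- if (length(slice_range) >= 3) slice_range[3] else 1L
    if (slice_range[1] < 1 || slice_range[2] > length(stack$slices))
      stop("slice_range outside stack bounds")
    idx <- seq(slice_range[1], slice_range[2], by = stride)
  }
  rej <- c(area = 0L, bbox_occupancy = 0L, solidity = 0L)
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    df <- measure_slice(stack$slices[[idx[k]]], params = params, s = s,
                        step = step, slice_index = idx[k],
                        apply_filters = apply_filters,
                        binary_input = binary_input)
    rej <- rej + attr(df, "rejections")
    rows[[k]] <- df
    if (verbose && k %% 100 == 0)
      message(sprintf("stack %s: %d/%d slices", stack$stack_id, k,
                      length(idx)))
  }
  out <- do.call(rbind, rows)
  out <- cbind(stack_id = rep(stack$stack_id, nrow(out)), out)
  attr(out, "rejections") <- rej
  out
}

#' Run the measurement pipeline over many stacks
#'
#' Processes a set of stacks (in memory, or a directory of multi-page
#' TIFFs with an optional `stacks.csv` metadata file) through fragment
#' extraction and waviness geometry. When `out_dir` is given, writes
#' `measurements.csv` (one row per fragment:
#' `stack_id,slice_index,region_id,area,geodesic_like,euclid_like,r_ec,s`)
#' and `manifest.json` recording all parameters and per-stack
#' kept/rejected counts, so a run can be reproduced from the manifest
#' alone.
#'
#' @param stacks List of [image_stack()] objects, or a directory path
#'   containing `*.tif`.
#' @inheritParams measure_stack
#' @param out_dir Optional output directory.
#' @param seed Seed recorded in the manifest (the measurement itself is
#'   deterministic).
#' @return The measurements data frame (invisibly carries the manifest as
#'   attribute `manifest`).
#' @export
run_measure <- function(stacks, params = extraction_params(), s = 3L,
                        step = 100, slice_range = NULL,
                        apply_filters = TRUE, binary_input = FALSE,
                        out_dir = NULL, seed = NA_integer_,
                        verbose = FALSE) {
  if (is.character(stacks)) {
    dir <- stacks
    files <- sort(list.files(dir, pattern = "\\.tiff?$", full.names = TRUE))
    if (!length(files)) stop(sprintf("no TIFF stacks found in %s", dir))
    meta_path <- file.path(dir, "stacks.csv")
    meta <- if (file.exists(meta_path))
      utils::read.csv(meta_path, stringsAsFactors = FALSE) else NULL
    stacks <- lapply(files, function(f) {
      st <- tryCatch(read_stack(f), error = function(e)
        stop(sprintf("cannot read TIFF %s: %s", f, conditionMessage(e)),
             call. = FALSE))
      if (!is.null(meta)) {
        row <- meta[meta$stack_id == st$stack_id, ]
        if (nrow(row)) {
          st$group_label <- row$group_label[1]
          st$region_label <- row$region_label[1]
        }
      }
      st
    })
  }
  per_stack <- lapply(stacks, measure_stack, params = params, s = s,
                      step = step, slice_range = slice_range,
                      apply_filters = apply_filters,
                      binary_input = binary_input, verbose = verbose)
  rej <- Reduce(`+`, lapply(per_stack, attr, "rejections"))
  measurements <- do.call(rbind, per_stack)
  rownames(measurements) <- NULL
  if (!nrow(measurements))
    warning("pipeline completed with zero kept fragments")
  manifest <- list(
    parameters = unclass(params), s = s, step = step,
    slice_range = slice_range, apply_filters = apply_filters,
    binary_input = binary_input, seed = seed,
    n_stacks = length(stacks), n_fragments = nrow(measurements),
    rejections = as.list(rej),
    version = as.character(utils::packageVersion("lamwave")))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(measurements, file.path(out_dir, "measurements.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  attr(measurements, "manifest") <- manifest
  measurements
}

#' Compare cohorts from measurement and metadata tables
#'
#' Aggregates fragment measurements per stack and runs the two-group
#' comparison for each requested scope. When `out_path` is given, the
#' full report is written as JSON.
#'
#' @param measurements Data frame (or CSV path) with columns `stack_id`
#'   and `r_ec`.
#' @param metadata Data frame (or CSV path) with columns `stack_id`,
#'   `group_label` and optionally `region_label`.
#' @param scopes Character vector of scopes (see [compare_cohorts()]).
#' @param out_path Optional JSON report path.
#' @return Named list of `cohort_comparison` objects, one per scope.
#' @export
run_compare <- function(measurements, metadata,
                        scopes = c("all", "thoracic", "abdominal"),
                        out_path = NULL) {
  if (is.character(measurements))
    measurements <- utils::read.csv(measurements, stringsAsFactors = FALSE)
  if (is.character(metadata))
    metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  need <- setdiff(c("stack_id", "r_ec"), names(measurements))
  if (length(need))
    stop("measurements table lacks columns: ", paste(need, collapse = ", "))
  need <- setdiff(c("stack_id", "group_label"), names(metadata))
  if (length(need))
    stop("metadata table lacks columns: ", paste(need, collapse = ", "))
  if (!nrow(measurements)) stop("measurements table is empty")
  summaries <- summarize_stacks(measurements, metadata)
  report <- lapply(scopes, function(sc) compare_cohorts(summaries, scope = sc))
  names(report) <- scopes
  if (!is.null(out_path)) {
    jsonlite::write_json(lapply(report, unclass), out_path,
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  report
}

#' Box chart of per-stack mean r_ec by group
#'
#' @param summaries Data frame from [summarize_stacks()] with
#'   `group_label` and `mean_rec`.
#' @param path Optional file to save to (via `ggplot2::ggsave`).
#' @return A ggplot object.
#' @export
plot_cohorts <- function(summaries, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  p <- ggplot2::ggplot(summaries,
                       ggplot2::aes(x = group_label, y = mean_rec)) +
    ggplot2::geom_boxplot(width = 0.5) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "per-stack mean r_ec") +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 4, height = 4)
  p
}
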