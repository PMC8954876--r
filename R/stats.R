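#' Per-stack summary of waviness records
#'
#' Aggregates fragment-level r_ec to one mean per stack — the statistical
#' unit of the cohort comparison. Testing on per-stack means (about ten
#' values per group) rather than the many thousands of individual
#' fragments avoids pseudo-replication across correlated fragments of one
#' specimen.
#'
#' @param records Data frame of fragment measurements with columns
#'   `stack_id` and `r_ec` (see [measure_stack()]).
#' @param metadata Optional data frame `stack_id`, `group_label`,
#'   `region_label` to merge in.
#' @return Data frame with one row per stack: `stack_id`, `n_fragments`,
#'   `mean_rec`, `sd_rec` (sample sd; 0 with a warning for a single
#'   fragment), plus metadata columns when supplied.
#' @export
summarize_stacks <- function(records, metadata = NULL) {
  if (!nrow(records)) stop("no records to summarize")
  sp <- split(records$r_ec, records$stack_id)
  out <- data.frame(
    stack_id = names(sp),
    n_fragments = vapply(sp, length, integer(1)),
    mean_rec = vapply(sp, mean, numeric(1)),
    sd_rec = vapply(sp, function(v) {
      if (length(v) == 1) {
        warning("single fragment in a stack; sd set to 0")
        return(0)
      }
      stats::sd(v)
    }, numeric(1)),
    row.names = NULL)
  if (!is.null(metadata))
    out <- merge(out, metadata, by = "stack_id", sort = TRUE)
  out
}

#' Wilcoxon-Mann-Whitney rank-sum comparison of two samples
#'
#' Two-sided rank-sum test with midranks for ties, normal approximation
#' with continuity correction. When both samples are small
#' (`n_a * n_b <= 400`) and tie-free, the exact permutation p-value is
#' reported alongside.
#'
#' @param a,b Numeric vectors, each of length at least 3.
#' @return List with `u_statistic`, `p_value` (continuity-corrected
#'   normal approximation) and `p_exact` (`NA` when not computed).
#' @export
rank_sum_test <- function(a, b) {
  if (length(a) < 3 || length(b) < 3)
    stop("need at least 3 values per group")
  if (length(unique(c(a, b))) == 1) {
    warning("all values identical; p = 1")
    return(list(u_statistic = length(a) * length(b) / 2, p_value = 1,
                p_exact = NA_real_))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  p_exact <- NA_real_
  if (length(a) * length(b) <= 400 && !anyDuplicated(c(a, b))) {
    p_exact <- stats::wilcox.test(a, b, exact = TRUE)$p.value
  }
  list(u_statistic = unname(wt$statistic), p_value = wt$p.value,
       p_exact = p_exact)
}

#' Shapiro-Wilk normality diagnostic
#'
#' Reported as a diagnostic motivating the nonparametric group test; it
#' never gates the comparison.
#'
#' @param values Numeric vector, 3 to 5000 values.
#' @return List with `w_statistic` and `p_value`.
#' @export
shapiro_wilk <- function(values) {
  if (length(values) < 3 || length(values) > 5000)
    stop("Shapiro-Wilk requires between 3 and 5000 values")
  sw <- stats::shapiro.test(values)
  list(w_statistic = unname(sw$statistic), p_value = sw$p.value)
}

# five-number summary for box charts
box_quantiles <- function(v) {
  q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), names = FALSE)
  list(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5])
}

#' Compare two cohorts of stack summaries
#'
#' Applies the rank-sum test to the per-stack mean r_ec of the two
#' groups, overall or restricted to one anatomical region. Shapiro-Wilk
#' p-values are attached as diagnostics. No correction is applied across
#' regional scopes (each scope is reported as-is).
#'
#' @param summaries Data frame from [summarize_stacks()] with columns
#'   `stack_id`, `group_label`, `mean_rec` and (for regional scopes)
#'   `region_label`.
#' @param scope `"all"` or one of `"arch"`, `"thoracic"`, `"abdominal"`.
#' @param group_a,group_b Labels of the two groups (defaults control vs
#'   diabetic).
#' @return An object of class `cohort_comparison`: group sizes, means,
#'   sds, `u_statistic`, `p_value`, `p_exact`, Shapiro-Wilk p per group,
#'   the scope, and box-chart quantiles per group.
#' @export
compare_cohorts <- function(summaries, scope = "all",
                            group_a = "control", group_b = "diabetic") {
  scope <- match.arg(scope, c("all", "arch", "thoracic", "abdominal"))
  if (scope != "all") {
    if (!"region_label" %in% names(summaries))
      stop("regional scope requested but summaries carry no region_label")
    summaries <- summaries[!is.na(summaries$region_label) &
                             summaries$region_label == scope, ]
  }
  va <- summaries$mean_rec[summaries$group_label == group_a]
  vb <- summaries$mean_rec[summaries$group_label == group_b]
  if (!length(va) || !length(vb))
    stop(sprintf("no stacks for one of the groups in scope '%s'", scope))
  ts <- rank_sum_test(va, vb)
  sh <- function(v) if (length(v) >= 3) shapiro_wilk(v)$p_value else NA_real_
  structure(list(group_a_label = group_a, group_b_label = group_b,
                 n_a = length(va), n_b = length(vb),
                 mean_a = mean(va), sd_a = stats::sd(va),
                 mean_b = mean(vb), sd_b = stats::sd(vb),
                 u_statistic = ts$u_statistic, p_value = ts$p_value,
                 p_exact = ts$p_exact,
                 shapiro_p_a = sh(va), shapiro_p_b = sh(vb),
                 region_scope = scope,
                 quantiles_a = box_quantiles(va),
                 quantiles_b = box_quantiles(vb)),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("Cohort comparison of mean r_ec (scope: %s)\n", x$region_scope))
  cat(sprintf("  %s: n = %d, mean = %.3f, sd = %.3f\n",
              x$group_a_label, x$n_a, x$mean_a, x$sd_a))
  cat(sprintf("  %s: n = %d, mean = %.3f, sd = %.3f\n",
              x$group_b_label, x$n_b, x$mean_b, x$sd_b))
  cat(sprintf("  rank-sum U = %.1f, p = %.4g (continuity-corrected)\n",
              x$u_statistic, x$p_value))
  if (!is.na(x$p_exact))
    cat(sprintf("  exact permutation p = %.4g\n", x$p_exact))
  invisible(x)
}
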