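# Region-class aggregation of per-cell metrics, fold changes and the
# unpaired two-sample comparison used for group contrasts.

#' Summarize per-cell metrics by region class
#'
#' Aggregates the long per-cell metric table from [neighborhood_metrics()]
#' into one row per region class and metric. Two aggregation hierarchies are
#' supported because group means depend on it when ROIs differ in size:
#' `"per_roi_then_pool"` first averages cells within each ROI, then averages
#' the ROI means (each ROI weighs equally); `"pooled_cells"` averages all
#' cells of the region class directly (each cell weighs equally). Missing
#' per-cell values are excluded and counted.
#'
#' @param records Long tibble with columns `roi_id`, `region_class`,
#'   `cell_id`, `metric`, `value` (as produced by [neighborhood_metrics()]).
#' @param level `"per_roi_then_pool"` (default) or `"pooled_cells"`.
#' @return A tibble of class `nbhood_region_summary`: `region_class`,
#'   `metric`, `n_rois`, `n_focal_cells`, `n_missing`, `mean`, `sem`.
#' @export
summarize_by_region <- function(records,
                                level = c("per_roi_then_pool",
                                          "pooled_cells")) {
  level <- match.arg(level)
  needed <- c("roi_id", "region_class", "cell_id", "metric", "value")
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0L) {
    abort(paste0("`records` lacks column(s): ", paste(miss, collapse = ", ")),
          class = "nbhood_schema_error")
  }
  out <- if (level == "per_roi_then_pool") {
    records |>
      dplyr::summarise(
        roi_mean = if (all(is.na(.data$value))) NA_real_ else
          mean(.data$value, na.rm = TRUE),
        n_cells = dplyr::n(),
        n_missing = sum(is.na(.data$value)),
        .by = c("region_class", "metric", "roi_id")
      ) |>
      dplyr::summarise(
        n_rois = dplyr::n_distinct(.data$roi_id),
        n_focal_cells = sum(.data$n_cells),
        n_missing = sum(.data$n_missing),
        mean = if (all(is.na(.data$roi_mean))) NA_real_ else
          mean(.data$roi_mean, na.rm = TRUE),
        sem = sem(.data$roi_mean),
        .by = c("region_class", "metric")
      )
  } else {
    records |>
      dplyr::summarise(
        n_rois = dplyr::n_distinct(.data$roi_id),
        n_focal_cells = dplyr::n(),
        n_missing = sum(is.na(.data$value)),
        mean = if (all(is.na(.data$value))) NA_real_ else
          mean(.data$value, na.rm = TRUE),
        sem = sem(.data$value),
        .by = c("region_class", "metric")
      )
  }
  out <- dplyr::arrange(out, .data$region_class, .data$metric)
  attr(out, "level") <- level
  class(out) <- unique(c("nbhood_region_summary", class(out)))
  out
}

#' Fold change between two region summaries
#'
#' Ratio of the group means of one metric between two summaries (orientation
#' `a / b`), with both orientations available since a "2.5-fold reduction"
#' can be read either way. Missing when either mean is missing or the
#' denominator is zero.
#'
#' @param summary_a,summary_b Rows of an `nbhood_region_summary` (or any data
#'   frame with `metric` and `mean` columns), e.g. the treated and control
#'   classes.
#' @param metric Metric name to compare.
#' @return One-row tibble `metric`, `mean_a`, `mean_b`, `fold_a_over_b`,
#'   `fold_b_over_a`.
#' @export
fold_change <- function(summary_a, summary_b, metric) {
  pick <- function(s) {
    row <- s[s$metric == metric, , drop = FALSE]
    if (nrow(row) == 0L) {
      abort(paste0("Metric '", metric, "' absent from a summary."),
            class = "nbhood_parameter_error")
    }
    row$mean[1]
  }
  a <- pick(summary_a)
  b <- pick(summary_b)
  ratio <- function(num, den) {
    if (is.na(num) || is.na(den) || den == 0) NA_real_ else num / den
  }
  out <- tibble::tibble(metric = metric, mean_a = a, mean_b = b,
                        fold_a_over_b = ratio(a, b),
                        fold_b_over_a = ratio(b, a))
  if (!is.na(a) && !is.na(b) && (a == 0 || b == 0)) {
    warn("Zero group mean: one fold-change orientation is undefined.")
  }
  out
}

#' Unpaired two-sample t test
#'
#' Two-sided unpaired comparison of two groups of per-cell or per-ROI values.
#' The Welch (unequal-variance) variant is the default; `"pooled"` gives the
#' classical equal-variance test. p-values are nominal — no multiplicity
#' correction is applied.
#'
#' @param group_a,group_b Numeric vectors (each of length >= 2 after removing
#'   `NA`).
#' @param variant `"welch"` (default) or `"pooled"`.
#' @return A one-row tibble of class `nbhood_ttest`: `estimate_a`,
#'   `estimate_b`, `statistic` (t), `df`, `p_value`, `variant`; the full
#'   `htest` object is kept in the `htest` attribute.
#' @export
unpaired_t <- function(group_a, group_b, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2L || length(group_b) < 2L) {
    abort("Each group needs at least 2 non-missing values.",
          class = "nbhood_insufficient_data_error")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = (variant == "pooled"),
                      alternative = "two.sided")
  out <- tibble::tibble(
    estimate_a = mean(group_a), estimate_b = mean(group_b),
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = ht$p.value, variant = variant
  )
  attr(out, "htest") <- ht
  class(out) <- unique(c("nbhood_ttest", class(out)))
  out
}

#' @export
tidy.nbhood_ttest <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("estimate_a", "estimate_b", "statistic",
                                 "df", "p_value", "variant")])
}

#' @export
glance.nbhood_ttest <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 method = paste0(x$variant, " unpaired t-test"))
}

#' @export
tidy.nbhood_region_summary <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "nbhood_region_summary")
  attr(out, "level") <- NULL
  out
}

#' @export
glance.nbhood_region_summary <- function(x, ...) {
  per_metric <- tibble::as_tibble(as.data.frame(x)) |>
    dplyr::summarise(n = sum(.data$n_focal_cells), .by = "metric")
  tibble::tibble(
    level = attr(x, "level") %||% NA_character_,
    n_region_classes = dplyr::n_distinct(x$region_class),
    n_metrics = dplyr::n_distinct(x$metric),
    n_focal_cells = max(per_metric$n)
  )
}
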