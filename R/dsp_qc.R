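# Probe-level QC and normalization for digital spatial profiler count data:
# signal-to-background against the per-segment IgG geometric mean, four
# normalization factors (housekeeping geomean, IgG geomean, area, nuclei),
# geNorm-style concordance (SD of log2 factor ratios), and background-probe
# filtering.

#' Assemble a DSP segment table
#'
#' @param counts Numeric matrix of probe counts, probes as rows (rownames =
#'   probe ids), segments as columns (colnames = segment ids). Counts must be
#'   finite and, unless `pseudocount > 0`, strictly positive (geometric means
#'   are log-based).
#' @param probe_meta Data frame `probe_id`, `class` with class one of
#'   `"target"`, `"IgG"`, `"housekeeping"`, covering every row of `counts`.
#' @param segment_meta Data frame `segment_id`, `area`, `nuclei` (area > 0,
#'   nuclei >= 0), covering every column of `counts`.
#' @param pseudocount Optional value added to every count before any
#'   log/geomean operation (default 0: zero counts are an error instead).
#' @return A list of class `nbhood_dsp`.
#' @export
dsp_table <- function(counts, probe_meta, segment_meta, pseudocount = 0) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("`counts` needs probe rownames and segment colnames.",
          class = "nbhood_schema_error")
  }
  probe_meta <- tibble::as_tibble(probe_meta)
  segment_meta <- tibble::as_tibble(segment_meta)
  if (!all(c("probe_id", "class") %in% names(probe_meta)) ||
      !all(rownames(counts) %in% probe_meta$probe_id)) {
    abort("`probe_meta` must give a class for every probe.",
          class = "nbhood_schema_error")
  }
  if (!all(probe_meta$class %in% c("target", "IgG", "housekeeping"))) {
    abort("Probe class must be target, IgG or housekeeping.",
          class = "nbhood_schema_error")
  }
  if (!all(c("segment_id", "area", "nuclei") %in% names(segment_meta)) ||
      !all(colnames(counts) %in% segment_meta$segment_id)) {
    abort("`segment_meta` must cover every segment.",
          class = "nbhood_schema_error")
  }
  if (any(segment_meta$area <= 0) || any(segment_meta$nuclei < 0)) {
    abort("Segment area must be > 0 and nuclei >= 0.",
          class = "nbhood_invariant_error")
  }
  counts <- counts + pseudocount
  if (any(!is.finite(counts)) || any(counts <= 0)) {
    abort("Counts must be finite and > 0 (use `pseudocount` for zeros).",
          class = "nbhood_domain_error")
  }
  probe_meta <- probe_meta[match(rownames(counts), probe_meta$probe_id), ]
  segment_meta <- segment_meta[match(colnames(counts),
                                     segment_meta$segment_id), ]
  structure(list(counts = counts, probe_meta = probe_meta,
                 segment_meta = segment_meta), class = "nbhood_dsp")
}

#' Read DSP tables from CSV
#'
#' @param counts_path CSV with probes as rows (first column `probe_id`) and
#'   segments as columns.
#' @param probe_meta_path CSV `probe_id`, `class`.
#' @param segment_meta_path CSV `segment_id`, `area`, `nuclei`.
#' @inheritParams dsp_table
#' @return An `nbhood_dsp` object.
#' @export
read_dsp_tables <- function(counts_path, probe_meta_path, segment_meta_path,
                            pseudocount = 0) {
  cts <- readr::read_csv(counts_path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- as.character(cts[[1]])
  dsp_table(m,
            readr::read_csv(probe_meta_path, show_col_types = FALSE,
                            progress = FALSE),
            readr::read_csv(segment_meta_path, show_col_types = FALSE,
                            progress = FALSE),
            pseudocount = pseudocount)
}

#' Geometric mean
#'
#' `exp(mean(log(x)))`; equals the common value for constant input.
#'
#' @param values Strictly positive numeric vector.
#' @return The geometric mean.
#' @export
geometric_mean <- function(values) {
  if (length(values) == 0L) {
    abort("Geometric mean of an empty vector is undefined.",
          class = "nbhood_domain_error")
  }
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort("Geometric mean requires strictly positive finite values.",
          class = "nbhood_domain_error")
  }
  exp(mean(log(values)))
}

igg_geomeans <- function(table) {
  igg <- table$probe_meta$class == "IgG"
  if (!any(igg)) {
    abort("No IgG probes: signal-to-background undefined.",
          class = "nbhood_configuration_error")
  }
  apply(table$counts[igg, , drop = FALSE], 2L, geometric_mean)
}

#' Signal-to-background ratios
#'
#' For every target probe and segment, the probe count divided by the
#' geometric mean of that segment's IgG negative-control counts. The IgG
#' probes' own ratios within a segment have geometric mean 1 by construction.
#'
#' @param table An `nbhood_dsp` from [dsp_table()].
#' @param classes Probe classes for which ratios are returned (default
#'   `"target"`).
#' @return Numeric matrix (probes of the requested classes x segments).
#' @export
signal_to_background <- function(table, classes = "target") {
  bg <- igg_geomeans(table)
  rows <- table$probe_meta$class %in% classes
  sweep(table$counts[rows, , drop = FALSE], 2L, bg, "/")
}

#' Filter probes hovering at background
#'
#' A target probe is excluded when its signal-to-background ratio stays at or
#' below `background_band` in all but fewer than `min_high_segments`
#' segments; a probe with near-background values but at least
#' `min_high_segments` clearly higher segments is kept. Kept and excluded
#' sets partition the targets.
#'
#' @param ratios Target x segment ratio matrix from
#'   [signal_to_background()].
#' @param background_band Ratio at or below which a segment counts as
#'   background-level (default 1.5).
#' @param min_high_segments Minimum number of above-band segments required to
#'   keep a probe (default 1).
#' @return A list `kept`, `excluded` (character vectors of probe ids) and
#'   `n_high` (named integer vector of above-band segment counts).
#' @export
filter_probes <- function(ratios, background_band = 1.5,
                          min_high_segments = 1L) {
  if (background_band < 0 || min_high_segments < 0) {
    abort("`background_band` and `min_high_segments` must be >= 0.",
          class = "nbhood_parameter_error")
  }
  n_high <- rowSums(ratios > background_band)
  keep <- n_high >= min_high_segments
  list(kept = rownames(ratios)[keep],
       excluded = rownames(ratios)[!keep],
       n_high = setNames(as.integer(n_high), rownames(ratios)))
}

#' Per-segment normalization factors
#'
#' The four factors compared for normalizing DSP counts: the geometric mean
#' of housekeeping counts (`HK_geomean`), the geometric mean of IgG
#' negative-control counts (`Neg_geomean`), and segment `area` and `nuclei`
#' passed through verbatim.
#'
#' @param table An `nbhood_dsp`.
#' @param methods Which factors to compute (default all four).
#' @return Tibble: `segment_id` plus one column per requested factor.
#' @export
normalization_factors <- function(table,
                                  methods = c("HK_geomean", "Neg_geomean",
                                              "area", "nuclei")) {
  methods <- match.arg(methods, several.ok = TRUE)
  out <- tibble::tibble(segment_id = colnames(table$counts))
  if ("HK_geomean" %in% methods) {
    hk <- table$probe_meta$class == "housekeeping"
    if (!any(hk)) {
      abort("No housekeeping probes: HK_geomean unavailable.",
            class = "nbhood_configuration_error")
    }
    out$HK_geomean <- unname(apply(table$counts[hk, , drop = FALSE], 2L,
                                   geometric_mean))
  }
  if ("Neg_geomean" %in% methods) {
    out$Neg_geomean <- unname(igg_geomeans(table))
  }
  if ("area" %in% methods) out$area <- table$segment_meta$area
  if ("nuclei" %in% methods) out$nuclei <- as.numeric(table$segment_meta$nuclei)
  out
}

#' Concordance of two normalization factors
#'
#' Sample standard deviation (n - 1 denominator) of the per-segment
#' `log2(a / b)` ratios — the geNorm-style stability measure: factors that
#' track the same signal have a low SD, and rescaling either factor by a
#' constant leaves the SD unchanged. Proportional factors give exactly 0.
#'
#' @param factor_a,factor_b Strictly positive per-segment factor values of
#'   equal length >= 2.
#' @return The SD of the log2 ratios.
#' @export
factor_concordance <- function(factor_a, factor_b) {
  if (length(factor_a) != length(factor_b)) {
    abort("Factors must cover the same segments.",
          class = "nbhood_parameter_error")
  }
  if (length(factor_a) < 2L) {
    abort("Concordance needs at least 2 segments.",
          class = "nbhood_insufficient_data_error")
  }
  if (any(factor_a <= 0) || any(factor_b <= 0)) {
    abort("Factors must be strictly positive.", class = "nbhood_domain_error")
  }
  stats::sd(log2(factor_a / factor_b))
}

#' Normalize counts by a per-segment factor
#'
#' Divides each segment's counts by its factor, then multiplies by the
#' geometric mean of the factors over segments so the result stays on the
#' raw-count scale. Recomputing the same factor on the normalized table gives
#' a constant across segments (the normalization's fixed point).
#'
#' @param table An `nbhood_dsp`.
#' @param factor_method One of `"HK_geomean"`, `"Neg_geomean"`, `"area"`,
#'   `"nuclei"`.
#' @param rescale If `FALSE`, skip the global-scale restoration and return
#'   plain count / factor ratios.
#' @return An `nbhood_dsp` with normalized counts.
#' @export
apply_normalization <- function(table,
                                factor_method = c("HK_geomean", "Neg_geomean",
                                                  "area", "nuclei"),
                                rescale = TRUE) {
  factor_method <- match.arg(factor_method)
  f <- normalization_factors(table, methods = factor_method)[[factor_method]]
  if (any(!is.finite(f)) || any(f <= 0)) {
    abort("Normalization factor must be positive for every segment.",
          class = "nbhood_domain_error")
  }
  scale <- if (rescale) geometric_mean(f) else 1
  out <- table
  out$counts <- sweep(table$counts, 2L, f, "/") * scale
  out
}
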