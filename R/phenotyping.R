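# Threshold-based phenotype gating: ordered marker-predicate rules with a
# fallback label, quantile gating, and lipid-positivity flagging.

#' Build an ordered phenotype rule set
#'
#' A rule set is an ordered list of `(label, predicates)` pairs evaluated
#' first-match-wins, plus a fallback label for cells matching no rule (the
#' "double negative" class in a two-marker panel). Each predicate compares one
#' marker's mean intensity to a threshold: `positive` means strictly greater
#' than the threshold, `negative` means less than or equal to it. Strict ">"
#' makes a zero threshold well defined (intensity 0 is negative).
#'
#' @param ... Named arguments, one per phenotype in evaluation order. Each is
#'   a list of predicates built with [marker_above()] / [marker_below()], e.g.
#'   `TAM = list(marker_below("CD31", 2), marker_above("CD68", 3))`.
#' @param fallback Label assigned to cells matching no rule.
#' @return An object of class `nbhood_rules`.
#' @seealso [rules_human_gbm()], [rules_human_immune()], [rules_mouse_gbm()]
#'   for the shipped panels; [classify_cells()] to apply a rule set.
#' @export
phenotype_rules <- function(..., fallback = "other") {
  rules <- list(...)
  if (length(rules) == 0L) {
    abort("A rule set needs at least one rule.",
          class = "nbhood_parameter_error")
  }
  if (is.null(names(rules)) || any(names(rules) == "")) {
    abort("Every rule must be named with its phenotype label.",
          class = "nbhood_parameter_error")
  }
  if (anyDuplicated(names(rules))) {
    abort("Rule labels must be unique.", class = "nbhood_parameter_error")
  }
  for (lab in names(rules)) {
    preds <- rules[[lab]]
    if (!is.list(preds) || length(preds) == 0L ||
        !all(vapply(preds, inherits, logical(1), "nbhood_predicate"))) {
      abort(paste0("Rule '", lab, "' must be a list of marker_above()/",
                   "marker_below() predicates."),
            class = "nbhood_parameter_error")
    }
  }
  structure(list(rules = rules, fallback = fallback), class = "nbhood_rules")
}

#' @rdname phenotype_rules
#' @param marker Marker (intensity column) name.
#' @param threshold Intensity threshold.
#' @export
marker_above <- function(marker, threshold) {
  structure(list(marker = marker, relation = "positive",
                 threshold = threshold), class = "nbhood_predicate")
}

#' @rdname phenotype_rules
#' @export
marker_below <- function(marker, threshold) {
  structure(list(marker = marker, relation = "negative",
                 threshold = threshold), class = "nbhood_predicate")
}

#' @export
print.nbhood_rules <- function(x, ...) {
  cat("<phenotype rule set>", length(x$rules), "rules, fallback:",
      x$fallback, "\n")
  for (lab in names(x$rules)) {
    preds <- vapply(x$rules[[lab]], function(p) {
      paste0(p$marker, if (p$relation == "positive") "+" else "-",
             " (thr ", format(p$threshold), ")")
    }, character(1))
    cat("  ", lab, ": ", paste(preds, collapse = " & "), "\n", sep = "")
  }
  invisible(x)
}

#' Shipped rule sets
#'
#' `rules_human_gbm()` encodes the three-class human glioblastoma labeling
#' used for neighborhood analysis: M2-TAM (CD163+), TRPC (FABP7+), fallback
#' TSC (double negative). `rules_mouse_gbm()` is the murine analogue: cancer
#' cell (RFP+), TAM (CD68+), fallback "other". `rules_human_immune()` encodes
#' the hyperplexed immune-contexture hierarchy (CD31− gating throughout, most
#' specific first so first-match-wins reproduces the marker logic): LS-TAM
#' (FABP7+ TAM), MDSC (CD68+/CD11b+/HLA-DR−), TAM (CD68+), CTL
#' (CD68−/CD4−/CD8+), Th (CD68−/CD4+), T lymphocyte (CD3+), APC (HLA-DR+).
#'
#' Positivity thresholds are user-defined, per-marker, per-dataset inputs;
#' `thresholds` maps marker name to its threshold and defaults to 1 for every
#' marker so that the rule structure can be exercised on synthetic data.
#'
#' @param thresholds Named numeric vector of per-marker intensity thresholds;
#'   markers not named fall back to `default_threshold`.
#' @param default_threshold Threshold used for unnamed markers.
#' @return An `nbhood_rules` object.
#' @export
rules_human_gbm <- function(thresholds = c(), default_threshold = 1) {
  thr <- function(m) unname(thresholds[m] %|na|% default_threshold)
  phenotype_rules(
    `M2-TAM` = list(marker_above("CD163", thr("CD163"))),
    TRPC = list(marker_above("FABP7", thr("FABP7"))),
    fallback = "TSC"
  )
}

#' @rdname rules_human_gbm
#' @export
rules_mouse_gbm <- function(thresholds = c(), default_threshold = 1) {
  thr <- function(m) unname(thresholds[m] %|na|% default_threshold)
  phenotype_rules(
    `cancer cell` = list(marker_above("RFP", thr("RFP"))),
    TAM = list(marker_above("CD68", thr("CD68"))),
    fallback = "other"
  )
}

#' @rdname rules_human_gbm
#' @export
rules_human_immune <- function(thresholds = c(), default_threshold = 1) {
  thr <- function(m) unname(thresholds[m] %|na|% default_threshold)
  notCD31 <- marker_below("CD31", thr("CD31"))
  phenotype_rules(
    `LS-TAM` = list(notCD31, marker_above("CD68", thr("CD68")),
                    marker_above("FABP7", thr("FABP7"))),
    MDSC = list(notCD31, marker_above("CD68", thr("CD68")),
                marker_above("CD11b", thr("CD11b")),
                marker_below("HLA-DR", thr("HLA-DR"))),
    TAM = list(notCD31, marker_above("CD68", thr("CD68"))),
    CTL = list(notCD31, marker_below("CD68", thr("CD68")),
               marker_below("CD4", thr("CD4")),
               marker_above("CD8", thr("CD8"))),
    Th = list(notCD31, marker_below("CD68", thr("CD68")),
              marker_above("CD4", thr("CD4"))),
    `T lymphocyte` = list(notCD31, marker_above("CD3", thr("CD3"))),
    APC = list(notCD31, marker_above("HLA-DR", thr("HLA-DR"))),
    fallback = "other"
  )
}

`%|na|%` <- function(x, y) {
  if (length(x) == 0L || is.na(x)) y else x
}

#' Assign one phenotype label per cell
#'
#' Evaluates an ordered rule set against each cell's marker intensities.
#' Rules are tried in their listed order and the first whose predicates all
#' hold wins; cells matching no rule receive the fallback label. The result
#' is a deterministic, pure function of intensities and rules (re-running
#' changes nothing; cell order is irrelevant).
#'
#' @param cells A cell table ([as_cell_table()]).
#' @param rules An `nbhood_rules` object from [phenotype_rules()].
#' @return `cells` with the `phenotype` column filled in.
#' @export
classify_cells <- function(cells, rules) {
  if (!inherits(rules, "nbhood_rules")) {
    abort("`rules` must come from phenotype_rules().",
          class = "nbhood_parameter_error")
  }
  for (lab in names(rules$rules)) {
    for (p in rules$rules[[lab]]) {
      if (!p$marker %in% names(cells)) {
        abort(paste0("Rule '", lab, "' references marker '", p$marker,
                     "' which is not a column of the cell table."),
              class = "nbhood_configuration_error")
      }
    }
  }
  n <- nrow(cells)
  label <- rep(rules$fallback, n)
  assigned <- rep(FALSE, n)
  for (lab in names(rules$rules)) {
    hit <- rep(TRUE, n)
    for (p in rules$rules[[lab]]) {
      v <- cells[[p$marker]]
      hit <- hit & if (p$relation == "positive") v > p$threshold
                   else v <= p$threshold
    }
    take <- hit & !assigned
    label[take] <- lab
    assigned <- assigned | hit
  }
  cells$phenotype <- label
  cells
}

#' Partition cells by intensity quantiles (high / low gating)
#'
#' Splits cells on one marker into a high set (top `top_frac` of the
#' empirical intensity distribution), a low set (bottom `bottom_frac`) and an
#' unassigned middle — the gating used to call FABP7-high vs FABP7-low cells
#' from the top and bottom 10% of mean fluorescence intensity. With distinct
#' intensities the high set has exactly `ceiling(top_frac * n)` members and
#' the low set `ceiling(bottom_frac * n)`. Cells tied exactly at a gate
#' boundary are all included (the set may then exceed that count; a warning
#' is raised), which keeps the gate deterministic under reordering.
#'
#' @param cells A cell table.
#' @param marker Marker column to gate on.
#' @param top_frac,bottom_frac Fractions in (0, 1) with
#'   `top_frac + bottom_frac <= 1`.
#' @return `cells` with an added `gate` column: `"high"`, `"low"` or
#'   `"unassigned"`.
#' @export
quantile_gate <- function(cells, marker, top_frac = 0.1, bottom_frac = 0.1) {
  if (nrow(cells) == 0L) {
    abort("Cannot gate an empty cell table.", class = "nbhood_empty_error")
  }
  if (!marker %in% names(cells)) {
    abort(paste0("Marker '", marker, "' not present."),
          class = "nbhood_configuration_error")
  }
  if (top_frac <= 0 || top_frac >= 1 || bottom_frac <= 0 || bottom_frac >= 1 ||
      top_frac + bottom_frac > 1) {
    abort("Need 0 < top_frac, bottom_frac < 1 and top_frac + bottom_frac <= 1.",
          class = "nbhood_parameter_error")
  }
  v <- cells[[marker]]
  if (length(unique(v)) == 1L) {
    abort(paste0("All '", marker, "' intensities are identical; ",
                 "quantile gating is undefined."), class = "nbhood_ties_error")
  }
  n <- length(v)
  sorted <- sort(v)
  # Gate at the order statistics so |high| = ceiling(top_frac*n) when values
  # are distinct: the high cut is the (n - ceiling(top_frac*n) + 1)-th order
  # statistic, the low cut the ceiling(bottom_frac*n)-th.
  k_hi <- ceiling(top_frac * n)
  k_lo <- ceiling(bottom_frac * n)
  # When both ceilings jointly exceed n (e.g. 0.5/0.5 on odd n) the low gate
  # yields to the high gate so the partition stays disjoint.
  if (k_hi + k_lo > n) k_lo <- n - k_hi
  hi_cut <- sorted[n - k_hi + 1L]
  lo_cut <- if (k_lo >= 1L) sorted[k_lo] else -Inf
  gate <- rep("unassigned", n)
  gate[v >= hi_cut] <- "high"
  gate[v <= lo_cut] <- "low"
  if (any(v >= hi_cut & v <= lo_cut)) {
    abort("Gate fractions overlap on tied intensities; lower the fractions.",
          class = "nbhood_ties_error")
  }
  if (sum(gate == "high") > k_hi || sum(gate == "low") > k_lo) {
    warn("Ties at a gate boundary: all tied cells included, so a gate set exceeds ceiling(frac * n).")
  }
  cells$gate <- gate
  cells
}

#' Flag lipid-loaded cells
#'
#' Sets `lipid_positive` from a neutral-lipid stain channel (e.g. LipidSpot):
#' a cell is lipid-loaded iff its stain intensity is strictly greater than
#' the threshold. The flag is independent of the phenotype label.
#'
#' @param cells A cell table.
#' @param marker Lipid-stain intensity column.
#' @param threshold Positivity threshold (strict ">").
#' @return `cells` with `lipid_positive` set to `TRUE`/`FALSE`.
#' @export
assign_lipid_flag <- function(cells, marker, threshold) {
  if (!marker %in% names(cells)) {
    abort(paste0("Lipid marker '", marker, "' not present."),
          class = "nbhood_configuration_error")
  }
  cells$lipid_positive <- cells[[marker]] > threshold
  cells
}
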