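# Marked point-process tissue generator. Emulates the spatial structure the
# neighborhood analysis assumes: disk-shaped tumor niches enriched in
# macrophages over a background, per-type lipid-positivity probabilities, and
# a two-component marker-intensity model so threshold gating is exercised.
# Counts are Poisson (area x density) so density-based expectations are
# exact; a fixed-count mode exists for deterministic tests.

#' Synthetic tissue configuration
#'
#' Defines a rectangular tissue field containing non-overlapping disk-shaped
#' niches. Tumor cells are laid down as a homogeneous Poisson process over
#' the whole field; inside a niche a tumor cell is a treatment-resistant
#' persister cell (TRPC) with probability `trpc_in_niche_fraction`, otherwise
#' (and always outside niches) a treatment-sensitive cell (TSC). Macrophages
#' (TAM) have background density `lambda_tam`, multiplied by `tam_enrichment`
#' inside niches. Each cell draws lipid positivity from
#' `lipid_prob[type, region]` and marker intensities from a per-type
#' two-component Gaussian model (positive component for the type's own
#' marker, negative for the others, truncated at 0).
#'
#' The defaults describe the regime the analysis is designed for: a
#' 1000 x 1000 um field holding roughly 4,700 cells, four 150-um niches
#' covering ~28% of the field, a 2.5-fold TAM enrichment, and lipid
#' probabilities of 0.746 (TRPC, niche), 0.30 (TSC, background), 0.774 (TAM,
#' niche) and 0.586 (TAM, background).
#'
#' @param field_w_um,field_h_um Field size in micrometers.
#' @param niche_centers Two-column matrix of niche centers (um).
#' @param niche_radius_um Niche disk radius (um).
#' @param lambda_tumor Tumor-cell density, cells/um^2 (uniform over field).
#' @param lambda_tam Background TAM density, cells/um^2.
#' @param tam_enrichment Multiplier (>= 0) on TAM density inside niches.
#' @param trpc_in_niche_fraction Probability a niche tumor cell is TRPC.
#' @param lipid_prob Named list of named numeric vectors:
#'   `lipid_prob$<type>[c("niche", "background")]`, probabilities in [0, 1].
#' @param marker_means,marker_sds Named lists mapping cell type to a named
#'   numeric vector of per-marker intensity means / SDs.
#' @param lipid_marker Name of the lipid-stain channel; its intensity is
#'   drawn high for lipid-positive cells and low otherwise so
#'   [assign_lipid_flag()] recovers the generated flag.
#' @param fixed_counts If `TRUE`, expected counts are rounded and used
#'   verbatim instead of Poisson draws (deterministic cell numbers).
#' @return A list of class `nbhood_sim_config`.
#' @export
tissue_config <- function(
    field_w_um = 1000, field_h_um = 1000,
    niche_centers = rbind(c(250, 250), c(750, 250), c(250, 750), c(750, 750)),
    niche_radius_um = 150,
    lambda_tumor = 0.003,
    lambda_tam = 0.0012,
    tam_enrichment = 2.5,
    trpc_in_niche_fraction = 0.8,
    lipid_prob = list(
      TRPC = c(niche = 0.746, background = 0.746),
      TSC = c(niche = 0.30, background = 0.30),
      `M2-TAM` = c(niche = 0.774, background = 0.586)
    ),
    marker_means = list(
      TRPC = c(FABP7 = 8, CD163 = 0.5),
      TSC = c(FABP7 = 0.5, CD163 = 0.5),
      `M2-TAM` = c(FABP7 = 0.5, CD163 = 8)
    ),
    marker_sds = list(
      TRPC = c(FABP7 = 1, CD163 = 0.3),
      TSC = c(FABP7 = 0.3, CD163 = 0.3),
      `M2-TAM` = c(FABP7 = 0.3, CD163 = 1)
    ),
    lipid_marker = "LipidSpot",
    fixed_counts = FALSE) {
  niche_centers <- matrix(as.numeric(niche_centers), ncol = 2)
  if (any(unlist(lipid_prob) < 0) || any(unlist(lipid_prob) > 1)) {
    abort("Lipid probabilities must lie in [0, 1].",
          class = "nbhood_config_error")
  }
  if (lambda_tumor < 0 || lambda_tam < 0 || tam_enrichment < 0) {
    abort("Densities and enrichment must be >= 0.",
          class = "nbhood_config_error")
  }
  if (trpc_in_niche_fraction < 0 || trpc_in_niche_fraction > 1) {
    abort("`trpc_in_niche_fraction` must lie in [0, 1].",
          class = "nbhood_config_error")
  }
  r <- niche_radius_um
  inside <- niche_centers[, 1] >= r & niche_centers[, 1] <= field_w_um - r &
    niche_centers[, 2] >= r & niche_centers[, 2] <= field_h_um - r
  if (!all(inside)) {
    abort("Every niche disk must lie entirely within the field.",
          class = "nbhood_config_error")
  }
  structure(list(
    field_w_um = field_w_um, field_h_um = field_h_um,
    niche_centers = niche_centers, niche_radius_um = niche_radius_um,
    lambda_tumor = lambda_tumor, lambda_tam = lambda_tam,
    tam_enrichment = tam_enrichment,
    trpc_in_niche_fraction = trpc_in_niche_fraction,
    lipid_prob = lipid_prob, marker_means = marker_means,
    marker_sds = marker_sds, lipid_marker = lipid_marker,
    fixed_counts = fixed_counts
  ), class = "nbhood_sim_config")
}

niches_overlap <- function(config) {
  ctr <- config$niche_centers
  n <- nrow(ctr)
  if (n < 2L) return(FALSE)
  dmin <- min(stats::dist(ctr))
  dmin < 2 * config$niche_radius_um
}

niche_area <- function(config) {
  nrow(config$niche_centers) * pi * config$niche_radius_um^2
}

# TRUE for points inside any niche disk.
in_niche <- function(x, y, config) {
  ctr <- config$niche_centers
  r2 <- config$niche_radius_um^2
  hit <- rep(FALSE, length(x))
  for (i in seq_len(nrow(ctr))) {
    hit <- hit | ((x - ctr[i, 1])^2 + (y - ctr[i, 2])^2 <= r2)
  }
  hit
}

# Uniform points in the background (field minus niches) by rejection.
sample_background <- function(n, config) {
  x <- numeric(0); y <- numeric(0)
  while (length(x) < n) {
    m <- max(2L * (n - length(x)), 16L)
    cx <- runif(m, 0, config$field_w_um)
    cy <- runif(m, 0, config$field_h_um)
    keep <- !in_niche(cx, cy, config)
    x <- c(x, cx[keep]); y <- c(y, cy[keep])
  }
  cbind(x[seq_len(n)], y[seq_len(n)])
}

# Uniform points in the union of niche disks (disk chosen by area share,
# position by sqrt-radius sampling).
sample_niche <- function(n, config) {
  ctr <- config$niche_centers
  which_disk <- sample.int(nrow(ctr), n, replace = TRUE)
  rad <- config$niche_radius_um * sqrt(runif(n))
  ang <- runif(n, 0, 2 * pi)
  cbind(ctr[which_disk, 1] + rad * cos(ang),
        ctr[which_disk, 2] + rad * sin(ang))
}

truncnorm0 <- function(n, mean, sd) pmax(0, rnorm(n, mean, sd))

#' Generate a synthetic tissue
#'
#' Realizes the marked point process of a [tissue_config()]: Poisson cell
#' counts per (type, region) from area x density, uniform positions within
#' the region, Bernoulli lipid flags, and Gaussian marker intensities
#' (truncated at 0). A single seeded random stream is used and the
#' (type, region) blocks are drawn in a fixed documented order — background
#' tumor, niche tumor, background TAM, niche TAM — so adding configuration
#' downstream never perturbs earlier draws. Identical seeds give identical
#' tables.
#'
#' @param config A [tissue_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param roi_id,region_class Identifier and region label stamped on the
#'   output (the whole field is one ROI).
#' @return A list of class `nbhood_sim`: `cells` (a cell table with
#'   `true_type`, `true_lipid` and `in_niche` ground-truth columns),
#'   `roi` (the field rectangle), `config`, and `truth` (per-(type, region)
#'   realized counts plus the configured probabilities).
#' @export
generate_tissue <- function(config = tissue_config(), seed = NULL,
                            roi_id = "sim1", region_class = "other") {
  if (!inherits(config, "nbhood_sim_config")) {
    abort("`config` must come from tissue_config().",
          class = "nbhood_parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)
  a_niche <- niche_area(config)
  a_bg <- config$field_w_um * config$field_h_um - a_niche

  n_draw <- function(lambda, area) {
    mu <- lambda * area
    if (config$fixed_counts) as.integer(round(mu)) else rpois(1L, mu)
  }
  # Fixed block order: background tumor, niche tumor, background TAM,
  # niche TAM.
  n_tu_bg <- n_draw(config$lambda_tumor, a_bg)
  pos_tu_bg <- sample_background(n_tu_bg, config)
  n_tu_ni <- n_draw(config$lambda_tumor, a_niche)
  pos_tu_ni <- sample_niche(n_tu_ni, config)
  type_tu_ni <- ifelse(
    runif(n_tu_ni) < config$trpc_in_niche_fraction, "TRPC", "TSC")
  n_tam_bg <- n_draw(config$lambda_tam, a_bg)
  pos_tam_bg <- sample_background(n_tam_bg, config)
  n_tam_ni <- n_draw(config$lambda_tam * config$tam_enrichment, a_niche)
  pos_tam_ni <- sample_niche(n_tam_ni, config)

  blocks <- tibble::tibble(
    x_um = c(pos_tu_bg[, 1], pos_tu_ni[, 1], pos_tam_bg[, 1], pos_tam_ni[, 1]),
    y_um = c(pos_tu_bg[, 2], pos_tu_ni[, 2], pos_tam_bg[, 2], pos_tam_ni[, 2]),
    true_type = c(rep("TSC", n_tu_bg), type_tu_ni,
                  rep("M2-TAM", n_tam_bg + n_tam_ni)),
    region = c(rep("background", n_tu_bg), rep("niche", n_tu_ni),
               rep("background", n_tam_bg), rep("niche", n_tam_ni))
  )
  n <- nrow(blocks)
  p_lip <- vapply(seq_len(n), function(i) {
    pv <- config$lipid_prob[[blocks$true_type[i]]]
    unname(pv[blocks$region[i]])
  }, numeric(1))
  blocks$true_lipid <- runif(n) < p_lip

  marker_names <- unique(unlist(lapply(config$marker_means, names)))
  intens <- lapply(marker_names, function(m) {
    mu <- vapply(blocks$true_type, function(tp) config$marker_means[[tp]][[m]],
                 numeric(1))
    sdv <- vapply(blocks$true_type, function(tp) config$marker_sds[[tp]][[m]],
                  numeric(1))
    truncnorm0(n, mu, sdv)
  })
  names(intens) <- marker_names
  # Lipid channel: well-separated positive/negative components around the
  # generated flag so a mid-range threshold recovers it exactly.
  lip_int <- truncnorm0(n, ifelse(blocks$true_lipid, 8, 0.5),
                        ifelse(blocks$true_lipid, 1, 0.3))

  cells <- tibble::tibble(
    cell_id = sprintf("c%05d", seq_len(n)),
    roi_id = roi_id,
    x_um = blocks$x_um, y_um = blocks$y_um
  )
  for (m in marker_names) cells[[m]] <- intens[[m]]
  cells[[config$lipid_marker]] <- lip_int
  cells$true_type <- blocks$true_type
  cells$true_lipid <- blocks$true_lipid
  cells$in_niche <- blocks$region == "niche"
  cells <- as_cell_table(cells,
                         markers = c(marker_names, config$lipid_marker))

  roi <- roi_rect(roi_id, 0, config$field_w_um, 0, config$field_h_um,
                  region_class = region_class)
  truth <- blocks |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_lipid = sum(.data$true_lipid),
                     .by = c("true_type", "region"))
  structure(list(cells = cells, roi = roi, config = config, truth = truth),
            class = "nbhood_sim")
}

#' Analytic expectations for a synthetic tissue
#'
#' Closed-form expectations against which pipeline estimates can be checked,
#' available when the niches are non-overlapping disks inside the field
#' (otherwise region areas are no longer additive and the analytic branch is
#' flagged unavailable):
#' \describe{
#'   \item{lipid fractions}{expected lipid-positive fraction of each
#'     (type, region) equals the configured probability.}
#'   \item{TAM density ratio}{niche over background TAM density equals the
#'     configured enrichment multiplier.}
#'   \item{TAM neighbor-fraction ratio}{expected fraction of a cell's
#'     neighbors that are TAMs, deep inside a niche vs deep in the
#'     background, from the density mix: `f = lam_TAM* / (lam_TAM* +
#'     lam_tumor)` with the enriched density inside niches; the ratio
#'     `f_niche / f_background` is what the classify-neighborhood-summarize
#'     pipeline estimates.}
#' }
#'
#' @param config A [tissue_config()].
#' @return A list: `available` (logical), `lipid_fraction` (tibble),
#'   `tam_density_ratio`, `tam_neighbor_fraction_niche`,
#'   `tam_neighbor_fraction_background`, `tam_neighbor_fraction_ratio`.
#' @export
expected_metrics <- function(config) {
  if (niches_overlap(config)) {
    warn("Niches overlap: analytic expectations unavailable.")
    return(list(available = FALSE))
  }
  lipid <- purrr::imap(config$lipid_prob, function(pv, tp) {
    tibble::tibble(true_type = tp, region = names(pv),
                   expected_fraction = unname(pv))
  }) |> dplyr::bind_rows()
  lam_tam_niche <- config$lambda_tam * config$tam_enrichment
  f_ni <- lam_tam_niche / (lam_tam_niche + config$lambda_tumor)
  f_bg <- config$lambda_tam / (config$lambda_tam + config$lambda_tumor)
  list(
    available = TRUE,
    lipid_fraction = lipid,
    tam_density_ratio = config$tam_enrichment,
    tam_neighbor_fraction_niche = f_ni,
    tam_neighbor_fraction_background = f_bg,
    tam_neighbor_fraction_ratio = if (f_bg > 0) f_ni / f_bg else NA_real_
  )
}

#' Region membership with an interior buffer
#'
#' Classifies cells as `"niche"`, `"background"` or `"boundary"`. With
#' `buffer_um > 0`, niche cells must be at least `buffer_um` inside the niche
#' boundary and background cells at least `buffer_um` away from every niche;
#' the remaining ring is `"boundary"`. Buffering by the neighbor radius makes
#' region-wise neighborhood compositions comparable to the analytic density
#' mix, because a focal cell's whole neighborhood then lies in its own
#' region.
#'
#' @param cells A cell table.
#' @param config The generating [tissue_config()].
#' @param buffer_um Interior buffer in micrometers (default 0).
#' @return Character vector along `cells` rows.
#' @export
region_of_cells <- function(cells, config, buffer_um = 0) {
  ctr <- config$niche_centers
  d2ctr <- cross_dist(cells$x_um, cells$y_um, ctr[, 1], ctr[, 2])
  dmin <- apply(d2ctr, 1L, min)
  r <- config$niche_radius_um
  dplyr::case_when(
    dmin <= r - buffer_um ~ "niche",
    dmin >= r + buffer_um ~ "background",
    .default = "boundary"
  )
}

#' Write a synthetic tissue to disk
#'
#' Writes the cell table as CSV in the standard schema plus a ground-truth
#' sidecar (structured key-value text) holding the realized per-(type,
#' region) counts.
#'
#' @param sim An `nbhood_sim` from [generate_tissue()].
#' @param path Output CSV path; the sidecar is written to
#'   `<path>.truth.txt`.
#' @return `path`, invisibly.
#' @export
write_tissue <- function(sim, path) {
  readr::write_csv(tibble::as_tibble(as.data.frame(sim$cells)), path,
                   progress = FALSE)
  write_summary(sim$truth, paste0(path, ".truth.txt"), format = "structured")
  invisible(path)
}
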