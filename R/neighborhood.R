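# Fixed-radius neighborhood quantification: the package core. All distances
# are Euclidean center-to-center in micrometers; the neighbor boundary is
# inclusive (d <= radius). Border exclusion removes focal cells whose 55 um
# neighborhood would be truncated by the ROI boundary, but keeps them as
# neighbors/targets of retained cells.

#' Neighborhood parameters
#'
#' @param radius_um Neighbor radius in micrometers (default 55: cells are
#'   neighbors when their centers are at most 55 um apart).
#' @param k Number of nearest target cells averaged by [mean_k_nearest()]
#'   (default 10).
#' @param border_policy `"exclude_focal_within_radius"` (default) drops focal
#'   cells closer than `radius_um` to the ROI boundary; `"none"` keeps all.
#' @return A list of class `nbhood_params`.
#' @export
neighborhood_params <- function(radius_um = 55, k = 10L,
                                border_policy = c("exclude_focal_within_radius",
                                                  "none")) {
  if (!is.numeric(radius_um) || radius_um <= 0) {
    abort("`radius_um` must be > 0.", class = "nbhood_parameter_error")
  }
  if (!is.numeric(k) || k < 1) {
    abort("`k` must be a positive integer.", class = "nbhood_parameter_error")
  }
  structure(list(radius_um = radius_um, k = as.integer(k),
                 border_policy = match.arg(border_policy)),
            class = "nbhood_params")
}

# Grid-bucket fixed-radius search. Bins cells into radius-sized grid cells;
# each cell's neighbors can only lie in the 3x3 block of bins around its own,
# so only those candidate pairs are measured. Returns the full directed
# relation as integer indices.
grid_pairs <- function(x, y, radius) {
  n <- length(x)
  if (n < 2L) {
    return(tibble::tibble(i = integer(), j = integer(), dist = numeric()))
  }
  ix <- floor(x / radius)
  iy <- floor(y / radius)
  key <- paste(ix, iy, sep = ",")
  bins <- split(seq_len(n), key)
  bin_i <- as.integer(vapply(strsplit(names(bins), ",", fixed = TRUE),
                             `[[`, character(1), 1L))
  bin_j <- as.integer(vapply(strsplit(names(bins), ",", fixed = TRUE),
                             `[[`, character(1), 2L))
  lookup <- setNames(seq_along(bins), names(bins))
  res_i <- vector("list", length(bins))
  res_j <- vector("list", length(bins))
  res_d <- vector("list", length(bins))
  offsets <- expand.grid(dx = -1:1, dy = -1:1)
  for (b in seq_along(bins)) {
    I <- bins[[b]]
    cand_keys <- paste(bin_i[b] + offsets$dx, bin_j[b] + offsets$dy, sep = ",")
    J <- unlist(bins[lookup[cand_keys[!is.na(lookup[cand_keys])]]],
                use.names = FALSE)
    dx <- outer(x[I], x[J], "-")
    dy <- outer(y[I], y[J], "-")
    d <- sqrt(dx * dx + dy * dy)
    keep <- which(d <= radius & outer(I, J, "!="), arr.ind = TRUE)
    res_i[[b]] <- I[keep[, 1L]]
    res_j[[b]] <- J[keep[, 2L]]
    res_d[[b]] <- d[keep]
  }
  tibble::tibble(i = unlist(res_i, use.names = FALSE),
                 j = unlist(res_j, use.names = FALSE),
                 dist = unlist(res_d, use.names = FALSE))
}

#' All neighbor pairs within a radius
#'
#' Computes the symmetric neighbor relation among the cells of one ROI: pair
#' (i, j) is included iff the Euclidean center-to-center distance is at most
#' `radius_um`. Self-pairs are excluded. Both directions of every pair are
#' returned, so each unordered neighbor pair contributes two rows.
#'
#' @param cells A cell table from one ROI.
#' @param radius_um Neighbor radius in micrometers.
#' @return Tibble with columns `cell_id`, `neighbor_id`, `distance_um`.
#' @export
all_pairs_within <- function(cells, radius_um = 55) {
  if (nrow(cells) == 0L) {
    abort("Need at least one cell.", class = "nbhood_empty_error")
  }
  assert_single_roi(cells)
  if (radius_um <= 0) {
    abort("`radius_um` must be > 0.", class = "nbhood_parameter_error")
  }
  pr <- grid_pairs(cells$x_um, cells$y_um, radius_um)
  tibble::tibble(
    cell_id = cells$cell_id[pr$i],
    neighbor_id = cells$cell_id[pr$j],
    distance_um = pr$dist
  )
}

# Distance from points to the ROI boundary, positive inside. Rectangle fast
# path; polygons use exact point-to-edge distances with sign from the
# even-odd (ray casting) inside test.
boundary_distance <- function(x, y, roi) {
  poly <- roi$boundary[[1]]
  if (is.null(poly)) {
    pmin(x - roi$xmin, roi$xmax - x, y - roi$ymin, roi$ymax - y)
  } else {
    d <- point_polygon_distance(x, y, poly)
    inside <- point_in_polygon(x, y, poly)
    ifelse(inside, d, -d)
  }
}

point_in_polygon <- function(x, y, poly) {
  nv <- nrow(poly)
  px <- poly[, 1]; py <- poly[, 2]
  inside <- rep(FALSE, length(x))
  j <- nv
  for (i in seq_len(nv)) {
    crosses <- ((py[i] > y) != (py[j] > y)) &
      (x < (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

point_polygon_distance <- function(x, y, poly) {
  nv <- nrow(poly)
  dmin <- rep(Inf, length(x))
  j <- nv
  for (i in seq_len(nv)) {
    ax <- poly[j, 1]; ay <- poly[j, 2]
    bx <- poly[i, 1]; by <- poly[i, 2]
    vx <- bx - ax; vy <- by - ay
    len2 <- vx * vx + vy * vy
    t <- if (len2 == 0) rep(0, length(x)) else {
      pmin(1, pmax(0, ((x - ax) * vx + (y - ay) * vy) / len2))
    }
    dmin <- pmin(dmin, sqrt((x - (ax + t * vx))^2 + (y - (ay + t * vy))^2))
    j <- i
  }
  dmin
}

#' Border exclusion of focal cells
#'
#' Returns the subset of cells whose full neighborhood fits inside the ROI:
#' cells closer than `radius_um` to any boundary edge are dropped as focal
#' cells (their neighborhoods would be truncated), but stay available as
#' neighbors of the retained cells. On a W x H rectangle the retained set is
#' exactly the inset rectangle `[r, W - r] x [r, H - r]`.
#'
#' @param cells A cell table from one ROI.
#' @param roi A one-row `nbhood_roi` (rectangle or polygon).
#' @param radius_um Neighbor radius in micrometers.
#' @return The focal subset of `cells` (possibly empty, with a warning when
#'   the ROI is smaller than `2 * radius_um` in either dimension).
#' @export
exclude_border_focal <- function(cells, roi, radius_um = 55) {
  if ((roi$xmax - roi$xmin) < 2 * radius_um ||
      (roi$ymax - roi$ymin) < 2 * radius_um) {
    warn(paste0("ROI '", roi$roi_id, "' is smaller than twice the ",
                "neighbor radius; no focal cell has a full neighborhood."))
  }
  keep <- boundary_distance(cells$x_um, cells$y_um, roi) >= radius_um
  cells[keep, , drop = FALSE]
}

#' Neighborhood composition per focal cell
#'
#' For every border-retained focal cell of `focal_type`, counts its neighbors
#' within `params$radius_um` by phenotype and converts them to fractions of
#' the total neighbor count. This is the per-cell quantity behind
#' "percentage of M2-TAMs within 55 um of a tumor cell". Focal cells with no
#' neighbor get zero counts and `NA` fractions, flagged by `empty = TRUE`.
#'
#' @param cells A classified cell table from one ROI.
#' @param focal_type Phenotype of the focal cells.
#' @param params [neighborhood_params()].
#' @param roi The ROI geometry row (used for border exclusion; ignored when
#'   `params$border_policy == "none"`).
#' @return A tibble with one row per focal cell and phenotype:
#'   `cell_id`, `focal_phenotype`, `phenotype`, `n_neighbors` (that
#'   phenotype), `total_neighbors`, `fraction`, `empty`. Fractions over
#'   phenotypes sum to 1 for every focal cell with at least one neighbor.
#' @export
neighborhood_composition <- function(cells, focal_type,
                                     params = neighborhood_params(),
                                     roi = NULL) {
  assert_single_roi(cells)
  assert_phenotyped(cells)
  focal <- focal_cells(cells, focal_type, params, roi)
  labels <- sort(unique(cells$phenotype))
  if (nrow(focal) == 0L) {
    warn(paste0("No focal cells of type '", focal_type,
                "' after border exclusion."))
    return(tibble::tibble(cell_id = character(), focal_phenotype = character(),
                          phenotype = character(), n_neighbors = integer(),
                          total_neighbors = integer(), fraction = numeric(),
                          empty = logical()))
  }
  # Neighbor counts by phenotype: distances from focal to all cells, self
  # excluded, thresholded at the radius.
  d <- cross_dist(focal$x_um, focal$y_um, cells$x_um, cells$y_um)
  nb <- d <= params$radius_um
  nb[cbind(seq_len(nrow(focal)), match(focal$cell_id, cells$cell_id))] <- FALSE
  counts <- vapply(labels, function(lab) {
    as.integer(nb %*% (cells$phenotype == lab))
  }, integer(nrow(focal)))
  counts <- matrix(counts, nrow = nrow(focal),
                   dimnames = list(NULL, labels))
  total <- as.integer(rowSums(counts))
  out <- tibble::tibble(
    cell_id = rep(focal$cell_id, each = length(labels)),
    focal_phenotype = focal_type,
    phenotype = rep(labels, times = nrow(focal)),
    n_neighbors = as.integer(t(counts)),
    total_neighbors = rep(total, each = length(labels))
  )
  out$fraction <- ifelse(out$total_neighbors > 0L,
                         out$n_neighbors / out$total_neighbors, NA_real_)
  out$empty <- out$total_neighbors == 0L
  out
}

# Focal subset: phenotype filter + border policy.
focal_cells <- function(cells, focal_type, params, roi) {
  focal <- cells[cells$phenotype == focal_type, , drop = FALSE]
  if (params$border_policy == "exclude_focal_within_radius") {
    if (is.null(roi)) {
      abort("Border exclusion needs the ROI geometry; pass `roi` or set border_policy = \"none\".",
            class = "nbhood_parameter_error")
    }
    focal <- exclude_border_focal(focal, roi, params$radius_um)
  }
  focal
}

#' Distance to the closest cell of a type
#'
#' For every focal cell of `focal_type`, the Euclidean distance to the
#' closest cell of `target_type` (the focal cell itself never counts, so a
#' cell can be its own phenotype's focal and still get the distance to the
#' nearest *other* such cell). The default search is unbounded within the
#' ROI; `radius_policy = "within_radius"` returns `NA` beyond `radius_um`.
#'
#' @param cells A classified cell table from one ROI.
#' @param focal_type,target_type Phenotype labels.
#' @param params [neighborhood_params()].
#' @param roi ROI geometry row (for border exclusion).
#' @param radius_policy `"unbounded"` (default) or `"within_radius"`.
#' @return Tibble `cell_id`, `focal_phenotype`, `target_phenotype`,
#'   `distance_um` (`NA` when no target exists), with attribute
#'   `group_mean` = mean over focal cells with a defined value (`NA` if none).
#' @export
nearest_of_type <- function(cells, focal_type, target_type,
                            params = neighborhood_params(), roi = NULL,
                            radius_policy = c("unbounded", "within_radius")) {
  radius_policy <- match.arg(radius_policy)
  res <- k_nearest_distances(cells, focal_type, target_type, k = 1L,
                             params = params, roi = roi)
  if (radius_policy == "within_radius") {
    res$distance_um[!is.na(res$distance_um) &
                      res$distance_um > params$radius_um] <- NA_real_
  }
  out <- tibble::tibble(cell_id = res$cell_id, focal_phenotype = focal_type,
                        target_phenotype = target_type,
                        distance_um = res$distance_um)
  attr(out, "group_mean") <- if (all(is.na(out$distance_um))) NA_real_ else {
    mean(out$distance_um, na.rm = TRUE)
  }
  out
}

#' Mean distance to the k closest cells of a type
#'
#' Per focal cell, the mean of the `k` smallest distances to `target_type`
#' cells (self excluded). When fewer than `k` targets exist the value is
#' missing rather than a partial mean (a partial mean would bias low); the
#' number of such focal cells is reported in the `n_missing` attribute.
#'
#' @inheritParams nearest_of_type
#' @param k Number of nearest targets to average (`k = 1` reduces to
#'   [nearest_of_type()]).
#' @return Tibble `cell_id`, `focal_phenotype`, `target_phenotype`, `k`,
#'   `mean_distance_um`; attributes `group_mean` and `n_missing`.
#' @export
mean_k_nearest <- function(cells, focal_type, target_type, k = 10L,
                           params = neighborhood_params(), roi = NULL) {
  if (!is.numeric(k) || k < 1) {
    abort("`k` must be a positive integer.", class = "nbhood_parameter_error")
  }
  res <- k_nearest_distances(cells, focal_type, target_type, k = as.integer(k),
                             params = params, roi = roi)
  out <- tibble::tibble(cell_id = res$cell_id, focal_phenotype = focal_type,
                        target_phenotype = target_type, k = as.integer(k),
                        mean_distance_um = res$distance_um)
  attr(out, "group_mean") <- if (all(is.na(out$mean_distance_um))) NA_real_ else {
    mean(out$mean_distance_um, na.rm = TRUE)
  }
  attr(out, "n_missing") <- sum(is.na(out$mean_distance_um))
  out
}

# Shared engine: per focal cell, mean of the k smallest focal-to-target
# distances (k = 1 gives the nearest). NA when fewer than k targets remain
# after self-exclusion.
k_nearest_distances <- function(cells, focal_type, target_type, k,
                                params, roi) {
  assert_single_roi(cells)
  assert_phenotyped(cells)
  focal <- focal_cells(cells, focal_type, params, roi)
  targets <- cells[cells$phenotype == target_type, , drop = FALSE]
  n_f <- nrow(focal)
  if (n_f == 0L) {
    return(tibble::tibble(cell_id = character(), distance_um = numeric()))
  }
  d <- cross_dist(focal$x_um, focal$y_um, targets$x_um, targets$y_um)
  if (nrow(targets) > 0L) {
    self_idx <- match(focal$cell_id, targets$cell_id)
    hit <- which(!is.na(self_idx))
    if (length(hit) > 0L) d[cbind(hit, self_idx[hit])] <- Inf
  }
  vals <- vapply(seq_len(n_f), function(i) {
    di <- d[i, ]
    di <- di[is.finite(di)]
    if (length(di) < k) NA_real_ else mean_k_smallest(di, k)
  }, numeric(1))
  tibble::tibble(cell_id = focal$cell_id, distance_um = vals)
}

#' Lipid-loaded-neighbor metrics
#'
#' For each border-retained focal cell of `focal_type`, three quantities
#' describing lipid-loaded macrophages in its neighborhood:
#' \describe{
#'   \item{frac_lipid_tam_neighbors}{fraction of *all* neighbors within the
#'     radius that are lipid-positive cells of `tam_label` (0 when the focal
#'     cell has neighbors but none qualify; `NA` with zero neighbors).}
#'   \item{frac_tam_neighbors_lipid}{among neighbor `tam_label` cells only,
#'     the lipid-positive fraction (`NA` when the focal cell has no
#'     `tam_label` neighbor).}
#'   \item{dist_lipid_tam_um}{distance to the closest lipid-positive
#'     `tam_label` cell, unbounded search.}
#' }
#' The per-phenotype lipid-positive fractions over the whole ROI (e.g.
#' "74.6% of TRPCs contain lipids") are attached as the
#' `lipid_fraction_by_phenotype` attribute; see
#' [lipid_fraction_by_phenotype()].
#'
#' @param cells A classified, lipid-flagged cell table from one ROI.
#' @param focal_type Phenotype of focal cells.
#' @param tam_label Phenotype label of the macrophage class (e.g. `"M2-TAM"`).
#' @param params [neighborhood_params()].
#' @param roi ROI geometry row.
#' @return Tibble with one row per focal cell; attributes `group_means`
#'   (named numeric) and `lipid_fraction_by_phenotype` (tibble).
#' @export
lipid_neighborhood_metrics <- function(cells, focal_type, tam_label,
                                       params = neighborhood_params(),
                                       roi = NULL) {
  assert_single_roi(cells)
  assert_phenotyped(cells)
  if (anyNA(cells$lipid_positive)) {
    abort("Lipid flags are unset; run assign_lipid_flag() first.",
          class = "nbhood_state_error")
  }
  focal <- focal_cells(cells, focal_type, params, roi)
  is_tam <- cells$phenotype == tam_label
  is_lipid_tam <- is_tam & cells$lipid_positive

  if (nrow(focal) == 0L) {
    out <- tibble::tibble(cell_id = character(),
                          frac_lipid_tam_neighbors = numeric(),
                          frac_tam_neighbors_lipid = numeric(),
                          dist_lipid_tam_um = numeric())
  } else {
    d <- cross_dist(focal$x_um, focal$y_um, cells$x_um, cells$y_um)
    self_pos <- cbind(seq_len(nrow(focal)),
                      match(focal$cell_id, cells$cell_id))
    nb <- d <= params$radius_um
    nb[self_pos] <- FALSE
    n_all <- rowSums(nb)
    n_tam <- as.numeric(nb %*% is_tam)
    n_lipid_tam <- as.numeric(nb %*% is_lipid_tam)
    d_self <- d
    d_self[self_pos] <- Inf
    d_lipid <- d_self[, is_lipid_tam, drop = FALSE]
    dist_lt <- if (ncol(d_lipid) == 0L) rep(NA_real_, nrow(focal)) else {
      apply(d_lipid, 1L, min)
    }
    out <- tibble::tibble(
      cell_id = focal$cell_id,
      frac_lipid_tam_neighbors = ifelse(n_all > 0, n_lipid_tam / n_all,
                                        NA_real_),
      frac_tam_neighbors_lipid = ifelse(n_tam > 0, n_lipid_tam / n_tam,
                                        NA_real_),
      dist_lipid_tam_um = dist_lt
    )
  }
  gm <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  attr(out, "group_means") <- c(
    frac_lipid_tam_neighbors = gm(out$frac_lipid_tam_neighbors),
    frac_tam_neighbors_lipid = gm(out$frac_tam_neighbors_lipid),
    dist_lipid_tam_um = gm(out$dist_lipid_tam_um)
  )
  attr(out, "lipid_fraction_by_phenotype") <- lipid_fraction_by_phenotype(cells)
  out
}

#' Lipid-positive fraction per phenotype
#'
#' @param cells A classified, lipid-flagged cell table.
#' @return Tibble `phenotype`, `n_cells`, `n_lipid_positive`, `fraction`.
#' @export
lipid_fraction_by_phenotype <- function(cells) {
  assert_phenotyped(cells)
  if (anyNA(cells$lipid_positive)) {
    abort("Lipid flags are unset; run assign_lipid_flag() first.",
          class = "nbhood_state_error")
  }
  cells |>
    dplyr::summarise(n_cells = dplyr::n(),
                     n_lipid_positive = sum(.data$lipid_positive),
                     fraction = mean(.data$lipid_positive),
                     .by = "phenotype") |>
    dplyr::arrange(.data$phenotype)
}

#' Per-cell neighborhood metrics across ROIs
#'
#' Convenience orchestrator for multi-ROI tables: runs border exclusion,
#' neighborhood composition, nearest- and k-nearest-of-type distances (and,
#' when lipid flags are set, the lipid-neighbor metrics) ROI by ROI and binds
#' the per-focal-cell results with the ROI's `region_class` attached, ready
#' for [summarize_by_region()].
#'
#' @param cells A classified cell table (one or many ROIs).
#' @param rois `nbhood_roi` tibble covering every `roi_id` in `cells`.
#' @param focal_type Phenotype of the focal cells.
#' @param target_types Phenotypes to which nearest/k-nearest distances are
#'   computed.
#' @param params [neighborhood_params()].
#' @param tam_label If non-`NULL` and lipid flags are set, also compute
#'   [lipid_neighborhood_metrics()] against this label.
#' @return A long tibble: `roi_id`, `region_class`, `cell_id`, `metric`,
#'   `value`. Metrics are `frac_<phenotype>` (neighbor fractions),
#'   `nearest_<target>_um`, `mean_<k>nearest_<target>_um`, and the lipid
#'   metrics when requested.
#' @export
neighborhood_metrics <- function(cells, rois, focal_type, target_types,
                                 params = neighborhood_params(),
                                 tam_label = NULL) {
  assert_phenotyped(cells)
  purrr::map(unique(cells$roi_id), function(id) {
    roi <- roi_row(rois, id)
    sub <- cells[cells$roi_id == id, , drop = FALSE]
    comp <- neighborhood_composition(sub, focal_type, params, roi)
    res <- comp |>
      dplyr::transmute(.data$cell_id,
                       metric = paste0("frac_", .data$phenotype),
                       value = .data$fraction)
    for (tt in target_types) {
      nd <- nearest_of_type(sub, focal_type, tt, params, roi)
      kd <- mean_k_nearest(sub, focal_type, tt, params$k, params, roi)
      res <- dplyr::bind_rows(
        res,
        tibble::tibble(cell_id = nd$cell_id,
                       metric = paste0("nearest_", tt, "_um"),
                       value = nd$distance_um),
        tibble::tibble(cell_id = kd$cell_id,
                       metric = paste0("mean_", params$k, "nearest_", tt, "_um"),
                       value = kd$mean_distance_um)
      )
    }
    if (!is.null(tam_label) && !anyNA(sub$lipid_positive)) {
      lip <- lipid_neighborhood_metrics(sub, focal_type, tam_label, params, roi)
      res <- dplyr::bind_rows(
        res,
        lip |> tidyr::pivot_longer(-"cell_id", names_to = "metric",
                                   values_to = "value")
      )
    }
    res$roi_id <- id
    res$region_class <- roi$region_class
    res
  }) |>
    dplyr::bind_rows() |>
    dplyr::select("roi_id", "region_class", "cell_id", "metric", "value")
}
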