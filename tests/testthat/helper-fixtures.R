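# Fixture builders and independent brute-force oracles used across tests.
# The oracles deliberately use full O(n^2) distance matrices (base dist()),
# independent of the package's grid-bucket neighbor search.

make_cells <- function(x, y, phenotype = NULL, lipid = NULL, roi_id = "r1",
                       ids = NULL, ...) {
  n <- length(x)
  cells <- tibble::tibble(
    cell_id = ids %||% sprintf("c%04d", seq_len(n)),
    roi_id = roi_id, x_um = x, y_um = y, ...
  )
  cells <- as_cell_table(cells)
  if (!is.null(phenotype)) cells$phenotype <- phenotype
  if (!is.null(lipid)) cells$lipid_positive <- lipid
  cells
}

random_cells <- function(n, w = 500, h = 500, labels = c("A", "B", "C"),
                         roi_id = "r1") {
  make_cells(runif(n, 0, w), runif(n, 0, h),
             phenotype = sample(labels, n, replace = TRUE),
             lipid = sample(c(TRUE, FALSE), n, replace = TRUE),
             roi_id = roi_id)
}

full_dist <- function(cells) {
  as.matrix(dist(cbind(cells$x_um, cells$y_um)))
}

# Directed neighbor pairs by exhaustive scan.
brute_pairs <- function(cells, r) {
  dm <- full_dist(cells)
  idx <- which(dm <= r & row(dm) != col(dm), arr.ind = TRUE)
  tibble::tibble(cell_id = cells$cell_id[idx[, 1]],
                 neighbor_id = cells$cell_id[idx[, 2]],
                 distance_um = dm[idx])
}

# Per-focal mean of the k smallest distances to target cells, self excluded.
brute_k_nearest <- function(cells, focal_ids, target_type, k) {
  dm <- full_dist(cells)
  diag(dm) <- Inf
  tcol <- which(cells$phenotype == target_type)
  vapply(match(focal_ids, cells$cell_id), function(i) {
    d <- dm[i, tcol]
    d <- d[is.finite(d)]
    if (length(d) < k) NA_real_ else mean(sort(d)[seq_len(k)])
  }, numeric(1))
}

# Per-focal neighbor fraction of one phenotype by exhaustive recount.
brute_fraction <- function(cells, focal_ids, phenotype, r) {
  dm <- full_dist(cells)
  diag(dm) <- Inf
  vapply(match(focal_ids, cells$cell_id), function(i) {
    nb <- which(dm[i, ] <= r)
    if (length(nb) == 0L) NA_real_ else mean(cells$phenotype[nb] == phenotype)
  }, numeric(1))
}

grid_cells_11 <- function() {
  g <- expand.grid(x = 0:10, y = 0:10)
  make_cells(g$x, g$y, phenotype = "A")
}

# Tiny DSP table with hand-computable values.
toy_dsp <- function() {
  counts <- rbind(
    t1 = c(s1 = 12, s2 = 20, s3 = 6),
    t2 = c(4, 4, 4),
    igg1 = c(2, 4, 1),
    igg2 = c(8, 4, 4),
    hk1 = c(4, 10, 2),
    hk2 = c(16, 10, 8)
  )
  dsp_table(counts,
            probe_meta = tibble::tibble(
              probe_id = rownames(counts),
              class = c("target", "target", "IgG", "IgG",
                        "housekeeping", "housekeeping")),
            segment_meta = tibble::tibble(
              segment_id = colnames(counts),
              area = c(100, 200, 50), nuclei = c(10, 20, 5)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
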