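params55 <- neighborhood_params() # radius 55 um, k = 10

test_that("the neighbor boundary is inclusive at exactly the radius", {
  cells <- make_cells(c(0, 0), c(0, 55))
  pairs <- all_pairs_within(cells, 55)
  expect_equal(nrow(pairs), 2L) # both directions of one pair
  expect_equal(unique(pairs$distance_um), 55)

  apart <- make_cells(c(0, 0), c(0, 55.1))
  none <- all_pairs_within(apart, 55)
  expect_equal(nrow(none), 0L)
})

test_that("grid neighbor search equals the exhaustive scan on random fields", {
  set.seed(21)
  for (rep in 1:5) {
    n <- sample(100:500, 1)
    cells <- random_cells(n)
    r <- runif(1, 20, 80)
    got <- all_pairs_within(cells, r)
    want <- brute_pairs(cells, r)
    key <- function(p) paste(p$cell_id, p$neighbor_id)
    expect_setequal(key(got), key(want))
    expect_equal(nrow(got), nrow(want))
    # symmetric relation, no self pairs
    expect_setequal(key(got),
                    paste(got$neighbor_id, got$cell_id))
    expect_false(any(got$cell_id == got$neighbor_id))
    m <- merge(got, want, by = c("cell_id", "neighbor_id"))
    expect_equal(m$distance_um.x, m$distance_um.y)
  }
})

test_that("mixed ROIs in one coordinate-frame call is an error", {
  cells <- make_cells(c(0, 1), c(0, 1), roi_id = c("r1", "r2"))
  expect_error(all_pairs_within(cells, 55), class = "nbhood_frame_error")
})

test_that("border exclusion retains exactly the analytic inset rectangle", {
  roi <- roi_rect("r1", 0, 10, 0, 10)
  grid <- grid_cells_11()
  kept <- suppressWarnings(exclude_border_focal(grid, roi, 3))
  expect_equal(nrow(kept), 25L)
  expect_true(all(kept$x_um >= 3 & kept$x_um <= 7 &
                    kept$y_um >= 3 & kept$y_um <= 7))

  roi200 <- roi_rect("r1", 0, 200, 0, 200)
  two <- make_cells(c(100, 30), c(100, 100))
  kept200 <- exclude_border_focal(two, roi200, 55)
  expect_equal(kept200$x_um, 100)
})

test_that("an ROI smaller than twice the radius warns and empties the focal set", {
  roi <- roi_rect("r1", 0, 100, 0, 100)
  cells <- make_cells(c(50, 10), c(50, 90))
  expect_warning(kept <- exclude_border_focal(cells, roi, 55), "full neighborhood")
  expect_equal(nrow(kept), 0L)
})

test_that("border exclusion works on polygon ROIs via boundary distance", {
  # right triangle (0,0)-(100,0)-(0,100); its incenter is the deepest point
  roi <- roi_polygon("p1", rbind(c(0, 0), c(100, 0), c(0, 100)))
  inc <- 100 * (2 - sqrt(2)) / 2 # inradius of this triangle ~ 29.3
  cells <- make_cells(c(inc, 5, 60), c(inc, 5, 60))
  kept <- exclude_border_focal(cells, roi, 25)
  expect_equal(kept$cell_id, cells$cell_id[1])
  none <- exclude_border_focal(cells, roi, 30)
  expect_equal(nrow(none), 0L)
})

test_that("composition counts and fractions match the worked example", {
  cells <- make_cells(c(0, 10, 20, 60), c(0, 0, 0, 0),
                      phenotype = c("TRPC", "TAM", "TSC", "TAM"))
  comp <- neighborhood_composition(cells, "TRPC",
                                   neighborhood_params(border_policy = "none"))
  tam <- comp[comp$phenotype == "TAM", ]
  tsc <- comp[comp$phenotype == "TSC", ]
  expect_equal(tam$n_neighbors, 1L) # the TAM at 60 um is out of range
  expect_equal(tam$fraction, 0.5)
  expect_equal(tsc$fraction, 0.5)
  expect_equal(unique(comp$total_neighbors), 2L)
})

test_that("a focal cell with no neighbors is flagged empty", {
  cells <- make_cells(c(0, 500), c(0, 0), phenotype = c("TRPC", "TAM"))
  comp <- neighborhood_composition(cells, "TRPC",
                                   neighborhood_params(border_policy = "none"))
  expect_true(all(comp$empty))
  expect_true(all(is.na(comp$fraction)))
  expect_equal(unique(comp$total_neighbors), 0L)
})

test_that("per-focal fractions equal an exhaustive recount on random labelings", {
  set.seed(31)
  cells <- random_cells(1000, labels = c("TRPC", "TSC", "TAM"))
  roi <- roi_rect("r1", 0, 500, 0, 500)
  comp <- neighborhood_composition(cells, "TRPC", params55, roi)
  tam <- comp[comp$phenotype == "TAM" & !comp$empty, ]
  oracle <- brute_fraction(cells, tam$cell_id, "TAM", 55)
  expect_equal(tam$fraction, oracle)
  # fractions sum to 1 for focal cells with neighbors
  sums <- tapply(comp$fraction[!comp$empty], comp$cell_id[!comp$empty], sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("nearest-of-type excludes self and averages over defined values", {
  cells <- make_cells(c(0, 10, 20), c(0, 0, 0),
                      phenotype = c("TRPC", "TAM", "TAM"))
  nd <- nearest_of_type(cells, "TRPC", "TAM",
                        neighborhood_params(border_policy = "none"))
  expect_equal(nd$distance_um, 10)
  expect_equal(attr(nd, "group_mean"), 10)

  # focal cell of the target type: self never counts
  selfies <- make_cells(c(0, 5), c(0, 0), phenotype = c("TAM", "TAM"))
  nd2 <- nearest_of_type(selfies, "TAM", "TAM",
                         neighborhood_params(border_policy = "none"))
  expect_equal(nd2$distance_um, c(5, 5))
})

test_that("no targets means missing distances and a missing mean", {
  cells <- make_cells(c(0, 10), c(0, 0), phenotype = c("TRPC", "TSC"))
  nd <- nearest_of_type(cells, "TRPC", "TAM",
                        neighborhood_params(border_policy = "none"))
  expect_true(all(is.na(nd$distance_um)))
  expect_true(is.na(attr(nd, "group_mean")))
})

test_that("the within-radius policy censors distances beyond the radius", {
  cells <- make_cells(c(0, 80), c(0, 0), phenotype = c("TRPC", "TAM"))
  unbounded <- nearest_of_type(cells, "TRPC", "TAM",
                               neighborhood_params(border_policy = "none"))
  expect_equal(unbounded$distance_um, 80)
  capped <- nearest_of_type(cells, "TRPC", "TAM",
                            neighborhood_params(border_policy = "none"),
                            radius_policy = "within_radius")
  expect_true(is.na(capped$distance_um))
})

test_that("k-nearest means match the worked example and reduce to nearest at k=1", {
  cells <- make_cells(c(0, 10, 20, 30), c(0, 0, 0, 0),
                      phenotype = c("TRPC", "TAM", "TAM", "TAM"))
  p <- neighborhood_params(border_policy = "none")
  k2 <- mean_k_nearest(cells, "TRPC", "TAM", k = 2, p)
  expect_equal(k2$mean_distance_um, 15)
  k1 <- mean_k_nearest(cells, "TRPC", "TAM", k = 1, p)
  n1 <- nearest_of_type(cells, "TRPC", "TAM", p)
  expect_equal(k1$mean_distance_um, n1$distance_um)
  expect_error(mean_k_nearest(cells, "TRPC", "TAM", k = 0, p),
               class = "nbhood_parameter_error")
})

test_that("fewer than k targets yields missing, not a partial mean", {
  cells <- make_cells(c(0, 10), c(0, 0), phenotype = c("TRPC", "TAM"))
  p <- neighborhood_params(border_policy = "none")
  k3 <- mean_k_nearest(cells, "TRPC", "TAM", k = 3, p)
  expect_true(is.na(k3$mean_distance_um))
  expect_equal(attr(k3, "n_missing"), 1L)
})

test_that("nearest and k-nearest match the sort-based oracle on random fields", {
  set.seed(41)
  for (n in c(200, 300)) {
    cells <- random_cells(n, labels = c("TRPC", "TAM", "TSC"))
    p <- neighborhood_params(border_policy = "none")
    nd <- nearest_of_type(cells, "TRPC", "TAM", p)
    expect_equal(nd$distance_um, brute_k_nearest(cells, nd$cell_id, "TAM", 1))
    kd <- mean_k_nearest(cells, "TRPC", "TAM", k = 10, p)
    expect_equal(kd$mean_distance_um,
                 brute_k_nearest(cells, kd$cell_id, "TAM", 10))
  }
})

test_that("adding target cells never increases a nearest-of-type distance", {
  set.seed(51)
  cells <- random_cells(300, labels = c("TRPC", "TAM", "TSC"))
  p <- neighborhood_params(border_policy = "none")
  before <- nearest_of_type(cells, "TRPC", "TAM", p)
  extra <- make_cells(runif(50, 0, 500), runif(50, 0, 500),
                      phenotype = rep("TAM", 50),
                      ids = sprintf("x%03d", 1:50))
  more <- as_cell_table(dplyr::bind_rows(cells, extra))
  more$phenotype <- c(cells$phenotype, extra$phenotype)
  after <- nearest_of_type(more, "TRPC", "TAM", p)
  expect_true(all(after$distance_um <= before$distance_um + 1e-12))
})

test_that("lipid-neighbor metrics follow the two-denominator contract", {
  # neighbors of the focal TRPC: lipid+ TAM, lipid- TAM, lipid- TSC
  cells <- make_cells(c(0, 10, 20, 30), c(0, 0, 0, 0),
                      phenotype = c("TRPC", "TAM", "TAM", "TSC"),
                      lipid = c(FALSE, TRUE, FALSE, FALSE))
  p <- neighborhood_params(border_policy = "none")
  m <- lipid_neighborhood_metrics(cells, "TRPC", "TAM", p)
  expect_equal(m$frac_lipid_tam_neighbors, 1 / 3)
  expect_equal(m$frac_tam_neighbors_lipid, 1 / 2)
  expect_equal(m$dist_lipid_tam_um, 10)

  # zero TAM neighbors: metric2 missing, metric1 zero
  no_tam <- make_cells(c(0, 10), c(0, 0), phenotype = c("TRPC", "TSC"),
                       lipid = c(FALSE, FALSE))
  m2 <- lipid_neighborhood_metrics(no_tam, "TRPC", "TAM", p)
  expect_equal(m2$frac_lipid_tam_neighbors, 0)
  expect_true(is.na(m2$frac_tam_neighbors_lipid))
})

test_that("lipid metrics demand lipid flags and report per-phenotype fractions", {
  cells <- make_cells(c(0, 10), c(0, 0), phenotype = c("TRPC", "TAM"))
  p <- neighborhood_params(border_policy = "none")
  expect_error(lipid_neighborhood_metrics(cells, "TRPC", "TAM", p),
               class = "nbhood_state_error")
  flagged <- cells
  flagged$lipid_positive <- c(TRUE, FALSE)
  m <- lipid_neighborhood_metrics(flagged, "TRPC", "TAM", p)
  frac <- attr(m, "lipid_fraction_by_phenotype")
  expect_equal(frac$fraction[frac$phenotype == "TRPC"], 1)
  expect_equal(frac$fraction[frac$phenotype == "TAM"], 0)
})

test_that("neighborhood_metrics orchestrates per-ROI and tags region classes", {
  set.seed(61)
  c1 <- random_cells(150, labels = c("TRPC", "TAM", "TSC"), roi_id = "r1")
  c2 <- random_cells(150, labels = c("TRPC", "TAM", "TSC"), roi_id = "r2")
  cells <- as_cell_table(dplyr::bind_rows(c1, c2))
  cells$phenotype <- c(c1$phenotype, c2$phenotype)
  cells$lipid_positive <- c(c1$lipid_positive, c2$lipid_positive)
  rois <- dplyr::bind_rows(
    roi_rect("r1", 0, 500, 0, 500, region_class = "TRPC"),
    roi_rect("r2", 0, 500, 0, 500, region_class = "TSC"))
  rec <- neighborhood_metrics(cells, rois, focal_type = "TRPC",
                              target_types = "TAM", params55,
                              tam_label = "TAM")
  expect_setequal(unique(rec$region_class), c("TRPC", "TSC"))
  expect_true(all(c("frac_TAM", "nearest_TAM_um", "mean_10nearest_TAM_um",
                    "frac_lipid_tam_neighbors") %in% rec$metric))
  # every focal cell of r1 survives border exclusion rules applied per ROI
  r1_focal <- suppressWarnings(exclude_border_focal(
    cells[cells$roi_id == "r1" & cells$phenotype == "TRPC", ],
    rois[1, ], 55))
  expect_setequal(unique(rec$cell_id[rec$roi_id == "r1"]), r1_focal$cell_id)
})
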