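human_tam_rules <- function() {
  phenotype_rules(
    TAM = list(marker_below("CD31", 1), marker_above("CD68", 1)),
    fallback = "TSC"
  )
}

test_that("marker-rule classification reproduces the panel definitions", {
  cells <- make_cells(
    x = c(0, 1, 2), y = c(0, 0, 0),
    CD31 = c(0.2, 0.1, 3.0), CD68 = c(5.0, 0.3, 5.0)
  )
  out <- classify_cells(cells, human_tam_rules())
  # CD31-/CD68+ is a TAM; double negative falls back; CD31+ blocks the rule
  expect_equal(out$phenotype, c("TAM", "TSC", "TSC"))
})

test_that("rules are evaluated first-match-wins in listed order", {
  cells <- make_cells(0, 0, M = 5)
  rules <- phenotype_rules(A = list(marker_above("M", 1)),
                           B = list(marker_above("M", 1)),
                           fallback = "other")
  expect_equal(classify_cells(cells, rules)$phenotype, "A")
  flipped <- phenotype_rules(B = list(marker_above("M", 1)),
                             A = list(marker_above("M", 1)),
                             fallback = "other")
  expect_equal(classify_cells(cells, flipped)$phenotype, "B")
})

test_that("classification is idempotent and order-independent", {
  set.seed(7)
  n <- 200
  cells <- make_cells(runif(n), runif(n),
                      CD31 = runif(n, 0, 2), CD68 = runif(n, 0, 2))
  once <- classify_cells(cells, human_tam_rules())
  twice <- classify_cells(once, human_tam_rules())
  expect_identical(once$phenotype, twice$phenotype)
  perm <- sample.int(n)
  shuffled <- classify_cells(cells[perm, ], human_tam_rules())
  expect_identical(shuffled$phenotype, once$phenotype[perm])
})

test_that("a missing marker is a configuration error naming marker and rule", {
  cells <- make_cells(0, 0, CD68 = 2)
  err <- expect_error(classify_cells(cells, human_tam_rules()),
                      class = "nbhood_configuration_error")
  expect_match(conditionMessage(err), "CD31")
  expect_match(conditionMessage(err), "TAM")
})

test_that("shipped rule sets encode the published hierarchies", {
  # human immune panel: MDSC is CD31-/CD68+/CD11b+/HLA-DR-, evaluated before
  # the generic TAM rule
  cells <- make_cells(
    x = 1:3, y = rep(0, 3),
    CD31 = c(0, 0, 0), CD68 = c(5, 5, 0), CD11b = c(5, 0, 0),
    `HLA-DR` = c(0, 0, 5), FABP7 = c(0, 0, 0), CD4 = c(0, 0, 0),
    CD8 = c(0, 0, 0), CD3 = c(0, 0, 0)
  )
  out <- classify_cells(cells, rules_human_immune())
  expect_equal(out$phenotype, c("MDSC", "TAM", "APC"))

  # three-class human labeling: CD163+ TAM, FABP7+ TRPC, double negative TSC
  hs <- make_cells(1:3, rep(0, 3), FABP7 = c(5, 0, 0), CD163 = c(0, 5, 0))
  expect_equal(classify_cells(hs, rules_human_gbm())$phenotype,
               c("TRPC", "M2-TAM", "TSC"))

  # murine labeling: RFP+ cancer cell, CD68+ TAM, double negative other
  ms <- make_cells(1:3, rep(0, 3), RFP = c(5, 0, 0), CD68 = c(0, 5, 0))
  expect_equal(classify_cells(ms, rules_mouse_gbm())$phenotype,
               c("cancer cell", "TAM", "other"))
})

test_that("quantile gate selects exact top and bottom sets", {
  cells <- make_cells(1:10, rep(0, 10), MFI = as.numeric(1:10))
  out <- quantile_gate(cells, "MFI", top_frac = 0.1, bottom_frac = 0.1)
  expect_equal(cells$cell_id[out$gate == "high"],
               cells$cell_id[cells$MFI == 10])
  expect_equal(cells$cell_id[out$gate == "low"],
               cells$cell_id[cells$MFI == 1])
  expect_equal(sum(out$gate == "unassigned"), 8L)

  half <- quantile_gate(cells, "MFI", top_frac = 0.5, bottom_frac = 0.5)
  expect_false(any(half$gate == "unassigned"))
  expect_equal(sum(half$gate == "high"), 5L)
})

test_that("gate sizes match the sort-based oracle on random intensities", {
  set.seed(11)
  n <- 1000
  v <- runif(n)
  cells <- make_cells(runif(n), runif(n), MFI = v)
  out <- quantile_gate(cells, "MFI", top_frac = 0.1, bottom_frac = 0.1)
  expect_equal(sum(out$gate == "high"), 100L)
  expect_equal(sum(out$gate == "low"), 100L)
  # oracle: sort and take the extreme deciles
  expect_setequal(cells$cell_id[out$gate == "high"],
                  cells$cell_id[order(v, decreasing = TRUE)[1:100]])
  expect_setequal(cells$cell_id[out$gate == "low"],
                  cells$cell_id[order(v)[1:100]])
})

test_that("gate is disjoint, monotone, and permutation-invariant", {
  set.seed(3)
  n <- 300
  cells <- make_cells(runif(n), runif(n), MFI = runif(n))
  out <- quantile_gate(cells, "MFI", 0.2, 0.2)
  expect_equal(sum(out$gate == "high"), 60L)
  expect_equal(sum(out$gate == "low"), 60L)
  # raising a low cell's intensity above the high cut moves it to high
  lo <- which(out$gate == "low")[1]
  cells2 <- cells
  cells2$MFI[lo] <- max(cells$MFI) + 1
  out2 <- quantile_gate(cells2, "MFI", 0.2, 0.2)
  expect_equal(out2$gate[lo], "high")
  # permutation invariance
  perm <- sample.int(n)
  out_perm <- quantile_gate(cells[perm, ], "MFI", 0.2, 0.2)
  expect_identical(out_perm$gate, out$gate[perm])
})

test_that("gate edge cases error as specified", {
  empty <- make_cells(numeric(), numeric(), MFI = numeric())
  expect_error(quantile_gate(empty, "MFI"), class = "nbhood_empty_error")
  const <- make_cells(1:5, rep(0, 5), MFI = rep(2, 5))
  expect_error(quantile_gate(const, "MFI"), class = "nbhood_ties_error")
  cells <- make_cells(1:10, rep(0, 10), MFI = as.numeric(1:10))
  expect_error(quantile_gate(cells, "MFI", 0.6, 0.6),
               class = "nbhood_parameter_error")
  expect_warning(
    quantile_gate(make_cells(1:5, rep(0, 5), MFI = c(1, 2, 3, 9, 9)),
                  "MFI", 0.2, 0.2),
    "Ties"
  )
})

test_that("lipid flag is a strict threshold, independent of phenotype", {
  cells <- make_cells(1:3, rep(0, 3), LipidSpot = c(0, 0.5, 2),
                      phenotype = c("TAM", "TSC", "TAM"))
  out <- assign_lipid_flag(cells, "LipidSpot", 0)
  expect_equal(out$lipid_positive, c(FALSE, TRUE, TRUE)) # 0 is not > 0
  all_pos <- assign_lipid_flag(cells, "LipidSpot", -1)
  expect_true(all(all_pos$lipid_positive))
  expect_identical(out$phenotype, cells$phenotype)
  expect_error(assign_lipid_flag(cells, "NileRed", 1),
               class = "nbhood_configuration_error")
})

test_that("lipid flags match the elementwise oracle on random cells", {
  set.seed(5)
  n <- 500
  v <- runif(n, 0, 10)
  thr <- 4.2
  cells <- make_cells(runif(n), runif(n), LipidSpot = v)
  out <- assign_lipid_flag(cells, "LipidSpot", thr)
  oracle <- vapply(seq_len(n), function(i) v[i] > thr, logical(1))
  expect_identical(out$lipid_positive, oracle)
})
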