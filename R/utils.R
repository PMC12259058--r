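# Internal helpers shared across modules.

# Squared-distance-free Euclidean distance between one point and many.
dist_to_points <- function(x0, y0, x, y) {
  sqrt((x - x0)^2 + (y - y0)^2)
}

# Full cross-distance matrix between two point sets, computed in row chunks to
# bound memory (nrow(chunk) * length(xt) doubles at a time).
cross_dist <- function(xf, yf, xt, yt, chunk = 2000L) {
  nf <- length(xf)
  nt <- length(xt)
  out <- matrix(NA_real_, nrow = nf, ncol = nt)
  if (nf == 0L || nt == 0L) return(out)
  starts <- seq.int(1L, nf, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, nf)
    dx <- outer(xf[s:e], xt, "-")
    dy <- outer(yf[s:e], yt, "-")
    out[s:e, ] <- sqrt(dx * dx + dy * dy)
  }
  out
}

# Mean of the k smallest values of a vector. The k values are averaged in
# ascending order so the result is reproducible bit-for-bit regardless of the
# input ordering.
mean_k_smallest <- function(d, k) {
  if (k >= length(d)) return(mean(sort(d)))
  mean(sort(sort(d, partial = k)[seq_len(k)]))
}

assert_single_roi <- function(cells, call = rlang::caller_env()) {
  ids <- unique(cells$roi_id)
  if (length(ids) > 1L) {
    abort(
      paste0(
        "Cells from multiple ROIs share one coordinate frame call (found: ",
        paste(ids, collapse = ", "),
        "). Compute per ROI, e.g. via neighborhood_metrics()."
      ),
      class = "nbhood_frame_error", call = call
    )
  }
  invisible(ids)
}

assert_phenotyped <- function(cells, call = rlang::caller_env()) {
  if (!"phenotype" %in% names(cells) || anyNA(cells$phenotype)) {
    abort(
      "Cells carry no complete phenotype labels; run classify_cells() first.",
      class = "nbhood_state_error", call = call
    )
  }
  invisible(TRUE)
}

# Standard error of the mean, NA-safe; NA for n < 2.
sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
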