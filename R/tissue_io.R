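# Reading and writing segmented-cell tables, ROI geometry and result
# summaries. All coordinates are stored in micrometers after ingestion, image
# convention: origin top-left, x rightward, y downward.

#' Read a segmented-cell table
#'
#' Reads a delimited (comma or tab) export of a cell-segmentation pipeline
#' (one row per cell) into the standard cell table used throughout the
#' package. Pixel coordinates are converted to micrometers by multiplying by
#' `pixel_size_um`; the scale is a required input because segmentation exports
#' never carry it reliably.
#'
#' @param path Path to a CSV/TSV file with a header row.
#' @param schema Named character vector mapping the standard roles to the
#'   file's column names. Required roles: `cell_id`, `x`, `y`; optional:
#'   `roi_id` (defaults to a single ROI named `"roi1"`), `intensities`
#'   (character vector of marker-intensity column names; by default every
#'   remaining numeric column is treated as a marker intensity).
#' @param pixel_size_um Micrometers per pixel (> 0). Use 1 when the export is
#'   already in micrometers.
#' @param delim Field delimiter; `NULL` (default) guesses from the file
#'   extension (`.tsv`/`.txt` means tab, otherwise comma).
#'
#' @return A tibble of class `nbhood_cells` with columns `cell_id`, `roi_id`,
#'   `x_um`, `y_um`, one numeric column per marker, plus `phenotype`
#'   (`NA` until [classify_cells()]) and `lipid_positive` (`NA` until
#'   [assign_lipid_flag()]).
#'
#' @examples
#' path <- tempfile(fileext = ".csv")
#' writeLines(c("id,px,py,FABP7", "c1,10,20,4.5", "c2,30,40,0.2"), path)
#' read_cell_table(path, schema = c(cell_id = "id", x = "px", y = "py"),
#'                 pixel_size_um = 0.5)
#' @export
read_cell_table <- function(path, schema, pixel_size_um, delim = NULL) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "nbhood_io_error")
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    abort("`pixel_size_um` must be a single positive number.",
          class = "nbhood_parameter_error")
  }
  for (role in c("cell_id", "x", "y")) {
    if (!role %in% names(schema)) {
      abort(paste0("`schema` must name a `", role, "` column."),
            class = "nbhood_schema_error")
    }
  }
  delim <- delim %||%
    (if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ",")
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(),
                           show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(unname(schema[c("cell_id", "x", "y")]), names(raw))
  if (length(missing_cols) > 0L) {
    abort(paste0("Column(s) missing from ", path, ": ",
                 paste(missing_cols, collapse = ", ")),
          class = "nbhood_schema_error")
  }

  coerce_coord <- function(col_name) {
    v <- raw[[col_name]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v))
    if (length(bad) > 0L) {
      # +1 for the header row so the number matches the file line.
      abort(paste0("Non-numeric coordinate in column '", col_name,
                   "' at file line(s): ",
                   paste(head(bad + 1L, 10L), collapse = ", ")),
            class = "nbhood_parse_error")
    }
    num
  }
  x_px <- coerce_coord(schema[["x"]])
  y_px <- coerce_coord(schema[["y"]])

  cells <- tibble::tibble(
    cell_id = as.character(raw[[schema[["cell_id"]]]]),
    roi_id = if ("roi_id" %in% names(schema)) {
      as.character(raw[[schema[["roi_id"]]]])
    } else {
      "roi1"
    },
    x_um = x_px * pixel_size_um,
    y_um = y_px * pixel_size_um
  )

  marker_cols <- if ("intensities" %in% names(schema) ||
                     any(startsWith(names(schema), "intensities"))) {
    sch <- as.list(schema)
    unname(unlist(sch[startsWith(names(sch), "intensities")]))
  } else {
    used <- unname(schema[c("cell_id", "x", "y",
                            intersect("roi_id", names(schema)))])
    names(raw)[vapply(raw, is.numeric, logical(1)) & !names(raw) %in% used]
  }
  for (m in marker_cols) {
    if (!m %in% names(raw)) {
      abort(paste0("Intensity column missing: ", m),
            class = "nbhood_schema_error")
    }
    cells[[m]] <- as.numeric(raw[[m]])
  }
  as_cell_table(cells, markers = marker_cols)
}

#' Construct / validate a cell table
#'
#' Validates the invariants of a segmented-cell tibble (finite coordinates,
#' non-negative intensities, unique `cell_id` within each ROI) and tags it so
#' downstream functions know which columns hold marker intensities.
#'
#' @param cells A data frame with columns `cell_id`, `roi_id`, `x_um`, `y_um`
#'   and numeric marker columns.
#' @param markers Character vector of marker column names; by default every
#'   numeric column other than the coordinates.
#' @return The validated tibble, with `phenotype` / `lipid_positive` columns
#'   added when absent.
#' @export
as_cell_table <- function(cells, markers = NULL) {
  cells <- tibble::as_tibble(cells)
  for (col in c("cell_id", "roi_id", "x_um", "y_um")) {
    if (!col %in% names(cells)) {
      abort(paste0("Cell table lacks required column `", col, "`."),
            class = "nbhood_schema_error")
    }
  }
  if (!all(is.finite(cells$x_um)) || !all(is.finite(cells$y_um))) {
    abort("Cell coordinates must be finite.", class = "nbhood_invariant_error")
  }
  markers <- markers %||% setdiff(
    names(cells)[vapply(cells, is.numeric, logical(1))],
    c("x_um", "y_um")
  )
  for (m in markers) {
    if (any(cells[[m]] < 0, na.rm = TRUE)) {
      abort(paste0("Marker intensities must be non-negative (column '", m,
                   "')."), class = "nbhood_invariant_error")
    }
  }
  dup <- cells |>
    dplyr::count(.data$roi_id, .data$cell_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup) > 0L) {
    abort(paste0("Duplicated cell_id within ROI: ",
                 paste(paste0(dup$roi_id, "/", dup$cell_id), collapse = ", ")),
          class = "nbhood_invariant_error")
  }
  if (!"phenotype" %in% names(cells)) cells$phenotype <- NA_character_
  if (!"lipid_positive" %in% names(cells)) cells$lipid_positive <- NA
  attr(cells, "markers") <- markers
  class(cells) <- unique(c("nbhood_cells", class(cells)))
  cells
}

#' Marker columns of a cell table
#'
#' @param cells A cell table from [as_cell_table()] or [read_cell_table()].
#' @return Character vector of marker-intensity column names.
#' @export
markers <- function(cells) attr(cells, "markers") %||% character()

#' Define a rectangular region of interest
#'
#' @param roi_id ROI identifier.
#' @param xmin,xmax,ymin,ymax Axis-aligned bounds in micrometers
#'   (`xmax > xmin`, `ymax > ymin`).
#' @param region_class Region label, e.g. `"TRPC"`, `"TSC"`, `"treated"`,
#'   `"control"`, `"other"`.
#' @param pixel_size_um Micrometers per pixel of the source image.
#' @return A one-row `nbhood_roi` tibble; bind several with [dplyr::bind_rows()].
#' @export
roi_rect <- function(roi_id, xmin, xmax, ymin, ymax,
                     region_class = "other", pixel_size_um = 1) {
  if (!(xmax > xmin) || !(ymax > ymin)) {
    abort("ROI bounds need xmax > xmin and ymax > ymin.",
          class = "nbhood_invariant_error")
  }
  out <- tibble::tibble(
    roi_id = as.character(roi_id), region_class = as.character(region_class),
    xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax,
    pixel_size_um = pixel_size_um, boundary = list(NULL)
  )
  class(out) <- unique(c("nbhood_roi", class(out)))
  out
}

#' Define a polygonal region of interest
#'
#' @inheritParams roi_rect
#' @param vertices Two-column matrix (x, y in micrometers) of polygon vertices
#'   in order; the polygon is closed implicitly and must be simple.
#' @return A one-row `nbhood_roi` tibble with the polygon in the `boundary`
#'   list-column; bounds are the polygon's bounding box.
#' @export
roi_polygon <- function(roi_id, vertices, region_class = "other",
                        pixel_size_um = 1) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2L || nrow(vertices) < 3L) {
    abort("`vertices` must be an n x 2 matrix with n >= 3.",
          class = "nbhood_parameter_error")
  }
  # Drop an explicitly repeated closing vertex.
  if (all(vertices[1, ] == vertices[nrow(vertices), ])) {
    vertices <- vertices[-nrow(vertices), , drop = FALSE]
  }
  out <- roi_rect(roi_id,
                  xmin = min(vertices[, 1]), xmax = max(vertices[, 1]),
                  ymin = min(vertices[, 2]), ymax = max(vertices[, 2]),
                  region_class = region_class, pixel_size_um = pixel_size_um)
  out$boundary <- list(unname(vertices))
  out
}

#' Read an ROI metadata table
#'
#' Expects a CSV with columns `roi_id`, `region_class`, `xmin`, `xmax`,
#' `ymin`, `ymax` and optionally `pixel_size_um` (bounds already in
#' micrometers unless `pixel_size_um` is supplied here, in which case pixel
#' bounds are converted).
#'
#' @param path CSV file path.
#' @param pixel_size_um Optional scale applied to the bounds.
#' @return An `nbhood_roi` tibble, one row per ROI.
#' @export
read_roi_table <- function(path, pixel_size_um = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  needed <- c("roi_id", "region_class", "xmin", "xmax", "ymin", "ymax")
  miss <- setdiff(needed, names(raw))
  if (length(miss) > 0L) {
    abort(paste0("ROI table lacks column(s): ", paste(miss, collapse = ", ")),
          class = "nbhood_schema_error")
  }
  scale <- pixel_size_um %||% 1
  rois <- purrr::pmap(raw[needed], function(roi_id, region_class,
                                            xmin, xmax, ymin, ymax) {
    roi_rect(roi_id, xmin * scale, xmax * scale, ymin * scale, ymax * scale,
             region_class = region_class,
             pixel_size_um = pixel_size_um %||% 1)
  })
  dplyr::bind_rows(rois)
}

roi_row <- function(rois, roi_id) {
  i <- match(roi_id, rois$roi_id)
  if (is.na(i)) {
    abort(paste0("Unknown ROI: ", roi_id), class = "nbhood_parameter_error")
  }
  rois[i, ]
}

#' Write and read region summaries
#'
#' `write_summary()` writes a summary tibble (e.g. from
#' [summarize_by_region()]) either as delimited CSV or as a structured
#' key-value text report. Numeric fields round-trip at full double precision:
#' `read_summary(write_summary(x))` reproduces every value exactly.
#'
#' @param summaries A data frame of summary rows.
#' @param path Output file path.
#' @param format `"delimited"` (CSV) or `"structured"` (key-value blocks).
#' @return `write_summary()` returns `path` invisibly; `read_summary()`
#'   returns a tibble.
#' @export
write_summary <- function(summaries, path, format = c("delimited", "structured")) {
  format <- match.arg(format)
  summaries <- tibble::as_tibble(as.data.frame(summaries))
  ok <- tryCatch({
    if (format == "delimited") {
      readr::write_csv(summaries, path, progress = FALSE)
    } else {
      lines <- c("# nbhood summary v1",
                 paste0("columns: ", paste(names(summaries), collapse = "\t")))
      fmt_val <- function(v) {
        if (is.numeric(v)) sprintf("%.17g", v) else as.character(v)
      }
      for (i in seq_len(nrow(summaries))) {
        lines <- c(lines, paste0("record ", i))
        for (col in names(summaries)) {
          lines <- c(lines, paste0("  ", col, " = ",
                                   fmt_val(summaries[[col]][i])))
        }
      }
      writeLines(lines, path)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort(paste0("Cannot write summary to ", path, ": ",
                 conditionMessage(ok)), class = "nbhood_io_error")
  }
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path, format = c("delimited", "structured")) {
  format <- match.arg(format)
  if (format == "delimited") {
    return(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
  }
  lines <- readLines(path)
  col_line <- sub("^columns: ", "", lines[2])
  cols <- strsplit(col_line, "\t", fixed = TRUE)[[1]]
  body <- lines[-(1:2)]
  rec_starts <- grep("^record ", body)
  rows <- purrr::map(rec_starts, function(s) {
    e <- if (s == max(rec_starts)) length(body) else {
      rec_starts[which(rec_starts == s) + 1L] - 1L
    }
    kv <- body[(s + 1L):e]
    keys <- sub("^  ([^=]+) = .*$", "\\1", kv)
    vals <- sub("^  [^=]+ = ", "", kv)
    setNames(as.list(vals), trimws(keys))
  })
  out <- dplyr::bind_rows(purrr::map(rows, tibble::as_tibble))
  out <- out[, cols, drop = FALSE]
  # Restore numeric columns (full-precision %.17g strings parse exactly).
  for (col in names(out)) {
    num <- suppressWarnings(as.numeric(out[[col]]))
    if (!anyNA(num) || all(is.na(num) == (out[[col]] %in% c("NA", "")))) {
      out[[col]] <- num
    }
  }
  out
}
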