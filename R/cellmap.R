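#' Construct and validate a cell map
#'
#' A `cell_map` is the central container of the package: one row per
#' segmented cell, carrying its centroid in micrometres, its sample of
#' origin, its cell-type label and an optional broader lineage label.
#' Every downstream analysis (neighborhood enrichment, colocalization,
#' niches, TLS detection) consumes a `cell_map` and operates strictly
#' within samples.
#'
#' @param cell_id character vector, unique within each sample.
#' @param x,y numeric centroid coordinates in micrometres.
#' @param cell_type character cell-type labels; must be non-empty.
#' @param sample_id character sample labels; defaults to `"sample1"`.
#' @param lineage optional character lineage labels (e.g. `"T"`,
#'   `"B/plasma"`, `"Myeloid"`, `"Stromal"`).
#' @return a `data.frame` with class `cell_map`.
#' @export
cell_map <- function(cell_id, x, y, cell_type,
                     sample_id = "sample1", lineage = NULL) {
  df <- data.frame(
    cell_id = as.character(cell_id),
    sample_id = rep_len(as.character(sample_id), length(cell_id)),
    x = as.numeric(x),
    y = as.numeric(y),
    cell_type = as.character(cell_type),
    stringsAsFactors = FALSE
  )
  if (!is.null(lineage)) df$lineage <- rep_len(as.character(lineage), nrow(df))
  validate_cell_map(df)
  class(df) <- c("cell_map", "data.frame")
  df
}

#' @rdname cell_map
#' @param cells object to validate.
#' @export
validate_cell_map <- function(cells) {
  stopifnot(is.data.frame(cells))
  need <- c("cell_id", "sample_id", "x", "y", "cell_type")
  missing_cols <- setdiff(need, names(cells))
  if (length(missing_cols)) {
    stop("cell map is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(cells) < 1L) stop("cell map must contain at least one cell")
  if (!all(is.finite(cells$x)) || !all(is.finite(cells$y))) {
    stop("cell coordinates must be finite")
  }
  ct <- cells$cell_type
  if (anyNA(ct) || any(!nzchar(ct))) stop("every cell needs a non-empty cell_type")
  dup <- stats::ave(seq_len(nrow(cells)), cells$sample_id, cells$cell_id,
                    FUN = length)
  if (any(dup > 1L)) {
    bad <- unique(cells$cell_id[dup > 1L])
    stop("duplicate cell_id within sample: ", paste(head(bad, 5), collapse = ", "))
  }
  invisible(cells)
}

#' Read a delimited cell table into a cell map
#'
#' Reads a per-cell CSV/TSV in the Xenium `cells.csv` dialect (columns
#' `cell_id`, `x_centroid`, `y_centroid` plus a label column) or any
#' dialect via `column_map`. Rows whose label is missing or empty are
#' dropped with a logged count: all analyses here are conditional on a
#' label, so unlabeled cells carry no information.
#'
#' @param path path to a delimited text file.
#' @param column_map named character vector mapping the canonical names
#'   `cell_id`, `x`, `y`, `cell_type` (and optionally `sample_id`,
#'   `lineage`) to columns in the file.
#' @param unit_scale micrometres per coordinate unit; coordinates are
#'   multiplied by this (e.g. 0.2125 for Xenium pixel coordinates).
#' @param sample_id sample label used when the file has no sample column.
#' @return a [cell_map] in the file's row order (after filtering).
#' @export
read_cell_table <- function(path,
                            column_map = c(cell_id = "cell_id",
                                           x = "x_centroid",
                                           y = "y_centroid",
                                           cell_type = "cell_type"),
                            unit_scale = 1,
                            sample_id = "sample1") {
  if (!file.exists(path)) stop("file not found: ", path)
  stopifnot(is.numeric(unit_scale), unit_scale > 0)
  raw <- data.table::fread(path, data.table = FALSE, showProgress = FALSE)
  need <- c("cell_id", "x", "y", "cell_type")
  if (!all(need %in% names(column_map))) {
    stop("column_map must map: ", paste(setdiff(need, names(column_map)),
                                        collapse = ", "))
  }
  absent <- setdiff(unname(column_map), names(raw))
  if (length(absent)) {
    stop("mapped column(s) not in file: ", paste(absent, collapse = ", "))
  }
  lab <- as.character(raw[[column_map[["cell_type"]]]])
  keep <- !is.na(lab) & nzchar(lab)
  n_drop <- sum(!keep)
  if (n_drop > 0) sc_log("dropped ", n_drop, " unlabeled cell(s)")
  raw <- raw[keep, , drop = FALSE]
  sid <- if ("sample_id" %in% names(column_map) &&
             column_map[["sample_id"]] %in% names(raw)) {
    as.character(raw[[column_map[["sample_id"]]]])
  } else {
    rep(sample_id, nrow(raw))
  }
  lin <- if ("lineage" %in% names(column_map) &&
             column_map[["lineage"]] %in% names(raw)) {
    as.character(raw[[column_map[["lineage"]]]])
  } else NULL
  out <- cell_map(
    cell_id = raw[[column_map[["cell_id"]]]],
    x = as.numeric(raw[[column_map[["x"]]]]) * unit_scale,
    y = as.numeric(raw[[column_map[["y"]]]]) * unit_scale,
    cell_type = raw[[column_map[["cell_type"]]]],
    sample_id = sid,
    lineage = lin
  )
  attr(out, "n_dropped_unlabeled") <- n_drop
  out
}

#' @export
print.cell_map <- function(x, ...) {
  cat(sprintf("cell_map: %d cells, %d sample(s), %d cell type(s)\n",
              nrow(x), length(unique(x$sample_id)),
              length(unique(x$cell_type))))
  NextMethod()
}
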