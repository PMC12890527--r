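#' Construct an expression matrix container
#'
#' Holds a sparse cells-by-genes matrix of nonnegative values together
#' with a flag recording whether log-normalization has been applied.
#'
#' @param values matrix or sparse Matrix, cells in rows, genes in columns.
#' @param cells character cell ids (row names).
#' @param genes character gene symbols (column names).
#' @param normalized logical; `TRUE` once [normalize_expression] has run.
#' @return an `expr_matrix` object.
#' @export
expr_matrix <- function(values, cells = rownames(values),
                        genes = colnames(values), normalized = FALSE) {
  if (!methods::is(values, "Matrix")) {
    values <- Matrix::Matrix(as.matrix(values), sparse = TRUE)
  }
  # force numeric general compressed-column storage whatever came in
  values <- methods::as(methods::as(methods::as(values * 1, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(cells) || is.null(genes)) {
    stop("cell ids and gene symbols are required")
  }
  cells <- as.character(cells); genes <- as.character(genes)
  if (nrow(values) != length(cells) || ncol(values) != length(genes)) {
    stop(sprintf("dimension mismatch: matrix %d x %d vs %d cells, %d genes",
                 nrow(values), ncol(values), length(cells), length(genes)))
  }
  if (any(values@x < 0)) stop("expression values must be nonnegative")
  dimnames(values) <- list(cells, genes)
  structure(list(values = values, cells = cells, genes = genes,
                 normalized = isTRUE(normalized)),
            class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d cells x %d genes (%s)\n",
              length(x$cells), length(x$genes),
              if (x$normalized) "log-normalized" else "raw counts"))
  invisible(x)
}

#' Read a 10x-style MatrixMarket triplet directory
#'
#' Expects `matrix.mtx`, `features.tsv` and `barcodes.tsv` (optionally
#' `.gz`, and `genes.tsv` accepted for `features.tsv`). The on-disk 10x
#' convention stores genes as rows; the result is always oriented cells
#' x genes with barcodes as cell ids.
#'
#' @param dir directory containing the triplet.
#' @return an [expr_matrix] of raw counts.
#' @export
read_expression_mtx <- function(dir) {
  find1 <- function(cands) {
    for (f in cands) {
      p <- file.path(dir, f)
      if (file.exists(p)) return(p)
    }
    stop("missing file in MTX directory ", dir, ": tried ",
         paste(cands, collapse = ", "))
  }
  mtx_p <- find1(c("matrix.mtx", "matrix.mtx.gz"))
  feat_p <- find1(c("features.tsv", "features.tsv.gz", "genes.tsv", "genes.tsv.gz"))
  bc_p <- find1(c("barcodes.tsv", "barcodes.tsv.gz"))
  m <- Matrix::readMM(mtx_p)
  feats <- data.table::fread(feat_p, header = FALSE, data.table = FALSE,
                             showProgress = FALSE)
  # 10x features.tsv: id, symbol, type; use symbol when present
  genes <- as.character(if (ncol(feats) >= 2) feats[[2]] else feats[[1]])
  barcodes <- as.character(data.table::fread(bc_p, header = FALSE,
                                             data.table = FALSE,
                                             showProgress = FALSE)[[1]])
  if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m) # genes-as-rows on disk -> cells x genes
  } else if (nrow(m) == length(barcodes) && ncol(m) == length(genes)) {
    # already cells x genes
  } else {
    stop(sprintf(
      "MTX header %d x %d matches neither %d features x %d barcodes nor its transpose",
      nrow(m), ncol(m), length(genes), length(barcodes)))
  }
  expr_matrix(m, cells = barcodes, genes = genes, normalized = FALSE)
}

#' Gene set container and GMT reader
#'
#' Gene symbols are normalized to uppercase so set membership is robust
#' to case conventions across annotation sources.
#'
#' @param name set name.
#' @param genes character vector of symbols.
#' @return a `gene_set` object.
#' @export
gene_set <- function(name, genes) {
  genes <- unique(toupper(as.character(genes)))
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("gene set '", name, "' is empty")
  structure(list(name = as.character(name), genes = genes), class = "gene_set")
}

#' @rdname gene_set
#' @param path path to a GMT file (name, description, genes... per line).
#' @return `read_gmt`: a named list of `gene_set` objects.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stop("malformed GMT line: ", substr(l, 1, 60))
    gene_set(parts[1], parts[-(1:2)])
  })
  setNames(sets, vapply(sets, `[[`, "", "name"))
}
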