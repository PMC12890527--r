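# TSV serialization shared by every result type: header line, floats at 6
# significant digits, infinities spelled "inf" so they survive round-trips,
# and a deterministic row order supplied by the per-type as.data.frame
# method (each result class sorts by its natural key before writing).

format_num <- function(v) {
  out <- character(length(v))
  out[is.na(v)] <- "NA"
  inf <- !is.na(v) & is.infinite(v)
  out[inf] <- ifelse(v[inf] > 0, "inf", "-inf")
  fin <- !is.na(v) & is.finite(v)
  out[fin] <- formatC(signif(v[fin], 6), digits = 6, format = "g")
  out
}

#' Write an analysis result as a TSV file
#'
#' Generic writer used by every result type in the package. Output has a
#' header line, floats at 6 significant digits, `inf` for infinite
#' distances and a deterministic, documented row order (see each result
#' class). A file written here is read back value-preservingly (at the
#' stated precision) by [read_result_table].
#'
#' @param result a result object (enrichment, colocalization field, niche
#'   assignment, TLS region set, or any data.frame).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(result, path) {
  if (is.null(result)) stop("result is NULL")
  UseMethod("write_result_table")
}

write_tsv_impl <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- format_num(out[[j]])
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot open for writing: ", path)
  })
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' @export
write_result_table.data.frame <- function(result, path) {
  write_tsv_impl(result, path)
}

#' @export
write_result_table.default <- function(result, path) {
  write_tsv_impl(as.data.frame(result), path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "NA",
                          check.names = FALSE)
  for (j in seq_along(df)) {
    if (is.character(df[[j]]) && all(df[[j]] %in% c("inf", "-inf", "NA") |
                                     !is.na(suppressWarnings(as.numeric(df[[j]]))),
                                     na.rm = TRUE) &&
        any(df[[j]] %in% c("inf", "-inf"), na.rm = TRUE)) {
      v <- df[[j]]
      v[v == "inf"] <- "Inf"; v[v == "-inf"] <- "-Inf"
      df[[j]] <- as.numeric(v)
    }
  }
  df
}
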