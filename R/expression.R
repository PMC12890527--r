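#' Median-total log-normalization
#'
#' Scales each cell's counts so its total equals the median per-cell
#' total, then applies `log(1 + x)`. Refuses to run twice (the
#' `normalized` flag guards idempotence). All-zero cells are retained as
#' zeros with a warning.
#'
#' @param expr a raw-count [expr_matrix].
#' @return a normalized [expr_matrix].
#' @export
normalize_expression <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$normalized) stop("expression is already normalized")
  totals <- Matrix::rowSums(expr$values)
  med <- median(totals[totals > 0])
  if (any(totals == 0)) {
    warning(sum(totals == 0), " all-zero cell(s) retained as zeros")
  }
  sf <- ifelse(totals > 0, med / totals, 0)
  v <- Matrix::Diagonal(x = sf) %*% expr$values
  v@x <- log1p(v@x)
  expr_matrix(v, cells = expr$cells, genes = expr$genes, normalized = TRUE)
}

#' Control-matched gene-module score
#'
#' Per-cell mean expression of the set genes minus the mean over matched
#' control genes: genes are ranked by average expression and split into
#' `n_bins` equal-frequency bins; each set gene contributes
#' `n_ctrl_per_gene` controls drawn (seeded, without replacement where
#' the bin allows) from its own bin. This cancels depth and
#' detection-efficiency effects, so the score reflects set-specific
#' signal. Set genes absent from the matrix are dropped with a log
#' message; an empty intersection is an error.
#'
#' @param expr a normalized [expr_matrix].
#' @param gene_set a [gene_set].
#' @param config list with `n_bins` (default 25), `n_ctrl_per_gene`
#'   (default 50) and `seed`.
#' @return named numeric vector, one score per cell.
#' @export
module_score <- function(expr, gene_set,
                         config = list(n_bins = 25, n_ctrl_per_gene = 50,
                                       seed = 1)) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(gene_set, "gene_set"))
  n_bins <- config$n_bins %||% 25
  n_ctrl <- config$n_ctrl_per_gene %||% 50
  seed <- config$seed %||% 1
  stopifnot(n_bins >= 2, n_ctrl >= 1)
  genes_up <- toupper(expr$genes)
  present <- which(genes_up %in% gene_set$genes)
  missing <- setdiff(gene_set$genes, genes_up)
  if (length(missing)) {
    sc_log("module_score('", gene_set$name, "'): ", length(missing),
           " set gene(s) absent: ", paste(head(missing, 5), collapse = ", "))
  }
  if (!length(present)) {
    stop("no gene of set '", gene_set$name, "' present in the matrix")
  }
  avg <- Matrix::colMeans(expr$values)
  # equal-frequency bins on average expression (ties broken by index)
  rk <- rank(avg, ties.method = "first")
  bin <- ceiling(rk / length(avg) * n_bins)
  ctrl_idx <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      pool <- setdiff(which(bin == bin[g]), g)
      if (!length(pool)) return(integer(0))
      if (length(pool) <= n_ctrl) pool
      else sort(sample(pool, n_ctrl))
    }), use.names = FALSE)
  })
  set_mean <- Matrix::rowMeans(expr$values[, present, drop = FALSE])
  ctrl_mean <- if (length(ctrl_idx)) {
    # controls keep multiplicity: each set gene contributes its own draw
    Matrix::rowMeans(expr$values[, ctrl_idx, drop = FALSE])
  } else {
    warning("no control genes available; score is the raw set mean")
    0
  }
  out <- as.numeric(set_mean - ctrl_mean)
  names(out) <- expr$cells
  out
}

#' Distance-binned expression / score profile
#'
#' Bins cells by their distance to the nearest cell of a target type and
#' reports the per-bin mean of each queried gene or per-cell score.
#' The accompanying Spearman statistic is computed on the unbinned
#' per-cell (distance, value) pairs — bins are display resolution only.
#'
#' @param values named list of per-cell numeric vectors (scores), or an
#'   [expr_matrix] with `genes` naming columns to profile.
#' @param distance a `distance_field` from [nearest_distance_to_type].
#' @param bin_width bin width in micrometres (default 10).
#' @param max_dist upper range in micrometres (default 300); cells beyond
#'   are excluded.
#' @param genes genes to profile when `values` is an [expr_matrix].
#' @return a `distance_profile`: `$bins` (lo, hi, mid), `$means` (bin x
#'   variable), `$counts`, `$spearman` (rho, p, n per variable).
#' @export
binned_distance_profile <- function(values, distance, bin_width = 10,
                                    max_dist = 300, genes = NULL) {
  stopifnot(inherits(distance, "distance_field"), bin_width > 0,
            max_dist > bin_width)
  if (inherits(values, "expr_matrix")) {
    stopifnot(!is.null(genes))
    m <- match(distance$cell_id, values$cells)
    if (anyNA(m)) stop("distance field contains cells absent from the matrix")
    bad <- setdiff(genes, values$genes)
    if (length(bad)) stop("gene(s) absent: ", paste(bad, collapse = ", "))
    vlist <- lapply(genes, function(g) as.numeric(values$values[m, g]))
    names(vlist) <- genes
  } else {
    if (!is.list(values)) values <- list(value = values)
    vlist <- lapply(values, function(v) {
      stopifnot(length(v) == length(distance$distance))
      as.numeric(v)
    })
  }
  d <- distance$distance
  in_range <- is.finite(d) & d < max_dist
  if (sum(in_range) < 10) stop("fewer than 10 cells with finite distance in range")
  lo <- seq(0, max_dist - bin_width, by = bin_width)
  hi <- lo + bin_width
  bin_of <- findInterval(d[in_range], c(lo, max_dist),
                         rightmost.closed = FALSE)
  nb <- length(lo)
  counts <- tabulate(bin_of, nb)
  means <- sapply(vlist, function(v) {
    vv <- v[in_range]
    out <- rep(NA_real_, nb)
    agg <- rowsum(vv, bin_of)
    out[as.integer(rownames(agg))] <- agg / counts[as.integer(rownames(agg))]
    out
  })
  means <- matrix(means, nrow = nb,
                  dimnames = list(NULL, names(vlist)))
  spear <- lapply(vlist, function(v) spearman_cor(d[in_range], v[in_range]))
  structure(list(bins = data.frame(lo = lo, hi = hi, mid = (lo + hi) / 2),
                 counts = counts, means = means,
                 spearman = data.frame(
                   variable = names(vlist),
                   rho = vapply(spear, function(s) s$rho, 1),
                   p = vapply(spear, function(s) s$p, 1),
                   n = vapply(spear, function(s) s$n, 1),
                   stringsAsFactors = FALSE),
                 target_type = distance$target_type),
            class = "distance_profile")
}

#' @export
as.data.frame.distance_profile <- function(x, ...) {
  df <- cbind(x$bins, n_cells = x$counts, as.data.frame(x$means))
  df[order(df$lo), , drop = FALSE]
}

#' @export
write_result_table.distance_profile <- function(result, path) {
  write_tsv_impl(as.data.frame(result), path)
}

#' Spearman correlation between a per-cell score and a distance field
#'
#' @param score per-cell numeric vector aligned with the distance field.
#' @param distance a `distance_field`.
#' @param cells optional [cell_map] (needed when `subset_type` is given).
#' @param subset_type optional cell-type filter (e.g. restrict to
#'   macrophages).
#' @param min_cells minimum cells with finite distance (default 10).
#' @return list `(rho, p, n)`.
#' @export
correlate_score_distance <- function(score, distance, cells = NULL,
                                     subset_type = NULL, min_cells = 10) {
  stopifnot(inherits(distance, "distance_field"),
            length(score) == length(distance$distance))
  keep <- is.finite(distance$distance) & is.finite(score)
  if (!is.null(subset_type)) {
    stopifnot(!is.null(cells), nrow(cells) == length(score))
    keep <- keep & cells$cell_type %in% subset_type
  }
  if (sum(keep) < min_cells) {
    stop("only ", sum(keep), " usable cells (need >= ", min_cells, ")")
  }
  spearman_cor(score[keep], distance$distance[keep])
}

#' Per-cell gene-set score attached to spatial coordinates
#'
#' [module_score] followed by a join onto the cell map, for rendering
#' spatial maps of pathway activity; numerics are identical to
#' [module_score].
#'
#' @inheritParams module_score
#' @param cells a [cell_map]; only cells present in the matrix appear in
#'   the output.
#' @return data.frame `cell_id, sample_id, x, y, score`.
#' @export
spatial_gene_set_score_map <- function(expr, gene_set, cells,
                                       config = list(n_bins = 25,
                                                     n_ctrl_per_gene = 50,
                                                     seed = 1)) {
  validate_cell_map(cells)
  sc <- module_score(expr, gene_set, config)
  m <- match(cells$cell_id, names(sc))
  keep <- !is.na(m)
  data.frame(cell_id = cells$cell_id[keep], sample_id = cells$sample_id[keep],
             x = cells$x[keep], y = cells$y[keep],
             score = as.numeric(sc[m[keep]]), stringsAsFactors = FALSE)
}

#' Rank-sum comparison of a score across cell groups
#'
#' Thin utility wrapping the two-sided Wilcoxon rank-sum test for every
#' group against the rest, Benjamini-Hochberg adjusted.
#'
#' @param score per-cell numeric vector.
#' @param group per-cell group labels.
#' @return data.frame `group, n, median, median_rest, p, p_adj`.
#' @export
compare_score_groups <- function(score, group) {
  stopifnot(length(score) == length(group))
  groups <- sort(unique(as.character(group)))
  res <- lapply(groups, function(g) {
    a <- score[group == g]; b <- score[group != g]
    p <- if (length(a) >= 2 && length(b) >= 2) {
      suppressWarnings(wilcox.test(a, b)$p.value)
    } else NA_real_
    data.frame(group = g, n = length(a), median = median(a),
               median_rest = median(b), p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  out
}
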