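#' Configuration for single-spot colocalization scoring
#'
#' The score at a cell is the product of the kernel-weighted local masses
#' of the anchor type and the target type within `radius_um`; it is zero
#' unless both types are simultaneously present in the neighborhood and
#' grows as they pack closer. The default 10 um radius targets immediate
#' cell-cell contact distances; the linear kernel down-weights the edge
#' of the neighborhood smoothly. The Gaussian kernel uses
#' `sigma = radius/2`, truncated at the radius; `w(0) = 1` for every
#' kernel.
#'
#' @param radius_um neighborhood radius in micrometres (> 0).
#' @param kernel `"linear"` (default, `w(d) = 1 - d/radius`),
#'   `"uniform"`, or `"gaussian"`.
#' @param include_self whether a cell of the anchor/target type
#'   contributes `w(0) = 1` to its own type's mass.
#' @param evaluate_at `"all_cells"` (default) or `"anchor_cells"`.
#' @return a `coloc_config` list.
#' @export
coloc_config <- function(radius_um = 10,
                         kernel = c("linear", "uniform", "gaussian"),
                         include_self = TRUE,
                         evaluate_at = c("all_cells", "anchor_cells")) {
  kernel <- match.arg(kernel)
  evaluate_at <- match.arg(evaluate_at)
  if (!is.numeric(radius_um) || radius_um <= 0) stop("radius_um must be > 0")
  structure(list(radius_um = radius_um, kernel = kernel,
                 include_self = isTRUE(include_self),
                 evaluate_at = evaluate_at),
            class = "coloc_config")
}

kernel_weight <- function(d, config) {
  r <- config$radius_um
  switch(config$kernel,
         uniform = rep(1, length(d)),
         linear = 1 - d / r,
         gaussian = exp(-d^2 / (2 * (r / 2)^2)))
}

# Kernel-weighted mass of `type` cells around each evaluation cell,
# within one sample. eval_rows / type_rows are row indices into `cells`.
type_mass <- function(cells, eval_rows, type_rows, config) {
  if (!length(type_rows)) return(numeric(length(eval_rows)))
  if (config$include_self) {
    excl <- rep(0L, length(eval_rows))
  } else {
    excl <- match(eval_rows, type_rows)
    excl[is.na(excl)] <- 0L
  }
  res <- cpp_radius_cross(cells$x[eval_rows], cells$y[eval_rows],
                          cells$x[type_rows], cells$y[type_rows],
                          config$radius_um, excl)
  w <- kernel_weight(res$dist, config)
  off <- res$offsets
  out <- numeric(length(eval_rows))
  if (length(w)) {
    grp <- rep.int(seq_along(eval_rows), diff(off))
    agg <- rowsum(w, grp)
    out[as.integer(rownames(agg))] <- agg
  }
  out
}

#' Single-spot colocalization score field
#'
#' Per-cell score `f_anchor(i) * f_target(i)`, where `f_T(i)` is the sum
#' of kernel weights `w(d_ij)` over type-T cells within the radius of
#' cell i. High values mark spots where the two types coexist closely;
#' zero wherever either type contributes no mass. Computed strictly
#' within samples; a sample lacking either type yields a zero field there
#' with a warning.
#'
#' @param cells a [cell_map].
#' @param anchor_type,target_type cell-type labels (both must occur
#'   somewhere in `cells`).
#' @param config a [coloc_config].
#' @return a `coloc_field`: evaluation cell ids, coordinates and scores.
#' @export
coloc_score <- function(cells, anchor_type, target_type,
                        config = coloc_config()) {
  validate_cell_map(cells)
  for (ty in c(anchor_type, target_type)) {
    if (!any(cells$cell_type == ty)) stop("type '", ty, "' absent from cells")
  }
  n <- nrow(cells)
  eval_mask <- if (config$evaluate_at == "anchor_cells") {
    cells$cell_type == anchor_type
  } else rep(TRUE, n)
  score <- rep(NA_real_, n)
  for (s in unique(cells$sample_id)) {
    rows <- which(cells$sample_id == s)
    ev <- rows[eval_mask[rows]]
    if (!length(ev)) next
    a_rows <- rows[cells$cell_type[rows] == anchor_type]
    t_rows <- rows[cells$cell_type[rows] == target_type]
    if (!length(a_rows) || !length(t_rows)) {
      warning("sample '", s, "' lacks '",
              if (!length(a_rows)) anchor_type else target_type,
              "'; colocalization score is zero there")
      score[ev] <- 0
      next
    }
    fa <- type_mass(cells, ev, a_rows, config)
    ft <- type_mass(cells, ev, t_rows, config)
    score[ev] <- fa * ft
  }
  keep <- which(eval_mask)
  structure(list(anchor_type = anchor_type, target_type = target_type,
                 cell_id = cells$cell_id[keep],
                 sample_id = cells$sample_id[keep],
                 x = cells$x[keep], y = cells$y[keep],
                 score = score[keep], eval_rows = keep,
                 config = config),
            class = "coloc_field")
}

#' @export
as.data.frame.coloc_field <- function(x, ...) {
  df <- data.frame(cell_id = x$cell_id, sample_id = x$sample_id,
                   x = x$x, y = x$y, score = x$score,
                   stringsAsFactors = FALSE)
  if (!is.null(x$p_perm)) df$p_perm <- x$p_perm
  df[order(df$sample_id, df$cell_id), , drop = FALSE]
}

#' @export
write_result_table.coloc_field <- function(result, path) {
  write_tsv_impl(as.data.frame(result), path)
}

#' @export
print.coloc_field <- function(x, ...) {
  cat(sprintf("coloc_field: %s vs %s, %d cells, radius %g um (%s kernel)\n",
              x$anchor_type, x$target_type, length(x$score),
              x$config$radius_um, x$config$kernel))
  cat(sprintf("  score range [%.4g, %.4g], %.1f%% nonzero\n",
              min(x$score), max(x$score), 100 * mean(x$score > 0)))
  invisible(x)
}

#' Per-cell permutation significance for a colocalization field
#'
#' Empirical p-value per evaluation cell against a null built by
#' shuffling cell-type labels within each sample with coordinates fixed:
#' `p = (1 + #\{null score >= observed\}) / (n_perm + 1)`.
#'
#' @param cells the [cell_map] the field was computed on.
#' @param field a `coloc_field` from [coloc_score].
#' @param n_perm number of label shuffles (a warning is raised below 20,
#'   where the resolution floor `1/(n_perm+1)` exceeds 0.05).
#' @param seed master seed (sub-seeded per permutation by counter).
#' @return the field with a `$p_perm` vector attached.
#' @export
coloc_significance <- function(cells, field, n_perm = 200, seed = 1) {
  stopifnot(inherits(field, "coloc_field"))
  if (n_perm < 20) {
    warning("n_perm < 20: per-cell p-values cannot resolve below ",
            signif(1 / (n_perm + 1), 3))
  }
  lab <- cells$cell_type
  ev <- field$eval_rows
  obs <- field$score
  count_ge <- integer(length(ev))
  tol <- 1e-12
  sample_f <- factor(cells$sample_id)
  cfg_all <- field$config
  cfg_all$evaluate_at <- "all_cells" # evaluation set is fixed by position
  for (t in seq_len(n_perm)) {
    cp <- cells
    with_seed(perm_seed(seed, t), {
      cp$cell_type <- permute_labels_chr(lab, sample_f)
    })
    sc <- coloc_field_at(cp, field$anchor_type, field$target_type,
                         cfg_all, ev)
    count_ge <- count_ge + (sc >= obs - tol)
  }
  field$p_perm <- (1 + count_ge) / (n_perm + 1)
  field
}

permute_labels_chr <- function(lab, sample_f) {
  out <- lab
  for (rows in split(seq_along(lab), sample_f)) {
    out[rows] <- lab[rows][sample.int(length(rows))]
  }
  out
}

# Score at a fixed set of evaluation rows (used by the permutation null;
# types may be absent after shuffling, giving zero mass).
coloc_field_at <- function(cells, anchor_type, target_type, config, ev) {
  score <- numeric(length(ev))
  for (s in unique(cells$sample_id[ev])) {
    in_s <- cells$sample_id[ev] == s
    rows <- which(cells$sample_id == s)
    a_rows <- rows[cells$cell_type[rows] == anchor_type]
    t_rows <- rows[cells$cell_type[rows] == target_type]
    if (!length(a_rows) || !length(t_rows)) next
    fa <- type_mass(cells, ev[in_s], a_rows, config)
    ft <- type_mass(cells, ev[in_s], t_rows, config)
    score[in_s] <- fa * ft
  }
  score
}

#' Correlate externally inferred ligand-receptor signals with a
#' colocalization field
#'
#' Takes a per-cell signal table from an external ligand-receptor
#' inference tool (one row per cell, one column per `LIGAND-RECEPTOR`
#' pair) and ranks pairs by Spearman correlation of their signal with
#' the colocalization score over the overlapping cells.
#'
#' @param signal data.frame whose first column is `cell_id`, remaining
#'   columns numeric per-pair signals.
#' @param field a `coloc_field`.
#' @param min_overlap minimum number of shared cells (default 10).
#' @return data.frame with columns `lr_pair`, `rho`, `p`, `p_adj`, `n`,
#'   `note`, sorted by descending `rho` (NAs last).
#' @export
correlate_signal_with_coloc <- function(signal, field, min_overlap = 10) {
  stopifnot(is.data.frame(signal), ncol(signal) >= 2,
            inherits(field, "coloc_field"))
  ids <- as.character(signal[[1]])
  m <- match(field$cell_id, ids)
  keep <- !is.na(m)
  if (sum(keep) < min_overlap) {
    stop("only ", sum(keep), " overlapping cells (need >= ", min_overlap, ")")
  }
  sc <- field$score[keep]
  rows <- m[keep]
  pairs <- names(signal)[-1]
  res <- lapply(pairs, function(p) {
    v <- as.numeric(signal[[p]][rows])
    if (length(unique(v[is.finite(v)])) <= 1L) {
      return(data.frame(lr_pair = p, rho = NA_real_, p = NA_real_,
                        n = sum(is.finite(v)), note = "zero variance",
                        stringsAsFactors = FALSE))
    }
    ct <- spearman_cor(v, sc)
    data.frame(lr_pair = p, rho = ct$rho, p = ct$p, n = ct$n, note = "",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- bh_adjust(out$p)
  out <- out[order(-out$rho, out$lr_pair, na.last = TRUE),
             c("lr_pair", "rho", "p", "p_adj", "n", "note")]
  rownames(out) <- NULL
  out
}
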