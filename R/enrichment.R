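#' Configuration for the neighborhood enrichment test
#'
#' Defaults encode the validated operating point: a 30 um neighborhood
#' radius (the scale at which planted proximity is reliably detected),
#' 1000 label permutations, a 10-cell minimum per type, one-sided
#' enrichment, and label shuffling within sample so that differences in
#' sample composition cannot masquerade as spatial structure.
#'
#' @param query neighborhood descriptor, `list(mode = "radius",
#'   radius_um = 30)` by default; `list(mode = "knn", k = ...)` accepted.
#' @param n_perm number of label permutations (>= 1).
#' @param seed master seed; permutation `t` uses a sub-seed derived from
#'   it by counter, so results do not depend on how permutations are
#'   partitioned across workers.
#' @param min_cells_per_type a type below this count in every sample is
#'   not tested (its pairs are reported `skipped_low_count`).
#' @param alternative `"enrichment"` (default), `"depletion"`, or
#'   `"two-sided"`.
#' @param within_sample_permutation shuffle labels within each sample
#'   (default) or across the whole table.
#' @param threads accepted for interface compatibility; permutations are
#'   sub-seeded by counter, so results are identical for any value.
#' @return an `enrichment_config` list.
#' @export
enrichment_config <- function(query = list(mode = "radius", radius_um = 30),
                              n_perm = 1000, seed = 1,
                              min_cells_per_type = 10,
                              alternative = c("enrichment", "depletion",
                                              "two-sided"),
                              within_sample_permutation = TRUE,
                              threads = 1) {
  alternative <- match.arg(alternative)
  stopifnot(n_perm >= 1)
  if (identical(query$mode, "radius") &&
      (!is.numeric(query$radius_um) || query$radius_um <= 0)) {
    stop("radius_um must be > 0")
  }
  structure(list(query = query, n_perm = as.integer(n_perm),
                 seed = as.integer(seed),
                 min_cells_per_type = as.integer(min_cells_per_type),
                 alternative = alternative,
                 within_sample_permutation = isTRUE(within_sample_permutation),
                 threads = as.integer(threads)),
            class = "enrichment_config")
}

#' Per-cell neighborhood cell-type composition
#'
#' For each cell, the fraction of each cell type among its neighbors
#' under the graph's query. Cells with zero neighbors get an all-zero
#' row and are flagged in the `"no_neighbors"` attribute.
#'
#' @param cells a [cell_map].
#' @param graph a `neighbor_graph` built on `cells`.
#' @return numeric matrix, cells x types, rows summing to 1 (or 0 for
#'   isolated cells); attribute `no_neighbors` is a logical vector.
#' @export
neighborhood_composition <- function(cells, graph) {
  stopifnot(inherits(graph, "neighbor_graph"), graph$n == nrow(cells))
  types <- sort(unique(cells$cell_type))
  lab <- match(cells$cell_type, types)
  nT <- length(types)
  n <- nrow(cells)
  comp <- matrix(0, n, nT, dimnames = list(cells$cell_id, types))
  deg <- lengths(graph$idx)
  for (i in seq_len(n)) {
    if (deg[i] == 0L) next
    tb <- tabulate(lab[graph$idx[[i]]], nT)
    comp[i, ] <- tb / deg[i]
  }
  attr(comp, "no_neighbors") <- deg == 0L
  comp
}

# Flatten a neighbor graph to row-normalized edge triplets. ww[e] is
# 1/deg(anchor), so summing ww by (anchor type, neighbor type) gives the
# per-pair sum of neighbor fractions in O(edges) per permutation.
graph_edges <- function(graph) {
  deg <- lengths(graph$idx)
  ii <- rep.int(seq_len(graph$n), deg)
  jj <- unlist(graph$idx, use.names = FALSE)
  ww <- 1 / rep.int(pmax(deg, 1L), deg)
  list(ii = ii, jj = jj, ww = ww, has_nbr = deg > 0L)
}

# Directed pair statistic matrix for one labeling. Entry [a, b] is the
# mean, over type-a cells with >= 1 neighbor, of the neighbor fraction of
# type b. `lab` is an integer type index vector.
pair_stat_matrix <- function(lab, nT, edges) {
  num <- numeric(nT * nT)
  code <- (lab[edges$ii] - 1L) * nT + lab[edges$jj]
  agg <- rowsum(edges$ww, code)
  num[as.integer(rownames(agg))] <- agg
  num <- matrix(num, nT, nT, byrow = TRUE)
  den <- tabulate(lab[edges$has_nbr], nT)
  stat <- num / den
  stat[den == 0L, ] <- NA_real_
  stat
}

p_from_alternative <- function(c_ge, c_le, n_tot, alternative) {
  p_ge <- (1 + c_ge) / (n_tot + 1)
  p_le <- (1 + c_le) / (n_tot + 1)
  switch(alternative,
         enrichment = p_ge,
         depletion = p_le,
         `two-sided` = pmin(1, 2 * pmin(p_ge, p_le)))
}

#' Spatial neighborhood enrichment test
#'
#' For every directed cell-type pair (A, B), compares the observed mean
#' neighbor fraction of B around A-cells against a null built by
#' shuffling cell-type labels with coordinates fixed (within each sample
#' by default), recomputing the statistic `n_perm` times with a seeded
#' generator. Reports the permutation z-score, a permutation p-value and
#' Benjamini-Hochberg adjusted p across all tested directed pairs.
#' Anchor cells with zero neighbors are excluded from the mean, in the
#' observed data and in every permutation, to avoid sparsity bias.
#'
#' @param cells a [cell_map].
#' @param config an [enrichment_config].
#' @return an `enrichment_result` whose `$table` has one row per directed
#'   pair (including A to A), sorted by anchor then target type:
#'   `observed_stat`, `perm_mean`, `perm_sd`, `z`, `p_perm`, `p_adj`,
#'   `n_anchor_cells`, `status`.
#' @export
enrichment_test <- function(cells, config = enrichment_config()) {
  validate_cell_map(cells)
  graph <- build_neighbor_graph(cells, config$query)
  enrichment_core(cells, graph, config, mode = "montecarlo")
}

#' Exact enrichment null by exhaustive enumeration
#'
#' Identical contract to [enrichment_test], but the null enumerates every
#' distinct assignment of the observed label multiset to coordinates
#' (within each sample), so p-values are exact. Refuses when the number
#' of distinct labelings exceeds `max_labelings`. This is the small-n
#' oracle the Monte-Carlo test is validated against.
#'
#' @inheritParams enrichment_test
#' @param max_labelings enumeration bound (default 1e6).
#' @export
exhaustive_null <- function(cells, config = enrichment_config(),
                            max_labelings = 1e6) {
  validate_cell_map(cells)
  graph <- build_neighbor_graph(cells, config$query)
  enrichment_core(cells, graph, config, mode = "exhaustive",
                  max_labelings = max_labelings)
}

enrichment_core <- function(cells, graph, config, mode,
                            max_labelings = 1e6) {
  types <- sort(unique(cells$cell_type))
  nT <- length(types)
  lab <- match(cells$cell_type, types)
  sample_f <- factor(cells$sample_id)

  per_sample_counts <- table(cells$cell_type, cells$sample_id)
  tested_type <- apply(per_sample_counts, 1L,
                       function(r) any(r >= config$min_cells_per_type))
  tested_type <- tested_type[types]
  if (sum(tested_type) < 2L) {
    stop("fewer than 2 cell types pass min_cells_per_type = ",
         config$min_cells_per_type)
  }

  edges <- graph_edges(graph)
  obs <- pair_stat_matrix(lab, nT, edges)
  n_anchor <- tabulate(lab[edges$has_nbr], nT)

  tol <- 1e-12
  if (mode == "montecarlo") {
    n_null <- config$n_perm
    group_of <- if (config$within_sample_permutation) {
      as.integer(sample_f)
    } else {
      rep(1L, length(lab))
    }
    nul <- cpp_perm_null(edges$ii, edges$jj, edges$ww, lab, nT,
                         group_of, max(group_of), edges$has_nbr,
                         obs, n_null, config$seed)
    sum_s <- nul$sum; sum_s2 <- nul$sumsq
    c_ge <- nul$c_ge; c_le <- nul$c_le
    n_valid <- nul$n_valid
    denom_p <- n_null
  } else {
    labelings <- enumerate_labelings(lab, sample_f, nT, max_labelings)
    n_null <- nrow(labelings)
    sum_s <- matrix(0, nT, nT); sum_s2 <- matrix(0, nT, nT)
    c_ge <- matrix(0L, nT, nT); c_le <- matrix(0L, nT, nT)
    n_valid <- matrix(0L, nT, nT)
    for (t in seq_len(n_null)) {
      s <- pair_stat_matrix(labelings[t, ], nT, edges)
      ok <- !is.na(s) & !is.na(obs)
      sum_s[ok] <- sum_s[ok] + s[ok]
      sum_s2[ok] <- sum_s2[ok] + s[ok]^2
      n_valid[ok] <- n_valid[ok] + 1L
      c_ge[ok] <- c_ge[ok] + (s[ok] >= obs[ok] - tol)
      c_le[ok] <- c_le[ok] + (s[ok] <= obs[ok] + tol)
    }
    # exact p over the full enumeration (observed labeling is included)
    denom_p <- NULL
  }

  perm_mean <- sum_s / n_valid
  perm_var <- pmax(0, sum_s2 / n_valid - perm_mean^2)
  perm_sd <- sqrt(perm_var)
  z <- (obs - perm_mean) / perm_sd
  z[perm_sd == 0 | !is.finite(perm_sd)] <- NA_real_

  if (mode == "montecarlo") {
    p_perm <- p_from_alternative(c_ge, c_le, denom_p, config$alternative)
  } else {
    p_ge <- c_ge / n_valid
    p_le <- c_le / n_valid
    p_perm <- switch(config$alternative,
                     enrichment = p_ge,
                     depletion = p_le,
                     `two-sided` = pmin(1, 2 * pmin(p_ge, p_le)))
  }
  p_perm[is.na(obs)] <- NA_real_

  pair_tested <- outer(tested_type, tested_type, `&`)
  tab <- data.frame(
    anchor_type = rep(types, each = nT),
    target_type = rep(types, times = nT),
    observed_stat = as.vector(t(obs)),
    perm_mean = as.vector(t(perm_mean)),
    perm_sd = as.vector(t(perm_sd)),
    z = as.vector(t(z)),
    p_perm = as.vector(t(p_perm)),
    n_anchor_cells = rep(n_anchor, each = nT),
    status = ifelse(as.vector(t(pair_tested)), "tested", "skipped_low_count"),
    stringsAsFactors = FALSE
  )
  skip <- tab$status != "tested"
  tab$z[skip] <- NA_real_
  tab$p_adj <- NA_real_
  tab$p_adj[!skip] <- bh_adjust(tab$p_perm[!skip])
  tab <- tab[, c("anchor_type", "target_type", "observed_stat", "perm_mean",
                 "perm_sd", "z", "p_perm", "p_adj", "n_anchor_cells",
                 "status")]
  tab <- tab[order(tab$anchor_type, tab$target_type), ]
  rownames(tab) <- NULL
  structure(list(table = tab, types = types, config = config,
                 null = if (mode == "exhaustive") "exhaustive" else "montecarlo",
                 n_null = n_null),
            class = "enrichment_result")
}

# All distinct assignments of the observed label multiset to positions,
# within each sample independently (Cartesian product across samples).
enumerate_labelings <- function(lab, sample_f, nT, max_labelings) {
  groups <- split(seq_along(lab), sample_f)
  per_sample <- lapply(groups, function(rows) {
    counts <- tabulate(lab[rows], nT)
    multiset_perms(counts)
  })
  total <- prod(vapply(per_sample, nrow, 1))
  if (total > max_labelings) {
    stop(sprintf("exhaustive null refused: %.0f distinct labelings exceed the bound %g",
                 total, max_labelings))
  }
  out <- matrix(0L, total, length(lab))
  reps <- 1L
  for (g in seq_along(groups)) {
    rows <- groups[[g]]
    block <- per_sample[[g]]
    nb <- nrow(block)
    each <- total / (reps * nb)
    sel <- rep(rep(seq_len(nb), each = each), times = reps)
    out[, rows] <- block[sel, , drop = FALSE]
    reps <- reps * nb
  }
  out
}

# All distinct orderings of a label multiset given per-type counts.
multiset_perms <- function(counts) {
  n <- sum(counts)
  if (n == 0L) return(matrix(integer(0), 1, 0))
  res <- list()
  for (t in seq_along(counts)) {
    if (counts[t] == 0L) next
    cnt2 <- counts
    cnt2[t] <- cnt2[t] - 1L
    sub <- multiset_perms(cnt2)
    res[[length(res) + 1L]] <- cbind(rep(t, nrow(sub)), sub)
  }
  do.call(rbind, res)
}

#' @export
as.data.frame.enrichment_result <- function(x, ...) x$table

#' @export
write_result_table.enrichment_result <- function(result, path) {
  write_tsv_impl(result$table, path)
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: %d types, %d directed pairs, %s null (%d draws)\n",
              length(x$types), nrow(x$table), x$null, x$n_null))
  sig <- sum(x$table$p_adj < 0.05, na.rm = TRUE)
  cat(sprintf("  pairs with p_adj < 0.05: %d\n", sig))
  invisible(x)
}

#' Symmetrized view of a directed enrichment result
#'
#' Averages the A-to-B and B-to-A z-scores and statistics; p-values are
#' not combined (the directed table remains the inferential object).
#'
#' @param result an `enrichment_result`.
#' @return data.frame with one row per unordered pair.
#' @export
symmetrize_enrichment <- function(result) {
  tab <- result$table
  key <- t(apply(tab[, c("anchor_type", "target_type")], 1L, sort))
  agg <- stats::aggregate(cbind(observed_stat, z) ~ key1 + key2,
                          data = data.frame(key1 = key[, 1], key2 = key[, 2],
                                            observed_stat = tab$observed_stat,
                                            z = tab$z),
                          FUN = mean, na.action = stats::na.pass)
  names(agg)[1:2] <- c("type_a", "type_b")
  agg[order(agg$type_a, agg$type_b), ]
}
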