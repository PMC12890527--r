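#' Configuration for spatial niche construction
#'
#' Each cell's microenvironment is summarized as the cell-type
#' composition of its 30 nearest spatial neighbors (self excluded), and
#' cells with similar compositions are grouped by k-means into discrete
#' niches (30 by default, matching the granularity at which niche
#' heterogeneity is interpretable tissue-wide), which are then annotated
#' into a small number of lineage-level classes.
#'
#' @param k_neighbors neighbors per cell for the composition (default 30).
#' @param n_niches number of k-means clusters (default 30, >= 2).
#' @param seed seed controlling k-means++ initialization.
#' @param restarts independent k-means++ starts; best inertia kept.
#' @param class_z_threshold z-score at which a second lineage is appended
#'   to a niche-class label (e.g. "Myeloid+T").
#' @return a `niche_config` list.
#' @export
niche_config <- function(k_neighbors = 30, n_niches = 30, seed = 1,
                         restarts = 10, class_z_threshold = 1.0) {
  stopifnot(k_neighbors >= 1, n_niches >= 2, restarts >= 1)
  structure(list(k_neighbors = as.integer(k_neighbors),
                 n_niches = as.integer(n_niches),
                 seed = as.integer(seed),
                 restarts = as.integer(restarts),
                 class_z_threshold = class_z_threshold),
            class = "niche_config")
}

#' Per-cell k-nearest-neighbor cell-type composition
#'
#' Fraction of each cell type among the `k_neighbors` nearest
#' within-sample neighbors of each cell, self excluded. In samples with
#' fewer than `k_neighbors + 1` cells, k truncates to `n - 1` with a
#' warning and the affected rows are flagged.
#'
#' @param cells a [cell_map].
#' @param k_neighbors neighborhood size (default 30).
#' @return numeric matrix cells x types, rows summing to 1; attribute
#'   `truncated` flags rows computed with a reduced k.
#' @export
niche_composition <- function(cells, k_neighbors = 30) {
  validate_cell_map(cells)
  graph <- build_neighbor_graph(cells,
                                list(mode = "knn", k = k_neighbors))
  comp <- neighborhood_composition(cells, graph)
  deg <- lengths(graph$idx)
  attr(comp, "truncated") <- deg < k_neighbors
  attr(comp, "no_neighbors") <- NULL
  comp
}

# Lloyd's k-means with k-means++ seeding and deterministic behavior:
# input rows are visited in a canonical order supplied by the caller,
# assignment ties go to the lowest centroid index, and an emptied
# cluster is re-seeded at the point farthest from its centroid.
kmeanspp_lloyd <- function(X, k, iter_max = 100) {
  n <- nrow(X)
  # k-means++ seeding
  centers <- matrix(0, k, ncol(X))
  first <- sample.int(n, 1L)
  centers[1L, ] <- X[first, ]
  d2 <- rowSums((X - matrix(centers[1L, ], n, ncol(X), byrow = TRUE))^2)
  for (c in seq_len(k)[-1]) {
    if (sum(d2) <= 0) {
      pick <- sample.int(n, 1L)
    } else {
      pick <- sample.int(n, 1L, prob = d2)
    }
    centers[c, ] <- X[pick, ]
    d2 <- pmin(d2, rowSums((X - matrix(centers[c, ], n, ncol(X),
                                       byrow = TRUE))^2))
  }
  assign_step <- function(centers) {
    D <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    max.col(-D, ties.method = "first")
  }
  cl <- assign_step(centers)
  for (it in seq_len(iter_max)) {
    for (c in seq_len(k)) {
      rows <- which(cl == c)
      if (!length(rows)) {
        # empty-cluster repair: re-seed at the globally farthest point
        D <- vapply(seq_len(k), function(cc)
          rowSums((X - matrix(centers[cc, ], n, ncol(X), byrow = TRUE))^2),
          numeric(n))
        far <- which.max(D[cbind(seq_len(n), cl)])
        centers[c, ] <- X[far, ]
        sc_log("k-means: empty cluster ", c, " re-seeded at farthest point")
      } else {
        centers[c, ] <- colMeans(X[rows, , drop = FALSE])
      }
    }
    cl_new <- assign_step(centers)
    if (all(cl_new == cl)) { cl <- cl_new; break }
    cl <- cl_new
  }
  inertia <- 0
  for (c in seq_len(k)) {
    rows <- which(cl == c)
    if (length(rows)) {
      inertia <- inertia +
        sum((X[rows, , drop = FALSE] -
               matrix(centers[c, ], length(rows), ncol(X), byrow = TRUE))^2)
    }
  }
  list(cluster = cl, centers = centers, inertia = inertia)
}

#' Cluster niche composition vectors by k-means
#'
#' k-means++ seeding with `restarts` independent starts, keeping the run
#' with the lowest within-cluster sum of squares. Deterministic given the
#' seed and invariant to input row order (seeding operates on rows taken
#' in a canonical lexicographic order).
#'
#' @param composition cells x types composition matrix
#'   (from [niche_composition]).
#' @param config a [niche_config].
#' @return a `niche_assignment`: per-cell `$niche_id` (1..n_niches,
#'   relabeled by decreasing size), `$niche_profiles` (niche x type mean
#'   composition, rows summing to 1), `$inertia`.
#' @export
cluster_niches <- function(composition, config = niche_config()) {
  X <- as.matrix(composition)
  n <- nrow(X)
  k <- config$n_niches
  if (n < k) stop("n_niches = ", k, " exceeds ", n, " composition rows")
  n_distinct <- nrow(unique(X))
  if (n_distinct < k) {
    stop("n_niches = ", k, " exceeds ", n_distinct,
         " distinct composition vectors")
  }
  # canonical row order for order-invariant seeding
  ord <- do.call(order, c(as.data.frame(X), list(rownames(X))))
  Xs <- X[ord, , drop = FALSE]
  best <- NULL
  for (r in seq_len(config$restarts)) {
    fit <- with_seed(perm_seed(config$seed, r), kmeanspp_lloyd(Xs, k))
    if (is.null(best) || fit$inertia < best$inertia - 1e-12) best <- fit
  }
  cl_sorted <- best$cluster
  cl <- integer(n)
  cl[ord] <- cl_sorted
  # relabel niches by decreasing size (ties by first occurrence in the
  # canonical order) so ids are stable and meaningful
  sizes <- tabulate(cl, k)
  first_seen <- match(seq_len(k), cl_sorted)
  relab <- order(-sizes, first_seen)
  new_id <- integer(k); new_id[relab] <- seq_len(k)
  cl <- new_id[cl]
  profiles <- matrix(0, k, ncol(X),
                     dimnames = list(paste0("niche", seq_len(k)),
                                     colnames(X)))
  for (c in seq_len(k)) {
    rows <- which(cl == c)
    profiles[c, ] <- colMeans(X[rows, , drop = FALSE])
  }
  structure(list(niche_id = cl, cell_id = rownames(X),
                 niche_profiles = profiles, inertia = best$inertia,
                 config = config),
            class = "niche_assignment")
}

#' @export
print.niche_assignment <- function(x, ...) {
  cat(sprintf("niche_assignment: %d cells in %d niches (inertia %.4f)\n",
              length(x$niche_id), nrow(x$niche_profiles), x$inertia))
  if (!is.null(x$class_label)) {
    cat("  classes: ", paste(unique(x$class_label), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Annotate niches with lineage-level class labels
#'
#' Aggregates each niche's cell-type profile to lineage shares, z-scores
#' each lineage across niches, and labels every niche by its top-z
#' lineage, appending the runner-up with a `+` when its z-score reaches
#' `class_z_threshold` (e.g. `"Myeloid+T"`). If every niche has an
#' identical lineage composition (all z = 0), labels fall back to the
#' globally most abundant lineage with a flag.
#'
#' @param assignment a `niche_assignment`.
#' @param lineage_map named character vector mapping every cell type to a
#'   lineage.
#' @return the assignment with `$class_label` (per niche) and
#'   `$lineage_profiles` attached.
#' @export
annotate_niche_classes <- function(assignment, lineage_map) {
  stopifnot(inherits(assignment, "niche_assignment"))
  prof <- assignment$niche_profiles
  unmapped <- setdiff(colnames(prof), names(lineage_map))
  if (length(unmapped)) {
    stop("cell type(s) missing from lineage_map: ",
         paste(unmapped, collapse = ", "))
  }
  lin <- factor(lineage_map[colnames(prof)])
  L <- t(rowsum(t(prof), lin)) # niche x lineage shares
  zs <- apply(L, 2L, function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  })
  zs <- matrix(zs, nrow = nrow(L), dimnames = dimnames(L))
  thr <- assignment$config$class_z_threshold %||% 1.0
  degenerate <- all(zs == 0)
  labels <- character(nrow(L))
  if (degenerate) {
    top_global <- colnames(L)[which.max(colMeans(L))]
    labels[] <- top_global
    sc_log("all niches share one lineage composition; ",
           "class labels fall back to '", top_global, "'")
  } else {
    for (i in seq_len(nrow(L))) {
      ord <- order(-zs[i, ], -L[i, ])
      lab <- colnames(L)[ord[1]]
      if (ncol(L) >= 2 && zs[i, ord[2]] >= thr) {
        lab <- paste0(lab, "+", colnames(L)[ord[2]])
      }
      labels[i] <- lab
    }
  }
  assignment$class_label <- labels
  assignment$lineage_profiles <- L
  assignment$class_degenerate <- degenerate
  assignment
}

#' @export
as.data.frame.niche_assignment <- function(x, ...) {
  df <- data.frame(cell_id = x$cell_id, niche_id = x$niche_id,
                   stringsAsFactors = FALSE)
  if (!is.null(x$class_label)) df$niche_class <- x$class_label[x$niche_id]
  df[order(df$cell_id), , drop = FALSE]
}

#' @export
write_result_table.niche_assignment <- function(result, path) {
  write_tsv_impl(as.data.frame(result), path)
}
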