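# Independent brute-force oracles. These deliberately share no code with
# the package internals: plain vectorized R, O(n^2), no C++.

# all pairwise Euclidean distances
oracle_dist <- function(x, y) {
  as.matrix(stats::dist(cbind(x, y)))
}

# kNN with (distance, index) tie-break, self excluded
oracle_knn <- function(x, y, k) {
  D <- oracle_dist(x, y)
  n <- length(x)
  idx <- matrix(0L, n, k); dst <- matrix(0, n, k)
  for (i in seq_len(n)) {
    ord <- order(D[i, ], seq_len(n))
    ord <- ord[ord != i][seq_len(k)]
    idx[i, ] <- ord
    dst[i, ] <- D[i, ord]
  }
  list(idx = idx, dist = dst)
}

# neighbours within radius, sorted by (distance, index)
oracle_radius <- function(x, y, r) {
  D <- oracle_dist(x, y)
  n <- length(x)
  lapply(seq_len(n), function(i) {
    j <- setdiff(which(D[i, ] <= r), i)
    j[order(D[i, j], j)]
  })
}

# directed mean-neighbour-fraction statistic for one labeling
oracle_pair_stat <- function(x, y, lab, r, a, b) {
  nb <- oracle_radius(x, y, r)
  anchors <- which(lab == a & lengths(nb) > 0)
  if (!length(anchors)) return(NA_real_)
  mean(vapply(anchors, function(i) mean(lab[nb[[i]]] == b), 1))
}

# exact enrichment p by enumerating all distinct labelings of a 2-type
# instance (single sample)
oracle_exact_p <- function(x, y, lab, r, a, b) {
  n <- length(lab)
  pos_a <- combn(n, sum(lab == a))
  stats_all <- apply(pos_a, 2, function(pa) {
    l <- rep(b, n); l[pa] <- a
    oracle_pair_stat(x, y, l, r, a, b)
  })
  obs <- oracle_pair_stat(x, y, lab, r, a, b)
  mean(stats_all >= obs - 1e-12)
}

# uniform-kernel, exclude-self colocalization score: count product
oracle_count_product <- function(cells, anchor, target, r) {
  D <- oracle_dist(cells$x, cells$y)
  same <- outer(cells$sample_id, cells$sample_id, "==")
  vapply(seq_len(nrow(cells)), function(i) {
    within <- D[i, ] <= r & same[i, ]
    within[i] <- FALSE
    sum(within & cells$cell_type == anchor) *
      sum(within & cells$cell_type == target)
  }, 1)
}

# kNN composition by brute force
oracle_niche_composition <- function(cells, k) {
  types <- sort(unique(cells$cell_type))
  out <- matrix(0, nrow(cells), length(types),
                dimnames = list(cells$cell_id, types))
  for (s in unique(cells$sample_id)) {
    rows <- which(cells$sample_id == s)
    kn <- oracle_knn(cells$x[rows], cells$y[rows],
                     min(k, length(rows) - 1))
    for (i in seq_along(rows)) {
      tb <- table(factor(cells$cell_type[rows[kn$idx[i, ]]], levels = types))
      out[rows[i], ] <- as.numeric(tb) / sum(tb)
    }
  }
  out
}

# single-linkage components over a thresholded distance matrix
oracle_components <- function(x, y, r) {
  D <- oracle_dist(x, y)
  n <- length(x)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      linked <- which(D[i, ] <= r)
      m <- min(comp[linked])
      if (any(comp[linked] != m)) {
        comp[linked] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(comp, sort(unique(comp)))
}

# tiny deterministic cell map used across IO tests
toy_cells <- function() {
  cell_map(cell_id = c("c1", "c2", "c3", "c4"),
           x = c(0, 10, 25, 100), y = c(0, 0, 0, 0),
           cell_type = c("A", "A", "B", "B"))
}

write_toy_csv <- function(path, labels = c("T", "B", "T")) {
  df <- data.frame(cell_id = c("c1", "c2", "c3"),
                   x_centroid = c(0, 3, 10),
                   y_centroid = c(0, 4, 0),
                   cell_type = labels)
  utils::write.csv(df, path, row.names = FALSE)
  df
}
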