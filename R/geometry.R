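#' Build a spatial neighbor graph
#'
#' k-nearest-neighbor or fixed-radius neighborhoods for every cell,
#' computed strictly within each sample (biopsies are physically separate
#' tissues, so cross-sample neighbor pairs are meaningless). Neighbor
#' lists are ordered by increasing distance with ties broken by ascending
#' cell index, which makes every downstream permutation test reproducible
#' bit-for-bit.
#'
#' @param cells a [cell_map].
#' @param query a list: either `list(mode = "knn", k = <count>)` or
#'   `list(mode = "radius", radius_um = <length>)`.
#' @return a `neighbor_graph`: per-cell integer vectors of neighbor row
#'   indices into `cells` (`$idx`) and matching distances in micrometres
#'   (`$dist`), plus the query descriptor. kNN lists have length
#'   `min(k, n_sample - 1)`; a warning is raised when truncation occurs.
#' @export
build_neighbor_graph <- function(cells, query) {
  validate_cell_map(cells)
  mode <- match.arg(query$mode, c("knn", "radius"))
  n <- nrow(cells)
  idx <- vector("list", n)
  dist <- vector("list", n)
  if (mode == "knn") {
    k <- query$k
    stopifnot(is.numeric(k), length(k) == 1L, k >= 1)
    k <- as.integer(k)
  } else {
    r <- query$radius_um
    stopifnot(is.numeric(r), length(r) == 1L, r > 0)
  }
  for (s in unique(cells$sample_id)) {
    rows <- which(cells$sample_id == s)
    ns <- length(rows)
    if (ns == 1L) {
      idx[rows] <- list(integer(0))
      dist[rows] <- list(numeric(0))
      next
    }
    xs <- cells$x[rows]; ys <- cells$y[rows]
    if (mode == "knn") {
      ks <- k
      if (ks >= ns) {
        warning(sprintf("k = %d >= %d cells in sample '%s'; truncating to %d",
                        ks, ns, s, ns - 1L))
        ks <- ns - 1L
      }
      res <- cpp_knn(xs, ys, ks)
      for (i in seq_len(ns)) {
        idx[[rows[i]]] <- rows[res$idx[i, ]]
        dist[[rows[i]]] <- res$dist[i, ]
      }
    } else {
      res <- cpp_radius(xs, ys, r)
      off <- res$offsets
      for (i in seq_len(ns)) {
        sel <- if (off[i + 1L] > off[i]) (off[i] + 1L):off[i + 1L] else integer(0)
        idx[[rows[i]]] <- rows[res$idx[sel]]
        dist[[rows[i]]] <- res$dist[sel]
      }
    }
  }
  structure(list(query = query, idx = idx, dist = dist,
                 n = n, sample_id = cells$sample_id),
            class = "neighbor_graph")
}

#' @export
print.neighbor_graph <- function(x, ...) {
  q <- if (x$query$mode == "knn") paste0("knn k=", x$query$k)
       else paste0("radius ", x$query$radius_um, " um")
  cat(sprintf("neighbor_graph: %d cells, query %s, mean degree %.2f\n",
              x$n, q, mean(lengths(x$idx))))
  invisible(x)
}

#' Distance from every cell to the nearest cell of a given type
#'
#' Per-cell Euclidean distance (micrometres) to the closest cell carrying
#' `target_type`, within the same sample. Cells of the target type get 0,
#' unless `exclude_self_type` in which case they get the distance to the
#' nearest *other* target cell. Samples lacking the target yield `Inf`
#' with a warning ("inf" in TSV output).
#'
#' @param cells a [cell_map].
#' @param target_type cell-type label to measure distance to.
#' @param exclude_self_type see description.
#' @return a `distance_field`: list with per-cell `$distance` and the
#'   query metadata.
#' @export
nearest_distance_to_type <- function(cells, target_type,
                                     exclude_self_type = FALSE) {
  validate_cell_map(cells)
  if (!any(cells$cell_type == target_type)) {
    stop("target type '", target_type, "' absent from every sample")
  }
  n <- nrow(cells)
  d <- rep(Inf, n)
  for (s in unique(cells$sample_id)) {
    rows <- which(cells$sample_id == s)
    trows <- rows[cells$cell_type[rows] == target_type]
    if (!length(trows)) {
      warning("target type '", target_type, "' absent from sample '", s,
              "'; distances are Inf there")
      next
    }
    is_target <- cells$cell_type[rows] == target_type
    if (!exclude_self_type) {
      skip <- rep(0L, length(rows))
      d[rows] <- cpp_nearest_cross(cells$x[rows], cells$y[rows],
                                   cells$x[trows], cells$y[trows], skip)
      d[rows[is_target]] <- 0
    } else {
      # target cells skip themselves in the target list
      pos_in_targets <- match(rows, trows)
      pos_in_targets[is.na(pos_in_targets)] <- 0L
      d[rows] <- cpp_nearest_cross(cells$x[rows], cells$y[rows],
                                   cells$x[trows], cells$y[trows],
                                   pos_in_targets)
    }
  }
  structure(list(target_type = target_type,
                 exclude_self_type = exclude_self_type,
                 distance = d,
                 cell_id = cells$cell_id,
                 sample_id = cells$sample_id),
            class = "distance_field")
}

#' @export
as.data.frame.distance_field <- function(x, ...) {
  df <- data.frame(cell_id = x$cell_id, sample_id = x$sample_id,
                   distance_um = x$distance, stringsAsFactors = FALSE)
  df[order(df$sample_id, df$cell_id), , drop = FALSE]
}
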