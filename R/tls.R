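#' Configuration for TLS detection
#'
#' Tertiary lymphoid structures are detected as connected regions of
#' high T-B/plasma colocalization score: cells above a per-sample score
#' quantile (computed over nonzero scores) are linked by single linkage
#' at `linkage_radius_um`, and components with at least `min_cells`
#' members become regions. The three knobs are the operational
#' definition in place of pathologist annotation and are all exposed for
#' calibration.
#'
#' @param score_quantile quantile of nonzero scores, per sample
#'   (default 0.90).
#' @param linkage_radius_um single-linkage distance (default 30).
#' @param min_cells minimum component size (default 20).
#' @return a `tls_config` list.
#' @export
tls_config <- function(score_quantile = 0.90, linkage_radius_um = 30,
                       min_cells = 20) {
  stopifnot(score_quantile > 0, score_quantile < 1,
            linkage_radius_um > 0, min_cells >= 1)
  structure(list(score_quantile = score_quantile,
                 linkage_radius_um = linkage_radius_um,
                 min_cells = as.integer(min_cells)),
            class = "tls_config")
}

# Union-find over cells linked when within `radius`; returns component id
# per row. Deterministic and order-invariant (components are relabeled by
# smallest member index).
link_components <- function(x, y, radius) {
  n <- length(x)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  res <- cpp_radius(x, y, radius)
  off <- res$offsets
  for (i in seq_len(n)) {
    sel <- if (off[i + 1L] > off[i]) (off[i] + 1L):off[i + 1L] else integer(0)
    for (j in res$idx[sel]) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  match(roots, sort(unique(roots)))
}

#' Detect TLS candidate regions from a colocalization field
#'
#' @param field a `coloc_field` computed for the T versus B/plasma pair
#'   (any pair is accepted; TLS is the motivating use).
#' @param cells the [cell_map] the field was computed on.
#' @param config a [tls_config].
#' @return a `tls_regions` object: per-region member cell ids, convex
#'   hull polygons (micrometres), per-type counts, ordered by descending
#'   size (ties by smallest member row index). No cell above threshold
#'   yields an empty region set, not an error.
#' @export
detect_tls <- function(field, cells, config = tls_config()) {
  stopifnot(inherits(field, "coloc_field"))
  validate_cell_map(cells)
  regions <- list()
  for (s in unique(field$sample_id)) {
    in_s <- which(field$sample_id == s)
    sc <- field$score[in_s]
    nz <- sc[sc > 0]
    if (!length(nz)) next
    thr <- quantile(nz, config$score_quantile, names = FALSE)
    sel <- in_s[sc >= thr & sc > 0]
    if (!length(sel)) next
    comp <- link_components(field$x[sel], field$y[sel],
                            config$linkage_radius_um)
    for (c in sort(unique(comp))) {
      mem <- sel[comp == c]
      if (length(mem) < config$min_cells) next
      regions[[length(regions) + 1L]] <- list(
        sample_id = s,
        member_rows = field$eval_rows[mem],
        member_cells = field$cell_id[mem],
        x = field$x[mem], y = field$y[mem],
        mean_score = mean(field$score[mem])
      )
    }
  }
  if (length(regions)) {
    ord <- order(-vapply(regions, function(r) length(r$member_cells), 1),
                 vapply(regions, function(r) min(r$member_rows), 1))
    regions <- regions[ord]
    for (i in seq_along(regions)) {
      r <- regions[[i]]
      hull_i <- grDevices::chull(r$x, r$y)
      regions[[i]]$region_id <- i
      regions[[i]]$hull <- cbind(x = r$x[hull_i], y = r$y[hull_i])
      ct <- cells$cell_type[r$member_rows]
      regions[[i]]$type_counts <- table(ct)
    }
  }
  structure(list(regions = regions, config = config,
                 anchor_type = field$anchor_type,
                 target_type = field$target_type),
            class = "tls_regions")
}

#' @export
print.tls_regions <- function(x, ...) {
  cat(sprintf("tls_regions: %d region(s) [%s vs %s]\n", length(x$regions),
              x$anchor_type, x$target_type))
  for (r in x$regions) {
    cat(sprintf("  region %d (sample %s): %d cells, mean score %.4g\n",
                r$region_id, r$sample_id, length(r$member_cells),
                r$mean_score))
  }
  invisible(x)
}

#' @export
as.data.frame.tls_regions <- function(x, ...) {
  if (!length(x$regions)) {
    return(data.frame(region_id = integer(0), sample_id = character(0),
                      cell_id = character(0), x = numeric(0),
                      y = numeric(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(x$regions, function(r) {
    data.frame(region_id = r$region_id, sample_id = r$sample_id,
               cell_id = r$member_cells, x = r$x, y = r$y,
               stringsAsFactors = FALSE)
  }))
  out[order(out$region_id, out$cell_id), , drop = FALSE]
}

#' @export
write_result_table.tls_regions <- function(result, path) {
  write_tsv_impl(as.data.frame(result), path)
}

#' Write TLS hull polygons as GeoJSON
#'
#' Coordinates are tissue micrometres (not geographic); each region is a
#' closed Polygon feature with its id, sample and cell count as
#' properties.
#'
#' @param regions a `tls_regions` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_tls_geojson <- function(regions, path) {
  stopifnot(inherits(regions, "tls_regions"))
  feats <- lapply(regions$regions, function(r) {
    ring <- rbind(r$hull, r$hull[1, , drop = FALSE])
    list(type = "Feature",
         properties = list(region_id = r$region_id,
                           sample_id = r$sample_id,
                           n_cells = length(r$member_cells),
                           mean_score = r$mean_score),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                           function(i) c(ring[i, 1], ring[i, 2])))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Distance from every cell to the nearest TLS B cell in its sample; Inf
# where the sample has none. "TLS B cell" = a b_label cell within the
# region footprint: a region member, or within the linkage radius of one
# (edge cells of an aggregate can fall just below the score threshold yet
# belong to the structure; the linkage radius that defined the region
# also defines its footprint).
region_b_distance <- function(cells, regions, b_label) {
  member_rows <- unlist(lapply(regions$regions, `[[`, "member_rows"),
                        use.names = FALSE)
  is_b <- cells$cell_type == b_label
  link_r <- regions$config$linkage_radius_um
  near_member <- rep(FALSE, nrow(cells))
  for (r in regions$regions) {
    cand <- which(is_b & cells$sample_id == r$sample_id & !near_member)
    if (length(cand)) {
      d_mem <- cpp_nearest_cross(cells$x[cand], cells$y[cand],
                                 r$x, r$y, rep(0L, length(cand)))
      near_member[cand] <- d_mem <= link_r
    }
  }
  b_rows <- sort(unique(c(member_rows[is_b[member_rows]],
                          which(near_member))))
  if (!length(b_rows)) stop("no region member carries label '", b_label, "'")
  d <- rep(Inf, nrow(cells))
  for (s in unique(cells$sample_id)) {
    rows <- which(cells$sample_id == s)
    tb <- b_rows[cells$sample_id[b_rows] == s]
    if (!length(tb)) next
    d[rows] <- cpp_nearest_cross(cells$x[rows], cells$y[rows],
                                 cells$x[tb], cells$y[tb],
                                 rep(0L, length(rows)))
  }
  d
}

#' Cell-type composition versus distance to the nearest TLS B cell
#'
#' Restricted to the TLS neighborhood (region members plus cells closer
#' to a region B cell than the top bin edge), computes for each cell
#' type the fraction of that type's cells falling in each distance bin;
#' each type's curve sums to 1 over the bins. Distance is measured to
#' TLS B cells only (B/plasma region members, plus B/plasma cells inside
#' a region's hull footprint), never to tissue-wide B cells.
#'
#' @param cells a [cell_map].
#' @param regions a `tls_regions` from [detect_tls].
#' @param b_label the B/plasma cell-type label.
#' @param bins increasing numeric vector of bin edges in micrometres
#'   (default 5 um bins to 50 um).
#' @param min_type_cells types with fewer neighborhood cells are omitted
#'   with a note (default 1).
#' @return a `tls_composition`: `$bins`, `$proportions` (type x bin),
#'   `$type_n`, plus the per-cell distances used.
#' @export
tls_distance_composition <- function(cells, regions, b_label,
                                     bins = seq(0, 50, by = 5),
                                     min_type_cells = 1) {
  stopifnot(inherits(regions, "tls_regions"), length(bins) >= 3,
            all(diff(bins) > 0))
  if (!length(regions$regions)) stop("no detected regions")
  if (!any(cells$cell_type == b_label)) stop("no '", b_label, "' cells")
  d <- region_b_distance(cells, regions, b_label)
  max_edge <- bins[length(bins)]
  # TLS neighborhood: any cell closer to a region B cell than the top bin
  # edge (region members beyond the range carry no bin and are excluded)
  rows <- which(is.finite(d) & d < max_edge)
  bin_of <- findInterval(d[rows], bins, rightmost.closed = FALSE)
  nb <- length(bins) - 1L
  types <- sort(unique(cells$cell_type[rows]))
  prop <- matrix(0, length(types), nb,
                 dimnames = list(types, sprintf("[%g,%g)", bins[-length(bins)],
                                                bins[-1])))
  type_n <- integer(length(types))
  for (i in seq_along(types)) {
    sel <- cells$cell_type[rows] == types[i]
    type_n[i] <- sum(sel)
    if (type_n[i] < min_type_cells) next
    prop[i, ] <- tabulate(bin_of[sel], nb) / type_n[i]
  }
  keep <- type_n >= min_type_cells
  if (any(!keep)) {
    sc_log("types omitted from TLS composition (too few cells): ",
           paste(types[!keep], collapse = ", "))
  }
  structure(list(bins = bins, proportions = prop[keep, , drop = FALSE],
                 type_n = setNames(type_n[keep], types[keep]),
                 distance = d, neighborhood_rows = rows,
                 neighborhood_type = cells$cell_type[rows],
                 b_label = b_label),
            class = "tls_composition")
}

#' @export
as.data.frame.tls_composition <- function(x, ...) {
  df <- data.frame(cell_type = rep(rownames(x$proportions),
                                   each = ncol(x$proportions)),
                   bin_lo = rep(x$bins[-length(x$bins)],
                                times = nrow(x$proportions)),
                   bin_hi = rep(x$bins[-1], times = nrow(x$proportions)),
                   proportion = as.vector(t(x$proportions)),
                   stringsAsFactors = FALSE)
  df[order(df$cell_type, df$bin_lo), , drop = FALSE]
}

#' @export
write_result_table.tls_composition <- function(result, path) {
  write_tsv_impl(as.data.frame(result), path)
}

# Closed-form simple OLS of y on x with the standard slope error and a
# 95% t confidence interval.
ols_slope <- function(x, y, conf = 0.95) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  resid <- y - intercept - slope * x
  se <- if (n > 2) sqrt(sum(resid^2) / (n - 2) / sxx) else NA_real_
  tq <- if (n > 2) qt(1 - (1 - conf) / 2, df = n - 2) else NA_real_
  list(slope = slope, se = se,
       ci_lo = slope - tq * se, ci_hi = slope + tq * se, n = n)
}

#' Proximity share and spatial decay slope per cell type around TLS B
#' cells
#'
#' For each cell type in the TLS neighborhood: the share of its cells
#' within `near_radius` of a region B cell, and the decay slope (change
#' in per-bin proportion per micrometre of distance) from an ordinary
#' least-squares fit of the composition curve on bin midpoints, with a
#' 95% confidence interval from the standard slope error. Strongly
#' negative slopes mark types tightly packed against the B-cell core.
#'
#' @param composition a `tls_composition` from [tls_distance_composition].
#' @param near_radius proximity cutoff in micrometres (default 10).
#' @return data.frame `cell_type, n, pct_within_near, slope_per_um,
#'   slope_se, ci_lo, ci_hi` (slope NA with fewer than 3 nonempty bins).
#' @export
tls_proximity_summary <- function(composition, near_radius = 10) {
  stopifnot(inherits(composition, "tls_composition"))
  bins <- composition$bins
  mids <- (bins[-1] + bins[-length(bins)]) / 2
  prop <- composition$proportions
  d <- composition$distance
  rows <- composition$neighborhood_rows
  d_hood <- d[rows]
  res <- lapply(rownames(prop), function(ty) {
    sel <- composition$neighborhood_type == ty
    share <- 100 * mean(d_hood[sel] <= near_radius)
    p <- prop[ty, ]
    nonempty <- p > 0
    sl <- if (sum(nonempty) >= 3) {
      ols_slope(mids[nonempty], p[nonempty])
    } else list(slope = NA_real_, se = NA_real_, ci_lo = NA_real_,
                ci_hi = NA_real_)
    data.frame(cell_type = ty, n = composition$type_n[[ty]],
               pct_within_near = share, slope_per_um = sl$slope,
               slope_se = sl$se, ci_lo = sl$ci_lo, ci_hi = sl$ci_hi,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out <- out[order(out$cell_type), ]
  rownames(out) <- NULL
  out
}
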