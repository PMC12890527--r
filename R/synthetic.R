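# Seeded synthetic tissue generators. Each returns list(cells = cell_map,
# truth = <machine-readable ground truth>, expr = optional expr_matrix).
# Planted inter-type gaps are enforced geometrically (types are placed in
# disjoint regions whose boundaries are exactly gap_um apart), so the
# realized minimal inter-type distance is always >= the declared gap.

runif_disk <- function(n, r0, cx = 0, cy = 0) {
  r <- r0 * sqrt(runif(n))
  th <- runif(n, 0, 2 * pi)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

runif_annulus <- function(n, r1, r2, cx = 0, cy = 0) {
  r <- sqrt(r1^2 + runif(n) * (r2^2 - r1^2))
  th <- runif(n, 0, 2 * pi)
  cbind(x = cx + r * cos(th), y = cy + r * sin(th))
}

mk_cells <- function(coords, types, sample_id = "sim1", lineage = NULL) {
  cell_map(cell_id = sprintf("c%06d", seq_len(nrow(coords))),
           x = coords[, 1], y = coords[, 2], cell_type = types,
           sample_id = sample_id, lineage = lineage)
}

#' Synthetic tissue generators
#'
#' Seeded point-pattern generators used to validate every analysis
#' module without patient data. All generators are deterministic given
#' `seed` and return the planted ground truth (memberships, gaps, target
#' correlations) alongside the cells.
#'
#' `sim_concentric`: type A uniform on a thin concentric ring, type B on
#' a second ring whose inner edge sits exactly `gap_um` beyond A's outer
#' edge, so the planted minimal A-B distance is guaranteed `>= gap_um`;
#' an optional decoy type C occupies a third ring `decoy_gap_um` beyond
#' B. A background type `BG` fills the square extent under complete
#' spatial randomness — without it no bulk proximity pattern can be
#' *enriched* relative to the label-shuffle null, because the anchor
#' type's own region would dominate every neighborhood while the null
#' equals the global type share. `sim_layers` is the same construction
#' with thin parallel vertical bands. `sim_csr`: complete spatial
#' randomness for each type over the extent — the type-I calibration
#' null.
#'
#' @param n_per_type cells per planted type (default 500).
#' @param gap_um planted minimal distance between the A and B regions.
#' @param seed integer seed.
#' @param ring_radius outer radius of the A ring, micrometres.
#' @param band_width width of each planted ring/band, micrometres.
#' @param n_background background (`BG`) cells over the extent.
#' @param extent side of the square field, micrometres.
#' @param length_um band length for `sim_layers`.
#' @param decoy_gap_um when non-NULL, adds decoy type C this far from B.
#' @return list with `cells` ([cell_map]) and `truth` (planted pair,
#'   decoy pair, gap).
#' @export
sim_concentric <- function(n_per_type = 500, gap_um = 20, seed = 1,
                           ring_radius = 200, band_width = 5,
                           n_background = 4000, extent = 1600,
                           decoy_gap_um = NULL) {
  stopifnot(ring_radius > band_width, gap_um >= 0)
  b_outer <- ring_radius + gap_um + band_width
  if (!is.null(decoy_gap_um)) {
    c_outer <- b_outer + decoy_gap_um + band_width
    if (2 * c_outer > extent) stop("decoy ring exceeds the field extent")
  } else if (2 * b_outer > extent) stop("rings exceed the field extent")
  with_seed(seed, {
    a <- runif_annulus(n_per_type, ring_radius - band_width, ring_radius)
    b <- runif_annulus(n_per_type, ring_radius + gap_um,
                       ring_radius + gap_um + band_width)
    coords <- rbind(a, b)
    types <- rep(c("A", "B"), each = n_per_type)
    if (!is.null(decoy_gap_um)) {
      c1 <- b_outer + decoy_gap_um
      cc <- runif_annulus(n_per_type, c1, c1 + band_width)
      coords <- rbind(coords, cc)
      types <- c(types, rep("C", n_per_type))
    }
    bg <- cbind(x = runif(n_background, -extent / 2, extent / 2),
                y = runif(n_background, -extent / 2, extent / 2))
    coords <- rbind(coords, bg)
    types <- c(types, rep("BG", n_background))
    list(cells = mk_cells(coords, types),
         truth = list(pattern = "concentric", gap_um = gap_um,
                      planted_pair = c("A", "B"),
                      decoy_pair = if (!is.null(decoy_gap_um)) c("B", "C"),
                      decoy_gap_um = decoy_gap_um,
                      background_type = "BG"))
  })
}

#' @rdname sim_concentric
#' @export
sim_layers <- function(n_per_type = 500, gap_um = 20, seed = 1,
                       band_width = 5, length_um = 1600,
                       n_background = 4000, extent = 1600,
                       decoy_gap_um = NULL) {
  stopifnot(gap_um >= 0, band_width > 0)
  x_a <- extent / 4 # A band sits at a quarter of the field width
  with_seed(seed, {
    xa <- runif(n_per_type, x_a - band_width, x_a)
    xb <- runif(n_per_type, x_a + gap_um, x_a + gap_um + band_width)
    xs <- c(xa, xb)
    types <- rep(c("A", "B"), each = n_per_type)
    if (!is.null(decoy_gap_um)) {
      c0 <- x_a + gap_um + band_width + decoy_gap_um
      if (c0 + band_width > extent) stop("decoy band exceeds the field extent")
      xs <- c(xs, runif(n_per_type, c0, c0 + band_width))
      types <- c(types, rep("C", n_per_type))
    }
    coords <- cbind(x = xs, y = runif(length(xs), 0, length_um))
    bg <- cbind(x = runif(n_background, 0, extent),
                y = runif(n_background, 0, length_um))
    coords <- rbind(coords, bg)
    types <- c(types, rep("BG", n_background))
    list(cells = mk_cells(coords, types),
         truth = list(pattern = "layers", gap_um = gap_um,
                      planted_pair = c("A", "B"),
                      decoy_pair = if (!is.null(decoy_gap_um)) c("B", "C"),
                      decoy_gap_um = decoy_gap_um,
                      background_type = "BG"))
  })
}

#' @rdname sim_concentric
#' @param types type labels for `sim_csr`; ignored when `n_per_type` is a
#'   named vector of per-type counts (types with count 0 are absent).
#' @export
sim_csr <- function(n_per_type = 500, types = c("A", "B", "C"), seed = 1,
                    extent = c(1000, 1000)) {
  counts <- if (!is.null(names(n_per_type))) {
    n_per_type
  } else {
    setNames(rep(n_per_type[1], length(types)), types)
  }
  counts <- counts[counts > 0]
  extent <- rep(extent, length.out = 2)
  with_seed(seed, {
    n <- sum(counts)
    coords <- cbind(x = runif(n, 0, extent[1]), y = runif(n, 0, extent[2]))
    list(cells = mk_cells(coords, rep(names(counts), times = counts)),
         truth = list(pattern = "csr"))
  })
}

#' Mixed-aggregate versus segregated-background pattern
#'
#' `n_agg` disks contain an even A/B mixture (the colocalized
#' condition); the background holds A and B in two spatially segregated
#' blocks (present, but never co-occurring). High single-spot
#' colocalization scores should concentrate in the aggregates.
#'
#' @param n_agg number of aggregates.
#' @param agg_radius aggregate radius, micrometres. The default radius
#'   and count give ~0.03 cells/um^2 — tight lymphoid-aggregate packing —
#'   so nearly every member has both types within 10 um.
#' @param n_per_agg cells per aggregate (half A, half B).
#' @param min_sep minimal distance between aggregate centers
#'   (rejection-sampled) so regions never merge under 30 um linkage.
#' @param n_background_per_type cells per segregated background block.
#' @param extent field extent, micrometres.
#' @param seed integer seed.
#' @return list(cells, truth) with per-cell `aggregate_id` (0 =
#'   background).
#' @export
sim_coloc_aggregate <- function(n_agg = 3, agg_radius = 40, n_per_agg = 150,
                                n_background_per_type = 200,
                                extent = c(1000, 1000), seed = 1,
                                min_sep = 2 * agg_radius + 100) {
  extent <- rep(extent, length.out = 2)
  with_seed(seed, {
    margin <- agg_radius * 2
    centers <- matrix(0, 0, 2)
    while (nrow(centers) < n_agg) {
      cand <- c(runif(1, margin, extent[1] - margin),
                runif(1, margin, extent[2] / 2 - margin))
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                             byrow = TRUE))^2))) >= min_sep) {
        centers <- rbind(centers, cand)
      }
    }
    coords <- NULL; types <- character(0); agg_id <- integer(0)
    for (i in seq_len(n_agg)) {
      pts <- runif_disk(n_per_agg, agg_radius, centers[i, 1], centers[i, 2])
      coords <- rbind(coords, pts)
      types <- c(types, rep(c("A", "B"), length.out = n_per_agg))
      agg_id <- c(agg_id, rep(i, n_per_agg))
    }
    # segregated background: A in the left, B in the right upper half
    bg_a <- cbind(runif(n_background_per_type, 0, extent[1] / 2 - 50),
                  runif(n_background_per_type, extent[2] / 2, extent[2]))
    bg_b <- cbind(runif(n_background_per_type, extent[1] / 2 + 50, extent[1]),
                  runif(n_background_per_type, extent[2] / 2, extent[2]))
    coords <- rbind(coords, bg_a, bg_b)
    types <- c(types, rep("A", n_background_per_type),
               rep("B", n_background_per_type))
    agg_id <- c(agg_id, rep(0L, 2 * n_background_per_type))
    cells <- mk_cells(coords, types)
    list(cells = cells,
         truth = list(pattern = "coloc_aggregate", centers = centers,
                      aggregate_id = agg_id))
  })
}

#' TLS-like tissue: B-cell cores with concentric immune shells
#'
#' Each aggregate is a dense disk of B/plasma cells mixed with T cells,
#' surrounded by optional shells (distances measured from the core edge)
#' for types such as "Tph/Tfh" and "mregDC", over a stromal background.
#'
#' @param n_cores number of aggregates.
#' @param core_radius core disk radius, micrometres.
#' @param n_b_per_core,n_t_per_core B/plasma and T cells per core.
#' @param shells named list of `c(lo, hi)` distances from the core edge;
#'   defaults plant a "Tph/Tfh" ring at 5-10 um and an "mregDC" ring at
#'   10-20 um.
#' @param n_per_shell cells per shell per core.
#' @param n_stromal background stromal cells over the extent.
#' @param extent field extent, micrometres.
#' @param min_core_sep minimal distance between core centers.
#' @param seed integer seed.
#' @return list(cells, truth) with per-cell `aggregate_id` (0 =
#'   background) covering core and shell cells.
#' @export
sim_tls_tissue <- function(n_cores = 2, core_radius = 40,
                           n_b_per_core = 80, n_t_per_core = 80,
                           shells = list(`Tph/Tfh` = c(5, 10),
                                         mregDC = c(10, 20)),
                           n_per_shell = 40, n_stromal = 600,
                           extent = c(1000, 1000), min_core_sep = 300,
                           seed = 1) {
  with_seed(seed, {
    margin <- core_radius + 60
    centers <- matrix(0, 0, 2)
    while (nrow(centers) < n_cores) {
      cand <- c(runif(1, margin, extent[1] - margin),
                runif(1, margin, extent[2] - margin))
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums((centers - matrix(cand, nrow(centers), 2,
                                             byrow = TRUE))^2))) >=
          min_core_sep) {
        centers <- rbind(centers, cand)
      }
    }
    coords <- NULL; types <- character(0); agg_id <- integer(0)
    for (i in seq_len(n_cores)) {
      cb <- runif_disk(n_b_per_core, core_radius, centers[i, 1], centers[i, 2])
      ct <- runif_disk(n_t_per_core, core_radius, centers[i, 1], centers[i, 2])
      coords <- rbind(coords, cb, ct)
      types <- c(types, rep("B/plasma", n_b_per_core), rep("T", n_t_per_core))
      agg_id <- c(agg_id, rep(i, n_b_per_core + n_t_per_core))
      for (sh in names(shells)) {
        lohi <- shells[[sh]]
        pts <- runif_annulus(n_per_shell, core_radius + lohi[1],
                             core_radius + lohi[2],
                             centers[i, 1], centers[i, 2])
        coords <- rbind(coords, pts)
        types <- c(types, rep(sh, n_per_shell))
        agg_id <- c(agg_id, rep(i, n_per_shell))
      }
    }
    bg <- cbind(runif(n_stromal, 0, extent[1]), runif(n_stromal, 0, extent[2]))
    coords <- rbind(coords, bg)
    types <- c(types, rep("Stromal", n_stromal))
    agg_id <- c(agg_id, rep(0L, n_stromal))
    lineage_map <- c("B/plasma" = "B/plasma", "T" = "T", "Tph/Tfh" = "T",
                     "mregDC" = "Myeloid", "Stromal" = "Stromal")
    cells <- mk_cells(coords, types, lineage = lineage_map[types])
    list(cells = cells,
         truth = list(pattern = "tls_tissue", centers = centers,
                      core_radius = core_radius, shells = shells,
                      aggregate_id = agg_id))
  })
}

#' Expression-gradient tissue with calibrated Spearman correlation
#'
#' Plants a target cell type (e.g. endothelium) under complete spatial
#' randomness among query cells, then generates per-cell expression for
#' named genes whose Spearman correlation with
#' distance-to-nearest-target hits a requested value. Calibration uses a
#' Gaussian copula on the distance ranks (latent
#' `r = 2 sin(pi * rho_s / 6)` gives Spearman `rho_s` for a bivariate
#' Gaussian), so the target is met regardless of marginals. Values are
#' mapped through the standard normal CDF, hence lie in (0, 1); the
#' matrix is flagged as normalized. Target-type cells receive
#' independent noise (they sit at distance 0 and are excluded from
#' calibration).
#'
#' @param n_cells query cells (default 2000).
#' @param target_rho named numeric vector: one gene per entry, values in
#'   (-1, 1).
#' @param target_type,query_type type labels.
#' @param frac_target fraction of additional target-type cells.
#' @param extent field extent, micrometres.
#' @param seed integer seed.
#' @return list(cells, expr, truth); truth records target and realized
#'   Spearman per gene (computed on query cells).
#' @export
sim_gradient_tissue <- function(n_cells = 2000,
                                target_rho = c(GRADGENE1 = 0.35),
                                target_type = "Endothelial",
                                query_type = "Macrophage",
                                frac_target = 0.1,
                                extent = c(1000, 1000), seed = 1) {
  stopifnot(!is.null(names(target_rho)), all(abs(target_rho) < 1))
  with_seed(seed, {
    n_t <- max(5L, round(n_cells * frac_target))
    n <- n_cells + n_t
    coords <- cbind(x = runif(n, 0, extent[1]), y = runif(n, 0, extent[2]))
    types <- c(rep(query_type, n_cells), rep(target_type, n_t))
    cells <- mk_cells(coords, types)
    dfield <- nearest_distance_to_type(cells, target_type)
    q <- which(types == query_type)
    d <- dfield$distance[q]
    zd <- qnorm((rank(d, ties.method = "average") - 0.5) / length(d))
    vals <- matrix(0, n, length(target_rho),
                   dimnames = list(cells$cell_id, names(target_rho)))
    realized <- numeric(length(target_rho))
    for (g in seq_along(target_rho)) {
      r <- 2 * sin(pi * target_rho[g] / 6)
      lat <- numeric(n)
      lat[q] <- r * zd + sqrt(1 - r^2) * rnorm(length(q))
      lat[-q] <- rnorm(n - length(q))
      vals[, g] <- pnorm(lat)
      realized[g] <- spearman_cor(d, vals[q, g])$rho
    }
    expr <- expr_matrix(vals, cells = cells$cell_id,
                        genes = names(target_rho), normalized = TRUE)
    list(cells = cells, expr = expr,
         truth = list(pattern = "gradient_tissue",
                      target_type = target_type, query_type = query_type,
                      target_rho = target_rho,
                      realized_rho = setNames(realized, names(target_rho))))
  })
}

#' Dispatch a simulation from a declarative spec
#'
#' @param spec list with `pattern` in `concentric`, `layers`, `csr`,
#'   `coloc_aggregate`, `tls_tissue`, `gradient_tissue`, plus that
#'   generator's parameters.
#' @return the generator's list(cells, truth[, expr]).
#' @export
generate_tissue <- function(spec) {
  pattern <- match.arg(spec$pattern,
                       c("concentric", "layers", "csr", "coloc_aggregate",
                         "tls_tissue", "gradient_tissue"))
  fn <- switch(pattern,
               concentric = sim_concentric, layers = sim_layers,
               csr = sim_csr, coloc_aggregate = sim_coloc_aggregate,
               tls_tissue = sim_tls_tissue,
               gradient_tissue = sim_gradient_tissue)
  args <- spec[setdiff(names(spec), "pattern")]
  do.call(fn, args)
}

#' Detection-boundary sweep over planted gaps and seeds
#'
#' Runs [enrichment_test] on generated concentric or layered tissues for
#' every (gap, seed) combination and records z and BH-adjusted p for the
#' planted pair and, when a decoy is planted, the decoy pair.
#'
#' @param pattern `"concentric"` or `"layers"`.
#' @param gaps planted gaps in micrometres.
#' @param seeds integer seeds.
#' @param n_per_type cells per type.
#' @param decoy_gap_um decoy gap (NULL for none).
#' @param config an [enrichment_config] used for every run.
#' @return data.frame: pattern, gap_um, seed, pair, anchor, target, z,
#'   p_adj.
#' @export
sweep_enrichment <- function(pattern = c("concentric", "layers"),
                             gaps = c(10, 20, 30), seeds = 1:20,
                             n_per_type = 500, decoy_gap_um = 150,
                             config = enrichment_config()) {
  pattern <- match.arg(pattern)
  gen <- if (pattern == "concentric") sim_concentric else sim_layers
  rows <- list()
  for (gap in gaps) {
    for (sd in seeds) {
      sim <- gen(n_per_type = n_per_type, gap_um = gap, seed = sd,
                 decoy_gap_um = decoy_gap_um)
      cfg <- config
      cfg$seed <- perm_seed(config$seed, sd)
      res <- enrichment_test(sim$cells, cfg)
      grab <- function(pair, label) {
        row <- res$table[res$table$anchor_type == pair[1] &
                           res$table$target_type == pair[2], ]
        data.frame(pattern = pattern, gap_um = gap, seed = sd,
                   pair = label, anchor = pair[1], target = pair[2],
                   z = row$z, p_adj = row$p_adj, stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- grab(sim$truth$planted_pair, "planted")
      if (!is.null(sim$truth$decoy_pair)) {
        rows[[length(rows) + 1L]] <- grab(sim$truth$decoy_pair, "decoy")
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
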