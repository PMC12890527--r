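tls_pipeline <- function(sim, quantile = 0.1, min_cells = 20) {
  fld <- coloc_score(sim$cells, "T", "B/plasma",
                     coloc_config(radius_um = 10))
  detect_tls(fld, sim$cells,
             tls_config(score_quantile = quantile, linkage_radius_um = 30,
                        min_cells = min_cells))
}

test_that("all-zero fields yield an empty region set, not an error", {
  cm <- cell_map(c(sprintf("t%02d", 1:25), sprintf("b%02d", 1:25)),
                 x = c(runif(25, 0, 50), runif(25, 500, 550)),
                 y = runif(50, 0, 50),
                 cell_type = rep(c("T", "B/plasma"), each = 25))
  fld <- coloc_score(cm, "T", "B/plasma", coloc_config(radius_um = 10))
  expect_true(all(fld$score == 0))
  regions <- detect_tls(fld, cm, tls_config())
  expect_length(regions$regions, 0)
  expect_equal(nrow(as.data.frame(regions)), 0)
})

test_that("two planted aggregates 200+ um apart give exactly 2 regions", {
  sim <- sim_tls_tissue(n_cores = 2, min_core_sep = 300, seed = 9)
  regions <- tls_pipeline(sim)
  expect_length(regions$regions, 2)
  # hulls contain their members
  for (r in regions$regions) {
    expect_true(all(r$x >= min(r$hull[, "x"]) & r$x <= max(r$hull[, "x"])))
  }
})

test_that("region membership recovers planted mixed aggregates (IoU)", {
  sim <- sim_coloc_aggregate(n_agg = 3, seed = 9)
  fld <- coloc_score(sim$cells, "A", "B", coloc_config(radius_um = 10))
  regions <- detect_tls(fld, sim$cells,
                        tls_config(score_quantile = 0.1,
                                   linkage_radius_um = 30, min_cells = 20))
  expect_length(regions$regions, 3)
  planted <- split(seq_len(nrow(sim$cells)), sim$truth$aggregate_id)
  planted <- planted[names(planted) != "0"]
  for (r in regions$regions) {
    ious <- vapply(planted, function(p) {
      length(intersect(r$member_rows, p)) / length(union(r$member_rows, p))
    }, 1)
    expect_gt(max(ious), 0.8)
  }
})

test_that("detection is deterministic and order-invariant", {
  sim <- sim_tls_tissue(seed = 10)
  r1 <- tls_pipeline(sim)
  perm <- withr::with_seed(1, sample(nrow(sim$cells)))
  sim2 <- sim
  sim2$cells <- sim$cells[perm, ]
  class(sim2$cells) <- class(sim$cells)
  r2 <- tls_pipeline(sim2)
  expect_equal(length(r1$regions), length(r2$regions))
  for (i in seq_along(r1$regions)) {
    expect_setequal(r1$regions[[i]]$member_cells,
                    r2$regions[[i]]$member_cells)
  }
})

test_that("single-linkage components match the union-find oracle", {
  set.seed(12)
  for (rep in 1:3) {
    n <- 300
    x <- runif(n, 0, 400); y <- runif(n, 0, 400)
    got <- spatialcoloc:::link_components(x, y, 30)
    want <- oracle_components(x, y, 30)
    # same partition (labels may differ)
    expect_equal(adjusted_rand_index(got, want), 1)
  }
})

test_that("distance composition curves sum to 1 and B sits in the 0 bin", {
  sim <- sim_tls_tissue(seed = 13)
  regions <- tls_pipeline(sim)
  comp <- tls_distance_composition(sim$cells, regions, "B/plasma",
                                   bins = seq(0, 50, by = 5))
  expect_equal(unname(rowSums(comp$proportions)),
               rep(1, nrow(comp$proportions)), tolerance = 1e-9)
  # B cells are distance 0 from themselves
  expect_equal(unname(comp$proportions["B/plasma", 1]), 1)
  # the planted Tph/Tfh ring at 5-10 um from the core edge has its modal
  # bin at small distances (members of the ring sit close to edge B cells)
  tph <- comp$proportions["Tph/Tfh", ]
  expect_lte(which.max(tph), 3)
})

test_that("proximity summary: closed-form OLS slope and shares", {
  # hand-worked 3-bin case: proportions (0.6, 0.3, 0.1) at midpoints
  # (5, 15, 25) -> slope -0.025 per um
  sl <- spatialcoloc:::ols_slope(c(5, 15, 25), c(0.6, 0.3, 0.1))
  expect_equal(sl$slope, -0.025, tolerance = 1e-12)

  sim <- sim_tls_tissue(seed = 14)
  regions <- tls_pipeline(sim)
  # 3 um bins so the core T population spans >= 3 nonempty bins
  comp <- tls_distance_composition(sim$cells, regions, "B/plasma",
                                   bins = seq(0, 30, by = 3))
  summ <- tls_proximity_summary(comp, near_radius = 10)
  expect_equal(summ$pct_within_near[summ$cell_type == "B/plasma"], 100)
  expect_equal(summ$pct_within_near[summ$cell_type == "T"], 100)
  # B sits in fewer than 3 nonempty bins -> slope NA by contract
  expect_true(is.na(summ$slope_per_um[summ$cell_type == "B/plasma"]))
  # T is packed against B and decays with distance
  expect_lt(summ$slope_per_um[summ$cell_type == "T"], 0)
  expect_true(all(summ$ci_lo <= summ$slope_per_um + 1e-12, na.rm = TRUE))
  # a uniform background type has no decay: its CI covers 0
  st <- summ[summ$cell_type == "Stromal", ]
  expect_true(st$ci_lo <= 0 && st$ci_hi >= 0)
})

test_that("GeoJSON export writes closed polygons with region properties", {
  sim <- sim_tls_tissue(n_cores = 1, seed = 15)
  regions <- tls_pipeline(sim)
  f <- withr::local_tempfile(fileext = ".geojson")
  write_tls_geojson(regions, f)
  gj <- jsonlite::read_json(f)
  expect_equal(gj$type, "FeatureCollection")
  expect_length(gj$features, length(regions$regions))
  ring <- gj$features[[1]]$geometry$coordinates[[1]]
  expect_equal(ring[[1]], ring[[length(ring)]])
})
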