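mk_expr <- function(m, cells = sprintf("c%02d", seq_len(nrow(m))),
                    genes = sprintf("G%02d", seq_len(ncol(m))),
                    normalized = FALSE) {
  expr_matrix(m, cells = cells, genes = genes, normalized = normalized)
}

test_that("normalization scales to the median total then log1p", {
  m <- rbind(c(2, 0), c(1, 1), c(4, 0))
  em <- normalize_expression(mk_expr(m))
  # totals 2,2,4; median 2 -> cell1 scale 1: log1p(2), 0
  expect_equal(as.numeric(em$values[1, ]), c(log1p(2), 0))
  expect_equal(as.numeric(em$values[3, ]), c(log1p(2), 0))
  expect_true(em$normalized)
  expect_error(normalize_expression(em), "already normalized")
  # all-zero cell retained with warning
  expect_warning(z <- normalize_expression(mk_expr(rbind(c(1, 1), c(0, 0)))),
                 "all-zero")
  expect_equal(as.numeric(z$values[2, ]), c(0, 0))
  # single cell: scale factor 1
  one <- normalize_expression(mk_expr(matrix(c(3, 1), 1)))
  expect_equal(as.numeric(one$values), log1p(c(3, 1)))
})

test_that("module score cancels for self-matching sets and recovers shifts", {
  # 10 expression levels x 10 genes per level, every gene identical to its
  # level mates; equal-frequency bins (n_bins = 10) coincide with levels,
  # so every control equals the set gene exactly
  set.seed(14)
  n_cells <- 80
  pattern <- matrix(rpois(n_cells * 10, 3), n_cells, 10)
  base <- sweep(pattern[, rep(1:10, each = 10)], 2,
                5 * rep(1:10, each = 10), "+")
  em <- mk_expr(base, normalized = TRUE)
  gs <- gene_set("SELFCANCEL", c("G01", "G35"))
  sc <- module_score(em, gs, list(n_bins = 10, n_ctrl_per_gene = 9, seed = 1))
  expect_equal(unname(sc), rep(0, n_cells), tolerance = 1e-12)

  # planted shift: set genes sit exactly delta above their level mates
  # (delta < level spacing, so bins are unchanged)
  delta <- 2
  shifted <- base
  shifted[, c(1, 35)] <- base[, c(1, 35)] + delta
  em2 <- mk_expr(shifted, normalized = TRUE)
  sc2 <- module_score(em2, gs, list(n_bins = 10, n_ctrl_per_gene = 9,
                                    seed = 2))
  expect_equal(unname(sc2), rep(delta, n_cells), tolerance = 1e-12)

  # determinism and missing-gene handling
  sc3 <- module_score(em2, gs, list(n_bins = 10, n_ctrl_per_gene = 9,
                                    seed = 2))
  expect_identical(sc2, sc3)
  gs2 <- gene_set("PARTIAL", c("G01", "NOT_A_GENE"))
  expect_silent(suppressMessages(module_score(em2, gs2, list(seed = 1))))
  expect_error(module_score(em2, gene_set("NONE", "ZZZ"), list(seed = 1)),
               "no gene")
})

test_that("module score is location-invariant with deterministic controls", {
  set.seed(15)
  m <- matrix(rpois(60 * 40, 4), 60, 40)
  em <- mk_expr(m, normalized = TRUE)
  gs <- gene_set("SET", c("G05", "G10"))
  cfg <- list(n_bins = 5, n_ctrl_per_gene = 100, seed = 3) # whole-bin controls
  s1 <- module_score(em, gs, cfg)
  em2 <- mk_expr(m + 3, normalized = TRUE)
  s2 <- module_score(em2, gs, cfg)
  expect_equal(s1, s2, tolerance = 1e-10)
})

test_that("spearman matches the rank-then-Pearson oracle incl. ties", {
  set.seed(16)
  x <- rnorm(200); y <- rnorm(200)
  s <- spatialcoloc:::spearman_cor(x, y)
  expect_equal(s$rho, cor(rank(x), rank(y)), tolerance = 1e-12)
  xt <- sample(1:10, 200, TRUE); yt <- sample(1:5, 200, TRUE) # heavy ties
  st <- spatialcoloc:::spearman_cor(xt, yt)
  expect_equal(st$rho, cor(rank(xt), rank(yt)), tolerance = 1e-12)
  expect_equal(st$rho,
               suppressWarnings(cor.test(xt, yt, method = "spearman")$estimate),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("distance profiles: bin means, monotone and constant cases", {
  set.seed(17)
  n <- 300
  cm <- cell_map(sprintf("c%03d", 1:n),
                 x = c(0, runif(n - 1, 1, 290)), y = 0,
                 cell_type = c("Endothelial", rep("Mac", n - 1)))
  dfield <- nearest_distance_to_type(cm, "Endothelial")
  vals <- list(ident = dfield$distance, const = rep(2, n))
  prof <- binned_distance_profile(vals, dfield, bin_width = 10, max_dist = 300)
  expect_equal(prof$spearman$rho[prof$spearman$variable == "ident"], 1)
  expect_true(is.na(prof$spearman$rho[prof$spearman$variable == "const"]))
  expect_equal(sum(prof$counts), sum(dfield$distance < 300))
  # bin means of the identity lie inside their bin
  ok <- !is.na(prof$means[, "ident"])
  expect_true(all(prof$means[ok, "ident"] >= prof$bins$lo[ok] &
                    prof$means[ok, "ident"] < prof$bins$hi[ok]))
})

test_that("planted gradient rho is recovered on cells, not bins", {
  sim <- sim_gradient_tissue(n_cells = 2000,
                             target_rho = c(GENE_NEG = -0.35), seed = 19)
  d <- nearest_distance_to_type(sim$cells, "Endothelial")
  q <- sim$cells$cell_type == "Macrophage"
  v <- as.numeric(sim$expr$values[, "GENE_NEG"])
  r <- correlate_score_distance(v, d, cells = sim$cells,
                                subset_type = "Macrophage")
  expect_lt(abs(r$rho - (-0.35)), 0.07)
  expect_lt(r$p, 0.001)
  # monotone score: rho exactly 1
  r2 <- correlate_score_distance(d$distance^2, d, cells = sim$cells,
                                 subset_type = "Macrophage")
  expect_equal(r2$rho, 1)
  # null: independent score
  set.seed(20)
  pvals <- replicate(10, {
    correlate_score_distance(rnorm(nrow(sim$cells)), d)$rho
  })
  expect_true(mean(abs(pvals) < 0.06) >= 0.9)
})

test_that("spatial score map preserves module_score numerics and aggregates", {
  set.seed(22)
  n <- 50
  m <- matrix(rpois(n * 30, 4), n, 30)
  cells <- cell_map(sprintf("c%02d", 1:n), runif(n, 0, 100),
                    runif(n, 0, 100), rep(c("T", "B"), n / 2))
  em <- mk_expr(m, cells = cells$cell_id, normalized = TRUE)
  gs <- gene_set("SET", c("G02", "G07"))
  cfg <- list(n_bins = 5, n_ctrl_per_gene = 10, seed = 4)
  map <- spatial_gene_set_score_map(em, gs, cells, cfg)
  sc <- module_score(em, gs, cfg)
  expect_equal(map$score, unname(sc[map$cell_id]))
  # per-group mean equals mean over member cells
  grp_mean <- tapply(map$score, cells$cell_type, mean)
  expect_equal(unname(grp_mean["T"]), mean(map$score[cells$cell_type == "T"]))
})

test_that("rank-sum group comparison flags a shifted group", {
  set.seed(23)
  score <- c(rnorm(100, 2), rnorm(100, 0), rnorm(100, 0))
  grp <- rep(c("hot", "cold1", "cold2"), each = 100)
  res <- compare_score_groups(score, grp)
  expect_lt(res$p_adj[res$group == "hot"], 0.001)
  expect_equal(nrow(res), 3)
})
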