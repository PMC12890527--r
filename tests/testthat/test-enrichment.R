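# two radius-30 cliques on a line: x = 0,1,2 and 100,101,102
clique_cells <- function(types) {
  cell_map(sprintf("c%d", 1:6), x = c(0, 1, 2, 100, 101, 102), y = 0,
           cell_type = types)
}

cfg30 <- function(...) {
  enrichment_config(query = list(mode = "radius", radius_um = 30),
                    min_cells_per_type = 1, ...)
}

test_that("neighborhood composition gives exact fractions and flags", {
  cm <- cell_map(c("a", "n1", "n2", "n3", "far"),
                 x = c(0, 1, 2, 3, 500), y = 0,
                 cell_type = c("A", "B", "B", "T", "A"))
  g <- build_neighbor_graph(cm, list(mode = "radius", radius_um = 5))
  comp <- neighborhood_composition(cm, g)
  expect_equal(comp["a", ], c(A = 0, B = 2 / 3, T = 1 / 3))
  expect_equal(sum(comp["far", ]), 0)
  expect_true(attr(comp, "no_neighbors")[5])
  expect_equal(comp["n3", ], c(A = 1 / 3, B = 2 / 3, T = 0))
  expect_equal(rowSums(comp)[1:4], setNames(rep(1, 4), cm$cell_id[1:4]))
})

test_that("exhaustive null matches hand enumeration on the 6-cell instances", {
  # segregated: A,A,A | B,B,B -> observed A->B = 0, p = 1 over all 20 labelings
  cm <- clique_cells(c("A", "A", "A", "B", "B", "B"))
  res <- exhaustive_null(cm, cfg30())
  expect_equal(res$n_null, 20) # C(6,3)
  ab <- res$table[res$table$anchor_type == "A" & res$table$target_type == "B", ]
  expect_equal(ab$observed_stat, 0)
  expect_equal(ab$p_perm, 1)
  expect_equal(ab$p_perm,
               oracle_exact_p(cm$x, cm$y, cm$cell_type, 30, "A", "B"))

  # alternating: observed maximal, p lowest attainable
  cm2 <- clique_cells(c("A", "B", "A", "B", "A", "B"))
  res2 <- exhaustive_null(cm2, cfg30())
  ab2 <- res2$table[res2$table$anchor_type == "A" &
                      res2$table$target_type == "B", ]
  stats_all <- apply(combn(6, 3), 2, function(pa) {
    l <- rep("B", 6); l[pa] <- "A"
    oracle_pair_stat(cm2$x, cm2$y, l, 30, "A", "B")
  })
  expect_equal(ab2$observed_stat, max(stats_all))
  expect_equal(ab2$p_perm, mean(stats_all >= max(stats_all) - 1e-12))
  expect_equal(ab2$p_perm,
               oracle_exact_p(cm2$x, cm2$y, cm2$cell_type, 30, "A", "B"))
})

test_that("exhaustive null enumerates C(4,2)=6 labelings and refuses blowups", {
  cm <- cell_map(c("a", "b", "c", "d"), x = c(0, 5, 10, 15), y = 0,
                 cell_type = c("A", "A", "B", "B"))
  res <- exhaustive_null(cm, cfg30())
  expect_equal(res$n_null, 6)
  expect_error(exhaustive_null(cm, cfg30(), max_labelings = 3),
               "labelings")
})

test_that("degenerate geometry (all cells out of radius) gives p = 1", {
  cm <- cell_map(sprintf("c%d", 1:4), x = c(0, 100, 200, 300), y = 0,
                 cell_type = c("A", "A", "B", "B"))
  res <- exhaustive_null(cm, cfg30())
  expect_true(all(is.na(res$table$observed_stat)))
  expect_true(all(is.na(res$table$p_perm)))
})

test_that("Monte-Carlo p converges to the exhaustive p (binomial bound)", {
  set.seed(11)
  for (rep in 1:4) {
    cm <- cell_map(sprintf("c%d", 1:6),
                   x = runif(6, 0, 60), y = runif(6, 0, 60),
                   cell_type = sample(rep(c("A", "B"), 3)))
    ex <- exhaustive_null(cm, cfg30())
    mc <- enrichment_test(cm, cfg30(n_perm = 1e4, seed = rep))
    for (dir in list(c("A", "B"), c("B", "A"))) {
      pe <- ex$table$p_perm[ex$table$anchor_type == dir[1] &
                              ex$table$target_type == dir[2]]
      pm <- mc$table$p_perm[mc$table$anchor_type == dir[1] &
                              mc$table$target_type == dir[2]]
      se <- sqrt(pe * (1 - pe) / 1e4)
      expect_lt(abs(pm - pe), 3 * se + 2 / 1e4)
    }
  }
})

test_that("z is invariant to translation, rotation and reflection", {
  sim <- sim_csr(n_per_type = 80, types = c("A", "B"), seed = 5,
                 extent = c(300, 300))
  cm <- sim$cells
  res0 <- enrichment_test(cm, cfg30(n_perm = 200, seed = 3))
  th <- 0.7
  rot <- cm
  rot$x <- cos(th) * cm$x - sin(th) * cm$y + 50
  rot$y <- sin(th) * cm$x + cos(th) * cm$y - 20
  res1 <- enrichment_test(rot, cfg30(n_perm = 200, seed = 3))
  refl <- cm; refl$x <- -cm$x
  res2 <- enrichment_test(refl, cfg30(n_perm = 200, seed = 3))
  expect_equal(res1$table$z, res0$table$z, tolerance = 1e-8)
  expect_equal(res2$table$z, res0$table$z, tolerance = 1e-12)
})

test_that("same seed reproduces results exactly; threads flag is inert", {
  cm <- sim_csr(n_per_type = 60, seed = 2, extent = c(300, 300))$cells
  r1 <- enrichment_test(cm, cfg30(n_perm = 300, seed = 17, threads = 1))
  r2 <- enrichment_test(cm, cfg30(n_perm = 300, seed = 17, threads = 4))
  expect_identical(r1$table, r2$table)
  r3 <- enrichment_test(cm, cfg30(n_perm = 300, seed = 18))
  expect_false(identical(r1$table$p_perm, r3$table$p_perm))
})

test_that("min_cells filter skips rare types; p floor and BH invariants hold", {
  set.seed(9)
  n <- 120
  cm <- cell_map(sprintf("c%d", 1:n), runif(n, 0, 200), runif(n, 0, 200),
                 c(rep("A", 57), rep("B", 57), rep("Rare", 6)))
  res <- enrichment_test(cm, enrichment_config(n_perm = 99, seed = 1,
                                               min_cells_per_type = 10))
  tab <- res$table
  rare <- tab[tab$anchor_type == "Rare" | tab$target_type == "Rare", ]
  expect_true(all(rare$status == "skipped_low_count"))
  expect_true(all(is.na(rare$z)))
  tested <- tab[tab$status == "tested", ]
  expect_true(all(tested$p_perm >= 1 / 100 & tested$p_perm <= 1))
  expect_true(all(tested$p_adj >= tested$p_perm - 1e-12))
  # permutations are within-sample by default: labels shuffle inside s1/s2
  cm$sample_id <- rep(c("s1", "s2"), each = n / 2)
  expect_s3_class(enrichment_test(cm, cfg30(n_perm = 50, seed = 1)),
                  "enrichment_result")
})

test_that("depletion and two-sided alternatives mirror enrichment", {
  cm <- clique_cells(c("A", "A", "A", "B", "B", "B"))
  dep <- exhaustive_null(cm, cfg30(alternative = "depletion"))
  abd <- dep$table[dep$table$anchor_type == "A" & dep$table$target_type == "B", ]
  expect_equal(abd$p_perm, 2 / 20) # only the 2 fully segregated labelings
  two <- exhaustive_null(cm, cfg30(alternative = "two-sided"))
  abt <- two$table[two$table$anchor_type == "A" & two$table$target_type == "B", ]
  expect_equal(abt$p_perm, min(1, 2 * min(1, 2 / 20)))
})
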