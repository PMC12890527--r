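`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
sc_log <- function(..., verbose = getOption("spatialcoloc.verbose", TRUE)) {
  if (isTRUE(verbose)) message("[spatialcoloc] ", ...)
  invisible(NULL)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All stochastic entry points funnel through
# this so a user-level seed gives bit-identical results.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Sub-seed for permutation `counter` derived from a master seed. Derivation
# by counter (not by stream position) makes results invariant to how
# permutations are partitioned across workers.
perm_seed <- function(master_seed, counter) {
  (as.integer(master_seed) + 10007L * as.integer(counter)) %% 2147483647L
}

# Benjamini-Hochberg over a vector that may contain NAs (skipped tests).
bh_adjust <- function(p) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- p.adjust(p[ok], method = "BH")
  out
}

# Spearman rank correlation with average ranks for ties, plus the two-sided
# t-approximation p-value (the standard large-sample test; exact
# enumeration is never needed at the n this package handles).
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) return(list(rho = NA_real_, p = NA_real_, n = n))
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, n = n, note = "zero variance"))
  }
  rho <- cor(rx, ry)
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p, n = n)
}

# Adjusted Rand index between two labelings (used to score planted-niche
# recovery against ground truth).
#' Adjusted Rand index
#'
#' Agreement between two partitions of the same cells, corrected for
#' chance; 1 means identical partitions, 0 is the expectation under
#' independent random labelings.
#'
#' @param a,b label vectors of equal length.
#' @return a single number in (-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
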