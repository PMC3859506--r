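# Functional profiling: weight arithmetic, rollup, correlations, PCA
# against a hand eigendecomposition, and the inclusive 90/90 filter.

ann_row <- function(sample, ko, gene_len_aa, n = 1) {
  data.frame(sample = sample,
             peptide_id = sprintf("%s_%s_%d", sample, ko, seq_len(n)),
             read_id = "r", ko = ko, gene_len_aa = gene_len_aa,
             stringsAsFactors = FALSE)
}

test_that("equal gene lengths make normalized abundances proportional to
           counts", {
  ann <- rbind(ann_row("s1", "K00001", 300, n = 2),
               ann_row("s1", "K00002", 300, n = 1))
  rl <- data.frame(sample = "s1", mean_read_len = 350)
  m <- ko_abundance(ann, rl)
  expect_equal(unname(m["s1", c("K00001", "K00002")]), c(2 / 3, 1 / 3))
  expect_equal(sum(m["s1", ]), 1)
})

test_that("the start-position weight 1/(3*aa + mean_len - 1) drives the
           abundance ratio", {
  # genes of 1000 vs 2000 nt at mean read length 350: hand arithmetic
  ann <- rbind(ann_row("s1", "KA", 1000 / 3 * 1),  # not integer aa; use nt/3
               ann_row("s1", "KB", 2000 / 3 * 1))
  ann$gene_len_aa <- c(1000 / 3, 2000 / 3)
  rl <- data.frame(sample = "s1", mean_read_len = 350)
  m <- ko_abundance(ann, rl)
  wA <- 1 / (1000 + 350 - 1)
  wB <- 1 / (2000 + 350 - 1)
  expect_equal(unname(m["s1", "KA"] / m["s1", "KB"]), wA / wB,
               tolerance = 1e-12)
  expect_equal(wA / wB, 2349 / 1349)   # = 1.741...
})

test_that("raw mode counts peptides and missing gene lengths only matter
           when normalizing", {
  ann <- rbind(ann_row("s1", "K00001", NA, n = 3),
               ann_row("s1", "K00002", NA, n = 1))
  m <- ko_abundance(ann, mode = "raw")
  expect_equal(unname(m["s1", c("K00001", "K00002")]), c(3, 1))
  expect_error(ko_abundance(ann, data.frame(sample = "s1",
                                            mean_read_len = 350)),
               "gene length")
})

test_that("length normalization removes read-length bias between samples
           with identical composition", {
  # Two samples share one true KO composition but differ in mean read
  # length. Observed peptide counts scale with the number of read start
  # positions overlapping each gene, 3*aa + L - 1, so raw profiles are
  # biased; normalization must recover the common composition.
  withr::with_seed(401, {
    kos <- sprintf("K%05d", 1:20)
    gene_len <- sample(100:800, 20)
    comp <- stats::runif(20, 0.5, 2)
    comp <- comp / sum(comp)
  })
  build <- function(sample, L) {
    counts <- round(4 * comp * (3 * gene_len + L - 1))
    data.frame(sample = sample,
               peptide_id = sprintf("%s_p%d", sample,
                                    seq_len(sum(counts))),
               read_id = "r", ko = rep(kos, counts),
               gene_len_aa = rep(gene_len, counts),
               stringsAsFactors = FALSE)
  }
  ann <- rbind(build("short_reads", 250), build("long_reads", 450))
  rl <- data.frame(sample = c("short_reads", "long_reads"),
                   mean_read_len = c(250, 450))
  m <- ko_abundance(ann, rl)
  rel_diff <- abs(m["short_reads", ] - m["long_reads", ]) / m["long_reads", ]
  expect_lt(max(rel_diff), 0.02)
  # whereas the raw count shares differ by more than 2% for some KO
  raw <- ko_abundance(ann, mode = "raw")
  raw_share <- raw / rowSums(raw)
  raw_diff <- abs(raw_share["short_reads", ] - raw_share["long_reads", ]) /
    raw_share["long_reads", ]
  expect_gt(max(raw_diff), 0.02)
})

test_that("category rollup counts multi-membership once per category and
           renormalizes", {
  mat <- matrix(c(0.2, 0.3, 0.5), nrow = 1,
                dimnames = list("s1", c("K1", "K2", "K3")))
  map <- data.frame(ko = c("K1", "K2", "K3", "K3"),
                    category = c("catA", "catA", "catA", "catB"))
  out <- category_rollup(mat, map)
  # before renormalization catA = 1.0, catB = 0.5
  expect_equal(unname(out["s1", c("catA", "catB")]), c(1, 0.5) / 1.5)
  expect_equal(sum(out["s1", ]), 1)
  # unmapped KOs accumulate under "unmapped"
  out2 <- category_rollup(mat, map[1:2, ])
  expect_true("unmapped" %in% colnames(out2))
})

test_that("profile correlations: identical -> 1, reversed -> -1, mean over
           pairs", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(3, 2, 1))
  res <- profile_correlation(m)
  expect_equal(res$matrix["a", "b"], 1)
  expect_equal(res$matrix["a", "c"], -1)
  expect_equal(res$mean_pairwise, mean(c(1, -1, -1)))
  expect_error(profile_correlation(m[1, , drop = FALSE]), "two samples")
})

test_that("PCA variance fractions match a hand eigendecomposition to
           1e-8", {
  withr::with_seed(402, {
    mat <- matrix(stats::runif(4 * 3), nrow = 4,
                  dimnames = list(paste0("s", 1:4), paste0("f", 1:3)))
  })
  ord <- pca_ordination(mat)
  oracle <- eigen_pca_oracle(mat)
  k <- length(ord$var_explained)
  expect_equal(ord$var_explained, oracle$var_explained[1:k],
               tolerance = 1e-8)
  expect_true(all(diff(ord$var_explained) <= 1e-12))
  expect_lte(sum(ord$var_explained), 1 + 1e-12)
})

test_that("PCA is feature-translation invariant with stable loading signs
           and a rank-1 matrix loads everything on PC1", {
  base <- matrix(c(1, 2, 4, 8), nrow = 4) %*% t(c(0.2, 0.5, 0.3))
  dimnames(base) <- list(paste0("s", 1:4), paste0("f", 1:3))
  ord <- pca_ordination(base)
  expect_equal(ord$var_explained[1], 1, tolerance = 1e-12)
  shifted <- sweep(base, 2, c(10, -5, 3), "+")
  ord2 <- pca_ordination(shifted)
  expect_equal(ord$scores[, 1], ord2$scores[, 1], tolerance = 1e-8)
  # sign convention: the largest-|loading| entry is positive
  expect_gt(max(ord$top_loadings$PC1$loading), 0)
  expect_error(pca_ordination(base[1:2, ]), "3 samples")
})

test_that("the resistance/virulence filter is inclusive at 90/90", {
  hits <- data.frame(pct_identity = c(90, 89.9, 95, 90),
                     pct_coverage = c(90, 99, 89.9, 100))
  kept <- stringent_match_filter(hits)
  expect_equal(nrow(kept), 2L)   # rows 1 and 4
  expect_true(all(kept$pct_identity >= 90 & kept$pct_coverage >= 90))
  expect_equal(nrow(stringent_match_filter(hits[0, ])), 0L)
})
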