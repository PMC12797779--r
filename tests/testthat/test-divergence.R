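test_that("pairwise F_ST matches hand computation and is symmetric", {
  f <- locus_freqs(c("A", "B"), "L1", c(0.9, 0.1), 100)
  expect_equal(pairwise_fst(f, "A", "B"), 0.64)
  expect_equal(pairwise_fst(f, "B", "A"), pairwise_fst(f, "A", "B"))
  same <- locus_freqs(c("A", "A", "B", "B"), c("L1", "L2", "L1", "L2"),
                      c(0.3, 0.7, 0.3, 0.7), 50)
  expect_equal(pairwise_fst(same, "A", "B"), 0)
  expect_equal(pairwise_fst(same, "A", "B", method = "wc"), 0)
  f2 <- locus_freqs(c("A", "C"), c("L1", "L2"), c(0.5, 0.5), 10)
  expect_error(pairwise_fst(f2, "A", "C"), "share no typed loci")
})

test_that("Nei D_A matches hand values and attains its extremes", {
  f <- locus_freqs(c("A", "B"), "L1", c(0.9, 0.1), 100)
  expect_equal(nei_da(f, "A", "B"), 1 - 2 * sqrt(0.09))
  same <- locus_freqs(c("A", "B"), "L1", c(0.4, 0.4), 50)
  expect_equal(nei_da(same, "A", "B"), 0)
  fixed <- locus_freqs(c("A", "A", "B", "B"), c("L1", "L2", "L1", "L2"),
                       c(1, 1, 0, 0), 50)
  expect_equal(nei_da(fixed, "A", "B"), 1)
})

test_that("distance matrices are symmetric, zero-diagonal and bounded", {
  set.seed(61)
  f <- locus_freqs(rep(c("A", "B", "C"), each = 10),
                   rep(sprintf("L%02d", 1:10), 3), runif(30, 0.05, 0.95), 40)
  for (metric in c("FST", "DA")) {
    m <- distance_matrix(f, metric)
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(0, 3))
    expect_true(all(m >= 0 & m <= 1))
  }
})

test_that("F_ST recovers the Balding-Nichols divergence parameter", {
  spec <- panel_spec(superpopulations = list(A = c(A1 = 200), B = c(B1 = 200)),
                     n_loci = 500, fst_between = 0.05, fst_within = 1e-9,
                     ancestral_maf_range = c(0.1, 0.5), seed = 71)
  bn <- balding_nichols_freqs(spec)
  gt <- sample_genotypes(bn$freqs, bn$pop_sizes, bn$pop_map, seed = 72)
  est <- allele_frequencies(gt)
  expect_lt(abs(pairwise_fst(est, "A1", "B1", method = "wc") - 0.05), 0.015)
  # the Nei G_ST variant is downward biased as F/(2-F) under this model
  expect_lt(abs(pairwise_fst(est, "A1", "B1") - 0.05 / 1.95), 0.015)
})

test_that("informativeness matches the brute-force Rosenberg summation", {
  # term-by-term: 2 * (-0.5 log 0.5 + (0.9 log 0.9 + 0.1 log 0.1)/2)
  expect_equal(informativeness_in(c(0.9, 0.1)),
               2 * (-0.5 * log(0.5) + (0.9 * log(0.9) + 0.1 * log(0.1)) / 2))
  expect_equal(informativeness_in(c(0.9, 0.1)), 0.368064, tolerance = 1e-5)
  expect_equal(informativeness_in(c(0.4, 0.4, 0.4)), 0)
  expect_equal(informativeness_in(c(1, 0)), log(2))
  set.seed(81)
  for (rep in 1:50) {
    K <- sample(2:6, 1)
    p <- runif(K)
    expect_equal(informativeness_in(p), in_oracle(p), tolerance = 1e-12)
    expect_gte(informativeness_in(p), -1e-12)
    expect_lte(informativeness_in(p), log(K) + 1e-12)
  }
})

test_that("cumulative informativeness is additive and ranks a planted outlier first", {
  f1 <- locus_freqs(c("A", "B"), "L1", c(0.9, 0.2), 50)
  it1 <- informativeness_table(f1)
  expect_equal(it1$cumulative, it1$per_locus$I_n)
  # duplicating a locus doubles the cumulative value
  f2 <- locus_freqs(c("A", "A", "B", "B"), c("L1", "L2", "L1", "L2"),
                    c(0.9, 0.9, 0.2, 0.2), 50)
  expect_equal(informativeness_table(f2)$cumulative, 2 * it1$cumulative)
  # a strongly diverged group attains the top one-vs-rest cumulative I_n
  set.seed(91)
  base <- runif(20, 0.4, 0.6)
  pops <- c("G1", "G2", "G3", "G4", "G5")
  rows <- lapply(pops, function(g) {
    p <- if (g == "G3") pmin(0.99, base + 0.39) else base + runif(20, -0.03, 0.03)
    locus_freqs(g, sprintf("L%02d", 1:20), p, 50)
  })
  f <- do.call(rbind, rows)
  class(f) <- c("locus_freqs", "data.frame")
  cums <- vapply(pops, function(g)
    informativeness_table(f, focal = g)$cumulative, numeric(1))
  expect_equal(names(which.max(cums)), "G3")
  # pairwise mode: the outlier's pairs dominate its non-outlier pairs
  expect_gt(informativeness_table(f, pair = c("G1", "G3"))$cumulative,
            informativeness_table(f, pair = c("G1", "G2"))$cumulative)
})

test_that("PCA separates orthogonal clusters and cos2 sums to one", {
  x <- rbind(matrix(rnorm(40, sd = 0.01), 20, 2) + cbind(rep(5, 20), 0),
             matrix(rnorm(40, sd = 0.01), 20, 2) + cbind(rep(-5, 20), 0))
  colnames(x) <- c("f1", "f2")
  ord <- pca_ordination(x, standardize = FALSE)
  expect_gt(ord$explained[1], 0.99)
  expect_true(all(diff(ord$explained) <= 1e-12))
  # standardized full-rank case: cos2 of every feature sums to 1
  set.seed(101)
  y <- matrix(rnorm(60), 12, 5)
  colnames(y) <- paste0("v", 1:5)
  ord2 <- pca_ordination(y, standardize = TRUE)
  expect_equal(unname(rowSums(ord2$cos2)), rep(1, 5), tolerance = 1e-8)
  expect_equal(unname(colSums(ord2$contrib)), rep(1, ncol(ord2$contrib)))
  # duplicate entities obtain identical scores
  z <- rbind(y, y[1, ])
  ord3 <- pca_ordination(z, standardize = TRUE)
  expect_equal(unname(ord3$coordinates[13, ]), unname(ord3$coordinates[1, ]))
  # zero-variance feature dropped under standardization
  y0 <- cbind(y, v6 = 1)
  expect_warning(pca_ordination(y0, standardize = TRUE), "zero-variance")
})

test_that("classical MDS reproduces Euclidean configurations", {
  # collinear points at 0, 1, 3
  d <- as.matrix(dist(c(0, 1, 3)))
  fit <- classical_mds(d, k = 2)
  expect_equal(as.matrix(dist(fit$coordinates[, 1])), unname(d),
               tolerance = 1e-9, ignore_attr = TRUE)
  # random planar points: all pairwise distances recovered
  set.seed(111)
  pts <- matrix(rnorm(14), 7, 2)
  d2 <- as.matrix(dist(pts))
  fit2 <- classical_mds(d2, k = 2)
  expect_equal(as.matrix(dist(fit2$coordinates)), unname(d2),
               tolerance = 1e-9, ignore_attr = TRUE)
  # degenerate inputs
  z <- matrix(0, 3, 3)
  expect_warning(fz <- classical_mds(z, k = 2), "component")
  expect_true(all(abs(fz$coordinates) < 1e-12))
  d3 <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(abs(diff(classical_mds(d3, k = 1)$coordinates[, 1])), 2,
               ignore_attr = TRUE)
  expect_error(classical_mds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("neighbor joining recovers additive trees exactly", {
  # additive 4-taxon matrix from ((A:1,B:2):1,(C:3,D:4))
  lab <- c("A", "B", "C", "D")
  d <- matrix(0, 4, 4, dimnames = list(lab, lab))
  d["A", "B"] <- d["B", "A"] <- 3
  d["A", "C"] <- d["C", "A"] <- 5
  d["A", "D"] <- d["D", "A"] <- 6
  d["B", "C"] <- d["C", "B"] <- 6
  d["B", "D"] <- d["D", "B"] <- 7
  d["C", "D"] <- d["D", "C"] <- 7
  tr <- nj_tree(d)
  expect_setequal(tr$tip.label, lab)
  # split AB|CD with exact path lengths
  coph <- ape::cophenetic.phylo(tr)
  expect_equal(coph[lab, lab], d, tolerance = 1e-10)
  # random additive matrices from random trees, up to 8 taxa
  set.seed(121)
  for (rep in 1:10) {
    k <- sample(4:8, 1)
    gen <- ape::rtree(k, br = function(n) runif(n, 0.1, 1))
    dm <- ape::cophenetic.phylo(gen)
    rec <- nj_tree(dm)
    expect_equal(phangorn::RF.dist(ape::unroot(gen), rec), 0)
  }
})

test_that("nj_tree clamps negative branch lengths and ignores label order", {
  set.seed(131)
  # near-degenerate distances often force negative NJ branches
  for (rep in 1:20) {
    n <- 6
    d <- as.matrix(dist(matrix(runif(n), n, 1)))
    dimnames(d) <- list(letters[1:n], letters[1:n])
    tr <- nj_tree(d)
    expect_true(all(tr$edge.length >= 0))
  }
  d <- as.matrix(dist(matrix(rnorm(10), 5, 2)))
  dimnames(d) <- list(LETTERS[1:5], LETTERS[1:5])
  perm <- c(3, 1, 5, 2, 4)
  t1 <- nj_tree(d)
  t2 <- nj_tree(d[perm, perm])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
})

test_that("average-linkage ordering recovers planted clusters", {
  set.seed(141)
  x <- rbind(matrix(rnorm(50, mean = 0, sd = 0.1), 10, 5),
             matrix(rnorm(50, mean = 5, sd = 0.1), 10, 5))
  ord <- hclust_order(x)
  cut <- cutree(ord$row_hclust, k = 2)
  expect_equal(length(unique(cut[1:10])), 1)
  expect_equal(length(unique(cut[11:20])), 1)
  expect_true(cut[1] != cut[11])
  # identical rows merge at height zero
  xx <- rbind(x[1, ], x[1, ], x[15, ])
  hc <- hclust_order(xx)$row_hclust
  expect_equal(hc$height[1], 0)
  # single entity: trivial ordering, no dendrogram
  one <- hclust_order(x[1, , drop = FALSE])
  expect_equal(one$row_order, 1)
  expect_null(one$row_hclust)
})
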