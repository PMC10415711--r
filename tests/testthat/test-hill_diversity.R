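test_that("taxonomic Hill numbers match closed forms", {
  expect_identical(taxonomic_alpha(rep(0.25, 4), 0), 4L)
  expect_equal(taxonomic_alpha(c(0.5, 0.5), 2), 2)
  expect_equal(taxonomic_alpha(c(0.8, 0.2), 1),
               exp(-(0.8 * log(0.8) + 0.2 * log(0.2))))
  expect_equal(taxonomic_alpha(c(0.8, 0.2), 1), 1.6493849, tolerance = 1e-6)
  expect_error(taxonomic_alpha(c(0, 0), 1), "empty")
  expect_error(taxonomic_alpha(c(0.5, 0.5), -1), "order")
})

test_that("Hill numbers are monotone in q, continuous at q = 1, and replicate", {
  withr::with_seed(1, {
    for (r in 1:200) {
      p <- rgamma(sample(3:20, 1), 0.7)
      p <- p / sum(p)
      qs <- c(0, 0.5, 1 - 1e-5, 1, 1 + 1e-5, 2, 3)
      d <- vapply(qs, function(q) taxonomic_alpha(p, q), numeric(1))
      expect_true(all(diff(d) <= 1e-9))           # non-increasing in q
      expect_lt(abs(d[3] - d[5]), 1e-3)           # continuity across q = 1
      expect_lt(abs(d[3] - d[4]), 1e-3)
      expect_gte(d[length(d)], 1)
    }
    # replication principle: pooling two disjoint copies doubles diversity
    for (q in c(0, 1, 2)) {
      p <- rgamma(8, 1); p <- p / sum(p)
      pooled <- c(p, p) / 2
      expect_equal(taxonomic_alpha(pooled, q), 2 * taxonomic_alpha(p, q),
                   tolerance = 1e-12)
    }
  })
})

test_that("total effective phylogenetic distance matches closed forms", {
  d2 <- matrix(c(0, 1, 1, 0), 2)
  for (q in c(0, 0.5, 1, 2, 3))
    expect_equal(phylo_alpha(c(0.5, 0.5), d2, q), 2, tolerance = 1e-6)
  d4 <- matrix(0.3, 4, 4); diag(d4) <- 0
  for (q in c(0, 1, 2))
    expect_equal(phylo_alpha(rep(0.25, 4), d4, q), 0.3 * 4 * 3, tolerance = 1e-6)
  expect_equal(phylo_alpha(c(1, 0), d2, 1), 0)   # single ASV: Q = 0 convention
})

test_that("phylogenetic alpha equals the naive double-sum oracle", {
  withr::with_seed(2, {
    for (r in 1:100) {
      S <- sample(2:10, 1)
      p <- rgamma(S, 1)
      if (r %% 4 == 0) p[sample(S, 1)] <- 0
      if (all(p == 0)) p[1] <- 1
      d <- as.matrix(dist(matrix(runif(S * 2), S)))
      q <- sample(c(0, 0.5, 1, 2), 1)
      expect_equal(phylo_alpha(p / sum(p), d, q), oracle_qpd(p, d, q),
                   tolerance = 1e-9)
    }
  })
})

test_that("dissimilarities hit the 0 and 1 endpoints for identical and disjoint pairs", {
  withr::with_seed(3, {
    p <- rgamma(8, 1); p <- p / sum(p)
    d <- as.matrix(dist(matrix(runif(16), 8)))
    pa <- c(p[1:4], rep(0, 4)); pb <- c(rep(0, 4), p[5:8])
    for (q in c(0, 1, 2)) {
      expect_equal(taxonomic_dissimilarity(p, p, q), 0, tolerance = 1e-12)
      expect_equal(phylo_dissimilarity(p, p, d, q), 0, tolerance = 1e-12)
      expect_equal(taxonomic_dissimilarity(pa, pb, q), 1, tolerance = 1e-12)
      expect_equal(phylo_dissimilarity(pa, pb, d, q), 1, tolerance = 1e-12)
    }
  })
  # two single-ASV samples at distance 1 share nothing
  expect_equal(phylo_dissimilarity(c(1, 0), c(0, 1), matrix(c(0, 1, 1, 0), 2), 0), 1)
  # identical single-ASV samples: pooled Q = 0, dissimilarity defined as 0
  expect_equal(phylo_dissimilarity(c(1, 0), c(1, 0), matrix(c(0, 1, 1, 0), 2), 2), 0)
})

test_that("taxonomic dissimilarity matches hand and set-arithmetic oracles", {
  expect_equal(taxonomic_dissimilarity(c(1, 1, 0), c(0, 1, 1), 0), 0.5)
  # q = 0 local overlap equals Sorensen dissimilarity on binary data
  withr::with_seed(4, {
    for (r in 1:50) {
      a <- rbinom(10, 1, 0.5); b <- rbinom(10, 1, 0.5)
      if (sum(a) == 0) a[1] <- 1
      if (sum(b) == 0) b[2] <- 1
      sorensen <- 1 - 2 * sum(a & b) / (sum(a) + sum(b))
      expect_equal(taxonomic_dissimilarity(a, b, 0), sorensen, tolerance = 1e-12)
      # and against the literal formula evaluation at several orders
      pr <- random_pair(8)
      for (q in c(0, 1, 2))
        expect_equal(taxonomic_dissimilarity(pr$a, pr$b, q),
                     oracle_tax_dissim(pr$a, pr$b, q), tolerance = 1e-12)
    }
  })
})

test_that("phylogenetic dissimilarity equals the literal-formula oracle", {
  withr::with_seed(5, {
    for (r in 1:50) {
      S <- sample(3:9, 1)
      pr <- random_pair(S)
      d <- as.matrix(dist(matrix(runif(S * 2), S)))
      for (q in c(0, 0.5, 1, 2))
        expect_equal(phylo_dissimilarity(pr$a, pr$b, d, q),
                     oracle_phylo_dissim(pr$a, pr$b, d, q), tolerance = 1e-12)
    }
  })
})

test_that("equidistant taxa tie the functional index to the taxonomic endpoints", {
  # With all between-ASV distances equal the functional dissimilarity keeps
  # the 0/1 endpoints of the taxonomic index and orders pairs the same way,
  # but the two indices differ in between (the functional measure works on
  # effective ASV pairs, whose zero within-ASV distance breaks the collapse).
  d <- matrix(1, 6, 6); diag(d) <- 0
  withr::with_seed(6, {
    vals <- t(sapply(1:30, function(r) {
      pr <- random_pair(6, zero_frac = 0.5)
      c(taxonomic_dissimilarity(pr$a, pr$b, 0),
        phylo_dissimilarity(pr$a, pr$b, d, 0))
    }))
    expect_true(all(vals >= 0 & vals <= 1))
    expect_gt(cor(vals[, 1], vals[, 2], method = "spearman"), 0.9)
  })
})

test_that("pairwise dissimilarity tables are complete, symmetric and consistent", {
  tab <- random_table(n_asv = 10, n_sample = 5, seed = 7)
  dd <- dissimilarity_matrix(tab, q = c(0, 1, 2), kind = "taxonomic")
  expect_equal(nrow(dd), 3 * choose(5, 2))
  expect_true(all(dd$value >= 0 & dd$value <= 1))

  p <- relative_abundances(tab)
  for (i in sample(nrow(dd), 10))
    expect_equal(dd$value[i],
                 taxonomic_dissimilarity(p[, dd$sample_a[i]], p[, dd$sample_b[i]],
                                         dd$q[i]), tolerance = 1e-12)

  # permuting sample order leaves pair values unchanged
  tab2 <- community_table(unclass(tab)[, c(3, 1, 5, 2, 4)])
  dd2 <- dissimilarity_matrix(tab2, q = 1, kind = "taxonomic")
  m1 <- as_dissimilarity_matrix(dd[dd$q == 1, ])
  m2 <- as_dissimilarity_matrix(dd2)
  expect_equal(m1[rownames(m2), colnames(m2)], m2, tolerance = 1e-12)

  expect_error(dissimilarity_matrix(tab, q = 1, kind = "phylogenetic"),
               "distance")
})

test_that("alpha tables report qTD and qPD per sample and order", {
  tab <- random_table(n_asv = 8, n_sample = 3, seed = 8)
  tree <- simulate_tree(8, seed = 1)
  d <- patristic_distances(tree, rownames(tab))
  at <- alpha_table(tab, q = c(0, 1, 2), distances = d)
  expect_equal(nrow(at), 9)
  expect_true(all(c("qTD", "qPD") %in% names(at)))
  p <- relative_abundances(tab)
  expect_equal(at$qTD[at$sample_id == "s1" & at$q == 0],
               sum(p[, "s1"] > 0))
})
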