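layers4 <- c("pancreas", "salivary gland", "mammary gland", "skin")

test_that("specialist fraction reproduces the printed worked examples", {
  # 5 genes present only in the pancreas layer
  c1 <- ml_community(sprintf("g%d", 1:5), rep("pancreas", 5))
  sf1 <- specialist_fraction(c1)
  expect_equal(round(sf1$fraction, 3), 1.000)
  expect_identical(sf1$tissue, "pancreas")

  # 76 pancreas-only genes + 10 genes in two other layers (96 nodes)
  c2 <- ml_community(
    c(sprintf("p%02d", 1:76), rep(sprintf("d%02d", 1:10), times = 2)),
    c(rep("pancreas", 76), rep(c("mammary gland", "skin"), each = 10)))
  sf2 <- specialist_fraction(c2)
  expect_identical(sf2$n_nodes, 96L)
  expect_equal(round(sf2$fraction, 3), 0.792)
  expect_identical(sf2$tissue, "pancreas")

  # 82 salivary-only + 1 pancreas-only + 3 genes in two layers (89 nodes)
  c3 <- ml_community(
    c(sprintf("s%02d", 1:82), "p1", rep(sprintf("d%d", 1:3), times = 2)),
    c(rep("salivary gland", 82), "pancreas",
      rep(c("mammary gland", "skin"), each = 3)))
  sf3 <- specialist_fraction(c3)
  expect_identical(sf3$n_nodes, 89L)
  expect_equal(round(sf3$fraction, 3), 0.921)
  expect_identical(sf3$tissue, "salivary gland")
})

test_that("specialist fraction is 1 iff the community lies in one layer, 0 if none unique", {
  one_layer <- ml_community(sprintf("g%d", 1:7), rep("skin", 7))
  expect_equal(specialist_fraction(one_layer)$fraction, 1)
  shared <- ml_community(rep(sprintf("g%d", 1:4), 2),
                         rep(c("skin", "pancreas"), each = 4))
  sf <- specialist_fraction(shared)
  expect_equal(sf$fraction, 0)
  expect_true(is.na(sf$tissue))
  # ties: two layers with equal unique counts -> lexicographically first
  tied <- ml_community(c("a", "b"), c("skin", "pancreas"))
  sft <- specialist_fraction(tied)
  expect_identical(sft$tissue, "pancreas")
  expect_identical(sft$tied, c("pancreas", "skin"))
})

test_that("classification uses a strict threshold", {
  expect_identical(classify_community(0.792), "specialist")
  expect_identical(classify_community(0.160), "generalist")
  expect_identical(classify_community(0.5), "generalist")
})

test_that("community gene sets apply the layer-presence filter to generalists", {
  comm <- ml_community(
    c("a", "a", "a", "b", "c", "c", "c", "c"),
    c("l1", "l2", "l3", "l1", "l1", "l2", "l3", "l4"))
  expect_identical(community_gene_set(comm, "generalist", 3), c("a", "c"))
  expect_identical(community_gene_set(comm, "specialist"), c("a", "b", "c"))
})

test_that("gene distances follow the gap definition", {
  loci <- gene_loci(c("a", "b", "c", "d"),
                    c("1", "1", "2", "1"),
                    c(100, 500, 50, 90),
                    c(200, 600, 80, 220))
  expect_equal(gene_distance(loci[1, ], loci[2, ]), 300)
  expect_equal(gene_distance(loci[2, ], loci[1, ]), 300)     # symmetric
  expect_true(is.na(gene_distance(loci[1, ], loci[3, ])))
  expect_equal(gene_distance(loci[1, ], loci[4, ]), 0)       # overlap
  adj <- gene_loci(c("x", "y"), c("3", "3"), c(1, 101), c(100, 150))
  expect_equal(gene_distance(adj[1, ], adj[2, ]), 1)
})

test_that("same-chromosome fraction enumerates pairs correctly", {
  loci <- gene_loci(sprintf("g%d", 1:4), c("1", "1", "2", "2"),
                    rep(1, 4), rep(10, 4))
  expect_equal(same_chromosome_fraction(sprintf("g%d", 1:4), loci), 1 / 3)
  expect_equal(same_chromosome_fraction(c("g1", "g2"), loci), 1)
  loci2 <- gene_loci(sprintf("g%d", 1:3), c("1", "2", "3"), rep(1, 3),
                     rep(10, 3))
  expect_equal(same_chromosome_fraction(sprintf("g%d", 1:3), loci2), 0)
  expect_error(same_chromosome_fraction("g1", loci), "two genes")
})

test_that("x_c and d_c match brute-force pair enumeration on small groups", {
  set.seed(19)
  bg <- planted_gene_loci(sprintf("g%02d", 1:40), seed = 19, n_chrom = 4)
  genes <- sample(bg$gene_id, 8)
  sub <- bg[match(genes, bg$gene_id), ]
  # brute force over all 28 pairs
  same <- 0; dsum <- 0; dn <- 0
  for (i in 1:7) for (j in (i + 1):8) {
    d <- gene_distance(sub[i, ], sub[j, ])
    if (!is.na(d)) {
      same <- same + 1
      dsum <- dsum + d
      dn <- dn + 1
    }
  }
  expect_equal(same_chromosome_fraction(genes, bg), same / 28)
  loc <- localization_tests(genes, bg, n_rand = 10, seed = 1)
  expect_equal(loc$x_c, same / 28)
  expect_equal(loc$d_c, if (dn) dsum / dn else NA_real_)
})

test_that("localization tests are seeded with lattice-valued empirical p", {
  bg <- planted_gene_loci(sprintf("g%02d", 1:60), seed = 4, n_chrom = 6)
  genes <- bg$gene_id[1:10]
  r1 <- localization_tests(genes, bg, n_rand = 50, seed = 8)
  r2 <- localization_tests(genes, bg, n_rand = 50, seed = 8)
  expect_identical(r1, r2)
  if (nrow(r1$per_chromosome))
    expect_true(all(abs(r1$per_chromosome$p_empirical * 50 -
                          round(r1$per_chromosome$p_empirical * 50)) < 1e-9))
})

test_that("a planted tight cluster is detected and Bonferroni-flagged", {
  genes <- sprintf("g%03d", 1:80)
  bg <- planted_gene_loci(genes, seed = 33, n_chrom = 8,
                          clustered = list("2" = genes[1:5]))
  loc <- localization_tests(genes[1:5], bg, n_rand = 100, seed = 12)
  expect_lte(loc$z_d, -2)
  flagged <- loc$per_chromosome$chromosome[loc$per_chromosome$significant]
  expect_true("2" %in% flagged)
})

test_that("degenerate randomizations are flagged, not errors", {
  # group = entire background on one chromosome: every draw is identical
  bg <- gene_loci(sprintf("g%d", 1:5), rep("1", 5),
                  c(1, 1000, 4000, 9000, 20000),
                  c(500, 1500, 4500, 9500, 20500))
  loc <- localization_tests(bg$gene_id, bg, n_rand = 20, seed = 3)
  expect_true(is.na(loc$z_d))
  expect_true(loc$degenerate[["d"]])
})

test_that("shared eQTL pairs require both co-expression and variant overlap", {
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- 0.6
  R[1, 3] <- R[3, 1] <- 0.4
  dimnames(R) <- list(c("gA", "gB", "gC"), c("gA", "gB", "gC"))
  eqtl <- data.frame(gene_id = c("gA", "gA", "gB", "gC"),
                     variant_id = c("v1", "v2", "v1", "v2"))
  hits <- shared_eqtl_pairs(R, eqtl, r_min = 0.5)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$gene_i, "gA")
  expect_identical(hits$shared_variants, "v1")
  # r = 0.4 pair shares v2 but fails the threshold
  expect_identical(nrow(shared_eqtl_pairs(R, eqtl, r_min = 0.65)), 0L)
  # disjoint variant sets are never reported
  eqtl2 <- data.frame(gene_id = c("gA", "gB"), variant_id = c("v1", "v9"))
  expect_identical(nrow(shared_eqtl_pairs(R, eqtl2)), 0L)
})
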