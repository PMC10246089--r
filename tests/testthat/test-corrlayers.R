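test_that("log transform maps TPM to the natural log scale with 0 -> 0", {
  expect_identical(log_transform(matrix(0)), matrix(0))
  expect_equal(log_transform(matrix(exp(1) - 1)), matrix(1))
  expect_equal(as.vector(log_transform(matrix(c(0, 1, 3), 1))),
               c(0, log(2), log(4)), tolerance = 1e-12)
  expect_error(log_transform(matrix(-0.5)), "negative")
})

test_that("layer correlation matches the two-pass definition and its edge cases", {
  set.seed(3)
  tpm <- matrix(rexp(30, 0.2), 5, 6,
                dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:6)))
  ly <- expression_layer("t", tpm, donor_ids = sprintf("d%d", 1:6))
  R <- layer_correlation(ly)
  expect_equal(R, naive_log_correlation(tpm), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_lt(max(abs(R - t(R))), 1e-12)
  expect_identical(diag(R), setNames(rep(1, 5), rownames(tpm)))
  expect_true(all(abs(R) <= 1 + 1e-12))

  # affinely related log rows give r = 1; anti-monotone rows keep r < 0
  tpm2 <- rbind(g1 = c(0, 1, 3), g2 = c(1, 3, 7), g3 = c(9, 3, 0))
  colnames(tpm2) <- sprintf("s%d", 1:3)
  ly2 <- expression_layer("t", tpm2, donor_ids = sprintf("d%d", 1:3))
  R2 <- layer_correlation(ly2)
  expect_equal(R2["g1", "g2"], 1, tolerance = 1e-12)
  expect_lt(R2["g1", "g3"], 0)
})

test_that("zero-variance genes error in library mode and drop in pipeline mode", {
  tpm <- rbind(gA = c(2, 2, 2, 2), gB = c(1, 4, 2, 9))
  colnames(tpm) <- sprintf("s%d", 1:4)
  ly <- expression_layer("t", tpm, donor_ids = sprintf("d%d", 1:4))
  expect_error(layer_correlation(ly), "gA")
  expect_warning(R <- layer_correlation(ly, drop_zero_variance = TRUE), "gA")
  expect_identical(rownames(R), "gB")
})

test_that("top-variance selection sorts by raw TPM variance with lexicographic ties", {
  tpm <- rbind(a = c(0, 5, 0, 5), b = c(1, 2, 1, 2), c = c(0, 9, 0, 9))
  colnames(tpm) <- sprintf("s%d", 1:4)
  ly <- expression_layer("t1", tpm, donor_ids = sprintf("d%d", 1:4))
  sel <- select_top_variance_genes(list(ly), 2)
  expect_identical(sel$per_layer$t1, c("c", "a"))   # variances 9>5>1 scaled
  expect_identical(select_top_variance_genes(list(ly), 3)$union,
                   c("a", "b", "c"))
  # tie at rank k: identical rows 'a' and 'z' -> lexicographically first kept
  tpm2 <- rbind(z = c(0, 5, 0, 5), a = c(0, 5, 0, 5), m = c(1, 2, 1, 2))
  colnames(tpm2) <- sprintf("s%d", 1:4)
  ly2 <- expression_layer("t2", tpm2, donor_ids = sprintf("d%d", 1:4))
  expect_identical(select_top_variance_genes(list(ly2), 1)$per_layer$t2, "a")
  # two layers with disjoint top-k union to size 2k
  sel2 <- select_top_variance_genes(list(ly, ly2), 1)
  expect_identical(sel2$union, c("a", "c"))
})

test_that("rank diagnostics compute Jaccard and average expression rank", {
  tpm <- rbind(a = rep(10, 3), b = rep(5, 3), c = rep(2, 3), d = rep(1, 3))
  colnames(tpm) <- sprintf("s%d", 1:3)
  ly <- expression_layer("t", tpm, donor_ids = sprintf("d%d", 1:3))
  expect_equal(expression_rank_stats(ly, c("a", "b"), 2)$jaccard, 1)
  expect_equal(expression_rank_stats(ly, c("c", "d"), 2)$jaccard, 0)
  # |A intersect B| = 2, |A union B| = 4
  expect_equal(expression_rank_stats(ly, c("a", "b", "c", "d"), 2)$jaccard, 0.5)
  expect_equal(expression_rank_stats(ly, c("a", "c"), 2)$average_rank, 2)
  expect_error(expression_rank_stats(ly, character(0), 2), "empty")
})

test_that("interlayer couplings correlate by donor, clamp negatives, and ignore sample order", {
  set.seed(41)
  gids <- c("g1", "g2")
  donors <- sprintf("D%d", 1:10)
  y <- matrix(rnorm(20, 4), 2, 10)
  l1 <- expression_layer("A", pmax(exp(y) - 1, 0), gids,
                         sprintf("A%02d", 1:10), donors)
  # same donors, g1 identical, g2 sign-flipped around the mean (anti-correlated)
  y2 <- y
  y2[2, ] <- 2 * mean(y[2, ]) - y[2, ]
  l2 <- expression_layer("B", pmax(exp(y2) - 1, 0), gids,
                         sprintf("B%02d", 1:10), donors)
  om <- interlayer_couplings(list(l1, l2))
  expect_equal(om$omega["g1", "A", "B"], 1, tolerance = 1e-8)
  expect_equal(om$omega["g2", "A", "B"], 0)   # clamped
  expect_gt(om$n_clamped, 0)
  expect_identical(om$omega[, "A", "A"], setNames(c(0, 0), gids))

  # permuting one layer's sample columns leaves omega unchanged (donor matching)
  perm <- sample(10)
  l2p <- expression_layer("B", l2$values[, perm], gids,
                          l2$sample_ids[perm], l2$donor_ids[perm])
  expect_equal(interlayer_couplings(list(l1, l2p))$omega, om$omega)

  l3 <- expression_layer("C", l1$values[, 1:3, drop = FALSE], gids,
                         sprintf("C%02d", 1:3), c("X1", "X2", "X3"))
  expect_error(interlayer_couplings(list(l1, l3)), "A and C")
})

test_that("multilayer assembly enforces the correlation and coupling invariants", {
  R <- diag(2)
  R[1, 2] <- R[2, 1] <- 0.4
  dimnames(R) <- list(c("g1", "g2"), c("g1", "g2"))
  om <- array(0, c(2, 2, 2))
  om[, 1, 2] <- om[, 2, 1] <- c(0.5, 0.2)
  mlc <- assemble_multilayer(list(a = R, b = R), om, c(10, 12))
  expect_s3_class(mlc, "multilayer_correlation")
  bad <- R
  diag(bad) <- 0.99
  expect_error(assemble_multilayer(list(a = bad, b = R), om, c(10, 12)),
               "diagonal")
  om_bad <- om
  om_bad[1, 1, 2] <- -0.1
  expect_error(assemble_multilayer(list(a = R, b = R), om_bad, c(10, 12)),
               "omega")
})
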