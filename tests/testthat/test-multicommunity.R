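# small helper: assemble a random 2-layer multilayer correlation object
random_mlc <- function(n_genes = 4, seed = 1, n_obs = 60) {
  set.seed(seed)
  gids <- sprintf("g%02d", seq_len(n_genes))
  mk <- function() {
    R <- random_correlation(n_genes, n_obs = n_obs)
    dimnames(R) <- list(gids, gids)
    R
  }
  om <- array(stats::runif(n_genes * 4, 0, 0.4), c(n_genes, 2, 2))
  om[, 1, 1] <- om[, 2, 2] <- 0
  om[, 2, 1] <- om[, 1, 2]
  assemble_multilayer(list(a = mk(), b = mk()), om, c(n_obs, n_obs))
}

test_that("supra-modularity matrix matches its definition entry by entry", {
  # two genes, two layers, hand-checkable entries
  R1 <- matrix(c(1, 0.8, 0.8, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  R2 <- matrix(c(1, -0.2, -0.2, 1), 2, dimnames = dimnames(R1))
  om <- array(0, c(2, 2, 2))
  om[, 1, 2] <- om[, 2, 1] <- c(0.6, 0.1)
  mlc <- assemble_multilayer(list(a = R1, b = R2), om, c(9, 9))
  n1 <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = dimnames(R1))
  n2 <- matrix(c(1, 0.0, 0.0, 1), 2, dimnames = dimnames(R1))
  g <- 2
  sup <- build_supra_modularity(mlc, list(n1, n2), gamma = g)
  expected <- rbind(
    c(1 - g,        0.8 - g * 0.5, 0.6, 0),
    c(0.8 - g * 0.5, 1 - g,        0,   0.1),
    c(0.6, 0,        1 - g,        -0.2),
    c(0,   0.1,      -0.2,         1 - g))
  expect_equal(sup$B, expected, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(sup$c_norm, sum(R1) + sum(R2) + sum(om))

  # gamma = 1 with null = input: intralayer off-diagonals vanish
  sup1 <- build_supra_modularity(mlc, list(R1, R2), gamma = 1)
  expect_equal(sup1$B[1, 2], 0)
  expect_equal(sup1$B[3, 4], 0)
})

test_that("modularity equals the brute-force pair sum over co-assigned nodes", {
  mlc <- random_mlc(4, seed = 2)
  nulls <- lapply(mlc$rho, fit_configuration_model)
  sup <- build_supra_modularity(mlc, nulls, gamma = 1.5)
  n <- nrow(sup$B)
  expect_equal(modularity_score(rep(1, n), sup), sum(sup$B) / sup$c_norm)
  expect_equal(modularity_score(seq_len(n), sup),
               sum(diag(sup$B)) / sup$c_norm)
  set.seed(4)
  for (rep in 1:5) {
    part <- sample(1:3, n, replace = TRUE)
    q <- 0
    for (i in 1:n) for (j in 1:n)
      if (part[i] == part[j]) q <- q + sup$B[i, j]
    expect_equal(modularity_score(part, sup), q / sup$c_norm,
                 tolerance = 1e-12)
  }
  expect_error(modularity_score(rep(1, n - 1), sup), "every node")
})

test_that("network-variant modularity reduces to Newman-Girvan (igraph oracle)", {
  skip_if_not_installed("igraph")
  set.seed(8)
  n <- 12
  A <- matrix(rbinom(n * n, 1, 0.3), n, n)
  A <- 1 * ((A + t(A)) > 0)
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  sup <- build_supra_modularity_network(list(l1 = A), gamma = 1)
  for (rep in 1:5) {
    part <- sample(1:3, n, replace = TRUE)
    expect_equal(modularity_score(part, sup),
                 igraph::modularity(g, part), tolerance = 1e-12)
  }
  # zero couplings leave the supra matrix block diagonal
  sup2 <- build_supra_modularity_network(list(l1 = A, l2 = A), gamma = 1)
  expect_equal(sup2$B[1:n, n + 1:n], matrix(0, n, n))
})

test_that("Louvain recovers planted blocks, respects signs, and is seeded", {
  B <- matrix(-0.1, 10, 10)
  B[1:5, 1:5] <- 0.5
  B[6:10, 6:10] <- 0.5
  diag(B) <- 0
  p <- genlouvain(B, seed = 7)
  expect_identical(unname(canonical_labels(p)), rep(1:2, each = 5))
  expect_identical(genlouvain(B, seed = 7), genlouvain(B, seed = 7))

  # all-negative off-diagonals: no merge ever gains
  Bneg <- -matrix(1, 4, 4) + diag(2, 4)
  expect_identical(unname(genlouvain(Bneg, seed = 1)), 1:4)
})

test_that("Louvain never beats exhaustive enumeration and usually matches it", {
  matched <- 0
  for (seed in 1:10) {
    set.seed(seed)
    B <- matrix(rnorm(36, sd = 0.5), 6, 6)
    B <- (B + t(B)) / 2
    bf <- brute_force_max_modularity(B)
    p <- iterated_genlouvain(B, seed = seed)
    q <- sum(vapply(split(seq_len(6), p), function(i) sum(B[i, i]), 0))
    expect_lte(q, bf$Q + 1e-10)
    if (abs(q - bf$Q) < 1e-10) matched <- matched + 1
  }
  expect_gte(matched, 5)
})

test_that("merge gain identity: Q(merge) - Q = 2 * between-sum / C_norm", {
  mlc <- random_mlc(4, seed = 6)
  nulls <- lapply(mlc$rho, fit_configuration_model)
  sup <- build_supra_modularity(mlc, nulls, gamma = 1)
  part <- c(1, 1, 2, 2, 3, 3, 4, 4)
  merged <- ifelse(part == 2, 1, part)
  between <- sum(sup$B[part == 1, part == 2])
  expect_equal(modularity_score(merged, sup) - modularity_score(part, sup),
               2 * between / sup$c_norm, tolerance = 1e-12)
})

test_that("intralayer diagonal entries never change the argmax", {
  for (seed in 1:5) {
    set.seed(seed)
    B <- matrix(rnorm(36, sd = 0.5), 6, 6)
    B <- (B + t(B)) / 2
    B0 <- B
    diag(B0) <- 0
    expect_identical(brute_force_max_modularity(B)$partition,
                     brute_force_max_modularity(B0)$partition)
  }
})

test_that("iterated Louvain is monotone in Q and idempotent at a fixed point", {
  mlc <- random_mlc(5, seed = 12)
  nulls <- lapply(mlc$rho, fit_configuration_model)
  sup <- build_supra_modularity(mlc, nulls, gamma = 2)
  set.seed(3)
  p0 <- genlouvain(sup)
  p1 <- genlouvain(sup, init = p0)
  expect_gte(modularity_score(p1, sup), modularity_score(p0, sup) - 1e-12)
  pfix <- iterated_genlouvain(sup, seed = 5)
  p2 <- genlouvain(sup, seed = 6, init = pfix)
  expect_gte(modularity_score(p2, sup), modularity_score(pfix, sup) - 1e-12)
})

test_that("consensus reproduces unanimous, majority, and relabeled partitions", {
  P <- rep(1:2, each = 5)
  expect_identical(unname(consensus_partition(rep(list(P), 5), seed = 1)), P)
  other <- rep(1:5, each = 2)
  expect_identical(
    unname(consensus_partition(c(rep(list(P), 19), list(other)), seed = 2)),
    P)
  relabeled <- c(rep(2, 5), rep(1, 5))
  expect_identical(
    unname(consensus_partition(list(P, relabeled, P), seed = 3)), P)
  expect_error(consensus_partition(list(P)), "two partitions")
})

test_that("brute force handles trivial two-node cases and refuses large inputs", {
  Bpos <- matrix(c(0, 1, 1, 0), 2)
  expect_identical(brute_force_max_modularity(Bpos)$partition, c(1L, 1L))
  Bneg <- matrix(c(0, -1, -1, 0), 2)
  expect_identical(brute_force_max_modularity(Bneg)$partition, c(1L, 2L))
  expect_error(brute_force_max_modularity(diag(11)), "10 nodes")
})
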