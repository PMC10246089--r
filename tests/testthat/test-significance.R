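two_layer_nulls <- function(n_genes = 15, seed = 51, n_obs = 100) {
  set.seed(seed)
  gids <- sprintf("g%02d", seq_len(n_genes))
  mk <- function() {
    R <- random_correlation(n_genes, n_obs = n_obs)
    dimnames(R) <- list(gids, gids)
    R
  }
  rho <- list(a = mk(), b = mk())
  list(rho = rho, gids = gids,
       nulls = lapply(rho, fit_configuration_model))
}

test_that("community weight sums intralayer pairs only, excluding the diagonal", {
  R1 <- matrix(c(1, 0.4, 0.4, 1), 2, dimnames = list(c("x", "y"), c("x", "y")))
  R2 <- matrix(c(1, -0.3, -0.3, 1), 2, dimnames = dimnames(R1))
  om <- array(0.9, c(2, 2, 2))
  om[, 1, 1] <- om[, 2, 2] <- 0
  mlc <- assemble_multilayer(list(a = R1, b = R2), om, c(9, 9))
  expect_equal(community_weight(ml_community("x", "a"), mlc), 0)
  expect_equal(community_weight(ml_community(c("x", "y"), c("a", "a")), mlc),
               0.4)
  # spanning both layers: the two within-layer pair sums; omega never counts
  expect_equal(community_weight(
    ml_community(c("x", "y", "x", "y"), c("a", "a", "b", "b")), mlc),
    0.4 - 0.3)
})

test_that("closed-form null moments match the hand expansion for one pair", {
  C <- matrix(c(1, 0.35, 0.35, 1), 2,
              dimnames = list(c("x", "y"), c("x", "y")))
  nulls <- list(a = C)
  comm <- ml_community(c("x", "y"), c("a", "a"))
  mom <- null_moments(comm, nulls, c(a = 50))
  expect_equal(mom$mu, 0.35)
  expect_equal(mom$var, (1 + 0.35^2) / 50, tolerance = 1e-12)
  # variance scales exactly as 1/L
  mom2 <- null_moments(comm, nulls, c(a = 100))
  expect_equal(mom$var / mom2$var, 2, tolerance = 1e-14)
  # single node: empty sums
  mom0 <- null_moments(ml_community("x", "a"), nulls, c(a = 50))
  expect_equal(c(mom0$mu, mom0$var), c(0, 0))
  expect_error(null_moments(ml_community("x", "q"), nulls, 50), "missing null")
})

test_that("vectorized variance equals the quadruple-loop oracle and is non-negative", {
  fx <- two_layer_nulls()
  set.seed(7)
  for (rep in 1:6) {
    k1 <- sample(2:6, 1)
    k2 <- sample(0:4, 1)
    g1 <- sample(fx$gids, k1)
    g2 <- if (k2 > 0) sample(fx$gids, k2) else character(0)
    comm <- ml_community(c(g1, g2), c(rep("a", k1), rep("b", k2)))
    n_obs <- c(a = 80, b = 120)
    mom <- null_moments(comm, fx$nulls, n_obs)
    naive <- naive_weight_variance(
      list(fx$nulls$a$null_rho, fx$nulls$b$null_rho),
      list(match(g1, fx$gids), match(g2, fx$gids)),
      list(80, 120))
    expect_equal(mom$var, naive, tolerance = 1e-12)
    expect_gte(mom$var, 0)
  }
})

test_that("variance times L is constant across observation counts", {
  fx <- two_layer_nulls(10, seed = 3)
  comm <- ml_community(fx$gids[c(1, 3, 5, 7)], rep("a", 4))
  vls <- vapply(c(50, 100, 200), function(L)
    null_moments(comm, fx$nulls, c(a = L, b = L))$var * L, 0)
  expect_equal(vls[1], vls[2], tolerance = 1e-14)
  expect_equal(vls[2], vls[3], tolerance = 1e-14)
})

test_that("Z scores handle the degenerate zero-variance case as undefined", {
  expect_equal(z_score(5, 5, 2), 0)
  expect_equal(z_score(5 + 2 * sqrt(2), 5, 2), 2)
  expect_true(is.na(z_score(1, 0, 0)))
  expect_error(z_score(1, 0, -1), "non-negative")
})

test_that("Monte-Carlo moments agree with the closed form", {
  fx <- two_layer_nulls(10, seed = 13)
  comm <- ml_community(fx$gids[c(1, 2, 4, 6, 9)],
                       c("a", "a", "a", "b", "b"))
  n_obs <- c(a = 150, b = 150)
  mom <- null_moments(comm, fx$nulls, n_obs)
  mc <- mc_weight_moments(comm, fx$nulls, n_obs, n_rep = 4000, seed = 17)
  se_mu <- sqrt(mc$var_hat / mc$n_rep)
  expect_lt(abs(mc$mu_hat - mom$mu), 4 * se_mu)
  expect_lt(abs(mc$var_hat - mom$var) / mom$var, 0.15)
  mc2 <- mc_weight_moments(comm, fx$nulls, n_obs, n_rep = 50, seed = 17)
  mc3 <- mc_weight_moments(comm, fx$nulls, n_obs, n_rep = 50, seed = 17)
  expect_identical(mc2, mc3)
})

test_that("significance table flags trivial communities and orders by label", {
  fx <- two_layer_nulls(4, seed = 23)
  om <- array(0, c(4, 2, 2))
  mlc <- assemble_multilayer(fx$rho, om, c(100, 100))
  n <- 8
  tab <- significance_table(seq_len(n), mlc, fx$nulls)
  expect_identical(tab$community, 1:n)
  expect_true(all(is.na(tab$z)))
  expect_true(all(tab$trivial))
  # a real community gets a finite Z
  part <- c(1, 1, 1, 2, 3, 4, 5, 6)
  tab2 <- significance_table(part, mlc, fx$nulls)
  expect_false(tab2$trivial[1])
  expect_true(is.finite(tab2$z[1]))
})
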