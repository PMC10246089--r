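# shared fixtures and independent oracles, all built in code at test time

# sample correlation matrix of Gaussian data: always a valid, PD correlation
random_correlation <- function(n, n_obs = 20 * n, seed = NULL,
                               base = 0.3) {
  if (!is.null(seed)) set.seed(seed)
  Sig <- base * diag(n) + (1 - base) / n *
    tcrossprod(matrix(rnorm(n * 2), n, 2)) + diag(n) * 0.5
  X <- matrix(rnorm(n_obs * n), n_obs, n) %*% chol(cov2cor(Sig))
  R <- cor(X)
  dimnames(R) <- list(sprintf("g%02d", 1:n), sprintf("g%02d", 1:n))
  R
}

# naive two-pass Pearson correlation of log(TPM+1) rows (definition oracle)
naive_log_correlation <- function(tpm) {
  x <- log(tpm + 1)
  n <- nrow(x)
  m <- rowMeans(x)
  R <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    num <- sum((x[i, ] - m[i]) * (x[j, ] - m[j]))
    den <- sqrt(sum((x[i, ] - m[i])^2) * sum((x[j, ] - m[j])^2))
    R[i, j] <- num / den
  }
  R
}

# independent constrained log-det maximizer: parametrize the off-diagonal
# entries, eliminate the row-sum constraints through a null-space basis, and
# run a generic quasi-Newton optimizer on the free coordinates
oracle_max_logdet <- function(rho) {
  n <- nrow(rho)
  pairs <- which(upper.tri(rho), arr.ind = TRUE)
  p <- nrow(pairs)
  A <- matrix(0, n, p)                     # rowsum_i as linear map of offdiags
  for (q in seq_len(p)) {
    A[pairs[q, 1], q] <- 1
    A[pairs[q, 2], q] <- 1
  }
  x0 <- rho[upper.tri(rho)]                # feasible particular solution
  ns <- svd(A, nv = p)$v[, -(seq_len(qr(A)$rank)), drop = FALSE]
  build <- function(z) {
    x <- x0 + if (ncol(ns)) as.vector(ns %*% z) else 0
    M <- diag(n)
    M[upper.tri(M)] <- x
    M[lower.tri(M)] <- t(M)[lower.tri(M)]
    M
  }
  f <- function(z) {
    M <- build(z)
    ch <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    -2 * sum(log(diag(ch)))
  }
  if (ncol(ns) == 0) return(rho)
  opt <- optim(rep(0, ncol(ns)), f, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  build(opt$par)
}

# brute-force quadruple loop for the community-weight variance (Eq. oracle)
naive_weight_variance <- function(C_by_layer, idx_by_layer, L_by_layer) {
  v <- 0
  for (al in seq_along(C_by_layer)) {
    C <- C_by_layer[[al]]
    idx <- idx_by_layer[[al]]
    if (length(idx) < 2) next
    pr <- list()
    for (i in seq_along(idx)) for (j in seq_len(i - 1)) {
      pr[[length(pr) + 1]] <- c(idx[i], idx[j])
    }
    acc <- 0
    for (p1 in pr) for (p2 in pr) {
      i <- p1[1]; j <- p1[2]; k <- p2[1]; r <- p2[2]
      acc <- acc + C[i, k] * C[j, r] + C[i, r] * C[j, k]
    }
    v <- v + acc / L_by_layer[[al]]
  }
  v
}

# tiny two-layer expression fixture with donors overlapping between layers
toy_two_layers <- function(seed = 5, n_genes = 6, S = 40) {
  set.seed(seed)
  gids <- sprintf("g%02d", 1:n_genes)
  donors <- sprintf("D%03d", 1:(2 * S))
  mk <- function(name, donor_idx) {
    Y <- matrix(rnorm(n_genes * S, mean = 4), n_genes, S)
    expression_layer(name, pmax(exp(Y) - 1, 0), gids,
                     sprintf("%s-s%03d", name, 1:S), donors[donor_idx])
  }
  list(mk("liver", 1:S), mk("lung", (S / 2):(S / 2 + S - 1)))
}

# small planted scenario used by non-acceptance pipeline tests
small_synth_params <- function() {
  synth_params(n_genes = 30L, n_layers = 3L,
               generalist_blocks = c(8L, 8L), specialist_block = 6L,
               n_samples = 120L)
}
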