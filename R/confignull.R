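#' Maximum-entropy configuration model for a correlation matrix
#'
#' Fits the null correlation matrix that maximizes Gaussian differential
#' entropy (equivalently, the log-determinant) subject to (a) unit diagonal
#' and (b) each node's strength (row sum, including the diagonal) matching the
#' input's. By stationarity the inverse of the null has off-diagonal entries
#' of the form (a_i + a_j)/2 plus a node-specific diagonal term, so the fit
#' reduces to 2N Lagrange multipliers. These are found by a damped Newton
#' iteration on the (strictly convex) dual, whose gradient is exactly the
#' vector of constraint violations.
#'
#' @param rho symmetric correlation matrix (unit diagonal, positive
#'   semidefinite within tolerance).
#' @param tol convergence tolerance on the maximum absolute constraint
#'   violation (default 1e-8).
#' @param max_iter maximum Newton iterations.
#' @param ridge diagonal lift applied (with a warning) when the input is
#'   numerically singular; the lifted matrix is renormalized to a correlation
#'   matrix before fitting.
#' @return object of class `null_layer`: `null_rho`, `multipliers` (list with
#'   `diagonal` and `strength` vectors), `residual`, `iterations`, `logdet`,
#'   `layer_name`.
#' @export
fit_configuration_model <- function(rho, tol = 1e-8, max_iter = 200L,
                                    ridge = 1e-8) {
  check_square_symmetric(rho, 1e-8, "rho")
  n <- nrow(rho)
  if (max(abs(diag(rho) - 1)) > 1e-8)
    stop_mlcoex("input must have unit diagonal")
  ev <- eigen((rho + t(rho)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_mlcoex("input is not positive semidefinite (min eigenvalue ",
                format(min(ev)), ")")
  if (min(ev) < 1e-10) {
    warning("near-singular input: applying ridge lift of ", ridge)
    rho <- (rho + ridge * diag(n)) / (1 + ridge)
  }
  lname <- attr(rho, "layer_name")
  if (n <= 2L) {
    # diagonal plus row-sum constraints pin every entry: null equals input
    out <- rho
    diag(out) <- 1
    return(structure(list(null_rho = out,
                          multipliers = list(diagonal = rep(NA_real_, n),
                                             strength = rep(NA_real_, n)),
                          residual = 0, iterations = 0L,
                          logdet = as.numeric(determinant(out)$modulus),
                          layer_name = lname),
                     class = "null_layer"))
  }

  s <- rowSums(rho)
  # multipliers: eta (diagonal constraints), nu (strength constraints);
  # precision J_jk = (nu_j + nu_k)/2 for j != k, J_jj = eta_j + nu_j
  build_J <- function(eta, nu) {
    J <- (outer(nu, rep(1, n)) + outer(rep(1, n), nu)) / 2
    diag(J) <- eta + nu
    J
  }
  eta <- rep(1, n)
  nu <- rep(0, n)
  resid <- Inf
  it <- 0L
  Sg <- NULL
  while (it < max_iter) {
    it <- it + 1L
    J <- build_J(eta, nu)
    ch <- tryCatch(chol(J), error = function(e) NULL)
    if (is.null(ch)) stop_mlcoex("internal error: precision lost definiteness")
    Sg <- chol2inv(ch)
    r <- rowSums(Sg)
    g <- c(1 - diag(Sg), s - r)      # dual gradient = constraint violation
    resid <- max(abs(g))
    if (resid <= tol) break
    # closed-form dual Hessian
    H11 <- Sg * Sg
    H12 <- Sg * r                    # [i, j] = Sigma_ij * r_i
    H22 <- (outer(r, r) + sum(Sg) * Sg) / 2
    H <- rbind(cbind(H11, H12), cbind(t(H12), H22))
    step <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(step))
      step <- -solve(H + 1e-10 * mean(diag(H)) * diag(2 * n), g)
    # backtrack so the dual decreases and the precision stays PD
    dual <- function(eta, nu) {
      J <- build_J(eta, nu)
      ld <- tryCatch(2 * sum(log(diag(chol(J)))), error = function(e) NA_real_)
      if (is.na(ld)) return(Inf)
      sum(eta) + sum(nu * s) - ld
    }
    f0 <- dual(eta, nu)
    t_step <- 1
    repeat {
      eta_new <- eta + t_step * step[seq_len(n)]
      nu_new <- nu + t_step * step[n + seq_len(n)]
      f1 <- dual(eta_new, nu_new)
      if (is.finite(f1) && f1 <= f0 + 1e-12 * abs(f0)) break
      t_step <- t_step / 2
      if (t_step < 1e-12)
        stop_mlcoex("line search failed at residual ", format(resid))
    }
    eta <- eta_new
    nu <- nu_new
  }
  if (resid > tol)
    stop_mlcoex("configuration-model fit did not converge in ", max_iter,
                " iterations (residual ", format(resid), ")")
  out <- (Sg + t(Sg)) / 2
  diag(out) <- 1                     # final projection onto the unit diagonal
  dimnames(out) <- dimnames(rho)
  structure(list(null_rho = out,
                 multipliers = list(diagonal = eta, strength = nu),
                 residual = resid, iterations = it,
                 logdet = as.numeric(determinant(out)$modulus),
                 layer_name = lname),
            class = "null_layer")
}

#' @export
print.null_layer <- function(x, ...) {
  cat(sprintf("<null_layer%s> %d nodes, residual %.2e, %d iterations, logdet %.4f\n",
              if (is.null(x$layer_name)) "" else paste0(" ", x$layer_name),
              nrow(x$null_rho), x$residual, x$iterations, x$logdet))
  invisible(x)
}

#' Sample a covariance matrix realization from a fitted null
#'
#' Draws `n_obs` independent zero-mean Gaussian vectors with covariance equal
#' to the null correlation matrix and returns their sample covariance
#' (denominator `n_obs - 1`, so its expectation equals the null matrix).
#'
#' @param null a `null_layer` from [fit_configuration_model()], or a
#'   covariance matrix.
#' @param n_obs number of observations (>= 2).
#' @param seed integer seed; the draw is bit-reproducible for a fixed seed.
#' @return list of class `sampled_covariance` with `matrix`, `n_obs`, `seed`.
#' @export
sample_null_covariance <- function(null, n_obs, seed = NULL) {
  C <- if (inherits(null, "null_layer")) null$null_rho else as.matrix(null)
  if (n_obs < 2L) stop_mlcoex("n_obs must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  R <- chol(C)
  X <- matrix(stats::rnorm(n_obs * nrow(C)), n_obs, nrow(C)) %*% R
  S <- crossprod(X) / (n_obs - 1)
  dimnames(S) <- dimnames(C)
  structure(list(matrix = S, n_obs = as.integer(n_obs), seed = seed),
            class = "sampled_covariance")
}
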