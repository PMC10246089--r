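# intralayer index pairs of a community: list per layer of the gene indices
# (into mlc$gene_ids) of community members in that layer
community_layer_members <- function(community, gene_ids, layer_names) {
  stopifnot(is.data.frame(community), all(c("gene", "layer") %in% names(community)))
  miss <- setdiff(community$gene, gene_ids)
  if (length(miss))
    stop_mlcoex("community genes not in the multilayer object: ",
                paste(miss, collapse = ", "))
  lapply(stats::setNames(layer_names, layer_names), function(al)
    match(community$gene[community$layer == al], gene_ids))
}

#' Construct a community node set
#'
#' @param genes,layers equal-length vectors giving the (gene, layer) nodes.
#' @return data.frame with columns `gene`, `layer`.
#' @export
ml_community <- function(genes, layers) {
  stopifnot(length(genes) == length(layers))
  df <- data.frame(gene = as.character(genes), layer = as.character(layers),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df)) stop_mlcoex("duplicate (gene, layer) nodes")
  if (nrow(df) == 0L) stop_mlcoex("community is empty")
  df
}

# communities of a partition as a list of node-set data frames
partition_communities <- function(partition, nodes) {
  lab <- canonical_labels(partition)
  lapply(seq_len(max(lab)), function(c)
    nodes[lab == c, c("gene", "layer"), drop = FALSE])
}

#' Total intralayer weight of a community
#'
#' W: the sum over layers of the empirical correlation (or covariance)
#' entries over unordered within-layer pairs of community nodes; the diagonal
#' is excluded and interlayer couplings never count.
#'
#' @param community data.frame of (gene, layer) nodes, e.g. [ml_community()].
#' @param mlc a `multilayer_correlation`.
#' @return scalar W.
#' @export
community_weight <- function(community, mlc) {
  mem <- community_layer_members(community, mlc$gene_ids, mlc$layer_names)
  W <- 0
  for (al in mlc$layer_names) {
    idx <- mem[[al]]
    if (length(idx) >= 2L) {
      R <- mlc$rho[[al]][idx, idx]
      W <- W + (sum(R) - sum(diag(R))) / 2
    }
  }
  W
}

# number of unordered intralayer pairs of a community
community_pair_count <- function(community) {
  n_al <- table(community$layer)
  sum(n_al * (n_al - 1) / 2)
}

#' Closed-form null moments of the community intralayer weight
#'
#' Mean and variance of W when per-layer sample covariance matrices of L
#' observations are drawn from the fitted configuration-model null. The mean
#' is the within-community sum of null entries; the variance is the Gaussian
#' (Isserlis) fourth-moment expression summed over ordered pair-of-pairs,
#' scaled by 1/L per layer. Layers may carry different observation counts, in
#' which case 1/L_alpha is applied inside the layer sum (reducing to a common
#' 1/L when all counts are equal).
#'
#' @param community data.frame of (gene, layer) nodes.
#' @param nulls named list of `null_layer` objects (names = layer labels).
#' @param n_obs per-layer observation counts: named vector or scalar.
#' @return list with `mu` and `var`.
#' @export
null_moments <- function(community, nulls, n_obs) {
  lnames <- names(nulls)
  if (is.null(lnames)) stop_mlcoex("nulls must be a named list")
  miss <- setdiff(unique(community$layer), lnames)
  if (length(miss))
    stop_mlcoex("missing null layer(s): ", paste(miss, collapse = ", "))
  if (is.null(names(n_obs))) n_obs <- stats::setNames(rep_len(n_obs, length(lnames)), lnames)
  mu <- 0
  v <- 0
  for (al in unique(community$layer)) {
    nl <- nulls[[al]]
    C <- if (inherits(nl, "null_layer")) nl$null_rho else as.matrix(nl)
    gids <- rownames(C)
    idx <- match(community$gene[community$layer == al], gids)
    if (anyNA(idx)) stop_mlcoex("community gene missing from null of ", al)
    if (length(idx) < 2L) next
    L_al <- n_obs[[al]]
    if (is.na(L_al) || L_al < 2) stop_mlcoex("n_obs must be >= 2 for layer ", al)
    pr <- which(lower.tri(matrix(0, length(idx), length(idx))), arr.ind = TRUE)
    iv <- idx[pr[, 1L]]  # i > j ordering within the community block
    jv <- idx[pr[, 2L]]
    mu <- mu + sum(C[cbind(iv, jv)])
    # sum over ordered pairs-of-pairs of C_ik C_jr + C_ir C_jk
    v <- v + (sum(C[iv, iv, drop = FALSE] * C[jv, jv, drop = FALSE]) +
                sum(C[iv, jv, drop = FALSE] * C[jv, iv, drop = FALSE])) / L_al
  }
  list(mu = mu, var = v)
}

#' Z score of an observed quality measure against null moments
#'
#' Returns `(x - mu) / sqrt(var)`; when the variance is zero (trivial
#' communities with no intralayer pairs) the Z score is undefined and `NA` is
#' returned rather than an error.
#'
#' @param x observed value.
#' @param mu,var null mean and variance (`var >= 0`).
#' @return numeric Z score, or `NA` when `var == 0`.
#' @export
z_score <- function(x, mu, var) {
  if (var < 0) stop_mlcoex("variance must be non-negative")
  if (var == 0) return(NA_real_)
  (x - mu) / sqrt(var)
}

#' Monte-Carlo moments of the community weight (oracle)
#'
#' Re-estimates the null mean and variance of W empirically by drawing
#' `n_rep` sample covariance matrices per layer from the fitted null and
#' recomputing W on each. Serves as an independent check of the closed-form
#' moments; the sample covariance uses denominator L - 1.
#'
#' @inheritParams null_moments
#' @param n_rep number of Monte-Carlo replicates (>= 2).
#' @param seed integer seed.
#' @return list with `mu_hat`, `var_hat`, `n_rep`.
#' @export
mc_weight_moments <- function(community, nulls, n_obs, n_rep = 1000L,
                              seed = NULL) {
  if (n_rep < 2L) stop_mlcoex("n_rep must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  lnames <- names(nulls)
  if (is.null(names(n_obs))) n_obs <- stats::setNames(rep_len(n_obs, length(lnames)), lnames)
  layers_used <- intersect(lnames, unique(community$layer))
  chols <- lapply(nulls[layers_used], function(nl) {
    C <- if (inherits(nl, "null_layer")) nl$null_rho else as.matrix(nl)
    list(R = chol(C), gids = rownames(C))
  })
  idxs <- lapply(layers_used, function(al)
    match(community$gene[community$layer == al], chols[[al]]$gids))
  names(idxs) <- layers_used
  Ws <- vapply(seq_len(n_rep), function(r) {
    W <- 0
    for (al in layers_used) {
      idx <- idxs[[al]]
      if (length(idx) < 2L) next
      L_al <- n_obs[[al]]
      X <- matrix(stats::rnorm(L_al * ncol(chols[[al]]$R)), L_al) %*% chols[[al]]$R
      S <- crossprod(X) / (L_al - 1)
      Ssub <- S[idx, idx]
      W <- W + (sum(Ssub) - sum(diag(Ssub))) / 2
    }
    W
  }, 0)
  list(mu_hat = mean(Ws), var_hat = stats::var(Ws), n_rep = n_rep)
}

#' Significance table for all communities of a partition
#'
#' One row per community: node and intralayer pair counts, observed weight W,
#' closed-form null mean and variance, and the Z score (NA, flagged, for
#' communities without intralayer pairs).
#'
#' @param partition label vector over the supra nodes (layer-major order).
#' @param mlc a `multilayer_correlation`.
#' @param nulls named list of `null_layer` objects (one per layer; an unnamed
#'   list is named from `mlc$layer_names`).
#' @param n_obs per-layer observation counts; defaults to `mlc$sample_counts`.
#' @return data.frame with columns `community`, `n_nodes`, `n_pairs`, `W`,
#'   `mu`, `var`, `z`, `trivial`.
#' @export
significance_table <- function(partition, mlc, nulls,
                               n_obs = mlc$sample_counts) {
  if (is.null(names(nulls))) names(nulls) <- mlc$layer_names
  nodes <- data.frame(gene = rep(mlc$gene_ids, times = length(mlc$layer_names)),
                      layer = rep(mlc$layer_names, each = length(mlc$gene_ids)),
                      stringsAsFactors = FALSE)
  comms <- partition_communities(partition, nodes)
  rows <- lapply(seq_along(comms), function(c) {
    comm <- comms[[c]]
    np <- community_pair_count(comm)
    W <- community_weight(comm, mlc)
    mom <- null_moments(comm, nulls, n_obs)
    data.frame(community = c, n_nodes = nrow(comm), n_pairs = np, W = W,
               mu = mom$mu, var = mom$var,
               z = z_score(W, mom$mu, mom$var),
               trivial = np == 0L || mom$var == 0)
  })
  do.call(rbind, rows)
}
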