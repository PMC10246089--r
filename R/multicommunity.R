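#' Build the supra-modularity matrix for a multilayer correlation matrix
#'
#' Over the N*L nodes (gene, layer), the supra-modularity matrix has
#' intralayer blocks rho_alpha - gamma_alpha * null_alpha (diagonal included)
#' and interlayer entries omega_i_ab on the replica diagonal. The
#' normalization constant is the total weight
#' C_norm = sum_i sum_alpha (sum_j rho_ij_alpha + sum_beta omega_i_ab),
#' diagonal rho terms included.
#'
#' @param mlc a `multilayer_correlation` from [assemble_multilayer()].
#' @param nulls list of `null_layer` objects, one per layer, fitted from the
#'   corresponding `mlc$rho` matrices.
#' @param gamma resolution parameter: scalar (shared across layers) or one
#'   value per layer; must be positive.
#' @return object of class `supra_modularity`: `nodes` (data.frame with
#'   `gene`, `layer`), `B`, `gamma`, `c_norm`.
#' @export
build_supra_modularity <- function(mlc, nulls, gamma = 1) {
  stopifnot(inherits(mlc, "multilayer_correlation"))
  L <- length(mlc$layer_names)
  N <- length(mlc$gene_ids)
  if (length(nulls) != L) stop_mlcoex("need one fitted null per layer")
  gamma <- rep_len(gamma, L)
  if (any(gamma <= 0)) stop_mlcoex("gamma must be positive")
  B <- matrix(0, N * L, N * L)
  for (a in seq_len(L)) {
    nr <- if (inherits(nulls[[a]], "null_layer")) nulls[[a]]$null_rho
          else as.matrix(nulls[[a]])
    idx <- (a - 1L) * N + seq_len(N)
    B[idx, idx] <- mlc$rho[[a]] - gamma[a] * nr
  }
  if (L >= 2L) for (a in seq_len(L - 1L)) for (b in (a + 1L):L) {
    ia <- (a - 1L) * N + seq_len(N)
    ib <- (b - 1L) * N + seq_len(N)
    w <- mlc$omega[, a, b]
    B[cbind(ia, ib)] <- w
    B[cbind(ib, ia)] <- w
  }
  c_norm <- sum(vapply(mlc$rho, sum, 0)) + sum(mlc$omega)
  if (c_norm <= 0) stop_mlcoex("normalization constant C_norm is not positive")
  nodes <- data.frame(gene = rep(mlc$gene_ids, times = L),
                      layer = rep(mlc$layer_names, each = N),
                      stringsAsFactors = FALSE)
  structure(list(nodes = nodes, B = B, gamma = gamma, c_norm = c_norm),
            class = "supra_modularity")
}

#' Supra-modularity matrix for ordinary multilayer networks
#'
#' Network-input variant: intralayer blocks use the Newman-Girvan
#' configuration-model null A_ij - gamma * k_i k_j / (2 m), interlayer
#' couplings sit on the replica diagonal, and the normalization is twice the
#' total edge weight (intralayer strengths plus interlayer couplings).
#'
#' @param adj list of symmetric non-negative adjacency matrices with zero
#'   diagonal, one per layer, all N x N in the same node order.
#' @param omega optional N x L x L coupling array (default: no couplings).
#' @param gamma resolution parameter(s), as in [build_supra_modularity()].
#' @return a `supra_modularity` (with `c_norm` = 2 mu).
#' @export
build_supra_modularity_network <- function(adj, omega = NULL, gamma = 1) {
  L <- length(adj)
  stopifnot(L >= 1L)
  N <- nrow(adj[[1L]])
  gamma <- rep_len(gamma, L)
  lnames <- names(adj) %||% paste0("layer", seq_len(L))
  gids <- rownames(adj[[1L]]) %||% paste0("n", seq_len(N))
  if (is.null(omega)) omega <- array(0, dim = c(N, L, L))
  B <- matrix(0, N * L, N * L)
  two_mu <- sum(omega)
  for (a in seq_len(L)) {
    A <- adj[[a]]
    check_square_symmetric(A, 1e-8, paste0("adjacency[", lnames[a], "]"))
    if (any(A < 0)) stop_mlcoex("adjacency weights must be non-negative")
    if (max(abs(diag(A))) > 0) stop_mlcoex("adjacency diagonal must be zero")
    k <- rowSums(A)
    m <- sum(k) / 2
    if (m <= 0) stop_mlcoex("layer ", lnames[a], " has no edges")
    idx <- (a - 1L) * N + seq_len(N)
    B[idx, idx] <- A - gamma[a] * outer(k, k) / (2 * m)
    two_mu <- two_mu + sum(k)
  }
  if (L >= 2L) for (a in seq_len(L - 1L)) for (b in (a + 1L):L) {
    ia <- (a - 1L) * N + seq_len(N)
    ib <- (b - 1L) * N + seq_len(N)
    B[cbind(ia, ib)] <- omega[, a, b]
    B[cbind(ib, ia)] <- omega[, b, a]
  }
  nodes <- data.frame(gene = rep(gids, times = L),
                      layer = rep(lnames, each = N), stringsAsFactors = FALSE)
  structure(list(nodes = nodes, B = B, gamma = gamma, c_norm = two_mu),
            class = "supra_modularity")
}

#' Multilayer modularity of a partition
#'
#' Q = (1 / C_norm) * sum of supra-modularity entries over ordered co-assigned
#' node pairs (both (i, j) and (j, i) count, and each node pairs with itself).
#'
#' @param partition integer vector of community labels, one per supra node in
#'   `supra$nodes` order.
#' @param supra a `supra_modularity`.
#' @return scalar modularity.
#' @export
modularity_score <- function(partition, supra) {
  stopifnot(inherits(supra, "supra_modularity"))
  if (length(partition) != nrow(supra$B))
    stop_mlcoex("partition must assign every node")
  if (anyNA(partition)) stop_mlcoex("partition contains unassigned nodes")
  within_community_sum(supra$B, canonical_labels(partition)) / supra$c_norm
}

# core: full Louvain (local moves + aggregation) on a modularity matrix
genlouvain_matrix <- function(B, init = NULL, prob_move = FALSE) {
  n <- nrow(B)
  membership <- canonical_labels(init %||% seq_len(n))
  Bcur <- B
  level_labels <- membership          # labels of current-level super-nodes
  mapping <- seq_len(n)               # original node -> current-level node
  repeat {
    moved <- canonical_labels(louvain_local_move(Bcur, level_labels,
                                                 prob_move))
    if (identical(moved, canonical_labels(level_labels))) break
    membership <- moved[mapping]
    k <- max(moved)
    if (k == nrow(Bcur)) break        # nothing merged; fixed point
    Bcur <- aggregate_matrix(Bcur, moved)
    mapping <- moved[mapping]
    level_labels <- seq_len(k)
  }
  canonical_labels(membership)
}

#' Generalized Louvain on a supra-modularity matrix
#'
#' Locally maximizes the partition quality sum of within-community B entries
#' by repeated single-node moves and community aggregation. Stochastic in the
#' node visiting order, which is driven by the seed, so a fixed seed gives an
#' identical partition.
#'
#' Two move-selection rules are available. `"best"` takes the maximal-gain
#' move (keeping the current community on ties, else the lowest community
#' label) and is near-deterministic: the random visiting order rarely changes
#' the outcome. `"prob"` draws the target among all strictly improving
#' communities with probability proportional to the gain, the randomized
#' selection multilayer Louvain implementations use to diversify the runs
#' feeding a consensus; use it whenever many seeded runs are combined.
#'
#' @param supra a `supra_modularity` (or a bare symmetric matrix).
#' @param seed integer seed (optional; the current RNG state is used when
#'   omitted).
#' @param init optional initial partition (defaults to singletons).
#' @param method move selection: `"best"` (default) or `"prob"`.
#' @return integer community labels, canonicalized to `1..k`, with node keys
#'   as names when `supra` carries them.
#' @export
genlouvain <- function(supra, seed = NULL, init = NULL,
                       method = c("best", "prob")) {
  method <- match.arg(method)
  B <- if (inherits(supra, "supra_modularity")) supra$B else as.matrix(supra)
  if (any(!is.finite(B))) stop_mlcoex("B must be finite")
  if (!is.null(seed)) set.seed(seed)
  p <- genlouvain_matrix(B, init, prob_move = method == "prob")
  if (inherits(supra, "supra_modularity"))
    names(p) <- paste(supra$nodes$gene, supra$nodes$layer, sep = "|")
  p
}

#' Iterated generalized Louvain
#'
#' Repeats [genlouvain()], feeding each output partition back as the initial
#' partition, until two successive outputs are identical. The partition
#' quality is non-decreasing across iterations.
#'
#' @inheritParams genlouvain
#' @param max_iter iteration cap; on hitting it the best partition so far is
#'   returned with a warning.
#' @return integer community labels.
#' @export
iterated_genlouvain <- function(supra, seed = NULL, max_iter = 100L,
                                method = c("best", "prob")) {
  method <- match.arg(method)
  pm <- method == "prob"
  B <- if (inherits(supra, "supra_modularity")) supra$B else as.matrix(supra)
  if (!is.null(seed)) set.seed(seed)
  p <- genlouvain_matrix(B, prob_move = pm)
  for (i in seq_len(max_iter)) {
    p2 <- genlouvain_matrix(B, init = p, prob_move = pm)
    if (identical(canonical_labels(p2), canonical_labels(p))) {
      p <- p2
      if (inherits(supra, "supra_modularity"))
        names(p) <- paste(supra$nodes$gene, supra$nodes$layer, sep = "|")
      return(p)
    }
    p <- p2
  }
  warning("iterated_genlouvain did not reach a fixed point in ", max_iter,
          " iterations; returning the last partition")
  if (inherits(supra, "supra_modularity"))
    names(p) <- paste(supra$nodes$gene, supra$nodes$layer, sep = "|")
  p
}

# mean co-assignment fraction over a list of partitions
agreement_matrix <- function(partitions) {
  n <- length(partitions[[1L]])
  A <- matrix(0, n, n)
  for (p in partitions) A <- A + outer(p, p, "==")
  A / length(partitions)
}

# expected off-diagonal agreement under size-preserving label permutations;
# community sizes are invariant under permuting node-label assignments, so the
# mean over permutations has the closed form sum_c n_c (n_c - 1) / (n (n - 1))
# averaged over partitions (the limit of the usual permutation scheme)
permutation_agreement_level <- function(partitions) {
  n <- length(partitions[[1L]])
  lev <- vapply(partitions,
                function(p) (sum(tabulate(p)^2) - n) / (n * (n - 1)), 0)
  mean(lev)
}

#' Consensus partition over stochastic runs
#'
#' Builds the node-by-node agreement matrix (fraction of input partitions
#' co-assigning each pair), subtracts the mean agreement level obtained from
#' the same partitions with labels randomly permuted (preserving community
#' sizes; computed in closed form, the exact mean of that scheme), and
#' clusters the resulting matrix with generalized Louvain repeatedly until all
#' runs agree. Negative entries are kept and act as repulsion.
#'
#' @param partitions list (>= 2) of label vectors over the same node set.
#' @param supra optional `supra_modularity`, used only to carry node names.
#' @param seed integer seed.
#' @param n_runs Louvain runs per consensus round.
#' @param max_rounds safety cap on consensus rounds.
#' @param method move selection for the re-clustering runs (see
#'   [genlouvain()]); `"prob"` keeps the rounds stochastic.
#' @return integer community labels.
#' @export
consensus_partition <- function(partitions, supra = NULL, seed = NULL,
                                n_runs = 20L, max_rounds = 100L,
                                method = c("prob", "best")) {
  method <- match.arg(method)
  pm <- method == "prob"
  if (length(partitions) < 2L) stop_mlcoex("need at least two partitions")
  partitions <- lapply(partitions, canonical_labels)
  n <- length(partitions[[1L]])
  if (!all(vapply(partitions, length, 1L) == n))
    stop_mlcoex("partitions cover different node sets")
  if (!is.null(seed)) set.seed(seed)
  for (round in seq_len(max_rounds)) {
    if (length(unique(partitions)) == 1L) {
      p <- partitions[[1L]]
      if (!is.null(supra))
        names(p) <- paste(supra$nodes$gene, supra$nodes$layer, sep = "|")
      return(p)
    }
    A <- agreement_matrix(partitions)
    thr <- permutation_agreement_level(partitions)
    D <- A - thr
    diag(D) <- 0
    partitions <- lapply(seq_len(n_runs),
                         function(i) genlouvain_matrix(D, prob_move = pm))
  }
  warning("consensus did not converge in ", max_rounds,
          " rounds; returning the modal partition")
  p <- partitions[[1L]]
  if (!is.null(supra))
    names(p) <- paste(supra$nodes$gene, supra$nodes$layer, sep = "|")
  p
}

# enumerate all set partitions of n items as restricted-growth strings
set_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxlab) {
    i <- length(prefix) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible())
    }
    for (lab in seq_len(maxlab + 1L))
      rec(c(prefix, lab), max(maxlab, lab))
  }
  rec(integer(0), 0L)
  do.call(rbind, out)
}

#' Exact maximum-modularity partition by enumeration
#'
#' Test oracle: enumerates every set partition (Bell-number many) of the supra
#' nodes and returns the one maximizing the partition quality. Limited to 10
#' nodes.
#'
#' @param supra a `supra_modularity` or bare symmetric matrix.
#' @return list with `partition` (labels) and `Q` (modularity; for a bare
#'   matrix the unnormalized within-community sum).
#' @export
brute_force_max_modularity <- function(supra) {
  B <- if (inherits(supra, "supra_modularity")) supra$B else as.matrix(supra)
  n <- nrow(B)
  if (n > 10L) stop_mlcoex("brute force limited to 10 nodes")
  parts <- set_partitions(n)
  vals <- apply(parts, 1L, function(lab) within_community_sum(B, lab))
  best <- which.max(vals)
  cn <- if (inherits(supra, "supra_modularity")) supra$c_norm else 1
  list(partition = canonical_labels(parts[best, ]), Q = vals[best] / cn)
}
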