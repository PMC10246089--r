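#' Construct a tissue expression layer
#'
#' Bundles a genes-by-samples TPM matrix with its identifiers and the donor of
#' each sample. TPM values must be non-negative; rows are genes, columns are
#' samples.
#'
#' @param layer_name tissue label.
#' @param values numeric N x S matrix of TPM.
#' @param gene_ids character vector of length N.
#' @param sample_ids character vector of length S.
#' @param donor_ids character vector of length S mapping each sample to its
#'   donor.
#' @return an object of class `expression_layer`.
#' @export
expression_layer <- function(layer_name, values, gene_ids = rownames(values),
                             sample_ids = colnames(values), donor_ids) {
  values <- as.matrix(values)
  if (is.null(gene_ids) || is.null(sample_ids))
    stop_mlcoex("gene_ids and sample_ids are required")
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids))
    stop_mlcoex("dimensions of values do not match id lists")
  if (length(donor_ids) != length(sample_ids))
    stop_mlcoex("donor_ids must have one entry per sample")
  if (anyDuplicated(gene_ids))
    stop_mlcoex("duplicate gene ids: ",
                paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  if (any(!is.finite(values)) || any(values < 0))
    stop_mlcoex("TPM values must be finite and non-negative")
  dimnames(values) <- list(gene_ids, sample_ids)
  structure(list(layer_name = layer_name, gene_ids = as.character(gene_ids),
                 sample_ids = as.character(sample_ids),
                 donor_ids = as.character(donor_ids), values = values),
            class = "expression_layer")
}

#' @export
print.expression_layer <- function(x, ...) {
  cat(sprintf("<expression_layer> %s: %d genes x %d samples (%d donors)\n",
              x$layer_name, length(x$gene_ids), length(x$sample_ids),
              length(unique(x$donor_ids))))
  invisible(x)
}

#' Log-transform TPM values
#'
#' Applies the entrywise natural logarithm of (TPM + 1) so that a TPM of zero
#' maps to zero. Used before every Pearson correlation in the pipeline to
#' suppress the effect of extreme TPM outliers.
#'
#' @param expr an [expression_layer()] or a non-negative numeric matrix.
#' @return matrix of log(TPM + 1), same shape as the input values.
#' @export
log_transform <- function(expr) {
  v <- if (inherits(expr, "expression_layer")) expr$values else as.matrix(expr)
  if (any(v < 0, na.rm = TRUE)) stop_mlcoex("negative TPM value in input")
  log1p(v)
}

#' Pearson correlation layer on the log scale
#'
#' Computes the N x N Pearson correlation of log(TPM + 1) across samples, the
#' co-expression matrix of one tissue layer.
#'
#' @param expr an [expression_layer()].
#' @param drop_zero_variance drop genes whose log(TPM+1) has zero variance
#'   (with a warning) instead of raising an error. Correlation is undefined
#'   for such genes.
#' @return symmetric correlation matrix with unit diagonal, dimnames set to
#'   the (possibly reduced) gene ids.
#' @export
layer_correlation <- function(expr, drop_zero_variance = FALSE) {
  stopifnot(inherits(expr, "expression_layer"))
  if (length(expr$sample_ids) < 3L)
    stop_mlcoex("need at least 3 samples to estimate correlations")
  lx <- log_transform(expr)
  v <- apply(lx, 1L, stats::var)
  bad <- which(v == 0)
  if (length(bad)) {
    if (!drop_zero_variance)
      stop_mlcoex("zero-variance genes: ",
                  paste(expr$gene_ids[bad], collapse = ", "))
    warning("dropping ", length(bad), " zero-variance gene(s): ",
            paste(expr$gene_ids[bad], collapse = ", "))
    lx <- lx[-bad, , drop = FALSE]
  }
  r <- stats::cor(t(lx))
  r <- (r + t(r)) / 2
  diag(r) <- 1
  r
}

#' Select the union of top-variance genes across layers
#'
#' Per layer, ranks genes by the variance of raw TPM across that layer's
#' samples and keeps the top `k`; returns the union over layers together with
#' per-layer membership. Ties at rank k are broken by gene id (lexicographic),
#' so the selection is deterministic.
#'
#' @param layers list of [expression_layer()] objects over the same gene set.
#' @param k number of genes to keep per layer.
#' @param use_log rank by variance of log(TPM+1) instead of raw TPM.
#' @return list with `union` (sorted character vector) and `per_layer`
#'   (named list of the k selected ids per layer).
#' @export
select_top_variance_genes <- function(layers, k, use_log = FALSE) {
  stopifnot(length(layers) >= 1L)
  per_layer <- lapply(layers, function(ly) {
    if (k > length(ly$gene_ids))
      stop_mlcoex("k exceeds the number of genes in layer ", ly$layer_name)
    v <- if (use_log) apply(log1p(ly$values), 1L, stats::var)
         else apply(ly$values, 1L, stats::var)
    ord <- order(-v, ly$gene_ids)
    ly$gene_ids[ord[seq_len(k)]]
  })
  names(per_layer) <- vapply(layers, `[[`, "", "layer_name")
  list(union = sort(unique(unlist(per_layer))), per_layer = per_layer)
}

#' Overlap diagnostics between variance- and expression-ranked genes
#'
#' Jaccard index between the top-k genes by mean TPM and a given gene set,
#' plus the average rank (by mean TPM, rank 1 = most expressed, over all genes
#' in the layer) of the given set. Used to check that highly variable genes
#' are also highly expressed.
#'
#' @param layer an [expression_layer()].
#' @param gene_set non-empty character vector of gene ids.
#' @param k top-k size for the mean-TPM ranking.
#' @return list with `jaccard` and `average_rank`.
#' @export
expression_rank_stats <- function(layer, gene_set, k) {
  stopifnot(inherits(layer, "expression_layer"))
  if (length(gene_set) == 0L) stop_mlcoex("gene_set is empty")
  if (k < 1L || k > length(layer$gene_ids)) stop_mlcoex("invalid k")
  m <- rowMeans(layer$values)
  top_mean <- layer$gene_ids[order(-m, layer$gene_ids)][seq_len(k)]
  jac <- length(intersect(top_mean, gene_set)) /
    length(union(top_mean, gene_set))
  rk <- rank(-m, ties.method = "average")
  names(rk) <- layer$gene_ids
  miss <- setdiff(gene_set, layer$gene_ids)
  if (length(miss))
    stop_mlcoex("genes not in layer: ", paste(miss, collapse = ", "))
  list(jaccard = jac, average_rank = mean(rk[gene_set]))
}

# one sample per donor: first sample id (sorted) for each donor
dedupe_by_donor <- function(layer) {
  ord <- order(layer$donor_ids, layer$sample_ids)
  keep <- ord[!duplicated(layer$donor_ids[ord])]
  keep[order(keep)]
}

#' Empirical interlayer couplings
#'
#' For each gene i and each pair of layers (alpha, beta), the interlayer
#' coupling omega is the Pearson correlation of gene i's log(TPM+1) across
#' donors common to the two layers (one sample per donor per tissue). Since
#' the modularity maximization assumes non-negative interlayer edges, negative
#' values are clamped to 0. The alpha = beta diagonal is 0.
#'
#' @param layers list of [expression_layer()] with identical, identically
#'   ordered gene lists.
#' @param min_common_donors smallest admissible number of shared donors for a
#'   layer pair (default 3).
#' @return list with `omega` (N x L x L array), `n_clamped` (count of negative
#'   values clamped), and `pair_sample_counts` (L x L matrix of common donors).
#' @export
interlayer_couplings <- function(layers, min_common_donors = 3L) {
  L <- length(layers)
  stopifnot(L >= 1L)
  gids <- layers[[1L]]$gene_ids
  for (ly in layers)
    if (!identical(ly$gene_ids, gids))
      stop_mlcoex("gene lists must be identical and ordered across layers")
  N <- length(gids)
  lnames <- vapply(layers, `[[`, "", "layer_name")
  omega <- array(0, dim = c(N, L, L),
                 dimnames = list(gids, lnames, lnames))
  pair_n <- matrix(0L, L, L, dimnames = list(lnames, lnames))
  n_clamped <- 0L
  keep <- lapply(layers, dedupe_by_donor)
  if (L >= 2L) for (a in seq_len(L - 1L)) for (b in (a + 1L):L) {
    da <- layers[[a]]$donor_ids[keep[[a]]]
    db <- layers[[b]]$donor_ids[keep[[b]]]
    common <- intersect(da, db)
    if (length(common) < min_common_donors)
      stop_mlcoex("layers ", lnames[a], " and ", lnames[b], " share only ",
                  length(common), " donors (need >= ", min_common_donors, ")")
    pair_n[a, b] <- pair_n[b, a] <- length(common)
    xa <- log1p(layers[[a]]$values[, keep[[a]][match(common, da)], drop = FALSE])
    xb <- log1p(layers[[b]]$values[, keep[[b]][match(common, db)], drop = FALSE])
    for (i in seq_len(N)) {
      if (stats::sd(xa[i, ]) == 0 || stats::sd(xb[i, ]) == 0) {
        w <- 0
      } else {
        w <- stats::cor(xa[i, ], xb[i, ])
      }
      if (w < 0) {
        n_clamped <- n_clamped + 1L
        w <- 0
      }
      omega[i, a, b] <- omega[i, b, a] <- w
    }
  }
  list(omega = omega, n_clamped = n_clamped, pair_sample_counts = pair_n)
}

#' Assemble and validate a multilayer correlation object
#'
#' @param corrs named list of N x N correlation matrices, one per layer, all
#'   over the same ordered gene ids.
#' @param omega N x L x L array of interlayer couplings in `[0, 1]`, symmetric
#'   in its layer indices, zero on the layer diagonal.
#' @param sample_counts integer vector of per-layer sample counts used to
#'   estimate the correlations.
#' @param pair_sample_counts optional L x L matrix of common-donor counts.
#' @param tol validation tolerance for symmetry/diagonal checks.
#' @return object of class `multilayer_correlation` with fields `gene_ids`,
#'   `layer_names`, `rho` (list of matrices), `omega`, `sample_counts`,
#'   `pair_sample_counts`.
#' @export
assemble_multilayer <- function(corrs, omega, sample_counts,
                                pair_sample_counts = NULL, tol = 1e-8) {
  L <- length(corrs)
  stopifnot(L >= 1L)
  gids <- rownames(corrs[[1L]])
  if (is.null(gids)) stop_mlcoex("correlation matrices must carry gene ids")
  N <- length(gids)
  lnames <- names(corrs) %||% paste0("layer", seq_len(L))
  for (a in seq_len(L)) {
    r <- corrs[[a]]
    check_square_symmetric(r, tol, paste0("rho[", lnames[a], "]"))
    if (!identical(rownames(r), gids))
      stop_mlcoex("gene ids differ between layers")
    if (max(abs(diag(r) - 1)) > tol)
      stop_mlcoex("rho[", lnames[a], "] diagonal is not 1")
    if (max(abs(r)) > 1 + tol)
      stop_mlcoex("rho[", lnames[a], "] has entries outside [-1, 1]")
  }
  if (!is.array(omega) || !all(dim(omega) == c(N, L, L)))
    stop_mlcoex("omega must be an N x L x L array")
  if (min(omega) < -tol || max(omega) > 1 + tol)
    stop_mlcoex("omega entries must lie in [0, 1]")
  for (a in seq_len(L)) {
    if (max(abs(omega[, a, a])) > tol)
      stop_mlcoex("omega layer diagonal must be zero")
    for (b in seq_len(L))
      if (max(abs(omega[, a, b] - omega[, b, a])) > tol)
        stop_mlcoex("omega not symmetric in its layer indices")
  }
  if (length(sample_counts) != L)
    stop_mlcoex("sample_counts must have one entry per layer")
  structure(list(gene_ids = gids, layer_names = lnames, rho = corrs,
                 omega = omega,
                 sample_counts = stats::setNames(as.integer(sample_counts), lnames),
                 pair_sample_counts = pair_sample_counts),
            class = "multilayer_correlation")
}

#' @export
print.multilayer_correlation <- function(x, ...) {
  cat(sprintf("<multilayer_correlation> %d genes x %d layers (%s)\n",
              length(x$gene_ids), length(x$layer_names),
              paste(x$layer_names, collapse = ", ")))
  invisible(x)
}

#' Build a multilayer correlation object from expression layers
#'
#' Convenience wrapper: restricts every layer to a common ordered gene set,
#' computes per-layer log-scale correlation matrices and empirical interlayer
#' couplings, and assembles the validated multilayer object.
#'
#' @param layers list of [expression_layer()] objects.
#' @param genes character vector of gene ids to use (must be present in every
#'   layer); defaults to the intersection of all layers' genes.
#' @param drop_zero_variance passed to [layer_correlation()]. If any layer
#'   drops genes, those genes are removed from every layer before assembly.
#' @return a `multilayer_correlation`.
#' @export
multilayer_from_layers <- function(layers, genes = NULL,
                                   drop_zero_variance = FALSE) {
  genes <- genes %||% Reduce(intersect, lapply(layers, `[[`, "gene_ids"))
  genes <- sort(genes)
  sub <- lapply(layers, function(ly) {
    idx <- match(genes, ly$gene_ids)
    if (anyNA(idx))
      stop_mlcoex("layer ", ly$layer_name, " is missing ",
                  sum(is.na(idx)), " requested genes")
    expression_layer(ly$layer_name, ly$values[idx, , drop = FALSE],
                     genes, ly$sample_ids, ly$donor_ids)
  })
  if (drop_zero_variance) {
    keep <- genes
    for (ly in sub) {
      v <- apply(log1p(ly$values), 1L, stats::var)
      keep <- setdiff(keep, ly$gene_ids[v == 0])
    }
    if (length(keep) < length(genes))
      sub <- lapply(sub, function(ly)
        expression_layer(ly$layer_name,
                         ly$values[match(keep, ly$gene_ids), , drop = FALSE],
                         keep, ly$sample_ids, ly$donor_ids))
    genes <- keep
  }
  corrs <- lapply(sub, layer_correlation)
  names(corrs) <- vapply(sub, `[[`, "", "layer_name")
  ic <- interlayer_couplings(sub)
  assemble_multilayer(corrs, ic$omega,
                      vapply(sub, function(ly) length(ly$sample_ids), 1L),
                      ic$pair_sample_counts)
}
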