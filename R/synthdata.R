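#' Default parameters for the synthetic multilayer scenario
#'
#' Four tissue layers over 60 genes: three 12-gene generalist blocks planted
#' in every layer, one 10-gene specialist block planted in the first layer
#' only, background correlation 0.05, within-block correlation 0.7, 500
#' samples per layer, and donors shared across layers at an expected pairwise
#' overlap fraction of 0.5.
#'
#' @param n_genes,n_layers problem size.
#' @param generalist_blocks vector of generalist block sizes.
#' @param specialist_block size of the single-layer specialist block (0 for
#'   none); it lives in `specialist_layer`.
#' @param specialist_layer index of the specialist block's home layer.
#' @param rho_in,rho_out within-block and background correlations
#'   (`rho_in > rho_out >= 0`).
#' @param n_samples per-layer sample count (scalar or per-layer vector).
#' @param donor_overlap expected pairwise donor overlap fraction in `[0, 1]`.
#' @param mu_g,sigma_g per-gene mean and scale of Gaussian log-expression;
#'   the defaults make exp(value) - 1 almost surely positive so that
#'   log(TPM + 1) recovers the planted correlations.
#' @return named list of parameters.
#' @export
synth_params <- function(n_genes = 60L, n_layers = 4L,
                         generalist_blocks = c(12L, 12L, 12L),
                         specialist_block = 10L, specialist_layer = 1L,
                         rho_in = 0.7, rho_out = 0.05, n_samples = 500L,
                         donor_overlap = 0.5, mu_g = 5, sigma_g = 1) {
  if (!(rho_in > rho_out && rho_out >= 0 && rho_in < 1))
    stop_mlcoex("need rho_in in (rho_out, 1) and rho_out >= 0")
  if (sum(generalist_blocks) + specialist_block > n_genes)
    stop_mlcoex("blocks exceed the gene count")
  list(n_genes = n_genes, n_layers = n_layers,
       generalist_blocks = generalist_blocks,
       specialist_block = specialist_block,
       specialist_layer = specialist_layer,
       rho_in = rho_in, rho_out = rho_out,
       n_samples = rep_len(n_samples, n_layers),
       donor_overlap = donor_overlap, mu_g = mu_g, sigma_g = sigma_g)
}

# planted block label per gene: 1..k for blocks, 0 for background genes
planted_gene_blocks <- function(params) {
  blocks <- integer(params$n_genes)
  at <- 0L
  for (b in seq_along(params$generalist_blocks)) {
    blocks[at + seq_len(params$generalist_blocks[b])] <- b
    at <- at + params$generalist_blocks[b]
  }
  if (params$specialist_block > 0L) {
    blocks[at + seq_len(params$specialist_block)] <-
      length(params$generalist_blocks) + 1L
  }
  blocks
}

# target correlation matrix of one layer given which blocks are active there
target_layer_correlation <- function(params, active_blocks, blocks) {
  n <- params$n_genes
  R <- matrix(params$rho_out, n, n)
  for (b in active_blocks) {
    idx <- which(blocks == b)
    R[idx, idx] <- params$rho_in
  }
  diag(R) <- 1
  R
}

#' Generate a planted multilayer expression dataset
#'
#' Draws per-layer Gaussian log-expression with block-structured target
#' correlations: generalist blocks are identical across all layers and share
#' a per-donor latent factor across layers (so interlayer couplings come out
#' high for generalist genes on common donors); the specialist block is
#' active in its home layer only; every remaining gene pair sits at the
#' background correlation. Values are mapped to TPM as exp(value) - 1,
#' clipped at 0.
#'
#' @param params from [synth_params()].
#' @param seed integer seed; the dataset is identical for a fixed seed.
#' @return list of class `synthetic_dataset`: `layers` (list of
#'   [expression_layer()]), `truth` (data.frame gene/layer/block with block 0
#'   = background), `params`, `seed`, and `target_rho` (list of per-layer
#'   target correlation matrices, checked positive definite).
#' @export
planted_multilayer_expression <- function(params = synth_params(),
                                          seed = 1L) {
  set.seed(seed)
  n <- params$n_genes
  L <- params$n_layers
  blocks <- planted_gene_blocks(params)
  n_gen <- length(params$generalist_blocks)
  spec_b <- if (params$specialist_block > 0L) n_gen + 1L else NA_integer_
  gids <- sprintf("g%03d", seq_len(n))
  lnames <- paste0("tissue", seq_len(L))

  active <- lapply(seq_len(L), function(al) {
    ab <- seq_len(n_gen)
    if (!is.na(spec_b) && al == params$specialist_layer) ab <- c(ab, spec_b)
    ab
  })
  target_rho <- lapply(seq_len(L), function(al)
    target_layer_correlation(params, active[[al]], blocks))
  for (al in seq_len(L)) {
    ev <- eigen(target_rho[[al]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0)
      stop_mlcoex("target correlation of layer ", al,
                  " is not positive definite")
  }

  # donor pool sized so that independent draws of S donors overlap at the
  # configured expected fraction: pool = S / overlap
  pool_size <- max(params$n_samples,
                   ceiling(max(params$n_samples) / max(params$donor_overlap,
                                                       1e-6)))
  donors <- sprintf("D%05d", seq_len(pool_size))
  r_in <- params$rho_in
  r_out <- params$rho_out
  w_shared <- sqrt(r_out)           # global (layer-private) factor loading
  w_block <- sqrt(r_in - r_out)     # block factor loading
  w_noise <- sqrt(1 - r_in)

  # generalist block factors are keyed by donor and reused across layers;
  # specialist and global factors are private to (layer, donor)
  gen_factor <- matrix(stats::rnorm(pool_size * n_gen), pool_size, n_gen)

  layers <- vector("list", L)
  for (al in seq_len(L)) {
    S <- params$n_samples[al]
    donor_idx <- sample.int(pool_size, S)
    sample_ids <- sprintf("%s-S%04d", lnames[al], seq_len(S))
    g_global <- stats::rnorm(S)
    spec_factor <- stats::rnorm(S)
    Y <- matrix(0, n, S)
    for (i in seq_len(n)) {
      b <- blocks[i]
      f <- if (b == 0L) 0
           else if (b <= n_gen) gen_factor[donor_idx, b]
           else spec_factor
      in_layer <- b != 0L && (b <= n_gen || al == params$specialist_layer)
      if (in_layer) {
        Y[i, ] <- params$mu_g + params$sigma_g *
          (w_shared * g_global + w_block * f + w_noise * stats::rnorm(S))
      } else {
        Y[i, ] <- params$mu_g + params$sigma_g *
          (w_shared * g_global + sqrt(1 - r_out) * stats::rnorm(S))
      }
    }
    tpm <- pmax(exp(Y) - 1, 0)
    layers[[al]] <- expression_layer(lnames[al], tpm, gids, sample_ids,
                                     donors[donor_idx])
  }
  truth <- data.frame(gene = rep(gids, times = L),
                      layer = rep(lnames, each = n),
                      block = 0L, stringsAsFactors = FALSE)
  for (al in seq_len(L)) {
    idx <- (al - 1L) * n + seq_len(n)
    bl <- blocks
    if (!is.na(spec_b) && al != params$specialist_layer) bl[bl == spec_b] <- 0L
    truth$block[idx] <- bl
  }
  structure(list(layers = layers, truth = truth, params = params, seed = seed,
                 target_rho = target_rho,
                 gene_blocks = blocks),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %d genes x %d layers, seed %d\n",
              x$params$n_genes, x$params$n_layers, x$seed))
  invisible(x)
}

#' Planted gene coordinates on synthetic chromosomes
#'
#' Places genes uniformly on a set of synthetic chromosomes, except for
#' designated clustered groups which receive consecutive tight intervals
#' (small fixed gaps) on a single chromosome.
#'
#' @param gene_ids character vector of genes to place.
#' @param seed integer seed.
#' @param n_chrom number of synthetic chromosomes.
#' @param chrom_length chromosome length in bp.
#' @param gene_length gene body length in bp.
#' @param clustered named list: element names are chromosome labels, values
#'   are character vectors of gene ids to cluster there.
#' @param cluster_gap gap in bp between consecutive clustered genes.
#' @return a [gene_loci()] table with an extra logical column `clustered`.
#' @export
planted_gene_loci <- function(gene_ids, seed = 1L, n_chrom = 10L,
                              chrom_length = 1e8, gene_length = 1e4,
                              clustered = list(), cluster_gap = 1e3) {
  set.seed(seed)
  gene_ids <- as.character(gene_ids)
  chroms <- as.character(seq_len(n_chrom))
  clustered_genes <- unlist(clustered, use.names = FALSE)
  if (length(setdiff(clustered_genes, gene_ids)))
    stop_mlcoex("clustered genes must be among gene_ids")
  chr <- sample(chroms, length(gene_ids), replace = TRUE)
  start <- floor(stats::runif(length(gene_ids), 1, chrom_length - gene_length))
  names(chr) <- names(start) <- gene_ids
  for (k in names(clustered)) {
    gs <- clustered[[k]]
    anchor <- floor(stats::runif(1, chrom_length * 0.25, chrom_length * 0.5))
    for (q in seq_along(gs)) {
      chr[gs[q]] <- k
      start[gs[q]] <- anchor + (q - 1L) * (gene_length + cluster_gap)
    }
  }
  loci <- gene_loci(gene_ids, chr, start, start + gene_length - 1)
  loci$clustered <- loci$gene_id %in% clustered_genes
  loci
}

#' Toy eQTL association table with planted shared variants
#'
#' Assigns each gene a small random set of private variants and plants
#' overlapping variant sets for designated gene pairs.
#'
#' @param gene_ids character vector of genes.
#' @param seed integer seed.
#' @param shared_pairs list of character 2-vectors of genes that must share
#'   variants.
#' @param n_shared number of shared variants per planted pair.
#' @param max_private maximum private variants per gene (uniform on
#'   0..max_private).
#' @return data.frame with `gene_id`, `variant_id`, `pval_nominal`.
#' @export
toy_eqtl_table <- function(gene_ids, seed = 1L, shared_pairs = list(),
                           n_shared = 2L, max_private = 3L) {
  set.seed(seed)
  rows <- list()
  vc <- 0L
  new_variants <- function(k) {
    ids <- sprintf("rsS%06d", vc + seq_len(k))
    vc <<- vc + k
    ids
  }
  for (g in gene_ids) {
    k <- sample.int(max_private + 1L, 1L) - 1L
    if (k > 0L)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, variant_id = new_variants(k),
        pval_nominal = stats::runif(k, 1e-12, 1e-5))
  }
  for (pr in shared_pairs) {
    v <- new_variants(n_shared)
    for (g in pr)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = g, variant_id = v,
        pval_nominal = stats::runif(n_shared, 1e-12, 1e-5))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Planted-truth labels for recovery scoring
#'
#' Returns the planted partition over supra nodes (layer-major order) for a
#' synthetic dataset: generalist blocks keep one label across all layers, the
#' specialist block is labelled in its home layer, and all remaining nodes
#' carry the background label 0. Recovery is scored on planted
#' (non-background) nodes; see [recovery_ari()].
#'
#' @param sd_obj a `synthetic_dataset`.
#' @return integer vector of planted labels (0 = background).
#' @export
truth_partition <- function(sd_obj) {
  stopifnot(inherits(sd_obj, "synthetic_dataset"))
  sd_obj$truth$block
}

#' Adjusted Rand index of a detected partition against the planted truth
#'
#' @param partition detected labels over supra nodes (layer-major order).
#' @param sd_obj a `synthetic_dataset`.
#' @param planted_only score only nodes with a planted (non-background) label
#'   (default TRUE); background nodes have no ground-truth community.
#' @return adjusted Rand index.
#' @export
recovery_ari <- function(partition, sd_obj, planted_only = TRUE) {
  tr <- truth_partition(sd_obj)
  if (length(partition) != length(tr))
    stop_mlcoex("partition length does not match the dataset's node count")
  keep <- if (planted_only) tr != 0L else rep(TRUE, length(tr))
  adjusted_rand_index(partition[keep], tr[keep])
}
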