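#' Specialist fraction of a multilayer community
#'
#' Counts, per layer, the genes present in exactly one layer within the
#' community; the layer with the most unique genes is the specialist tissue,
#' and the specialist fraction is its unique-gene count divided by the total
#' number of (gene, layer) nodes in the community. A community confined to a
#' single layer has fraction 1; a community in which every gene appears in at
#' least two layers has fraction 0 (and no specialist tissue).
#'
#' @param community data.frame of (gene, layer) nodes, e.g. [ml_community()].
#' @return list with `fraction`, `tissue` (`NA` when no gene is unique; the
#'   lexicographically first on ties, all tied layers in `tied`),
#'   `unique_counts` (named per-layer counts), `n_nodes`, `n_genes`.
#' @export
specialist_fraction <- function(community) {
  stopifnot(nrow(community) >= 1L)
  layers_per_gene <- tapply(community$layer, community$gene,
                            function(x) length(unique(x)))
  uniq <- community[community$gene %in%
                      names(layers_per_gene)[layers_per_gene == 1L], ]
  counts <- table(factor(uniq$layer, levels = sort(unique(community$layer))))
  counts <- stats::setNames(as.integer(counts), names(counts))
  n_nodes <- nrow(community)
  if (all(counts == 0L)) {
    return(list(fraction = 0, tissue = NA_character_, tied = character(0),
                unique_counts = counts, n_nodes = n_nodes,
                n_genes = length(layers_per_gene)))
  }
  best <- max(counts)
  tied <- sort(names(counts)[counts == best])
  list(fraction = best / n_nodes, tissue = tied[1L], tied = tied,
       unique_counts = counts, n_nodes = n_nodes,
       n_genes = length(layers_per_gene))
}

#' Classify a community as specialist or generalist
#'
#' Specialist iff the specialist fraction strictly exceeds the threshold.
#'
#' @param fraction specialist fraction in `[0, 1]`.
#' @param threshold classification threshold (default 0.5).
#' @return `"specialist"` or `"generalist"`.
#' @export
classify_community <- function(fraction, threshold = 0.5) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (fraction > threshold) "specialist" else "generalist"
}

#' Gene set of a community for downstream genomic analyses
#'
#' Specialist communities contribute all their distinct genes; generalist
#' communities are restricted to genes present in at least `min_layers`
#' layers within the community, so that the retained genes plausibly carry
#' the cross-tissue function the community represents.
#'
#' @param community data.frame of (gene, layer) nodes.
#' @param klass `"specialist"` or `"generalist"`.
#' @param min_layers layer-presence cutoff for generalist communities.
#' @return character vector of gene ids.
#' @export
community_gene_set <- function(community, klass, min_layers = 3L) {
  klass <- match.arg(klass, c("specialist", "generalist"))
  if (klass == "specialist") return(sort(unique(community$gene)))
  nl <- tapply(community$layer, community$gene,
               function(x) length(unique(x)))
  sort(names(nl)[nl >= min_layers])
}

#' Construct a gene locus table
#'
#' @param gene_id,chromosome,start,end equal-length vectors; positions are
#'   1-based inclusive with `end >= start >= 1`. Chromosome labels are
#'   normalized by stripping a "chr" prefix; "MT" is folded into "M".
#' @return data.frame of class `gene_loci`.
#' @export
gene_loci <- function(gene_id, chromosome, start, end) {
  chromosome <- sub("^chr", "", as.character(chromosome))
  chromosome[chromosome == "MT"] <- "M"
  df <- data.frame(gene_id = as.character(gene_id), chromosome = chromosome,
                   start = as.numeric(start), end = as.numeric(end),
                   stringsAsFactors = FALSE)
  if (any(df$start < 1) || any(df$end < df$start))
    stop_mlcoex("loci must satisfy 1 <= start <= end")
  if (anyDuplicated(df$gene_id)) stop_mlcoex("duplicate gene ids in loci")
  class(df) <- c("gene_loci", "data.frame")
  df
}

#' Genomic gap between two gene loci
#'
#' Distance in base pairs between the end of the earlier gene and the start
#' of the later gene on the same chromosome. Overlapping genes give 0 (the
#' gap is never negative); genes on different chromosomes give `NA`
#' (undefined).
#'
#' @param a,b single-row entries of a [gene_loci()] table (or lists with
#'   `chromosome`, `start`, `end`).
#' @return numeric distance in bp, or `NA`.
#' @export
gene_distance <- function(a, b) {
  if (a$chromosome != b$chromosome) return(NA_real_)
  if (a$start > b$start) { tmp <- a; a <- b; b <- tmp }
  max(0, b$start - a$end)
}

# pairwise gap matrix restricted to one chromosome's loci (vectorized)
chrom_gap_sum <- function(starts, ends) {
  n <- length(starts)
  ord <- order(starts, ends)
  s <- starts[ord]; e <- ends[ord]
  tot <- 0
  for (i in seq_len(n - 1L))
    tot <- tot + sum(pmax(0, s[(i + 1L):n] - e[i]))
  tot
}

#' Fraction of gene pairs on the same chromosome
#'
#' @param genes character vector (n >= 2) of gene ids.
#' @param loci a [gene_loci()] table covering the genes.
#' @return fraction of the n(n-1)/2 pairs sharing a chromosome.
#' @export
same_chromosome_fraction <- function(genes, loci) {
  n <- length(genes)
  if (n < 2L) stop_mlcoex("need at least two genes")
  chr <- loci$chromosome[match(genes, loci$gene_id)]
  if (anyNA(chr)) stop_mlcoex("genes missing from loci")
  cnt <- table(chr)
  sum(cnt * (cnt - 1) / 2) / (n * (n - 1) / 2)
}

# mean same-chromosome pair gap for a set of loci rows; NA if no such pair
mean_pair_distance <- function(sub) {
  tot <- 0
  npair <- 0
  for (k in unique(sub$chromosome)) {
    rows <- sub[sub$chromosome == k, , drop = FALSE]
    nk <- nrow(rows)
    if (nk >= 2L) {
      tot <- tot + chrom_gap_sum(rows$start, rows$end)
      npair <- npair + nk * (nk - 1) / 2
    }
  }
  if (npair == 0) NA_real_ else tot / npair
}

#' Chromosomal localization permutation tests for a gene group
#'
#' Three randomization tests against a background gene set: (1) is the
#' fraction of same-chromosome pairs larger than expected when chromosome
#' labels are shuffled across the background (Z for x_c, one-sided upper)?
#' (2) preserving the group's per-chromosome counts, is the average
#' same-chromosome gap smaller than for genes drawn uniformly per chromosome
#' (Z for d_c, one-sided lower)? (3) per chromosome carrying at least
#' `min_genes_per_chrom` group genes, is the average gap on that chromosome
#' smaller than for a uniform draw, with Bonferroni correction over the
#' group's tested chromosomes? Both a normal-approximation p (from the Z
#' score) and the empirical permutation p are reported.
#'
#' @param genes character vector of gene ids (n >= 2), a subset of the
#'   background.
#' @param background a [gene_loci()] table of all candidate genes.
#' @param n_rand number of randomizations (default 100).
#' @param seed integer seed; results are bit-reproducible for a fixed seed.
#' @param min_genes_per_chrom minimum group genes on a chromosome for the
#'   per-chromosome test (default 3).
#' @param alpha significance level for the Bonferroni flag.
#' @return list of class `localization_result`: `n`, `x_c`, `z_x`, `p_x`,
#'   `d_c`, `z_d`, `p_d`, `per_chromosome` (data.frame), `n_rand`, `seed`.
#'   Z scores are `NA` (flagged via `degenerate`) when the randomization
#'   spread is zero.
#' @export
localization_tests <- function(genes, background, n_rand = 100L, seed = NULL,
                               min_genes_per_chrom = 3L, alpha = 0.05) {
  stopifnot(inherits(background, "data.frame"))
  genes <- as.character(genes)
  n <- length(genes)
  if (n < 2L) stop_mlcoex("need at least two genes")
  idx <- match(genes, background$gene_id)
  if (anyNA(idx)) stop_mlcoex("group genes must belong to the background")
  if (!is.null(seed)) set.seed(seed)
  sub <- background[idx, , drop = FALSE]
  npairs_tot <- n * (n - 1) / 2

  # test 1: same-chromosome pair fraction under label shuffling
  x_obs <- same_chromosome_fraction(genes, background)
  x_rand <- vapply(seq_len(n_rand), function(r) {
    chr <- sample(background$chromosome)
    cnt <- table(chr[idx])
    sum(cnt * (cnt - 1) / 2) / npairs_tot
  }, 0)
  z_x <- if (stats::sd(x_rand) == 0) NA_real_
         else (x_obs - mean(x_rand)) / stats::sd(x_rand)
  p_x <- if (is.na(z_x)) NA_real_ else stats::pnorm(z_x, lower.tail = FALSE)

  # test 2: average same-chromosome gap, per-chromosome counts preserved
  nk <- table(sub$chromosome)
  nk <- nk[nk >= 2L]
  d_obs <- mean_pair_distance(sub)
  d_rand <- rep(NA_real_, n_rand)
  if (length(nk) > 0L) {
    by_chrom <- lapply(names(nk), function(k)
      background[background$chromosome == k, , drop = FALSE])
    names(by_chrom) <- names(nk)
    for (k in names(nk))
      if (nrow(by_chrom[[k]]) < nk[[k]])
        stop_mlcoex("chromosome ", k, " has fewer background genes than the group")
    d_rand <- vapply(seq_len(n_rand), function(r) {
      tot <- 0; npair <- 0
      for (k in names(nk)) {
        pick <- by_chrom[[k]][sample.int(nrow(by_chrom[[k]]), nk[[k]]), ,
                              drop = FALSE]
        tot <- tot + chrom_gap_sum(pick$start, pick$end)
        npair <- npair + nk[[k]] * (nk[[k]] - 1) / 2
      }
      tot / npair
    }, 0)
  }
  z_d <- if (all(is.na(d_rand)) || is.na(d_obs) || stats::sd(d_rand) == 0)
    NA_real_ else (d_obs - mean(d_rand)) / stats::sd(d_rand)
  p_d <- if (is.na(z_d)) NA_real_ else stats::pnorm(z_d)

  # test 3: per-chromosome average gap
  per <- list()
  test_chroms <- names(nk)[nk[names(nk)] >= min_genes_per_chrom]
  for (k in test_chroms) {
    rows <- sub[sub$chromosome == k, , drop = FALSE]
    n_k <- nrow(rows)
    obs_k <- chrom_gap_sum(rows$start, rows$end) / (n_k * (n_k - 1) / 2)
    bg_k <- background[background$chromosome == k, , drop = FALSE]
    rand_k <- vapply(seq_len(n_rand), function(r) {
      pick <- bg_k[sample.int(nrow(bg_k), n_k), , drop = FALSE]
      chrom_gap_sum(pick$start, pick$end) / (n_k * (n_k - 1) / 2)
    }, 0)
    sdk <- stats::sd(rand_k)
    zk <- if (sdk == 0) NA_real_ else (obs_k - mean(rand_k)) / sdk
    per[[k]] <- data.frame(chromosome = k, n_k = n_k, d_tilde = obs_k,
                           z = zk,
                           p_normal = if (is.na(zk)) NA_real_ else stats::pnorm(zk),
                           p_empirical = mean(rand_k <= obs_k),
                           degenerate = sdk == 0)
  }
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(chromosome = character(0), n_k = integer(0),
               d_tilde = numeric(0), z = numeric(0), p_normal = numeric(0),
               p_empirical = numeric(0), degenerate = logical(0))
  if (nrow(per)) {
    per$p_bonferroni <- pmin(1, per$p_normal * nrow(per))
    per$significant <- !is.na(per$p_bonferroni) & per$p_bonferroni < alpha
  } else {
    per$p_bonferroni <- numeric(0)
    per$significant <- logical(0)
  }
  rownames(per) <- NULL
  structure(list(n = n, x_c = x_obs, z_x = z_x, p_x = p_x,
                 d_c = d_obs, z_d = z_d, p_d = p_d,
                 per_chromosome = per, n_rand = as.integer(n_rand),
                 seed = seed,
                 degenerate = c(x = is.na(z_x), d = is.na(z_d))),
            class = "localization_result")
}

#' @export
print.localization_result <- function(x, ...) {
  cat(sprintf("<localization_result> n = %d genes\n", x$n))
  cat(sprintf("  same-chromosome fraction x_c = %.4f, Z = %s (p = %s)\n",
              x$x_c, format(x$z_x, digits = 4), format(x$p_x, digits = 3)))
  cat(sprintf("  mean pair distance d_c = %s, Z = %s (p = %s)\n",
              format(x$d_c, digits = 6), format(x$z_d, digits = 4),
              format(x$p_d, digits = 3)))
  if (nrow(x$per_chromosome)) print(x$per_chromosome)
  invisible(x)
}

#' Co-expressed gene pairs sharing eQTL variants
#'
#' Among all unordered gene pairs whose layer co-expression exceeds `r_min`,
#' reports those whose associated-variant sets intersect, together with the
#' shared variants.
#'
#' @param rho_layer correlation matrix with gene ids as dimnames.
#' @param eqtl data.frame with columns `gene_id` and `variant_id` (rows
#'   assumed pre-filtered to significant associations).
#' @param r_min co-expression threshold (default 0.5, strict inequality).
#' @return data.frame with `gene_i`, `gene_j`, `r`, `shared_variants`
#'   (comma-separated) and `n_shared`, ordered by decreasing `r`.
#' @export
shared_eqtl_pairs <- function(rho_layer, eqtl, r_min = 0.5) {
  stopifnot(all(c("gene_id", "variant_id") %in% names(eqtl)))
  gids <- rownames(rho_layer)
  if (is.null(gids)) stop_mlcoex("rho_layer must carry gene ids")
  vsets <- split(as.character(eqtl$variant_id), as.character(eqtl$gene_id))
  cand <- which(rho_layer > r_min & upper.tri(rho_layer), arr.ind = TRUE)
  rows <- list()
  for (q in seq_len(nrow(cand))) {
    gi <- gids[cand[q, 1L]]
    gj <- gids[cand[q, 2L]]
    shared <- intersect(vsets[[gi]], vsets[[gj]])
    if (length(shared))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_i = gi, gene_j = gj, r = rho_layer[cand[q, 1L], cand[q, 2L]],
        shared_variants = paste(sort(shared), collapse = ","),
        n_shared = length(shared), stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_i = character(0), gene_j = character(0), r = numeric(0),
               shared_variants = character(0), n_shared = integer(0))
  out <- out[order(-out$r), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize every community of a partition
#'
#' Applies [specialist_fraction()] and [classify_community()] to each
#' community and reports the reusable gene set per [community_gene_set()].
#' Duplicate appearances of a gene across several generalist gene sets are
#' reported (not enforced away).
#'
#' @param partition label vector over supra nodes (layer-major order).
#' @param mlc a `multilayer_correlation`.
#' @param threshold specialist-fraction threshold.
#' @param min_layers generalist layer-presence cutoff.
#' @return list with `summary` (data.frame: community, n_nodes, n_genes,
#'   n_specialist, specialist_fraction, specialist_tissue, klass),
#'   `gene_sets` (list), `duplicated_generalist_genes`.
#' @export
community_summaries <- function(partition, mlc, threshold = 0.5,
                                min_layers = 3L) {
  nodes <- data.frame(gene = rep(mlc$gene_ids, times = length(mlc$layer_names)),
                      layer = rep(mlc$layer_names, each = length(mlc$gene_ids)),
                      stringsAsFactors = FALSE)
  comms <- partition_communities(partition, nodes)
  gene_sets <- list()
  rows <- lapply(seq_along(comms), function(c) {
    sf <- specialist_fraction(comms[[c]])
    klass <- classify_community(sf$fraction, threshold)
    gene_sets[[as.character(c)]] <<- community_gene_set(comms[[c]], klass,
                                                        min_layers)
    data.frame(community = c, n_nodes = sf$n_nodes, n_genes = sf$n_genes,
               n_specialist = if (is.na(sf$tissue)) 0L else
                 sf$unique_counts[[sf$tissue]],
               specialist_fraction = sf$fraction,
               specialist_tissue = sf$tissue, klass = klass,
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  gen_genes <- unlist(gene_sets[summary$klass == "generalist"], use.names = FALSE)
  dup <- sort(unique(gen_genes[duplicated(gen_genes)]))
  if (length(dup))
    message("gene(s) present in more than one generalist community gene set: ",
            paste(dup, collapse = ", "))
  list(summary = summary, gene_sets = gene_sets,
       duplicated_generalist_genes = dup)
}
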