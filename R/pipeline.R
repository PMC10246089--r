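#' Pipeline configuration
#'
#' Defaults mirror the study design: 75 top-variance genes per tissue, a
#' 15-point resolution grid on `[1, 4]`, 200 partitions for the final
#' consensus, 100 localization randomizations, specialist and co-expression
#' thresholds of 0.5, a 3-of-4-layer presence filter for generalist gene
#' sets, and at least 3 genes per chromosome for the per-chromosome test.
#'
#' @param top_k top-variance genes per layer (`NULL` to skip selection and
#'   use all common genes).
#' @param gamma_grid resolution sweep grid.
#' @param consensus_runs partitions fed to the final consensus.
#' @param n_rand localization randomization count.
#' @param seed master seed; stage seeds are derived deterministically.
#' @param specialist_threshold,coexpression_threshold,min_layers,min_genes_per_chrom
#'   thresholds as documented above.
#' @param gamma_pin optional explicit gamma values to pin inside the selected
#'   domains (see [select_gamma()]).
#' @return list of class `run_config`.
#' @export
run_config <- function(top_k = 75L, gamma_grid = seq(1, 4, length.out = 15),
                       consensus_runs = 200L, n_rand = 100L, seed = 1L,
                       specialist_threshold = 0.5,
                       coexpression_threshold = 0.5, min_layers = 3L,
                       min_genes_per_chrom = 3L, gamma_pin = NULL) {
  stopifnot(consensus_runs >= 2L, n_rand >= 1L,
            length(gamma_grid) >= 1L, !is.unsorted(gamma_grid))
  structure(list(top_k = top_k, gamma_grid = gamma_grid,
                 consensus_runs = as.integer(consensus_runs),
                 n_rand = as.integer(n_rand), seed = as.integer(seed),
                 specialist_threshold = specialist_threshold,
                 coexpression_threshold = coexpression_threshold,
                 min_layers = as.integer(min_layers),
                 min_genes_per_chrom = as.integer(min_genes_per_chrom),
                 gamma_pin = gamma_pin),
            class = "run_config")
}

# derived stage seeds: deterministic, well below 2^31
stage_seed <- function(config, stage) {
  (config$seed * 1000L + stage) %% 2000000011L
}

#' Run the full multilayer community detection pipeline
#'
#' Sequences gene selection, correlation-layer construction, null fitting,
#' the resolution sweep with envelope-based selection, consensus community
#' detection at the selected resolutions, significance scoring, community
#' classification, chromosomal localization, and shared-eQTL search, writing
#' every artifact plus a machine-readable manifest under `out_dir`.
#'
#' @param layers list of [expression_layer()] objects.
#' @param config a [run_config()].
#' @param out_dir output directory (created if missing).
#' @param loci optional [gene_loci()] background for localization.
#' @param eqtl optional eQTL table for shared-variant search (uses the first
#'   layer's correlation matrix by default; see `eqtl_layer`).
#' @param eqtl_layer layer name whose co-expression gates the eQTL search.
#' @param truth optional planted labels over supra nodes (0 = background) for
#'   recovery reporting in the manifest.
#' @return manifest list, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(layers, config = run_config(), out_dir,
                         loci = NULL, eqtl = NULL, eqtl_layer = NULL,
                         truth = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(...) message(format(Sys.time(), "%H:%M:%S"), " [", ..., "]")

  log_stage("select")
  genes <- if (is.null(config$top_k)) {
    sort(Reduce(intersect, lapply(layers, `[[`, "gene_ids")))
  } else {
    select_top_variance_genes(layers, config$top_k)$union
  }

  log_stage("correlate")
  mlc <- multilayer_from_layers(layers, genes, drop_zero_variance = TRUE)
  for (al in mlc$layer_names)
    write_matrix_tsv(mlc$rho[[al]],
                     file.path(out_dir, paste0("rho_", gsub("\\W", "_", al), ".tsv")))
  write_omega_tsv(mlc$omega, file.path(out_dir, "omega.tsv"))

  log_stage("fit-null")
  nulls <- lapply(mlc$layer_names, function(al) {
    r <- mlc$rho[[al]]
    attr(r, "layer_name") <- al
    fit_configuration_model(r)
  })
  names(nulls) <- mlc$layer_names
  for (al in mlc$layer_names) {
    write_matrix_tsv(nulls[[al]]$null_rho,
                     file.path(out_dir, paste0("null_", gsub("\\W", "_", al), ".tsv")))
    write_null_diagnostics(nulls[[al]],
                           file.path(out_dir, paste0("null_", gsub("\\W", "_", al), ".json")))
  }

  log_stage("sweep")
  sweep <- gamma_sweep(mlc, nulls, config$gamma_grid,
                       seed = stage_seed(config, 1L))
  supra1 <- build_supra_modularity(mlc, nulls, gamma = 1)
  sweep_tab <- data.frame(gamma = vapply(sweep, `[[`, 0, "gamma"),
                          Q = vapply(sweep, `[[`, 0, "Q"),
                          n_communities = vapply(sweep, function(s)
                            max(s$partition), 0L))
  utils::write.table(sweep_tab, file.path(out_dir, "sweep.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  log_stage("champ")
  lines <- lapply(sweep, function(s) partition_line(s$partition, mlc, nulls))
  domains <- champ_1d(lines, min(config$gamma_grid), max(config$gamma_grid))
  write_domains_json(domains, file.path(out_dir, "champ_domains.json"))
  selected <- select_gamma(domains, pin = config$gamma_pin)

  log_stage("detect")
  results <- list()
  for (q in seq_len(nrow(selected))) {
    g <- selected$gamma[q]
    supra <- build_supra_modularity(mlc, nulls, gamma = g)
    set.seed(stage_seed(config, 10L + q))
    runs <- lapply(seq_len(config$consensus_runs),
                   function(i) iterated_genlouvain(supra, method = "prob"))
    part <- consensus_partition(runs, supra)
    tag <- sprintf("gamma_%0.4g", g)
    write_partition_tsv(part, supra, file.path(out_dir,
                                               paste0("partition_", tag, ".tsv")))

    sig <- significance_table(part, mlc, nulls)
    utils::write.table(sig, file.path(out_dir, paste0("significance_", tag, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    cs <- community_summaries(part, mlc, config$specialist_threshold,
                              config$min_layers)
    utils::write.table(cs$summary,
                       file.path(out_dir, paste0("communities_", tag, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    loc <- NULL
    if (!is.null(loci)) {
      loc <- lapply(seq_len(nrow(cs$summary)), function(c) {
        gs <- cs$gene_sets[[as.character(c)]]
        gs <- intersect(gs, loci$gene_id)
        if (length(gs) < 2L) return(NULL)
        localization_tests(gs, loci, config$n_rand,
                           seed = stage_seed(config, 100L + 10L * q + c),
                           min_genes_per_chrom = config$min_genes_per_chrom)
      })
      loc_tab <- do.call(rbind, lapply(seq_along(loc), function(c) {
        if (is.null(loc[[c]])) return(NULL)
        data.frame(community = c, n = loc[[c]]$n, x_c = loc[[c]]$x_c,
                   z_x = loc[[c]]$z_x, d_c = loc[[c]]$d_c, z_d = loc[[c]]$z_d)
      }))
      if (!is.null(loc_tab))
        utils::write.table(loc_tab,
                           file.path(out_dir, paste0("localization_", tag, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    }
    results[[tag]] <- list(gamma = g, partition = part, significance = sig,
                           summaries = cs, localization = loc)
  }

  eqtl_pairs <- NULL
  if (!is.null(eqtl)) {
    log_stage("eqtl-pairs")
    lay <- eqtl_layer %||% mlc$layer_names[1L]
    eqtl_pairs <- shared_eqtl_pairs(mlc$rho[[lay]], eqtl,
                                    config$coexpression_threshold)
    utils::write.table(eqtl_pairs, file.path(out_dir, "shared_eqtl_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mlcoex")),
    seed = config$seed,
    stage_seeds = list(sweep = stage_seed(config, 1L)),
    n_genes = length(mlc$gene_ids), layers = mlc$layer_names,
    sample_counts = as.list(mlc$sample_counts),
    gamma_grid = config$gamma_grid,
    selected_gamma = selected$gamma,
    consensus_runs = config$consensus_runs,
    n_communities = lapply(results, function(r) max(r$partition)))
  if (!is.null(truth)) {
    first <- results[[1L]]$partition
    manifest$recovery_ari_planted <- adjusted_rand_index(
      first[truth != 0L], truth[truth != 0L])
    manifest$recovery_ari_all <- adjusted_rand_index(first, truth)
  }
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(list(mlc = mlc, nulls = nulls, sweep = sweep, domains = domains,
                   selected = selected, eqtl_pairs = eqtl_pairs,
                   manifest = manifest), results))
}
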