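#' Read an expression matrix (GCT 1.2 or TSV)
#'
#' GCT 1.2 files carry a `#1.2` version line, a dimensions line, and a body
#' whose first two columns are `Name` and `Description` followed by one
#' column per sample. Plain TSV files are genes (rows, first column = id) by
#' samples (columns). The sample attribute table maps samples to donors and
#' tissues.
#'
#' @param path expression file.
#' @param attributes sample attribute table: data.frame (or TSV path) with
#'   columns `sample_id`, `donor_id`, `tissue`.
#' @param layer_name tissue label; defaults to the (unique) tissue of the
#'   mapped samples.
#' @param format `"auto"` (sniff the `#1.2` header), `"gct"`, or `"tsv"`.
#' @return an [expression_layer()].
#' @export
read_expression <- function(path, attributes, layer_name = NULL,
                            format = c("auto", "gct", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, "#1.2")) "gct" else "tsv"
  }
  if (format == "gct") {
    header <- readLines(path, n = 2L)
    dims <- as.integer(strsplit(header[2L], "\t")[[1L]][1:2])
    body <- utils::read.delim(path, skip = 2L, check.names = FALSE,
                              stringsAsFactors = FALSE)
    if (nrow(body) != dims[1L] || ncol(body) - 2L != dims[2L])
      stop_mlcoex("GCT body (", nrow(body), " x ", ncol(body) - 2L,
                  ") does not match declared dimensions (", dims[1L], " x ",
                  dims[2L], ")")
    gene_ids <- as.character(body[[1L]])
    values <- as.matrix(body[, -(1:2), drop = FALSE])
  } else {
    body <- utils::read.delim(path, check.names = FALSE,
                              stringsAsFactors = FALSE)
    gene_ids <- as.character(body[[1L]])
    values <- as.matrix(body[, -1L, drop = FALSE])
  }
  if (anyDuplicated(gene_ids))
    stop_mlcoex("duplicate gene id: ",
                paste(unique(gene_ids[duplicated(gene_ids)]), collapse = ", "))
  storage.mode(values) <- "double"
  if (is.character(attributes)) attributes <- read_sample_attributes(attributes)
  stopifnot(all(c("sample_id", "donor_id", "tissue") %in% names(attributes)))
  idx <- match(colnames(values), attributes$sample_id)
  if (anyNA(idx))
    stop_mlcoex("unmapped sample(s): ",
                paste(colnames(values)[is.na(idx)], collapse = ", "))
  tissues <- unique(attributes$tissue[idx])
  layer_name <- layer_name %||% {
    if (length(tissues) != 1L)
      stop_mlcoex("samples map to several tissues; pass layer_name")
    tissues
  }
  expression_layer(layer_name, values, gene_ids, colnames(values),
                   attributes$donor_id[idx])
}

#' Read a sample attribute table
#' @param path TSV with columns `sample_id`, `donor_id`, `tissue`.
#' @return data.frame.
#' @export
read_sample_attributes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "donor_id", "tissue") %in% names(df)))
  df
}

#' Write an expression layer as GCT 1.2
#' @param layer an [expression_layer()].
#' @param path output file.
#' @export
write_gct <- function(layer, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("#1.2", paste(length(layer$gene_ids), length(layer$sample_ids),
                             sep = "\t")), con)
  body <- data.frame(Name = layer$gene_ids, Description = layer$gene_ids,
                     layer$values, check.names = FALSE)
  colnames(body) <- c("Name", "Description", layer$sample_ids)
  utils::write.table(body, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write/read a named numeric matrix as TSV (ids in the first column)
#' @param m matrix with dimnames.
#' @param path file path.
#' @return `read_matrix_tsv` returns the matrix.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("id", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- as.character(df[[1L]])
  m
}

#' Write interlayer couplings in long format
#' @param omega N x L x L array with dimnames.
#' @param path TSV path; columns gene, layer_a, layer_b, weight (a < b only).
#' @export
write_omega_tsv <- function(omega, path) {
  dn <- dimnames(omega)
  L <- dim(omega)[2L]
  rows <- list()
  if (L >= 2L) for (a in seq_len(L - 1L)) for (b in (a + 1L):L)
    rows[[length(rows) + 1L]] <- data.frame(gene = dn[[1L]],
                                            layer_a = dn[[2L]][a],
                                            layer_b = dn[[3L]][b],
                                            weight = omega[, a, b])
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write/read a partition as TSV (gene_id, layer, community)
#' @param partition labels over supra nodes.
#' @param nodes data.frame with `gene`, `layer` in node order (or a
#'   `supra_modularity`).
#' @param path TSV path.
#' @export
write_partition_tsv <- function(partition, nodes, path) {
  if (inherits(nodes, "supra_modularity")) nodes <- nodes$nodes
  utils::write.table(data.frame(gene_id = nodes$gene, layer = nodes$layer,
                                community = as.integer(partition)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_partition_tsv
#' @return `read_partition_tsv` returns a data.frame with columns `gene_id`,
#'   `layer`, `community`.
#' @export
read_partition_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read gene loci from a BED file
#'
#' BED is 0-based half-open; coordinates are converted to 1-based inclusive.
#' Chromosome names are normalized by stripping any "chr" prefix; "MT" is
#' folded into "M".
#'
#' @param path BED file (>= 4 columns: chrom, start, end, name).
#' @return a [gene_loci()] table.
#' @export
read_bed_loci <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm)) stop_mlcoex("BED file must carry gene names (column 4)")
  gene_loci(nm, as.character(GenomicRanges::seqnames(gr)),
            GenomicRanges::start(gr), GenomicRanges::end(gr))
}

#' Write gene loci as BED6
#' @param loci a [gene_loci()] table.
#' @param path output BED path.
#' @export
write_bed_loci <- function(loci, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chromosome,
    ranges = IRanges::IRanges(start = loci$start, end = loci$end),
    name = loci$gene_id, score = 0)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read an eQTL association table
#'
#' TSV in the single-tissue significant-pair layout: columns `gene_id`,
#' `variant_id`, optionally `pval_nominal` (rows assumed pre-filtered to
#' significant associations).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_eqtl <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "variant_id") %in% names(df)))
  df
}

#' Write fit diagnostics of a null layer as JSON
#' @param null a `null_layer`.
#' @param path JSON path.
#' @export
write_null_diagnostics <- function(null, path) {
  jsonlite::write_json(list(layer_name = null$layer_name,
                            residual = null$residual,
                            iterations = null$iterations,
                            logdet = null$logdet),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write CHAMP domains as JSON
#' @param domains a `gamma_domains`.
#' @param path JSON path.
#' @export
write_domains_json <- function(domains, path) {
  jsonlite::write_json(domains$intervals, path, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
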