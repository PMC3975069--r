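#' Write / read a synthetic genome as FASTA
#' @param genome a [synthetic_genome()].
#' @param path file path.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  synthetic_genome(stats::setNames(as.character(ss), names(ss)))
}

#' Write gene models as BED12 plus a feature sidecar TSV
#'
#' BED12 holds the structure (0-based half-open, blocks = exons, score 0,
#' thick range unused); the sidecar, keyed by gene id, carries
#' `gene_class`, the planted-feature annotations and the exonic length.
#' The strand-aware TSS is recoverable from the BED interval (start on +,
#' end - 1 on -).
#'
#' @param genes gene models.
#' @param bed_path,sidecar_path output files.
#' @export
write_gene_models <- function(genes, bed_path, sidecar_path) {
  n <- nrow(genes)
  start <- vapply(genes$exon_starts, function(s) min(s), numeric(1))
  end <- vapply(genes$exon_ends, function(e) max(e), numeric(1))
  sizes <- vapply(seq_len(n), function(i)
    paste(genes$exon_ends[[i]] - genes$exon_starts[[i]], collapse = ","),
    character(1))
  rel <- vapply(seq_len(n), function(i)
    paste(genes$exon_starts[[i]] - start[i], collapse = ","), character(1))
  bed <- data.frame(
    chrom = genes$chrom, start = as.integer(start), end = as.integer(end),
    name = genes$gene_id, score = 0L, strand = genes$strand,
    thickStart = as.integer(start), thickEnd = as.integer(start),
    itemRgb = "0",
    blockCount = vapply(genes$exon_starts, length, integer(1)),
    blockSizes = sizes, blockStarts = rel, stringsAsFactors = FALSE)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  side <- data.frame(
    gene_id = genes$gene_id,
    gene_class = genes$gene_class,
    promoter_gc = genes$promoter_gc,
    exonic_gc = genes$exonic_gc,
    tss_t_run = genes$tss_t_run,
    antisense_site_offsets = vapply(genes$antisense_site_offsets,
                                    paste, character(1), collapse = ","),
    exonic_length = as.integer(exonic_length(genes)),
    stringsAsFactors = FALSE)
  utils::write.table(side, sidecar_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(bed_path)
}

#' @rdname write_gene_models
#' @export
read_gene_models <- function(bed_path, sidecar_path) {
  bed <- utils::read.table(bed_path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand", "thickStart",
                                         "thickEnd", "itemRgb", "blockCount",
                                         "blockSizes", "blockStarts"))
  side <- utils::read.table(sidecar_path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  n <- nrow(bed)
  exon_starts <- vector("list", n)
  exon_ends <- vector("list", n)
  for (i in seq_len(n)) {
    sizes <- as.integer(strsplit(bed$blockSizes[i], ",")[[1]])
    rel <- as.integer(strsplit(bed$blockStarts[i], ",")[[1]])
    if (length(sizes) != bed$blockCount[i] || length(rel) != bed$blockCount[i])
      stop("malformed BED12 blocks at line ", i)
    st <- bed$start[i] + rel
    en <- st + sizes
    if (is.unsorted(st, strictly = TRUE) || any(st[-1] < en[-length(en)]))
      stop("overlapping or unsorted exons at line ", i)
    if (min(st) != bed$start[i] || max(en) != bed$end[i])
      stop("blocks do not span the BED interval at line ", i)
    exon_starts[[i]] <- st
    exon_ends[[i]] <- en
  }
  genes <- data.frame(
    gene_id = bed$name, chrom = bed$chrom, strand = bed$strand,
    tss = ifelse(bed$strand == "+", bed$start, bed$end - 1L),
    stringsAsFactors = FALSE)
  genes$gene_class <- side$gene_class[match(genes$gene_id, side$gene_id)]
  if (anyNA(genes$gene_class)) stop("sidecar missing gene ids")
  genes$exon_starts <- exon_starts
  genes$exon_ends <- exon_ends
  m <- match(genes$gene_id, side$gene_id)
  genes$promoter_gc <- side$promoter_gc[m]
  genes$exonic_gc <- side$exonic_gc[m]
  genes$antisense_site_offsets <- lapply(side$antisense_site_offsets[m],
    function(s) if (is.na(s) || s == "") integer(0)
                else as.integer(strsplit(as.character(s), ",")[[1]]))
  genes$tss_t_run <- as.integer(side$tss_t_run[m])
  class(genes) <- c("gene_models", "data.frame")
  genes
}

#' Write / read a CTSS table as BED6
#'
#' One record per 1-bp position (`chrom pos pos+1 ctss count strand`),
#' sorted by (chrom, pos, strand). The reader sorts unsorted input and
#' rejects duplicate keys.
#'
#' @param ctss a `ctss_table`.
#' @param path file path.
#' @export
write_ctss <- function(ctss, path) {
  tab <- as.data.frame(ctss)
  tab <- tab[order(tab$chrom, tab$pos, tab$strand), , drop = FALSE]
  bed <- data.frame(tab$chrom, tab$pos, tab$pos + 1L,
                    rep_len("ctss", nrow(tab)), tab$count, tab$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_ctss
#' @export
read_ctss <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand"))
  if (nrow(bed) && any(bed$end != bed$start + 1L))
    stop("CTSS records must be 1-bp intervals")
  tab <- data.frame(chrom = bed$chrom, pos = bed$start, strand = bed$strand,
                    count = as.integer(bed$score), stringsAsFactors = FALSE)
  tab <- tab[order(tab$chrom, tab$pos, tab$strand), , drop = FALSE]
  key <- paste(tab$chrom, tab$pos, tab$strand)
  if (anyDuplicated(key)) stop("duplicate CTSS key in ", path)
  if (nrow(tab) && any(tab$count < 1)) stop("CTSS counts must be positive")
  rownames(tab) <- NULL
  structure(tab, class = c("ctss_table", "data.frame"), rrna_count = 0L)
}

#' Write / read a count matrix as TSV with a library-size header
#'
#' The first line is `#library_sizes` followed by one value per sample;
#' a missing header makes the reader fall back to column sums with a
#' warning. Gene lengths travel in the gene-model sidecar, not here.
#'
#' @param counts a [count_matrix()].
#' @param path file path.
#' @export
write_counts <- function(counts, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("#library_sizes", counts$lib_sizes), collapse = "\t"), con)
  tab <- data.frame(gene_id = rownames(counts$counts), counts$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @param gene_lengths optional named lengths to attach.
#' @export
read_counts <- function(path, gene_lengths = NULL) {
  first <- readLines(path, n = 1)
  has_header <- startsWith(first, "#library_sizes")
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           skip = if (has_header) 1 else 0,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  storage.mode(m) <- "integer"
  if (has_header) {
    lib <- as.numeric(strsplit(first, "\t")[[1]][-1])
  } else {
    warning("no #library_sizes header; inferring from column sums")
    lib <- colSums(m)
  }
  count_matrix(m, lib_sizes = lib, gene_lengths = gene_lengths)
}

#' Read / write a run configuration as YAML
#'
#' A run configuration fully determines a simulation run: it must carry an
#' integer `seed`; all other keys are free-form module settings.
#'
#' @param path YAML file.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) stop("run config must name a seed")
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

#' @rdname read_run_config
#' @param config named list including `seed`.
#' @export
write_run_config <- function(config, path) {
  if (is.null(config$seed)) stop("run config must name a seed")
  yaml::write_yaml(config, path)
  invisible(path)
}
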