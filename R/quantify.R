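#' Gene-by-sample count matrix container
#'
#' @param counts integer matrix, genes x samples (dimnames required).
#' @param lib_sizes per-sample library sizes (total mapped reads); defaults
#'   to column sums.
#' @param gene_lengths optional per-gene exonic lengths in bp (needed for
#'   RPKM).
#' @export
count_matrix <- function(counts, lib_sizes = colSums(counts),
                         gene_lengths = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene and sample dimnames")
  if (any(counts < 0)) stop("counts must be nonnegative")
  lib_sizes <- stats::setNames(as.numeric(lib_sizes), colnames(counts))
  if (any(lib_sizes < apply(counts, 2, max)))
    stop("library sizes smaller than largest count")
  if (!is.null(gene_lengths)) {
    gene_lengths <- gene_lengths[rownames(counts)]
    if (any(is.na(gene_lengths)) || any(gene_lengths <= 0))
      stop("gene_lengths must be positive for every gene")
  }
  structure(list(counts = counts, lib_sizes = lib_sizes,
                 gene_lengths = gene_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("library sizes:", paste(signif(x$lib_sizes, 4), collapse = " "), "\n")
  invisible(x)
}

#' Collapse a CAGE read set to a CTSS table
#'
#' Exact aggregation of tag 5' ends by (chromosome, position, strand) at
#' 1-bp resolution. Ribosomal-labelled tags are excluded from the table and
#' reported in the `rrna_count` attribute, so
#' `sum(count) + rrna_count == nrow(reads)`.
#'
#' @param reads a CAGE `read_set`.
#' @return a `ctss_table` data frame (`chrom`, `pos`, `strand`, `count`),
#'   sorted by (chrom, pos, strand), with attribute `rrna_count`.
#' @export
count_ctss <- function(reads) {
  if (!identical(read_type(reads), "cage"))
    stop("count_ctss() requires CAGE-type reads")
  rr <- reads$origin_gene == "rrna"
  x <- reads[!rr, , drop = FALSE]
  if (nrow(x) == 0) {
    tab <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), count = integer(0),
                      stringsAsFactors = FALSE)
  } else {
    agg <- stats::aggregate(list(count = rep(1L, nrow(x))),
                            by = list(chrom = x$chrom, pos = x$pos5,
                                      strand = x$strand), FUN = sum)
    tab <- agg[order(agg$chrom, agg$pos, agg$strand), , drop = FALSE]
    tab$count <- as.integer(tab$count)
    rownames(tab) <- NULL
  }
  structure(tab, class = c("ctss_table", "data.frame"),
            rrna_count = sum(rr))
}

## nearest same-strand TSS for positions on one (chrom, strand); returns
## data.frame(gene, dist). Ties at equal distance go to the smallest
## gene_id (duplicated TSS values collapse to their smallest id first).
nearest_tss <- function(pos, tss, gene_id) {
  o <- order(tss, gene_id)
  tss <- tss[o]; gene_id <- gene_id[o]
  first <- !duplicated(tss)
  utss <- tss[first]; uid <- gene_id[first]    # min id per distinct TSS
  k <- findInterval(pos, utss)
  left <- ifelse(k >= 1, utss[pmax(k, 1)], NA_integer_)
  right <- ifelse(k < length(utss), utss[pmin(k + 1, length(utss))], NA_integer_)
  dl <- abs(pos - left); dr <- abs(right - pos)
  dl[is.na(dl)] <- Inf; dr[is.na(dr)] <- Inf
  use_left <- dl < dr | (dl == dr & !is.na(left) & !is.na(right) &
                           uid[pmax(k, 1)] <= uid[pmin(k + 1, length(utss))])
  gene <- ifelse(use_left, uid[pmax(k, 1)], uid[pmin(pmax(k + 1, 1), length(utss))])
  dist <- pmin(dl, dr)
  data.frame(gene = gene, dist = dist, stringsAsFactors = FALSE)
}

#' Gene-level CAGE counts by promoter-window assignment
#'
#' A CTSS position contributes to a gene iff it lies on the same strand
#' within `window` bp (inclusive both sides) of the gene's TSS; a position
#' inside several windows is assigned to the nearest TSS, with distance
#' ties broken toward the lexicographically smallest gene id.
#'
#' @param ctss a `ctss_table`, or a named list of them (one per sample).
#' @param genes gene models.
#' @param window half-width of the TSS window in bp (default 500, the
#'   distance at which the capture curve saturates).
#' @return a [count_matrix()] whose library sizes are the total (non-rRNA)
#'   tags per sample, with attribute `unassigned` (tags outside every
#'   window, per sample).
#' @export
gene_counts_cage <- function(ctss, genes, window = 500) {
  if (window <= 0) stop("window must be > 0")
  if (nrow(genes) == 0) stop("empty gene set")
  if (inherits(ctss, "ctss_table")) ctss <- list(sample = ctss)
  samples <- names(ctss)
  m <- matrix(0L, nrow(genes), length(samples),
              dimnames = list(genes$gene_id, samples))
  unassigned <- stats::setNames(numeric(length(samples)), samples)
  lib <- stats::setNames(numeric(length(samples)), samples)
  for (s in seq_along(samples)) {
    tab <- ctss[[s]]
    lib[s] <- sum(tab$count)
    if (nrow(tab) == 0) next
    key <- paste(tab$chrom, tab$strand)
    for (grp in unique(key)) {
      rows <- which(key == grp)
      gsel <- genes$chrom == tab$chrom[rows[1]] & genes$strand == tab$strand[rows[1]]
      if (!any(gsel)) {
        unassigned[s] <- unassigned[s] + sum(tab$count[rows])
        next
      }
      nn <- nearest_tss(tab$pos[rows], genes$tss[gsel], genes$gene_id[gsel])
      inwin <- nn$dist <= window
      hit <- rows[inwin]
      if (length(hit)) {
        add <- tapply(tab$count[hit], nn$gene[inwin], sum)
        m[names(add), s] <- m[names(add), s] + as.integer(add)
      }
      unassigned[s] <- unassigned[s] + sum(tab$count[rows[!inwin]])
    }
  }
  cm <- count_matrix(m, lib_sizes = lib,
                     gene_lengths = stats::setNames(exonic_length(genes),
                                                    genes$gene_id))
  attr(cm, "unassigned") <- unassigned
  cm
}

#' Gene-level RNA-seq counts by exon overlap
#'
#' A fragment counts for a gene iff its genomic interval overlaps any exon
#' of the gene by at least 1 bp, irrespective of strand (set
#' `stranded = TRUE` for strict same-strand counting). A fragment
#' overlapping several genes is assigned by smallest distance between the
#' fragment start and the nearest exon start, then smallest gene id.
#' Ribosomal-labelled fragments are excluded and counted separately.
#'
#' @param reads an RNA-seq `read_set`, or a named list of them.
#' @param genes gene models.
#' @param stranded require matching strand (default FALSE).
#' @return a [count_matrix()]; attribute `unassigned` counts fragments
#'   overlapping no exon.
#' @export
gene_counts_rnaseq <- function(reads, genes, stranded = FALSE) {
  if (inherits(reads, "read_set")) reads <- list(sample = reads)
  if (nrow(genes) == 0) stop("empty gene set")
  samples <- names(reads)
  exdf <- exon_table(genes)
  m <- matrix(0L, nrow(genes), length(samples),
              dimnames = list(genes$gene_id, samples))
  unassigned <- stats::setNames(numeric(length(samples)), samples)
  lib <- stats::setNames(numeric(length(samples)), samples)
  for (s in seq_along(samples)) {
    rs <- reads[[s]]
    if (!identical(read_type(rs), "rnaseq"))
      stop("gene_counts_rnaseq() requires fragment-type reads")
    rs <- rs[rs$origin_gene != "rrna", , drop = FALSE]
    lib[s] <- nrow(rs)
    if (nrow(rs) == 0) next
    assigned <- assign_fragments(rs, exdf, stranded)
    hit <- !is.na(assigned)
    if (any(hit)) {
      add <- table(assigned[hit])
      m[names(add), s] <- m[names(add), s] + as.integer(add)
    }
    unassigned[s] <- sum(!hit)
  }
  cm <- count_matrix(m, lib_sizes = lib,
                     gene_lengths = stats::setNames(exonic_length(genes),
                                                    genes$gene_id))
  attr(cm, "unassigned") <- unassigned
  cm
}

exon_table <- function(genes) {
  n_ex <- vapply(genes$exon_starts, length, integer(1))
  data.frame(
    gene_id = rep(genes$gene_id, n_ex),
    chrom = rep(genes$chrom, n_ex),
    strand = rep(genes$strand, n_ex),
    start = unlist(genes$exon_starts),
    end = unlist(genes$exon_ends),
    stringsAsFactors = FALSE)
}

## per-fragment gene assignment (NA when no exon overlaps)
assign_fragments <- function(rs, exdf, stranded) {
  out <- rep(NA_character_, nrow(rs))
  groups <- if (stranded) paste(rs$chrom, rs$strand) else rs$chrom
  egroups <- if (stranded) paste(exdf$chrom, exdf$strand) else exdf$chrom
  for (grp in unique(groups)) {
    ri <- which(groups == grp)
    ei <- which(egroups == grp)
    if (length(ei) == 0) next
    q <- IRanges::IRanges(rs$frag_start[ri] + 1L, rs$frag_end[ri])
    subj <- IRanges::IRanges(exdf$start[ei] + 1L, exdf$end[ei])
    ov <- IRanges::findOverlaps(q, subj)
    if (length(ov) == 0) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    d <- abs(rs$frag_start[ri][qh] - exdf$start[ei][sh])
    gid <- exdf$gene_id[ei][sh]
    o <- order(qh, d, gid)
    first <- !duplicated(qh[o])
    out[ri[qh[o][first]]] <- gid[o][first]
  }
  out
}

#' Normalize a count matrix
#'
#' `tpm_tags` is tags per million mapped reads (count / library size x 1e6,
#' the CAGE normalization); `rpkm` additionally divides by exon-model
#' length in kb (the RNA-seq normalization).
#'
#' @param counts a [count_matrix()].
#' @param method `"tpm_tags"` or `"rpkm"`.
#' @return numeric matrix with the dimensions of the counts.
#' @export
normalize_counts <- function(counts, method = c("tpm_tags", "rpkm")) {
  method <- match.arg(method)
  if (any(counts$lib_sizes <= 0)) stop("library sizes must be > 0")
  tpm <- sweep(counts$counts, 2, counts$lib_sizes, "/") * 1e6
  if (method == "tpm_tags") return(tpm)
  if (is.null(counts$gene_lengths))
    stop("rpkm requested but gene lengths are absent")
  sweep(tpm, 1, counts$gene_lengths / 1000, "/")
}

#' Signal-quality metrics of a read set
#'
#' `promoter_rate` is the fraction of non-ribosomal reads that land inside
#' any gene's TSS window (CAGE) or overlap any exon (RNA-seq); `rrna_rate`
#' is the ribosomal fraction of all reads.
#'
#' @param reads a `read_set`.
#' @param genes gene models.
#' @param window TSS window half-width for CAGE reads.
#' @return list with `promoter_rate`, `rrna_rate`, `mapped_total`.
#' @export
signal_metrics <- function(reads, genes, window = 500) {
  if (nrow(reads) == 0) stop("signal metrics undefined for an empty read set")
  rr <- reads$origin_gene == "rrna"
  rrna_rate <- mean(rr)
  x <- reads[!rr, , drop = FALSE]
  if (nrow(x) == 0) {
    warning("all reads are ribosomal; promoter_rate reported as 0")
    return(list(promoter_rate = 0, rrna_rate = rrna_rate,
                mapped_total = nrow(reads)))
  }
  if (identical(read_type(reads), "cage")) {
    d <- read_tss_distance(x, genes)
    promoter_rate <- mean(d <= window)
  } else {
    exdf <- exon_table(genes)
    promoter_rate <- mean(!is.na(assign_fragments(x, exdf, stranded = FALSE)))
  }
  list(promoter_rate = promoter_rate, rrna_rate = rrna_rate,
       mapped_total = nrow(reads))
}

## distance from each read 5' end to the nearest same-strand TSS (Inf if
## that chrom/strand has no gene)
read_tss_distance <- function(reads, genes) {
  d <- rep(Inf, nrow(reads))
  key <- paste(reads$chrom, reads$strand)
  for (grp in unique(key)) {
    ri <- which(key == grp)
    gsel <- genes$chrom == reads$chrom[ri[1]] & genes$strand == reads$strand[ri[1]]
    if (!any(gsel)) next
    nn <- nearest_tss(reads$pos5[ri], genes$tss[gsel], genes$gene_id[gsel])
    d[ri] <- nn$dist
  }
  d
}

#' Cumulative capture fraction versus distance from annotated TSSs
#'
#' The curve whose saturation point motivates the 500-bp promoter window:
#' fraction of (non-ribosomal) CAGE tags within +/- d of the nearest
#' same-strand annotated TSS, for d = 0..max_dist.
#'
#' @param reads a CAGE `read_set`.
#' @param genes gene models.
#' @param max_dist maximum distance evaluated.
#' @return data frame (`distance`, `fraction`), monotone nondecreasing.
#' @export
tss_distance_profile <- function(reads, genes, max_dist = 1000) {
  if (!identical(read_type(reads), "cage"))
    stop("tss_distance_profile() requires CAGE-type reads")
  x <- reads[reads$origin_gene != "rrna", , drop = FALSE]
  if (nrow(x) == 0) stop("no non-ribosomal reads")
  d <- read_tss_distance(x, genes)
  dist <- 0:max_dist
  frac <- vapply(dist, function(k) mean(d <= k), numeric(1))
  data.frame(distance = dist, fraction = frac)
}
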