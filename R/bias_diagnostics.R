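## Shared helper: per-gene log2 ratio of two normalized profiles over genes
## detected (> 0) in both.
detected_log2_ratio <- function(expr_X, expr_Y, pseudocount) {
  if (!setequal(names(expr_X), names(expr_Y))) stop("mismatched gene sets")
  y <- expr_Y[names(expr_X)]
  keep <- expr_X > 0 & y > 0
  list(ratio = log2((expr_X[keep] + pseudocount) / (y[keep] + pseudocount)),
       genes = names(expr_X)[keep])
}

#' Relative expression stratified by GC content
#'
#' Splits genes detected in both profiles into equal-width GC bins over the
#' observed range and reports per-bin median and IQR of
#' `log2(X / Y)` (with pseudocount), plus the least-squares slope of the
#' per-gene log2 ratio on GC. A PCR-amplified platform shows a nonzero
#' slope against a PCR-free reference; identical profiles give all-zero
#' medians and slope 0.
#'
#' @param expr_X,expr_Y named normalized vectors (tags per million) over
#'   the same genes.
#' @param gc_per_gene named GC fractions (promoter GC for CAGE-vs-CAGE,
#'   exonic GC for comparisons against RNA-seq).
#' @param n_bins number of equal-width bins (>= 2, default 10).
#' @param pseudocount pseudocount for the ratio (default 0.5).
#' @return object of class `relative_expression_report`: list with `strata`
#'   (data frame: stratum, n_genes, median_log2_ratio, iqr), `slope`,
#'   `n_genes_used`.
#' @export
relative_expression_by_gc <- function(expr_X, expr_Y, gc_per_gene,
                                      n_bins = 10, pseudocount = 0.5) {
  if (n_bins < 2) stop("n_bins must be >= 2")
  lr <- detected_log2_ratio(expr_X, expr_Y, pseudocount)
  gc <- gc_per_gene[lr$genes]
  if (anyNA(gc)) stop("gc_per_gene missing for some detected genes")
  rng <- range(gc)
  if (rng[1] == rng[2]) rng <- rng + c(-1e-6, 1e-6)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- cut(gc, edges, include.lowest = TRUE)
  strata <- data.frame(
    stratum = levels(bin),
    n_genes = as.integer(table(bin)),
    median_log2_ratio = as.numeric(tapply(lr$ratio, bin, stats::median)),
    iqr = as.numeric(tapply(lr$ratio, bin, stats::IQR)),
    stringsAsFactors = FALSE)
  slope <- if (stats::sd(gc) == 0) 0 else
    unname(stats::coef(stats::lm(lr$ratio ~ gc))[2])
  structure(list(strata = strata, slope = slope,
                 n_genes_used = length(lr$ratio)),
            class = "relative_expression_report")
}

#' Classify genes by downstream antisense EcoP15I context
#'
#' Scans the sense-strand sequence downstream of each TSS for CTGCTG (an
#' EcoP15I recognition site CAGCAG on the antisense strand) and classifies
#' each gene by the minimal motif offset: `antisense_le_max` (within
#' `max_dist`), `antisense_gt_max` (present but farther, within the scan
#' range), or `none`. A TSS too close to the contig end for the full scan
#' is flagged in the `partial_scan` column.
#'
#' @param genes gene models.
#' @param genome a [synthetic_genome()].
#' @param max_dist class boundary in bp (default 400).
#' @param scan_range downstream extent scanned (default 800).
#' @return data frame: `gene_id`, `class`, `min_offset` (NA when none),
#'   `partial_scan`.
#' @export
scan_ecop15i_context <- function(genes, genome, max_dist = 400,
                                 scan_range = 800) {
  n <- nrow(genes)
  cls <- character(n); off <- rep(NA_integer_, n); partial <- logical(n)
  for (i in seq_len(n)) {
    win <- sense_window(genome, genes$chrom[i], genes$tss[i],
                        genes$strand[i], 0L, as.integer(scan_range) + 5L)
    partial[i] <- isTRUE(attr(win, "clipped"))
    hits <- motif_offsets(win, "CTGCTG")
    hits <- hits[hits <= scan_range]
    if (length(hits) == 0) {
      cls[i] <- "none"
    } else {
      off[i] <- min(hits)
      cls[i] <- if (off[i] <= max_dist) "antisense_le_max" else "antisense_gt_max"
    }
  }
  if (any(partial))
    warning(sum(partial), " gene(s) scanned partially (TSS near contig end)")
  data.frame(gene_id = genes$gene_id, class = cls, min_offset = off,
             partial_scan = partial, stringsAsFactors = FALSE)
}

#' Relative expression stratified by EcoP15I context class
#'
#' Median log2(X / Y) per context class, plus the difference between the
#' near-antisense-site class and the site-free class — the signature of
#' internal-site cleavage competition (an extra cleavage opportunity
#' inflates the tag yield of affected genes on the PCR tag platform).
#'
#' @param expr_X,expr_Y named normalized vectors over the same genes.
#' @param classes output of [scan_ecop15i_context()].
#' @param pseudocount pseudocount for the ratio.
#' @param min_n classes with fewer genes are flagged `low_n`.
#' @return object of class `relative_expression_report` with `strata`
#'   (stratum, n_genes, median_log2_ratio, iqr, low_n) and
#'   `le_max_minus_none` (difference of class medians).
#' @export
relative_expression_by_ecop15i <- function(expr_X, expr_Y, classes,
                                           pseudocount = 0.5, min_n = 10) {
  lr <- detected_log2_ratio(expr_X, expr_Y, pseudocount)
  cls <- classes$class[match(lr$genes, classes$gene_id)]
  if (anyNA(cls)) stop("classes missing for some detected genes")
  lev <- c("none", "antisense_le_max", "antisense_gt_max")
  cls <- factor(cls, levels = lev)
  strata <- data.frame(
    stratum = lev,
    n_genes = as.integer(table(cls)),
    median_log2_ratio = as.numeric(tapply(lr$ratio, cls, stats::median)),
    iqr = as.numeric(tapply(lr$ratio, cls, stats::IQR)),
    stringsAsFactors = FALSE)
  strata$low_n <- strata$n_genes < min_n
  diff <- strata$median_log2_ratio[strata$stratum == "antisense_le_max"] -
    strata$median_log2_ratio[strata$stratum == "none"]
  structure(list(strata = strata, le_max_minus_none = diff,
                 n_genes_used = length(lr$ratio)),
            class = "relative_expression_report")
}

ctss_tpm <- function(ctss) ctss$count / sum(ctss$count) * 1e6

#' Start-base-resolved activity ratio between two CTSS tables
#'
#' At 1-bp positions carrying at least `min_count` tags in both tables,
#' computes log2 ratios of tags-per-million-scaled activities (pseudocount
#' 0.5) and summarizes them by the genomic base at the position on the CTSS
#' strand. Linker first-base preference shows up as an elevated G median
#' and depressed C median.
#'
#' @param ctss_X,ctss_Y `ctss_table`s on the same genome.
#' @param genome a [synthetic_genome()].
#' @param min_count minimum raw count in both tables (default 5).
#' @param pseudocount pseudocount on the TPM scale.
#' @return list with `by_base` (data frame: base, n_positions,
#'   median_log2_ratio) and `positions` (per-position table). Disjoint
#'   position sets give an empty report with a warning.
#' @export
start_base_activity <- function(ctss_X, ctss_Y, genome, min_count = 5,
                                pseudocount = 0.5) {
  kx <- paste(ctss_X$chrom, ctss_X$pos, ctss_X$strand)
  ky <- paste(ctss_Y$chrom, ctss_Y$pos, ctss_Y$strand)
  i <- match(kx, ky)
  share <- !is.na(i) & ctss_X$count >= min_count &
    ctss_Y$count[ifelse(is.na(i), 1L, i)] >= min_count
  empty <- data.frame(base = BASES, n_positions = 0L,
                      median_log2_ratio = NA_real_, stringsAsFactors = FALSE)
  if (!any(share)) {
    warning("no shared positions at the requested count threshold")
    return(list(by_base = empty,
                positions = data.frame(chrom = character(0), pos = integer(0),
                                       strand = character(0), base = character(0),
                                       log2_ratio = numeric(0))))
  }
  xs <- ctss_X[share, , drop = FALSE]
  ys <- ctss_Y[i[share], , drop = FALSE]
  xv <- ctss_tpm(ctss_X)[share]
  yv <- ctss_tpm(ctss_Y)[i[share]]
  lr <- log2((xv + pseudocount) / (yv + pseudocount))
  base <- sense_base(genome, xs$chrom, xs$pos, xs$strand)
  f <- factor(base, levels = BASES)
  by_base <- data.frame(
    base = BASES,
    n_positions = as.integer(table(f)),
    median_log2_ratio = as.numeric(tapply(lr, f, stats::median)),
    stringsAsFactors = FALSE)
  list(by_base = by_base,
       positions = data.frame(chrom = xs$chrom, pos = xs$pos,
                              strand = xs$strand, base = base, log2_ratio = lr,
                              stringsAsFactors = FALSE))
}

#' Detect fill-and-lock T-stretch start shifts
#'
#' For every reference CTSS position with at least `min_count` tags whose
#' sense-strand sequence starting there is a T run of length
#' `L >= min_run`, the position is flagged shifted when the query table
#' puts at least `min_count` tags at the position L bases downstream
#' (strand-aware) and fewer than `min_count` at the run start itself.
#'
#' @param ctss_shifted query table (suspected of shifting).
#' @param ctss_reference reference table defining examined positions.
#' @param genome a [synthetic_genome()].
#' @param min_run minimal T-run length examined (default 4).
#' @param min_count count threshold (default 5).
#' @return object of class `tss_shift_report`: list with `sites` (data
#'   frame: chrom, pos, strand, run_length, count_reference,
#'   count_at_start, count_downstream, shifted), `n_shifted`, `n_examined`,
#'   `fraction`.
#' @export
detect_tstretch_shifts <- function(ctss_shifted, ctss_reference, genome,
                                   min_run = 4, min_count = 5) {
  ref <- ctss_reference[ctss_reference$count >= min_count, , drop = FALSE]
  n <- nrow(ref)
  run <- integer(n)
  for (i in seq_len(n)) {
    win <- sense_window(genome, ref$chrom[i], ref$pos[i], ref$strand[i],
                        0L, 30L)
    run[i] <- leading_t_run(win)
  }
  ex <- run >= min_run
  sites <- ref[ex, c("chrom", "pos", "strand", "count"), drop = FALSE]
  names(sites)[4] <- "count_reference"
  sites$run_length <- run[ex]
  key <- paste(ctss_shifted$chrom, ctss_shifted$pos, ctss_shifted$strand)
  lookup <- function(ch, p, s) {
    j <- match(paste(ch, p, s), key)
    ifelse(is.na(j), 0L, ctss_shifted$count[j])
  }
  sites$count_at_start <- lookup(sites$chrom, sites$pos, sites$strand)
  down <- downstream_pos(sites$pos, sites$strand, sites$run_length)
  sites$count_downstream <- lookup(sites$chrom, down, sites$strand)
  sites$shifted <- sites$count_downstream >= min_count &
    sites$count_at_start < min_count
  rownames(sites) <- NULL
  structure(list(sites = sites,
                 n_shifted = sum(sites$shifted),
                 n_examined = nrow(sites),
                 fraction = if (nrow(sites)) mean(sites$shifted) else NA_real_),
            class = "tss_shift_report")
}

#' @export
print.tss_shift_report <- function(x, ...) {
  cat(sprintf("T-stretch shifts: %d of %d examined T-run TSSs (%.2f%%)\n",
              x$n_shifted, x$n_examined, 100 * x$fraction))
  invisible(x)
}

#' Smooth a CTSS table by a centered moving average
#'
#' The smoothed count at position p is the mean of counts over
#' `[p - halfwidth, p + halfwidth]` on the same strand (absent positions
#' count as zero). Away from signal edges the total is conserved.
#'
#' @param ctss a `ctss_table`.
#' @param halfwidth window half-width (0 = identity).
#' @return data frame (`chrom`, `pos`, `strand`, `count`) with fractional
#'   counts; zero-valued positions are dropped.
#' @export
smooth_ctss <- function(ctss, halfwidth = 1) {
  if (halfwidth < 0) stop("halfwidth must be >= 0")
  if (halfwidth == 0 || nrow(ctss) == 0) {
    out <- as.data.frame(ctss)[, c("chrom", "pos", "strand", "count")]
    return(out)
  }
  offs <- (-halfwidth):halfwidth
  expanded <- data.frame(
    chrom = rep(ctss$chrom, each = length(offs)),
    pos = rep(ctss$pos, each = length(offs)) + offs,
    strand = rep(ctss$strand, each = length(offs)),
    count = rep(ctss$count, each = length(offs)) / (2 * halfwidth + 1),
    stringsAsFactors = FALSE)
  expanded <- expanded[expanded$pos >= 0, , drop = FALSE]
  agg <- stats::aggregate(count ~ chrom + pos + strand, expanded, sum)
  agg <- agg[order(agg$chrom, agg$pos, agg$strand), , drop = FALSE]
  rownames(agg) <- NULL
  agg[, c("chrom", "pos", "strand", "count")]
}

#' Single-base correlation before and after smoothing
#'
#' Spearman correlation over positions nonzero in both tables, computed on
#' the raw tables and again after 3-base (or wider) smoothing. When two
#' platforms disagree by 1-bp start jitter, smoothing recovers the
#' underlying agreement.
#'
#' @param ctss_X,ctss_Y `ctss_table`s.
#' @param halfwidth smoothing half-width (default 1, i.e. 3-base).
#' @return list with `rho_raw`, `rho_smoothed`, `n_raw`, `n_smoothed`.
#' @export
correlate_at_resolution <- function(ctss_X, ctss_Y, halfwidth = 1) {
  rho <- function(a, b) {
    ka <- paste(a$chrom, a$pos, a$strand)
    kb <- paste(b$chrom, b$pos, b$strand)
    i <- match(ka, kb)
    keep <- !is.na(i)
    if (sum(keep) < 3) return(list(rho = NA_real_, n = sum(keep)))
    list(rho = stats::cor(a$count[keep], b$count[i[keep]],
                          method = "spearman"),
         n = sum(keep))
  }
  raw <- rho(ctss_X, ctss_Y)
  sm <- rho(smooth_ctss(ctss_X, halfwidth), smooth_ctss(ctss_Y, halfwidth))
  list(rho_raw = raw$rho, rho_smoothed = sm$rho,
       n_raw = raw$n, n_smoothed = sm$n)
}

#' Platform-specific TSS discovery
#'
#' Candidate TSSs are positions with strictly more than `min_count` tags in
#' at least one table. A candidate is X-exclusive when it exceeds the
#' threshold in X but not in Y (symmetrically for Y); an exclusive position
#' is additionally "unneighbored" when the other table has no position with
#' at least `neighbor_count` tags within `neighborhood_bp` on the same
#' strand.
#'
#' @param ctss_X,ctss_Y `ctss_table`s.
#' @param min_count exclusivity threshold (default 10; strict `>`).
#' @param neighbor_count minimal neighbor support (default 3; `>=`).
#' @param neighborhood_bp neighborhood half-width (default 20).
#' @return list with data frames `x_only`, `y_only`, `shared`, and logical
#'   columns `unneighbored` on the exclusive sets; plus `n_candidates`.
#' @export
platform_specific_tss <- function(ctss_X, ctss_Y, min_count = 10,
                                  neighbor_count = 3, neighborhood_bp = 20) {
  stopifnot(min_count >= 1, neighbor_count >= 1, neighborhood_bp >= 0)
  kx <- paste(ctss_X$chrom, ctss_X$pos, ctss_X$strand)
  ky <- paste(ctss_Y$chrom, ctss_Y$pos, ctss_Y$strand)
  all_keys <- union(kx, ky)
  cx <- ctss_X$count[match(all_keys, kx)]; cx[is.na(cx)] <- 0L
  cy <- ctss_Y$count[match(all_keys, ky)]; cy[is.na(cy)] <- 0L
  parts <- do.call(rbind, strsplit(all_keys, " ", fixed = TRUE))
  pos_tab <- data.frame(chrom = parts[, 1], pos = as.integer(parts[, 2]),
                        strand = parts[, 3], count_X = cx, count_Y = cy,
                        stringsAsFactors = FALSE)
  cand <- pos_tab$count_X > min_count | pos_tab$count_Y > min_count
  pt <- pos_tab[cand, , drop = FALSE]
  x_only <- pt[pt$count_X > min_count & pt$count_Y <= min_count, , drop = FALSE]
  y_only <- pt[pt$count_Y > min_count & pt$count_X <= min_count, , drop = FALSE]
  shared <- pt[pt$count_X > min_count & pt$count_Y > min_count, , drop = FALSE]
  neighbored <- function(px, other) {
    if (nrow(px) == 0) return(logical(0))
    vapply(seq_len(nrow(px)), function(i) {
      sel <- other$chrom == px$chrom[i] & other$strand == px$strand[i] &
        abs(other$pos - px$pos[i]) <= neighborhood_bp &
        other$count >= neighbor_count
      any(sel)
    }, logical(1))
  }
  x_only$unneighbored <- !neighbored(x_only, ctss_Y)
  y_only$unneighbored <- !neighbored(y_only, ctss_X)
  rownames(x_only) <- rownames(y_only) <- rownames(shared) <- NULL
  list(x_only = x_only, y_only = y_only, shared = shared,
       n_candidates = nrow(pt))
}

#' Estimate the nontemplated 5' G-addition probability
#'
#' Measures the reverse-transcriptase G-addition rate from a simulated tag
#' set: restricted to TSSs where neither the strand-aware upstream genomic
#' base nor the start base itself is G (so a raw leading G can only be
#' nontemplated) and to tags aligned exactly at the annotated TSS, the
#' estimate is the fraction of tags whose raw leading base is G.
#'
#' @param reads a CAGE `read_set` with `raw_leading_base` recorded.
#' @param genes gene models.
#' @param genome a [synthetic_genome()].
#' @return list with `rate`, `n_tags`, `n_tss` (informative TSSs).
#' @export
estimate_g_addition <- function(reads, genes, genome) {
  up <- sense_base(genome, genes$chrom, genes$tss - ifelse(genes$strand == "+", 1L, -1L),
                   genes$strand)
  start <- sense_base(genome, genes$chrom, genes$tss, genes$strand)
  informative <- genes$gene_id[up != "G" & start != "G" &
                                 genes$gene_class != "rrna"]
  x <- reads[reads$origin_gene %in% informative, , drop = FALSE]
  at_tss <- x$pos5 == genes$tss[match(x$origin_gene, genes$gene_id)]
  x <- x[at_tss, , drop = FALSE]
  if (nrow(x) == 0) stop("no informative tags for G-addition estimation")
  list(rate = mean(x$raw_leading_base == "G"),
       n_tags = nrow(x), n_tss = length(informative))
}
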