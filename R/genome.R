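#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

comp_base <- function(x) chartr("ACGT", "TGCA", x)

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(comp_base(s), "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Construct a synthetic genome object
#'
#' A synthetic genome is a named list of chromosome sequences over the
#' alphabet ACGT, stored as plain character strings (0-based coordinates are
#' used everywhere in this package).
#'
#' @param chromosomes named character vector or list of sequences.
#' @return an object of class `synthetic_genome`.
#' @export
synthetic_genome <- function(chromosomes) {
  chromosomes <- as.list(chromosomes)
  if (is.null(names(chromosomes)) || any(names(chromosomes) == ""))
    stop("chromosomes must be named")
  bad <- vapply(chromosomes, function(s) grepl("[^ACGT]", s), logical(1))
  if (any(bad))
    stop("chromosome alphabet restricted to ACGT: ",
         paste(names(chromosomes)[bad], collapse = ", "))
  structure(chromosomes, class = "synthetic_genome")
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome with", length(x), "chromosome(s):\n")
  for (nm in names(x)) cat(" ", nm, nchar(x[[nm]]), "bp\n")
  invisible(x)
}

chrom_len <- function(genome, chrom) nchar(genome[[chrom]])

## Genomic plus-strand bases at 0-based positions (vectorized over pos).
genome_base <- function(genome, chrom, pos) {
  seqs <- unlist(genome[chrom], use.names = FALSE)
  substring(seqs, pos + 1, pos + 1)
}

## Sense-strand base at a 0-based position for a feature on `strand`.
sense_base <- function(genome, chrom, pos, strand) {
  b <- genome_base(genome, chrom, pos)
  minus <- strand == "-"
  b[minus] <- comp_base(b[minus])
  b
}

## Sense-strand sequence spanning sense offsets `from..to` (0-based,
## inclusive) relative to `pos`. Clipped to the contig; the attribute
## "clipped" records whether truncation occurred.
sense_window <- function(genome, chrom, pos, strand, from, to) {
  len <- chrom_len(genome, chrom)
  if (strand == "+") {
    lo <- pos + from; hi <- pos + to
  } else {
    lo <- pos - to; hi <- pos - from
  }
  clipped <- lo < 0 || hi > len - 1
  lo <- max(lo, 0); hi <- min(hi, len - 1)
  s <- substr(genome[[chrom]], lo + 1, hi + 1)
  if (strand == "-") s <- revcomp(s)
  attr(s, "clipped") <- clipped
  s
}

## Write a sense-strand string into the genome starting at sense offset
## `from` relative to pos. Returns the modified genome.
sense_write <- function(genome, chrom, pos, strand, from, value) {
  n <- nchar(value)
  if (strand == "+") {
    lo <- pos + from
    ins <- value
  } else {
    lo <- pos - from - (n - 1)
    ins <- revcomp(value)
  }
  stopifnot(lo >= 0, lo + n <= chrom_len(genome, chrom))
  substr(genome[[chrom]], lo + 1, lo + n) <- ins
  genome
}

## Position `d` bases downstream of `pos` in the sense direction.
downstream_pos <- function(pos, strand, d) {
  ifelse(strand == "+", pos + d, pos - d)
}

gc_fraction <- function(seq) {
  n <- nchar(seq)
  if (n == 0) return(NA_real_)
  gc <- nchar(gsub("[AT]", "", seq))
  gc / n
}

## Length of the T run at the start of a sense-strand string.
leading_t_run <- function(seq) {
  m <- regmatches(seq, regexpr("^T+", seq))
  if (length(m) == 0) 0L else nchar(m)
}

## All start offsets (0-based) of `motif` inside `seq`, allowing overlap.
motif_offsets <- function(seq, motif) {
  hits <- integer(0)
  start <- 1L
  repeat {
    i <- regexpr(motif, substr(seq, start, nchar(seq)), fixed = TRUE)
    if (i == -1L) break
    hits <- c(hits, start + i - 2L)  # 0-based
    start <- start + i               # allow overlapping matches
  }
  hits
}
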