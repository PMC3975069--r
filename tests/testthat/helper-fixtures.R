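# Shared fixtures, all generated in code.

# Small planted reference used across files; memoised per test run.
.fixture_env <- new.env(parent = emptyenv())

fixture_ref <- function(n_genes = 60, seed = 4, ...) {
  key <- paste0("ref_", n_genes, "_", seed, "_",
                paste(unlist(list(...)), collapse = "_"))
  if (is.null(.fixture_env[[key]]))
    .fixture_env[[key]] <- generate_reference(
      c(list(n_genes = n_genes), list(...)), seed = seed)
  .fixture_env[[key]]
}

# Hand-built gene models on a hand-written genome (for exact-sequence cases).
manual_genes <- function(gene_id, chrom, strand, tss, exon_starts, exon_ends,
                         gene_class = "coding") {
  g <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                  tss = as.integer(tss), gene_class = gene_class,
                  stringsAsFactors = FALSE)
  g$exon_starts <- exon_starts
  g$exon_ends <- exon_ends
  g$promoter_gc <- rep(0.5, nrow(g))
  g$exonic_gc <- rep(0.5, nrow(g))
  g$antisense_site_offsets <- rep(list(integer(0)), nrow(g))
  g$tss_t_run <- rep(0L, nrow(g))
  class(g) <- c("gene_models", "data.frame")
  g
}

manual_profile <- function(abundance, quantifiable_fraction = 1,
                           sample_id = "s") {
  cagecompare:::expression_profile(sample_id, abundance / sum(abundance),
                                   quantifiable_fraction)
}

# Minimal CAGE read set from explicit columns.
manual_cage_reads <- function(chrom, pos5, strand, origin_gene,
                              raw_leading_base = "A", shifted_by = 0L,
                              sample_id = "s") {
  n <- length(pos5)
  df <- data.frame(sample_id = rep_len(sample_id, n),
                   chrom = rep_len(chrom, n), strand = rep_len(strand, n),
                   pos5 = as.integer(pos5),
                   origin_gene = rep_len(origin_gene, n),
                   raw_leading_base = rep_len(raw_leading_base, n),
                   shifted_by = as.integer(rep_len(shifted_by, n)),
                   stringsAsFactors = FALSE)
  cagecompare:::new_read_set(df, "cage")
}

manual_rnaseq_reads <- function(chrom, frag_start, frag_end, strand,
                                origin_gene, sample_id = "s") {
  df <- data.frame(sample_id = sample_id, chrom = chrom, strand = strand,
                   frag_start = as.integer(frag_start),
                   frag_end = as.integer(frag_end),
                   pos5 = as.integer(frag_start),
                   origin_gene = origin_gene, raw_leading_base = "A",
                   shifted_by = 0L, stringsAsFactors = FALSE)
  cagecompare:::new_read_set(df, "rnaseq")
}

manual_ctss <- function(chrom, pos, strand, count) {
  tab <- data.frame(chrom = chrom, pos = as.integer(pos), strand = strand,
                    count = as.integer(count), stringsAsFactors = FALSE)
  structure(tab, class = c("ctss_table", "data.frame"), rrna_count = 0L)
}

# Simulate a platform and return a one-column TPM profile.
tpm_profile <- function(ref, expr, pm, depth, seed) {
  rs <- simulate_cage(ref$genome, ref$genes, expr, pm, depth, seed)
  cm <- gene_counts_cage(count_ctss(rs), ref$genes)
  normalize_counts(cm, "tpm_tags")[, 1]
}
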