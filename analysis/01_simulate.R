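#!/usr/bin/env Rscript
# Build the synthetic study: a planted reference genome, two cell-line-like
# expression profiles, the six-point RNA mixture panel, and read sets for
# the three platform models. Artifacts go to results/simulation/.

suppressPackageStartupMessages(library(cagecompare))

outdir <- "results/simulation"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

config <- list(
  seed = 20260923L,
  n_genes = 300L,
  depth_cage = 200000L,
  depth_rnaseq = 200000L,
  mixture_depth = 500000L
)
write_run_config(config, file.path(outdir, "run_config.yaml"))
message("seed: ", config$seed)

ref <- generate_reference(list(n_genes = config$n_genes), seed = config$seed)
write_genome_fasta(ref$genome, file.path(outdir, "genome.fa"))
write_gene_models(ref$genes, file.path(outdir, "genes.bed"),
                  file.path(outdir, "genes_features.tsv"))
message(nrow(ref$genes), " genes over ", nchar(ref$genome[[1]]), " bp; ",
        sum(ref$genes$tss_t_run >= 4), " with TSS T-runs, ",
        sum(vapply(ref$genes$antisense_site_offsets, length, 1L) > 0),
        " with antisense EcoP15I sites")

# two cell-line-like RNA sources with unequal quantifiable fractions
profA <- sample_expression(ref$genes, seed = config$seed + 1L, log_sd = 2,
                           quantifiable_fraction = 0.84, sample_id = "cellA")
profB <- sample_expression(ref$genes, seed = config$seed + 2L, log_sd = 2,
                           quantifiable_fraction = 0.36, sample_id = "cellB")

platforms <- list(
  heliscope_cage = platform_model("heliscope_cage"),
  illumina_cage = platform_model("illumina_cage"),
  rnaseq = platform_model("rnaseq")
)

# pure-sample read sets per platform (triplicates for the CAGE platforms)
for (pn in names(platforms)) {
  for (src in c("A", "B")) {
    prof <- if (src == "A") profA else profB
    for (repi in 1:3) {
      seed <- config$seed + 100L * repi + match(pn, names(platforms)) * 10L +
        (src == "B")
      if (pn == "rnaseq") {
        rs <- simulate_rnaseq(ref$genome, ref$genes, prof, platforms[[pn]],
                              config$depth_rnaseq, seed = seed)
        cm <- gene_counts_rnaseq(rs, ref$genes)
      } else {
        rs <- simulate_cage(ref$genome, ref$genes, prof, platforms[[pn]],
                            config$depth_cage, seed = seed)
        ct <- count_ctss(rs)
        write_ctss(ct, file.path(outdir, sprintf("ctss_%s_%s_rep%d.bed",
                                                 pn, src, repi)))
        cm <- gene_counts_cage(ct, ref$genes)
      }
      colnames(cm$counts) <- sprintf("%s_%s_rep%d", pn, src, repi)
      write_counts(cm, file.path(outdir, sprintf("counts_%s_%s_rep%d.tsv",
                                                 pn, src, repi)))
    }
  }
}

# the mixture panel, sequenced on the single-molecule CAGE model
panel <- mixture_panel(profA, profB)
panel_counts <- vapply(seq_along(panel), function(i)
  sample_profile_counts(panel[[i]], config$mixture_depth,
                        seed = config$seed + 900L + i),
  integer(length(profA$abundance)))
dimnames(panel_counts) <- list(names(profA$abundance), names(panel))
write_counts(count_matrix(panel_counts),
             file.path(outdir, "counts_mixture_panel.tsv"))

message("simulation artifacts written to ", outdir)
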