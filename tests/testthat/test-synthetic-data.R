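test_that("reference generation handles the empty case and stays in-bounds", {
  ref <- generate_reference(list(n_genes = 0), seed = 1)
  expect_equal(nrow(ref$genes), 0)
  expect_gt(nchar(ref$genome[[1]]), 0)

  ref <- fixture_ref()
  g <- ref$genes
  len <- nchar(ref$genome[[g$chrom[1]]])
  expect_true(all(g$tss >= 0 & g$tss < len))
  expect_true(all(unlist(g$exon_ends) <= len))
  for (i in seq_len(nrow(g))) {
    st <- g$exon_starts[[i]]; en <- g$exon_ends[[i]]
    expect_true(all(diff(st) > 0))
    expect_true(all(en[-length(en)] <= st[-1]))  # disjoint
    # strand-aware 5'-most exon boundary is the TSS
    if (g$strand[i] == "+") expect_equal(min(st), g$tss[i])
    else expect_equal(max(en) - 1L, g$tss[i])
  }
  expect_equal(sum(g$gene_class == "rrna"), 1)
  expect_gt(sum(g$gene_class == "histone_like"), 0)
})

test_that("planted contexts are present in the emitted sequence and stratify at 400 bp", {
  ref <- fixture_ref()
  g <- ref$genes
  planted <- which(vapply(g$antisense_site_offsets, length, integer(1)) > 0)
  expect_gt(length(planted), 0)
  for (i in planted) {
    off <- min(g$antisense_site_offsets[[i]])
    slice <- cagecompare:::sense_window(ref$genome, g$chrom[i], g$tss[i],
                                        g$strand[i], off, off + 5L)
    expect_equal(as.character(slice), "CTGCTG")
  }
  min_off <- vapply(g$antisense_site_offsets, function(o)
    if (length(o)) min(o) else NA_integer_, integer(1))
  expect_gt(sum(!is.na(min_off) & min_off <= 400), 0)
  expect_gt(sum(!is.na(min_off) & min_off > 400), 0)

  # T runs readable from sequence
  ts <- which(g$tss_t_run >= 4)
  expect_gt(length(ts), 0)
  for (i in ts) {
    run <- cagecompare:::sense_window(ref$genome, g$chrom[i], g$tss[i],
                                      g$strand[i], 0L, g$tss_t_run[i])
    expect_match(as.character(run), sprintf("^T{%d}[^T]$", g$tss_t_run[i]))
  }
})

test_that("stored features are exactly recomputable from the FASTA round trip", {
  ref <- fixture_ref()
  fa <- withr::local_tempfile(fileext = ".fa")
  write_genome_fasta(ref$genome, fa)
  genome2 <- read_genome_fasta(fa)
  g2 <- annotate_gene_features(ref$genes, genome2)
  expect_identical(g2$promoter_gc, ref$genes$promoter_gc)
  expect_identical(g2$exonic_gc, ref$genes$exonic_gc)
  expect_identical(g2$antisense_site_offsets, ref$genes$antisense_site_offsets)
  expect_identical(g2$tss_t_run, ref$genes$tss_t_run)
})

test_that("expression profiles normalize, are deterministic, and are symmetric on the log scale", {
  g1 <- manual_genes("only", "chr1", "+", 100, list(100L), list(200L))
  p <- sample_expression(g1, seed = 1)
  expect_equal(unname(p$abundance), 1)

  a <- sample_expression(paste0("g", 1:50), seed = 7, log_sd = 1.5)
  b <- sample_expression(paste0("g", 1:50), seed = 7, log_sd = 1.5)
  expect_identical(a, b)

  big <- sample_expression(paste0("g", 1:10000), seed = 5, log_sd = 2)
  la <- log(big$abundance)
  skew <- mean((la - mean(la))^3) / stats::sd(la)^3
  expect_lt(abs(skew), 0.1)

  expect_error(sample_expression(paste0("g", 1), seed = 1, log_sd = 0),
               "log_sd")
})

test_that("mass mixing follows the quantifiable-fraction read-share formula", {
  ids <- paste0("g", 1:200)
  pa <- sample_expression(ids, seed = 1, quantifiable_fraction = 0.84,
                          sample_id = "A")
  pb <- sample_expression(ids, seed = 2, quantifiable_fraction = 0.36,
                          sample_id = "B")
  expect_identical(compose_mixture(pa, pb, 1), pa)

  mix <- compose_mixture(pa, pb, 0.5)
  wa <- 0.5 * 0.84; wb <- 0.5 * 0.36
  expect_equal(wa / (wa + wb), 0.7)   # effective read share of A
  expect_equal(mix$quantifiable_fraction, wa + wb)
  expect_equal(unname(mix$abundance),
               unname((wa * pa$abundance + wb * pb$abundance) / (wa + wb)))

  panel <- mixture_panel(pa, pb)
  expect_identical(names(panel),
                   c("100:0", "99:1", "95:5", "90:10", "50:50", "0:100"))
  expect_error(compose_mixture(pa, pb, 1.2), "mass_ratio_A")
})

test_that("empirical mixture read share matches the formula within 3 binomial sigma", {
  ids <- paste0("g", 1:100)
  pa <- sample_expression(ids, seed = 3, quantifiable_fraction = 0.84, sample_id = "A")
  pb <- sample_expression(ids, seed = 4, quantifiable_fraction = 0.36, sample_id = "B")
  p_share <- 0.5 * 0.84 / (0.5 * 0.84 + 0.5 * 0.36)
  n <- 1e5
  set.seed(11)
  from_a <- stats::rbinom(1, n, p_share)   # source label under the mixture
  expect_lt(abs(from_a / n - p_share), 3 * sqrt(p_share * (1 - p_share) / n))
})

test_that("G addition aligns upstream on a genomic G and is trimmed otherwise", {
  # plus-strand gene, upstream base G
  genome <- synthetic_genome(c(chr1 = paste0(strrep("A", 50), "G", "C",
                                             strrep("A", 48))))
  g <- manual_genes("gp", "chr1", "+", 51, list(51L), list(90L))
  pm <- platform_model("illumina_cage", g_add_prob = 1, jitter_frac = 0,
                       gc_bias_coef = 0, ecop15i_boost = 1,
                       rrna_rate_mean = 0, rrna_rate_sd = 0)
  expr <- manual_profile(c(gp = 1))
  rs <- simulate_cage(genome, g, expr, pm, 200, seed = 1)
  expect_true(all(rs$pos5 == 50))            # aligned one base upstream
  expect_true(all(rs$raw_leading_base == "G"))
  expect_true(all(rs$shifted_by == -1))

  # non-G upstream: trimmed, stays at the TSS
  genome2 <- synthetic_genome(c(chr1 = paste0(strrep("A", 50), "T", "C",
                                              strrep("A", 48))))
  rs2 <- simulate_cage(genome2, g, expr, pm, 200, seed = 1)
  expect_true(all(rs2$pos5 == 51))
  expect_true(all(rs2$raw_leading_base == "G"))
  expect_true(all(rs2$shifted_by == 0))
})

test_that("T-stretch shifting displaces starts past the run, strand-aware", {
  # sense TTTTTA... at the TSS on the plus strand -> pos5 = tss + 5
  genome <- synthetic_genome(c(chr1 = paste0(strrep("C", 50), "TTTTTA",
                                             strrep("C", 44))))
  g <- manual_genes("gt", "chr1", "+", 50, list(50L), list(90L))
  g$tss_t_run <- 5L
  pm <- platform_model("heliscope_cage", jitter_frac = 0,
                       rrna_rate_mean = 0, rrna_rate_sd = 0,
                       tstretch_min_run = 4)
  expr <- manual_profile(c(gt = 1))
  rs <- simulate_cage(genome, g, expr, pm, 100, seed = 2)
  expect_true(all(rs$pos5 == 55))
  expect_true(all(rs$shifted_by == 5))

  # minus strand: sense T run = genomic A run leftward; shift decreases pos
  genome_m <- synthetic_genome(c(chr1 = paste0(strrep("C", 45), "GAAAAA",
                                               strrep("C", 49))))
  gm <- manual_genes("gm", "chr1", "-", 50, list(20L), list(51L))
  gm$tss_t_run <- 5L
  rsm <- simulate_cage(genome_m, gm, manual_profile(c(gm = 1)), pm, 100, seed = 3)
  expect_true(all(rsm$pos5 == 45))
  expect_true(all(rsm$shifted_by == 5))
})

test_that("clean simulation conserves truth: all tags at the TSS, multinomial counts", {
  ref <- fixture_ref(n_genes = 30, seed = 8)
  g <- ref$genes
  expr <- sample_expression(g, seed = 2, log_sd = 0.5)
  pm <- platform_model_clean()
  pvals <- vapply(1:20, function(s) {
    rs <- simulate_cage(ref$genome, g, expr, pm, 20000, seed = 100 + s)
    expect_true(all(rs$pos5 == g$tss[match(rs$origin_gene, g$gene_id)]))
    expect_true(all(rs$shifted_by == 0))
    obs <- table(factor(rs$origin_gene, levels = names(expr$abundance)))
    suppressWarnings(stats::chisq.test(obs, p = expr$abundance)$p.value)
  }, numeric(1))
  expect_true(all(pvals > 0.001))
})

test_that("simulators are deterministic and reject bad inputs", {
  ref <- fixture_ref(n_genes = 20, seed = 9)
  expr <- sample_expression(ref$genes, seed = 1)
  pm <- platform_model("illumina_cage")
  a <- simulate_cage(ref$genome, ref$genes, expr, pm, 5000, seed = 7)
  b <- simulate_cage(ref$genome, ref$genes, expr, pm, 5000, seed = 7)
  expect_identical(a, b)
  expect_equal(nrow(simulate_cage(ref$genome, ref$genes, expr, pm, 0, seed = 1)), 0)
  expect_error(simulate_cage(ref$genome, ref$genes, expr, pm, -1, seed = 1), "depth")
  expect_error(simulate_cage(ref$genome, ref$genes, expr,
                             platform_model("rnaseq"), 10, seed = 1))
  expect_error(platform_model("heliscope_cage", nonsense = 1), "unknown")
  expect_error(platform_model("illumina_cage", g_add_prob = 2))
})

test_that("polyA selection removes histone-like transcripts; rRNA rate varies by replicate", {
  ref <- fixture_ref(n_genes = 20, seed = 9)
  g <- ref$genes
  g$gene_class[g$gene_class == "coding"] <- "histone_like"
  expr <- sample_expression(g, seed = 3)
  pm <- platform_model("rnaseq", polya_escape_rate = 0,
                       rrna_rate_mean = 0.1, rrna_rate_sd = 0)
  rs <- simulate_rnaseq(ref$genome, g, expr, pm, 5000, seed = 4)
  expect_true(all(rs$origin_gene == "rrna"))

  pm2 <- platform_model("rnaseq", rrna_rate_mean = 0.08, rrna_rate_sd = 0.03)
  rates <- vapply(1:6, function(s) {
    r <- simulate_rnaseq(ref$genome, ref$genes,
                         sample_expression(ref$genes, seed = 3),
                         pm2, 5000, seed = 40 + s)
    mean(r$origin_gene == "rrna")
  }, numeric(1))
  expect_gt(stats::sd(rates), 0)
})

test_that("unbiased fragment sampling is symmetric between equal genes", {
  # two identical single-exon genes, equal abundance
  genome <- synthetic_genome(c(chr1 = strrep("ACGT", 2500)))
  g <- manual_genes(c("a", "b"), "chr1", "+", c(1000L, 6000L),
                    list(1000L, 6000L), list(2000L, 7000L))
  pm <- platform_model("rnaseq", gc_bias_coef = 0, polya_select = FALSE,
                       rrna_rate_mean = 0, rrna_rate_sd = 0)
  expr <- manual_profile(c(a = 1, b = 1))
  rs <- simulate_rnaseq(genome, g, expr, pm, 100000, seed = 5)
  na <- sum(rs$origin_gene == "a")
  expect_lt(abs(na - 50000), 4 * sqrt(100000 * 0.25))
})
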