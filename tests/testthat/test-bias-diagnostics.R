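# Planted-parameter recovery for each diagnostic, plus identity nulls.

make_expr_ref <- function() {
  ref <- fixture_ref(n_genes = 300, seed = 3, frac_histone = 0)
  list(ref = ref, expr = sample_expression(ref$genes, seed = 2, log_sd = 1))
}

test_that("every diagnostic returns an exact null on identical inputs", {
  fx <- make_expr_ref()
  g <- fx$ref$genes
  X <- tpm_profile(fx$ref, fx$expr, platform_model_clean(), 5e4, seed = 70)
  gc <- stats::setNames(g$promoter_gc, g$gene_id)

  r1 <- relative_expression_by_gc(X, X, gc)
  expect_true(all(r1$strata$median_log2_ratio[r1$strata$n_genes > 0] == 0))
  expect_equal(r1$slope, 0)

  cls <- scan_ecop15i_context(g, fx$ref$genome)
  r2 <- relative_expression_by_ecop15i(X, X, cls)
  expect_true(all(r2$strata$median_log2_ratio[r2$strata$n_genes > 0] == 0))
  expect_equal(r2$le_max_minus_none, 0)

  ct <- count_ctss(simulate_cage(fx$ref$genome, g, fx$expr,
                                 platform_model_clean(jitter_frac = 0.2),
                                 5e4, seed = 71))
  r3 <- start_base_activity(ct, ct, fx$ref$genome)
  expect_true(all(r3$by_base$median_log2_ratio[r3$by_base$n_positions > 0] == 0))

  r4 <- detect_tstretch_shifts(ct, ct, fx$ref$genome)
  expect_equal(r4$n_shifted, 0)

  r5 <- platform_specific_tss(ct, ct)
  expect_equal(nrow(r5$x_only), 0)
  expect_equal(nrow(r5$y_only), 0)

  r6 <- correlate_at_resolution(ct, ct)
  expect_equal(r6$rho_raw, 1)
  expect_equal(r6$rho_smoothed, 1)
})

test_that("the GC amplification slope is recovered and null under a PCR-free model", {
  fx <- make_expr_ref()
  g <- fx$ref$genes
  gc <- stats::setNames(g$promoter_gc, g$gene_id)
  pmX <- platform_model("heliscope_cage", gc_bias_coef = -2,
                        tstretch_shift_enabled = FALSE,
                        rrna_rate_mean = 0, rrna_rate_sd = 0, jitter_frac = 0)
  expected <- -2 / log(2)
  slopes <- vapply(1:10, function(s) {
    X <- tpm_profile(fx$ref, fx$expr, pmX, 2e5, seed = 900 + s)
    Y <- tpm_profile(fx$ref, fx$expr, platform_model_clean(), 2e5, seed = 950 + s)
    relative_expression_by_gc(X, Y, gc)$slope
  }, numeric(1))
  expect_lt(abs(mean(slopes) - expected) / abs(expected), 0.15)

  # PCR-free null: slope within sampling noise
  X0 <- tpm_profile(fx$ref, fx$expr, platform_model_clean(), 2e5, seed = 975)
  Y0 <- tpm_profile(fx$ref, fx$expr, platform_model_clean(), 2e5, seed = 976)
  expect_lte(abs(relative_expression_by_gc(X0, Y0, gc)$slope), 0.2)
})

test_that("EcoP15I context classes come from the sequence and the boost is recovered", {
  fx <- make_expr_ref()
  g <- fx$ref$genes
  cls <- scan_ecop15i_context(g, fx$ref$genome)
  # classes agree with the stored annotation
  min_off <- vapply(g$antisense_site_offsets, function(o)
    if (length(o)) min(o) else NA_integer_, integer(1))
  expect_equal(cls$class[is.na(min_off)],
               rep("none", sum(is.na(min_off))))
  expect_equal(cls$class[!is.na(min_off) & min_off <= 400],
               rep("antisense_le_max", sum(!is.na(min_off) & min_off <= 400)))
  expect_equal(cls$class[!is.na(min_off) & min_off > 400],
               rep("antisense_gt_max", sum(!is.na(min_off) & min_off > 400)))

  pmE <- platform_model("heliscope_cage", ecop15i_boost = 1.5,
                        tstretch_shift_enabled = FALSE,
                        rrna_rate_mean = 0, rrna_rate_sd = 0, jitter_frac = 0)
  diffs <- vapply(1:10, function(s) {
    X <- tpm_profile(fx$ref, fx$expr, pmE, 2e5, seed = 1500 + s)
    Y <- tpm_profile(fx$ref, fx$expr, platform_model_clean(), 2e5, seed = 1550 + s)
    relative_expression_by_ecop15i(X, Y, cls)$le_max_minus_none
  }, numeric(1))
  expect_lt(abs(mean(diffs) - log2(1.5)), 0.15)

  # boost = 1 gives a null class difference
  X1 <- tpm_profile(fx$ref, fx$expr, platform_model_clean(), 2e5, seed = 1600)
  Y1 <- tpm_profile(fx$ref, fx$expr, platform_model_clean(), 2e5, seed = 1601)
  expect_lt(abs(relative_expression_by_ecop15i(X1, Y1, cls)$le_max_minus_none),
            0.15)
})

test_that("first-base capture preference yields the G > A = T > C ordering", {
  fx <- make_expr_ref()
  pmB <- platform_model("illumina_cage", g_add_prob = 0, gc_bias_coef = 0,
                        ecop15i_boost = 1, rrna_rate_mean = 0,
                        rrna_rate_sd = 0, jitter_frac = 0)
  X <- count_ctss(simulate_cage(fx$ref$genome, fx$ref$genes, fx$expr, pmB,
                                2e5, seed = 81))
  Y <- count_ctss(simulate_cage(fx$ref$genome, fx$ref$genes, fx$expr,
                                platform_model_clean(), 2e5, seed = 82))
  med <- with(start_base_activity(X, Y, fx$ref$genome),
              stats::setNames(by_base$median_log2_ratio, by_base$base))
  expect_gt(med["G"], med["A"])
  expect_gt(med["G"], med["T"])
  expect_gt(med["A"], med["C"])
  expect_gt(med["T"], med["C"])
  expect_lt(abs(med["A"] - med["T"]), 0.3)

  disjoint_x <- manual_ctss("chr1", c(10, 20), "+", c(9, 9))
  disjoint_y <- manual_ctss("chr1", c(100, 200), "+", c(9, 9))
  expect_warning(out <- start_base_activity(disjoint_x, disjoint_y,
                                            fx$ref$genome), "shared")
  expect_equal(nrow(out$positions), 0)
})

test_that("T-stretch shifts are recovered exactly and only when the mechanism is on", {
  fx <- make_expr_ref()
  g <- fx$ref$genes
  pmT <- platform_model("heliscope_cage", rrna_rate_mean = 0,
                        rrna_rate_sd = 0, jitter_frac = 0)
  ref_ct <- count_ctss(simulate_cage(fx$ref$genome, g, fx$expr,
                                     platform_model_clean(), 2e5, seed = 92))
  shifted_ct <- count_ctss(simulate_cage(fx$ref$genome, g, fx$expr, pmT,
                                         2e5, seed = 91))
  rep1 <- detect_tstretch_shifts(shifted_ct, ref_ct, fx$ref$genome)
  planted <- g[g$tss_t_run >= 4, ]
  # every planted T-run gene detected at its own count threshold, no others
  detectable <- sum(ref_ct$count[match(
    paste(planted$chrom, planted$tss, planted$strand),
    paste(ref_ct$chrom, ref_ct$pos, ref_ct$strand))] >= 5, na.rm = TRUE)
  expect_equal(rep1$n_shifted, detectable)
  expect_equal(rep1$n_examined, detectable)
  expect_equal(rep1$fraction, 1.0)

  off <- detect_tstretch_shifts(ref_ct, ref_ct, fx$ref$genome)
  expect_equal(off$n_shifted, 0)
  expect_equal(off$fraction,
               if (off$n_examined > 0) 0 else NA_real_)
})

test_that("smoothing averages windows, conserves isolated peaks, and helps under jitter", {
  ct <- manual_ctss("chr1", 500, "+", 3)
  expect_equal(smooth_ctss(ct, halfwidth = 0)$count, 3)
  sm <- smooth_ctss(ct, halfwidth = 1)
  expect_equal(sm$pos, c(499, 500, 501))
  expect_equal(sm$count, rep(1, 3))
  expect_equal(sum(sm$count), sum(ct$count))  # conservation for isolated peak

  fx <- make_expr_ref()
  pmJ <- platform_model_clean(jitter_frac = 0.2)
  wins <- vapply(1:20, function(s) {
    X <- count_ctss(simulate_cage(fx$ref$genome, fx$ref$genes, fx$expr, pmJ,
                                  3e4, seed = 1100 + s))
    Y <- count_ctss(simulate_cage(fx$ref$genome, fx$ref$genes, fx$expr, pmJ,
                                  3e4, seed = 1200 + s))
    cr <- correlate_at_resolution(X, Y)
    cr$rho_smoothed > cr$rho_raw
  }, logical(1))
  expect_gte(sum(wins), 18)
})

test_that("platform-exclusive TSSs follow the strict count and neighborhood rules", {
  # count exactly 10 is not a candidate (strict >)
  x <- manual_ctss("chr1", c(100, 300, 600), "+", c(10, 25, 12))
  y <- manual_ctss("chr1", c(100, 302), "+", c(10, 4))
  res <- platform_specific_tss(x, y, min_count = 10, neighbor_count = 3,
                               neighborhood_bp = 20)
  expect_false(100 %in% res$x_only$pos)      # 10 is not > 10 in either
  expect_true(all(c(300, 600) %in% res$x_only$pos))
  # 300 has a neighbor with >= 3 counts at 302; 600 has none
  expect_equal(res$x_only$unneighbored[res$x_only$pos == 300], FALSE)
  expect_equal(res$x_only$unneighbored[res$x_only$pos == 600], TRUE)
  expect_equal(nrow(res$y_only), 0)
})

test_that("the G-addition rate estimate matches the planted probability", {
  ref <- fixture_ref(n_genes = 300, seed = 3, frac_histone = 0)
  expr <- sample_expression(ref$genes, seed = 2, log_sd = 1)
  pm <- platform_model("illumina_cage", g_add_prob = 0.6)
  rs <- simulate_cage(ref$genome, ref$genes, expr, pm, 1e5, seed = 77)
  est <- estimate_g_addition(rs, ref$genes, ref$genome)
  expect_gt(est$n_tags, 1000)
  expect_lt(abs(est$rate - 0.6), 0.02)
})
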