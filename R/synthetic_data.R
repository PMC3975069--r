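#' Platform readout model
#'
#' Bundles the bias parameters that define how one sequencing platform
#' distorts the true transcriptome into an observed read set. Three presets
#' mirror the protocols compared in the package:
#'
#' * `heliscope_cage`: single-molecule, PCR-free. No nontemplated G addition
#'   (suppressed by fill-and-lock template treatment), no GC amplification
#'   bias, no EcoP15I competition, but deterministic downstream shifting of
#'   observed starts past genomic T runs.
#' * `illumina_cage`: PCR-amplified tag protocol. Nontemplated 5' G addition
#'   at the reverse-transcriptase rate of 0.87, GC-dependent amplification,
#'   a capture boost for genes carrying an antisense-strand EcoP15I
#'   recognition site near the TSS (the internal site offers an extra
#'   cleavage opportunity), and linker-driven first-base capture preference
#'   (G favoured, C disfavoured).
#' * `rnaseq`: polyA-selected fragment readout; non-polyadenylated
#'   (histone-like) transcripts are lost except for a small escape rate, and
#'   ribosomal carryover is the most variable across replicates.
#'
#' @param platform one of `"heliscope_cage"`, `"illumina_cage"`, `"rnaseq"`.
#' @param ... named overrides for any field listed below.
#' @return an object of class `platform_model` with fields `g_add_prob`,
#'   `first_base_weights`, `gc_bias_coef` (log-linear slope, natural log, of
#'   amplification weight vs GC), `ecop15i_boost`, `ecop15i_max_dist`,
#'   `tstretch_shift_enabled`, `tstretch_min_run`, `polya_select`,
#'   `polya_escape_rate`, `rrna_rate_mean`, `rrna_rate_sd`, `jitter_frac`,
#'   `fragment_len`.
#' @export
platform_model <- function(platform = c("heliscope_cage", "illumina_cage", "rnaseq"),
                           ...) {
  platform <- match.arg(platform)
  base <- list(
    platform = platform,
    g_add_prob = 0,
    first_base_weights = c(A = 1, C = 1, G = 1, T = 1),
    gc_bias_coef = 0,
    ecop15i_boost = 1,
    ecop15i_max_dist = 400,
    tstretch_shift_enabled = FALSE,
    tstretch_min_run = 4L,
    polya_select = FALSE,
    polya_escape_rate = 0.05,
    rrna_rate_mean = 0.05,
    rrna_rate_sd = 0.01,
    jitter_frac = 0.2,
    fragment_len = 35L
  )
  preset <- switch(platform,
    heliscope_cage = list(
      tstretch_shift_enabled = TRUE,
      rrna_rate_mean = 0.10, rrna_rate_sd = 0.01
    ),
    illumina_cage = list(
      g_add_prob = 0.87,
      first_base_weights = c(A = 1, C = 0.6, G = 1.3, T = 1),
      gc_bias_coef = -1.0,
      ecop15i_boost = 1.5,
      rrna_rate_mean = 0.02, rrna_rate_sd = 0.005
    ),
    rnaseq = list(
      polya_select = TRUE,
      rrna_rate_mean = 0.08, rrna_rate_sd = 0.03
    )
  )
  base[names(preset)] <- preset
  dots <- list(...)
  unknown <- setdiff(names(dots), names(base))
  if (length(unknown))
    stop("unknown platform_model field(s): ", paste(unknown, collapse = ", "))
  base[names(dots)] <- dots
  pm <- structure(base, class = "platform_model")
  validate_platform_model(pm)
  pm
}

validate_platform_model <- function(pm) {
  stopifnot(
    pm$g_add_prob >= 0, pm$g_add_prob <= 1,
    all(pm$first_base_weights > 0),
    setequal(names(pm$first_base_weights), BASES),
    pm$ecop15i_boost >= 1,
    pm$ecop15i_max_dist >= 0,
    pm$polya_escape_rate >= 0, pm$polya_escape_rate <= 1,
    pm$rrna_rate_mean >= 0, pm$rrna_rate_mean <= 1,
    pm$rrna_rate_sd >= 0,
    pm$jitter_frac >= 0, pm$jitter_frac <= 1,
    pm$fragment_len >= 1
  )
  invisible(pm)
}

## A platform with every artifact mechanism switched off: used as the
## truth-readout reference in diagnostics tests.
#' Unbiased readout model (all artifact mechanisms disabled)
#' @param platform preset whose read type (tag or fragment) to keep.
#' @param ... overrides as in [platform_model()].
#' @export
platform_model_clean <- function(platform = "heliscope_cage", ...) {
  platform_model(platform,
    g_add_prob = 0, gc_bias_coef = 0, ecop15i_boost = 1,
    first_base_weights = c(A = 1, C = 1, G = 1, T = 1),
    tstretch_shift_enabled = FALSE, polya_select = FALSE,
    rrna_rate_mean = 0, rrna_rate_sd = 0, jitter_frac = 0, ...)
}

default_reference_config <- function() {
  list(
    n_genes = 60L,
    chrom_name = "chr1",
    gene_spacing = 2500L,       # min distance between neighbouring TSS slots
    promoter_flank = 500L,      # +/- window used for promoter GC
    gc_range = c(0.30, 0.70),   # planted promoter GC spans this range
    frac_ecop_near = 0.20,      # sense-strand CTGCTG within ecop15i_max_dist
    frac_ecop_far = 0.10,       # sense-strand CTGCTG beyond it (<= scan range)
    frac_tstretch = 0.10,       # genomic T run starting at the TSS
    frac_histone = 0.10,        # non-polyadenylated, histone-like
    tstretch_min_run = 4L,
    tstretch_max_run = 15L,
    ecop15i_max_dist = 400L,
    ecop_scan_range = 800L
  )
}

#' Generate a synthetic genome and gene models with planted contexts
#'
#' Lays out genes on alternating strands in fixed slots along one
#' chromosome, then plants the sequence contexts every diagnostic needs:
#' promoter GC spanning a controlled range, sense-strand CTGCTG motifs
#' (antisense-strand EcoP15I recognition sites) at controlled offsets from
#' the TSS, genomic T runs starting at the TSS, non-polyadenylated
#' histone-like genes, and one ribosomal gene. All stored feature fields
#' (`promoter_gc`, `exonic_gc`, `antisense_site_offsets`, `tss_t_run`) are
#' recomputed from the emitted sequence, so they agree with the FASTA
#' exactly. Accidental CTGCTG occurrences in the scanned window and
#' accidental TSS T runs are scrubbed before planting so the strata stay
#' controlled.
#'
#' @param config list of generator settings; see
#'   `cagecompare:::default_reference_config()` for fields and defaults.
#'   Unspecified fields take their defaults.
#' @param seed integer seed.
#' @return list with elements `genome` (a [synthetic_genome()]) and `genes`
#'   (a `gene_models` data frame: `gene_id`, `chrom`, `strand`, `tss`,
#'   `exon_starts`/`exon_ends` list columns of 0-based half-open intervals,
#'   `gene_class`, `promoter_gc`, `exonic_gc`, `antisense_site_offsets` list
#'   column, `tss_t_run`).
#' @export
generate_reference <- function(config = list(), seed = 1L) {
  cfg <- default_reference_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown reference config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  fr <- c(cfg$frac_ecop_near, cfg$frac_ecop_far, cfg$frac_tstretch, cfg$frac_histone)
  if (any(fr < 0) || any(fr > 1) || sum(fr[1:3]) > 1)
    stop("invalid feature fractions")
  n <- as.integer(cfg$n_genes)
  if (n < 0) stop("n_genes must be >= 0")
  set.seed(seed)

  spacing <- as.integer(cfg$gene_spacing)
  if (spacing < 2200L) stop("gene_spacing too small for requested gene layout")
  n_slots <- if (n > 0) n else 0L
  glen <- 1000L + n_slots * spacing + 2000L
  chrom <- cfg$chrom_name
  ## the genome is built as a per-base character vector (string surgery on
  ## a multi-Mb chromosome would copy it on every edit) and collapsed once
  seq_vec <- sample(BASES, glen, replace = TRUE)
  if (n == 0) {
    genome <- synthetic_genome(stats::setNames(
      list(paste(seq_vec, collapse = "")), chrom))
    return(list(genome = genome, genes = empty_gene_models()))
  }

  width <- max(3L, nchar(as.character(n)))
  gene_id <- sprintf("g%0*d", width, seq_len(n))
  strand <- rep(c("+", "-"), length.out = n)
  slot_start <- 1000L + (seq_len(n) - 1L) * spacing

  ## gene body: 3 exons spanning ~1.2 kb downstream of the TSS (sense)
  body_span <- 1200L
  tss <- ifelse(strand == "+", slot_start + 600L, slot_start + 600L + body_span)

  ## assign disjoint feature groups
  idx <- sample.int(n)
  n_near <- round(cfg$frac_ecop_near * n)
  n_far <- round(cfg$frac_ecop_far * n)
  n_ts <- round(cfg$frac_tstretch * n)
  grp_near <- idx[seq_len(n_near)]
  grp_far <- idx[n_near + seq_len(n_far)]
  grp_ts <- idx[n_near + n_far + seq_len(n_ts)]
  gene_class <- rep("coding", n)
  plain <- setdiff(seq_len(n), c(grp_near, grp_far, grp_ts))
  n_hist <- min(length(plain), round(cfg$frac_histone * n))
  gene_class[sample(plain, n_hist)] <- "histone_like"
  gene_class[plain[1]] <- "rrna"   # one ribosomal gene, feature-free slot

  flank <- as.integer(cfg$promoter_flank)
  gc_target <- stats::runif(n, cfg$gc_range[1], cfg$gc_range[2])

  vec_write <- function(pos, std, from, value) {
    chars <- strsplit(value, "", fixed = TRUE)[[1]]
    if (std == "+") {
      idx <- pos + from + seq_along(chars)          # 1-based
    } else {
      chars <- rev(comp_base(chars))
      lo <- pos - from - (length(chars) - 1L)
      idx <- lo + seq_along(chars)
    }
    seq_vec[idx] <<- chars
  }
  vec_window <- function(pos, std, from, to) {
    if (std == "+") {
      paste(seq_vec[(pos + from + 1L):(pos + to + 1L)], collapse = "")
    } else {
      paste(comp_base(seq_vec[(pos - from + 1L):(pos - to + 1L)]), collapse = "")
    }
  }

  ## 1) promoter fill at the planted GC
  for (i in seq_len(n)) {
    w <- 2L * flank + 1L
    gcmask <- stats::runif(w) < gc_target[i]
    bases <- ifelse(gcmask, sample(c("G", "C"), w, replace = TRUE),
                    sample(c("A", "T"), w, replace = TRUE))
    vec_write(tss[i], strand[i], -flank, paste(bases, collapse = ""))
  }

  scan_hi <- as.integer(cfg$ecop_scan_range)
  motif <- "CTGCTG"
  ## 2) scrub accidental motifs in every gene's scanned window, and
  ##    accidental TSS T runs ('A' can appear in neither pattern)
  for (i in seq_len(n)) {
    repeat {
      win <- vec_window(tss[i], strand[i], 0L, scan_hi + 5L)
      offs <- motif_offsets(win, motif)
      if (length(offs) == 0) break
      vec_write(tss[i], strand[i], offs[1] + 3L, "A")
    }
    start2 <- vec_window(tss[i], strand[i], 0L, cfg$tstretch_min_run)
    if (leading_t_run(start2) >= cfg$tstretch_min_run)
      vec_write(tss[i], strand[i], 1L, "A")
  }

  ## 3) plant designated motifs and T runs
  ecop_off <- rep(NA_integer_, n)
  for (i in grp_near)
    ecop_off[i] <- sample(10:(cfg$ecop15i_max_dist - 6L), 1)
  for (i in grp_far)
    ecop_off[i] <- sample((cfg$ecop15i_max_dist + 1L):(scan_hi - 6L), 1)
  for (i in c(grp_near, grp_far))
    vec_write(tss[i], strand[i], ecop_off[i], motif)
  t_run_len <- rep(0L, n)
  for (i in grp_ts) {
    L <- sample(cfg$tstretch_min_run:cfg$tstretch_max_run, 1)
    t_run_len[i] <- L
    vec_write(tss[i], strand[i], 0L, paste0(strrep("T", L), "A"))
  }
  genome <- synthetic_genome(stats::setNames(
    list(paste(seq_vec, collapse = "")), chrom))

  ## exon structure: sense 5'-most exon boundary is the TSS
  exon_starts <- vector("list", n)
  exon_ends <- vector("list", n)
  for (i in seq_len(n)) {
    sizes <- sample(150:400, 3, replace = TRUE)
    gaps <- sample(80:150, 2, replace = TRUE)
    off <- cumsum(c(0L, sizes[1] + gaps[1], sizes[2] + gaps[2]))
    if (strand[i] == "+") {
      st <- tss[i] + off
      en <- st + sizes
    } else {
      en <- tss[i] + 1L - off
      st <- en - sizes
      o <- order(st); st <- st[o]; en <- en[o]
    }
    exon_starts[[i]] <- as.integer(st)
    exon_ends[[i]] <- as.integer(en)
  }

  genes <- data.frame(
    gene_id = gene_id, chrom = chrom, strand = strand, tss = as.integer(tss),
    gene_class = gene_class, stringsAsFactors = FALSE
  )
  genes$exon_starts <- exon_starts
  genes$exon_ends <- exon_ends
  genes <- annotate_gene_features(genes, genome,
    promoter_flank = flank, scan_range = scan_hi)
  class(genes) <- c("gene_models", "data.frame")

  ## planted features must survive intact
  stopifnot(all(t_run_len[grp_ts] == genes$tss_t_run[grp_ts]))
  for (i in c(grp_near, grp_far))
    stopifnot(ecop_off[i] %in% genes$antisense_site_offsets[[i]])

  list(genome = genome, genes = genes)
}

empty_gene_models <- function() {
  genes <- data.frame(
    gene_id = character(0), chrom = character(0), strand = character(0),
    tss = integer(0), gene_class = character(0), stringsAsFactors = FALSE)
  genes$exon_starts <- list()
  genes$exon_ends <- list()
  genes$promoter_gc <- numeric(0)
  genes$exonic_gc <- numeric(0)
  genes$antisense_site_offsets <- list()
  genes$tss_t_run <- integer(0)
  class(genes) <- c("gene_models", "data.frame")
  genes
}

#' Recompute planted sequence features from the genome
#'
#' Fills `promoter_gc`, `exonic_gc`, `antisense_site_offsets` (0-based
#' offsets of sense-strand CTGCTG motif starts downstream of the TSS within
#' `scan_range`) and `tss_t_run` from the sequence, guaranteeing exact
#' agreement between the annotation and the emitted FASTA.
#'
#' @param genes gene models data frame.
#' @param genome a [synthetic_genome()].
#' @param promoter_flank half-width (bp) of the promoter GC window.
#' @param scan_range downstream extent (bp) scanned for the motif.
#' @export
annotate_gene_features <- function(genes, genome, promoter_flank = 500L,
                                   scan_range = 800L) {
  n <- nrow(genes)
  genes$promoter_gc <- numeric(n)
  genes$exonic_gc <- numeric(n)
  genes$antisense_site_offsets <- vector("list", n)
  genes$tss_t_run <- integer(n)
  for (i in seq_len(n)) {
    ch <- genes$chrom[i]; s <- genes$strand[i]; t <- genes$tss[i]
    genes$promoter_gc[i] <- gc_fraction(
      sense_window(genome, ch, t, s, -promoter_flank, promoter_flank))
    ex <- mapply(function(a, b) substr(genome[[ch]], a + 1, b),
                 genes$exon_starts[[i]], genes$exon_ends[[i]])
    genes$exonic_gc[i] <- gc_fraction(paste(ex, collapse = ""))
    win <- sense_window(genome, ch, t, s, 0L, scan_range + 5L)
    genes$antisense_site_offsets[[i]] <- motif_offsets(win, "CTGCTG")
    genes$tss_t_run[i] <- leading_t_run(win)
  }
  class(genes) <- c("gene_models", "data.frame")
  genes
}

#' Draw a log-normal expression profile over the gene models
#'
#' Abundances are relative molar abundances over the quantifiable
#' (non-ribosomal) genes and sum to one; `quantifiable_fraction` records
#' what share of the total RNA mass those genes represent (the remainder
#' being ribosomal and unannotated RNA).
#'
#' @param genes gene models (ribosomal genes are excluded from the map) or
#'   a plain character vector of gene ids for genome-free profile work.
#' @param seed integer seed.
#' @param log_sd standard deviation of log abundance (> 0).
#' @param quantifiable_fraction in (0, 1].
#' @param sample_id label carried into read sets.
#' @return object of class `expression_profile`: list with `sample_id`,
#'   `abundance` (named, sums to 1), `quantifiable_fraction`.
#' @export
sample_expression <- function(genes, seed = 1L, log_sd = 2,
                              quantifiable_fraction = 1,
                              sample_id = "sample") {
  ids <- if (is.character(genes)) genes
         else genes$gene_id[genes$gene_class != "rrna"]
  if (length(ids) == 0) stop("no quantifiable genes to draw expression for")
  if (log_sd <= 0) stop("log_sd must be > 0")
  if (quantifiable_fraction <= 0 || quantifiable_fraction > 1)
    stop("quantifiable_fraction must be in (0, 1]")
  set.seed(seed)
  a <- exp(stats::rnorm(length(ids), 0, log_sd))
  expression_profile(sample_id, stats::setNames(a / sum(a), ids),
                     quantifiable_fraction)
}

expression_profile <- function(sample_id, abundance, quantifiable_fraction) {
  stopifnot(all(abundance >= 0), abs(sum(abundance) - 1) < 1e-8,
            quantifiable_fraction > 0, quantifiable_fraction <= 1)
  structure(list(sample_id = sample_id, abundance = abundance,
                 quantifiable_fraction = quantifiable_fraction),
            class = "expression_profile")
}

#' Mix two expression profiles by RNA mass
#'
#' The defining subtlety: mixing is by total RNA mass, but only the
#' quantifiable fraction of each source yields mappable reads. The
#' quantifiable read share of source A is therefore
#' `r*qA / (r*qA + (1-r)*qB)` rather than `r`, which is exactly the
#' mechanism behind an equal-mass mixture reading out as 70:30.
#'
#' @param profile_A,profile_B [expression_profile]s over the same genes.
#' @param mass_ratio_A mass fraction of A in \[0, 1\].
#' @export
compose_mixture <- function(profile_A, profile_B, mass_ratio_A) {
  r <- mass_ratio_A
  if (r < 0 || r > 1) stop("mass_ratio_A must be in [0, 1]")
  if (!setequal(names(profile_A$abundance), names(profile_B$abundance)))
    stop("profiles must cover the same gene universe")
  if (r == 1) return(profile_A)
  if (r == 0) return(profile_B)
  ids <- names(profile_A$abundance)
  qa <- profile_A$quantifiable_fraction
  qb <- profile_B$quantifiable_fraction
  wa <- r * qa
  wb <- (1 - r) * qb
  mix <- wa * profile_A$abundance[ids] + wb * profile_B$abundance[ids]
  expression_profile(
    sample_id = paste0(profile_A$sample_id, r * 100, ":",
                       profile_B$sample_id, (1 - r) * 100),
    abundance = mix / sum(mix),
    quantifiable_fraction = wa + wb)
}

#' The study's six-point mixture panel
#'
#' @param profile_A,profile_B pure-sample profiles.
#' @param ratios mass ratios of A; defaults to the panel
#'   100:0, 99:1, 95:5, 90:10, 50:50, 0:100.
#' @return named list of mixed profiles labelled `"100:0"`, `"99:1"`, ...
#' @export
mixture_panel <- function(profile_A, profile_B,
                          ratios = c(1, 0.99, 0.95, 0.90, 0.50, 0)) {
  labs <- paste0(ratios * 100, ":", (1 - ratios) * 100)
  out <- lapply(ratios, function(r) compose_mixture(profile_A, profile_B, r))
  stats::setNames(out, labs)
}

gene_sampling_weights <- function(genes, expr, platform, context = c("promoter", "exon")) {
  context <- match.arg(context)
  ids <- names(expr$abundance)
  gi <- match(ids, genes$gene_id)
  if (anyNA(gi)) stop("expression profile names not all present in gene models")
  gc <- if (context == "promoter") genes$promoter_gc[gi] else genes$exonic_gc[gi]
  w <- expr$abundance * exp(platform$gc_bias_coef * (gc - 0.5))
  if (platform$ecop15i_boost != 1) {
    near <- vapply(genes$antisense_site_offsets[gi], function(o)
      length(o) > 0 && min(o) <= platform$ecop15i_max_dist, logical(1))
    w[near] <- w[near] * platform$ecop15i_boost
  }
  list(w = w, gi = gi, ids = ids)
}

draw_rrna_rate <- function(platform) {
  if (platform$rrna_rate_sd == 0) return(platform$rrna_rate_mean)
  min(1, max(0, stats::rnorm(1, platform$rrna_rate_mean, platform$rrna_rate_sd)))
}

new_read_set <- function(df, type) {
  class(df) <- c("read_set", "data.frame")
  attr(df, "read_type") <- type
  df
}

read_type <- function(reads) attr(reads, "read_type")

#' Simulate a CAGE tag set under a platform model
#'
#' Genes are sampled proportional to abundance x first-base capture weight
#' x GC amplification weight x EcoP15I boost; a per-sample ribosomal
#' carryover rate is drawn once. Per tag, biological start heterogeneity
#' (`jitter_frac` of tags start one base up- or downstream) is applied
#' first, then the artifact transforms: (1) nontemplated G addition with
#' probability `g_add_prob` — if the strand-aware upstream genomic base is
#' G the tag aligns one base upstream, otherwise the raw leading G
#' mismatches and is trimmed back to the start; (2) if T-stretch shifting is
#' enabled and the gene's TSS T run is at least `tstretch_min_run`, the
#' aligned start moves to just past the run. `shifted_by` records the
#' artifact displacement in sense coordinates (0 when all mechanisms are
#' off); `raw_leading_base` records the first base of the raw tag before
#' trimming.
#'
#' @param genome a [synthetic_genome()].
#' @param genes gene models.
#' @param expr an [expression_profile][sample_expression()].
#' @param platform a [platform_model()] of a CAGE preset.
#' @param depth number of tags (>= 0).
#' @param seed integer seed.
#' @return a `read_set` data frame (read type `"cage"`) with columns
#'   `sample_id`, `chrom`, `strand`, `pos5`, `origin_gene`,
#'   `raw_leading_base`, `shifted_by`.
#' @export
simulate_cage <- function(genome, genes, expr, platform, depth, seed = 1L) {
  if (!inherits(platform, "platform_model")) stop("platform must be a platform_model")
  if (platform$platform == "rnaseq")
    stop("use simulate_rnaseq() for fragment platforms")
  if (depth < 0) stop("depth must be >= 0")
  depth <- as.integer(depth)
  set.seed(seed)
  empty <- data.frame(
    sample_id = character(0), chrom = character(0), strand = character(0),
    pos5 = integer(0), origin_gene = character(0),
    raw_leading_base = character(0), shifted_by = integer(0),
    stringsAsFactors = FALSE)
  if (depth == 0) return(new_read_set(empty, "cage"))

  rr <- draw_rrna_rate(platform)
  n_rrna <- stats::rbinom(1, depth, rr)
  n_tag <- depth - n_rrna

  gw <- gene_sampling_weights(genes, expr, platform, "promoter")
  tssb <- sense_base(genome, genes$chrom[gw$gi], genes$tss[gw$gi],
                     genes$strand[gw$gi])
  w <- gw$w * platform$first_base_weights[tssb]
  cnt <- as.vector(stats::rmultinom(1, n_tag, w))

  gi <- rep(gw$gi, cnt)                      # gene-model row per tag
  ord <- sample.int(length(gi))              # shuffle tag order
  gi <- gi[ord]
  ch <- genes$chrom[gi]
  st <- genes$strand[gi]
  tss <- genes$tss[gi]
  n <- length(gi)
  sgn <- ifelse(st == "+", 1L, -1L)

  ## biological start heterogeneity at +/- 1 bp
  eps <- integer(n)
  if (platform$jitter_frac > 0) {
    j <- stats::runif(n) < platform$jitter_frac
    eps[j] <- sample(c(-1L, 1L), sum(j), replace = TRUE)
  }
  b <- tss + sgn * eps                       # true biological start
  raw_base <- sense_base(genome, ch, b, st)
  pos5 <- b
  shift <- integer(n)

  ## (1) nontemplated G addition
  if (platform$g_add_prob > 0) {
    add <- stats::runif(n) < platform$g_add_prob
    up <- sense_base(genome, ch, b - sgn, st)  # strand-aware upstream base
    raw_base[add] <- "G"
    aligned_up <- add & up == "G"
    pos5[aligned_up] <- b[aligned_up] - sgn[aligned_up]
    shift[aligned_up] <- -1L
    ## trimmed otherwise: pos5 stays at b, shift 0
  }

  ## (2) fill-and-lock T-stretch shifting (anchored at the annotated TSS)
  if (platform$tstretch_shift_enabled) {
    run <- genes$tss_t_run[gi]
    sh <- run >= platform$tstretch_min_run
    pos5[sh] <- tss[sh] + sgn[sh] * run[sh]
    shift[sh] <- run[sh]
  }

  clens <- vapply(names(genome), function(c) chrom_len(genome, c), numeric(1))
  pos5 <- pmin(pmax(pos5, 0L), as.integer(clens[ch]) - 1L)

  tags <- data.frame(
    sample_id = expr$sample_id, chrom = ch, strand = st,
    pos5 = as.integer(pos5), origin_gene = genes$gene_id[gi],
    raw_leading_base = raw_base, shifted_by = as.integer(shift),
    stringsAsFactors = FALSE)

  if (n_rrna > 0) {
    rrna <- rrna_reads_cage(genome, genes, n_rrna, expr$sample_id)
    tags <- rbind(tags, rrna)
  }
  rownames(tags) <- NULL
  new_read_set(tags, "cage")
}

rrna_gene <- function(genes) {
  i <- which(genes$gene_class == "rrna")
  if (length(i) == 0) NULL else i[1]
}

rrna_reads_cage <- function(genome, genes, n, sample_id) {
  i <- rrna_gene(genes)
  if (is.null(i)) {
    ## no ribosomal model: park carryover at contig start on +
    ch <- names(genome)[1]
    pos <- rep(0L, n); st <- rep("+", n)
  } else {
    ch <- rep(genes$chrom[i], n)
    st <- rep(genes$strand[i], n)
    ## spread over the ribosomal gene body
    lo <- min(genes$exon_starts[[i]]); hi <- max(genes$exon_ends[[i]]) - 1L
    pos <- sample(lo:hi, n, replace = TRUE)
  }
  data.frame(sample_id = sample_id, chrom = ch, strand = st,
             pos5 = as.integer(pos), origin_gene = "rrna",
             raw_leading_base = sense_base(genome, ch, pos, st),
             shifted_by = 0L, stringsAsFactors = FALSE)
}

## spliced transcript length
exonic_length <- function(genes) {
  vapply(seq_len(nrow(genes)), function(i)
    sum(genes$exon_ends[[i]] - genes$exon_starts[[i]]), numeric(1))
}

#' Simulate a polyA-selected RNA-seq fragment set
#'
#' Under polyA selection, histone-like (non-polyadenylated) genes are
#' retained only with probability `polya_escape_rate`. Gene sampling weight
#' further includes the exonic-GC amplification term; fragment 5' ends are
#' uniform over each transcript's spliced coordinates, with a fixed fragment
#' length clipped at the transcript end; the interval is projected back to
#' genomic coordinates. A per-sample ribosomal carryover rate is drawn once.
#'
#' @inheritParams simulate_cage
#' @param platform a [platform_model()] `rnaseq` preset.
#' @return a `read_set` (read type `"rnaseq"`) with columns `sample_id`,
#'   `chrom`, `strand`, `frag_start`, `frag_end` (0-based half-open genomic
#'   span), `pos5` (genomic 5' position), `origin_gene`, `raw_leading_base`,
#'   `shifted_by`.
#' @export
simulate_rnaseq <- function(genome, genes, expr, platform, depth, seed = 1L) {
  if (!inherits(platform, "platform_model")) stop("platform must be a platform_model")
  if (platform$platform != "rnaseq")
    stop("use simulate_cage() for tag platforms")
  if (depth < 0) stop("depth must be >= 0")
  depth <- as.integer(depth)
  set.seed(seed)
  empty <- data.frame(
    sample_id = character(0), chrom = character(0), strand = character(0),
    frag_start = integer(0), frag_end = integer(0), pos5 = integer(0),
    origin_gene = character(0), raw_leading_base = character(0),
    shifted_by = integer(0), stringsAsFactors = FALSE)
  if (depth == 0) return(new_read_set(empty, "rnaseq"))

  rr <- draw_rrna_rate(platform)
  n_rrna <- stats::rbinom(1, depth, rr)
  n_frag <- depth - n_rrna

  gw <- gene_sampling_weights(genes, expr, platform, "exon")
  w <- gw$w
  if (platform$polya_select) {
    hist_like <- genes$gene_class[gw$gi] == "histone_like"
    w[hist_like] <- w[hist_like] * platform$polya_escape_rate
  }
  if (sum(w) == 0) {
    cnt <- integer(length(w))
  } else {
    cnt <- as.vector(stats::rmultinom(1, n_frag, w))
  }

  out <- vector("list", length(gw$gi) + 1L)
  for (k in seq_along(gw$gi)) {
    if (cnt[k] == 0) next
    i <- gw$gi[k]
    out[[k]] <- gene_fragments(genes, i, cnt[k], platform$fragment_len,
                               expr$sample_id, genome)
  }
  if (n_rrna > 0) {
    i <- rrna_gene(genes)
    if (!is.null(i)) {
      rf <- gene_fragments(genes, i, n_rrna, platform$fragment_len,
                           expr$sample_id, genome)
      rf$origin_gene <- "rrna"
      out[[length(out)]] <- rf
    }
  }
  frags <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(frags)) frags <- empty
  rownames(frags) <- NULL
  new_read_set(frags, "rnaseq")
}

## n fragments from gene i: 5' ends uniform on spliced coords, fixed length
## clipped to transcript end, projected to a genomic interval.
gene_fragments <- function(genes, i, n, frag_len, sample_id, genome) {
  st <- genes$exon_starts[[i]]; en <- genes$exon_ends[[i]]
  sizes <- en - st
  tx_len <- sum(sizes)
  strand <- genes$strand[i]
  ## spliced coordinate -> genomic position map (sense order)
  gpos <- unlist(mapply(function(a, b) a:(b - 1L), st, en, SIMPLIFY = FALSE))
  if (strand == "-") gpos <- rev(gpos)
  s5 <- sample.int(tx_len, n, replace = TRUE)          # 1-based spliced start
  s3 <- pmin(s5 + frag_len - 1L, tx_len)
  g5 <- gpos[s5]
  g3 <- gpos[s3]
  frag_start <- pmin(g5, g3)
  frag_end <- pmax(g5, g3) + 1L
  data.frame(
    sample_id = sample_id, chrom = genes$chrom[i], strand = strand,
    frag_start = as.integer(frag_start), frag_end = as.integer(frag_end),
    pos5 = as.integer(g5), origin_gene = genes$gene_id[i],
    raw_leading_base = sense_base(genome, genes$chrom[i], g5, strand),
    shifted_by = 0L, stringsAsFactors = FALSE)
}

#' Multinomial gene counts from an expression profile
#'
#' Depth-limited sampling of a count vector directly from per-gene
#' abundances — the genome-free counterpart of the read simulators, used for
#' profile-level experiments (mixtures, replicate panels) at realistic
#' depths.
#'
#' @param expr an expression profile.
#' @param depth total reads.
#' @param seed integer seed.
#' @return named integer vector of counts.
#' @export
sample_profile_counts <- function(expr, depth, seed = 1L) {
  set.seed(seed)
  cnt <- stats::rmultinom(1, depth, expr$abundance)[, 1]
  stats::setNames(as.integer(cnt), names(expr$abundance))
}

#' Negative-binomial replicate counts at a common overdispersion
#'
#' Generates technical-replicate count columns around library-size-scaled
#' expected values with a shared overdispersion `phi`
#' (variance = mu + phi * mu^2); `phi = 0` gives Poisson counts.
#'
#' @param expr an expression profile (expected share per gene).
#' @param lib_sizes vector of per-replicate library sizes.
#' @param phi common overdispersion (>= 0).
#' @param seed integer seed.
#' @return a [count_matrix()] with one column per replicate.
#' @export
simulate_nb_replicates <- function(expr, lib_sizes, phi, seed = 1L) {
  stopifnot(phi >= 0, all(lib_sizes > 0))
  set.seed(seed)
  mu <- outer(expr$abundance, lib_sizes)
  x <- if (phi == 0) {
    stats::rpois(length(mu), mu)
  } else {
    stats::rnbinom(length(mu), mu = mu, size = 1 / phi)
  }
  m <- matrix(as.integer(x), nrow = nrow(mu),
              dimnames = list(names(expr$abundance),
                              paste0("rep", seq_along(lib_sizes))))
  count_matrix(m, lib_sizes = colSums(m))
}
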