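#' Hierarchical clustering of samples with gene-bootstrap support
#'
#' Samples are clustered on Spearman-correlation distance (1 - rho) over
#' the `top_n` most highly expressed genes (ranked by mean normalized
#' expression) with average linkage. Edge support is the fraction of `B`
#' gene resamples (with replacement, same size) whose dendrogram contains
#' the same leaf bipartition.
#'
#' @param mat normalized matrix (genes x samples) or a [count_matrix()]
#'   (normalized internally to tags per million).
#' @param top_n genes retained (default 8000; capped at the gene count with
#'   a warning).
#' @param B bootstrap resamples (default 1000).
#' @param seed integer seed.
#' @param linkage agglomeration method (default "average").
#' @return object of class `boot_dendrogram`: list with `hclust`, `phylo`
#'   (node labels carry supports), `support` (per internal edge, in
#'   \[0, 1\]), `B`, `genes_used`.
#' @export
cluster_with_bootstrap <- function(mat, top_n = 8000, B = 1000, seed = 1L,
                                   linkage = "average") {
  m <- if (inherits(mat, "count_matrix")) normalize_counts(mat, "tpm_tags")
       else as.matrix(mat)
  if (ncol(m) < 3) stop("need at least 3 samples to cluster")
  if (top_n > nrow(m)) {
    warning("top_n exceeds gene count; using all ", nrow(m), " genes")
    top_n <- nrow(m)
  }
  keep <- order(rowMeans(m), decreasing = TRUE)[seq_len(top_n)]
  m <- m[keep, , drop = FALSE]
  set.seed(seed)
  tree_of <- function(x) {
    cc <- suppressWarnings(stats::cor(x, method = "spearman"))
    cc[is.na(cc)] <- 0
    stats::hclust(stats::as.dist(1 - cc), method = linkage)
  }
  hc <- tree_of(m)
  phy <- ape::as.phylo(hc)
  boots <- vector("list", B)
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(m), nrow(m), replace = TRUE)
    boots[[b]] <- ape::as.phylo(tree_of(m[idx, , drop = FALSE]))
  }
  counts <- ape::prop.clades(phy, boots, rooted = TRUE)
  counts[is.na(counts)] <- 0
  support <- counts / B
  phy$node.label <- sprintf("%.3f", support)
  structure(list(hclust = hc, phylo = phy, support = support, B = B,
                 genes_used = rownames(m)),
            class = "boot_dendrogram")
}

#' @export
print.boot_dendrogram <- function(x, ...) {
  cat("bootstrap dendrogram over", length(x$hclust$labels), "samples, B =",
      x$B, "\n")
  cat("supports:", paste(sprintf("%.2f", x$support), collapse = " "), "\n")
  invisible(x)
}

#' Write a bootstrap dendrogram as Newick with supports as node labels
#' @param x a `boot_dendrogram`.
#' @param path output file.
#' @export
write_dendrogram <- function(x, path) {
  ape::write.tree(x$phylo, file = path)
  invisible(path)
}

#' Differential genes between two replicated conditions
#'
#' A Wald-style test on the negative-binomial approximation: with
#' library-size-scaled mean estimates and pseudocount 0.5,
#' `z = (log(muA) - log(muB)) / sqrt(1/sum(xA) + 1/sum(xB) + 2 * phi)`,
#' where `phi` is the common overdispersion pooled from the within-
#' condition estimates; two-sided normal p-values are adjusted by
#' Benjamini-Hochberg.
#'
#' @param counts_A,counts_B matrices (genes x replicates) or
#'   [count_matrix()] objects over the same genes.
#' @param fdr BH threshold (default 0.05).
#' @param phi optional fixed common overdispersion; estimated from the
#'   replicates when NULL.
#' @return list with `table` (gene, log2_fc, z, p, q), `up` and `down`
#'   gene-id vectors (up = higher in A), `phi`.
#' @export
differential_genes <- function(counts_A, counts_B, fdr = 0.05, phi = NULL) {
  getm <- function(x) if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  getl <- function(x) if (inherits(x, "count_matrix")) x$lib_sizes else colSums(getm(x))
  xa <- getm(counts_A); xb <- getm(counts_B)
  if (!identical(rownames(xa), rownames(xb)))
    stop("conditions must share the same gene rows")
  la <- getl(counts_A); lb <- getl(counts_B)
  if (is.null(phi)) {
    fits <- list()
    if (ncol(xa) >= 2)
      fits <- c(fits, list(estimate_common_dispersion(
        count_matrix(xa, lib_sizes = la))))
    if (ncol(xb) >= 2)
      fits <- c(fits, list(estimate_common_dispersion(
        count_matrix(xb, lib_sizes = lb))))
    if (length(fits) == 0) {
      warning("single replicate in both conditions; assuming phi = 0")
      phi <- 0
    } else {
      phi <- mean(vapply(fits, function(f) f$phi, numeric(1)))
    }
  }
  if (ncol(xa) < 2 || ncol(xb) < 2)
    warning("fewer than 2 replicates in a condition; test is approximate")
  mean_lib <- mean(c(la, lb))
  sa <- sum(la / mean_lib); sb <- sum(lb / mean_lib)
  ta <- rowSums(xa); tb <- rowSums(xb)
  keep <- ta + tb > 0
  mu_a <- (ta[keep] + 0.5) / sa
  mu_b <- (tb[keep] + 0.5) / sb
  z <- (log(mu_a) - log(mu_b)) /
    sqrt(1 / (ta[keep] + 0.5) + 1 / (tb[keep] + 0.5) + 2 * phi)
  p <- 2 * stats::pnorm(-abs(z))
  q <- stats::p.adjust(p, method = "BH")
  tab <- data.frame(
    gene = rownames(xa)[keep],
    log2_fc = (log(mu_a) - log(mu_b)) / log(2),
    z = z, p = p, q = q, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab,
       up = tab$gene[tab$q < fdr & tab$z > 0],
       down = tab$gene[tab$q < fdr & tab$z < 0],
       phi = phi)
}

#' Venn-style overlap counts of named gene sets
#'
#' @param sets named list (>= 2) of character vectors.
#' @return list with `regions` (data frame: one row per nonempty-pattern
#'   membership region, columns per set plus `n`), `common_fraction`
#'   (size of the full intersection over the union).
#' @export
overlap_sets <- function(sets) {
  if (length(sets) < 2) stop("need at least 2 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  universe <- unique(unlist(sets))
  memb <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) memb <- matrix(memb, nrow = 1,
                                            dimnames = list(NULL, names(sets)))
  pat <- apply(memb, 1, function(r) paste(as.integer(r), collapse = ""))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  key <- apply(combos, 1, function(r) paste(as.integer(unlist(r)), collapse = ""))
  n <- as.integer(table(factor(pat, levels = key)))
  regions <- cbind(combos, n = n)
  rownames(regions) <- NULL
  inter <- Reduce(intersect, sets)
  list(regions = regions,
       common_fraction = length(inter) / length(universe))
}
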