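#' Pairwise Spearman correlation between samples
#'
#' For each sample pair the correlation is computed with midranks over the
#' genes that are nonzero in at least one of the two samples; a constant
#' vector within a pair makes the correlation undefined and raises an
#' error.
#'
#' @param x a [count_matrix()] or a plain numeric matrix (genes x samples).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
spearman_pairwise <- function(x) {
  m <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  if (ncol(m) < 2) stop("need at least 2 samples")
  n <- ncol(m)
  out <- diag(1, n)
  dimnames(out) <- list(colnames(m), colnames(m))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      keep <- m[, i] != 0 | m[, j] != 0
      a <- m[keep, i]; b <- m[keep, j]
      if (length(a) < 2 || stats::sd(a) == 0 || stats::sd(b) == 0)
        stop("undefined Spearman correlation for pair (",
             colnames(m)[i], ", ", colnames(m)[j], "): constant vector")
      out[i, j] <- out[j, i] <- stats::cor(a, b, method = "spearman")
    }
  }
  out
}

#' Common negative-binomial overdispersion across technical replicates
#'
#' Fits `count_gi ~ NB(mean = s_i * mu_g, dispersion = phi)` with
#' library-size factors `s_i = lib_i / mean(lib)` and per-gene moment
#' plug-in means `mu_g = sum_i x_gi / sum_i s_i`, and maximizes the
#' Cox-Reid adjusted profile log-likelihood over a single shared `phi` by
#' golden-section search on \[1e-6, 1\] (tolerance 1e-6). The adjustment
#' (minus half the log Fisher information of each fitted gene mean)
#' removes the downward bias that plug-in means would otherwise cause with
#' few replicates. `sqrt(phi)` is the relative standard error of expression
#' between replicates — a reproducibility metric independent of sequencing
#' depth, unlike the correlation coefficient.
#'
#' Genes with mean count below `min_mean` are dropped before fitting; at
#' least `min_genes` must survive.
#'
#' @param replicates a [count_matrix()] of technical replicates (>= 2
#'   columns).
#' @param min_mean per-gene mean-count filter (default 5).
#' @param min_genes minimum usable genes (default 50).
#' @return object of class `dispersion_fit`: list with `phi`,
#'   `relative_se` (= sqrt(phi)), `n_genes_used`, `log_likelihood`.
#' @export
estimate_common_dispersion <- function(replicates, min_mean = 5,
                                       min_genes = 50) {
  x <- if (inherits(replicates, "count_matrix")) replicates$counts
       else as.matrix(replicates)
  lib <- if (inherits(replicates, "count_matrix")) replicates$lib_sizes
         else colSums(x)
  if (ncol(x) < 2) stop("need at least 2 replicate columns")
  s <- lib / mean(lib)
  keep <- rowMeans(x) >= min_mean
  if (sum(keep) < min_genes)
    stop("too few usable genes after the mean-count filter (",
         sum(keep), " < ", min_genes, ")")
  x <- x[keep, , drop = FALSE]
  mu <- rowSums(x) / sum(s)
  M <- outer(mu, s)
  apl <- function(phi) {
    w <- M / (1 + phi * M)   # Fisher information per observation for log-mean
    sum(stats::dnbinom(x, mu = M, size = 1 / phi, log = TRUE)) -
      0.5 * sum(log(rowSums(w)))
  }
  opt <- golden_section_max(apl, 1e-6, 1, tol = 1e-6)
  structure(list(phi = opt$x, relative_se = sqrt(opt$x),
                 n_genes_used = nrow(x), log_likelihood = opt$value),
            class = "dispersion_fit")
}

#' @export
print.dispersion_fit <- function(x, ...) {
  cat(sprintf("common overdispersion phi = %.6f (relative SE %.2f%%), %d genes\n",
              x$phi, 100 * x$relative_se, x$n_genes_used))
  invisible(x)
}

## 1-D golden-section maximization on [lo, hi]
golden_section_max <- function(f, lo, hi, tol = 1e-6) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c <- b - gr * (b - a)
  d <- a + gr * (b - a)
  fc <- f(c); fd <- f(d)
  while (b - a > tol) {
    if (fc > fd) {
      b <- d; d <- c; fd <- fc
      c <- b - gr * (b - a); fc <- f(c)
    } else {
      a <- c; c <- d; fc <- fd
      d <- a + gr * (b - a); fd <- f(d)
    }
  }
  x <- (a + b) / 2
  list(x = x, value = f(x))
}
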