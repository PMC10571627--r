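#' Remove genes with low average expression
#'
#' Keeps a gene only when its mean read count per sample is at least
#' `min_mean_reads_per_sample`. The default 0.1 corresponds to the rule of
#' excluding genes with less than 1 read per 10 samples on average; the
#' boundary is inclusive (a gene exactly at the threshold survives).
#'
#' @param counts Count matrix, genes x samples.
#' @param min_mean_reads_per_sample Minimum mean reads per sample to keep a
#'   gene (default 0.1).
#' @return A list with `counts` (surviving genes, original order) and
#'   `n_removed`.
#' @export
filter_low_expression <- function(counts, min_mean_reads_per_sample = 0.1) {
  means <- rowSums(counts) / ncol(counts)
  keep <- means >= min_mean_reads_per_sample
  if (!any(keep))
    stop("all genes removed by the expression filter; review the threshold (",
         min_mean_reads_per_sample, " mean reads/sample)", call. = FALSE)
  list(counts = counts[keep, , drop = FALSE], n_removed = sum(!keep))
}

#' Log2 counts-per-million transform
#'
#' The voom-style normalization scale: for count y in a sample with library
#' size L (total raw reads), the value is log2((y + 0.5) / (L + 1) * 1e6).
#' Library sizes are taken from the matrix passed in, so filtering decisions
#' about when to compute them rest with the caller; [sgsea()] computes them
#' on the pre-filter matrix.
#'
#' @param counts Count matrix, genes x samples.
#' @param lib_sizes Optional per-sample library sizes; defaults to the column
#'   sums of `counts`.
#' @return Matrix of log2-CPM values with `attr(, "lib_sizes")`.
#' @export
logcpm_transform <- function(counts, lib_sizes = NULL) {
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) {
    bad <- colnames(counts)[lib_sizes <= 0]
    stop("zero library size for sample(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  expr <- log2(sweep(counts + 0.5, 2, lib_sizes + 1, "/") * 1e6)
  dimnames(expr) <- dimnames(counts)
  attr(expr, "lib_sizes") <- lib_sizes
  expr
}

#' Mean-variance precision weights
#'
#' Estimates the mean-variance trend of the log-CPM values with a lowess fit
#' of the square-root residual standard deviation against the per-gene mean,
#' in the spirit of voom, and converts the trend-predicted square-root
#' standard deviation s into inverse-variance weights 1 / max(s, floor)^4.
#' The weights are informational: the Cox ranking deliberately fits
#' unweighted models (see the methods vignette), so nothing downstream
#' consumes them.
#'
#' @param expr log2-CPM matrix from [logcpm_transform()].
#' @param span Lowess span for the trend fit.
#' @param floor Lower bound on the predicted square-root standard deviation.
#' @return Matrix of positive weights, same shape as `expr` (constant within
#'   a gene in this per-gene approximation).
#' @export
mean_variance_weights <- function(expr, span = 0.5, floor = 1e-2) {
  if (nrow(expr) < 10L)
    stop("mean-variance trend needs at least 10 genes", call. = FALSE)
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1, stats::sd)
  if (all(sdv == 0)) {
    warning("all genes constant: uniform precision weights", call. = FALSE)
    w <- matrix(1, nrow(expr), ncol(expr), dimnames = dimnames(expr))
    return(w)
  }
  fit <- stats::lowess(mu, sqrt(sdv), f = span)
  pred <- stats::approx(fit$x, fit$y, xout = mu, rule = 2, ties = mean)$y
  pred <- pmax(pred, floor)
  w <- matrix(1 / pred^4, nrow(expr), ncol(expr), dimnames = dimnames(expr))
  w
}

#' Median-of-ratios size factors
#'
#' The DESeq-style normalization for the negative-binomial mode: for each
#' sample, the size factor is the median over genes (restricted to genes
#' with positive counts in every sample) of the ratio of the sample's count
#' to the gene's geometric mean across samples.
#'
#' @param counts Count matrix, genes x samples.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  pos <- rowSums(counts <= 0) == 0L
  if (!any(pos))
    stop("no gene has positive counts in every sample; cannot estimate ",
         "median-of-ratios size factors", call. = FALSE)
  lc <- log(counts[pos, , drop = FALSE])
  geo <- rowMeans(lc)
  sf <- apply(lc, 2, function(col) exp(stats::median(col - geo)))
  names(sf) <- colnames(counts)
  sf
}
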