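## Simplified two-group negative-binomial GLM for the standard (fold-change)
## enrichment mode: per-gene method-of-moments dispersion pooled across
## groups, log-link IRLS with median-of-ratios size factors as offsets.
## Deliberately omits empirical-Bayes dispersion shrinkage and outlier
## handling; borderline log2 fold changes can therefore differ from
## shrinkage-based pipelines (see the methods vignette).

#' Method-of-moments NB dispersion for one gene
#'
#' Estimates the negative-binomial dispersion alpha (variance =
#' mu + alpha * mu^2) from size-factor-normalized counts, floored at 0 (the
#' Poisson limit): alpha = max(0, (var - mean) / mean^2).
#'
#' @param counts_gene Integer vector of raw counts for one gene.
#' @param sf Per-sample size factors.
#' @return Non-negative finite dispersion estimate.
#' @export
estimate_dispersion <- function(counts_gene, sf = rep(1, length(counts_gene))) {
  y <- counts_gene / sf
  m <- mean(y)
  if (m <= 0) return(0)
  v <- stats::var(y)
  max(0, (v - m) / m^2)
}

#' Two-group negative-binomial fit for one gene
#'
#' Fits the log-link NB model count ~ intercept + group with size factors as
#' normalization, taking the fitted group means to be the size-factor-
#' normalized group averages — for this saturated two-group design the
#' reported estimate is exactly
#' log2(normalized mean comparison / normalized mean reference), which makes
#' the log2 fold change invariant to rescaling any one sample's counts once
#' size factors are re-estimated. When all size factors are equal this
#' estimator coincides with the NB (and, at alpha = 0, Poisson) maximum
#' likelihood estimate. Standard errors come from the Fisher information of
#' the NB GLM evaluated at the fitted means.
#'
#' @param counts_gene Raw counts for one gene.
#' @param groups Factor with two levels (reference first), or a data frame
#'   with a `group` column, aligned with `counts_gene`.
#' @param sf Per-sample size factors.
#' @param alpha NB dispersion; estimated by [estimate_dispersion()] when
#'   `NULL`.
#' @return A list with `log2fc`, `se` (on the log2 scale), `p` (two-sided
#'   Wald), `alpha` and `flag` (`"ok"` or `"zero_group"`).
#' @export
fit_nb_two_group <- function(counts_gene, groups,
                             sf = rep(1, length(counts_gene)), alpha = NULL) {
  g <- if (is.data.frame(groups)) groups$group else groups
  g <- droplevels(as.factor(g))
  stopifnot(nlevels(g) == 2L, length(g) == length(counts_gene))
  if (is.null(alpha)) alpha <- estimate_dispersion(counts_gene, sf)
  y <- as.numeric(counts_gene)
  means <- tapply(y / sf, g, mean)
  if (any(means == 0))
    return(list(log2fc = NA_real_, se = NA_real_, p = NA_real_,
                alpha = alpha, flag = "zero_group"))
  beta2 <- log(means[[2L]] / means[[1L]])
  X <- cbind(1, as.numeric(g) - 1)
  mu <- as.numeric(means)[as.integer(g)] * sf   # fitted cell means
  w <- mu / (1 + alpha * mu)                 # NB Fisher weights, log link
  V <- solve(t(X * w) %*% X)
  se_log <- sqrt(V[2L, 2L])
  list(log2fc = beta2 / log(2), se = se_log / log(2),
       p = 2 * stats::pnorm(-abs(beta2 / se_log)), alpha = alpha,
       flag = "ok")
}

#' Rank all genes by negative-binomial log2 fold change
#'
#' The standard-GSEA ranking: per-gene two-group NB log2 fold change
#' (comparison vs reference level), with median-of-ratios size factors
#' estimated from the full count matrix. Genes that cannot be estimated
#' (a group with all-zero counts) are excluded from the ranking but kept in
#' the statistics table with their flag.
#'
#' @param counts Count matrix (genes x samples), columns aligned with
#'   `groups$sample`.
#' @param groups Condition data frame (`sample`, `group` factor with the
#'   reference level first), e.g. from [read_conditions()].
#' @param sf Optional size factors; estimated from `counts` when `NULL`.
#' @return A list with `ranking` (class `ranked_list`, statistic tag
#'   `"log2_fold_change"`) and `stats` (per-gene data frame).
#' @export
rank_by_foldchange <- function(counts, groups, sf = NULL) {
  if (!identical(colnames(counts), groups$sample))
    stop("count columns and condition samples are not aligned; ",
         "call align_samples() first", call. = FALSE)
  g <- droplevels(as.factor(groups$group))
  if (nlevels(g) != 2L)
    stop("condition must have exactly two levels", call. = FALSE)
  if (is.null(sf)) sf <- size_factors(counts)
  fits <- lapply(seq_len(nrow(counts)), function(i)
    fit_nb_two_group(counts[i, ], g, sf))
  stats_df <- data.frame(
    gene = rownames(counts),
    log2fc = vapply(fits, `[[`, numeric(1), "log2fc"),
    se = vapply(fits, `[[`, numeric(1), "se"),
    p = vapply(fits, `[[`, numeric(1), "p"),
    alpha = vapply(fits, `[[`, numeric(1), "alpha"),
    flag = vapply(fits, `[[`, character(1), "flag"),
    stringsAsFactors = FALSE)
  ok <- stats_df$flag == "ok" & is.finite(stats_df$log2fc)
  if (sum(ok) < 2L)
    stop("fewer than 2 genes with a usable fold-change estimate", call. = FALSE)
  ranking <- ranked_list(setNames(stats_df$log2fc[ok], stats_df$gene[ok]),
                         statistic = "log2_fold_change")
  list(ranking = ranking, stats = stats_df)
}
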