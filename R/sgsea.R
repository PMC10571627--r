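#' Survival-based (or fold-change-based) gene set enrichment analysis
#'
#' The one-stop fitting function. In `"survival"` mode it filters
#' low-expression genes, computes voom-style log2-CPM normalized expression,
#' ranks genes by the per-gene Cox log hazard ratio of mortality on
#' expression, and runs preranked weighted Kolmogorov-Smirnov enrichment
#' against the supplied gene sets: pathways with positive normalized
#' enrichment scores are enriched in genes whose increased expression is
#' associated with a higher risk of death, negative scores with survival.
#' In `"foldchange"` mode the ranking statistic is instead the two-group
#' negative-binomial log2 fold change (comparison vs reference level) with
#' median-of-ratios size factors — the standard case-vs-control analysis.
#'
#' @param counts Count matrix, genes x samples (see [read_counts()]).
#' @param genesets Named list of gene sets (see [read_gmt()]).
#' @param survival Survival data frame (`sample`, `time`, `status`);
#'   required in survival mode.
#' @param conditions Condition data frame (`sample`, two-level `group`);
#'   required in foldchange mode.
#' @param mode `"survival"` or `"foldchange"`.
#' @param min_mean_reads Low-expression filter threshold, mean reads per
#'   sample (default 0.1, i.e. 1 read per 10 samples).
#' @param ties,rank_stat Cox fit options, see [rank_by_hazard()].
#' @param min_size,max_size,n_perm,exponent Enrichment options, see
#'   [run_enrichment()].
#' @param alpha Significance level on BH-adjusted p-values used by
#'   [summary.sgsea()] and [top_tables()] (default 0.15).
#' @param seed Optional integer seed making the permutation null
#'   reproducible.
#' @return An object of class `sgsea`: a list with `results` (the
#'   enrichment table), `ranking`, `gene_stats`, `mode`, `n_filtered`,
#'   `lib_sizes`, `params` and `call`. Methods: `print`, `summary`, `plot`.
#' @examples
#' sim <- simulate_dataset(sim_config(n_samples = 60, n_genes = 300,
#'                                    seed = 7, n_decoy_sets = 5), "survival")
#' fit <- sgsea(sim$counts, sim$sets, survival = sim$survival,
#'              n_perm = 200, seed = 7)
#' head(summary(fit))
#' @export
sgsea <- function(counts, genesets, survival = NULL, conditions = NULL,
                  mode = c("survival", "foldchange"),
                  min_mean_reads = 0.1,
                  ties = c("efron", "breslow"), rank_stat = c("beta", "z"),
                  min_size = 15L, max_size = 500L, n_perm = 10000L,
                  exponent = 1, alpha = 0.15, seed = NULL) {
  mode <- match.arg(mode)
  ties <- match.arg(ties)
  rank_stat <- match.arg(rank_stat)
  cl <- match.call()
  if (mode == "survival" && is.null(survival))
    stop("survival mode requires a survival table", call. = FALSE)
  if (mode == "foldchange" && is.null(conditions))
    stop("foldchange mode requires condition labels", call. = FALSE)

  meta <- if (mode == "survival") survival else conditions
  al <- align_samples(counts, meta)
  counts <- al$counts; meta <- al$meta
  lib_sizes <- colSums(counts)              # pre-filter, by design
  flt <- filter_low_expression(counts, min_mean_reads)

  if (mode == "survival") {
    expr <- logcpm_transform(flt$counts, lib_sizes = lib_sizes)
    rk <- rank_by_hazard(expr, meta, ties = ties, rank_stat = rank_stat)
  } else {
    rk <- rank_by_foldchange(flt$counts, meta)
  }
  results <- run_enrichment(rk$ranking, genesets, min_size = min_size,
                            max_size = max_size, n_perm = n_perm,
                            exponent = exponent, seed = seed)
  structure(list(results = results, ranking = rk$ranking,
                 gene_stats = rk$stats, mode = mode,
                 n_samples = al$n_common,
                 n_filtered = flt$n_removed, lib_sizes = lib_sizes,
                 params = list(min_mean_reads = min_mean_reads, ties = ties,
                               rank_stat = rank_stat, min_size = min_size,
                               max_size = max_size, n_perm = n_perm,
                               exponent = exponent, alpha = alpha,
                               seed = seed),
                 call = cl),
            class = "sgsea")
}

#' @export
print.sgsea <- function(x, ...) {
  stat <- attr(x$ranking, "statistic")
  cat("Gene set enrichment on a", stat, "ranking (mode:", x$mode, ")\n")
  cat(sprintf("  %d samples, %d ranked genes (%d filtered, %d degenerate)\n",
              x$n_samples, length(x$ranking), x$n_filtered,
              sum(x$gene_stats$flag != "ok")))
  cat(sprintf("  %d pathways tested, %d permutations per set size\n",
              nrow(x$results), x$params$n_perm))
  nsig <- sum(x$results$padj < x$params$alpha)
  cat(sprintf("  %d pathway(s) with adjusted p < %.2f\n", nsig,
              x$params$alpha))
  min_p <- 1 / (x$params$n_perm + 1)
  if (any(x$results$pval <= min_p))
    cat(sprintf("  note: p-values saturate at <= %.3g (permutation floor)\n",
                min_p))
  invisible(x)
}

#' Summarize an enrichment fit
#'
#' @param object An `sgsea` object.
#' @param significant_only Keep only pathways with `padj < alpha`.
#' @param alpha Significance level; defaults to the one stored in the fit.
#' @param ... Unused.
#' @return The enrichment result data frame (leading edge collapsed to a
#'   comma-separated string), sorted by ascending p-value.
#' @export
summary.sgsea <- function(object, significant_only = FALSE, alpha = NULL,
                          ...) {
  if (is.null(alpha)) alpha <- object$params$alpha
  df <- as.data.frame(object$results)
  df$leading_edge <- vapply(df$leading_edge, paste, character(1),
                            collapse = ",")
  if (significant_only) df <- df[df$padj < alpha, , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Top significant pathways by direction
#'
#' Mirrors the headline output of the analysis: among pathways with
#' BH-adjusted p below `alpha`, the `k` strongest positive-NES pathways
#' (associated with mortality on a hazard-ratio ranking) and the `k`
#' strongest negative-NES pathways (associated with survival), each sorted
#' by decreasing |NES|. Fewer rows are returned when fewer qualify.
#'
#' @param results An `sgsea` fit or an enrichment result data frame.
#' @param k Rows per table (default 10).
#' @param alpha Significance level on the adjusted p-value (default 0.15).
#' @return A list with data frames `positive` and `negative`.
#' @export
top_tables <- function(results, k = 10L, alpha = 0.15) {
  if (inherits(results, "sgsea")) results <- results$results
  df <- as.data.frame(results)
  df$leading_edge <- NULL
  sig <- df[!is.na(df$nes) & df$padj < alpha, , drop = FALSE]
  take <- function(d) {
    d <- d[order(-abs(d$nes), d$pathway), , drop = FALSE]
    d <- utils::head(d, k)
    rownames(d) <- NULL
    d
  }
  list(positive = take(sig[sig$nes > 0, , drop = FALSE]),
       negative = take(sig[sig$nes < 0, , drop = FALSE]))
}

#' Data behind an enrichment plot
#'
#' Recomputes the running-sum curve, hit tick positions and enrichment-score
#' marker for one pathway of a fit, so plots can be tested on data rather
#' than pixels. The curve's signed extremum equals the stored enrichment
#' score.
#'
#' @param ranked A `ranked_list`.
#' @param members Gene set members.
#' @param exponent Weighting exponent used in the fit.
#' @return A list with `running_sum`, `hits`, `es`, `es_position` and
#'   `leading_edge`.
#' @export
enrichment_plot_data <- function(ranked, members, exponent = 1) {
  if (!any(members %in% names(ranked)))
    stop("pathway has no members in the ranked universe", call. = FALSE)
  sc <- enrichment_score(ranked, members, exponent)
  es_pos <- if (sc$es >= 0) which.max(sc$running_sum) else
    which.min(sc$running_sum)
  list(running_sum = sc$running_sum, hits = sc$hits, es = sc$es,
       es_position = es_pos, leading_edge = sc$leading_edge)
}

#' Plot the running enrichment score for one pathway
#'
#' The classic enrichment plot: the running sum across the ranked list, tick
#' marks at the positions of the pathway's genes, and a marker at the
#' extremum whose height above (or below) zero is the enrichment score.
#'
#' @param x An `sgsea` object.
#' @param pathway Pathway name to plot; defaults to the smallest-p pathway.
#' @param genesets The gene set collection used in the fit (needed to
#'   recover the full membership).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sgsea <- function(x, pathway = NULL, genesets = NULL, ...) {
  if (is.null(pathway)) pathway <- x$results$pathway[1L]
  i <- match(pathway, x$results$pathway)
  if (is.na(i))
    stop("pathway '", pathway, "' was not tested in this fit", call. = FALSE)
  members <- if (!is.null(genesets)) genesets[[pathway]] else
    x$results$leading_edge[[i]]
  pd <- enrichment_plot_data(x$ranking, members,
                             exponent = x$params$exponent)
  graphics::plot(seq_along(pd$running_sum), pd$running_sum, type = "l",
                 xlab = "rank in gene list", ylab = "running enrichment score",
                 main = sprintf("%s (ES = %.3f, NES = %.2f)", pathway,
                                x$results$es[i], x$results$nes[i]), ...)
  graphics::abline(h = 0, lty = 2, col = "grey50")
  graphics::rug(pd$hits)
  graphics::points(pd$es_position, pd$es, pch = 19, col = "red3")
  invisible(pd)
}
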