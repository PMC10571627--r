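## Preranked weighted Kolmogorov-Smirnov enrichment: running-sum enrichment
## score, gene-set permutation null, sign-stratified NES, permutation
## p-values with add-one correction, BH adjustment, leading edge. Shared
## back end of the survival (log hazard ratio) and fold-change modes.

#' Weighted running-sum enrichment score for one gene set
#'
#' Walks the ranked list from top to bottom; at a gene in the set the running
#' sum increases by |r|^exponent / sum of |r|^exponent over set members, at a
#' gene outside the set it decreases by 1 / (N - Nh). The enrichment score is
#' the signed extremum of largest magnitude (positive extremum preferred on
#' an exact magnitude tie). The leading edge contains the set members at or
#' before the positive extremum (es > 0), or at or after the negative
#' extremum (es < 0).
#'
#' @param ranked A `ranked_list` (named statistics sorted decreasingly).
#' @param members Character vector of member gene ids.
#' @param exponent Weighting exponent on |statistic| (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov statistic).
#' @return A list with `es`, `running_sum` (length-N curve), `hits` (ranked
#'   positions of the members present) and `leading_edge`.
#' @export
enrichment_score <- function(ranked, members, exponent = 1) {
  stats <- as.numeric(ranked)
  genes <- names(ranked)
  N <- length(stats)
  hit <- genes %in% members
  nh <- sum(hit)
  if (nh == 0L)
    stop("gene set has no members in the ranked list", call. = FALSE)
  if (nh == N)
    stop("gene set covers the entire ranked list; the miss decrement is ",
         "undefined", call. = FALSE)
  w <- abs(stats)^exponent
  nr <- sum(w[hit])
  if (nr == 0) {
    warning("all member statistics are zero; using unweighted increments",
            call. = FALSE)
    w[] <- 1
    nr <- nh
  }
  incr <- ifelse(hit, w / nr, -1 / (N - nh))
  running <- cumsum(incr)
  top <- max(running, 0)
  bottom <- min(running, 0)
  es <- if (es_tie_positive(top, bottom)) top else bottom
  hits <- which(hit)
  leading_edge <- if (es > 0) {
    genes[hits[hits <= which.max(running)]]
  } else if (es < 0) {
    genes[hits[hits >= which.min(running)]]
  } else character()
  list(es = es, running_sum = running, hits = hits,
       leading_edge = leading_edge)
}

## Enrichment scores for many same-size gene subsets, given only their sorted
## hit positions. O(set size) per subset: between hits the running sum falls
## linearly, so its extrema lie just before hits, just after hits, or at the
## endpoints (where it is 0). Agrees exactly with enrichment_score().
es_from_positions <- function(w_abs, N, pos, exponent = 1) {
  if (is.null(dim(pos))) pos <- matrix(pos, ncol = 1L)
  k <- nrow(pos)
  W <- matrix(w_abs[pos]^exponent, k, ncol(pos))
  nr <- colSums(W)
  zero <- nr == 0
  if (any(zero)) {
    W[, zero] <- 1
    nr[zero] <- k
  }
  cumW <- if (k == 1L) W else apply(W, 2, cumsum)
  cumW <- matrix(cumW, k, ncol(pos))
  miss <- (pos - row(pos)) / (N - k)
  after <- sweep(cumW, 2, nr, "/") - miss
  before <- sweep(rbind(0, cumW[-k, , drop = FALSE]), 2, nr, "/") - miss
  top <- pmax(apply(after, 2, max), 0)
  bottom <- pmin(apply(before, 2, min), 0)
  ifelse(es_tie_positive(top, bottom), top, bottom)
}

## Sign choice of the extremum of largest magnitude. Exact magnitude ties
## (e.g. a positive extremum of 2/7 against a negative one of -2/7, which
## arise structurally in small universes) resolve to the positive side; the
## comparison uses a relative tolerance so that the choice cannot depend on
## the floating-point summation order of the code path that produced it.
es_tie_positive <- function(top, bottom) {
  top - (-bottom) >= -1e-12 * pmax(top, -bottom)
}

#' Null distribution of enrichment scores for a set size
#'
#' Samples `n_perm` gene subsets of the given size uniformly at random from
#' the ranked universe and computes each subset's enrichment score. This is
#' the plain Monte-Carlo gene-set permutation null; p-values therefore
#' saturate at 1 / (n_perm + 1).
#'
#' @param ranked A `ranked_list`.
#' @param set_size Subset size (0 < set_size < length of the ranking).
#' @param n_perm Number of permutations (>= 100).
#' @param exponent Weighting exponent, as in [enrichment_score()].
#' @param seed Optional integer seed for reproducibility.
#' @return A list with `set_size`, `es` (the null sample), `n_perm`, `seed`.
#' @export
build_null <- function(ranked, set_size, n_perm = 10000L, exponent = 1,
                       seed = NULL) {
  N <- length(ranked)
  if (set_size <= 0L || set_size >= N)
    stop("set_size must lie strictly between 0 and the ranking length ", N,
         call. = FALSE)
  if (n_perm < 100L)
    stop("n_perm must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  pos <- vapply(seq_len(n_perm),
                function(i) sort.int(sample.int(N, set_size)),
                integer(set_size))
  pos <- matrix(pos, nrow = set_size)
  w_abs <- abs(as.numeric(ranked))
  es <- es_from_positions(w_abs, N, pos, exponent)
  list(set_size = set_size, es = es, n_perm = n_perm, seed = seed)
}

#' Normalized enrichment score and permutation p-value
#'
#' Normalizes an observed enrichment score by the mean magnitude of the
#' same-sign null scores (so nes = 1 means "as extreme as an average random
#' set of the same size and sign") and computes the add-one-corrected
#' permutation p-value: (1 + number of same-sign null scores with |null| >=
#' |es|) / (1 + number of same-sign null scores). Ties count as exceedances,
#' which is conservative; the add-one correction keeps p > 0.
#'
#' @param es Observed enrichment score.
#' @param null A null distribution from [build_null()] (or a numeric vector
#'   of null scores).
#' @return A list with `nes`, `pval`, and `degenerate` (TRUE when no null
#'   score shares the sign of `es`, in which case nes is NA and pval 1).
#' @export
nes_pvalue <- function(es, null) {
  null_es <- if (is.list(null)) null$es else null
  if (es == 0)
    return(list(nes = 0, pval = 1, degenerate = FALSE))
  stratum <- if (es > 0) null_es[null_es > 0] else null_es[null_es < 0]
  if (length(stratum) == 0L)
    return(list(nes = NA_real_, pval = 1, degenerate = TRUE))
  nes <- es / mean(abs(stratum))
  pval <- (1 + sum(abs(stratum) >= abs(es))) / (1 + length(stratum))
  list(nes = nes, pval = pval, degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment across the tested pathways.
#'
#' @param pvals Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvals) {
  stats::p.adjust(pvals, method = "BH")
}

#' Preranked gene set enrichment analysis
#'
#' Runs the weighted Kolmogorov-Smirnov enrichment over a gene set
#' collection against a ranked gene list: per set the enrichment score,
#' sign-stratified normalized enrichment score against a gene-set
#' permutation null (one null per distinct set size, cached), add-one
#' permutation p-value, and BH adjustment computed jointly across all
#' retained sets. Positive scores mean the set concentrates at the top of
#' the ranking — with a log-hazard-ratio ranking, association with
#' mortality; negative scores, with survival.
#'
#' @param ranked A `ranked_list`.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param min_size,max_size Retain sets whose overlap with the ranked
#'   universe falls in this range (defaults 15 and 500).
#' @param n_perm Permutations per distinct set size (default 10000).
#' @param exponent Weighting exponent (default 1).
#' @param seed Optional integer seed; fixing it makes results reproducible.
#' @return A data frame of class `enrichment_result` with columns `pathway`,
#'   `size`, `es`, `nes`, `pval`, `padj` and list column `leading_edge`,
#'   sorted by ascending p-value (ties by pathway name). Sets skipped by the
#'   size filter are listed in `attr(, "skipped")`.
#' @export
run_enrichment <- function(ranked, collection, min_size = 15L,
                           max_size = 500L, n_perm = 10000L, exponent = 1,
                           seed = NULL) {
  stopifnot(length(collection) > 0L, !is.null(names(collection)))
  N <- length(ranked)
  universe <- names(ranked)
  overlaps <- lapply(collection, intersect, x = universe)
  sizes <- lengths(overlaps)
  keep <- sizes >= min_size & sizes <= max_size & sizes < N
  if (!any(keep))
    stop("no gene set within size bounds [", min_size, ", ", max_size,
         "]; observed overlap sizes: ",
         paste(range(sizes), collapse = "-"), call. = FALSE)
  skipped <- data.frame(pathway = names(collection)[!keep],
                        size = sizes[!keep], stringsAsFactors = FALSE)
  sets <- collection[keep]
  sizes <- sizes[keep]
  if (!is.null(seed)) set.seed(seed)
  nulls <- new.env(parent = emptyenv())
  for (s in sort(unique(sizes)))   # deterministic null-building order
    assign(as.character(s), build_null(ranked, s, n_perm, exponent),
           envir = nulls)
  scored <- lapply(names(sets), function(nm) {
    sc <- enrichment_score(ranked, sets[[nm]], exponent)
    np <- nes_pvalue(sc$es, get(as.character(sizes[[nm]]), envir = nulls))
    list(pathway = nm, es = sc$es, nes = np$nes, pval = np$pval,
         leading_edge = sc$leading_edge, degenerate = np$degenerate)
  })
  res <- data.frame(
    pathway = vapply(scored, `[[`, character(1), "pathway"),
    size = as.integer(sizes),
    es = vapply(scored, `[[`, numeric(1), "es"),
    nes = vapply(scored, `[[`, numeric(1), "nes"),
    pval = vapply(scored, `[[`, numeric(1), "pval"),
    stringsAsFactors = FALSE)
  res$padj <- bh_adjust(res$pval)
  res$leading_edge <- lapply(scored, `[[`, "leading_edge")
  res <- res[order(res$pval, res$pathway), , drop = FALSE]
  rownames(res) <- NULL
  res <- res[, c("pathway", "size", "es", "nes", "pval", "padj",
                 "leading_edge")]
  attr(res, "skipped") <- skipped
  attr(res, "n_perm") <- n_perm
  attr(res, "statistic") <- attr(ranked, "statistic")
  class(res) <- c("enrichment_result", "data.frame")
  res
}

#' Compare the significant pathway sets of two analyses
#'
#' Counts the pathways significant (BH-adjusted p below `alpha`) in only the
#' first analysis, only the second, and both, over the universe of pathways
#' tested in both — the Venn-diagram comparison between the survival-based
#' and fold-change-based modes.
#'
#' @param resA,resB Enrichment result data frames over a shared pathway
#'   universe.
#' @param alpha Significance level on the adjusted p-value (default 0.15).
#' @return A list with counts `n_A_only`, `n_B_only`, `n_overlap`,
#'   `n_universe` and the pathway name vectors `A_only`, `B_only`, `overlap`.
#' @export
compare_significant <- function(resA, resB, alpha = 0.15) {
  universe <- intersect(resA$pathway, resB$pathway)
  if (length(universe) == 0L)
    stop("the two result sets share no tested pathways", call. = FALSE)
  sigA <- resA$pathway[resA$padj < alpha & resA$pathway %in% universe]
  sigB <- resB$pathway[resB$padj < alpha & resB$pathway %in% universe]
  ov <- intersect(sigA, sigB)
  list(n_A_only = length(setdiff(sigA, sigB)),
       n_B_only = length(setdiff(sigB, sigA)),
       n_overlap = length(ov),
       n_universe = length(universe),
       A_only = sort(setdiff(sigA, sigB)),
       B_only = sort(setdiff(sigB, sigA)),
       overlap = sort(ov))
}
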