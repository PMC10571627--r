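## Univariate Cox proportional hazards fitting by Newton-Raphson on the
## partial likelihood, with Efron (default) or Breslow handling of tied event
## times. The baseline hazard cancels in the partial likelihood and is never
## materialized. One prepared survival structure is shared across all genes.

## Precompute everything about (time, status) that does not depend on the
## covariate: sort order, tie groups, event positions, and the per-(group,
## event) tie fractions l/d used by Efron's correction (0 for Breslow).
cox_prepare <- function(time, status, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(length(time) == length(status), all(time > 0),
            all(status %in% c(0, 1)))
  if (sum(status) < 2L)
    stop("need at least 2 events to fit a Cox model", call. = FALSE)
  ord <- order(time)
  t_s <- time[ord]
  d_s <- as.integer(status[ord])
  grp <- cumsum(c(TRUE, t_s[-1L] != t_s[-length(t_s)]))  # tie-group id
  first_idx <- which(c(TRUE, t_s[-1L] != t_s[-length(t_s)]))
  n_events_g <- as.integer(rowsum(d_s, grp))
  ev_groups <- which(n_events_g > 0L)
  d <- n_events_g[ev_groups]
  gl_group <- rep(ev_groups, d)              # group index per (group, l) term
  frac <- if (ties == "efron") {
    unlist(lapply(d, function(k) seq_len(k) - 1L), use.names = FALSE) /
      rep(d, d)
  } else {
    numeric(sum(d))
  }
  list(n = length(t_s), ord = ord, d_s = d_s, grp = grp,
       first_idx = first_idx, ev_groups = ev_groups,
       gl_group = gl_group, frac = frac,
       events = which(d_s == 1L), n_groups = max(grp), ties = ties)
}

## Partial log-likelihood, score and information at beta for a prepared
## structure and a covariate already in sorted order.
cox_ll <- function(prep, x_s, beta, info = TRUE) {
  eta <- beta * x_s
  eta <- pmin(eta, 500)                      # guard exp overflow mid-iteration
  w <- exp(eta)
  wx <- w * x_s
  rc0 <- rev(cumsum(rev(w)))                 # risk-set sums: time >= t
  rc1 <- rev(cumsum(rev(wx)))
  S0 <- rc0[prep$first_idx]
  S1 <- rc1[prep$first_idx]
  ev <- prep$events
  sd0 <- as.numeric(rowsum(w[ev], prep$grp[ev]))
  sd1 <- as.numeric(rowsum(wx[ev], prep$grp[ev]))
  gidx <- match(prep$gl_group, prep$ev_groups)
  denom <- S0[prep$gl_group] - prep$frac * sd0[gidx]
  num1 <- S1[prep$gl_group] - prep$frac * sd1[gidx]
  ll <- sum(eta[ev]) - sum(log(denom))
  U <- sum(x_s[ev]) - sum(num1 / denom)
  out <- list(ll = ll, U = U)
  if (info) {
    wx2 <- wx * x_s
    rc2 <- rev(cumsum(rev(wx2)))
    S2 <- rc2[prep$first_idx]
    sd2 <- as.numeric(rowsum(wx2[ev], prep$grp[ev]))
    num2 <- S2[prep$gl_group] - prep$frac * sd2[gidx]
    out$I <- sum(num2 / denom - (num1 / denom)^2)
  }
  out
}

cox_fit_prepared <- function(prep, x, tol_beta = 1e-9, tol_ll = 1e-12,
                             max_iter = 50L, beta_cap = 15) {
  x_s <- x[prep$ord]
  if (stats::sd(x_s) == 0)
    return(list(beta = NA_real_, se = NA_real_, z = NA_real_, p = NA_real_,
                loglik = NA_real_, converged = FALSE, flag = "zero_variance"))
  xbar <- mean(x_s)
  x_c <- x_s - xbar                          # centering for stability only
  beta <- 0
  cur <- cox_ll(prep, x_c, beta)
  converged <- FALSE
  flag <- "ok"
  for (iter in seq_len(max_iter)) {
    if (!is.finite(cur$I) || cur$I <= 0) { flag <- "nonconverged"; break }
    step <- cur$U / cur$I
    new_beta <- beta + step
    nxt <- cox_ll(prep, x_c, new_beta)
    halvings <- 0L
    while ((!is.finite(nxt$ll) || nxt$ll < cur$ll) && halvings < 30L) {
      step <- step / 2
      new_beta <- beta + step
      nxt <- cox_ll(prep, x_c, new_beta)
      halvings <- halvings + 1L
    }
    if (abs(new_beta) > beta_cap) { flag <- "monotone_likelihood"; break }
    done <- abs(step) < tol_beta ||
      abs(nxt$ll - cur$ll) < tol_ll * (abs(cur$ll) + tol_ll)
    beta <- new_beta
    cur <- nxt
    if (done) { converged <- TRUE; break }
  }
  if (!converged && flag == "ok") flag <- "nonconverged"
  se <- if (converged && is.finite(cur$I) && cur$I > 0) 1 / sqrt(cur$I) else NA_real_
  z <- if (!is.na(se)) beta / se else NA_real_
  p <- if (!is.na(z)) 2 * stats::pnorm(-abs(z)) else NA_real_
  list(beta = if (flag %in% c("ok")) beta else NA_real_,
       se = se, z = z, p = p, loglik = cur$ll,
       converged = converged, flag = flag)
}

#' Fit a univariate Cox proportional hazards model for one gene
#'
#' Maximizes the partial likelihood of the hazard model
#' h(t, x) = h0(t) exp(beta * x), where x is the normalized expression of a
#' single gene, by Newton-Raphson with step-halving. beta is the log hazard
#' ratio for a one-unit increase in expression. Tied event times use Efron's
#' approximation by default.
#'
#' @param x Numeric vector of per-sample expression, aligned with `surv`.
#' @param surv Survival data frame with columns `time` (> 0) and `status`
#'   (1 = event, 0 = censored), or a prepared structure from `cox_prepare`.
#' @param ties `"efron"` or `"breslow"`.
#' @return A list with `beta`, `se`, `z`, two-sided Wald `p`, `loglik`,
#'   `converged`, and `flag` (one of `"ok"`, `"zero_variance"`,
#'   `"nonconverged"`, `"monotone_likelihood"`).
#' @export
fit_cox_gene <- function(x, surv, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  prep <- if (is.list(surv) && !is.null(surv$first_idx)) surv
          else cox_prepare(surv$time, surv$status, ties)
  if (length(x) != prep$n)
    stop("expression vector and survival table have different lengths",
         call. = FALSE)
  cox_fit_prepared(prep, x)
}

#' Rank all genes by Cox log hazard ratio
#'
#' Fits one univariate Cox model per gene on normalized expression and
#' returns the ranked gene list used by the survival mode of the enrichment
#' analysis: genes sorted by decreasing log hazard ratio (or Wald z), ties
#' broken by gene id ascending. Genes whose fit is degenerate
#' (zero variance, non-convergence, monotone likelihood) are excluded from
#' the ranking but retained, with their flag, in the statistics table.
#'
#' @param expr log2-CPM expression matrix (genes x samples) whose columns are
#'   aligned with `surv$sample`.
#' @param surv Survival data frame (`sample`, `time`, `status`).
#' @param ties Tie handling, `"efron"` (default) or `"breslow"`.
#' @param rank_stat Ranking statistic: `"beta"` (log hazard ratio, default)
#'   or `"z"` (Wald statistic).
#' @return A list with `ranking` (a named, decreasingly sorted numeric vector
#'   of class `ranked_list`, statistic tag `"log_hazard_ratio"`) and `stats`
#'   (per-gene data frame: gene, beta, se, z, p, converged, flag).
#' @export
rank_by_hazard <- function(expr, surv, ties = c("efron", "breslow"),
                           rank_stat = c("beta", "z")) {
  ties <- match.arg(ties)
  rank_stat <- match.arg(rank_stat)
  if (!identical(colnames(expr), surv$sample))
    stop("expression columns and survival samples are not aligned; ",
         "call align_samples() first", call. = FALSE)
  prep <- cox_prepare(surv$time, surv$status, ties)
  fits <- lapply(seq_len(nrow(expr)), function(i)
    cox_fit_prepared(prep, expr[i, ]))
  stats_df <- data.frame(
    gene = rownames(expr),
    beta = vapply(fits, `[[`, numeric(1), "beta"),
    se = vapply(fits, `[[`, numeric(1), "se"),
    z = vapply(fits, `[[`, numeric(1), "z"),
    p = vapply(fits, `[[`, numeric(1), "p"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    flag = vapply(fits, `[[`, character(1), "flag"),
    stringsAsFactors = FALSE)
  ok <- stats_df$flag == "ok"
  if (sum(ok) < 2L)
    stop("fewer than 2 genes with a usable Cox fit", call. = FALSE)
  stat <- if (rank_stat == "beta") stats_df$beta else stats_df$z
  ranking <- ranked_list(setNames(stat[ok], stats_df$gene[ok]),
                         statistic = "log_hazard_ratio")
  list(ranking = ranking, stats = stats_df)
}

#' Construct a ranked gene list
#'
#' Sorts a named statistic vector decreasingly, breaking exact ties by gene
#' id ascending, so that rankings are deterministic.
#'
#' @param x Named numeric vector of ranking statistics (no NA/NaN).
#' @param statistic Tag describing the statistic semantics, e.g.
#'   `"log_hazard_ratio"` or `"log2_fold_change"`.
#' @return The sorted vector with class `ranked_list` and attribute
#'   `statistic`.
#' @export
ranked_list <- function(x, statistic = "statistic") {
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("ranking statistics must carry unique gene names", call. = FALSE)
  if (any(!is.finite(x)))
    stop("ranking statistics must be finite", call. = FALSE)
  ord <- order(-x, names(x), method = "radix")
  out <- x[ord]
  attr(out, "statistic") <- statistic
  class(out) <- "ranked_list"
  out
}
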