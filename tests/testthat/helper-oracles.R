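## Independent oracles, deliberately written with naive loops and none of
## the package's internals, so they can stand as references.

## Efron partial log-likelihood by direct double loop over event times.
oracle_partial_loglik <- function(beta, time, status, x) {
  ll <- 0
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    eR <- sum(exp(beta * x[R]))
    eD <- sum(exp(beta * x[D]))
    ll <- ll + sum(beta * x[D])
    for (l in seq_len(d) - 1) ll <- ll - log(eR - (l / d) * eD)
  }
  ll
}

## 1-D maximizer of the partial likelihood (golden-section via optimize).
oracle_cox_beta <- function(time, status, x, interval = c(-20, 20)) {
  stats::optimize(oracle_partial_loglik, interval, time = time,
                  status = status, x = x, maximum = TRUE,
                  tol = 1e-10)$maximum
}

## Weighted KS enrichment score by a literal position-by-position walk.
oracle_es <- function(stats_sorted, is_member, exponent = 1) {
  N <- length(stats_sorted)
  nh <- sum(is_member)
  nr <- sum(abs(stats_sorted[is_member])^exponent)
  run <- 0
  best_pos <- 0
  best_neg <- 0
  for (i in seq_len(N)) {
    if (is_member[i]) {
      run <- run + abs(stats_sorted[i])^exponent / nr
    } else {
      run <- run - 1 / (N - nh)
    }
    if (run > best_pos) best_pos <- run
    if (run < best_neg) best_neg <- run
  }
  # magnitude ties go to the positive side, compared with a relative
  # tolerance so floating summation order cannot decide the sign
  if (best_pos + best_neg >= -1e-12 * max(best_pos, -best_neg))
    best_pos else best_neg
}

## All enrichment scores of every size-k subset of an N-gene ranking.
oracle_exhaustive_null <- function(ranked, k, exponent = 1) {
  N <- length(ranked)
  combos <- utils::combn(N, k)
  apply(combos, 2, function(pos) {
    is_member <- seq_len(N) %in% pos
    oracle_es(as.numeric(ranked), is_member, exponent)
  })
}

random_survival <- function(n, censor_prob = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  time <- round(rexp(n, 0.2), 2) + 0.01
  status <- rbinom(n, 1, 1 - censor_prob)
  if (sum(status) < 2) status[seq_len(2)] <- 1L
  data.frame(sample = sprintf("s%03d", seq_len(n)), time = time,
             status = status, stringsAsFactors = FALSE)
}

tiny_counts <- function(n_genes = 6, n_samples = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_genes * n_samples, 30), n_genes, n_samples,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  storage.mode(m) <- "integer"
  m
}
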