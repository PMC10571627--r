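test_that("the worked 5-gene running sum gives es = 5/7 with the rank-1 leading edge", {
  rk <- ranked_list(c(g1 = 5, g2 = 4, g3 = 3, g4 = 2, g5 = 1))
  sc <- enrichment_score(rk, c("g1", "g4"))
  expect_equal(sc$running_sum,
               c(5 / 7, 5 / 7 - 1 / 3, 5 / 7 - 2 / 3, 5 / 7 - 2 / 3 + 2 / 7, 0),
               tolerance = 1e-12)
  expect_equal(sc$es, 5 / 7, tolerance = 1e-12)
  expect_identical(sc$leading_edge, "g1")
  expect_identical(sc$hits, c(1L, 4L))

  # single member at rank 1 forces the maximal deviation
  expect_equal(enrichment_score(rk, "g1")$es, 1, tolerance = 1e-12)

  expect_error(enrichment_score(rk, c("x", "y")), "no members")
  expect_error(enrichment_score(rk, names(rk)), "entire ranked list")
})

test_that("enrichment_score matches a brute-force walk on random instances", {
  set.seed(17)
  for (i in 1:60) {
    N <- sample(10:80, 1)
    stats <- rnorm(N)
    names(stats) <- sprintf("g%03d", seq_len(N))
    rk <- ranked_list(stats)
    members <- sample(names(stats), sample(1:(N - 1), 1))
    expo <- sample(c(0, 1, 1.5), 1)
    sc <- enrichment_score(rk, members, exponent = expo)
    expect_equal(sc$es,
                 oracle_es(as.numeric(rk), names(rk) %in% members, expo),
                 tolerance = 1e-12)
    # the curve extremum reproduces the stored es
    extremum <- if (sc$es >= 0) max(sc$running_sum, 0) else min(sc$running_sum)
    expect_equal(extremum, sc$es, tolerance = 1e-12)
    # curve returns to zero by construction
    expect_equal(sc$running_sum[N], 0, tolerance = 1e-9)
  }
})

test_that("reversing the ranking and negating statistics negates the score", {
  set.seed(23)
  for (i in 1:20) {
    stats <- rnorm(40)
    names(stats) <- sprintf("g%02d", 1:40)
    rk <- ranked_list(stats)
    rk_neg <- ranked_list(-stats)
    members <- sample(names(stats), 7)
    expect_equal(enrichment_score(rk_neg, members)$es,
                 -enrichment_score(rk, members)$es, tolerance = 1e-12)
  }
})

test_that("exponent 1 scores respond to monotone rescaling (not rank-only)", {
  set.seed(2)
  stats <- sort(abs(rnorm(30)) + 0.1, decreasing = TRUE)
  names(stats) <- sprintf("g%02d", 1:30)
  rk <- ranked_list(stats)
  rk_cubed <- ranked_list(stats^3)   # same ranks, different weights
  members <- c("g03", "g07", "g21")
  es1 <- enrichment_score(rk, members, exponent = 1)$es
  es1_cubed <- enrichment_score(rk_cubed, members, exponent = 1)$es
  expect_gt(abs(es1 - es1_cubed), 1e-6)
  # while exponent 0 is invariant to any monotone rescaling
  expect_equal(enrichment_score(rk, members, exponent = 0)$es,
               enrichment_score(rk_cubed, members, exponent = 0)$es,
               tolerance = 1e-12)
})

test_that("the Monte-Carlo null is seeded, reproducible, and matches exhaustive enumeration", {
  stats <- c(a = 2.0, b = 1.2, c = 0.7, d = -0.5, e = -1.9)
  rk <- ranked_list(stats)
  exact <- oracle_exhaustive_null(rk, 2)   # all C(5,2) = 10 subsets
  expect_length(exact, 10)

  null1 <- build_null(rk, 2, n_perm = 10000, seed = 42)
  null2 <- build_null(rk, 2, n_perm = 10000, seed = 42)
  expect_identical(null1$es, null2$es)
  expect_length(null1$es, 10000)
  # every sampled value is one of the 10 enumerable scores
  expect_true(all(vapply(null1$es, function(e)
    any(abs(e - exact) < 1e-12), logical(1))))
  # tail frequencies within 3 binomial standard errors of enumeration
  for (thr in c(0.3, 0.6, 0.9)) {
    p_exact <- mean(abs(exact) >= thr)
    p_mc <- mean(abs(null1$es) >= thr)
    se <- sqrt(p_exact * (1 - p_exact) / 10000)
    expect_lt(abs(p_mc - p_exact), 3 * se + 1e-12)
  }
  expect_error(build_null(rk, 5, n_perm = 100), "strictly between")
  expect_error(build_null(rk, 2, n_perm = 50), "at least 100")
})

test_that("NES normalization and add-one p-values follow their definitions", {
  null_es <- c(0.5, 0.3, 0.2, -0.4, -0.1)
  # es equal to the mean positive magnitude -> nes = 1
  np <- nes_pvalue(mean(c(0.5, 0.3, 0.2)), null_es)
  expect_equal(np$nes, 1, tolerance = 1e-12)
  # es equal to the largest same-sign null -> p = 2 / (1 + n_same_sign)
  np2 <- nes_pvalue(0.5, null_es)
  expect_equal(np2$pval, 2 / 4)
  # negative side uses the negative stratum
  np3 <- nes_pvalue(-0.4, null_es)
  expect_equal(np3$nes, -0.4 / mean(c(0.4, 0.1)), tolerance = 1e-12)
  expect_equal(np3$pval, 2 / 3)
  # no same-sign null -> flagged fallback
  np4 <- nes_pvalue(-0.2, c(0.1, 0.4))
  expect_true(np4$degenerate)
  expect_equal(np4$pval, 1)
})

test_that("BH adjustment matches the hand-computed step-up", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)),
               c(0.04, 0.04, 0.04, 0.04))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
})

test_that("run_enrichment finds a planted top-loaded set and is order-invariant", {
  set.seed(61)
  n <- 2000
  stats <- rnorm(n)
  names(stats) <- sprintf("g%04d", seq_len(n))
  rk <- ranked_list(stats)
  top5pct <- names(rk)[1:100]
  sets <- list(planted = sample(top5pct, 30))
  for (i in 1:10) sets[[sprintf("decoy%02d", i)]] <- sample(names(stats), 30)
  res <- run_enrichment(rk, sets, n_perm = 1000, seed = 5)
  expect_identical(res$pathway[which.max(res$nes)], "planted")
  expect_lt(res$padj[res$pathway == "planted"], 0.15)
  # invariants on the result table
  expect_true(all(abs(res$es) <= 1))
  expect_true(all(res$pval > 0 & res$pval <= 1))
  expect_true(all(res$padj >= res$pval - 1e-12 & res$padj <= 1))
  expect_true(all(sign(res$nes) == sign(res$es)))
  expect_true(all(mapply(function(le, p) all(le %in% sets[[p]]),
                         res$leading_edge, res$pathway)))

  # permuting the collection leaves results identical up to row order
  res2 <- run_enrichment(rk, rev(sets), n_perm = 1000, seed = 5)
  res2 <- res2[match(res$pathway, res2$pathway), ]
  expect_equal(res$es, res2$es, tolerance = 1e-12)
  expect_equal(res$pval, res2$pval)   # same seed, same per-size null

  # size bounds
  expect_error(run_enrichment(rk, list(tiny = names(stats)[1:3]),
                              n_perm = 1000), "size bounds")
})

test_that("leading edge recomputation reproduces the stored score", {
  set.seed(14)
  stats <- rnorm(300)
  names(stats) <- sprintf("g%03d", 1:300)
  rk <- ranked_list(stats)
  sets <- lapply(1:5, function(i) sample(names(stats), 25))
  names(sets) <- paste0("S", 1:5)
  res <- run_enrichment(rk, sets, min_size = 10, n_perm = 500, seed = 3)
  for (i in seq_len(nrow(res))) {
    sc <- enrichment_score(rk, sets[[res$pathway[i]]])
    expect_equal(sc$es, res$es[i], tolerance = 1e-12)
    expect_identical(sc$leading_edge, res$leading_edge[[i]])
    if (res$es[i] != 0) expect_gt(length(res$leading_edge[[i]]), 0)
  }
})

test_that("compare_significant partitions the shared universe", {
  mk <- function(pathways, padj) {
    data.frame(pathway = pathways, padj = padj, stringsAsFactors = FALSE)
  }
  # 3 shared + 2 A-only + 1 B-only significant out of 10 shared pathways
  paths <- sprintf("P%02d", 1:10)
  resA <- mk(paths, c(0.01, 0.02, 0.03, 0.05, 0.10, 0.9, 0.9, 0.9, 0.9, 0.9))
  resB <- mk(paths, c(0.01, 0.02, 0.03, 0.9, 0.9, 0.05, 0.9, 0.9, 0.9, 0.9))
  cmpr <- compare_significant(resA, resB, alpha = 0.15)
  expect_equal(cmpr$n_A_only, 2)
  expect_equal(cmpr$n_B_only, 1)
  expect_equal(cmpr$n_overlap, 3)
  expect_equal(cmpr$n_universe, 10)
  expect_identical(cmpr$overlap, c("P01", "P02", "P03"))

  ident <- compare_significant(resA, resA, alpha = 0.15)
  expect_equal(ident$n_overlap, 5)
  expect_equal(ident$n_A_only + ident$n_B_only, 0)

  none <- compare_significant(resA, resB, alpha = 0)
  expect_equal(none$n_overlap + none$n_A_only + none$n_B_only, 0)

  expect_error(compare_significant(resA, mk(c("Q1", "Q2"), c(0.1, 0.2))),
               "share no tested pathways")
})
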