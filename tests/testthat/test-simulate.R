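test_that("simulated counts are reproducible and match their target moments", {
  cfg <- sim_config(n_samples = 40, n_genes = 50, seed = 3,
                    planted_sets = list(list(name = "p", size = 10,
                                             beta = 0.8, log2fc = 1)))
  c1 <- simulate_counts(cfg)
  c2 <- simulate_counts(cfg)
  expect_identical(c1, c2)
  expect_identical(dim(c1), c(50L, 40L))
  expect_true(all(c1 >= 0))

  # high-expression genes: empirical mean near the drawn mean at n = 500
  cfg_big <- sim_config(n_samples = 500, n_genes = 60, seed = 5,
                        nb_mean_log_range = log(c(200, 400)),
                        nb_dispersion = 0.05)
  cm <- simulate_counts(cfg_big)
  set.seed(cfg_big$seed)
  mu <- exp(runif(60, log(200), log(400)))   # the generator's own draw
  expect_lt(max(abs(rowMeans(cm) / mu - 1)), 0.10)

  # zero dispersion is Poisson: variance tracks the mean
  cfg_pois <- sim_config(n_samples = 500, n_genes = 200, seed = 6,
                         nb_dispersion = 0,
                         nb_mean_log_range = log(c(50, 100)),
                         planted_sets = list(list(name = "p", size = 10,
                                                  beta = 0.8, log2fc = 1)))
  cp <- simulate_counts(cfg_pois)
  ratio <- apply(cp, 1, var) / rowMeans(cp)
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("survival generation hits the censoring target and zero target means no censoring", {
  cfg <- sim_config(n_samples = 400, n_genes = 100, seed = 9,
                    censoring_fraction = 0.3,
                    planted_sets = list(list(name = "p", size = 10,
                                             beta = 0.8, log2fc = 1)))
  expr <- logcpm_transform(simulate_counts(cfg))
  sv <- simulate_survival(expr, cfg)
  expect_true(all(sv$time > 0))
  expect_lt(abs(mean(sv$status == 0) - 0.3), 0.05)

  cfg0 <- sim_config(n_samples = 50, n_genes = 50, seed = 2,
                     censoring_fraction = 0,
                     planted_sets = list(list(name = "p", size = 10,
                                              beta = 0.8, log2fc = 1)))
  expr0 <- logcpm_transform(simulate_counts(cfg0))
  sv0 <- simulate_survival(expr0, cfg0)
  expect_true(all(sv0$status == 1L))
})

test_that("with no planted effects, per-gene Cox p-values are uniform", {
  cfg <- sim_config(n_samples = 150, n_genes = 400, seed = 13,
                    censoring_fraction = 0.2,
                    planted_sets = list(list(name = "null_set", size = 10,
                                             beta = 0, log2fc = 0)))
  counts <- simulate_counts(cfg)
  expr <- logcpm_transform(counts)
  sv <- simulate_survival(expr, cfg)
  rk <- rank_by_hazard(expr, sv)
  ks <- suppressWarnings(stats::ks.test(rk$stats$p[rk$stats$flag == "ok"],
                                        "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a single planted log hazard ratio is recovered with small bias", {
  est <- vapply(1:25, function(r) {
    cfg <- sim_config(n_samples = 500, n_genes = 30, seed = 1000 + r,
                      censoring_fraction = 0.2, nb_dispersion = 0.1,
                      planted_sets = list(list(name = "p", size = 1,
                                               beta = 1, log2fc = 0)))
    counts <- simulate_counts(cfg)
    expr <- logcpm_transform(counts)
    sv <- simulate_survival(expr, cfg)
    z <- as.numeric(scale(expr["g00001", ]))
    fit_cox_gene(z, sv)$beta
  }, numeric(1))
  expect_lt(abs(mean(est) - 1), 0.15)
})

test_that("the gene-set fixture is disjoint, sized as configured, and GMT round-trips", {
  cfg <- sim_config(n_samples = 20, n_genes = 200, seed = 4,
                    n_decoy_sets = 5, decoy_size = 15)
  sets <- make_gmt_fixture(cfg)
  expect_length(sets, 2 + 5)
  planted <- unlist(sets[c("planted_1", "planted_2")])
  decoys <- unlist(sets[grep("^decoy", names(sets))])
  expect_length(intersect(planted, decoys), 0)
  expect_true(all(lengths(sets[grep("^decoy", names(sets))]) == 15))
  expect_true(all(lengths(sets[c("planted_1", "planted_2")]) == 30))

  tf <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, tf)
  back <- read_gmt(tf)
  expect_identical(names(back), names(sets))
  expect_identical(lapply(back, identity), lapply(sets, identity))
})

test_that("fold-change mode plants the configured group effect", {
  cfg <- sim_config(n_samples = 80, n_genes = 300, seed = 19,
                    n_decoy_sets = 4,
                    planted_sets = list(list(name = "up", size = 20,
                                             beta = 0, log2fc = 2)))
  sim <- simulate_dataset(cfg, "foldchange")
  tumor <- sim$conditions$group == "tumor"
  planted_rows <- sim$truth$gene
  ratio <- rowMeans(sim$counts[planted_rows, tumor]) /
    rowMeans(sim$counts[planted_rows, !tumor])
  expect_lt(abs(mean(log2(ratio)) - 2), 0.3)
})
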