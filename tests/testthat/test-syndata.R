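test_that("every generator is seed-deterministic", {
  cfg <- synConfig(n_genes = 120L, frac_de = 0.1, db_noise = 15L, seed = 7L)
  a <- simCohorts(cfg); b <- simCohorts(cfg)
  expect_identical(exprsMat(a$train), exprsMat(b$train))
  expect_identical(exprsMat(a$valid), exprsMat(b$valid))
  expect_identical(a$truth, b$truth)
  u <- rownames(a$train)
  expect_identical(simTargetDBs(a$truth, u, cfg), simTargetDBs(b$truth, u, cfg))
  expect_identical(networkEdges(simNetwork(a$truth, u, cfg)),
                   networkEdges(simNetwork(b$truth, u, cfg)))
  expect_identical(simAbundance(cfg), simAbundance(cfg))
})

test_that("generators use independent substreams per call name", {
  cfg <- synConfig(n_genes = 120L, frac_de = 0.1, db_noise = 15L, seed = 7L)
  a <- simCohorts(cfg)
  simAbundance(cfg)  # interleaved call must not shift the cohort stream
  b <- simCohorts(cfg)
  expect_identical(exprsMat(a$train), exprsMat(b$train))
})

test_that("no-signal configuration plants nothing and matrices are complete", {
  cfg <- synConfig(n_genes = 100L, frac_de = 0, seed = 3L)
  syn <- simCohorts(cfg)
  expect_equal(nrow(syn$truth$de_genes), 0L)
  expect_false(anyNA(exprsMat(syn$train)))
  expect_false(anyNA(exprsMat(syn$valid)))
  # group means differ only by sampling noise: moderated test finds ~nothing
  dd <- thresholdDegs(fitModerated(syn$train), 0.5, 0.05)
  expect_lt(length(c(dd$up, dd$down)) / 100, 0.1)
})

test_that("degenerate database coverage behaves exactly", {
  cfg <- synConfig(n_genes = 200L, frac_de = 0.1, db_coverage = 1,
                   db_noise = 0L, seed = 5L)
  syn <- simCohorts(cfg)
  dbs <- simTargetDBs(syn$truth, rownames(syn$train), cfg)
  for (db in dbs)
    expect_setequal(symbols(db), syn$truth$target_genes)

  cfg0 <- synConfig(n_genes = 200L, frac_de = 0.1, db_coverage = 0,
                    db_noise = 25L, seed = 5L)
  dbs0 <- simTargetDBs(syn$truth, rownames(syn$train), cfg0)
  for (db in dbs0)
    expect_length(intersect(symbols(db), syn$truth$target_genes), 0L)
})

test_that("planted database membership matches the binomial expectation", {
  # 30 planted targets at coverage 0.8: expect 24 per database on average
  cnt <- vapply(1:60, function(sd) {
    cfg <- synConfig(n_genes = 500L, frac_de = 0.06, db_coverage = 0.8,
                     db_noise = 20L, seed = sd)
    syn <- simCohorts(cfg)
    dbs <- simTargetDBs(syn$truth, rownames(syn$train), cfg)
    sum(symbols(dbs$disease) %in% syn$truth$target_genes)
  }, numeric(1L))
  se <- sqrt(30 * 0.8 * 0.2 / length(cnt))
  expect_lt(abs(mean(cnt) - 24), 3 * se)
})

test_that("planted hubs are wired far above the median degree", {
  cfg <- synConfig(n_genes = 150L, frac_de = 0.1, n_hubs = 3L, seed = 11L)
  syn <- simCohorts(cfg)
  net <- simNetwork(syn$truth, rownames(syn$train), cfg)
  e <- networkEdges(net)
  deg <- table(factor(c(e$nodeA, e$nodeB), levels = networkNodes(net)))
  expect_true(all(deg[syn$truth$hub_genes] >= 3 * median(deg)))
  expect_true(all(e$score > 0.4 & e$score <= 1))
  expect_false(any(e$nodeA == e$nodeB))
})

test_that("abundance rows lie on the simplex and respect the null", {
  cfg <- synConfig(seed = 13L)  # shift_effect 1: shared Dirichlet
  ab <- simAbundance(cfg)
  expect_equal(unname(rowSums(ab$abundance)), rep(1, nrow(ab$abundance)),
               tolerance = 1e-12)
  expect_equal(ncol(ab$abundance), 22L)
  res <- abundanceGroupTest(ab$abundance, ab$groups)
  expect_true(all(res$q >= res$p))
})

test_that("config validation rejects impossible settings", {
  expect_error(synConfig(n_train_case = 1L), "group sizes")
  expect_error(synConfig(frac_de = 1.2), "frac_de")
  expect_error(synConfig(effect_range = c(2, 1)), "effect_range")
  expect_error(synConfig(var_prior_scale = -1), "positive")
  cfg <- synConfig(n_genes = 50L, frac_de = 0.1, db_noise = 100L, seed = 1L)
  syn <- simCohorts(cfg)
  expect_error(simTargetDBs(syn$truth, rownames(syn$train), cfg), "db_noise")
})

test_that("synthetic supplement stand-in has the engineered cardinalities", {
  s <- supplementMimic(seed = 2L)
  expect_length(s$chem, 1040L)
  expect_length(s$disease, 1617L)
  expect_length(s$degs, 3491L)
  expect_length(s$core43, 43L)
})
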