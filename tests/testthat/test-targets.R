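test_that("standardization merges case variants and applies aliases", {
  ts <- standardizeTargets(c("mmp9", "MMP9"))
  expect_equal(symbols(ts), "MMP9")

  ts2 <- standardizeTargets("MMP-9", alias_map = c("MMP-9" = "MMP9"))
  expect_equal(symbols(ts2), "MMP9")

  # 5 entries, 2 duplicates after mapping -> cardinality 3, none dropped
  ts3 <- standardizeTargets(c("hpse", "HPSE", "MMP-9", "MMP9", "INSR"),
                            alias_map = c("MMP-9" = "MMP9"))
  expect_length(ts3, 3L)
  expect_equal(attr(ts3, "dropped"), 0L)
})

test_that("standardization keeps max fit score and unions annotations", {
  e <- data.frame(symbol = c("a1", "A1", "b2"),
                  source = c("ctd", "pharmmapper", "ctd"),
                  interaction_type = c("direct", "indirect", NA),
                  fit_score = c(2, 5, NA))
  ts <- standardizeTargets(e)
  ent <- targetEntries(ts)
  a <- ent[ent$symbol == "A1", ]
  expect_equal(a$fit_score, 5)
  expect_equal(a$interaction_type, "direct;indirect")
  expect_equal(a$source, "ctd;pharmmapper")
})

test_that("standardization is idempotent and counts dropped blanks", {
  e <- data.frame(symbol = c(" il6 ", "", "TNF", "il6"),
                  fit_score = c(1, 2, 3, 4))
  once <- standardizeTargets(e)
  twice <- standardizeTargets(targetEntries(once))
  expect_identical(targetEntries(once), targetEntries(twice))
  expect_equal(attr(once, "dropped"), 1L)
  expect_error(standardizeTargets("A", alias_map = c(A = "B", B = "C")),
               "idempotent")
})

test_that("context filter applies the per-source rules", {
  co <- toyCohort(n_genes = 30, seed = 2)  # symbols T001..T030, all positive
  e <- data.frame(
    symbol = sprintf("T%03d", 1:14),
    source = c(rep("ctd", 4), rep("pharmmapper", 10)),
    interaction_type = c("direct", "indirect", "direct", NA,
                         rep(NA_character_, 10)),
    fit_score = c(rep(NA_real_, 4), 1:10))
  ts <- targetSet(e, "chem")

  out <- contextFilter(ts, co, direct_only = TRUE, fit_top_frac = 0.2)
  kept <- symbols(out)
  # ctd: only annotated direct survive
  expect_true(all(c("T001", "T003") %in% kept))
  expect_false(any(c("T002", "T004") %in% kept))
  # pharmmapper: scores {9, 10} are the hand-computed top-20% quantile cut
  expect_setequal(grep("T01[0-4]|T00[5-9]", kept, value = TRUE),
                  c("T013", "T014"))

  # identity configuration returns the detectable input unchanged
  ident <- contextFilter(ts, co, direct_only = FALSE, fit_top_frac = 1)
  expect_setequal(symbols(ident), symbols(ts))

  # contractive in every configuration
  expect_true(all(kept %in% symbols(ts)))
})

test_that("context filter removes undetectable or absent symbols", {
  co <- toyCohort(n_genes = 10, seed = 3)
  m <- exprsMat(co); m["T002", ] <- 0   # never positive
  co <- cohortExperiment(m, sampleGroups(co))
  ts <- targetSet(data.frame(symbol = c("T001", "T002", "ZZZ9"),
                             source = "ctd", interaction_type = "direct"))
  out <- contextFilter(ts, co, direct_only = TRUE, fit_top_frac = 1)
  expect_equal(symbols(out), "T001")
  # pharmmapper entries without scores cannot be score-filtered
  bad <- targetSet(data.frame(symbol = "T001", source = "pharmmapper"))
  expect_error(contextFilter(bad, co, fit_top_frac = 0.2), "fit_score")
})

test_that("three-way intersection is exact with recorded provenance", {
  cand <- intersectCandidates(c("a", "b", "c"),
                              targetSet(c("b", "c", "d")),
                              targetSet(c("c", "b", "e")))
  expect_setequal(cand$symbols, c("b", "c"))
  expect_equal(unname(cand$provenance), c(3L, 3L, 3L))

  expect_warning(empty <- intersectCandidates(character(), targetSet("x"),
                                              targetSet("x")), "empty")
  expect_length(empty$symbols, 0L)

  same <- intersectCandidates(c("x", "y"), targetSet(c("x", "y")),
                              targetSet(c("y", "x")))
  expect_setequal(same$symbols, c("x", "y"))
})

test_that("perfect database coverage recovers exactly the detected planted set", {
  cfg <- synConfig(n_genes = 400L, frac_de = 0.08, effect_range = c(1.5, 2),
                   db_coverage = 1, db_noise = 0L, seed = 17L)
  syn <- simCohorts(cfg)
  dbs <- simTargetDBs(syn$truth, rownames(syn$train), cfg)
  dd <- thresholdDegs(fitModerated(syn$train), 0.5, 0.05)
  detected <- intersect(c(dd$up, dd$down), syn$truth$target_genes)
  cand <- intersectCandidates(c(dd$up, dd$down), dbs$disease, dbs$chemA)
  expect_setequal(cand$symbols, detected)
})

test_that("drug comparison partitions the two candidate sets", {
  d <- drugCompare(c("x", "y"), c("y", "z"))
  expect_equal(d, list(shared = "y", onlyA = "x", onlyB = "z"))
  d2 <- drugCompare(c("a", "b"), c("a", "b"))
  expect_equal(d2$shared, c("a", "b"))
  expect_length(d2$onlyA, 0L)
})

test_that("target CSV round-trips through the readers", {
  ts <- targetSet(data.frame(symbol = c("MMP9", "HPSE"),
                             source = c("ctd", "pharmmapper"),
                             interaction_type = c("direct", NA),
                             fit_score = c(NA, 6.1)), name = "demo")
  f <- tempfile(fileext = ".csv")
  writeTargetCSV(ts, f)
  back <- readTargetCSV(f, name = "demo")
  expect_equal(targetEntries(back)$symbol, targetEntries(ts)$symbol)
  expect_equal(targetEntries(back)$fit_score, targetEntries(ts)$fit_score)
  unlink(f)
})
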