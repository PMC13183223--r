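test_that("a gene flat across all samples gives log2FC 0, t 0, p 1", {
  co <- toyCohort(n_genes = 30, seed = 1)
  m <- exprsMat(co)
  m["T001", ] <- 5
  co <- cohortExperiment(m, sampleGroups(co))
  deg <- fitModerated(co)
  row <- deg[deg$symbol == "T001", ]
  expect_equal(row$log2FC, 0)
  expect_equal(row$t, 0)
  expect_equal(row$p, 1)
  expect_true(row$flat)
})

test_that("prior df forced to 0 reproduces the classical pooled t", {
  withr::with_seed(9, {
    x1 <- matrix(rnorm(9, 8, 1), 3, 3)   # 3 genes, 3 case samples
    x2 <- matrix(rnorm(9, 7, 1), 3, 3)
  })
  m <- cbind(x1, x2)
  dimnames(m) <- list(paste0("g", 1:3), paste0("s", 1:6))
  co <- cohortExperiment(m, rep(c("case", "control"), each = 3))
  deg <- fitModerated(co, prior_df = 0)
  for (i in 1:3) {
    tt <- t.test(m[i, 1:3], m[i, 4:6], var.equal = TRUE)
    expect_equal(deg$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(deg$p[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("infinite prior df scales the statistic by a common variance", {
  co <- toyCohort(n_genes = 40, seed = 4)
  deg <- fitModerated(co, prior_df = Inf)
  # t must be exactly proportional to log2FC when all variances are shrunk
  # to s0^2
  ratio <- deg$t / deg$log2FC
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-10)
})

test_that("moderated statistics agree with the limma cross-check", {
  skip_if_not_installed("limma")
  syn <- simCohorts(synConfig(n_genes = 500L, frac_de = 0.05, seed = 21L))
  m <- exprsMat(syn$train)
  design <- cbind(1, sampleGroups(syn$train) == "case")
  fit <- limma::eBayes(limma::lmFit(m, design))
  deg <- fitModerated(syn$train)
  pri <- attr(deg, "prior")
  expect_equal(pri$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(pri$s02, fit$s2.prior, tolerance = 1e-6)
  expect_equal(deg$t, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(deg$p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("variance-prior parameters are recovered within the frozen bound", {
  err <- t(vapply(1:5, function(sd) {
    syn <- simCohorts(synConfig(n_genes = 2000L, seed = sd))
    p <- attr(fitModerated(syn$train), "prior")
    c(abs(p$d0 - 4) / 4, abs(p$s02 - 0.05) / 0.05)
  }, numeric(2L)))
  expect_true(all(err < 0.25))
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhAdjust(rep(0.2, 5)), rep(0.2, 5))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # permutation invariance after realignment
  p <- c(0.4, 0.01, 0.9, 0.02, 0.33)
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(bhAdjust(p)[perm], bhAdjust(p[perm]))
})

test_that("threshold classification uses strict inequalities", {
  deg <- data.frame(symbol = c("a", "b", "c", "d"),
                    log2FC = c(0.5, 0.6, -0.7, 0.2),
                    p = c(0.001, 0.01, 0.04, 0.2),
                    p_adj = c(0.004, 0.02, 0.08, 0.2))
  dd <- thresholdDegs(deg, 0.5, 0.05)
  expect_false("a" %in% dd$up)      # boundary log2FC excluded
  expect_true("b" %in% dd$up)
  expect_true("c" %in% dd$down)
  dd2 <- thresholdDegs(deg, 0, 1)
  expect_setequal(c(dd2$up, dd2$down), deg$symbol)  # all classified by sign
  dd3 <- thresholdDegs(deg, 0.5, 0.05, use_adjusted = TRUE)
  expect_false("c" %in% dd3$down)   # q = 0.08 fails the adjusted cutoff
  expect_error(thresholdDegs(deg, -1), "non-negative")
})

test_that("DEG counts shrink monotonically along threshold grids", {
  deg <- fitModerated(toyCohort(n_genes = 200, seed = 6,
                                shift = setNames(rep(1, 20),
                                                 sprintf("T%03d", 1:20))))
  sizes_lfc <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(th) {
    dd <- thresholdDegs(deg, th, 0.05)
    length(dd$up) + length(dd$down)
  }, numeric(1L))
  expect_true(all(diff(sizes_lfc) <= 0))
  sizes_p <- vapply(c(0.2, 0.1, 0.05, 0.01), function(pm) {
    dd <- thresholdDegs(deg, 0.5, pm)
    length(dd$up) + length(dd$down)
  }, numeric(1L))
  expect_true(all(diff(sizes_p) <= 0))
})

test_that("expression readers round-trip and collapse duplicate symbols", {
  d <- tempfile(); dir.create(d)
  fx <- makeFixture(d, "tiny", seed = 2)
  m <- readExpressionTSV(fx$paths$train)
  co <- readExpressionTSV(fx$paths$train, fx$paths$train_labels)
  expect_identical(m, exprsMat(co))
  expect_equal(sum(sampleGroups(co) == "case"), 6L)
  # duplicate probe rows collapse by mean
  mm <- matrix(c(1, 3, 2, 4, 10, 20), 3, 2, byrow = TRUE,
               dimnames = list(NULL, c("s1", "s2")))
  out <- collapseBySymbol(mm, c("A", "A", "B"), "mean")
  expect_equal(out["A", ], c(s1 = 1.5, s2 = 3.5))
  expect_equal(out["B", ], c(s1 = 10, s2 = 20))
  unlink(d, recursive = TRUE)
})

test_that("series-matrix text files parse between the table delimiters", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("!Series_title\t\"demo\"", "!Series_platform_id\tGPLX",
               "!series_matrix_table_begin",
               "ID_REF\tGSM1\tGSM2\tGSM3",
               "\"G1\"\t1.5\t2.5\t3.5",
               "\"G2\"\t4\t5\t6",
               "!series_matrix_table_end"), f)
  m <- readSeriesMatrix(f)
  expect_equal(dim(m), c(2L, 3L))
  expect_equal(m["G1", "GSM2"], 2.5)
  unlink(f)
})
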