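# Shared seeded toys for the selection algorithms.
sepToy <- function(seed = 1, n = 40, p_noise = 10, shift = 3) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * (p_noise + 1)), n,
                dimnames = list(NULL, c("SIGNAL", paste0("NOISE", 1:p_noise))))
    y <- rep(c(1L, 0L), each = n / 2)
    X[y == 1, "SIGNAL"] <- X[y == 1, "SIGNAL"] + shift
  })
  list(X = X, y = y)
}

test_that("lasso selects a perfectly separating feature and is deterministic", {
  toy <- sepToy(seed = 2)
  r1 <- lassoSelect(toy$X, toy$y, n_folds = 5, seed = 3)
  expect_true("SIGNAL" %in% r1$selected)
  expect_equal(unname(which.max(r1$scores)),
               which(colnames(toy$X) == "SIGNAL"))
  r2 <- lassoSelect(toy$X, toy$y, n_folds = 5, seed = 3)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$lambda_min, r2$lambda_min)
})

test_that("lasso on pure noise stays near the frozen null selection size", {
  nsel <- vapply(1:20, function(sd) {
    withr::with_seed(sd, {
      X <- matrix(rnorm(40 * 20), 40, 20,
                  dimnames = list(NULL, paste0("F", 1:20)))
      y <- rep(c(1L, 0L), each = 20)
    })
    length(lassoSelect(X, y, seed = sd)$selected)
  }, numeric(1L))
  expect_lte(mean(nsel), 2.5)
})

test_that("boosted-tree gain concentrates on a deterministic step feature", {
  withr::with_seed(4, {
    X <- matrix(rnorm(60 * 6), 60, dimnames = list(NULL, paste0("F", 1:6)))
  })
  y <- as.integer(X[, "F3"] > 0)   # label is a step function of F3
  r <- gbtSelect(X, y, seed = 1)
  expect_equal(unname(which.max(r$scores)), 3L)
  expect_true("F3" %in% r$selected)
})

test_that("constant features yield empty boosted-tree selections", {
  X <- matrix(1, 20, 4, dimnames = list(NULL, paste0("F", 1:4)))
  y <- rep(c(1L, 0L), each = 10)
  r <- gbtSelect(X, y, seed = 1)
  expect_length(r$selected, 0L)
  expect_true(all(r$scores == 0))
  expect_error(gbtSelect(X, rep(1L, 20), seed = 1), "classes")
})

test_that("shadow selection confirms a planted feature and partitions statuses", {
  hits <- vapply(1:5, function(sd) {
    toy <- sepToy(seed = sd, n = 40, p_noise = 20, shift = 2)
    r <- shadowSelect(toy$X, toy$y, max_runs = 100, alpha = 0.01, seed = sd,
                      num_trees = 150)
    expect_length(intersect(r$selected, r$rejected), 0L)
    expect_setequal(c(r$selected, r$rejected, r$tentative), colnames(toy$X))
    "SIGNAL" %in% r$selected
  }, logical(1L))
  expect_gte(sum(hits), 4L)
})

test_that("shadow selection on pure noise stays near the frozen null rate", {
  nconf <- vapply(1:5, function(sd) {
    withr::with_seed(sd, {
      X <- matrix(rnorm(40 * 20), 40, 20,
                  dimnames = list(NULL, paste0("N", 1:20)))
      y <- rep(c(1L, 0L), each = 20)
    })
    length(shadowSelect(X, y, max_runs = 60, alpha = 0.01, seed = sd,
                        num_trees = 150)$selected)
  }, numeric(1L))
  expect_lte(mean(nconf), 3)
})

test_that("shadow selection refuses degenerate inputs and is deterministic", {
  toy <- sepToy(seed = 6, n = 20, p_noise = 5)
  expect_error(shadowSelect(toy$X[1:4, ], toy$y[1:4]), "fewer than 5")
  expect_error(shadowSelect(toy$X, toy$y, max_runs = 5), "max_runs")
  a <- shadowSelect(toy$X, toy$y, max_runs = 30, seed = 9, num_trees = 100)
  b <- shadowSelect(toy$X, toy$y, max_runs = 30, seed = 9, num_trees = 100)
  expect_identical(a$selected, b$selected)
  expect_identical(a$scores, b$scores)
})

test_that("consensus is the exact intersection and a subset of each input", {
  r1 <- list(selected = c("a", "b", "c"))
  r2 <- list(selected = c("b", "c", "d"))
  r3 <- list(selected = c("c", "b"))
  expect_setequal(consensusIntersect(list(r1, r2, r3)), c("b", "c"))
  expect_length(consensusIntersect(list(r1, list(selected = character()))), 0L)
  expect_error(consensusIntersect(list(r1)), "at least two")
  cons <- consensusIntersect(list(r1, r2))
  expect_true(all(cons %in% r1$selected) && all(cons %in% r2$selected))
})

test_that("nested CV reaches AUC 1 on separable data", {
  toy <- sepToy(seed = 7, shift = 4)
  cv <- nestedCv(toy$X, toy$y, outer = 5, inner = 5, repeats = 3, seed = 1)
  expect_equal(unname(cv$means["auc"]), 1)
  expect_true(all(cv$per_eval$auc == 1))
  expect_equal(cv$auc_skipped, 0L)
})

test_that("nested CV is centred at 0.5 on label-permuted data", {
  aucs <- vapply(1:5, function(sd) {
    withr::with_seed(sd, {
      X <- matrix(rnorm(40 * 8), 40, 8,
                  dimnames = list(NULL, paste0("F", 1:8)))
      y <- rep(c(1L, 0L), each = 20)   # labels independent of X
    })
    nestedCv(X, y, outer = 5, inner = 5, repeats = 3,
             seed = sd)$means[["auc"]]
  }, numeric(1L))
  expect_lt(abs(mean(aucs) - 0.5), 0.06)
})

test_that("nested CV is seed-deterministic", {
  toy <- sepToy(seed = 8, shift = 1)
  a <- nestedCv(toy$X, toy$y, repeats = 2, seed = 5)
  b <- nestedCv(toy$X, toy$y, repeats = 2, seed = 5)
  expect_identical(a$per_eval, b$per_eval)
})

test_that("bootstrap stability frequencies behave at the extremes", {
  toy <- sepToy(seed = 9)
  one <- bootstrapStability(toy$X, toy$y, B = 1L, seed = 2)
  expect_true(all(one$frequency %in% c(0, 1)))
  rep1 <- bootstrapStability(toy$X, toy$y, B = 40L, seed = 3)
  rep2 <- bootstrapStability(toy$X, toy$y, B = 40L, seed = 3)
  expect_identical(rep1$frequency, rep2$frequency)
  expect_true(all(rep1$frequency >= 0 & rep1$frequency <= 1))
  expect_equal(rep1$counted + rep1$skipped_empty_oob, 40L)
})

test_that("a planted predictor out-ranks noise in bootstrap frequency", {
  wins <- vapply(1:6, function(sd) {
    toy <- sepToy(seed = sd, n = 30, p_noise = 8, shift = 2.5)
    st <- bootstrapStability(toy$X, toy$y, B = 40L, seed = sd)
    st$frequency["SIGNAL"] >
      median(st$frequency[names(st$frequency) != "SIGNAL"])
  }, logical(1L))
  expect_gte(sum(wins), 5L)   # sign test: planted nearly always wins
})
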