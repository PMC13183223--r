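# Tri-algorithm feature selection on the candidate genes, consensus
# intersection, nested cross-validated performance, and bootstrap stability.
#
# The L1 path and the boosted trees are standard library fits (glmnet,
# xgboost); the shadow-feature algorithm is implemented here, with a ranger
# random forest as its importance engine. Everything is seeded and
# stratified: at n = 17-scale data unstratified resampling frequently
# produces single-class fits.

#' Build a sample-by-feature matrix for the ML stage
#'
#' @param cohort a [CohortExperiment-class].
#' @param features gene symbols to use as columns (must exist in the
#'   cohort; missing symbols are dropped with a warning).
#' @return list with `X` (samples x features) and `y` (integer, case = 1).
#' @export
featureMatrix <- function(cohort, features) {
  features <- unique(as.character(features))
  miss <- setdiff(features, rownames(cohort))
  if (length(miss)) {
    warning(length(miss), " feature(s) absent from cohort dropped")
    features <- setdiff(features, miss)
  }
  if (!length(features)) stop("no usable features")
  X <- t(exprsMat(cohort)[features, , drop = FALSE])
  y <- as.integer(sampleGroups(cohort) == "case")
  list(X = X, y = y)
}

# Stratified fold assignment; k is reduced (with warning) if a class has
# fewer members than folds.
.stratFolds <- function(y, k, warn = TRUE) {
  k0 <- k
  k <- max(2L, min(k, min(table(y))))
  if (warn && k < k0)
    warning("reduced folds from ", k0, " to ", k,
            " so every fold keeps both classes")
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

# cv.glmnet emits advisory warnings on every small-n fit ("dangerous
# ground", "grouped=FALSE enforced"); at the 17-sample scale this pipeline
# targets they fire hundreds of times per run, so these two specific
# messages are muffled. Anything else propagates.
.cvGlmnet <- function(...) {
  withCallingHandlers(
    glmnet::cv.glmnet(...),
    warning = function(w) {
      m <- conditionMessage(w)
      if (grepl("dangerous ground|grouped=FALSE enforced", m))
        invokeRestart("muffleWarning")
    })
}

.selectionResult <- function(algorithm, selected, scores, settings, seed,
                             extra = list()) {
  res <- c(list(algorithm = algorithm, selected = sort(selected),
                scores = scores, settings = settings, seed = seed), extra)
  class(res) <- "selection_result"
  res
}

#' @export
print.selection_result <- function(x, ...) {
  cat("SelectionResult [", x$algorithm, "]: ", length(x$selected),
      " of ", length(x$scores), " features selected\n", sep = "")
  if (length(x$selected)) cat(" ", paste(x$selected, collapse = ", "), "\n")
  invisible(x)
}

#' L1-penalized logistic selection (cross-validated lambda)
#'
#' Fits the lasso path for a binomial model with features standardized
#' internally, picks lambda minimizing mean cross-validated binomial
#' deviance over stratified folds (the lambda.min convention), and selects
#' the features with nonzero coefficients there.
#'
#' @param X samples x features numeric matrix.
#' @param y binary labels (case = 1).
#' @param n_folds cross-validation folds (default 5).
#' @param seed integer seed (controls fold assignment).
#' @return a `selection_result` with `scores` = |coefficient| on the
#'   original scale and `lambda_min` recorded.
#' @export
lassoSelect <- function(X, y, n_folds = 5L, seed = 1L) {
  if (length(unique(y)) < 2L) stop("both classes required")
  withr::with_seed(substreamSeed(seed, "lasso"), {
    fold <- .stratFolds(y, n_folds)
    cv <- .cvGlmnet(X, y, family = "binomial", alpha = 1,
                            foldid = fold, type.measure = "deviance",
                            standardize = TRUE)
    cf <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1L, 1L]
    .selectionResult("l1_logistic",
                     selected = colnames(X)[cf != 0],
                     scores = setNames(abs(cf), colnames(X)),
                     settings = list(n_folds = max(fold)),
                     seed = seed,
                     extra = list(lambda_min = cv$lambda.min,
                                  coefficients = cf))
  })
}

#' Gradient-boosted-tree importance selection
#'
#' Fits a shallow boosted-tree classifier and ranks features by total gain;
#' by default every feature with positive gain (i.e. used in at least one
#' split) is selected. A feature never used in a split has importance 0.
#'
#' @param X samples x features matrix.
#' @param y binary labels (case = 1).
#' @param n_rounds boosting rounds (default 50).
#' @param top_frac optional fraction of top-gain features to keep instead
#'   of the nonzero-gain rule.
#' @param seed integer seed.
#' @param max_depth,eta tree depth and learning rate (shallow defaults).
#' @return a `selection_result` with `scores` = gain share per feature.
#' @export
gbtSelect <- function(X, y, n_rounds = 50L, top_frac = NULL, seed = 1L,
                      max_depth = 3L, eta = 0.3, subsample = 0.8,
                      colsample = 0.3) {
  if (n_rounds < 1L) stop("need at least one boosting round")
  if (length(unique(y)) < 2L) stop("both classes required")
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
  dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
  # row/column subsampling decorrelates the trees so gain spreads across
  # informative features instead of collapsing onto one greedy split
  bst <- xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = max_depth,
                  eta = eta, subsample = subsample,
                  colsample_bytree = colsample, nthread = 1L,
                  seed = substreamSeed(seed, "gbt")),
    data = dtrain, nrounds = n_rounds, verbose = 0L)
  imp <- tryCatch(xgboost::xgb.importance(model = bst),
                  error = function(e) NULL)
  scores <- setNames(numeric(ncol(X)), colnames(X))
  if (!is.null(imp) && nrow(imp))
    scores[imp$Feature] <- imp$Gain
  sel <- if (is.null(top_frac)) names(scores)[scores > 0]
         else names(sort(scores, decreasing = TRUE))[
           seq_len(max(1L, ceiling(top_frac * ncol(X))))]
  sel <- sel[scores[sel] > 0]
  .selectionResult("gbt_importance", selected = sel, scores = scores,
                   settings = list(n_rounds = n_rounds,
                                   max_depth = max_depth, eta = eta,
                                   subsample = subsample,
                                   colsample = colsample,
                                   rule = if (is.null(top_frac)) "nonzero_gain"
                                          else paste0("top_", top_frac)),
                   seed = seed)
}

#' Shadow-feature (Boruta-style) selection
#'
#' Iteratively appends a permuted shadow copy of every undecided feature,
#' fits a random forest, and credits a "hit" to each undecided feature whose
#' impurity importance exceeds the maximum shadow importance. After each
#' iteration, two-sided binomial tests of the hit counts against
#' Binomial(runs, 0.5) with BH correction at `alpha` Confirm (upper tail)
#' or Reject (lower tail) features. Stops when nothing is undecided or at
#' `max_runs`; features still undecided are reported as tentative, not
#' selected.
#'
#' @param X samples x features matrix (at least 5 samples).
#' @param y binary labels (case = 1).
#' @param max_runs maximum iterations (default 1000).
#' @param alpha BH-adjusted significance level for the binomial decisions
#'   (default 0.01).
#' @param seed integer seed.
#' @param num_trees forest size per iteration (default 300).
#' @return a `selection_result` with `selected` = Confirmed, plus
#'   `tentative`, `rejected`, `runs`, and `scores` = hit fraction.
#' @export
shadowSelect <- function(X, y, max_runs = 1000L, alpha = 0.01, seed = 1L,
                         num_trees = 300L) {
  if (nrow(X) < 5L) stop("fewer than 5 samples: ensemble unreliable")
  if (max_runs < 10L) stop("max_runs must be >= 10")
  if (length(unique(y)) < 2L) stop("both classes required")
  if (is.null(colnames(X))) colnames(X) <- paste0("F", seq_len(ncol(X)))
  p <- ncol(X)
  status <- setNames(rep("Undecided", p), colnames(X))
  hits <- setNames(integer(p), colnames(X))
  yf <- factor(y)
  withr::with_seed(substreamSeed(seed, "shadow"), {
    runs <- 0L
    while (any(status == "Undecided") && runs < max_runs) {
      runs <- runs + 1L
      active <- which(status != "Rejected")
      und <- which(status == "Undecided")
      shadows <- X[, und, drop = FALSE]
      for (j in seq_len(ncol(shadows))) shadows[, j] <- sample(shadows[, j])
      colnames(shadows) <- paste0(".shadow.", colnames(X)[und])
      dat <- cbind(X[, active, drop = FALSE], shadows)
      fit <- ranger::ranger(x = dat, y = yf, num.trees = num_trees,
                            importance = "impurity", num.threads = 1L,
                            seed = sample.int(.Machine$integer.max, 1L))
      imp <- fit$variable.importance
      shadow_max <- max(imp[startsWith(names(imp), ".shadow.")])
      beat <- names(imp)[!startsWith(names(imp), ".shadow.") &
                           imp > shadow_max]
      beat <- intersect(beat, names(status)[status == "Undecided"])
      hits[beat] <- hits[beat] + 1L
      undn <- names(status)[status == "Undecided"]
      p_up <- stats::pbinom(hits[undn] - 1L, runs, 0.5, lower.tail = FALSE)
      p_dn <- stats::pbinom(hits[undn], runs, 0.5)
      status[undn[bhAdjust(p_up) < alpha]] <- "Confirmed"
      undn2 <- names(status)[status == "Undecided"]
      status[undn2[bhAdjust(p_dn[match(undn2, undn)]) < alpha]] <- "Rejected"
    }
    .selectionResult("shadow_feature",
                     selected = names(status)[status == "Confirmed"],
                     scores = setNames(hits / max(runs, 1L), names(hits)),
                     settings = list(max_runs = max_runs, alpha = alpha,
                                     num_trees = num_trees),
                     seed = seed,
                     extra = list(
                       tentative = names(status)[status == "Undecided"],
                       rejected = names(status)[status == "Rejected"],
                       runs = runs))
  })
}

#' Consensus intersection of selection results
#'
#' @param results list of at least two `selection_result` objects.
#' @return sorted character vector of features selected by every algorithm.
#' @export
consensusIntersect <- function(results) {
  if (length(results) < 2L) stop("need at least two selection results")
  sel <- lapply(results, function(r) r$selected)
  sort(Reduce(intersect, sel))
}

.binMetrics <- function(prob, y, cutoff = 0.5) {
  pred <- as.integer(prob > cutoff)
  tp <- sum(pred == 1L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  fp <- sum(pred == 1L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  auc <- if (length(unique(y)) == 2L) {
    r <- rank(prob)
    n1 <- sum(y == 1L); n0 <- sum(y == 0L)
    (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else NA_real_
  c(auc = auc,
    accuracy = (tp + tn) / length(y),
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_)
}

#' Nested cross-validated performance of the L1 model
#'
#' Per repeat, stratified outer folds split the samples; within each outer
#' training set an inner stratified CV selects lambda (lambda.min, binomial
#' deviance), and the refit model is scored on the held-out outer fold.
#' AUC is undefined on a single-class test fold; such folds are skipped for
#' AUC and tallied. Aggregate means carry bootstrap 95 percent confidence
#' intervals over the per-evaluation values.
#'
#' @param X samples x features matrix.
#' @param y binary labels (case = 1).
#' @param outer,inner outer and inner fold counts (defaults 5, 5).
#' @param repeats repetitions of the outer split (default 100).
#' @param seed integer seed.
#' @param ci_boot bootstrap resamples for the CIs (default 1000).
#' @return list of class `cv_report`: `per_eval` (one row per outer fold
#'   per repeat), `means`, `ci` (2.5/97.5 percent bounds per metric),
#'   `auc_skipped`, settings.
#' @export
nestedCv <- function(X, y, outer = 5L, inner = 5L, repeats = 100L,
                     seed = 1L, ci_boot = 1000L) {
  if (repeats < 1L) stop("repeats must be >= 1")
  if (length(unique(y)) < 2L) stop("both classes required")
  withr::with_seed(substreamSeed(seed, "nested_cv"), {
    rows <- vector("list", repeats * outer)
    i <- 0L
    for (r in seq_len(repeats)) {
      fold <- .stratFolds(y, outer, warn = (r == 1L))
      for (f in seq_len(max(fold))) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2L) next
        inner_fold <- .stratFolds(y[tr], inner, warn = FALSE)
        cv <- .cvGlmnet(X[tr, , drop = FALSE], y[tr],
                                family = "binomial", alpha = 1,
                                foldid = inner_fold, standardize = TRUE)
        prob <- as.numeric(stats::predict(cv, X[!tr, , drop = FALSE],
                                          s = "lambda.min",
                                          type = "response"))
        i <- i + 1L
        rows[[i]] <- c(rep = r, fold = f, .binMetrics(prob, y[!tr]))
      }
    }
    per_eval <- as.data.frame(do.call(rbind, rows[seq_len(i)]))
    metric_cols <- c("auc", "accuracy", "sensitivity", "specificity",
                     "ppv", "npv")
    means <- colMeans(per_eval[metric_cols], na.rm = TRUE)
    ci <- sapply(metric_cols, function(mc) {
      v <- per_eval[[mc]][!is.na(per_eval[[mc]])]
      bm <- replicate(ci_boot, mean(sample(v, replace = TRUE)))
      stats::quantile(bm, c(0.025, 0.975), names = FALSE)
    })
    rownames(ci) <- c("lower", "upper")
    res <- list(per_eval = per_eval, means = means, ci = ci,
                auc_skipped = sum(is.na(per_eval$auc)),
                settings = list(outer = outer, inner = inner,
                                repeats = repeats, ci_boot = ci_boot),
                seed = seed)
    class(res) <- "cv_report"
    res
  })
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "Nested CV (%d x %d, %d repeats): mean AUC %.3f (95%% CI %.3f-%.3f)\n",
    x$settings$outer, x$settings$inner, x$settings$repeats,
    x$means["auc"], x$ci["lower", "auc"], x$ci["upper", "auc"]))
  cat(sprintf("  accuracy %.3f (95%% CI %.3f-%.3f); %d fold(s) without AUC\n",
              x$means["accuracy"], x$ci["lower", "accuracy"],
              x$ci["upper", "accuracy"], x$auc_skipped))
  invisible(x)
}

#' Bootstrap stability of the L1 selection with OOB performance
#'
#' Per iteration, samples are resampled with replacement within each class;
#' the inner-CV-tuned L1 model is fit on the bootstrap sample, its selected
#' gene set recorded, and performance evaluated on the out-of-bag samples.
#' Iterations with an empty OOB set are skipped and tallied. The selection
#' frequency of a gene is its selection count over the counted iterations.
#'
#' @param X samples x features matrix.
#' @param y binary labels (case = 1).
#' @param B bootstrap iterations (default 1000).
#' @param seed integer seed.
#' @param n_folds inner CV folds for lambda (default 5).
#' @return list of class `stability_report`: `frequency` (per gene),
#'   `per_iter` (OOB metrics), `mean_abs_coef`, `B`, `counted`,
#'   `skipped_empty_oob`, `seed`.
#' @export
bootstrapStability <- function(X, y, B = 1000L, seed = 1L, n_folds = 5L) {
  if (B < 1L) stop("B must be >= 1")
  if (length(unique(y)) < 2L) stop("both classes required")
  n <- length(y)
  withr::with_seed(substreamSeed(seed, "bootstrap"), {
    counts <- setNames(numeric(ncol(X)), colnames(X))
    coefsum <- setNames(numeric(ncol(X)), colnames(X))
    rows <- vector("list", B)
    counted <- 0L; skipped <- 0L
    for (b in seq_len(B)) {
      idx <- unlist(lapply(split(seq_len(n), y),
                           function(ii) sample(ii, replace = TRUE)),
                    use.names = FALSE)
      oob <- setdiff(seq_len(n), unique(idx))
      if (!length(oob)) { skipped <- skipped + 1L; next }
      fold <- .stratFolds(y[idx], n_folds, warn = FALSE)
      cv <- .cvGlmnet(X[idx, , drop = FALSE], y[idx],
                              family = "binomial", alpha = 1,
                              foldid = fold, standardize = TRUE)
      cf <- as.matrix(stats::coef(cv, s = "lambda.min"))[-1L, 1L]
      counted <- counted + 1L
      counts[cf != 0] <- counts[cf != 0] + 1
      coefsum <- coefsum + abs(cf)
      prob <- as.numeric(stats::predict(cv, X[oob, , drop = FALSE],
                                        s = "lambda.min", type = "response"))
      rows[[b]] <- .binMetrics(prob, y[oob])
    }
    if (counted == 0L)
      stop("every bootstrap iteration had an empty out-of-bag set")
    per_iter <- as.data.frame(do.call(rbind, rows[!vapply(rows, is.null,
                                                          logical(1L))]))
    res <- list(frequency = counts / counted,
                per_iter = per_iter,
                mean_abs_coef = coefsum / counted,
                oob_means = colMeans(per_iter, na.rm = TRUE),
                B = B, counted = counted, skipped_empty_oob = skipped,
                seed = seed)
    class(res) <- "stability_report"
    res
  })
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Bootstrap stability: %d/%d iterations counted (%d empty OOB)\n",
              x$counted, x$B, x$skipped_empty_oob))
  cat(sprintf("  mean OOB AUC %.3f, accuracy %.3f\n",
              x$oob_means["auc"], x$oob_means["accuracy"]))
  top <- sort(x$frequency, decreasing = TRUE)
  cat("  top selection frequencies:",
      paste(names(utils::head(top, 5L)),
            sprintf("%.1f%%", 100 * utils::head(top, 5L)), collapse = ", "),
      "\n")
  invisible(x)
}

#' Write the per-gene stability table as TSV
#'
#' Columns: symbol, frequency, mean |coefficient|.
#'
#' @param x a `stability_report`.
#' @param path output path.
#' @export
writeStabilityTSV <- function(x, path) {
  utils::write.table(
    data.frame(symbol = names(x$frequency), frequency = x$frequency,
               mean_abs_coef = x$mean_abs_coef, row.names = NULL),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}
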