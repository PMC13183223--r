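# Two-group moderated differential expression with BH correction.
#
# The moderated statistic shrinks per-gene sample variances toward a prior
# (d0, s0^2) estimated by moment-matching the marginal distribution of
# log(s_g^2): under the hierarchical model, e_g = log(s_g^2) - digamma(d_g/2)
# + log(d_g/2) has mean log(s0^2) + digamma(d0/2) - log(d0/2) and variance
# trigamma(d_g/2) + trigamma(d0/2), giving closed-form estimates via a
# trigamma inversion. This is a deterministic approximation to the familiar
# empirical-Bayes variance-shrinkage estimator.

# Invert the trigamma function by Newton iteration (monotone decreasing).
trigammaInverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:60) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif) < 1e-10 * y) break
  }
  y
}

# Moment-matching estimate of the variance prior from pooled variances s2
# with common residual df. Returns list(d0, s02); d0 may be Inf.
estimateVariancePrior <- function(s2, df) {
  s2 <- s2[s2 > 0 & is.finite(s2)]
  if (length(s2) < 2L) return(list(d0 = Inf, s02 = mean(s2)))
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  target <- stats::var(e) - trigamma(df / 2)
  if (target <= 0) {
    d0 <- Inf
    s02 <- exp(mean(e))
  } else {
    d0 <- 2 * trigammaInverse(target)
    s02 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s02 = s02)
}

#' Empirical-Bayes moderated two-group differential expression
#'
#' Computes, per gene, the case-minus-control log2 fold change and a
#' moderated t-statistic whose variance is the posterior
#' \eqn{\tilde{s}_g^2 = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)} under a
#' scaled inverse-chi-square prior \eqn{(d_0, s_0^2)} estimated by
#' moment-matching the marginal distribution of \eqn{\log s_g^2}. P-values
#' come from a t distribution with \eqn{d_0 + d_g} degrees of freedom;
#' BH-adjusted values are included. Genes flat across *all* samples are
#' reported and flagged but excluded from prior estimation.
#'
#' @param cohort a [CohortExperiment-class].
#' @param lfc_min,p_max,use_adjusted thresholds used only to fill the
#'   `direction` column (strict inequalities; see [thresholdDegs()]).
#' @param prior_df optional override of the estimated prior df: `0` gives
#'   the classical pooled two-sample t, `Inf` fully shrunken variances.
#' @return data.frame (one row per gene, input order) with columns
#'   `symbol`, `log2FC`, `t`, `df_total`, `p`, `p_adj`, `direction`,
#'   `flat`; the estimated prior is attached as `attr(, "prior")`
#'   (list `d0`, `s02`).
#' @examples
#' syn <- simCohorts(synConfig(n_genes = 200, seed = 7))
#' deg <- fitModerated(syn$train)
#' head(deg)
#' @export
fitModerated <- function(cohort, lfc_min = 0.5, p_max = 0.05,
                         use_adjusted = FALSE, prior_df = NULL) {
  stopifnot(is(cohort, "CohortExperiment"))
  m <- exprsMat(cohort)
  g <- sampleGroups(cohort)
  x1 <- m[, g == "case", drop = FALSE]
  x2 <- m[, g == "control", drop = FALSE]
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2L || n2 < 2L) stop("each group needs >= 2 samples")
  lfc <- rowMeans(x1) - rowMeans(x2)
  v1 <- apply(x1, 1L, stats::var)
  v2 <- apply(x2, 1L, stats::var)
  df_resid <- n1 + n2 - 2L
  s2 <- ((n1 - 1L) * v1 + (n2 - 1L) * v2) / df_resid
  flat <- apply(m, 1L, function(r) all(r == r[1L]))

  prior <- estimateVariancePrior(s2[!flat], df_resid)
  if (!is.null(prior_df)) prior$d0 <- prior_df
  d0 <- prior$d0; s02 <- prior$s02

  if (is.infinite(d0)) {
    s2_post <- rep(s02, length(s2))
  } else if (d0 == 0) {
    s2_post <- s2
  } else {
    s2_post <- (d0 * s02 + df_resid * s2) / (d0 + df_resid)
  }
  se <- sqrt(s2_post * (1 / n1 + 1 / n2))
  tstat <- ifelse(se > 0, lfc / se, ifelse(lfc == 0, 0, NaN))
  df_total <- d0 + df_resid
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  p[lfc == 0 & se == 0] <- 1
  if (anyNA(tstat) || any(is.nan(p)))
    warning("zero-variance genes with no prior produced NaN p-values")
  p_adj <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  p_adj[ok] <- bhAdjust(p[ok])

  out <- data.frame(symbol = rownames(m), log2FC = lfc, t = tstat,
                    df_total = df_total, p = p, p_adj = p_adj,
                    flat = flat, stringsAsFactors = FALSE,
                    row.names = NULL)
  pstar <- if (use_adjusted) out$p_adj else out$p
  out$direction <- ifelse(!is.na(pstar) & pstar < p_max & out$log2FC > lfc_min,
                          "up",
                   ifelse(!is.na(pstar) & pstar < p_max & out$log2FC < -lfc_min,
                          "down", "ns"))
  attr(out, "prior") <- list(d0 = d0, s02 = s02)
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return adjusted values, capped at 1, aligned with the input order.
#' @export
bhAdjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Classify genes as up/down at strict thresholds
#'
#' `up = {g : log2FC > lfc_min and p* < p_max}` with `p*` the raw or
#' BH-adjusted p-value; `down` symmetric. Inequalities are strict, so a gene
#' sitting exactly on a threshold is excluded.
#'
#' @param deg a DEG table from [fitModerated()].
#' @param lfc_min non-negative log2-fold-change threshold (default 0.5).
#' @param p_max p-value threshold (default 0.05).
#' @param use_adjusted use `p_adj` instead of `p`.
#' @return list with character vectors `up` and `down`.
#' @export
thresholdDegs <- function(deg, lfc_min = 0.5, p_max = 0.05,
                          use_adjusted = FALSE) {
  if (lfc_min < 0) stop("lfc_min must be non-negative")
  pstar <- if (use_adjusted) deg$p_adj else deg$p
  ok <- !is.na(pstar) & pstar < p_max
  list(up = deg$symbol[ok & deg$log2FC > lfc_min],
       down = deg$symbol[ok & deg$log2FC < -lfc_min])
}

# ---- readers / writers ------------------------------------------------------

#' Read an expression TSV (gene symbols in the first column)
#'
#' @param path TSV with a header row of sample IDs; first column gene
#'   symbols.
#' @param labels_path optional two-column TSV (`sample`, `group`) giving
#'   case/control labels; when supplied a [CohortExperiment-class] is
#'   returned, otherwise a bare matrix.
#' @param collapse how to resolve symbols occurring on several rows:
#'   `"mean"` (default) averages them, `"max"` keeps the row with the
#'   highest mean intensity, `"none"` errors on duplicates.
#' @return matrix or [CohortExperiment-class].
#' @export
readExpressionTSV <- function(path, labels_path = NULL, collapse = "mean") {
  d <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  sym <- as.character(d[[1L]])
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  m <- collapseBySymbol(m, sym, collapse)
  if (is.null(labels_path)) return(m)
  lab <- utils::read.delim(labels_path, stringsAsFactors = FALSE)
  grp <- lab$group[match(colnames(m), lab$sample)]
  cohortExperiment(m, grp)
}

#' Collapse duplicate gene symbols in an expression matrix
#'
#' @param m numeric matrix, one row per probe/row entry.
#' @param symbols per-row gene symbols.
#' @param collapse `"mean"`, `"max"` (row with highest mean), or `"none"`.
#' @return matrix with unique symbol rownames.
#' @export
collapseBySymbol <- function(m, symbols = rownames(m), collapse = "mean") {
  if (!anyDuplicated(symbols)) { rownames(m) <- symbols; return(m) }
  if (collapse == "none") stop("duplicate symbols present")
  if (collapse == "mean") {
    out <- rowsum(m, group = symbols) / as.vector(table(symbols)[
      sort(unique(symbols))])
    return(out[match(unique(symbols), rownames(out)), , drop = FALSE])
  }
  if (collapse == "max") {
    o <- order(-rowMeans(m))
    m2 <- m[o, , drop = FALSE]; s2 <- symbols[o]
    keep <- !duplicated(s2)
    out <- m2[keep, , drop = FALSE]
    rownames(out) <- s2[keep]
    return(out[match(unique(symbols), rownames(out)), , drop = FALSE])
  }
  stop("unknown collapse mode: ", collapse)
}

#' Read a GEO-style series-matrix text file
#'
#' Skips the metadata header and parses the block between the
#' `!series_matrix_table_begin` and `!series_matrix_table_end` delimiters.
#'
#' @param path series-matrix text file (uncompressed).
#' @param collapse duplicate-symbol policy, see [readExpressionTSV()].
#' @return numeric matrix (rows = IDs from the first column).
#' @export
readSeriesMatrix <- function(path, collapse = "mean") {
  lines <- readLines(path)
  b <- grep("^!series_matrix_table_begin", lines)
  e <- grep("^!series_matrix_table_end", lines)
  if (length(b) != 1L || length(e) != 1L || e <= b + 1L)
    stop("series-matrix table delimiters not found")
  d <- utils::read.delim(text = lines[(b + 1L):(e - 1L)], check.names = FALSE,
                         stringsAsFactors = FALSE)
  sym <- gsub('^"|"$', "", as.character(d[[1L]]))
  m <- as.matrix(d[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  collapseBySymbol(m, sym, collapse)
}

#' Write a DEG table as TSV
#'
#' Columns mirror the usual supplementary-table layout: symbol, log2FC, t,
#' p, p_adj, direction.
#'
#' @param deg DEG table from [fitModerated()].
#' @param path output path.
#' @export
writeDegTable <- function(deg, path) {
  utils::write.table(deg[, c("symbol", "log2FC", "t", "p", "p_adj",
                             "direction")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
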