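# Two-cohort validation, fold-change sensitivity grid, and group-difference
# testing for compositional abundance tables.

#' Two-sided Wilcoxon-Mann-Whitney rank-sum test
#'
#' Exact null distribution (by enumeration of rank assignments) when the
#' pooled sample size is at most 12 and there are no ties; otherwise the
#' normal approximation with tie correction (and continuity correction).
#'
#' @param x,y numeric vectors (non-empty).
#' @return list with `statistic` (W, ranks of `x`) and `p`.
#' @examples
#' ranksumTest(c(1, 2, 3), c(4, 5, 6))$p  # complete separation, 3 vs 3: 0.1
#' @export
ranksumTest <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty input")
  if (length(unique(c(x, y))) == 1L) {
    # all observations tied: no evidence against the null
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- (length(x) + length(y)) <= 12L && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Validate candidate genes across two cohorts
#'
#' Per gene, a rank-sum test of case vs control in each cohort and a
#' direction from the sign of the case-minus-control median difference
#' (set `direction = "mean"` for mean differences). A gene is a core target
#' when both p-values fall below `p_max` and the directions agree.
#'
#' @param genes character vector of symbols to check.
#' @param train,valid [CohortExperiment-class] cohorts.
#' @param p_max significance cutoff applied in both cohorts (default 0.05).
#' @param direction `"median"` (default) or `"mean"` difference.
#' @return data.frame with per-gene `p_train`, `p_valid`,
#'   `direction_train`, `direction_valid`, `is_core`, `present` (FALSE for
#'   genes absent from either cohort; such genes are reported, not
#'   dropped).
#' @export
validateCore <- function(genes, train, valid, p_max = 0.05,
                         direction = c("median", "mean")) {
  direction <- match.arg(direction)
  genes <- unique(as.character(genes))
  loc <- if (direction == "median") stats::median else mean
  one <- function(co, g) {
    m <- exprsMat(co); grp <- sampleGroups(co)
    if (!g %in% rownames(m)) return(c(NA_real_, NA_real_))
    xs <- m[g, grp == "case"]; ys <- m[g, grp == "control"]
    c(ranksumTest(xs, ys)$p, loc(xs) - loc(ys))
  }
  rows <- lapply(genes, function(g) {
    tr <- one(train, g); va <- one(valid, g)
    data.frame(symbol = g, p_train = tr[1L], p_valid = va[1L],
               direction_train = if (is.na(tr[2L])) NA_character_
                                 else if (tr[2L] >= 0) "up" else "down",
               direction_valid = if (is.na(va[2L])) NA_character_
                                 else if (va[2L] >= 0) "up" else "down",
               present = !is.na(tr[1L]) && !is.na(va[1L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$is_core <- out$present & !is.na(out$p_train) & !is.na(out$p_valid) &
    out$p_train < p_max & out$p_valid < p_max &
    out$direction_train == out$direction_valid
  out$is_core[is.na(out$is_core)] <- FALSE
  rownames(out) <- NULL
  out
}

#' Fold-change threshold sensitivity grid
#'
#' Re-runs DEG thresholding and the three-way intersection at each
#' |log2FC| threshold with the p-value cutoff held fixed (unadjusted
#' p < `p_max`), and records how many DEGs and candidates survive and
#' whether each tracked gene is retained. Strict thresholds make the
#' candidate sets nested: a tracked gene lost at one threshold never
#' reappears at a larger one.
#'
#' @param train a [CohortExperiment-class] (or a precomputed DEG table via
#'   `deg`).
#' @param disease,chem [TargetSet-class] objects or symbol vectors.
#' @param thresholds ascending |log2FC| thresholds
#'   (default 0.25, 0.50, 0.75, 1.00, 1.25, 1.50).
#' @param tracked symbols whose retention is reported per threshold.
#' @param p_max fixed p cutoff (default 0.05, unadjusted).
#' @param deg optional DEG table from [fitModerated()] to reuse.
#' @return data.frame with one row per threshold: `threshold`, `n_deg`,
#'   `n_candidates`, and one logical `retained_<gene>` column per tracked
#'   gene.
#' @export
sensitivityGrid <- function(train, disease, chem,
                            thresholds = c(0.25, 0.5, 0.75, 1, 1.25, 1.5),
                            tracked = character(), p_max = 0.05,
                            deg = NULL) {
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be sorted strictly ascending")
  if (is.null(deg)) deg <- fitModerated(train)
  rows <- lapply(thresholds, function(th) {
    dd <- thresholdDegs(deg, lfc_min = th, p_max = p_max,
                        use_adjusted = FALSE)
    degs <- c(dd$up, dd$down)
    cand <- intersectCandidates(degs, disease, chem)
    row <- data.frame(threshold = th, n_deg = length(degs),
                      n_candidates = length(cand$symbols))
    for (g in tracked)
      row[[paste0("retained_", g)]] <- g %in% cand$symbols
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group-difference tests on a compositional abundance table
#'
#' Per component, a two-sided rank-sum test of case vs control abundances
#' with BH correction across the component family (e.g. the 22 cell types
#' of a standard immune panel). Flags at p < 0.05 and q < 0.05 are
#' reported separately.
#'
#' @param abundance samples x components matrix, rows on the simplex.
#' @param groups per-sample labels (`case`/`control`), at least 3 per
#'   group.
#' @return data.frame with `component`, `p`, `q`, `sig_p`, `sig_q`.
#' @export
abundanceGroupTest <- function(abundance, groups) {
  groups <- as.character(groups)
  if (sum(groups == "case") < 3L || sum(groups == "control") < 3L)
    stop("need >= 3 samples per group")
  p <- apply(abundance, 2L, function(v)
    ranksumTest(v[groups == "case"], v[groups == "control"])$p)
  q <- bhAdjust(p)
  data.frame(component = colnames(abundance), p = p, q = q,
             sig_p = p < 0.05, sig_q = q < 0.05,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a sensitivity grid as TSV
#'
#' @param grid output of [sensitivityGrid()].
#' @param path output path.
#' @export
writeGridTSV <- function(grid, path) {
  utils::write.table(grid, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}
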