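# Significance of multi-list overlap: exact hypergeometric tail and a
# size-matched permutation null with fold enrichment.

#' Upper hypergeometric tail probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): drawing `n` items without
#' replacement from a universe of `N` containing `K` successes. Computed in
#' log space; symmetric in (K, n).
#'
#' @param k observed overlap (successes drawn).
#' @param K number of successes in the universe.
#' @param n number of draws.
#' @param N universe size.
#' @return the tail probability.
#' @examples
#' hypergeomTail(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeomTail <- function(k, K, n, N) {
  if (k < 0 || K < 0 || n < 0 || N < 0) stop("counts must be non-negative")
  if (k > K || k > n || K > N || n > N)
    stop("inconsistent counts: need k <= min(K, n) <= N")
  if (k == 0) return(1)
  exp(stats::phyper(k - 1, m = K, n = N - K, k = n,
                    lower.tail = FALSE, log.p = TRUE))
}

#' Permutation test for a three-way gene-list overlap
#'
#' Draws, for each of `B` iterations, random subsets of the background
#' matching the three observed cardinalities and records the size of their
#' three-way intersection. The permutation p-value uses the +1 pseudo-count
#' on both numerator and denominator (so it can never be 0), and fold
#' enrichment is the observed overlap divided by the null mean. By default
#' all three sets are resampled — the most conservative null; mode
#' `"deg_only"` resamples only the third (DEG) set.
#'
#' @param setA,setB,setC character vectors (e.g. chemical targets, disease
#'   targets, DEGs); each must be contained in `background`.
#' @param background character vector, the gene universe (typically all
#'   genes measured on the platform).
#' @param B number of permutations (default 10,000).
#' @param seed integer seed.
#' @param mode `"all"` (resample all three sets) or `"deg_only"`.
#' @return list of class `overlap_result`: `k_obs`, `set_sizes`,
#'   `background_size`, `p_hyper` (two-set reduction, see Details),
#'   `p_perm`, `fold_enrichment`, `null_mean`, `null_sd`, `null_hist`
#'   (table of null overlap counts), `B`, `seed`, `mode`.
#' @details The hypergeometric reduction of a three-way design is not
#'   unique; here `K = |setA` \eqn{\cap} `setB|` (both restricted to the
#'   background), `n = |setC|`, and the observed overlap is the three-way
#'   count — i.e. the DEG draw is tested against the chemical-and-disease
#'   joint target pool. Use [hypergeomTail()] directly for other
#'   constructions.
#' @export
permuteOverlap <- function(setA, setB, setC, background, B = 10000L,
                           seed = 1L, mode = c("all", "deg_only")) {
  mode <- match.arg(mode)
  if (B < 1L) stop("B must be >= 1")
  background <- unique(as.character(background))
  sets <- list(A = unique(as.character(setA)), B = unique(as.character(setB)),
               C = unique(as.character(setC)))
  for (nm in names(sets)) {
    out <- setdiff(sets[[nm]], background)
    if (length(out))
      stop("set ", nm, " not contained in background: ",
           paste(utils::head(out, 5L), collapse = ", "),
           if (length(out) > 5L) " ...")
  }
  N <- length(background)
  sizes <- lengths(sets)
  k_obs <- length(intersect(intersect(sets$A, sets$B), sets$C))
  idx <- lapply(sets, function(s) match(s, background))

  withr::with_seed(substreamSeed(seed, "permute_overlap"), {
    k_null <- integer(B)
    if (mode == "all") {
      for (b in seq_len(B)) {
        draws <- c(sample.int(N, sizes[1L]), sample.int(N, sizes[2L]),
                   sample.int(N, sizes[3L]))
        k_null[b] <- sum(tabulate(draws, N) == 3L)
      }
    } else {
      fixedAB <- tabulate(c(idx$A, idx$B), N) == 2L
      for (b in seq_len(B)) {
        k_null[b] <- sum(fixedAB[sample.int(N, sizes[3L])])
      }
    }
    null_mean <- mean(k_null)
    res <- list(
      k_obs = k_obs,
      set_sizes = sizes,
      background_size = N,
      p_hyper = hypergeomTail(k_obs,
                              K = length(intersect(sets$A, sets$B)),
                              n = sizes[3L], N = N),
      p_perm = (1 + sum(k_null >= k_obs)) / (B + 1),
      fold_enrichment = if (null_mean > 0) k_obs / null_mean else NA_real_,
      null_mean = null_mean,
      null_sd = stats::sd(k_null),
      null_hist = table(k_null),
      B = B, seed = seed, mode = mode)
    class(res) <- "overlap_result"
    res
  })
}

#' @export
print.overlap_result <- function(x, ...) {
  cat(sprintf(
    "Overlap: k = %d of sets (%s) in background N = %d\n",
    x$k_obs, paste(x$set_sizes, collapse = ", "), x$background_size))
  cat(sprintf("  hypergeometric tail p = %.3g\n", x$p_hyper))
  cat(sprintf("  permutation p = %.3g (B = %d, %s), fold enrichment = %.2f\n",
              x$p_perm, x$B, x$mode, x$fold_enrichment))
  cat(sprintf("  null overlap: mean %.2f, sd %.2f\n", x$null_mean, x$null_sd))
  invisible(x)
}

#' Serialize an overlap result (with null histogram) as JSON
#'
#' @param x an `overlap_result`.
#' @param path output path.
#' @export
writeOverlapJSON <- function(x, path) {
  out <- x[c("k_obs", "set_sizes", "background_size", "p_hyper", "p_perm",
             "fold_enrichment", "null_mean", "null_sd", "B", "seed", "mode")]
  out$null_hist <- list(overlap = as.integer(names(x$null_hist)),
                        count = as.integer(x$null_hist))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(out)
}
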