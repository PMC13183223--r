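# Independent oracles, deliberately implemented with different algorithms
# than the package code paths they check.

# Hypergeometric upper tail by exhaustive enumeration of all draws:
# universe 1..N with successes 1..K, all C(N, n) unordered draws.
enumHyperTail <- function(k, K, n, N) {
  if (k == 0) return(1)
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Two-sided exact rank-sum p by enumeration of all group assignments of the
# pooled sample (no ties assumed).
enumRanksumP <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  sets <- utils::combn(length(pooled), n1)
  u <- apply(sets, 2L, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u <= u_obs), mean(u >= u_obs)))
}

# Degree / betweenness / stress via Floyd-Warshall distances plus a
# distance-ordered DP for geodesic counts (contrast: package uses BFS).
bruteCentralities <- function(edges, nodes) {
  n <- length(nodes)
  A <- matrix(FALSE, n, n)
  ia <- match(edges$nodeA, nodes); ib <- match(edges$nodeB, nodes)
  for (j in seq_along(ia)) {
    A[ia[j], ib[j]] <- TRUE
    A[ib[j], ia[j]] <- TRUE
  }
  D <- matrix(Inf, n, n); diag(D) <- 0; D[A] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  S <- matrix(0, n, n); diag(S) <- 1
  for (s in seq_len(n)) {
    for (t in order(D[s, ])) {
      if (t == s || !is.finite(D[s, t])) next
      nb <- which(A[, t])
      pred <- nb[D[s, nb] == D[s, t] - 1]
      S[s, t] <- sum(S[s, pred])
    }
  }
  btw <- str <- numeric(n)
  for (v in seq_len(n)) for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || s == v || t == v || !is.finite(D[s, t])) next
    if (D[s, v] + D[v, t] == D[s, t]) {
      str[v] <- str[v] + S[s, v] * S[v, t]
      btw[v] <- btw[v] + S[s, v] * S[v, t] / S[s, t]
    }
  }
  data.frame(symbol = nodes, degree = rowSums(A), betweenness = btw,
             stress = str, stringsAsFactors = FALSE)
}

# Seeded Erdos-Renyi-ish random simple graph as an edge data.frame.
randomGraphEdges <- function(n, p = 0.35, seed = 1) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(n, 2)
  withr::with_seed(seed, keep <- stats::runif(ncol(pairs)) < p)
  data.frame(nodeA = nodes[pairs[1, keep]], nodeB = nodes[pairs[2, keep]],
             score = rep(1, sum(keep)), stringsAsFactors = FALSE)
}

# Small deterministic two-group cohort for unit tests.
toyCohort <- function(n_genes = 50, n_case = 5, n_ctrl = 5, shift = NULL,
                      sd = 0.3, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnorm(n_genes * (n_case + n_ctrl), 7, sd), n_genes,
                dimnames = list(sprintf("T%03d", seq_len(n_genes)),
                                sprintf("S%02d", seq_len(n_case + n_ctrl))))
    if (!is.null(shift))
      m[names(shift), seq_len(n_case)] <-
        m[names(shift), seq_len(n_case)] + unlist(shift)
  })
  cohortExperiment(m, rep(c("case", "control"), c(n_case, n_ctrl)))
}
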