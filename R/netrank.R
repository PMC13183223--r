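# Composite centrality ranking of candidates in a PPI network.
#
# Degree, betweenness, and stress are computed from one BFS-based all-pairs
# shortest-path-count pass (unweighted; edge confidence scores are used only
# for thresholding at network construction, matching how interaction-score
# cutoffs are used in practice).

# Breadth-first all-pairs geodesic distances and path counts.
# adj: list of integer neighbour vectors. Returns D (distances, Inf if
# unreachable) and S (number of shortest paths), both n x n.
.apspCounts <- function(adj) {
  n <- length(adj)
  D <- matrix(Inf, n, n)
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    sigma <- numeric(n)
    dist[s] <- 0L; sigma[s] <- 1
    frontier <- s; d <- 0L
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (dist[w] == -1L) {
            dist[w] <- d + 1L
            nxt <- c(nxt, w)
          }
          if (dist[w] == d + 1L) sigma[w] <- sigma[w] + sigma[v]
        }
      }
      frontier <- unique(nxt)
      d <- d + 1L
    }
    reach <- dist >= 0L
    D[s, reach] <- dist[reach]
    S[s, ] <- sigma
  }
  list(D = D, S = S)
}

.adjList <- function(net) {
  nodes <- networkNodes(net)
  e <- networkEdges(net)
  ia <- match(e$nodeA, nodes); ib <- match(e$nodeB, nodes)
  adj <- vector("list", length(nodes))
  for (i in seq_along(nodes)) adj[[i]] <- integer(0)
  for (j in seq_along(ia)) {
    adj[[ia[j]]] <- c(adj[[ia[j]]], ib[j])
    adj[[ib[j]]] <- c(adj[[ib[j]]], ia[j])
  }
  adj
}

#' Node centralities: degree, betweenness, stress
#'
#' Degree counts incident edges; betweenness sums, over unordered node pairs
#' (s, t) distinct from v, the fraction of geodesics through v
#' \eqn{\sigma_{st}(v)/\sigma_{st}}; stress sums the raw geodesic counts
#' \eqn{\sigma_{st}(v)}. Shortest paths are unweighted and computed per
#' connected component.
#'
#' @param net an [InteractionNetwork-class].
#' @return data.frame with columns `symbol`, `degree`, `betweenness`,
#'   `stress` (node order of the network).
#' @examples
#' net <- interactionNetwork(data.frame(nodeA = c("a", "b"),
#'                                      nodeB = c("b", "c"), score = 1))
#' centralities(net)  # b bridges a and c
#' @export
centralities <- function(net) {
  stopifnot(is(net, "InteractionNetwork"))
  nodes <- networkNodes(net)
  n <- length(nodes)
  if (n == 0L) stop("empty graph")
  adj <- .adjList(net)
  ap <- .apspCounts(adj)
  D <- ap$D; S <- ap$S
  btw <- numeric(n); str <- numeric(n)
  if (n > 2L) {
    for (v in seq_len(n)) {
      cond <- outer(D[, v], D[v, ], `+`) == D & is.finite(D)
      cond[v, ] <- FALSE; cond[, v] <- FALSE; diag(cond) <- FALSE
      num <- outer(S[, v], S[v, ])
      str[v] <- 0.5 * sum(num[cond])
      ok <- cond & S > 0
      btw[v] <- 0.5 * sum(num[ok] / S[ok])
    }
  }
  data.frame(symbol = nodes, degree = lengths(adj), betweenness = btw,
             stress = str, stringsAsFactors = FALSE, row.names = NULL)
}

#' Composite centrality ranking
#'
#' Min-max normalizes each centrality to \[0, 1\] (a constant metric maps to
#' all zeros), averages the three normalized values into a composite score,
#' and ranks descending. Ties break by higher degree, then lexicographic
#' symbol, so top-k lists are reproducible.
#'
#' @param tab centrality table from [centralities()].
#' @param top_k number of top-ranked nodes to return (default 20; capped at
#'   the node count).
#' @return data.frame of the `top_k` best nodes, ordered, with added
#'   columns `norm_degree`, `norm_betweenness`, `norm_stress`, `composite`,
#'   `rank`.
#' @export
compositeRank <- function(tab, top_k = 20L) {
  if (top_k <= 0L) stop("top_k must be positive")
  top_k <- min(as.integer(top_k), nrow(tab))
  mm <- function(x) {
    r <- range(x)
    if (r[1L] == r[2L]) rep(0, length(x)) else (x - r[1L]) / (r[2L] - r[1L])
  }
  tab$norm_degree <- mm(tab$degree)
  tab$norm_betweenness <- mm(tab$betweenness)
  tab$norm_stress <- mm(tab$stress)
  tab$composite <- (tab$norm_degree + tab$norm_betweenness +
                      tab$norm_stress) / 3
  o <- order(-tab$composite, -tab$degree, tab$symbol)
  tab <- tab[o, , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  tab[seq_len(top_k), , drop = FALSE]
}

#' Read a three-column edge-list TSV (nodeA, nodeB, score)
#'
#' @param path TSV path with header.
#' @param score_min confidence threshold (strict), default 0.4.
#' @return [InteractionNetwork-class].
#' @export
readEdgeList <- function(path, score_min = 0.4) {
  interactionNetwork(utils::read.delim(path, stringsAsFactors = FALSE),
                     score_min = score_min)
}

#' @rdname readEdgeList
#' @param net network to write.
#' @export
writeEdgeList <- function(net, path) {
  utils::write.table(networkEdges(net), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Write a ranked centrality table as TSV
#'
#' @param tab output of [compositeRank()].
#' @param path output path.
#' @export
writeRankTable <- function(tab, path) {
  utils::write.table(tab[, c("symbol", "degree", "betweenness", "stress",
                             "composite", "rank")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
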