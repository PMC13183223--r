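#' Two-group expression cohort
#'
#' A [SummarizedExperiment::SummarizedExperiment] carrying one `exprs` assay
#' of log2 intensities (genes x samples) and a mandatory `group` column in
#' `colData` with levels `case` and `control`. Validity requires at least two
#' samples per group, unique non-empty gene symbols, and no missing values —
#' the invariants every downstream stage assumes.
#'
#' @slot .  inherits all slots from `SummarizedExperiment`.
#' @seealso [cohortExperiment()] for construction from a plain matrix.
#' @export
setClass("CohortExperiment", contains = "SummarizedExperiment")

setValidity("CohortExperiment", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'exprs' is required")
  else {
    m <- SummarizedExperiment::assay(object, "exprs")
    if (anyNA(m)) msg <- c(msg, "expression values must not contain NA")
  }
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn) || any(!nzchar(rn)))
    msg <- c(msg, "gene symbols (rownames) must be unique and non-empty")
  if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must contain a 'group' column")
  else {
    g <- as.character(object$group)
    if (!all(g %in% c("case", "control")))
      msg <- c(msg, "group labels must be 'case' or 'control'")
    if (sum(g == "case") < 2L || sum(g == "control") < 2L)
      msg <- c(msg, "need >= 2 samples per group")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CohortExperiment
#'
#' @param values numeric matrix of log2 intensities, genes in rows (rownames
#'   are gene symbols), samples in columns.
#' @param groups character vector of per-sample labels, `"case"` or
#'   `"control"`, in column order.
#' @return A [CohortExperiment-class] object.
#' @examples
#' m <- matrix(rnorm(40, 7), 10, 4,
#'             dimnames = list(paste0("G", 1:10), paste0("S", 1:4)))
#' ce <- cohortExperiment(m, c("case", "case", "control", "control"))
#' @export
cohortExperiment <- function(values, groups) {
  values <- as.matrix(values)
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  if (length(groups) != ncol(values))
    stop("length(groups) must equal ncol(values)")
  se <- SummarizedExperiment::SummarizedExperiment(
    assays  = list(exprs = values),
    colData = S4Vectors::DataFrame(group = as.character(groups),
                                   row.names = colnames(values)))
  new("CohortExperiment", se)
}

#' @describeIn cohortExperiment expression matrix accessor.
#' @param x a `CohortExperiment`.
#' @export
exprsMat <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn cohortExperiment per-sample group labels (character).
#' @export
sampleGroups <- function(x) as.character(x$group)

setMethod("show", "CohortExperiment", function(object) {
  g <- sampleGroups(object)
  cat("CohortExperiment:", nrow(object), "genes x", ncol(object), "samples",
      sprintf("(%d case / %d control)\n",
              sum(g == "case"), sum(g == "control")))
})

#' Curated target set
#'
#' A named collection of gene-symbol entries with optional per-entry
#' attributes (`source`, `interaction_type`, `fit_score`, `species`), the
#' in-memory form of a chemical- or disease-target table. Symbols are unique
#' after standardization.
#'
#' @slot name single character label.
#' @slot entries data.frame with at least a `symbol` column; unique symbols.
#' @export
setClass("TargetSet",
         representation(name = "character", entries = "data.frame"))

setValidity("TargetSet", function(object) {
  msg <- character()
  e <- object@entries
  if (!"symbol" %in% colnames(e)) msg <- c(msg, "entries need a 'symbol' column")
  else {
    if (any(!nzchar(e$symbol))) msg <- c(msg, "empty symbols not allowed")
    if (anyDuplicated(e$symbol)) msg <- c(msg, "duplicate symbols not allowed")
  }
  if (length(object@name) != 1L) msg <- c(msg, "name must be length 1")
  if (length(msg)) msg else TRUE
})

.targetCols <- c("symbol", "source", "interaction_type", "fit_score", "species")

#' Construct a TargetSet
#'
#' @param entries a data.frame with a `symbol` column (extra recognised
#'   columns: `source`, `interaction_type`, `fit_score`, `species`), or a
#'   character vector of symbols.
#' @param name label for the set.
#' @return A [TargetSet-class].
#' @examples
#' ts <- targetSet(c("MMP9", "HPSE"), name = "demo")
#' symbols(ts)
#' @export
targetSet <- function(entries, name = "targets") {
  if (is.character(entries))
    entries <- data.frame(symbol = entries, stringsAsFactors = FALSE)
  entries <- as.data.frame(entries)
  for (col in .targetCols)
    if (!col %in% colnames(entries))
      entries[[col]] <- rep(if (col == "fit_score") NA_real_
                            else NA_character_, nrow(entries))
  entries <- entries[, .targetCols, drop = FALSE]
  rownames(entries) <- NULL
  new("TargetSet", name = name, entries = entries)
}

#' @rdname targetSet
#' @param x,object a `TargetSet`.
#' @export
setGeneric("symbols", function(x) standardGeneric("symbols"))

#' @rdname targetSet
#' @export
setMethod("symbols", "TargetSet", function(x) x@entries$symbol)

#' @rdname targetSet
#' @export
targetEntries <- function(x) x@entries

setMethod("length", "TargetSet", function(x) nrow(x@entries))

setMethod("show", "TargetSet", function(object) {
  cat("TargetSet '", object@name, "': ", nrow(object@entries),
      " unique symbols\n", sep = "")
  src <- table(object@entries$source, useNA = "no")
  if (length(src))
    cat("  sources:", paste(names(src), src, sep = "=", collapse = ", "), "\n")
})

#' Protein-protein interaction network
#'
#' An undirected simple graph over gene symbols with per-edge confidence
#' scores in \[0, 1\]. The constructor drops self loops, collapses duplicate
#' edges (keeping the maximum score), and removes edges at or below
#' `score_min` — mirroring the common confidence-score cutoff used when
#' assembling interaction networks (default threshold 0.4, strict).
#'
#' @slot edges data.frame with columns `nodeA`, `nodeB`, `score`.
#' @slot nodes character vector of node symbols (isolated nodes allowed).
#' @slot score_min numeric scalar; retained edges have `score > score_min`.
#' @export
setClass("InteractionNetwork",
         representation(edges = "data.frame", nodes = "character",
                        score_min = "numeric"))

setValidity("InteractionNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (!all(c("nodeA", "nodeB", "score") %in% colnames(e)))
    msg <- c(msg, "edges need columns nodeA, nodeB, score")
  else if (nrow(e)) {
    if (any(e$nodeA == e$nodeB)) msg <- c(msg, "self loops not allowed")
    key <- paste(pmin(e$nodeA, e$nodeB), pmax(e$nodeA, e$nodeB))
    if (anyDuplicated(key)) msg <- c(msg, "multi-edges not allowed")
    if (any(e$score < 0 | e$score > 1)) msg <- c(msg, "scores must be in [0,1]")
    if (any(e$score <= object@score_min))
      msg <- c(msg, "all retained edges must have score > score_min")
    if (!all(c(e$nodeA, e$nodeB) %in% object@nodes))
      msg <- c(msg, "edge endpoints must be listed in nodes")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an InteractionNetwork
#'
#' @param edges data.frame with columns `nodeA`, `nodeB`, `score` (score may
#'   be omitted; it then defaults to 1).
#' @param nodes optional full node set (to keep isolated nodes); defaults to
#'   the union of edge endpoints.
#' @param score_min confidence threshold; edges with `score <= score_min`
#'   are dropped (strict `>`, default 0.4).
#' @return An [InteractionNetwork-class].
#' @examples
#' net <- interactionNetwork(data.frame(nodeA = "A", nodeB = "B", score = 0.9))
#' @export
interactionNetwork <- function(edges, nodes = NULL, score_min = 0.4) {
  edges <- as.data.frame(edges)
  if (!"score" %in% colnames(edges)) edges$score <- 1
  edges <- edges[, c("nodeA", "nodeB", "score")]
  edges$nodeA <- as.character(edges$nodeA)
  edges$nodeB <- as.character(edges$nodeB)
  edges <- edges[edges$nodeA != edges$nodeB & edges$score > score_min, ,
                 drop = FALSE]
  if (nrow(edges)) {
    a <- pmin(edges$nodeA, edges$nodeB)
    b <- pmax(edges$nodeA, edges$nodeB)
    edges$nodeA <- a; edges$nodeB <- b
    key <- paste(a, b)
    # collapse parallel edges, keep highest confidence
    o <- order(key, -edges$score)
    edges <- edges[o, , drop = FALSE]
    edges <- edges[!duplicated(key[o]), , drop = FALSE]
    edges <- edges[order(edges$nodeA, edges$nodeB), , drop = FALSE]
  }
  rownames(edges) <- NULL
  if (is.null(nodes)) nodes <- sort(unique(c(edges$nodeA, edges$nodeB)))
  new("InteractionNetwork", edges = edges, nodes = as.character(nodes),
      score_min = score_min)
}

#' @rdname interactionNetwork
#' @param x an `InteractionNetwork`.
#' @export
networkEdges <- function(x) x@edges

#' @rdname interactionNetwork
#' @export
networkNodes <- function(x) x@nodes

setMethod("show", "InteractionNetwork", function(object) {
  cat("InteractionNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges (score >", object@score_min, ")\n")
})
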