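# Target-list standardization, context-aware filtering, and the Venn stage.

#' Standardize a target table into a TargetSet
#'
#' Trims whitespace, maps aliases, upper-cases symbols, drops empty symbols
#' (counted), and merges duplicates keeping the maximum fit score and the
#' union of interaction-type labels. Idempotent: standardizing twice changes
#' nothing.
#'
#' @param entries data.frame with a `symbol` column (plus optional `source`,
#'   `interaction_type`, `fit_score`, `species`), or a character vector.
#' @param alias_map named character vector mapping alias -> canonical symbol
#'   (applied after upper-casing both sides); must be idempotent on its
#'   range and acyclic.
#' @param name label for the resulting set.
#' @return A [TargetSet-class]; the number of dropped empty entries is
#'   attached as `attr(, "dropped")`.
#' @examples
#' standardizeTargets(c("mmp9", "MMP9", "MMP-9"),
#'                    alias_map = c("MMP-9" = "MMP9"))
#' @export
standardizeTargets <- function(entries, alias_map = character(),
                               name = "targets") {
  if (is.character(entries))
    entries <- data.frame(symbol = entries, stringsAsFactors = FALSE)
  entries <- as.data.frame(entries)
  for (col in .targetCols)   # normalise columns; duplicates still allowed here
    if (!col %in% colnames(entries))
      entries[[col]] <- rep(if (col == "fit_score") NA_real_
                            else NA_character_, nrow(entries))
  entries <- entries[, .targetCols, drop = FALSE]
  sym <- toupper(trimws(entries$symbol))
  if (length(alias_map)) {
    names(alias_map) <- toupper(trimws(names(alias_map)))
    alias_map <- toupper(trimws(alias_map))
    bad <- alias_map[alias_map %in% names(alias_map) &
                     alias_map != names(alias_map)]
    if (length(bad) && any(alias_map[bad] != bad))
      stop("alias_map is not idempotent on its range (chained/cyclic aliases)")
    hit <- sym %in% names(alias_map)
    sym[hit] <- alias_map[sym[hit]]
  }
  dropped <- sum(!nzchar(sym) | is.na(sym))
  keep <- nzchar(sym) & !is.na(sym)
  entries <- entries[keep, , drop = FALSE]
  sym <- sym[keep]
  entries$symbol <- sym
  merged <- lapply(split(entries, sym), function(d) {
    data.frame(
      symbol = d$symbol[1L],
      source = paste(sort(unique(stats::na.omit(d$source))), collapse = ";"),
      interaction_type = paste(sort(unique(stats::na.omit(d$interaction_type))),
                               collapse = ";"),
      fit_score = if (all(is.na(d$fit_score))) NA_real_
                  else max(d$fit_score, na.rm = TRUE),
      species = paste(sort(unique(stats::na.omit(d$species))), collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  if (is.null(out)) out <- entries[0, , drop = FALSE]
  for (col in c("source", "interaction_type", "species"))
    out[[col]][!nzchar(out[[col]])] <- NA_character_
  out <- out[match(unique(sym), out$symbol), , drop = FALSE]
  ts <- targetSet(out, name = name)
  attr(ts, "dropped") <- dropped
  ts
}

#' Context-aware filtering of a chemical target set
#'
#' Applies the stricter triage used in sensitivity analyses of chemical
#' target lists, per source: entries from curated interaction databases
#' (source `ctd`) must be annotated as `direct` interactions (when
#' `direct_only`); pharmacophore-mapping entries (source `pharmmapper`) must
#' score at or above the `1 - fit_top_frac` quantile of that source's fit
#' scores (default: top 20 percent, ties kept). Optionally the species label
#' must be `Homo sapiens` or absent. All surviving entries must have a
#' strictly positive expression value for their symbol in at least one
#' sample of at least one supplied cohort; symbols absent from every cohort
#' are removed.
#'
#' @param chem a [TargetSet-class].
#' @param cohorts a [CohortExperiment-class] or list of them defining
#'   detectability.
#' @param direct_only require `direct` interaction annotation for
#'   `ctd`-source entries (default TRUE).
#' @param fit_top_frac fraction of top fit scores to keep, in (0, 1\];
#'   1 disables the score filter.
#' @param human_only drop entries labeled with a non-human species.
#' @return the filtered [TargetSet-class] (always a subset of `chem`).
#' @export
contextFilter <- function(chem, cohorts, direct_only = TRUE,
                          fit_top_frac = 0.2, human_only = TRUE) {
  stopifnot(is(chem, "TargetSet"))
  if (fit_top_frac <= 0 || fit_top_frac > 1)
    stop("fit_top_frac must lie in (0, 1]")
  if (is(cohorts, "CohortExperiment")) cohorts <- list(cohorts)
  e <- targetEntries(chem)
  keep <- rep(TRUE, nrow(e))
  src <- ifelse(is.na(e$source), "", e$source)
  is_ctd <- grepl("\\bctd\\b", src)
  is_pm <- grepl("\\bpharmmapper\\b", src)
  if (direct_only) {
    it <- ifelse(is.na(e$interaction_type), "", e$interaction_type)
    # exact label match: "indirect" must not satisfy a "direct" requirement
    has_direct <- vapply(strsplit(it, ";", fixed = TRUE),
                         function(v) "direct" %in% v, logical(1L))
    keep[is_ctd] <- keep[is_ctd] & has_direct[is_ctd]
  }
  if (fit_top_frac < 1) {
    scores <- e$fit_score[is_pm]
    if (any(is_pm) && all(is.na(scores)))
      stop("no pharmmapper entry carries a fit_score; cannot apply the ",
           "top-fraction filter")
    if (any(is_pm)) {
      cut <- stats::quantile(scores, probs = 1 - fit_top_frac, na.rm = TRUE,
                             type = 7)
      keep[is_pm] <- keep[is_pm] & !is.na(scores) & scores >= cut
    }
  }
  if (human_only) {
    sp <- e$species
    keep <- keep & (is.na(sp) | sp == "" | grepl("Homo sapiens", sp))
  }
  detectable <- Reduce(`|`, lapply(cohorts, function(co) {
    m <- exprsMat(co)
    hit <- e$symbol %in% rownames(m)
    pos <- rep(FALSE, nrow(e))
    pos[hit] <- apply(m[e$symbol[hit], , drop = FALSE] > 0, 1L, any)
    pos
  }))
  keep <- keep & detectable
  targetSet(e[keep, , drop = FALSE], name = paste0(chem@name, "_filtered"))
}

#' Three-way candidate intersection (the Venn stage)
#'
#' Exact intersection of the differentially expressed genes with the
#' disease- and chemical-target lists, with parent provenance recorded.
#'
#' @param deg_symbols character vector of DEG symbols.
#' @param disease,chem [TargetSet-class] objects (or character vectors).
#' @return list of class `candidate_set` with `symbols` (sorted) and
#'   `provenance` (named parent sizes).
#' @export
intersectCandidates <- function(deg_symbols, disease, chem) {
  asSym <- function(x) if (is(x, "TargetSet")) symbols(x) else as.character(x)
  d <- asSym(disease); c2 <- asSym(chem); g <- as.character(deg_symbols)
  if (!length(g) || !length(d) || !length(c2))
    warning("empty parent set; candidate set is empty")
  out <- list(symbols = sort(intersect(intersect(g, d), c2)),
              provenance = c(degs = length(unique(g)),
                             disease = length(unique(d)),
                             chemical = length(unique(c2))))
  class(out) <- "candidate_set"
  out
}

#' @export
print.candidate_set <- function(x, ...) {
  cat("CandidateSet:", length(x$symbols), "symbols from parents",
      paste(names(x$provenance), x$provenance, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Compare candidate sets of two chemicals
#'
#' @param candA,candB `candidate_set` objects (or character vectors).
#' @return list with `shared`, `onlyA`, `onlyB` (sorted character vectors).
#' @export
drugCompare <- function(candA, candB) {
  a <- if (is.list(candA)) candA$symbols else as.character(candA)
  b <- if (is.list(candB)) candB$symbols else as.character(candB)
  list(shared = sort(intersect(a, b)),
       onlyA = sort(setdiff(a, b)),
       onlyB = sort(setdiff(b, a)))
}

# ---- readers / writers ------------------------------------------------------

#' Read / write the target-set CSV format
#'
#' CSV columns: `symbol,source,interaction_type,fit_score,species` (missing
#' columns tolerated on read).
#'
#' @param path CSV path.
#' @param name set label.
#' @return [TargetSet-class].
#' @export
readTargetCSV <- function(path, name = basename(path)) {
  targetSet(utils::read.csv(path, stringsAsFactors = FALSE), name = name)
}

#' @rdname readTargetCSV
#' @param x a [TargetSet-class] to write.
#' @export
writeTargetCSV <- function(x, path) {
  utils::write.csv(targetEntries(x), path, row.names = FALSE, quote = FALSE)
}

#' Venn-style summary of three gene lists as JSON
#'
#' @param deg_symbols,disease,chem the three parents (vectors or
#'   [TargetSet-class]).
#' @param path output JSON path.
#' @return the summary list, invisibly.
#' @export
writeVennSummary <- function(deg_symbols, disease, chem, path) {
  asSym <- function(x) if (is(x, "TargetSet")) symbols(x) else as.character(x)
  g <- unique(asSym(deg_symbols)); d <- unique(asSym(disease))
  c2 <- unique(asSym(chem))
  s <- list(sizes = list(degs = length(g), disease = length(d),
                         chemical = length(c2)),
            pairwise = list(degs_disease = length(intersect(g, d)),
                            degs_chemical = length(intersect(g, c2)),
                            disease_chemical = length(intersect(d, c2))),
            threeway = length(intersect(intersect(g, d), c2)))
  jsonlite::write_json(s, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(s)
}
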