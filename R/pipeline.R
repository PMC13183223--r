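# Orchestration: configuration, fixture generation, and the end-to-end run
# tying every stage together. Stages communicate through typed on-disk
# artifacts (TSV/CSV/JSON) so each is independently testable from files.

#' Pipeline configuration with field-standard defaults
#'
#' Defaults are the values conventional in this workflow: |log2FC| > 0.5
#' and p < 0.05 (unadjusted) for DEGs, top 20 percent of fit scores and
#' direct-interaction annotation for the context filter, 10,000
#' permutations for the overlap null, top-20 composite-centrality hubs,
#' 5-fold CV (5 x 5 nested, 100 repeats), 1,000 bootstrap iterations,
#' shadow-feature maxRuns 1000, and the six-threshold fold-change grid.
#'
#' @param paths named list of input files: `train`, `train_labels`,
#'   `valid`, `valid_labels`, `disease`, `chem` (character vector of one or
#'   more CSVs), `network`, optional `abundance`.
#' @param ... overrides for any nested setting, e.g.
#'   `thresholds = list(lfc = 0.25)`.
#' @param seed global seed fanned out to every stage.
#' @return nested list of class `pipeline_config`.
#' @export
pipelineConfig <- function(paths = list(), ..., seed = 1L) {
  cfg <- list(
    paths = paths,
    collapse = "mean",
    thresholds = list(lfc = 0.5, p = 0.05, use_adjusted = FALSE),
    filter = list(apply = FALSE, direct_only = TRUE, fit_top_frac = 0.2),
    overlap = list(B = 10000L, mode = "all"),
    centrality = list(top_k = 20L, score_min = 0.4),
    ml = list(n_folds = 5L, outer = 5L, inner = 5L, repeats = 100L,
              bootstrap_B = 1000L, max_runs = 1000L, alpha = 0.01,
              gbt_rounds = 50L, num_trees = 300L),
    grid = list(thresholds = c(0.25, 0.5, 0.75, 1, 1.25, 1.5)),
    seed = as.integer(seed))
  dots <- list(...)
  for (nm in names(dots)) {
    cfg[[nm]] <- if (is.list(dots[[nm]]) && is.list(cfg[[nm]]))
      utils::modifyList(cfg[[nm]], dots[[nm]]) else dots[[nm]]
  }
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Settings present in the file override the defaults of
#' [pipelineConfig()]; relative input paths are resolved against the YAML
#' file's directory.
#'
#' @param path YAML file.
#' @return `pipeline_config` list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipelineConfig(seed = if (!is.null(y$seed)) y$seed else 1L)
  for (nm in setdiff(names(y), "seed")) {
    cfg[[nm]] <- if (is.list(y[[nm]]) && is.list(cfg[[nm]]))
      utils::modifyList(cfg[[nm]], y[[nm]]) else y[[nm]]
  }
  base <- dirname(normalizePath(path))
  cfg$paths <- lapply(cfg$paths, function(p) {
    ifelse(file.exists(p), p, file.path(base, p))
  })
  cfg
}

.configHash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                           digits = NA)), tmp)
  unname(tools::md5sum(tmp))
}

#' Combine several target sets into one standardized set
#'
#' @param sets list of [TargetSet-class] objects.
#' @param name label for the merged set.
#' @return a [TargetSet-class] with duplicates merged (max fit score,
#'   union of annotations).
#' @export
combineTargetSets <- function(sets, name = "combined") {
  ent <- do.call(rbind, lapply(sets, targetEntries))
  standardizeTargets(ent, name = name)
}

#' Induce the subnetwork on a symbol set
#'
#' @param net an [InteractionNetwork-class].
#' @param symbols node symbols to keep.
#' @return the induced [InteractionNetwork-class] (isolated members kept
#'   as nodes).
#' @export
induceSubnetwork <- function(net, symbols) {
  e <- networkEdges(net)
  keep <- e$nodeA %in% symbols & e$nodeB %in% symbols
  interactionNetwork(e[keep, , drop = FALSE],
                     nodes = intersect(networkNodes(net), symbols),
                     score_min = net@score_min)
}

#' Run the full target-identification pipeline
#'
#' Executes differential expression, target standardization and
#' intersection, overlap statistics, network hub ranking, tri-algorithm
#' consensus selection with nested CV and bootstrap stability, two-cohort
#' validation, the fold-change sensitivity grid, and (when an abundance
#' table is supplied) compositional group tests. A stage failure is
#' recorded and its dependent stages are skipped with a reason; identical
#' (config, seed) gives an identical report apart from the timestamp.
#'
#' @param config a `pipeline_config` from [pipelineConfig()] or
#'   [readPipelineConfig()].
#' @param out_dir optional directory; when given, stage artifacts (TSV/JSON
#'   tables) are written there.
#' @return list of class `run_report` with one element per stage (each a
#'   result or a `skip` record) plus `provenance`.
#' @export
runPipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  report <- list()
  skipped <- function(reason) structure(list(skip = reason), class = "stage_skip")
  runStage <- function(name, deps, expr) {
    for (d in deps) {
      if (inherits(report[[d]], "stage_skip")) {
        report[[name]] <<- skipped(paste0("dependency '", d, "' unavailable"))
        return(invisible(NULL))
      }
    }
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e) skipped(conditionMessage(e)))
    message(sprintf("[nettox] stage %-12s %6.2fs%s", name,
                    as.numeric(difftime(Sys.time(), t0, units = "secs")),
                    if (inherits(res, "stage_skip"))
                      paste0("  SKIPPED: ", res$skip) else ""))
    report[[name]] <<- res
    invisible(NULL)
  }

  runStage("inputs", character(), {
    p <- config$paths
    for (req in c("train", "train_labels", "valid", "valid_labels",
                  "disease", "chem", "network"))
      if (is.null(p[[req]])) stop("missing input path: ", req)
    train <- readExpressionTSV(p$train, p$train_labels, config$collapse)
    valid <- readExpressionTSV(p$valid, p$valid_labels, config$collapse)
    if (!length(intersect(rownames(train), rownames(valid))))
      stop("cohorts share no gene symbols")
    chem_sets <- lapply(seq_along(p$chem), function(i)
      standardizeTargets(targetEntries(readTargetCSV(p$chem[[i]])),
                         name = paste0("chem", i)))
    list(train = train, valid = valid,
         disease = standardizeTargets(
           targetEntries(readTargetCSV(p$disease)), name = "disease"),
         chem_sets = chem_sets,
         chem = combineTargetSets(chem_sets, "chemical"),
         network = readEdgeList(p$network, config$centrality$score_min),
         abundance = if (!is.null(p$abundance))
           utils::read.delim(p$abundance, stringsAsFactors = FALSE)
         else NULL)
  })

  runStage("diffexpr", "inputs", {
    inp <- report$inputs
    deg <- fitModerated(inp$train, lfc_min = config$thresholds$lfc,
                        p_max = config$thresholds$p,
                        use_adjusted = config$thresholds$use_adjusted)
    sets <- thresholdDegs(deg, config$thresholds$lfc, config$thresholds$p,
                          config$thresholds$use_adjusted)
    list(table = deg, up = sets$up, down = sets$down,
         degs = c(sets$up, sets$down))
  })

  runStage("candidates", c("inputs", "diffexpr"), {
    inp <- report$inputs
    chem <- inp$chem
    if (isTRUE(config$filter$apply))
      chem <- contextFilter(chem, list(inp$train, inp$valid),
                            direct_only = config$filter$direct_only,
                            fit_top_frac = config$filter$fit_top_frac)
    cand <- intersectCandidates(report$diffexpr$degs, inp$disease, chem)
    if (!length(cand$symbols)) stop("empty candidate set")
    drug <- NULL
    if (length(inp$chem_sets) >= 2L) {
      per_drug <- lapply(inp$chem_sets, function(cs)
        intersectCandidates(report$diffexpr$degs, inp$disease, cs))
      drug <- drugCompare(per_drug[[1L]], per_drug[[2L]])
      drug$per_drug_sizes <- vapply(per_drug,
                                    function(x) length(x$symbols), integer(1L))
    }
    list(candidates = cand, chem_used = chem, drug = drug)
  })

  runStage("overlap", c("inputs", "diffexpr", "candidates"), {
    inp <- report$inputs
    background <- rownames(inp$train)
    inBg <- function(s) intersect(s, background)
    permuteOverlap(inBg(symbols(report$candidates$chem_used)),
                   inBg(symbols(inp$disease)),
                   inBg(report$diffexpr$degs),
                   background, B = config$overlap$B, seed = seed,
                   mode = config$overlap$mode)
  })

  runStage("netrank", c("inputs", "candidates"), {
    sub <- induceSubnetwork(report$inputs$network,
                            report$candidates$candidates$symbols)
    tab <- centralities(sub)
    ranked <- compositeRank(tab, config$centrality$top_k)
    list(table = tab, ranked = ranked, hubs = ranked$symbol)
  })

  runStage("consensus", c("inputs", "candidates"), {
    fm <- featureMatrix(report$inputs$train,
                        report$candidates$candidates$symbols)
    ml <- config$ml
    sel <- list(
      lasso = lassoSelect(fm$X, fm$y, ml$n_folds, seed),
      gbt = gbtSelect(fm$X, fm$y, ml$gbt_rounds, seed = seed),
      shadow = shadowSelect(fm$X, fm$y, ml$max_runs, ml$alpha, seed,
                            ml$num_trees))
    list(selections = sel,
         consensus = consensusIntersect(sel),
         cv = nestedCv(fm$X, fm$y, ml$outer, ml$inner, ml$repeats, seed),
         stability = bootstrapStability(fm$X, fm$y, ml$bootstrap_B, seed,
                                        ml$n_folds))
  })

  runStage("validation", c("inputs", "consensus"), {
    genes <- report$consensus$consensus
    if (!length(genes)) stop("empty consensus set")
    validateCore(genes, report$inputs$train, report$inputs$valid,
                 p_max = config$thresholds$p)
  })

  runStage("grid", c("inputs", "diffexpr", "candidates"), {
    tracked <- if (!inherits(report$validation, "stage_skip"))
      report$validation$symbol[report$validation$is_core] else character()
    sensitivityGrid(report$inputs$train, report$inputs$disease,
                    report$candidates$chem_used,
                    thresholds = config$grid$thresholds,
                    tracked = tracked, p_max = config$thresholds$p,
                    deg = report$diffexpr$table)
  })

  runStage("abundance", "inputs", {
    ab <- report$inputs$abundance
    if (is.null(ab)) stop("no abundance table supplied")
    m <- as.matrix(ab[, setdiff(colnames(ab), c("sample", "group"))])
    rownames(m) <- ab$sample
    abundanceGroupTest(m, ab$group)
  })

  report$provenance <- list(config_hash = .configHash(config), seed = seed,
                            package_version = as.character(
                              utils::packageVersion("nettox")),
                            timestamp = format(Sys.time(), tz = "UTC"))
  class(report) <- "run_report"
  if (!is.null(out_dir)) writeRunReport(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("nettox run report (seed", x$provenance$seed, ")\n")
  for (nm in setdiff(names(x), "provenance")) {
    if (inherits(x[[nm]], "stage_skip"))
      cat(sprintf("  %-12s SKIPPED: %s\n", nm, x[[nm]]$skip))
    else cat(sprintf("  %-12s ok\n", nm))
  }
  invisible(x)
}

#' Write the stage artifacts of a run report to a directory
#'
#' @param report a `run_report`.
#' @param out_dir output directory (created if needed).
#' @export
writeRunReport <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ok <- function(nm) !is.null(report[[nm]]) &&
    !inherits(report[[nm]], "stage_skip")
  if (ok("diffexpr"))
    writeDegTable(report$diffexpr$table, file.path(out_dir, "deg_table.tsv"))
  if (ok("candidates"))
    jsonlite::write_json(report$candidates$candidates[c("symbols",
                                                        "provenance")],
                         file.path(out_dir, "candidates.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  if (ok("overlap"))
    writeOverlapJSON(report$overlap, file.path(out_dir, "overlap.json"))
  if (ok("netrank"))
    writeRankTable(report$netrank$ranked, file.path(out_dir, "hub_rank.tsv"))
  if (ok("consensus")) {
    writeStabilityTSV(report$consensus$stability,
                      file.path(out_dir, "stability.tsv"))
    jsonlite::write_json(
      list(consensus = report$consensus$consensus,
           per_algorithm = lapply(report$consensus$selections,
                                  function(s) s$selected),
           cv_means = as.list(report$consensus$cv$means),
           cv_ci = as.data.frame(report$consensus$cv$ci)),
      file.path(out_dir, "consensus.json"), auto_unbox = TRUE, pretty = TRUE,
      digits = NA)
  }
  if (ok("validation"))
    utils::write.table(report$validation,
                       file.path(out_dir, "validation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  if (ok("grid"))
    writeGridTSV(report$grid, file.path(out_dir, "sensitivity_grid.tsv"))
  if (ok("abundance"))
    utils::write.table(report$abundance,
                       file.path(out_dir, "abundance_tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' Write a complete synthetic input bundle
#'
#' `tiny` is sized to run the whole pipeline in well under a minute;
#' `paper_mimic` matches the cohort sizes (9 case / 8 control training,
#' 6 / 6 validation) and the order of magnitude of the curated list sizes
#' (about 1,600 disease and 1,000 chemical targets) typical of published
#' triages of this kind. Two calls with the same seed produce
#' byte-identical bundles.
#'
#' @param dir output directory (created).
#' @param scale `"tiny"` or `"paper_mimic"`.
#' @param seed integer seed.
#' @return invisibly, a list with the written `paths`, the generator
#'   `truth`, and a matching `config` ready for [runPipeline()].
#' @export
makeFixture <- function(dir, scale = c("tiny", "paper_mimic"), seed = 1L) {
  scale <- match.arg(scale)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- if (scale == "tiny") {
    synConfig(n_genes = 300L, n_train_case = 6L, n_train_ctrl = 6L,
              n_valid_case = 5L, n_valid_ctrl = 5L, frac_de = 0.1,
              effect_range = c(1.5, 2.5), db_coverage = 0.9,
              db_noise = 30L, n_hubs = 3L, n_abn_case = 6L, n_abn_ctrl = 6L,
              shift_effect = 3, seed = seed)
  } else {
    # moderate-signal regime: per-gene residual SD ~ 0.35 log2 units and
    # effects of 0.6-1.6, so candidate counts, per-algorithm selection
    # sizes and list magnitudes land near those of published triages
    synConfig(n_genes = 6000L, frac_de = 0.01, effect_range = c(0.6, 1.6),
              var_prior_df = 4, var_prior_scale = 0.12,
              db_coverage = 0.85, n_hubs = 5L,
              shift_effect = 3, seed = seed)
  }
  syn <- simCohorts(cfg)
  universe <- rownames(syn$train)
  noise <- if (scale == "paper_mimic")
    c(disease = 1550L, chemA = 480L, chemB = 480L) else NULL
  dbs <- simTargetDBs(syn$truth, universe, cfg, noise = noise)
  # the interaction network mimics a candidate-scale PPI retrieval: planted
  # targets plus a few-fold decoy pool, so the induced candidate subgraph
  # keeps the planted hub wiring (a genome-wide graph would dilute it)
  db_pool <- setdiff(unique(c(symbols(dbs$disease), symbols(dbs$chemA),
                              symbols(dbs$chemB))), syn$truth$target_genes)
  net_universe <- withr::with_seed(
    substreamSeed(seed, "net_universe"),
    c(syn$truth$target_genes,
      sample(db_pool, min(length(db_pool),
                          3L * max(1L, length(syn$truth$target_genes))))))
  net <- simNetwork(syn$truth, net_universe, cfg)
  ab <- simAbundance(cfg)

  fp <- function(f) file.path(dir, f)
  writeCohortTSV <- function(co, f, fl) {
    m <- exprsMat(co)
    utils::write.table(data.frame(symbol = rownames(m), m,
                                  check.names = FALSE),
                       fp(f), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample = colnames(m),
                                  group = sampleGroups(co)),
                       fp(fl), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  writeCohortTSV(syn$train, "train.tsv", "train_labels.tsv")
  writeCohortTSV(syn$valid, "valid.tsv", "valid_labels.tsv")
  writeTargetCSV(dbs$disease, fp("disease.csv"))
  writeTargetCSV(dbs$chemA, fp("chemA.csv"))
  writeTargetCSV(dbs$chemB, fp("chemB.csv"))
  writeEdgeList(net, fp("network.tsv"))
  utils::write.table(data.frame(sample = rownames(ab$abundance),
                                group = ab$groups, ab$abundance,
                                check.names = FALSE),
                     fp("abundance.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(syn$truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  paths <- list(train = fp("train.tsv"), train_labels = fp("train_labels.tsv"),
                valid = fp("valid.tsv"), valid_labels = fp("valid_labels.tsv"),
                disease = fp("disease.csv"),
                chem = c(fp("chemA.csv"), fp("chemB.csv")),
                network = fp("network.tsv"), abundance = fp("abundance.tsv"))
  pcfg <- pipelineConfig(paths = paths, seed = seed)
  if (scale == "tiny")
    pcfg <- pipelineConfig(paths = paths, seed = seed,
                           overlap = list(B = 1000L),
                           ml = list(repeats = 5L, bootstrap_B = 50L,
                                     max_runs = 60L, num_trees = 150L))
  invisible(list(paths = paths, truth = syn$truth, config = pcfg,
                 syn_config = cfg))
}
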