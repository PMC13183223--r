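# Synthetic cohorts with planted, recoverable structure. All generators are
# seeded through named substreams so adding one generator never shifts the
# random stream of another.

#' Synthetic-study configuration
#'
#' Bundles every tunable of the synthetic-data generators with validated
#' defaults. The default cohort sizes (9 case / 8 control training, 6 / 6
#' validation) mimic the small peripheral-blood microarray cohorts typical of
#' this literature; intensities are Gaussian on the log2 scale as on arrays,
#' and per-gene variances are drawn from a scaled inverse-chi-square so the
#' empirical-Bayes variance prior of the moderated-t stage is exactly
#' recoverable.
#'
#' @param n_genes number of genes in the universe.
#' @param n_train_case,n_train_ctrl training-cohort group sizes.
#' @param n_valid_case,n_valid_ctrl validation-cohort group sizes.
#' @param frac_de fraction of genes planted as differential, in (0, 1)
#'   (0 allowed as the explicit no-signal case).
#' @param effect_range length-2 numeric, low/high |log2 fold change| of
#'   planted effects.
#' @param baseline_mean,baseline_sd mean and SD of per-gene baseline log2
#'   intensity.
#' @param var_prior_df,var_prior_scale degrees of freedom and scale of the
#'   scaled inverse-chi-square draw of per-gene variances.
#' @param db_coverage probability that each planted target enters each
#'   target database.
#' @param db_noise number of random non-planted decoy genes per database.
#' @param n_hubs number of planted network hubs (taken from the planted
#'   targets).
#' @param net_n_edges_per_node preferential-attachment edges per added node.
#' @param n_components,n_abn_case,n_abn_ctrl abundance-table shape:
#'   components (default 22, as in standard immune deconvolution panels) and
#'   per-group sample counts.
#' @param abn_concentration base Dirichlet concentration per component.
#' @param shift_component,shift_effect name of the abundance component whose
#'   concentration is multiplied by `shift_effect` in cases (1 = null).
#' @param seed integer seed.
#' @return A validated list of class `syn_config`.
#' @export
synConfig <- function(n_genes = 2000L,
                      n_train_case = 9L, n_train_ctrl = 8L,
                      n_valid_case = 6L, n_valid_ctrl = 6L,
                      frac_de = 0.05,
                      effect_range = c(1.0, 2.0),
                      baseline_mean = 7, baseline_sd = 1.5,
                      var_prior_df = 4, var_prior_scale = 0.05,
                      db_coverage = 0.8, db_noise = 150L,
                      n_hubs = 5L, net_n_edges_per_node = 3L,
                      n_components = 22L, n_abn_case = 9L, n_abn_ctrl = 8L,
                      abn_concentration = 2,
                      shift_component = "Neutrophils", shift_effect = 1,
                      seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_train_case = as.integer(n_train_case),
              n_train_ctrl = as.integer(n_train_ctrl),
              n_valid_case = as.integer(n_valid_case),
              n_valid_ctrl = as.integer(n_valid_ctrl),
              frac_de = frac_de, effect_range = effect_range,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              var_prior_df = var_prior_df, var_prior_scale = var_prior_scale,
              db_coverage = db_coverage, db_noise = as.integer(db_noise),
              n_hubs = as.integer(n_hubs),
              net_n_edges_per_node = as.integer(net_n_edges_per_node),
              n_components = as.integer(n_components),
              n_abn_case = as.integer(n_abn_case),
              n_abn_ctrl = as.integer(n_abn_ctrl),
              abn_concentration = abn_concentration,
              shift_component = shift_component,
              shift_effect = shift_effect,
              seed = as.integer(seed))
  ns <- unlist(cfg[c("n_train_case", "n_train_ctrl",
                     "n_valid_case", "n_valid_ctrl")])
  if (cfg$n_genes < 1L) stop("n_genes must be positive")
  if (any(ns < 2L)) stop("all group sizes must be >= 2")
  if (cfg$frac_de < 0 || cfg$frac_de >= 1)
    stop("frac_de must lie in [0, 1)")
  if (cfg$frac_de > 0 && cfg$frac_de * cfg$n_genes < 1)
    stop("frac_de * n_genes must be >= 1 when frac_de > 0")
  if (length(cfg$effect_range) != 2L || any(cfg$effect_range <= 0) ||
      diff(cfg$effect_range) < 0)
    stop("effect_range must be an increasing pair of positive values")
  if (cfg$var_prior_df <= 0 || cfg$var_prior_scale <= 0)
    stop("variance prior parameters must be positive")
  if (cfg$db_coverage < 0 || cfg$db_coverage > 1)
    stop("db_coverage must be a probability")
  if (cfg$abn_concentration <= 0) stop("abn_concentration must be positive")
  class(cfg) <- "syn_config"
  cfg
}

# Derive a deterministic per-generator seed below 2^31 from (seed, name).
substreamSeed <- function(seed, name) {
  v <- utf8ToInt(name)
  h <- sum(v * seq_along(v)) %% 19997L
  (abs(as.integer(seed)) %% 100000L) * 20011L + h
}

#' Simulate two case/control cohorts with planted differential genes
#'
#' Draws per-gene baseline means from Normal(`baseline_mean`,
#' `baseline_sd`^2) and per-gene variances from a scaled inverse-chi-square
#' with (`var_prior_df`, `var_prior_scale`). A fraction `frac_de` of genes
#' receives a signed log2 effect, uniform in magnitude over `effect_range`,
#' added to case samples. The validation cohort redraws baselines, variances
#' and noise but keeps the same planted genes with the same signed effects —
#' the structure a two-cohort consistency validation relies on.
#'
#' @param config a [synConfig()] list.
#' @return list with elements `train` and `valid`
#'   ([CohortExperiment-class]) and `truth`, a list recording
#'   `de_genes` (data.frame symbol/effect), `target_genes`, `hub_genes`,
#'   and `composition_shift`.
#' @export
simCohorts <- function(config) {
  stopifnot(inherits(config, "syn_config"))
  genes <- sprintf("G%05d", seq_len(config$n_genes))
  n_de <- as.integer(round(config$frac_de * config$n_genes))
  withr::with_seed(substreamSeed(config$seed, "cohorts"), {
    de_idx <- if (n_de > 0) sort(sample.int(config$n_genes, n_de)) else integer()
    eff <- numeric(0)
    if (n_de > 0) {
      eff <- runif(n_de, config$effect_range[1], config$effect_range[2]) *
        sample(c(-1, 1), n_de, replace = TRUE)
    }
    effects <- setNames(numeric(config$n_genes), genes)
    effects[de_idx] <- eff

    drawCohort <- function(n_case, n_ctrl, tag) {
      mu <- rnorm(config$n_genes, config$baseline_mean, config$baseline_sd)
      s2 <- config$var_prior_df * config$var_prior_scale /
        rchisq(config$n_genes, config$var_prior_df)
      n <- n_case + n_ctrl
      noise <- matrix(rnorm(config$n_genes * n), config$n_genes, n) * sqrt(s2)
      m <- mu + noise
      m[, seq_len(n_case)] <- m[, seq_len(n_case)] + effects
      dimnames(m) <- list(genes, sprintf("%s%02d", tag, seq_len(n)))
      cohortExperiment(m, rep(c("case", "control"), c(n_case, n_ctrl)))
    }
    train <- drawCohort(config$n_train_case, config$n_train_ctrl, "TR")
    valid <- drawCohort(config$n_valid_case, config$n_valid_ctrl, "VA")

    de_genes <- data.frame(symbol = genes[de_idx], effect = eff,
                           stringsAsFactors = FALSE)
    hub_genes <- if (n_de >= config$n_hubs) de_genes$symbol[seq_len(config$n_hubs)]
                 else de_genes$symbol
    truth <- list(de_genes = de_genes,
                  target_genes = de_genes$symbol,
                  hub_genes = hub_genes,
                  composition_shift = list(component = config$shift_component,
                                           effect = config$shift_effect))
    list(train = train, valid = valid, truth = truth)
  })
}

.simOneDb <- function(truth_genes, universe, coverage, noise, name, chem) {
  planted <- truth_genes[runif(length(truth_genes)) < coverage]
  decoys <- setdiff(universe, truth_genes)
  if (noise > length(decoys))
    stop("db_noise exceeds the number of available decoy genes")
  picked <- c(planted, sample(decoys, noise))
  is_planted <- picked %in% truth_genes
  if (chem) {
    src <- sample(c("ctd", "pharmmapper"), length(picked), replace = TRUE)
    itype <- ifelse(runif(length(picked)) < ifelse(is_planted, 0.85, 0.30),
                    "direct", "indirect")
    itype[src != "ctd"] <- NA_character_
    fit <- rnorm(length(picked), mean = ifelse(is_planted, 6, 4), sd = 1)
    fit[src != "pharmmapper"] <- NA_real_
    df <- data.frame(symbol = picked, source = src, interaction_type = itype,
                     fit_score = fit, stringsAsFactors = FALSE)
  } else {
    df <- data.frame(symbol = picked, source = "disease_db",
                     stringsAsFactors = FALSE)
  }
  targetSet(df, name = name)
}

#' Simulate disease and chemical target databases
#'
#' Each planted target enters each database independently with probability
#' `db_coverage`; `db_noise` random decoys are added per database. Chemical
#' entries carry database-style attributes: a source label (`ctd` or
#' `pharmmapper`), an interaction-type annotation biased toward `direct`
#' for planted genes, and a pharmacophore fit score biased higher for
#' planted genes.
#'
#' @param truth planted-truth list from [simCohorts()].
#' @param universe character vector, the full gene universe.
#' @param config a [synConfig()] list.
#' @param noise optional named vector overriding `db_noise` per database
#'   (names `disease`, `chemA`, `chemB`), e.g. to mimic published list
#'   sizes.
#' @return list of three [TargetSet-class] objects: `disease`, `chemA`,
#'   `chemB`.
#' @export
simTargetDBs <- function(truth, universe, config, noise = NULL) {
  stopifnot(all(truth$target_genes %in% universe))
  nz <- c(disease = config$db_noise, chemA = config$db_noise,
          chemB = config$db_noise)
  if (!is.null(noise)) nz[names(noise)] <- noise
  withr::with_seed(substreamSeed(config$seed, "target_dbs"), {
    list(disease = .simOneDb(truth$target_genes, universe, config$db_coverage,
                             nz[["disease"]], "disease", chem = FALSE),
         chemA = .simOneDb(truth$target_genes, universe, config$db_coverage,
                           nz[["chemA"]], "chemA", chem = TRUE),
         chemB = .simOneDb(truth$target_genes, universe, config$db_coverage,
                           nz[["chemB"]], "chemB", chem = TRUE))
  })
}

#' Simulate a scale-free-ish interaction network with planted hubs
#'
#' Grows an undirected simple graph by preferential attachment
#' (`net_n_edges_per_node` edges per added node), then wires each planted hub
#' with extra random edges until its degree is at least three times the
#' median degree. Edge confidence scores are uniform in (0.4, 1], so the
#' default score threshold retains all of them.
#'
#' @param truth planted-truth list (uses `hub_genes`).
#' @param universe character vector of node symbols (hubs must be included).
#' @param config a [synConfig()] list.
#' @return An [InteractionNetwork-class].
#' @export
simNetwork <- function(truth, universe, config) {
  hubs <- intersect(truth$hub_genes, universe)
  if (length(universe) < length(hubs) || length(universe) < 2L)
    stop("universe must contain the hubs and at least two nodes")
  withr::with_seed(substreamSeed(config$seed, "network"), {
    n <- length(universe)
    # put hubs at the front: early preferential-attachment nodes attract edges
    ord <- c(match(hubs, universe), setdiff(seq_len(n), match(hubs, universe)))
    nodes <- universe[ord]
    g <- igraph::sample_pa(n, m = config$net_n_edges_per_node, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    a <- nodes[el[, 1]]; b <- nodes[el[, 2]]
    keep <- a != b
    a <- a[keep]; b <- b[keep]
    deg <- table(factor(c(a, b), levels = nodes))
    target_deg <- max(3L, ceiling(3 * stats::median(deg)))
    for (h in hubs) {
      need <- target_deg - deg[[h]]
      if (need > 0) {
        nbr <- unique(c(b[a == h], a[b == h]))
        cand <- setdiff(nodes, c(h, nbr))
        extra <- sample(cand, min(need, length(cand)))
        a <- c(a, rep(h, length(extra))); b <- c(b, extra)
        deg <- table(factor(c(a, b), levels = nodes))
      }
    }
    edges <- data.frame(nodeA = a, nodeB = b,
                        score = runif(length(a), 0.4 + 1e-9, 1),
                        stringsAsFactors = FALSE)
    interactionNetwork(edges, nodes = nodes, score_min = 0.4)
  })
}

#' Simulate a compositional abundance table
#'
#' Per-sample compositions are Dirichlet draws over `n_components`
#' components (default 22, the size of the standard immune-cell panel); in
#' case samples the concentration of `shift_component` is multiplied by
#' `shift_effect` (1 = shared null). Rows sum to one.
#'
#' @param config a [synConfig()] list.
#' @return list with `abundance` (samples x components matrix, rows on the
#'   simplex) and `groups` (per-sample labels).
#' @export
simAbundance <- function(config) {
  stopifnot(inherits(config, "syn_config"))
  k <- config$n_components
  if (k < 2L) stop("need at least 2 components")
  if (config$n_abn_case < 3L || config$n_abn_ctrl < 3L)
    stop("need >= 3 samples per group")
  if (config$shift_effect <= 0) stop("shift_effect must be positive")
  comp <- c("Neutrophils", "NK.cells.activated",
            sprintf("Cell.type.%02d", seq_len(max(0, k - 2L))))[seq_len(k)]
  if (!config$shift_component %in% comp)
    stop("shift_component not among component names")
  withr::with_seed(substreamSeed(config$seed, "abundance"), {
    alpha_ctrl <- rep(config$abn_concentration, k)
    alpha_case <- alpha_ctrl
    alpha_case[match(config$shift_component, comp)] <-
      config$abn_concentration * config$shift_effect
    drawGroup <- function(n, alpha) {
      g <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), n, k)
      g / rowSums(g)
    }
    m <- rbind(drawGroup(config$n_abn_case, alpha_case),
               drawGroup(config$n_abn_ctrl, alpha_ctrl))
    dimnames(m) <- list(sprintf("AB%02d", seq_len(nrow(m))), comp)
    list(abundance = m,
         groups = rep(c("case", "control"),
                      c(config$n_abn_case, config$n_abn_ctrl)))
  })
}

#' Synthetic stand-in for published supplementary target lists
#'
#' Builds three gene lists at the cardinalities reported for a published
#' anesthetic/diabetes triage (1,040 chemical targets, 1,617 disease
#' targets, 3,491 differentially expressed genes) whose exact three-way
#' intersection has 43 members including MMP9 and HPSE. This is a
#' *synthetic* construction — the real supplementary tables are not
#' redistributable here — built so that set arithmetic can be exercised at
#' realistic scale against a known answer.
#'
#' @param seed integer seed.
#' @return list of character vectors `chem` (1,040), `disease` (1,617),
#'   `degs` (3,491), and `core43`, the engineered 43-member intersection.
#' @export
supplementMimic <- function(seed = 1L) {
  withr::with_seed(substreamSeed(seed, "supplement_mimic"), {
    universe <- sprintf("GENE%05d", seq_len(20000L))
    core <- c("MMP9", "HPSE", sample(universe, 41))
    pool <- setdiff(universe, core)
    # pairwise-only and private members, sized to hit the printed totals
    takeFrom <- function(pool, n) {
      picked <- sample(pool, n)
      list(picked = picked, pool = setdiff(pool, picked))
    }
    x <- takeFrom(pool, 300);  cd <- x$picked; pool <- x$pool  # chem & disease
    x <- takeFrom(pool, 200);  cg <- x$picked; pool <- x$pool  # chem & degs
    x <- takeFrom(pool, 400);  dg <- x$picked; pool <- x$pool  # disease & degs
    x <- takeFrom(pool, 1040L - 43L - 300L - 200L); chem_only <- x$picked
    pool <- x$pool
    x <- takeFrom(pool, 1617L - 43L - 300L - 400L); dis_only <- x$picked
    pool <- x$pool
    x <- takeFrom(pool, 3491L - 43L - 200L - 400L); deg_only <- x$picked
    list(chem = sample(c(core, cd, cg, chem_only)),
         disease = sample(c(core, cd, dg, dis_only)),
         degs = sample(c(core, cg, dg, deg_only)),
         core43 = core)
  })
}
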