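#' Pipeline configuration
#'
#' Collects every tunable of the full inference pipeline with the reference
#' defaults: 10 cross-validation portions, a 5\% gene-wise screen, 10
#' partners per anchor, an ensemble vote keeping the top 10\% per method
#' with at least 3 of 5 votes, a 1.5 fold-change criterion, hub connectivity
#' above 5, and 20 label permutations for model evaluation.
#'
#' @param k_folds cross-validation portions (>= 2).
#' @param theta_frac gene-wise screen fraction in (0, 1].
#' @param top_partners partners kept per anchor.
#' @param top_frac per-method ensemble selection fraction in (0, 1].
#' @param min_votes ensemble vote threshold in 1..5.
#' @param fc_threshold fold-change criterion.
#' @param hub_connectivity minimal hub degree.
#' @param permutation_M label permutations for the evaluation stage.
#' @param classifier a \linkS4class{ClassifierSpec}.
#' @param seed root seed; per-stage seeds are derived from it.
#' @param run_permutation toggle the permutation-test stage.
#' @return validated configuration list (class \code{RunConfig}).
#' @export
runConfig <- function(k_folds = 10L, theta_frac = 0.05, top_partners = 10L,
                      top_frac = 0.1, min_votes = 3L, fc_threshold = 1.5,
                      hub_connectivity = 6L, permutation_M = 20L,
                      classifier = classifierSpec(), seed = 1L,
                      run_permutation = TRUE) {
  cfg <- list(k_folds = as.integer(k_folds), theta_frac = theta_frac,
              top_partners = as.integer(top_partners), top_frac = top_frac,
              min_votes = as.integer(min_votes),
              fc_threshold = fc_threshold,
              hub_connectivity = as.integer(hub_connectivity),
              permutation_M = as.integer(permutation_M),
              classifier = classifier, seed = as.integer(seed),
              run_permutation = isTRUE(run_permutation))
  if (cfg$k_folds < 2L) stop("k_folds must be >= 2")
  if (cfg$theta_frac <= 0 || cfg$theta_frac > 1)
    stop("theta_frac must lie in (0, 1]")
  if (cfg$top_frac <= 0 || cfg$top_frac > 1)
    stop("top_frac must lie in (0, 1]")
  if (cfg$min_votes < 1L || cfg$min_votes > 5L)
    stop("min_votes must lie in 1..5")
  if (cfg$top_partners < 1L) stop("top_partners must be >= 1")
  if (cfg$fc_threshold <= 0) stop("fc_threshold must be positive")
  validObject(cfg$classifier)
  structure(cfg, class = "RunConfig")
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the \code{\link{runConfig}} arguments, plus a
#' \code{classifier} block with \code{family}, \code{cost}, \code{gamma},
#' \code{scale}, \code{seed}.
#'
#' @param path YAML file.
#' @return a \code{RunConfig}.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  cl <- y$classifier %||% list()
  spec <- classifierSpec(
    family = cl$family %||% "svm_rbf",
    cost = cl$cost %||% 1,
    gamma = cl$gamma %||% "reciprocal_of_feature_count",
    scale = cl$scale %||% TRUE,
    seed = cl$seed %||% 1L)
  y$classifier <- NULL
  args <- y[intersect(names(y), names(formals(runConfig)))]
  do.call(runConfig, c(args, list(classifier = spec)))
}

# Deterministic per-stage seed derived from the root seed and stage name;
# kept below 2^31.
stageSeed <- function(root, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(root) * 1009 + h) %% .Machine$integer.max)
}

#' Hash of a pipeline configuration
#'
#' @param cfg a \code{RunConfig}.
#' @return character hash; changes iff any configuration field changes.
#' @export
configHash <- function(cfg) {
  flat <- cfg
  flat$classifier <- list(family = cfg$classifier@family,
                          cost = cfg$classifier@cost,
                          gamma = cfg$classifier@gamma,
                          scale = cfg$classifier@scale,
                          seed = cfg$classifier@seed)
  rlang::hash(flat)
}

#' Run the full inference pipeline
#'
#' Normalizes the dataset if needed, builds stratified folds, then executes
#' the three inference stages (gene-wise screen, partner search, ensemble
#' vote), gene classification, optionally the interaction-path expansion
#' and mutation landscape (when a PPI network is given), gene-set
#' enrichment (when gene sets are given) and the permutation evaluation.
#' Re-running with an identical configuration and seed reproduces every
#' output bit-for-bit.
#'
#' @param ds a \linkS4class{MalaniDataSet}.
#' @param config a \code{\link{runConfig}}.
#' @param ppi optional \pkg{igraph} interaction network.
#' @param mutations optional \linkS4class{MutationTable}.
#' @param gene_sets optional \linkS4class{GeneSetCollection}.
#' @param out_dir optional directory; when given, score tables, networks
#'   (edge TSV + GraphML) and the manifest are written there.
#' @param verbose progress messages.
#' @return list with elements \code{theta}, \code{pairs}, \code{stage3}
#'   (including the inferred network \code{$min}), \code{de},
#'   \code{classes}, \code{hubs}, \code{piemin}, \code{landscape},
#'   \code{enrichment}, \code{pvalues}, \code{permutation} and
#'   \code{manifest}.
#' @export
runPipeline <- function(ds, config = runConfig(), ppi = NULL,
                        mutations = NULL, gene_sets = NULL, out_dir = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(config, "RunConfig"))
  t0 <- proc.time()[["elapsed"]]
  timings <- c()
  tick <- function(stage) {
    t1 <- proc.time()[["elapsed"]]
    timings[[stage]] <<- round(t1 - t0, 3)
    t0 <<- t1
    if (verbose) message(sprintf("[%s] done (%.1fs)", stage,
                                 timings[[stage]]))
  }
  if (!isNormalized(ds)) ds <- normalizePerSample(ds)
  spec <- config$classifier
  folds <- stratifiedFolds(sampleClasses(ds), k = config$k_folds,
                           seed = stageSeed(config$seed, "folds"))
  tick("normalize_folds")
  theta <- selectTheta(ds, folds, spec, frac = config$theta_frac,
                       verbose = verbose)
  tick("stage1")
  pairs <- topPartners(ds, theta, folds, spec, n = config$top_partners,
                       verbose = verbose)
  tick("stage2")
  s3 <- stage3Ensemble(ds, pairs, folds, spec,
                       min_votes = config$min_votes,
                       top_frac = config$top_frac)
  tick("stage3")
  de <- foldChangeStatus(ds, threshold = config$fc_threshold)
  classes <- classifyGenes(s3$min, de,
                           muts = mutations %||% MutationTable())
  hubs <- findHubs(s3$min, config$hub_connectivity)
  pvalues <- perGenePvalues(ds)
  tick("classify")
  piemin <- NULL; landscape <- NULL
  if (!is.null(ppi)) {
    piemin <- buildPieMin(s3$min, ppi)
    landscape <- mutationLandscape(piemin, mutations %||% MutationTable(),
                                   ppi, classes = classes, pvals = pvalues)
    tick("piemin")
  }
  enrichment <- NULL
  if (!is.null(gene_sets) && igraph::vcount(s3$min) > 0L) {
    enrichment <- hypergeomEnrich(igraph::V(s3$min)$name, gene_sets,
                                  mode = "min")
    tick("enrich")
  }
  permutation <- NULL
  if (config$run_permutation && nrow(pairTable(pairs)) > 0L) {
    stat <- finalModelStatistic(ds, pairs, folds, spec,
                                min_votes = config$min_votes,
                                top_frac = config$top_frac)
    permutation <- permutationTest(stat,
                                   as.character(sampleClasses(ds)),
                                   M = config$permutation_M,
                                   seed = stageSeed(config$seed,
                                                    "permutation"))
    tick("permutation")
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("malani")),
    config = config[setdiff(names(config), "classifier")],
    classifier = list(family = spec@family, cost = spec@cost,
                      gamma = spec@gamma, scale = spec@scale),
    config_hash = configHash(config),
    seeds = list(root = config$seed,
                 folds = stageSeed(config$seed, "folds"),
                 permutation = stageSeed(config$seed, "permutation")),
    n_genes = nrow(ds), n_samples = ncol(ds),
    theta_size = length(thetaGenes(theta)),
    n_pairs = nrow(pairTable(pairs)),
    n_min_edges = igraph::ecount(s3$min),
    n_hubs = length(hubs),
    timings = as.list(timings))
  result <- list(dataset = ds, folds = folds, theta = theta, pairs = pairs,
                 stage3 = s3, de = de, classes = classes, hubs = hubs,
                 piemin = piemin, landscape = landscape,
                 enrichment = enrichment, pvalues = pvalues,
                 permutation = permutation, manifest = manifest)
  if (!is.null(out_dir)) writePipelineOutputs(result, out_dir)
  result
}

#' Write the tabular and graph outputs of a pipeline run
#'
#' @param result the \code{\link{runPipeline}} return value.
#' @param out_dir output directory (created if absent).
#' @return the directory, invisibly.
#' @export
writePipelineOutputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write.table(geneScores(result$theta), fp("stage1_gene_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(pairScores(result$pairs), fp("stage2_pair_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  votes_tab <- cbind(result$stage3$Q@pairs,
                     as.data.frame(lapply(result$stage3$scores,
                                          `[[`, "score")),
                     votes = result$stage3$vote@votes)
  write.table(votes_tab, fp("stage3_votes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  writeEdgeTSV(result$stage3$min, fp("min_edges.tsv"))
  writeGraphML(result$stage3$min, fp("min.graphml"))
  cls <- result$classes
  cls$pvalue <- result$pvalues[cls$gene]
  write.table(cls, fp("gene_classes.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(result$piemin)) {
    writeEdgeTSV(pieminGraph(result$piemin), fp("piemin_edges.tsv"))
    writeGraphML(pieminGraph(result$piemin), fp("piemin.graphml"))
    freq <- nodeFrequency(result$piemin)
    write.table(data.frame(gene = names(freq), frequency = freq),
                fp("piemin_node_frequency.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(pathRecords(result$piemin), fp("piemin_paths.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(result$enrichment))
    write.table(result$enrichment, fp("enrichment.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  manifest <- result$manifest
  if (!is.null(result$permutation))
    manifest$permutation <- list(
      observed = result$permutation@observedStat,
      alpha = result$permutation@alpha,
      ci = c(result$permutation@ciLow, result$permutation@ciHigh))
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(out_dir)
}

#' Recovery of planted pairs by an inferred network
#'
#' Convenience for simulation studies: recall and precision of an inferred
#' network's edge set against a table of true pairs (unordered comparison).
#'
#' @param min_net \pkg{igraph} inferred network.
#' @param true_pairs data.frame with columns \code{gene_a}, \code{gene_b}.
#' @return list with \code{recall}, \code{precision}, \code{n_edges},
#'   \code{recovered} (logical per true pair).
#' @export
pairRecovery <- function(min_net, true_pairs) {
  el <- igraph::as_edgelist(min_net)
  edge_key <- if (nrow(el)) paste(pmin(el[, 1], el[, 2]),
                                  pmax(el[, 1], el[, 2])) else character(0)
  true_key <- paste(pmin(true_pairs$gene_a, true_pairs$gene_b),
                    pmax(true_pairs$gene_a, true_pairs$gene_b))
  recovered <- true_key %in% edge_key
  list(recall = if (length(true_key)) mean(recovered) else NA_real_,
       precision = if (length(edge_key)) mean(edge_key %in% true_key)
                   else NA_real_,
       n_edges = length(edge_key), recovered = recovered)
}
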