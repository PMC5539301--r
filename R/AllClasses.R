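#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' MalaniDataSet: labelled expression matrix
#'
#' Container for a gene x sample intensity matrix with a binary condition
#' (\code{cancer} / \code{normal}) per sample, built on
#' \linkS4class{SummarizedExperiment}. Values must be finite and
#' non-negative; gene and sample identifiers must be unique; both conditions
#' must be present. The \code{normalized} flag in the metadata records
#' whether every sample column has been divided by its own sum (see
#' \code{\link{normalizePerSample}}).
#'
#' @slot .Data inherited \code{SummarizedExperiment} structure with a single
#'   assay \code{"exprs"} and a \code{condition} column in \code{colData}.
#' @export
setClass("MalaniDataSet", contains = "SummarizedExperiment")

.validMalaniDataSet <- function(object) {
  msg <- character(0)
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    return("assay 'exprs' is missing")
  m <- SummarizedExperiment::assay(object, "exprs")
  gid <- rownames(m); sid <- colnames(m)
  if (is.null(gid) || anyDuplicated(gid))
    msg <- c(msg, "gene identifiers must be present and unique")
  if (is.null(sid) || anyDuplicated(sid))
    msg <- c(msg, "sample identifiers must be present and unique")
  if (!all(is.finite(m)))
    msg <- c(msg, "expression values must be finite")
  else if (any(m < 0))
    msg <- c(msg, "expression values must be non-negative")
  cond <- colData(object)$condition
  if (is.null(cond)) {
    msg <- c(msg, "colData must carry a 'condition' column")
  } else {
    if (!all(as.character(cond) %in% c("cancer", "normal")))
      msg <- c(msg, "condition labels must be 'cancer' or 'normal'")
    if (length(unique(as.character(cond))) < 2L)
      msg <- c(msg, "both conditions (cancer and normal) must be present")
  }
  if (isTRUE(metadata(object)$normalized) && ncol(m) > 0L) {
    cs <- colSums(m)
    if (any(abs(cs - 1) > 1e-9))
      msg <- c(msg, "normalized flag is set but column sums deviate from 1")
  }
  if (length(msg)) msg else TRUE
}
setValidity("MalaniDataSet", .validMalaniDataSet)

#' Construct a MalaniDataSet
#'
#' @param values numeric gene x sample matrix with row and column names.
#' @param labels character or factor of per-sample conditions, values
#'   \code{"cancer"} or \code{"normal"} (case-insensitive). Either unnamed and
#'   in column order, or named by sample identifier.
#' @param normalized logical; set \code{TRUE} only if every column already
#'   sums to one.
#' @return a \linkS4class{MalaniDataSet}.
#' @examples
#' m <- matrix(1:6, 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' MalaniDataSet(m, c("cancer", "normal"))
#' @export
MalaniDataSet <- function(values, labels, normalized = FALSE) {
  values <- as.matrix(values)
  labels <- tolower(as.character(labels))
  if (!is.null(names(labels))) {
    missing <- setdiff(names(labels), colnames(values))
    if (length(missing))
      stop("samples in labels missing from matrix: ",
           paste(missing, collapse = ", "))
    labels <- labels[colnames(values)]
    if (anyNA(labels))
      stop("no label supplied for samples: ",
           paste(colnames(values)[is.na(labels)], collapse = ", "))
  }
  bad <- setdiff(unique(labels), c("cancer", "normal"))
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (expected 'cancer' or 'normal')")
  se <- SummarizedExperiment(
    assays = list(exprs = values),
    colData = DataFrame(condition = factor(labels,
                                           levels = c("cancer", "normal")),
                        row.names = colnames(values)))
  obj <- new("MalaniDataSet", se)
  metadata(obj)$normalized <- isTRUE(normalized)
  validObject(obj)
  obj
}

#' FoldPlan: stratified cross-validation portions
#'
#' Assignment of every sample to one of \code{k} portions, stratified so each
#' portion holds at least one sample of each condition and per-condition
#' portion sizes differ by at most one. Portion \code{f} serves as the test
#' set once; training rotates over the remaining \code{k - 1} portions
#' (the first training fold tests portion \code{k}, the second portion 1,
#' and so on).
#'
#' @slot k integer fold count.
#' @slot assignment named integer vector, portion index in \code{1..k} per
#'   sample.
#' @slot classes factor of per-sample conditions, parallel to
#'   \code{assignment}.
#' @export
setClass("FoldPlan",
         representation(k = "integer", assignment = "integer",
                        classes = "factor"))

setValidity("FoldPlan", function(object) {
  msg <- character(0)
  k <- object@k; a <- object@assignment
  if (length(a) != length(object@classes))
    return("assignment and classes lengths differ")
  if (any(a < 1L | a > k)) msg <- c(msg, "portion indices outside 1..k")
  for (cl in levels(object@classes)) {
    tab <- tabulate(a[object@classes == cl], nbins = k)
    if (any(tab == 0L))
      msg <- c(msg, sprintf("class '%s' absent from some portion", cl))
    if (diff(range(tab)) > 1L)
      msg <- c(msg, sprintf("class '%s' portion sizes differ by > 1", cl))
  }
  if (length(msg)) msg else TRUE
})

#' ClassifierSpec: binary classifier configuration
#'
#' The default reproduces the reference configuration: a C-classification
#' support vector machine with radial kernel, \code{cost = 1} and
#' \code{gamma} equal to the reciprocal of the feature count, as fitted by
#' \pkg{e1071} with its default parameters (which include per-feature
#' standardisation). \code{gamma} may be set to a positive constant to
#' reproduce a fixed-kernel-width configuration.
#'
#' @slot family one of \code{"svm_rbf"}, \code{"svm_linear"},
#'   \code{"random_forest"}, \code{"logistic"}.
#' @slot cost positive cost of constraint violation (SVM families).
#' @slot gamma kernel width: the string \code{"reciprocal_of_feature_count"}
#'   or a positive number.
#' @slot scale logical; standardise features on the training portion of each
#'   fold (the \pkg{e1071} default behaviour).
#' @slot seed integer seed for stochastic families (random forest).
#' @export
setClass("ClassifierSpec",
         representation(family = "character", cost = "numeric",
                        gamma = "ANY", scale = "logical", seed = "integer"))

setValidity("ClassifierSpec", function(object) {
  msg <- character(0)
  fams <- c("svm_rbf", "svm_linear", "random_forest", "logistic")
  if (!object@family %in% fams)
    msg <- c(msg, paste("family must be one of:", paste(fams, collapse = ", ")))
  if (object@cost <= 0) msg <- c(msg, "cost must be > 0")
  g <- object@gamma
  if (is.character(g)) {
    if (g != "reciprocal_of_feature_count")
      msg <- c(msg, "character gamma must be 'reciprocal_of_feature_count'")
  } else if (!(is.numeric(g) && length(g) == 1L && g > 0)) {
    msg <- c(msg, "numeric gamma must be a single positive value")
  }
  if (length(msg)) msg else TRUE
})

#' @param family,cost,gamma,scale,seed see the class slots.
#' @rdname ClassifierSpec-class
#' @export
classifierSpec <- function(family = c("svm_rbf", "svm_linear",
                                      "random_forest", "logistic"),
                           cost = 1, gamma = "reciprocal_of_feature_count",
                           scale = TRUE, seed = 1L) {
  new("ClassifierSpec", family = match.arg(family), cost = cost,
      gamma = gamma, scale = isTRUE(scale), seed = as.integer(seed))
}

#' CVResult: cross-validated classification performance
#'
#' @slot perFoldAccuracy numeric accuracies in fold rotation order.
#' @slot meanAccuracy arithmetic mean of the per-fold accuracies.
#' @export
setClass("CVResult",
         representation(perFoldAccuracy = "numeric", meanAccuracy = "numeric"))

setValidity("CVResult", function(object) {
  if (length(object@perFoldAccuracy) &&
      abs(object@meanAccuracy - mean(object@perFoldAccuracy)) > 1e-12)
    return("meanAccuracy must equal the mean of perFoldAccuracy")
  if (any(object@perFoldAccuracy < 0 | object@perFoldAccuracy > 1))
    return("accuracies must lie in [0, 1]")
  TRUE
})

#' ThetaSet: genes surviving the gene-wise screen
#'
#' The top fraction (default 5\%) of genes ranked by the cross-validated
#' accuracy of their gene-wise product models; the screen of the first
#' inference stage.
#'
#' @slot genes character vector of selected gene identifiers, best first.
#' @slot scores data.frame with columns \code{gene}, \code{mean_accuracy},
#'   \code{rank}, \code{in_theta} for every gene in the dataset.
#' @slot frac the selection fraction used.
#' @export
setClass("ThetaSet",
         representation(genes = "character", scores = "data.frame",
                        frac = "numeric"))

setValidity("ThetaSet", function(object) {
  msg <- character(0)
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate genes in theta")
  sc <- object@scores
  need <- c("gene", "mean_accuracy", "rank", "in_theta")
  if (!all(need %in% names(sc)))
    return(paste("scores must have columns:", paste(need, collapse = ", ")))
  if (nrow(sc) && !setequal(sc$rank, seq_len(nrow(sc))))
    msg <- c(msg, "ranks must be a permutation of 1..G")
  if (!all(object@genes %in% sc$gene))
    msg <- c(msg, "theta genes must appear in the score table")
  if (length(msg)) msg else TRUE
})

#' PairList: candidate gene pairs from the partner search
#'
#' Unique unordered gene pairs kept after the per-anchor top-\code{n} partner
#' selection of the second stage, with provenance (which selected-set genes
#' anchored each pair).
#'
#' @slot pairs data.frame with columns \code{gene_a}, \code{gene_b},
#'   \code{anchors} (comma-separated anchor genes), \code{mean_accuracy}.
#' @slot scores data.frame of all anchor-partner evaluations with columns
#'   \code{anchor}, \code{partner}, \code{mean_accuracy}, \code{kept}.
#' @export
setClass("PairList",
         representation(pairs = "data.frame", scores = "data.frame"))

setValidity("PairList", function(object) {
  p <- object@pairs
  need <- c("gene_a", "gene_b", "anchors", "mean_accuracy")
  if (!all(need %in% names(p)))
    return(paste("pairs must have columns:", paste(need, collapse = ", ")))
  if (nrow(p)) {
    key <- paste(pmin(p$gene_a, p$gene_b), pmax(p$gene_a, p$gene_b))
    if (anyDuplicated(key)) return("pairs must be unique as unordered pairs")
    if (any(p$gene_a == p$gene_b)) return("self-pairs are not allowed")
  }
  TRUE
})

#' PairMatrix: per-sample product features for surviving pairs
#'
#' Row \code{r} holds, for pair \code{{a, b}}, the per-sample products
#' \code{x_a(s) * x_b(s)}.
#'
#' @slot pairs data.frame with columns \code{gene_a}, \code{gene_b}.
#' @slot values numeric R x S matrix, one row per pair, rownames
#'   \code{"a|b"}.
#' @export
setClass("PairMatrix",
         representation(pairs = "data.frame", values = "matrix"))

setValidity("PairMatrix", function(object) {
  if (nrow(object@pairs) != nrow(object@values))
    return("pairs and values row counts differ")
  TRUE
})

#' FSVote: ensemble feature-selection vote over pair features
#'
#' Per-method rankings of the pair-product features, each method's selected
#' top fraction, and the per-pair vote count; pairs with at least
#' \code{minVotes} votes survive.
#'
#' @slot ranks integer R x method matrix (1 = best).
#' @slot selected logical R x method matrix of per-method top sets.
#' @slot votes integer votes per pair (0..number of methods).
#' @slot minVotes,topFrac the vote threshold and per-method selection
#'   fraction used.
#' @export
setClass("FSVote",
         representation(ranks = "matrix", selected = "matrix",
                        votes = "integer", minVotes = "integer",
                        topFrac = "numeric"))

setValidity("FSVote", function(object) {
  if (!identical(dim(object@ranks), dim(object@selected)))
    return("ranks and selected must have identical dimensions")
  if (length(object@votes) != nrow(object@ranks))
    return("votes length must equal the pair count")
  if (!all(object@votes == rowSums(object@selected)))
    return("votes must count per-method selections")
  TRUE
})

#' GeneSetCollection: named gene categories with a reference size
#'
#' @slot sets named list of character vectors (category members).
#' @slot referenceSize integer count of genes in the reference background.
#' @export
setClass("GeneSetCollection",
         representation(sets = "list", referenceSize = "integer"))

setValidity("GeneSetCollection", function(object) {
  msg <- character(0)
  nm <- names(object@sets)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == ""))
    msg <- c(msg, "category names must be present and unique")
  if (any(lengths(object@sets) == 0L))
    msg <- c(msg, "every category must be non-empty")
  if (object@referenceSize < 1L)
    msg <- c(msg, "referenceSize must be positive")
  if (length(msg)) msg else TRUE
})

#' @param sets,referenceSize see the class slots.
#' @rdname GeneSetCollection-class
#' @export
GeneSetCollection <- function(sets, referenceSize) {
  new("GeneSetCollection", sets = lapply(sets, as.character),
      referenceSize = as.integer(referenceSize))
}

#' Default mutation-type vocabulary
#'
#' @return character vector of recognised mutation types.
#' @export
mutationVocabulary <- function() {
  c("missense", "silent", "nonsense", "splicing", "frameshift_insertion",
    "frameshift_deletion", "amplified", "intronic", "in_frame_indel", "other")
}

#' MutationTable: (gene, mutation type) catalogue
#'
#' @slot records data.frame with columns \code{gene}, \code{mutation_type};
#'   no duplicated (gene, type) rows.
#' @slot vocabulary character vector of admissible types.
#' @export
setClass("MutationTable",
         representation(records = "data.frame", vocabulary = "character"))

setValidity("MutationTable", function(object) {
  r <- object@records
  if (!all(c("gene", "mutation_type") %in% names(r)))
    return("records must have columns gene, mutation_type")
  if (anyDuplicated(r[c("gene", "mutation_type")]))
    return("duplicate (gene, mutation_type) records")
  TRUE
})

#' @param records,vocabulary see the class slots.
#' @param strict reject records whose type is outside the vocabulary.
#' @rdname MutationTable-class
#' @export
MutationTable <- function(records = data.frame(gene = character(0),
                                               mutation_type = character(0)),
                          vocabulary = mutationVocabulary(), strict = TRUE) {
  records <- data.frame(gene = as.character(records$gene),
                        mutation_type = as.character(records$mutation_type),
                        stringsAsFactors = FALSE)
  if (strict) {
    bad <- setdiff(unique(records$mutation_type), vocabulary)
    if (length(bad))
      stop("mutation types outside the vocabulary: ",
           paste(bad, collapse = ", "))
  }
  records <- unique(records)
  rownames(records) <- NULL
  new("MutationTable", records = records, vocabulary = vocabulary)
}

#' PIEMIN: interaction-path expansion of an inferred network
#'
#' The union of the found network pairs' endpoints with every node and edge
#' on the shortest interaction path connecting each pair, plus per-node
#' visit frequencies (how many shortest paths pass through each node).
#'
#' @slot graph undirected \pkg{igraph} graph.
#' @slot nodeFrequency named integer of shortest-path visit counts.
#' @slot paths data.frame of per-pair path records with columns
#'   \code{gene_a}, \code{gene_b}, \code{status}, \code{length},
#'   \code{path} (pipe-separated node sequence, empty when not found).
#' @export
setClass("PIEMIN",
         representation(graph = "ANY", nodeFrequency = "integer",
                        paths = "data.frame"))

#' PermutationResult: Monte-Carlo permutation test summary
#'
#' @slot observedStat statistic on the true labels.
#' @slot permutedStats statistic on each of \code{M} label permutations.
#' @slot alpha Monte-Carlo p-value: fraction of permuted statistics at least
#'   as extreme (in absolute value) as the observed one.
#' @slot ciLow,ciHigh normal-approximation 95\% bounds
#'   \code{alpha +/- 1.96 * sqrt(alpha * (1 - alpha) / M)}, clipped to
#'   \code{[0, 1]}.
#' @export
setClass("PermutationResult",
         representation(observedStat = "numeric", permutedStats = "numeric",
                        alpha = "numeric", ciLow = "numeric",
                        ciHigh = "numeric"))

setValidity("PermutationResult", function(object) {
  if (object@alpha < 0 || object@alpha > 1) return("alpha must be in [0, 1]")
  TRUE
})
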