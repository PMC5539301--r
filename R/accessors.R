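#' @describeIn MalaniDataSet-class expression matrix (genes x samples).
#' @param x,object a \code{MalaniDataSet}.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "exprs")

#' @describeIn MalaniDataSet-class per-sample condition factor with levels
#'   \code{cancer}, \code{normal}.
#' @export
sampleClasses <- function(x) colData(x)$condition

#' @describeIn MalaniDataSet-class gene identifiers.
#' @export
geneIds <- function(x) rownames(x)

#' @describeIn MalaniDataSet-class sample identifiers.
#' @export
sampleIds <- function(x) colnames(x)

#' @describeIn MalaniDataSet-class whether columns are sum-normalized.
#' @export
isNormalized <- function(x) isTRUE(metadata(x)$normalized)

setMethod("show", "MalaniDataSet", function(object) {
  cond <- table(sampleClasses(object))
  cat(sprintf("MalaniDataSet: %d genes x %d samples (%s)\n",
              nrow(object), ncol(object),
              paste(sprintf("%d %s", cond, names(cond)), collapse = ", ")))
  cat(sprintf("  normalized: %s\n", isNormalized(object)))
})

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: k = %d over %d samples\n",
              object@k, length(object@assignment)))
})

#' @describeIn FoldPlan-class portion index per sample.
#' @param x a \code{FoldPlan}.
#' @export
foldAssignment <- function(x) x@assignment

setMethod("show", "CVResult", function(object) {
  cat(sprintf("CVResult: mean accuracy %.4f over %d folds\n",
              object@meanAccuracy, length(object@perFoldAccuracy)))
})

#' @describeIn CVResult-class mean cross-validated accuracy.
#' @param x a \code{CVResult}.
#' @export
meanAccuracy <- function(x) x@meanAccuracy

#' @describeIn CVResult-class per-fold accuracies in rotation order.
#' @export
perFoldAccuracy <- function(x) x@perFoldAccuracy

setMethod("show", "ThetaSet", function(object) {
  cat(sprintf("ThetaSet: %d of %d genes (frac = %.3g)\n",
              length(object@genes), nrow(object@scores), object@frac))
})

#' @describeIn ThetaSet-class selected gene identifiers, best first.
#' @param x a \code{ThetaSet}.
#' @export
thetaGenes <- function(x) x@genes

#' @describeIn ThetaSet-class per-gene score table.
#' @export
geneScores <- function(x) x@scores

setMethod("show", "PairList", function(object) {
  cat(sprintf("PairList: %d unique pairs (%d anchor-partner scores)\n",
              nrow(object@pairs), nrow(object@scores)))
})

#' @describeIn PairList-class unique unordered pairs with provenance.
#' @param x a \code{PairList}.
#' @export
pairTable <- function(x) x@pairs

#' @describeIn PairList-class all anchor-partner evaluations.
#' @export
pairScores <- function(x) x@scores

setMethod("show", "PairMatrix", function(object) {
  cat(sprintf("PairMatrix: %d pairs x %d samples\n",
              nrow(object@values), ncol(object@values)))
})

#' @describeIn PairMatrix-class product-feature matrix (pairs x samples).
#' @param x a \code{PairMatrix}.
#' @export
pairValues <- function(x) x@values

setMethod("show", "FSVote", function(object) {
  cat(sprintf(
    "FSVote: %d pairs, %d methods, %d selected (votes >= %d, top %.0f%%)\n",
    nrow(object@ranks), ncol(object@ranks),
    sum(object@votes >= object@minVotes), object@minVotes,
    100 * object@topFrac))
})

#' @describeIn FSVote-class integer vote count per pair.
#' @param x an \code{FSVote}.
#' @export
pairVotes <- function(x) x@votes

setMethod("show", "GeneSetCollection", function(object) {
  cat(sprintf("GeneSetCollection: %d categories over %d reference genes\n",
              length(object@sets), object@referenceSize))
})

#' @describeIn GeneSetCollection-class named list of category member sets.
#' @param x a \code{GeneSetCollection}.
#' @export
geneSets <- function(x) x@sets

#' @describeIn GeneSetCollection-class background gene count.
#' @export
referenceSize <- function(x) x@referenceSize

setMethod("show", "MutationTable", function(object) {
  cat(sprintf("MutationTable: %d records over %d genes\n",
              nrow(object@records), length(unique(object@records$gene))))
})

#' @describeIn MutationTable-class the (gene, type) records.
#' @param x a \code{MutationTable}.
#' @export
mutationRecords <- function(x) x@records

#' @describeIn MutationTable-class genes with at least one record.
#' @export
mutatedGenes <- function(x) unique(x@records$gene)

setMethod("show", "PIEMIN", function(object) {
  cat(sprintf("PIEMIN: %d nodes, %d edges (%d/%d pairs with a found path)\n",
              igraph::vcount(object@graph), igraph::ecount(object@graph),
              sum(object@paths$status == "found"), nrow(object@paths)))
})

#' @describeIn PIEMIN-class the expanded interaction graph.
#' @param x a \code{PIEMIN}.
#' @export
pieminGraph <- function(x) x@graph

#' @describeIn PIEMIN-class per-node shortest-path visit counts.
#' @export
nodeFrequency <- function(x) x@nodeFrequency

#' @describeIn PIEMIN-class per-pair path records.
#' @export
pathRecords <- function(x) x@paths

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    "PermutationResult: observed %.4f, alpha = %.3f (95%% CI %.3f-%.3f, M = %d)\n",
    object@observedStat, object@alpha, object@ciLow, object@ciHigh,
    length(object@permutedStats)))
})
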