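#' @importFrom stats p.adjust phyper pt fisher.test
NULL

#' Monte-Carlo permutation test
#'
#' Computes a statistic on the true labels and on \code{M} independent
#' label permutations. The Monte-Carlo p-value is the uncorrected estimator
#' \code{alpha = #\{|stat_perm| >= |stat_obs|\} / M} (no +1 smoothing, so
#' \code{alpha = 0} is attainable, in which case the normal-approximation
#' confidence interval collapses to \code{[0, 0]}); the 95\% interval is
#' \code{alpha +/- 1.96 sqrt(alpha (1 - alpha) / M)} clipped to
#' \code{[0, 1]}.
#'
#' @param statistic function taking a label vector and returning a single
#'   finite number (e.g. the mean cross-validated accuracy of a model
#'   rebuilt under those labels; see \code{\link{finalModelStatistic}}).
#' @param labels the true per-sample conditions.
#' @param M number of permutations (default 20).
#' @param seed integer seed driving the permutations.
#' @return a \linkS4class{PermutationResult}.
#' @export
permutationTest <- function(statistic, labels, M = 20L, seed = 1L) {
  if (M < 1L) stop("M must be >= 1")
  labels <- as.character(labels)
  observed <- statistic(labels)
  if (!is.finite(observed)) stop("statistic returned a non-finite value")
  perms <- withr::with_seed(as.integer(seed),
    replicate(M, sample(labels)))
  permuted <- apply(perms, 2L, function(lab) {
    s <- statistic(lab)
    if (!is.finite(s)) stop("statistic returned a non-finite value")
    s
  })
  alpha <- mean(abs(permuted) >= abs(observed))
  half <- 1.96 * sqrt(alpha * (1 - alpha) / M)
  new("PermutationResult", observedStat = observed,
      permutedStats = permuted, alpha = alpha,
      ciLow = max(0, alpha - half), ciHigh = min(1, alpha + half))
}

#' Permutation statistic: accuracy of the re-selected final model
#'
#' Returns a closure suitable for \code{\link{permutationTest}}: given a
#' label vector it re-runs the ensemble feature-selection vote on the fixed
#' pair-product matrix under those labels, then reports the mean
#' cross-validated accuracy of the classifier on the surviving pair
#' features. Re-running the selection under each relabelling keeps the null
#' distribution comparable to the observed statistic (both enjoy the same
#' selection optimism); the earlier screening stages are treated as fixed
#' feature engineering. If no pair reaches the vote threshold under a
#' relabelling, the maximally-voted pairs are used.
#'
#' @param ds a normalized \linkS4class{MalaniDataSet}.
#' @param pairs a \linkS4class{PairList} (or pair data.frame).
#' @param folds a \linkS4class{FoldPlan}.
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param min_votes,top_frac ensemble vote parameters.
#' @return function(labels) -> mean CV accuracy.
#' @export
finalModelStatistic <- function(ds, pairs, folds, spec = classifierSpec(),
                                min_votes = 3L, top_frac = 0.1) {
  Q <- pairProductMatrix(ds, pairs)
  values <- pairValues(Q)
  fold <- folds@assignment
  k <- folds@k
  function(labels) {
    y <- factor(tolower(as.character(labels)),
                levels = c("cancer", "normal"))
    methods <- c("IG", "ReliefF", "SU", "SVM_RFE", "IA")
    ranks <- lapply(methods, function(mth)
      scoreFeatures(Q, y, method = mth, spec = spec, folds = folds)$rank)
    vote <- ensembleSelect(ranks, min_votes = min_votes,
                           top_frac = top_frac)
    sel <- vote@votes >= min_votes
    if (!any(sel)) sel <- vote@votes == max(vote@votes)
    mean(.cvAccuracyCore(t(values[sel, , drop = FALSE]), y, fold, k, spec))
  }
}

#' Per-gene parametric p-values
#'
#' Row-wise two-sample t-test (pooled variance by default, Welch optional),
#' two-sided, comparing cancer against normal samples for every gene.
#' Zero-variance rows yield p = 1 with a warning.
#'
#' @param ds a \linkS4class{MalaniDataSet}.
#' @param welch use the Welch (unequal-variance) statistic.
#' @return named numeric vector of raw p-values.
#' @export
perGenePvalues <- function(ds, welch = FALSE) {
  m <- exprValues(ds)
  cancer <- sampleClasses(ds) == "cancer"
  x <- m[, cancer, drop = FALSE]; y <- m[, !cancer, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  if (n1 < 2L || n2 < 2L) stop("each class needs at least two samples")
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- rowSums((x - m1)^2) / (n1 - 1)
  v2 <- rowSums((y - m2)^2) / (n2 - 1)
  if (welch) {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep.int(n1 + n2 - 2, length(se2))
  }
  p <- rep.int(1, nrow(m))
  zero <- se2 <= 0
  if (any(zero)) warning(sum(zero), " gene(s) with zero pooled variance")
  tt <- (m1[!zero] - m2[!zero]) / sqrt(se2[!zero])
  p[!zero] <- 2 * pt(-abs(tt), df[!zero])
  stats::setNames(p, rownames(m))
}

#' Multiple-testing adjustment
#'
#' Bonferroni (\code{min(1, m p)}) or Benjamini-Hochberg step-up adjusted
#' p-values.
#'
#' @param p numeric p-values in [0, 1].
#' @param method \code{"bonferroni"} or \code{"bh"}.
#' @return adjusted p-values, same length and names.
#' @export
adjustPvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' Hypergeometric gene-set over-representation
#'
#' For each category C with j genes in the reference of m genes, given a
#' query of n genes with k of them in C: the expected overlap is
#' \code{k_expected = (n / m) j}, the enrichment ratio
#' \code{r = k / k_expected}, and the raw p-value is the upper-tail
#' hypergeometric probability P(X >= k). Bonferroni correction is applied
#' across categories. Two significance filters are provided: \code{min}
#' keeps the top 10 categories by raw p-value with at least 3 query genes;
#' \code{piemin} keeps categories with adjusted p < 0.05 and at least 5
#' query genes.
#'
#' @param query character vector of query genes (a subset of the
#'   reference).
#' @param sets a \linkS4class{GeneSetCollection}.
#' @param mode filter to apply: \code{"min"}, \code{"piemin"} or
#'   \code{"none"}.
#' @return data.frame with columns \code{category}, \code{n}, \code{m},
#'   \code{j}, \code{k_obs}, \code{k_expected}, \code{r}, \code{p_raw},
#'   \code{p_adj}, \code{passes_filter}, sorted by raw p-value.
#' @export
hypergeomEnrich <- function(query, sets, mode = c("min", "piemin", "none")) {
  mode <- match.arg(mode)
  query <- unique(as.character(query))
  m <- referenceSize(sets)
  if (m < 1L) stop("empty reference gene set")
  n <- length(query)
  cats <- geneSets(sets)
  res <- do.call(rbind, lapply(names(cats), function(nm) {
    members <- cats[[nm]]
    j <- length(members)
    k <- length(intersect(query, members))
    k_exp <- (n / m) * j
    data.frame(category = nm, n = n, m = m, j = j, k_obs = k,
               k_expected = k_exp,
               r = if (k_exp > 0) k / k_exp else NA_real_,
               p_raw = phyper(k - 1, j, m - j, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- pmin(1, res$p_raw * nrow(res))
  res <- res[order(res$p_raw, res$category), , drop = FALSE]
  rownames(res) <- NULL
  res$passes_filter <- switch(mode,
    none = rep(TRUE, nrow(res)),
    min = seq_len(nrow(res)) <= 10L & res$k_obs >= 3L,
    piemin = res$p_adj < 0.05 & res$k_obs >= 5L)
  res
}

#' Hub-to-Class II connectivity test
#'
#' Fisher's exact test on the 2 x 2 table crossing hub adjacency (a gene is
#' adjacent to at least one hub of the network) with Class II membership,
#' against a background of \code{background_size} genes.
#'
#' @param net \pkg{igraph} network (an inferred network or its
#'   interaction-path expansion).
#' @param classes the \code{\link{classifyGenes}} table.
#' @param background_size background gene count (must be at least the
#'   number of genes involved).
#' @param min_connectivity hub threshold passed to \code{\link{findHubs}}.
#' @return list with \code{table} (2 x 2 counts) and \code{p} (two-sided
#'   Fisher p-value).
#' @export
fisherHubClass2 <- function(net, classes, background_size,
                            min_connectivity = 6L) {
  hubs <- findHubs(net, min_connectivity)
  adj <- character(0)
  if (length(hubs)) {
    nm <- igraph::V(net)$name
    adj <- unique(unlist(lapply(igraph::adjacent_vertices(net, hubs),
                                function(v) nm[as.integer(v)])))
  }
  class2 <- classes$gene[classes$label == "class_II"]
  universe <- unique(c(igraph::V(net)$name, classes$gene))
  a <- length(intersect(adj, class2))
  b <- length(setdiff(adj, class2))
  c_ <- length(setdiff(class2, adj))
  d <- background_size - a - b - c_
  if (d < 0) stop("background_size smaller than the observed totals")
  tab <- matrix(c(a, b, c_, d), 2L, 2L, byrow = TRUE,
                dimnames = list(c("hub_adjacent", "not_adjacent"),
                                c("class_II", "not_class_II")))
  list(table = tab, p = fisher.test(tab)$p.value, universe = universe)
}

#' Number of classifier fits of the screening stages
#'
#' The screening and partner-search stages train about
#' \code{k * G * (1 + (G - 1) / 20)} classifiers for G genes under k-fold
#' cross-validation (G gene-wise models per fold, plus the pair models of
#' the 5\% screened anchors against their G - 1 partners).
#'
#' @param G gene count.
#' @param k fold count.
#' @return the model count (numeric).
#' @examples
#' modelCount(21, 10)     # 420
#' modelCount(20075, 10)  # 201,693,525 — more than 2e8
#' @export
modelCount <- function(G, k) {
  if (G < 1 || k < 1) stop("G and k must be >= 1")
  k * G * (1 + (G - 1) / 20)
}
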