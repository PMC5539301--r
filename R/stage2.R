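#' Two-gene raw-expression features
#'
#' The 2 x S matrix stacking the expression rows of two genes; the feature
#' space of the pair models in the partner-search stage. Swapping the genes
#' swaps the rows.
#'
#' @param ds a \linkS4class{MalaniDataSet}.
#' @param a,b distinct gene identifiers.
#' @return numeric 2 x S matrix with rows named by the genes.
#' @export
pairFeatures <- function(ds, a, b) {
  if (identical(a, b)) stop("a pair must consist of two distinct genes")
  m <- exprValues(ds)
  ia <- match(a, rownames(m)); ib <- match(b, rownames(m))
  if (is.na(ia) || is.na(ib))
    stop("unknown gene: ", paste(c(a, b)[is.na(c(ia, ib))], collapse = ", "))
  m[c(ia, ib), , drop = FALSE]
}

#' Partner-search stage
#'
#' For every screened (anchor) gene, evaluates the two-feature model of the
#' anchor with each of the other G - 1 genes by cross-validated accuracy and
#' keeps the top \code{n} partners per anchor (ties broken by dataset gene
#' order). Partners range over all genes, including other screened genes.
#' Pairs found from both ends are merged into a single unordered pair with
#' both anchors recorded, so the returned pair list is unique.
#'
#' @param ds a normalized \linkS4class{MalaniDataSet}.
#' @param theta a \linkS4class{ThetaSet}.
#' @param folds a \linkS4class{FoldPlan}.
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param n partners kept per anchor (default 10).
#' @param verbose print progress per anchor.
#' @return a \linkS4class{PairList}.
#' @export
topPartners <- function(ds, theta, folds, spec = classifierSpec(), n = 10L,
                        verbose = FALSE) {
  if (n < 1L) stop("n must be >= 1")
  anchors <- thetaGenes(theta)
  if (length(anchors) == 0L) stop("theta set is empty")
  m <- exprValues(ds)
  genes <- rownames(m)
  y <- sampleClasses(ds)
  fold <- folds@assignment
  all_scores <- vector("list", length(anchors))
  for (ai in seq_along(anchors)) {
    a <- anchors[ai]
    ia <- match(a, genes)
    partners <- genes[-ia]
    xa <- m[ia, ]
    acc <- vapply(partners, function(p) {
      X <- cbind(xa, m[p, ])
      mean(.cvAccuracyCore(X, y, fold, folds@k, spec))
    }, numeric(1))
    keep_ord <- order(-acc, seq_along(partners))
    kept <- logical(length(partners))
    kept[keep_ord[seq_len(min(n, length(partners)))]] <- TRUE
    all_scores[[ai]] <- data.frame(anchor = a, partner = partners,
                                   mean_accuracy = acc, kept = kept,
                                   stringsAsFactors = FALSE)
    if (verbose)
      message(sprintf("anchor %d / %d (%s): best partner accuracy %.3f",
                      ai, length(anchors), a, max(acc)))
  }
  scores <- do.call(rbind, all_scores)
  rownames(scores) <- NULL
  kept <- scores[scores$kept, , drop = FALSE]
  ga <- pmin(kept$anchor, kept$partner)
  gb <- pmax(kept$anchor, kept$partner)
  key <- paste(ga, gb, sep = "\r")
  first <- !duplicated(key)
  anchors_merged <- vapply(split(kept$anchor, key), function(v)
    paste(unique(v), collapse = ","), character(1))
  pairs <- data.frame(gene_a = ga[first], gene_b = gb[first],
                      anchors = as.vector(anchors_merged[key[first]]),
                      mean_accuracy = kept$mean_accuracy[first],
                      stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  new("PairList", pairs = pairs, scores = scores)
}
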