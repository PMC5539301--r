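#' Gene-wise product features
#'
#' For gene i, the feature matrix whose row for gene j (j != i) holds the
#' per-sample products x_i(s) * x_j(s); rows keep the dataset gene order
#' with gene i removed. This is the feature space in which the gene-wise
#' models of the first stage classify.
#'
#' @param ds a normalized \linkS4class{MalaniDataSet}.
#' @param gene a gene identifier present in the dataset.
#' @return numeric (G - 1) x S matrix.
#' @examples
#' m <- matrix(c(1, 3, 5, 2, 4, 6), 3, 2,
#'             dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ds <- MalaniDataSet(m, c("cancer", "normal"))
#' genewiseProducts(ds, "g1")  # rows (3, 8) and (5, 12)
#' @export
genewiseProducts <- function(ds, gene) {
  m <- exprValues(ds)
  i <- match(gene, rownames(m))
  if (is.na(i)) stop("unknown gene: ", gene)
  sweep(m[-i, , drop = FALSE], 2L, m[i, ], "*")
}

#' Number of genes kept by the gene-wise screen
#'
#' @param G gene count.
#' @param frac selection fraction (default 0.05); the count is rounded up
#'   so the screen never returns an empty set.
#' @return \code{ceiling(frac * G)}.
#' @export
thetaSize <- function(G, frac = 0.05) as.integer(ceiling(frac * G))

#' Gene-wise screening stage
#'
#' Scores every gene by the cross-validated accuracy of a classifier
#' trained on its gene-wise product features, ranks genes by mean accuracy
#' (ties broken by dataset gene order, earlier wins), and selects the top
#' fraction as the screened set.
#'
#' @param ds a normalized \linkS4class{MalaniDataSet}.
#' @param folds a \linkS4class{FoldPlan}.
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param frac selection fraction in (0, 1], default 0.05.
#' @param verbose print progress every 50 genes.
#' @return a \linkS4class{ThetaSet}.
#' @export
selectTheta <- function(ds, folds, spec = classifierSpec(), frac = 0.05,
                        verbose = FALSE) {
  if (!isNormalized(ds)) stop("dataset must be normalized (per-sample sums)")
  if (frac <= 0 || frac > 1) stop("frac must lie in (0, 1]")
  m <- exprValues(ds)
  G <- nrow(m)
  y <- sampleClasses(ds)
  fold <- folds@assignment
  mean_acc <- vapply(seq_len(G), function(i) {
    feats <- sweep(m[-i, , drop = FALSE], 2L, m[i, ], "*")
    if (verbose && i %% 50L == 0L)
      message(sprintf("gene-wise models: %d / %d", i, G))
    mean(.cvAccuracyCore(t(feats), y, fold, folds@k, spec))
  }, numeric(1))
  ord <- order(-mean_acc, seq_len(G))
  rank <- integer(G); rank[ord] <- seq_len(G)
  n_keep <- thetaSize(G, frac)
  in_theta <- rank <= n_keep
  scores <- data.frame(gene = rownames(m), mean_accuracy = mean_acc,
                       rank = rank, in_theta = in_theta,
                       stringsAsFactors = FALSE)
  new("ThetaSet", genes = rownames(m)[ord[seq_len(n_keep)]],
      scores = scores, frac = frac)
}
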