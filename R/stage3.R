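#' Pair-product feature matrix
#'
#' Row r holds, for pair {a, b}, the per-sample products
#' x_a(s) * x_b(s); rows follow the pair-list order. The row is identical
#' whichever orientation the pair was stored in.
#'
#' @param ds a \linkS4class{MalaniDataSet}.
#' @param pairs a \linkS4class{PairList} or a data.frame with columns
#'   \code{gene_a}, \code{gene_b}.
#' @return a \linkS4class{PairMatrix}.
#' @export
pairProductMatrix <- function(ds, pairs) {
  if (is(pairs, "PairList")) pairs <- pairTable(pairs)
  pairs <- pairs[, c("gene_a", "gene_b"), drop = FALSE]
  m <- exprValues(ds)
  ia <- match(pairs$gene_a, rownames(m))
  ib <- match(pairs$gene_b, rownames(m))
  if (anyNA(ia) || anyNA(ib))
    stop("unknown gene(s): ",
         paste(unique(c(pairs$gene_a[is.na(ia)], pairs$gene_b[is.na(ib)])),
               collapse = ", "))
  values <- m[ia, , drop = FALSE] * m[ib, , drop = FALSE]
  rownames(values) <- paste(pairs$gene_a, pairs$gene_b, sep = "|")
  new("PairMatrix", pairs = pairs, values = values)
}

# Equal-frequency discretization into at most `bins` bins; returns an
# integer bin index per value. Features with few distinct values keep one
# bin per value; constant features collapse to one bin.
.equalFreqBins <- function(x, bins = 10L) {
  ux <- unique(x)
  if (length(ux) <= bins) return(as.integer(factor(x, levels = sort(ux))))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1L),
                        names = FALSE, type = 7))
  if (length(br) < 2L) return(rep.int(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

.entropyBits <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

# Plug-in mutual information (bits) between a discretized feature and the
# class, plus the two marginal entropies.
.miParts <- function(bin, y) {
  tab <- table(bin, y)
  hx <- .entropyBits(rowSums(tab))
  hy <- .entropyBits(colSums(tab))
  hxy <- .entropyBits(as.vector(tab))
  list(mi = hx + hy - hxy, hx = hx, hy = hy)
}

.igScores <- function(values, y, bins = 10L) {
  apply(values, 1L, function(x) .miParts(.equalFreqBins(x, bins), y)$mi)
}

.suScores <- function(values, y, bins = 10L) {
  apply(values, 1L, function(x) {
    p <- .miParts(.equalFreqBins(x, bins), y)
    if (p$hx + p$hy <= 0) 0 else 2 * p$mi / (p$hx + p$hy)
  })
}

# Relief-F with k nearest hits/misses per instance, every sample used once,
# Manhattan distance on range-normalized features.
.relieffScores <- function(values, y, k_neighbors = 10L) {
  X <- t(values)
  rng <- apply(X, 2L, function(col) diff(range(col)))
  use <- rng > 0
  Xn <- X
  Xn[, use] <- sweep(sweep(X[, use, drop = FALSE], 2L,
                           apply(X[, use, drop = FALSE], 2L, min)),
                     2L, rng[use], "/")
  Xn[, !use] <- 0
  S <- nrow(Xn)
  D <- as.matrix(stats::dist(Xn, method = "manhattan"))
  W <- numeric(ncol(Xn))
  for (i in seq_len(S)) {
    same <- which(y == y[i]); same <- same[same != i]
    diff_cl <- which(y != y[i])
    kh <- min(k_neighbors, length(same))
    km <- min(k_neighbors, length(diff_cl))
    hits <- same[order(D[i, same])[seq_len(kh)]]
    misses <- diff_cl[order(D[i, diff_cl])[seq_len(km)]]
    di <- Xn[rep(i, length(hits)), , drop = FALSE]
    W <- W - colSums(abs(Xn[hits, , drop = FALSE] - di)) / (S * kh)
    dm <- Xn[rep(i, length(misses)), , drop = FALSE]
    W <- W + colSums(abs(Xn[misses, , drop = FALSE] - dm)) / (S * km)
  }
  names(W) <- rownames(values)
  W
}

# SVM-RFE: recursive elimination by squared linear-SVM weights, dropping
# the lowest 10% (at least one) per iteration. Returns per-feature scores
# equal to the elimination step (later eliminated = higher = better).
.svmRfeScores <- function(values, y, cost = 1, drop_frac = 0.1) {
  X <- t(values)
  mu <- colMeans(X); s <- apply(X, 2L, sd)
  use <- s > 0
  X[, use] <- sweep(sweep(X[, use, drop = FALSE], 2L, mu[use]), 2L,
                    s[use], "/")
  X[, !use] <- 0
  R <- ncol(X)
  remaining <- seq_len(R)
  score <- numeric(R)
  step <- 0L
  while (length(remaining) > 1L) {
    fit <- e1071::svm(X[, remaining, drop = FALSE], y,
                      type = "C-classification", kernel = "linear",
                      cost = cost, scale = FALSE, fitted = FALSE)
    w <- as.vector(crossprod(fit$coefs, fit$SV))
    w2 <- w * w
    n_rm <- max(1L, floor(drop_frac * length(remaining)))
    rm_local <- order(w2, seq_along(remaining))[seq_len(n_rm)]
    step <- step + 1L
    score[remaining[rm_local]] <- step + seq_along(rm_local) * 1e-9
    remaining <- remaining[-rm_local]
  }
  score[remaining] <- step + 1L
  names(score) <- rownames(values)
  score
}

.iaScores <- function(values, y, fold, k, spec) {
  apply(values, 1L, function(x)
    mean(.cvAccuracyCore(matrix(x, ncol = 1L), y, fold, k, spec)))
}

#' Score pair features with one feature-selection method
#'
#' Five methods over the identical pair-product matrix: \code{IG}
#' (information gain: plug-in mutual information in bits between the
#' equal-frequency-discretized feature and the class), \code{SU}
#' (symmetrical uncertainty, \code{2 I(X;Y) / (H(X) + H(Y))}),
#' \code{ReliefF} (nearest hit/miss weights, Manhattan distance on
#' range-normalized features), \code{SVM_RFE} (recursive linear-SVM weight
#' elimination; later-eliminated features score higher) and \code{IA}
#' (individual accuracy: single-feature cross-validated accuracy). Higher
#' scores are better for every method; ranks break ties by pair order.
#'
#' @param Q a \linkS4class{PairMatrix}.
#' @param labels per-sample conditions.
#' @param method one of \code{"IG"}, \code{"ReliefF"}, \code{"SU"},
#'   \code{"SVM_RFE"}, \code{"IA"}.
#' @param spec a \linkS4class{ClassifierSpec} (used by \code{IA} and for the
#'   \code{SVM_RFE} cost).
#' @param folds a \linkS4class{FoldPlan}; required for \code{IA}.
#' @param bins discretization bins for \code{IG}/\code{SU}.
#' @param k_neighbors Relief-F neighbor count.
#' @return list with \code{score} (named numeric, higher = better) and
#'   \code{rank} (integer, 1 = best).
#' @export
scoreFeatures <- function(Q, labels, method = c("IG", "ReliefF", "SU",
                                                "SVM_RFE", "IA"),
                          spec = classifierSpec(), folds = NULL,
                          bins = 10L, k_neighbors = 10L) {
  method <- match.arg(method)
  values <- pairValues(Q)
  if (nrow(values) == 0L) stop("empty pair matrix")
  y <- factor(tolower(as.character(labels)), levels = c("cancer", "normal"))
  score <- switch(method,
    IG = .igScores(values, y, bins),
    SU = .suScores(values, y, bins),
    ReliefF = .relieffScores(values, y, k_neighbors),
    SVM_RFE = .svmRfeScores(values, y, cost = spec@cost),
    IA = {
      if (is.null(folds)) stop("IA scoring requires a fold plan")
      .iaScores(values, y, folds@assignment, folds@k, spec)
    })
  ord <- order(-score, seq_along(score))
  rank <- integer(length(score)); rank[ord] <- seq_along(score)
  list(score = score, rank = rank)
}

#' Ensemble vote over per-method rankings
#'
#' Each method selects its top \code{ceiling(top_frac * R)} pairs (ties
#' already resolved in the rankings by pair order); pairs selected by at
#' least \code{min_votes} methods survive.
#'
#' @param rankings named list of integer rank vectors (1 = best), all over
#'   the same pair universe.
#' @param min_votes vote threshold in 1..number of methods (default 3).
#' @param top_frac per-method selection fraction (default 0.1).
#' @return an \linkS4class{FSVote}.
#' @export
ensembleSelect <- function(rankings, min_votes = 3L, top_frac = 0.1) {
  stopifnot(length(rankings) >= 1L)
  R <- length(rankings[[1L]])
  if (!all(lengths(rankings) == R))
    stop("all methods must rank the same pair universe")
  if (min_votes < 1L || min_votes > length(rankings))
    stop("min_votes must lie in 1..", length(rankings))
  if (top_frac <= 0 || top_frac > 1) stop("top_frac must lie in (0, 1]")
  n_top <- as.integer(ceiling(top_frac * R))
  ranks <- do.call(cbind, rankings)
  selected <- ranks <= n_top
  votes <- as.integer(rowSums(selected))
  new("FSVote", ranks = ranks, selected = selected, votes = votes,
      minVotes = as.integer(min_votes), topFrac = top_frac)
}

#' Agglomerate selected pairs into an inferred network
#'
#' The graph union of the selected pairs: nodes are genes, edges are the
#' pairs, each edge annotated with its vote count. No transitive edges are
#' added; isolated nodes cannot occur by construction.
#'
#' @param pairs data.frame with columns \code{gene_a}, \code{gene_b}.
#' @param votes integer vote count per pair (optional).
#' @return an undirected \pkg{igraph} graph with a \code{votes} edge
#'   attribute.
#' @export
assembleMIN <- function(pairs, votes = NULL) {
  if (nrow(pairs) == 0L)
    return(igraph::make_empty_graph(0, directed = FALSE))
  el <- data.frame(from = pairs$gene_a, to = pairs$gene_b,
                   stringsAsFactors = FALSE)
  if (!is.null(votes)) el$votes <- votes
  igraph::graph_from_data_frame(el, directed = FALSE)
}

#' Full ensemble stage: products, five scorings, vote, network
#'
#' @param ds a normalized \linkS4class{MalaniDataSet}.
#' @param pairs a \linkS4class{PairList} (or pair data.frame).
#' @param folds a \linkS4class{FoldPlan}.
#' @param spec a \linkS4class{ClassifierSpec}.
#' @param min_votes,top_frac vote parameters (see
#'   \code{\link{ensembleSelect}}).
#' @param labels optional label override (used by permutation testing);
#'   defaults to the dataset conditions.
#' @return list with \code{Q} (\linkS4class{PairMatrix}), \code{scores}
#'   (per-method list), \code{vote} (\linkS4class{FSVote}),
#'   \code{selected_pairs} (data.frame with votes) and \code{min}
#'   (\pkg{igraph} network).
#' @export
stage3Ensemble <- function(ds, pairs, folds, spec = classifierSpec(),
                           min_votes = 3L, top_frac = 0.1, labels = NULL) {
  Q <- pairProductMatrix(ds, pairs)
  if (is.null(labels)) labels <- sampleClasses(ds)
  methods <- c("IG", "ReliefF", "SU", "SVM_RFE", "IA")
  scores <- lapply(methods, function(mth)
    scoreFeatures(Q, labels, method = mth, spec = spec, folds = folds))
  names(scores) <- methods
  vote <- ensembleSelect(lapply(scores, `[[`, "rank"),
                         min_votes = min_votes, top_frac = top_frac)
  sel <- vote@votes >= min_votes
  selected_pairs <- cbind(Q@pairs[sel, , drop = FALSE],
                          votes = vote@votes[sel])
  rownames(selected_pairs) <- NULL
  list(Q = Q, scores = scores, vote = vote,
       selected_pairs = selected_pairs,
       min = assembleMIN(selected_pairs, selected_pairs$votes))
}
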