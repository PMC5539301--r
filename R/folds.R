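#' Stratified cross-validation portions
#'
#' Splits samples into \code{k} portions separately within each condition,
#' so every portion carries a near-equal share of cancer and of normal
#' samples (per-condition sizes differ by at most one). Deterministic for a
#' fixed seed; the global random state is left untouched.
#'
#' @param labels factor or character of per-sample conditions; names, if
#'   present, become the assignment names.
#' @param k number of portions (default 10).
#' @param seed integer seed.
#' @return a \linkS4class{FoldPlan}.
#' @examples
#' stratifiedFolds(rep(c("cancer", "normal"), each = 20), k = 10, seed = 1)
#' @export
stratifiedFolds <- function(labels, k = 10L, seed = 1L) {
  cls <- factor(tolower(as.character(labels)), levels = c("cancer", "normal"))
  k <- as.integer(k)
  if (k < 2L) stop("k must be at least 2")
  short <- table(cls) < k
  if (any(short))
    stop("class(es) with fewer than k samples: ",
         paste(names(short)[short], collapse = ", "),
         "; use a smaller k")
  assignment <- integer(length(cls))
  withr::with_seed(as.integer(seed), {
    for (cl in levels(cls)) {
      idx <- which(cls == cl)
      assignment[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  names(assignment) <- names(labels)
  new("FoldPlan", k = k, assignment = assignment, classes = cls)
}

# Test-portion order mirroring the rotation scheme: the first training fold
# tests portion k, the second portion 1, ..., the k-th portion k - 1.
foldRotation <- function(k) c(k, seq_len(k - 1L))
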