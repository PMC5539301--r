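#' Per-sample sum normalization
#'
#' Divides each sample column by its own sum, so every column sums to one.
#' This normalizes each array independently (the same result whether samples
#' are processed together or separately) and preserves within-sample
#' expression ratios. Applying it twice is a no-op.
#'
#' @param ds a \linkS4class{MalaniDataSet} with non-negative values.
#' @return the dataset with normalized columns and the \code{normalized}
#'   flag set.
#' @examples
#' m <- matrix(c(1, 3, 2, 2), 2, 2,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' ds <- MalaniDataSet(m, c("cancer", "normal"))
#' exprValues(normalizePerSample(ds))
#' @export
normalizePerSample <- function(ds) {
  m <- exprValues(ds)
  cs <- colSums(m)
  zero <- cs <= 0
  if (any(zero))
    stop("all-zero expression column(s): ",
         paste(colnames(m)[zero], collapse = ", "))
  MalaniDataSet(sweep(m, 2L, cs, "/"), as.character(sampleClasses(ds)),
                normalized = TRUE)
}
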