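test_that("pair products follow the forced arithmetic and commute", {
  ds <- tinyDataset()
  Q <- pairProductMatrix(ds, data.frame(gene_a = "g1", gene_b = "g2"))
  expect_equal(unname(pairValues(Q)[1, ]),
               unname(exprValues(ds)["g1", ] * exprValues(ds)["g2", ]))
  Qr <- pairProductMatrix(ds, data.frame(gene_a = "g2", gene_b = "g1"))
  expect_equal(unname(pairValues(Q)), unname(pairValues(Qr)))
  pairs <- data.frame(gene_a = c("g1", "g2"), gene_b = c("g2", "g3"))
  expect_equal(nrow(pairValues(pairProductMatrix(ds, pairs))), 2)
  expect_error(pairProductMatrix(ds, data.frame(gene_a = "g1",
                                                gene_b = "gX")),
               "unknown gene")
})

test_that("a class-indicator feature gives IG = 1 bit and SU = 1", {
  labels <- defaultLabels(10)
  v <- matrix(as.numeric(labels == "cancer"), 1, 20,
              dimnames = list("p1", NULL))
  Q <- new("PairMatrix", pairs = data.frame(gene_a = "a", gene_b = "b"),
           values = v)
  ig <- scoreFeatures(Q, labels, method = "IG")
  su <- scoreFeatures(Q, labels, method = "SU")
  expect_equal(unname(ig$score), 1, tolerance = 1e-12)
  expect_equal(unname(su$score), 1, tolerance = 1e-12)
})

test_that("a constant feature carries zero information and chance accuracy", {
  labels <- defaultLabels(10)
  v <- matrix(1, 1, 20, dimnames = list("p1", NULL))
  Q <- new("PairMatrix", pairs = data.frame(gene_a = "a", gene_b = "b"),
           values = v)
  expect_equal(unname(scoreFeatures(Q, labels, "IG")$score), 0)
  expect_equal(unname(scoreFeatures(Q, labels, "SU")$score), 0)
  folds <- stratifiedFolds(labels, k = 4, seed = 1)
  ia <- scoreFeatures(Q, labels, "IA", folds = folds)
  expect_equal(unname(ia$score), 0.5, tolerance = 0.1)
})

test_that("information gain matches brute-force contingency counting", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      x <- rnorm(40)
      labels <- sample(rep(c("cancer", "normal"), each = 20))
      v <- matrix(x, 1, 40, dimnames = list("p1", NULL))
      Q <- new("PairMatrix",
               pairs = data.frame(gene_a = "a", gene_b = "b"), values = v)
      ig <- unname(scoreFeatures(Q, labels, "IG")$score)
      bin <- malani:::.equalFreqBins(x, 10L)
      expect_equal(ig, oracleMutualInfo(bin, labels), tolerance = 1e-12)
    }
  })
})

test_that("informative features outrank noise for every scoring method", {
  withr::with_seed(22, {
    labels <- defaultLabels(20)
    sig <- ifelse(labels == "cancer", 2, 0) + rnorm(40, sd = 0.3)
    noise <- matrix(rnorm(40 * 9), 9, 40)
    v <- rbind(matrix(sig, 1, 40), noise)
    rownames(v) <- paste0("p", 1:10)
    Q <- new("PairMatrix",
             pairs = data.frame(gene_a = paste0("a", 1:10),
                                gene_b = paste0("b", 1:10)), values = v)
    folds <- stratifiedFolds(labels, k = 4, seed = 2)
    for (mth in c("IG", "SU", "ReliefF", "SVM_RFE", "IA")) {
      r <- scoreFeatures(Q, labels, mth, folds = folds)
      expect_equal(r$rank[1], 1L, info = mth)
      # ranks are a permutation with ties broken by pair order
      expect_setequal(r$rank, 1:10)
    }
  })
})

test_that("the ensemble vote counts per-method selections and thresholds", {
  # 10 pairs; construct rankings where pair 1 is in the top set of exactly
  # 3 methods and pair 2 of exactly 2 (top set size = ceiling(0.1 * 10) = 1
  # with top_frac = 0.1 -> use top_frac 0.2 for a 2-pair top set)
  mk <- function(best) {
    r <- seq_len(10)
    r[c(best, setdiff(1:10, best))] <- seq_len(10)
    o <- c(best, setdiff(1:10, best))
    rank <- integer(10); rank[o] <- seq_len(10)
    rank
  }
  rankings <- list(A = mk(c(1, 2)), B = mk(c(1, 2)), C = mk(c(1, 3)),
                   D = mk(c(3, 4)), E = mk(c(4, 5)))
  vote <- ensembleSelect(rankings, min_votes = 3, top_frac = 0.2)
  expect_equal(pairVotes(vote)[1], 3L)
  expect_equal(pairVotes(vote)[2], 2L)
  expect_true(pairVotes(vote)[1] >= vote@minVotes)   # selected
  expect_false(pairVotes(vote)[2] >= vote@minVotes)  # rejected
  # saturation: top_frac = 1 selects everything with 5 votes
  sat <- ensembleSelect(rankings, min_votes = 3, top_frac = 1)
  expect_true(all(pairVotes(sat) == 5L))
  expect_error(ensembleSelect(rankings, min_votes = 6), "min_votes")
})

test_that("vote selection is monotone in min_votes and top_frac", {
  withr::with_seed(23, {
    rankings <- lapply(1:5, function(i) sample(30))
    sel <- function(mv, tf)
      which(pairVotes(ensembleSelect(rankings, mv, tf)) >= mv)
    expect_true(all(sel(4, 0.2) %in% sel(3, 0.2)))
    expect_true(all(sel(3, 0.1) %in% sel(3, 0.3)))
  })
})

test_that("the network union of selected pairs has exactly those edges", {
  pairs <- data.frame(gene_a = c("a", "b"), gene_b = c("b", "c"))
  g <- assembleMIN(pairs, votes = c(3L, 5L))
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  expect_equal(unname(igraph::degree(g)["b"]), 2)
  expect_setequal(igraph::E(g)$votes, c(3L, 5L))
  empty <- assembleMIN(pairs[0, ])
  expect_equal(igraph::ecount(empty), 0)
})

test_that("the full ensemble stage only ever selects stage-2 pairs", {
  sim <- smallSim(seed = 13, G = 40, n_pairs = 2, n_up = 3, n_down = 3)
  ds <- normalizePerSample(sim$dataset)
  folds <- stratifiedFolds(sampleClasses(ds), k = 4, seed = 13)
  theta <- selectTheta(ds, folds, classifierSpec(), frac = 0.1)
  pl <- topPartners(ds, theta, folds, classifierSpec(), n = 5)
  s3 <- stage3Ensemble(ds, pl, folds, classifierSpec())
  expect_true(all(edgeKeys(s3$min) %in%
                    paste(pairTable(pl)$gene_a, pairTable(pl)$gene_b)))
  expect_true(all(igraph::E(s3$min)$votes >= 3))
  # pair-product rows reproduce from the dataset
  m <- exprValues(ds)
  p <- s3$Q@pairs
  for (r in seq_len(min(3, nrow(p))))
    expect_equal(unname(pairValues(s3$Q)[r, ]),
                 unname(m[p$gene_a[r], ] * m[p$gene_b[r], ]),
                 tolerance = 1e-12)
})
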