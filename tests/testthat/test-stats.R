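test_that("the Monte-Carlo interval follows alpha +/- 1.96 sqrt(a(1-a)/M)", {
  labels <- defaultLabels(5)
  # observed call first, then M permutation calls: script the returns
  mkStat <- function(obs, perms) {
    i <- 0L
    function(lab) {
      i <<- i + 1L
      if (i == 1L) obs else perms[i - 1L]
    }
  }
  # alpha = 0 with M = 20: interval collapses to [0, 0]
  r0 <- permutationTest(mkStat(1, rep(0, 20)), labels, M = 20, seed = 1)
  expect_equal(r0@alpha, 0)
  expect_equal(c(r0@ciLow, r0@ciHigh), c(0, 0))
  # alpha = 0.5 with M = 100: half-width 1.96 * sqrt(0.25 / 100) = 0.098
  r5 <- permutationTest(mkStat(1, rep(c(2, 0), 50)), labels, M = 100,
                        seed = 1)
  expect_equal(r5@alpha, 0.5)
  expect_equal(r5@ciLow, 0.5 - 0.098)
  expect_equal(r5@ciHigh, 0.5 + 0.098)
  # alpha = 0.5 with M = 20
  r20 <- permutationTest(mkStat(1, rep(c(2, 0), 10)), labels, M = 20,
                         seed = 1)
  expect_equal(r20@alpha, 0.5)
  expect_equal(r20@ciHigh - r20@ciLow, 2 * 1.96 * sqrt(0.25 / 20))
  # interval always contains alpha; width shrinks with M
  expect_true(r5@ciLow <= r5@alpha && r5@alpha <= r5@ciHigh)
  expect_lt(r5@ciHigh - r5@ciLow, r20@ciHigh - r20@ciLow)
  expect_error(permutationTest(function(lab) NaN, labels, M = 5, seed = 1),
               "non-finite")
})

test_that("permutations are label rearrangements, deterministic per seed", {
  labels <- defaultLabels(6)
  seen <- list()
  stat <- function(lab) { seen[[length(seen) + 1L]] <<- lab; 0 }
  permutationTest(stat, labels, M = 3, seed = 9)
  for (lab in seen[-1]) expect_equal(sort(lab), sort(labels))
  r1 <- permutationTest(function(l) sum(l == "cancer" & seq_along(l) < 6),
                        labels, M = 10, seed = 4)
  r2 <- permutationTest(function(l) sum(l == "cancer" & seq_along(l) < 6),
                        labels, M = 10, seed = 4)
  expect_identical(r1@permutedStats, r2@permutedStats)
})

test_that("row-wise t-tests agree with the textbook test to 1e-10", {
  withr::with_seed(41, {
    v <- matrix(rexp(100 * 20) + 0.1, 100, 20,
                dimnames = list(sprintf("g%03d", 1:100),
                                sprintf("s%02d", 1:20)))
    ds <- MalaniDataSet(v, defaultLabels(10))
    p <- perGenePvalues(ds)
    cancer <- sampleClasses(ds) == "cancer"
    for (g in rownames(v)) {
      ref <- stats::t.test(v[g, cancer], v[g, !cancer],
                           var.equal = TRUE)$p.value
      expect_equal(unname(p[g]), ref, tolerance = 1e-10)
    }
    pw <- perGenePvalues(ds, welch = TRUE)
    ref_w <- stats::t.test(v[1, cancer], v[1, !cancer])$p.value
    expect_equal(unname(pw[1]), ref_w, tolerance = 1e-10)
  })
})

test_that("extreme separation and degenerate rows behave as forced", {
  withr::with_seed(42, {
    v <- rbind(g1 = c(rnorm(10, 10, 0.1), rnorm(10, 1, 0.1)),
               g2 = rep(c(2, 2), 10),
               g3 = rnorm(20, 5, 1))
    colnames(v) <- sprintf("s%02d", 1:20)
  })
  ds <- MalaniDataSet(v, defaultLabels(10))
  expect_warning(p <- perGenePvalues(ds), "zero pooled variance")
  expect_lt(p["g1"], 1e-10)
  expect_equal(unname(p["g2"]), 1)
  expect_gt(p["g3"], 0.01)
})

test_that("null per-gene p-values are approximately uniform", {
  ks <- vapply(1:5, function(seed) {
    sim <- simulateExpression(simConfig(G = 300, n_up = 0, n_down = 0,
                                        n_pairs = 0, seed = seed))
    p <- perGenePvalues(normalizePerSample(sim$dataset))
    as.numeric(stats::ks.test(p, "punif")$statistic)
  }, numeric(1))
  expect_gte(sum(ks < 0.1), 4)
})

test_that("multiple-testing adjustments match their closed forms", {
  expect_equal(unname(adjustPvalues(c(0.01, 0.5, 0.6, 0.7, 0.8),
                                    "bonferroni")[1]), 0.05)
  expect_equal(unname(adjustPvalues(c(0.01, 0.02, 0.03), "bh")),
               c(0.03, 0.03, 0.03))
  withr::with_seed(43, {
    for (rep in 1:5) {
      p <- runif(37)
      expect_equal(adjustPvalues(p, "bh"), oracleBH(p), tolerance = 1e-12)
      expect_equal(adjustPvalues(p, "bonferroni"), pmin(1, p * 37),
                   tolerance = 1e-12)
      expect_true(all(adjustPvalues(p, "bh") >= p))
      expect_true(all(adjustPvalues(p, "bonferroni") >= p))
    }
  })
  expect_error(adjustPvalues(c(0.5, 1.2), "bh"), "0, 1")
})

test_that("enrichment reproduces expected counts, ratios and tail masses", {
  ref_genes <- sprintf("r%03d", 1:100)
  sets <- GeneSetCollection(list(C = ref_genes[1:20]), referenceSize = 100)
  query <- c(ref_genes[1:6], ref_genes[90:93])  # n = 10, k = 6
  res <- hypergeomEnrich(query, sets, mode = "none")
  expect_equal(res$k_expected, 2)   # (10 / 100) * 20
  expect_equal(res$r, 3)
  expect_equal(res$p_raw, oracleHyperUpper(6, 20, 100, 10),
               tolerance = 1e-12)
  # k = k_expected gives r = 1
  q2 <- c(ref_genes[1:2], ref_genes[50:57])
  expect_equal(hypergeomEnrich(q2, sets, mode = "none")$r, 1)
  # brute-force oracle across random small configurations (m <= 50)
  withr::with_seed(44, {
    for (rep in 1:20) {
      m <- sample(10:50, 1); j <- sample(2:(m - 2), 1)
      n <- sample(2:(m - 2), 1); ref <- sprintf("x%02d", 1:m)
      gs <- GeneSetCollection(list(C = ref[1:j]), referenceSize = m)
      q <- sample(ref, n)
      res <- hypergeomEnrich(q, gs, mode = "none")
      expect_equal(res$p_raw,
                   oracleHyperUpper(res$k_obs, j, m, n), tolerance = 1e-12)
    }
  })
})

test_that("enrichment filters implement the two significance rules", {
  ref <- sprintf("r%03d", 1:200)
  sets <- GeneSetCollection(
    c(list(big = ref[1:30], tiny = ref[31:33]),
      lapply(stats::setNames(1:12, paste0("s", 1:12)), function(i)
        ref[(40 + 3 * i):(49 + 3 * i)])),
    referenceSize = 200)
  query <- ref[c(1:10, 31:33)]
  res_min <- hypergeomEnrich(query, sets, mode = "min")
  expect_true(all(which(res_min$passes_filter) <= 10))
  expect_true(all(res_min$k_obs[res_min$passes_filter] >= 3))
  res_pie <- hypergeomEnrich(query, sets, mode = "piemin")
  expect_true(all(res_pie$p_adj[res_pie$passes_filter] < 0.05))
  expect_true(all(res_pie$k_obs[res_pie$passes_filter] >= 5))
  expect_equal(res_pie$p_adj, pmin(1, res_pie$p_raw * length(geneSets(sets))))
})

test_that("the hub connectivity test matches enumeration over fixed margins", {
  # a hub adjacent to all class II genes against a clean background
  net <- assembleMIN(data.frame(gene_a = "hub",
                                gene_b = paste0("c", 1:10)))
  classes <- data.frame(gene = c("hub", paste0("c", 1:10),
                                 paste0("z", 1:10)),
                        status = "not_de", fold_change = 1, degree = 0,
                        mutated = FALSE,
                        label = c("class_I", rep("class_II", 10),
                                  rep("class_I", 10)),
                        stringsAsFactors = FALSE)
  out <- fisherHubClass2(net, classes, background_size = 40)
  expect_equal(out$p, oracleFisherTwoSided(out$table), tolerance = 1e-10)
  expect_equal(unname(out$table[1, 1]), 10)
  # identical rows: no association, p = 1
  even <- matrix(c(5, 5, 5, 5), 2, 2)
  expect_equal(oracleFisherTwoSided(even), 1, tolerance = 1e-12)
  expect_equal(stats::fisher.test(even)$p.value, 1, tolerance = 1e-12)
  # random tables with totals <= 40 against the enumeration oracle
  withr::with_seed(45, {
    for (rep in 1:20) {
      tab <- matrix(sample(0:10, 4, replace = TRUE), 2, 2)
      if (sum(tab) == 0) next
      expect_equal(stats::fisher.test(tab)$p.value,
                   oracleFisherTwoSided(tab), tolerance = 1e-10)
    }
  })
  expect_error(fisherHubClass2(net, classes, background_size = 5),
               "background_size")
})

test_that("the screening-stage model count follows the closed form", {
  expect_equal(modelCount(21, 10), 420)
  expect_equal(modelCount(20075, 10), 201693525)
  expect_gt(modelCount(20075, 10), 2e8)
  for (G in c(1, 50, 999)) for (k in c(1, 5, 10))
    expect_equal(modelCount(G, k), k * G * (1 + (G - 1) / 20))
})
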