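pathGraph <- function(nodes) {
  igraph::graph_from_data_frame(
    data.frame(from = nodes[-length(nodes)], to = nodes[-1]),
    directed = FALSE)
}

test_that("shortest paths report the node sequence and interior length", {
  g <- pathGraph(c("a", "b", "c", "d"))
  rec <- shortestPath(g, "a", "d")
  expect_equal(rec$status, "found")
  expect_equal(rec$path, c("a", "b", "c", "d"))
  expect_equal(rec$length, 2L)
  adj <- shortestPath(g, "a", "b")
  expect_equal(adj$length, 0L)
})

test_that("missing endpoints and disconnected pairs yield statuses", {
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "c"), to = c("b", "d")), directed = FALSE)
  expect_equal(shortestPath(g, "a", "z")$status, "endpoint_missing")
  expect_equal(shortestPath(g, "a", "c")$status, "disconnected")
})

test_that("equal-length paths break ties lexicographically", {
  # diamond: a-b-d and a-c-d; the b route sorts first
  g <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "b", "a", "c"), to = c("b", "d", "c", "d")),
    directed = FALSE)
  expect_equal(shortestPath(g, "a", "d")$path, c("a", "b", "d"))
})

test_that("path lengths equal breadth-first-search distances", {
  withr::with_seed(31, {
    for (rep in 1:100) {
      g <- randomConnectedGraph(n = sample(8:20, 1), p = 0.2,
                                seed = sample.int(1e6, 1))
      adj <- adjacencyList(g)
      nm <- igraph::V(g)$name
      ends <- sample(nm, 2)
      rec <- shortestPath(g, ends[1], ends[2])
      expect_equal(rec$status, "found")
      expect_equal(length(rec$path) - 1L,
                   oracleBfsDistance(adj, ends[1], ends[2]))
      # consecutive nodes are edges; no repeats
      expect_false(anyDuplicated(rec$path) > 0)
      for (i in seq_len(length(rec$path) - 1L))
        expect_true(igraph::are_adjacent(g, rec$path[i], rec$path[i + 1]))
    }
  })
})

test_that("the expansion unions endpoints with interior path nodes", {
  ppi <- pathGraph(c("a", "b", "c", "d"))
  min_net <- assembleMIN(data.frame(gene_a = "a", gene_b = "d"))
  pm <- buildPieMin(min_net, ppi)
  expect_setequal(igraph::V(pieminGraph(pm))$name, c("a", "b", "c", "d"))
  expect_equal(unname(nodeFrequency(pm)[c("b", "c")]), c(1L, 1L))
  expect_equal(unname(nodeFrequency(pm)[c("a", "d")]), c(0L, 0L))
  # endpoints switchable into the counts
  pm_e <- buildPieMin(min_net, ppi, count_endpoints = TRUE)
  expect_equal(unname(nodeFrequency(pm_e)["a"]), 1L)
})

test_that("shared interior nodes accumulate visit frequency", {
  ppi <- igraph::graph_from_data_frame(
    data.frame(from = c("a", "m", "c", "m", "x"),
               to = c("m", "b", "m", "d", "a")), directed = FALSE)
  min_net <- assembleMIN(data.frame(gene_a = c("a", "c"),
                                    gene_b = c("b", "d")))
  pm <- buildPieMin(min_net, ppi)
  expect_equal(unname(nodeFrequency(pm)["m"]), 2L)
  # directly adjacent pair adds only its edge
  min2 <- assembleMIN(data.frame(gene_a = "x", gene_b = "a"))
  pm2 <- buildPieMin(min2, ppi)
  expect_setequal(igraph::V(pieminGraph(pm2))$name, c("x", "a"))
  expect_equal(igraph::ecount(pieminGraph(pm2)), 1)
})

test_that("non-found pairs are excluded from the graph and frequencies", {
  ppi <- pathGraph(c("a", "b", "c"))
  min_net <- assembleMIN(data.frame(gene_a = c("a", "a"),
                                    gene_b = c("c", "zz")))
  pm <- buildPieMin(min_net, ppi)
  recs <- pathRecords(pm)
  expect_setequal(recs$status, c("found", "endpoint_missing"))
  expect_false("zz" %in% igraph::V(pieminGraph(pm))$name)
  # node set = endpoints of found pairs plus interior nodes, exactly
  expect_setequal(igraph::V(pieminGraph(pm))$name, c("a", "b", "c"))
})

test_that("the mutation landscape matches manual enumeration on a fixture", {
  # 12-node interaction network; expanded network covers g1..g6
  ppi <- igraph::graph_from_data_frame(
    data.frame(from = c("g1", "g2", "g3", "g4", "g5", "g1", "g7", "g8",
                        "g9", "g10", "g11"),
               to   = c("g2", "g3", "g4", "g5", "g6", "g7", "g8", "g9",
                        "g10", "g11", "g12")), directed = FALSE)
  min_net <- assembleMIN(data.frame(gene_a = c("g1", "g4"),
                                    gene_b = c("g3", "g6")))
  pm <- buildPieMin(min_net, ppi)
  muts <- MutationTable(data.frame(
    gene = c("g1", "g2", "g2", "g3", "g3", "g3", "g9"),
    mutation_type = c("missense", "missense", "silent", "missense",
                      "nonsense", "splicing", "missense")))
  land <- mutationLandscape(pm, muts, ppi)
  tc <- land$type_counts
  # g9 is outside the expanded network; missense genes inside: g1, g2, g3
  expect_equal(tc$n_genes[tc$mutation_type == "missense"], 3)
  # cumulative neighbors: degree(g1)=2, degree(g2)=2, degree(g3)=2 -> 6
  expect_equal(tc$cumulative_neighbors[tc$mutation_type == "missense"], 6)
  expect_equal(tc$n_genes[tc$mutation_type == "silent"], 1)
  expect_equal(land$multi_type_genes, "g3")  # three distinct types
})

test_that("cumulative neighbors sum interaction degrees per type", {
  ppi <- igraph::graph_from_data_frame(
    data.frame(from = c(rep("h1", 4), rep("h2", 7)),
               to = c(paste0("x", 1:4), paste0("y", 1:7))),
    directed = FALSE)
  min_net <- assembleMIN(data.frame(gene_a = "h1", gene_b = "x1"))
  pm0 <- buildPieMin(min_net, ppi)
  # force both hubs into the expanded network via a second pair
  min2 <- assembleMIN(data.frame(gene_a = c("h1", "h2"),
                                 gene_b = c("x1", "y1")))
  pm <- buildPieMin(min2, ppi)
  muts <- MutationTable(data.frame(gene = c("h1", "h2"),
                                   mutation_type = "missense"))
  land <- mutationLandscape(pm, muts, ppi)
  expect_equal(land$type_counts$cumulative_neighbors[1], 4 + 7)
})

test_that("the p-value filter keeps candidates above the third quartile", {
  ppi <- pathGraph(c("a", "b", "c", "d", "e"))
  min_net <- assembleMIN(data.frame(gene_a = c("a", "b"),
                                    gene_b = c("c", "e")))
  pm <- buildPieMin(min_net, ppi)
  classes <- data.frame(gene = c("a", "b", "c", "d", "e"),
                        status = c("up", "not_de", "not_de", "not_de",
                                   "down"),
                        fold_change = 1, degree = 1, mutated = FALSE,
                        label = c("class_I", "class_II", "class_II",
                                  "class_II", "class_I"),
                        stringsAsFactors = FALSE)
  pvals <- c(a = 0.9, b = 0.2, c = 0.6, d = 0.4, e = 0.05)
  land <- mutationLandscape(pm, MutationTable(), ppi, classes = classes,
                            pvals = pvals)
  # candidates: class_II or DE genes in the expanded network (all 5 here)
  expect_setequal(land$candidates, c("a", "b", "c", "d", "e"))
  expect_equal(land$q3, unname(quantile(pvals, 0.75)))
  expect_setequal(igraph::V(land$subnetwork)$name,
                  names(pvals)[pvals > land$q3])
})
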