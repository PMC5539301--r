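#' Shortest interaction path between two genes
#'
#' Unweighted shortest path in the interaction network (with unit edge
#' costs, Dijkstra's algorithm reduces to breadth-first search). Among
#' equal-length paths the lexicographically smallest node-name sequence is
#' returned, making the result deterministic. Missing endpoints and
#' disconnected pairs are reported through the \code{status} field rather
#' than as errors.
#'
#' @param ppi undirected \pkg{igraph} network with named vertices.
#' @param a,b endpoint gene identifiers.
#' @return list with \code{gene_a}, \code{gene_b}, \code{status} (one of
#'   \code{found}, \code{endpoint_missing}, \code{disconnected}),
#'   \code{path} (character node sequence from a to b, empty unless found)
#'   and \code{length} (interior node count, \code{NA} unless found).
#' @export
shortestPath <- function(ppi, a, b) {
  rec <- list(gene_a = a, gene_b = b, status = "found",
              path = character(0), length = NA_integer_)
  nodes <- igraph::V(ppi)$name
  if (!(a %in% nodes) || !(b %in% nodes)) {
    rec$status <- "endpoint_missing"
    return(rec)
  }
  sp <- suppressWarnings(
    igraph::all_shortest_paths(ppi, from = a, to = b, mode = "all"))
  paths <- sp$vpaths %||% sp$res
  if (length(paths) == 0L) {
    rec$status <- "disconnected"
    return(rec)
  }
  seqs <- lapply(paths, function(p) igraph::V(ppi)$name[as.integer(p)])
  if (length(seqs) > 1L) {
    tab <- as.data.frame(do.call(rbind, seqs), stringsAsFactors = FALSE)
    seqs <- seqs[do.call(order, tab)]
  }
  rec$path <- seqs[[1L]]
  rec$length <- length(rec$path) - 2L
  rec
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Expand an inferred network along shortest interaction paths
#'
#' For every edge of the inferred network, finds the shortest
#' protein-protein interaction path between its genes; the expanded network
#' is the union of the found pairs' endpoints with every node and edge on
#' those paths. Node visit frequencies count, for each gene, the shortest
#' paths passing through it (interior nodes only by default; endpoints are
#' included when \code{count_endpoints} is set). Pairs whose endpoints are
#' missing from the interaction network or disconnected are recorded with
#' their status and excluded from the graph and the frequencies.
#'
#' @param min_net \pkg{igraph} inferred network.
#' @param ppi \pkg{igraph} interaction network.
#' @param count_endpoints also count path endpoints in the visit
#'   frequencies.
#' @return a \linkS4class{PIEMIN}.
#' @export
buildPieMin <- function(min_net, ppi, count_endpoints = FALSE) {
  el <- igraph::as_edgelist(min_net)
  recs <- lapply(seq_len(nrow(el)), function(i)
    shortestPath(ppi, el[i, 1L], el[i, 2L]))
  paths_df <- data.frame(
    gene_a = vapply(recs, `[[`, character(1), "gene_a"),
    gene_b = vapply(recs, `[[`, character(1), "gene_b"),
    status = vapply(recs, `[[`, character(1), "status"),
    length = vapply(recs, `[[`, integer(1), "length"),
    path = vapply(recs, function(r) paste(r$path, collapse = "|"),
                  character(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  found <- recs[paths_df$status == "found"]
  freq_tab <- integer(0)
  edges <- matrix(character(0), 0, 2)
  nodes <- character(0)
  if (length(found)) {
    visits <- unlist(lapply(found, function(r) {
      if (count_endpoints) r$path
      else if (length(r$path) > 2L) r$path[-c(1L, length(r$path))]
      else character(0)
    }))
    nodes <- unique(unlist(lapply(found, `[[`, "path")))
    freq_tab <- table(factor(visits, levels = nodes))
    edges <- do.call(rbind, lapply(found, function(r) {
      p <- r$path
      cbind(p[-length(p)], p[-1L])
    }))
  }
  g <- if (length(nodes)) {
    igraph::simplify(igraph::graph_from_data_frame(
      as.data.frame(edges, stringsAsFactors = FALSE), directed = FALSE,
      vertices = nodes))
  } else igraph::make_empty_graph(0, directed = FALSE)
  freq <- stats::setNames(as.integer(freq_tab), nodes)
  new("PIEMIN", graph = g, nodeFrequency = freq, paths = paths_df)
}

#' Mutation landscape of an expanded network
#'
#' Per mutation type, the number of expanded-network genes carrying it and
#' the cumulative direct-neighbor count (the sum of interaction-network
#' degrees over those genes, multiplicity kept); the set of genes with at
#' least three distinct mutation types; per-class gene counts over the
#' network; and, when per-gene p-values are supplied, the subnetwork
#' induced by Class II-or-differentially-expressed genes whose p-value
#' exceeds the third quartile of that candidate list's p-values.
#'
#' @param pm a \linkS4class{PIEMIN}.
#' @param muts a \linkS4class{MutationTable}.
#' @param ppi the interaction network used for neighbor counts.
#' @param classes the \code{\link{classifyGenes}} table (optional; enables
#'   the class overlay and the subnetwork filter).
#' @param pvals named per-gene p-values (optional).
#' @return list with \code{type_counts} (data.frame: \code{mutation_type},
#'   \code{n_genes}, \code{cumulative_neighbors}), \code{multi_type_genes},
#'   \code{class_counts}, \code{candidates}, \code{q3} and
#'   \code{subnetwork} (\pkg{igraph} or \code{NULL}).
#' @export
mutationLandscape <- function(pm, muts, ppi, classes = NULL, pvals = NULL) {
  genes <- igraph::V(pieminGraph(pm))$name
  rec <- mutationRecords(muts)
  rec <- rec[rec$gene %in% genes, , drop = FALSE]
  deg <- igraph::degree(ppi)
  types <- mutationVocabulary()
  types <- unique(c(types[types %in% rec$mutation_type],
                    setdiff(rec$mutation_type, types)))
  type_counts <- do.call(rbind, lapply(types, function(tp) {
    g <- unique(rec$gene[rec$mutation_type == tp])
    data.frame(mutation_type = tp, n_genes = length(g),
               cumulative_neighbors =
                 sum(deg[intersect(g, names(deg))]),
               stringsAsFactors = FALSE)
  }))
  if (is.null(type_counts))
    type_counts <- data.frame(mutation_type = character(0),
                              n_genes = integer(0),
                              cumulative_neighbors = integer(0))
  n_types <- tapply(rec$mutation_type, rec$gene,
                    function(v) length(unique(v)))
  multi <- names(n_types)[n_types >= 3L]
  class_counts <- NULL
  candidates <- character(0)
  q3 <- NA_real_
  subnet <- NULL
  if (!is.null(classes)) {
    cl_in <- classes[classes$gene %in% genes, , drop = FALSE]
    class_counts <- table(cl_in$label)
    candidates <- cl_in$gene[cl_in$label == "class_II" |
                               cl_in$status != "not_de"]
    if (!is.null(pvals) && length(candidates)) {
      pv <- pvals[candidates]
      pv <- pv[!is.na(pv)]
      if (length(pv)) {
        q3 <- as.numeric(quantile(pv, 0.75))
        keep <- names(pv)[pv > q3]
        subnet <- igraph::induced_subgraph(
          pieminGraph(pm), intersect(keep, genes))
      }
    }
  }
  list(type_counts = type_counts, multi_type_genes = sort(multi),
       class_counts = class_counts, candidates = candidates,
       q3 = q3, subnetwork = subnet)
}
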