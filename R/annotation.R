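#' Per-gene differential-expression status by fold change
#'
#' Class means are computed on the (normalized) intensities; a gene is
#' \code{up} when the cancer/normal mean ratio exceeds the threshold,
#' \code{down} when the normal/cancer ratio does, otherwise \code{not_de}.
#' Zero class means are guarded with a pseudo-count and a warning.
#'
#' @param ds a \linkS4class{MalaniDataSet}.
#' @param threshold positive fold-change threshold (default 1.5).
#' @param pseudo pseudo-count applied to zero class means.
#' @return data.frame with columns \code{gene}, \code{mean_cancer},
#'   \code{mean_normal}, \code{fold_change} (cancer over normal) and
#'   \code{status}.
#' @export
foldChangeStatus <- function(ds, threshold = 1.5, pseudo = 1e-12) {
  if (threshold <= 0) stop("threshold must be positive")
  m <- exprValues(ds)
  cancer <- sampleClasses(ds) == "cancer"
  mc <- rowMeans(m[, cancer, drop = FALSE])
  mn <- rowMeans(m[, !cancer, drop = FALSE])
  if (any(mc == 0 | mn == 0)) {
    warning("zero class mean(s); pseudo-count ", pseudo, " applied")
    mc <- mc + pseudo * (mc == 0)
    mn <- mn + pseudo * (mn == 0)
  }
  fc <- mc / mn
  status <- ifelse(fc > threshold, "up",
                   ifelse(1 / fc > threshold, "down", "not_de"))
  data.frame(gene = rownames(m), mean_cancer = mc, mean_normal = mn,
             fold_change = fc, status = status,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify genes as Class I, Class II or outside the network
#'
#' Class II genes reside in the inferred network but are neither
#' differentially expressed (by the fold-change criterion) nor mutated —
#' the candidate coordinator genes. Class I genes reside in the network and
#' are differentially expressed and/or mutated. Genes absent from the
#' network are \code{outside_network} regardless of status.
#'
#' @param min_net \pkg{igraph} inferred network.
#' @param de the \code{\link{foldChangeStatus}} table (defines the genome).
#' @param muts a \linkS4class{MutationTable} (may be empty).
#' @return data.frame with columns \code{gene}, \code{status},
#'   \code{fold_change}, \code{degree}, \code{mutated}, \code{label}, plus
#'   attribute \code{summary} (named counts and the fraction of non-DE
#'   genes labelled Class II).
#' @export
classifyGenes <- function(min_net, de,
                          muts = MutationTable()) {
  in_net <- de$gene %in% igraph::V(min_net)$name
  deg <- integer(nrow(de))
  deg[in_net] <- igraph::degree(min_net)[de$gene[in_net]]
  mutated <- de$gene %in% mutatedGenes(muts)
  is_de <- de$status != "not_de"
  label <- ifelse(!in_net, "outside_network",
                  ifelse(!is_de & !mutated, "class_II", "class_I"))
  out <- data.frame(gene = de$gene, status = de$status,
                    fold_change = de$fold_change, degree = deg,
                    mutated = mutated, label = label,
                    row.names = NULL, stringsAsFactors = FALSE)
  n_not_de <- sum(!is_de)
  attr(out, "summary") <- c(
    n_class_I = sum(label == "class_I"),
    n_class_II = sum(label == "class_II"),
    n_outside = sum(label == "outside_network"),
    frac_not_de_class_II =
      if (n_not_de > 0) sum(label == "class_II") / n_not_de else 0)
  out
}

#' Hub genes of a network
#'
#' Hubs are nodes whose connectivity exceeds 5 under the default, i.e.
#' degree at least \code{min_connectivity}.
#'
#' @param net an \pkg{igraph} graph.
#' @param min_connectivity minimal degree of a hub (default 6).
#' @return character vector of hub genes.
#' @export
findHubs <- function(net, min_connectivity = 6L) {
  if (igraph::vcount(net) == 0L) return(character(0))
  deg <- igraph::degree(net)
  names(deg)[deg >= min_connectivity]
}

#' Cross-network union and sharing tables
#'
#' Unifies several inferred networks into one graph, recording for each
#' node and edge which input networks contain it, and tabulates genes and
#' edges present in at least t networks for every t from 2 to the input
#' count.
#'
#' @param mins named list of \pkg{igraph} networks.
#' @return list with \code{graph} (union, with \code{presence} counts on
#'   nodes and edges), \code{node_presence} and \code{edge_presence}
#'   data.frames, and \code{shared_genes} / \code{shared_edges} lists
#'   indexed by \code{t}.
#' @export
crossCancerUnion <- function(mins) {
  stopifnot(length(mins) >= 1L)
  if (is.null(names(mins)) || any(names(mins) == ""))
    names(mins) <- paste0("network_", seq_along(mins))
  node_sets <- lapply(mins, function(g) igraph::V(g)$name)
  edge_sets <- lapply(mins, function(g) {
    if (igraph::ecount(g) == 0L) return(character(0))
    el <- igraph::as_edgelist(g)
    paste(pmin(el[, 1L], el[, 2L]), pmax(el[, 1L], el[, 2L]), sep = "\r")
  })
  all_nodes <- sort(unique(unlist(node_sets)))
  all_edges <- sort(unique(unlist(edge_sets)))
  node_count <- vapply(all_nodes, function(v)
    sum(vapply(node_sets, function(s) v %in% s, logical(1))), integer(1))
  edge_count <- vapply(all_edges, function(e)
    sum(vapply(edge_sets, function(s) e %in% s, logical(1))), integer(1))
  node_presence <- data.frame(gene = all_nodes, n_networks = node_count,
                              row.names = NULL, stringsAsFactors = FALSE)
  ep <- if (length(all_edges)) do.call(rbind, strsplit(all_edges, "\r"))
        else matrix(character(0), 0, 2)
  edge_presence <- data.frame(gene_a = ep[, 1L], gene_b = ep[, 2L],
                              n_networks = edge_count,
                              row.names = NULL, stringsAsFactors = FALSE)
  N <- length(mins)
  shared_genes <- lapply(2:max(2L, N), function(t)
    node_presence$gene[node_presence$n_networks >= t])
  names(shared_genes) <- paste0("t", 2:max(2L, N))
  shared_edges <- lapply(2:max(2L, N), function(t)
    edge_presence[edge_presence$n_networks >= t, , drop = FALSE])
  names(shared_edges) <- paste0("t", 2:max(2L, N))
  g <- if (nrow(edge_presence)) {
    gg <- igraph::graph_from_data_frame(
      edge_presence[, c("gene_a", "gene_b")], directed = FALSE,
      vertices = node_presence$gene)
    igraph::set_edge_attr(gg, "presence", value = edge_presence$n_networks)
  } else {
    igraph::make_empty_graph(0, directed = FALSE) +
      igraph::vertices(node_presence$gene)
  }
  g <- igraph::set_vertex_attr(
    g, "presence",
    value = node_presence$n_networks[match(igraph::V(g)$name,
                                           node_presence$gene)])
  list(graph = g, node_presence = node_presence,
       edge_presence = edge_presence, shared_genes = shared_genes,
       shared_edges = shared_edges)
}
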