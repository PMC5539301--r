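#' @importFrom utils read.delim write.table
NULL

#' Read a gene x sample expression matrix from TSV
#'
#' Dialect: tab-separated, header row of sample identifiers, first column of
#' gene identifiers, decimal floats. Rows sharing a gene identifier (e.g.
#' several probesets mapped to the same gene upstream) are averaged with a
#' warning rather than rejected.
#'
#' @param expression_path path to the expression TSV.
#' @param labels_path path to a two-column (sample, label) TSV, no header
#'   required; labels are case-insensitive \code{cancer}/\code{normal}.
#' @return a \linkS4class{MalaniDataSet} (unnormalized).
#' @export
readExpression <- function(expression_path, labels_path) {
  tab <- read.delim(expression_path, header = TRUE, sep = "\t",
                    check.names = FALSE, stringsAsFactors = FALSE)
  gid <- as.character(tab[[1L]])
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (anyDuplicated(gid)) {
    warning("duplicate gene identifiers averaged: ",
            paste(unique(gid[duplicated(gid)]), collapse = ", "))
    m <- rowsum(m, group = gid, reorder = FALSE)
    counts <- as.vector(table(factor(gid, levels = rownames(m))))
    m <- m / counts
    gid <- rownames(m)
  }
  rownames(m) <- gid
  labels <- readLabels(labels_path)
  missing <- setdiff(names(labels), colnames(m))
  if (length(missing))
    stop("samples in labels missing from matrix: ",
         paste(missing, collapse = ", "))
  MalaniDataSet(m[, names(labels), drop = FALSE], labels)
}

#' Read per-sample class labels
#'
#' @param path two-column TSV (sample identifier, label); a header line is
#'   tolerated and detected by its second field not being a known label.
#' @return named character vector of lower-case labels.
#' @export
readLabels <- function(path) {
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("labels file must have two columns")
  if (nrow(tab) && !tolower(tab[1L, 2L]) %in% c("cancer", "normal") &&
      tolower(tab[1L, 2L]) %in% c("label", "class", "condition"))
    tab <- tab[-1L, , drop = FALSE]
  lab <- tolower(as.character(tab[[2L]]))
  bad <- setdiff(unique(lab), c("cancer", "normal"))
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (expected 'cancer' or 'normal')")
  stats::setNames(lab, as.character(tab[[1L]]))
}

#' Write an expression matrix and labels as TSV
#'
#' @param ds a \linkS4class{MalaniDataSet}.
#' @param expression_path,labels_path output paths.
#' @export
writeExpression <- function(ds, expression_path, labels_path = NULL) {
  m <- exprValues(ds)
  out <- data.frame(gene = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  write.table(out, expression_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(labels_path)) {
    write.table(data.frame(sample = sampleIds(ds),
                           label = as.character(sampleClasses(ds))),
                labels_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(expression_path)
}

#' Read an undirected protein-protein interaction network
#'
#' Accepts SIF lines (\code{A pp B}, whitespace-separated, any relation
#' token) or a plain two-column edge list (TSV). Self-loops are dropped with
#' a warning; duplicate edges are merged.
#'
#' @param path input file.
#' @return an undirected, simple \pkg{igraph} graph with named vertices.
#' @export
readPPI <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[\t ]+")
  nfield <- lengths(parts)
  edges <- do.call(rbind, lapply(parts, function(p) {
    if (length(p) >= 3L) c(p[1L], p[3L]) else c(p[1L], p[2L])
  }))
  if (any(nfield < 2L)) stop("unparseable interaction line(s)")
  loops <- edges[, 1L] == edges[, 2L]
  if (any(loops)) {
    warning(sum(loops), " self-loop(s) dropped")
    edges <- edges[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network as a SIF file
#'
#' @param g an \pkg{igraph} graph with named vertices.
#' @param path output path.
#' @param relation the SIF relation token, default \code{"pp"}.
#' @export
writePPI <- function(g, path, relation = "pp") {
  el <- igraph::as_edgelist(g)
  writeLines(paste(el[, 1L], relation, el[, 2L], sep = "\t"), path)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT: one category per line, tab-separated fields name,
#' description, members.
#'
#' @param path GMT file path.
#' @param reference_size background gene count; defaults to the number of
#'   distinct genes in the collection.
#' @return a \linkS4class{GeneSetCollection}.
#' @export
readGMT <- function(path, reference_size = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, character(1), 1L)
  if (is.null(reference_size))
    reference_size <- length(unique(unlist(sets)))
  GeneSetCollection(sets, reference_size)
}

#' Write a gene-set collection as GMT
#'
#' @param gsc a \linkS4class{GeneSetCollection}.
#' @param path output path.
#' @export
writeGMT <- function(gsc, path) {
  writeLines(vapply(names(geneSets(gsc)), function(nm) {
    paste(c(nm, nm, geneSets(gsc)[[nm]]), collapse = "\t")
  }, character(1)), path)
  invisible(path)
}

#' Read a mutation catalogue
#'
#' @param path two-column TSV (gene, mutation_type); a header line is
#'   tolerated.
#' @param vocabulary admissible mutation types.
#' @param strict reject records with types outside the vocabulary.
#' @return a \linkS4class{MutationTable}.
#' @export
readMutations <- function(path, vocabulary = mutationVocabulary(),
                          strict = TRUE) {
  tab <- read.delim(path, header = FALSE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("mutation file must have two columns")
  if (nrow(tab) && tolower(tab[1L, 1L]) %in% c("gene", "gene_id"))
    tab <- tab[-1L, , drop = FALSE]
  MutationTable(data.frame(gene = tab[[1L]], mutation_type = tab[[2L]]),
                vocabulary = vocabulary, strict = strict)
}

#' Write a mutation catalogue as TSV
#'
#' @param muts a \linkS4class{MutationTable}.
#' @param path output path.
#' @export
writeMutations <- function(muts, path) {
  write.table(mutationRecords(muts), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load every input of a full analysis
#'
#' @param expression_path,labels_path required expression matrix and labels.
#' @param ppi_path,gmt_path,mutations_path optional network, gene sets and
#'   mutation catalogue; absent files yield \code{NULL} fields.
#' @return list with elements \code{dataset}, \code{ppi}, \code{gene_sets},
#'   \code{mutations}.
#' @export
loadInputs <- function(expression_path, labels_path, ppi_path = NULL,
                       gmt_path = NULL, mutations_path = NULL) {
  list(dataset = readExpression(expression_path, labels_path),
       ppi = if (!is.null(ppi_path)) readPPI(ppi_path),
       gene_sets = if (!is.null(gmt_path)) readGMT(gmt_path),
       mutations = if (!is.null(mutations_path)) readMutations(mutations_path))
}

#' Write a network as a flat TSV edge list with attributes
#'
#' @param g an \pkg{igraph} graph; all edge attributes are emitted as
#'   columns after \code{gene_a}, \code{gene_b}.
#' @param path output path.
#' @export
writeEdgeTSV <- function(g, path) {
  el <- igraph::as_edgelist(g)
  out <- data.frame(gene_a = el[, 1L], gene_b = el[, 2L],
                    stringsAsFactors = FALSE)
  for (attr in igraph::edge_attr_names(g))
    out[[attr]] <- igraph::edge_attr(g, attr)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a network as GraphML
#'
#' @param g an \pkg{igraph} graph.
#' @param path output path.
#' @export
writeGraphML <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
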