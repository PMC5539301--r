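#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: 300 genes, 30
#' cancer and 30 normal samples, 10 up- and 10 down-regulated genes at a
#' 3-fold change, and 5 coordinator pairs with latent log-scale correlation
#' 0.9 that switches sign between conditions. Background intensities are
#' log-normal (log-mean 6, log-sd 0.5, arbitrary units).
#'
#' @param G gene count.
#' @param n_cancer,n_normal per-condition sample counts.
#' @param n_up,n_down counts of planted fold-change (Class I) genes.
#' @param fc planted fold change in cancer (up genes multiplied, down genes
#'   divided).
#' @param n_pairs planted coordinator pairs (Class II structure).
#' @param rho latent log-scale correlation magnitude within a coordinator
#'   pair, in (0, 1); positive in cancer, negative in normal.
#' @param noise_sd residual log-scale standard deviation of coordinator
#'   genes around their shared latent factor.
#' @param base_log_mean,base_log_sd background log-normal parameters.
#' @param seed integer seed; all randomness in the generators flows from it.
#' @return a validated configuration (class \code{SimConfig}).
#' @export
simConfig <- function(G = 300L, n_cancer = 30L, n_normal = 30L,
                      n_up = 10L, n_down = 10L, fc = 3.0, n_pairs = 5L,
                      rho = 0.9, noise_sd = 0.25, base_log_mean = 6,
                      base_log_sd = 0.5, seed = 1L) {
  cfg <- list(G = as.integer(G), n_cancer = as.integer(n_cancer),
              n_normal = as.integer(n_normal), n_up = as.integer(n_up),
              n_down = as.integer(n_down), fc = fc,
              n_pairs = as.integer(n_pairs), rho = rho, noise_sd = noise_sd,
              base_log_mean = base_log_mean, base_log_sd = base_log_sd,
              seed = as.integer(seed))
  if (2L * cfg$n_pairs + cfg$n_up + cfg$n_down > cfg$G)
    stop("2*n_pairs + n_up + n_down must not exceed G")
  if (cfg$rho <= 0 || cfg$rho >= 1) stop("rho must lie in (0, 1)")
  if (any(unlist(cfg[c("G", "n_cancer", "n_normal", "n_up", "n_down",
                       "n_pairs")]) < 0L))
    stop("counts must be non-negative")
  if (cfg$fc <= 0 || cfg$noise_sd < 0 || cfg$base_log_sd <= 0)
    stop("fc and base_log_sd must be positive, noise_sd non-negative")
  structure(cfg, class = "SimConfig")
}

#' Simulate a labelled expression dataset with planted structure
#'
#' Background genes are i.i.d. log-normal and identical across conditions.
#' Up/down genes have their log-mean shifted by +/- log(fc) in cancer.
#' Each coordinator pair (a, b) shares a per-sample latent factor z: both
#' genes load +z in cancer while gene b loads -z in normal, so each gene's
#' marginal distribution is exactly matched across conditions (z is
#' symmetric) while the per-sample product a*b carries the class signal —
#' primarily as a dispersion difference at moderate n, and as a mean shift
#' (factor exp(2*lambda^2)) visible at large n. Loadings are
#' \code{lambda = noise_sd * sqrt(rho / (1 - rho))} so the within-pair
#' log-scale correlation is +rho in cancer and -rho in normal. Values are
#' exponentiated to keep positive support. Planted genes are placed at
#' seed-determined random positions.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{dataset} (unnormalized
#'   \linkS4class{MalaniDataSet}) and \code{truth} (list with
#'   \code{up_genes}, \code{down_genes}, \code{coordinator_pairs} — a
#'   data.frame with columns \code{gene_a}, \code{gene_b} — and
#'   \code{coordinator_genes}).
#' @examples
#' sim <- simulateExpression(simConfig(G = 40, n_pairs = 2, n_up = 3,
#'                                     n_down = 3, seed = 7))
#' sim$truth$coordinator_pairs
#' @export
simulateExpression <- function(cfg = simConfig()) {
  stopifnot(inherits(cfg, "SimConfig"))
  G <- cfg$G; S <- cfg$n_cancer + cfg$n_normal
  gene_ids <- sprintf("gene%0*d", nchar(G), seq_len(G))
  sample_ids <- c(sprintf("cancer_%02d", seq_len(cfg$n_cancer)),
                  sprintf("normal_%02d", seq_len(cfg$n_normal)))
  labels <- rep(c("cancer", "normal"), c(cfg$n_cancer, cfg$n_normal))
  lambda <- cfg$noise_sd * sqrt(cfg$rho / (1 - cfg$rho))
  withr::with_seed(cfg$seed, {
    n_special <- 2L * cfg$n_pairs + cfg$n_up + cfg$n_down
    special <- sample(G, n_special)
    coord_idx <- if (cfg$n_pairs > 0)
      matrix(special[seq_len(2L * cfg$n_pairs)], ncol = 2L, byrow = TRUE)
    else matrix(integer(0), ncol = 2L)
    up_idx <- special[2L * cfg$n_pairs + seq_len(cfg$n_up)]
    down_idx <- special[2L * cfg$n_pairs + cfg$n_up + seq_len(cfg$n_down)]
    logm <- matrix(stats::rnorm(G * S, cfg$base_log_mean, cfg$base_log_sd),
                   G, S)
    cancer <- labels == "cancer"
    if (cfg$n_up > 0)
      logm[up_idx, cancer] <- logm[up_idx, cancer] + log(cfg$fc)
    if (cfg$n_down > 0)
      logm[down_idx, cancer] <- logm[down_idx, cancer] - log(cfg$fc)
    for (p in seq_len(cfg$n_pairs)) {
      a <- coord_idx[p, 1L]; b <- coord_idx[p, 2L]
      z <- stats::rnorm(S)
      sgn <- ifelse(cancer, 1, -1)
      logm[a, ] <- cfg$base_log_mean + lambda * z +
        cfg$noise_sd * stats::rnorm(S)
      logm[b, ] <- cfg$base_log_mean + lambda * z * sgn +
        cfg$noise_sd * stats::rnorm(S)
    }
  })
  values <- exp(logm)
  dimnames(values) <- list(gene_ids, sample_ids)
  truth <- list(
    up_genes = gene_ids[up_idx],
    down_genes = gene_ids[down_idx],
    coordinator_pairs = data.frame(
      gene_a = gene_ids[coord_idx[, 1L]],
      gene_b = gene_ids[coord_idx[, 2L]],
      stringsAsFactors = FALSE),
    coordinator_genes = gene_ids[as.vector(t(coord_idx))])
  list(dataset = MalaniDataSet(values, labels), truth = truth)
}

#' Simulate a connected scale-free interaction network
#'
#' Preferential attachment (Barabasi-Albert) over all gene identifiers,
#' which guarantees a connected graph with a heavy-tailed degree
#' distribution. The highest-degree nodes are reported as mediator
#' candidates (nodes likely to sit on many shortest paths).
#'
#' @param gene_ids vertex names (one per gene).
#' @param attach_m edges attached per new node (>= 1).
#' @param seed integer seed.
#' @param n_mediators how many top-degree nodes to report.
#' @return list with \code{graph} (undirected \pkg{igraph}) and
#'   \code{mediator_nodes}.
#' @export
simulatePPI <- function(gene_ids, attach_m = 2L, seed = 1L,
                        n_mediators = 5L) {
  n <- length(gene_ids)
  if (attach_m < 1L) stop("attach_m must be >= 1")
  if (n < attach_m + 1L) stop("need at least attach_m + 1 genes")
  g <- withr::with_seed(as.integer(seed),
    igraph::sample_pa(n, m = attach_m, directed = FALSE))
  g <- igraph::set_vertex_attr(g, "name", value = gene_ids)
  g <- igraph::simplify(g)
  deg <- igraph::degree(g)
  mediators <- names(sort(deg, decreasing = TRUE))[seq_len(min(n_mediators, n))]
  list(graph = g, mediator_nodes = mediators)
}

#' Simulate a mutation catalogue
#'
#' Each gene is mutated independently with probability \code{rate}; a
#' mutated gene receives 1-4 distinct types drawn from the vocabulary.
#' Genes listed in \code{exclude} (by construction, the coordinator genes,
#' so the planted Class II truth is preserved) are never mutated.
#'
#' @param genes candidate gene identifiers.
#' @param rate per-gene mutation probability in [0, 1].
#' @param exclude genes never to mutate.
#' @param vocabulary admissible mutation types.
#' @param seed integer seed.
#' @return a \linkS4class{MutationTable}.
#' @export
simulateMutations <- function(genes, rate = 0.1, exclude = character(0),
                              vocabulary = mutationVocabulary(), seed = 1L) {
  if (rate < 0 || rate > 1) stop("rate must lie in [0, 1]")
  genes <- setdiff(genes, exclude)
  withr::with_seed(as.integer(seed), {
    hit <- genes[stats::runif(length(genes)) < rate]
    recs <- lapply(hit, function(g) {
      k <- sample(1:4, 1L)
      data.frame(gene = g, mutation_type = sample(vocabulary, k),
                 stringsAsFactors = FALSE)
    })
  })
  if (length(recs) == 0L) return(MutationTable(vocabulary = vocabulary))
  MutationTable(do.call(rbind, recs), vocabulary = vocabulary)
}

#' Serialize simulation ground truth as JSON
#'
#' @param truth the \code{truth} element of
#'   \code{\link{simulateExpression}} (optionally augmented with
#'   \code{mediator_nodes}).
#' @param path output path.
#' @export
writeGroundTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Re-load serialized ground truth
#'
#' @param path JSON path written by \code{\link{writeGroundTruth}}.
#' @return the truth list with the same fields and types.
#' @export
readGroundTruth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(x$coordinator_pairs) && length(x$coordinator_pairs))
    x$coordinator_pairs <- as.data.frame(x$coordinator_pairs,
                                         stringsAsFactors = FALSE)
  x
}
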