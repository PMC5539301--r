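# Independent oracles used to cross-check package computations. These are
# deliberately naive implementations (queues, exhaustive enumeration,
# explicit contingency counting) kept separate from the code paths they
# verify.

# Breadth-first-search distance between two named vertices; adj is a named
# list of neighbor character vectors. NA when unreachable.
oracleBfsDistance <- function(adj, from, to) {
  if (from == to) return(0L)
  dist <- stats::setNames(0L, from)
  queue <- from
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!w %in% names(dist)) {
        dist[w] <- dist[[v]] + 1L
        if (w == to) return(dist[[w]])
        queue <- c(queue, w)
      }
    }
  }
  NA_integer_
}

adjacencyList <- function(g) {
  nm <- igraph::V(g)$name
  lapply(stats::setNames(seq_along(nm), nm), function(i)
    nm[as.integer(igraph::neighbors(g, i))])
}

# Upper-tail hypergeometric probability P(X >= k) by summing the mass
# term by term with explicit binomial coefficients.
oracleHyperUpper <- function(k, j, m, n) {
  i <- seq(from = k, to = min(j, n))
  if (k > min(j, n)) return(0)
  sum(choose(j, i) * choose(m - j, n - i)) / choose(m, n)
}

# Two-sided Fisher p for a 2x2 table by enumerating every table with the
# observed margins and summing the probabilities of tables no more likely
# than the observed one (the standard convention, with a small tolerance).
oracleFisherTwoSided <- function(tab) {
  r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L]); n <- sum(tab)
  amin <- max(0L, r1 + c1 - n); amax <- min(r1, c1)
  probs <- stats::dhyper(amin:amax, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1L, 1L], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Plug-in mutual information (bits) by explicit contingency counting over
# supplied bin and class assignments.
oracleMutualInfo <- function(bin, cls) {
  ub <- sort(unique(bin)); uc <- sort(unique(cls))
  n <- length(bin)
  mi <- 0
  for (b in ub) for (cl in uc) {
    nxy <- sum(bin == b & cls == cl)
    if (nxy > 0) {
      nx <- sum(bin == b); ny <- sum(cls == cl)
      mi <- mi + (nxy / n) * log2((nxy * n) / (nx * ny))
    }
  }
  mi
}

# Benjamini-Hochberg step-up adjusted values from the closed form:
# running minimum over the tail of p * m / rank.
oracleBH <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, cummin((p[o] * m / seq_len(m))[m:1])[m:1])
  out <- numeric(m); out[o] <- adj
  out
}

# A small connected random graph with named vertices.
randomConnectedGraph <- function(n, p = 0.15, seed = 1) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
  g <- igraph::set_vertex_attr(g, "name",
                               value = sprintf("n%02d", seq_len(n)))
  comp <- igraph::components(g)
  # stitch components together so BFS always has a target
  if (comp$no > 1L) {
    reps <- vapply(seq_len(comp$no), function(cc)
      which(comp$membership == cc)[1L], integer(1))
    extra <- cbind(reps[-length(reps)], reps[-1L])
    g <- igraph::add_edges(g, as.vector(t(extra)))
  }
  igraph::simplify(g)
}
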