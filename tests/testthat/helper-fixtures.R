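# Small in-code fixtures shared across test files.

tinyDataset <- function(values = NULL, labels = NULL) {
  if (is.null(values))
    values <- matrix(c(1, 3, 5,
                       2, 4, 6,
                       3, 5, 7,
                       4, 6, 8), nrow = 3,
                     dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  if (is.null(labels))
    labels <- c("cancer", "cancer", "normal", "normal")
  MalaniDataSet(values, labels)
}

# A clearly separable one-feature dataset: cancer samples at 10, normal at 0.
separableDataset <- function(n_per_class = 12) {
  v <- matrix(rep(c(10, 0), each = n_per_class), nrow = 1,
              dimnames = list("g1", sprintf("s%02d", seq_len(2 * n_per_class))))
  MalaniDataSet(v, rep(c("cancer", "normal"), each = n_per_class))
}

defaultLabels <- function(n_per_class = 12)
  rep(c("cancer", "normal"), each = n_per_class)

# Deterministic small simulated dataset for module tests.
smallSim <- function(seed = 1, G = 60, n_pairs = 2, n_up = 4, n_down = 4,
                     nc = 12, nn = 12) {
  simulateExpression(simConfig(G = G, n_cancer = nc, n_normal = nn,
                               n_up = n_up, n_down = n_down,
                               n_pairs = n_pairs, seed = seed))
}
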