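# Shared fixtures, memoized so expensive objects (featurization, small
# trained models) are built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Small but full-featured configuration used by most model-level tests.
tiny_config <- function(...) {
  synergy_config(max_atoms = 32L, cloud_len = 40L, d_l = 8L, gmlp_layers = 2L,
                 gmlp_dim = 16L, heads = 2L, d_k = 4L, d_v = 4L,
                 gcn_width = 8L, cloud_channels = c(3L, 8L, 16L),
                 cell_hidden = 32L, cell_dim = 16L, head_width = 32L, ...)
}

tiny_bundle <- function() {
  fixture("tiny_bundle", function() {
    make_dataset(synthetic_spec(n_drugs = 6L, n_cells = 5L, n_examples = 40L,
                                expr_factors = 8L, mut_genes = 30L, seed = 3L))
  })
}

tiny_fit <- function() {
  fixture("tiny_fit", function() {
    b <- tiny_bundle()
    m <- build_variant("MMFSyn", tiny_config(), bundle_dims(b))
    train_synergy(m, b, train_config(batch_size = 16L, epochs = 2L,
                                     patience = Inf, seed = 7L))
  })
}

# Erdos-Renyi adjacency with at least one edge; seeded.
random_adjacency <- function(n, p = 0.35, seed = 1L) {
  set.seed(seed)
  repeat {
    a <- matrix(0, n, n)
    up <- which(upper.tri(a))
    a[up] <- stats::rbinom(length(up), 1L, p)
    a <- a + t(a)
    if (sum(a) > 0) return(a)
  }
}

# Independent shortest-path oracle built on igraph.
bfs_distances <- function(adjacency) {
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected")
  igraph::distances(g)
}

numeric_gradient <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps
    x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}
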