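# Graph algebra for molecular graphs: k-hop power graphs, symmetric degree
# normalization, and block-diagonal assembly of drug-pair graphs.

check_adjacency <- function(adjacency) {
  if (!is.matrix(adjacency) || nrow(adjacency) != ncol(adjacency))
    stop("invalid graph: adjacency must be a square matrix")
  if (!all(adjacency %in% c(0, 1)))
    stop("invalid graph: adjacency must be binary")
  if (any(diag(adjacency) != 0))
    stop("invalid graph: adjacency diagonal must be zero")
  if (!isTRUE(all.equal(adjacency, t(adjacency))))
    stop("invalid graph: adjacency must be symmetric")
  invisible(adjacency)
}

#' Molecular graph
#'
#' A simple undirected graph over the heavy atoms of a molecule: a binary
#' symmetric adjacency matrix (an edge for every chemical bond, regardless of
#' bond order) and a per-atom feature matrix whose rows follow the atom
#' ordering of the SMILES parse (0-based atom indices map to rows 1..N).
#'
#' @param adjacency N x N binary symmetric matrix with zero diagonal.
#' @param node_features N x C numeric matrix of per-atom features.
#' @return An object of class `molgraph` with fields `adjacency`,
#'   `node_features` and `atom_count`.
#' @export
molgraph <- function(adjacency, node_features) {
  check_adjacency(adjacency)
  node_features <- as.matrix(node_features)
  if (nrow(node_features) != nrow(adjacency))
    stop("node_features must have one row per atom")
  structure(list(adjacency = adjacency, node_features = node_features,
                 atom_count = nrow(adjacency)), class = "molgraph")
}

#' @export
print.molgraph <- function(x, ...) {
  cat(sprintf("<molgraph> %d atoms, %d bonds, %d features/atom\n",
              x$atom_count, sum(x$adjacency) / 2, ncol(x$node_features)))
  invisible(x)
}

#' Power-graph adjacency
#'
#' Connects every pair of nodes whose shortest-path distance in the input
#' graph lies within the given order. With `mode = "cumulative"` (the default)
#' an order-k power graph has an edge for every pair at distance 1..k, so each
#' order is a standalone message-passing support that contains the original
#' bonds; with `mode = "exact"` only pairs at distance exactly k are
#' connected. Order 1 returns the input unchanged.
#'
#' @param adjacency N x N binary symmetric matrix, zero diagonal.
#' @param order integer in {1, 2, 3}.
#' @param mode `"cumulative"` (distance in \[1, order\]) or `"exact"`.
#' @return Binary symmetric adjacency of the power graph.
#' @export
power_adjacency <- function(adjacency, order, mode = c("cumulative", "exact")) {
  mode <- match.arg(mode)
  check_adjacency(adjacency)
  if (!order %in% 1:3) stop("order must be 1, 2 or 3")
  if (order == 1L) return(adjacency)
  # boolean matrix powers accumulate reachability within `order` steps
  reach <- adjacency
  step <- adjacency
  exact <- adjacency
  for (k in 2:order) {
    step <- (step %*% adjacency > 0) * 1
    exact <- step * (reach == 0)
    diag(exact) <- 0
    reach <- ((reach + step) > 0) * 1
  }
  diag(reach) <- 0
  out <- if (mode == "cumulative") reach else exact
  storage.mode(out) <- "double"
  out
}

#' Symmetric degree normalization of an adjacency matrix
#'
#' Computes D^{-1/2} A D^{-1/2} where D is the diagonal degree matrix, the
#' standard propagation support for graph convolution. No self-loops are added
#' unless `add_self_loops = TRUE` (in which case degrees count the loop).
#' Zero-degree nodes have their degree clamped to 1, leaving their row zero
#' instead of producing a division by zero.
#'
#' @param adjacency N x N binary symmetric matrix.
#' @param add_self_loops add identity before normalizing (common GCN variant;
#'   default `FALSE`, matching the plain D^{-1/2} A D^{-1/2} formula).
#' @return N x N numeric matrix with entries in \[0, 1\].
#' @export
normalize_adjacency <- function(adjacency, add_self_loops = FALSE) {
  check_adjacency(adjacency)
  a <- adjacency
  if (add_self_loops) a <- a + diag(nrow(a))
  deg <- pmax(rowSums(a), 1)
  dinv <- 1 / sqrt(deg)
  a * outer(dinv, dinv)
}

#' Normalized power-graph set
#'
#' The three message-passing supports used by the multiscale graph branch:
#' degree-normalized adjacencies of the order-1, order-2 and order-3 power
#' graphs of a molecular graph.
#'
#' @param adjacency N x N binary symmetric matrix.
#' @param mode power-graph convention, see [power_adjacency()].
#' @param add_self_loops see [normalize_adjacency()].
#' @return list with fields `a1`, `a2`, `a3` (normalized) and the raw binary
#'   power adjacencies `p1`, `p2`, `p3`.
#' @export
power_graph_set <- function(adjacency, mode = c("cumulative", "exact"),
                            add_self_loops = FALSE) {
  mode <- match.arg(mode)
  p1 <- power_adjacency(adjacency, 1L, mode)
  p2 <- power_adjacency(adjacency, 2L, mode)
  p3 <- power_adjacency(adjacency, 3L, mode)
  list(a1 = normalize_adjacency(p1, add_self_loops),
       a2 = normalize_adjacency(p2, add_self_loops),
       a3 = normalize_adjacency(p3, add_self_loops),
       p1 = p1, p2 = p2, p3 = p3)
}

#' Block-diagonal pair graph
#'
#' Assembles the drug-combination graph of two molecules: adjacencies on the
#' block diagonal (no cross-drug edges) and node features stacked vertically,
#' drug one first.
#'
#' @param g1,g2 [molgraph()] objects with equal feature width.
#' @return A [molgraph()] with `atom_count = N1 + N2`.
#' @export
pair_graph <- function(g1, g2) {
  if (!inherits(g1, "molgraph") || !inherits(g2, "molgraph"))
    stop("pair_graph expects two molgraph objects")
  if (ncol(g1$node_features) != ncol(g2$node_features))
    stop("feature-width mismatch between the two graphs")
  n1 <- g1$atom_count; n2 <- g2$atom_count
  a <- matrix(0, n1 + n2, n1 + n2)
  a[1:n1, 1:n1] <- g1$adjacency
  a[(n1 + 1):(n1 + n2), (n1 + 1):(n1 + n2)] <- g2$adjacency
  molgraph(a, rbind(g1$node_features, g2$node_features))
}
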