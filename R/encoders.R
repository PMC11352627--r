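# Public encoder operations. Each runs the same tape ops as the training
# pipeline, in evaluation mode, with explicitly supplied weights -- so the
# displayed equations of every branch can be checked against longhand
# dense-algebra computations on small inputs.

#' BiLSTM parameters
#'
#' @param in_dim input feature width.
#' @param d_l LSTM units per direction.
#' @param seed initialization seed.
#' @return list with `fw` and `bw` sublists (`Wx`, `Wh`, `b`).
#' @export
bilstm_params <- function(in_dim, d_l, seed = 1L) {
  with_seed(seed, list(fw = params_lstm_dir(in_dim, d_l),
                       bw = params_lstm_dir(in_dim, d_l), d_l = d_l))
}

#' Bidirectional LSTM encoding of an atom sequence
#'
#' Per-position concatenation of the forward and backward recurrent states:
#' width exactly `2 * d_l`.
#'
#' @param seq an [atom_sequence()] result or a plain N x C matrix.
#' @param params from [bilstm_params()].
#' @return N x 2d_l matrix.
#' @export
bilstm_encode <- function(seq, params) {
  x <- if (is.list(seq)) seq$features else seq
  if (!is.matrix(x) || nrow(x) < 1L) stop("empty sequence")
  n <- nrow(x)
  p <- list("b.lstm.fw.Wx" = params$fw$Wx, "b.lstm.fw.Wh" = params$fw$Wh,
            "b.lstm.fw.b" = params$fw$b, "b.lstm.bw.Wx" = params$bw$Wx,
            "b.lstm.bw.Wh" = params$bw$Wh, "b.lstm.bw.b" = params$bw$b)
  rt <- rt_new(p, new.env(parent = emptyenv()), FALSE)
  out <- fw_bilstm(rt, tp_const(rt$tp, x), n, n, prefix = "b.lstm")
  tp_val(rt$tp, out)
}

#' Gated-MLP block parameters
#'
#' @param d_in input width.
#' @param gmlp_dim channel-projection width (even; split in half by the gate).
#' @param L sequence length (token-mixing matrix is L x L).
#' @param seed initialization seed.
#' @return list with `U`, `bu`, `W`, `b`, `V`, `bv`.
#' @export
gmlp_params <- function(d_in, gmlp_dim, L, seed = 1L) {
  if (gmlp_dim %% 2L != 0L) stop("gmlp channel width must be even")
  with_seed(seed, list(U = init_glorot(d_in, gmlp_dim), bu = numeric(gmlp_dim),
                       W = matrix(stats::rnorm(L * L, 0, 1e-3), L, L),
                       b = rep(1, L),
                       V = init_glorot(gmlp_dim %/% 2L, d_in),
                       bv = numeric(d_in)))
}

#' One gated-MLP block with spatial gating unit
#'
#' Computes `Z = sigma(h U)`, splits Z channel-wise into halves Z1, Z2, gates
#' `s(Z) = Z1 * (W Z2 + b)` (W mixes across the N token positions), and
#' returns `Y = s(Z) V` (plus biases where supplied). The activation is GELU.
#'
#' @param h N x d input matrix.
#' @param params from [gmlp_params()] (d_in must equal `ncol(h)`, L = N).
#' @return N x d output matrix.
#' @export
gmlp_block <- function(h, params) {
  if (!is.matrix(h)) h <- as.matrix(h)
  if (ncol(params$U) %% 2L != 0L)
    stop("gmlp channel width must be even for the half/half gate split")
  if (nrow(params$W) != nrow(h))
    stop("token-mixing matrix W must be N x N for an N-row input")
  p <- list("g.gmlp1.U" = params$U, "g.gmlp1.bu" = params$bu,
            "g.gmlp1.W" = params$W, "g.gmlp1.b" = params$b,
            "g.gmlp1.V" = params$V, "g.gmlp1.bv" = params$bv)
  rt <- rt_new(p, new.env(parent = emptyenv()), FALSE)
  out <- fw_gmlp_stack(rt, tp_const(rt$tp, h), 1L, nrow(h), 1L, prefix = "g.gmlp")
  tp_val(rt$tp, out)
}

#' Multi-head attention parameters
#'
#' @param d token width.
#' @param heads,d_k,d_v heads and per-head query/key/value widths.
#' @param seed initialization seed.
#' @return list with `Wq`, `Wk`, `Wv`, `Wo` and the dimensions.
#' @export
mha_params <- function(d, heads = 4L, d_k = 32L, d_v = 32L, seed = 1L) {
  with_seed(seed, list(Wq = init_glorot(d, heads * d_k),
                       Wk = init_glorot(d, heads * d_k),
                       Wv = init_glorot(d, heads * d_v),
                       Wo = init_glorot(heads * d_v, d),
                       heads = as.integer(heads), d_k = as.integer(d_k),
                       d_v = as.integer(d_v)))
}

#' Multi-head self-attention fusion of two sequence features
#'
#' The two drug sequence features are added position-wise (`X_c = H_s1 +
#' H_s2`), passed through h-head scaled dot-product self-attention
#' (`softmax(Q K^T / sqrt(d_k)) V` per head), the heads concatenated and
#' projected by `W_o`, and the positions reduced to a vector. The attention
#' probabilities are attached as attribute `"attention"` (an
#' `N x N x heads` array; rows sum to one).
#'
#' @param h1,h2 N x d matrices (equal shapes).
#' @param params from [mha_params()].
#' @param pool `"max"` (default) or `"mean"` over positions; `"none"` returns
#'   the N x d token matrix.
#' @return fused feature vector (or matrix for `pool = "none"`), with the
#'   attention array attached.
#' @export
mha_fuse <- function(h1, h2, params, pool = c("max", "mean", "none")) {
  pool <- match.arg(pool)
  if (!identical(dim(h1), dim(h2)))
    stop("shape mismatch between the two sequence features")
  xc <- h1 + h2
  n <- nrow(xc)
  p <- list("f.mha.Wq" = params$Wq, "f.mha.Wk" = params$Wk,
            "f.mha.Wv" = params$Wv, "f.mha.Wo" = params$Wo)
  rt <- rt_new(p, new.env(parent = emptyenv()), FALSE)
  tp <- rt$tp
  xn <- tp_const(tp, xc)
  q <- fw_linear(rt, xn, "f.mha.Wq")
  k <- fw_linear(rt, xn, "f.mha.Wk")
  v <- fw_linear(rt, xn, "f.mha.Wv")
  core <- op_attn_core(tp, q, k, v, 1L, n, n, params$heads, params$d_k, params$d_v)
  probs <- attr(tp_val(tp, core), "probs")
  out <- fw_linear(rt, core, "f.mha.Wo")
  tokens <- tp_val(tp, out)
  res <- switch(pool,
                max = apply(tokens, 2L, max),
                mean = colMeans(tokens),
                none = tokens)
  attr(res, "attention") <- array(probs, dim = c(n, n, params$heads))
  res
}

#' One graph convolution layer
#'
#' `sigma(A_norm H W)` with ReLU activation, the elementary message-passing
#' step of the graph branch.
#'
#' @param a_norm N x N normalized support (see [normalize_adjacency()]).
#' @param h N x d node features.
#' @param w d x d' weight matrix.
#' @return N x d' matrix.
#' @export
gcn_layer <- function(a_norm, h, w) {
  if (ncol(a_norm) != nrow(h) || ncol(h) != nrow(w))
    stop("shape mismatch in gcn_layer: A is ", nrow(a_norm), "x", ncol(a_norm),
         ", H is ", nrow(h), "x", ncol(h), ", W is ", nrow(w), "x", ncol(w))
  rt <- rt_new(list(), new.env(parent = emptyenv()), FALSE)
  tp <- rt$tp
  out <- op_relu(tp, op_mm(tp, op_gcn_prop(tp, tp_const(tp, h), list(a_norm),
                                           nrow(h)), tp_const(tp, w)))
  tp_val(tp, out)
}

#' Multiscale GCN parameters
#'
#' Weights of the fixed three-part stack: three layers on the order-1 support,
#' two on the order-2 support, one on the order-3 support.
#'
#' @param in_dim node-feature width.
#' @param width output width of every layer.
#' @param seed initialization seed.
#' @return named weight list.
#' @export
multiscale_params <- function(in_dim, width = 64L, seed = 1L) {
  with_seed(seed, params_graph_encoder(list(atom_feat_dim = in_dim,
                                            gcn_width = width)))
}

#' Multiscale graph encoding of one molecule
#'
#' Runs the three GCN stacks on the order-1/2/3 power-graph supports,
#' concatenates the three per-node outputs and reduces them with global max
#' pooling to a fixed-length graph vector.
#'
#' @param graph a [molgraph()].
#' @param powers a [power_graph_set()] for the same graph.
#' @param params from [multiscale_params()].
#' @return numeric vector of length `3 * width`.
#' @export
multiscale_gcn <- function(graph, powers, params) {
  n <- graph$atom_count
  if (nrow(powers$a1) != n) stop("node-count mismatch between graph and supports")
  rt <- rt_new(params, new.env(parent = emptyenv()), FALSE)
  out <- fw_multiscale_gcn(rt, tp_const(rt$tp, graph$node_features),
                           list(powers$a1), list(powers$a2), list(powers$a3), n)
  as.numeric(tp_val(rt$tp, out))
}

#' Graph-branch encoding of a drug pair
#'
#' Ordered concatenation of the multiscale encodings of drug one, the
#' block-diagonal pair graph, and drug two (all three share one weight set).
#'
#' @param g_a,g_b,g_pair lists with `graph` and `powers` fields (as returned
#'   by [molecular_graph()]; `g_pair` built from [pair_graph()]).
#' @param params from [multiscale_params()].
#' @return numeric vector of length `3 * 3 * width`.
#' @export
graph_branch <- function(g_a, g_b, g_pair, params) {
  c(multiscale_gcn(g_a$graph, g_a$powers, params),
    multiscale_gcn(g_pair$graph, g_pair$powers, params),
    multiscale_gcn(g_b$graph, g_b$powers, params))
}

#' Point-cloud encoder parameters
#'
#' @param channels channel schedule; default `c(3, 32, 64, 128, 160)`.
#' @param kernel convolution kernel size (odd).
#' @param seed initialization seed.
#' @return named weight list plus the schedule.
#' @export
cloud_params <- function(channels = c(3L, 32L, 64L, 128L, 160L), kernel = 1L,
                         seed = 1L) {
  p <- with_seed(seed, params_cloud_encoder(list(cloud_channels = channels,
                                                 cloud_kernel = kernel)))
  attr(p, "channels") <- as.integer(channels)
  attr(p, "kernel") <- as.integer(kernel)
  p
}

#' Residual 1D-convolution embedding of an atomic point cloud
#'
#' Maps the n x 3 padded coordinates through the channel schedule
#' 3 -> 32 -> 64 -> 128 -> 160 (convolution, batch normalization, ReLU, with a
#' residual connection per stage) and pools over the n positions to a fixed
#' 160-vector. Runs in evaluation mode, so the output is deterministic.
#'
#' @param cloud a [point_cloud()] result or a plain n x 3 matrix.
#' @param params from [cloud_params()].
#' @param pool `"max"` (default) or `"mean"` over positions.
#' @return numeric vector of length `channels[length(channels)]`.
#' @export
pointcloud_encode <- function(cloud, params, pool = c("max", "mean")) {
  pool <- match.arg(pool)
  x <- if (is.list(cloud)) cloud$coords else cloud
  if (!is.matrix(x) || ncol(x) != attr(params, "channels")[1L])
    stop("point cloud must be n x ", attr(params, "channels")[1L])
  cfg <- list(cloud_channels = attr(params, "channels"),
              cloud_kernel = attr(params, "kernel"), cloud_pool = pool)
  rt <- rt_new(params, new.env(parent = emptyenv()), FALSE)
  out <- fw_cloud_stack(rt, tp_const(rt$tp, x), 1L, nrow(x), cfg)
  as.numeric(tp_val(rt$tp, out))
}

#' Cell-line encoder parameters
#'
#' @param k expression-factor width.
#' @param m mutation-gene width.
#' @param hidden hidden width of the feed-forward reduction.
#' @param out output (cell feature) width.
#' @param seed initialization seed.
#' @return named weight list plus the expected input widths.
#' @export
cell_params <- function(k, m, hidden = 256L, out = 128L, seed = 1L) {
  p <- with_seed(seed, params_cell_encoder(k + m, hidden, out))
  attr(p, "k") <- as.integer(k)
  attr(p, "m") <- as.integer(m)
  p
}

#' Cell-line feature encoding
#'
#' Concatenates the z-scored expression-factor vector with the binary mutation
#' vector and reduces the result with a feed-forward network:
#' `F_cell = FNN(G' || M)`.
#'
#' @param expr numeric vector of length k (z-scored factors).
#' @param mut 0/1 vector of length m.
#' @param params from [cell_params()].
#' @return numeric cell-feature vector.
#' @export
cell_encode <- function(expr, mut, params) {
  k <- attr(params, "k"); m <- attr(params, "m")
  if (length(expr) != k || length(mut) != m)
    stop("input width mismatch: expected k = ", k, ", m = ", m,
         ", got ", length(expr), " and ", length(mut))
  rt <- rt_new(params, new.env(parent = emptyenv()), FALSE)
  out <- fw_cell_ffn(rt, tp_const(rt$tp, matrix(c(expr, mut), 1L)), 2L)
  as.numeric(tp_val(rt$tp, out))
}

#' Column-wise z-score standardization
#'
#' Centers and scales each column to mean 0 and (population) standard
#' deviation 1; constant columns map to all zeros.
#'
#' @param m numeric matrix with finite entries.
#' @param axis 2 standardizes columns (the default; columns = factors),
#'   1 standardizes rows.
#' @return matrix of the same shape.
#' @export
zscore <- function(m, axis = 2L) {
  if (!is.matrix(m)) m <- as.matrix(m)
  if (length(m) == 0L) stop("empty matrix")
  if (any(!is.finite(m))) stop("non-finite entries")
  if (axis == 1L) return(t(zscore(t(m), 2L)))
  n <- nrow(m)
  mu <- colMeans(m)
  xc <- m - rep(mu, each = n)
  sd <- sqrt(colMeans(xc * xc))
  sd[sd == 0] <- Inf
  xc * rep(1 / sd, each = n)
}
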