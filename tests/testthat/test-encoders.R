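test_that("BiLSTM output width is twice the unit count and handles N = 1", {
  ps <- bilstm_params(in_dim = 5L, d_l = 7L, seed = 1L)
  x <- matrix(rnorm(15), 3, 5)
  h <- bilstm_encode(x, ps)
  expect_equal(dim(h), c(3L, 14L))
  h1 <- bilstm_encode(x[1, , drop = FALSE], ps)
  expect_equal(dim(h1), c(1L, 14L))
  expect_error(bilstm_encode(matrix(0, 0, 5), ps), "empty")
})

test_that("reversing the input swaps the forward/backward halves (tied weights)", {
  ps <- bilstm_params(in_dim = 4L, d_l = 3L, seed = 2L)
  ps$bw <- ps$fw   # tie the two directions
  x <- matrix(rnorm(20), 5, 4)
  fwd <- bilstm_encode(x, ps)
  rev_out <- bilstm_encode(x[5:1, , drop = FALSE], ps)
  expect_equal(rev_out[5:1, 1:3], fwd[, 4:6])
  expect_equal(rev_out[5:1, 4:6], fwd[, 1:3])
})

test_that("gated-MLP block computes the displayed composition", {
  set.seed(3)
  h <- matrix(rnorm(8), 2, 4)
  ps <- gmlp_params(d_in = 4L, gmlp_dim = 6L, L = 2L, seed = 3L)
  # W = 0, b = 1: the gate reduces to the identity on Z1, so Y = Z1 V + bv
  ps$W <- matrix(0, 2, 2); ps$b <- rep(1, 2)
  y <- gmlp_block(h, ps)
  z <- h %*% ps$U + rep(ps$bu, each = 2)
  z <- z * pnorm(z)   # GELU
  manual <- z[, 1:3] %*% ps$V + rep(ps$bv, each = 2)
  expect_equal(y, manual, tolerance = 1e-12)
  # U = 0: Z is the constant sigma(bu), so rows of the output are identical
  ps2 <- gmlp_params(4L, 6L, 2L, seed = 4L)
  ps2$U <- matrix(0, 4, 6)
  y2 <- gmlp_block(h, ps2)
  expect_equal(y2[1, ], y2[2, ])
})

test_that("gated-MLP toy input matches longhand evaluation of all three formulas", {
  h <- matrix(c(0.2, -0.1, 0.4, 0.3, -0.5, 0.1, 0.7, -0.2), 2, 4)
  ps <- gmlp_params(d_in = 4L, gmlp_dim = 4L, L = 2L, seed = 5L)
  y <- gmlp_block(h, ps)
  z <- h %*% ps$U + rep(ps$bu, each = 2)
  z <- z * pnorm(z)
  z1 <- z[, 1:2]; z2 <- z[, 3:4]
  s <- z1 * (ps$W %*% z2 + ps$b)
  manual <- s %*% ps$V + rep(ps$bv, each = 2)
  expect_equal(y, manual, tolerance = 1e-12)
  expect_error(gmlp_block(h, gmlp_params(4L, 6L, 3L)), "N x N")
})

test_that("attention weights are row-normalized and degenerate cases are exact", {
  set.seed(6)
  h1 <- matrix(rnorm(12), 3, 4)
  h2 <- matrix(rnorm(12), 3, 4)
  ps <- mha_params(d = 4L, heads = 2L, d_k = 3L, d_v = 3L, seed = 6L)
  out <- mha_fuse(h1, h2, ps)
  att <- attr(out, "attention")
  expect_equal(dim(att), c(3L, 3L, 2L))
  expect_equal(apply(att, c(1, 3), sum), matrix(1, 3, 2), tolerance = 1e-6)
  # zero query/key projections: uniform attention, rows become the value mean
  ps0 <- ps
  ps0$Wq <- ps$Wq * 0; ps0$Wk <- ps$Wk * 0
  toks <- mha_fuse(h1, h2, ps0, pool = "none")
  xc <- h1 + h2
  vbar <- colMeans(xc %*% ps0$Wv)
  manual <- matrix(vbar, 3, 6, byrow = TRUE) %*% ps0$Wo
  expect_equal(unclass(toks), manual, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(mha_fuse(h1, h2[1:2, ], ps), "shape")
})

test_that("single-head attention reproduces a longhand softmax(QK'/sqrt(dk))V", {
  h1 <- matrix(c(0.3, -0.2, 0.5, 0.1), 2, 2)
  h2 <- matrix(c(0.0, 0.4, -0.3, 0.2), 2, 2)
  ps <- mha_params(d = 2L, heads = 1L, d_k = 2L, d_v = 2L, seed = 7L)
  toks <- mha_fuse(h1, h2, ps, pool = "none")
  xc <- h1 + h2
  q <- xc %*% ps$Wq; k <- xc %*% ps$Wk; v <- xc %*% ps$Wv
  sc <- q %*% t(k) / sqrt(2)
  p <- exp(sc) / rowSums(exp(sc))
  manual <- (p %*% v) %*% ps$Wo
  expect_equal(unclass(toks), manual, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("gcn_layer is exactly relu(A_norm H W)", {
  c4 <- matrix(0, 4, 4)
  for (i in 1:4) { j <- i %% 4 + 1; c4[i, j] <- 1; c4[j, i] <- 1 }
  an <- normalize_adjacency(c4)
  h <- matrix(1, 4, 3)
  out <- gcn_layer(an, h, diag(3))
  expect_equal(out, matrix(1, 4, 3))          # regular graph: rows sum to 1
  expect_equal(gcn_layer(matrix(0, 2, 2), matrix(rnorm(4), 2, 2),
                         matrix(rnorm(4), 2, 2)), matrix(0, 2, 2))
  set.seed(8)
  a <- random_adjacency(5L, seed = 9L)
  an <- normalize_adjacency(a)
  h <- matrix(rnorm(15), 5, 3)
  w <- matrix(rnorm(6), 3, 2)
  expect_equal(gcn_layer(an, h, w), pmax(an %*% h %*% w, 0), tolerance = 1e-12)
  expect_error(gcn_layer(an, h, matrix(0, 2, 2)), "mismatch")
})

test_that("multiscale GCN pools to 3x width and is invariant to graph duplication", {
  ps <- multiscale_params(in_dim = 3L, width = 5L, seed = 10L)
  a <- random_adjacency(4L, seed = 11L)
  g <- molgraph(a, matrix(rnorm(12), 4, 3))
  pw <- power_graph_set(a)
  v <- multiscale_gcn(g, pw, ps)
  expect_length(v, 15L)
  # single node: no edges, zero propagation
  g1 <- molgraph(matrix(0, 1, 1), matrix(rnorm(3), 1, 3))
  v1 <- multiscale_gcn(g1, power_graph_set(matrix(0, 1, 1)), ps)
  expect_equal(v1, rep(0, 15L))
  # a disconnected duplicate of the same molecule leaves the pooled vector
  # unchanged (identical rows cannot raise a maximum)
  gp <- pair_graph(g, g)
  vp <- multiscale_gcn(gp, power_graph_set(gp$adjacency), ps)
  expect_equal(vp, v, tolerance = 1e-12)
})

test_that("graph_branch concatenates drug-1, pair, drug-2 and swaps with order", {
  ps <- multiscale_params(3L, 4L, seed = 12L)
  a1 <- random_adjacency(4L, seed = 13L)
  a2 <- random_adjacency(3L, seed = 14L)
  ga <- list(graph = molgraph(a1, matrix(rnorm(12), 4, 3)))
  gb <- list(graph = molgraph(a2, matrix(rnorm(9), 3, 3)))
  ga$powers <- power_graph_set(a1)
  gb$powers <- power_graph_set(a2)
  mk_pair <- function(x, y) {
    gp <- pair_graph(x$graph, y$graph)
    list(graph = gp, powers = power_graph_set(gp$adjacency))
  }
  hab <- graph_branch(ga, gb, mk_pair(ga, gb), ps)
  hba <- graph_branch(gb, ga, mk_pair(gb, ga), ps)
  expect_length(hab, 3L * 12L)
  expect_equal(hab[1:12], hba[25:36])
  expect_equal(hab[25:36], hba[1:12])
  expect_equal(hab[13:24], hba[13:24])  # pair encoding is order-insensitive here
})

test_that("point-cloud embedding has the 3->32->...->160 schedule and fixed output", {
  ps <- cloud_params(seed = 15L)
  expect_equal(nrow(ps[["cloud.s1.W"]]), 3L)
  expect_equal(ncol(ps[["cloud.s1.W"]]), 32L)
  expect_equal(ncol(ps[["cloud.s4.W"]]), 160L)
  x <- matrix(rnorm(30), 10, 3)
  v <- pointcloud_encode(x, ps)
  expect_length(v, 160L)
  z <- pointcloud_encode(matrix(0, 10, 3), ps)
  expect_true(all(is.finite(z)))
  expect_identical(z, pointcloud_encode(matrix(0, 10, 3), ps))
  # extra zero padding only adds duplicate zero-row positions; under max
  # pooling the embedding is unchanged
  small <- rbind(matrix(rnorm(15), 5, 3), matrix(0, 5, 3))
  bigger <- rbind(small[1:5, ], matrix(0, 15, 3))
  expect_equal(pointcloud_encode(small, ps), pointcloud_encode(bigger, ps))
  expect_error(pointcloud_encode(matrix(0, 5, 4), ps), "n x 3")
})

test_that("cell encoder enforces widths, is pure, and supports omics ablation", {
  ps <- cell_params(k = 6L, m = 10L, hidden = 8L, out = 5L, seed = 16L)
  expr <- rnorm(6)
  mut <- rbinom(10, 1, 0.3)
  f1 <- cell_encode(expr, mut, ps)
  expect_length(f1, 5L)
  expect_identical(f1, cell_encode(expr, mut, ps))
  expect_error(cell_encode(rnorm(5), mut, ps), "width mismatch")
  # with the mutation half zeroed the output depends only on expression
  z1 <- cell_encode(expr, mut * 0, ps)
  z2 <- cell_encode(expr, rep(0, 10), ps)
  expect_identical(z1, z2)
})

test_that("zscore standardizes columns with population sd", {
  z <- zscore(matrix(c(1, 2, 3), 3, 1))
  expect_equal(as.numeric(z), c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  zc <- zscore(cbind(c(1, 2, 3), c(5, 5, 5)))
  expect_equal(zc[, 2], rep(0, 3))
  set.seed(17)
  m <- matrix(rnorm(50, 3, 2), 10, 5)
  zm <- zscore(m)
  expect_true(all(abs(colMeans(zm)) < 1e-9))
  expect_equal(colMeans(zm^2), rep(1, 5), tolerance = 1e-9)
  expect_error(zscore(matrix(numeric(0), 0, 0)), "empty")
  expect_error(zscore(matrix(c(1, NA), 1, 2)), "finite")
})
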