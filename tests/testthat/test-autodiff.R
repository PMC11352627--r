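# The engine behind every trainable branch: analytic gradients of each tape
# op are checked against central finite differences.

sn <- asNamespace("synergynet")

grad_check <- function(build, x0, tol = 1e-6) {
  f <- function(x) {
    tp <- sn$tape_new()
    node <- build(tp, sn$tp_leaf(tp, x))
    sum(sn$tp_val(tp, node))
  }
  tp <- sn$tape_new()
  leaf <- sn$tp_leaf(tp, x0)
  node <- build(tp, leaf)
  sn$tape_backward(tp, sn$op_sum(tp, node))
  ga <- sn$tp_grad(tp, leaf)
  gn <- numeric_gradient(f, x0)
  expect_lt(max(abs(ga - gn)), tol)
}

test_that("elementary op gradients match finite differences", {
  set.seed(1)
  x <- matrix(rnorm(12), 3, 4)
  w <- matrix(rnorm(20), 4, 5)
  grad_check(function(tp, a) sn$op_mm(tp, a, sn$tp_const(tp, w)), x)
  grad_check(function(tp, a) sn$op_relu(tp, a), x)
  grad_check(function(tp, a) sn$op_gelu(tp, a), x)
  grad_check(function(tp, a) sn$op_sigmoid(tp, a), x)
  grad_check(function(tp, a) sn$op_tanh(tp, a), x)
  grad_check(function(tp, a) sn$op_softmax_rows(tp, a), x)
  grad_check(function(tp, a) sn$op_rows(tp, a, c(1L, 2L, 2L, 3L, 1L)), x)
  grad_check(function(tp, a) sn$op_cols(tp, a, c(2L, 4L)), x)
  grad_check(function(tp, a) sn$op_max_rows(tp, a), x)
  grad_check(function(tp, a) sn$op_group_max(tp, a, c(1L, 2L)), x)
  grad_check(function(tp, a) sn$op_mse(tp, a, c(1, 2, 3)), matrix(rnorm(3), 3, 1))
  bias <- rnorm(4)
  grad_check(function(tp, a) {
    b <- sn$op_mul(tp, a, sn$tp_const(tp, x * 2))
    sn$op_add_bias(tp, b, sn$tp_const(tp, bias))
  }, x)
})

test_that("graph propagation and attention-core gradients are exact", {
  set.seed(2)
  x <- matrix(rnorm(12), 3, 4)
  a1 <- matrix(c(0, 1, 1, 0), 2, 2)
  grad_check(function(tp, h)
    sn$op_gcn_prop(tp, h, list(a1, matrix(0.5, 1, 1)), c(2L, 1L)), x)
  q0 <- matrix(rnorm(24), 6, 4)
  k0 <- matrix(rnorm(24), 6, 4)
  v0 <- matrix(rnorm(24), 6, 4)
  for (role in c("q", "k", "v")) {
    grad_check(function(tp, leaf) {
      qq <- if (role == "q") leaf else sn$tp_const(tp, q0)
      kk <- if (role == "k") leaf else sn$tp_const(tp, k0)
      vv <- if (role == "v") leaf else sn$tp_const(tp, v0)
      sn$op_attn_core(tp, qq, kk, vv, 2L, 3L, 3L, 2L, 2L, 2L)
    }, switch(role, q = q0, k = k0, v = v0))
  }
})

test_that("spatial-mix and batch-normalization gradients are exact", {
  set.seed(3)
  z <- matrix(rnorm(16), 4, 4)
  wl <- matrix(rnorm(4), 2, 2)
  bl <- rnorm(2)
  grad_check(function(tp, a)
    sn$op_spatial_mix(tp, a, sn$tp_const(tp, wl), sn$tp_const(tp, bl), 2L, 2L), z)
  grad_check(function(tp, a)
    sn$op_spatial_mix(tp, sn$tp_const(tp, z), a, sn$tp_const(tp, bl), 2L, 2L), wl)
  x <- matrix(rnorm(12), 3, 4)
  wmat <- matrix(rnorm(12), 3, 4)
  rs <- list(mean = rnorm(4) * 0.1, var = runif(4, 0.5, 2))
  for (training in c(TRUE, FALSE)) {
    grad_check(function(tp, a) {
      st <- new.env()
      if (!training) st[["k"]] <- rs
      bn <- sn$op_batchnorm(tp, a, sn$tp_const(tp, rep(1.5, 4)),
                            sn$tp_const(tp, rep(0.2, 4)), st, "k", training)
      sn$op_mul(tp, bn, sn$tp_const(tp, wmat))
    }, x, tol = 1e-5)
  }
})

test_that("fused BiLSTM gradients match finite differences under padding", {
  set.seed(4)
  nb <- 2L; L <- 4L; C <- 3L; H <- 2L
  lens <- c(4L, 2L)
  x <- matrix(rnorm(nb * L * C), nb * L, C)
  x[7:8, ] <- 0
  ps <- sn$with_seed(5, list(
    wxf = sn$init_glorot(C, 4 * H), whf = sn$init_glorot(H, 4 * H), bf = rnorm(4 * H),
    wxb = sn$init_glorot(C, 4 * H), whb = sn$init_glorot(H, 4 * H), bb = rnorm(4 * H)))
  wout <- matrix(rnorm(nb * L * 2 * H), nb * L, 2 * H)
  f <- function(ps, xx = x) {
    tp <- sn$tape_new()
    nd <- sn$op_bilstm(tp, sn$tp_const(tp, xx), lens, L,
                       sn$tp_leaf(tp, ps$wxf), sn$tp_leaf(tp, ps$whf),
                       sn$tp_leaf(tp, ps$bf), sn$tp_leaf(tp, ps$wxb),
                       sn$tp_leaf(tp, ps$whb), sn$tp_leaf(tp, ps$bb))
    sum(sn$tp_val(tp, nd) * wout)
  }
  tp <- sn$tape_new()
  xn <- sn$tp_leaf(tp, x)
  leaves <- lapply(ps, function(p) sn$tp_leaf(tp, p))
  nd <- sn$op_bilstm(tp, xn, lens, L, leaves$wxf, leaves$whf, leaves$bf,
                     leaves$wxb, leaves$whb, leaves$bb)
  sn$tape_backward(tp, sn$op_sum(tp, sn$op_mul(tp, nd, sn$tp_const(tp, wout))))
  for (nm in names(ps)) {
    ga <- sn$tp_grad(tp, leaves[[nm]])
    gn <- numeric_gradient(function(p) {
      ps2 <- ps; ps2[[nm]] <- p; f(ps2)
    }, ps[[nm]])
    expect_lt(max(abs(ga - gn)), 1e-6)
  }
  gx <- sn$tp_grad(tp, xn)
  gnx <- numeric_gradient(function(xx) f(ps, xx), x)
  expect_lt(max(abs(gx - gnx)), 1e-6)
})

test_that("masked batched BiLSTM equals exact-length processing", {
  set.seed(6)
  C <- 3L; H <- 2L; L <- 5L
  lens <- c(5L, 3L)
  x <- matrix(rnorm(2 * L * C), 2 * L, C)
  x[9:10, ] <- 0
  ps <- sn$with_seed(7, list(
    wxf = sn$init_glorot(C, 4 * H), whf = sn$init_glorot(H, 4 * H), bf = rnorm(4 * H),
    wxb = sn$init_glorot(C, 4 * H), whb = sn$init_glorot(H, 4 * H), bb = rnorm(4 * H)))
  batched <- sn$bilstm_fwd(x, lens, L, ps$wxf, ps$whf, ps$bf,
                           ps$wxb, ps$whb, ps$bb)$out
  single <- sn$bilstm_fwd(x[6:8, , drop = FALSE], 3L, 3L, ps$wxf, ps$whf,
                          ps$bf, ps$wxb, ps$whb, ps$bb)$out
  expect_equal(batched[6:8, ], single)
  expect_equal(batched[9:10, ], matrix(0, 2, 2 * H))
})
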