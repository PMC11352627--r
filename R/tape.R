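# Reverse-mode automatic differentiation on a linear tape.
#
# All trainable computation in the package runs through this engine. An op
# returns a lightweight node -- a list holding the node id, its forward value
# and its needs-gradient flag -- while the tape environment accumulates, per
# id, the parent ids and a backward closure mapping the incoming gradient to
# per-parent gradients. Forward passes only ever write to the tape (reads go
# through the node objects), which keeps the backing lists unshared so R can
# grow and update them in place. Ops perform no input validation beyond what
# a correct gradient needs; public functions validate at the package surface.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$n <- 0L
  tp$cap <- 1024L
  tp$par <- vector("list", 1024L)
  tp$bk <- vector("list", 1024L)
  tp$ng <- logical(1024L)
  tp$grads <- NULL
  tp
}

tp_push <- function(tp, val, parents, backward, ng) {
  n <- tp$n + 1L
  if (n > tp$cap) {
    extra <- tp$cap
    tp$par <- c(tp$par, vector("list", extra))
    tp$bk <- c(tp$bk, vector("list", extra))
    tp$ng <- c(tp$ng, logical(extra))
    tp$cap <- tp$cap + extra
  }
  tp$n <- n
  if (!is.null(parents)) tp$par[[n]] <- parents
  if (!is.null(backward)) tp$bk[[n]] <- backward
  tp$ng[n] <- ng
  list(id = n, v = val, ng = ng)
}

tp_const <- function(tp, x) tp_push(tp, x, NULL, NULL, FALSE)

tp_leaf <- function(tp, x) tp_push(tp, x, NULL, NULL, TRUE)

tp_val <- function(tp, node) node$v

# Backward sweep from a scalar-valued node. Gradients for every needs-grad
# node are left in tp$grads, indexed by node id.
tape_backward <- function(tp, node) {
  grads <- vector("list", tp$n)
  v <- node$v
  grads[[node$id]] <- if (is.matrix(v)) matrix(1, nrow(v), ncol(v)) else 1
  bks <- tp$bk
  pars <- tp$par
  ngv <- tp$ng
  for (i in seq.int(node$id, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    bfn <- bks[[i]]
    if (is.null(bfn)) next
    pg <- bfn(g)
    ps <- pars[[i]]
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (!ngv[[p]]) next
      gj <- pg[[j]]
      if (is.null(gj)) next
      grads[[p]] <- if (is.null(grads[[p]])) gj else grads[[p]] + gj
    }
  }
  tp$grads <- grads
  invisible(tp)
}

tp_grad <- function(tp, node) tp$grads[[node$id]]

# ---- elementary ops ---------------------------------------------------------

op_mm <- function(tp, a, b) {
  A <- a$v; B <- b$v
  ng <- a$ng || b$ng
  bk <- if (ng) function(g) list(g %*% t(B), crossprod(A, g))
  tp_push(tp, A %*% B, c(a$id, b$id), bk, ng)
}

op_add <- function(tp, a, b) {
  ng <- a$ng || b$ng
  bk <- if (ng) function(g) list(g, g)
  tp_push(tp, a$v + b$v, c(a$id, b$id), bk, ng)
}

op_sub <- function(tp, a, b) {
  ng <- a$ng || b$ng
  bk <- if (ng) function(g) list(g, -g)
  tp_push(tp, a$v - b$v, c(a$id, b$id), bk, ng)
}

# bias is a length-ncol(a) vector node, broadcast across rows
op_add_bias <- function(tp, a, b) {
  A <- a$v
  ng <- a$ng || b$ng
  bk <- if (ng) function(g) list(g, colSums(g))
  tp_push(tp, A + rep(b$v, each = nrow(A)), c(a$id, b$id), bk, ng)
}

op_mul <- function(tp, a, b) {
  A <- a$v; B <- b$v
  ng <- a$ng || b$ng
  bk <- if (ng) function(g) list(g * B, g * A)
  tp_push(tp, A * B, c(a$id, b$id), bk, ng)
}

op_scale <- function(tp, a, k) {
  bk <- if (a$ng) function(g) list(g * k)
  tp_push(tp, a$v * k, a$id, bk, a$ng)
}

op_relu <- function(tp, a) {
  A <- a$v
  pos <- A > 0
  bk <- if (a$ng) function(g) list(g * pos)
  tp_push(tp, A * pos, a$id, bk, a$ng)
}

op_gelu <- function(tp, a) {
  A <- a$v
  ph <- stats::pnorm(A)
  bk <- if (a$ng) function(g) list(g * (ph + A * stats::dnorm(A)))
  tp_push(tp, A * ph, a$id, bk, a$ng)
}

op_sigmoid <- function(tp, a) {
  y <- 1 / (1 + exp(-a$v))
  bk <- if (a$ng) function(g) list(g * y * (1 - y))
  tp_push(tp, y, a$id, bk, a$ng)
}

op_tanh <- function(tp, a) {
  y <- tanh(a$v)
  bk <- if (a$ng) function(g) list(g * (1 - y * y))
  tp_push(tp, y, a$id, bk, a$ng)
}

op_softmax_rows <- function(tp, a) {
  e <- exp(a$v - apply(a$v, 1L, max))
  p <- e / rowSums(e)
  bk <- if (a$ng) function(g) list(p * (g - rowSums(g * p)))
  tp_push(tp, p, a$id, bk, a$ng)
}

# nodes: a list of node objects, bound column-wise
op_cbind <- function(tp, nodes) {
  vals <- lapply(nodes, function(n) n$v)
  ng <- any(vapply(nodes, function(n) n$ng, TRUE))
  bk <- if (ng) {
    widths <- vapply(vals, ncol, 1L)
    ends <- cumsum(widths); starts <- ends - widths + 1L
    function(g) lapply(seq_along(nodes),
                       function(j) g[, starts[j]:ends[j], drop = FALSE])
  }
  tp_push(tp, do.call(cbind, vals), vapply(nodes, function(n) n$id, 1L), bk, ng)
}

op_rbind <- function(tp, nodes) {
  vals <- lapply(nodes, function(n) n$v)
  ng <- any(vapply(nodes, function(n) n$ng, TRUE))
  bk <- if (ng) {
    heights <- vapply(vals, nrow, 1L)
    ends <- cumsum(heights); starts <- ends - heights + 1L
    function(g) lapply(seq_along(nodes),
                       function(j) g[starts[j]:ends[j], , drop = FALSE])
  }
  tp_push(tp, do.call(rbind, vals), vapply(nodes, function(n) n$id, 1L), bk, ng)
}

op_cols <- function(tp, a, idx) {
  A <- a$v
  bk <- if (a$ng) function(g) {
    out <- matrix(0, nrow(A), ncol(A))
    out[, idx] <- g
    list(out)
  }
  tp_push(tp, A[, idx, drop = FALSE], a$id, bk, a$ng)
}

# Row gather with scatter-add backward; idx may repeat rows.
op_rows <- function(tp, a, idx) {
  A <- a$v
  bk <- if (a$ng) function(g) {
    gg <- rowsum(g, group = idx)
    out <- matrix(0, nrow(A), ncol(A))
    out[as.integer(rownames(gg)), ] <- gg
    list(out)
  }
  tp_push(tp, A[idx, , drop = FALSE], a$id, bk, a$ng)
}

# Column-wise max over all rows -> 1 x d
op_max_rows <- function(tp, a) {
  A <- a$v
  w <- max.col(t(A), ties.method = "first")
  y <- matrix(A[cbind(w, seq_len(ncol(A)))], 1L)
  bk <- if (a$ng) function(g) {
    out <- matrix(0, nrow(A), ncol(A))
    out[cbind(w, seq_len(ncol(A)))] <- g
    list(out)
  }
  tp_push(tp, y, a$id, bk, a$ng)
}

op_sum <- function(tp, a) {
  A <- a$v
  bk <- if (a$ng) function(g) list(matrix(as.numeric(g), nrow(A), ncol(A)))
  tp_push(tp, matrix(sum(A), 1L, 1L), a$id, bk, a$ng)
}

# Mean squared error against a constant truth vector; scalar node.
op_mse <- function(tp, pred, truth) {
  P <- pred$v
  r <- as.numeric(P) - as.numeric(truth)
  n <- length(r)
  bk <- if (pred$ng)
    function(g) list(matrix(as.numeric(g) * 2 * r / n, nrow(P), ncol(P)))
  tp_push(tp, matrix(mean(r * r), 1L, 1L), pred$id, bk, pred$ng)
}

# ---- fused / structured ops -------------------------------------------------

# Per-group column-wise max over row blocks (sizes gives block lengths).
op_group_max <- function(tp, a, sizes) {
  A <- a$v
  res <- group_max_fwd(A, as.integer(sizes))
  bk <- if (a$ng) function(g) list(group_max_bwd(g, res$argmax, nrow(A)))
  tp_push(tp, res$value, a$id, bk, a$ng)
}

# Block-diagonal graph propagation: rows of h are grouped per graph, mats is a
# list of per-graph (symmetric) support matrices. Computes A_i %*% h_i per block.
op_gcn_prop <- function(tp, h, mats, sizes) {
  y <- gcn_prop_fwd(h$v, mats, as.integer(sizes))
  bk <- if (h$ng) function(g) list(gcn_prop_fwd(g, mats, as.integer(sizes)))
  tp_push(tp, y, h$id, bk, h$ng)
}

# Scaled dot-product attention core, batched over `nb` blocks of Lq query rows
# and Lk key rows. q: (nb*Lq) x (h*dk), k: (nb*Lk) x (h*dk), v: (nb*Lk) x (h*dv).
# Returns (nb*Lq) x (h*dv) of concatenated per-head attention outputs; the
# softmax probabilities are attached to the node value as attribute "probs".
op_attn_core <- function(tp, q, k, v, nb, lq, lk, heads, dk, dv) {
  Q <- q$v; K <- k$v; V <- v$v
  fw <- attn_fwd(Q, K, V, as.integer(nb), as.integer(lq), as.integer(lk),
                 as.integer(heads), as.integer(dk), as.integer(dv))
  ng <- q$ng || k$ng || v$ng
  bk <- if (ng) function(g) {
    bw <- attn_bwd(g, Q, K, V, fw$probs, as.integer(nb), as.integer(lq),
                   as.integer(lk), as.integer(heads), as.integer(dk),
                   as.integer(dv))
    list(bw$gq, bw$gk, bw$gv)
  }
  out <- fw$out
  attr(out, "probs") <- fw$probs
  tp_push(tp, out, c(q$id, k$id, v$id), bk, ng)
}

# Batched, masked bidirectional LSTM over nb padded sequences of common
# length L (one fused node; forward and backward-in-time recurrences run in
# compiled code). x: (nb*L) x C sequence-major; lens gives true lengths.
# Output: (nb*L) x 2H sequence-major with padded rows zeroed.
op_bilstm <- function(tp, x, lens, L, wxf, whf, bf, wxb, whb, bb) {
  fw <- bilstm_fwd(x$v, as.integer(lens), as.integer(L),
                   wxf$v, whf$v, bf$v, wxb$v, whb$v, bb$v)
  ng <- x$ng || wxf$ng || whf$ng || bf$ng || wxb$ng || whb$ng || bb$ng
  bk <- if (ng) function(g) {
    bw <- bilstm_bwd(g, x$v, as.integer(lens), as.integer(L),
                     wxf$v, whf$v, bf$v, wxb$v, whb$v, bb$v, fw)
    list(bw$gx, bw$gwxf, bw$gwhf, as.numeric(bw$gbf),
         bw$gwxb, bw$gwhb, as.numeric(bw$gbb))
  }
  tp_push(tp, fw$out, c(x$id, wxf$id, whf$id, bf$id, wxb$id, whb$id, bb$id),
          bk, ng)
}

# Spatial token mixing for the gated-MLP block. z2 holds `nb` stacked blocks of
# L rows and c columns (block-major rows); computes per block W %*% z2_b + b,
# with W an L x L token-mixing matrix and b a length-L bias.
op_spatial_mix <- function(tp, z2, w, b, nb, L) {
  Z <- z2$v; W <- w$v
  cc <- ncol(Z)
  # permute (nb*L) x c block-major into L x (c*nb): column-major over (L, c, nb)
  arr <- aperm(array(Z, dim = c(L, nb, cc)), c(1L, 3L, 2L))
  M <- matrix(arr, nrow = L)
  Y <- W %*% M + b$v
  out <- matrix(aperm(array(Y, dim = c(L, cc, nb)), c(1L, 3L, 2L)), nrow = nb * L)
  ng <- z2$ng || w$ng || b$ng
  bk <- if (ng) function(g) {
    gM <- matrix(aperm(array(g, dim = c(L, nb, cc)), c(1L, 3L, 2L)), nrow = L)
    gZ <- matrix(aperm(array(crossprod(W, gM), dim = c(L, cc, nb)),
                       c(1L, 3L, 2L)), nrow = nb * L)
    list(gZ, tcrossprod(gM, M), rowSums(gM))
  }
  tp_push(tp, out, c(z2$id, w$id, b$id), bk, ng)
}

# Batch normalization over rows (features = columns). `state` is an environment
# holding running moments under `key`; updated as a side effect in training mode.
op_batchnorm <- function(tp, x, gamma, beta, state, key, training,
                         momentum = 0.1, eps = 1e-5) {
  X <- x$v; gm <- gamma$v; bt <- beta$v
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    xc <- X - rep(mu, each = n)
    va <- colMeans(xc * xc)
    rs <- state[[key]]
    if (is.null(rs)) rs <- list(mean = mu * 0, var = mu * 0 + 1)
    state[[key]] <- list(mean = (1 - momentum) * rs$mean + momentum * mu,
                         var = (1 - momentum) * rs$var + momentum * va)
  } else {
    rs <- state[[key]]
    if (is.null(rs)) rs <- list(mean = numeric(ncol(X)), var = rep(1, ncol(X)))
    mu <- rs$mean
    xc <- X - rep(mu, each = n)
    va <- rs$var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- xc * rep(inv, each = n)
  y <- xhat * rep(gm, each = n) + rep(bt, each = n)
  ng <- x$ng || gamma$ng || beta$ng
  bk <- if (ng) {
    if (training) {
      function(g) {
        dxhat <- g * rep(gm, each = n)
        t1 <- colSums(dxhat)
        t2 <- colSums(dxhat * xhat)
        dx <- (dxhat - rep(t1 / n, each = n) - xhat * rep(t2 / n, each = n)) *
          rep(inv, each = n)
        list(dx, colSums(g * xhat), colSums(g))
      }
    } else {
      function(g) list(g * rep(gm * inv, each = n), colSums(g * xhat), colSums(g))
    }
  }
  tp_push(tp, y, c(x$id, gamma$id, beta$id), bk, ng)
}
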