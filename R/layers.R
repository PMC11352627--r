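# Trainable layers composed from tape ops. A "runtime" (rt) bundles one tape,
# the flat named parameter list, a lazy map from parameter name to tape leaf,
# the batch-norm running-moment store, and the training-mode flag.

rt_new <- function(params, state, training) {
  list(tp = tape_new(), params = params,
       leafmap = new.env(parent = emptyenv()),
       state = state, training = training)
}

# Leaf node for a named parameter, created once per tape.
pid <- function(rt, name) {
  id <- rt$leafmap[[name]]
  if (is.null(id)) {
    p <- rt$params[[name]]
    if (is.null(p)) stop("unknown parameter: ", name)
    id <- tp_leaf(rt$tp, p)
    rt$leafmap[[name]] <- id
  }
  id
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

init_glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# ---- parameter constructors -------------------------------------------------

params_lstm_dir <- function(in_dim, hidden) {
  b <- numeric(4L * hidden)
  b[(hidden + 1L):(2L * hidden)] <- 1  # forget-gate bias
  list(Wx = init_glorot(in_dim, 4L * hidden),
       Wh = init_glorot(hidden, 4L * hidden),
       b = b)
}

params_seq_encoder <- function(cfg) {
  d <- 2L * cfg$d_l
  cc <- cfg$gmlp_dim %/% 2L
  p <- list()
  for (dir in c("fw", "bw")) {
    lp <- params_lstm_dir(cfg$atom_feat_dim, cfg$d_l)
    p[[paste0("seq.lstm.", dir, ".Wx")]] <- lp$Wx
    p[[paste0("seq.lstm.", dir, ".Wh")]] <- lp$Wh
    p[[paste0("seq.lstm.", dir, ".b")]] <- lp$b
  }
  gin <- if (identical(cfg$gmlp_input, "forward_half")) cfg$d_l else d
  for (l in seq_len(cfg$gmlp_layers)) {
    din <- if (l == 1L) gin else d
    p[[sprintf("seq.gmlp%d.U", l)]] <- init_glorot(din, cfg$gmlp_dim)
    p[[sprintf("seq.gmlp%d.bu", l)]] <- numeric(cfg$gmlp_dim)
    # near-identity spatial gate at init (token-mixing weights ~ 0, bias 1)
    p[[sprintf("seq.gmlp%d.W", l)]] <- matrix(stats::rnorm(cfg$max_atoms^2, 0, 1e-3),
                                              cfg$max_atoms, cfg$max_atoms)
    p[[sprintf("seq.gmlp%d.b", l)]] <- rep(1, cfg$max_atoms)
    p[[sprintf("seq.gmlp%d.V", l)]] <- init_glorot(cc, d)
    p[[sprintf("seq.gmlp%d.bv", l)]] <- numeric(d)
  }
  if (isTRUE(cfg$use_mha)) {
    p[["seq.mha.Wq"]] <- init_glorot(d, cfg$heads * cfg$d_k)
    p[["seq.mha.Wk"]] <- init_glorot(d, cfg$heads * cfg$d_k)
    p[["seq.mha.Wv"]] <- init_glorot(d, cfg$heads * cfg$d_v)
    p[["seq.mha.Wo"]] <- init_glorot(cfg$heads * cfg$d_v, d)
  }
  p
}

params_graph_encoder <- function(cfg) {
  w <- cfg$gcn_width
  cin <- cfg$atom_feat_dim
  list("gcn.p1.W1" = init_glorot(cin, w), "gcn.p1.W2" = init_glorot(w, w),
       "gcn.p1.W3" = init_glorot(w, w),
       "gcn.p2.W1" = init_glorot(cin, w), "gcn.p2.W2" = init_glorot(w, w),
       "gcn.p3.W1" = init_glorot(cin, w))
}

params_cloud_encoder <- function(cfg) {
  ch <- cfg$cloud_channels  # e.g. c(3, 32, 64, 128, 160)
  k <- cfg$cloud_kernel
  p <- list()
  for (s in seq_len(length(ch) - 1L)) {
    cin <- ch[s]; cout <- ch[s + 1L]
    # no convolution biases: each convolution is followed by batch
    # normalization, which absorbs any constant channel shift
    p[[sprintf("cloud.s%d.W", s)]] <- init_glorot(k * cin, cout)
    p[[sprintf("cloud.s%d.g", s)]] <- rep(1, cout)
    p[[sprintf("cloud.s%d.be", s)]] <- numeric(cout)
    p[[sprintf("cloud.s%d.Wr", s)]] <- init_glorot(k * cout, cout)
    p[[sprintf("cloud.s%d.gr", s)]] <- rep(1, cout)
    p[[sprintf("cloud.s%d.ber", s)]] <- numeric(cout)
  }
  p
}

params_cell_encoder <- function(in_dim, hidden, out_dim) {
  widths <- c(in_dim, hidden, out_dim)
  p <- list()
  for (l in seq_len(length(widths) - 1L)) {
    p[[sprintf("cell.l%d.W", l)]] <- init_glorot(widths[l], widths[l + 1L])
    p[[sprintf("cell.l%d.b", l)]] <- numeric(widths[l + 1L])
  }
  p
}

params_head <- function(in_dim, width1) {
  width2 <- width1 %/% 2L
  list("head.l1.W" = init_glorot(in_dim, width1), "head.l1.b" = numeric(width1),
       "head.bn1.g" = rep(1, width1), "head.bn1.be" = numeric(width1),
       "head.l2.W" = init_glorot(width1, width2), "head.l2.b" = numeric(width2),
       "head.bn2.g" = rep(1, width2), "head.bn2.be" = numeric(width2),
       "head.l3.W" = init_glorot(width2, 1L), "head.l3.b" = numeric(1L))
}

# ---- forward compositions ---------------------------------------------------

fw_linear <- function(rt, x, wname, bname = NULL) {
  y <- op_mm(rt$tp, x, pid(rt, wname))
  if (!is.null(bname)) y <- op_add_bias(rt$tp, y, pid(rt, bname))
  y
}

# Bidirectional LSTM over nb padded sequences of common length L, fused in
# compiled code (forward and backward-in-time recurrences plus BPTT).
# x is a node holding the (nb*L) x C sequence-major input; lens gives true
# lengths. Output node: (nb*L) x 2H, padded rows zeroed.
fw_bilstm <- function(rt, x, lens, L, prefix = "seq.lstm") {
  op_bilstm(rt$tp, x, lens, L,
            pid(rt, paste0(prefix, ".fw.Wx")), pid(rt, paste0(prefix, ".fw.Wh")),
            pid(rt, paste0(prefix, ".fw.b")),
            pid(rt, paste0(prefix, ".bw.Wx")), pid(rt, paste0(prefix, ".bw.Wh")),
            pid(rt, paste0(prefix, ".bw.b")))
}

# Stack of gated-MLP blocks over nb sequence blocks of L rows (block-major).
fw_gmlp_stack <- function(rt, x, nb, L, layers, prefix = "seq.gmlp") {
  tp <- rt$tp
  for (l in seq_len(layers)) {
    pfx <- sprintf("%s%d", prefix, l)
    z <- op_gelu(tp, op_add_bias(tp, op_mm(tp, x, pid(rt, paste0(pfx, ".U"))),
                                 pid(rt, paste0(pfx, ".bu"))))
    cc <- ncol(tp_val(tp, z)) %/% 2L
    z1 <- op_cols(tp, z, 1L:cc)
    z2 <- op_cols(tp, z, (cc + 1L):(2L * cc))
    gate <- op_spatial_mix(tp, z2, pid(rt, paste0(pfx, ".W")),
                           pid(rt, paste0(pfx, ".b")), nb, L)
    s <- op_mul(tp, z1, gate)
    x <- op_add_bias(tp, op_mm(tp, s, pid(rt, paste0(pfx, ".V"))),
                     pid(rt, paste0(pfx, ".bv")))
  }
  x
}

# Multi-head attention over nb blocks; xq (nb*lq) x d, xkv (nb*lk) x d.
fw_mha <- function(rt, xq, xkv, nb, lq, lk, heads, dk, dv, prefix = "seq.mha") {
  tp <- rt$tp
  q <- fw_linear(rt, xq, paste0(prefix, ".Wq"))
  k <- fw_linear(rt, xkv, paste0(prefix, ".Wk"))
  v <- fw_linear(rt, xkv, paste0(prefix, ".Wv"))
  core <- op_attn_core(tp, q, k, v, nb, lq, lk, heads, dk, dv)
  fw_linear(rt, core, paste0(prefix, ".Wo"))
}

# Three-scale GCN over a batch of graphs: x is the stacked node-feature matrix,
# mats1/2/3 are per-graph normalized supports of orders 1..3, sizes the node
# counts. Output: per-graph pooled vectors, G x (3*width).
fw_multiscale_gcn <- function(rt, x, mats1, mats2, mats3, sizes, prefix = "gcn") {
  tp <- rt$tp
  gl <- function(h, mats, wname)
    op_relu(tp, op_mm(tp, op_gcn_prop(tp, h, mats, sizes), pid(rt, wname)))
  h1 <- gl(x, mats1, paste0(prefix, ".p1.W1"))
  h1 <- gl(h1, mats1, paste0(prefix, ".p1.W2"))
  h1 <- gl(h1, mats1, paste0(prefix, ".p1.W3"))
  h2 <- gl(x, mats2, paste0(prefix, ".p2.W1"))
  h2 <- gl(h2, mats2, paste0(prefix, ".p2.W2"))
  h3 <- gl(x, mats3, paste0(prefix, ".p3.W1"))
  op_group_max(tp, op_cbind(tp, list(h1, h2, h3)), sizes)
}

# Same-padding 1D convolution over nb stacked blocks of L rows; kernel k (odd).
# For k = 1 this is a pointwise (per-position) linear map.
fw_conv1d <- function(rt, x, nb, L, k, wname, bname) {
  tp <- rt$tp
  if (k == 1L) return(fw_linear(rt, x, wname, bname))
  half <- (k - 1L) %/% 2L
  nr <- nb * L
  zrow <- tp_const(tp, matrix(0, 1L, ncol(tp_val(tp, x))))
  xz <- op_rbind(tp, list(x, zrow))
  pos <- seq_len(nr)
  blk <- (pos - 1L) %/% L
  loc <- (pos - 1L) %% L
  cols <- lapply((-half):half, function(o) {
    tgt <- loc + o
    idx <- ifelse(tgt < 0L | tgt >= L, nr + 1L, blk * L + tgt + 1L)
    op_rows(tp, xz, as.integer(idx))
  })
  fw_linear(rt, op_cbind(tp, cols), wname, bname)
}

fw_bn <- function(rt, x, gname, bename, key) {
  op_batchnorm(rt$tp, x, pid(rt, gname), pid(rt, bename), rt$state, key,
               rt$training)
}

# Residual point-cloud embedding: stages of conv -> BN -> ReLU followed by a
# same-width residual conv -> BN, skip addition, ReLU; global max pool last.
fw_cloud_stack <- function(rt, x, nb, L, cfg) {
  tp <- rt$tp
  k <- cfg$cloud_kernel
  nstage <- length(cfg$cloud_channels) - 1L
  for (s in seq_len(nstage)) {
    pfx <- sprintf("cloud.s%d", s)
    y <- fw_conv1d(rt, x, nb, L, k, paste0(pfx, ".W"), NULL)
    y <- op_relu(tp, fw_bn(rt, y, paste0(pfx, ".g"), paste0(pfx, ".be"),
                           paste0(pfx, ".bn1")))
    r <- fw_conv1d(rt, y, nb, L, k, paste0(pfx, ".Wr"), NULL)
    r <- fw_bn(rt, r, paste0(pfx, ".gr"), paste0(pfx, ".ber"), paste0(pfx, ".bn2"))
    x <- op_relu(tp, op_add(tp, y, r))
  }
  if (identical(cfg$cloud_pool, "mean")) {
    pm <- matrix(0, nb, nb * L)
    for (b in seq_len(nb)) pm[b, ((b - 1L) * L + 1L):(b * L)] <- 1 / L
    return(op_mm(tp, tp_const(tp, pm), x))
  }
  op_group_max(tp, x, rep(L, nb))
}

fw_cell_ffn <- function(rt, x, nlayers) {
  tp <- rt$tp
  for (l in seq_len(nlayers)) {
    x <- fw_linear(rt, x, sprintf("cell.l%d.W", l), sprintf("cell.l%d.b", l))
    if (l < nlayers) x <- op_relu(tp, x)
  }
  x
}

# Three fully connected layers; the first two use ReLU followed by batch
# normalization, the last has a single output neuron.
fw_head <- function(rt, x) {
  tp <- rt$tp
  x <- fw_linear(rt, x, "head.l1.W", "head.l1.b")
  x <- fw_bn(rt, op_relu(tp, x), "head.bn1.g", "head.bn1.be", "head.bn1")
  x <- fw_linear(rt, x, "head.l2.W", "head.l2.b")
  x <- fw_bn(rt, op_relu(tp, x), "head.bn2.g", "head.bn2.be", "head.bn2")
  fw_linear(rt, x, "head.l3.W", "head.l3.b")
}

# ---- optimizer --------------------------------------------------------------

# AdamW with decoupled weight decay. State is kept per parameter name.
adamw_new <- function(params, beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                      weight_decay = 0.01) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st$beta1 <- beta1; st$beta2 <- beta2; st$eps <- eps; st$wd <- weight_decay
  st
}

adamw_step <- function(opt, params, grads, lr) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  c1 <- 1 - b1^opt$t; c2 <- 1 - b2^opt$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    p <- params[[nm]]
    if (!is.matrix(p)) g <- as.numeric(g)
    m <- b1 * opt$m[[nm]] + (1 - b1) * g
    v <- b2 * opt$v[[nm]] + (1 - b2) * g * g
    opt$m[[nm]] <- m
    opt$v[[nm]] <- v
    params[[nm]] <- p - lr * ((m / c1) / (sqrt(v / c2) + opt$eps) + opt$wd * p)
  }
  params
}

# Collect named gradients after a backward sweep.
rt_grads <- function(rt) {
  out <- list()
  for (nm in ls(rt$leafmap)) {
    g <- rt$tp$grads[[rt$leafmap[[nm]]$id]]
    if (!is.null(g)) {
      p <- rt$params[[nm]]
      if (!is.matrix(p)) g <- as.numeric(g)
      out[[nm]] <- g
    }
  }
  out
}
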