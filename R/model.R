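# Model assembly: the full synergy regressor, its ablation variants, the
# batched forward pass shared by training and prediction, and the loss.

variant_names <- c("MMFSyn", "MMFSyn_base", "Seq_A", "Seq_B", "Graph_A",
                   "Graph_B", "MMFSyn-CA", "MMFSyn-SA", "Cell_base",
                   "Cell_gen", "Cell_mut")

apply_variant <- function(cfg, name) {
  if (!name %in% variant_names)
    stop("unknown variant '", name, "'; valid names: ",
         paste(variant_names, collapse = ", "))
  cfg$variant <- name
  cfg$use_seq <- TRUE; cfg$use_mha <- TRUE
  cfg$use_graph <- TRUE; cfg$use_pair_graph <- TRUE
  cfg$cell_mode <- "omics"; cfg$fusion <- "concat"
  switch(name,
    "MMFSyn_base" = { cfg$use_seq <- FALSE; cfg$use_graph <- FALSE },
    "Seq_A" = { cfg$use_graph <- FALSE },
    "Seq_B" = { cfg$use_graph <- FALSE; cfg$use_mha <- FALSE },
    "Graph_A" = { cfg$use_seq <- FALSE },
    "Graph_B" = { cfg$use_seq <- FALSE; cfg$use_pair_graph <- FALSE },
    "MMFSyn-CA" = { cfg$fusion <- "cross" },
    "MMFSyn-SA" = { cfg$fusion <- "self" },
    "Cell_base" = { cfg$cell_mode <- "onehot" },
    "Cell_gen" = { cfg$cell_mode <- "expr" },
    "Cell_mut" = { cfg$cell_mode <- "mut" },
    NULL)
  cfg
}

seq_out_dim <- function(cfg) 2L * cfg$d_l

drug_feature_dim <- function(cfg) {
  d <- 2L * cfg$fp_bits
  if (cfg$use_seq) d <- d + seq_out_dim(cfg)
  if (cfg$use_graph)
    d <- d + (if (cfg$use_pair_graph) 3L else 2L) * 3L * cfg$gcn_width
  d + 2L * cfg$cloud_channels[length(cfg$cloud_channels)]
}

cell_input_dim <- function(cfg, dims) {
  switch(cfg$cell_mode,
         omics = dims$expr_k + dims$mut_m,
         expr = dims$expr_k,
         mut = dims$mut_m,
         onehot = length(dims$cell_ids),
         stop("unknown cell_mode: ", cfg$cell_mode))
}

fuse_dim <- 128L

head_input_dim <- function(cfg) {
  switch(cfg$fusion,
         concat = drug_feature_dim(cfg) + cfg$cell_dim,
         self = 5L * fuse_dim,
         cross = fuse_dim + cfg$cell_dim)
}

#' Build a synergy model variant
#'
#' Constructs the regressor named by `name`: the full model (`"MMFSyn"`), the
#' drug-feature ablations (`"MMFSyn_base"` = Morgan + point cloud only;
#' `"Seq_A"`/`"Seq_B"` add the sequence branch with/without the attention
#' fuser; `"Graph_A"`/`"Graph_B"` add the graph branch with/without the
#' pair-graph fusion), the fusion variants (`"MMFSyn-CA"`/`"MMFSyn-SA"`,
#' cross-/self-attention over per-modality tokens), and the cell-line
#' ablations (`"Cell_base"` one-hot cell identity, `"Cell_gen"` expression
#' only, `"Cell_mut"` mutations only).
#'
#' @param name one of the variant names above.
#' @param config a [synergy_config()].
#' @param dims list with `expr_k`, `mut_m` and `cell_ids` (data-driven input
#'   widths; `cell_ids` fixes the one-hot column order for `Cell_base`).
#' @return An object of class `synergy_model`.
#' @export
build_variant <- function(name, config = synergy_config(), dims) {
  cfg <- apply_variant(config, name)
  if (is.null(dims$expr_k) || is.null(dims$mut_m) || is.null(dims$cell_ids))
    stop("dims must provide expr_k, mut_m and cell_ids")
  params <- with_seed(cfg$seed, {
    p <- list()
    if (cfg$use_seq) p <- c(p, params_seq_encoder(cfg))
    if (cfg$use_graph) p <- c(p, params_graph_encoder(cfg))
    p <- c(p, params_cloud_encoder(cfg))
    p <- c(p, params_cell_encoder(cell_input_dim(cfg, dims), cfg$cell_hidden,
                                  cfg$cell_dim))
    if (cfg$fusion != "concat") {
      segs <- fusion_segments(cfg)
      for (i in seq_along(segs)) {
        p[[sprintf("fuse.proj%d.W", i)]] <- init_glorot(segs[i], fuse_dim)
        p[[sprintf("fuse.proj%d.b", i)]] <- numeric(fuse_dim)
      }
      p[["fuse.mha.Wq"]] <- init_glorot(fuse_dim, cfg$heads * cfg$d_k)
      p[["fuse.mha.Wk"]] <- init_glorot(fuse_dim, cfg$heads * cfg$d_k)
      p[["fuse.mha.Wv"]] <- init_glorot(fuse_dim, cfg$heads * cfg$d_v)
      p[["fuse.mha.Wo"]] <- init_glorot(cfg$heads * cfg$d_v, fuse_dim)
    }
    c(p, params_head(head_input_dim(cfg), cfg$head_width))
  })
  structure(list(config = cfg, params = params, dims = dims,
                 state = new.env(parent = emptyenv()),
                 version = "synergynet-checkpoint-1"),
            class = "synergy_model")
}

# per-modality segment widths for the token-fusion variants:
# fingerprint pair, sequence fusion, graph fusion, cloud pair (drug tokens),
# then the cell feature.
fusion_segments <- function(cfg) {
  c(2L * cfg$fp_bits,
    seq_out_dim(cfg),
    (if (cfg$use_pair_graph) 3L else 2L) * 3L * cfg$gcn_width,
    2L * cfg$cloud_channels[length(cfg$cloud_channels)],
    cfg$cell_dim)
}

#' Mean squared error loss
#'
#' @param pred,truth numeric vectors of equal length.
#' @return mean of squared residuals.
#' @export
mse_loss <- function(pred, truth) {
  if (length(pred) != length(truth))
    stop("length mismatch: ", length(pred), " vs ", length(truth))
  if (length(pred) < 1L) stop("empty input")
  mean((as.numeric(pred) - as.numeric(truth))^2)
}

# Cell-line input matrix (rows = cells of `dims$cell_ids` order).
cell_input_matrix <- function(cfg, dims, cells) {
  ids <- dims$cell_ids
  switch(cfg$cell_mode,
    omics = cbind(cells$expr[ids, , drop = FALSE], cells$mut[ids, , drop = FALSE]),
    expr = cells$expr[ids, , drop = FALSE],
    mut = cells$mut[ids, , drop = FALSE],
    onehot = { m <- diag(length(ids)); rownames(m) <- ids; m })
}

# ---- batched forward --------------------------------------------------------

# One forward pass over a batch of (drug_a, drug_b, cell_line) rows.
# Deduplicates drugs, ordered pairs and cells so each unique entity is
# encoded once; per-example rows are gathered afterwards. Returns the
# runtime (tape), the prediction node, and the index bookkeeping.
forward_batch <- function(model, feats, batch, cellmat, training = FALSE) {
  cfg <- model$config
  rt <- rt_new(model$params, model$state, training)
  tp <- rt$tp
  L <- cfg$max_atoms
  ud <- unique(c(batch$drug_a, batch$drug_b))
  pk <- pair_key(batch$drug_a, batch$drug_b)
  upk <- unique(pk)
  uab <- do.call(rbind, strsplit(upk, "\r", fixed = TRUE))
  P <- length(upk)
  ia <- match(uab[, 1L], ud)
  ib <- match(uab[, 2L], ud)
  drugs <- feats$drugs[ud]
  segs <- list()

  # Morgan fingerprints (constant inputs)
  fpm <- t(vapply(seq_len(P), function(p) c(drugs[[ia[p]]]$fp, drugs[[ib[p]]]$fp),
                  numeric(2L * cfg$fp_bits)))
  segs$fp <- tp_const(tp, fpm)

  if (cfg$use_seq) {
    lens <- vapply(drugs, function(d) d$seq$length, 0L)
    xseq <- tp_const(tp, do.call(rbind, lapply(drugs, function(d) d$seq_padded)))
    hs <- fw_bilstm(rt, xseq, lens, L)
    if (identical(cfg$gmlp_input, "forward_half"))
      hs <- op_cols(tp, hs, seq_len(cfg$d_l))
    hs <- fw_gmlp_stack(rt, hs, length(ud), L, cfg$gmlp_layers)
    idxA <- unlist(lapply(ia, function(i) ((i - 1L) * L + 1L):(i * L)))
    idxB <- unlist(lapply(ib, function(i) ((i - 1L) * L + 1L):(i * L)))
    xc <- op_add(tp, op_rows(tp, hs, idxA), op_rows(tp, hs, idxB))
    tok <- if (cfg$use_mha)
      fw_mha(rt, xc, xc, P, L, L, cfg$heads, cfg$d_k, cfg$d_v)
    else xc
    segs$seq <- if (identical(cfg$seq_pool, "mean")) {
      pm <- matrix(0, P, P * L)
      for (p in seq_len(P)) pm[p, ((p - 1L) * L + 1L):(p * L)] <- 1 / L
      op_mm(tp, tp_const(tp, pm), tok)
    } else op_group_max(tp, tok, rep(L, P))
  }

  if (cfg$use_graph) {
    glist <- lapply(drugs, function(d)
      list(p = d$powers, x = d$graph$node_features, n = d$graph$atom_count))
    if (cfg$use_pair_graph) {
      pf <- feats$pairs[upk]
      glist <- c(glist, lapply(pf, function(f)
        list(p = f$powers, x = f$node_features, n = f$n)))
    }
    sizes <- vapply(glist, function(g) g$n, 0L)
    X <- tp_const(tp, do.call(rbind, lapply(glist, function(g) g$x)))
    ge <- fw_multiscale_gcn(rt, X,
                            lapply(glist, function(g) g$p$a1),
                            lapply(glist, function(g) g$p$a2),
                            lapply(glist, function(g) g$p$a3), sizes)
    segs$graph <- if (cfg$use_pair_graph)
      op_cbind(tp, list(op_rows(tp, ge, ia),
                        op_rows(tp, ge, length(ud) + seq_len(P)),
                        op_rows(tp, ge, ib)))
    else op_cbind(tp, list(op_rows(tp, ge, ia), op_rows(tp, ge, ib)))
  }

  cl <- do.call(rbind, lapply(drugs, function(d) d$cloud$coords))
  hd <- fw_cloud_stack(rt, tp_const(tp, cl), length(ud), cfg$cloud_len, cfg)
  segs$cloud <- op_cbind(tp, list(op_rows(tp, hd, ia), op_rows(tp, hd, ib)))

  ucells <- unique(batch$cell_line)
  cx <- tp_const(tp, cellmat[ucells, , drop = FALSE])
  fcell <- fw_cell_ffn(rt, cx, 2L)

  pidx <- match(pk, upk)
  cidx <- match(batch$cell_line, ucells)
  B <- nrow(batch)
  drug_segs <- segs[intersect(c("fp", "seq", "graph", "cloud"), names(segs))]
  if (cfg$fusion == "concat") {
    hdrug <- op_cbind(tp, drug_segs)
    x <- op_cbind(tp, list(op_rows(tp, hdrug, pidx), op_rows(tp, fcell, cidx)))
  } else {
    toks <- lapply(seq_along(drug_segs), function(i)
      fw_linear(rt, op_rows(tp, drug_segs[[i]], pidx),
                sprintf("fuse.proj%d.W", i), sprintf("fuse.proj%d.b", i)))
    fcell_rows <- op_rows(tp, fcell, cidx)
    ctok <- fw_linear(rt, fcell_rows, "fuse.proj5.W", "fuse.proj5.b")
    interleave <- function(nodes) {
      tt <- length(nodes)
      stacked <- op_rbind(tp, nodes)
      idx <- as.integer(vapply(seq_len(B), function(b) (seq_len(tt) - 1L) * B + b,
                               integer(tt)))
      op_rows(tp, stacked, idx)
    }
    if (cfg$fusion == "self") {
      allt <- interleave(c(toks, list(ctok)))
      fused <- fw_mha(rt, allt, allt, B, 5L, 5L, cfg$heads, cfg$d_k, cfg$d_v,
                      prefix = "fuse.mha")
      x <- op_cbind(tp, lapply(seq_len(5L), function(t)
        op_rows(tp, fused, (seq_len(B) - 1L) * 5L + t)))
    } else {
      kv <- interleave(toks)
      fused <- fw_mha(rt, ctok, kv, B, 1L, 4L, cfg$heads, cfg$d_k, cfg$d_v,
                      prefix = "fuse.mha")
      x <- op_cbind(tp, list(fused, fcell_rows))
    }
  }
  pred <- fw_head(rt, x)
  list(rt = rt, pred = pred, ud = ud, upk = upk)
}

#' Predict synergy scores
#'
#' Runs the model in evaluation mode (batch-normalization uses running
#' moments, so single examples are well defined). With `order_augment` the
#' reported score is the mean of the predictions for both drug orderings.
#'
#' @param object a [build_variant()] model (trained or not).
#' @param examples data frame with columns `drug_a`, `drug_b`, `cell_line`.
#' @param feats a feature store from the training pipeline (see [train_synergy()]).
#' @param cellmat cell-line input matrix (built internally by the train/predict
#'   wrappers).
#' @param chunk examples per forward pass.
#' @param ... unused.
#' @return numeric vector of predicted synergy scores.
#' @export
predict.synergy_model <- function(object, examples, feats, cellmat,
                                  chunk = 1024L, ...) {
  one_pass <- function(ex) {
    out <- numeric(nrow(ex))
    for (s in seq(1L, nrow(ex), by = chunk)) {
      e <- s:min(s + chunk - 1L, nrow(ex))
      fb <- forward_batch(object, feats, ex[e, , drop = FALSE], cellmat,
                          training = FALSE)
      out[e] <- as.numeric(tp_val(fb$rt$tp, fb$pred))
    }
    out
  }
  p1 <- one_pass(examples)
  if (!isTRUE(object$config$order_augment)) return(p1)
  swapped <- examples
  swapped$drug_a <- examples$drug_b
  swapped$drug_b <- examples$drug_a
  (p1 + one_pass(swapped)) / 2
}

#' Model summary: parameter groups and counts
#'
#' @param object a `synergy_model`.
#' @param ... unused.
#' @return invisibly, a data frame of parameter-group sizes.
#' @export
summary.synergy_model <- function(object, ...) {
  grp <- sub("\\..*$", "", names(object$params))
  sizes <- vapply(object$params, length, 0L)
  df <- stats::aggregate(list(parameters = sizes), list(group = grp), sum)
  total <- sum(sizes)
  cat(sprintf("<synergy_model> variant %s, %d parameters in %d tensors\n",
              object$config$variant, total, length(object$params)))
  for (i in seq_len(nrow(df)))
    cat(sprintf("  %-8s %10d\n", df$group[i], df$parameters[i]))
  invisible(df)
}

#' @export
print.synergy_model <- function(x, ...) {
  cat(sprintf("<synergy_model> variant %s (%d parameter tensors)\n",
              x$config$variant, length(x$params)))
  invisible(x)
}
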