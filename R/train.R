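# Training loop (AdamW + step-decay learning rate), metric computation with
# stratified reporting, and the cross-validation driver.

#' Training configuration
#'
#' Defaults follow the training protocol of the model: batch size 256, AdamW,
#' step-decay learning rate starting at 0.001 with factor 0.9 every 20
#' epochs. Epoch count and early stopping are package choices (100 epochs,
#' patience 20 on validation MSE).
#'
#' @param batch_size minibatch size.
#' @param lr0 initial learning rate (> 0).
#' @param gamma decay factor per step (0 < gamma <= 1).
#' @param step_size epochs per decay step (>= 1).
#' @param epochs maximum training epochs.
#' @param patience early-stopping patience on validation MSE (`Inf` disables).
#' @param weight_decay AdamW decoupled weight decay.
#' @param val_fraction fraction of the training examples held out for early
#'   stopping.
#' @param seed seed for the validation split, batch shuffling.
#' @return list of class `train_config`.
#' @export
train_config <- function(batch_size = 256L, lr0 = 0.001, gamma = 0.9,
                         step_size = 20L, epochs = 100L, patience = 20L,
                         weight_decay = 0.01, val_fraction = 0.1, seed = 1L) {
  stopifnot(lr0 > 0, gamma > 0, gamma <= 1, step_size >= 1, batch_size >= 1,
            epochs >= 1, val_fraction >= 0, val_fraction < 1)
  structure(list(batch_size = as.integer(batch_size), lr0 = lr0, gamma = gamma,
                 step_size = as.integer(step_size), epochs = as.integer(epochs),
                 patience = patience, weight_decay = weight_decay,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Step-decay learning rate
#'
#' `lr0 * gamma^floor(epoch / step_size)` for a 0-based epoch index: the
#' learning rate decays by `gamma` every `step_size` epochs.
#'
#' @param epoch 0-based epoch index (>= 0).
#' @param lr0 initial learning rate.
#' @param gamma decay factor.
#' @param step_size epochs per decay.
#' @return learning rate for that epoch.
#' @export
step_lr <- function(epoch, lr0 = 0.001, gamma = 0.9, step_size = 20L) {
  stopifnot(all(epoch >= 0))
  lr0 * gamma^(floor(epoch / step_size))
}

# Extend a feature store with any ordered pairs it has not seen yet.
ensure_pairs <- function(feats, drug_map, examples, cfg) {
  if (!cfg$use_graph || !cfg$use_pair_graph) return(feats)
  keys <- unique(pair_key(examples$drug_a, examples$drug_b))
  new <- setdiff(keys, names(feats$pairs))
  for (k in new) {
    ab <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    gp <- pair_graph(feats$drugs[[ab[1L]]]$graph, feats$drugs[[ab[2L]]]$graph)
    feats$pairs[[k]] <- list(
      powers = power_graph_set(gp$adjacency, cfg$power_mode, cfg$add_self_loops),
      node_features = gp$node_features, n = gp$atom_count)
  }
  feats
}

augment_orders <- function(examples) {
  sw <- examples
  sw$drug_a <- examples$drug_b
  sw$drug_b <- examples$drug_a
  rbind(examples, sw)
}

#' Train a synergy model
#'
#' Minibatch AdamW with the step-decay schedule, per-epoch training and
#' validation loss history, and early stopping on validation MSE. The model
#' with the best validation loss is returned. Fully reproducible per seed.
#'
#' @param model a [build_variant()] model.
#' @param bundle a [synergy_bundle()] of training examples.
#' @param config a [train_config()].
#' @param feats optional precomputed feature store (built if `NULL`).
#' @param quiet suppress per-epoch progress.
#' @return list of class `synergy_fit` with `model`, `history` (per-epoch
#'   data frame), `feats` and `cellmat`.
#' @export
train_synergy <- function(model, bundle, config = train_config(), feats = NULL,
                          quiet = TRUE) {
  cfg <- model$config
  # work on a private copy of the normalization state so training never
  # mutates the caller's model and equal seeds give equal runs
  st <- new.env(parent = emptyenv())
  for (nm in ls(model$state)) st[[nm]] <- model$state[[nm]]
  model$state <- st
  ex <- canonical_order(bundle$examples)
  if (nrow(ex) < 2L) stop("need at least two training examples")
  if (is.null(feats)) {
    allpairs0 <- unique(ex[, c("drug_a", "drug_b")])
    allpairs <- if (cfg$order_augment)
      unique(rbind(allpairs0, stats::setNames(allpairs0[, 2:1],
                                              c("drug_a", "drug_b"))))
    else allpairs0
    used <- unique(c(ex$drug_a, ex$drug_b))
    feats <- prepare_features(bundle$drugs[used], allpairs, cfg,
                              need_pair_graphs = cfg$use_graph && cfg$use_pair_graph)
  }
  cellmat <- cell_input_matrix(cfg, model$dims, bundle$cells)
  run <- function() {
    set.seed(config$seed)
    nval <- floor(config$val_fraction * nrow(ex))
    vidx <- if (nval > 0L) sample.int(nrow(ex), nval) else integer(0)
    val <- ex[vidx, , drop = FALSE]
    tr <- if (nval > 0L) ex[-vidx, , drop = FALSE] else ex
    if (cfg$order_augment) tr <- augment_orders(tr)
    opt <- adamw_new(model$params, weight_decay = config$weight_decay)
    params <- model$params
    best <- list(loss = Inf, params = params, state = as.list(model$state),
                 epoch = 0L)
    hist <- data.frame(epoch = integer(), lr = numeric(),
                       train_mse = numeric(), val_mse = numeric())
    waited <- 0L
    for (epoch in seq_len(config$epochs)) {
      lr <- step_lr(epoch - 1L, config$lr0, config$gamma, config$step_size)
      ord <- sample.int(nrow(tr))
      losses <- numeric(0)
      for (s in seq(1L, nrow(tr), by = config$batch_size)) {
        bidx <- ord[s:min(s + config$batch_size - 1L, nrow(tr))]
        batch <- tr[bidx, , drop = FALSE]
        model$params <- params
        fb <- forward_batch(model, feats, batch, cellmat, training = TRUE)
        loss <- op_mse(fb$rt$tp, fb$pred, batch$synergy)
        lval <- as.numeric(tp_val(fb$rt$tp, loss))
        if (!is.finite(lval))
          stop("non-finite training loss in epoch ", epoch,
               " (batch starting at shuffled index ", s, ")")
        losses <- c(losses, lval)
        tape_backward(fb$rt$tp, loss)
        params <- adamw_step(opt, params, rt_grads(fb$rt), lr)
      }
      model$params <- params
      vmse <- if (nrow(val) > 0L) {
        vp <- predict(model, val, feats, cellmat)
        mse_loss(vp, val$synergy)
      } else mean(losses)
      hist <- rbind(hist, data.frame(epoch = epoch, lr = lr,
                                     train_mse = mean(losses), val_mse = vmse))
      if (!quiet)
        message(sprintf("epoch %3d  lr %.5f  train %8.3f  val %8.3f",
                        epoch, lr, mean(losses), vmse))
      if (vmse < best$loss) {
        best <- list(loss = vmse, params = params,
                     state = as.list(model$state), epoch = epoch)
        waited <- 0L
      } else {
        waited <- waited + 1L
        if (waited >= config$patience) break
      }
    }
    model$params <- best$params
    st <- new.env(parent = emptyenv())
    for (nm in names(best$state)) st[[nm]] <- best$state[[nm]]
    model$state <- st
    list(model = model, history = hist, best_epoch = best$epoch)
  }
  res <- with_seed(config$seed, run())
  structure(list(model = res$model, history = res$history,
                 best_epoch = res$best_epoch, feats = feats, cellmat = cellmat),
            class = "synergy_fit")
}

#' Predict synergy scores with a fitted model
#'
#' @param fit a `synergy_fit` from [train_synergy()].
#' @param examples data frame with `drug_a`, `drug_b`, `cell_line`.
#' @return numeric vector of predictions.
#' @export
predict_synergy <- function(fit, examples) {
  feats <- ensure_pairs(fit$feats, NULL, if (fit$model$config$order_augment)
    augment_orders(examples) else examples, fit$model$config)
  predict(fit$model, examples, feats, fit$cellmat)
}

metric_set <- function(pred, truth) {
  res <- c(mse = mse_loss(pred, truth), rmse = sqrt(mse_loss(pred, truth)),
           pcc = NA_real_, scc = NA_real_)
  if (stats::sd(pred) > 0 && stats::sd(truth) > 0) {
    res["pcc"] <- stats::cor(pred, truth)
    res["scc"] <- stats::cor(pred, truth, method = "spearman")
  }
  res
}

#' Evaluate predictions against true synergy scores
#'
#' MSE, RMSE, Pearson and Spearman correlations, overall and per stratum
#' (e.g. tissue or cell line). Correlations on zero-variance inputs are
#' reported as `NA` and listed in `notes` rather than propagating NaN.
#'
#' @param pred,truth numeric vectors of equal length (>= 2).
#' @param strata optional named list of factors (e.g.
#'   `list(tissue = ..., cell_line = ...)`), each of `length(pred)`.
#' @return list of class `metrics_report` with fields `mse`, `rmse`, `pcc`,
#'   `scc`, `n`, per-stratum data frames, and `notes`.
#' @export
evaluate_predictions <- function(pred, truth, strata = NULL) {
  if (length(pred) != length(truth))
    stop("length mismatch: ", length(pred), " vs ", length(truth))
  if (length(pred) < 2L) stop("need at least two examples to evaluate")
  pred <- as.numeric(pred); truth <- as.numeric(truth)
  overall <- metric_set(pred, truth)
  notes <- character(0)
  if (is.na(overall["pcc"]))
    notes <- c(notes, "correlations undefined: zero-variance input")
  out <- list(mse = unname(overall["mse"]), rmse = unname(overall["rmse"]),
              pcc = unname(overall["pcc"]), scc = unname(overall["scc"]),
              n = length(pred), notes = notes)
  for (sname in names(strata)) {
    f <- strata[[sname]]
    rows <- lapply(split(seq_along(pred), f), function(i) {
      if (length(i) < 2L) return(NULL)
      m <- metric_set(pred[i], truth[i])
      data.frame(stratum = f[i[1L]], n = length(i), mse = m["mse"],
                 rmse = m["rmse"], pcc = m["pcc"], scc = m["scc"],
                 row.names = NULL)
    })
    out[[paste0("per_", sname)]] <- do.call(rbind, rows)
  }
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("MSE %.4f  RMSE %.4f  PCC %.4f  SCC %.4f  (n = %d)\n",
              x$mse, x$rmse, x$pcc, x$scc, x$n))
  for (note in x$notes) cat("note:", note, "\n")
  invisible(x)
}

#' k-fold cross-validation
#'
#' Trains one model per fold on the [kfold()] partition and reports per-fold
#' and aggregate (mean +/- sd) metrics. With `scale_mode = "train"` (the
#' default) expression factors are re-standardized per fold using only the
#' statistics of cell lines that occur in that fold's training examples,
#' avoiding information leakage; `"global"` keeps the load-time scaling.
#'
#' @param bundle a [synergy_bundle()].
#' @param k number of folds.
#' @param model_config a [synergy_config()].
#' @param config a [train_config()].
#' @param variant model variant name.
#' @param scale_mode `"train"` or `"global"` expression scaling.
#' @param quiet suppress progress.
#' @return list of class `cv_result` with `folds` (metrics per fold),
#'   `summary` (mean and sd per metric), and `reports`.
#' @export
cross_validate <- function(bundle, k = 5L, model_config = synergy_config(),
                           config = train_config(), variant = "MMFSyn",
                           scale_mode = c("train", "global"), quiet = TRUE) {
  scale_mode <- match.arg(scale_mode)
  folds <- kfold(bundle$examples, k, config$seed)
  dims <- bundle_dims(bundle)
  reports <- vector("list", k)
  for (f in seq_len(k)) {
    fb <- bundle
    if (scale_mode == "train") {
      tc <- unique(folds[[f]]$train$cell_line)
      raw <- bundle$cells$expr_raw
      mu <- colMeans(raw[tc, , drop = FALSE])
      s <- sqrt(colMeans((raw[tc, , drop = FALSE] -
                            rep(mu, each = length(tc)))^2))
      s[s == 0] <- Inf
      fb$cells$expr <- (raw - rep(mu, each = nrow(raw))) *
        rep(1 / s, each = nrow(raw))
    }
    mcfg <- model_config
    mcfg$seed <- model_config$seed + f
    model <- build_variant(variant, mcfg, dims)
    tcfg <- config
    tcfg$seed <- config$seed + f
    fitbundle <- synergy_bundle(folds[[f]]$train, bundle$drugs, fb$cells)
    fit <- train_synergy(model, fitbundle, tcfg, quiet = quiet)
    vp <- predict_synergy(fit, folds[[f]]$validation)
    truth <- folds[[f]]$validation$synergy
    strata <- list(cell_line = folds[[f]]$validation$cell_line)
    tissue <- bundle$cells$tissue[folds[[f]]$validation$cell_line]
    if (!all(is.na(tissue))) strata$tissue <- tissue
    reports[[f]] <- evaluate_predictions(vp, truth, strata)
    if (!quiet) message(sprintf("fold %d: %s", f,
                                format(round(reports[[f]]$mse, 2))))
  }
  met <- t(vapply(reports, function(r) c(mse = r$mse, rmse = r$rmse,
                                         pcc = r$pcc, scc = r$scc),
                  numeric(4L)))
  structure(list(folds = as.data.frame(met),
                 summary = data.frame(metric = colnames(met),
                                      mean = colMeans(met),
                                      sd = apply(met, 2L, stats::sd),
                                      row.names = NULL),
                 reports = reports), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (mean +/- sd):\n", nrow(x$folds)))
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-5s %8.3f +/- %.3f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}

#' Data-driven model dimensions of a bundle
#'
#' @param bundle a [synergy_bundle()].
#' @return list with `expr_k`, `mut_m`, `cell_ids`.
#' @export
bundle_dims <- function(bundle) {
  list(expr_k = ncol(bundle$cells$expr), mut_m = ncol(bundle$cells$mut),
       cell_ids = rownames(bundle$cells$expr))
}
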