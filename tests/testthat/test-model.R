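test_that("the predictor emits one scalar per example, deterministically", {
  fit <- tiny_fit()
  b <- tiny_bundle()
  one <- b$examples[1, , drop = FALSE]
  p1 <- predict_synergy(fit, one)
  expect_length(p1, 1L)
  expect_true(is.finite(p1))
  expect_identical(p1, predict_synergy(fit, one))
})

test_that("batched prediction equals example-by-example prediction", {
  fit <- tiny_fit()
  ex <- tiny_bundle()$examples[1:6, ]
  batched <- predict_synergy(fit, ex)
  looped <- vapply(seq_len(6), function(i)
    predict_synergy(fit, ex[i, , drop = FALSE]), 0)
  expect_equal(batched, looped, tolerance = 1e-12)
})

test_that("mse_loss matches the direct formula", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(c(0, 2), c(2, 2)), 2)
  set.seed(21)
  for (i in 1:100) {
    p <- rnorm(7); t <- rnorm(7)
    expect_equal(mse_loss(p, t), mean((p - t)^2))
  }
  expect_error(mse_loss(1:3, 1:2), "mismatch")
})

test_that("build_variant covers all named variants and rejects unknown names", {
  b <- tiny_bundle()
  dims <- bundle_dims(b)
  expect_error(build_variant("nope", tiny_config(), dims), "MMFSyn_base")
  base <- build_variant("MMFSyn_base", tiny_config(), dims)
  expect_false(any(grepl("^seq\\.|^gcn\\.", names(base$params))))
  onehot <- build_variant("Cell_base", tiny_config(), dims)
  expect_equal(nrow(onehot$params[["cell.l1.W"]]), length(dims$cell_ids))
  gen <- build_variant("Cell_gen", tiny_config(), dims)
  expect_equal(nrow(gen$params[["cell.l1.W"]]), dims$expr_k)
  mut <- build_variant("Cell_mut", tiny_config(), dims)
  expect_equal(nrow(mut$params[["cell.l1.W"]]), dims$mut_m)
})

test_that("every variant trains one step and predicts without error", {
  b <- tiny_bundle()
  dims <- bundle_dims(b)
  small <- synergy_bundle(b$examples[1:12, ], b$drugs, b$cells)
  for (v in c("MMFSyn", "MMFSyn_base", "Seq_A", "Seq_B", "Graph_A", "Graph_B",
              "MMFSyn-CA", "MMFSyn-SA", "Cell_base", "Cell_gen", "Cell_mut")) {
    m <- build_variant(v, tiny_config(), dims)
    fit <- train_synergy(m, small, train_config(batch_size = 12L, epochs = 1L,
                                                patience = Inf, val_fraction = 0,
                                                seed = 5L))
    expect_true(all(is.finite(fit$history$train_mse)), info = v)
    p <- predict_synergy(fit, small$examples[1:3, ])
    expect_length(p, 3L)
    expect_true(all(is.finite(p)), info = v)
  }
})

test_that("parameter count is a pure function of the configuration", {
  dims <- bundle_dims(tiny_bundle())
  m1 <- build_variant("MMFSyn", tiny_config(), dims)
  m2 <- build_variant("MMFSyn", tiny_config(), dims)
  expect_identical(lapply(m1$params, dim), lapply(m2$params, dim))
  expect_identical(m1$params, m2$params)   # same seed, same init
  expect_equal(sum(vapply(m1$params, length, 0L)),
               sum(vapply(m2$params, length, 0L)))
})

test_that("every modality contributes to the prediction", {
  fit <- tiny_fit()
  b <- tiny_bundle()
  ex <- b$examples[1, , drop = FALSE]
  p0 <- predict_synergy(fit, ex)
  perturb <- function(mutator) {
    f2 <- fit
    f2$feats <- mutator(fit$feats)
    predict(f2$model, ex, f2$feats, f2$cellmat)
  }
  d <- ex$drug_a
  # fingerprint
  pf <- perturb(function(fe) { fe$drugs[[d]]$fp <- 1L - fe$drugs[[d]]$fp; fe })
  expect_false(isTRUE(all.equal(p0, pf)))
  # sequence features
  ps <- perturb(function(fe) {
    fe$drugs[[d]]$seq_padded <- fe$drugs[[d]]$seq_padded + 0.5
    fe
  })
  expect_false(isTRUE(all.equal(p0, ps)))
  # graph node features
  pg <- perturb(function(fe) {
    fe$drugs[[d]]$graph$node_features <- fe$drugs[[d]]$graph$node_features + 0.5
    fe
  })
  expect_false(isTRUE(all.equal(p0, pg)))
  # point cloud
  pc <- perturb(function(fe) { fe$drugs[[d]]$cloud$coords <- fe$drugs[[d]]$cloud$coords + 1; fe })
  expect_false(isTRUE(all.equal(p0, pc)))
  # cell features
  f3 <- fit
  f3$cellmat <- fit$cellmat + 0.5
  pcell <- predict(f3$model, ex, f3$feats, f3$cellmat)
  expect_false(isTRUE(all.equal(p0, pcell)))
})

test_that("prediction averages both drug orders when order augmentation is on", {
  fit <- tiny_fit()
  ex <- tiny_bundle()$examples[2, , drop = FALSE]
  swapped <- ex
  swapped$drug_a <- ex$drug_b
  swapped$drug_b <- ex$drug_a
  expect_equal(predict_synergy(fit, ex), predict_synergy(fit, swapped))
})

test_that("model summary reports stable parameter-group totals", {
  m <- tiny_fit()$model
  df <- summary(m)
  expect_true(all(c("cell", "cloud", "gcn", "head", "seq") %in% df$group))
  expect_equal(sum(df$parameters), sum(vapply(m$params, length, 0L)))
})
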