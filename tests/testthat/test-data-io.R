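make_toy_files <- function(dir = tempfile("io")) {
  dir.create(dir)
  ex <- data.frame(drug_a = c("d1", "d1", "d2"), drug_b = c("d2", "d3", "d3"),
                   cell_line = c("c1", "c1", "c2"), synergy = c(1.5, -2, 10))
  write_synergy_table(ex, file.path(dir, "syn.csv"))
  expr <- data.frame(cell_line = c("c1", "c2"), F1 = c(1, 2), F2 = c(0.5, -1))
  write.table(expr, file.path(dir, "expr.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  mut <- data.frame(cell_line = c("c1", "c2"), G1 = c(0, 1), G2 = c(1, 0))
  write.table(mut, file.path(dir, "mut.tsv"), sep = "\t", row.names = FALSE,
              quote = FALSE)
  dir
}

test_that("synergy tables round-trip and errors carry line positions", {
  dir <- make_toy_files()
  ex <- read_synergy_table(file.path(dir, "syn.csv"))
  expect_equal(nrow(ex), 3L)
  expect_equal(ex$synergy, c(1.5, -2, 10))
  p2 <- file.path(dir, "again.tsv")
  write_synergy_table(ex, p2)
  expect_equal(read_synergy_table(p2), ex)
  # missing column
  bad1 <- file.path(dir, "bad1.csv")
  writeLines("drug_a,drug_b,score\na,b,1", bad1)
  expect_error(read_synergy_table(bad1), "missing column")
  # non-numeric score with the offending line number
  bad2 <- file.path(dir, "bad2.csv")
  writeLines(c("drug_a,drug_b,cell_line,synergy", "a,b,c,1.0", "a,d,c,oops"), bad2)
  expect_error(read_synergy_table(bad2), "line 3")
})

test_that("duplicated combinations are rejected, treating pairs as unordered", {
  dir <- tempfile("dup"); dir.create(dir)
  p <- file.path(dir, "syn.csv")
  writeLines(c("drug_a,drug_b,cell_line,synergy",
               "a,b,c1,1", "b,a,c1,2"), p)
  expect_error(read_synergy_table(p), "duplicated")
})

test_that("omics readers z-score expression and validate mutations", {
  dir <- make_toy_files()
  cells <- read_omics(file.path(dir, "expr.tsv"), file.path(dir, "mut.tsv"))
  expect_s3_class(cells, "cell_profiles")
  expect_true(all(abs(colMeans(cells$expr)) < 1e-9))
  expect_true(all(cells$mut %in% c(0, 1)))
  expect_equal(rownames(cells$expr), rownames(cells$mut))
  # non-binary mutation entry
  bad <- file.path(dir, "mutbad.tsv")
  writeLines(c("cell_line\tG1", "c1\t2"), bad)
  expect_error(read_omics(file.path(dir, "expr.tsv"), bad), "non-binary")
  # mismatched cell sets are excluded with a warning
  extra <- file.path(dir, "mut3.tsv")
  writeLines(c("cell_line\tG1", "c1\t0", "c2\t1", "c9\t0"), extra)
  expect_warning(cells2 <- read_omics(file.path(dir, "expr.tsv"), extra), "c9")
  expect_equal(sort(rownames(cells2$mut)), c("c1", "c2"))
})

test_that("drug maps read from CSV and reject duplicates and bad SMILES", {
  dir <- tempfile("dm"); dir.create(dir)
  p <- file.path(dir, "drugs.csv")
  writeLines(c("drug_id,smiles", "d1,CCO", "d2,c1ccccc1"), p)
  dm <- read_drug_map(p)
  expect_equal(unname(dm["d1"]), "CCO")
  writeLines(c("drug_id,smiles", "d1,CCO", "d1,CCN"), p)
  expect_error(read_drug_map(p), "duplicated")
  writeLines(c("drug_id,smiles", "d1,((bad"), p)
  expect_error(read_drug_map(p), "parse error")
})

test_that("train/test split honors the ratio and is a pure function of ids and seed", {
  ex <- tiny_bundle()$examples
  big <- do.call(rbind, lapply(1:25, function(i) {
    e <- ex; e$cell_line <- paste0(e$cell_line, "_", i); e
  }))
  sp <- split_train_test(big, 0.9, seed = 4L)
  expect_equal(nrow(sp$train), floor(0.9 * nrow(big)))
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(big))
  key <- function(d) paste(d$drug_a, d$drug_b, d$cell_line)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  sp2 <- split_train_test(big, 0.9, seed = 4L)
  expect_identical(sp, sp2)
  # row order must not matter
  shuffled <- big[sample(nrow(big)), ]
  sp3 <- split_train_test(shuffled, 0.9, seed = 4L)
  expect_setequal(key(sp$train), key(sp3$train))
  expect_error(split_train_test(big[0, ], 0.9), "empty")
  expect_error(split_train_test(big, 1.2), "ratio")
})

test_that("group-wise splits hold out whole drug pairs or cell lines", {
  ex <- tiny_bundle()$examples
  sp <- split_train_test(ex, 0.7, seed = 2L, by = "cell-line")
  expect_length(intersect(unique(sp$train$cell_line),
                          unique(sp$test$cell_line)), 0L)
  sp2 <- split_train_test(ex, 0.7, seed = 2L, by = "drug-pair")
  pk <- function(d) paste(pmin(d$drug_a, d$drug_b), pmax(d$drug_a, d$drug_b))
  expect_length(intersect(unique(pk(sp2$train)), unique(pk(sp2$test))), 0L)
})

test_that("kfold partitions are exhaustive, exclusive and reproducible", {
  ex <- tiny_bundle()$examples[1:10, ]
  f5 <- kfold(ex, 5L, seed = 3L)
  expect_length(f5, 5L)
  expect_true(all(vapply(f5, function(f) nrow(f$validation), 0L) == 2L))
  key <- function(d) paste(d$drug_a, d$drug_b, d$cell_line)
  allval <- unlist(lapply(f5, function(f) key(f$validation)))
  expect_setequal(allval, key(ex))
  expect_equal(anyDuplicated(allval), 0L)
  for (k in c(2L, 3L, 7L)) {
    fk <- kfold(tiny_bundle()$examples, k, seed = k)
    sizes <- vapply(fk, function(f) nrow(f$validation), 0L)
    expect_lte(max(sizes) - min(sizes), 1L)
    for (f in fk)
      expect_equal(nrow(f$train) + nrow(f$validation),
                   nrow(tiny_bundle()$examples))
  }
  expect_identical(kfold(ex, 5L, seed = 3L), f5)
  expect_error(kfold(ex, 11L), "exceeds")
  expect_error(kfold(ex, 1L), "at least 2")
})

test_that("checkpoints round-trip bitwise and detect corruption", {
  fit <- tiny_fit()
  ex <- tiny_bundle()$examples[1:4, ]
  before <- predict_synergy(fit, ex)
  path <- tempfile(fileext = ".rds")
  save_checkpoint(fit$model, path)
  restored <- load_checkpoint(path)
  expect_identical(restored$config, fit$model$config)
  expect_identical(restored$params, fit$model$params)
  f2 <- fit
  f2$model <- restored
  expect_identical(predict_synergy(f2, ex), before)
  # truncated file gives a clean error
  raw <- readBin(path, "raw", file.size(path))
  trunc <- tempfile(fileext = ".rds")
  writeBin(raw[1:20], trunc)
  expect_error(load_checkpoint(trunc), "corrupt|truncated")
  # wrong version is rejected explicitly
  saveRDS(list(version = "other-1"), path)
  expect_error(load_checkpoint(path), "incompatible")
})
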