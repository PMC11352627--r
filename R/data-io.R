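# Readers and writers for synergy tables, drug maps, omics matrices, splits
# and checkpoints. Readers reject malformed input with line-addressed errors.

read_delim_checked <- function(path, required, what) {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                          check.names = FALSE, quote = "\"", comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " (", path, "): missing column(s) ", paste(missing, collapse = ", "))
  df
}

#' Read a synergy table
#'
#' CSV/TSV with header columns `drug_a`, `drug_b`, `cell_line`, `synergy`
#' (one quadruple per row). Scores must be numeric; duplicated combinations
#' (treating the drug pair as unordered) are rejected.
#'
#' @param path file path (`.csv` comma-separated, `.tsv`/`.txt` tab-separated).
#' @return data frame with the four columns, row order preserved.
#' @export
read_synergy_table <- function(path) {
  df <- read_delim_checked(path, c("drug_a", "drug_b", "cell_line", "synergy"),
                           "synergy table")
  sc <- suppressWarnings(as.numeric(df$synergy))
  bad <- which(is.na(sc) & !is.na(df$synergy) | is.na(df$synergy))
  if (length(bad))
    stop("synergy table (", path, "): non-numeric score at line ",
         bad[1L] + 1L)  # +1 for the header line
  df$synergy <- sc
  validate_examples(df)
  df[, c("drug_a", "drug_b", "cell_line", "synergy")]
}

validate_examples <- function(df) {
  lo <- pmin(df$drug_a, df$drug_b)
  hi <- pmax(df$drug_a, df$drug_b)
  key <- paste(lo, hi, df$cell_line, sep = "\r")
  d <- which(duplicated(key))
  if (length(d))
    stop("duplicated drug-drug-cell combination at row ", d[1L], ": ",
         df$drug_a[d[1L]], " + ", df$drug_b[d[1L]], " on ", df$cell_line[d[1L]])
  invisible(df)
}

#' Write a synergy table
#'
#' @param examples data frame with `drug_a`, `drug_b`, `cell_line`, `synergy`.
#' @param path output path; `.tsv` writes tab-separated, otherwise CSV.
#' @export
write_synergy_table <- function(examples, path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path)) "\t" else ","
  utils::write.table(examples, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a drug map (id to SMILES)
#'
#' CSV/TSV with columns `drug_id` and `smiles`, or an SDF file (converted
#' through OpenBabel; molecule titles become drug ids). Every SMILES must
#' parse.
#'
#' @param path file path.
#' @return named character vector, names = drug ids, values = SMILES.
#' @export
read_drug_map <- function(path) {
  if (grepl("\\.sdf$", path, ignore.case = TRUE)) {
    out <- ob_run(c(shQuote(path), "-osmi"))
    lines <- strsplit(out, "\n")[[1L]]
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[[:space:]]+")
    smiles <- vapply(parts, `[`, "", 1L)
    ids <- vapply(parts, function(x) if (length(x) > 1L) x[2L] else NA_character_, "")
    if (any(is.na(ids))) stop("SDF drug map (", path, "): molecules without titles")
  } else {
    df <- read_delim_checked(path, c("drug_id", "smiles"), "drug map")
    ids <- as.character(df$drug_id)
    smiles <- as.character(df$smiles)
  }
  if (any(duplicated(ids))) stop("drug map (", path, "): duplicated drug ids")
  for (i in seq_along(smiles)) mol_data(smiles[i])  # parse check, cached
  stats::setNames(smiles, ids)
}

#' Read cell-line omics tables
#'
#' Two TSV matrices whose first column is the cell-line id: dense real
#' expression factors and binary mutation calls. Expression factors are
#' z-scored per factor column at load (the raw matrix is kept alongside for
#' fold-wise re-scaling during cross-validation). Cells present in only one
#' file are excluded with a warning. An optional annotation table adds a
#' tissue label per cell line.
#'
#' @param expr_path TSV, cell lines x factors.
#' @param mut_path TSV, cell lines x genes, entries 0/1.
#' @param tissue_path optional CSV/TSV with columns `cell_line`, `tissue`.
#' @return list of class `cell_profiles` with matrices `expr` (z-scored),
#'   `expr_raw`, `mut`, and vector `tissue`.
#' @export
read_omics <- function(expr_path, mut_path, tissue_path = NULL) {
  ex <- read_delim_checked(expr_path, character(), "expression matrix")
  mu <- read_delim_checked(mut_path, character(), "mutation matrix")
  exm <- as.matrix(ex[, -1L, drop = FALSE])
  rownames(exm) <- as.character(ex[[1L]])
  mum <- as.matrix(mu[, -1L, drop = FALSE])
  rownames(mum) <- as.character(mu[[1L]])
  if (!all(mum %in% c(0, 1))) {
    bad <- which(!(mum %in% c(0, 1)))[1L]
    stop("mutation matrix (", mut_path, "): non-binary value ",
         mum[bad], " for cell ", rownames(mum)[(bad - 1L) %% nrow(mum) + 1L])
  }
  common <- intersect(rownames(exm), rownames(mum))
  dropped <- setdiff(union(rownames(exm), rownames(mum)), common)
  if (length(dropped))
    warning("cells present in only one omics file were excluded: ",
            paste(dropped, collapse = ", "))
  if (length(common) == 0L) stop("no cell lines shared between the omics files")
  exm <- exm[common, , drop = FALSE]
  mum <- mum[common, , drop = FALSE]
  tissue <- stats::setNames(rep(NA_character_, length(common)), common)
  if (!is.null(tissue_path)) {
    tt <- read_delim_checked(tissue_path, c("cell_line", "tissue"), "tissue table")
    hit <- intersect(common, as.character(tt$cell_line))
    tissue[hit] <- tt$tissue[match(hit, tt$cell_line)]
  }
  structure(list(expr = zscore(exm), expr_raw = exm, mut = mum, tissue = tissue),
            class = "cell_profiles")
}

#' Assemble a dataset bundle
#'
#' Validates that every example resolves against the drug map and cell
#' profiles.
#'
#' @param examples synergy table data frame.
#' @param drugs named SMILES vector from [read_drug_map()].
#' @param cells a `cell_profiles` object from [read_omics()].
#' @return list of class `synergy_bundle`.
#' @export
synergy_bundle <- function(examples, drugs, cells) {
  validate_examples(examples)
  ud <- unique(c(examples$drug_a, examples$drug_b))
  miss <- setdiff(ud, names(drugs))
  if (length(miss)) stop("drugs missing from the drug map: ",
                         paste(miss, collapse = ", "))
  missc <- setdiff(unique(examples$cell_line), rownames(cells$expr))
  if (length(missc)) stop("cell lines missing from the omics tables: ",
                          paste(missc, collapse = ", "))
  structure(list(examples = examples, drugs = drugs, cells = cells),
            class = "synergy_bundle")
}

#' @export
print.synergy_bundle <- function(x, ...) {
  cat(sprintf("<synergy_bundle> %d examples, %d drugs, %d cell lines\n",
              nrow(x$examples), length(x$drugs), nrow(x$cells$expr)))
  invisible(x)
}

canonical_order <- function(examples)
  examples[order(examples$drug_a, examples$drug_b, examples$cell_line), ,
           drop = FALSE]

#' Random train/test split of synergy examples
#'
#' Splits after canonical sorting, so the partition depends only on the
#' example identities and the seed, not on row order. The training set gets
#' `floor(ratio * n)` examples.
#'
#' @param examples synergy table data frame.
#' @param ratio training fraction in (0, 1); 0.9 gives the 9:1 protocol.
#' @param seed RNG seed.
#' @param by split unit: `"random"` over quadruples, `"drug-pair"` or
#'   `"cell-line"` hold out whole groups (stricter generalization tests).
#' @return list with `train` and `test` data frames.
#' @export
split_train_test <- function(examples, ratio = 0.9, seed = 1L,
                             by = c("random", "drug-pair", "cell-line")) {
  by <- match.arg(by)
  if (nrow(examples) == 0L) stop("empty example table")
  if (!(ratio > 0 && ratio < 1)) stop("ratio must be in (0, 1)")
  ex <- canonical_order(examples)
  n <- nrow(ex)
  if (by == "random") {
    k <- floor(ratio * n)
    idx <- with_seed(seed, sample.int(n, k))
    return(list(train = ex[idx, , drop = FALSE],
                test = ex[-idx, , drop = FALSE]))
  }
  grp <- if (by == "drug-pair")
    paste(pmin(ex$drug_a, ex$drug_b), pmax(ex$drug_a, ex$drug_b), sep = "\r")
  else ex$cell_line
  ug <- sort(unique(grp))
  kg <- max(1L, floor(ratio * length(ug)))
  tg <- with_seed(seed, sample(ug, kg))
  list(train = ex[grp %in% tg, , drop = FALSE],
       test = ex[!grp %in% tg, , drop = FALSE])
}

#' k-fold partition of synergy examples
#'
#' Every example lands in exactly one validation fold; fold sizes differ by at
#' most one. Fold assignment depends only on example identities and the seed.
#'
#' @param examples synergy table data frame.
#' @param k number of folds (>= 2).
#' @param seed RNG seed.
#' @return list of k lists, each with `train` and `validation` data frames.
#' @export
kfold <- function(examples, k = 5L, seed = 1L) {
  n <- nrow(examples)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k = ", k, " exceeds the number of examples (", n, ")")
  ex <- canonical_order(examples)
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  lapply(seq_len(k), function(f)
    list(train = ex[fold != f, , drop = FALSE],
         validation = ex[fold == f, , drop = FALSE]))
}

#' Save a model checkpoint
#'
#' Stores the configuration, all weights, batch-normalization running moments
#' and the data-driven dimensions, versioned; [load_checkpoint()] restores a
#' model whose predictions are bitwise identical.
#'
#' @param model a `synergy_model`.
#' @param path output file.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(version = model$version, config = model$config,
               params = model$params, dims = model$dims,
               state = as.list(model$state)), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path checkpoint file from [save_checkpoint()].
#' @return a `synergy_model`.
#' @export
load_checkpoint <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("corrupt or truncated checkpoint: ",
                                           path, call. = FALSE))
  if (!is.list(obj) || is.null(obj$version))
    stop("corrupt or truncated checkpoint: ", path)
  if (!identical(obj$version, "synergynet-checkpoint-1"))
    stop("incompatible checkpoint version: ", obj$version)
  st <- new.env(parent = emptyenv())
  for (nm in names(obj$state)) st[[nm]] <- obj$state[[nm]]
  structure(list(config = obj$config, params = obj$params, dims = obj$dims,
                 state = st, version = obj$version), class = "synergy_model")
}
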