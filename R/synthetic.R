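# Synthetic fixture generator. Emulates the shapes and statistical structure
# of a drug-combination screen -- drug-like SMILES, dense correlated
# expression factors, sparse binary mutations, and synergy scores
# concentrated near zero with a positive tail -- with a documented generating
# function, so optimization and plumbing are testable end to end and recovery
# has a known target. It makes no claim to real pharmacology.

# Curated molecule vocabulary: ring cores that accept a prefix substituent
# before the first ring atom and a tail after the last one. All combinations
# are valence-correct by construction and pre-validated in tests.
synth_cores <- c("c1ccccc1", "c1ccncc1", "c1cncnc1", "c1ccc2ccccc2c1",
                 "c1ccsc1", "c1ccoc1", "C1CCCCC1", "C1CCNCC1", "C1CCOCC1",
                 "C1CCCC1", "c1ccc2[nH]ccc2c1", "C1CCNC1")
synth_prefixes <- c("", "C", "CC", "CCC", "OC", "N", "FC", "ClC", "COC")
synth_tails <- c("", "C", "CC", "O", "OC", "N", "CO", "CN", "C(=O)N",
                 "C(=O)OC", "CCN", "F", "Cl", "C#N", "CC(=O)N", "S(=O)(=O)N")
synth_linkers <- c("C(=O)N", "CC(=O)N", "OC", "NC(=O)", "C(=O)OC", "CNC")

#' Specification of a synthetic synergy dataset
#'
#' Defaults emulate a desk-scale screen: a few tens of drug-like molecules, a
#' dozen cell lines, dense correlated expression factors, Bernoulli(0.02)
#' mutations, and scores centered near zero with spread and positive skew
#' giving a marginal concentrated in roughly \[-50, 75\]. `noise_sd = NULL`
#' derives the noise level from `target_pcc`, the Pearson correlation an
#' oracle knowing the generating function would attain (default 0.95).
#'
#' @param n_drugs,n_cells,n_examples dataset sizes.
#' @param expr_factors,mut_genes omics widths (k and m).
#' @param noise_sd additive Gaussian noise on the scores, or `NULL` to derive
#'   it from `target_pcc`.
#' @param target_pcc oracle correlation used when `noise_sd` is `NULL`.
#' @param score_center,score_spread location and scale of the score marginal.
#' @param score_tail_weight positive-skew weight of the marginal.
#' @param seed RNG seed for molecules, omics, triple sampling and noise.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_drugs = 16L, n_cells = 17L, n_examples = 2000L,
                           expr_factors = 40L, mut_genes = 200L,
                           noise_sd = NULL, target_pcc = 0.95,
                           score_center = 5, score_spread = 18,
                           score_tail_weight = 1, seed = 1L) {
  stopifnot(n_drugs >= 2L, n_cells >= 1L, n_examples >= 1L,
            expr_factors >= 1L, mut_genes >= 1L,
            is.null(noise_sd) || noise_sd >= 0)
  if (is.null(noise_sd))
    noise_sd <- score_spread * sqrt(1 / target_pcc^2 - 1)
  structure(list(n_drugs = as.integer(n_drugs), n_cells = as.integer(n_cells),
                 n_examples = as.integer(n_examples),
                 expr_factors = as.integer(expr_factors),
                 mut_genes = as.integer(mut_genes),
                 noise_sd = noise_sd, score_center = score_center,
                 score_spread = score_spread,
                 score_tail_weight = score_tail_weight,
                 seed = as.integer(seed)), class = "synthetic_spec")
}

#' Sample drug-like molecules from the curated vocabulary
#'
#' Molecules are assembled as prefix + core (+ linker + second core) + tail
#' from a fixed vocabulary of ring systems, substituents and linkers; the
#' construction is valence-correct, so every SMILES parses and embeds in 3D.
#'
#' @param n number of distinct molecules.
#' @param seed RNG seed.
#' @return data frame with `drug_id` and `smiles`.
#' @export
sample_molecules <- function(n, seed = 1L) {
  if (n < 1L) stop("n must be positive")
  combos <- expand.grid(prefix = synth_prefixes, core = synth_cores,
                        tail = synth_tails, stringsAsFactors = FALSE)
  small <- paste0(combos$prefix, combos$core, combos$tail)
  bridged <- expand.grid(core = synth_cores, linker = synth_linkers,
                         core2 = synth_cores, stringsAsFactors = FALSE)
  big <- paste0(bridged$core, bridged$linker, bridged$core2)
  pool <- unique(c(small, big))
  if (n > length(pool)) stop("vocabulary supports at most ", length(pool),
                             " distinct molecules")
  sm <- with_seed(seed, sample(pool, n))
  data.frame(drug_id = sprintf("D%02d", seq_len(n)), smiles = sm,
             stringsAsFactors = FALSE)
}

#' Generate synthetic cell-line omics tables
#'
#' Expression factors are drawn from a correlated Gaussian (AR(1) factor
#' covariance, rho = 0.5); mutations are Bernoulli(0.02) per gene. Tissue
#' labels cycle through five tissues.
#'
#' @param n_cells,k,m dimensions (cells, factors, genes).
#' @param seed RNG seed.
#' @return list with `expr` (n_cells x k), `mut` (n_cells x m), `tissue`.
#' @export
synth_omics <- function(n_cells, k, m, seed = 1L) {
  stopifnot(n_cells >= 1L, k >= 1L, m >= 1L)
  ids <- sprintf("CL%02d", seq_len(n_cells))
  with_seed(seed, {
    sig <- 0.5^abs(outer(seq_len(k), seq_len(k), `-`))
    z <- matrix(stats::rnorm(n_cells * k), n_cells, k) %*% chol(sig)
    mut <- matrix(stats::rbinom(n_cells * m, 1L, 0.02), n_cells, m)
    dimnames(z) <- list(ids, sprintf("F%02d", seq_len(k)))
    dimnames(mut) <- list(ids, sprintf("G%03d", seq_len(m)))
    tissues <- c("lung", "breast", "colon", "skin", "ovary")
    list(expr = z, mut = mut,
         tissue = stats::setNames(rep_len(tissues, n_cells), ids))
  })
}

# Deterministic part of the generating function, before dataset-level
# standardization: a weighted combination of fingerprint overlap (Tanimoto),
# an atom-count interaction, the projection of the cell's expression factors
# on a fixed direction, and an overlap-by-expression interaction. Symmetric
# in drug order by construction.
synth_signal_raw <- function(fp_a, fp_b, n_a, n_b, expr, spec) {
  inter <- sum(fp_a & fp_b)
  uni <- sum(fp_a | fp_b)
  o <- if (uni > 0) inter / uni else 0
  s <- (n_a / 20) * (n_b / 20)
  v <- with_seed(spec$seed + 211L, stats::rnorm(length(expr)))
  v <- v / sqrt(sum(v * v))
  e <- sum(v * expr)
  3 * o + 1.5 * s + 1.0 * e + 2 * o * e
}

#' Synthetic ground-truth synergy score of one example
#'
#' The documented generating function: `raw = 3*tanimoto(fp_a, fp_b) +
#' 1.5*(n_a/20)(n_b/20) + proj(expr) + 2*tanimoto*proj(expr)`, plus Gaussian
#' noise. [make_dataset()] standardizes `raw` over the dataset, applies the
#' positive-tail skew `z + tail_weight * max(z, 0)` (restandardized), and maps
#' it to `score_center + score_spread * z`. Symmetric in drug order.
#'
#' @param pair_features a [featurize_pair()] bundle (fingerprints and atom
#'   counts are used).
#' @param cell_profile list with an `expr` vector.
#' @param spec a [synthetic_spec()].
#' @param noise_seed seed for the additive noise draw.
#' @return list with `raw` (deterministic part) and `noise`.
#' @export
synth_synergy <- function(pair_features, cell_profile, spec, noise_seed = 1L) {
  raw <- synth_signal_raw(pair_features$fp_a, pair_features$fp_b,
                          pair_features$graph_a$atom_count,
                          pair_features$graph_b$atom_count,
                          cell_profile$expr, spec)
  noise <- if (spec$noise_sd > 0)
    with_seed(noise_seed, stats::rnorm(1L, 0, spec$noise_sd)) else 0
  list(raw = raw, noise = noise)
}

#' Generate a complete synthetic dataset
#'
#' Samples molecules and omics, draws `n_examples` distinct (drug pair, cell
#' line) triples, computes scores from the documented generating function
#' (see [synth_synergy()]), and either returns the in-memory bundle or also
#' writes the four files (synergy table, drug map, expression, mutations,
#' tissue annotation) in the package's file dialects.
#'
#' @param spec a [synthetic_spec()].
#' @param dir output directory, or `NULL` for in-memory only.
#' @return a [synergy_bundle()]; when `dir` is given, file paths are attached
#'   as attribute `"paths"`.
#' @export
make_dataset <- function(spec = synthetic_spec(), dir = NULL) {
  drugs_df <- sample_molecules(spec$n_drugs, spec$seed)
  drugs <- stats::setNames(drugs_df$smiles, drugs_df$drug_id)
  om <- synth_omics(spec$n_cells, spec$expr_factors, spec$mut_genes,
                    spec$seed + 1L)
  cells <- structure(list(expr = zscore(om$expr), expr_raw = om$expr,
                          mut = om$mut, tissue = om$tissue),
                     class = "cell_profiles")
  pairs <- t(utils::combn(drugs_df$drug_id, 2L))
  triples <- expand.grid(pair = seq_len(nrow(pairs)),
                         cell = rownames(om$expr), stringsAsFactors = FALSE)
  if (spec$n_examples > nrow(triples))
    stop("n_examples = ", spec$n_examples, " exceeds the ",
         nrow(triples), " distinct drug-pair x cell-line triples")
  pick <- with_seed(spec$seed + 2L, sample.int(nrow(triples), spec$n_examples))
  ex <- data.frame(drug_a = pairs[triples$pair[pick], 1L],
                   drug_b = pairs[triples$pair[pick], 2L],
                   cell_line = triples$cell[pick], stringsAsFactors = FALSE)
  # fingerprints and atom counts of each drug (radius-2, 256 bits)
  fps <- lapply(drugs, morgan_fingerprint)
  nat <- vapply(drugs, function(s) mol_data(s)$n, 0L)
  expr_std <- cells$expr
  raw <- vapply(seq_len(nrow(ex)), function(i)
    synth_signal_raw(fps[[ex$drug_a[i]]], fps[[ex$drug_b[i]]],
                     nat[[ex$drug_a[i]]], nat[[ex$drug_b[i]]],
                     expr_std[ex$cell_line[i], ], spec), 0)
  z <- (raw - mean(raw)) / stats::sd(raw)
  z <- z + spec$score_tail_weight * pmax(z, 0)
  z <- (z - mean(z)) / stats::sd(z)
  noise <- with_seed(spec$seed + 3L,
                     stats::rnorm(nrow(ex), 0, spec$noise_sd))
  ex$synergy <- spec$score_center + spec$score_spread * z + noise
  bundle <- synergy_bundle(ex, drugs, cells)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(
      synergy = file.path(dir, "synergy.csv"),
      drugs = file.path(dir, "drugs.csv"),
      expr = file.path(dir, "expression.tsv"),
      mut = file.path(dir, "mutations.tsv"),
      tissue = file.path(dir, "tissues.csv"))
    write_synergy_table(ex, paths$synergy)
    utils::write.table(drugs_df, paths$drugs, sep = ",", row.names = FALSE,
                       quote = FALSE)
    utils::write.table(data.frame(cell_line = rownames(om$expr), om$expr,
                                  check.names = FALSE),
                       paths$expr, sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(data.frame(cell_line = rownames(om$mut), om$mut,
                                  check.names = FALSE),
                       paths$mut, sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(data.frame(cell_line = names(om$tissue),
                                  tissue = om$tissue),
                       paths$tissue, sep = ",", row.names = FALSE, quote = FALSE)
    attr(bundle, "paths") <- paths
  }
  bundle
}
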