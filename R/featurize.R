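# Bundling of the four drug modalities for ordered drug pairs, plus the
# precomputed per-dataset feature store consumed by the training loop.

#' Featurization and model configuration
#'
#' One configuration object controls featurization, every encoder branch and
#' the predictor head. Defaults give the full model; [build_variant()] derives
#' the ablation variants by switching branch flags.
#'
#' @param max_atoms fixed sequence capacity (atoms); sequences are padded to
#'   this length inside the sequence branch, whose token-mixing weights are
#'   `max_atoms` x `max_atoms`.
#' @param cloud_len standard (padded) point-cloud length.
#' @param fp_bits,fp_radius Morgan fingerprint length and radius.
#' @param power_mode power-graph convention, see [power_adjacency()].
#' @param add_self_loops see [normalize_adjacency()].
#' @param d_l LSTM units per direction.
#' @param gmlp_layers,gmlp_dim gated-MLP depth and channel-projection width
#'   (split in two for the spatial gate).
#' @param gmlp_input `"full"` feeds the whole bidirectional output to the
#'   gated-MLP stack; `"forward_half"` only the forward states.
#' @param heads,d_k,d_v attention heads and per-head query/key/value widths.
#' @param seq_pool,cloud_pool reduction over positions: `"max"` or `"mean"`.
#' @param gcn_width output width of each graph-convolution layer.
#' @param cloud_channels channel schedule of the point-cloud embedding.
#' @param cloud_kernel 1D convolution kernel size (odd; 1 = pointwise).
#' @param cell_hidden,cell_dim hidden and output widths of the cell-line FNN.
#' @param head_width first fully connected layer width; the second is half.
#' @param variant model variant name, see [build_variant()].
#' @param order_augment train on both drug orders and predict the mean of both.
#' @param seed seed for parameter initialization.
#' @return A list of class `synergy_config`.
#' @export
synergy_config <- function(max_atoms = 64L, cloud_len = 100L,
                           fp_bits = 256L, fp_radius = 2L,
                           power_mode = "cumulative", add_self_loops = FALSE,
                           d_l = 64L, gmlp_layers = 3L, gmlp_dim = 128L,
                           gmlp_input = "full",
                           heads = 4L, d_k = 32L, d_v = 32L,
                           seq_pool = "max", cloud_pool = "max",
                           gcn_width = 64L,
                           cloud_channels = c(3L, 32L, 64L, 128L, 160L),
                           cloud_kernel = 1L,
                           cell_hidden = 256L, cell_dim = 128L,
                           head_width = 1024L,
                           variant = "MMFSyn", order_augment = TRUE,
                           seed = 1L) {
  if (gmlp_dim %% 2L != 0L)
    stop("gmlp_dim must be even (the spatial gate splits channels in half)")
  cfg <- list(max_atoms = as.integer(max_atoms), cloud_len = as.integer(cloud_len),
              fp_bits = as.integer(fp_bits), fp_radius = as.integer(fp_radius),
              power_mode = power_mode, add_self_loops = add_self_loops,
              atom_feat_dim = atom_feature_dim(),
              d_l = as.integer(d_l), gmlp_layers = as.integer(gmlp_layers),
              gmlp_dim = as.integer(gmlp_dim), gmlp_input = gmlp_input,
              heads = as.integer(heads), d_k = as.integer(d_k), d_v = as.integer(d_v),
              seq_pool = seq_pool, cloud_pool = cloud_pool,
              gcn_width = as.integer(gcn_width),
              cloud_channels = as.integer(cloud_channels),
              cloud_kernel = as.integer(cloud_kernel),
              cell_hidden = as.integer(cell_hidden), cell_dim = as.integer(cell_dim),
              head_width = as.integer(head_width),
              variant = variant, order_augment = isTRUE(order_augment),
              seed = as.integer(seed),
              # branch switches; overridden by build_variant()
              use_seq = TRUE, use_mha = TRUE, use_graph = TRUE,
              use_pair_graph = TRUE, cell_mode = "omics", fusion = "concat")
  class(cfg) <- "synergy_config"
  cfg
}

featurize_drug <- function(smiles, cfg) {
  seq <- atom_sequence(smiles, cfg$max_atoms)
  mg <- molecular_graph(smiles, cfg$power_mode, cfg$add_self_loops)
  list(fp = morgan_fingerprint(smiles, cfg$fp_bits, cfg$fp_radius),
       seq = seq,
       graph = mg$graph, powers = mg$powers,
       cloud = point_cloud(smiles, cfg$cloud_len))
}

#' Featurize an ordered drug pair
#'
#' Computes all four modalities for both drugs plus the block-diagonal pair
#' graph and its power-graph supports. Pair order is preserved everywhere
#' (fingerprint concatenation, pair-graph block order).
#'
#' @param drug_a,drug_b lists with fields `drug_id` and `smiles`.
#' @param config a [synergy_config()].
#' @return A list of class `drug_pair_features`.
#' @export
featurize_pair <- function(drug_a, drug_b, config = synergy_config()) {
  for (d in list(drug_a, drug_b))
    if (is.null(d$drug_id) || is.null(d$smiles))
      stop("drug records need fields drug_id and smiles")
  fa <- tryCatch(featurize_drug(drug_a$smiles, config),
                 error = function(e) stop("featurizing ", drug_a$drug_id, ": ",
                                          conditionMessage(e), call. = FALSE))
  fb <- tryCatch(featurize_drug(drug_b$smiles, config),
                 error = function(e) stop("featurizing ", drug_b$drug_id, ": ",
                                          conditionMessage(e), call. = FALSE))
  gp <- pair_graph(fa$graph, fb$graph)
  structure(list(
    drug_a = drug_a$drug_id, drug_b = drug_b$drug_id,
    fp_a = fa$fp, fp_b = fb$fp, fp_pair = concat_fingerprints(fa$fp, fb$fp),
    seq_a = fa$seq, seq_b = fb$seq,
    graph_a = fa$graph, graph_b = fb$graph, graph_pair = gp,
    powers_a = fa$powers, powers_b = fb$powers,
    powers_pair = power_graph_set(gp$adjacency, config$power_mode,
                                  config$add_self_loops),
    cloud_a = fa$cloud, cloud_b = fb$cloud), class = "drug_pair_features")
}

# Per-dataset feature store: everything the batch forward needs, precomputed
# once. `pairs` is a character matrix/data.frame of the ordered (drug_a,
# drug_b) pairs that occur; pair supports are only built when the pair-graph
# fusion is active.
prepare_features <- function(drug_map, pairs, cfg, need_pair_graphs = TRUE) {
  ids <- names(drug_map)
  drugs <- lapply(ids, function(id) featurize_drug(drug_map[[id]], cfg))
  names(drugs) <- ids
  for (id in ids) {
    n <- drugs[[id]]$seq$length
    # padded sequence block used by the sequence branch
    pad <- matrix(0, cfg$max_atoms, cfg$atom_feat_dim)
    pad[seq_len(n), ] <- drugs[[id]]$seq$features
    drugs[[id]]$seq_padded <- pad
  }
  pair_feats <- NULL
  if (need_pair_graphs && !is.null(pairs) && nrow(pairs) > 0L) {
    keys <- unique(paste(pairs[[1L]], pairs[[2L]], sep = "\r"))
    pair_feats <- lapply(keys, function(k) {
      ab <- strsplit(k, "\r", fixed = TRUE)[[1L]]
      gp <- pair_graph(drugs[[ab[1L]]]$graph, drugs[[ab[2L]]]$graph)
      list(powers = power_graph_set(gp$adjacency, cfg$power_mode,
                                    cfg$add_self_loops),
           node_features = gp$node_features, n = gp$atom_count)
    })
    names(pair_feats) <- keys
  }
  structure(list(drugs = drugs, pairs = pair_feats, cfg_max_atoms = cfg$max_atoms),
            class = "feature_store")
}

pair_key <- function(a, b) paste(a, b, sep = "\r")
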