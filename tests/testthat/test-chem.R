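test_that("Morgan fingerprints are 256-bit, binary and deterministic", {
  fp <- morgan_fingerprint("CCO")
  expect_length(fp, 256L)
  expect_true(all(fp %in% c(0L, 1L)))
  expect_identical(fp, morgan_fingerprint("CCO"))
})

test_that("Morgan fingerprints are invariant to SMILES rewriting", {
  pairs <- list(c("CCO", "OCC"),
                c("c1ccccc1", "C1=CC=CC=C1"),
                c("CC(=O)N", "NC(C)=O"),
                c("Cc1ccccc1", "c1ccccc1C"),
                c("c1ccncc1", "c1ccncc1"),
                c("CCOC(=O)C", "CC(=O)OCC"))
  for (p in pairs)
    expect_identical(morgan_fingerprint(p[1]), morgan_fingerprint(p[2]))
  # and sensitive to actual structural change
  expect_false(identical(morgan_fingerprint("CCO"), morgan_fingerprint("CCN")))
})

test_that("unparseable SMILES raises a parse error naming the string", {
  expect_error(morgan_fingerprint("not_a_smiles(("), "not_a_smiles")
})

test_that("fingerprint concatenation is ordered and length-checked", {
  a <- rep(0L, 256L); b <- rep(1L, 256L)
  h <- concat_fingerprints(a, b)
  expect_length(h, 512L)
  expect_equal(h[1:256], a)
  expect_equal(h[257:512], b)
  expect_false(identical(concat_fingerprints(morgan_fingerprint("CCO"),
                                             morgan_fingerprint("CCN")),
                         concat_fingerprints(morgan_fingerprint("CCN"),
                                             morgan_fingerprint("CCO"))))
  expect_error(concat_fingerprints(a, b[1:128]), "mismatch")
})

test_that("atom sequences carry the documented 27-wide feature rows", {
  expect_equal(atom_feature_dim(), 10L + 6L + 1L + 4L + 1L + 5L)
  met <- atom_sequence("C")
  expect_equal(dim(met$features), c(1L, atom_feature_dim()))
  expect_equal(met$features[1, 22], 0)        # aromaticity flag
  benz <- atom_sequence("c1ccccc1")
  expect_equal(benz$length, 6L)
  expect_equal(benz$features[, 22], rep(1, 6))
  expect_error(atom_sequence("c1ccc2ccccc2c1", max_atoms = 4L), "max_atoms")
})

test_that("molecular graphs mirror the bond structure and share sequence features", {
  eth <- molecular_graph("CC")
  expect_equal(eth$graph$atom_count, 2L)
  expect_equal(sum(eth$graph$adjacency) / 2, 1)
  benz <- molecular_graph("c1ccccc1")
  expect_equal(benz$graph$atom_count, 6L)
  expect_equal(sum(benz$graph$adjacency) / 2, 6)
  expect_equal(sum(benz$powers$p2) / 2, 12)   # order-2 power graph of C6
  expect_equal(benz$graph$node_features, atom_sequence("c1ccccc1")$features)
  mols <- sample_molecules(20L, seed = 4L)
  for (s in mols$smiles) {
    a <- molecular_graph(s)$graph$adjacency
    expect_equal(a, t(a))
    expect_true(all(diag(a) == 0))
  }
})

test_that("point clouds are padded, deterministic and chemically sane", {
  pc <- point_cloud("CC", n = 10L)
  expect_equal(dim(pc$coords), c(10L, 3L))
  expect_equal(pc$true_atom_count, 2L)
  expect_equal(pc$coords[3:10, ], matrix(0, 8L, 3L))
  expect_identical(pc, point_cloud("CC", n = 10L))
  cc_len <- sqrt(sum((pc$coords[1, ] - pc$coords[2, ])^2))
  expect_gt(cc_len, 1.3)
  expect_lt(cc_len, 1.7)
  expect_error(point_cloud("c1ccccc1", n = 3L), "capacity")
})

test_that("featurize_pair bundles all modalities and preserves order", {
  cfg <- synergy_config(max_atoms = 32L, cloud_len = 40L)
  d1 <- list(drug_id = "a", smiles = "CCO")
  d2 <- list(drug_id = "b", smiles = "c1ccncc1")
  ab <- featurize_pair(d1, d2, cfg)
  ba <- featurize_pair(d2, d1, cfg)
  expect_s3_class(ab, "drug_pair_features")
  expect_equal(ab$fp_pair, rev_halves <- c(ba$fp_b, ba$fp_a))
  n1 <- ab$graph_a$atom_count; n2 <- ab$graph_b$atom_count
  expect_equal(ab$graph_pair$atom_count, n1 + n2)
  # pair-graph node order reverses with the drug order
  expect_equal(ab$graph_pair$node_features,
               rbind(ba$graph_pair$node_features[(n2 + 1):(n2 + n1), ],
                     ba$graph_pair$node_features[1:n2, ]))
  expect_equal(nrow(ab$cloud_a$coords), cfg$cloud_len)
  expect_error(featurize_pair(list(drug_id = "x"), d2, cfg), "smiles")
  expect_error(featurize_pair(list(drug_id = "x", smiles = ")bad("), d2, cfg),
               "featurizing x")
})

test_that("the fixture vocabulary featurizes without error", {
  cfg <- synergy_config(max_atoms = 40L, cloud_len = 48L)
  mols <- sample_molecules(8L, seed = 2L)
  expect_equal(length(unique(mols$smiles)), 8L)
  for (i in seq_len(nrow(mols))) {
    f <- synergynet:::featurize_drug(mols$smiles[i], cfg)
    expect_length(f$fp, 256L)
    expect_true(f$seq$length >= 1L)
    expect_true(all(is.finite(f$cloud$coords)))
  }
})
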