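# SMILES featurization: the four drug modalities. Molecule perception (atoms,
# bonds, aromaticity, hybridization, formal charge) is delegated to OpenBabel
# (`obabel` on the PATH); the circular Morgan fingerprint (order-invariant
# iterative neighborhood hashing) and the deterministic distance-geometry 3D
# embed are computed here.

.chem_cache <- new.env(parent = emptyenv())

ob_run <- function(args, input = NULL) {
  out <- suppressWarnings(system2("obabel", args, stdout = TRUE, stderr = FALSE,
                                  input = input))
  paste(out, collapse = "\n")
}

parse_mol2 <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  ai <- grep("@<TRIPOS>ATOM", lines, fixed = TRUE)
  bi <- grep("@<TRIPOS>BOND", lines, fixed = TRUE)
  if (length(ai) != 1L || length(bi) != 1L) return(NULL)
  end <- grep("^@<TRIPOS>", lines)
  aend <- min(c(end[end > ai], length(lines) + 1L)) - 1L
  bend <- min(c(end[end > bi], length(lines) + 1L)) - 1L
  atom_lines <- lines[(ai + 1L):aend]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  af <- strsplit(trimws(atom_lines), "[[:space:]]+")
  atoms <- data.frame(
    elem = vapply(af, function(x) sub("\\..*$", "", x[6L]), ""),
    x = as.numeric(vapply(af, `[`, "", 3L)),
    y = as.numeric(vapply(af, `[`, "", 4L)),
    z = as.numeric(vapply(af, `[`, "", 5L)),
    type = vapply(af, `[`, "", 6L),
    stringsAsFactors = FALSE)
  bonds <- NULL
  if (bend > bi) {
    bond_lines <- lines[(bi + 1L):bend]
    bond_lines <- bond_lines[nzchar(trimws(bond_lines))]
    if (length(bond_lines)) {
      bf <- strsplit(trimws(bond_lines), "[[:space:]]+")
      bonds <- data.frame(
        a1 = as.integer(vapply(bf, `[`, "", 2L)),
        a2 = as.integer(vapply(bf, `[`, "", 3L)),
        type = vapply(bf, `[`, "", 4L),
        stringsAsFactors = FALSE)
    }
  }
  list(atoms = atoms, bonds = bonds)
}

parse_sdf_charges <- function(txt, n_atoms) {
  charges <- numeric(n_atoms)
  for (ln in grep("^M  CHG", strsplit(txt, "\n")[[1L]], value = TRUE)) {
    f <- as.integer(strsplit(trimws(sub("^M  CHG", "", ln)), "[[:space:]]+")[[1L]])
    k <- f[1L]
    for (i in seq_len(k)) {
      idx <- f[2L * i]; chg <- f[2L * i + 1L]
      if (idx <= n_atoms) charges[idx] <- chg
    }
  }
  charges
}

hyb_from_type <- function(type) {
  suffix <- sub("^[A-Za-z]+\\.?", "", type)
  if (suffix == "1") "sp"
  else if (suffix %in% c("2", "ar", "am", "co2", "pl3")) "sp2"
  else if (suffix %in% c("3", "3+", "o", "o2", "t")) "sp3"
  else "other"
}

# Parse one SMILES through OpenBabel. Returns heavy-atom records: element,
# coordinates (deterministic distance-free 3D embed), heavy-neighbor degree,
# attached-H count, aromaticity, hybridization, formal charge, and the
# heavy-atom bond list with order classes. Cached per (smiles, explicit flag).
mol_data <- function(smiles, cache = TRUE) {
  key <- paste0("m:", smiles)
  if (cache && !is.null(.chem_cache[[key]])) return(.chem_cache[[key]])
  m2 <- ob_run(c(shQuote(paste0("-:", smiles)), "-omol2", "-h"))
  parsed <- parse_mol2(m2)
  if (is.null(parsed) || nrow(parsed$atoms) == 0L)
    stop("SMILES parse error: ", smiles)
  atoms <- parsed$atoms
  bonds <- parsed$bonds
  heavy <- which(atoms$elem != "H")
  if (length(heavy) == 0L) stop("SMILES parse error (no heavy atoms): ", smiles)
  hidx <- match(seq_len(nrow(atoms)), heavy)  # old index -> heavy index
  n <- length(heavy)
  deg <- integer(n); nh <- integer(n); arom <- logical(n)
  border <- function(t) switch(t, "1" = 1, "2" = 2, "3" = 3, "ar" = 4, "am" = 1, 1)
  blist <- NULL
  if (!is.null(bonds)) for (i in seq_len(nrow(bonds))) {
    a1 <- bonds$a1[i]; a2 <- bonds$a2[i]; tt <- bonds$type[i]
    h1 <- hidx[a1]; h2 <- hidx[a2]
    if (!is.na(h1) && !is.na(h2)) {
      deg[h1] <- deg[h1] + 1L; deg[h2] <- deg[h2] + 1L
      if (tt == "ar") { arom[h1] <- TRUE; arom[h2] <- TRUE }
      blist <- rbind(blist, c(h1, h2, border(tt)))
    } else if (!is.na(h1) && atoms$elem[a2] == "H") {
      nh[h1] <- nh[h1] + 1L
    } else if (!is.na(h2) && atoms$elem[a1] == "H") {
      nh[h2] <- nh[h2] + 1L
    }
  }
  arom <- arom | grepl("\\.ar$", atoms$type[heavy])
  sdf <- ob_run(c(shQuote(paste0("-:", smiles)), "-osdf"))
  charges <- parse_sdf_charges(sdf, n)
  res <- list(
    n = n,
    elem = atoms$elem[heavy],
    degree = deg, n_h = nh, aromatic = arom,
    hyb = vapply(atoms$type[heavy], hyb_from_type, ""),
    charge = charges,
    bonds = blist)
  res$coords <- dg_embed(res)
  if (cache) .chem_cache[[key]] <- res
  res
}

# Atoms on a cycle: iteratively prune degree-1 vertices; survivors with
# positive remaining degree form the 2-core, i.e. the ring systems.
ring_atoms <- function(n, bonds) {
  if (is.null(bonds)) return(logical(n))
  deg <- integer(n)
  alive <- rep(TRUE, nrow(bonds))
  for (i in seq_len(nrow(bonds))) {
    deg[bonds[i, 1L]] <- deg[bonds[i, 1L]] + 1L
    deg[bonds[i, 2L]] <- deg[bonds[i, 2L]] + 1L
  }
  repeat {
    leaves <- which(deg == 1L)
    if (length(leaves) == 0L) break
    for (i in which(alive)) {
      if (bonds[i, 1L] %in% leaves || bonds[i, 2L] %in% leaves) {
        alive[i] <- FALSE
        deg[bonds[i, 1L]] <- deg[bonds[i, 1L]] - 1L
        deg[bonds[i, 2L]] <- deg[bonds[i, 2L]] - 1L
      }
    }
  }
  deg > 0L
}

hash_mix <- function(h, x) (h * 31 + x) %% 2147483647

#' Morgan (circular) fingerprint of a molecule
#'
#' Radius-2 circular substructure fingerprint hashed to a fixed-length binary
#' vector (default 256 bits). Atom identifiers start from an order-invariant
#' invariant (element, heavy degree, attached hydrogens, formal charge, ring
#' membership, aromaticity) and are iteratively rehashed with the sorted
#' (bond-order, neighbor-identifier) pairs of each neighborhood shell, so two
#' SMILES spellings of the same molecule give identical fingerprints.
#'
#' @param smiles a SMILES string.
#' @param nbits fingerprint length (bits); default 256.
#' @param radius neighborhood radius; default 2.
#' @return integer 0/1 vector of length `nbits`.
#' @export
morgan_fingerprint <- function(smiles, nbits = 256L, radius = 2L) {
  md <- mol_data(smiles)
  n <- md$n
  ring <- ring_atoms(n, md$bonds)
  elemnum <- match(md$elem, c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P"),
                   nomatch = 99L)
  ids <- vapply(seq_len(n), function(v) {
    h <- 7
    for (x in c(elemnum[v], md$degree[v], md$n_h[v], md$charge[v] + 10,
                as.integer(ring[v]), as.integer(md$aromatic[v])))
      h <- hash_mix(h, x)
    h
  }, 0)
  nbrs <- vector("list", n)
  if (!is.null(md$bonds)) for (i in seq_len(nrow(md$bonds))) {
    a <- md$bonds[i, 1L]; b <- md$bonds[i, 2L]; o <- md$bonds[i, 3L]
    nbrs[[a]] <- rbind(nbrs[[a]], c(o, b))
    nbrs[[b]] <- rbind(nbrs[[b]], c(o, a))
  }
  all_ids <- ids
  for (r in seq_len(radius)) {
    new_ids <- vapply(seq_len(n), function(v) {
      h <- hash_mix(11, r)
      h <- hash_mix(h, ids[v])
      nb <- nbrs[[v]]
      if (!is.null(nb)) {
        key <- cbind(nb[, 1L], ids[nb[, 2L]])
        key <- key[order(key[, 1L], key[, 2L]), , drop = FALSE]
        for (i in seq_len(nrow(key))) {
          h <- hash_mix(h, key[i, 1L])
          h <- hash_mix(h, key[i, 2L])
        }
      }
      h
    }, 0)
    ids <- new_ids
    all_ids <- c(all_ids, new_ids)
  }
  bits <- integer(nbits)
  bits[unique(all_ids %% nbits) + 1L] <- 1L
  bits
}

#' Concatenate the fingerprints of an ordered drug pair
#'
#' @param fp_a,fp_b binary fingerprint vectors of equal length.
#' @return `c(fp_a, fp_b)`; order-sensitive.
#' @export
concat_fingerprints <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b))
    stop("fingerprint length mismatch: ", length(fp_a), " vs ", length(fp_b))
  c(fp_a, fp_b)
}

atom_elements <- c("C", "N", "O", "S", "F", "Cl", "Br", "I", "P")
atom_hybs <- c("sp", "sp2", "sp3")

#' Per-atom feature width of the default featurization
#'
#' Element one-hot over C/N/O/S/F/Cl/Br/I/P/other (10), heavy-neighbor degree
#' one-hot 0-5 (6), formal charge (1), hybridization one-hot sp/sp2/sp3/other
#' (4), aromaticity flag (1) and attached-hydrogen one-hot 0-4 (5): 27.
#'
#' @return integer feature width.
#' @export
atom_feature_dim <- function() 10L + 6L + 1L + 4L + 1L + 5L

atom_feature_rows <- function(md) {
  n <- md$n
  out <- matrix(0, n, atom_feature_dim())
  ei <- match(md$elem, atom_elements, nomatch = 10L)
  out[cbind(seq_len(n), ei)] <- 1
  di <- pmin(md$degree, 5L)
  out[cbind(seq_len(n), 10L + di + 1L)] <- 1
  out[, 17L] <- md$charge
  hi <- match(md$hyb, atom_hybs, nomatch = 4L)
  out[cbind(seq_len(n), 17L + hi)] <- 1
  out[, 22L] <- as.numeric(md$aromatic)
  hh <- pmin(md$n_h, 4L)
  out[cbind(seq_len(n), 22L + hh + 1L)] <- 1
  out
}

#' Atom-sequence feature matrix of a drug
#'
#' Per-atom feature rows (see [atom_feature_dim()]) ordered by the atom index
#' of the SMILES parse; the input to the sequence (BiLSTM-gMLP) branch.
#'
#' @param smiles a SMILES string.
#' @param max_atoms capacity limit; molecules with more heavy atoms error.
#' @return list with `features` (N x C matrix) and `length` (N).
#' @export
atom_sequence <- function(smiles, max_atoms = 64L) {
  md <- mol_data(smiles)
  if (md$n > max_atoms)
    stop("molecule exceeds max_atoms (", md$n, " > ", max_atoms, "): ", smiles)
  list(features = atom_feature_rows(md), length = md$n)
}

#' Molecular graph and its power-graph supports from SMILES
#'
#' Vertices are heavy atoms, edges chemical bonds (any bond order becomes an
#' edge); node features are identical to the atom-sequence rows of the same
#' molecule. Also returns the normalized order-1/2/3 power-graph supports used
#' by the multiscale graph branch.
#'
#' @param smiles a SMILES string.
#' @param power_mode power-graph convention, see [power_adjacency()].
#' @param add_self_loops see [normalize_adjacency()].
#' @return list with `graph` ([molgraph()]) and `powers` ([power_graph_set()]).
#' @export
molecular_graph <- function(smiles, power_mode = "cumulative",
                            add_self_loops = FALSE) {
  md <- mol_data(smiles)
  a <- matrix(0, md$n, md$n)
  if (!is.null(md$bonds)) for (i in seq_len(nrow(md$bonds))) {
    a[md$bonds[i, 1L], md$bonds[i, 2L]] <- 1
    a[md$bonds[i, 2L], md$bonds[i, 1L]] <- 1
  }
  g <- molgraph(a, atom_feature_rows(md))
  list(graph = g, powers = power_graph_set(a, power_mode, add_self_loops))
}


# ---- deterministic distance-geometry embedding ------------------------------

covalent_radius <- c(C = 0.76, N = 0.71, O = 0.66, S = 1.05, F = 0.57,
                     Cl = 1.02, Br = 1.20, I = 1.39, P = 1.07)

bond_order_scale <- c(`1` = 1.0, `2` = 0.87, `3` = 0.78, `4` = 0.93)

# Contraction of a topological path into through-space distance: sums of bond
# lengths overestimate real distances because of bond angles; k-bond paths are
# shrunk toward typical tetrahedral/aromatic geometries.
path_contraction <- function(k) ifelse(k <= 1, 1, ifelse(k == 2, 0.82,
                                ifelse(k == 3, 0.76, 0.72)))

# Deterministic 3D coordinates for the heavy atoms of a parsed molecule:
# classical MDS of a target distance matrix plus fixed harmonic descent.
dg_embed <- function(md, relax = TRUE) {
  n <- md$n
  if (n == 1L) return(matrix(0, 1L, 3L))
  rad <- unname(covalent_radius[md$elem])
  rad[is.na(rad)] <- 1.1
  blen <- matrix(0, n, n)
  hops <- matrix(Inf, n, n)
  diag(hops) <- 0
  if (!is.null(md$bonds)) for (i in seq_len(nrow(md$bonds))) {
    a <- md$bonds[i, 1L]; b <- md$bonds[i, 2L]
    sc <- bond_order_scale[[as.character(md$bonds[i, 3L])]]
    if (is.null(sc) || is.na(sc)) sc <- 1
    blen[a, b] <- blen[b, a] <- (rad[a] + rad[b]) * sc
    hops[a, b] <- hops[b, a] <- 1
  }
  # all-pairs shortest paths in bond-length metric and in hop counts
  dist <- ifelse(hops == 1, blen, Inf)
  diag(dist) <- 0
  for (k in seq_len(n)) {
    dk <- outer(dist[, k], dist[k, ], `+`)
    upd <- dk < dist
    dist[upd] <- dk[upd]
    hk <- outer(hops[, k], hops[k, ], `+`)
    updh <- hk < hops
    hops[updh] <- hk[updh]
  }
  # disconnected fragments (e.g. salts): place far apart deterministically
  dist[!is.finite(dist)] <- max(dist[is.finite(dist)]) + 3
  hops[!is.finite(hops)] <- n
  target <- dist * path_contraction(hops)
  diag(target) <- 0
  # classical MDS into 3 dimensions
  d2 <- target^2
  jc <- diag(n) - 1 / n
  bmat <- -0.5 * jc %*% d2 %*% jc
  eg <- eigen(bmat, symmetric = TRUE)
  k <- min(3L, n)
  ev <- pmax(eg$values[seq_len(k)], 0)
  xyz <- matrix(0, n, 3L)
  xyz[, seq_len(k)] <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(ev), k)
  # fix reflection/sign indeterminacy for full determinism
  for (j in 1:3) {
    nz <- which(abs(xyz[, j]) > 1e-9)
    if (length(nz) && xyz[nz[1L], j] < 0) xyz[, j] <- -xyz[, j]
  }
  if (relax && !is.null(md$bonds)) {
    onethree <- hops == 2
    for (it in seq_len(60L)) {
      grad <- matrix(0, n, 3L)
      for (i in seq_len(nrow(md$bonds))) {
        a <- md$bonds[i, 1L]; b <- md$bonds[i, 2L]
        dv <- xyz[a, ] - xyz[b, ]
        dl <- sqrt(sum(dv * dv)) + 1e-9
        f <- 2 * (dl - blen[a, b]) * dv / dl
        grad[a, ] <- grad[a, ] + f
        grad[b, ] <- grad[b, ] - f
      }
      idx <- which(onethree & upper.tri(onethree), arr.ind = TRUE)
      if (nrow(idx)) for (r in seq_len(nrow(idx))) {
        a <- idx[r, 1L]; b <- idx[r, 2L]
        dv <- xyz[a, ] - xyz[b, ]
        dl <- sqrt(sum(dv * dv)) + 1e-9
        f <- 0.5 * (dl - target[a, b]) * dv / dl
        grad[a, ] <- grad[a, ] + f
        grad[b, ] <- grad[b, ] - f
      }
      xyz <- xyz - 0.05 * grad
    }
  }
  xyz
}

#' 3D atomic point cloud of a drug, padded to a standard length
#'
#' One conformer is generated by a deterministic distance-geometry embed:
#' target interatomic distances are derived from covalent radii (scaled by
#' bond order, with a contraction factor along longer topological paths),
#' the metric matrix is embedded into 3D by classical multidimensional
#' scaling, and the geometry is relaxed by a fixed number of deterministic
#' harmonic-spring descent steps (`relax = FALSE` disables the relaxation).
#' Coordinates are in Angstroms, for heavy atoms only; rows beyond the true
#' atom count are zero padding, and no centering or rotational normalization
#' is applied. The embed uses no randomness, so results are identical for
#' identical SMILES; `seed` is accepted for interface stability.
#'
#' @param smiles a SMILES string.
#' @param n standard (padded) length; default 100.
#' @param seed unused by the deterministic embed; kept in the signature.
#' @param relax apply the harmonic relaxation steps (default `TRUE`).
#' @return list with `coords` (n x 3) and `true_atom_count`.
#' @export
point_cloud <- function(smiles, n = 100L, seed = 0L, relax = TRUE) {
  md <- mol_data(smiles)
  if (md$n > n)
    stop("molecule exceeds point-cloud capacity (", md$n, " > ", n, "): ", smiles)
  xyz <- if (relax) md$coords else dg_embed(md, relax = FALSE)
  if (any(!is.finite(xyz)))
    stop("conformer generation failed for: ", smiles)
  coords <- matrix(0, n, 3L)
  coords[seq_len(md$n), ] <- xyz
  list(coords = coords, true_atom_count = md$n)
}
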