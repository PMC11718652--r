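# Morgan circular and 2D pharmacophore pair fingerprints ------------------

.PHARM_FAMILIES <- c("donor", "acceptor", "aromatic", "hydrophobe",
                     "pos_ionizable", "neg_ionizable")
.N_DIST_BINS <- 6L
.PHARM_N_BITS <- 21L * .N_DIST_BINS  # 21 unordered family pairs

# Stable 32-bit mix, independent of any host hash: h = 17, then for each
# component c (fixed order) h <- (h * 31 + c) mod 2^32. Doubles stay exact
# here: h*31 + c < 2^37 << 2^53.
mix_hash <- function(components) {
  h <- 17
  for (c in components) {
    h <- (h * 31 + c) %% 4294967296
  }
  h
}

new_fingerprint <- function(kind, n_bits, on_bits, params = list()) {
  on_bits <- sort(unique(as.integer(on_bits)))
  stopifnot(all(on_bits >= 0L), all(on_bits < n_bits))
  structure(list(kind = kind, n_bits = as.integer(n_bits),
                 on_bits = on_bits, params = params),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> kind=%s n_bits=%d on_bits=%d\n",
              x$kind, x$n_bits, length(x$on_bits)))
  invisible(x)
}

#' Initial per-atom invariants for circular fingerprints
#'
#' Maps every atom to the tuple (atomic number, heavy-atom degree, total
#' hydrogen count, formal charge, aromatic flag, ring flag) and hashes it
#' with a platform-stable 32-bit mix. These are the round-0 identifiers
#' of the Morgan update.
#'
#' @param graph A `molecular_graph`.
#' @return Named list with `tuples` (integer matrix, one row per atom)
#'   and `hashes` (numeric vector of 32-bit identifiers).
#' @export
atom_invariants <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  th <- total_h(graph)
  deg <- heavy_degree(graph)
  tuples <- cbind(
    atomic_number = graph$atoms$atomic_number,
    degree = deg,
    h_count = th,
    charge = graph$atoms$formal_charge,
    aromatic = as.integer(graph$atoms$aromatic),
    in_ring = as.integer(graph$atoms$in_ring)
  )
  hashes <- apply(tuples, 1L, mix_hash)
  list(tuples = tuples, hashes = as.numeric(hashes))
}

#' Morgan (ECFP-style) circular fingerprint
#'
#' Iteratively rehashes every atom's identifier from its previous
#' identifier and the sorted list of (bond order, neighbor identifier)
#' pairs, for `radius` rounds. Identifiers from all rounds are pooled,
#' deduplicated by value, and folded into `n_bits` by modulo. Atoms with
#' no neighbors contribute only their round-0 identifier. The default
#' radius 2 over 2048 bits corresponds to the common ECFP4 convention.
#'
#' @param graph A `molecular_graph`.
#' @param radius Number of update rounds (0-6; default 2).
#' @param n_bits Folded length, a power of two (default 2048).
#' @return A `fingerprint` of kind `"morgan"`.
#' @examples
#' fp <- morgan_fingerprint(parse_smiles("CCO"), radius = 1)
#' length(fp$on_bits)  # <= 6
#' @export
morgan_fingerprint <- function(graph, radius = 2L, n_bits = 2048L) {
  stopifnot(inherits(graph, "molecular_graph"))
  radius <- as.integer(radius)
  n_bits <- as.integer(n_bits)
  if (radius < 0L || radius > 6L) stop("`radius` must be in 0..6")
  if (n_bits < 1L || bitwAnd(n_bits, n_bits - 1L) != 0L) {
    stop("`n_bits` must be a positive power of two")
  }
  pool <- morgan_identifier_pool(graph, radius)
  new_fingerprint("morgan", n_bits, fold_bits(pool, n_bits),
                  params = list(radius = radius))
}

# all environment identifiers from rounds 0..radius, deduplicated
morgan_identifier_pool <- function(graph, radius) {
  inv <- atom_invariants(graph)
  ids <- inv$hashes
  n <- length(ids)
  nbrs <- vector("list", n)   # per atom: matrix of (order, neighbor index)
  for (k in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds$atom_a[k] + 1L
    b <- graph$bonds$atom_b[k] + 1L
    o <- graph$bonds$order_code[k]
    nbrs[[a]] <- rbind(nbrs[[a]], c(o, b))
    nbrs[[b]] <- rbind(nbrs[[b]], c(o, a))
  }
  pool <- ids
  if (radius > 0L) {
    for (r in seq_len(radius)) {
      new_ids <- ids
      for (a in seq_len(n)) {
        nb <- nbrs[[a]]
        if (is.null(nb)) next   # isolated atom: no wider environment
        pairs <- cbind(nb[, 1], ids[nb[, 2]])
        ord <- order(pairs[, 1], pairs[, 2])
        comps <- c(ids[a], t(pairs[ord, , drop = FALSE]))
        new_ids[a] <- mix_hash(comps)
      }
      changed <- vapply(seq_len(n), function(a) !is.null(nbrs[[a]]),
                        logical(1))
      pool <- c(pool, new_ids[changed])
      ids <- new_ids
    }
  }
  unique(pool)
}

#' Fold hashed identifiers into a fixed-length bit vector
#'
#' Maps each identifier to `identifier mod n_bits` and deduplicates;
#' distinct identifiers may collide onto one bit.
#'
#' @param identifiers Numeric vector of 32-bit identifiers.
#' @param n_bits Positive target length.
#' @return Sorted integer vector of distinct bit indices in `[0, n_bits)`.
#' @examples
#' fold_bits(c(5, 2053), 2048)  # 5: a collision
#' @export
fold_bits <- function(identifiers, n_bits) {
  if (n_bits <= 0) stop("`n_bits` must be positive")
  if (length(identifiers) == 0L) return(integer())
  sort(unique(as.integer(identifiers %% n_bits)))
}

# Pharmacophore features ---------------------------------------------------

#' Assign 2D pharmacophore features to a molecular graph
#'
#' Minimal rule-based typing on the heavy-atom graph, covering the six
#' classic families: hydrogen-bond donors and acceptors, aromatic rings,
#' hydrophobic atoms, and positive/negative ionizable groups. One
#' aromatic feature is emitted per aromatic ring (carrying the full ring
#' atom set); the other families are single-atom features. The rules:
#' donor = N/O with at least one hydrogen and charge >= 0; acceptor =
#' N/O with charge <= 0, excluding aromatic N-H; hydrophobe = halogen or
#' non-aromatic carbon whose heavy neighbors are all carbon;
#' pos_ionizable = positive formal charge, or non-aromatic amine N (only
#' C/H substituents, not adjacent to a carbonyl); neg_ionizable =
#' negative formal charge, or the hydroxyl oxygen of a carboxylic acid.
#'
#' @param graph A `molecular_graph`.
#' @return List of features, each a list with `family` and
#'   `atom_indices` (0-based), ordered by (family, lowest atom index).
#' @examples
#' assign_pharmacophore_features(parse_smiles("Oc1ccccc1"))
#' @export
assign_pharmacophore_features <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  at <- graph$atoms
  n <- nrow(at)
  th <- total_h(graph)
  adj <- adjacency_list(n, graph$bonds)

  neighbor_elements <- function(k) at$element[adj[[k]]]
  # does atom k (1-based) neighbor a carbonyl carbon (C with =O)?
  adjacent_to_carbonyl <- function(k) {
    for (v in adj[[k]]) {
      if (at$element[v] != "C") next
      for (w in adj[[v]]) {
        row <- (graph$bonds$atom_a == v - 1L & graph$bonds$atom_b == w - 1L) |
          (graph$bonds$atom_a == w - 1L & graph$bonds$atom_b == v - 1L)
        if (at$element[w] == "O" &&
            any(graph$bonds$order_code[row] == 2L)) {
          return(TRUE)
        }
      }
    }
    FALSE
  }
  double_bonded_o <- function(k) {
    for (w in adj[[k]]) {
      row <- (graph$bonds$atom_a == k - 1L & graph$bonds$atom_b == w - 1L) |
        (graph$bonds$atom_a == w - 1L & graph$bonds$atom_b == k - 1L)
      if (at$element[w] == "O" && any(graph$bonds$order_code[row] == 2L)) {
        return(TRUE)
      }
    }
    FALSE
  }

  feats <- list()
  add <- function(family, atoms0) {
    feats[[length(feats) + 1L]] <<- list(family = family,
                                         atom_indices = as.integer(atoms0))
  }

  for (k in seq_len(n)) {
    el <- at$element[k]
    chg <- at$formal_charge[k]
    idx0 <- at$index[k]
    if (el %in% c("N", "O") && th[k] >= 1L && chg >= 0L) {
      add("donor", idx0)
    }
    if (el %in% c("N", "O") && chg <= 0L &&
        !(el == "N" && at$aromatic[k] && th[k] >= 1L)) {
      add("acceptor", idx0)
    }
    if (el %in% c("F", "Cl", "Br", "I") ||
        (el == "C" && !at$aromatic[k] &&
         all(neighbor_elements(k) == "C"))) {
      add("hydrophobe", idx0)
    }
    if (chg > 0L ||
        (el == "N" && !at$aromatic[k] && chg == 0L &&
         all(neighbor_elements(k) == "C") &&
         !adjacent_to_carbonyl(k))) {
      add("pos_ionizable", idx0)
    }
    if (chg < 0L) {
      add("neg_ionizable", idx0)
    } else if (el == "O" && th[k] >= 1L && chg == 0L) {
      # hydroxyl O of C(=O)OH
      carbons <- adj[[k]][at$element[adj[[k]]] == "C"]
      if (any(vapply(carbons, double_bonded_o, logical(1)))) {
        add("neg_ionizable", idx0)
      }
    }
  }
  for (ri in graph$aromatic_rings) {
    add("aromatic", sort(graph$rings[[ri]]))
  }

  fam_rank <- match(vapply(feats, `[[`, character(1), "family"),
                    .PHARM_FAMILIES)
  min_atom <- vapply(feats, function(f) min(f$atom_indices), integer(1))
  feats[order(fam_rank, min_atom)]
}

# distance bin edges (bond counts): [0] [1] [2-3] [4-5] [6-7] [8,inf)
pharm_bin <- function(d) {
  if (d <= 0) 0L
  else if (d == 1) 1L
  else if (d <= 3) 2L
  else if (d <= 5) 3L
  else if (d <= 7) 4L
  else 5L
}

# lexicographic rank of the sorted family pair among the 21 unordered pairs
pharm_pair_rank <- function(fam_a, fam_b) {
  a <- match(fam_a, .PHARM_FAMILIES) - 1L
  b <- match(fam_b, .PHARM_FAMILIES) - 1L
  if (a > b) { tmp <- a; a <- b; b <- tmp }
  as.integer(a * 6L - a * (a - 1L) / 2L + (b - a))
}

# inverse of bit = pair_rank * n_bins + bin
decode_pharm_bit <- function(bit) {
  rank <- bit %/% .N_DIST_BINS
  bin <- bit %% .N_DIST_BINS
  pairs <- which(upper.tri(matrix(0, 6, 6), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, "row"], pairs[, "col"]), , drop = FALSE]
  list(family_a = .PHARM_FAMILIES[pairs[rank + 1L, "row"]],
       family_b = .PHARM_FAMILIES[pairs[rank + 1L, "col"]],
       bin = as.integer(bin))
}

#' 2D pharmacophore pair fingerprint
#'
#' For every unordered pair of distinct pharmacophore features (same
#' family allowed) the topological distance between the feature atom
#' sets (minimum bond-count distance over the cross pairs) is binned
#' into six bond-count ranges: 0, 1, 2-3, 4-5, 6-7, 8+. The bit index is
#' `pair_rank * 6 + bin`, where `pair_rank` is the lexicographic rank of
#' the sorted family pair among the 21 unordered family pairs, giving an
#' exact (hash-free, collision-free) 126-bit vector. Feature pairs in
#' different disconnected components are skipped.
#'
#' @param graph A `molecular_graph`.
#' @return A `fingerprint` of kind `"pharmacophore"` with 126 bits.
#' @examples
#' pharmacophore_fingerprint(parse_smiles("Oc1ccccc1"))$on_bits  # 3 bits
#' @export
pharmacophore_fingerprint <- function(graph) {
  stopifnot(inherits(graph, "molecular_graph"))
  feats <- assign_pharmacophore_features(graph)
  bits <- integer()
  if (length(feats) >= 2L) {
    d <- topological_distances(graph)
    for (i in seq_len(length(feats) - 1L)) {
      for (j in seq(i + 1L, length(feats))) {
        ai <- feats[[i]]$atom_indices + 1L
        aj <- feats[[j]]$atom_indices + 1L
        dist_ij <- min(d[ai, aj, drop = FALSE])
        if (is.infinite(dist_ij)) next
        rank <- pharm_pair_rank(feats[[i]]$family, feats[[j]]$family)
        bits <- c(bits, rank * .N_DIST_BINS + pharm_bin(dist_ij))
      }
    }
  }
  new_fingerprint("pharmacophore", .PHARM_N_BITS, bits,
                  params = list(n_bins = .N_DIST_BINS))
}
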