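# shared generators for property-style tests

# diverse valid molecules: decoy scaffolds plus decorated analogs of two
# different parent compounds
random_molecules <- function(n, seed = 1L) {
  pool <- hybridvs:::.DECOY_POOL
  extra <- c(
    generate_analogs(hvs_example_query(), 10, depth = 2, seed = seed),
    generate_analogs("CC(=O)Nc1ccc(O)cc1", 10, depth = 1, seed = seed + 1L)
  )
  all <- c(pool, extra)
  set.seed(seed)
  sample(all, n, replace = n > length(all))
}

# independent re-rooted/re-ordered SMILES of the same structure
rewrite_smiles <- function(smiles, seed = 1L) {
  g <- parse_smiles(smiles)
  set.seed(seed)
  root <- sample.int(nrow(g$atoms), 1L)
  hybridvs:::write_smiles(g, root = root, shuffle = TRUE)
}

# random sorted bit sets for similarity-metric oracles
random_bitset_pair <- function(n_bits = 256L) {
  na <- sample.int(40L, 1L)
  nb <- sample.int(40L, 1L)
  list(a = sort(sample.int(n_bits, na) - 1L),
       b = sort(sample.int(n_bits, nb) - 1L))
}

fp_from_bits <- function(bits, n_bits = 256L) {
  hybridvs:::new_fingerprint("morgan", n_bits, bits)
}

# dense 0/1-vector similarity oracles, independent of the set-based path
dense_tanimoto <- function(a, b, n_bits = 256L) {
  va <- integer(n_bits); va[a + 1L] <- 1L
  vb <- integer(n_bits); vb[b + 1L] <- 1L
  inter <- sum(va & vb); uni <- sum(va | vb)
  if (uni == 0) 0 else inter / uni
}

dense_cosine <- function(a, b, n_bits = 256L) {
  va <- integer(n_bits); va[a + 1L] <- 1L
  vb <- integer(n_bits); vb[b + 1L] <- 1L
  if (sum(va) == 0 || sum(vb) == 0) return(0)
  sum(va * vb) / sqrt(sum(va) * sum(vb))
}

dense_euclidean <- function(a, b, n_bits = 256L) {
  va <- integer(n_bits); va[a + 1L] <- 1L
  vb <- integer(n_bits); vb[b + 1L] <- 1L
  sqrt(sum((va - vb)^2))
}
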