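test_that("atom invariants distinguish environment tuples and hash stably", {
  inv <- atom_invariants(parse_smiles("CCO"))
  # terminal CH3 vs middle CH2: degree differs
  expect_true(inv$hashes[1] != inv$hashes[2])
  expect_equal(unname(inv$tuples[1, "degree"]), 1L)
  expect_equal(unname(inv$tuples[2, "degree"]), 2L)
  # identical tuples, identical hashes (two methyls of propane)
  inv2 <- atom_invariants(parse_smiles("CCC"))
  expect_equal(inv2$hashes[1], inv2$hashes[3])
  # different element, different hash
  expect_true(atom_invariants(parse_smiles("C"))$hashes !=
                atom_invariants(parse_smiles("N"))$hashes)
})

test_that("morgan fingerprint follows the iterative environment update", {
  # isolated atom: no neighborhood beyond round 0, one bit at any radius
  expect_length(morgan_fingerprint(parse_smiles("C"), radius = 2)$on_bits,
                1L)
  # CCO at radius 1: 3 round-0 + 3 round-1 identifiers
  pool <- hybridvs:::morgan_identifier_pool(parse_smiles("CCO"), 1L)
  expect_length(pool, 6L)
  fp <- morgan_fingerprint(parse_smiles("CCO"), radius = 1)
  expect_lte(length(fp$on_bits), 6L)
  # atom-order invariance
  expect_identical(morgan_fingerprint(parse_smiles("CCO"))$on_bits,
                   morgan_fingerprint(parse_smiles("OCC"))$on_bits)
  # parameter validation
  expect_error(morgan_fingerprint(parse_smiles("C"), radius = 7))
  expect_error(morgan_fingerprint(parse_smiles("C"), n_bits = 1000))
})

test_that("identifier pools grow monotonically with radius", {
  for (s in c("CCO", "c1ccccc1CCN", "CC(=O)NC1CCCCC1")) {
    for (r in 0:2) {
      p_r <- hybridvs:::morgan_identifier_pool(parse_smiles(s), r)
      p_r1 <- hybridvs:::morgan_identifier_pool(parse_smiles(s), r + 1L)
      expect_true(all(p_r %in% p_r1), label = sprintf("%s radius %d", s, r))
    }
  }
})

test_that("folding is modular, deduplicating, and never grows the set", {
  expect_identical(fold_bits(c(5, 2053), 2048), 5L)
  expect_identical(fold_bits(numeric(), 2048), integer())
  expect_identical(fold_bits(c(0, 1, 2), 2048), c(0L, 1L, 2L))
  set.seed(31)
  for (i in 1:20) {
    ids <- sample(0:(2^32 - 1), sample(1:300, 1))
    folded <- fold_bits(ids, 512)
    expect_lte(length(folded), length(ids))
    expect_true(all(folded >= 0 & folded < 512))
  }
})

test_that("pharmacophore typing reproduces the rule set on known molecules", {
  # benzene: the aromatic ring is the only feature
  fb <- assign_pharmacophore_features(parse_smiles("c1ccccc1"))
  expect_length(fb, 1L)
  expect_equal(fb[[1]]$family, "aromatic")
  expect_equal(sort(fb[[1]]$atom_indices), 0:5)

  # phenol: donor + acceptor on the hydroxyl O, one aromatic ring
  fp <- assign_pharmacophore_features(parse_smiles("Oc1ccccc1"))
  fams <- vapply(fp, `[[`, character(1), "family")
  expect_equal(fams, c("donor", "acceptor", "aromatic"))
  expect_equal(fp[[1]]$atom_indices, 0L)
  expect_equal(fp[[2]]$atom_indices, 0L)

  # acetate: charged O is the one neg_ionizable, both oxygens accept
  fa <- assign_pharmacophore_features(parse_smiles("CC(=O)[O-]"))
  fams <- vapply(fa, `[[`, character(1), "family")
  negs <- which(fams == "neg_ionizable")
  expect_length(negs, 1L)
  expect_equal(fa[[negs]]$atom_indices, 3L)
  expect_equal(sum(fams == "acceptor"), 2L)
  expect_setequal(unlist(lapply(fa[fams == "acceptor"], `[[`,
                                "atom_indices")), c(2L, 3L))
  expect_false("donor" %in% fams)

  # amine vs amide nitrogen
  amine <- assign_pharmacophore_features(parse_smiles("CCN"))
  expect_true("pos_ionizable" %in%
                vapply(amine, `[[`, character(1), "family"))
  amide <- assign_pharmacophore_features(parse_smiles("CC(=O)NC"))
  fams <- vapply(amide, `[[`, character(1), "family")
  expect_false("pos_ionizable" %in% fams)

  # carboxylic acid OH is neg_ionizable even when neutral
  acid <- assign_pharmacophore_features(parse_smiles("CC(=O)O"))
  fams <- vapply(acid, `[[`, character(1), "family")
  expect_true("neg_ionizable" %in% fams)
})

test_that("pharmacophore fingerprint encodes binned feature-pair distances exactly", {
  # benzene: single feature, no pairs
  expect_length(pharmacophore_fingerprint(parse_smiles("c1ccccc1"))$on_bits,
                0L)
  # phenol: donor-acceptor at 0, donor-ring at 1, acceptor-ring at 1
  pf <- pharmacophore_fingerprint(parse_smiles("Oc1ccccc1"))
  expect_equal(pf$n_bits, 126L)
  expect_length(pf$on_bits, 3L)
  da <- hybridvs:::pharm_pair_rank("donor", "acceptor") * 6L + 0L
  dr <- hybridvs:::pharm_pair_rank("donor", "aromatic") * 6L + 1L
  ar <- hybridvs:::pharm_pair_rank("acceptor", "aromatic") * 6L + 1L
  expect_setequal(pf$on_bits, c(da, dr, ar))
  # thiophene: only the ring is typed -> single feature, no pairs
  expect_length(pharmacophore_fingerprint(parse_smiles("c1ccsc1"))$on_bits,
                0L)
})

test_that("bit index decode/encode is the identity over all 126 bits", {
  for (bit in 0:125) {
    d <- hybridvs:::decode_pharm_bit(bit)
    expect_equal(
      hybridvs:::pharm_pair_rank(d$family_a, d$family_b) * 6L + d$bin, bit)
  }
  mols <- random_molecules(20, seed = 5)
  for (s in mols) {
    pf <- pharmacophore_fingerprint(parse_smiles(s))
    expect_true(all(pf$on_bits >= 0L & pf$on_bits < 126L), label = s)
  }
})

test_that("both fingerprints are invariant to SMILES re-rooting", {
  mols <- random_molecules(24, seed = 12)
  for (i in seq_along(mols)) {
    g <- parse_smiles(mols[i])
    alt <- rewrite_smiles(mols[i], seed = 1000 + i)
    g2 <- parse_smiles(alt)
    expect_identical(morgan_fingerprint(g2)$on_bits,
                     morgan_fingerprint(g)$on_bits,
                     label = sprintf("%s vs %s", mols[i], alt))
    expect_identical(pharmacophore_fingerprint(g2)$on_bits,
                     pharmacophore_fingerprint(g)$on_bits,
                     label = sprintf("%s vs %s", mols[i], alt))
  }
})

test_that("morgan Tanimoto rank-correlates with a reference toolkit", {
  # RDKit, driven through the system python, is the independent oracle;
  # bit-level equality is not expected (different hash), rank agreement is
  mols <- random_molecules(50, seed = 404)
  query <- hvs_example_query()
  qg <- parse_smiles(query)
  qfp <- morgan_fingerprint(qg)
  mine <- vapply(mols, function(s)
    tanimoto(morgan_fingerprint(parse_smiles(s)), qfp), numeric(1))

  smi_file <- tempfile(fileext = ".smi")
  writeLines(c(query, mols), smi_file)
  py <- sprintf('
import sys
from rdkit import Chem, RDLogger
from rdkit.Chem import AllChem, DataStructs
RDLogger.DisableLog("rdApp.*")
lines = [l.strip() for l in open("%s") if l.strip()]
mols = [Chem.MolFromSmiles(s) for s in lines]
fps = [AllChem.GetMorganFingerprintAsBitVect(m, 2, nBits=2048) for m in mols]
for fp in fps[1:]:
    print(DataStructs.TanimotoSimilarity(fps[0], fp))
', smi_file)
  ref <- suppressWarnings(
    as.numeric(system2("python", "-", input = py, stdout = TRUE)))
  expect_length(ref, length(mols))
  expect_false(anyNA(ref))
  rho <- cor(mine, ref, method = "spearman")
  expect_gt(rho, 0.7)
})
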