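test_that("linear and aromatic SMILES parse with correct implicit hydrogens", {
  g <- parse_smiles("CCO")
  expect_equal(nrow(g$atoms), 3L)
  expect_equal(nrow(g$bonds), 2L)
  expect_equal(g$atoms$implicit_h, c(3L, 2L, 1L))
  expect_equal(g$bonds$order_code, c(1L, 1L))

  b <- parse_smiles("c1ccccc1")
  expect_equal(nrow(b$atoms), 6L)
  expect_equal(nrow(b$bonds), 6L)
  expect_true(all(b$atoms$aromatic))
  expect_true(all(b$atoms$in_ring))
  expect_equal(b$atoms$implicit_h, rep(1L, 6))
  expect_true(all(b$bonds$order_code == 4L))

  # heteroaromatics: pyridine N bare, pyrrole N declares its H, furan O
  # donates a lone pair instead of carrying H
  expect_equal(parse_smiles("c1ccncc1")$atoms$implicit_h[4], 0L)
  py <- parse_smiles("c1cc[nH]c1")
  expect_equal(py$atoms$explicit_h[py$atoms$element == "N"], 1L)
  expect_equal(parse_smiles("c1ccoc1")$atoms$implicit_h[4], 0L)

  # charge-adjusted valences
  a <- parse_smiles("CC(=O)[O-]")
  expect_equal(a$atoms$formal_charge, c(0L, 0L, 0L, -1L))
  n <- parse_smiles("C[N+](C)(C)C")
  expect_equal(n$atoms$formal_charge[2], 1L)
  # hypervalent sulfur promotes to 6
  s <- parse_smiles("CCS(=O)(=O)CC")
  expect_equal(s$atoms$implicit_h[3], 0L)
})

test_that("malformed SMILES raise distinct, position-bearing errors", {
  expect_error(parse_smiles("C1CC"), class = "smiles_ring_closure_error")
  expect_error(parse_smiles("C(C"), class = "smiles_parenthesis_error")
  expect_error(parse_smiles("CC)C"), class = "smiles_parenthesis_error")
  expect_error(parse_smiles("CXy"), class = "smiles_element_error")
  expect_error(parse_smiles("C(=O)(=O)(=O)O"),
               class = "smiles_valence_error")
  expect_error(parse_smiles("cc"), class = "smiles_aromaticity_error")
  # messages carry a position
  err <- tryCatch(parse_smiles("C1CC"), error = identity)
  expect_match(conditionMessage(err), "position")
})

test_that("topological distances are BFS bond counts with Inf across components", {
  d <- topological_distances(parse_smiles("CCO"))
  expect_equal(d[1, 3], 2)
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  # para distance on benzene
  expect_equal(max(topological_distances(parse_smiles("c1ccccc1"))), 3)
  expect_true(is.infinite(topological_distances(parse_smiles("C.C"))[1, 2]))
})

test_that("ring perception finds fused aromatic rings and sets flags", {
  r <- ring_info(parse_smiles("c1ccccc1"))
  expect_length(r$rings, 1L)
  expect_length(r$rings[[1]], 6L)
  expect_equal(r$aromatic_rings, 1L)

  r3 <- ring_info(parse_smiles("C1CC1"))
  expect_length(r3$rings, 1L)
  expect_length(r3$rings[[1]], 3L)
  expect_length(r3$aromatic_rings, 0L)

  nap <- parse_smiles("c1ccc2ccccc2c1")
  expect_length(nap$rings, 2L)
  expect_true(all(lengths(nap$rings) == 6L))
  expect_length(nap$aromatic_rings, 2L)
  shared <- intersect(nap$rings[[1]], nap$rings[[2]])
  expect_length(shared, 2L)

  chain <- parse_smiles("CCCC")
  expect_false(any(chain$atoms$in_ring))
})

test_that("parsing is deterministic: same string gives identical graphs", {
  for (s in c("CCO", "c1ccc2ccccc2c1", "CC(=O)[O-]",
              "COc1cc2ncnc(Nc3ccc(F)cc3)c2cc1OC")) {
    expect_identical(parse_smiles(s), parse_smiles(s))
  }
})

test_that("implicit hydrogens satisfy an independent valence balance on generated molecules", {
  # hand oracle: bond-order sum (aromatic = 1 + one shared unit, unless
  # that unit alone overflows the element) + H count must equal an
  # allowed valence, charge-adjusted
  allowed_valence <- list(B = 3, C = 4, N = 3, O = 2, F = 1, P = c(3, 5),
                          S = c(2, 4, 6), Cl = 1, Br = 1, I = 1, H = 1)
  check_atom <- function(g, k) {
    at <- g$atoms[k, ]
    if (at$bracket) return(TRUE)   # H fixed by the input, nothing derived
    rows <- g$bonds$atom_a == at$index | g$bonds$atom_b == at$index
    orders <- g$bonds$order_code[rows]
    base <- sum(ifelse(orders == 4L, 1L, orders))
    av <- allowed_valence[[at$element]]
    if (at$element %in% c("N", "P")) av <- av + at$formal_charge
    if (at$element %in% c("O", "S") && at$formal_charge < 0) {
      av <- av - abs(at$formal_charge)
    }
    sums <- if (at$aromatic) {
      if (base + 1L <= max(av)) base + 1L else base
    } else base
    (sums + at$implicit_h) %in% av
  }
  mols <- random_molecules(50, seed = 202)
  for (s in mols) {
    g <- parse_smiles(s)
    for (k in seq_len(nrow(g$atoms))) {
      expect_true(check_atom(g, k),
                  label = sprintf("valence balance, %s atom %d", s, k - 1L))
    }
  }
})

test_that("ring flags equal brute-force cycle membership on small graphs", {
  # independent oracle: an edge lies on a cycle iff its endpoints stay
  # connected after removing it; an atom iff it touches such an edge
  edge_on_cycle <- function(g, e) {
    bonds <- g$bonds[-e, , drop = FALSE]
    n <- nrow(g$atoms)
    reach <- function(from, to) {
      seen <- logical(n); seen[from + 1L] <- TRUE; queue <- from
      while (length(queue)) {
        u <- queue[1]; queue <- queue[-1]
        nb <- c(bonds$atom_b[bonds$atom_a == u], bonds$atom_a[bonds$atom_b == u])
        for (v in nb) if (!seen[v + 1L]) {
          if (v == to) return(TRUE)
          seen[v + 1L] <- TRUE; queue <- c(queue, v)
        }
      }
      FALSE
    }
    reach(g$bonds$atom_a[e], g$bonds$atom_b[e])
  }
  cases <- c("C1CC1", "C1CCCCC1", "c1ccccc1C", "C1CC1CC2CC2",
             "c1ccc2ccccc2c1", "CC(C)C", "C1CCC1.CC", "C1CCCCC1O")
  for (s in cases) {
    g <- parse_smiles(s)
    stopifnot(nrow(g$atoms) <= 12)
    ring_bonds <- vapply(seq_len(nrow(g$bonds)), function(e)
      edge_on_cycle(g, e), logical(1))
    expect_equal(g$bonds$in_ring, ring_bonds, label = s)
    ring_atoms <- sort(unique(c(g$bonds$atom_a[ring_bonds],
                                g$bonds$atom_b[ring_bonds])))
    expect_equal(g$atoms$index[g$atoms$in_ring], ring_atoms, label = s)
  }
})

test_that(".smi conventions round-trip through the re-serializer", {
  mols <- random_molecules(20, seed = 77)
  set.seed(99)
  for (s in mols) {
    g <- parse_smiles(s)
    s2 <- hybridvs:::write_smiles(g, root = sample.int(nrow(g$atoms), 1),
                                  shuffle = TRUE)
    g2 <- parse_smiles(s2)
    expect_equal(nrow(g2$atoms), nrow(g$atoms), label = s)
    expect_equal(nrow(g2$bonds), nrow(g$bonds), label = s)
    expect_equal(sort(table(g2$atoms$element)), sort(table(g$atoms$element)),
                 label = s)
  }
})
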