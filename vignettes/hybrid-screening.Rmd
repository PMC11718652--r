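---
title: "Hybrid ligand-based virtual screening with dual fingerprints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid ligand-based virtual screening with dual fingerprints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridvs)
```

## The method

`hybridvs` implements a ligand-based virtual screening funnel: given a
compound library (SMILES) and one query compound, it ranks the library
by structural similarity to the query under **two independent molecular
representations**, clusters each similarity profile, and keeps only the
compounds that fall into the most query-like cluster under *both*
representations. The intersection — the consensus hit set — is the
funnel's output; in a full campaign it would be passed on to more
expensive stages (affinity prediction, docking, molecular dynamics),
none of which are part of this package.

The two representations are deliberately complementary:

* **Morgan (ECFP-style) circular fingerprints** encode local atom
  connectivity. Every atom starts from a hashed invariant tuple
  (atomic number, heavy degree, hydrogen count, formal charge,
  aromaticity, ring membership); each round rehashes an atom's
  identifier together with the sorted (bond order, neighbor identifier)
  list; identifiers from all rounds are pooled, deduplicated, and
  folded modulo the bit-vector length.
* **2D pharmacophore pair fingerprints** encode pharmacology-relevant
  features and their topological arrangement: every unordered pair of
  features (donor, acceptor, aromatic ring, hydrophobe,
  positive/negative ionizable) is recorded at a binned bond-count
  distance. With 21 family pairs and 6 distance bins the vector has
  exactly 126 positions and no hash collisions.

Similarity is the Tanimoto (Jaccard) coefficient on on-bit sets,
\(T(A,B) = |A \cap B| / |A \cup B|\); cosine similarity and Euclidean
distance are provided for comparison. For binary vectors
\(T \le \cos\) always, a bound the test suite asserts.

A structure scoring high under both a connectivity view and a
pharmacophore view is a stronger analog hypothesis than one scoring
high under either alone — that is the rationale for the consensus
intersection.

## Why cluster a 1-D similarity profile?

With a million-compound library, a fixed similarity cutoff is
arbitrary. Clustering the 1-D Tanimoto distribution with K-Means lets
the data choose its own strata; the "top" cluster is then selected as
the one whose *minimum* member similarity is maximal (ties: larger
maximum, then larger count, then lower id). We read "highest range of
Tanimoto values" as *highest-lying values* rather than *widest spread*:
on clustered 1-D data the top stratum is exactly the cluster with the
greatest lower bound, and a width reading would reward outlier-stretched
clusters. On the two bundled full-scale reference tables both readings
agree, but the lower-bound rule is the more robust formalization.

## K-Means choices

* **Initialization** is uniform random selection of k distinct data
  points, 10 restarts by default (k-means++ is available via
  `init = "kmeans++"`). Lloyd iterations stop when the maximum centroid
  displacement drops below `tol = 1e-6` or after `max_iter = 300`
  rounds. Assignment ties go to the lowest cluster index; a cluster
  emptied mid-run receives the point farthest from its current
  centroid. Every run is a pure function of its seed.
* **Cluster count** comes from the elbow rule unless fixed: scan k
  (default 1–20), normalize the (k, WCSS) curve to the unit square, and
  pick the interior k with the largest perpendicular distance to the
  chord joining the endpoints; ties resolve to the smaller k. The scan
  warm-starts each k with the previous best centroids plus one split
  point, which makes the WCSS curve exactly monotone non-increasing —
  without warm starts, restart noise can make it locally rise and the
  chord construction unreliable.
* **Validation**: the mean silhouette score
  \(s = (b - a)/\max(a, b)\); singleton clusters score 0. Above
  \(10^5\) points the score is estimated on a seeded subsample of
  \(10^4\) points, since the exact computation is quadratic.
* **Exact oracle**: `dp_kmeans_1d()` computes the globally optimal 1-D
  clustering by dynamic programming over contiguous segments of the
  sorted values. It exists to bound and test Lloyd's algorithm, never
  to replace it in the pipeline.

The test suite asserts that best-of-20-restart Lloyd matches the DP
optimum (within 1e-9) on at least 95 of 100 random clustered instances.
The instance family is k well-separated Gaussian components with the
fitted k equal to the component count, n = 20–60 — the regime the elbow
stage produces, since it selects k to match the data's structure. On
structureless (uniform) data, or when k exceeds the number of modes,
best-of-20 random restarts finds the exact optimum only ~80–90% of the
time; we verified those misses are genuine local minima of Lloyd's
algorithm (bit-identical WCSS to `stats::kmeans` with the same restart
budget), not implementation defects, and they do not affect cluster
*selection*, which only needs the top stratum isolated.

## The SMILES parser

Fingerprints are computed from a native parser covering the dialect
that drug-like screening libraries actually use: organic-subset atoms
(B, C, N, O, P, S, halogens), aromatic lowercase atoms, bracket atoms
with charge and explicit hydrogens, branches, ring closures (digits and
`%nn`), bond symbols, and dot-disconnection. Stereo markers and
isotopes are accepted and ignored — both fingerprint types are
stereo-agnostic. Aromaticity is taken from the input notation; no
Hückel perception is attempted.

Implicit hydrogens follow default valences (B 3, C 4, N 3, O 2, P 3,
S 2, halogens 1), with P promoting to 5 and S to 4 or 6 when the bond
sum demands, and charges adjusting N-family valence by +charge and
O-family anions by −|charge|. For aromatic atoms each aromatic bond
counts one unit plus one unit for the delocalized system (benzene C:
2+1=3 → one H; pyridine N: 3 → none). One refinement was needed: for
lone-pair-donor heteroatoms (furan O, thiophene S) that extra unit
alone would overflow the element's maximum valence, so it is dropped
exactly when the bare bond sum still fits — giving furan oxygen zero
hydrogens instead of a spurious valence error. Bracket atoms carry
exactly the hydrogens they declare.

Malformed input (unmatched ring closures, unbalanced parentheses,
unknown tokens, valence-deficient atoms) raises typed conditions naming
the offending position, and per-compound failures are logged, never
silently dropped: a screening run reports how many of its inputs it
actually used.

## Pharmacophore typing rules

No SMARTS engine is included; the six families use minimal structural
rules on the heavy-atom graph: donors are N/O with a hydrogen and
non-negative charge; acceptors are N/O with non-positive charge except
aromatic N–H (its lone pair is in the ring); hydrophobes are halogens
and non-aromatic carbons with all-carbon neighborhoods (aromatic
carbons are excluded — the ring feature already covers them, and typing
every benzene carbon hydrophobic would drown the pair spectrum);
positive ionizables are cations and non-amide aliphatic amines;
negative ionizables are anions and carboxylic-acid hydroxyls. Distance
bins are 0, 1, 2–3, 4–5, 6–7, 8+ bonds — the coarse binning commonly
used for 2D (topological) pharmacophore pairs.

These rules are intentionally conservative. They miss tautomer-aware
typing, thioether acceptors, and ring-system hydrophobes; for the
screening statistics the package computes, what matters is that the
typing is deterministic and applied identically to query and library.

## The synthetic benchmark

Because a million-compound library cannot ship with a package, the
generator builds the situation the screen assumes, at desk scale:

* **Analogs** are the query with 1–`depth` small substituents (methyl,
  hydroxyl, fluoro, amino, methoxy) inserted at seeded-random positions
  that still carry hydrogen. They contain the query scaffold by
  construction, so their Tanimoto values sit high.
* **Decoys** come from a fixed pool of 36 drug-like scaffolds
  (aliphatic chains, saturated rings and heterocycles, esters, amides,
  acids, sulfones, small heteroaromatics) chosen to be structurally
  unrelated to the default quinazoline-like query, each optionally
  decorated for diversity. A fixed pool guarantees chemical validity
  without a valence-repair algorithm.

The default benchmark plants 20 depth-1 analogs among 200 decoys
(seed 7). Analog/decoy labels never enter the screen — recovery is
measured afterwards against them. The generator emulates the
*separation structure* of a real campaign (a high-similarity analog
band over a low-similarity background); it does not emulate real
libraries' property distributions, activity cliffs, or near-decoy
analogs, so a passing benchmark demonstrates the pipeline's mechanics,
not prospective enrichment on real data.

Problem sizes used throughout the tests and the acceptance script (220
library compounds, 900-point mixtures, 100 oracle instances of up to 60
points) were chosen as the smallest sizes at which each property is
meaningfully exercised.

## Degenerate inputs and numerical conventions

* Two all-zero fingerprints have Tanimoto 0, not 1 — absence of
  features is no evidence of similarity (and matches common toolkit
  behavior).
* Similarity is computed on on-bit sets, never dense vectors, but is
  value-identical to the dense definition (property-tested against
  dense oracles).
* `k` is capped at the number of distinct values; an all-identical
  library therefore collapses to a single cluster and the consensus is
  the whole library.
* All ties (assignment, elbow, top-cluster) resolve deterministically,
  so a report is reproducible from its config.

## Known limitations

* The parser rejects SMILES outside its dialect (e.g. wildcard atoms,
  quadruple bonds) rather than guessing; kekulized aromatic input
  (uppercase with alternating double bonds) is read as non-aromatic.
* ECFP environment deduplication is by identifier value only, not by
  bond-set equality, so symmetric environments that differ structurally
  but hash equal are counted once.
* The consensus is an id-level intersection; duplicate structures under
  different ids are treated as distinct library entries.
* Elbow selection needs at least 3 curve points and is, like any knee
  heuristic, one defensible formalization among several.
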