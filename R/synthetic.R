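# Deterministic synthetic screening libraries ------------------------------
#
# Planted query analogs (scaffold + small substituent decorations, high
# Tanimoto to the query) among structurally unrelated drug-like decoys
# (low Tanimoto), so the whole screening funnel is testable without any
# external compound database.

# substituents appended as branches at positions that still carry H
.SUBSTITUENT_PALETTE <- c("C", "O", "F", "N", "OC")

# >= 30 diverse drug-like decoy scaffolds: aliphatic chains, saturated
# (hetero)cycles, small heteroaromatics, esters/amides/acids, sulfones --
# deliberately unrelated to the default quinazoline-like query
.DECOY_POOL <- c(
  "CCCCCCCC", "CCCCCC(C)C", "CC(C)CC(C)(C)C", "CCCCCCCCCC",
  "CCCCC(CC)CC",
  "C1CCCCC1", "C1CCCC1", "C1CCCCCC1", "C1CCNCC1", "C1CCOCC1",
  "C1CCSCC1", "C1CCC2CCCCC2C1", "CC1CCCCC1C",
  "CCOC(=O)CC", "CC(=O)NC1CCCCC1", "CCC(=O)CC", "CC(=O)OCC(C)C",
  "CCNC(=O)CC", "CCCC(=O)O", "OC(=O)CCC(=O)O",
  "OCC(O)CO", "OCCOCCO", "CCN(CC)CC", "NCCCCN", "OCCCCCO",
  "CCOCC", "CC(C)OC(C)C", "FC(F)(F)C1CCCCC1", "ClCCCl",
  "c1ccsc1", "c1ccoc1", "c1cc[nH]c1", "Cc1ccco1", "Cc1cccs1",
  "CCS(=O)(=O)CC", "CS(=O)(=O)NC"
)

#' Built-in example query compound
#'
#' A fixed drug-like anilino-quinazoline SMILES used as the default
#' query of the synthetic benchmark (fused bicyclic aromatic core,
#' aniline linker, fluoro and methoxy substituents -- typical kinase
#' inhibitor chemotype).
#'
#' @return A SMILES string.
#' @export
hvs_example_query <- function() {
  "COc1cc2ncnc(Nc3ccc(F)cc3)c2cc1OC"
}

#' Specification of a synthetic screening library
#'
#' A pure-function description of a library: the same spec always
#' generates the same compounds. Defaults plant 20 depth-1 analogs of
#' the built-in query among 200 decoys.
#'
#' @param query_smiles Query compound the analogs derive from.
#' @param n_analogs Number of planted query analogs (>= 0).
#' @param n_decoys Number of decoys (>= 0); total must be >= 2.
#' @param seed Integer seed (required).
#' @param depth Substituent decorations per analog (0 = exact copies).
#' @return A list of class `synthetic_library_spec`.
#' @export
synthetic_library_spec <- function(query_smiles = hvs_example_query(),
                                   n_analogs = 20L, n_decoys = 200L,
                                   seed = 7L, depth = 1L) {
  n_analogs <- as.integer(n_analogs)
  n_decoys <- as.integer(n_decoys)
  if (n_analogs < 0L || n_decoys < 0L || n_analogs + n_decoys < 2L) {
    stop("need n_analogs >= 0, n_decoys >= 0, total >= 2", call. = FALSE)
  }
  if (is.null(seed) || is.na(seed)) stop("`seed` is required", call. = FALSE)
  structure(list(query_smiles = query_smiles, n_analogs = n_analogs,
                 n_decoys = n_decoys, seed = as.integer(seed),
                 depth = as.integer(depth)),
            class = "synthetic_library_spec")
}

# positions where a "(X)" branch can be textually inserted: non-bracket
# atoms that still carry at least one implicit hydrogen
substitutable_positions <- function(graph) {
  which(graph$atoms$implicit_h >= 1L & !graph$atoms$bracket)
}

insert_branch <- function(smiles, token_end, substituent) {
  paste0(substr(smiles, 1L, token_end), "(", substituent, ")",
         substr(smiles, token_end + 1L, nchar(smiles)))
}

# one random decoration; returns the new SMILES (re-parsed for validity)
decorate_once <- function(graph) {
  pos <- substitutable_positions(graph)
  if (length(pos) == 0L) return(NULL)
  k <- pos[sample.int(length(pos), 1L)]
  sub <- .SUBSTITUENT_PALETTE[sample.int(length(.SUBSTITUENT_PALETTE), 1L)]
  parse_smiles(insert_branch(graph$source_smiles,
                             graph$atoms$token_end[k], sub))
}

#' Generate query analogs by substituent decoration
#'
#' Each analog is the query SMILES with up to `depth` small substituents
#' (methyl, hydroxyl, fluoro, amino, methoxy) inserted as branches at
#' seeded-random positions that still carry hydrogen. Every analog
#' parses and contains the query's heavy-atom scaffold as a subgraph by
#' construction.
#'
#' @param query Query SMILES or `molecular_graph`; must have at least
#'   one substitutable position.
#' @param n Number of analogs.
#' @param depth Decorations per analog (0 returns exact copies).
#' @param seed Integer seed.
#' @return Character vector of `n` SMILES.
#' @export
generate_analogs <- function(query, n, depth = 1L, seed = 1L) {
  qgraph <- if (inherits(query, "molecular_graph")) query else
    parse_smiles(query)
  if (length(substitutable_positions(qgraph)) == 0L) {
    stop("query has no substitutable position (no implicit hydrogens)",
         call. = FALSE)
  }
  if (n == 0L) return(character())
  with_local_seed(seed, {
    vapply(seq_len(n), function(i) {
      g <- qgraph
      if (depth > 0L) {
        for (e in seq_len(depth)) {
          g2 <- decorate_once(g)
          if (is.null(g2)) break
          g <- g2
        }
      }
      g$source_smiles
    }, character(1))
  })
}

#' Generate decoy compounds
#'
#' Seeded sampling from a built-in pool of 36 drug-like scaffolds
#' structurally unrelated to the default query, each optionally
#' decorated with one or two palette substituents for diversity. All
#' outputs parse.
#'
#' @param n Number of decoys (>= 0).
#' @param seed Integer seed.
#' @return Character vector of `n` SMILES.
#' @export
generate_decoys <- function(n, seed = 1L) {
  if (n == 0L) return(character())
  with_local_seed(seed, {
    vapply(seq_len(n), function(i) {
      g <- parse_smiles(.DECOY_POOL[sample.int(length(.DECOY_POOL), 1L)])
      n_dec <- sample.int(3L, 1L) - 1L   # 0, 1 or 2 decorations
      if (n_dec > 0L) {
        for (e in seq_len(n_dec)) {
          g2 <- decorate_once(g)
          if (is.null(g2)) break
          g <- g2
        }
      }
      g$source_smiles
    }, character(1))
  })
}

#' Generate a labeled synthetic screening library
#'
#' Analogs and decoys are generated from the spec's seed, shuffled
#' together, and labeled. The `is_analog` labels exist for evaluation
#' only; the screen itself sees just ids and SMILES.
#'
#' @param spec A [synthetic_library_spec()].
#' @return A data.frame with columns `id` (`lib_<n>`), `smiles`,
#'   `is_analog`, of `n_analogs + n_decoys` rows.
#' @examples
#' lib <- generate_library(synthetic_library_spec(n_analogs = 3,
#'                                                n_decoys = 10, seed = 1))
#' table(lib$is_analog)
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "synthetic_library_spec"))
  analogs <- generate_analogs(spec$query_smiles, spec$n_analogs,
                              depth = spec$depth, seed = spec$seed)
  decoys <- generate_decoys(spec$n_decoys, seed = spec$seed + 1L)
  smiles <- c(analogs, decoys)
  labels <- c(rep(TRUE, length(analogs)), rep(FALSE, length(decoys)))
  perm <- with_local_seed(spec$seed + 2L, sample.int(length(smiles)))
  data.frame(
    id = sprintf("lib_%04d", seq_along(smiles)),
    smiles = smiles[perm],
    is_analog = labels[perm],
    row.names = NULL
  )
}
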