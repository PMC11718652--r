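# Bit-set similarity metrics and the library-vs-query profile -------------

check_comparable <- function(a, b) {
  if (!inherits(a, "fingerprint") || !inherits(b, "fingerprint")) {
    stop("both arguments must be fingerprints", call. = FALSE)
  }
  if (a$kind != b$kind) {
    stop(sprintf("fingerprint kind mismatch: %s vs %s", a$kind, b$kind),
         call. = FALSE)
  }
  if (a$n_bits != b$n_bits) {
    stop(sprintf("fingerprint length mismatch: %d vs %d", a$n_bits, b$n_bits),
         call. = FALSE)
  }
}

#' Tanimoto (Jaccard) similarity of two fingerprints
#'
#' `|A intersect B| / |A union B|` over the on-bit sets. Two all-zero
#' fingerprints score 0: an empty bit vector carries no evidence of
#' similarity. Computed on the on-bit sets directly (never on dense
#' vectors) but value-identical to the dense 0/1 definition.
#'
#' @param a,b Fingerprints of the same kind and length.
#' @return Similarity in `[0, 1]`.
#' @examples
#' g1 <- morgan_fingerprint(parse_smiles("CCO"))
#' tanimoto(g1, g1)  # 1
#' @export
tanimoto <- function(a, b) {
  check_comparable(a, b)
  inter <- length(intersect(a$on_bits, b$on_bits))
  uni <- length(a$on_bits) + length(b$on_bits) - inter
  if (uni == 0L) return(0)
  inter / uni
}

#' Cosine similarity of two binary fingerprints
#'
#' `|A intersect B| / sqrt(|A| * |B|)`; 0 when either fingerprint is
#' empty. Always at least the Tanimoto value on the same pair.
#'
#' @inheritParams tanimoto
#' @return Similarity in `[0, 1]`.
#' @export
cosine_similarity <- function(a, b) {
  check_comparable(a, b)
  na <- length(a$on_bits)
  nb <- length(b$on_bits)
  if (na == 0L || nb == 0L) return(0)
  length(intersect(a$on_bits, b$on_bits)) / sqrt(na * nb)
}

#' Euclidean distance between two binary fingerprints
#'
#' For 0/1 vectors the straight-line distance reduces to the square root
#' of the symmetric-difference size of the on-bit sets.
#'
#' @inheritParams tanimoto
#' @return Non-negative distance.
#' @export
euclidean_distance <- function(a, b) {
  check_comparable(a, b)
  sym_diff <- length(setdiff(a$on_bits, b$on_bits)) +
    length(setdiff(b$on_bits, a$on_bits))
  sqrt(sym_diff)
}

#' Tanimoto similarity profile of a library against one query
#'
#' Parses every library compound, generates Morgan and 2D pharmacophore
#' fingerprints for it and for the query, and records both Tanimoto
#' values per compound. Compounds that fail to parse are dropped from
#' the table but logged with their error message; the query must parse.
#'
#' @param library A data.frame with columns `id` and `smiles` (e.g. from
#'   [read_library()]), or a character vector of SMILES (ids are
#'   auto-assigned `row_<n>`).
#' @param query A query SMILES string or a `molecular_graph`.
#' @param radius,n_bits Morgan fingerprint parameters.
#' @return A data.frame (class `similarity_table`) with columns `id`,
#'   `smiles`, `tanimoto_morgan`, `tanimoto_pharmacophore`, one row per
#'   parsed compound in input order. Attributes: `failures` (data.frame
#'   `id`, `smiles`, `error`) and `query_id`.
#' @export
similarity_profile <- function(library, query, radius = 2L, n_bits = 2048L) {
  if (is.character(library)) {
    library <- data.frame(id = paste0("row_", seq_along(library) - 1L),
                          smiles = library)
  }
  stopifnot(is.data.frame(library), all(c("id", "smiles") %in%
                                          names(library)))
  if (nrow(library) == 0L) stop("library is empty", call. = FALSE)
  qgraph <- if (inherits(query, "molecular_graph")) query else
    parse_smiles(query)
  q_morgan <- morgan_fingerprint(qgraph, radius, n_bits)
  q_pharm <- pharmacophore_fingerprint(qgraph)

  n <- nrow(library)
  tm <- numeric(n)
  tp <- numeric(n)
  ok <- logical(n)
  errs <- character(n)
  for (k in seq_len(n)) {
    g <- tryCatch(parse_smiles(library$smiles[k]), error = identity)
    if (inherits(g, "error")) {
      errs[k] <- conditionMessage(g)
      next
    }
    ok[k] <- TRUE
    tm[k] <- tanimoto(morgan_fingerprint(g, radius, n_bits), q_morgan)
    tp[k] <- tanimoto(pharmacophore_fingerprint(g), q_pharm)
  }
  out <- data.frame(
    id = library$id[ok], smiles = library$smiles[ok],
    tanimoto_morgan = tm[ok], tanimoto_pharmacophore = tp[ok],
    row.names = NULL
  )
  attr(out, "failures") <- data.frame(
    id = library$id[!ok], smiles = library$smiles[!ok], error = errs[!ok],
    row.names = NULL
  )
  attr(out, "query_id") <- if (inherits(query, "molecular_graph"))
    query$source_smiles else query
  class(out) <- c("similarity_table", "data.frame")
  out
}
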