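# The hybrid screen: dual profiles -> per-fingerprint K-Means -> consensus

#' Screening configuration
#'
#' Validates and freezes every tunable of a hybrid screen run. A seed is
#' mandatory: cluster initialization is random and a run must be
#' reproducible from its config alone.
#'
#' @param seed Integer seed controlling all randomness of the run.
#' @param radius Morgan fingerprint radius (default 2).
#' @param n_bits Morgan fingerprint length, power of two (default 2048).
#' @param k Fixed cluster count, or `NULL` (default) for automatic
#'   selection by the elbow rule.
#' @param k_range Length-2 integer vector, the k scan range for the
#'   elbow rule (default `c(1, 20)`).
#' @param n_restarts K-Means restarts per k (default 10).
#' @return A validated list of class `screen_config`.
#' @export
screen_config <- function(seed, radius = 2L, n_bits = 2048L, k = NULL,
                          k_range = c(1L, 20L), n_restarts = 10L) {
  if (missing(seed) || is.null(seed) || is.na(suppressWarnings(
    as.integer(seed)))) {
    stop("`seed` is required: screening runs must be reproducible",
         call. = FALSE)
  }
  radius <- as.integer(radius)
  n_bits <- as.integer(n_bits)
  if (radius < 0L || radius > 6L) stop("`radius` must be in 0..6",
                                       call. = FALSE)
  if (n_bits < 1L || bitwAnd(n_bits, n_bits - 1L) != 0L) {
    stop("`n_bits` must be a positive power of two", call. = FALSE)
  }
  if (!is.null(k)) {
    k <- as.integer(k)
    if (k < 1L) stop("`k` must be >= 1", call. = FALSE)
  }
  k_range <- as.integer(k_range)
  if (length(k_range) != 2L || k_range[1] < 1L || k_range[1] > k_range[2]) {
    stop("`k_range` must be c(k_min, k_max) with 1 <= k_min <= k_max",
         call. = FALSE)
  }
  n_restarts <- as.integer(n_restarts)
  if (n_restarts < 1L) stop("`n_restarts` must be >= 1", call. = FALSE)
  structure(list(seed = as.integer(seed), radius = radius, n_bits = n_bits,
                 k = k, k_range = k_range, n_restarts = n_restarts),
            class = "screen_config")
}

#' Select the top cluster of a screening run
#'
#' "Highest range of Tanimoto values" formalized as: the cluster whose
#' minimum member value is maximal; ties broken by maximal maximum, then
#' by larger count, then by lowest cluster id. On clustered similarity
#' profiles this picks the cluster sitting highest on the similarity
#' axis -- the query-like compounds.
#'
#' @param summaries A data.frame with columns `cluster`, `count`, `min`,
#'   `max` (see [cluster_summaries()] / [read_summaries()]).
#' @return The selected cluster id.
#' @export
select_top_cluster <- function(summaries) {
  stopifnot(is.data.frame(summaries),
            all(c("cluster", "count", "min", "max") %in% names(summaries)))
  if (nrow(summaries) == 0L) stop("no cluster summaries", call. = FALSE)
  ord <- order(-summaries$min, -summaries$max, -summaries$count,
               summaries$cluster)
  summaries$cluster[ord[1]]
}

#' Consensus hits of two selected clusters
#'
#' Exact intersection of the member identifier sets from the clusters
#' selected under each fingerprint. Both clusterings index one library,
#' so identity is by library identifier; no structure re-canonicalization
#' is involved.
#'
#' @param members_a,members_b Identifier vectors.
#' @return The common identifiers, in the order of `members_a`.
#' @export
consensus_hits <- function(members_a, members_b) {
  members_a[members_a %in% members_b]
}

# cluster the 1-D similarity values of one fingerprint type
cluster_profile <- function(values, config) {
  n_distinct <- length(unique(values))
  if (!is.null(config$k)) {
    k <- min(config$k, n_distinct)
    model <- kmeans_lloyd(values, k, seed = config$seed,
                          n_restarts = config$n_restarts)
    return(list(model = model, k = k, curve = NULL, auto = FALSE))
  }
  k_min <- config$k_range[1]
  k_max <- min(config$k_range[2], n_distinct)
  if (k_max - k_min + 1L < 3L) {
    k <- k_max
    model <- kmeans_lloyd(values, k, seed = config$seed,
                          n_restarts = config$n_restarts)
    return(list(model = model, k = k, curve = NULL, auto = TRUE))
  }
  curve <- wcss_curve(values, k_min, k_max, seed = config$seed,
                      n_restarts = config$n_restarts)
  k <- select_k_elbow(curve)
  list(model = attr(curve, "models")[[as.character(k)]], k = k,
       curve = curve[, c("k", "wcss")], auto = TRUE)
}

#' Run the hybrid virtual screen
#'
#' Executes the full ligand-based screening funnel against one query
#' compound: Morgan and 2D pharmacophore fingerprints for every library
#' compound, Tanimoto profiles against the query, independent K-Means
#' clustering of each 1-D profile (cluster count fixed or elbow-selected
#' per fingerprint), per-cluster count/min/max summaries, top-cluster
#' selection, and the consensus intersection of the two selected
#' clusters' member sets. Deterministic given `config$seed`.
#'
#' @param library A data.frame with `id` and `smiles` columns (e.g. from
#'   [read_library()] or [generate_library()]) or a character vector of
#'   SMILES. At least 2 compounds must parse.
#' @param query Query SMILES string or `molecular_graph`; a parse
#'   failure aborts the run.
#' @param config A [screen_config()].
#' @return An object of class `screen_report`: library/parse counts, the
#'   similarity profile, per-fingerprint results (`model`, `summaries`,
#'   `selected_cluster`, `members`, `k`, `wcss_curve`), the `consensus`
#'   data.frame (`id`, `smiles`, `tanimoto_morgan`,
#'   `tanimoto_pharmacophore`), the config echo, and stage timings.
#' @examples
#' lib <- generate_library(synthetic_library_spec(
#'   n_analogs = 5, n_decoys = 20, seed = 1))
#' rep <- run_hybrid_screen(lib, hvs_example_query(),
#'                          screen_config(seed = 1, k = 2))
#' nrow(rep$consensus)
#' @export
run_hybrid_screen <- function(library, query, config) {
  stopifnot(inherits(config, "screen_config"))
  t0 <- proc.time()[["elapsed"]]
  qgraph <- tryCatch(
    if (inherits(query, "molecular_graph")) query else parse_smiles(query),
    error = function(e) {
      stop(sprintf("query SMILES failed to parse: %s", conditionMessage(e)),
           call. = FALSE)
    }
  )
  profile <- similarity_profile(library, qgraph,
                                radius = config$radius,
                                n_bits = config$n_bits)
  failures <- attr(profile, "failures")
  if (nrow(profile) < 2L) {
    stop("library must contain at least 2 parseable compounds",
         call. = FALSE)
  }
  t_profile <- proc.time()[["elapsed"]]

  fp_results <- list()
  for (fp in c("morgan", "pharmacophore")) {
    col <- paste0("tanimoto_", fp)
    values <- profile[[col]]
    cp <- cluster_profile(values, config)
    summ <- cluster_summaries(cp$model, values)
    sel <- select_top_cluster(summ)
    members <- profile$id[cp$model$assignments == sel]
    fp_results[[fp]] <- list(
      model = cp$model, k = cp$k, auto_k = cp$auto,
      wcss_curve = cp$curve, summaries = summ,
      selected_cluster = sel, members = members
    )
  }
  t_cluster <- proc.time()[["elapsed"]]

  ids <- consensus_hits(fp_results$morgan$members,
                        fp_results$pharmacophore$members)
  consensus <- as.data.frame(profile)[match(ids, profile$id),
                                      c("id", "smiles", "tanimoto_morgan",
                                        "tanimoto_pharmacophore")]
  rownames(consensus) <- NULL
  attr(consensus, "failures") <- NULL
  attr(consensus, "query_id") <- NULL
  t_end <- proc.time()[["elapsed"]]

  structure(
    list(
      library_size = if (is.data.frame(library)) nrow(library) else
        length(library),
      n_parsed = nrow(profile),
      parse_failures = failures,
      query = qgraph$source_smiles,
      profile = as.data.frame(profile),
      fingerprints = fp_results,
      consensus = consensus,
      config = config,
      timings = c(profile = t_profile - t0,
                  clustering = t_cluster - t_profile,
                  total = t_end - t0)
    ),
    class = "screen_report"
  )
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  cat(sprintf("  query: %s\n", x$query))
  cat(sprintf("  library: %d compounds (%d parsed, %d failed)\n",
              x$library_size, x$n_parsed, nrow(x$parse_failures)))
  for (fp in names(x$fingerprints)) {
    r <- x$fingerprints[[fp]]
    cat(sprintf("  %s: k=%d%s, selected cluster %d (%d members, wcss %.4g)\n",
                fp, r$k, if (r$auto_k) " (elbow)" else "",
                r$selected_cluster, length(r$members), r$model$wcss))
  }
  cat(sprintf("  consensus: %d compounds\n", nrow(x$consensus)))
  invisible(x)
}

# Serialization ------------------------------------------------------------

#' Serialize a screen report to JSON
#'
#' Writes every result field (models included) so that
#' [report_from_json()] reconstructs an equivalent report. Timings are
#' serialized too but are the one field excluded from determinism
#' comparisons.
#'
#' @param report A `screen_report`.
#' @param path File path; if `NULL`, the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "screen_report"))
  ser <- report
  class(ser) <- NULL
  ser$config <- unclass(ser$config)
  ser$fingerprints <- lapply(ser$fingerprints, function(r) {
    m <- r$model
    r$model <- list(k = m$k, centroids = as.numeric(m$centroids),
                    assignments = m$assignments, wcss = m$wcss,
                    n_iter = m$n_iter, iter_log = m$iter_log,
                    seed = m$seed)
    r$summaries <- as.data.frame(r$summaries)
    r
  })
  json <- jsonlite::toJSON(ser, digits = NA, auto_unbox = TRUE,
                           null = "null")
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' Rebuild a screen report from its JSON form
#'
#' @param path Path to a JSON file from [report_to_json()], or a JSON
#'   string.
#' @return A `screen_report`.
#' @export
report_from_json <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  raw$config <- structure(
    list(seed = as.integer(raw$config$seed),
         radius = as.integer(raw$config$radius),
         n_bits = as.integer(raw$config$n_bits),
         k = if (is.null(raw$config$k)) NULL else as.integer(raw$config$k),
         k_range = as.integer(raw$config$k_range),
         n_restarts = as.integer(raw$config$n_restarts)),
    class = "screen_config")
  raw$fingerprints <- lapply(raw$fingerprints, function(r) {
    m <- r$model
    r$model <- structure(
      list(k = as.integer(m$k),
           centroids = matrix(m$centroids, ncol = 1L),
           assignments = as.integer(m$assignments),
           wcss = m$wcss, n_iter = as.integer(m$n_iter),
           iter_log = m$iter_log, seed = as.integer(m$seed)),
      class = "kmeans_model")
    r$summaries <- structure(as.data.frame(r$summaries),
                             class = c("cluster_summary", "data.frame"))
    r$selected_cluster <- as.integer(r$selected_cluster)
    if (!is.null(r$wcss_curve) && length(r$wcss_curve) > 0) {
      r$wcss_curve <- as.data.frame(r$wcss_curve)
    } else {
      r$wcss_curve <- NULL
    }
    r
  })
  raw$parse_failures <- as.data.frame(raw$parse_failures)
  raw$profile <- as.data.frame(raw$profile)
  raw$consensus <- as.data.frame(raw$consensus)
  raw$timings <- unlist(raw$timings)
  structure(raw, class = "screen_report")
}
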