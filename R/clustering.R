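# K-Means over similarity distributions ------------------------------------
#
# Lloyd's algorithm with seeded random initialization and restarts, an
# exact dynamic-programming 1-D oracle, WCSS/elbow k selection with warm
# starts, and silhouette validation. 1-D Tanimoto profiles are the primary
# use; all routines accept general d-dimensional points.

# run expr with a private RNG stream, leaving the caller's RNG untouched
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

as_point_matrix <- function(values) {
  if (is.matrix(values)) values else matrix(as.numeric(values), ncol = 1L)
}

# squared Euclidean distances: n x k
sq_dist_to_centroids <- function(x, centroids) {
  n <- nrow(x)
  k <- nrow(centroids)
  d2 <- matrix(0, n, k)
  for (j in seq_len(k)) {
    diff <- sweep(x, 2L, centroids[j, ], "-")
    d2[, j] <- rowSums(diff^2)
  }
  d2
}

lloyd_once <- function(x, init_centroids, max_iter, tol) {
  k <- nrow(init_centroids)
  centroids <- init_centroids
  iter_log <- numeric()
  assign_vec <- NULL
  for (it in seq_len(max_iter)) {
    d2 <- sq_dist_to_centroids(x, centroids)
    assign_vec <- max.col(-d2, ties.method = "first")  # ties -> lowest index
    # empty-cluster repair: farthest point from its centroid moves over
    repeat {
      counts <- tabulate(assign_vec, nbins = k)
      empty <- which(counts == 0L)
      if (length(empty) == 0L) break
      own_d2 <- d2[cbind(seq_len(nrow(x)), assign_vec)]
      donors <- which(counts[assign_vec] > 1L)
      far <- donors[which.max(own_d2[donors])]
      assign_vec[far] <- empty[1]
    }
    iter_log <- c(iter_log,
                  sum(d2[cbind(seq_len(nrow(x)), assign_vec)]))
    new_centroids <- centroids
    for (j in seq_len(k)) {
      new_centroids[j, ] <- colMeans(x[assign_vec == j, , drop = FALSE])
    }
    movement <- sqrt(max(rowSums((new_centroids - centroids)^2)))
    centroids <- new_centroids
    if (movement < tol) break
  }
  d2 <- sq_dist_to_centroids(x, centroids)
  assign_vec <- max.col(-d2, ties.method = "first")
  wcss <- sum(d2[cbind(seq_len(nrow(x)), assign_vec)])
  list(centroids = centroids, assignments = assign_vec, wcss = wcss,
       n_iter = it, iter_log = iter_log)
}

#' K-Means clustering by Lloyd's algorithm
#'
#' Random initialization from k distinct data points, assignment to the
#' nearest centroid (Euclidean; ties to the lowest cluster index), mean
#' update, until the maximum centroid displacement falls below `tol` or
#' `max_iter` is reached. The best of `n_restarts` runs by within-cluster
#' sum of squares (WCSS) is returned; clusters emptied during iteration
#' are repaired by donating the point farthest from its current centroid.
#' Fully deterministic given `seed`.
#'
#' @param values Numeric vector (1-D points) or matrix (rows = points).
#' @param k Number of clusters, at most the number of distinct points.
#' @param seed Integer seed for initialization.
#' @param n_restarts Independent random initializations (default 10).
#' @param max_iter Iteration cap per restart (default 300).
#' @param tol Convergence threshold on maximum centroid displacement.
#' @param init `"random"` (uniform choice of k distinct points) or
#'   `"kmeans++"` (distance-weighted seeding).
#' @param warm_starts Optional list of centroid matrices tried in
#'   addition to the random restarts.
#' @return An object of class `kmeans_model`: `k`, `centroids` (k x d
#'   matrix), `assignments` (1-based cluster index per point), `wcss`,
#'   `n_iter`, `iter_log` (WCSS after each assignment step of the
#'   winning run), `seed`.
#' @examples
#' m <- kmeans_lloyd(c(0, 1, 10, 11), k = 2, seed = 1)
#' m$wcss  # 1
#' @export
kmeans_lloyd <- function(values, k, seed, n_restarts = 10L, max_iter = 300L,
                         tol = 1e-6, init = c("random", "kmeans++"),
                         warm_starts = list()) {
  x <- as_point_matrix(values)
  init <- match.arg(init)
  if (nrow(x) == 0L) stop("empty input", call. = FALSE)
  if (max_iter < 1L) stop("`max_iter` must be >= 1", call. = FALSE)
  ux <- unique(x)
  if (k > nrow(ux)) {
    stop(sprintf("k = %d exceeds the number of distinct points (%d)",
                 k, nrow(ux)), call. = FALSE)
  }
  if (k < 1L) stop("k must be >= 1", call. = FALSE)

  best <- NULL
  with_local_seed(seed, {
    for (r in seq_len(n_restarts)) {
      init_c <- if (init == "random") {
        ux[sample.int(nrow(ux), k), , drop = FALSE]
      } else {
        kmeanspp_init(x, ux, k)
      }
      run <- lloyd_once(x, init_c, max_iter, tol)
      if (is.null(best) || run$wcss < best$wcss) best <- run
    }
  })
  for (w in warm_starts) {
    run <- lloyd_once(x, as_point_matrix(w), max_iter, tol)
    if (is.null(best) || run$wcss < best$wcss) best <- run
  }
  structure(
    list(k = as.integer(k), centroids = best$centroids,
         assignments = best$assignments, wcss = best$wcss,
         n_iter = best$n_iter, iter_log = best$iter_log,
         seed = as.integer(seed)),
    class = "kmeans_model"
  )
}

kmeanspp_init <- function(x, ux, k) {
  n <- nrow(ux)
  chosen <- sample.int(n, 1L)
  while (length(chosen) < k) {
    d2 <- sq_dist_to_centroids(ux, ux[chosen, , drop = FALSE])
    mind2 <- apply(d2, 1L, min)
    mind2[chosen] <- 0
    if (sum(mind2) == 0) {
      cand <- setdiff(seq_len(n), chosen)
      chosen <- c(chosen, cand[sample.int(length(cand), 1L)])
    } else {
      chosen <- c(chosen, sample.int(n, 1L, prob = mind2 / sum(mind2)))
    }
  }
  ux[chosen, , drop = FALSE]
}

#' @export
print.kmeans_model <- function(x, ...) {
  cat(sprintf("<kmeans_model> k=%d wcss=%.6g n_iter=%d seed=%d\n",
              x$k, x$wcss, x$n_iter, x$seed))
  invisible(x)
}

#' Exact 1-D k-means by dynamic programming
#'
#' Globally optimal 1-D k-means: sort, then dynamic programming over
#' contiguous segments (an optimal 1-D clustering is always a partition
#' of the sorted values into runs). Serves as the exact oracle that
#' bounds Lloyd's WCSS from below.
#'
#' @param values Numeric vector.
#' @param k Number of clusters, at most the number of distinct values.
#' @return List with `wcss` (optimal) and `assignments` (cluster index
#'   per input point, clusters numbered 1..k in ascending value order).
#' @examples
#' dp_kmeans_1d(c(0, 1, 10, 11), 2)$wcss  # 1
#' @export
dp_kmeans_1d <- function(values, k) {
  x <- as.numeric(values)
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  if (k > length(unique(x))) {
    stop(sprintf("k = %d exceeds the number of distinct values (%d)",
                 k, length(unique(x))), call. = FALSE)
  }
  ord <- order(x)
  xs <- x[ord]
  n <- length(xs)
  cs <- cumsum(xs)
  cs2 <- cumsum(xs^2)
  seg_cost <- function(i, j) {  # cost of xs[i..j]
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  D <- matrix(Inf, k, n)
  B <- matrix(0L, k, n)   # start index of last segment
  for (i in seq_len(n)) {
    D[1L, i] <- seg_cost(1L, i)
    B[1L, i] <- 1L
  }
  if (k > 1L) {
    for (j in 2:k) {
      for (i in j:n) {
        for (m in j:i) {
          cand <- D[j - 1L, m - 1L] + seg_cost(m, i)
          if (cand < D[j, i]) {
            D[j, i] <- cand
            B[j, i] <- m
          }
        }
      }
    }
  }
  # backtrack segment boundaries
  assign_sorted <- integer(n)
  i <- n
  for (j in k:1) {
    m <- B[j, i]
    assign_sorted[m:i] <- j
    i <- m - 1L
  }
  assignments <- integer(n)
  assignments[ord] <- assign_sorted
  list(wcss = max(D[k, n], 0), assignments = assignments)
}

#' WCSS-versus-k curve with warm starts
#'
#' Runs [kmeans_lloyd()] for each k in `k_min..k_max`. For k > k_min the
#' previous best centroids, augmented by the point farthest from its
#' assigned centroid, are supplied as an extra warm start, which makes
#' the curve exactly monotone non-increasing in k.
#'
#' @param values Numeric vector or matrix of points.
#' @param k_min,k_max Range of cluster counts (default 1 to 20).
#' @param seed Integer seed shared by every k.
#' @param n_restarts Random restarts per k.
#' @return A data.frame with columns `k` and `wcss`, with the fitted
#'   `kmeans_model` objects in attribute `models` (named by k).
#' @export
wcss_curve <- function(values, k_min = 1L, k_max = 20L, seed,
                       n_restarts = 10L) {
  x <- as_point_matrix(values)
  n_distinct <- nrow(unique(x))
  if (k_min < 1L || k_min > k_max) stop("need 1 <= k_min <= k_max",
                                        call. = FALSE)
  if (k_max > n_distinct) {
    stop(sprintf("k_max = %d exceeds the number of distinct points (%d)",
                 k_max, n_distinct), call. = FALSE)
  }
  ks <- k_min:k_max
  models <- vector("list", length(ks))
  prev <- NULL
  for (idx in seq_along(ks)) {
    k <- ks[idx]
    warm <- list()
    if (!is.null(prev)) {
      d2 <- sq_dist_to_centroids(x, prev$centroids)
      own <- d2[cbind(seq_len(nrow(x)), prev$assignments)]
      split_point <- x[which.max(own), , drop = FALSE]
      warm <- list(rbind(prev$centroids, split_point))
    }
    m <- kmeans_lloyd(x, k, seed = seed, n_restarts = n_restarts,
                      warm_starts = warm)
    models[[idx]] <- m
    prev <- m
  }
  out <- data.frame(k = ks, wcss = vapply(models, `[[`, numeric(1), "wcss"))
  names(models) <- as.character(ks)
  attr(out, "models") <- models
  out
}

#' Elbow selection of the cluster count
#'
#' Normalizes k and WCSS to `[0, 1]` and returns the interior k with the
#' maximum perpendicular distance to the chord joining the curve's
#' endpoints (the "knee"). Ties, and fully degenerate straight-line
#' curves, resolve to the smaller k.
#'
#' @param curve A data.frame with ascending `k` and `wcss` columns and
#'   at least 3 rows, e.g. from [wcss_curve()].
#' @return The selected k (integer).
#' @examples
#' select_k_elbow(data.frame(k = 1:5, wcss = c(100, 50, 10, 8, 6)))  # 3
#' @export
select_k_elbow <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("k", "wcss") %in% names(curve)))
  if (nrow(curve) < 3L) stop("elbow selection needs at least 3 curve points",
                             call. = FALSE)
  if (is.unsorted(curve$k, strictly = TRUE)) {
    stop("`curve$k` must be strictly ascending", call. = FALSE)
  }
  kr <- range(curve$k)
  wr <- range(curve$wcss)
  xn <- (curve$k - kr[1]) / (kr[2] - kr[1])
  yn <- if (diff(wr) > 0) (curve$wcss - wr[1]) / (wr[2] - wr[1]) else
    rep(0, nrow(curve))
  x1 <- xn[1]; y1 <- yn[1]
  x2 <- xn[length(xn)]; y2 <- yn[length(yn)]
  chord_len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  dist <- abs((y2 - y1) * xn - (x2 - x1) * yn + x2 * y1 - x1 * y2) /
    chord_len
  interior <- 2:(nrow(curve) - 1L)
  best <- interior[which.max(dist[interior])]  # which.max ties -> first
  as.integer(curve$k[best])
}

#' Mean silhouette score of a clustering
#'
#' Per point: `a` = mean distance to the other members of its own
#' cluster, `b` = smallest mean distance to the members of any other
#' cluster, `s = (b - a) / max(a, b)`. Points in singleton clusters
#' score 0. Returns the mean over points, in `[-1, 1]`. Above 10^5
#' points the score is estimated on a seeded subsample of 10^4 points
#' (exact below that).
#'
#' @param values Numeric vector or matrix of points.
#' @param assignments Integer cluster index per point (>= 2 non-empty
#'   clusters required).
#' @param seed Seed for the large-n subsample (default 1).
#' @return Mean silhouette in `[-1, 1]`.
#' @examples
#' silhouette_score(c(0, 0.02, 1, 1.02), c(1, 1, 2, 2))  # ~0.980
#' @export
silhouette_score <- function(values, assignments, seed = 1L) {
  x <- as_point_matrix(values)
  cl <- as.integer(assignments)
  stopifnot(nrow(x) == length(cl))
  if (length(unique(cl)) < 2L) {
    stop("silhouette requires at least 2 clusters", call. = FALSE)
  }
  if (nrow(x) > 1e5) {
    idx <- with_local_seed(seed, sample.int(nrow(x), 1e4))
    x <- x[idx, , drop = FALSE]
    cl <- cl[idx]
    if (length(unique(cl)) < 2L) {
      stop("subsample collapsed to a single cluster", call. = FALSE)
    }
  }
  n <- nrow(x)
  clusters <- sort(unique(cl))
  counts <- vapply(clusters, function(cc) sum(cl == cc), integer(1))
  # mean distance from every point to every cluster (n x n_clusters)
  M <- matrix(0, n, length(clusters))
  for (ci in seq_along(clusters)) {
    members <- x[cl == clusters[ci], , drop = FALSE]
    d2 <- sq_dist_to_centroids(x, members)  # n x m squared distances
    M[, ci] <- rowMeans(sqrt(d2))
  }
  s <- numeric(n)
  for (i in seq_len(n)) {
    ci <- match(cl[i], clusters)
    m <- counts[ci]
    if (m == 1L) { s[i] <- 0; next }
    a <- M[i, ci] * m / (m - 1L)   # exclude self (distance 0)
    b <- min(M[i, -ci])
    denom <- max(a, b)
    s[i] <- if (denom > 0) (b - a) / denom else 0
  }
  mean(s)
}

#' Per-cluster count and value range summaries
#'
#' Summarizes a 1-D clustering the way screening cluster tables are
#' reported: for every cluster its member count and the minimum and
#' maximum member value.
#'
#' @param model A `kmeans_model` fitted on `values`.
#' @param values The numeric vector the model was fitted on.
#' @return A data.frame (class `cluster_summary`) with columns
#'   `cluster`, `count`, `min`, `max`, sorted by cluster id; counts sum
#'   to `length(values)`.
#' @export
cluster_summaries <- function(model, values) {
  stopifnot(inherits(model, "kmeans_model"))
  x <- as.numeric(values)
  stopifnot(length(x) == length(model$assignments))
  ids <- sort(unique(model$assignments))
  out <- data.frame(
    cluster = ids,
    count = vapply(ids, function(j) sum(model$assignments == j), integer(1)),
    min = vapply(ids, function(j) min(x[model$assignments == j]), numeric(1)),
    max = vapply(ids, function(j) max(x[model$assignments == j]), numeric(1))
  )
  class(out) <- c("cluster_summary", "data.frame")
  out
}
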