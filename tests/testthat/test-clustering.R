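test_that("Lloyd k-means recovers exact partitions on worked examples", {
  m <- kmeans_lloyd(c(0, 1, 10, 11), k = 2, seed = 1)
  expect_equal(sort(m$centroids[, 1]), c(0.5, 10.5))
  expect_equal(m$wcss, 1.0)
  # every point sits with its nearest centroid
  d2 <- hybridvs:::sq_dist_to_centroids(matrix(c(0, 1, 10, 11)),
                                        m$centroids)
  expect_equal(m$assignments, max.col(-d2, ties.method = "first"))
  expect_equal(kmeans_lloyd(c(0, 1, 10, 11), k = 4, seed = 1)$wcss, 0)
  m1 <- kmeans_lloyd(c(0, 1, 10, 11), k = 1, seed = 1)
  expect_equal(m1$centroids[1, 1], 5.5)
  expect_equal(m1$wcss, sum((c(0, 1, 10, 11) - 5.5)^2))
  expect_error(kmeans_lloyd(c(1, 1, 1), k = 2, seed = 1), "distinct")
  expect_error(kmeans_lloyd(numeric(), k = 1, seed = 1), "empty")
})

test_that("models are bit-identical given the same seed and WCSS never rises", {
  set.seed(5); xs <- c(rnorm(30, 0), rnorm(30, 3))
  a <- kmeans_lloyd(xs, 3, seed = 9)
  b <- kmeans_lloyd(xs, 3, seed = 9)
  expect_identical(a, b)
  expect_true(all(diff(a$iter_log) <= 1e-12))
  c2 <- kmeans_lloyd(xs, 3, seed = 10)
  expect_s3_class(c2, "kmeans_model")  # different seed still valid
})

test_that("dynamic-programming oracle is optimal and matches closed forms", {
  expect_equal(dp_kmeans_1d(c(0, 1, 10, 11), 2)$wcss, 1.0)
  # k = 1: variance-sum closed form
  set.seed(3); xs <- runif(25)
  expect_equal(dp_kmeans_1d(xs, 1)$wcss, sum((xs - mean(xs))^2))
  # k = n distinct: zero
  expect_equal(dp_kmeans_1d(c(2, 4, 9), 3)$wcss, 0)
  # optimality bound vs Lloyd on random inputs
  for (t in 1:20) {
    set.seed(t); x <- runif(30); k <- sample(2:5, 1)
    lw <- kmeans_lloyd(x, k, seed = t, n_restarts = 5)$wcss
    expect_gte(lw, dp_kmeans_1d(x, k)$wcss - 1e-9)
  }
  # exhaustive-search cross-check on a tiny instance: all 2-partitions
  xs <- c(0.1, 0.4, 0.45, 0.9)
  best <- Inf
  for (mask in 1:(2^4 - 2)) {
    grp <- as.logical(bitwAnd(mask, 2^(0:3)))
    if (!any(grp) || all(grp)) next
    w <- sum((xs[grp] - mean(xs[grp]))^2) +
      sum((xs[!grp] - mean(xs[!grp]))^2)
    best <- min(best, w)
  }
  expect_equal(dp_kmeans_1d(xs, 2)$wcss, best)
})

test_that("warm-started WCSS curves are exactly monotone and hit known values", {
  cv <- wcss_curve(c(0, 1, 10, 11), 1, 4, seed = 3, n_restarts = 5)
  expect_equal(cv$wcss, c(101, 1.0, 0.5, 0), tolerance = 1e-9)
  expect_equal(cv$wcss[1], max(cv$wcss))  # k=1 tops the curve
  for (t in 1:10) {
    set.seed(t)
    xs <- c(rnorm(40, 0, 0.5), rnorm(40, 4, 0.5), runif(20, -2, 6))
    cv <- wcss_curve(xs, 1, 8, seed = t, n_restarts = 3)
    expect_true(all(diff(cv$wcss) <= 1e-12), label = paste("seed", t))
  }
})

test_that("the elbow rule picks the knee and honors the tie convention", {
  expect_equal(select_k_elbow(data.frame(k = 1:5,
                                         wcss = c(100, 50, 10, 8, 6))), 3L)
  # straight line: all interior distances 0, ties resolve to smallest k
  expect_equal(select_k_elbow(data.frame(k = 1:5,
                                         wcss = c(100, 75, 50, 25, 0))), 2L)
  # single sharp drop after k=2
  expect_equal(select_k_elbow(data.frame(k = 1:5,
                                         wcss = c(100, 5, 4, 3, 2))), 2L)
  expect_error(select_k_elbow(data.frame(k = 1:2, wcss = c(2, 1))),
               "3 curve points")
})

test_that("silhouette equals the hand-computed example and stays in range", {
  s <- silhouette_score(c(0, 0.02, 1.0, 1.02), c(1, 1, 2, 2))
  expect_equal(s, 0.980, tolerance = 1e-3)
  # interleaved identical points: b <= a forces non-positive score
  expect_lte(silhouette_score(c(0, 0, 1, 1), c(1, 2, 1, 2)), 0)
  expect_error(silhouette_score(1:4, rep(1, 4)), "2 clusters")
  set.seed(8)
  for (t in 1:10) {
    xs <- rnorm(50)
    cl <- sample(1:3, 50, replace = TRUE)
    if (length(unique(cl)) < 2) next
    s <- silhouette_score(xs, cl)
    expect_gte(s, -1); expect_lte(s, 1)
  }
})

test_that("cluster summaries partition the data with correct extremes", {
  m <- kmeans_lloyd(c(0, 1, 10, 11), 2, seed = 2)
  sm <- cluster_summaries(m, c(0, 1, 10, 11))
  expect_equal(sum(sm$count), 4L)
  expect_setequal(sm$count, c(2L, 2L))
  expect_setequal(sm$min, c(0, 10))
  expect_setequal(sm$max, c(1, 11))
  expect_true(all(sm$min <= sm$max))
  m1 <- kmeans_lloyd(c(3, 1, 2), 1, seed = 2)
  s1 <- cluster_summaries(m1, c(3, 1, 2))
  expect_equal(s1$count, 3L)
  expect_equal(s1$min, 1); expect_equal(s1$max, 3)
})

test_that("best-of-restarts Lloyd agrees with stats::kmeans as a cross-check", {
  for (t in 1:10) {
    set.seed(t)
    xs <- c(rnorm(30, 0, 0.3), rnorm(30, 2, 0.3))
    mine <- kmeans_lloyd(xs, 2, seed = t, n_restarts = 10)$wcss
    ref <- stats::kmeans(xs, 2, nstart = 10, iter.max = 100,
                         algorithm = "Lloyd")$tot.withinss
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("elbow and silhouette recover the component count of a 3-mixture", {
  set.seed(11)
  vals <- c(rnorm(300, 0.1, 0.02), rnorm(300, 0.5, 0.02),
            rnorm(300, 0.9, 0.02))
  cv <- wcss_curve(vals, 1, 10, seed = 11, n_restarts = 5)
  expect_equal(select_k_elbow(cv), 3L)
  models <- attr(cv, "models")
  s2 <- silhouette_score(vals, models[["2"]]$assignments)
  s3 <- silhouette_score(vals, models[["3"]]$assignments)
  s4 <- silhouette_score(vals, models[["4"]]$assignments)
  expect_gt(s3, s2)
  expect_gt(s3, s4)
})
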