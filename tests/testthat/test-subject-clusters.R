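mk_blobs <- function(n_per, centers, sd = 0.15, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    matrix(rnorm(n_per * ncol(centers), 0, sd), n_per) +
      matrix(centers[i, ], n_per, ncol(centers), byrow = TRUE)
  }))
  rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  X
}

test_that("k-means recovers well-separated groups exactly", {
  X <- mk_blobs(15, rbind(c(0, 0), c(6, 6)), sd = 0.5, seed = 2)
  truth <- rep(c("a", "b"), each = 15)
  cl <- kmeans_factor_space(X, n_clusters = 2, seed = 1)
  expect_equal(adjusted_rand_index(truth, cl$assignments$cluster), 1)
  # clusters are relabelled by size: C0 is never smaller than C1
  sizes <- table(cl$assignments$cluster)
  expect_true(all(diff(as.integer(sizes)) <= 0))
  # determinism under the seed
  cl2 <- kmeans_factor_space(X, n_clusters = 2, seed = 1)
  expect_identical(cl$assignments, cl2$assignments)
})

test_that("auto selection by variance ratio finds the planted cluster count", {
  X <- mk_blobs(12, rbind(c(0, 0), c(7, 0), c(0, 7)), sd = 0.4, seed = 3)
  cl <- kmeans_factor_space(X, n_clusters = "auto", seed = 1)
  expect_equal(cl$k, 3)
  expect_s3_class(cl$criterion, "data.frame")
})

test_that("degenerate clusterings are handled explicitly", {
  X <- mk_blobs(4, rbind(c(0, 0), c(5, 5)), sd = 0.2, seed = 4)
  # every point its own cluster: zero inertia
  cl <- kmeans_factor_space(X, n_clusters = nrow(X), seed = 1, minor_size = 0)
  expect_equal(cl$inertia, 0, tolerance = 1e-12)
  expect_equal(length(unique(cl$assignments$cluster)), nrow(X))
  # identical points cannot support more clusters than distinct values
  Xc <- matrix(1, 6, 2)
  expect_error(kmeans_factor_space(Xc, 3, seed = 1), "distinct")
  # minor flag marks clusters below the size threshold
  cl5 <- kmeans_factor_space(X, 2, seed = 1, minor_size = 5)
  expect_true(all(cl5$assignments$minor_flag))
})

test_that("representative subject is the member closest to the centroid", {
  X <- rbind(c(0, 0), c(1, 0), c(-1, 0), c(0.05, 0.02), c(9, 9))
  rownames(X) <- c("mid", "right", "left", "center", "far")
  cl <- kmeans_factor_space(X, 2, seed = 1, minor_size = 0)
  big <- names(sort(table(cl$assignments$cluster), decreasing = TRUE))[1]
  rep_id <- representative_subject(cl, X, big)
  expect_true(rep_id %in% c("mid", "center"))
  # singleton cluster returns its only member
  small <- setdiff(unique(cl$assignments$cluster), big)
  expect_equal(representative_subject(cl, X, small), "far")
  expect_error(representative_subject(cl, X, "C9"), "empty|unknown")
})

test_that("the decision tree is perfect on separable labels and chance on permuted ones", {
  set.seed(6)
  n <- 60
  feats <- data.frame(x = c(rnorm(n / 2, 0), rnorm(n / 2, 6)),
                      z = rnorm(n))
  labels <- rep(c("C0", "other"), each = n / 2)
  fit <- train_cluster_tree(feats, labels, seed = 1)
  expect_equal(fit$cv_accuracy, 1)
  expect_true("x" %in% fit$features_used)

  # permuted labels: accuracy near the majority-class rate over 20 seeds
  majority <- max(table(labels)) / n
  accs <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    train_cluster_tree(feats, sample(labels), seed = s,
                       screen_features = FALSE)$cv_accuracy
  }, 0)
  expect_lt(abs(mean(accs) - majority), 0.15)

  expect_error(train_cluster_tree(feats, rep("C0", n)), "2 classes")
  expect_error(train_cluster_tree(feats[1:4, ], c("a", "a", "a", "b")),
               "stratification")
})

test_that("fitted trees export to JSON and DOT", {
  set.seed(7)
  feats <- data.frame(x = c(rnorm(20), rnorm(20, 5)))
  fit <- train_cluster_tree(feats, rep(c("C0", "C5"), each = 20), seed = 1)
  j <- tempfile(fileext = ".json"); d <- tempfile(fileext = ".dot")
  write_cluster_tree(fit, j)
  write_cluster_tree(fit, d)
  parsed <- jsonlite::read_json(j)
  expect_equal(parsed$cv_accuracy, 1)
  expect_true(any(grepl("digraph", readLines(d))))
})

test_that("adjusted Rand index matches known values", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "a", "b", "b")), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("a", "b", "a", "b")), -0.5)
  set.seed(8)
  a <- sample(1:3, 3000, TRUE); b <- sample(1:3, 3000, TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.05)
})
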