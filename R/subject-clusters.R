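# Subject clustering in factor-score space: seeded multi-restart k-means with
# variance-ratio (Calinski-Harabasz) selection of the cluster count, minor
# cluster flagging, representative-subject lookup, and the decision-tree
# classifier with stratified cross-validation.

#' K-means clustering of subjects in factor-score space
#'
#' Runs k-means with `n_restarts` seeded initializations and keeps the best
#' inertia. With `n_clusters = "auto"` the cluster count maximizing the
#' Calinski-Harabasz variance-ratio criterion over 2..10 is chosen. Clusters
#' are relabelled `C0, C1, ...` by descending size; clusters smaller than
#' `minor_size` are flagged as minor (mirroring the exclusion of very small
#' subject clusters from cohort contrasts).
#'
#' @param scores subjects x k factor-score matrix (row names = subject ids).
#' @param n_clusters integer, or `"auto"`.
#' @param seed integer seed.
#' @param n_restarts k-means restarts.
#' @param minor_size clusters with fewer members are flagged (default 5).
#' @return object of class `subject_clusters`: `assignments` data frame
#'   (`subject_id`, `cluster`, `distance_to_centroid`, `minor_flag`),
#'   `centroids`, `inertia`, `criterion` table when auto-selected.
#' @export
kmeans_factor_space <- function(scores, n_clusters = "auto", seed = 1,
                                n_restarts = 20, minor_size = 5) {
  X <- as.matrix(scores)
  n <- nrow(X)
  auto <- identical(n_clusters, "auto")
  crit <- NULL
  if (auto) {
    ks <- 2:min(10, n - 1)
    ch <- vapply(ks, function(k) {
      km <- seeded_kmeans(X, k, seed, n_restarts)
      calinski_harabasz(X, km)
    }, 0)
    crit <- data.frame(k = ks, calinski_harabasz = ch)
    n_clusters <- ks[which.max(ch)]
  }
  k <- as.integer(n_clusters)
  stop_if(n < k, "fewer subjects than clusters")
  stop_if(nrow(unique(X)) < k, "fewer distinct score points than clusters")
  km <- seeded_kmeans(X, k, seed, n_restarts)
  # relabel by descending size; ties by original index for determinism
  ord <- order(-tabulate(km$cluster, k), seq_len(k))
  relab <- match(seq_len(k), ord)
  cl <- relab[km$cluster]
  centroids <- km$centers[ord, , drop = FALSE]
  rownames(centroids) <- paste0("C", seq_len(k) - 1L)
  d <- sqrt(rowSums((X - centroids[cl, , drop = FALSE])^2))
  sizes <- tabulate(cl, k)
  assignments <- data.frame(
    subject_id = rownames(X) %||% as.character(seq_len(n)),
    cluster = paste0("C", cl - 1L),
    distance_to_centroid = d,
    minor_flag = sizes[cl] < minor_size,
    stringsAsFactors = FALSE)
  structure(list(assignments = assignments, centroids = centroids,
                 inertia = km$tot.withinss, k = k, criterion = crit,
                 auto = auto, minor_size = minor_size),
            class = "subject_clusters")
}

seeded_kmeans <- function(X, k, seed, n_restarts) {
  set.seed(child_seed(seed, k))
  if (k == nrow(X)) {
    # every point its own cluster: exact zero-inertia solution
    return(list(cluster = seq_len(k), centers = X, tot.withinss = 0,
                betweenss = sum(scale(X, scale = FALSE)^2)))
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    km <- tryCatch(stats::kmeans(X, centers = k, iter.max = 100),
                   error = function(e)
                     tryCatch(stats::kmeans(X, centers = k, iter.max = 100,
                                            algorithm = "Lloyd"),
                              error = function(e2) NULL))
    if (is.null(km)) next
    if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
  }
  stop_if(is.null(best), "k-means failed for k = %d (degenerate data?)", k)
  best
}

calinski_harabasz <- function(X, km) {
  n <- nrow(X); k <- nrow(km$centers)
  if (km$tot.withinss <= .Machine$double.eps) return(Inf)
  (km$betweenss / (k - 1)) / (km$tot.withinss / (n - k))
}

#' @export
print.subject_clusters <- function(x, ...) {
  tab <- table(x$assignments$cluster)
  cat(sprintf("subject_clusters: k = %d%s, inertia %.3f\n", x$k,
              if (x$auto) " (auto, Calinski-Harabasz)" else "", x$inertia))
  cat("  sizes:", paste(sprintf("%s:%d", names(tab), tab), collapse = " "), "\n")
  if (any(x$assignments$minor_flag))
    cat("  minor clusters (<", x$minor_size, "members):",
        paste(unique(x$assignments$cluster[x$assignments$minor_flag]), collapse = " "), "\n")
  invisible(x)
}

#' Representative subject of a cluster
#'
#' The member minimizing the Euclidean distance to the cluster centroid in
#' factor-score space; ties break lexicographically on subject id.
#'
#' @param clusters a [kmeans_factor_space] result.
#' @param scores the score matrix used for clustering.
#' @param cluster_id cluster label (e.g. `"C0"`).
#' @return subject id.
#' @export
representative_subject <- function(clusters, scores, cluster_id) {
  stopifnot(inherits(clusters, "subject_clusters"))
  a <- clusters$assignments
  sel <- a$cluster == cluster_id
  stop_if(!any(sel), "cluster '%s' is empty or unknown", cluster_id)
  X <- as.matrix(scores)[sel, , drop = FALSE]
  ctr <- clusters$centroids[cluster_id, ]
  d <- sqrt(rowSums(sweep(X, 2, ctr)^2))
  ids <- a$subject_id[sel]
  ids[order(d, ids)][1]
}

#' Decision-tree classifier for cluster membership
#'
#' CART (Gini impurity, `rpart`) predicting a grouped cluster label from
#' clinical and imaging variables, with mean stratified k-fold
#' cross-validation accuracy. When `screen_features = TRUE` (default),
#' candidate features are first restricted to variables with a significant
#' Welch-ANOVA difference across the label groups.
#'
#' @param features data frame of candidate predictor columns.
#' @param labels factor/character vector of class labels (e.g. `C0`, `C5`,
#'   `other`), length `nrow(features)`.
#' @param max_depth tree depth (default 3).
#' @param n_folds stratified folds (default 3).
#' @param seed integer seed for fold assignment.
#' @param screen_features Welch-ANOVA screening at `alpha`.
#' @param alpha screening significance level.
#' @return object of class `cluster_tree`: fitted `rpart` tree, `cv_accuracy`,
#'   `features_used`, `folds`.
#' @export
train_cluster_tree <- function(features, labels, max_depth = 3, n_folds = 3,
                               seed = 1, screen_features = TRUE, alpha = 0.05) {
  y <- factor(labels)
  stop_if(nlevels(y) < 2, "need at least 2 classes")
  stop_if(any(table(y) < n_folds),
          "each class needs at least %d members for %d-fold stratification",
          n_folds, n_folds)
  features <- as.data.frame(features)
  keep <- names(features)
  if (screen_features) {
    keep <- names(features)[vapply(names(features), function(v) {
      x <- features[[v]]
      if (!is.numeric(x)) return(TRUE)
      sp <- split(x[is.finite(x)], y[is.finite(x)])
      if (any(lengths(sp) < 2)) return(FALSE)
      p <- tryCatch(welch_anova(sp)$p, error = function(e) NA_real_)
      is.finite(p) && p < alpha
    }, TRUE)]
    stop_if(!length(keep), "no feature passes the Welch-ANOVA screen")
  }
  dat <- cbind(.class = y, features[, keep, drop = FALSE])
  ctrl <- rpart::rpart.control(maxdepth = max_depth, cp = 0, minsplit = 5,
                               xval = 0)
  # stratified fold assignment
  set.seed(as.integer(seed))
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  acc <- vapply(seq_len(n_folds), function(f) {
    fit <- rpart::rpart(.class ~ ., data = dat[fold != f, , drop = FALSE],
                        method = "class", parms = list(split = "gini"),
                        control = ctrl)
    pred <- predict(fit, dat[fold == f, , drop = FALSE], type = "class")
    mean(pred == y[fold == f])
  }, 0)
  fit <- rpart::rpart(.class ~ ., data = dat, method = "class",
                      parms = list(split = "gini"), control = ctrl)
  structure(list(tree = fit, cv_accuracy = mean(acc), fold_accuracy = acc,
                 features_used = keep, folds = fold),
            class = "cluster_tree")
}

#' @export
print.cluster_tree <- function(x, ...) {
  cat(sprintf("cluster_tree: %d-fold stratified CV accuracy %.3f (features: %s)\n",
              length(x$fold_accuracy), x$cv_accuracy,
              paste(x$features_used, collapse = ", ")))
  print(x$tree)
  invisible(x)
}

#' Export a fitted cluster tree as JSON or Graphviz DOT
#'
#' @param model a [train_cluster_tree] result.
#' @param path output path ending in `.json` or `.dot`.
#' @export
write_cluster_tree <- function(model, path) {
  stopifnot(inherits(model, "cluster_tree"))
  fr <- model$tree$frame
  splits <- labels(model$tree)
  nodes <- lapply(seq_len(nrow(fr)), function(i) {
    list(node = as.integer(rownames(fr)[i]), rule = splits[i],
         variable = as.character(fr$var[i]), n = fr$n[i],
         class = attr(model$tree, "ylevels")[fr$yval[i]],
         is_leaf = fr$var[i] == "<leaf>")
  })
  if (grepl("\\.dot$", path)) {
    lines <- c("digraph cluster_tree {", "  node [shape=box];")
    ids <- as.integer(rownames(fr))
    for (nd in nodes) {
      lines <- c(lines, sprintf('  n%d [label="%s\\n%s (n=%d)"];',
                                nd$node, nd$rule, nd$class, nd$n))
      parent <- nd$node %/% 2L
      if (parent >= 1 && parent %in% ids)
        lines <- c(lines, sprintf("  n%d -> n%d;", parent, nd$node))
    }
    writeLines(c(lines, "}"), path)
  } else {
    jsonlite::write_json(list(cv_accuracy = model$cv_accuracy, nodes = nodes),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 = identical partitions, ~0 = independent.
#'
#' @param a,b label vectors of equal length.
#' @export
adjusted_rand_index <- function(a, b) {
  stop_if(length(a) != length(b), "label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(as.numeric(sum_ij == maxi))
  (sum_ij - expected) / (maxi - expected)
}
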