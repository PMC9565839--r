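test_that("feature_construct implements the arg-max gating rule", {
  e <- array(0, c(2, 2, 2, 3))
  e[, , , 1] <- 0.1 / 8; e[, , , 2] <- 5 / 8; e[, , , 3] <- 0.2 / 8
  fc <- feature_construct(e)
  expect_equal(fc$cluster_id, 1L)
  expect_true(all(fc$constructed[, , , c(1, 3)] == 0))
  expect_equal(fc$constructed[, , , 2], e[, , , 2])

  # exact tie: lowest index wins
  tie <- matrix(c(1, 1), 1, 2)
  expect_equal(feature_construct(tie)$cluster_id, 0L)

  # degenerate C = 1: identity pass-through
  one <- array(runif(8), c(2, 2, 2, 1))
  fc1 <- feature_construct(one)
  expect_equal(fc1$cluster_id, 0L)
  expect_equal(fc1$constructed, one)

  # all-zero embedding: cluster 0, flagged
  z <- feature_construct(matrix(0, 4, 3))
  expect_equal(z$cluster_id, 0L)
  expect_true(z$flagged)
  expect_equal(z$activation_strength, 0)

  expect_error(feature_construct(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("training separates the four planted texture classes", {
  fx <- mk_fixture_set(50, edge = 12, seed = 1)
  model <- train_caefc(fx$patches, C = 4, epochs = 20, seed = 1)
  asg <- assign_patches(model, fx$patches)
  expect_gte(purity(fx$labels, asg$cluster_id), 0.8)
  # ARI significantly above the label-permutation null
  ari <- adjusted_rand_index(fx$labels, asg$cluster_id)
  expect_gt(ari, 0)
  set.seed(99)
  null_ari <- replicate(200, adjusted_rand_index(sample(fx$labels),
                                                 asg$cluster_id))
  expect_lt(mean(null_ari >= ari), 0.01)
  # training reduced the loss on learnable data
  tl <- model$training_log
  expect_lt(tl$loss[nrow(tl)], tl$loss[1])
})

test_that("training and assignment are deterministic under the seed", {
  fx <- mk_fixture_set(10, edge = 12, seed = 3)
  m1 <- train_caefc(fx$patches, C = 2, epochs = 2, seed = 5)
  m2 <- train_caefc(fx$patches, C = 2, epochs = 2, seed = 5)
  expect_identical(m1$weights, m2$weights)
  a1 <- assign_patches(m1, fx$patches)
  # duplicate patch -> identical cluster
  dup <- c(fx$patches, fx$patches[1])
  a2 <- assign_patches(m1, dup)
  expect_equal(a2$cluster_id[length(dup)], a1$cluster_id[1])
  # empty patch list -> empty assignment
  expect_equal(nrow(assign_patches(m1, list())), 0)
  # shape mismatch rejected
  bad <- mk_class_patches(1, 8, 0.1, 0.5, 1)
  expect_error(assign_patches(m1, bad), "does not match")
})

test_that("single-channel reconstruction never beats the full embedding", {
  fx <- mk_fixture_set(25, edge = 12, seed = 2)
  model <- train_caefc(fx$patches, C = 4, epochs = 10, seed = 2)
  rc <- caefc_reconstruction_loss(model, fx$patches, constructed = TRUE)
  rf <- caefc_reconstruction_loss(model, fx$patches, constructed = FALSE)
  expect_gte(rc, rf * (1 - 0.05))  # small numerical slack
})

test_that("cluster-count selection prefers sufficient capacity", {
  fx <- mk_fixture_set(25, edge = 12, seed = 4)
  sel <- select_cluster_count(fx$patches, c(2, 4), epochs = 8, seed = 4)
  tab <- attr(sel, "loss_table")
  expect_lte(tab$final_loss[tab$C == 4], tab$final_loss[tab$C == 2])
  # degenerate single candidate is returned untouched
  expect_equal(select_cluster_count(fx$patches, 80), 80)
})

test_that("downstream metrics are invariant to cluster relabelling", {
  fx <- mk_fixture_set(25, edge = 12, seed = 6)
  model <- train_caefc(fx$patches, C = 4, epochs = 8, seed = 6)
  asg <- assign_patches(model, fx$patches)
  H1 <- histogram_matrix(asg, 4)
  perm <- c(2L, 3L, 0L, 1L)
  asg2 <- asg; asg2$cluster_id <- perm[asg$cluster_id + 1L]
  H2 <- histogram_matrix(asg2, 4)
  expect_equal(H1, H2[, perm + 1L, drop = FALSE], ignore_attr = TRUE)
  expect_equal(adjusted_rand_index(fx$labels, asg$cluster_id),
               adjusted_rand_index(fx$labels, asg2$cluster_id))
})
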