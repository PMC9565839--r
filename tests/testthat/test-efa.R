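# planted factor structure for recovery tests: simple-structure loadings,
# standard-normal scores, uniqueness noise
mk_factor_data <- function(n = 200, p = 12, k = 2, loading = 0.8,
                           noise_scale = 1, seed = 1) {
  set.seed(seed)
  L <- matrix(0, p, k)
  for (j in seq_len(k)) L[((j - 1) * p / k + 1):(j * p / k), j] <- loading
  S <- matrix(rnorm(n * k), n, k)
  E <- matrix(rnorm(n * p), n, p) %*% diag(sqrt(pmax(1 - rowSums(L^2), 0.05)) *
                                             noise_scale)
  X <- S %*% t(L) + E
  colnames(X) <- paste0("v", seq_len(p))
  list(X = X, L = L, S = S)
}

tucker_congruence <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

best_congruence <- function(Lhat, Ltrue) {
  # per planted factor, the best |congruence| over recovered factors
  vapply(seq_len(ncol(Ltrue)), function(j) {
    max(abs(apply(Lhat, 2, tucker_congruence, b = Ltrue[, j])))
  }, 0)
}

test_that("a noiseless rank-1 table is explained by a single factor", {
  set.seed(1)
  f <- rnorm(60)
  lambda <- runif(6, 0.5, 1)
  X <- outer(f, lambda)
  colnames(X) <- paste0("v", 1:6)
  m <- fit_efa(X, n_factors = 1)
  expect_gt(sum(m$communalities) / ncol(X), 0.99)
  expect_gt(min(abs(m$loadings)), 0.99)
})

test_that("planted two-factor loadings are recovered with high congruence", {
  d <- mk_factor_data(n = 200, seed = 7)
  m <- fit_efa(d$X, n_factors = 2)
  expect_true(all(best_congruence(m$loadings, d$L) >= 0.95))
})

test_that("varimax preserves communalities and the reconstruction fit", {
  d <- mk_factor_data(n = 150, seed = 3)
  m <- fit_efa(d$X, n_factors = 2, rotation = "varimax")
  h_rot <- rowSums(m$loadings^2)
  h_unrot <- rowSums(m$unrotated^2)
  expect_lt(max(abs(h_rot - h_unrot)), 1e-8)
  frob <- function(L) {
    M <- L %*% t(L); diag(M) <- diag(M) + (1 - rowSums(L^2))
    sqrt(sum((M - m$R)^2))
  }
  expect_lt(abs(frob(m$loadings) - frob(m$unrotated)), 1e-8)
})

test_that("regression scores are centred and track the planted factors", {
  d <- mk_factor_data(n = 150, seed = 5)
  m <- fit_efa(d$X, n_factors = 2)
  expect_lt(max(abs(colMeans(m$scores))), 1e-6)
  # a subject loaded purely on one planted factor scores highest there
  who <- which.max(abs(d$S[, 1]) - abs(d$S[, 2]))
  j1 <- which.max(best_congruence_col <- abs(apply(m$loadings, 2,
                                                   tucker_congruence, b = d$L[, 1])))
  expect_gt(abs(m$scores[who, j1]), max(abs(m$scores[who, -j1])))
  # duplicated subject rows give identical scores
  s2 <- score_subjects(m, d$X[c(1, 1), , drop = FALSE])
  expect_equal(s2[1, ], s2[2, ])
  expect_error(score_subjects(m, d$X[, 1:5]), "columns")
})

test_that("factor associations and bipolarity follow the loading threshold", {
  m <- structure(list(loadings = cbind(F0 = c(0.8, -0.5, 0.1))), class = "factor_model")
  rownames(m$loadings) <- paste0("pc", 0:2)
  a <- factor_associations(m, threshold = 0.4)
  expect_equal(a$F0$positive, "pc0")
  expect_equal(a$F0$negative, "pc1")
  expect_true(a$F0$bipolar)

  m$loadings[] <- c(0.1, -0.2, 0.3)
  a2 <- factor_associations(m, threshold = 0.4)
  expect_true(a2$F0$empty)
  expect_false(a2$F0$bipolar)
})

test_that("a planted bipolar factor is detected", {
  set.seed(11)
  n <- 200
  f <- rnorm(n)
  X <- cbind(outer(f, c(0.8, 0.7)), outer(-f, c(0.8, 0.7))) +
    matrix(rnorm(n * 4, 0, 0.4), n, 4)
  colnames(X) <- paste0("v", 1:4)
  m <- fit_efa(X, n_factors = 1)
  a <- factor_associations(m, 0.4)
  expect_true(a$F0$bipolar)
  expect_length(a$F0$positive, 2)
  expect_length(a$F0$negative, 2)
})

test_that("parallel analysis recovers the planted factor count reliably", {
  hits <- vapply(1:50, function(r) {
    d <- mk_factor_data(n = 120, p = 12, k = 2, noise_scale = 0.5, seed = 100 + r)
    parallel_analysis(d$X, n_sim = 30, seed = r) == 2
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("factor-variable correlations use the right test and mask by p", {
  set.seed(21)
  n <- 400
  s <- matrix(rnorm(n), ncol = 1); colnames(s) <- "F0"
  vars <- data.frame(lin = 2 * s[, 1],
                     noise = rnorm(n),
                     bin = as.integer(s[, 1] > 0),
                     const = 1)
  ct <- factor_variable_correlations(s, vars, binary = "bin")
  expect_equal(ct$r[ct$variable == "lin"], 1, tolerance = 1e-12)
  expect_equal(ct$type[ct$variable == "bin"], "point_biserial")
  expect_true(is.na(ct$r[ct$variable == "const"]))
  expect_match(ct$mask_reason[ct$variable == "const"], "constant")
  # a binary variable against its own indicator: point-biserial 1
  ct2 <- factor_variable_correlations(matrix(vars$bin, ncol = 1),
                                      data.frame(bin = vars$bin), binary = "bin")
  expect_equal(ct2$r[1], 1, tolerance = 1e-12)
})

test_that("under independence the mask removes about 95% of entries", {
  set.seed(31)
  hits <- replicate(300, {
    s <- matrix(rnorm(60), ncol = 1)
    v <- data.frame(x = rnorm(60))
    ct <- factor_variable_correlations(s, v)
    is.na(ct$r_masked)
  })
  expect_gt(mean(hits), 0.91)
  expect_lt(mean(hits), 0.985)
})

test_that("zero-variance histogram columns are dropped with a message", {
  d <- mk_factor_data(n = 60, seed = 9)
  X <- cbind(d$X, dead = 0.25)
  expect_message(m <- fit_efa(X, n_factors = 2), "dead")
  expect_false("dead" %in% rownames(m$loadings))
  expect_error(fit_efa(d$X, n_factors = 12), "smaller")
})
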