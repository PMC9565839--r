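# Exploratory factor analysis of the subjects x clusters frequency matrix:
# principal-axis factoring with iterated communalities, varimax (default) or
# promax rotation, Thomson regression scores, salient-loading factor
# associations, and the factor/variable correlation battery.

#' Fit an exploratory factor model
#'
#' Columns are standardized (zero-variance columns dropped with a message);
#' factors are extracted by principal-axis factoring with iterated
#' communalities (initialized at squared multiple correlations), then
#' rotated. `n_factors = "auto"` chooses k by Horn-style parallel analysis
#' (eigenvalues of the observed correlation matrix against the 95th
#' percentile of seeded random-normal data of the same size).
#'
#' @param histograms numeric subjects x C matrix (rows: subjects).
#' @param n_factors integer k, or `"auto"`.
#' @param rotation `"varimax"` (orthogonal, default) or `"promax"` or
#'   `"none"`.
#' @param seed integer seed (parallel analysis only).
#' @param tol,max_iter communality-iteration convergence control.
#' @return object of class `factor_model`: `loadings` (C x k),
#'   `communalities`, `uniquenesses`, `scores` (fitting-sample regression
#'   scores, columns `F0..F(k-1)`), `rotation`, `n_factors`, `converged`,
#'   `dropped` (zero-variance columns), plus the standardization `center` /
#'   `scale` and the correlation matrix.
#' @export
fit_efa <- function(histograms, n_factors = "auto", rotation = c("varimax", "promax", "none"),
                    seed = 1, tol = 1e-4, max_iter = 200) {
  rotation <- match.arg(rotation)
  X <- as.matrix(histograms)
  stop_if(nrow(X) < 3, "need at least 3 subjects")
  sds <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[sds == 0] %||% character(0)
  if (length(dropped)) {
    message("dropping zero-variance columns: ", paste(dropped, collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
  }
  p <- ncol(X)
  if (identical(n_factors, "auto")) {
    n_factors <- parallel_analysis(X, seed = seed)
  }
  k <- as.integer(n_factors)
  stop_if(k < 1, "n_factors must be >= 1")
  stop_if(k >= p, "n_factors must be smaller than the number of usable columns")
  stop_if(nrow(X) <= k, "need more subjects than factors")

  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  Z <- scale(X, center = ctr, scale = scl)
  R <- stats::cor(X)

  paf <- paf_extract(R, k, tol = tol, max_iter = max_iter)
  L <- paf$loadings
  rotmat <- diag(k)
  if (rotation == "varimax" && k > 1) {
    vm <- stats::varimax(L, normalize = TRUE)
    L <- unclass(vm$loadings); rotmat <- vm$rotmat
  } else if (rotation == "promax" && k > 1) {
    pm <- stats::promax(L)
    L <- unclass(pm$loadings); rotmat <- pm$rotmat
  }
  # orient each factor so its largest-magnitude loading is positive
  flip <- vapply(seq_len(k), function(j) sign(L[which.max(abs(L[, j])), j]), 0)
  flip[flip == 0] <- 1
  L <- sweep(L, 2, flip, `*`)
  colnames(L) <- paste0("F", seq_len(k) - 1L)
  rownames(L) <- colnames(X)
  h2 <- rowSums(L^2)
  model <- structure(list(loadings = L, communalities = h2,
                          uniquenesses = pmax(1 - h2, 0), rotation = rotation,
                          n_factors = k, converged = paf$converged,
                          iterations = paf$iterations, trace = paf$trace,
                          unrotated = paf$loadings, R = R,
                          center = ctr, scale = scl, columns = colnames(X),
                          dropped = dropped),
                     class = "factor_model")
  model$scores <- score_subjects(model, histograms)
  model
}

# tolerance-based symmetric pseudo-inverse solve: histogram columns sum to 1,
# so the correlation matrix of a compositional table is rank-deficient by one
psolve <- function(R, B, tol = 1e-10) {
  e <- eigen(R, symmetric = TRUE)
  keep <- e$values > tol * max(e$values)
  e$vectors[, keep, drop = FALSE] %*%
    ((crossprod(e$vectors[, keep, drop = FALSE], B)) / e$values[keep])
}

# principal-axis factoring with iterated communalities on a correlation matrix
paf_extract <- function(R, k, tol = 1e-4, max_iter = 200) {
  p <- ncol(R)
  smc <- tryCatch(1 - 1 / diag(psolve(R, diag(p))), error = function(e) rep(0.5, p))
  h2 <- pmin(pmax(smc, 0.05), 0.995)
  trace <- numeric(0)
  converged <- FALSE
  L <- NULL
  for (it in seq_len(max_iter)) {
    Rr <- R
    diag(Rr) <- h2
    e <- eigen(Rr, symmetric = TRUE)
    lam <- pmax(e$values[seq_len(k)], 0)
    L <- e$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(lam), k)
    h2_new <- pmin(rowSums(L^2), 0.995)
    delta <- max(abs(h2_new - h2))
    trace <- c(trace, delta)
    h2 <- h2_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("communality iteration did not converge in %d iterations (last delta %.2g)",
                    max_iter, trace[length(trace)]))
  list(loadings = L, communalities = h2, converged = converged,
       iterations = length(trace), trace = trace)
}

#' Horn-style parallel analysis
#'
#' Number of eigenvalues of the observed correlation matrix exceeding the
#' 95th percentile of eigenvalues from seeded random normal data of the same
#' dimensions.
#'
#' @param X data matrix.
#' @param n_sim random datasets.
#' @param quantile percentile of the random eigenvalue distribution.
#' @param seed integer seed.
#' @export
parallel_analysis <- function(X, n_sim = 50, quantile = 0.95, seed = 1) {
  set.seed(as.integer(seed))
  n <- nrow(X); p <- ncol(X)
  obs <- eigen(stats::cor(X), symmetric = TRUE, only.values = TRUE)$values
  sims <- replicate(n_sim, {
    eigen(stats::cor(matrix(stats::rnorm(n * p), n, p)), symmetric = TRUE,
          only.values = TRUE)$values
  })
  thresh <- apply(sims, 1, stats::quantile, probs = quantile)
  max(1L, sum(obs > thresh & obs > 0))
}

#' @export
print.factor_model <- function(x, ...) {
  cat(sprintf("factor_model: %d factors on %d pattern clusters (%s rotation)%s\n",
              x$n_factors, nrow(x$loadings), x$rotation,
              if (x$converged) "" else " [NOT converged]"))
  varex <- colSums(x$loadings^2) / nrow(x$loadings)
  cat("  variance explained per factor:",
      paste(sprintf("%s %.1f%%", colnames(x$loadings), 100 * varex), collapse = ", "),
      "\n")
  invisible(x)
}

#' Thomson regression factor scores
#'
#' \eqn{S = Z R^{-1} \Lambda}: standardized data times the inverse
#' correlation matrix times the loadings. Over the fitting sample each score
#' has mean 0.
#'
#' @param model a [fit_efa] model.
#' @param histograms subjects x C matrix on the model's columns.
#' @return subjects x k score matrix.
#' @export
score_subjects <- function(model, histograms) {
  stopifnot(inherits(model, "factor_model"))
  X <- as.matrix(histograms)
  stop_if(!all(model$columns %in% (colnames(X) %||% model$columns)),
          "histogram columns do not match the fitted model")
  if (!is.null(colnames(X))) X <- X[, model$columns, drop = FALSE]
  Z <- scale(X, center = model$center, scale = model$scale)
  S <- Z %*% psolve(model$R, model$loadings)
  colnames(S) <- colnames(model$loadings)
  rownames(S) <- rownames(X)
  S
}

#' Salient pattern clusters and polarity of each factor
#'
#' Positive set: clusters with loading >= threshold; negative set: loading <=
#' -threshold. A factor is bi-polar when both sets are nonempty (it measures
#' one latent trait in two opposite directions).
#'
#' @param model a [fit_efa] model.
#' @param threshold salient-loading magnitude (default 0.4, the conventional
#'   cutoff).
#' @return list per factor: `positive`, `negative` (cluster names),
#'   `bipolar`, `empty` (no salient cluster at all).
#' @export
factor_associations <- function(model, threshold = 0.4) {
  stopifnot(inherits(model, "factor_model"))
  L <- model$loadings
  lapply(stats::setNames(seq_len(ncol(L)), colnames(L)), function(j) {
    pos <- rownames(L)[L[, j] >= threshold]
    neg <- rownames(L)[L[, j] <= -threshold]
    list(positive = pos, negative = neg,
         bipolar = length(pos) > 0 && length(neg) > 0,
         empty = length(pos) + length(neg) == 0)
  })
}

#' Correlations of factor scores with clinical/imaging variables
#'
#' Pearson correlation for continuous variables, point-biserial (Pearson on
#' the 0/1 indicator) for binary ones, on complete cases per variable. The
#' full table is returned; entries with p >= `alpha` (or undefined for
#' constant variables) are masked to NA in the `r_masked` column.
#'
#' @param scores subjects x k factor-score matrix.
#' @param variables data frame of subject variables (rows aligned to scores).
#' @param binary character vector naming the binary columns.
#' @param alpha significance mask level (default 0.05).
#' @return data frame: `factor`, `variable`, `type`, `r`, `p`, `n`,
#'   `r_masked`, `mask_reason`.
#' @export
factor_variable_correlations <- function(scores, variables, binary = character(0),
                                         alpha = 0.05) {
  scores <- as.matrix(scores)
  stop_if(nrow(scores) != nrow(variables), "scores and variables differ in rows")
  if (is.null(colnames(scores)))
    colnames(scores) <- paste0("F", seq_len(ncol(scores)) - 1L)
  rows <- list()
  for (f in colnames(scores)) {
    fs <- scores[, f]
    for (v in names(variables)) {
      x <- variables[[v]]
      if (!is.numeric(x)) x <- as.numeric(as.factor(x)) - 1
      ok <- is.finite(fs) & is.finite(x)
      n <- sum(ok)
      type <- if (v %in% binary) "point_biserial" else "pearson"
      if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(fs[ok]) == 0) {
        rows[[length(rows) + 1L]] <- data.frame(
          factor = f, variable = v, type = type, r = NA_real_, p = NA_real_,
          n = n, r_masked = NA_real_,
          mask_reason = if (n < 3) "too few complete cases" else "constant variable",
          stringsAsFactors = FALSE)
        next
      }
      ht <- stats::cor.test(fs[ok], x[ok])
      masked <- ht$p.value >= alpha
      rows[[length(rows) + 1L]] <- data.frame(
        factor = f, variable = v, type = type, r = unname(ht$estimate),
        p = ht$p.value, n = n,
        r_masked = if (masked) NA_real_ else unname(ht$estimate),
        mask_reason = if (masked) sprintf("p >= %g", alpha) else "",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
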