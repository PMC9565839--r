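#' @keywords internal
"_PACKAGE"

# shared argument checks -------------------------------------------------

stop_if <- function(cond, msg, ...) {
  if (cond) stop(sprintf(msg, ...), call. = FALSE)
}

check_spacing <- function(spacing) {
  stop_if(!is.numeric(spacing) || length(spacing) != 3L || any(!is.finite(spacing)) ||
            any(spacing <= 0), "spacing must be 3 positive finite numbers (mm)")
  as.numeric(spacing)
}

is_volume <- function(x) is.array(x) && length(dim(x)) == 3L

# Separable Gaussian smoothing of a 3D array, sigma in voxels per axis.
# Each axis pass is a banded matrix product; kernel truncated at 3 sigma and
# renormalized at the borders (replicate-free, mass-preserving).
gaussian_smooth3 <- function(x, sigma) {
  stopifnot(is_volume(x))
  sigma <- rep_len(sigma, 3L)
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    n <- dim(x)[ax]
    r <- max(1L, ceiling(3 * s))
    k <- dnorm(seq(-r, r), sd = s)
    # band matrix with border renormalization
    A <- matrix(0, n, n)
    for (d in seq(-r, r)) {
      i <- seq_len(n)
      j <- i + d
      ok <- j >= 1L & j <= n
      A[cbind(i[ok], j[ok])] <- k[d + r + 1L]
    }
    A <- A / rowSums(A)
    x <- apply_along_axis(x, ax, A)
  }
  x
}

# multiply each 1D fiber of `x` along axis `ax` by matrix A (n_ax x n_ax)
apply_along_axis <- function(x, ax, A) {
  d <- dim(x)
  perm <- c(ax, setdiff(1:3, ax))
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[ax])
  m <- A %*% m
  xp <- array(m, dim = d[perm])
  aperm(xp, order(perm))
}

# deterministic child seed derived from a parent seed and a stage offset;
# kept below 2^31 so it is always a valid R integer seed
child_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000003 + offset) %% 2147483629)
}
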