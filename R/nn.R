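# Minimal 3D convolution engine for the patch autoencoder.
#
# Volumes are kept as matrices (flattened spatial voxels x (channel, sample))
# with the channel index fastest. Convolutions are expressed as one gather
# (precomputed index table into the padded volume), one BLAS matrix product,
# and - for gradients and transposed convolutions - one rowsum scatter. This
# keeps the whole training loop vectorized; a brute-force convolution loop in
# the tests serves as the independent oracle.

# geometry of a strided conv: output shape and gather table G (k^3 x n_out)
# of flattened input indices, sentinel n_in + 1 for out-of-range taps
conv_geom <- function(s_in, k = 3L, stride = 2L, pad = 1L) {
  s_in <- as.integer(s_in)
  s_out <- (s_in + 2L * pad - k) %/% stride + 1L
  stop_if(any(s_out < 1L), "input too small for this convolution")
  n_in <- prod(s_in); n_out <- prod(s_out)
  sent <- n_in + 1L
  # per-axis input coordinate for each (output position, tap)
  coord <- lapply(1:3, function(a) {
    outer((seq_len(s_out[a]) - 1L) * stride - pad, seq_len(k), `+`) # n_out_a x k
  })
  G <- matrix(0L, k^3, n_out)
  ox <- rep(seq_len(s_out[1]), times = s_out[2] * s_out[3])
  oy <- rep(rep(seq_len(s_out[2]), each = s_out[1]), times = s_out[3])
  oz <- rep(seq_len(s_out[3]), each = s_out[1] * s_out[2])
  t_idx <- 0L
  for (t3 in seq_len(k)) for (t2 in seq_len(k)) for (t1 in seq_len(k)) {
    t_idx <- t_idx + 1L
    ix <- coord[[1]][ox, t1]; iy <- coord[[2]][oy, t2]; iz <- coord[[3]][oz, t3]
    ok <- ix >= 1L & ix <= s_in[1] & iy >= 1L & iy <= s_in[2] &
      iz >= 1L & iz <= s_in[3]
    lin <- rep(sent, n_out)
    lin[ok] <- ix[ok] + (iy[ok] - 1L) * s_in[1] + (iz[ok] - 1L) * s_in[1] * s_in[2]
    G[t_idx, ] <- lin
  }
  list(s_in = s_in, s_out = s_out, n_in = n_in, n_out = n_out, k = k,
       G = G, Gvec = as.vector(G))
}

# gather columns: X (n_in, C*B) -> (k^3 * C, n_out * B)
im2col <- function(X, geom, C, B) {
  Xp <- rbind(X, 0)
  raw <- Xp[geom$Gvec, , drop = FALSE]                       # (k3*n_out, C*B)
  a <- array(raw, c(geom$k^3, geom$n_out, C, B))
  matrix(aperm(a, c(1, 3, 2, 4)), geom$k^3 * C, geom$n_out * B)
}

# scatter-add: cols (k^3 * C, n_out * B) -> (n_in, C*B)
col2im <- function(cols, geom, C, B) {
  a <- array(cols, c(geom$k^3, C, geom$n_out, B))
  m <- matrix(aperm(a, c(1, 3, 2, 4)), geom$k^3 * geom$n_out, C * B)
  rs <- rowsum(m, group = geom$Gvec)
  out <- matrix(0, geom$n_in + 1L, C * B)
  out[as.integer(rownames(rs)), ] <- rs
  out[seq_len(geom$n_in), , drop = FALSE]
}

# (n, C*B) <-> (C, n*B) layout swaps
to_cfirst <- function(X, n, C, B) matrix(aperm(array(X, c(n, C, B)), c(2, 1, 3)), C, n * B)
to_nfirst <- function(X, n, C, B) matrix(aperm(array(X, c(C, n, B)), c(2, 1, 3)), n, C * B)

# strided conv forward: W (C_out, k^3*C_in), b length C_out
conv_fwd <- function(X, W, b, geom, C_in, C_out, B) {
  cols <- im2col(X, geom, C_in, B)
  Y <- W %*% cols + b
  list(Y = to_nfirst(Y, geom$n_out, C_out, B), cols = cols)
}

conv_bwd <- function(dY, cols, W, geom, C_in, C_out, B) {
  dYm <- to_cfirst(dY, geom$n_out, C_out, B)
  dW <- dYm %*% t(cols)
  db <- rowSums(dYm)
  dX <- col2im(crossprod(W, dYm), geom, C_in, B)
  list(dX = dX, dW = dW, db = db)
}

# transposed conv (small -> large), parameterized by the geometry of the
# corresponding down-conv; W (C_small, k^3*C_large), b length C_large
tconv_fwd <- function(X, W, b, geom, C_small, C_large, B) {
  Xm <- to_cfirst(X, geom$n_out, C_small, B)
  Y <- col2im(crossprod(W, Xm), geom, C_large, B)
  list(Y = sweep(Y, 2, rep(b, times = B), "+"), Xm = Xm)
}

tconv_bwd <- function(dY, Xm, W, geom, C_small, C_large, B) {
  dcols <- im2col(dY, geom, C_large, B)
  dXm <- W %*% dcols
  dW <- Xm %*% t(dcols)
  db <- rowSums(to_cfirst(dY, geom$n_in, C_large, B))
  list(dX = to_nfirst(dXm, geom$n_out, C_small, B), dW = dW, db = db)
}

# brute-force strided 3D convolution (test oracle; O(n k^3) loops)
conv3d_naive <- function(x, w, b, stride = 2L, pad = 1L) {
  # x: (s, s, s, C_in); w: (k, k, k, C_in, C_out); b: C_out
  s_in <- dim(x)[1:3]; k <- dim(w)[1]
  C_in <- dim(x)[4]; C_out <- dim(w)[5]
  s_out <- (s_in + 2L * pad - k) %/% stride + 1L
  y <- array(0, c(s_out, C_out))
  for (co in seq_len(C_out)) for (ox in seq_len(s_out[1]))
    for (oy in seq_len(s_out[2])) for (oz in seq_len(s_out[3])) {
      acc <- b[co]
      for (tx in seq_len(k)) for (ty in seq_len(k)) for (tz in seq_len(k)) {
        ix <- (ox - 1L) * stride - pad + tx
        iy <- (oy - 1L) * stride - pad + ty
        iz <- (oz - 1L) * stride - pad + tz
        if (ix >= 1 && ix <= s_in[1] && iy >= 1 && iy <= s_in[2] &&
            iz >= 1 && iz <= s_in[3])
          acc <- acc + sum(x[ix, iy, iz, ] * w[tx, ty, tz, , co])
      }
      y[ox, oy, oz, co] <- acc
    }
  y
}

# pack a (k,k,k,C_in,C_out) kernel into the (C_out, k^3*C_in) matrix used by
# conv_fwd; tap index fastest, then channel — matches im2col ordering
pack_kernel <- function(w) {
  k3 <- prod(dim(w)[1:3])
  t(matrix(w, k3 * dim(w)[4], dim(w)[5]))
}

adam_init <- function(shapes) {
  lapply(shapes, function(s) list(m = array(0, s), v = array(0, s)))
}

adam_step <- function(par, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mh <- state$m / (1 - beta1^t)
  vh <- state$v / (1 - beta2^t)
  upd <- par - lr * mh / (sqrt(vh) + eps)
  attributes(upd) <- attributes(par)   # keep plain vectors plain
  list(par = upd, state = state)
}
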