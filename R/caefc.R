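# 3D convolutional autoencoder with feature constructor (CAE-FC).
#
# The encoder is two stride-2 3D conv blocks followed by a full-extent
# convolution that collapses the patch to a C-channel global embedding; the
# embedding pre-activations are batch-normalized per channel so the channels
# compete on one scale (without this a single channel absorbs every patch and
# the arg-max partition collapses). The feature constructor suppresses every
# embedding channel except the one with the greatest total rectified
# activation; the mirrored transposed-convolution decoder must reconstruct
# the two-channel patch from that single channel, and the index of the
# surviving channel is the patch's pattern cluster.
#
# Training couples three terms: (i) reconstruction from the constructed
# embedding (the FC objective); (ii) a small auxiliary reconstruction from
# the full embedding, so decoding more channels is never worse than decoding
# one; and (iii) by default a self-labelling alignment term - a seeded
# k-means on the per-patch channel means (the averaged density / averaged J
# plane that characterizes tissue patterns) provides fixed pseudo-labels,
# and a cross-entropy on the channel scores teaches each embedding channel
# to claim one pseudo-class. Inference is a pure forward pass: arg-max of
# the rectified channel activations under the stored normalization
# statistics.

caefc_geoms <- function(edge) {
  g1 <- conv_geom(rep(edge, 3L))
  g2 <- conv_geom(g1$s_out)
  g3 <- conv_geom(g2$s_out, k = max(g2$s_out), stride = 1L, pad = 0L)  # global
  list(g1, g2, g3)
}

caefc_init_weights <- function(C, channels, kg, seed) {
  set.seed(as.integer(seed))
  f1 <- channels[1]; f2 <- channels[2]; k3 <- 27L
  he <- function(nr, nc, fan) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan)), nr, nc)
  list(W1 = he(f1, k3 * 2, k3 * 2), b1 = numeric(f1),
       W2 = he(f2, k3 * f1, k3 * f1), b2 = numeric(f2),
       W3 = he(C, kg * f2, kg * f2), b3 = numeric(C),
       V3 = he(C, kg * f2, kg * f2), c3 = numeric(f2),
       V2 = he(f2, k3 * f1, k3 * f1), c2 = numeric(f1),
       V1 = he(f1, k3 * 2, k3 * 2), c1 = numeric(2))
}

# per-channel normalization of the embedding pre-activation; training uses
# batch statistics, inference the stored statistics
bn_forward <- function(Y, n3, C, B, stats = NULL, eps = 1e-5) {
  a <- array(Y, c(n3, C, B))
  if (is.null(stats)) {
    mu <- apply(a, 2, mean)
    v <- apply(a, 2, function(x) mean((as.vector(x) - mean(x))^2))
  } else {
    mu <- stats$mean; v <- stats$var
  }
  inv <- 1 / sqrt(v + eps)
  cc <- rep(rep(seq_len(C), times = B), each = n3)
  Yn <- matrix((as.vector(Y) - mu[cc]) * inv[cc], n3, C * B)
  list(Y = Yn, mean = mu, var = v, inv = inv)
}

bn_backward <- function(dYn, Yn, inv, n3, C, B) {
  cc <- rep(rep(seq_len(C), times = B), each = n3)
  dvec <- as.vector(dYn); yvec <- as.vector(Yn)
  m <- n3 * B
  sum_d <- tapply(dvec, cc, sum)
  sum_dy <- tapply(dvec * yvec, cc, sum)
  matrix(inv[cc] * (dvec - sum_d[cc] / m - yvec * sum_dy[cc] / m), n3, C * B)
}

# batch feature constructor on the embedding matrix E (n3, C*B):
# channel score = sum of rectified activations; winner takes all, ties to
# the lowest channel index
fc_select <- function(E, n3, C, B) {
  s <- matrix(colSums(array(E, c(n3, C, B))), C, B)
  win <- max.col(t(s), ties.method = "first")
  mask <- as.numeric(rep(seq_len(C), times = B) == win[rep(seq_len(B), each = C)])
  list(cluster = win - 1L, strength = s[cbind(win, seq_len(B))],
       mask = mask, scores = s)
}

caefc_encode <- function(wt, geoms, X, C, channels, B, bn_stats = NULL) {
  f1 <- channels[1]; f2 <- channels[2]
  c1 <- conv_fwd(X, wt$W1, wt$b1, geoms[[1]], 2L, f1, B)
  a1 <- pmax(c1$Y, 0)
  c2 <- conv_fwd(a1, wt$W2, wt$b2, geoms[[2]], f1, f2, B)
  a2 <- pmax(c2$Y, 0)
  c3 <- conv_fwd(a2, wt$W3, wt$b3, geoms[[3]], f2, C, B)
  bn <- bn_forward(c3$Y, geoms[[3]]$n_out, C, B, stats = bn_stats)
  list(emb = pmax(bn$Y, 0), bn = bn, c1 = c1, a1 = a1, c2 = c2, a2 = a2, c3 = c3)
}

caefc_decode <- function(wt, geoms, Ein, C, channels, B) {
  f1 <- channels[1]; f2 <- channels[2]
  d3 <- tconv_fwd(Ein, wt$V3, wt$c3, geoms[[3]], C, f2, B)
  a4 <- pmax(d3$Y, 0)
  d2 <- tconv_fwd(a4, wt$V2, wt$c2, geoms[[2]], f2, f1, B)
  a5 <- pmax(d2$Y, 0)
  d1 <- tconv_fwd(a5, wt$V1, wt$c1, geoms[[1]], f1, 2L, B)
  list(recon = d1$Y, Ein = Ein, a4 = a4, a5 = a5)
}

# gradient of a decoder branch wrt its input embedding and weights;
# dY is already scaled by the branch's loss weight
caefc_decode_bwd <- function(wt, geoms, dec, dY, C, channels, B) {
  f1 <- channels[1]; f2 <- channels[2]
  g1 <- tconv_bwd(dY, to_cfirst(dec$a5, geoms[[1]]$n_out, f1, B),
                  wt$V1, geoms[[1]], f1, 2L, B)
  d5 <- g1$dX * (dec$a5 > 0)
  g2 <- tconv_bwd(d5, to_cfirst(dec$a4, geoms[[2]]$n_out, f2, B),
                  wt$V2, geoms[[2]], f2, f1, B)
  d4 <- g2$dX * (dec$a4 > 0)
  g3 <- tconv_bwd(d4, to_cfirst(dec$Ein, geoms[[3]]$n_out, C, B),
                  wt$V3, geoms[[3]], C, f2, B)
  list(dEin = g3$dX,
       grads = list(V3 = g3$dW, c3 = g3$db, V2 = g2$dW, c2 = g2$db,
                    V1 = g1$dW, c1 = g1$db))
}

caefc_encode_bwd <- function(wt, geoms, enc, dEmb, C, channels, B) {
  f1 <- channels[1]; f2 <- channels[2]
  n3 <- geoms[[3]]$n_out
  dBn <- dEmb * (enc$emb > 0)
  d3 <- bn_backward(dBn, enc$bn$Y, enc$bn$inv, n3, C, B)
  b3 <- conv_bwd(d3, enc$c3$cols, wt$W3, geoms[[3]], f2, C, B)
  d2 <- b3$dX * (enc$a2 > 0)
  b2 <- conv_bwd(d2, enc$c2$cols, wt$W2, geoms[[2]], f1, f2, B)
  d1 <- b2$dX * (enc$a1 > 0)
  b1 <- conv_bwd(d1, enc$c1$cols, wt$W1, geoms[[1]], 2L, f1, B)
  list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db, W3 = b3$dW, b3 = b3$db)
}

patches_to_matrix <- function(patches) {
  arr <- patch_array(patches)
  d <- dim(arr)
  list(X = matrix(arr, prod(d[1:3]), d[4] * d[5]), edge = d[1], n = d[5])
}

sample_cols <- function(ids) as.vector(outer(1:2, (ids - 1L) * 2L, `+`))

#' Train the CAE-FC pattern-cluster model
#'
#' Minimizes the mean-squared reconstruction error between each two-channel
#' patch and the decoder output of its constructed (single-channel)
#' embedding, with Adam on shuffled minibatches, plus an auxiliary
#' full-embedding reconstruction term (`full_weight`) and, when
#' `align = TRUE`, a self-labelling cross-entropy (`align_weight`) that
#' aligns the channel competition with a seeded k-means partition of the
#' patches' (mean density, mean J) statistics. Deterministic under `seed`.
#'
#' @param patches list of two-channel patches (from [sample_random_rois]),
#'   sharing one cubic shape; at least `C` of them.
#' @param C number of pattern clusters (embedding channels).
#' @param epochs,batch_size,learning_rate optimizer budget.
#' @param channels hidden channel widths of the two intermediate conv blocks.
#' @param seed integer seed for init, shuffling and the pseudo-label k-means.
#' @param align enable self-labelled channel alignment (default TRUE).
#' @param align_weight,full_weight loss weights of the alignment and
#'   full-embedding reconstruction terms.
#' @return object of class `caefc`: weights, normalization statistics, and a
#'   per-epoch `training_log` data frame (total loss and reconstruction
#'   loss).
#' @export
train_caefc <- function(patches, C, epochs = 30, batch_size = 32,
                        learning_rate = 1e-3, channels = c(16, 32), seed = 1,
                        align = TRUE, align_weight = 1, full_weight = 0.3) {
  stop_if(length(patches) < C, "need at least C patches")
  pm <- patches_to_matrix(patches)
  geoms <- caefc_geoms(pm$edge)
  n3 <- geoms[[3]]$n_out
  wt <- caefc_init_weights(C, channels, geoms[[3]]$k^3, seed)
  opt <- adam_init(lapply(wt, dim_or_len))

  # fixed pseudo-labels on the averaged-density / averaged-J plane
  pl <- NULL
  if (align && C > 1) {
    feat <- t(matrix(colMeans(array(pm$X, c(geoms[[1]]$n_in, 2, pm$n))), 2, pm$n))
    feat <- feat[, apply(feat, 2, stats::sd) > 1e-12, drop = FALSE]
    set.seed(child_seed(seed, 7))
    pl <- if (ncol(feat) && nrow(unique(feat)) >= C) {
      stats::kmeans(scale(feat), C, nstart = 20, iter.max = 100)$cluster
    } else NULL
  }

  set.seed(as.integer(seed))
  t_step <- 0
  run_mean <- numeric(C); run_var <- rep(1, C); momentum <- 0.9
  map <- NULL
  log_loss <- numeric(epochs); log_recon <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(pm$n)
    losses <- c(); recons <- c()
    for (start in seq(1, pm$n, by = batch_size)) {
      ids <- ord[start:min(start + batch_size - 1, pm$n)]
      B <- length(ids)
      X <- pm$X[, sample_cols(ids), drop = FALSE]
      enc <- caefc_encode(wt, geoms, X, C, channels, B)
      run_mean <- momentum * run_mean + (1 - momentum) * enc$bn$mean
      run_var <- momentum * run_var + (1 - momentum) * enc$bn$var
      fc <- fc_select(enc$emb, n3, C, B)
      if (!is.null(pl) && is.null(map)) {
        # one-off pseudo-class -> channel mapping, greedy on mean scores
        ms <- t(vapply(seq_len(C), function(j) {
          sel <- pl[ids] == j
          if (any(sel)) rowMeans(fc$scores[, sel, drop = FALSE]) else numeric(C)
        }, numeric(C)))
        map <- integer(C); used <- logical(C)
        for (o in order(-apply(ms, 1, max))) {
          pref <- order(-ms[o, ]); pref <- pref[!used[pref]][1]
          map[o] <- pref; used[pref] <- TRUE
        }
      }
      forced <- if (!is.null(pl)) map[pl[ids]] else fc$cluster + 1L
      mask <- as.numeric(rep(seq_len(C), times = B) ==
                           forced[rep(seq_len(B), each = C)])
      dec_c <- caefc_decode(wt, geoms, enc$emb * rep(mask, each = n3),
                            C, channels, B)
      dec_f <- caefc_decode(wt, geoms, enc$emb, C, channels, B)
      N <- length(X)
      recon_loss <- mean((dec_c$recon - X)^2)
      full_loss <- mean((dec_f$recon - X)^2)
      loss <- recon_loss + full_weight * full_loss
      bw_c <- caefc_decode_bwd(wt, geoms, dec_c, 2 * (dec_c$recon - X) / N,
                               C, channels, B)
      bw_f <- caefc_decode_bwd(wt, geoms, dec_f,
                               full_weight * 2 * (dec_f$recon - X) / N,
                               C, channels, B)
      dEmb <- bw_c$dEin * rep(mask, each = n3) + bw_f$dEin
      if (!is.null(pl)) {
        # cross-entropy of softmax(channel scores / tau) against pseudo-labels
        s <- fc$scores
        tau <- max(stats::sd(s), 1e-6)
        z <- sweep(s / tau, 2, apply(s / tau, 2, max))
        P <- exp(z); P <- sweep(P, 2, colSums(P), "/")
        picked <- P[cbind(forced, seq_len(B))]
        loss <- loss - align_weight * mean(log(pmax(picked, 1e-12)))
        oh <- matrix(0, C, B); oh[cbind(forced, seq_len(B))] <- 1
        dS <- align_weight * (P - oh) / (B * tau)
        dEmb <- dEmb + matrix(as.vector(dS)[rep(seq_len(C * B), each = n3)],
                              n3, C * B)
      }
      stop_if(!is.finite(loss), "training diverged (non-finite loss)")
      losses <- c(losses, loss); recons <- c(recons, recon_loss)
      grads <- c(caefc_encode_bwd(wt, geoms, enc, dEmb, C, channels, B),
                 Map(`+`, bw_c$grads, bw_f$grads))
      t_step <- t_step + 1
      for (nm in names(wt)) {
        st <- adam_step(wt[[nm]], grads[[nm]], opt[[nm]], learning_rate, t_step)
        wt[[nm]] <- st$par; opt[[nm]] <- st$state
      }
    }
    log_loss[ep] <- mean(losses); log_recon[ep] <- mean(recons)
  }

  # exact normalization statistics over the training set (one forward pass)
  acc_mean <- numeric(C); acc_m2 <- numeric(C); acc_n <- 0
  for (start in seq(1, pm$n, by = 64)) {
    ids <- start:min(start + 63, pm$n)
    B <- length(ids)
    X <- pm$X[, sample_cols(ids), drop = FALSE]
    f1 <- channels[1]; f2 <- channels[2]
    c1 <- conv_fwd(X, wt$W1, wt$b1, geoms[[1]], 2L, f1, B)
    c2 <- conv_fwd(pmax(c1$Y, 0), wt$W2, wt$b2, geoms[[2]], f1, f2, B)
    c3 <- conv_fwd(pmax(c2$Y, 0), wt$W3, wt$b3, geoms[[3]], f2, C, B)
    a <- array(c3$Y, c(n3, C, B))
    acc_mean <- acc_mean + apply(a, 2, sum)
    acc_m2 <- acc_m2 + apply(a, 2, function(x) sum(as.vector(x)^2))
    acc_n <- acc_n + n3 * B
  }
  mu <- acc_mean / acc_n
  structure(list(weights = wt, C = C, channels = channels, edge = pm$edge,
                 seed = seed, align = align,
                 bn_stats = list(mean = mu, var = pmax(acc_m2 / acc_n - mu^2, 0)),
                 training_log = data.frame(epoch = seq_len(epochs),
                                           loss = log_loss,
                                           recon_loss = log_recon)),
            class = "caefc")
}

dim_or_len <- function(x) if (is.matrix(x)) dim(x) else length(x)

#' @export
print.caefc <- function(x, ...) {
  cat(sprintf("CAE-FC: %d pattern clusters, %d^3 two-channel patches, channels 2-%s-%d\n",
              x$C, x$edge, paste(x$channels, collapse = "-"), x$C))
  tl <- x$training_log
  cat(sprintf("  trained %d epochs; loss %.5f -> %.5f%s\n",
              nrow(tl), tl$loss[1], tl$loss[nrow(tl)],
              if (isTRUE(x$align)) " (self-labelled alignment on)" else ""))
  invisible(x)
}

#' Feature constructor on an embedding
#'
#' The channel score of channel c is the sum of its positive activations; the
#' patch's pattern cluster is the arg-max channel (ties break to the lowest
#' index), and the constructed embedding keeps only that channel. An all-zero
#' embedding is assigned cluster 0 with zero strength and flagged.
#'
#' @param embedding array whose last dimension indexes the C channels (or an
#'   `n x C` matrix).
#' @return list: `constructed` (same shape), `cluster_id` (0-based),
#'   `activation_strength`, `flagged`.
#' @export
feature_construct <- function(embedding) {
  stop_if(any(!is.finite(embedding)), "embedding must be finite")
  d <- dim(embedding) %||% c(length(embedding), 1L)
  C <- d[length(d)]
  m <- matrix(embedding, ncol = C)
  s <- colSums(pmax(m, 0))
  win <- which.max(s)                      # ties: lowest index
  constructed <- m
  constructed[, -win] <- 0
  dim(constructed) <- d
  list(constructed = constructed, cluster_id = win - 1L,
       activation_strength = s[win], flagged = s[win] == 0)
}

#' Assign patches to pattern clusters
#'
#' Inference pass (no weight updates): encode each patch and read its pattern
#' cluster off the feature constructor.
#'
#' @param model a trained [train_caefc] model.
#' @param patches list of patches with the model's patch shape.
#' @param batch_size inference batch size.
#' @return data frame: `patch_id`, `subject_id`, `cluster_id` (0-based),
#'   `activation_strength`.
#' @export
assign_patches <- function(model, patches, batch_size = 64) {
  stopifnot(inherits(model, "caefc"))
  if (!length(patches)) {
    return(data.frame(patch_id = integer(0), subject_id = character(0),
                      cluster_id = integer(0), activation_strength = numeric(0)))
  }
  pm <- patches_to_matrix(patches)
  stop_if(pm$edge != model$edge,
          "patch shape %d^3 does not match the model's %d^3", pm$edge, model$edge)
  geoms <- caefc_geoms(model$edge)
  n3 <- geoms[[3]]$n_out
  out_cl <- integer(pm$n); out_st <- numeric(pm$n)
  for (start in seq(1, pm$n, by = batch_size)) {
    ids <- start:min(start + batch_size - 1, pm$n)
    B <- length(ids)
    enc <- caefc_encode(model$weights, geoms, pm$X[, sample_cols(ids), drop = FALSE],
                        model$C, model$channels, B, bn_stats = model$bn_stats)
    fc <- fc_select(enc$emb, n3, model$C, B)
    out_cl[ids] <- fc$cluster
    out_st[ids] <- fc$strength
  }
  sid <- vapply(patches, function(p) p$subject_id %||% NA_character_, "")
  data.frame(patch_id = seq_len(pm$n), subject_id = sid,
             cluster_id = out_cl, activation_strength = out_st,
             stringsAsFactors = FALSE)
}

#' Reconstruction loss of a trained model
#'
#' Mean-squared reconstruction error over patches, decoding either the
#' constructed (single-channel) embedding or the full embedding. The decoder
#' is trained on both, so keeping all channels can only help: constructed
#' reconstruction is never better than full reconstruction.
#'
#' @inheritParams assign_patches
#' @param constructed decode the feature-constructed embedding (default) or
#'   the full embedding.
#' @export
caefc_reconstruction_loss <- function(model, patches, constructed = TRUE,
                                      batch_size = 64) {
  stopifnot(inherits(model, "caefc"))
  pm <- patches_to_matrix(patches)
  geoms <- caefc_geoms(model$edge)
  n3 <- geoms[[3]]$n_out
  sse <- 0; nel <- 0
  for (start in seq(1, pm$n, by = batch_size)) {
    ids <- start:min(start + batch_size - 1, pm$n)
    B <- length(ids)
    X <- pm$X[, sample_cols(ids), drop = FALSE]
    enc <- caefc_encode(model$weights, geoms, X, model$C, model$channels, B,
                        bn_stats = model$bn_stats)
    Ein <- enc$emb
    if (constructed) {
      fc <- fc_select(enc$emb, n3, model$C, B)
      Ein <- enc$emb * rep(fc$mask, each = n3)
    }
    dec <- caefc_decode(model$weights, geoms, Ein, model$C, model$channels, B)
    sse <- sse + sum((dec$recon - X)^2); nel <- nel + length(X)
  }
  sse / nel
}

#' Select the pattern-cluster count by training loss
#'
#' Trains one model per candidate C under an identical budget and returns the
#' candidate with the lowest final reconstruction loss; the full loss table
#' is attached as attribute `loss_table`. Candidates that fail to train are
#' excluded with a warning.
#'
#' @inheritParams train_caefc
#' @param candidate_Cs integer vector of candidate cluster counts (a single
#'   candidate is returned directly).
#' @return the selected C, with attributes `loss_table` and `models`.
#' @export
select_cluster_count <- function(patches, candidate_Cs, epochs = 30,
                                 batch_size = 32, learning_rate = 1e-3,
                                 channels = c(16, 32), seed = 1, ...) {
  stop_if(length(candidate_Cs) < 1, "no candidates")
  if (length(candidate_Cs) == 1L) return(candidate_Cs)
  fits <- lapply(candidate_Cs, function(C) {
    tryCatch(train_caefc(patches, C, epochs = epochs, batch_size = batch_size,
                         learning_rate = learning_rate, channels = channels,
                         seed = seed, ...),
             error = function(e) {
               warning(sprintf("C = %d failed to train: %s", C, conditionMessage(e)))
               NULL
             })
  })
  ok <- !vapply(fits, is.null, TRUE)
  stop_if(!any(ok), "all candidates failed to train")
  final <- vapply(fits[ok], function(m) {
    m$training_log$recon_loss[nrow(m$training_log)]
  }, 0)
  tab <- data.frame(C = candidate_Cs[ok], final_loss = final)
  best <- candidate_Cs[ok][which.min(final)]
  structure(best, loss_table = tab, models = fits[ok])
}
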