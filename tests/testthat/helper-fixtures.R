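# Fixtures built in code: texture-class patch sets, small phantoms, and a
# particle-tracking Monte-Carlo oracle for tube sedimentation.

# patches of one texture class: near-constant channels + voxel noise
mk_class_patches <- function(n, edge, density, jmean, seed,
                             sd_density = 0.03, sd_j = 0.05) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    d <- array(0, c(edge, edge, edge, 2))
    d[, , , 1] <- pmin(pmax(density + array(rnorm(edge^3, 0, sd_density),
                                            rep(edge, 3)), 0), 1)
    d[, , , 2] <- pmax(jmean + array(rnorm(edge^3, 0, sd_j), rep(edge, 3)), 0.05)
    list(data = d, subject_id = sprintf("fx%02d", i %% 4))
  })
}

# the four texture classes used across CAE-FC tests: (density, J) corners
fixture_classes <- list(c(0.11, 0.55), c(0.09, 0.77), c(0.27, 1.40), c(0.16, 0.45))

mk_fixture_set <- function(n_per_class = 50, edge = 12, seed = 1) {
  pats <- list(); labs <- integer(0)
  for (k in seq_along(fixture_classes)) {
    pats <- c(pats, mk_class_patches(n_per_class, edge, fixture_classes[[k]][1],
                                     fixture_classes[[k]][2], seed * 10 + k))
    labs <- c(labs, rep(k, n_per_class))
  }
  list(patches = pats, labels = labs)
}

# an all-lung two-channel cube (mask everywhere) for sampler tests
mk_all_lung_volume <- function(edge = 40, seed = 1) {
  set.seed(seed)
  structure(list(density = array(runif(edge^3, 0.05, 0.3), rep(edge, 3)),
                 jacobian = array(runif(edge^3, 0.4, 0.9), rep(edge, 3)),
                 lung_mask = array(TRUE, rep(edge, 3)),
                 spacing = c(1, 1, 1)),
            class = "two_channel")
}

purity <- function(labels, clusters) {
  tab <- table(labels, clusters)
  sum(apply(tab, 2, max)) / sum(tab)
}

# particle-tracking oracle: gravitational settling in laminar Poiseuille tube
# flow, flux-weighted inlet, absorbing wall; independent of the analytic
# efficiency formula it checks
mc_tube_sedimentation <- function(radius_m, length_m, ubar_ms, vs_ms,
                                  n = 1e5, n_steps = 1500, seed = 1) {
  set.seed(seed)
  pts <- matrix(0, 0, 2)
  while (nrow(pts) < n) {
    y <- runif(2 * n, -radius_m, radius_m)
    z <- runif(2 * n, -radius_m, radius_m)
    r2 <- y^2 + z^2
    keep <- r2 < radius_m^2 & runif(2 * n) < (1 - r2 / radius_m^2)
    add <- cbind(y, z)[keep, , drop = FALSE]
    pts <- rbind(pts, add[seq_len(min(nrow(add), n - nrow(pts))), , drop = FALSE])
  }
  y <- pts[, 1]; z <- pts[, 2]
  x <- numeric(n)
  alive <- rep(TRUE, n); deposited <- rep(FALSE, n)
  dt <- (2 * radius_m / vs_ms) / n_steps
  for (s in seq_len(4 * n_steps)) {
    if (!any(alive)) break
    u <- 2 * ubar_ms * (1 - (y[alive]^2 + z[alive]^2) / radius_m^2)
    x[alive] <- x[alive] + u * dt
    y[alive] <- y[alive] - vs_ms * dt
    hit <- y[alive]^2 + z[alive]^2 >= radius_m^2
    out <- x[alive] >= length_m
    idx <- which(alive)
    deposited[idx[hit & !out]] <- TRUE
    alive[idx[hit | out]] <- FALSE
  }
  mean(deposited)
}
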