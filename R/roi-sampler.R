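# Lobule-sized patch extraction from two-channel volumes: random centers for
# autoencoder training, and a deterministic sliding-window raster for
# whole-lung quantification. The 20 mm default edge matches the scale of a
# secondary pulmonary lobule.

patch_obj <- function(data, center_vox, spacing, subject_id, lung_fraction) {
  list(data = data, center_vox = center_vox,
       center_mm = (center_vox - 0.5) * spacing,
       subject_id = subject_id, lung_fraction = lung_fraction)
}

# 3D summed-area table; box_sum reads patch sums in O(1)
integral3 <- function(x) {
  s <- apply(x, c(2, 3), cumsum)
  s <- apply(s, c(1, 3), cumsum); s <- aperm(s, c(2, 1, 3))
  s <- apply(s, c(1, 2), cumsum); aperm(s, c(2, 3, 1))
}

# sum of x over the box [start, start+edge-1] per axis, start: matrix n x 3
box_sums <- function(S, starts, edge) {
  d <- dim(S)
  g <- function(i, j, k) {
    ok <- i >= 1L & j >= 1L & k >= 1L
    v <- numeric(nrow(starts)); v[ok] <- S[cbind(i[ok], j[ok], k[ok])]
    v
  }
  i0 <- starts[, 1] - 1L; j0 <- starts[, 2] - 1L; k0 <- starts[, 3] - 1L
  i1 <- starts[, 1] + edge - 1L; j1 <- starts[, 2] + edge - 1L
  k1 <- starts[, 3] + edge - 1L
  g(i1, j1, k1) - g(i0, j1, k1) - g(i1, j0, k1) - g(i1, j1, k0) +
    g(i0, j0, k1) + g(i0, j1, k0) + g(i1, j0, k0) - g(i0, j0, k0)
}

check_two_channel <- function(volume) {
  stop_if(!inherits(volume, "two_channel"), "volume must be a two_channel")
  sp <- volume$spacing
  stop_if(max(abs(sp - sp[1])) > 1e-6,
          "patch extraction requires isotropic spacing; resample first")
  volume
}

extract_patch <- function(volume, start, edge) {
  ix <- start[1]:(start[1] + edge - 1L)
  iy <- start[2]:(start[2] + edge - 1L)
  iz <- start[3]:(start[3] + edge - 1L)
  data <- array(0, c(edge, edge, edge, 2L))
  data[, , , 1] <- volume$density[ix, iy, iz]
  data[, , , 2] <- volume$jacobian[ix, iy, iz]
  data
}

#' Randomly sampled lobule-sized patches
#'
#' Draws `n` two-channel cubic patches whose centers are uniform over the
#' voxels whose surrounding patch lies inside the volume and covers at least
#' `min_lung_fraction` lung. Sampling is with replacement and bit-reproducible
#' under `seed`.
#'
#' @param volume a [build_two_channel] result (isotropic spacing).
#' @param n number of patches (>= 1).
#' @param roi_mm physical patch edge, mm (default 20, the scale of a
#'   secondary pulmonary lobule).
#' @param min_lung_fraction minimum fraction of lung voxels per patch.
#' @param seed integer seed.
#' @return list of patches: `data` (edge^3 x 2 array), `center_vox`,
#'   `center_mm`, `subject_id`, `lung_fraction`.
#' @export
sample_random_rois <- function(volume, n, roi_mm = 20, min_lung_fraction = 0.5,
                               seed = 1) {
  volume <- check_two_channel(volume)
  stop_if(n < 1, "n must be >= 1")
  edge <- as.integer(round(roi_mm / volume$spacing[1]))
  d <- dim(volume$density)
  stop_if(any(d < edge), "volume smaller than the patch")
  S <- integral3(volume$lung_mask + 0)
  starts_all <- as.matrix(expand.grid(seq_len(d[1] - edge + 1L),
                                      seq_len(d[2] - edge + 1L),
                                      seq_len(d[3] - edge + 1L)))
  frac <- box_sums(S, starts_all, edge) / edge^3
  valid <- which(frac >= min_lung_fraction)
  stop_if(length(valid) == 0,
          "no valid patch center: lung too small for roi_mm = %g at lung fraction >= %g",
          roi_mm, min_lung_fraction)
  set.seed(as.integer(seed))
  pick <- valid[sample.int(length(valid), n, replace = TRUE)]
  lapply(pick, function(p) {
    st <- starts_all[p, ]
    patch_obj(extract_patch(volume, st, edge), st + (edge - 1L) / 2,
              volume$spacing, attr(volume, "subject_id"), frac[p])
  })
}

#' Sliding-window patches over the lung
#'
#' Deterministic raster of cubic windows covering the lung bounding box with
#' the given stride; windows with lung coverage below `min_lung_fraction` are
#' dropped. Used to quantify pattern-cluster frequencies over the whole lung.
#'
#' @inheritParams sample_random_rois
#' @param stride_mm raster step, mm (default 10: 50% overlap at 20 mm ROI).
#' @return list of patches (possibly empty, with a warning, when no window
#'   reaches the lung fraction).
#' @export
sliding_window_rois <- function(volume, roi_mm = 20, stride_mm = 10,
                                min_lung_fraction = 0.5) {
  volume <- check_two_channel(volume)
  stop_if(stride_mm <= 0, "stride must be > 0")
  edge <- as.integer(round(roi_mm / volume$spacing[1]))
  step <- max(1L, as.integer(round(stride_mm / volume$spacing[1])))
  d <- dim(volume$density)
  stop_if(any(d < edge), "volume smaller than the patch")
  if (!any(volume$lung_mask)) {
    warning("empty lung mask: no windows")
    return(list())
  }
  bb <- apply(which(volume$lung_mask, arr.ind = TRUE), 2, range)
  ax <- lapply(1:3, function(a) {
    lo <- max(1L, bb[1, a])
    hi <- min(d[a] - edge + 1L, bb[2, a] - edge + 1L)
    if (hi < lo) lo <- hi <- max(1L, min(d[a] - edge + 1L, bb[1, a]))
    seq.int(lo, hi, by = step)
  })
  starts <- as.matrix(expand.grid(ax[[1]], ax[[2]], ax[[3]]))
  S <- integral3(volume$lung_mask + 0)
  frac <- box_sums(S, starts, edge) / edge^3
  keep <- which(frac >= min_lung_fraction)
  if (!length(keep)) {
    warning("no sliding window reaches the lung-fraction threshold")
    return(list())
  }
  lapply(keep, function(p) {
    st <- starts[p, ]
    patch_obj(extract_patch(volume, st, edge), st + (edge - 1L) / 2,
              volume$spacing, attr(volume, "subject_id"), frac[p])
  })
}

#' Stack patches into a batch array
#'
#' @param patches list of patches sharing one shape.
#' @return 5D array `edge x edge x edge x 2 x n`.
#' @export
patch_array <- function(patches) {
  stop_if(!length(patches), "no patches")
  d <- dim(patches[[1]]$data)
  arr <- array(0, c(d, length(patches)))
  for (i in seq_along(patches)) {
    stop_if(!identical(dim(patches[[i]]$data), d), "patches differ in shape")
    arr[, , , , i] <- patches[[i]]$data
  }
  arr
}

#' Resample a two-channel volume to isotropic spacing
#'
#' Nearest-neighbour resampling onto an isotropic grid (default 1 mm), so a
#' physical ROI cube maps to a cubic voxel block. Density and Jacobian are
#' sampled at the new voxel centers; the lung mask stays binary.
#'
#' @param volume a [build_two_channel] result.
#' @param spacing_mm target isotropic spacing, mm.
#' @return a `two_channel` volume on the new grid.
#' @export
resample_isotropic <- function(volume, spacing_mm = 1) {
  stop_if(!inherits(volume, "two_channel"), "volume must be a two_channel")
  stop_if(spacing_mm <= 0, "spacing must be > 0")
  d_old <- dim(volume$density)
  extent <- d_old * volume$spacing
  d_new <- pmax(1L, as.integer(round(extent / spacing_mm)))
  idx <- lapply(1:3, function(a) {
    centers <- (seq_len(d_new[a]) - 0.5) * spacing_mm
    pmin(pmax(ceiling(centers / volume$spacing[a]), 1L), d_old[a])
  })
  pick <- function(x) x[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  structure(list(density = pick(volume$density),
                 jacobian = pick(volume$jacobian),
                 lung_mask = pick(volume$lung_mask),
                 spacing = rep(spacing_mm, 3L)),
            class = "two_channel")
}
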