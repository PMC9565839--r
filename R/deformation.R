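# Two-channel image construction: rescaled CT density + registration Jacobian.
#
# The displacement field u maps inspiratory (IN/TLC) voxel coordinates to
# expiratory (EX/RV) coordinates in mm, so J = det(I + grad u) is the local
# EX-to-IN volume ratio: J < 1 where the region is larger at TLC than at RV
# (normal deflation), 1/J is the local expansion.

#' Jacobian determinant of a displacement field
#'
#' Computes \eqn{J = \det(I + \nabla u)} voxel-wise from a vector displacement
#' field by central finite differences (one-sided at the grid boundary), with
#' spacing in mm. \eqn{u} maps IN coordinates to EX coordinates, so \eqn{J} is
#' the local EX/IN volume ratio used as the second image channel.
#'
#' @param displacement 4D numeric array `dim = c(nx, ny, nz, 3)`, mm.
#' @param spacing voxel spacing, length-3 numeric, mm.
#' @param floor positive clipping floor applied to the result (default 1e-3);
#'   folded or degenerate voxels are clipped rather than propagated as
#'   non-positive volume ratios.
#' @return 3D numeric array of Jacobian determinants.
#' @export
#' @examples
#' u <- array(0, c(8, 8, 8, 3))
#' all(jacobian_determinant(u, c(1, 1, 1)) == 1)
jacobian_determinant <- function(displacement, spacing, floor = 1e-3) {
  stop_if(!is.array(displacement) || length(dim(displacement)) != 4L ||
            dim(displacement)[4] != 3L,
          "displacement must be a 4D array with 3 components on the 4th axis")
  stop_if(any(!is.finite(displacement)), "displacement contains non-finite values")
  spacing <- check_spacing(spacing)
  stop_if(!is.numeric(floor) || floor <= 0, "floor must be positive")

  d <- dim(displacement)[1:3]
  # g[[i]][[j]] = d u_i / d x_j
  g <- vector("list", 3L)
  for (i in 1:3) {
    ui <- displacement[, , , i]
    g[[i]] <- lapply(1:3, function(j) grad_axis(ui, j, spacing[j]))
  }
  J <- (1 + g[[1]][[1]]) * ((1 + g[[2]][[2]]) * (1 + g[[3]][[3]]) - g[[2]][[3]] * g[[3]][[2]]) -
    g[[1]][[2]] * (g[[2]][[1]] * (1 + g[[3]][[3]]) - g[[2]][[3]] * g[[3]][[1]]) +
    g[[1]][[3]] * (g[[2]][[1]] * g[[3]][[2]] - (1 + g[[2]][[2]]) * g[[3]][[1]])
  J[J < floor] <- floor
  J
}

# partial derivative of a 3D array along axis `ax`: central differences in the
# interior, one-sided first differences at the two boundary slabs
grad_axis <- function(x, ax, h) {
  n <- dim(x)[ax]
  stopifnot(n >= 2L)
  idx <- function(i) {
    sl <- list(quote(expr =), quote(expr =), quote(expr =))
    sl[[ax]] <- i
    do.call(`[`, c(list(x), sl, list(drop = FALSE)))
  }
  up <- idx(c(2:n, n))       # forward neighbour (clamped)
  dn <- idx(c(1L, 1:(n - 1))) # backward neighbour (clamped)
  den <- array(2 * h, dim(x))
  sl <- rep(list(TRUE), 3L); sl[[ax]] <- c(1L, n)
  den <- do.call(`[<-`, c(list(den), sl, list(value = h)))
  (up - dn) / den
}

#' Rescale CT attenuation to the unit interval
#'
#' Linear map from the Hounsfield window \[-1024, 200\] (air to soft tissue)
#' onto \[0, 1\], clamped outside the window. This is the first channel of the
#' two-channel image.
#'
#' @param hu numeric array or vector of CT attenuation values (HU).
#' @param window length-2 HU window mapped to \[0, 1\].
#' @return object of the same shape with values in \[0, 1\].
#' @export
#' @examples
#' rescale_density(c(-1024, -412, 200))
rescale_density <- function(hu, window = c(-1024, 200)) {
  stop_if(length(window) != 2L || window[2] <= window[1], "invalid HU window")
  pmin(pmax((hu - window[1]) / (window[2] - window[1]), 0), 1)
}

#' Assemble the two-channel volume
#'
#' Builds the co-located two-channel image on the IN grid: channel 1 is the
#' rescaled IN density, channel 2 the Jacobian determinant of the IN-to-EX
#' displacement. Outside the lung mask the channels are set to the fill
#' convention (0, 1): zero density, unit volume ratio.
#'
#' @param scan a [lung_scan] (paired IN/EX volumes, masks, displacement).
#' @param jacobian_floor positive clipping floor for the Jacobian channel.
#' @return object of class `two_channel` with fields `density`, `jacobian`,
#'   `lung_mask`, `spacing`.
#' @export
build_two_channel <- function(scan, jacobian_floor = 1e-3) {
  stop_if(!inherits(scan, "lung_scan"), "scan must be a lung_scan")
  stop_if(is.null(scan$displacement), "scan has no displacement field")
  d <- dim(scan$in_volume)
  stop_if(!identical(dim(scan$lung_mask), d) ||
            !identical(dim(scan$displacement)[1:3], d),
          "volume, mask and displacement shapes differ")
  density <- rescale_density(scan$in_volume)
  jac <- jacobian_determinant(scan$displacement, scan$spacing, floor = jacobian_floor)
  outside <- !(scan$lung_mask > 0)
  density[outside] <- 0
  jac[outside] <- 1
  structure(list(density = density, jacobian = jac,
                 lung_mask = scan$lung_mask > 0, spacing = scan$spacing),
            class = "two_channel")
}

#' @export
print.two_channel <- function(x, ...) {
  d <- dim(x$density)
  cat(sprintf("two_channel volume %d x %d x %d, spacing %s mm\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 3), collapse = " x ")))
  cat(sprintf("  lung voxels: %d (%.1f%%); J in lung: [%.3f, %.3f]\n",
              sum(x$lung_mask), 100 * mean(x$lung_mask),
              min(x$jacobian[x$lung_mask]), max(x$jacobian[x$lung_mask])))
  invisible(x)
}
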