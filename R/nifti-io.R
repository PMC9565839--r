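# NIfTI serialization of scans and two-channel volumes (RNifti). Volumes and
# masks are 3D images; the displacement field and the two-channel volume are
# 4D with the vector component / channel on the 4th axis; spacing is carried
# in pixdim (mm).

#' Write / read a paired lung scan as NIfTI files
#'
#' Writes `in.nii.gz`, `ex.nii.gz`, `ex_warped.nii.gz`, `lung_mask.nii.gz`,
#' `lobe_mask.nii.gz` and `displacement.nii.gz` (4D, mm, IN-grid frame) into
#' a directory.
#'
#' @param scan a `lung_scan`.
#' @param dir output directory (created if missing).
#' @export
write_lung_scan_nifti <- function(scan, dir) {
  stopifnot(inherits(scan, "lung_scan"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    RNifti::writeNifti(RNifti::asNifti(x, pixdim = scan$spacing),
                       file.path(dir, paste0(name, ".nii.gz")))
  }
  wr(scan$in_volume, "in")
  wr(scan$ex_volume, "ex")
  wr(scan$ex_warped, "ex_warped")
  wr(scan$lung_mask + 0L, "lung_mask")
  wr(scan$lobe_mask, "lobe_mask")
  wr(scan$displacement, "displacement")
  invisible(dir)
}

#' @rdname write_lung_scan_nifti
#' @param subject_id id attached to the returned scan.
#' @export
read_lung_scan_nifti <- function(dir, subject_id = basename(dir)) {
  rd <- function(name) {
    img <- RNifti::readNifti(file.path(dir, paste0(name, ".nii.gz")))
    a <- as.array(img)
    attr(a, "pixdim") <- RNifti::pixdim(img)
    a
  }
  vol <- rd("in")
  spacing <- attr(vol, "pixdim")[1:3]
  scan <- list(in_volume = strip_attrs(vol), ex_volume = strip_attrs(rd("ex")),
               ex_warped = strip_attrs(rd("ex_warped")),
               lung_mask = strip_attrs(rd("lung_mask")) > 0,
               ex_lung_mask = NULL,
               lobe_mask = strip_attrs(rd("lobe_mask")),
               displacement = strip_attrs(rd("displacement")),
               spacing = spacing, subject_id = subject_id)
  structure(scan, class = "lung_scan")
}

strip_attrs <- function(x) { a <- as.array(x); attributes(a) <- list(dim = dim(x)); a }

#' Write / read a two-channel volume as 4D NIfTI
#'
#' Channel (density, Jacobian) on the 4th axis; the lung mask is stored
#' alongside with suffix `_mask`.
#'
#' @param volume a [build_two_channel] result.
#' @param path output `.nii.gz` path.
#' @export
write_two_channel_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "two_channel"))
  arr <- array(0, c(dim(volume$density), 2L))
  arr[, , , 1] <- volume$density
  arr[, , , 2] <- volume$jacobian
  RNifti::writeNifti(RNifti::asNifti(arr, pixdim = volume$spacing), path)
  RNifti::writeNifti(RNifti::asNifti(volume$lung_mask + 0L, pixdim = volume$spacing),
                     sub("\\.nii(\\.gz)?$", "_mask.nii\\1", path))
  invisible(path)
}

#' @rdname write_two_channel_nifti
#' @export
read_two_channel_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  stop_if(length(dim(arr)) != 4L || dim(arr)[4] != 2L,
          "expected a 4D two-channel NIfTI")
  mask <- as.array(RNifti::readNifti(sub("\\.nii(\\.gz)?$", "_mask.nii\\1", path)))
  structure(list(density = arr[, , , 1], jacobian = arr[, , , 2],
                 lung_mask = mask > 0, spacing = RNifti::pixdim(img)[1:3]),
            class = "two_channel")
}
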