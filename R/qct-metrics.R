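# Quantitative CT metrics: low-attenuation area percentages, tissue fraction,
# parametric response mapping (fSAD), RV/TLC and airway-to-lung volume ratio.
# Thresholds follow field convention: -950 HU at TLC (emphysema-like), -856 HU
# at RV (gas trapping); all are arguments, not constants.

#' Low attenuation area percentage
#'
#' Percentage of masked voxels with attenuation below `threshold`
#' (conventionally -950 HU on inspiratory and -856 HU on expiratory scans).
#'
#' @param volume HU array.
#' @param mask logical/0-1 array, same shape.
#' @param threshold HU threshold.
#' @return percentage in \[0, 100\].
#' @export
laa_percent <- function(volume, mask, threshold) {
  mask <- check_mask(volume, mask)
  100 * mean(volume[mask] < threshold)
}

#' Tissue fraction percentage at TLC
#'
#' Mean fractional tissue content over the mask, from the linear air/tissue
#' HU mixture model: fraction = (HU - HU_air) / (HU_tissue - HU_air), clamped
#' to \[0, 1\], with air at -1000 HU and soft tissue at 55 HU.
#'
#' @inheritParams laa_percent
#' @param hu_air,hu_tissue HU anchors of pure air and pure soft tissue.
#' @return percentage in \[0, 100\].
#' @export
tissue_percent <- function(volume, mask, hu_air = -1000, hu_tissue = 55) {
  mask <- check_mask(volume, mask)
  frac <- pmin(pmax((volume[mask] - hu_air) / (hu_tissue - hu_air), 0), 1)
  100 * mean(frac)
}

#' Parametric response map classes
#'
#' Joint TLC/RV attenuation rule on co-registered grids. Voxels are classified
#' as `emphysema` (TLC < tlc_threshold), `fsad` (TLC >= tlc_threshold and
#' RV < rv_threshold: non-emphysematous but gas-trapping), `high_attenuation`
#' (TLC >= -250, not trapping) or `normal`. Percentages partition the mask.
#'
#' @param tlc HU array at TLC.
#' @param rv_registered HU array at RV, resampled onto the TLC frame.
#' @param mask logical/0-1 array on the TLC frame.
#' @param tlc_threshold,rv_threshold HU thresholds (defaults -950, -856).
#' @param high_threshold HU bound separating parenchyma from high-attenuation
#'   tissue (default -250).
#' @return named numeric vector of class percentages summing to 100.
#' @export
prm_classes <- function(tlc, rv_registered, mask,
                        tlc_threshold = -950, rv_threshold = -856,
                        high_threshold = -250) {
  stop_if(!identical(dim(tlc), dim(rv_registered)),
          "TLC and registered RV grids are not on the same frame")
  mask <- check_mask(tlc, mask)
  a <- tlc[mask]; b <- rv_registered[mask]
  emph <- a < tlc_threshold
  fsad <- !emph & b < rv_threshold          # same rule as fsad_percent
  high <- !emph & !fsad & a >= high_threshold
  normal <- !emph & !fsad & !high
  100 * c(normal = mean(normal), fsad = mean(fsad),
          emphysema = mean(emph), high_attenuation = mean(high))
}

#' Functional small airway disease percentage
#'
#' The fSAD class of the parametric response map: percentage of masked voxels
#' that are non-emphysematous at TLC (HU >= -950) but gas-trapping at RV
#' (HU < -856).
#'
#' @inheritParams prm_classes
#' @return percentage in \[0, 100\].
#' @export
fsad_percent <- function(tlc, rv_registered, mask,
                         tlc_threshold = -950, rv_threshold = -856) {
  stop_if(!identical(dim(tlc), dim(rv_registered)),
          "TLC and registered RV grids are not on the same frame")
  mask <- check_mask(tlc, mask)
  100 * mean(tlc[mask] >= tlc_threshold & rv_registered[mask] < rv_threshold)
}

#' RV/TLC volume ratio and airway-to-lung volume percentage
#'
#' Plain volume ratios; mask volumes are voxel count times voxel volume.
#'
#' @param rv_ml,tlc_ml lung volumes in mL.
#' @return the ratio (`rv_tlc_ratio`) or percentage (`awv_percent`).
#' @export
rv_tlc_ratio <- function(rv_ml, tlc_ml) {
  stop_if(!is.finite(rv_ml) || !is.finite(tlc_ml) || rv_ml <= 0 || tlc_ml <= 0,
          "volumes must be positive")
  rv_ml / tlc_ml
}

#' @rdname rv_tlc_ratio
#' @param airway_ml conducting-airway volume in mL (e.g. from
#'   [airway_tree_volume] when no airway mask is available).
#' @param lung_ml lung volume in mL.
#' @export
awv_percent <- function(airway_ml, lung_ml) {
  stop_if(!is.finite(airway_ml) || !is.finite(lung_ml) || airway_ml <= 0 ||
            lung_ml <= 0, "volumes must be positive")
  100 * airway_ml / lung_ml
}

#' Mask volume in mL
#'
#' @param mask logical/0-1 array.
#' @param spacing voxel spacing in mm.
#' @export
mask_volume_ml <- function(mask, spacing) {
  spacing <- check_spacing(spacing)
  sum(mask > 0) * prod(spacing) / 1000
}

#' Per-subject quantitative CT record
#'
#' Computes the imaging variable battery for one subject — LAA% at TLC and RV,
#' Tissue%, fSAD%, each for the whole lung and the five lobes, plus RV/TLC and
#' AWV% — as a one-row data frame with documented column names
#' (e.g. `LAA_TLC_pct_RUL`).
#'
#' @param scan a [lung_scan]; its `ex_warped` field (RV attenuation resampled
#'   onto the TLC frame) is used for the PRM metrics.
#' @param airway_ml optional conducting-airway volume in mL for AWV%.
#' @return one-row `data.frame`.
#' @export
qct_record <- function(scan, airway_ml = NULL) {
  stop_if(!inherits(scan, "lung_scan"), "scan must be a lung_scan")
  lobes <- c("LUL", "LLL", "RUL", "RML", "RLL")
  masks <- c(list(Total = scan$lung_mask > 0),
             stats::setNames(lapply(1:5, function(l) scan$lobe_mask == l), lobes))
  rvw <- scan$ex_warped
  stop_if(is.null(rvw), "scan has no RV-on-TLC-frame attenuation (ex_warped)")
  rec <- list(subject_id = scan$subject_id %||% NA_character_)
  for (nm in names(masks)) {
    m <- masks[[nm]]
    if (!any(m)) {
      vals <- rep(NA_real_, 4)
    } else {
      vals <- c(laa_percent(scan$in_volume, m, -950),
                laa_percent(rvw, m, -856),
                tissue_percent(scan$in_volume, m),
                fsad_percent(scan$in_volume, rvw, m))
    }
    rec[paste0(c("LAA_TLC_pct_", "LAA_RV_pct_", "Tissue_pct_", "fSAD_pct_"), nm)] <-
      as.list(vals)
  }
  tlc_ml <- mask_volume_ml(scan$lung_mask, scan$spacing)
  rv_ml <- if (!is.null(scan$ex_lung_mask)) {
    mask_volume_ml(scan$ex_lung_mask, scan$spacing)
  } else {
    # volume image of the lung under the deformation: integral of J over the mask
    sum(jacobian_determinant(scan$displacement, scan$spacing)[scan$lung_mask > 0]) *
      prod(scan$spacing) / 1000
  }
  rec$RV_TLC <- rv_tlc_ratio(rv_ml, tlc_ml)
  rec$AWV_pct <- if (is.null(airway_ml)) NA_real_ else awv_percent(airway_ml, tlc_ml)
  as.data.frame(rec, stringsAsFactors = FALSE)
}

check_mask <- function(volume, mask) {
  stop_if(!identical(dim(volume), dim(mask)), "volume and mask shapes differ")
  mask <- mask > 0
  stop_if(!any(mask), "mask is empty")
  mask
}

`%||%` <- function(a, b) if (is.null(a)) b else a
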