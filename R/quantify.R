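# Per-subject pattern-cluster frequency histograms from sliding-window
# assignments, and per-cluster channel summaries.

#' Pattern-cluster frequency histogram of one subject
#'
#' Frequencies are window counts divided by the total number of (lung-filter
#' passing) windows; they sum to 1 and are invariant to window order.
#'
#' @param assignments data frame from [assign_patches] for one subject.
#' @param C number of pattern clusters.
#' @return object of class `subject_histogram`: `subject_id`, `frequencies`
#'   (length C), `n_windows`.
#' @export
subject_histogram <- function(assignments, C) {
  stop_if(nrow(assignments) < 1, "subject has no windows (no lung coverage)")
  stop_if(any(assignments$cluster_id < 0 | assignments$cluster_id >= C),
          "cluster_id outside 0..C-1")
  counts <- tabulate(assignments$cluster_id + 1L, nbins = C)
  structure(list(subject_id = unique(assignments$subject_id)[1],
                 frequencies = counts / sum(counts), n_windows = sum(counts)),
            class = "subject_histogram")
}

#' Histogram matrix for a cohort
#'
#' @param assignments data frame from [assign_patches] over all subjects
#'   (column `subject_id` present).
#' @param C number of pattern clusters.
#' @return subjects x C matrix of frequencies, row names = subject ids,
#'   column names `pc0..pc(C-1)`.
#' @export
histogram_matrix <- function(assignments, C) {
  sp <- split(assignments, assignments$subject_id)
  H <- t(vapply(sp, function(a) subject_histogram(a, C)$frequencies,
                numeric(C)))
  colnames(H) <- paste0("pc", seq_len(C) - 1L)
  H
}

#' Per-cluster channel summaries
#'
#' For each pattern cluster, the mean over member patches of the patch-level
#' lung-voxel channel means (rescaled density and Jacobian). Empty clusters
#' are reported with `n_patches = 0` and `NA` means.
#'
#' @param assignments data frame from [assign_patches].
#' @param patches the patch list the assignments refer to (by `patch_id`).
#' @param C number of pattern clusters.
#' @return data frame: `cluster_id`, `mean_density`, `mean_j`, `n_patches`.
#' @export
pattern_summaries <- function(assignments, patches, C) {
  stop_if(any(assignments$patch_id > length(patches)),
          "assignment references a missing patch")
  ch_means <- t(vapply(patches[assignments$patch_id], function(p) {
    lungish <- p$data[, , , 1] > 0 | p$data[, , , 2] != 1
    if (!any(lungish)) lungish[] <- TRUE
    c(mean(p$data[, , , 1][lungish]), mean(p$data[, , , 2][lungish]))
  }, numeric(2)))
  out <- data.frame(cluster_id = seq_len(C) - 1L, mean_density = NA_real_,
                    mean_j = NA_real_, n_patches = 0L)
  for (c0 in seq_len(C) - 1L) {
    sel <- assignments$cluster_id == c0
    out$n_patches[c0 + 1] <- sum(sel)
    if (any(sel)) {
      out$mean_density[c0 + 1] <- mean(ch_means[sel, 1])
      out$mean_j[c0 + 1] <- mean(ch_means[sel, 2])
    }
  }
  out
}
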