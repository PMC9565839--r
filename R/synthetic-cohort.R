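# Synthetic paired-CT cohort with known ground truth.
#
# The phantom is not anatomically faithful: it exists so that every downstream
# stage (Jacobian channel, patch clustering, histograms, EFA, subject
# clustering, QCT metrics, deposition) can be tested against planted truth.
# A lung is an ellipsoid pair split into 5 lobes by fixed fractional planes;
# tissue patterns are spatially coherent blobs obtained by quantile-slicing a
# Gaussian-smoothed noise field, so the planted mixture proportions are
# realized almost exactly; the deformation is a single-axis displacement whose
# analytic Jacobian determinant equals the smoothed target field J* by
# construction (I + grad u is triangular with diagonal (1, 1, J*)).

#' Tissue pattern specification
#'
#' One synthetic tissue-pattern class: its CT attenuation distribution, its
#' local EX/IN volume-ratio (Jacobian) distribution, and the spatial scale of
#' its blobs.
#'
#' @param name pattern label.
#' @param mean_hu,sd_hu attenuation mean (in \[-1024, 200\]) and SD, HU.
#' @param mean_j,sd_j Jacobian (EX/IN volume ratio) mean (> 0) and SD.
#' @param blob_scale_mm spatial coherence scale of the pattern blobs, mm.
#' @return object of class `tissue_pattern_spec`.
#' @export
tissue_pattern_spec <- function(name, mean_hu, sd_hu, mean_j, sd_j,
                                blob_scale_mm = 8) {
  stop_if(sd_hu < 0 || sd_j < 0, "pattern '%s': SDs must be >= 0", name)
  stop_if(mean_hu < -1024 || mean_hu > 200,
          "pattern '%s': mean_hu outside [-1024, 200]", name)
  stop_if(mean_j <= 0, "pattern '%s': mean_j must be > 0", name)
  stop_if(blob_scale_mm <= 0, "pattern '%s': blob scale must be > 0", name)
  structure(list(name = name, mean_hu = mean_hu, sd_hu = sd_hu,
                 mean_j = mean_j, sd_j = sd_j, blob_scale_mm = blob_scale_mm),
            class = "tissue_pattern_spec")
}

#' Default synthetic tissue patterns
#'
#' Four pattern classes spanning the physiological corners of the
#' (attenuation, volume-ratio) plane: `normal` parenchyma, `air_trapping`
#' (low attenuation, poor deflation, high J), `hypoinflation` (dense tissue
#' that is no larger at TLC than RV, J > 1: inflammation/fibrosis-like) and
#' `hyperdeflation` (dense at RV, strong volume loss, low J). Attenuations
#' are chosen for separability on the rescaled-density scale; they are
#' generator settings, not literature densitometry.
#'
#' @return named list of [tissue_pattern_spec] objects.
#' @export
default_pattern_specs <- function() {
  list(
    normal        = tissue_pattern_spec("normal",        -889, 40, 0.55, 0.05),
    air_trapping  = tissue_pattern_spec("air_trapping",  -916, 35, 0.77, 0.05),
    hypoinflation = tissue_pattern_spec("hypoinflation", -697, 60, 1.40, 0.08),
    hyperdeflation = tissue_pattern_spec("hyperdeflation", -833, 45, 0.45, 0.05)
  )
}

#' Subject profile
#'
#' Demographics, lung function and the planted pattern mixture of one
#' synthetic subject.
#'
#' @param subject_id,group_id labels.
#' @param pattern_mixture named non-negative proportions over pattern names,
#'   summing to 1.
#' @param exposure 0/1 exposure indicator.
#' @param gender 0/1 (1 = female).
#' @param age years; @param height cm; @param weight kg (> 0).
#' @param fvc_pct,fev1_pct percent-predicted lung function.
#' @return object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, group_id, pattern_mixture, exposure = 0L,
                            gender = 0L, age = 50, height = 165, weight = 65,
                            fvc_pct = 90, fev1_pct = 93) {
  stop_if(is.null(names(pattern_mixture)) || any(names(pattern_mixture) == ""),
          "pattern_mixture must be named")
  stop_if(any(pattern_mixture < 0), "mixture entries must be >= 0")
  stop_if(abs(sum(pattern_mixture) - 1) > 1e-9, "mixture must sum to 1")
  stop_if(weight <= 0, "weight must be > 0")
  structure(list(subject_id = subject_id, group_id = group_id,
                 pattern_mixture = pattern_mixture, exposure = as.integer(exposure),
                 gender = as.integer(gender), age = age, height = height,
                 weight = weight, fvc_pct = fvc_pct, fev1_pct = fev1_pct),
            class = "subject_profile")
}

# ellipsoid indicator on the voxel grid (centers/semis in voxel fractions)
ellipsoid_mask <- function(shape, center_frac, semi_frac) {
  ax <- lapply(1:3, function(i) ((seq_len(shape[i]) - 0.5) / shape[i] -
                                   center_frac[i]) / semi_frac[i])
  g1 <- array(rep(ax[[1]], times = shape[2] * shape[3]), shape)
  g2 <- array(rep(rep(ax[[2]], each = shape[1]), times = shape[3]), shape)
  g3 <- array(rep(ax[[3]], each = shape[1] * shape[2]), shape)
  g1^2 + g2^2 + g3^2 <= 1
}

# left/right ellipsoid lungs, split into 5 lobes by fixed fractional planes
# along the inferior-superior (3rd) axis: left LLL/LUL at 0.5; right
# RLL/RML/RUL at 0.45 and 0.70
lung_phantom_masks <- function(shape) {
  left <- ellipsoid_mask(shape, c(0.30, 0.5, 0.52), c(0.16, 0.30, 0.40))
  right <- ellipsoid_mask(shape, c(0.70, 0.5, 0.52), c(0.16, 0.30, 0.40))
  body <- ellipsoid_mask(shape, c(0.50, 0.5, 0.55), c(0.44, 0.44, 0.47))
  lung <- left | right
  zfrac <- array(rep((seq_len(shape[3]) - 0.5) / shape[3],
                     each = shape[1] * shape[2]), shape)
  zf <- function(m) { # relative height within that lung's z extent
    zr <- range(zfrac[m])
    (zfrac - zr[1]) / max(zr[2] - zr[1], 1e-9)
  }
  lobe <- array(0L, shape)
  tl <- zf(left)
  lobe[left & tl < 0.5] <- 2L                 # LLL
  lobe[left & tl >= 0.5] <- 1L                # LUL
  tr <- zf(right)
  lobe[right & tr < 0.45] <- 5L               # RLL
  lobe[right & tr >= 0.45 & tr < 0.70] <- 4L  # RML
  lobe[right & tr >= 0.70] <- 3L              # RUL
  list(lung = lung, lobe = lobe, body = body)
}

# smooth unit-variance noise field (white noise, Gaussian-smoothed, restandardized)
smooth_noise <- function(shape, sigma_vox) {
  f <- gaussian_smooth3(array(stats::rnorm(prod(shape)), shape), sigma_vox)
  (f - mean(f)) / stats::sd(f)
}

#' Generate one synthetic paired lung scan
#'
#' Builds a paired inspiratory/expiratory phantom realizing the profile's
#' pattern mixture: lung and 5-lobe masks, IN attenuation with spatially
#' coherent per-pattern blobs, a smooth single-axis displacement field whose
#' analytic Jacobian equals the planted (smoothed) target J* exactly, the EX
#' volume obtained by warping the IN column-wise with mass-conserving
#' attenuation change, and the RV attenuation resampled on the TLC frame.
#'
#' @param profile a [subject_profile].
#' @param patterns named list of [tissue_pattern_spec]; must cover the
#'   mixture's names.
#' @param shape voxel grid, all axes >= 32 (default 64^3).
#' @param spacing voxel spacing in mm (default 1 mm isotropic).
#' @param seed integer seed; equal seeds give bit-identical scans.
#' @param j_smooth_vox smoothing (voxels) applied to the target Jacobian
#'   field so the displacement is smooth.
#' @return object of class `lung_scan` with fields `in_volume`, `ex_volume`,
#'   `ex_warped` (RV HU on the TLC frame), `lung_mask`, `ex_lung_mask`,
#'   `lobe_mask`, `displacement`, `spacing`, `subject_id`, and ground-truth
#'   fields `pattern_labels` (0 = outside lung) and `target_j`.
#' @export
generate_subject <- function(profile, patterns = default_pattern_specs(),
                             shape = c(64, 64, 64), spacing = c(1, 1, 1),
                             seed = 1, j_smooth_vox = 1.5) {
  stopifnot(inherits(profile, "subject_profile"))
  shape <- as.integer(shape)
  stop_if(length(shape) != 3L || any(shape < 32L), "shape must be >= 32 per axis")
  spacing <- check_spacing(spacing)
  mix <- profile$pattern_mixture
  stop_if(!all(names(mix) %in% names(patterns)),
          "mixture references undefined patterns: %s",
          paste(setdiff(names(mix), names(patterns)), collapse = ", "))
  stop_if(abs(sum(mix) - 1) > 1e-9, "mixture not normalized")
  patterns <- patterns[names(mix)]

  set.seed(as.integer(seed))
  masks <- lung_phantom_masks(shape)
  lung <- masks$lung
  nlung <- sum(lung)
  blob_sigma <- mean(vapply(patterns, `[[`, 0, "blob_scale_mm")) / spacing
  stop_if(min(shape * spacing) < 4 * mean(blob_sigma * spacing),
          "grid too small to host pattern blobs")

  # spatially coherent partition with (near-)exact mixture proportions:
  # quantile-slice one smooth field
  field <- smooth_noise(shape, blob_sigma)
  labels <- array(0L, shape)
  fl <- field[lung]
  qs <- stats::quantile(fl, probs = cumsum(mix), names = FALSE, type = 7)
  lab <- findInterval(fl, c(-Inf, qs[-length(qs)]), left.open = FALSE)
  labels[lung] <- lab

  mean_hu <- vapply(patterns, `[[`, 0, "mean_hu")
  sd_hu <- vapply(patterns, `[[`, 0, "sd_hu")
  mean_j <- vapply(patterns, `[[`, 0, "mean_j")
  sd_j <- vapply(patterns, `[[`, 0, "sd_j")

  hu_noise <- smooth_noise(shape, 1.2)
  in_vol <- array(-1000, shape)
  in_vol[masks$body & !lung] <- 40                 # soft-tissue rim
  in_vol[lung] <- mean_hu[lab] + sd_hu[lab] * hu_noise[lung]
  in_vol <- pmin(pmax(in_vol, -1024), 200)

  # smooth target Jacobian field: normalized (mask-weighted) convolution so
  # the smoothing never blends the outside-lung value (1) into lung voxels,
  # then a smoothstep blend to 1 beyond the lung surface
  j_noise <- smooth_noise(shape, 2)
  jraw <- array(0, shape)
  jraw[lung] <- pmax(mean_j[lab] + sd_j[lab] * j_noise[lung], 0.05)
  m <- lung + 0
  ms <- gaussian_smooth3(m, j_smooth_vox)
  jn <- gaussian_smooth3(jraw, j_smooth_vox) / pmax(ms, 1e-6)
  wb <- pmin(1, pmax(0, (ms - 0.15) / 0.35))
  jt <- wb * jn + (1 - wb)
  jt <- pmax(jt, 0.05)

  # single-axis displacement: u_z(x, y, z) = integral_0^z (J*(x,y,t) - 1) dt,
  # midpoint rule at voxel centers; analytic det(I + grad u) = J* exactly
  dz <- spacing[3]
  w <- apply(jt - 1, c(1, 2), function(col) cumsum(col) - col / 2) * dz
  w <- aperm(w, c(2, 3, 1))                        # apply() puts z first
  displacement <- array(0, c(shape, 3L))
  displacement[, , , 3] <- w

  # mass-conserving attenuation at RV, on the TLC frame
  ex_warped <- array(-1000, shape)
  ex_warped[lung] <- -1000 + (in_vol[lung] + 1000) / jt[lung]
  ex_warped <- pmin(pmax(ex_warped, -1024), 200)
  ex_warped[!lung] <- in_vol[!lung]

  # EX image on its own grid: columns are warped z -> z + w(z), inverted by
  # monotone interpolation (J* > 0 guarantees monotonicity)
  z_mm <- (seq_len(shape[3]) - 0.5) * dz
  ex_vol <- array(-1000, shape)
  ex_mask <- array(FALSE, shape)
  for (i in seq_len(shape[1])) for (j in seq_len(shape[2])) {
    wcol <- w[i, j, ]
    if (all(wcol == 0)) {
      ex_vol[i, j, ] <- in_vol[i, j, ]
      ex_mask[i, j, ] <- lung[i, j, ]
      next
    }
    zin <- stats::approx(z_mm + wcol, z_mm, xout = z_mm, rule = 2)$y
    k <- pmin(pmax(round(zin / dz + 0.5), 1L), shape[3])
    ex_vol[i, j, ] <- ex_warped[i, j, ][k]
    ex_mask[i, j, ] <- lung[i, j, ][k] &
      z_mm >= (z_mm + wcol)[1] & z_mm <= (z_mm + wcol)[shape[3]]
  }

  structure(list(in_volume = in_vol, ex_volume = ex_vol, ex_warped = ex_warped,
                 lung_mask = lung, ex_lung_mask = ex_mask, lobe_mask = masks$lobe,
                 displacement = displacement, spacing = spacing,
                 subject_id = profile$subject_id, profile = profile,
                 pattern_labels = labels, pattern_names = names(mix),
                 target_j = jt),
            class = "lung_scan")
}

#' @export
print.lung_scan <- function(x, ...) {
  d <- dim(x$in_volume)
  cat(sprintf("lung_scan '%s': %d x %d x %d @ %s mm, lung %.0f mL\n",
              x$subject_id %||% "?", d[1], d[2], d[3],
              paste(signif(x$spacing, 3), collapse = "x"),
              mask_volume_ml(x$lung_mask, x$spacing)))
  invisible(x)
}

#' Default group mixtures for a two-group synthetic cohort
#'
#' The exposure-like group is shifted towards the dense, poorly deflating
#' patterns (hypoinflation/hyperdeflation); the control-like group is
#' dominated by normal parenchyma with some air trapping. The separation is
#' deliberately strong: these are the planted study conditions for
#' end-to-end recovery tests.
#'
#' @return named list of named mixture vectors.
#' @export
default_group_mixtures <- function() {
  list(
    exposed = c(normal = 0.35, air_trapping = 0.15, hypoinflation = 0.30,
                hyperdeflation = 0.20),
    control = c(normal = 0.60, air_trapping = 0.25, hypoinflation = 0.05,
                hyperdeflation = 0.10)
  )
}

#' Generate a synthetic cohort
#'
#' Subjects are drawn per group; groups differ through their pattern mixtures
#' (plus per-subject logistic-normal mixture jitter) and configurable
#' covariate shifts (gender proportion, mean height). All randomness descends
#' from `seed`.
#'
#' @param n_per_group named integer vector, subjects per group (>= 1 each, at
#'   least 2 groups).
#' @param group_mixtures named list (same names) of mixture vectors.
#' @param patterns named list of [tissue_pattern_spec].
#' @param shape,spacing image grid passed to [generate_subject].
#' @param seed integer master seed.
#' @param mixture_jitter SD of per-subject log-ratio jitter on the mixture.
#' @param gender_prob named per-group probability that a subject is female.
#' @param height_shift named per-group additive shift of mean height (cm).
#' @param airway_scale named per-group multiplicative scale on airway calibre.
#' @return list with `subjects` (list of per-subject lists: `profile`,
#'   `scan`, `tree`) and `metadata` (one row per subject).
#' @export
generate_cohort <- function(n_per_group, group_mixtures = default_group_mixtures(),
                            patterns = default_pattern_specs(),
                            shape = c(64, 64, 64), spacing = c(1, 1, 1), seed = 1,
                            mixture_jitter = 0.15,
                            gender_prob = NULL, height_shift = NULL,
                            airway_scale = NULL) {
  stop_if(length(n_per_group) < 2, "need at least 2 groups")
  stop_if(is.null(names(n_per_group)), "n_per_group must be named")
  stop_if(any(n_per_group < 1), "empty group requested")
  stop_if(!setequal(names(n_per_group), names(group_mixtures)),
          "groups of n_per_group and group_mixtures differ")
  groups <- names(n_per_group)
  defaults <- function(x, value) {
    if (is.null(x)) stats::setNames(rep(value, length(groups)), groups) else x
  }
  gender_prob <- defaults(gender_prob, 0.5)
  height_shift <- defaults(height_shift, 0)
  airway_scale <- defaults(airway_scale, 1)

  subjects <- list()
  rows <- list()
  idx <- 0L
  for (g in groups) {
    for (r in seq_len(n_per_group[[g]])) {
      idx <- idx + 1L
      sseed <- child_seed(seed, idx)
      set.seed(sseed)
      mix <- group_mixtures[[g]]
      if (mixture_jitter > 0) {
        mix <- mix * exp(stats::rnorm(length(mix), 0, mixture_jitter))
        mix <- mix / sum(mix)
      }
      gender <- stats::rbinom(1, 1, gender_prob[[g]])
      height <- stats::rnorm(1, (if (gender == 1) 160 else 172) + height_shift[[g]], 6)
      bmi <- stats::rnorm(1, 23.7, 3)
      weight <- max(35, bmi * (height / 100)^2)
      profile <- subject_profile(
        subject_id = sprintf("S%03d", idx), group_id = g,
        pattern_mixture = mix,
        exposure = as.integer(g == groups[1]), gender = gender,
        age = round(stats::rnorm(1, 49, 14)), height = height, weight = weight,
        fvc_pct = stats::rnorm(1, 90, 15), fev1_pct = stats::rnorm(1, 93, 18))
      scan <- generate_subject(profile, patterns, shape, spacing,
                               seed = child_seed(sseed, 1))
      tree <- generate_airway_tree(
        n_generations = 6,
        root_diameter = 11 * (height / 165) * airway_scale[[g]],
        reduction_ratio = 0.78, asymmetry = 0.1,
        seed = child_seed(sseed, 2))
      subjects[[idx]] <- list(profile = profile, scan = scan, tree = tree)
      rows[[idx]] <- data.frame(
        subject_id = profile$subject_id, group_id = g,
        exposure = profile$exposure, gender = gender,
        age = profile$age, height = height, weight = weight,
        bmi = weight / (height / 100)^2,
        fvc_pct = profile$fvc_pct, fev1_pct = profile$fev1_pct,
        stringsAsFactors = FALSE)
    }
  }
  list(subjects = subjects, metadata = do.call(rbind, rows))
}

#' Generate a binary-branching airway tree
#'
#' A rooted binary tree with `n_generations` levels (generation 0 is the
#' trachea). Child diameters are `parent * reduction_ratio * (1 +/- asymmetry/2)`;
#' branch length is 3 diameters; lumens are circular. With enough levels the
#' five lobar bronchi are labelled on the anatomical layout (LUL/LLL off the
#' left main bronchus; RUL and the bronchus intermedius off the right main
#' bronchus; RML/RLL off the intermedius); their descendants inherit the lobe
#' label and the child + grandchild branches of a lobar bronchus form its
#' sub-lobar subset. `jitter` adds per-branch lognormal geometry noise
#' (default 0: fully deterministic given the arguments).
#'
#' @param n_generations number of levels, >= 3.
#' @param root_diameter trachea diameter, mm.
#' @param reduction_ratio per-generation diameter factor in (0, 1).
#' @param asymmetry sibling diameter imbalance in \[0, 1).
#' @param seed integer seed (used when `jitter > 0`).
#' @param jitter SD of lognormal geometry jitter.
#' @return an [airway_tree].
#' @export
generate_airway_tree <- function(n_generations, root_diameter = 12,
                                 reduction_ratio = 0.8, asymmetry = 0,
                                 seed = 1, jitter = 0) {
  stop_if(n_generations < 3, "need n_generations >= 3")
  stop_if(reduction_ratio <= 0 || reduction_ratio >= 1,
          "reduction_ratio must be in (0, 1): tree would not converge")
  stop_if(asymmetry < 0 || asymmetry >= 1, "asymmetry must be in [0, 1)")
  set.seed(as.integer(seed))
  rows <- list(list(id = "b1", parent = NA_character_, d = root_diameter,
                    generation = 0L, lobe = "central", side = ""))
  frontier <- 1L
  nid <- 1L
  for (gen in seq_len(n_generations - 1L)) {
    nxt <- integer(0)
    for (fi in frontier) {
      p <- rows[[fi]]
      for (side in 1:2) {
        nid <- nid + 1L
        fac <- reduction_ratio * (1 + (if (side == 1) 1 else -1) * asymmetry / 2)
        d <- p$d * fac
        if (jitter > 0) d <- d * exp(stats::rnorm(1, 0, jitter))
        lobe <- inherit_lobe(p, gen, side)
        rows[[nid]] <- list(id = paste0("b", nid), parent = p$id, d = d,
                            generation = gen, lobe = lobe,
                            side = paste0(p$side, side))
        nxt <- c(nxt, nid)
      }
    }
    frontier <- nxt
  }
  b <- do.call(rbind, lapply(rows, function(r) {
    data.frame(id = r$id, parent = r$parent, length_mm = 3 * r$d,
               area_mm2 = pi * r$d^2 / 4, perimeter_mm = pi * r$d,
               generation = r$generation, lobe = r$lobe,
               stringsAsFactors = FALSE)
  }))
  airway_tree(b)
}

# anatomical lobe labelling on the binary layout: side string encodes the
# path of 1/2 choices from the root
inherit_lobe <- function(parent, gen, side) {
  if (parent$lobe != "central") return(parent$lobe)
  path <- paste0(parent$side, side)
  switch(path,
         "11" = "LUL", "12" = "LLL",       # off the left main bronchus
         "21" = "RUL",                     # off the right main bronchus
         "221" = "RML", "222" = "RLL",     # off the bronchus intermedius
         "central")
}

#' Lobar and sub-lobar branch subsets
#'
#' The lobar branch of a lobe is its first labelled branch; the sub-lobar
#' subset contains its child and grandchild branches.
#'
#' @param tree an [airway_tree].
#' @return list per lobe: `lobar` id and `sublobar` ids.
#' @export
lobar_subsets <- function(tree) {
  b <- tree$branches
  out <- list()
  for (lb in intersect(c("LUL", "LLL", "RUL", "RML", "RLL"), unique(b$lobe))) {
    ids <- b$id[b$lobe == lb]
    lobar <- ids[which.min(b$generation[b$lobe == lb])]
    kids <- b$id[!is.na(b$parent) & b$parent == lobar]
    grandkids <- b$id[!is.na(b$parent) & b$parent %in% kids]
    out[[lb]] <- list(lobar = lobar, sublobar = c(kids, grandkids))
  }
  out
}

#' Write cohort metadata to CSV
#'
#' @param cohort result of [generate_cohort].
#' @param path output CSV path.
#' @export
write_cohort_metadata <- function(cohort, path) {
  utils::write.csv(cohort$metadata, path, row.names = FALSE)
  invisible(path)
}
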