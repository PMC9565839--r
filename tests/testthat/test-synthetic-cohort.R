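test_that("pattern and profile constructors validate their invariants", {
  expect_error(tissue_pattern_spec("x", -2000, 10, 1, 0), "mean_hu")
  expect_error(tissue_pattern_spec("x", -800, -1, 1, 0), "SDs")
  expect_error(tissue_pattern_spec("x", -800, 10, 0, 0), "mean_j")
  expect_error(subject_profile("s", "g", c(a = 0.5, b = 0.4)), "sum to 1")
  expect_error(subject_profile("s", "g", c(a = 1), weight = 0), "weight")
})

test_that("generate_subject realizes the planted pattern statistics", {
  p <- subject_profile("s1", "g", c(normal = 1))
  sc <- generate_subject(p, seed = 7)
  spec <- default_pattern_specs()$normal
  # single-pattern lung: mean HU within 15 HU of the planted mean
  expect_lt(abs(mean(sc$in_volume[sc$lung_mask]) - spec$mean_hu), 15)
  # masks nest and lobes partition the lung
  expect_true(all(sc$lobe_mask[!sc$lung_mask] == 0))
  expect_true(all(sc$lobe_mask[sc$lung_mask] %in% 1:5))
  expect_setequal(unique(as.vector(sc$lobe_mask[sc$lung_mask])), 1:5)
})

test_that("same profile and seed give bit-identical volumes", {
  p <- subject_profile("s1", "g", c(normal = 0.6, air_trapping = 0.4))
  a <- generate_subject(p, shape = c(32, 32, 32), seed = 11)
  b <- generate_subject(p, shape = c(32, 32, 32), seed = 11)
  expect_identical(a$in_volume, b$in_volume)
  expect_identical(a$ex_volume, b$ex_volume)
  expect_identical(a$displacement, b$displacement)
})

test_that("mixture proportions are realized and blobs are coherent", {
  mix <- c(normal = 0.4, air_trapping = 0.2, hypoinflation = 0.2,
           hyperdeflation = 0.2)
  sc <- generate_subject(subject_profile("s2", "g", mix), seed = 3)
  lab <- sc$pattern_labels[sc$lung_mask]
  realized <- tabulate(lab, 4) / length(lab)
  expect_true(all(abs(realized - mix) <= 0.05))
})

test_that("finite-difference Jacobian matches planted per-blob means in blob interiors", {
  mix <- c(normal = 0.4, air_trapping = 0.2, hypoinflation = 0.2,
           hyperdeflation = 0.2)
  sc <- generate_subject(subject_profile("s3", "g", mix), seed = 3)
  J <- jacobian_determinant(sc$displacement, sc$spacing)
  planted <- vapply(default_pattern_specs()[names(mix)], `[[`, 0, "mean_j")
  checked <- 0L
  for (k in seq_along(mix)) {
    ind <- (sc$pattern_labels == k) + 0
    # interior: voxels away from the blob boundary by the smoothing radius;
    # agreement is smoothness-limited, so thin blobs without an interior are
    # not informative
    interior <- hdlungct:::gaussian_smooth3(ind, 2.5) > 0.85 & sc$pattern_labels == k
    if (sum(interior) < 100) next
    checked <- checked + 1L
    expect_lt(abs(mean(J[interior]) - planted[k]) / planted[k], 0.05)
  }
  expect_gte(checked, 2)

  # a 50/50 two-pattern subject has large blobs for both patterns
  mix2 <- c(normal = 0.5, hypoinflation = 0.5)
  sc2 <- generate_subject(subject_profile("s3b", "g", mix2), seed = 5)
  J2 <- jacobian_determinant(sc2$displacement, sc2$spacing)
  planted2 <- vapply(default_pattern_specs()[names(mix2)], `[[`, 0, "mean_j")
  for (k in 1:2) {
    ind <- (sc2$pattern_labels == k) + 0
    interior <- hdlungct:::gaussian_smooth3(ind, 2.5) > 0.85 & sc2$pattern_labels == k
    expect_gt(sum(interior), 100)
    expect_lt(abs(mean(J2[interior]) - planted2[k]) / planted2[k], 0.05)
  }
})

test_that("zero-displacement configuration gives J identically 1 in the lung", {
  patterns <- list(static = tissue_pattern_spec("static", -880, 30, 1, 0))
  sc <- generate_subject(subject_profile("s4", "g", c(static = 1)),
                         patterns, shape = c(32, 32, 32), seed = 2)
  J <- jacobian_determinant(sc$displacement, sc$spacing)
  expect_lt(max(abs(J[sc$lung_mask] - 1)), 1e-9)
})

test_that("a planted global contraction yields the matching RV/TLC", {
  patterns <- list(c216 = tissue_pattern_spec("c216", -880, 20, 0.216, 0))
  sc <- generate_subject(subject_profile("s5", "g", c(c216 = 1)),
                         patterns, seed = 9, j_smooth_vox = 1)
  rec <- qct_record(sc)
  expect_lt(abs(rec$RV_TLC - 0.216), 0.03)  # mask-discretization error
})

test_that("generate_cohort enforces groups and counts and is reproducible", {
  expect_error(generate_cohort(c(A = 3), list(A = c(normal = 1))), "2 groups")
  expect_error(generate_cohort(c(A = 0, B = 2),
                               list(A = c(normal = 1), B = c(normal = 1))),
               "empty group")
  expect_error(generate_cohort(c(A = 2), default_group_mixtures()), "2 groups")

  mixes <- list(A = c(normal = 0.7, air_trapping = 0.3),
                B = c(normal = 0.3, air_trapping = 0.7))
  coh <- generate_cohort(c(A = 3, B = 4), mixes, shape = c(32, 32, 32), seed = 2)
  expect_equal(nrow(coh$metadata), 7)
  expect_equal(sum(coh$metadata$group_id == "A"), 3)
  coh2 <- generate_cohort(c(A = 3, B = 4), mixes, shape = c(32, 32, 32), seed = 2)
  expect_identical(coh$metadata, coh2$metadata)
  expect_identical(coh$subjects[[5]]$scan$in_volume,
                   coh2$subjects[[5]]$scan$in_volume)
})

test_that("generate_airway_tree builds the documented geometry", {
  expect_error(generate_airway_tree(3, reduction_ratio = 1.1), "converge")
  expect_error(generate_airway_tree(2), "n_generations")

  tr <- generate_airway_tree(3, root_diameter = 12, reduction_ratio = 0.8)
  expect_equal(nrow(tr$branches), 7)     # 1 + 2 + 4
  g2 <- tr$branches[tr$branches$generation == 2, ]
  d2 <- hydraulic_diameter(g2$area_mm2, g2$perimeter_mm)
  expect_equal(unique(round(d2, 10)), 12 * 0.8^2)  # asymmetry 0: all equal

  # asymmetry splits sibling diameters symmetrically around the ratio
  tra <- generate_airway_tree(3, 12, 0.8, asymmetry = 0.2)
  g1 <- tra$branches[tra$branches$generation == 1, ]
  d1 <- sort(hydraulic_diameter(g1$area_mm2, g1$perimeter_mm))
  expect_equal(d1, 12 * 0.8 * c(1 - 0.1, 1 + 0.1))

  # full anatomical labelling needs 4 levels
  tr4 <- generate_airway_tree(4, 12, 0.8)
  expect_setequal(setdiff(unique(tr4$branches$lobe), "central"),
                  c("LUL", "LLL", "RUL", "RML", "RLL"))
  subs <- lobar_subsets(tr4)
  expect_named(subs, c("LUL", "LLL", "RUL", "RML", "RLL"), ignore.order = TRUE)
  # children + grandchildren of a lobar branch (here only children exist)
  expect_length(subs$LUL$sublobar, 2)
})
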