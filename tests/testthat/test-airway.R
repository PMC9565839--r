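test_that("hydraulic diameter matches circle, square, and plain arithmetic", {
  D <- 7
  expect_equal(hydraulic_diameter(pi * D^2 / 4, pi * D), D)
  a <- 3
  expect_equal(hydraulic_diameter(a^2, 4 * a), a)
  expect_equal(hydraulic_diameter(3, 8), 1.5)
  expect_error(hydraulic_diameter(0, 5), "positive")
})

test_that("breathing waveform integrates to the tidal volume", {
  wf <- breathing_waveform(60)
  expect_equal(wf$tidal_volume_ml, 420)
  wf70 <- breathing_waveform(70)
  expect_equal(wf70$peak_flow_mls, pi * 490 / (2 * 2.4), tolerance = 1e-12)
  q <- integrate(wf70$flow, 0, wf70$t_insp_s, rel.tol = 1e-8)$value
  expect_lt(abs(q - wf70$tidal_volume_ml) / wf70$tidal_volume_ml, 0.001)
  expect_equal(wf70$flow(wf70$time_to_peak_s), wf70$peak_flow_mls)
  expect_error(breathing_waveform(-5), "positive")
})

test_that("Poiseuille pressure drops scale as Dh^-4 and respect symmetry", {
  tr <- generate_airway_tree(4, 12, 0.8)
  dp <- pressure_drop(tr, 300)
  # two identical siblings under symmetric split: equal drops
  sibs <- tr$branches$id[tr$branches$generation == 1]
  expect_equal(dp$dp_pa[dp$id == sibs[1]], dp$dp_pa[dp$id == sibs[2]])
  # uniformly scaled clone (all diameters x0.9): every path drop x 0.9^-4
  tr2 <- tr
  tr2$branches$area_mm2 <- tr$branches$area_mm2 * 0.9^2
  tr2$branches$perimeter_mm <- tr$branches$perimeter_mm * 0.9
  dp2 <- pressure_drop(tr2, 300)
  expect_equal(dp2$path_dp_pa / dp$path_dp_pa, rep(0.9^-4, nrow(dp)),
               tolerance = 1e-12)
  # halving Dh at fixed flow multiplies the branch drop by 16
  tr3 <- tr
  tr3$branches$area_mm2 <- tr$branches$area_mm2 / 4
  tr3$branches$perimeter_mm <- tr$branches$perimeter_mm / 2
  dp3 <- pressure_drop(tr3, 300)
  expect_equal(dp3$dp_pa / dp$dp_pa, rep(16, nrow(dp)), tolerance = 1e-12)
  # resistance strictly decreases with Dh at fixed geometry
  expect_true(all(dp3$resistance_pa_s_ml > dp$resistance_pa_s_ml))
})

test_that("deposition is conservative and vanishes with all mechanisms off", {
  tr <- generate_airway_tree(6, 12, 0.78, asymmetry = 0.1)
  wf <- breathing_waveform(65)
  dep <- deposition_1d(tr, wf)
  expect_equal(sum(dep$branches$df) + dep$escape, 1, tolerance = 1e-9)
  expect_true(all(dep$branches$df >= 0))
  expect_true(all(dep$branches$efficiency >= 0 & dep$branches$efficiency <= 1))
  # parent entering = own deposition + children entering (exact bookkeeping)
  b <- dep$branches
  for (id in b$id) {
    kids <- tr$branches$id[!is.na(tr$branches$parent) & tr$branches$parent == id]
    if (length(kids)) {
      expect_equal(b$entering[b$id == id] - b$df[b$id == id],
                   sum(b$entering[b$id %in% kids]), tolerance = 1e-12)
    }
  }
  # no mechanisms: everything escapes
  none <- deposition_1d(tr, wf, mechanisms = character(0))
  expect_equal(none$total_df, 0, tolerance = 1e-12)
  expect_equal(none$escape, 1, tolerance = 1e-12)
})

test_that("sedimentation efficiency matches the particle-tracking oracle within 2%", {
  # a single horizontal tube, gravity perpendicular, sedimentation only
  part <- particle_mechanics(0.5, 1)
  radius_mm <- 0.5; length_mm <- 120
  ubar <- 0.004                                   # m/s: moderate settling number
  flow_mls <- ubar * pi * (radius_mm * 1e-3)^2 * 1e6
  eta <- branch_efficiencies(length_mm, 2 * radius_mm, flow_mls, part,
                             gravity_angle_rad = 0, is_root = TRUE)
  # oracle: 1e5 tracked particles in Poiseuille flow
  mc <- mc_tube_sedimentation(radius_mm * 1e-3, length_mm * 1e-3, ubar,
                              part$settling_mps, n = 1e5, seed = 42)
  expect_gt(eta$sedimentation, 0.05)  # the regime actually exercises settling
  expect_lt(abs(eta$sedimentation - mc), 0.02)
  expect_equal(eta$impaction, 0)       # root branch: no upstream bifurcation
})

test_that("efficiencies rise with residence time and narrowing increases total DF", {
  part <- particle_mechanics(0.5, 1)
  lens <- c(10, 20, 40, 80)
  eta_s <- vapply(lens, function(L)
    branch_efficiencies(L, 2, 10, part, gravity_angle_rad = 0)$sedimentation, 0)
  eta_d <- vapply(lens, function(L)
    branch_efficiencies(L, 2, 10, part)$diffusion, 0)
  expect_true(all(diff(eta_s) > 0))
  expect_true(all(diff(eta_d) > 0))

  tr <- generate_airway_tree(6, 12, 0.78)
  wf <- breathing_waveform(65)
  base <- deposition_1d(tr, wf)$total_df
  tr2 <- tr
  tr2$branches$area_mm2 <- tr$branches$area_mm2 * 0.8^2
  tr2$branches$perimeter_mm <- tr$branches$perimeter_mm * 0.8
  narrowed <- deposition_1d(tr2, wf)$total_df
  expect_gte(narrowed, base)
})

test_that("airway trees validate structure and round-trip through CSV and JSON", {
  tr <- generate_airway_tree(4, 12, 0.8, asymmetry = 0.1)
  csv <- tempfile(fileext = ".csv"); json <- tempfile(fileext = ".json")
  write_airway_tree(tr, csv)
  write_airway_tree(tr, json)
  rt_csv <- read_airway_tree(csv)
  rt_json <- read_airway_tree(json)
  for (rt in list(rt_csv, rt_json)) {
    expect_equal(rt$branches$area_mm2, tr$branches$area_mm2, tolerance = 1e-9)
    expect_identical(rt$branches$lobe, tr$branches$lobe)
  }
  bad <- tr$branches; bad$parent[1] <- bad$id[5]  # two roots gone, cycle risk
  expect_error(airway_tree(bad), "root")
  tri <- tr$branches
  tri$parent[tri$id == "b2"] <- "b2"
  expect_error(airway_tree(tri), "cycle|root|disconnected|children")
})
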