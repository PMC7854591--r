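test_that("pore decomposition of hand-built solids matches voxel counting", {
  # solid cube: convex, no pores
  cube <- cube_mask(10)
  dec <- decompose_pores(cube)
  expect_equal(sum(dec$hull), 1000)
  expect_equal(sum(dec$closed_pores), 0)
  expect_equal(sum(dec$open_pores), 0)
  expect_equal(porosity(sum(cube), sum(dec$hull)), 0)

  # 10^3 cube with interior 4^3 cavity
  hollow <- cube_mask(10)
  hollow[6:9, 6:9, 6:9] <- FALSE
  dec2 <- decompose_pores(hollow)
  expect_equal(sum(dec2$closed_pores), 64)
  expect_equal(sum(dec2$open_pores), 0)
  expect_equal(porosity(sum(hollow), sum(dec2$hull)), 0.064)

  # 10^3 cube with a 2x2 through-channel (40 voxels)
  chan <- cube_mask(10)
  chan[7:8, 7:8, ] <- FALSE
  dec3 <- decompose_pores(chan)
  expect_equal(sum(chan), 960)
  expect_equal(sum(dec3$closed_pores), 0)
  expect_equal(sum(dec3$open_pores), 40)
})

test_that("decomposition preconditions are enforced", {
  expect_error(decompose_pores(array(FALSE, c(5, 5, 5))), "empty")
  touching <- array(FALSE, c(6, 6, 6))
  touching[1:3, 2:4, 2:4] <- TRUE
  expect_error(decompose_pores(touching), "border")
})

test_that("porosity guards its domain", {
  expect_equal(porosity(936, 1000), 0.064)
  expect_equal(porosity(50, 50), 0)
  expect_error(porosity(10, 0), "positive")
  expect_error(porosity(20, 10), "exceeds")
  expect_error(porosity(0, 10), "degenerate")
})

test_that("equivalent diameter and principal axes match analytic shapes", {
  # 1000-voxel solid at 2 um voxels
  bm <- basic_morphometrics(cube_mask(10), NULL, 2, "bead")
  expect_equal(bm$volume_um3, 8000)
  expect_equal(bm$equivalent_diameter_um, (6 * 8000 / pi)^(1 / 3),
               tolerance = 1e-12)

  # digitized ellipsoid with semi-axes (30, 20, 10) voxels
  ell <- ellipsoid_mask(c(30, 20, 10))
  bme <- basic_morphometrics(ell, NULL, 1, "bead")
  expect_true(all(abs(bme$principal_axes_um - c(60, 40, 20)) /
                  c(60, 40, 20) <= 0.03))

  # sphere: the three axes agree within 2%
  bms <- basic_morphometrics(ball_mask(12), NULL, 1, "bead")
  expect_lt(diff(range(bms$principal_axes_um)) /
            mean(bms$principal_axes_um), 0.02)

  # digitized spheres: equivalent diameter within 1 voxel of 2R
  for (r in c(10, 14, 20)) {
    bmr <- basic_morphometrics(ball_mask(r), NULL, 1, "bead")
    expect_lt(abs(bmr$equivalent_diameter_um - 2 * r), 1)
  }
})

test_that("Crofton surface areas track analytic values and units", {
  sph <- ball_mask(20)
  expect_equal(crofton_surface_area(sph, 1), 4 * pi * 400,
               tolerance = 0.05)
  # cubes are the estimator's worst case (all faces axis-aligned); the
  # classical 13-direction weights settle near -8% as the edge grows
  expect_equal(crofton_surface_area(cube_mask(24), 1), 6 * 24^2,
               tolerance = 0.10)
  expect_equal(crofton_surface_area(sph, 2),
               4 * crofton_surface_area(sph, 1))
  expect_error(crofton_surface_area(array(FALSE, c(4, 4, 4)), 1), "empty")
})

test_that("probe radii map to the standard cell sizes", {
  radii <- c(2, 3, 4, 10, 15, 20, 25, 38, 50, Inf)
  expect_equal(cell_size_um(radii, 2),
               c(4, 6, 8, 20, 30, 40, 50, 76, 100, Inf))
  expect_equal(cell_size_um(50, 2), 100)
})

test_that("accessible-surface profiles behave like alpha shapes", {
  # solid sphere: any probe radius sees about the convex area
  sph <- ball_mask(14)
  prof <- alpha_surface_profile(sph, c(2, 4, Inf), 1)
  expect_true(all(abs(prof - prof[["Inf"]]) / prof[["Inf"]] <= 0.10))

  # sphere with a radius-3 channel: a radius-2 probe reaches the channel
  # walls, so the accessible area beats the convex limit
  chan <- tunneled_ball(14, 3, pad = 4L)
  prof2 <- alpha_surface_profile(chan, c(2, 5, Inf), 1)
  expect_gt(prof2[[1]], prof2[["Inf"]])
  # and a radius-5 probe cannot enter: channel sealed, near-convex area
  expect_lt(prof2[[2]], prof2[[1]])

  # the infinite-probe limit agrees with Crofton on the hull image
  dec <- decompose_pores(chan)
  expect_equal(prof2[["Inf"]], crofton_surface_area(dec$hull, 1),
               tolerance = 0.10)
})

test_that("profiles are monotone non-increasing on phantom beads", {
  sp <- porous_pack_spec(shape = c(120, 120, 120), n_beads = 3, seed = 37)
  ph <- gen_porous_bead_pack(sp)
  for (i in 1:3) {
    m <- beadct:::crop_mask(ph$truth$label_volume$data == i, 2L)
    prof <- alpha_surface_profile(m, c(2, 3, 4, 10, Inf), 2)
    expect_true(all(diff(prof) <= 1e-9 * prof[1]))
  }
})

test_that("per-bead records satisfy conservation and carry the schema", {
  sp <- porous_pack_spec(shape = c(140, 140, 140), n_beads = 6, seed = 3)
  ph <- gen_porous_bead_pack(sp)
  rec <- bead_morphometrics(ph$truth$label_volume, "porous")
  expect_equal(nrow(rec), 6L)
  expect_equal(rec$convex_hull_volume_um3,
               rec$bead_volume_um3 + rec$open_pore_volume_um3 +
               rec$closed_pore_volume_um3)
  expect_true(all(rec$porosity >= 0 & rec$porosity < 1))
  expect_true(all(rec$principal_axis_1_um >= rec$principal_axis_2_um &
                  rec$principal_axis_2_um >= rec$principal_axis_3_um))
})
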