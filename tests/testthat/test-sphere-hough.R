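test_that("a bead-free scene yields an empty fit list", {
  sp <- phantom_spec(c(96, 96, 96), n_beads = 0, radius_range = c(10, 20),
                     noise_sigma = 8, seed = 2)
  ph <- gen_sphere_pack(sp)
  fits <- detect_spheres(ph$volume, hough_params(16, 44))
  expect_equal(nrow(fits), 0L)
})

test_that("five packed spheres are recovered with sub-voxel accuracy", {
  sp <- phantom_spec(c(128, 128, 128), n_beads = 5,
                     radius_range = c(20, 40), min_gap = 4, seed = 7)
  ph <- gen_sphere_pack(sp)
  fits <- detect_spheres(ph$volume, hough_params(16, 44))
  expect_equal(nrow(fits), 5L)
  m <- match_sphere_fits(fits, ph$truth)
  expect_setequal(m[, "truth_id"], 1:5)     # one fit per truth sphere
  expect_true(all(m[, "center_err_vox"] <= 2))
  expect_true(all(m[, "radius_err_vox"] <= 1))
})

test_that("a single known sphere is found within the radius step", {
  sp <- phantom_spec(c(96, 96, 96), n_beads = 1, radius_range = c(30, 30),
                     seed = 19)
  ph <- gen_sphere_pack(sp)
  fits <- detect_spheres(ph$volume, hough_params(16, 44, radius_step = 2))
  expect_equal(nrow(fits), 1L)
  expect_lte(abs(fits$radius_um - 30), 2)
})

test_that("detected sphere volumes agree with truth voxel counts", {
  sp <- phantom_spec(c(128, 128, 128), n_beads = 4,
                     radius_range = c(24, 40), min_gap = 4, seed = 23)
  ph <- gen_sphere_pack(sp)
  fits <- detect_spheres(ph$volume, hough_params(16, 44))
  m <- match_sphere_fits(fits, ph$truth)
  h3 <- ph$volume$voxel_size^3
  for (i in seq_len(nrow(fits))) {
    v_true <- ph$truth$table$volume_vox[m[i, "truth_id"]] * h3
    expect_equal(fits$volume_um3[i], v_true, tolerance = 0.05)
  }
})

test_that("sphere metrics evaluate the closed forms", {
  um <- sphere_metrics(1)
  expect_equal(um$surface_area, 4 * pi)
  expect_equal(um$volume, 4 * pi / 3)
  m100 <- sphere_metrics(100)
  expect_equal(m100$surface_area, 125663.706, tolerance = 1e-6)
  expect_equal(m100$volume, 4.1887902e6, tolerance = 1e-6)
  for (r in c(0.5, 7, 84.25)) {
    m <- sphere_metrics(r)
    expect_equal(m$surface_area / m$volume, 3 / r)
  }
  expect_error(sphere_metrics(0), "positive")
})

test_that("invalid radius bounds are refused", {
  expect_error(hough_params(0, 10), "r_min")
  expect_error(hough_params(20, 10), "r_min")
  sp <- phantom_spec(c(48, 48, 48), n_beads = 0, radius_range = c(5, 6),
                     seed = 1)
  ph <- gen_sphere_pack(sp)
  expect_error(detect_spheres(ph$volume,
                              hough_params(10, 200, downsample_factor = 1)),
               "grid extent")
})

test_that("shell masks trace the fitted radii", {
  expect_equal(sum(build_shell_mask(data.frame(cx_um = numeric(0),
    cy_um = numeric(0), cz_um = numeric(0), radius_um = numeric(0)),
    c(20, 20, 20))$data), 0)
  fit <- data.frame(cx_um = 63, cy_um = 63, cz_um = 63, radius_um = 30)
  sh <- build_shell_mask(fit, c(64, 64, 64), voxel_size = 2, thickness = 10)
  idx <- which(sh$data, arr.ind = TRUE)
  dd <- sqrt(rowSums((sweep(idx, 2, fit$cx_um / 2 + 1))^2)) * 2
  expect_true(all(dd >= 30 - 5 & dd <= 30 + 5))
  # two disjoint fits: the mask is the union of the two shells
  f2 <- data.frame(cx_um = c(40, 90), cy_um = c(40, 90), cz_um = c(40, 90),
                   radius_um = c(12, 12))
  sh2 <- build_shell_mask(f2, c(64, 64, 64), voxel_size = 2)
  sh_a <- build_shell_mask(f2[1, ], c(64, 64, 64), voxel_size = 2)
  sh_b <- build_shell_mask(f2[2, ], c(64, 64, 64), voxel_size = 2)
  expect_identical(sh2$data, sh_a$data | sh_b$data)
})
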