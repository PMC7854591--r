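test_that("empty spec yields an all-background volume and empty truth", {
  sp <- phantom_spec(c(40, 40, 40), n_beads = 0, radius_range = c(10, 20),
                     noise_sigma = 0, seed = 1)
  ph <- gen_sphere_pack(sp)
  expect_equal(nrow(ph$truth$table), 0L)
  expect_true(all(ph$truth$label_volume$data == 0L))
  # only the two background phases are present
  expect_setequal(unique(as.vector(ph$volume$data)),
                  sp$intensity_means[1:2])
})

test_that("sphere packs respect the pairwise minimum gap", {
  sp <- phantom_spec(c(128, 128, 128), n_beads = 5,
                     radius_range = c(20, 40), min_gap = 4, seed = 7)
  ph <- gen_sphere_pack(sp)
  expect_equal(nrow(ph$truth$table), 5L)
  ctr <- ph$truth$centers
  r <- ph$truth$radii
  dd <- as.matrix(dist(ctr))
  for (i in 1:4) for (j in (i + 1):5)
    expect_gte(dd[i, j], r[i] + r[j] + 4)
})

test_that("identical spec and seed reproduce the volume bit-for-bit", {
  sp <- phantom_spec(c(64, 64, 64), n_beads = 3, radius_range = c(10, 20),
                     min_gap = 2, seed = 11)
  a <- gen_sphere_pack(sp)
  b <- gen_sphere_pack(sp)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$label_volume$data, b$truth$label_volume$data)
})

test_that("adding beads does not perturb earlier placements", {
  base <- phantom_spec(c(128, 128, 128), n_beads = 3,
                       radius_range = c(12, 20), min_gap = 2, seed = 5)
  more <- phantom_spec(c(128, 128, 128), n_beads = 5,
                       radius_range = c(12, 20), min_gap = 2, seed = 5)
  a <- gen_sphere_pack(base)$truth
  b <- gen_sphere_pack(more)$truth
  expect_equal(a$centers, b$centers[1:3, ])
  expect_equal(a$radii, b$radii[1:3])
})

test_that("infeasible packing fails naming the first unplaceable bead", {
  sp <- phantom_spec(c(48, 48, 48), n_beads = 40, radius_range = c(20, 24),
                     min_gap = 4, seed = 1)
  expect_error(gen_sphere_pack(sp), "bead")
})

test_that("porous bead truth separates closed and open pore volumes", {
  # one interior cavity, no tunnels: truth closed volume = carved voxels
  sp <- phantom_spec(c(72, 72, 72), n_beads = 1, radius_range = c(24, 24),
    bead_kind = "porous_blob",
    pore_spec = list(n_closed = 1, closed_radius_range = c(8, 8),
                     n_open = 0, open_radius_range = c(0, 0)),
    min_gap = 2, seed = 9)
  ph <- gen_porous_bead_pack(sp)
  tt <- ph$truth$table
  expect_equal(nrow(tt), 1L)
  expect_gt(tt$closed_pore_vox, 0)
  # a radius-4-voxel cavity: compare against the discrete ball volume
  expect_equal(tt$closed_pore_vox, sum(ball_mask(4)), tolerance = 0.2)
  expect_lte(tt$open_pore_vox, 2L)   # ellipsoids are digitally convex

  # one through-tunnel, no cavities: closed 0, open > 0
  sp2 <- phantom_spec(c(72, 72, 72), n_beads = 1, radius_range = c(24, 24),
    bead_kind = "porous_blob",
    pore_spec = list(n_closed = 0, closed_radius_range = c(0, 0),
                     n_open = 1, open_radius_range = c(6, 6)),
    min_gap = 2, seed = 9)
  tt2 <- gen_porous_bead_pack(sp2)$truth$table
  expect_equal(tt2$closed_pore_vox, 0L)
  expect_gt(tt2$open_pore_vox, 0)
})

test_that("porous packs produce the requested number of distinct labels", {
  sp <- porous_pack_spec(shape = c(168, 168, 168), n_beads = 12, seed = 21)
  ph <- gen_porous_bead_pack(sp)
  labs <- sort(unique(as.vector(ph$truth$label_volume$data)))
  expect_equal(labs, 0:12)
})

test_that("pore radii at or above the bead radius are rejected", {
  sp <- phantom_spec(c(64, 64, 64), n_beads = 1, radius_range = c(20, 20),
    bead_kind = "porous_blob",
    pore_spec = list(n_closed = 1, closed_radius_range = c(20, 22),
                     n_open = 0, open_radius_range = c(0, 0)),
    seed = 1)
  expect_error(gen_porous_bead_pack(sp), "pore")
})

test_that("truth conservation: hull >= bead + closed pores", {
  sp <- porous_pack_spec(n_beads = 4, seed = 13)
  tt <- gen_porous_bead_pack(sp)$truth$table
  expect_true(all(tt$hull_vox >= tt$volume_vox + tt$closed_pore_vox))
})

test_that("staining renders the documented phase ordering", {
  sp <- phantom_spec(c(64, 64, 64), n_beads = 2, radius_range = c(10, 16),
                     min_gap = 2, noise_sigma = 0, seed = 3)
  ph <- gen_sphere_pack(sp)
  # noiseless positive: exactly three gray values
  expect_equal(sort(unique(as.vector(ph$volume$data))),
               sort(sp$intensity_means))
  # negative: bead gray strictly between air and liquid
  neg <- apply_staining(ph$truth, "negative", c(30, 200, 110),
                        noise_sigma = 0, seed = 1)
  lab <- ph$truth$label_volume$data
  bead_mean <- mean(neg$data[lab > 0])
  expect_gt(bead_mean, 30)
  expect_lt(bead_mean, 200)
  # fixed seed reproduces the noise field
  n1 <- apply_staining(ph$truth, "positive", sp$intensity_means, 8, seed = 4)
  n2 <- apply_staining(ph$truth, "positive", sp$intensity_means, 8, seed = 4)
  expect_identical(n1$data, n2$data)
  # degenerate contrast is refused
  expect_error(apply_staining(ph$truth, "positive", c(30, 30, 200), 0, 1),
               "degenerate|ordered")
  expect_error(apply_staining(ph$truth, "negative", c(30, 110, 200), 0, 1),
               "ordered")
})
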