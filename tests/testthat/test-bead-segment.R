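test_that("small-object removal keeps exactly the large components", {
  m <- array(FALSE, c(30, 30, 12))
  m[2:11, 2:11, 2:3] <- TRUE                  # 200 voxels
  m[20:22, 20:22, 5] <- TRUE                  # 9 voxels
  mk <- mask3d(m, 1)
  expect_identical(remove_small_objects(mk, 0)$data, m)
  out <- remove_small_objects(mk, 50)
  expect_equal(sum(out$data), 200)
  expect_true(all(out$data[2:11, 2:11, 2:3]))
})

test_that("18-connectivity merges edge-diagonal pairs that 6 does not", {
  m <- array(FALSE, c(8, 8, 8))
  m[3, 3, 3] <- TRUE
  m[4, 4, 3] <- TRUE                          # edge-diagonal neighbor
  mk <- mask3d(m, 1)
  expect_equal(sum(remove_small_objects(mk, 2, connectivity = 18)$data), 2)
  expect_equal(sum(remove_small_objects(mk, 2, connectivity = 6)$data), 0)
})

test_that("pore sealing leaves solid spheres essentially unchanged", {
  m <- ball_mask(10, pad = 6L)
  sealed <- seal_open_pores(mask3d(m, 1), r_p = 3, r_op = 2)
  changed <- which(xor(sealed$data, m))
  expect_lt(length(changed), 0.05 * sum(m))
  if (length(changed)) {
    # any perturbation is confined to the bead boundary
    surf_dist <- sqrt(beadct:::edt_sq(m))
    expect_true(all(surf_dist[changed] <= 1.5))
  }
})

test_that("tunnels below the throat radius are sealed, wide ones are not", {
  narrow <- tunneled_ball(12, 2, pad = 6L)
  sealed <- seal_open_pores(mask3d(narrow, 1), r_p = 3, r_op = 2)
  # tunnel voxels deeper than r_p below the surface must be sealed (at the
  # tunnel mouth the background is legitimately dilated back to the bead
  # boundary, rounding the opening)
  inner <- ball_mask_same_grid(dim(narrow)[1], 12 - 4.5)
  tunnel_vox <- which(inner & !narrow)
  expect_gt(length(tunnel_vox), 0)
  expect_true(all(sealed$data[tunnel_vox]))

  wide <- tunneled_ball(14, 8, pad = 8L)
  sealed2 <- seal_open_pores(mask3d(wide, 1), r_p = 2, r_op = 1)
  axis_vox <- which(ball_mask_same_grid(dim(wide)[1], 2) & !wide)
  expect_false(any(sealed2$data[axis_vox]))
})

test_that("watershed splits touching spheres and labels every voxel", {
  d <- c(60, 60, 40)
  f <- function(c0, r) {
    xs <- (1:d[1] - c0[1])^2; ys <- (1:d[2] - c0[2])^2
    zs <- (1:d[3] - c0[3])^2
    outer(outer(xs, ys, `+`), zs, `+`) <= r^2
  }
  a <- f(c(22, 30, 20), 12)
  b <- f(c(42, 30, 20), 12)
  lab <- split_touching_beads(mask3d(a | b, 2), gaussian_sigma = 3)
  expect_equal(max(lab$data), 2L)
  expect_true(all(lab$data[a | b] > 0L))
  # side-of-neck agreement with the nearest-center truth
  truth <- ifelse(a & !b, 1L, ifelse(b & !a, 2L, NA))
  ok <- !is.na(truth)
  agree <- mean(lab$data[ok] == truth[ok])
  agree <- max(agree, 1 - agree)   # label ids are arbitrary
  expect_gte(agree, 0.95)

  expect_equal(max(split_touching_beads(mask3d(f(c(30, 30, 20), 10), 2),
                                        gaussian_sigma = 3)$data), 1L)
  empty <- split_touching_beads(mask3d(array(FALSE, c(8, 8, 8)), 2))
  expect_equal(sum(empty$data), 0)
})

test_that("the porous pipeline recovers a moderate pack exactly", {
  sp <- porous_pack_spec(shape = c(160, 160, 160), n_beads = 10, seed = 11)
  ph <- gen_porous_bead_pack(sp)
  pars <- segmentation_params(v_small = 500, r_p = 7, r_op = 5,
                              variant = "porous")
  lab <- segment_beads(ph$volume, pars, "positive")
  expect_equal(max(lab$data), 10L)
  m <- match_labels(ph$truth$label_volume, lab)
  expect_gte(m$match_fraction, 0.9)
  expect_true(all(m$matches$iou >= 0.5))
  # determinism: identical labels on a rerun
  lab2 <- segment_beads(ph$volume, pars, "positive")
  expect_identical(lab$data, lab2$data)
})

test_that("the nonporous negative-stain variant recovers isolated beads", {
  sp <- phantom_spec(c(128, 128, 128), n_beads = 8,
                     radius_range = c(20, 30), bead_kind = "concave_blob",
                     min_gap = 4, staining = "negative", seed = 5)
  ph <- gen_porous_bead_pack(sp)
  pars <- segmentation_params(v_small = 500, r_cl = 6,
                              variant = "nonporous_negative")
  lab <- segment_beads(ph$volume, pars, "negative")
  expect_equal(max(lab$data), 8L)
})

test_that("raising the small-object cutoff never adds labels", {
  sp <- porous_pack_spec(shape = c(128, 128, 128), n_beads = 5, seed = 29)
  ph <- gen_porous_bead_pack(sp)
  counts <- vapply(c(0, 500, 5e4, 5e5), function(vs) {
    pars <- segmentation_params(v_small = vs, r_p = 7, r_op = 5,
                                variant = "porous")
    max(segment_beads(ph$volume, pars, "positive")$data)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("parameter validation distinguishes warnings from errors", {
  expect_warning(segmentation_params(100, r_p = 4, r_op = 2, r_cl = 5,
                                     variant = "porous"), "r_cl")
  expect_warning(segmentation_params(100, variant = "nonporous_negative"),
                 "r_cl")
  expect_error(segmentation_params(-1), "non-negative")
  expect_error(segmentation_params(100, gaussian_sigma = 0), "sigma")
})
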