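# Geometric fixtures built in code, used across the test files.

# digitized ball: logical array with TRUE where center distance <= r (voxels)
ball_mask <- function(r, pad = 3L) {
  n <- 2L * ceiling(r) + 1L + 2L * pad
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr)^2
  outer(outer(xs, xs, `+`), xs, `+`) <= r^2
}

# digitized axis-aligned ellipsoid with given semi-axes (voxels)
ellipsoid_mask <- function(semi, pad = 3L) {
  d <- 2L * ceiling(semi) + 1L + 2L * pad
  ctr <- (d + 1) / 2
  xs <- ((seq_len(d[1]) - ctr[1]) / semi[1])^2
  ys <- ((seq_len(d[2]) - ctr[2]) / semi[2])^2
  zs <- ((seq_len(d[3]) - ctr[3]) / semi[3])^2
  outer(outer(xs, ys, `+`), zs, `+`) <= 1
}

# solid cube of edge `edge` centered in a padded grid
cube_mask <- function(edge, pad = 3L) {
  n <- edge + 2L * pad
  m <- array(FALSE, c(n, n, n))
  idx <- pad + seq_len(edge)
  m[idx, idx, idx] <- TRUE
  m
}

# sphere of radius r with an axis-aligned through-channel of radius rc
tunneled_ball <- function(r, rc, pad = 3L) {
  m <- ball_mask(r, pad)
  n <- dim(m)[1]
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr)^2
  in_channel <- outer(xs, xs, `+`) <= rc^2   # (y,z) distance from axis
  for (x in seq_len(n)) m[x, , ][in_channel] <- FALSE
  m
}

# sphere of radius r with an interior cavity of radius rc at the center
hollow_ball <- function(r, rc, pad = 3L) {
  m <- ball_mask(r, pad)
  m & !ball_mask_same_grid(dim(m)[1], rc)
}
ball_mask_same_grid <- function(n, r) {
  ctr <- (n + 1) / 2
  xs <- (seq_len(n) - ctr)^2
  outer(outer(xs, xs, `+`), xs, `+`) <= r^2
}

# independent brute-force 3-class Otsu oracle: direct triple scan of the
# between-class variance over all threshold pairs of a discrete histogram
oracle_otsu3 <- function(counts, mids) {
  n <- sum(counts)
  mu <- sum(counts * mids) / n
  best <- -Inf
  bk <- c(NA, NA)
  nb <- length(counts)
  for (k1 in 1:(nb - 2)) {
    for (k2 in (k1 + 1):(nb - 1)) {
      w1 <- sum(counts[1:k1])
      w2 <- sum(counts[(k1 + 1):k2])
      w3 <- sum(counts[(k2 + 1):nb])
      if (w1 == 0 || w2 == 0 || w3 == 0) next
      m1 <- sum(counts[1:k1] * mids[1:k1]) / w1
      m2 <- sum(counts[(k1 + 1):k2] * mids[(k1 + 1):k2]) / w2
      m3 <- sum(counts[(k2 + 1):nb] * mids[(k2 + 1):nb]) / w3
      bcv <- w1 * (m1 - mu)^2 + w2 * (m2 - mu)^2 + w3 * (m3 - mu)^2
      if (bcv > best) {
        best <- bcv
        bk <- c(k1, k2)
      }
    }
  }
  list(k1 = bk[1], k2 = bk[2], bcv = best)
}

# brute-force outlier filter (sorted-data scan) used as the oracle for the
# boxplot interquartile rule
oracle_outliers <- function(x) {
  q1 <- quantile(x, 0.25, type = 5, names = FALSE)
  q3 <- quantile(x, 0.75, type = 5, names = FALSE)
  lo <- q1 - 1.5 * (q3 - q1)
  hi <- q3 + 1.5 * (q3 - q1)
  sort(x[x < lo | x > hi])
}

# greedy center matching of sphere fits against truth; returns per-fit
# center error (voxels) and radius error (voxels)
match_sphere_fits <- function(fits, truth, voxel_size = 2) {
  tr <- cbind(truth$centers, truth$radii)
  t(vapply(seq_len(nrow(fits)), function(i) {
    dd <- sqrt(rowSums((tr[, 1:3, drop = FALSE] -
      matrix(as.numeric(fits[i, c("cx_um", "cy_um", "cz_um")]),
             nrow(tr), 3, byrow = TRUE))^2))
    j <- which.min(dd)
    c(center_err_vox = dd[j] / voxel_size,
      radius_err_vox = abs(tr[j, 4] - fits$radius_um[i]) / voxel_size,
      truth_id = j)
  }, numeric(3)))
}

# the standard porous test pack used by several files
porous_pack_spec <- function(shape = c(140, 140, 140), n_beads = 6,
                             seed = 3) {
  phantom_spec(shape, n_beads = n_beads, radius_range = c(26, 36),
               bead_kind = "porous_blob",
               pore_spec = list(n_closed = 2, closed_radius_range = c(6, 10),
                                n_open = 2, open_radius_range = c(3, 5)),
               min_gap = 2, staining = "positive", seed = seed)
}

# label volume with n beads laid out as small cubes on a grid; pass a
# common `per_axis` to compare volumes with different bead counts
cube_grid_labels <- function(n, edge = 4L, gap = 3L, voxel_size = 2,
                             per_axis = ceiling(n^(1 / 3))) {
  pitch <- edge + gap
  d <- rep(per_axis * pitch + gap, 3L)
  lab <- array(0L, d)
  id <- 0L
  for (z in seq_len(per_axis)) for (y in seq_len(per_axis))
    for (x in seq_len(per_axis)) {
      if (id >= n) break
      id <- id + 1L
      ox <- gap + (x - 1L) * pitch
      oy <- gap + (y - 1L) * pitch
      oz <- gap + (z - 1L) * pitch
      lab[ox + seq_len(edge), oy + seq_len(edge), oz + seq_len(edge)] <- id
    }
  labelvol3d(lab, voxel_size)
}
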