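#' Phantom specification
#'
#' Describes a synthetic micro-CT scene: beads suspended in liquid inside a
#' cylindrical container (emulating a sample tube), surrounded by air. The
#' rendered histogram therefore has three modes — two background peaks (air,
#' liquid) and one bead peak — whose ordering depends on the staining
#' regime: with positive staining the bead is the brightest phase, with
#' negative staining the surrounding liquid is contrasted and the bead gray
#' value lies between air and liquid.
#'
#' @param shape integer vector of 3 grid dimensions (voxels).
#' @param n_beads number of beads to place.
#' @param radius_range bead radius range `[min, max]` in um (for ellipsoidal
#'   beads this is the largest semi-axis).
#' @param voxel_size um/voxel (default 2, the scan resolution the package
#'   is designed around).
#' @param bead_kind `"sphere"`, `"porous_blob"` (randomized ellipsoid with
#'   interior cavities and open channels) or `"concave_blob"` (ellipsoid
#'   with spherical surface bites).
#' @param pore_spec list with `n_closed`, `closed_radius_range` (um),
#'   `n_open`, `open_radius_range` (um), all per bead.
#' @param min_gap minimum surface-to-surface gap between beads in um;
#'   negative values allow touching/overlap.
#' @param staining `"positive"` or `"negative"`.
#' @param intensity_means gray levels of the three phases, in the order
#'   (air, liquid, bead); `NULL` picks defaults consistent with `staining`
#'   (air 30, and 110/200 for the other two phases).
#' @param noise_sigma additive Gaussian noise standard deviation in gray
#'   levels (8-bit range); default 8.
#' @param seed integer RNG seed.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape, n_beads, radius_range, voxel_size = 2,
                         bead_kind = c("sphere", "porous_blob",
                                       "concave_blob"),
                         pore_spec = list(n_closed = 0,
                                          closed_radius_range = c(0, 0),
                                          n_open = 0,
                                          open_radius_range = c(0, 0)),
                         min_gap = 4, staining = c("positive", "negative"),
                         intensity_means = NULL, noise_sigma = 8,
                         seed = 1) {
  bead_kind <- match.arg(bead_kind)
  staining <- match.arg(staining)
  if (length(shape) != 3L || any(shape < 1))
    stop("shape must be 3 positive dimensions")
  if (radius_range[1] <= 0 || radius_range[1] > radius_range[2])
    stop("radius_range must satisfy 0 < min <= max")
  if (is.null(intensity_means)) {
    intensity_means <- if (staining == "positive") c(30, 110, 200)
                       else c(30, 200, 110)
  }
  check_intensity_means(intensity_means, staining)
  spec <- list(shape = as.integer(shape), voxel_size = voxel_size,
               n_beads = as.integer(n_beads), radius_range = radius_range,
               bead_kind = bead_kind, pore_spec = pore_spec,
               min_gap = min_gap, staining = staining,
               intensity_means = intensity_means,
               noise_sigma = noise_sigma, seed = as.integer(seed))
  class(spec) <- "phantom_spec"
  spec
}

check_intensity_means <- function(means, staining) {
  if (length(means) != 3L || anyDuplicated(means))
    stop("degenerate contrast: intensity means must be 3 distinct values")
  air <- means[1]; liquid <- means[2]; bead <- means[3]
  ok <- if (staining == "positive") air < liquid && liquid < bead
        else air < bead && bead < liquid
  if (!ok)
    stop("intensity means are not ordered consistently with staining mode")
  invisible(TRUE)
}

# evaluate expr under a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic per-bead sub-seed so adding beads never perturbs earlier ones
bead_seed <- function(seed, i) {
  (as.double(seed) * 100003 + as.double(i) * 7919) %% 2147483629
}

container_of <- function(shape) {
  list(center = c((shape[1] + 1) / 2, (shape[2] + 1) / 2),
       radius_vox = 0.47 * min(shape[1], shape[2]))
}

# place bead centers/radii by per-bead rejection sampling (10,000 retries)
place_beads <- function(spec) {
  h <- spec$voxel_size
  cont <- container_of(spec$shape)
  centers <- matrix(0, spec$n_beads, 3) # voxel coords
  radii <- numeric(spec$n_beads)        # um
  for (i in seq_len(spec$n_beads)) {
    placed <- with_seed(bead_seed(spec$seed, i), {
      ok <- FALSE
      for (try in seq_len(10000L)) {
        r <- runif(1, spec$radius_range[1], spec$radius_range[2])
        r_vox <- r / h
        zlim <- c(1 + r_vox + 1, spec$shape[3] - r_vox - 1)
        rmax_c <- cont$radius_vox - r_vox - 2
        if (zlim[1] >= zlim[2] || rmax_c <= 0)
          stop(sprintf("packing failure: bead %d of radius %.1f um cannot fit the grid", i, r))
        ang <- runif(1, 0, 2 * pi)
        rad <- sqrt(runif(1)) * rmax_c
        ctr <- c(cont$center[1] + rad * cos(ang),
                 cont$center[2] + rad * sin(ang),
                 runif(1, zlim[1], zlim[2]))
        ok <- TRUE
        if (i > 1) {
          dd <- sqrt(colSums((t(centers[seq_len(i - 1), , drop = FALSE]) -
                              ctr)^2)) * h
          if (any(dd < radii[seq_len(i - 1)] + r + spec$min_gap)) ok <- FALSE
        }
        if (ok) break
      }
      if (!ok)
        stop(sprintf("packing failure: could not place bead %d after 10000 retries", i))
      list(ctr = ctr, r = r)
    })
    centers[i, ] <- placed$ctr
    radii[i] <- placed$r
  }
  list(centers = centers, radii = radii, container = cont)
}

empty_truth <- function(spec, labels, container) {
  list(label_volume = labelvol3d(labels, spec$voxel_size),
       centers = matrix(0, 0, 3), radii = numeric(0),
       table = data.frame(bead_id = integer(0), volume_vox = integer(0),
                          closed_pore_vox = integer(0),
                          open_pore_vox = integer(0), hull_vox = integer(0),
                          touches_border = logical(0)),
       container = container, spec = spec)
}

#' Generate a phantom of packed solid spheres
#'
#' Places `n_beads` non-overlapping spheres (given `min_gap` >= 0) inside
#' the scene container by per-bead rejection sampling, voxelizes them onto
#' the grid and renders the stained, noisy grayscale volume. The returned
#' truth carries exact centers and radii plus a per-voxel label volume.
#' Identical spec and seed reproduce the volume bit-for-bit.
#'
#' @param spec a [phantom_spec()] with `bead_kind = "sphere"`.
#' @return list with `volume` (a [vol3d()]) and `truth` (a `phantom_truth`
#'   list: `label_volume`, `centers` (um), `radii` (um), per-bead `table`,
#'   `container`, `spec`).
#' @export
gen_sphere_pack <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$bead_kind != "sphere")
    stop("gen_sphere_pack requires bead_kind = 'sphere'")
  h <- spec$voxel_size
  labels <- array(0L, spec$shape)
  if (spec$n_beads == 0L) {
    truth <- empty_truth(spec, labels, container_of(spec$shape))
    class(truth) <- "phantom_truth"
    return(list(volume = apply_staining(truth, spec$staining,
                                        spec$intensity_means,
                                        spec$noise_sigma, spec$seed),
                truth = truth))
  }
  pl <- place_beads(spec)
  for (i in seq_len(spec$n_beads)) {
    labels <- paint_ball(labels, pl$centers[i, ], pl$radii[i] / h,
                         as.integer(i))
  }
  vol_vox <- tabulate(labels[labels > 0L], nbins = spec$n_beads)
  truth <- list(label_volume = labelvol3d(labels, h),
                centers = (pl$centers - 1) * h, # 0-based physical coords
                radii = pl$radii,
                table = data.frame(bead_id = seq_len(spec$n_beads),
                                   volume_vox = vol_vox,
                                   closed_pore_vox = 0L, open_pore_vox = 0L,
                                   hull_vox = vol_vox,
                                   touches_border = FALSE),
                container = pl$container, spec = spec)
  class(truth) <- "phantom_truth"
  list(volume = apply_staining(truth, spec$staining, spec$intensity_means,
                               spec$noise_sigma, spec$seed),
       truth = truth)
}

# paint a ball (label id) into a label array where still background
paint_ball <- function(labels, center_vox, r_vox, id) {
  d <- dim(labels)
  lo <- pmax(floor(center_vox - r_vox), 1)
  hi <- pmin(ceiling(center_vox + r_vox), d)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  dx2 <- (xs - center_vox[1])^2
  dy2 <- (ys - center_vox[2])^2
  dz2 <- (zs - center_vox[3])^2
  inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= r_vox^2
  sub <- labels[xs, ys, zs, drop = FALSE]
  sub[inside & sub == 0L] <- id
  labels[xs, ys, zs] <- sub
  labels
}

# random rotation matrix from a private RNG stream (QR of a normal matrix)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a phantom of porous or concave ellipsoidal beads
#'
#' Beads are randomized ellipsoids (axis ratios drawn in `[0.6, 1]`,
#' mimicking near-spherical macro-porous carriers) carved with interior
#' cavities (closed pores) and/or channels to the surface (open pores).
#' Per-bead truth pore volumes are established by connected-component
#' analysis of the clean (noise-free) bead mask against the background, and
#' the truth convex-hull volume from the discrete hull image, so every
#' downstream estimate can be scored against exact voxel counts.
#'
#' @param spec a [phantom_spec()] with `bead_kind` `"porous_blob"` or
#'   `"concave_blob"`.
#' @return list with `volume` and `truth` as in [gen_sphere_pack()].
#' @export
gen_porous_bead_pack <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!spec$bead_kind %in% c("porous_blob", "concave_blob"))
    stop("gen_porous_bead_pack requires bead_kind porous_blob or concave_blob")
  ps <- spec$pore_spec
  if ((ps$n_closed > 0 && max(ps$closed_radius_range) >= spec$radius_range[1]) ||
      (ps$n_open > 0 && max(ps$open_radius_range) >= spec$radius_range[1]))
    stop("invalid pore specification: pore radii must be smaller than the bead radius")
  h <- spec$voxel_size
  labels <- array(0L, spec$shape)
  if (spec$n_beads == 0L) {
    truth <- empty_truth(spec, labels, container_of(spec$shape))
    class(truth) <- "phantom_truth"
    return(list(volume = apply_staining(truth, spec$staining,
                                        spec$intensity_means,
                                        spec$noise_sigma, spec$seed),
                truth = truth))
  }
  pl <- place_beads(spec)
  for (i in seq_len(spec$n_beads)) {
    labels <- with_seed(bead_seed(spec$seed, i) + 1, {
      paint_carved_ellipsoid(labels, pl$centers[i, ], pl$radii[i] / h,
                             as.integer(i), spec)
    })
  }
  # truth pore decomposition per bead on the clean label volume
  tab <- truth_table(labels, spec$n_beads)
  truth <- list(label_volume = labelvol3d(labels, h),
                centers = (pl$centers - 1) * h, radii = pl$radii,
                table = tab, container = pl$container, spec = spec)
  class(truth) <- "phantom_truth"
  list(volume = apply_staining(truth, spec$staining, spec$intensity_means,
                               spec$noise_sigma, spec$seed),
       truth = truth)
}

# carve one ellipsoidal bead with pores into the label array
paint_carved_ellipsoid <- function(labels, center_vox, a_vox, id, spec) {
  d <- dim(labels)
  h <- spec$voxel_size
  ratios <- c(1, runif(2, 0.6, 1))
  semi <- a_vox * ratios              # voxel units, descending
  rot <- random_rotation()
  lo <- pmax(floor(center_vox - a_vox), 1)
  hi <- pmin(ceiling(center_vox + a_vox), d)
  xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
  grid <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  rel <- sweep(grid, 2, center_vox) %*% rot       # body frame
  inside <- (rel[, 1] / semi[1])^2 + (rel[, 2] / semi[2])^2 +
            (rel[, 3] / semi[3])^2 <= 1
  ps <- spec$pore_spec
  carved <- rep(FALSE, nrow(grid))
  if (spec$bead_kind == "porous_blob") {
    # interior cavities: fully inside the shrunken ellipsoid
    if (ps$n_closed > 0) {
      for (k in seq_len(ps$n_closed)) {
        rc <- runif(1, ps$closed_radius_range[1], ps$closed_radius_range[2]) / h
        shr <- pmax(semi - rc - 2, 0.1)
        repeat {
          u <- rnorm(3); u <- u / sqrt(sum(u^2)) * runif(1)^(1 / 3)
          c_body <- u * shr
          if (all(abs(c_body) < shr) &&
              sum((c_body / shr)^2) <= 1) break
        }
        c_vox <- as.numeric(center_vox + rot %*% c_body)
        dd2 <- (grid[, 1] - c_vox[1])^2 + (grid[, 2] - c_vox[2])^2 +
               (grid[, 3] - c_vox[3])^2
        carved <- carved | dd2 <= rc^2
      }
    }
    # open channels: cylinders from the bead center out past the surface
    if (ps$n_open > 0) {
      for (k in seq_len(ps$n_open)) {
        rt <- runif(1, ps$open_radius_range[1], ps$open_radius_range[2]) / h
        dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
        relc <- sweep(grid, 2, center_vox)
        t_ <- relc %*% dir
        perp2 <- rowSums(relc^2) - t_^2
        carved <- carved | (t_ >= 0 & perp2 <= rt^2)
      }
    }
  } else { # concave_blob: spherical bites centered on the surface
    nb <- max(ps$n_open, 1L)
    for (k in seq_len(nb)) {
      rb <- if (ps$n_open > 0)
        runif(1, ps$open_radius_range[1], ps$open_radius_range[2]) / h
      else 0.35 * a_vox
      dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
      # surface point of the ellipsoid along body direction dir
      db <- t(rot) %*% dir
      scale <- 1 / sqrt(sum((db / semi)^2))
      c_vox <- as.numeric(center_vox + dir * scale)
      dd2 <- (grid[, 1] - c_vox[1])^2 + (grid[, 2] - c_vox[2])^2 +
             (grid[, 3] - c_vox[3])^2
      carved <- carved | dd2 <= rb^2
    }
  }
  keep <- inside & !carved
  sub <- labels[xs, ys, zs, drop = FALSE]
  sub_v <- as.vector(sub)
  sub_v[keep & sub_v == 0L] <- id
  labels[xs, ys, zs] <- array(sub_v, dim(sub))
  labels
}

# per-bead truth table via pore decomposition of the clean label volume
truth_table <- function(labels, n_beads) {
  d <- dim(labels)
  border_ids <- border_component_ids(labels)
  rows <- lapply(seq_len(n_beads), function(i) {
    idx <- which(labels == i)
    if (length(idx) == 0L)
      return(data.frame(bead_id = i, volume_vox = 0L, closed_pore_vox = 0L,
                        open_pore_vox = 0L, hull_vox = 0L,
                        touches_border = FALSE))
    if (i %in% border_ids) {
      return(data.frame(bead_id = i, volume_vox = length(idx),
                        closed_pore_vox = NA_integer_,
                        open_pore_vox = NA_integer_, hull_vox = NA_integer_,
                        touches_border = TRUE))
    }
    crop <- crop_mask(labels == i, pad = 2L)
    dec <- decompose_pores(crop)
    data.frame(bead_id = i, volume_vox = sum(crop),
               closed_pore_vox = sum(dec$closed_pores),
               open_pore_vox = sum(dec$open_pores),
               hull_vox = sum(dec$hull), touches_border = FALSE)
  })
  do.call(rbind, rows)
}

# crop a logical array to its bounding box with `pad` background voxels
crop_mask <- function(mask, pad = 1L) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("empty mask")
  d <- dim(mask)
  lo <- pmax(apply(idx, 2, min) - pad, 1L)
  hi <- pmin(apply(idx, 2, max) + pad, d)
  out <- array(FALSE, hi - lo + 1L + 2L * pad)
  # place the crop centrally so the result always has >= pad background
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  out <- array(FALSE, dim(sub) + 2L * pad)
  out[pad + seq_len(dim(sub)[1]), pad + seq_len(dim(sub)[2]),
      pad + seq_len(dim(sub)[3])] <- sub
  out
}

#' Render a stained, noisy grayscale volume from phantom geometry
#'
#' Maps the three scene phases (air, liquid, bead) to the given gray means
#' and adds Gaussian noise clipped to the 8-bit range `[0, 255]`. Under
#' positive staining the bead phase is brightest and air darkest; under
#' negative staining the liquid is brightest and the bead gray level lies
#' strictly between air and liquid.
#'
#' @param truth a `phantom_truth` (carries the label volume and the scene
#'   container geometry).
#' @param staining `"positive"` or `"negative"`.
#' @param intensity_means gray means in the order (air, liquid, bead).
#' @param noise_sigma Gaussian noise SD in gray levels; 0 gives a noiseless
#'   three-level rendering.
#' @param seed RNG seed for the noise field.
#' @return A [vol3d()].
#' @export
apply_staining <- function(truth, staining, intensity_means, noise_sigma,
                           seed) {
  check_intensity_means(intensity_means, staining)
  labels <- as_array3d(truth$label_volume)
  d <- dim(labels)
  cont <- truth$container
  xs <- (seq_len(d[1]) - cont$center[1])^2
  ys <- (seq_len(d[2]) - cont$center[2])^2
  in_cyl <- outer(xs, ys, `+`) <= cont$radius_vox^2
  phase <- array(1L, d)                       # 1 = air
  phase[rep(in_cyl, d[3])] <- 2L              # 2 = liquid
  phase[labels > 0L] <- 3L                    # 3 = bead
  gray <- array(intensity_means[phase], d)
  if (noise_sigma > 0) {
    noise <- with_seed(seed, rnorm(length(gray), 0, noise_sigma))
    gray <- gray + noise
  }
  gray <- round(pmin(pmax(gray, 0), 255))
  vol3d(array(gray, d), truth$spec$voxel_size %||% 2,
        provenance = sprintf("phantom(%s)", staining))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
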