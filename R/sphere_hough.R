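#' Parameters for 3D spherical Hough detection
#'
#' @param r_min,r_max radius search range in um; the range should bracket
#'   the expected bead radii (for commercial carriers, taken from the
#'   manufacturer's size specification).
#' @param radius_step radius discretization in um (default: one working-grid
#'   voxel).
#' @param edge_threshold edge voxels are those with gradient magnitude above
#'   this fraction of the maximum gradient (default 0.3).
#' @param accumulator_threshold minimum supported fraction of the
#'   theoretical full shell (`4 pi r^2` voxels) for a detection to be kept
#'   (default 0.5: at least half the shell must be supported by edges).
#' @param min_center_separation minimum distance between reported centers
#'   in um (default `r_min`), enforced by greedy non-maximum suppression.
#' @param downsample_factor integer resize factor applied before detection,
#'   for computational efficiency (default 2); all outputs are reported in
#'   um on the original grid.
#' @return A `hough_params` list.
#' @export
hough_params <- function(r_min, r_max, radius_step = NULL,
                         edge_threshold = 0.3, accumulator_threshold = 0.5,
                         min_center_separation = r_min,
                         downsample_factor = 2) {
  if (!(r_min > 0 && r_min < r_max))
    stop("configuration error: need 0 < r_min < r_max")
  if (!is.null(radius_step) && radius_step <= 0)
    stop("configuration error: radius_step must be positive")
  structure(list(r_min = r_min, r_max = r_max, radius_step = radius_step,
                 edge_threshold = edge_threshold,
                 accumulator_threshold = accumulator_threshold,
                 min_center_separation = min_center_separation,
                 downsample_factor = as.integer(downsample_factor)),
            class = "hough_params")
}

# central-difference gradient components of a 3D array
gradient3d <- function(a) {
  d <- dim(a)
  g <- function(axis) {
    hi <- shift_axis(a, axis, 1L)
    lo <- shift_axis(a, axis, -1L)
    (hi - lo) / 2
  }
  list(gx = g(1L), gy = g(2L), gz = g(3L))
}

# shift array along axis by s voxels with replicate boundary
shift_axis <- function(a, axis, s) {
  d <- dim(a)
  idx <- pmin(pmax(seq_len(d[axis]) + s, 1L), d[axis])
  switch(axis,
         a[idx, , , drop = FALSE],
         a[, idx, , drop = FALSE],
         a[, , idx, drop = FALSE])
}

#' Detect spherical beads by a 3D Hough transform
#'
#' Gradient-direction voting: every strong-edge voxel casts votes along its
#' (+/-) gradient ray at all radii in `[r_min, r_max]`; sphere centers
#' accumulate votes from their whole surface. Candidate centers are local
#' maxima of the (lightly smoothed) accumulator; each candidate's radius is
#' then estimated from the mode of the edge-voxel distance histogram, and
#' its score is the shell support normalized by the theoretical full-shell
#' voxel count `4 pi r^2`. Greedy non-maximum suppression enforces
#' `min_center_separation`. Detection runs on the block-mean downsampled
#' grid; centers and radii are reported in um of the original volume.
#'
#' @param volume a [vol3d()].
#' @param params a [hough_params()].
#' @return data.frame with columns `bead_id`, `cx_um`, `cy_um`, `cz_um`,
#'   `radius_um`, `surface_area_um2`, `volume_um3`, `score`, sorted by
#'   descending score. Empty (0-row) when no edges or no candidate exceeds
#'   the support threshold.
#' @export
detect_spheres <- function(volume, params) {
  stopifnot(inherits(volume, "vol3d"), inherits(params, "hough_params"))
  work <- downsample(volume, params$downsample_factor)
  h <- work$voxel_size
  d <- dim(work$data)
  if (params$r_max >= min(d) * h / 2)
    stop("configuration error: r_max must be below half the smallest grid extent")
  rmin_v <- params$r_min / h
  rmax_v <- params$r_max / h
  step_v <- if (is.null(params$radius_step)) 1 else params$radius_step / h

  gr <- gradient3d(work$data)
  gmag <- sqrt(gr$gx^2 + gr$gy^2 + gr$gz^2)
  gmax <- max(gmag)
  empty <- data.frame(bead_id = integer(0), cx_um = numeric(0),
                      cy_um = numeric(0), cz_um = numeric(0),
                      radius_um = numeric(0), surface_area_um2 = numeric(0),
                      volume_um3 = numeric(0), score = numeric(0))
  if (gmax <= 0) return(empty)
  edge <- gmag >= params$edge_threshold * gmax
  edge_idx <- which(edge)
  if (length(edge_idx) == 0L) return(empty)

  acc <- hough_vote_cpp(edge_idx, as.vector(gr$gx), as.vector(gr$gy),
                        as.vector(gr$gz), d, rmin_v, rmax_v, step_v)
  dim(acc) <- d
  acc <- gaussian_blur_cpp(acc, d, 1.0)
  dim(acc) <- d

  # candidate centers: strong accumulator voxels, greedy NMS
  cand <- which(acc >= 0.25 * max(acc))
  cand <- cand[order(acc[cand], decreasing = TRUE)]
  coords <- arrayInd(cand, d)
  sep_v <- params$min_center_separation / h
  keep <- integer(0)
  for (i in seq_along(cand)) {
    p <- coords[i, ]
    if (length(keep) == 0L ||
        all(rowSums((coords[keep, , drop = FALSE] -
                     matrix(p, length(keep), 3, byrow = TRUE))^2) >=
            sep_v^2)) {
      keep <- c(keep, i)
      if (length(keep) >= 200L) break
    }
  }
  centers <- coords[keep, , drop = FALSE]

  # radius estimation + shell-support score per candidate; the center is
  # refined as the centroid of the supporting shell (for a full sphere the
  # shell centroid is the center) and the radius as the gradient-weighted
  # mean edge distance, which centers the estimate on the intensity step
  eco <- arrayInd(edge_idx, d)
  ew <- gmag[edge_idx]
  fits <- lapply(seq_len(nrow(centers)), function(i) {
    ctr <- centers[i, ]
    r_hat <- NA_real_
    in_best <- NULL
    for (it in 1:3) {
      dd <- sqrt((eco[, 1] - ctr[1])^2 + (eco[, 2] - ctr[2])^2 +
                 (eco[, 3] - ctr[3])^2)
      sel <- dd >= rmin_v - 1 & dd <= rmax_v + 1
      if (!any(sel)) return(NULL)
      br <- seq(rmin_v - 1, rmax_v + 1 + step_v, by = step_v)
      hcount <- tabulate(findInterval(dd[sel], br), nbins = length(br) - 1L)
      kbest <- which.max(hcount)
      in_best <- sel
      in_best[sel] <- dd[sel] >= br[kbest] - step_v &
                      dd[sel] <= br[kbest + 1] + step_v
      r_hat <- mean(dd[in_best])
      ctr <- colMeans(eco[in_best, , drop = FALSE])
    }
    # narrow re-centered passes around the converged radius
    for (it in 1:2) {
      dd <- sqrt((eco[, 1] - ctr[1])^2 + (eco[, 2] - ctr[2])^2 +
                 (eco[, 3] - ctr[3])^2)
      in_best <- abs(dd - r_hat) <= max(1.25, step_v)
      if (!any(in_best)) return(NULL)
      r_hat <- sum(dd[in_best] * ew[in_best]) / sum(ew[in_best])
      ctr <- colMeans(eco[in_best, , drop = FALSE])
    }
    support <- sum(in_best)
    score <- support / (4 * pi * r_hat^2)
    c(ctr, r_hat, score, support)
  })
  fits <- do.call(rbind, fits[!vapply(fits, is.null, logical(1))])
  if (is.null(fits) || nrow(fits) == 0L) return(empty)
  ok <- fits[, 5] >= params$accumulator_threshold &
        fits[, 4] >= rmin_v - 1 & fits[, 4] <= rmax_v + 1
  fits <- fits[ok, , drop = FALSE]
  if (nrow(fits) == 0L) return(empty)
  fits <- fits[order(fits[, 5], decreasing = TRUE), , drop = FALSE]
  # refinement can pull two candidates onto one sphere: dedupe by score
  keep <- integer(0)
  for (i in seq_len(nrow(fits))) {
    if (length(keep) == 0L ||
        all(rowSums((fits[keep, 1:3, drop = FALSE] -
                     matrix(fits[i, 1:3], length(keep), 3,
                            byrow = TRUE))^2) >= sep_v^2))
      keep <- c(keep, i)
  }
  fits <- fits[keep, , drop = FALSE]

  r_um <- fits[, 4] * h
  met <- sphere_metrics(r_um)
  # working-grid voxel centers sit (f-1)/2 original voxels into each block
  off <- (params$downsample_factor - 1) / 2 * volume$voxel_size
  data.frame(bead_id = seq_len(nrow(fits)),
             cx_um = (fits[, 1] - 1) * h + off,
             cy_um = (fits[, 2] - 1) * h + off,
             cz_um = (fits[, 3] - 1) * h + off,
             radius_um = r_um,
             surface_area_um2 = met$surface_area,
             volume_um3 = met$volume,
             score = fits[, 5])
}

#' Closed-form sphere surface area and volume
#'
#' For a detected sphere of radius `R` (um) the approximate surface area
#' and volume are `4 pi R^2` and `4/3 pi R^3`.
#'
#' @param r_um radius (um), vectorized.
#' @return list with `surface_area` (um^2) and `volume` (um^3).
#' @export
sphere_metrics <- function(r_um) {
  if (any(r_um <= 0)) stop("radius must be positive")
  list(surface_area = 4 * pi * r_um^2, volume = 4 / 3 * pi * r_um^3)
}

#' Build a binary shell mask from sphere fits
#'
#' For visual quality control the detected spheres are rendered as binary
#' shells of the given thickness (default 10 um) centred on the fitted
#' radii: a voxel is in the shell of fit `i` when its center distance `d`
#' to the fit center satisfies `R_i - t/2 <= d <= R_i + t/2`. The mask is
#' the union over all fits.
#'
#' @param fits data.frame from [detect_spheres()] (needs `cx_um`, `cy_um`,
#'   `cz_um`, `radius_um`).
#' @param dims grid dimensions (voxels) of the target volume.
#' @param voxel_size um/voxel of the target volume.
#' @param thickness shell thickness in um (default 10).
#' @return A [mask3d()].
#' @export
build_shell_mask <- function(fits, dims, voxel_size = 2, thickness = 10) {
  mask <- array(FALSE, dims)
  for (i in seq_len(nrow(fits))) {
    ctr <- c(fits$cx_um[i], fits$cy_um[i], fits$cz_um[i]) / voxel_size + 1
    r_v <- fits$radius_um[i] / voxel_size
    t2 <- thickness / 2 / voxel_size
    lo <- pmax(floor(ctr - r_v - t2), 1)
    hi <- pmin(ceiling(ctr + r_v + t2), dims)
    if (any(lo > hi)) next
    xs <- lo[1]:hi[1]; ys <- lo[2]:hi[2]; zs <- lo[3]:hi[3]
    dd <- sqrt(outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, `+`),
                     (zs - ctr[3])^2, `+`))
    shell <- dd >= r_v - t2 & dd <= r_v + t2
    mask[xs, ys, zs] <- mask[xs, ys, zs] | shell
  }
  mask3d(mask, voxel_size)
}
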