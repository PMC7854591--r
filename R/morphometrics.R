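#' Decompose a single bead into hull, filled body, closed and open pores
#'
#' Given the binary image `I` of one bead (padded by at least one
#' background voxel on every face), computes:
#' * `hull` — the discrete convex hull image `I_conv` (voxel centers inside
#'   the exact hull polytope of the bead's surface voxel centers);
#' * `closed_pores` — components of `!I` not connected to the image border
#'   (`I_cl`);
#' * `filled` — `I | I_cl` (`I_fill`);
#' * `open_pores` — `hull & !filled` (`I_op`).
#'
#' Voxel counts of the four masks satisfy the conservation identity
#' `V_conv = V_bead + V_open + V_closed` exactly by construction.
#'
#' @param bead_mask 3D logical array (or [mask3d()]) containing exactly one
#'   bead, padded by background on all faces.
#' @return list of logical arrays `hull`, `filled`, `closed_pores`,
#'   `open_pores`.
#' @export
decompose_pores <- function(bead_mask) {
  m <- as_array3d(bead_mask)
  storage.mode(m) <- "logical"
  if (!any(m)) stop("empty mask")
  d <- dim(m)
  if (any(m[c(1, d[1]), , ]) || any(m[, c(1, d[2]), ]) ||
      any(m[, , c(1, d[3])]))
    stop("bead touches the crop border; pad the mask by >= 1 background voxel")
  # closed pores: background components with no path to the border
  bglab <- label_components(!m, 26L)
  exterior <- border_component_ids(bglab)
  ext <- logical(max(bglab) + 1L)
  ext[exterior + 1L] <- TRUE
  closed <- array(bglab > 0L & !ext[bglab + 1L], d)
  filled <- m | closed
  hull <- convex_hull_image(m)
  hull <- hull | filled  # guard: digitization must never lose bead voxels
  open <- hull & !filled
  list(hull = hull, filled = filled, closed_pores = closed,
       open_pores = open)
}

# discrete convex hull image of a logical array: voxel centers inside the
# exact hull polytope of the foreground surface voxel centers
convex_hull_image <- function(m) {
  pts <- surface_points(m)
  if (nrow(pts) < 4L)
    stop("fewer than 4 non-coplanar points; convex hull undefined")
  hp <- quickhull_cpp(pts)
  img <- hull_fill_cpp(hp$normals, hp$offsets, dim(m), c(1, 1, 1))
  array(img, dim(m))
}

# voxel centers on the object surface (foreground with a 6-neighbor in the
# background); sufficient support for the convex hull of all foreground
surface_points <- function(m) {
  interior <- shift_axis(m, 1L, 1L) & shift_axis(m, 1L, -1L) &
              shift_axis(m, 2L, 1L) & shift_axis(m, 2L, -1L) &
              shift_axis(m, 3L, 1L) & shift_axis(m, 3L, -1L)
  surf <- m & !interior
  idx <- which(surf, arr.ind = TRUE)
  storage.mode(idx) <- "double"
  idx
}

#' Porosity of an individual bead
#'
#' `P = 1 - V_bead / V_conv`.
#'
#' @param v_i bead volume.
#' @param v_conv_i convex hull volume (same units).
#' @return porosity in `[0, 1)`.
#' @export
porosity <- function(v_i, v_conv_i) {
  if (any(v_conv_i <= 0)) stop("convex hull volume must be positive")
  if (any(v_i > v_conv_i)) stop("bead volume exceeds convex hull volume")
  if (any(v_i <= 0)) stop("degenerate bead: zero volume gives porosity 1")
  1 - v_i / v_conv_i
}

#' Size and shape morphometrics of one bead
#'
#' Equivalent diameter (diameter of the sphere with the bead's volume,
#' `(6 V / pi)^(1/3)`) and the three principal axis lengths, defined as the
#' major-axis lengths of the ellipsoid with the same normalized second
#' central moments as the region: eigenvalues `lambda_k` of the voxel
#' coordinate covariance (with the per-voxel `1/12` moment correction on
#' the diagonal) give `L_k = 2 sqrt(5 lambda_k)`, sorted descending. For
#' macro-porous carriers these metrics are conventionally computed on the
#' convex hull image (`support = "hull"`); for non-porous carriers on the
#' bead mask itself (`support = "bead"`).
#'
#' @param bead_mask logical array of the bead.
#' @param hull_mask logical array of its convex hull image (only needed for
#'   `support = "hull"`).
#' @param voxel_size um/voxel.
#' @param support `"hull"` or `"bead"`.
#' @return list with `equivalent_diameter_um`, `principal_axes_um`
#'   (length 3, descending) and `volume_um3` of the chosen support.
#' @export
basic_morphometrics <- function(bead_mask, hull_mask = NULL, voxel_size = 2,
                                support = c("hull", "bead")) {
  support <- match.arg(support)
  m <- if (support == "hull") {
    if (is.null(hull_mask)) stop("hull_mask required for support = 'hull'")
    as_array3d(hull_mask)
  } else as_array3d(bead_mask)
  idx <- which(m, arr.ind = TRUE)
  n <- nrow(idx)
  if (n == 0L) stop("empty mask")
  v_um3 <- n * voxel_size^3
  eqd <- (6 * v_um3 / pi)^(1 / 3)
  cov_ <- crossprod(sweep(idx, 2, colMeans(idx))) / n + diag(1 / 12, 3)
  lam <- sort(eigen(cov_, symmetric = TRUE, only.values = TRUE)$values,
              decreasing = TRUE)
  axes <- 2 * sqrt(5 * lam) * voxel_size
  list(equivalent_diameter_um = eqd, principal_axes_um = axes,
       volume_um3 = v_um3)
}

# 13-direction scheme: 3 axis, 6 face-diagonal, 4 body-diagonal directions
# with the classical direction weights (sum over all 13 = 1/2)
crofton_directions <- function() {
  dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                c(0, 1, 1), c(0, 1, -1),
                c(1, 1, 1), c(1, -1, 1), c(1, 1, -1), c(1, -1, -1))
  w <- c(rep(0.04577789120476, 3), rep(0.03698062787608, 6),
         rep(0.03519563978232, 4))
  list(dirs = dirs, weights = w)
}

#' Surface area by Crofton's intercept-count formula
#'
#' Stereological surface-area estimate from the number of foreground /
#' background transitions along systematically oriented lines in 13
#' directions (3 axis, 6 face-diagonal, 4 body-diagonal), with the
#' classical direction weights:
#' `S = 4 h^2 * sum_k c_k * n_k / |d_k|`, where `n_k` counts transitions
#' along direction `d_k` and `h` is the voxel size. The mask must not touch
#' the array border (pad first), otherwise border chords are missed.
#'
#' @param mask logical array (or [mask3d()]).
#' @param voxel_size um/voxel.
#' @return surface area in um^2.
#' @export
crofton_surface_area <- function(mask, voxel_size = 2) {
  m <- as_array3d(mask)
  storage.mode(m) <- "logical"
  if (!any(m)) stop("empty mask")
  cd <- crofton_directions()
  total <- 0
  for (k in seq_len(nrow(cd$dirs))) {
    d <- cd$dirs[k, ]
    n_k <- count_transitions(m, d)
    total <- total + cd$weights[k] * n_k / sqrt(sum(d^2))
  }
  4 * total * voxel_size^2
}

# transitions between m[p] and m[p + d] over all in-bounds voxel pairs
count_transitions <- function(m, d) {
  dm <- dim(m)
  rngA <- vector("list", 3)
  rngB <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] == 1L) {
      rngA[[ax]] <- seq_len(dm[ax] - 1L)
      rngB[[ax]] <- 2L:dm[ax]
    } else if (d[ax] == -1L) {
      rngA[[ax]] <- 2L:dm[ax]
      rngB[[ax]] <- seq_len(dm[ax] - 1L)
    } else {
      rngA[[ax]] <- seq_len(dm[ax])
      rngB[[ax]] <- seq_len(dm[ax])
    }
  }
  a <- m[rngA[[1]], rngA[[2]], rngA[[3]], drop = FALSE]
  b <- m[rngB[[1]], rngB[[2]], rngB[[3]], drop = FALSE]
  sum(xor(a, b))
}

#' Probe-radius to cell-size conversion for accessible-surface profiles
#'
#' The probing radius of the accessible-surface (alpha-shape) sweep models
#' the size of a cell exploring the bead surface; a probing radius of `r`
#' voxels corresponds to a cell size of `r * voxel_size` um (e.g. 50 voxels
#' -> 100 um at 2 um voxels).
#'
#' @param radius_vox probe radius in voxels (may be `Inf`).
#' @param voxel_size um/voxel.
#' @return cell size in um.
#' @export
cell_size_um <- function(radius_vox, voxel_size = 2) {
  radius_vox * voxel_size
}

#' Accessible surface area as a function of probe radius
#'
#' Computes the alpha-hull of the bead solid for each probing radius via
#' its ball-rolling formulation: the alpha-hull with probe radius `r` is
#' the complement of the union of all radius-`r` balls that avoid the
#' object, which for a voxel solid is exactly the morphological closing by
#' the Euclidean ball of radius `r`. The boundary area of the closed solid
#' is measured by the 13-direction Crofton estimator. An infinite probing
#' radius returns the convex surface area (exact triangulated facet area of
#' the hull polytope). Small probes can enter pores and channels, so the
#' accessible area typically decreases as the probe (cell) grows.
#'
#' @param bead_mask logical array (or [mask3d()]) of one bead.
#' @param probe_radii_vox probe radii in voxels, `Inf` allowed (default:
#'   the standard sweep 2, 3, 4, 10, 15, 20, 25, 38, 50, Inf).
#' @param voxel_size um/voxel.
#' @return named numeric vector of areas (um^2); names are the cell sizes
#'   in um (`"Inf"` for the convex limit).
#' @export
alpha_surface_profile <- function(bead_mask,
                                  probe_radii_vox = c(2, 3, 4, 10, 15, 20,
                                                      25, 38, 50, Inf),
                                  voxel_size = 2) {
  m <- as_array3d(bead_mask)
  storage.mode(m) <- "logical"
  if (!any(m)) stop("empty mask")
  if (any(probe_radii_vox <= 0)) stop("probe radii must be positive")
  rmax <- max(probe_radii_vox[is.finite(probe_radii_vox)], 0)
  pad <- as.integer(ceiling(rmax) + 2L)
  mp <- pad_mask(m, pad)
  out <- numeric(length(probe_radii_vox))
  for (i in seq_along(probe_radii_vox)) {
    r <- probe_radii_vox[i]
    if (is.finite(r)) {
      out[i] <- crofton_surface_area(close_ball(mp, r), voxel_size)
    } else {
      pts <- surface_points(m)
      if (nrow(pts) < 4L)
        stop("fewer than 4 non-coplanar points; convex hull undefined")
      out[i] <- quickhull_cpp(pts)$area * voxel_size^2
    }
  }
  names(out) <- as.character(cell_size_um(probe_radii_vox, voxel_size))
  out
}

pad_mask <- function(m, pad) {
  d <- dim(m)
  out <- array(FALSE, d + 2L * pad)
  out[pad + seq_len(d[1]), pad + seq_len(d[2]), pad + seq_len(d[3])] <- m
  out
}

#' Per-bead morphometrics table for a label volume
#'
#' Crops each labelled bead (with background padding), runs the pore
#' decomposition and computes the full record: volumes of bead, convex
#' hull, open and closed pores; porosity; equivalent diameter and principal
#' axis lengths (on the hull image for `variant = "porous"`, on the bead
#' mask for `variant = "nonporous"`); convex surface area (Crofton estimate
#' on the hull image); and optionally the accessible-surface profile.
#' Beads touching the volume border are flagged — their morphometrics are
#' truncated by the field of view and are excluded from cohort statistics
#' by default.
#'
#' @param labels a [labelvol3d()].
#' @param variant `"porous"` or `"nonporous"` (controls the moment support).
#' @param probe_radii_vox probe radii (voxels) for the accessible-surface
#'   profile, or `NULL` to skip it.
#' @return data.frame, one row per bead, with the column schema of
#'   [write_morphometrics()].
#' @export
bead_morphometrics <- function(labels, variant = c("porous", "nonporous"),
                               probe_radii_vox = NULL) {
  stopifnot(inherits(labels, "labelvol3d"))
  variant <- match.arg(variant)
  h <- labels$voxel_size
  lab <- labels$data
  nl <- max(lab)
  border_ids <- border_component_ids(lab)
  rows <- vector("list", nl)
  for (i in seq_len(nl)) {
    rows[[i]] <- tryCatch(
      bead_record(lab == i, h, variant, probe_radii_vox,
                  touches_border = i %in% border_ids, bead_id = i),
      error = function(e) empty_record(i, i %in% border_ids,
                                       probe_radii_vox, h))
  }
  do.call(rbind, rows)
}

bead_record <- function(mask, h, variant, probe_radii_vox, touches_border,
                        bead_id) {
  crop <- crop_mask(mask, pad = 2L)
  dec <- decompose_pores(crop)
  v_bead <- sum(crop)
  v_hull <- sum(dec$hull)
  v_open <- sum(dec$open_pores)
  v_closed <- sum(dec$closed_pores)
  bm <- basic_morphometrics(crop, dec$hull, h,
                            support = if (variant == "porous") "hull"
                                      else "bead")
  rec <- data.frame(bead_id = bead_id, touches_border = touches_border,
                    equivalent_diameter_um = bm$equivalent_diameter_um,
                    principal_axis_1_um = bm$principal_axes_um[1],
                    principal_axis_2_um = bm$principal_axes_um[2],
                    principal_axis_3_um = bm$principal_axes_um[3],
                    bead_volume_um3 = v_bead * h^3,
                    convex_hull_volume_um3 = v_hull * h^3,
                    open_pore_volume_um3 = v_open * h^3,
                    closed_pore_volume_um3 = v_closed * h^3,
                    porosity = porosity(v_bead, v_hull),
                    convex_surface_area_um2 =
                      crofton_surface_area(dec$hull, h))
  if (!is.null(probe_radii_vox)) {
    prof <- alpha_surface_profile(crop, probe_radii_vox, h)
    for (j in seq_along(prof))
      rec[[paste0("alpha_area_um2_at_", names(prof)[j])]] <- prof[j]
  }
  rec
}

empty_record <- function(bead_id, touches_border, probe_radii_vox, h) {
  rec <- data.frame(bead_id = bead_id, touches_border = touches_border,
                    equivalent_diameter_um = NA_real_,
                    principal_axis_1_um = NA_real_,
                    principal_axis_2_um = NA_real_,
                    principal_axis_3_um = NA_real_,
                    bead_volume_um3 = NA_real_,
                    convex_hull_volume_um3 = NA_real_,
                    open_pore_volume_um3 = NA_real_,
                    closed_pore_volume_um3 = NA_real_, porosity = NA_real_,
                    convex_surface_area_um2 = NA_real_)
  if (!is.null(probe_radii_vox)) {
    cs <- as.character(cell_size_um(probe_radii_vox, h))
    for (s in cs) rec[[paste0("alpha_area_um2_at_", s)]] <- NA_real_
  }
  rec
}
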