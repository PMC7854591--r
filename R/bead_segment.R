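#' Parameters of the bead-isolation pipeline
#'
#' @param v_small noise-object volume cutoff in um^3: connected components
#'   (3D connectivity 18) smaller than this are removed before anything
#'   else.
#' @param r_p half pore-throat thickness in um; background farther than
#'   `r_p` from the beads is taken as true background, which disconnects
#'   pore space from the exterior.
#' @param r_op radius (um) of the spherical structuring element used to
#'   morphologically open the far-background mask, cutting the remaining
#'   thin connections into larger pores.
#' @param r_cl closing radius in um; only used by the nonporous
#'   negative-stain variant.
#' @param gaussian_sigma standard deviation (in working-grid voxels) of the
#'   Gaussian filter applied to the distance transform before watershed
#'   (default 7).
#' @param object_connectivity 3D connectivity for object components
#'   (default 18).
#' @param variant `"porous"` (pore-sealing steps active) or
#'   `"nonporous_negative"` (pore steps skipped; closing and removal of
#'   small dark volumes added, for negative-stain data).
#' @param black_volume_cutoff um^3 cutoff for the "small black volumes"
#'   (enclosed background pockets) filled in the nonporous variant;
#'   defaults to `v_small`.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(v_small, r_p = 0, r_op = 0, r_cl = NULL,
                                gaussian_sigma = 7,
                                object_connectivity = 18,
                                variant = c("porous", "nonporous_negative"),
                                black_volume_cutoff = v_small) {
  variant <- match.arg(variant)
  if (v_small < 0 || r_p < 0 || r_op < 0 || (!is.null(r_cl) && r_cl < 0))
    stop("radii and V_small must be non-negative")
  if (gaussian_sigma <= 0) stop("gaussian_sigma must be positive")
  if (variant == "porous" && !is.null(r_cl))
    warning("r_cl is ignored by the porous variant")
  if (variant == "nonporous_negative" && is.null(r_cl)) {
    warning("nonporous_negative variant without r_cl; using r_cl = 0")
    r_cl <- 0
  }
  structure(list(v_small = v_small, r_p = r_p, r_op = r_op, r_cl = r_cl,
                 gaussian_sigma = gaussian_sigma,
                 object_connectivity = as.integer(object_connectivity),
                 variant = variant,
                 black_volume_cutoff = black_volume_cutoff),
            class = "segmentation_params")
}

#' Remove small foreground objects
#'
#' Deletes every 18-connected (configurable) foreground component with a
#' volume smaller than `v_small` um^3. No surviving voxel is changed.
#'
#' @param mask a [mask3d()].
#' @param v_small volume cutoff in um^3.
#' @param connectivity 6, 18 or 26.
#' @return A [mask3d()].
#' @export
remove_small_objects <- function(mask, v_small, connectivity = 18) {
  stopifnot(inherits(mask, "mask3d"))
  if (v_small < 0) stop("v_small must be >= 0")
  if (v_small == 0) return(mask)
  h3 <- mask$voxel_size^3
  lab <- label_components(mask$data, connectivity)
  nl <- max(lab)
  if (nl == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = nl)
  keep <- c(FALSE, sizes * h3 >= v_small)
  mask3d(array(keep[lab + 1L], dim(lab)), mask$voxel_size)
}

#' Seal open pores so touching beads become solid objects
#'
#' The pore-sealing sequence that turns a binarized porous-bead mask
#' (MASK1) into solid beads:
#' (a) the Euclidean distance transform of the background (distance to the
#' nearest bead voxel) is thresholded at `> r_p`, giving the far background
#' MASK2 and disconnecting pore space from the exterior; (b) MASK2 is
#' morphologically opened with a spherical structuring element of radius
#' `r_op` (MASK3), cutting residual thin connections into larger pores;
#' (c) background objects of MASK3 not touching the volume border — the
#' isolated pores — are cleared by AND-ing with their complement; (d) the
#' remaining true background is dilated by a spherical element of radius
#' `r_p` back to the bead boundary (MASK4). The returned mask is the
#' complement of MASK4: beads with their open pores sealed.
#'
#' With `r_p = r_op = 0` the operation degenerates to filling only fully
#' enclosed background regions.
#'
#' @param mask a [mask3d()] (MASK1, after noise removal).
#' @param r_p half pore-throat thickness in um.
#' @param r_op opening radius in um.
#' @return A [mask3d()] of sealed beads.
#' @export
seal_open_pores <- function(mask, r_p, r_op) {
  stopifnot(inherits(mask, "mask3d"))
  if (r_p < 0 || r_op < 0) stop("r_p and r_op must be >= 0")
  h <- mask$voxel_size
  rp_v <- r_p / h
  rop_v <- r_op / h
  mask2 <- edt_sq(mask$data) > rp_v^2            # far background
  mask3 <- open_ball(mask2, rop_v)
  lab <- label_components(mask3, 26L)
  keep_ids <- border_component_ids(lab)          # border-connected = exterior
  keep <- logical(max(lab) + 1L)
  keep[keep_ids + 1L] <- TRUE
  mask3b <- array(keep[lab + 1L], dim(lab))
  mask4 <- dilate_ball(mask3b, rp_v)
  mask3d(!mask4, h)
}

#' Split touching beads by watershed of the distance transform
#'
#' Computes the Euclidean distance transform of the sealed bead mask
#' (distance to background), smooths it with a 3D Gaussian filter
#' (`sigma` in working-grid voxels, default 7) to suppress spurious minima,
#' and floods the negated map with a marker-free watershed restricted to
#' the foreground. Each catchment basin becomes one bead label; voxels
#' where basins meet are absorbed into an adjacent basin so that every
#' foreground voxel is labelled. Deterministic for fixed input.
#'
#' @param sealed a [mask3d()] of sealed beads.
#' @param gaussian_sigma Gaussian standard deviation in voxels.
#' @return A [labelvol3d()].
#' @export
split_touching_beads <- function(sealed, gaussian_sigma = 7) {
  stopifnot(inherits(sealed, "mask3d"))
  d <- dim(sealed$data)
  if (!any(sealed$data))
    return(labelvol3d(array(0L, d), sealed$voxel_size))
  dist <- sqrt(edt_sq(!sealed$data))
  sm <- gaussian_blur_cpp(as.vector(dist), d, gaussian_sigma)
  lab <- watershed_cpp(-sm, as.vector(sealed$data), d, 18L)
  dim(lab) <- d
  labelvol3d(lab, sealed$voxel_size,
             touches_border = label_border_flags(lab))
}

label_border_flags <- function(lab) {
  nl <- max(lab)
  if (nl == 0L) return(logical(0))
  flags <- logical(nl)
  flags[border_component_ids(lab)] <- TRUE
  flags
}

#' Isolate individual beads in a grayscale volume
#'
#' Full segmentation pipeline. `"porous"` variant: 3-class Otsu
#' binarization with staining-aware foreground selection, small-object
#' removal (`v_small`), pore sealing ([seal_open_pores()]), then
#' distance-transform watershed ([split_touching_beads()]).
#' `"nonporous_negative"` variant (for non-porous beads imaged with
#' negative staining): the pore-sealing steps are skipped; instead the mask
#' is morphologically closed with a spherical element of radius `r_cl` and
#' small enclosed background pockets ("black volumes", below
#' `black_volume_cutoff`) are filled before the watershed.
#'
#' Labels are consecutive; beads touching the volume border are flagged in
#' the result's `touches_border` vector.
#'
#' @param volume a [vol3d()].
#' @param params a [segmentation_params()].
#' @param staining `"positive"` or `"negative"`.
#' @return A [labelvol3d()].
#' @export
segment_beads <- function(volume, params,
                          staining = c("positive", "negative")) {
  stopifnot(inherits(volume, "vol3d"),
            inherits(params, "segmentation_params"))
  staining <- match.arg(staining)
  ot <- multi_otsu(volume)
  fg <- select_foreground(volume, ot, staining)
  mask1 <- remove_small_objects(fg, params$v_small,
                                params$object_connectivity)
  if (params$variant == "porous") {
    sealed <- seal_open_pores(mask1, params$r_p, params$r_op)
    lab <- split_touching_beads(sealed, params$gaussian_sigma)
    # morphometrics are computed on the binarized bead image, so the labels
    # are restricted back to it: pores reopen inside each watershed region
    return(restrict_labels(lab, mask1$data))
  } else {
    h <- mask1$voxel_size
    closed <- close_ball(mask1$data, params$r_cl / h)
    # fill small enclosed dark pockets left by the negative staining
    bg <- label_components(!closed, 26L)
    nl <- max(bg)
    if (nl > 0L) {
      sizes <- tabulate(bg[bg > 0L], nbins = nl)
      small <- sizes * h^3 < params$black_volume_cutoff
      small[border_component_ids(bg)] <- FALSE
      closed <- closed | array(c(FALSE, small)[bg + 1L], dim(bg))
    }
    sealed <- mask3d(closed, h)
  }
  # nonporous beads: the closed mask IS the bead (the closing removes
  # binarization noise, not real pore space)
  split_touching_beads(sealed, params$gaussian_sigma)
}

# zero labels outside `mask`, renumber consecutively, refresh border flags
restrict_labels <- function(lab, mask) {
  a <- lab$data
  a[!mask] <- 0L
  ids <- sort(unique(a[a > 0L]))
  if (length(ids) && !identical(ids, seq_along(ids))) {
    remap <- integer(max(ids) + 1L)
    remap[ids + 1L] <- seq_along(ids)
    a <- array(remap[a + 1L], dim(a))
  }
  labelvol3d(a, lab$voxel_size, touches_border = label_border_flags(a))
}
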