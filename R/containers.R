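#' 3D grayscale volume
#'
#' A `vol3d` holds a 3D scalar intensity grid with an isotropic voxel size.
#' The coordinate convention used throughout the package is 0-based
#' `(x, y, z)` with `z` the slice index (third array dimension); all public
#' physical quantities are in micrometres (um, um^2, um^3).
#'
#' @param intensities 3D numeric array of gray values.
#' @param voxel_size isotropic voxel edge length in um/voxel (default 2).
#' @param provenance free-text source tag.
#' @return An object of class `vol3d` with elements `data`, `voxel_size`,
#'   `provenance`.
#' @export
vol3d <- function(intensities, voxel_size = 2, provenance = "") {
  if (length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array")
  if (any(dim(intensities) < 1L))
    stop("all three grid dimensions must be >= 1")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("voxel_size must be a single positive number")
  structure(list(data = intensities, voxel_size = voxel_size,
                 provenance = provenance),
            class = "vol3d")
}

#' Binary (foreground) volume
#'
#' @param mask 3D logical array (TRUE = foreground).
#' @param voxel_size isotropic voxel size in um/voxel.
#' @return An object of class `mask3d`.
#' @export
mask3d <- function(mask, voxel_size = 2) {
  if (length(dim(mask)) != 3L) stop("mask must be a 3D array")
  storage.mode(mask) <- "logical"
  structure(list(data = mask, voxel_size = voxel_size), class = "mask3d")
}

#' Per-bead label volume
#'
#' Integer labels on the same grid as the source volume; 0 is background and
#' positive labels are consecutive bead ids.
#'
#' @param labels 3D integer array.
#' @param voxel_size isotropic voxel size in um/voxel.
#' @param touches_border optional logical vector, one flag per label.
#' @return An object of class `labelvol3d`.
#' @export
labelvol3d <- function(labels, voxel_size = 2, touches_border = NULL) {
  if (length(dim(labels)) != 3L) stop("labels must be a 3D array")
  storage.mode(labels) <- "integer"
  structure(list(data = labels, voxel_size = voxel_size,
                 touches_border = touches_border),
            class = "labelvol3d")
}

#' @export
print.vol3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<vol3d> %d x %d x %d voxels, %.3g um/voxel\n",
              d[1], d[2], d[3], x$voxel_size))
  cat(sprintf("  gray range [%.4g, %.4g]%s\n",
              min(x$data), max(x$data),
              if (nzchar(x$provenance)) paste0("  (", x$provenance, ")")
              else ""))
  invisible(x)
}

#' @export
print.mask3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<mask3d> %d x %d x %d voxels, %.3g um/voxel, %d foreground\n",
              d[1], d[2], d[3], x$voxel_size, sum(x$data)))
  invisible(x)
}

#' @export
print.labelvol3d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<labelvol3d> %d x %d x %d voxels, %.3g um/voxel, %d beads\n",
              d[1], d[2], d[3], x$voxel_size, max(x$data)))
  invisible(x)
}

n_labels <- function(lv) max(0L, max(lv$data))

# internal: coerce vol3d/mask3d/array to bare array
as_array3d <- function(x) {
  if (inherits(x, c("vol3d", "mask3d", "labelvol3d"))) x$data else x
}

# internal: connected-component labels of a logical array
label_components <- function(mask, connectivity = 18L) {
  lab <- cc_label_cpp(as.logical(mask), dim(mask), as.integer(connectivity))
  dim(lab) <- dim(mask)
  lab
}

# internal: squared EDT (voxel units) to the nearest TRUE voxel
edt_sq <- function(feature) {
  d <- edt_sq_cpp(as.logical(feature), dim(feature))
  dim(d) <- dim(feature)
  d
}

# internal: exact Euclidean ball morphology via distance thresholding.
# The structuring element is the discrete ball {voxels at center distance <= r}.
dilate_ball <- function(mask, r_vox) {
  if (r_vox <= 0) return(mask)
  edt_sq(mask) <= r_vox^2
}
erode_ball <- function(mask, r_vox) {
  if (r_vox <= 0) return(mask)
  !(edt_sq(!mask) <= r_vox^2)
}
open_ball <- function(mask, r_vox) dilate_ball(erode_ball(mask, r_vox), r_vox)
close_ball <- function(mask, r_vox) erode_ball(dilate_ball(mask, r_vox), r_vox)

# internal: ids of components touching the array border
border_component_ids <- function(lab) {
  d <- dim(lab)
  ids <- c(lab[c(1, d[1]), , ], lab[, c(1, d[2]), ], lab[, , c(1, d[3])])
  sort(unique(ids[ids > 0L]))
}
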