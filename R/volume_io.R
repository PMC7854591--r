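#' Read a TIFF stack into a volume
#'
#' Accepts either a multi-page TIFF file or a directory of equally sized
#' single-page TIFF slices (lexicographic file order). Slice order maps to
#' the third grid axis; 8- and 16-bit samples are preserved losslessly.
#'
#' @param path multi-page TIFF file or slice directory.
#' @param voxel_size isotropic voxel size in um/voxel.
#' @return A [vol3d()].
#' @export
read_stack <- function(path, voxel_size = 2) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF slices found in ", path)
    slices <- lapply(files, function(f) slice_to_int(tiff::readTIFF(f,
                                                      as.is = TRUE), f))
    d1 <- dim(slices[[1]])
    for (i in seq_along(slices))
      if (!identical(dim(slices[[i]]), d1))
        stop("inconsistent slice dimensions in file ", files[i])
  } else {
    pages <- tiff::readTIFF(path, as.is = TRUE, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    slices <- lapply(pages, slice_to_int, f = path)
  }
  nz <- length(slices)
  d <- dim(slices[[1]])
  # slice matrices are (row = y, col = x); store as (x, y, z)
  vol <- array(0, c(d[2], d[1], nz))
  for (z in seq_len(nz)) vol[, , z] <- t(slices[[z]])
  vol3d(vol, voxel_size, provenance = path)
}

slice_to_int <- function(m, f) {
  if (length(dim(m)) == 3L) {
    if (dim(m)[3] != 1L)
      stop("unsupported sample format (multi-channel TIFF): ", f)
    m <- m[, , 1]
  }
  if (!is.matrix(m)) stop("unsupported sample format in ", f)
  m
}

#' Write a volume (or mask/label volume) as a multi-page TIFF
#'
#' @param volume a [vol3d()], [mask3d()] or [labelvol3d()].
#' @param path output file.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_stack <- function(volume, path, bits = 8) {
  if (!bits %in% c(8, 16)) stop("bits must be 8 or 16")
  a <- as_array3d(volume)
  storage.mode(a) <- "double"
  maxv <- 2^bits - 1
  if (min(a) < 0 || max(a) > maxv)
    stop(sprintf("gray values outside [0, %d]; rescale before writing", maxv))
  slices <- lapply(seq_len(dim(a)[3]),
                   function(z) t(a[, , z]) / maxv)
  tiff::writeTIFF(slices, path, bits.per.sample = bits, compression = "none")
  invisible(path)
}

#' Clear everything outside a circular in-slice region of interest
#'
#' Reproduces the sample-tube clean-up applied before analysis: every voxel
#' whose in-slice (x, y) distance from `center_xy` exceeds `radius` is set
#' to `fill` on all slices; voxels inside (center distance <= radius) are
#' untouched.
#'
#' @param volume a [vol3d()].
#' @param center_xy ROI center in voxel coordinates (x, y), 1-based.
#' @param radius ROI radius in voxels; must be positive.
#' @param fill gray value written outside the ROI.
#' @return A [vol3d()].
#' @export
circular_roi <- function(volume, center_xy, radius, fill = 0) {
  stopifnot(inherits(volume, "vol3d"))
  if (radius <= 0) stop("radius must be positive")
  a <- volume$data
  d <- dim(a)
  dx2 <- (seq_len(d[1]) - center_xy[1])^2
  dy2 <- (seq_len(d[2]) - center_xy[2])^2
  outside <- outer(dx2, dy2, `+`) > radius^2
  if (any(outside)) {
    idx <- which(rep(outside, d[3]))
    a[idx] <- fill
  }
  vol3d(a, volume$voxel_size, volume$provenance)
}

#' Downsample a volume by integer block averaging
#'
#' Each output voxel is the mean of its `factor`^3 input block (blocks are
#' truncated at the far edges by flooring the grid dimensions). The voxel
#' size is multiplied by `factor`, so physical quantities derived later are
#' unchanged in expectation. Block averaging (rather than decimation)
#' preserves the three-peak histogram structure the binarizer relies on.
#'
#' @param volume a [vol3d()].
#' @param factor integer >= 1.
#' @return A [vol3d()].
#' @export
downsample <- function(volume, factor) {
  stopifnot(inherits(volume, "vol3d"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("factor must be an integer >= 1")
  if (factor == 1L) return(volume)
  a <- volume$data
  d <- dim(a)
  m <- d %/% factor
  if (any(m < 1L)) stop("factor larger than grid")
  a <- a[seq_len(m[1] * factor), seq_len(m[2] * factor),
         seq_len(m[3] * factor), drop = FALSE]
  a <- collapse_axis(a, 1L, factor)
  a <- collapse_axis(a, 2L, factor)
  a <- collapse_axis(a, 3L, factor)
  vol3d(a, volume$voxel_size * factor, volume$provenance)
}

# mean-pool one axis by `f`: permute the axis to the front, reshape, colMeans
collapse_axis <- function(a, axis, f) {
  perm <- c(axis, setdiff(1:3, axis))
  b <- aperm(a, perm)
  d <- dim(b)
  dim(b) <- c(f, d[1] %/% f * d[2] * d[3])
  b <- colMeans(b)
  dim(b) <- c(d[1] %/% f, d[2], d[3])
  aperm(b, order(perm))
}

#' Write per-bead morphometrics to CSV
#'
#' One row per bead with the documented, stable column set: `bead_id`,
#' `touches_border`, `equivalent_diameter_um`, `principal_axis_1_um` ..
#' `principal_axis_3_um`, `bead_volume_um3`, `convex_hull_volume_um3`,
#' `open_pore_volume_um3`, `closed_pore_volume_um3`, `porosity`,
#' `convex_surface_area_um2`, and one `alpha_area_um2_at_<cellsize>` column
#' per configured probe cell size. Floats are written at full precision.
#'
#' @param records data.frame of bead records (see [bead_morphometrics()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_morphometrics <- function(records, path) {
  base_cols <- c("bead_id", "touches_border", "equivalent_diameter_um",
                 "principal_axis_1_um", "principal_axis_2_um",
                 "principal_axis_3_um", "bead_volume_um3",
                 "convex_hull_volume_um3", "open_pore_volume_um3",
                 "closed_pore_volume_um3", "porosity",
                 "convex_surface_area_um2")
  if (is.list(records) && !is.data.frame(records)) {
    alpha_sets <- unique(lapply(records, function(r)
      grep("^alpha_area_um2_at_", names(r), value = TRUE)))
    if (length(alpha_sets) > 1L)
      stop("records have alpha profiles on differing radius grids; ",
           "a common cell-size grid is required")
    records <- do.call(rbind, lapply(records, as.data.frame))
  }
  if (nrow(records) == 0L) {
    records <- as.data.frame(setNames(rep(list(numeric(0)),
                                          length(base_cols)), base_cols))
  }
  missing <- setdiff(base_cols, names(records))
  if (length(missing))
    stop("records are missing columns: ", paste(missing, collapse = ", "))
  alpha_cols <- grep("^alpha_area_um2_at_", names(records), value = TRUE)
  records <- records[, c(base_cols, alpha_cols), drop = FALSE]
  write.csv(format(records, digits = 17, trim = TRUE, scientific = FALSE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a morphometrics CSV written by [write_morphometrics()]
#'
#' @param path CSV path.
#' @return data.frame of bead records.
#' @export
read_morphometrics <- function(path) {
  read.csv(path, check.names = FALSE)
}
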