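#' Multilevel (3-class) Otsu thresholding
#'
#' Computes the two thresholds that maximize the between-class variance of
#' the gray-level histogram split into three classes, by exhaustive search
#' over all threshold pairs. Micro-CT scenes of stained beads show three
#' histogram modes — two background peaks (air, liquid) and one bead peak —
#' which is why a two-threshold split is the right model. Native integer
#' bins are used for 8-bit data and 256 equal-width bins for wider ranges,
#' so the exhaustive optimum is exact and fast.
#'
#' Threshold semantics: a gray value `g` belongs to the upper class of a
#' threshold `t` iff `g > t` (thresholds are reported as the upper bin edge
#' of the lower class).
#'
#' @param volume a [vol3d()] (or bare numeric array).
#' @param n_classes number of classes; only 3 is supported.
#' @return An `otsu_result` list: `thresholds` (t_low < t_high),
#'   `class_fractions` (3 fractions summing to 1).
#' @export
multi_otsu <- function(volume, n_classes = 3) {
  if (n_classes != 3) stop("only the 3-class split is implemented")
  a <- as_array3d(volume)
  vals <- as.vector(a)
  uv <- unique(vals)
  if (length(uv) < n_classes)
    stop("degenerate histogram: fewer distinct gray values than classes")
  lo <- min(vals); hi <- max(vals)
  if (lo >= 0 && hi <= 255 && all(vals == round(vals))) {
    breaks <- seq(-0.5, 255.5, by = 1)
    mids <- 0:255
  } else {
    breaks <- seq(lo, hi, length.out = 257)
    breaks[1] <- breaks[1] - 1e-9
    mids <- (breaks[-1] + breaks[-257]) / 2
  }
  counts <- hist_counts(vals, breaks)
  ot <- otsu_pair_search(counts, mids)
  # report thresholds as bin upper edges
  t_low <- breaks[ot$k1 + 1]
  t_high <- breaks[ot$k2 + 1]
  if (lo >= 0 && hi <= 255 && all(vals == round(vals))) {
    t_low <- mids[ot$k1]   # integer gray: upper edge k - 0.5 -> report k - ?
    t_high <- mids[ot$k2]
  }
  structure(list(thresholds = c(t_low = t_low, t_high = t_high),
                 class_fractions = ot$fractions),
            class = "otsu_result")
}

hist_counts <- function(vals, breaks) {
  idx <- findInterval(vals, breaks, rightmost.closed = TRUE,
                      left.open = TRUE)
  idx[idx < 1L] <- 1L
  nb <- length(breaks) - 1L
  idx[idx > nb] <- nb
  tabulate(idx, nbins = nb)
}

# exhaustive search for the 3-class between-class-variance maximum.
# k1 < k2 index the last bin of class 1 and class 2 respectively.
otsu_pair_search <- function(counts, mids) {
  nb <- length(counts)
  n <- sum(counts)
  w <- cumsum(counts)
  m <- cumsum(counts * mids)
  nonempty <- which(counts > 0)
  best <- -Inf; bk <- c(NA, NA)
  for (k1 in nonempty[-length(nonempty)]) {
    if (k1 >= nb - 1L) break
    w1 <- w[k1]; m1 <- m[k1]
    k2s <- (k1 + 1L):(nb - 1L)
    w2 <- w[k2s] - w1
    w3 <- n - w[k2s]
    ok <- w2 > 0 & w3 > 0
    if (!any(ok)) next
    k2s <- k2s[ok]; w2 <- w2[ok]; w3 <- w3[ok]
    mu1 <- m1 / w1
    mu2 <- (m[k2s] - m1) / w2
    mu3 <- (m[nb] - m[k2s]) / w3
    mu <- m[nb] / n
    bcv <- w1 * (mu1 - mu)^2 + w2 * (mu2 - mu)^2 + w3 * (mu3 - mu)^2
    j <- which.max(bcv)
    if (bcv[j] > best) {
      best <- bcv[j]
      bk <- c(k1, k2s[j])
    }
  }
  if (!is.finite(best)) stop("degenerate histogram")
  w1 <- w[bk[1]]; w2 <- w[bk[2]] - w1; w3 <- n - w[bk[2]]
  list(k1 = bk[1], k2 = bk[2], fractions = c(w1, w2, w3) / n, bcv = best)
}

#' Select the bead foreground from a 3-class Otsu split
#'
#' With positive staining the beads are the brightest phase, so the
#' foreground is every voxel above the highest threshold; with negative
#' staining the contrasted liquid is brightest and the beads form the
#' middle class, so the foreground is the gray band between the two
#' thresholds (`t_low < g <= t_high`).
#'
#' @param volume a [vol3d()].
#' @param otsu an `otsu_result` from [multi_otsu()].
#' @param staining `"positive"` or `"negative"`.
#' @return A [mask3d()].
#' @export
select_foreground <- function(volume, otsu,
                              staining = c("positive", "negative")) {
  staining <- match.arg(staining)
  stopifnot(inherits(otsu, "otsu_result"))
  a <- as_array3d(volume)
  t_low <- otsu$thresholds[["t_low"]]
  t_high <- otsu$thresholds[["t_high"]]
  fg <- if (staining == "positive") a > t_high
        else a > t_low & a <= t_high
  mask3d(array(fg, dim(a)),
         if (inherits(volume, "vol3d")) volume$voxel_size else 2)
}

#' @export
print.otsu_result <- function(x, ...) {
  cat(sprintf("<otsu_result> t_low = %.4g, t_high = %.4g; fractions %s\n",
              x$thresholds[["t_low"]], x$thresholds[["t_high"]],
              paste(sprintf("%.3f", x$class_fractions), collapse = "/")))
  invisible(x)
}
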