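#' Boxplot summary with the interquartile outlier rule
#'
#' Quantiles use linear interpolation of the order statistics at
#' probabilities `(k - 0.5)/n` (R's `type = 5`, the convention of the
#' original analysis environment). Values greater than
#' `q3 + 1.5 (q3 - q1)` or less than `q1 - 1.5 (q3 - q1)` are outliers;
#' the whiskers are the extreme non-outlier values.
#'
#' @param values numeric vector, `length >= 1`, no NAs.
#' @return A `boxplot_summary` list: `n`, `mean`, `std`, `q1`, `median`,
#'   `q3`, `whisker_low`, `whisker_high`, `outliers`.
#' @export
boxplot_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("empty input")
  if (anyNA(values)) stop("values must not contain NA")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 5))
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  out <- values[values < lo | values > hi]
  inliers <- values[values >= lo & values <= hi]
  structure(list(n = length(values), mean = mean(values),
                 std = if (length(values) > 1) sd(values) else 0,
                 q1 = q[1], median = q[2], q3 = q[3],
                 whisker_low = min(inliers), whisker_high = max(inliers),
                 outliers = out),
            class = "boxplot_summary")
}

#' @export
print.boxplot_summary <- function(x, ...) {
  cat(sprintf(paste0("<boxplot_summary> n = %d, mean = %.4g, ",
                     "median = %.4g [q1 %.4g, q3 %.4g], %d outliers\n"),
              x$n, x$mean, x$median, x$q1, x$q3, length(x$outliers)))
  invisible(x)
}

#' Percent change of a central morphometric between dry and wet cohorts
#'
#' Swelling is quantified as `100 * (wet - dry) / dry` of the configured
#' central measure (median by default) of the same metric in the two
#' states.
#'
#' @param dry,wet [boxplot_summary()] objects (or numeric vectors, which
#'   are summarized first) of the same metric and units.
#' @param central `"median"` or `"mean"`.
#' @return percent change (positive = swelling).
#' @export
swelling_change <- function(dry, wet, central = c("median", "mean")) {
  central <- match.arg(central)
  if (!inherits(dry, "boxplot_summary")) dry <- boxplot_summary(dry)
  if (!inherits(wet, "boxplot_summary")) wet <- boxplot_summary(wet)
  d <- dry[[central]]
  w <- wet[[central]]
  if (d == 0) stop("dry central value is zero")
  100 * (w - d) / d
}

#' Dry-weight specification for surface-per-dry-weight estimates
#'
#' @param mode `"nonswelling"` (surface over volume times density),
#'   `"swelling_countpergram"` (median surface times the manufacturer's
#'   beads-per-gram), or `"swelling_imagedcount"` (beads-per-gram estimated
#'   as beads imaged in the dry sample over the sample weight).
#' @param density bead material density in g/ml (nonswelling mode).
#' @param count_per_gram beads per gram dry weight (swelling_countpergram).
#' @param sample_weight dry sample weight in g (swelling_imagedcount).
#' @param imaged_count number of beads imaged in the dry sample
#'   (swelling_imagedcount).
#' @return A `dry_weight_spec` list.
#' @export
dry_weight_spec <- function(mode = c("nonswelling", "swelling_countpergram",
                                     "swelling_imagedcount"),
                            density = NULL, count_per_gram = NULL,
                            sample_weight = NULL, imaged_count = NULL) {
  mode <- match.arg(mode)
  need <- switch(mode,
    nonswelling = !is.null(density) && density > 0,
    swelling_countpergram = !is.null(count_per_gram) && count_per_gram > 0,
    swelling_imagedcount = !is.null(sample_weight) && sample_weight > 0 &&
      !is.null(imaged_count) && imaged_count > 0)
  if (!need)
    stop("missing or invalid fields for dry-weight mode '", mode, "'")
  structure(list(mode = mode, density = density,
                 count_per_gram = count_per_gram,
                 sample_weight = sample_weight,
                 imaged_count = imaged_count),
            class = "dry_weight_spec")
}

#' Attachment surface area per gram dry weight
#'
#' For non-swelling beads: `S~ / (V~ * d)` where `S~` and `V~` are the
#' median surface area (um^2) and median volume (um^3) of the cohort and
#' `d` the material density (g/ml); the result is converted to cm^2/g.
#' For swelling beads the dry volume no longer relates to the wet surface,
#' so the estimate is the median wet surface area times the number of beads
#' per gram dry weight — either given directly or estimated as
#' `imaged_count / sample_weight`.
#'
#' @param records data.frame of bead records; the surface column is
#'   `surface_area_um2` (spheres) or `convex_surface_area_um2`, the volume
#'   column `volume_um3` or `bead_volume_um3`.
#' @param spec a [dry_weight_spec()].
#' @return surface per dry weight in cm^2/g.
#' @export
surface_per_dry_weight <- function(records, spec) {
  stopifnot(inherits(spec, "dry_weight_spec"))
  if (NROW(records) == 0L) stop("no bead records")
  s_col <- intersect(c("surface_area_um2", "convex_surface_area_um2"),
                     names(records))[1]
  if (is.na(s_col)) stop("records lack a surface area column")
  s_med <- quantile(records[[s_col]], 0.5, type = 5, names = FALSE)
  s_cm2 <- s_med * 1e-8                       # um^2 -> cm^2
  switch(spec$mode,
    nonswelling = {
      v_col <- intersect(c("volume_um3", "bead_volume_um3"),
                         names(records))[1]
      if (is.na(v_col)) stop("records lack a volume column")
      v_med <- quantile(records[[v_col]], 0.5, type = 5, names = FALSE)
      v_cm3 <- v_med * 1e-12                  # um^3 -> cm^3
      s_cm2 / (v_cm3 * spec$density)
    },
    swelling_countpergram = s_cm2 * spec$count_per_gram,
    swelling_imagedcount =
      s_cm2 * spec$imaged_count / spec$sample_weight)
}

#' Two-sample Student's t-test between cohorts
#'
#' Unpaired, equal-variance two-sample t-test (the default for comparing
#' pooled morphometric distributions of unequal size); a paired test is
#' available via `paired = TRUE`. Degenerate zero-variance input is handled
#' by convention: equal means give `p = 1`, unequal means `p = 0`.
#'
#' @param a,b numeric samples (`n >= 2` each).
#' @param paired logical.
#' @param alpha significance level for the flag (default 0.05).
#' @return list with `t`, `p`, `significant`.
#' @export
compare_groups_ttest <- function(a, b, paired = FALSE, alpha = 0.05) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group")
  pooled_var <- if (paired) var(a - b) else
    (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
      (length(a) + length(b) - 2)
  if (pooled_var == 0) {
    same <- isTRUE(all.equal(mean(a), mean(b)))
    t_ <- if (same) 0 else sign(mean(a) - mean(b)) * Inf
    p <- if (same) 1 else 0
  } else {
    tt <- t.test(a, b, paired = paired, var.equal = TRUE)
    t_ <- unname(tt$statistic)
    p <- tt$p.value
  }
  list(t = t_, p = p, significant = p < alpha)
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Tests the z-scored sample (centered by its mean, scaled by its SD)
#' against the standard normal distribution — testing raw morphometrics
#' against the standard normal would be rejected for scale reasons alone,
#' so the z-scoring makes the test a shape check.
#'
#' @param values numeric sample, `n >= 5`, nonzero variance.
#' @param alpha significance level (default 0.05).
#' @return list with `D`, `p`, `significant` (TRUE = normality rejected).
#' @export
ks_normality <- function(values, alpha = 0.05) {
  if (length(values) < 5L) stop("need n >= 5")
  s <- sd(values)
  if (s == 0) stop("zero variance")
  z <- (values - mean(values)) / s
  kt <- suppressWarnings(ks.test(z, "pnorm"))
  list(D = unname(kt$statistic), p = kt$p.value,
       significant = kt$p.value < alpha)
}
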