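#' Score a segmentation against a reference labelling
#'
#' Reproduces the manual-vs-automatic validation protocol: per-bead
#' morphometrics are computed for every label in the reference and the test
#' volume, the two groups are compared as pooled distributions (no bead
#' matching) for each morphometric — mean, SD, 25% quantile, median, 75%
#' quantile per group plus a two-sample Student's t-test — and the bead
#' count error is reported as `100 (n_ref - n_test) / n_ref` (headline
#' value rounded to the nearest integer percent; full precision kept).
#'
#' @param reference,test [labelvol3d()] objects on the same grid.
#' @param variant `"porous"` or `"nonporous"` moment support for the
#'   morphometrics.
#' @param alpha significance level (default 0.05).
#' @return A `validation_report` list: `n_reference`, `n_test`,
#'   `percent_count_error`, `percent_count_error_headline`, `metrics`
#'   (data.frame with one row per morphometric), and the two record tables.
#' @export
validate_segmentation <- function(reference, test,
                                  variant = c("porous", "nonporous"),
                                  alpha = 0.05) {
  stopifnot(inherits(reference, "labelvol3d"),
            inherits(test, "labelvol3d"))
  variant <- match.arg(variant)
  if (!identical(dim(reference$data), dim(test$data)))
    stop("grid mismatch between reference and test label volumes")
  ref_rec <- bead_morphometrics(reference, variant)
  test_rec <- bead_morphometrics(test, variant)
  validation_report(ref_rec, test_rec, alpha = alpha)
}

# build the report from two record tables (also used to pool several
# volume pairs: rbind the records, then call this once)
#' Build a validation report from two bead-record tables
#'
#' Lower-level entry of [validate_segmentation()]: use it to pool records
#' from several volume pairs before comparing (pooling increases
#' statistical power).
#'
#' @param ref_rec,test_rec data.frames from [bead_morphometrics()].
#' @param alpha significance level.
#' @return A `validation_report` list.
#' @export
validation_report <- function(ref_rec, test_rec, alpha = 0.05) {
  metrics <- c(equivalent_diameter_um = "Equivalent diameter [um]",
               principal_axis_1_um = "Principal axis 1 length [um]",
               principal_axis_2_um = "Principal axis 2 length [um]",
               principal_axis_3_um = "Principal axis 3 length [um]",
               convex_surface_area_um2 = "Convex surface area [um2]",
               bead_volume_um3 = "Bead volume [um3]",
               convex_hull_volume_um3 = "Convex hull volume [um3]",
               open_pore_volume_um3 = "Open pore volume [um3]",
               closed_pore_volume_um3 = "Closed pore volume [um3]",
               porosity = "Porosity [/]")
  n_ref <- nrow(ref_rec)
  n_test <- nrow(test_rec)
  if (n_ref == 0L) stop("reference has no beads")
  rows <- lapply(names(metrics), function(m) {
    a <- ref_rec[[m]]
    b <- test_rec[[m]]
    a <- a[!is.na(a)]
    b <- b[!is.na(b)]
    sa <- boxplot_summary(a)
    sb <- boxplot_summary(b)
    tt <- if (length(a) >= 2 && length(b) >= 2)
      compare_groups_ttest(a, b, alpha = alpha)
    else list(t = NA_real_, p = NA_real_, significant = NA)
    data.frame(metric = metrics[[m]],
               ref_mean = sa$mean, ref_std = sa$std, ref_q1 = sa$q1,
               ref_median = sa$median, ref_q3 = sa$q3,
               p = tt$p, significant = tt$significant,
               test_mean = sb$mean, test_std = sb$std, test_q1 = sb$q1,
               test_median = sb$median, test_q3 = sb$q3)
  })
  err <- 100 * (n_ref - n_test) / n_ref
  structure(list(n_reference = n_ref, n_test = n_test,
                 percent_count_error = err,
                 percent_count_error_headline = round(err),
                 metrics = do.call(rbind, rows),
                 reference_records = ref_rec, test_records = test_rec),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(paste0("<validation_report> %d reference vs %d test beads ",
                     "(count error %.2f%%, headline %d%%)\n"),
              x$n_reference, x$n_test, x$percent_count_error,
              x$percent_count_error_headline))
  print(x$metrics[, c("metric", "ref_median", "test_median", "p",
                      "significant")], row.names = FALSE)
  invisible(x)
}

#' Match segmented beads to ground-truth beads by overlap
#'
#' Greedy one-to-one matching of test labels to reference labels by
#' intersection-over-union (IoU), used to score phantom recoveries.
#'
#' @param reference,test [labelvol3d()] objects on the same grid.
#' @param iou_min minimum IoU for an accepted match (default 0.5).
#' @return list with `matches` (data.frame of `ref_id`, `test_id`, `iou`),
#'   `match_fraction` (matched reference beads / reference beads).
#' @export
match_labels <- function(reference, test, iou_min = 0.5) {
  r <- reference$data
  t_ <- test$data
  if (!identical(dim(r), dim(t_))) stop("grid mismatch")
  both <- r > 0L & t_ > 0L
  pairs <- paste(r[both], t_[both])
  ov <- table(pairs)
  key <- do.call(rbind, strsplit(names(ov), " "))
  ref_sz <- tabulate(r[r > 0L], nbins = max(r))
  test_sz <- tabulate(t_[t_ > 0L], nbins = max(0L, max(t_)))
  ri <- as.integer(key[, 1])
  ti <- as.integer(key[, 2])
  inter <- as.integer(ov)
  iou <- inter / (ref_sz[ri] + test_sz[ti] - inter)
  ord <- order(iou, decreasing = TRUE)
  used_r <- logical(max(r)); used_t <- logical(max(0L, max(t_)))
  out <- list()
  for (k in ord) {
    if (iou[k] < iou_min) break
    if (used_r[ri[k]] || used_t[ti[k]]) next
    used_r[ri[k]] <- TRUE
    used_t[ti[k]] <- TRUE
    out[[length(out) + 1L]] <- data.frame(ref_id = ri[k], test_id = ti[k],
                                          iou = iou[k])
  }
  matches <- if (length(out)) do.call(rbind, out)
             else data.frame(ref_id = integer(0), test_id = integer(0),
                             iou = numeric(0))
  list(matches = matches,
       match_fraction = nrow(matches) / max(1L, max(r)))
}
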