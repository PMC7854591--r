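test_that("boxplot summaries apply the interquartile outlier rule", {
  s <- boxplot_summary(c(1:10, 100))
  expect_equal(s$outliers, 100)
  expect_equal(s$whisker_high, 10)
  expect_equal(s$whisker_low, 1)
  expect_equal(s$median, 6)
  # quantiles at (k - 0.5)/n interpolation
  expect_equal(s$q1, 3.25)
  expect_equal(s$q3, 8.75)

  cs <- boxplot_summary(rep(4.2, 9))
  expect_equal(cs$q1, 4.2)
  expect_equal(cs$median, 4.2)
  expect_equal(cs$q3, 4.2)
  expect_length(cs$outliers, 0)

  one <- boxplot_summary(7)
  expect_equal(one$q1, 7)
  expect_equal(one$whisker_low, 7)
  expect_equal(one$whisker_high, 7)
  expect_error(boxplot_summary(numeric(0)), "empty")
})

test_that("the outlier rule matches a brute-force oracle on random data", {
  set.seed(71)
  for (i in 1:200) {
    n <- sample(3:60, 1)
    x <- switch(sample(3, 1),
                rnorm(n), rlnorm(n, sdlog = 1.2), rt(n, df = 2))
    s <- boxplot_summary(x)
    expect_identical(sort(s$outliers), oracle_outliers(x))
  }
})

test_that("swelling is the percent change of the central value", {
  expect_equal(swelling_change(boxplot_summary(rep(100, 5)),
                               boxplot_summary(rep(151.64, 5))), 51.64)
  x <- rlnorm(50, 5, 0.2)
  expect_equal(swelling_change(x, x), 0)
  expect_error(swelling_change(rep(0, 5), rep(1, 5)), "zero")
})

test_that("isotropically dilated beads swell by the dilation factor", {
  radii_dry <- c(10, 11, 12, 13, 14)
  eqd <- function(r) {
    vapply(r, function(ri) basic_morphometrics(ball_mask(ri), NULL, 1,
           "bead")$equivalent_diameter_um, numeric(1))
  }
  change <- swelling_change(eqd(radii_dry), eqd(1.2 * radii_dry))
  expect_equal(change, 20, tolerance = 0.1)  # +/- 2 percentage points
})

test_that("surface per dry weight follows the mode-specific formulas", {
  # monodisperse spheres, closed forms: S/(V d) = 3/(R d), in cm^2/g
  r <- 84.25
  met <- sphere_metrics(rep(r, 9))
  rec <- data.frame(surface_area_um2 = met$surface_area,
                    volume_um3 = met$volume)
  got <- surface_per_dry_weight(rec, dry_weight_spec("nonswelling",
                                                     density = 1.026))
  expect_equal(got, 3 / (r * 1e-4 * 1.026), tolerance = 1e-12)  # 347.06

  # digitized spheres converge to the same closed form
  counts <- sum(ball_mask(42))            # R = 84 um at 2 um voxels
  rec2 <- data.frame(surface_area_um2 = crofton_surface_area(ball_mask(42),
                                                             2),
                     volume_um3 = counts * 8)
  got2 <- surface_per_dry_weight(rec2, dry_weight_spec("nonswelling",
                                                       density = 1.026))
  expect_equal(got2, 3 / (84 * 1e-4 * 1.026), tolerance = 0.03)

  # swelling via count per gram: 1e5 um^2 = 1e-3 cm^2, 8e5 beads/g
  rec3 <- data.frame(convex_surface_area_um2 = rep(1e5, 5))
  expect_equal(surface_per_dry_weight(rec3,
    dry_weight_spec("swelling_countpergram", count_per_gram = 8e5)), 800)

  # imaged-count mode needs a positive count
  expect_error(dry_weight_spec("swelling_imagedcount", sample_weight = 0.01,
                               imaged_count = 0), "missing|invalid")
  expect_equal(surface_per_dry_weight(rec3,
    dry_weight_spec("swelling_imagedcount", sample_weight = 0.005,
                    imaged_count = 4000)),
    1e-3 * 4000 / 0.005)
})

test_that("the two-sample t-test behaves at its edges", {
  x <- c(5, 5, 5)
  r <- compare_groups_ttest(x, x)
  expect_equal(r$p, 1)
  expect_equal(r$t, 0)
  r2 <- compare_groups_ttest(c(5, 5), c(7, 7))
  expect_equal(r2$p, 0)
  set.seed(91)
  a <- rnorm(200)
  b <- rnorm(200, mean = 5)
  r3 <- compare_groups_ttest(a, b)
  expect_lt(r3$p, 0.001)
  r4 <- compare_groups_ttest(b, a)
  expect_equal(r4$t, -r3$t)
  expect_equal(r4$p, r3$p)
  # agrees with the reference implementation on regular data
  expect_equal(r3$t, unname(t.test(a, b, var.equal = TRUE)$statistic))
})

test_that("the KS check flags lognormal and passes normal samples", {
  set.seed(17)
  norm <- rnorm(10000)
  kn <- ks_normality(norm)
  expect_gt(kn$p, 0.05)
  expect_false(kn$significant)
  logn <- rlnorm(10000, sdlog = 0.8)
  kl <- ks_normality(logn)
  expect_lt(kl$p, 0.05)
  expect_true(kl$significant)
  expect_true(kn$D >= 0 && kn$D <= 1)
  expect_true(kl$D >= 0 && kl$D <= 1)
  expect_error(ks_normality(rep(3, 10)), "variance")
  expect_error(ks_normality(rnorm(4)), "n >= 5")
})
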