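mk_dist <- function(ccs, intensity, voltage) {
  structure(data.frame(ccs = ccs, intensity = intensity), voltage = voltage,
            class = c("ccs_dist", "data.frame"))
}

test_that("centroid CCS is the intensity-weighted mean", {
  expect_equal(centroid_ccs(mk_dist(c(30, 33.8, 40), c(0, 5, 0), 30)), 33.8)
  expect_equal(centroid_ccs(mk_dist(c(30, 40), c(2, 2), 30)), 35)
  expect_error(centroid_ccs(mk_dist(c(30, 40), c(0, 0), 30)), "all-zero")
})

test_that("fingerprints are column-normalised, ordered and bimodal", {
  bins <- seq(25, 45, 0.1)
  d1 <- mk_dist(bins, dnorm(bins, 34, 0.5), 30)
  d2 <- mk_dist(bins, 0.2 * dnorm(bins, 34, 0.5) + 0.2 * dnorm(bins, 37, 0.5), 42)
  d3 <- mk_dist(bins, dnorm(bins, 37, 0.5), 55)
  fp <- build_fingerprint(list(d3, d1, d2), ccs_bins = bins)
  expect_equal(unname(apply(fp, 2, max)), c(1, 1, 1))
  expect_equal(attr(fp, "voltages"), c(30, 42, 55))
  fp2 <- build_fingerprint(list(d1, d2, d3), ccs_bins = bins)
  expect_equal(unclass(fp), unclass(fp2))
  expect_error(build_fingerprint(list(d1, d1)), "duplicate")
  # mid-transition column shows exactly two ridges
  col <- fp[, "42"]
  peaks <- which(diff(sign(diff(col))) == -2) + 1
  expect_length(peaks[col[peaks] > 0.2], 2)
})

test_that("delta-CCS zeroes the reference voltage", {
  cv <- structure(data.frame(voltage = c(30, 35, 40), ccs = c(34, 35, 37)),
                  reference_voltage = 30,
                  class = c("unfolding_curve", "data.frame"))
  d <- delta_ccs(cv)
  expect_equal(d$ccs, c(0, 1, 3))
  cv$ccs <- rep(5, 3)
  expect_equal(delta_ccs(cv)$ccs, rep(0, 3))
  attr(cv, "reference_voltage") <- 99
  expect_error(delta_ccs(cv), "missing")
})

four_pl_curve <- function(v, L, U, v50, h) {
  structure(data.frame(voltage = v, ccs = L + (U - L) / (1 + exp(-h * (v - v50)))),
            reference_voltage = min(v), class = c("unfolding_curve", "data.frame"))
}

test_that("4PL fit recovers noise-free parameters and shifts equivariantly", {
  v <- seq(30, 60, 1)
  truth <- c(L = 33.8, U = 37.3, v50 = 40.3, h = 0.8)
  f <- fit_4pl(four_pl_curve(v, 33.8, 37.3, 40.3, 0.8))
  expect_true(f$converged)
  expect_equal(f$L, 33.8, tolerance = 1e-3)
  expect_equal(f$U, 37.3, tolerance = 1e-3)
  expect_equal(f$v50, 40.3, tolerance = 1e-3)
  expect_equal(f$hill, 0.8, tolerance = 1e-3)
  # uniform voltage shift moves v50 only
  f5 <- fit_4pl(four_pl_curve(v + 5, 33.8, 37.3, 45.3, 0.8))
  expect_equal(f5$v50, f$v50 + 5, tolerance = 1e-6)
  expect_equal(f5$hill, f$hill, tolerance = 1e-6)
  # constant curve flagged degenerate, not fitted
  flat <- four_pl_curve(v, 34, 34 + 1e-12, 40, 1)
  expect_true(fit_4pl(flat)$degenerate)
  expect_error(fit_4pl(four_pl_curve(seq(30, 34, 1), 33, 37, 32, 1)[1:5, ]),
               ">= 6")
})

test_that("ciu_chi inverts the fitted logistic exactly", {
  f <- fit_4pl(four_pl_curve(seq(30, 60, 1), 33.8, 37.3, 43.8, 1.0))
  expect_identical(ciu_chi(f, 50), f$v50)
  expect_equal(ciu_chi(f, 10), f$v50 - log(9) / f$hill)
  expect_equal(ciu_chi(f, 10), 43.8 - log(9), tolerance = 1e-3)
  chis <- seq(5, 95, 5)
  vchi <- ciu_chi(f, chis)
  expect_true(all(diff(vchi) > 0))
  # inverse property: the unfolded fraction at ciu_chi(chi) is chi/100
  frac <- 1 / (1 + exp(-f$hill * (vchi - f$v50)))
  expect_equal(frac, chis / 100, tolerance = 1e-12)
  expect_error(ciu_chi(f, 0), "strictly")
  expect_error(ciu_chi(f, 100), "strictly")
  bad <- f; bad$converged <- FALSE
  expect_error(ciu_chi(bad, 50), "converged")
})

test_that("chi profiles aggregate replicates and exclude failures", {
  v <- seq(30, 60, 1)
  fits <- lapply(1:3, function(i) fit_4pl(four_pl_curve(v, 33.8, 37.3, 40.3, 0.8)))
  prof <- chi_profile(fits)
  expect_equal(nrow(prof), 9)
  expect_equal(prof$sd_v, rep(0, 9), tolerance = 1e-9)
  expect_true(all(diff(prof$mean_v) > 0))
  bad <- fits[[1]]; bad$converged <- FALSE
  expect_warning(p2 <- chi_profile(c(fits, list(bad))), "excluding 1")
  expect_equal(p2$n[1], 3)
  expect_error(suppressWarnings(chi_profile(list(bad))), "no converged")
})

test_that("one-way ANOVA matches hand computation and the t-test identity", {
  cmp <- anova_compare(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
  expect_equal(cmp$f_stat, 3.0)
  expect_equal(cmp$p_value, pf(3, 2, 6, lower.tail = FALSE))
  # two groups: F equals the squared pooled-variance t statistic
  g1 <- c(40.1, 40.7, 39.9, 40.5); g2 <- c(43.0, 43.6, 43.2, 43.9)
  cmp2 <- anova_compare(list(a = g1, b = g2))
  tt <- t.test(g1, g2, var.equal = TRUE)
  expect_equal(cmp2$f_stat, unname(tt$statistic)^2)
  expect_equal(cmp2$p_value, tt$p.value)
  # degenerate null: equal constants
  cmp3 <- anova_compare(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(cmp3$p_value, 1)
  expect_true(cmp3$degenerate)
  expect_error(anova_compare(list(a = 1:3)), ">= 2 groups")
  expect_error(anova_compare(list(a = 1, b = 1:2)), "replicate")
})

test_that("ejection fractions and logistic ejection fits round-trip 42 V", {
  expect_equal(ejection_fraction(100, 100), 0.5)
  expect_equal(ejection_fraction(100, 0), 0)
  expect_error(ejection_fraction(0, 0), "> 0")
  expect_error(ejection_fraction(-1, 2), ">= 0")

  v <- seq(30, 55, 1)
  frac <- 1 - survival_fraction(v, 42, 1.5)
  fit <- fit_ejection(v, frac)
  expect_true(fit$converged)
  expect_equal(fit$v50_eject, 42, tolerance = 0.1 / 42)
  expect_equal(fit$slope_eject, 1.5, tolerance = 1e-3)
  expect_gt(fit$slope_eject, 0)
  expect_true(fit_ejection(v, rep(0, length(v)))$degenerate)
  expect_error(fit_ejection(v[1:4], frac[1:4]), ">= 5")
})

test_that("laboratory-frame collision energy is charge times voltage", {
  expect_identical(elab(30, 12), 360)
  expect_identical(elab(60, 12), 720)
  expect_identical(elab(40, 12), 480)
  expect_error(elab(30, 0), ">= 1")
})
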