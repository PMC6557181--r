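# A reusable noise-free D2O curve of the tiny two-layer system
tiny_d2o <- function() {
  render_contrast_series(tiny_two_layer_system())[["D2O"]]
}

test_that("kinematic transform is linear and matches a numeric cosine oracle", {
  D <- 120; ns <- 15
  q <- seq(0.03, 0.25, length.out = 40)
  # zero coefficients -> zero prediction
  sp0 <- spline_correlation(D, rep(0, ns))
  expect_equal(kinematic_transform(sp0, q), rep(0, length(q)))
  # random coefficient vectors against brute-force integration of p(z)
  set.seed(11)
  for (i in 1:3) {
    cf <- rnorm(ns)
    sp <- spline_correlation(D, cf)
    got <- kinematic_transform(sp, q)
    want <- oracle_cosine_transform(function(z) evaluate_p(sp, z), D, q)
    expect_equal(got, want, tolerance = 1e-4)
  }
})

test_that("a narrow p(z) near z = 0 gives a Porod-like plateau", {
  D <- 200; ns <- 40
  cf <- c(1, rep(0, ns - 1))  # first spline hugs z = 0
  sp <- spline_correlation(D, cf)
  q <- seq(0.02, 0.2, length.out = 30)
  u <- kinematic_transform(sp, q)
  want <- oracle_cosine_transform(function(z) evaluate_p(sp, z), D, q)
  expect_equal(u, want, tolerance = 1e-2)
  # q^4 R barely varies while q changes tenfold
  expect_lt(diff(range(u)) / mean(u), 0.25)
})

test_that("transform of a slab's p(z) reproduces its kinematic reflectivity", {
  # sharp slab: drho/dz is two deltas; its autocorrelation is a delta pair.
  # Approximate the deltas by narrow Gaussians well inside the spline
  # resolution and compare with the closed form.
  a1 <- 3e-6; a2 <- -2e-6; t <- 60; D <- 100
  s <- 1.5
  pfun <- function(z) {
    (a1^2 + a2^2) / 2 * 2 * exp(-z^2 / (2 * s^2)) / sqrt(2 * pi * s^2) +
      a1 * a2 * exp(-(z - t)^2 / (2 * s^2)) / sqrt(2 * pi * s^2)
  }
  q <- seq(0.04, 0.2, length.out = 25)
  u <- oracle_cosine_transform(pfun, D, q)
  want <- q^4 * oracle_kinematic_slab(q, a1, a2, t) / (16 * pi^2)
  # Gaussian widening damps by exp(-q^2 s^2); undo it for the comparison
  expect_equal(u / exp(-q^2 * s^2 / 2 * 2), want, tolerance = 0.02)
})

test_that("regularized fits behave across the lambda range", {
  ct <- tiny_d2o()
  D <- 90
  f0 <- fit_given_lambda(ct, D, 0)
  finf <- fit_given_lambda(ct, D, 1e12 * f0$chi2 / max(f0$Nc, 1e-30))
  # strong regularization: much smoother, worse fit
  expect_lt(finf$Nc, 1e-3 * f0$Nc)
  expect_gt(finf$chi2, f0$chi2)
  expect_error(fit_given_lambda(ct, D, -1), "non-negative")
  expect_error(fit_given_lambda(ct, -10, 1), "positive")
})

test_that("scaling all weights with lambda leaves the minimizer unchanged", {
  ct <- tiny_d2o()
  lam <- 3e-4
  d1 <- reflift:::ift_design(ct, 90)
  f1 <- fit_given_lambda(ct, 90, lam, design = d1)
  d2 <- d1; d2$w <- 2 * d1$w
  f2 <- fit_given_lambda(ct, 90, 2 * lam, design = d2)
  expect_equal(f1$spline$coefficients, f2$spline$coefficients,
               tolerance = 1e-9)
})

test_that("stability scans are monotone in the penalty sense", {
  ct <- tiny_d2o()
  sc <- stability_scan(ct, 90, n_lambda = 25)
  expect_true(all(diff(sc$Nc) < 1e-9 * max(sc$Nc)))
  expect_true(all(diff(sc$chi2) > -1e-9 * max(sc$chi2)))
  expect_true(all(is.finite(sc$Nc)) && all(is.finite(sc$chi2)))
  expect_error(stability_scan(ct, 90, n_lambda = 10), "at least 20")
})

test_that("lambda selection finds the inflection of a synthetic scan", {
  # logistic-shaped log Nc with known inflection at lambda = 10^c
  lg <- 10^seq(-4, 4, length.out = 41)
  cc <- 0.7; b <- 2; w <- 1.2
  scan <- structure(list(lambda = lg,
                         Nc = 10^(2 - b * tanh((log10(lg) - cc) / w)),
                         chi2 = rep(1, 41)),
                    class = "stability_scan")
  sel <- select_lambda(scan)
  expect_false(sel$flagged)
  step <- diff(log10(lg))[1]
  expect_lt(abs(log10(sel$lambda) - cc), step)
  # refinement by 2x moves the choice by less than one coarse step
  lg2 <- 10^seq(-4, 4, length.out = 81)
  scan2 <- structure(list(lambda = lg2,
                          Nc = 10^(2 - b * tanh((log10(lg2) - cc) / w)),
                          chi2 = rep(1, 81)),
                     class = "stability_scan")
  sel2 <- select_lambda(scan2)
  expect_lt(abs(log10(sel2$lambda) - log10(sel$lambda)), step)
})

test_that("a featureless scan triggers the flagged plateau fallback", {
  lg <- 10^seq(-4, 4, length.out = 40)
  scan <- structure(list(lambda = lg, Nc = 10^seq(3, 2, length.out = 40),
                         chi2 = rep(1, 40)),
                    class = "stability_scan")
  sel <- select_lambda(scan)
  expect_true(sel$flagged)
  expect_true(sel$lambda >= min(lg) && sel$lambda <= max(lg))
})

test_that("trial-D estimation flags underestimated extents of a small system", {
  sys <- tiny_two_layer_system()
  curves <- render_contrast_series(sys)
  est <- estimate_D(list(curves$D2O, curves$H2O), seq(30, 150, by = 10),
                    n_splines = 18)
  # truth: 70 A of layers plus roughness tails. The knee on this small,
  # jittery scan is not sharp, but it must sit at or beyond the true
  # extent and badly underestimated D must fit far worse.
  expect_gte(est$D_best, 60)
  expect_named(est$table, c("D", "tail", "oscillations",
                            "chi2n_1", "chi2n_2"), ignore.order = TRUE)
  tab <- est$table
  for (col in c("chi2n_1", "chi2n_2")) {
    expect_gt(tab[[col]][tab$D == 40], 10 * tab[[col]][tab$D == 100])
  }
  expect_length(est$per_curve_D, 2)
})
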