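test_that("smeared components reduce to the expected plateaus", {
  # uniform model: erf terms telescope to the constant
  m <- interfacial_model(D = 120, N = 12, rho = 3e-6, h = 0)
  z <- seq(10, 110, by = 7)
  expect_equal(smeared_component(m, z, "sld", rho_fronting = 3e-6,
                                 rho_backing = 3e-6),
               rep(3e-6, length(z)))
  # hydration boundary conditions far outside the film
  expect_equal(smeared_component(m, 1e5, "hydration"), 1, tolerance = 1e-12)
  expect_equal(smeared_component(m, -1e5, "hydration"), 0, tolerance = 1e-12)
  expect_error(smeared_component(m, NaN, "hydration"), "finite")
})

test_that("sigma -> 0 limit recovers the step profile inside each layer", {
  rho <- c(1e-6, 2e-6, 3e-6, 4e-6)
  m <- interfacial_model(D = 100, N = 4, rho = rho, h = 0, q_max = 1e4)
  expect_lt(m$sigma, 1e-3)
  centres <- c(12.5, 37.5, 62.5, 87.5)
  expect_equal(smeared_component(m, centres, "sld", rho_fronting = 0,
                                 rho_backing = 6e-6), rho, tolerance = 1e-12)
})

test_that("composite SLD combines the profiles with the solvent", {
  m <- interfacial_model(D = 100, N = 10, rho = 2e-6, h = 0.5)
  # plateau limit of the mixing rule: rho (1-h) + h rho_solv
  expect_equal(composite_sld(m, 50, 6.35e-6, 2.07e-6), 4.175e-6,
               tolerance = 1e-9)
  # full hydration: pure solvent well inside the film
  mf <- interfacial_model(D = 100, N = 10, rho = 2e-6, h = 1)
  expect_equal(composite_sld(mf, 50, 6.35e-6, 2.07e-6), 6.35e-6,
               tolerance = 1e-9)
  # no hydration: equals the smeared non-solvent profile away from the
  # backing virtual boundary (where h necessarily rises to 1)
  m0 <- interfacial_model(D = 100, N = 10, rho = 2e-6, h = 0)
  z <- seq(-10, 75, by = 3)
  expect_equal(composite_sld(m0, z, 6.35e-6, 2.07e-6),
               smeared_component(m0, z, "sld", rho_fronting = 2.07e-6,
                                 rho_backing = 6.35e-6))
})

test_that("composite SLD stays inside the hull of the step values", {
  # rho(z) is a convex mixture of {rho_f, rho_n, rho_s} and the composite a
  # further mixture with rho_s, so it can never leave that hull; the
  # hydration profile likewise stays in [0, 1]
  set.seed(41)
  bad <- 0L
  for (i in 1:20) {
    N <- sample(5:40, 1)
    m <- interfacial_model(D = runif(1, 50, 300), N = N,
                           rho = runif(N, -0.56e-6, 6.35e-6),
                           h = runif(N),
                           sigma = runif(1, 3.15, 6.28))
    rho_s <- runif(1, -0.56e-6, 6.35e-6)
    rho_f <- runif(1, 0, 4e-6)
    z <- seq(-30, m$D + 30, length.out = 200)
    v <- composite_sld(m, z, rho_s, rho_f)
    hull <- range(c(rho_f, rho_s, m$rho))
    hz <- smeared_component(m, z, "hydration")
    bad <- bad + (min(v) < hull[1] - 1e-15) + (max(v) > hull[2] + 1e-15) +
      any(hz < -1e-15 | hz > 1 + 1e-15)
  }
  expect_equal(bad, 0L)
  # for a monotone composite sequence the tighter per-layer bound holds
  mm <- interfacial_model(D = 100, N = 10,
                          rho = seq(0.5e-6, 4e-6, length.out = 10),
                          h = seq(0, 0.8, length.out = 10), sigma = 4)
  z <- seq(-20, 120, by = 1)
  v <- composite_sld(mm, z, 6.35e-6, 0)
  sources <- c(0, 6.35e-6, mm$rho * (1 - mm$h) + mm$h * 6.35e-6)
  expect_gte(min(v), min(sources) - 1e-15)
  expect_lte(max(v), max(sources) + 1e-15)
})

test_that("merging two identical adjacent layers leaves the profile unchanged", {
  # same physical profile described with N and 2N sub-layers
  rho <- c(5e-6, 5e-6, 1e-6, 1e-6)
  m1 <- interfacial_model(D = 100, N = 4, rho = rho, h = c(0, 0, 0.4, 0.4),
                          sigma = 4)
  m2 <- interfacial_model(D = 100, N = 2, rho = c(5e-6, 1e-6), h = c(0, 0.4),
                          sigma = 4)
  z <- seq(-10, 110, by = 1)
  expect_equal(composite_sld(m1, z, 6.35e-6, 2.07e-6),
               composite_sld(m2, z, 6.35e-6, 2.07e-6), tolerance = 1e-12)
})

test_that("model validation rejects bad inputs", {
  expect_error(interfacial_model(D = 0), "positive")
  expect_error(interfacial_model(D = 100, h = 1.2), "hydration")
  expect_error(interfacial_model(D = 100, rho = 1e-5), "rho")
  expect_error(interfacial_model(D = 100, sigma = 100), "sigma")
  lim <- sigma_limits(0.25)
  expect_equal(lim, c(pi, 2 * pi), tolerance = 1e-12)
})

test_that("discretization covers the smeared tails and uses d = D/N", {
  m <- interfacial_model(D = 170, N = 50, rho = 4e-6, h = 0.2,
                         sigma = sigma_limits(0.25)[2])
  dz <- discretize_model(m, rho_solvent = 6.35e-6, rho_fronting = 2.07e-6)
  expect_equal(unique(dz$thickness), 170 / 50)
  # padding of at least 3 sigma on each side
  expect_gte(-min(dz$z) + m$d / 2, 3 * m$sigma)
  expect_gte(max(dz$z) - m$D + m$d / 2, 3 * m$sigma)
  # sampled tail reaches within 1% of the plateau values
  n <- length(dz$sld)
  expect_lt(abs(dz$sld[2] - 2.07e-6) / abs(6.35e-6 - 2.07e-6), 0.01)
  expect_lt(abs(dz$sld[n - 1] - 6.35e-6) / abs(6.35e-6 - 2.07e-6), 0.01)
})

test_that("profile tables carry one composite column per contrast", {
  m <- interfacial_model(D = 60, N = 6, rho = 2e-6, h = 0.1)
  cts <- list(contrast_curve(c(0.01, 0.02), c(1, 0.5), rho_fronting = 2.07e-6,
                             rho_solvent = 6.35e-6, label = "D2O"),
              contrast_curve(c(0.01, 0.02), c(1, 0.5), rho_fronting = 2.07e-6,
                             rho_solvent = -0.56e-6, label = "H2O"))
  tab <- profile_table(m, cts)
  expect_named(tab, c("z", "rho_nonsolvent", "hydration",
                      "rho_composite_D2O", "rho_composite_H2O"))
  expect_equal(tab$z, seq(-20, 80, by = 1))
})
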