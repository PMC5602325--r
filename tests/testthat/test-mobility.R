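test_that("MSD matches analytic cases", {
  still <- data.frame(frame = 1:10, x_um = rep(1, 10), y_um = rep(2, 10))
  m <- msd(still, dt = 5)
  expect_true(all(m$msd_um2 == 0))

  ballistic <- data.frame(frame = 1:10, x_um = (1:10) * 0.1, y_um = 0)
  mb <- msd(ballistic, dt = 5)
  expect_equal(mb$msd_um2, (mb$n * 0.1)^2, tolerance = 1e-12)

  set.seed(1)
  slopes <- vapply(1:300, function(i) {
    fit_D(msd(mk_brownian_track(1, 12)))
  }, 0)
  expect_equal(mean(slopes), 1, tolerance = 0.07)

  expect_error(msd(still[1:4, ]), "too short")
})

test_that("fit_D reads the gradient of the first four MSD points", {
  tau <- seq(5, 40, 5)
  exact <- data.frame(tau_ms = tau,
                      msd_um2 = 4 * 1 * tau / 1000 + 4 * (0.04)^2, n = 1:8)
  expect_equal(as.numeric(fit_D(exact)), 1, tolerance = 1e-9)
  expect_equal(as.numeric(fit_D(exact, sigma = 40, fix_intercept = TRUE)), 1,
               tolerance = 1e-9)
  expect_error(fit_D(exact[1:3, ]), "at least 4")

  # unbiased on Brownian tracks at moderate length
  set.seed(2)
  Ds <- vapply(1:500, function(i) fit_D(msd(mk_brownian_track(1.5, 10,
                                                              sigma = 40))),
               0)
  expect_lt(abs(mean(Ds) - 1.5) / 1.5, 0.05)

  # stationary tracks with pure localization noise give D near zero
  set.seed(3)
  D0 <- vapply(1:300, function(i) {
    tr <- data.frame(frame = 1:10,
                     x_um = rnorm(10, 0, 0.04), y_um = rnorm(10, 0, 0.04))
    fit_D(msd(tr))
  }, 0)
  expect_lt(abs(mean(D0)), 3 * sd(D0) / sqrt(length(D0)) + 0.02)
})

test_that("CDF mixture fitting resolves two populations and rejects one", {
  mix <- data.frame(A = c(0.2, 0.8), D = c(0.15, 1.5))
  r2 <- generate_displacements(1000, mix, dt = 5, sigma = 40, seed = 1)
  fit <- fit_cdf_mixture(r2, dt = 5)
  expect_equal(fit$n_components, 2)
  expect_lt(abs(fit$components$A[1] - 0.2), 0.15)
  expect_true(all(diff(fit$components$D) > 0))
  expect_equal(sum(fit$components$A), 1, tolerance = 1e-6)

  # spurious second component rejected on single-population data
  ns <- vapply(1:10, function(s) {
    r2 <- generate_displacements(1000, data.frame(A = 1, D = 1), dt = 5,
                                 sigma = 40, seed = 200 + s)
    fit_cdf_mixture(r2, dt = 5)$n_components
  }, 0L)
  expect_gte(mean(ns == 1), 0.9)

  expect_error(fit_cdf_mixture(rep(0.01, 200)), "degenerate")
  expect_error(fit_cdf_mixture(r2[1:50]), "at least 100")
})

test_that("Gamma mixture fits recover diffusion-coefficient distributions", {
  set.seed(4)
  single <- rgamma(600, shape = 4, rate = 4 / 1.3)
  g <- fit_gamma_mixture(single, m = 4)
  expect_lt(abs(weighted.mean(g$components$D, g$components$A) - 1.3) / 1.3,
            0.1)

  two <- c(rgamma(500, shape = 4, rate = 4 / 0.2),
           rgamma(500, shape = 4, rate = 4 / 2))
  g2 <- fit_gamma_mixture(two, m = 4)
  expect_lt(abs(g2$components$D[1] - 0.2) / 0.2, 0.3)
  expect_lt(abs(g2$components$D[2] - 2) / 2, 0.3)

  # m = 1 reduces the component density to an exponential
  x <- seq(0.01, 5, by = 0.01)
  dens_m1 <- (1 / 1.5)^1 * x^0 * exp(-x / 1.5) / gamma(1)
  expect_equal(dens_m1, dexp(x, 1 / 1.5), tolerance = 1e-12)
})

test_that("anomalous-diffusion fits recover (K, alpha) and the Brownian limit", {
  tau <- seq(5, 30, 5)
  off <- 4 * (40 / 1000)^2
  exact <- data.frame(tau_ms = tau,
                      msd_um2 = off + 4 * 0.1 * (tau / 1000)^0.6)
  fa <- fit_anomalous(exact, sigma = 40)
  expect_equal(fa$K, 0.1, tolerance = 1e-3)
  expect_equal(fa$alpha, 0.6, tolerance = 1e-3)

  # Brownian data: alpha near 1 and the Brownian fit at least as good
  set.seed(5)
  curves <- lapply(1:400, function(i) msd(mk_brownian_track(1, 12),
                                          max_lag = 6))
  mean_msd <- data.frame(
    tau_ms = curves[[1]]$tau_ms,
    msd_um2 = rowMeans(vapply(curves, function(c) c$msd_um2,
                              numeric(6))))
  fb <- fit_anomalous(mean_msd, sigma = 0)
  expect_gt(fb$alpha, 0.9)
  expect_lte(fb$chisq, fb$brownian$chisq + 1e-12)

  bad <- data.frame(tau_ms = tau, msd_um2 = rep(off / 2, 6))
  expect_error(fit_anomalous(bad, sigma = 40), "negative MSD")
  expect_error(fit_anomalous(exact[1:3, ]), "at least 4")
})
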