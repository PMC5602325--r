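test_that("single-fluorophore brightness is the modal foci intensity", {
  tr <- do.call(rbind, lapply(1:4, function(S) {
    generate_bleach_traces(60, S, I_GFP = 5000, t_b = 40, noise_cv = 0.08,
                           n_frames = 30, seed = S)
  }))
  I <- as.vector(tr)
  est <- suppressWarnings(estimate_single_brightness(I[I > 0]))
  expect_lt(abs(as.numeric(est) - 5000) / 5000, 0.1)
  expect_error(estimate_single_brightness(rep(5000, 10)), "at least 50")
})

test_that("photobleach constants are recovered from decay fits", {
  tm <- seq(0, 200, by = 5)
  expect_equal(as.numeric(fit_bleach_constant(3e4 * exp(-tm / 40), tm)), 40,
               tolerance = 1e-6)
  tr <- generate_bleach_traces(300, 5, t_b = 40, noise_cv = 0.1,
                               n_frames = 40, seed = 4)
  expect_lt(abs(as.numeric(fit_bleach_constant(tr)) - 40) / 40, 0.1)
  expect_error(fit_bleach_constant(rep(5, 20), seq(0, 95, 5)), "decay")
})

test_that("bleach correction is the exact inverse of exponential decay", {
  calib <- calibration(I_GFP = 5000, t_b = 40)
  frames <- 1:20
  decayed <- 7 * 5000 * exp(-(frames - 1) * 5 / 40)
  s <- track_stoichiometry(data.frame(frame = frames, intensity = decayed),
                           calib, dt = 5)
  expect_equal(s$S, 7, tolerance = 1e-9)
  corrected <- decayed * exp((frames - 1) * 5 / 40)
  expect_equal(corrected, rep(7 * 5000, 20), tolerance = 1e-9)

  flat <- track_stoichiometry(
    data.frame(frame = 1:5, intensity = rep(7 * 5000, 5)), calib, dt = 0)
  expect_equal(flat$S, 7)

  late <- track_stoichiometry(
    data.frame(frame = 100:110, intensity = rep(5000, 11)), calib)
  expect_false(late$included)
  expect_match(late$reason, "frame 70")
})

test_that("stoichiometry recovery from synthetic bleaching tracks", {
  calib <- calibration(I_GFP = 5000, t_b = 40)
  set.seed(10)
  est <- vapply(1:20, function(i) {
    tr <- generate_bleach_traces(1, 7, I_GFP = 5000, t_b = 40,
                                 noise_cv = 0.05, n_frames = 8,
                                 seed = 400 + i)
    track_stoichiometry(
      data.frame(frame = 1:8, intensity = tr[1, ]), calib)$S
  }, 0)
  expect_lte(abs(median(est) - 7), 1)
})

test_that("periodicity finds the cluster unit and rejects null samples", {
  for (u in c(3, 5, 7, 9)) {
    s <- generate_stoichiometries(300, u = u, k_range = 1:4,
                                  noise_sd = u / 7, seed = 50 + u)
    p <- periodicity(s)
    expect_lt(abs(p$period - u), 0.5)
  }
  s3 <- rep(c(3, 6, 9, 12), each = 10)
  expect_lt(abs(periodicity(s3)$period - 3), 0.3)

  nulls <- vapply(1:5, function(i) {
    set.seed(70 + i)
    is.na(periodicity(runif(200, 1, 30))$period)
  }, TRUE)
  expect_gte(mean(nulls), 0.8)
  expect_error(periodicity(1:10), "at least 30")
})

test_that("autofluorescence correction subtracts the scaled red channel", {
  set.seed(1)
  green <- matrix(runif(100, 10, 50), 10)
  red <- green / 0.9
  expect_true(all(autofluorescence_correct(green, red, 0.9) < 1e-9))
  expect_equal(autofluorescence_correct(green, red, 0), green)
  expect_error(autofluorescence_correct(green, matrix(0, 5, 5)), "differ")
})

test_that("CoPro deconvolution recovers pool copy numbers", {
  p <- sim_params(seed = 41)
  sim <- generate_cell_stack(p, pool_counts = c(cytoplasm = 500,
                                                nucleus = 100),
                             n_frames = 1)
  fr <- sim$stack[[1]] - p$offset
  ctr <- sim$truth$center_px
  cellb <- mk_circle_boundary(ctr["x"], ctr["y"], sim$truth$r_cell_px,
                              label = "cell")
  nucb <- mk_circle_boundary(ctr["x"], ctr["y"], sim$truth$r_nucleus_px)
  cp <- copro_pool_counts(fr, cellb, nucb, calibration(),
                          psf_sigma_px = 230 / 80)
  expect_lt(abs(cp$nuclear - 100) / 100, 0.1)
  expect_lt(abs(cp$cytoplasmic - 500) / 500, 0.1)

  z <- copro_pool_counts(matrix(0, 80, 80), cellb, nucb)
  expect_equal(c(z$nuclear, z$cytoplasmic), c(0, 0))

  # nuclear-only pool: cytoplasmic estimate collapses
  nuc_only <- generate_cell_stack(sim_params(seed = 42),
                                  pool_counts = c(cytoplasm = 0,
                                                  nucleus = 200),
                                  n_frames = 1, noise = FALSE)
  cp2 <- copro_pool_counts(nuc_only$stack[[1]], cellb, nucb, calibration(),
                           psf_sigma_px = 230 / 80)
  expect_lt(cp2$cytoplasmic, 0.05 * cp2$nuclear)

  # linearity: doubling the pools doubles the noise-free estimates
  half <- generate_cell_stack(sim_params(seed = 43),
                              pool_counts = c(cytoplasm = 250, nucleus = 50),
                              n_frames = 1, noise = FALSE)
  dbl <- generate_cell_stack(sim_params(seed = 43),
                             pool_counts = c(cytoplasm = 500, nucleus = 100),
                             n_frames = 1, noise = FALSE)
  e1 <- copro_pool_counts(half$stack[[1]], cellb, nucb, calibration(),
                          psf_sigma_px = 230 / 80)
  e2 <- copro_pool_counts(dbl$stack[[1]], cellb, nucb, calibration(),
                          psf_sigma_px = 230 / 80)
  expect_equal(e2$nuclear / e1$nuclear, 2, tolerance = 0.01)
  expect_equal(e2$cytoplasmic / e1$cytoplasmic, 2, tolerance = 0.01)
})

test_that("the pool stoichiometry bound matches its closed form", {
  b <- pool_stoichiometry_bound(949, D = 6, dt = 5, w = 230, d = 5)
  expect_equal(b$b_nm, sqrt(4 * 6 * 0.005) * 1000, tolerance = 1e-9)
  expect_equal(round(b$b_nm), 346)

  fixed_b <- pool_stoichiometry_bound(949, w = 230, d = 5, b = 340)
  expect_equal(fixed_b$S_max, 949 * ((340 + 230) / 5000)^3,
               tolerance = 1e-12)
  expect_equal(fixed_b$S_max, 1.41, tolerance = 0.01)

  expect_equal(pool_stoichiometry_bound(0, D = 6)$S_max, 0)
})

test_that("stoichiometry KDEs are normalized densities", {
  set.seed(2)
  k <- stoich_kde(rep(7, 50) + rnorm(50, 0, 0.05))
  expect_equal(sum(k$density) * diff(k$grid[1:2]), 1, tolerance = 0.01)
  expect_lt(abs(k$mode - 7), 0.2)

  bim <- stoich_kde(c(rnorm(300, 7, 0.5), rnorm(300, 21, 0.5)))
  dens <- bim$density
  peaks <- which(diff(sign(diff(dens))) < 0) + 1
  big <- bim$grid[peaks[dens[peaks] > 0.25 * max(dens)]]
  expect_equal(length(big), 2)
  expect_lt(abs(big[1] - 7), 1)
  expect_lt(abs(big[2] - 21), 1)

  expect_error(stoich_kde(numeric(0)), "at least 2")
})
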