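test_that("image stacks conserve photons and honour the bleach constant", {
  p <- sim_params(seed = 11)
  sim <- generate_cell_stack(p, pool_counts = c(cytoplasm = 200, nucleus = 50),
                             foci_spec = data.frame(S = 7, D = 1,
                                                    compartment = "nucleus"),
                             n_frames = 5, noise = FALSE)
  total_true <- (200 + 50 + 7) * p$single_brightness *
    exp(-sim$truth$times_ms / p$bleach_constant)
  expect_equal(vapply(sim$stack, sum, 0), total_true, tolerance = 0.01)

  # a single immobile fluorophore integrates to I_GFP at t = 0
  one <- generate_cell_stack(sim_params(seed = 2),
                             foci_spec = data.frame(S = 1, D = 0,
                                                    compartment = "cytoplasm"),
                             n_frames = 1, noise = FALSE)
  expect_equal(sum(one$stack[[1]]), 5000, tolerance = 1e-6)
  # peak pixel of a pixel-integrated PSF is near I_GFP / (2 pi sigma_px^2)
  expect_equal(max(one$stack[[1]]), 5000 / (2 * pi * (230 / 80)^2),
               tolerance = 0.05)

  # linearity of brightness in stoichiometry
  seven <- generate_cell_stack(sim_params(seed = 2),
                               foci_spec = data.frame(S = 7, D = 0,
                                                      compartment = "cytoplasm"),
                               n_frames = 1, noise = FALSE)
  expect_equal(sum(seven$stack[[1]]), 7 * 5000, tolerance = 1e-6)
})

test_that("empty stacks contain only camera noise and fixed seeds reproduce", {
  p <- sim_params(seed = 5)
  sim <- generate_cell_stack(p, n_frames = 3)
  fr <- sim$stack[[1]]
  expect_equal(mean(fr), p$offset, tolerance = 0.05)
  expect_lt(sd(fr), 3 * p$read_noise)

  sim2 <- generate_cell_stack(sim_params(seed = 5), n_frames = 3)
  expect_identical(sim$stack, sim2$stack)

  expect_error(
    generate_cell_stack(p, foci_spec = data.frame(S = 1, D = 0,
                                                  compartment = "moon"),
                        n_frames = 1),
    "compartment")
  expect_error(
    generate_cell_stack(p, foci_spec = data.frame(S = 1, D = 0,
                                                  compartment = "cytoplasm"),
                        foci_xy = matrix(c(1, 1), 1), n_frames = 1),
    "outside cell")
})

test_that("displacement generator matches the Brownian mixture law", {
  r2 <- generate_displacements(20000, data.frame(A = 1, D = 1), dt = 5,
                               sigma = 0, seed = 1)
  expect_equal(mean(r2), 4 * 1 * 0.005, tolerance = 0.03)

  expect_true(all(generate_displacements(100, data.frame(A = 1, D = 0),
                                         sigma = 0, seed = 1) == 0))
  expect_error(generate_displacements(10, data.frame(A = 1, D = -1)),
               "non-negative")
  expect_error(generate_displacements(10, data.frame(A = c(0.5, 0.2),
                                                     D = c(1, 2))),
               "sum to 1")

  # empirical CDF converges to the closed-form two-component mixture
  mix <- data.frame(A = c(0.2, 0.8), D = c(0.15, 1.5))
  pc <- function(x) {
    0.2 * (1 - exp(-x / (4 * 0.15 * 0.005))) +
      0.8 * (1 - exp(-x / (4 * 1.5 * 0.005)))
  }
  ks <- vapply(c(500, 5000), function(n) {
    r2 <- generate_displacements(n, mix, dt = 5, sigma = 0, seed = 7)
    x <- sort(r2)
    max(abs(seq_along(x) / length(x) - pc(x)))
  }, 0)
  expect_lt(ks[2], ks[1])
  expect_lt(ks[2], 0.02)
})

test_that("bleach traces step in units of I_GFP with exponential decay", {
  tr <- generate_bleach_traces(1, 1, I_GFP = 5000, t_b = 40, noise_cv = 0,
                               n_frames = 60, seed = 3)
  expect_true(all(tr %in% c(0, 5000)))
  expect_true(all(diff(tr[1, ]) <= 0))  # one irreversible step

  ens <- generate_bleach_traces(2000, 3, I_GFP = 5000, t_b = 40,
                                noise_cv = 0, n_frames = 30, seed = 4)
  tm <- attr(ens, "times_ms")
  expect_equal(colMeans(ens), 3 * 5000 * exp(-tm / 40), tolerance = 0.05)

  # pairwise differences of intensity levels cluster at multiples of I_GFP
  lv <- unique(as.vector(ens[1:50, ]))
  dd <- abs(as.numeric(dist(lv)))
  expect_true(all(abs(dd / 5000 - round(dd / 5000)) < 1e-9))

  expect_error(generate_bleach_traces(2, 0), "S must")
  expect_error(generate_bleach_traces(2, 1, noise_cv = -1), "noise_cv")
})

test_that("FRAP and stoichiometry generators obey their closed forms", {
  f <- generate_frap_curve(10, 133, c(0, 133, 1e6))
  expect_equal(f$C[1], 0)
  expect_equal(f$C[2], 10 * (1 - exp(-1)))
  expect_equal(f$C[3], 10, tolerance = 1e-6)
  expect_error(generate_frap_curve(10, 133, numeric(0)), "non-empty")
  expect_error(generate_frap_curve(10, -1, 1), "positive")

  s <- generate_stoichiometries(200, u = 7, k_range = 1:2, noise_sd = 0,
                                seed = 1)
  expect_true(all(s %in% c(7, 14)))
  d <- abs(as.numeric(dist(s)))
  expect_true(all(abs(d / 7 - round(d / 7)) < 1e-9))
  expect_length(generate_stoichiometries(0, 7), 0)
})

test_that("toy genomes plant recoverable sites inside the nucleus", {
  g <- generate_toy_genome(2, 20000, "TTTWWGCGGRG", n_sites = 8,
                           promoter_fraction = 0.5, seed = 33)
  expect_equal(nrow(g$sites), 8)
  sites <- scan_sites(g$sequences, "TTTWWGCGGRG", g$annotation)
  found <- paste(sites$chrom, sites$start)
  expect_true(all(paste(g$sites$chrom, g$sites$start) %in% found))

  r <- sqrt(g$coords$x_nm^2 + g$coords$y_nm^2 + g$coords$z_nm^2)
  expect_true(all(r < 1000))

  g0 <- generate_toy_genome(1, 5000, "ACGTACGT", n_sites = 0, seed = 1)
  expect_equal(nrow(scan_sites(g0$sequences, "TTTTTTTTTTTT")), 0)

  expect_error(generate_toy_genome(1, 2000, "ACGT", n_sites = 1000),
               "capacity")
  expect_error(generate_toy_genome(1, 2000, "AXGT", n_sites = 1),
               "IUPAC")

  g1 <- generate_toy_genome(2, 10000, "TTTGCGGGG", n_sites = 4, seed = 9)
  g2 <- generate_toy_genome(2, 10000, "TTTGCGGGG", n_sites = 4, seed = 9)
  expect_identical(as.character(g1$sequences), as.character(g2$sequences))
  expect_identical(g1$coords, g2$coords)
})

test_that("TIFF round trip preserves the stack", {
  p <- sim_params(seed = 8)
  sim <- generate_cell_stack(p, pool_counts = c(cytoplasm = 50, nucleus = 0),
                             n_frames = 2)
  path <- tempfile(fileext = ".tif")
  write_stack_tiff(sim$stack, path)
  back <- read_stack_tiff(path)
  expect_length(back, 2)
  expect_equal(back[[1]], sim$stack[[1]], tolerance = 1)
})
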