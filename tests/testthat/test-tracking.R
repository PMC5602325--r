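test_that("blank frames yield no foci and tiny frames error", {
  set.seed(1)
  blank <- matrix(rnorm(80 * 80, 100, 7), 80)
  expect_equal(nrow(detect_foci(blank, detection_params())), 0)
  expect_error(detect_foci(matrix(0, 5, 5), detection_params()), "smaller")
})

test_that("bright foci are localized within the nominal precision", {
  errs <- unlist(lapply(1:10, function(s) {
    p <- sim_params(seed = s)
    sim <- generate_cell_stack(
      p, pool_counts = c(cytoplasm = 100, nucleus = 30),
      foci_spec = data.frame(S = 7, D = 0, compartment = "cytoplasm"),
      n_frames = 1)
    det <- detect_foci(sim$stack[[1]], detection_params())
    if (nrow(det) == 0) return(NA_real_)
    min(match_detections(det, sim$truth$foci)) * p$pixel_size
  }))
  expect_true(all(is.finite(errs)))
  expect_lte(sqrt(mean(errs^2)), 40)
})

test_that("nearby spots are resolved with consistent intensities", {
  p <- sim_params(seed = 3)
  sim <- generate_cell_stack(
    p, pool_counts = c(cytoplasm = 100, nucleus = 30),
    foci_spec = data.frame(S = c(7, 7), D = c(0, 0),
                           compartment = c("cytoplasm", "cytoplasm")),
    n_frames = 1,
    foci_xy = rbind(c(25, 32), c(35, 32)))
  det <- detect_foci(sim$stack[[1]], detection_params())
  expect_equal(nrow(det), 2)
  expect_lt(abs(det$intensity[1] / det$intensity[2] - 1), 0.1)
  expect_true(all(match_detections(det, sim$truth$foci) < 1))
  # fitted widths near the PSF sigma
  expect_true(all(abs(det$sigma_px - 230 / 80) < 1))
})

test_that("linking follows the PSF-width and factor-two rules", {
  base <- data.frame(x_px = 20, y_px = 20, intensity = 1000, sigma_px = 2,
                     snr = 5, background = 0)
  # one immobile spot over 10 frames -> a single track of length 10
  foci <- do.call(rbind, lapply(1:10, function(f) cbind(base, frame = f)))
  tr <- link_tracks(foci, detection_params())
  expect_equal(length(unique(tr$track_id)), 1)
  expect_equal(nrow(tr), 10)

  # two spots far apart stay two tracks
  two <- rbind(cbind(base, frame = rep(1:5, each = 1)),
               cbind(transform(base, x_px = 50), frame = 1:5))
  tr2 <- link_tracks(two, detection_params())
  expect_equal(length(unique(tr2$track_id)), 2)

  # a factor-three brightness jump breaks the link
  jump <- rbind(cbind(base, frame = 1),
                cbind(transform(base, intensity = 3000), frame = 2))
  tr3 <- link_tracks(jump, detection_params())
  expect_equal(length(unique(tr3$track_id)), 2)

  # a displacement beyond one PSF width breaks the link
  far <- rbind(cbind(base, frame = 1),
               cbind(transform(base, x_px = 20 + 230 / 80 + 1), frame = 2))
  expect_equal(length(unique(link_tracks(far, detection_params())$track_id)),
               2)
})

test_that("linking is invariant to within-frame ordering", {
  set.seed(4)
  foci <- do.call(rbind, lapply(1:6, function(f) {
    data.frame(frame = f,
               x_px = c(20, 40, 60) + rnorm(3, 0, 0.3),
               y_px = c(20, 40, 60) + rnorm(3, 0, 0.3),
               intensity = c(1000, 1500, 2000), sigma_px = 2, snr = 5,
               background = 0)
  }))
  tr_a <- link_tracks(foci, detection_params())
  shuffled <- foci[sample(nrow(foci)), ]
  tr_b <- link_tracks(shuffled, detection_params())
  key <- function(tr) {
    split(paste(tr$frame, round(tr$x_px, 3)), tr$track_id) |>
      lapply(paste, collapse = ";") |> unlist() |> sort() |> unname()
  }
  expect_identical(key(tr_a), key(tr_b))
})

test_that("tracks are classified by compartment", {
  cell <- mk_circle_boundary(40, 40, 30, label = "cell")
  nuc <- mk_circle_boundary(40, 40, 12, label = "nucleus")
  inside <- data.frame(x_px = c(38, 42), y_px = c(40, 40))
  expect_equal(classify_track(inside, cell, nuc), "nuclear")
  cyt <- data.frame(x_px = c(60, 62), y_px = c(40, 40))
  expect_equal(classify_track(cyt, cell, nuc), "cytoplasmic")
  straddle <- data.frame(x_px = c(45, 55), y_px = c(40, 40))
  expect_equal(classify_track(straddle, cell, nuc), "trans-nuclear")
  outside <- data.frame(x_px = c(40, 90), y_px = c(40, 40))
  expect_error(classify_track(outside, cell, nuc), "outside the cell")
})

test_that("a synthetic crossing track is trans-nuclear end to end", {
  set.seed(6)
  path <- slimcluster:::trans_nuclear_path(40, 40, 12, 1.2, 20, 0, 5)
  tr <- data.frame(x_px = path[, 1], y_px = path[, 2])
  cell <- mk_circle_boundary(40, 40, 30, label = "cell")
  nuc <- mk_circle_boundary(40, 40, 12, label = "nucleus")
  expect_equal(classify_track(tr, cell, nuc), "trans-nuclear")
})
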