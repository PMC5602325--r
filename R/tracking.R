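#' Detection parameters for focus finding
#'
#' @param snr_min Minimum signal-to-noise ratio for acceptance (default
#'   0.4), with SNR defined as characteristic intensity per ROI pixel
#'   divided by the local background sd per pixel.
#' @param roi_radius Circular region-of-interest radius in pixels used for
#'   the characteristic intensity (default 5).
#' @param psf_width PSF width in nm (default 230); also the linking gate:
#'   foci in consecutive frames are linked only within one PSF width.
#' @param precision Nominal lateral localization precision sigma in nm
#'   (default 40).
#' @param pixel_size Pixel size in nm/pixel.
#' @param candidate_threshold Candidate seeding threshold on the band-passed
#'   image, in units of its noise sd (exposed because the seeding level is
#'   a free choice).
#' @param max_iter Maximum iterations for Gaussian masking.
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(snr_min = 0.4, roi_radius = 5, psf_width = 230,
                             precision = 40, pixel_size = 80,
                             candidate_threshold = 3.5, max_iter = 100) {
  vals <- c(snr_min, roi_radius, psf_width, precision, pixel_size,
            candidate_threshold, max_iter)
  if (any(vals <= 0)) stop("all detection parameters must be positive")
  structure(list(snr_min = snr_min, roi_radius = roi_radius,
                 psf_width = psf_width, precision = precision,
                 pixel_size = pixel_size,
                 candidate_threshold = candidate_threshold,
                 max_iter = max_iter),
            class = "detection_params")
}

#' Detect diffraction-limited foci in a single frame
#'
#' Candidate bright foci are seeded by a band-pass (difference-of-Gaussians)
#' transformation followed by top-percentile thresholding of local maxima.
#' Each candidate is refined by iterative Gaussian masking: the sub-pixel
#' intensity centroid is recomputed under a Gaussian mask of the PSF width
#' until convergence. The characteristic intensity is the sum of
#' background-corrected pixel values inside a circular ROI (radius
#' `roi_radius` px) around the focus, with the local background taken as
#' the median of an annulus (radii `roi_radius` to `roi_radius + 3` px),
#' optionally after flat-field correction. Foci with SNR above `snr_min`
#' are accepted and their Gaussian sigma width fitted with a 2D radial
#' Gaussian.
#'
#' @param frame Numeric matrix.
#' @param params A [detection_params()] object.
#' @param flat_field Optional illumination profile matrix the frame is
#'   divided by (identity by default).
#' @return Data frame (one row per accepted focus): `x_px`, `y_px`,
#'   `intensity`, `sigma_px`, `snr`, `background`.
#' @export
detect_foci <- function(frame, params = detection_params(),
                        flat_field = NULL) {
  stopifnot(is.matrix(frame))
  rr <- params$roi_radius
  if (nrow(frame) < 2 * rr + 1 || ncol(frame) < 2 * rr + 1) {
    stop("frame smaller than the region of interest")
  }
  if (!is.null(flat_field)) {
    if (!identical(dim(flat_field), dim(frame))) {
      stop("flat_field dimensions must match the frame")
    }
    frame <- frame / pmax(flat_field, .Machine$double.eps)
  }
  s_px <- params$psf_width / params$pixel_size
  # band-pass: difference of Gaussians removes offset and slow background
  bp <- gaussian_blur(frame, max(s_px / 2, 0.8)) - gaussian_blur(frame, 3 * s_px)
  # noise floor from the negative side of the band-passed image: robust to
  # frames densely covered by (strictly positive) spot signal
  neg <- bp[bp <= 0]
  noise_sd <- if (length(neg) > 20) {
    stats::median(abs(neg)) / 0.6745
  } else stats::mad(bp)
  thr <- params$candidate_threshold * noise_sd
  cand <- which(bp > thr & local_maxima(bp), arr.ind = TRUE)
  # brightest candidates first so duplicate suppression keeps true peaks
  cand <- cand[order(bp[cand], decreasing = TRUE), , drop = FALSE]
  if (nrow(cand) == 0) return(empty_foci())

  out <- list()
  used <- NULL
  for (i in seq_len(nrow(cand))) {
    y0 <- cand[i, 1]; x0 <- cand[i, 2]
    # centroid on the band-passed image: free of pool-background gradients
    fit <- gaussian_mask_centroid(bp, x0, y0, s_px, rr, params$max_iter)
    if (is.null(fit)) next  # non-convergent masking: candidate dropped
    # suppress duplicates converging to the same focus
    if (!is.null(used) &&
        any((used[, 1] - fit$x)^2 + (used[, 2] - fit$y)^2 < s_px^2)) next
    used <- rbind(used, c(fit$x, fit$y))
    roi <- roi_pixels(frame, fit$x, fit$y, rr)
    ann <- annulus_pixels(frame, fit$x, fit$y, rr, rr + 3)
    bg <- stats::median(ann)
    bg_sd <- stats::sd(ann)
    intensity <- sum(roi$values - bg)
    snr <- (intensity / length(roi$values)) / max(bg_sd, .Machine$double.eps)
    if (!is.finite(snr) || snr <= params$snr_min) next
    sig <- fit_radial_sigma(roi, fit$x, fit$y, bg, s_px)
    out[[length(out) + 1]] <- data.frame(
      x_px = fit$x, y_px = fit$y, intensity = max(intensity, 0),
      sigma_px = sig, snr = snr, background = bg)
  }
  if (!length(out)) return(empty_foci())
  do.call(rbind, out)
}

empty_foci <- function() {
  data.frame(x_px = numeric(), y_px = numeric(), intensity = numeric(),
             sigma_px = numeric(), snr = numeric(), background = numeric())
}

local_maxima <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  pad <- matrix(-Inf, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- img
  res <- matrix(TRUE, nr, nc)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    res <- res & img >= pad[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]
  }
  res
}

gaussian_mask_centroid <- function(frame, x, y, s_px, rr, max_iter) {
  nr <- nrow(frame); nc <- ncol(frame)
  for (it in seq_len(max_iter)) {
    cols <- max(1, floor(x - rr)):min(nc, ceiling(x + rr))
    rows <- max(1, floor(y - rr)):min(nr, ceiling(y + rr))
    sub <- frame[rows, cols, drop = FALSE]
    bg <- stats::median(annulus_pixels(frame, x, y, rr, rr + 3))
    w <- exp(-(outer((rows - y)^2, (cols - x)^2, "+")) / (2 * s_px^2))
    iw <- pmax(sub - bg, 0) * w
    tot <- sum(iw)
    if (tot <= 0) return(NULL)
    nx <- sum(iw * matrix(cols, nrow(sub), ncol(sub), byrow = TRUE)) / tot
    ny <- sum(iw * matrix(rows, nrow(sub), ncol(sub))) / tot
    shift <- sqrt((nx - x)^2 + (ny - y)^2)
    x <- nx; y <- ny
    if (shift < 1e-3) return(list(x = x, y = y))
  }
  NULL
}

roi_pixels <- function(frame, x, y, rr) {
  cols <- max(1, floor(x - rr)):min(ncol(frame), ceiling(x + rr))
  rows <- max(1, floor(y - rr)):min(nrow(frame), ceiling(y + rr))
  d2 <- outer((rows - y)^2, (cols - x)^2, "+")
  sel <- d2 <= rr^2
  list(values = frame[rows, cols, drop = FALSE][sel],
       r2 = d2[sel])
}

annulus_pixels <- function(frame, x, y, r_in, r_out) {
  cols <- max(1, floor(x - r_out)):min(ncol(frame), ceiling(x + r_out))
  rows <- max(1, floor(y - r_out)):min(nrow(frame), ceiling(y + r_out))
  d2 <- outer((rows - y)^2, (cols - x)^2, "+")
  sel <- d2 > r_in^2 & d2 <= r_out^2
  frame[rows, cols, drop = FALSE][sel]
}

# 2D radial Gaussian sigma by least squares on the ROI pixels
fit_radial_sigma <- function(roi, x, y, bg, s0) {
  v <- roi$values - bg
  r2 <- roi$r2
  a0 <- max(v)
  obj <- function(par) {
    a <- exp(par[1]); s <- exp(par[2])
    sum((v - a * exp(-r2 / (2 * s^2)))^2)
  }
  fit <- stats::optim(c(log(max(a0, 1e-6)), log(s0)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 200))
  exp(fit$par[2])
}

#' Link per-frame foci into tracks
#'
#' Greedy nearest-neighbour linking between consecutive frames: a focus is
#' linked to the closest focus in the next frame provided the displacement
#' is at most one PSF width and neither the brightness nor the sigma width
#' differ by more than a factor of two. Ambiguities are resolved by minimal
#' displacement; there is no gap closing, and unlinked foci become
#' length-one tracks. The result is invariant to the within-frame ordering
#' of the input foci.
#'
#' @param foci Data frame as returned by [detect_foci()] plus a `frame`
#'   column.
#' @param params A [detection_params()] object.
#' @return The input data frame with a `track_id` column, ordered by track
#'   and frame.
#' @export
link_tracks <- function(foci, params = detection_params()) {
  if (nrow(foci) == 0) return(cbind(foci, track_id = integer(0)))
  stopifnot("frame" %in% names(foci))
  max_disp <- params$psf_width / params$pixel_size
  foci <- foci[order(foci$frame, foci$x_px, foci$y_px), , drop = FALSE]
  foci$track_id <- NA_integer_
  next_id <- 1L
  frames <- sort(unique(foci$frame))
  idx_of <- function(f) which(foci$frame == f)
  first <- idx_of(frames[1])
  foci$track_id[first] <- seq_len(length(first))
  next_id <- length(first) + 1L
  for (fi in seq_along(frames)[-1]) {
    prev <- idx_of(frames[fi - 1])
    cur <- idx_of(frames[fi])
    if (frames[fi] != frames[fi - 1] + 1) prev <- integer(0)  # no gaps
    if (length(prev) && length(cur)) {
      d <- outer(seq_along(prev), seq_along(cur), function(i, j) {
        sqrt((foci$x_px[prev[i]] - foci$x_px[cur[j]])^2 +
             (foci$y_px[prev[i]] - foci$y_px[cur[j]])^2)
      })
      ratio_ok <- outer(seq_along(prev), seq_along(cur), function(i, j) {
        rb <- foci$intensity[prev[i]] / foci$intensity[cur[j]]
        rs <- foci$sigma_px[prev[i]] / foci$sigma_px[cur[j]]
        rb <- pmax(rb, 1 / rb); rs <- pmax(rs, 1 / rs)
        rb <= 2 & rs <= 2
      })
      d[!ratio_ok | d > max_disp] <- Inf
      while (any(is.finite(d))) {
        k <- arrayInd(which.min(d), dim(d))
        i <- k[1]; j <- k[2]
        foci$track_id[cur[j]] <- foci$track_id[prev[i]]
        d[i, ] <- Inf
        d[, j] <- Inf
      }
    }
    new <- cur[is.na(foci$track_id[cur])]
    if (length(new)) {
      foci$track_id[new] <- next_id + seq_along(new) - 1L
      next_id <- next_id + length(new)
    }
  }
  foci[order(foci$track_id, foci$frame), , drop = FALSE]
}

#' Classify a track by compartment
#'
#' A track is `"nuclear"` if every localization lies inside the nuclear
#' boundary, `"cytoplasmic"` if every localization lies outside the nucleus
#' but inside the cell, and `"trans-nuclear"` if it has localizations on
#' both sides of the nuclear envelope.
#'
#' @param track Data frame with `x_px`, `y_px`.
#' @param cell_boundary,nucleus_boundary `compartment_boundary` objects.
#' @return Character scalar label.
#' @export
classify_track <- function(track, cell_boundary, nucleus_boundary) {
  in_cell <- inside_boundary(cell_boundary, track$x_px, track$y_px)
  if (!all(in_cell)) stop("track point outside the cell boundary")
  in_nuc <- inside_boundary(nucleus_boundary, track$x_px, track$y_px)
  if (all(in_nuc)) "nuclear"
  else if (!any(in_nuc)) "cytoplasmic"
  else "trans-nuclear"
}

#' Write tracks to a tidy CSV
#'
#' @param tracks Data frame with a `track_id` column.
#' @param path Output path.
#' @param pixel_size nm per pixel for the nm columns.
#' @export
write_tracks_csv <- function(tracks, path, pixel_size = 80) {
  tracks$x_nm <- tracks$x_px * pixel_size
  tracks$y_nm <- tracks$y_px * pixel_size
  utils::write.csv(tracks, path, row.names = FALSE)
  invisible(path)
}
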