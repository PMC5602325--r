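# Shared internal helpers: pixel-integrated Gaussian rendering, FFT
# convolution, EMCCD-like noise, rotations.

# Render 2D Gaussian spots into a matrix. Coordinates are in pixels with
# pixel centres at integer positions (col = x, row = y); each spot's
# amplitude `amp` is its total integrated intensity (counts), so that
# sum(image) == sum(amp) up to truncation of the Gaussian tails at the
# image edge.
render_spots <- function(nrow, ncol, x, y, amp, sigma_px) {
  img <- matrix(0, nrow, ncol)
  if (length(x) == 0L) return(img)
  sigma_px <- rep_len(sigma_px, length(x))
  amp <- rep_len(amp, length(x))
  for (k in seq_along(x)) {
    if (amp[k] == 0) next
    s <- sigma_px[k]
    half <- ceiling(6 * s)
    cols <- max(1L, floor(x[k] - half)):min(ncol, ceiling(x[k] + half))
    rows <- max(1L, floor(y[k] - half)):min(nrow, ceiling(y[k] + half))
    if (!length(cols) || !length(rows)) next
    # integral of the Gaussian over each pixel, separably per axis
    fx <- stats::pnorm(cols + 0.5, x[k], s) - stats::pnorm(cols - 0.5, x[k], s)
    fy <- stats::pnorm(rows + 0.5, y[k], s) - stats::pnorm(rows - 0.5, y[k], s)
    img[rows, cols] <- img[rows, cols] + amp[k] * (fy %o% fx)
  }
  img
}

# Circular FFT convolution of an image with a centred Gaussian kernel.
# Preserves the image sum (kernel normalised on the full grid).
gaussian_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  nr <- nrow(img); nc <- ncol(img)
  gy <- stats::dnorm(c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)), sd = sigma_px)
  gx <- stats::dnorm(c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)), sd = sigma_px)
  ker <- (gy / sum(gy)) %o% (gx / sum(gx))
  Re(stats::fft(stats::fft(img) * stats::fft(ker), inverse = TRUE)) / (nr * nc)
}

# EMCCD-like noise: Poisson shot noise on the expected signal (optional),
# camera gain, Gaussian read noise and a constant offset.
apply_camera_noise <- function(expected, read_sd = 7, shot = TRUE, gain = 1,
                               offset = 100) {
  out <- expected
  if (shot) {
    out[] <- stats::rpois(length(out), pmax(out, 0))
  }
  out <- out * gain + offset
  if (read_sd > 0) {
    out <- out + stats::rnorm(length(out), 0, read_sd)
  }
  out
}

# Uniform random 3D rotation matrix (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d),   2 * (b * d + a * c),
    2 * (b * c + a * d),   a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c),   2 * (c * d + a * b),   a^2 - b^2 - c^2 + d^2
  ), 3, 3, byrow = TRUE)
}

# Projected column density of a uniform sphere (optionally hollowed by an
# inner sphere), normalised to unit sum: the forward model for a diffuse
# fluorophore pool observed in a 2D projection.
project_sphere_shell <- function(nrow, ncol, cx, cy, r_outer_px,
                                 r_inner_px = 0) {
  xs <- matrix(rep(seq_len(ncol), each = nrow), nrow)
  ys <- matrix(rep(seq_len(nrow), ncol), nrow)
  r2 <- (xs - cx)^2 + (ys - cy)^2
  dens <- 2 * sqrt(pmax(r_outer_px^2 - r2, 0))
  if (r_inner_px > 0) {
    dens <- dens - 2 * sqrt(pmax(r_inner_px^2 - r2, 0))
  }
  s <- sum(dens)
  if (s <= 0) stop("degenerate sphere projection")
  dens / s
}

`%||%` <- function(x, y) if (is.null(x)) y else x
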