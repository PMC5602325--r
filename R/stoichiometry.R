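#' Calibration of single-fluorophore brightness and photobleaching
#'
#' @param I_GFP Characteristic single-fluorophore brightness (counts).
#' @param t_b Photobleach time constant (ms).
#' @param autofluorescence_factor Red-to-green autofluorescence scaling
#'   factor (default 0.9).
#' @return Object of class `calibration`.
#' @export
calibration <- function(I_GFP = 5000, t_b = 40,
                        autofluorescence_factor = 0.9) {
  if (I_GFP <= 0 || t_b <= 0) stop("I_GFP and t_b must be positive")
  structure(list(I_GFP = I_GFP, t_b = t_b,
                 autofluorescence_factor = autofluorescence_factor),
            class = "calibration")
}

#' Estimate the single-fluorophore brightness from foci intensities
#'
#' The characteristic brightness of one fluorophore, `I_GFP`, is taken as
#' the modal value of all foci intensities observed over time (the argmax
#' of a Silverman-bandwidth Gaussian KDE of the pooled distribution).
#' Because bleaching proceeds in integer steps of `I_GFP`, the estimate is
#' cross-checked against the fundamental peak of the power spectrum of the
#' pairwise intensity-difference distribution; a warning is raised if the
#' two disagree by more than 30%.
#'
#' @param intensities Numeric vector of foci intensities over time (all
#'   tracks pooled), at least 50 values.
#' @param check_spectrum Cross-check against the pairwise-difference
#'   spectrum?
#' @return Estimated `I_GFP` (counts) with attribute
#'   `"spectral_estimate"`.
#' @export
estimate_single_brightness <- function(intensities, check_spectrum = TRUE) {
  intensities <- intensities[is.finite(intensities) & intensities > 0]
  if (length(intensities) < 50) {
    stop("need at least 50 positive intensity observations")
  }
  d <- stats::density(intensities, bw = "nrd0")
  mode_est <- d$x[which.max(d$y)]
  spec_est <- NA_real_
  if (check_spectrum) {
    spec_est <- tryCatch(
      periodicity(intensities, min_period = mode_est / 3)$period,
      error = function(e) NA_real_)
    if (is.finite(spec_est) &&
        abs(spec_est - mode_est) / mode_est > 0.3) {
      warning(sprintf(
        "modal (%.0f) and spectral (%.0f) brightness estimates disagree by > 30%%",
        mode_est, spec_est))
    }
  }
  structure(mode_est, spectral_estimate = spec_est)
}

#' Fit the photobleach time constant
#'
#' Least-squares single-exponential decay fit `I(t) = I0 * exp(-t/t_b)` to
#' intensity traces (foci or whole-cell) over time. Multiple traces are
#' averaged pointwise before fitting.
#'
#' @param intensity Numeric vector, or matrix with traces in rows.
#' @param times Sampling times (ms); defaults to the `"times_ms"` attribute
#'   of `intensity`.
#' @return Fitted `t_b` (ms) with attributes `"I0"` and `"fit"`.
#' @export
fit_bleach_constant <- function(intensity, times = NULL) {
  if (is.null(times)) times <- attr(intensity, "times_ms")
  if (is.matrix(intensity)) intensity <- colMeans(intensity)
  if (is.null(times)) stop("sampling times required")
  if (length(intensity) < 10) stop("need at least 10 time points")
  if (stats::sd(intensity) == 0 || stats::cor(times, intensity) >= 0) {
    stop("input does not decay; cannot fit a photobleach constant")
  }
  df <- data.frame(t = times, I = intensity)
  i0 <- max(intensity)
  tb0 <- max(times[which(intensity <= i0 * exp(-1))][1], diff(times)[1],
             na.rm = TRUE)
  fit <- minpack.lm::nlsLM(I ~ I0 * exp(-t / tb), data = df,
                           start = list(I0 = i0, tb = tb0),
                           lower = c(0, 1e-6),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- stats::coef(fit)
  structure(unname(est["tb"]), I0 = unname(est["I0"]), fit = fit)
}

#' Stoichiometry of a tracked focus
#'
#' Corrects the measured intensities of a focus track for photobleaching by
#' weighting the intensity at time `t` after the start of laser
#' illumination with `exp(+t/t_b)`, estimates the initial unbleached
#' intensity `I0` and divides by the single-fluorophore brightness:
#' `S = I0 / I_GFP`. Only tracks starting within `frame_cutoff` frames of
#' the start of illumination are analysed.
#'
#' @param track Data frame with columns `frame` (1-based, frame 1 = start
#'   of illumination) and `intensity`.
#' @param calib A [calibration()] object.
#' @param dt Frame interval (ms).
#' @param frame_cutoff Latest admissible starting frame (default 70).
#' @param estimator `"mean"` (bleach-corrected track mean, default),
#'   `"first"` (first corrected point) or `"fit"` (exponential-fit
#'   intercept).
#' @return List with `S`, `I0`, `included` (logical) and `reason`.
#' @export
track_stoichiometry <- function(track, calib, dt = 5, frame_cutoff = 70,
                                estimator = c("mean", "first", "fit")) {
  estimator <- match.arg(estimator)
  if (min(track$frame) > frame_cutoff) {
    return(list(S = NA_real_, I0 = NA_real_, included = FALSE,
                reason = sprintf("track starts after frame %d", frame_cutoff)))
  }
  t_ms <- (track$frame - 1) * dt
  corrected <- track$intensity * exp(t_ms / calib$t_b)
  I0 <- switch(estimator,
    mean = mean(corrected),
    first = corrected[1],
    fit = {
      f <- tryCatch(fit_bleach_constant(track$intensity, t_ms),
                    error = function(e) NULL)
      if (is.null(f)) mean(corrected) else attr(f, "I0")
    })
  list(S = I0 / calib$I_GFP, I0 = I0, included = TRUE, reason = "ok")
}

#' Periodicity of a stoichiometry distribution
#'
#' Computes the distribution of all pairwise differences of the input
#' values (as a kernel density estimate on a regular grid) and returns the
#' period of the dominant non-DC peak of its power spectrum. A periodic
#' stoichiometry built from multiples of a cluster unit `u` yields pairwise
#' differences concentrated at multiples of `u` and hence a spectral peak
#' at period `u`.
#'
#' The difference KDE is detrended with a wide running median (removing
#' the smooth triangular envelope of any difference distribution) and the
#' spectrum evaluated on a continuous grid of candidate periods from
#' `min_period` upwards. The dominant local spectral maximum is accepted
#' only if its normalized Fourier coherence (peak power divided by the
#' Cauchy-Schwarz bound, in `[0, 1]`) exceeds `coherence_min`; otherwise
#' the result is "no periodicity" (`NA` period). The reported period is
#' refined to the local maximum of the difference KDE nearest the spectral
#' peak.
#'
#' @param values Numeric vector (>= 30 values unless `min_n` overridden).
#' @param min_period Smallest candidate period (default 2, excluding DC
#'   and sub-unit harmonics).
#' @param coherence_min Minimum normalized spectral coherence at the peak
#'   required to call a periodicity (default 0.15).
#' @param min_n Minimum number of values.
#' @param n_grid KDE grid size for the difference distribution.
#' @return List with `period` (NA if none), `coherence`, `spectrum` (data
#'   frame period/power).
#' @export
periodicity <- function(values, min_period = 2, coherence_min = 0.15,
                        min_n = 30, n_grid = 1024) {
  values <- values[is.finite(values)]
  if (length(values) < min_n) stop("need at least ", min_n, " values")
  d <- abs(as.numeric(stats::dist(values)))
  d <- d[d > 0]
  max_d <- max(d)
  kde <- stats::density(d, bw = "nrd0", from = 0, to = max_d, n = n_grid)
  h <- kde$y
  x <- kde$x
  w <- max(31, 2 * round(n_grid / 8) + 1)
  hd <- h - stats::runmed(h, w)
  periods <- seq(min_period, max_d / 2, length.out = 2000)
  power <- vapply(periods, function(T) {
    Mod(sum(hd * exp(-2i * pi * x / T)))^2
  }, 0)
  spectrum <- data.frame(period = periods, power = power)
  is_peak <- c(FALSE, diff(sign(diff(power))) < 0, FALSE)
  if (!any(is_peak)) {
    return(list(period = NA_real_, coherence = NA_real_,
                spectrum = spectrum))
  }
  best <- which(is_peak)[which.max(power[is_peak])]
  coherence <- power[best] / (sum(hd^2) * length(hd))
  if (coherence < coherence_min) {
    return(list(period = NA_real_, coherence = coherence,
                spectrum = spectrum))
  }
  # refine at the difference-KDE peak nearest the spectral estimate
  T0 <- periods[best]
  sel <- which(x >= 0.7 * T0 & x <= 1.3 * T0)
  period <- if (length(sel)) x[sel[which.max(h[sel])]] else T0
  list(period = period, coherence = coherence, spectrum = spectrum)
}

#' Autofluorescence correction of a green-channel image
#'
#' Subtracts the co-registered red-channel image, scaled by the measured
#' red-to-green autofluorescence correlation factor, from the green-channel
#' image, clipping at zero.
#'
#' @param green,red Numeric matrices of identical dimension.
#' @param factor Scaling factor (default 0.9).
#' @return Corrected green image.
#' @export
autofluorescence_correct <- function(green, red, factor = 0.9) {
  if (!identical(dim(green), dim(red))) stop("image dimensions differ")
  pmax(green - factor * red, 0)
}

#' Pool copy numbers by linear deconvolution (CoPro)
#'
#' Models the diffuse nuclear and cytoplasmic fluorophore pools as uniform
#' densities over the segmented spherical nucleus and cell, projects each
#' through the PSF to obtain per-molecule basis images, and solves the
#' non-negative least-squares system
#' `image ~ n_nuc * basis_nuc + n_cyt * basis_cyt + background` pixelwise.
#' Basis amplitudes are per molecule (each basis integrates to `I_GFP`
#' counts), so the fitted amplitudes are copy numbers directly. An optional
#' depth-of-field correction divides each estimate by the fraction of the
#' compartment volume within the focal depth.
#'
#' @param image Background- and autofluorescence-corrected green image.
#' @param cell_boundary,nucleus_boundary `compartment_boundary` objects
#'   from [segment_compartment()].
#' @param calib A [calibration()] object.
#' @param psf_sigma_px PSF sigma in pixels.
#' @param depth_of_field Depth of field in um; `Inf` (default) assumes the
#'   whole compartment volume is observed, as in the synthetic forward
#'   model.
#' @param pixel_size nm/pixel (used only for the depth correction).
#' @return List `c(nuclear, cytoplasmic)` copy numbers plus `background`
#'   and residual RMS.
#' @export
copro_pool_counts <- function(image, cell_boundary, nucleus_boundary,
                              calib = calibration(), psf_sigma_px = 230 / 80,
                              depth_of_field = Inf, pixel_size = 80) {
  cc <- cell_boundary$center
  r_cell <- mean(sqrt((cell_boundary$points[, 1] - cc[1])^2 +
                      (cell_boundary$points[, 2] - cc[2])^2))
  nc_ <- nucleus_boundary$center
  r_nuc <- mean(sqrt((nucleus_boundary$points[, 1] - nc_[1])^2 +
                     (nucleus_boundary$points[, 2] - nc_[2])^2))
  nr <- nrow(image); ncl <- ncol(image)
  basis_nuc <- gaussian_blur(
    project_sphere_shell(nr, ncl, nc_[1], nc_[2], r_nuc), psf_sigma_px) *
    calib$I_GFP
  basis_cyt <- gaussian_blur(
    project_sphere_shell(nr, ncl, cc[1], cc[2], r_cell, r_nuc),
    psf_sigma_px) * calib$I_GFP
  A <- cbind(as.vector(basis_nuc), as.vector(basis_cyt), 1)
  if (qr(A)$rank < 3) stop("singular design: compartments not distinguishable")
  fit <- pracma::lsqnonneg(A, as.vector(image))
  counts <- fit$x[1:2]
  if (is.finite(depth_of_field)) {
    counts[1] <- counts[1] / volume_fraction_in_depth(r_nuc, depth_of_field,
                                                      pixel_size)
    counts[2] <- counts[2] / volume_fraction_in_depth(r_cell, depth_of_field,
                                                      pixel_size)
  }
  list(nuclear = counts[1], cytoplasmic = counts[2], background = fit$x[3],
       residual_rms = sqrt(mean(fit$resid.norm^2 / length(image))))
}

# fraction of a sphere's volume within +-depth/2 of the equatorial plane
volume_fraction_in_depth <- function(r_px, depth_um, pixel_size) {
  r_um <- r_px * pixel_size / 1000
  h <- min(depth_um / 2, r_um)
  # slab volume: 2 * (pi h r^2 - pi h^3 / 3)
  (2 * pi * h * r_um^2 - 2 * pi * h^3 / 3) / (4 / 3 * pi * r_um^3)
}

#' Upper bound on the pool stoichiometry
#'
#' If diffuse pool fluorophores were organized in foci of mean
#' stoichiometry `S`, nearest-neighbour separations below the optical
#' resolution `w` would render them unresolvable. Equating the cell volume
#' with the combined equivalent-sphere volumes of `n_pool/S` foci and
#' correcting the separation for the diffusion blur length
#' `b = sqrt(4*D*dt)` gives the bound `S < n_pool * ((b + w) / d)^3`.
#'
#' @param n_pool Pool copy number (molecules).
#' @param D Pool diffusion coefficient (um^2/s).
#' @param dt Camera sampling time (ms).
#' @param w Optical resolution limit (nm).
#' @param d Cell diameter (um).
#' @param b Optional diffusion blur length override (nm); computed from
#'   `D` and `dt` when `NULL`.
#' @return List with `S_max` and `b_nm`.
#' @export
pool_stoichiometry_bound <- function(n_pool, D = 6, dt = 5, w = 230, d = 5,
                                     b = NULL) {
  if (n_pool < 0 || D < 0 || dt <= 0 || w <= 0 || d <= 0) {
    stop("inputs must be positive (n_pool non-negative)")
  }
  b_nm <- b %||% (sqrt(4 * D * dt / 1000) * 1000)
  list(S_max = n_pool * ((b_nm + w) / (d * 1000))^3, b_nm = b_nm)
}

#' Gaussian kernel density estimate of a stoichiometry distribution
#'
#' Silverman ("normal reference") bandwidth by default, as appropriate for
#' approximately normally distributed data.
#'
#' @param values Numeric vector (>= 2 values).
#' @param bw Bandwidth rule or numeric bandwidth (see [stats::density()]).
#' @param n Grid size.
#' @return List of class `stoich_kde` with `grid`, `density`, `bandwidth`,
#'   `mode`.
#' @export
stoich_kde <- function(values, bw = "nrd0", n = 512) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 values")
  d <- stats::density(values, bw = bw, n = n)
  structure(list(grid = d$x, density = d$y, bandwidth = d$bw,
                 mode = d$x[which.max(d$y)]),
            class = "stoich_kde")
}
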