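#' Transform a trans-nuclear track into envelope-relative coordinates
#'
#' Finds the nuclear-envelope crossing point by linear interpolation
#' between the first pair of consecutive localizations on opposite sides
#' of the smoothed nuclear boundary, then translates all coordinates to the
#' crossing point and rotates them so that `x'` lies parallel (tangent) and
#' `y'` perpendicular (normal) to the envelope at the crossing, with the
#' nucleus interior at `y' < 0`. Times are normalized to the interpolated
#' crossing time. The transformation is rigid. If the track crosses more
#' than once, the first crossing is used and the result flagged.
#'
#' @param track Data frame with `frame`, `x_px`, `y_px`.
#' @param nucleus_boundary A smoothed `compartment_boundary`.
#' @param dt Frame interval (ms).
#' @return List of class `transnuclear_track`: `coords` (data frame
#'   `t_rel_ms`, `x_para_px`, `y_perp_px`), `crossing` (x, y, t_ms),
#'   `direction` ("entering"/"leaving"), `n_crossings`, `flagged`.
#' @export
transform_transnuclear <- function(track, nucleus_boundary, dt = 5) {
  inside <- inside_boundary(nucleus_boundary, track$x_px, track$y_px)
  sw <- which(diff(inside) != 0)
  if (!length(sw)) stop("track does not cross the nuclear boundary")
  flagged <- length(sw) > 1
  i <- sw[1]
  p1 <- c(track$x_px[i], track$y_px[i])
  p2 <- c(track$x_px[i + 1], track$y_px[i + 1])
  # fraction along the segment where the boundary is crossed
  f <- tryCatch({
    g <- function(f) {
      p <- p1 + f * (p2 - p1)
      th <- atan2(p[2] - nucleus_boundary$center["y"],
                  p[1] - nucleus_boundary$center["x"])
      sqrt(sum((p - nucleus_boundary$center)^2)) -
        nucleus_boundary$radius_fun(th)
    }
    stats::uniroot(g, c(0, 1))$root
  }, error = function(e) 0.5)
  cross <- p1 + f * (p2 - p1)
  t_cross <- ((track$frame[i] - 1) + f) * dt
  # tangent from the boundary spline derivative at the crossing angle
  th0 <- atan2(cross[2] - nucleus_boundary$center["y"],
               cross[1] - nucleus_boundary$center["x"])
  eps <- 1e-4
  r0 <- nucleus_boundary$radius_fun(th0)
  drdth <- (nucleus_boundary$radius_fun(th0 + eps) -
            nucleus_boundary$radius_fun(th0 - eps)) / (2 * eps)
  # boundary point derivative wrt theta
  tangent <- c(drdth * cos(th0) - r0 * sin(th0),
               drdth * sin(th0) + r0 * cos(th0))
  tangent <- tangent / sqrt(sum(tangent^2))
  normal <- c(-tangent[2], tangent[1])
  # orient the normal outwards (interior at y' < 0)
  if (sum(normal * c(cos(th0), sin(th0))) < 0) {
    normal <- -normal
    tangent <- -tangent
  }
  dx <- track$x_px - cross[1]
  dy <- track$y_px - cross[2]
  coords <- data.frame(
    t_rel_ms = (track$frame - 1) * dt - t_cross,
    x_para_px = dx * tangent[1] + dy * tangent[2],
    y_perp_px = dx * normal[1] + dy * normal[2])
  direction <- if (inside[i + 1]) "entering" else "leaving"
  structure(list(coords = coords,
                 crossing = c(x = unname(cross[1]), y = unname(cross[2]),
                              t_ms = t_cross),
                 direction = direction, n_crossings = length(sw),
                 flagged = flagged),
            class = "transnuclear_track")
}

#' Dwell times at the nuclear envelope
#'
#' A dwell is a contiguous run of localizations with
#' `|y'| <= envelope_band/2` in envelope-relative coordinates. Durations
#' are observed in whole frames, so the exponential dwell constant is
#' estimated by the maximum-likelihood estimator for frame-censored
#' (geometric) counts, `tau = -dt / log(1 - 1/kbar)` with `kbar` the mean
#' number of in-band frames per dwell; the plain sample mean of the
#' durations is also reported.
#'
#' @param transformed List of `transnuclear_track` objects (or a single
#'   one).
#' @param envelope_band Band width around the envelope in nm (default 40,
#'   matching the nuclear-envelope thickness).
#' @param pixel_size nm/pixel.
#' @param dt Frame interval (ms).
#' @param min_crossings Minimum number of dwells required for fitting.
#' @return List: `dwell_ms` (durations), `tau_ms` (ML exponential
#'   constant), `mean_ms` (plain ML mean), `n`.
#' @export
dwell_times <- function(transformed, envelope_band = 40, pixel_size = 80,
                        dt = 5, min_crossings = 20) {
  if (inherits(transformed, "transnuclear_track")) {
    transformed <- list(transformed)
  }
  half_px <- envelope_band / 2 / pixel_size
  counts <- integer(0)
  for (tr in transformed) {
    inb <- abs(tr$coords$y_perp_px) <= half_px
    # in-band run containing (or adjacent to) the crossing
    r <- rle(inb)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    if (!length(runs)) next
    t0 <- which.min(abs(tr$coords$t_rel_ms))
    hit <- runs[starts[runs] <= t0 + 1 & ends[runs] >= t0 - 1]
    if (!length(hit)) hit <- runs[1]
    counts <- c(counts, r$lengths[hit[1]])
  }
  if (!length(counts)) {
    return(list(dwell_ms = numeric(0), tau_ms = NA_real_,
                mean_ms = NA_real_, n = 0L))
  }
  if (length(counts) < min_crossings) {
    warning("fewer than ", min_crossings, " dwells; estimate unreliable")
  }
  kbar <- mean(counts)
  tau <- if (kbar > 1) -dt / log(1 - 1 / kbar) else dt / 2
  list(dwell_ms = counts * dt, tau_ms = tau, mean_ms = kbar * dt,
       n = length(counts))
}

#' Fit a FRAP recovery curve
#'
#' Nonlinear least-squares fit of the single-exponential recovery model
#' `C(t) = C0 * (1 - exp(-t/t_R))` to post-bleach copy-number samples.
#' Sampling times are taken from the input (no uniform-grid assumption).
#'
#' @param t Post-bleach times (s), at least 5.
#' @param C Recovered copy numbers at those times; alternatively a data
#'   frame with columns `t` and `C` passed as the first argument.
#' @return List of class `frap_fit`: `C0`, `t_R`, `residual_sd`, `fit`.
#' @export
fit_frap <- function(t, C = NULL) {
  if (is.data.frame(t)) {
    C <- t$C
    t <- t$t
  }
  if (length(t) < 5) stop("need at least 5 post-bleach time points")
  if (stats::sd(C) == 0 || stats::cor(t, C) < 0) {
    stop("input decreases with time; not a recovery curve")
  }
  df <- data.frame(t = t, C = C)
  C0_0 <- max(C)
  tR_0 <- {
    half <- t[which(C >= C0_0 / 2)][1]
    max(half %|na|% stats::median(t), min(t[t > 0]))
  }
  fit <- minpack.lm::nlsLM(C ~ C0 * (1 - exp(-t / tR)), data = df,
                           start = list(C0 = C0_0, tR = tR_0),
                           lower = c(0, 1e-9),
                           control = minpack.lm::nls.lm.control(maxiter = 500))
  est <- stats::coef(fit)
  structure(list(C0 = unname(est["C0"]), t_R = unname(est["tR"]),
                 residual_sd = stats::sd(stats::resid(fit)), fit = fit),
            class = "frap_fit")
}

#' Photobleach-correct a FRAP time series
#'
#' Reweights post-bleach intensities with `exp(+t_ill/t_b)` where `t_ill`
#' is the cumulative illumination time at each stroboscopic sample, as in
#' the stoichiometry analysis.
#'
#' @param C Measured copy numbers.
#' @param illumination_ms Cumulative illumination time at each sample (ms).
#' @param t_b Photobleach constant (ms).
#' @return Corrected copy numbers.
#' @export
frap_bleach_correct <- function(C, illumination_ms, t_b = 40) {
  C * exp(illumination_ms / t_b)
}
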