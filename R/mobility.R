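#' Time-averaged mean square displacement of a track
#'
#' For a track of `N` consecutive frames sampled at interval `dt`, the MSD
#' at lag `tau = n*dt` is the average over all start points `i` of the
#' squared displacement between frames `i` and `i + n`, with normalization
#' `1/(N - 1 - n)`. For Brownian motion with localization precision
#' `sigma`, `MSD(tau) = 4*D*tau + 4*sigma^2`.
#'
#' @param track Data frame with `x_um`, `y_um` (or `x_px`, `y_px` plus
#'   `pixel_size` in nm).
#' @param dt Frame interval (ms).
#' @param pixel_size nm/pixel, used when only pixel coordinates are
#'   present.
#' @param max_lag Largest lag `n` (default `N - 2`).
#' @return Data frame of class `msd_curve` with `tau_ms`, `msd_um2`, `n`,
#'   `n_pairs` and attribute `"N"`.
#' @export
msd <- function(track, dt = 5, pixel_size = 80, max_lag = NULL) {
  if (!all(c("x_um", "y_um") %in% names(track))) {
    track$x_um <- track$x_px * pixel_size / 1000
    track$y_um <- track$y_px * pixel_size / 1000
  }
  N <- nrow(track)
  if (N < 5) stop("track too short for MSD (need >= 5 frames)")
  max_lag <- min(max_lag %||% (N - 2L), N - 2L)
  res <- lapply(seq_len(max_lag), function(n) {
    i <- seq_len(N - 1 - n)
    dx <- track$x_um[i + n] - track$x_um[i]
    dy <- track$y_um[i + n] - track$y_um[i]
    data.frame(tau_ms = n * dt, msd_um2 = sum(dx^2 + dy^2) / (N - 1 - n),
               n = n, n_pairs = length(i))
  })
  out <- do.call(rbind, res)
  attr(out, "N") <- N
  class(out) <- c("msd_curve", class(out))
  out
}

#' Microscopic diffusion coefficient from the first MSD points
#'
#' Straight-line fit (slope and intercept) to the first four points of the
#' MSD-vs-tau curve; `D` is the gradient divided by 4. With
#' `fix_intercept = TRUE` the intercept is constrained to the
#' localization-precision offset `4*sigma^2`.
#'
#' @param msd_curve Output of [msd()].
#' @param sigma Localization precision (nm), used only when the intercept
#'   is fixed.
#' @param n_points Number of leading points fitted (default 4).
#' @param fix_intercept Constrain the intercept to `4*sigma^2`?
#' @return `D` (um^2/s) with attribute `"intercept_um2"`.
#' @export
fit_D <- function(msd_curve, sigma = 40, n_points = 4,
                  fix_intercept = FALSE) {
  if (nrow(msd_curve) < n_points) {
    stop("need at least ", n_points, " MSD points")
  }
  pts <- msd_curve[seq_len(n_points), ]
  tau_s <- pts$tau_ms / 1000
  if (fix_intercept) {
    off <- 4 * (sigma / 1000)^2
    slope <- sum((pts$msd_um2 - off) * tau_s) / sum(tau_s^2)
    intercept <- off
  } else {
    fit <- stats::lm(msd_um2 ~ tau_s, data = cbind(pts, tau_s = tau_s))
    slope <- stats::coef(fit)[2]
    intercept <- stats::coef(fit)[1]
  }
  structure(unname(slope) / 4, intercept_um2 = unname(intercept))
}

# EM for a k-component exponential mixture (means mu_i); used as a
# starting point for the least-squares CDF fit.
em_exp_mixture <- function(x, k, iters = 300) {
  mu <- as.numeric(stats::quantile(x, seq(0.2, 0.8, length.out = k)))
  if (any(mu <= 0)) return(NULL)
  A <- rep(1 / k, k)
  for (it in seq_len(iters)) {
    dens <- vapply(seq_len(k), function(i) A[i] / mu[i] * exp(-x / mu[i]),
                   numeric(length(x)))
    tot <- rowSums(dens)
    if (any(tot <= 0) || any(!is.finite(tot))) return(NULL)
    g <- dens / tot
    A <- colMeans(g)
    mu <- colSums(g * x) / colSums(g)
  }
  o <- order(mu)
  list(A = A[o], mu = mu[o])
}

cdf_mixture_model <- function(r2, A, D, dt_s) {
  rowSums(vapply(seq_along(A), function(i) {
    A[i] * (1 - exp(-r2 / (4 * D[i] * dt_s)))
  }, numeric(length(r2))))
}

#' Fit a Brownian mixture to first-step squared displacements (CDF)
#'
#' Fits the empirical cumulative distribution of squared first-step
#' displacements to a weighted sum of Brownian components,
#' `p_c(r2) = sum_i A_i * (1 - exp(-r2 / (4*D_i*dt)))`, with 1, 2 and then
#' 3 components. A model with more components is retained only if it
#' lowers the reduced chi-squared by more than 10%. The empirical CDF is
#' evaluated at every observed `r2` (no binning); residuals are weighted
#' by the binomial sampling variance of the empirical CDF,
#' `p*(1-p)/N`, and reduced chi-squared uses `N - n_params` degrees of
#' freedom. Note the fitted `D_i` include the localization-error offset
#' `sigma^2/dt`; pass `sigma` to subtract it.
#'
#' @param r2 Squared displacements (um^2), at least 100.
#' @param dt Frame interval (ms).
#' @param max_components Maximum number of components (default 3).
#' @param improvement Minimum fractional reduced-chi-squared improvement to
#'   accept an extra component (default 0.1).
#' @param sigma Localization precision (nm); when nonzero, the offset
#'   `sigma^2/dt` is subtracted from the fitted apparent `D_i` (default 0,
#'   reporting apparent coefficients).
#' @return List of class `cdf_mixture_fit`: `n_components`, `components`
#'   (data frame A, D sorted by D), `red_chisq`, `fits` (all candidates),
#'   `flagged`.
#' @export
fit_cdf_mixture <- function(r2, dt = 5, max_components = 3,
                            improvement = 0.1, sigma = 0) {
  r2 <- sort(r2[is.finite(r2)])
  if (length(r2) < 100) stop("need at least 100 displacements")
  if (stats::sd(r2) == 0) stop("degenerate displacements: zero variance")
  n <- length(r2)
  p_emp <- seq_len(n) / n
  # binomial sampling variance of the empirical CDF (midpoint plotting
  # positions avoid the zero-variance endpoint)
  p_mid <- (seq_len(n) - 0.5) / n
  wts <- n / (p_mid * (1 - p_mid))
  dt_s <- dt / 1000
  D1 <- max(mean(r2) / (4 * dt_s), 1e-6)

  fit_k <- function(k) {
    unpack <- function(par) {
      A <- rep(1, k)
      if (k > 1) {
        stick <- 1
        for (i in seq_len(k - 1)) {
          frac <- stats::plogis(par[i])
          A[i] <- stick * frac
          stick <- stick * (1 - frac)
        }
        A[k] <- stick
      }
      list(A = A, D = exp(par[k:(2 * k - 1)]))
    }
    obj <- function(par) {
      pp <- unpack(par)
      sum(wts * (p_emp - cdf_mixture_model(r2, pp$A, pp$D, dt_s))^2)
    }
    pack <- function(A, D) {
      logits <- numeric(k - 1)
      if (k > 1) {
        stick <- 1
        for (i in seq_len(k - 1)) {
          logits[i] <- stats::qlogis(min(max(A[i] / stick, 1e-6), 1 - 1e-6))
          stick <- stick * (1 - A[i] / stick)
        }
      }
      c(logits, log(pmax(D, 1e-8)))
    }
    # multi-start: decade-spread, quantile-based, and an EM maximum-
    # likelihood start for the exponential mixture (stabilizes the A-D
    # ridge of the least-squares surface)
    starts <- list(c(rep(0, k - 1), log(D1 * 10^(seq(-1, 1, length.out = k) *
                                                   (k > 1)))))
    if (k > 1) {
      qs <- stats::quantile(r2, seq(0.15, 0.85, length.out = k))
      starts <- c(starts,
                  list(c(rep(0, k - 1), log(pmax(qs / (4 * dt_s), 1e-6)))))
      em <- em_exp_mixture(r2, k)
      if (!is.null(em)) {
        starts <- c(starts, list(pack(em$A, em$mu / (4 * dt_s))))
      }
    }
    best <- NULL
    for (par0 in starts) {
      opt <- tryCatch(
        if (length(par0) == 1) {
          stats::optim(par0, obj, method = "Brent",
                       lower = par0 - 8, upper = par0 + 8)
        } else {
          stats::optim(par0, obj, method = "Nelder-Mead",
                       control = list(maxit = 3000, reltol = 1e-12))
        },
        error = function(e) NULL)
      if (!is.null(opt) && (is.null(best) || opt$value < best$value)) {
        best <- opt
      }
    }
    if (is.null(best)) stop("CDF mixture optimization failed")
    pp <- unpack(best$par)
    ord <- order(pp$D)
    red <- best$value / (n - (2 * k - 1))
    list(components = data.frame(A = pp$A[ord], D = pp$D[ord]),
         red_chisq = red, converged = best$convergence == 0)
  }

  # identifiability guard: an extra component is only meaningful if it is
  # resolvable from its neighbours (adjacent D ratio >= 2) and carries
  # non-negligible weight
  distinct_ok <- function(cmp) {
    all(cmp$A >= 0.05) &&
      (nrow(cmp) < 2 || all(cmp$D[-1] / cmp$D[-nrow(cmp)] >= 2))
  }
  fits <- list(fit_k(1))
  chosen <- 1L
  flagged <- FALSE
  for (k in 2:max_components) {
    fk <- tryCatch(fit_k(k), error = function(e) NULL)
    if (is.null(fk)) { flagged <- TRUE; break }
    fits[[k]] <- fk
    if (fk$red_chisq < (1 - improvement) * fits[[chosen]]$red_chisq &&
        distinct_ok(fk$components)) {
      chosen <- k
    } else break
  }
  best <- fits[[chosen]]
  if (sigma > 0) {
    best$components$D <- pmax(best$components$D -
                                (sigma / 1000)^2 / (dt / 1000), 0)
  }
  structure(list(n_components = chosen, components = best$components,
                 red_chisq = best$red_chisq, fits = fits,
                 flagged = flagged || !best$converged),
            class = "cdf_mixture_fit")
}

#' Gamma-mixture fit to microscopic diffusion coefficients
#'
#' Fits the distribution of per-track microscopic `D` estimates with a
#' two-component mixture of Gamma densities,
#' `p(x) = sum_i A_i * (m/D_i)^m * x^(m-1) * exp(-m*x/D_i) / (m-1)!`,
#' where `m` is the number of MSD points used in each `D` estimate
#' (default 4; `m = 1` reduces to an exponential density). Fitted by least
#' squares against a histogram density of the `D` sample (binned finely
#' enough to resolve a slow component); falls back to a single component
#' (flagged) if the two-component fit does not converge.
#'
#' @param D_values Per-track diffusion coefficients (um^2/s), at least
#'   100.
#' @param m MSD steps per estimate (shape parameter).
#' @param n_components 1 or 2.
#' @return List of class `gamma_fit`: `components` (A, D sorted by D), `m`,
#'   `red_chisq`, `flagged`.
#' @export
fit_gamma_mixture <- function(D_values, m = 4, n_components = 2) {
  D_values <- D_values[is.finite(D_values) & D_values > 0]
  if (length(D_values) < 100) stop("need at least 100 D estimates")
  if (m < 1) stop("m must be >= 1")
  brk <- seq(0, max(D_values) * 1.02, length.out = 65)
  h <- graphics::hist(D_values, breaks = brk, plot = FALSE)
  x <- h$mids
  y <- h$density
  dens_k <- function(x, D) {
    (m / D)^m * x^(m - 1) * exp(-m * x / D) / gamma(m)
  }
  fit_k <- function(k) {
    q <- if (k == 1) 0.5 else c(0.25, 0.75)
    par0 <- c(rep(0, k - 1), log(stats::quantile(D_values, q)))
    unpack <- function(par) {
      A <- if (k == 1) 1 else {
        a1 <- stats::plogis(par[1]); c(a1, 1 - a1)
      }
      list(A = A, D = exp(par[k:(2 * k - 1)]))
    }
    obj <- function(par) {
      pp <- unpack(par)
      model <- rowSums(vapply(seq_len(k), function(i) {
        pp$A[i] * dens_k(x, pp$D[i])
      }, numeric(length(x))))
      sum((y - model)^2)
    }
    opt <- stats::optim(par0, obj, method = "Nelder-Mead",
                        control = list(maxit = 3000))
    pp <- unpack(opt$par)
    ord <- order(pp$D)
    list(components = data.frame(A = pp$A[ord], D = pp$D[ord]),
         red_chisq = opt$value / (length(x) - (2 * k - 1)),
         converged = opt$convergence == 0)
  }
  flagged <- FALSE
  fit <- if (n_components == 1) fit_k(1) else {
    f2 <- tryCatch(fit_k(2), error = function(e) NULL)
    if (is.null(f2) || !f2$converged) {
      flagged <- TRUE
      fit_k(1)
    } else f2
  }
  structure(list(components = fit$components, m = m,
                 red_chisq = fit$red_chisq, flagged = flagged),
            class = "gamma_fit")
}

#' Anomalous (subdiffusion) fit to a mean MSD curve
#'
#' Fits the precision-corrected subdiffusion model
#' `MSD(tau) = 4*sigma^2 + 4*K*tau^alpha` to points with `tau <= tau_max`
#' by nonlinear least squares, and also reports the Brownian special case
#' (`alpha` fixed at 1) for comparison.
#'
#' @param msd_curve Output of [msd()] or a data frame with `tau_ms`,
#'   `msd_um2` (a mean curve over tracks).
#' @param sigma Localization precision (nm).
#' @param tau_max Largest lag used (ms, default 30).
#' @return List of class `anomalous_fit`: `K` (um^2/s^alpha), `alpha`,
#'   `chisq`, `brownian` (list D, chisq).
#' @export
fit_anomalous <- function(msd_curve, sigma = 40, tau_max = 30) {
  pts <- msd_curve[msd_curve$tau_ms <= tau_max, ]
  if (nrow(pts) < 4) stop("need at least 4 MSD points with tau <= tau_max")
  off <- 4 * (sigma / 1000)^2
  y <- pts$msd_um2 - off
  if (any(y <= 0)) stop("negative MSD after precision correction")
  tau_s <- pts$tau_ms / 1000
  # log-log linear fit as a (often exact) starting point, then refine
  ll <- stats::lm(log(y) ~ log(tau_s))
  a0 <- min(max(unname(stats::coef(ll)[2]), 0.05), 1)
  K0 <- unname(exp(stats::coef(ll)[1])) / 4
  obj <- function(par) {
    K <- exp(par[1]); a <- stats::plogis(par[2])
    sum((y - 4 * K * tau_s^a)^2)
  }
  opt <- stats::optim(c(log(K0), stats::qlogis(min(a0, 0.999))), obj,
                      method = "BFGS", control = list(maxit = 1000))
  K <- unname(exp(opt$par[1])); alpha <- unname(stats::plogis(opt$par[2]))
  D_b <- sum(y * tau_s) / sum(tau_s^2) / 4
  chisq_b <- sum((y - 4 * D_b * tau_s)^2)
  structure(list(K = K, alpha = alpha, chisq = opt$value,
                 brownian = list(D = D_b, chisq = chisq_b)),
            class = "anomalous_fit")
}
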