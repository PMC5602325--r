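#' Effective cluster diameter from the measured focus width
#'
#' The physical diameter of a cluster is estimated from the fitted focus
#' PSF width `p_foci` (twice the Gaussian sigma of the tracking fit) by
#' subtracting the reference single-fluorophore PSF width `p_GFP` and the
#' motion-blur length accumulated over one camera exposure,
#' `sqrt(4*D*dt)`:
#' `d = p_foci - p_GFP - sqrt(4*D*dt)`. A non-positive result means the
#' cluster is unresolvable at this width and is returned as such rather
#' than as an error. `raw_formula = TRUE` instead subtracts the squared
#' blur term `4*D*dt` directly (in nm^2-as-nm), for comparison only.
#'
#' @param p_foci Fitted focus width (nm, = 2 x Gaussian sigma).
#' @param p_GFP Reference single-fluorophore width (nm, default 460).
#' @param D Microscopic diffusion coefficient of the track (um^2/s).
#' @param dt Camera exposure (ms).
#' @param raw_formula Use the uncorrected area-form blur term?
#' @return List of class `cluster_diameter`: `d_nm` (NA when
#'   unresolvable), `resolvable`, `blur_nm`.
#' @export
cluster_diameter <- function(p_foci, p_GFP = 460, D = 0, dt = 5,
                             raw_formula = FALSE) {
  if (any(c(p_foci, p_GFP, D, dt) < 0)) stop("inputs must be non-negative")
  blur <- if (raw_formula) 4 * D * dt * 1e6 / 1000 else
    sqrt(4 * D * dt / 1000) * 1000  # nm
  d <- p_foci - p_GFP - blur
  structure(list(d_nm = ifelse(d > 0, d, NA_real_), resolvable = d > 0,
                 blur_nm = blur),
            class = "cluster_diameter")
}

#' Packing exponent of cluster diameter versus stoichiometry
#'
#' Fits the power law `d ~ S^a` by least squares on log-log axes. For
#' tightly packed spherical clusters of identical monomers `a = 1/3`; a
#' rigid rod gives `a = 1` and a size-invariant anchor `a = 0`.
#'
#' @param S Stoichiometries (> 0), at least 5.
#' @param d Diameters (> 0, same length).
#' @return List of class `packing_fit`: `a`, `sem`, `prefactor`, `fit`.
#' @export
packing_exponent <- function(S, d) {
  if (length(S) < 5) stop("need at least 5 (S, d) pairs")
  if (any(S <= 0) || any(d <= 0)) stop("S and d must be positive")
  fit <- stats::lm(log(d) ~ log(S))
  sm <- summary(fit)$coefficients
  structure(list(a = unname(sm[2, 1]), sem = unname(sm[2, 2]),
                 prefactor = exp(unname(sm[1, 1])), fit = fit),
            class = "packing_fit")
}

#' Gaussian overlap integral between two foci
#'
#' For two normalized 2D Gaussian foci with centres `(x1, y1)`, `(x2, y2)`
#' and sigma widths `sigma1`, `sigma2`, the overlap integral is
#' `v = exp(-dr^2 / (2*(sigma1^2 + sigma2^2)))` with
#' `dr^2 = (x1 - x2)^2 + (y1 - y2)^2`. `v` is 1 for identical centres,
#' symmetric in its arguments and strictly decreasing in `dr^2`; foci with
#' `v` above the threshold (default 0.75) are flagged as colocalized.
#'
#' @param x1,y1,sigma1 First focus centre and sigma (any consistent unit).
#' @param x2,y2,sigma2 Second focus.
#' @param threshold Colocalization threshold on `v` (default 0.75).
#' @return List of class `overlap_result`: `v`, `dr2`, `colocalized`.
#' @export
overlap_integral <- function(x1, y1, sigma1, x2, y2, sigma2,
                             threshold = 0.75) {
  if (any(c(sigma1, sigma2) <= 0)) stop("sigma widths must be positive")
  dr2 <- (x1 - x2)^2 + (y1 - y2)^2
  v <- exp(-dr2 / (2 * (sigma1^2 + sigma2^2)))
  structure(list(v = v, dr2 = dr2, colocalized = v > threshold),
            class = "overlap_result")
}

#' Pairwise overlap integrals between two channels of foci
#'
#' Pairs each focus in the first channel with foci in the second channel
#' whose centroids are within `pair_radius` (default 5 px); pairs beyond
#' that radius are never formed.
#'
#' @param foci1,foci2 Data frames with `x_px`, `y_px`, `sigma_px`.
#' @param pair_radius Pairing radius (px).
#' @param threshold Colocalization threshold.
#' @return Data frame: indices `i`, `j`, `v`, `colocalized`.
#' @export
pair_overlap <- function(foci1, foci2, pair_radius = 5, threshold = 0.75) {
  out <- list()
  for (i in seq_len(nrow(foci1))) {
    d2 <- (foci1$x_px[i] - foci2$x_px)^2 + (foci1$y_px[i] - foci2$y_px)^2
    js <- which(d2 <= pair_radius^2)
    for (j in js) {
      ov <- overlap_integral(foci1$x_px[i], foci1$y_px[i],
                             foci1$sigma_px[i], foci2$x_px[j],
                             foci2$y_px[j], foci2$sigma_px[j], threshold)
      out[[length(out) + 1]] <- data.frame(i = i, j = j, v = ov$v,
                                           colocalized = ov$colocalized)
    }
  }
  if (!length(out)) {
    return(data.frame(i = integer(), j = integer(), v = numeric(),
                      colocalized = logical()))
  }
  do.call(rbind, out)
}

#' Genome packing geometry: DNA tube length and mesh diameter
#'
#' Treats the genome as a single tube of length `L = genome_bp * rise` and
#' computes the tube diameter required for the tube volume to fill a
#' spherical nucleus: `pi*(d/2)^2*L = (4/3)*pi*R^3`. For the budding-yeast
#' genome (12.1 Mbp at 0.34 nm/bp) in a 2 um nucleus this gives a tube of
#' about 4.1 mm and an effective DNA mesh diameter of 30-40 nm.
#'
#' @param genome_bp Genome size (bp).
#' @param rise_per_bp Helical rise (nm/bp, default 0.34).
#' @param nucleus_diameter Nuclear diameter (um, default 2).
#' @return List: `tube_length_mm`, `tube_diameter_nm`.
#' @export
genome_mesh_size <- function(genome_bp = 12.1e6, rise_per_bp = 0.34,
                             nucleus_diameter = 2) {
  if (any(c(genome_bp, rise_per_bp, nucleus_diameter) <= 0)) {
    stop("inputs must be positive")
  }
  L_nm <- genome_bp * rise_per_bp
  R_nm <- nucleus_diameter * 1000 / 2
  d_nm <- 2 * sqrt(4 * R_nm^3 / (3 * L_nm))
  list(tube_length_mm = L_nm / 1e6, tube_diameter_nm = d_nm)
}

#' Monomer (subunit) diameter from a cluster diameter
#'
#' Under the spherical tight-packing model a cluster of `S` monomers has
#' `d_cluster = d_monomer * S^(1/3)`, so the subunit diameter is
#' `d_cluster / S^(1/3)`.
#'
#' @param cluster_d Cluster diameter (nm).
#' @param S Stoichiometry (>= 1).
#' @return Monomer diameter (nm).
#' @export
subunit_diameter <- function(cluster_d, S) {
  if (any(S < 1)) stop("S must be >= 1")
  cluster_d / S^(1 / 3)
}

#' Render a Gaussian heat map of localizations
#'
#' Sums one 2D Gaussian per point, weighted, on a regular grid. Two
#' conventions are provided: `"foci"` renders onto a 1000 x 1000 pixel
#' grid spanning the data with Gaussians of the configured pixel width;
#' `"storm"` renders a super-resolved map with 20 nm pixels and 40 nm
#' Gaussian sigma (localization-precision-sized kernels).
#'
#' @param x,y Point coordinates. For `"foci"` mode these are in arbitrary
#'   units mapped onto the grid; for `"storm"` they are in nm.
#' @param weights Per-point weights (default 1).
#' @param mode `"foci"` or `"storm"`.
#' @param grid_size Grid side for `"foci"` mode (default 1000).
#' @param gaussian_width Gaussian sigma in grid pixels for `"foci"` mode
#'   (default 15).
#' @param storm_pixel_nm,storm_sigma_nm STORM rendering pixel size and
#'   kernel sigma (defaults 20 and 40 nm).
#' @return Numeric matrix with attributes `"extent"` (x/y ranges) and
#'   `"pixel_size"`.
#' @export
render_heatmap <- function(x, y, weights = 1,
                           mode = c("foci", "storm"), grid_size = 1000,
                           gaussian_width = 15, storm_pixel_nm = 20,
                           storm_sigma_nm = 40) {
  mode <- match.arg(mode)
  if (length(x) == 0) stop("no points to render")
  weights <- rep_len(weights, length(x))
  if (mode == "foci") {
    pad <- 0.05 * max(diff(range(x)), diff(range(y)), 1)
    x0 <- min(x) - pad; x1 <- max(x) + pad
    y0 <- min(y) - pad; y1 <- max(y) + pad
    sx <- (grid_size - 1) / (x1 - x0)
    gx <- 1 + (x - x0) * sx
    gy <- 1 + (y - y0) * sx
    img <- render_spots(grid_size, grid_size, gx, gy, weights,
                        gaussian_width)
    structure(img, extent = c(x0, x1, y0, y1), pixel_size = 1 / sx)
  } else {
    pad <- 3 * storm_sigma_nm
    x0 <- min(x) - pad; y0 <- min(y) - pad
    ncol_ <- ceiling((max(x) + pad - x0) / storm_pixel_nm) + 1
    nrow_ <- ceiling((max(y) + pad - y0) / storm_pixel_nm) + 1
    gx <- 1 + (x - x0) / storm_pixel_nm
    gy <- 1 + (y - y0) / storm_pixel_nm
    img <- render_spots(nrow_, ncol_, gx, gy, weights,
                        storm_sigma_nm / storm_pixel_nm)
    structure(img, extent = c(x0, x0 + (ncol_ - 1) * storm_pixel_nm,
                              y0, y0 + (nrow_ - 1) * storm_pixel_nm),
              pixel_size = storm_pixel_nm)
  }
}
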