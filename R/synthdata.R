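#' Simulation parameters for synthetic Slimfield data
#'
#' Bundles the acquisition and optical parameters used by all synthetic-data
#' generators. Defaults describe millisecond Slimfield imaging of budding
#' yeast: 80 nm/pixel magnification, 5 ms exposure per frame, a Gaussian PSF
#' of sigma 230 nm, a spherical cell of diameter 5 um containing a nucleus
#' of diameter 2 um, a single-GFP brightness of 5000 camera counts and a
#' photobleach time constant of 40 ms under continuous illumination.
#'
#' @param pixel_size Pixel size in nm/pixel.
#' @param dt Frame interval (camera exposure) in ms.
#' @param psf_sigma Gaussian PSF sigma in nm (optical resolution w ~ 230 nm;
#'   the full PSF width `p_GFP` is twice this, 460 nm).
#' @param cell_diameter Cell diameter in um.
#' @param nucleus_diameter Nucleus diameter in um.
#' @param bleach_constant Photobleach time constant `t_b` in ms.
#' @param single_brightness Brightness of a single fluorophore `I_GFP` in
#'   integrated camera counts.
#' @param read_noise Gaussian read noise sd in counts.
#' @param shot_noise Apply Poisson shot noise to expected counts?
#' @param gain Camera gain (counts out per count in); kept at 1.
#' @param offset Constant camera baseline offset in counts.
#' @param seed Optional integer seed fixed into the parameter set; when set,
#'   generators that receive these parameters are reproducible.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(pixel_size = 80, dt = 5, psf_sigma = 230,
                       cell_diameter = 5, nucleus_diameter = 2,
                       bleach_constant = 40, single_brightness = 5000,
                       read_noise = 7, shot_noise = TRUE, gain = 1,
                       offset = 100, seed = NULL) {
  num <- c(pixel_size = pixel_size, dt = dt, psf_sigma = psf_sigma,
           cell_diameter = cell_diameter, nucleus_diameter = nucleus_diameter,
           bleach_constant = bleach_constant,
           single_brightness = single_brightness, gain = gain)
  if (any(!is.finite(num)) || any(num <= 0)) {
    stop("all lengths, times, brightnesses and gain must be strictly positive")
  }
  if (read_noise < 0) stop("read_noise must be >= 0")
  if (nucleus_diameter >= cell_diameter) {
    stop("nucleus_diameter must be smaller than cell_diameter")
  }
  structure(list(pixel_size = pixel_size, dt = dt, psf_sigma = psf_sigma,
                 cell_diameter = cell_diameter,
                 nucleus_diameter = nucleus_diameter,
                 bleach_constant = bleach_constant,
                 single_brightness = single_brightness,
                 read_noise = read_noise, shot_noise = shot_noise,
                 gain = gain, offset = offset, seed = seed),
            class = "sim_params")
}

psf_sigma_px <- function(params) params$psf_sigma / params$pixel_size

#' Generate a synthetic Slimfield image stack of one cell
#'
#' Renders a time series of fluorescence frames of a spherical cell with a
#' concentric spherical nucleus containing (i) diffuse fluorophore pools in
#' the cytoplasm and nucleoplasm, rendered as the PSF-blurred 2D projection
#' of a uniform volume density, and (ii) discrete multi-fluorophore foci
#' diffusing within their compartment. All fluorescence decays exponentially
#' with the photobleach constant `t_b`, and optional EMCCD-like noise
#' (Poisson shot noise plus Gaussian read noise on a constant offset) is
#' added per frame. Ground truth sufficient to score downstream detection,
#' tracking, stoichiometry and copy-number recovery is returned alongside.
#'
#' Trans-nuclear foci follow a straight path crossing the nuclear envelope
#' at constant speed, with an optional exponentially distributed pause at
#' the envelope.
#'
#' @param params A [sim_params()] object.
#' @param pool_counts Named numeric vector `c(cytoplasm = , nucleus = )` of
#'   pool copy numbers (molecules).
#' @param foci_spec Optional data frame with columns `S` (stoichiometry,
#'   molecules), `D` (diffusion coefficient, um^2/s) and `compartment`
#'   (one of `"cytoplasm"`, `"nucleus"`, `"trans-nuclear"`). Optional column
#'   `pause_ms` gives the mean envelope pause for trans-nuclear foci (0 = no
#'   pause).
#' @param n_frames Number of frames.
#' @param img_size Image side length in pixels (square frames); default
#'   fits the cell with a margin.
#' @param noise Add camera noise? When `FALSE` frames are noiseless expected
#'   counts with zero offset, so photon conservation is exact.
#' @param foci_xy Optional matrix of initial focus positions (px,
#'   image coordinates); defaults to random positions inside the declared
#'   compartment.
#' @return A list with elements `stack` (list of matrices), `truth` (list
#'   with `foci` data frame of per-frame true positions, `pool_counts`,
#'   geometry and parameters) — class `cell_stack`.
#' @export
generate_cell_stack <- function(params = sim_params(),
                                pool_counts = c(cytoplasm = 0, nucleus = 0),
                                foci_spec = NULL, n_frames = 10,
                                img_size = NULL, noise = TRUE,
                                foci_xy = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  px <- params$pixel_size
  r_cell <- params$cell_diameter * 1000 / 2 / px    # px
  r_nuc <- params$nucleus_diameter * 1000 / 2 / px  # px
  if (is.null(img_size)) img_size <- ceiling(2 * r_cell) + 16
  cx <- cy <- (img_size + 1) / 2
  s_px <- psf_sigma_px(params)

  pool_cyt <- unname(pool_counts["cytoplasm"] %|na|% 0)
  pool_nuc <- unname(pool_counts["nucleus"] %|na|% 0)
  if (pool_cyt < 0 || pool_nuc < 0) stop("pool counts must be non-negative")

  pool_img <- matrix(0, img_size, img_size)
  if (pool_cyt > 0) {
    pool_img <- pool_img + pool_cyt *
      project_sphere_shell(img_size, img_size, cx, cy, r_cell, r_nuc)
  }
  if (pool_nuc > 0) {
    pool_img <- pool_img + pool_nuc *
      project_sphere_shell(img_size, img_size, cx, cy, r_nuc)
  }
  if (any(pool_img > 0)) pool_img <- gaussian_blur(pool_img, s_px)
  pool_img <- pool_img * params$single_brightness

  n_foci <- if (is.null(foci_spec)) 0L else nrow(foci_spec)
  if (n_foci > 0) {
    if (!all(foci_spec$compartment %in%
             c("cytoplasm", "nucleus", "trans-nuclear"))) {
      stop("compartment must be cytoplasm, nucleus or trans-nuclear")
    }
    if (any(foci_spec$S < 1) || any(foci_spec$D < 0)) {
      stop("foci_spec requires S >= 1 and D >= 0")
    }
  }

  # simulate focus trajectories (px), one row per focus per frame
  paths <- vector("list", n_foci)
  for (k in seq_len(n_foci)) {
    comp <- foci_spec$compartment[k]
    Dk <- foci_spec$D[k]
    step_sd <- sqrt(2 * Dk * params$dt / 1000) * 1000 / px  # px per axis
    if (comp == "trans-nuclear") {
      pause_ms <- if ("pause_ms" %in% names(foci_spec)) foci_spec$pause_ms[k] else 0
      paths[[k]] <- trans_nuclear_path(cx, cy, r_nuc, step_sd, n_frames,
                                       pause_ms, params$dt)
    } else {
      r_max <- if (comp == "nucleus") r_nuc else r_cell
      r_min <- if (comp == "nucleus") 0 else r_nuc
      if (!is.null(foci_xy)) {
        p0 <- foci_xy[k, ]
        r0 <- sqrt(sum((p0 - c(cx, cy))^2))
        if (r0 > r_cell) stop("focus placed outside cell")
      } else {
        repeat {
          p0 <- c(cx, cy) + stats::runif(2, -r_max, r_max)
          r0 <- sqrt(sum((p0 - c(cx, cy))^2))
          if (r0 <= 0.8 * r_max && (r_min == 0 || r0 >= 1.1 * r_min)) break
        }
      }
      xy <- matrix(NA_real_, n_frames, 2)
      xy[1, ] <- p0
      for (f in seq_len(n_frames - 1)) {
        prop <- xy[f, ] + stats::rnorm(2, 0, step_sd)
        # reflect at the compartment boundary
        rr <- sqrt(sum((prop - c(cx, cy))^2))
        if (rr > r_max) prop <- c(cx, cy) + (prop - c(cx, cy)) * (2 * r_max - rr) / rr
        rr <- sqrt(sum((prop - c(cx, cy))^2))
        if (r_min > 0 && rr < r_min) {
          prop <- c(cx, cy) + (prop - c(cx, cy)) * (2 * r_min - rr) / max(rr, 1e-9)
        }
        xy[f + 1, ] <- prop
      }
      paths[[k]] <- xy
    }
  }

  times <- (seq_len(n_frames) - 1) * params$dt
  decay <- exp(-times / params$bleach_constant)
  stack <- vector("list", n_frames)
  truth_rows <- list()
  for (f in seq_len(n_frames)) {
    frame <- pool_img * decay[f]
    if (n_foci > 0) {
      xs <- vapply(paths, function(p) p[f, 1], 0)
      ys <- vapply(paths, function(p) p[f, 2], 0)
      amps <- foci_spec$S * params$single_brightness * decay[f]
      frame <- frame + render_spots(img_size, img_size, xs, ys, amps, s_px)
      truth_rows[[f]] <- data.frame(
        frame = f, focus = seq_len(n_foci), x_px = xs, y_px = ys,
        S = foci_spec$S, D = foci_spec$D,
        compartment = foci_spec$compartment)
    }
    stack[[f]] <- if (noise) {
      apply_camera_noise(frame, params$read_noise, params$shot_noise,
                         params$gain, params$offset)
    } else frame
  }

  truth <- list(
    foci = if (length(truth_rows)) do.call(rbind, truth_rows) else NULL,
    pool_counts = c(cytoplasm = pool_cyt, nucleus = pool_nuc),
    center_px = c(x = cx, y = cy), r_cell_px = r_cell, r_nucleus_px = r_nuc,
    times_ms = times, params = params)
  structure(list(stack = stack, truth = truth), class = "cell_stack")
}

`%|na|%` <- function(x, y) if (length(x) == 0 || is.na(x)) y else x

# Straight crossing path through the nuclear envelope with an optional
# exponential pause at the crossing point.
trans_nuclear_path <- function(cx, cy, r_nuc, step_sd, n_frames, pause_ms,
                               dt) {
  theta <- stats::runif(1, 0, 2 * pi)
  dir_in <- -c(cos(theta), sin(theta))              # towards the centre
  cross <- c(cx, cy) + r_nuc * c(cos(theta), sin(theta))
  speed <- max(step_sd, 1e-6)                       # px per frame
  pause <- if (pause_ms > 0) stats::rexp(1, 1 / pause_ms) else 0
  # random phase: the pause starts mid-frame-interval
  t_arrive <- stats::runif(1, 0, dt)
  xy <- matrix(NA_real_, n_frames, 2)
  for (f in seq_len(n_frames)) {
    t <- (f - 1) * dt
    if (t < t_arrive) {
      xy[f, ] <- cross - dir_in * speed * (t_arrive - t) / dt
    } else if (t < t_arrive + pause) {
      xy[f, ] <- cross
    } else {
      xy[f, ] <- cross + dir_in * speed * (t - t_arrive - pause) / dt
    }
  }
  xy
}

#' Generate squared first-step displacements from a Brownian mixture
#'
#' Draws one squared 2D displacement per track from a weighted mixture of
#' Brownian components with diffusion coefficients `D_i` (um^2/s), observed
#' at frame interval `dt` (ms) with Gaussian localization error of sd
#' `sigma` (nm) on each coordinate of both endpoints, so that
#' `E[r^2] = 4*D*dt + 4*sigma^2` for each component.
#'
#' @param n_tracks Number of tracks (one displacement each).
#' @param mixture Data frame with columns `A` (fractions summing to 1) and
#'   `D` (um^2/s).
#' @param dt Frame interval in ms.
#' @param sigma Localization precision in nm.
#' @param seed Optional integer seed.
#' @return Numeric vector of squared displacements (um^2), with the true
#'   component index as attribute `"component"`.
#' @export
generate_displacements <- function(n_tracks, mixture, dt = 5, sigma = 40,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(mixture$D < 0)) stop("diffusion coefficients must be non-negative")
  if (abs(sum(mixture$A) - 1) > 1e-8) stop("mixture fractions must sum to 1")
  comp <- sample.int(nrow(mixture), n_tracks, replace = TRUE,
                     prob = mixture$A)
  sig_um <- sigma / 1000
  var_axis <- 2 * mixture$D[comp] * dt / 1000 + 2 * sig_um^2
  dx <- stats::rnorm(n_tracks, 0, sqrt(var_axis))
  dy <- stats::rnorm(n_tracks, 0, sqrt(var_axis))
  structure(dx^2 + dy^2, component = comp)
}

#' Generate stepwise-photobleaching intensity traces
#'
#' Each trace starts with `S` active fluorophores of brightness `I_GFP`;
#' individual fluorophores bleach irreversibly at exponentially distributed
#' times with mean `t_b`, so the trace decays in integer steps of `I_GFP`
#' and the ensemble mean follows `S * I_GFP * exp(-t/t_b)`.
#'
#' @param n Number of traces.
#' @param S Stoichiometry (fluorophores per trace), `S >= 1`.
#' @param I_GFP Single-fluorophore brightness (counts).
#' @param t_b Photobleach time constant (ms).
#' @param noise_cv Multiplicative Gaussian noise coefficient of variation
#'   applied to the nonzero intensity levels (0 = noiseless).
#' @param dt Frame interval (ms).
#' @param n_frames Trace length in frames.
#' @param seed Optional integer seed.
#' @return `n` x `n_frames` matrix of intensities with attribute
#'   `"times_ms"`.
#' @export
generate_bleach_traces <- function(n, S, I_GFP = 5000, t_b = 40,
                                   noise_cv = 0, dt = 5, n_frames = 50,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (S < 1) stop("S must be >= 1")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  times <- (seq_len(n_frames) - 1) * dt
  out <- matrix(0, n, n_frames)
  for (i in seq_len(n)) {
    bleach_t <- stats::rexp(S, 1 / t_b)
    active <- vapply(times, function(t) sum(bleach_t > t), 0L)
    trace <- active * I_GFP
    if (noise_cv > 0) {
      trace <- trace * (1 + stats::rnorm(n_frames, 0, noise_cv)) *
        (active > 0)
    }
    out[i, ] <- trace
  }
  structure(out, times_ms = times)
}

#' Generate a synthetic FRAP recovery curve
#'
#' Samples the single-exponential recovery model
#' `C(t) = C0 * (1 - exp(-t/t_R))` at the given timepoints with additive
#' Gaussian noise.
#'
#' @param C0 Recovery plateau (molecules).
#' @param t_R Recovery (turnover) time constant, same unit as `timepoints`.
#' @param timepoints Post-bleach sampling times (s); must be non-empty.
#' @param noise_sd Additive Gaussian noise sd.
#' @param seed Optional integer seed.
#' @return Data frame with columns `t` and `C`.
#' @export
generate_frap_curve <- function(C0, t_R, timepoints, noise_sd = 0,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(timepoints) == 0) stop("timepoints must be non-empty")
  if (t_R <= 0) stop("t_R must be positive")
  C <- C0 * (1 - exp(-timepoints / t_R))
  if (noise_sd > 0) C <- C + stats::rnorm(length(C), 0, noise_sd)
  data.frame(t = timepoints, C = C)
}

#' Generate periodic synthetic stoichiometries
#'
#' Values are `k * u + noise` with the multiplicity `k` drawn uniformly
#' from `k_range`, emulating foci built from `k` copies of a `u`-mer
#' cluster unit.
#'
#' @param n Sample size.
#' @param u Cluster unit (molecules), `u > 0`.
#' @param k_range Integer vector of allowed multiplicities.
#' @param noise_sd Additive Gaussian noise sd (molecules).
#' @param seed Optional integer seed.
#' @return Numeric vector of stoichiometries with attribute `"k"`.
#' @export
generate_stoichiometries <- function(n, u = 7, k_range = 1:4, noise_sd = 0,
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (u <= 0) stop("u must be positive")
  if (n == 0) return(numeric(0))
  k <- sample(k_range, n, replace = TRUE)
  structure(k * u + stats::rnorm(n, 0, noise_sd), k = k)
}

#' Generate a toy genome with planted binding sites and 3D coordinates
#'
#' Builds random chromosome sequences with instances of an IUPAC pattern
#' planted at known, non-overlapping positions; annotates genes so that a
#' chosen fraction of planted sites fall within 500 bp upstream of a gene
#' start (promoter sites); and lays each chromosome out as a confined
#' random-walk polymer inside a sphere of the nuclear diameter, one bead
#' per `bp_per_bead` bp with Kuhn-segment steps of `step_nm` (default
#' 100 nm per kb, roughly two persistence lengths of chromatinized DNA,
#' so chromosome territories span the nucleus). This toy model stands in
#' for a population-consensus 3D chromosome structure.
#'
#' @param n_chrom Number of chromosomes.
#' @param lengths Chromosome lengths in bp (recycled).
#' @param pattern IUPAC pattern to plant (character).
#' @param n_sites Total number of planted sites.
#' @param promoter_fraction Fraction of planted sites placed within 500 bp
#'   upstream of an annotated gene start.
#' @param nucleus_diameter Nuclear diameter in um.
#' @param bp_per_bead Polymer coarse-graining (bp per modeled locus).
#' @param step_nm Polymer step length per bead (nm).
#' @param seed Optional integer seed.
#' @return List with `sequences` (named [Biostrings::DNAStringSet]),
#'   `annotation` (data frame: chrom, start, end, strand, gene_id; 1-based
#'   inclusive), `coords` (data frame: chrom, bp, x_nm, y_nm, z_nm) and
#'   `sites` (planted-site data frame: chrom, start, strand, promoter).
#' @export
generate_toy_genome <- function(n_chrom = 2, lengths = 20000,
                                pattern = "TTTTTGCGGGG", n_sites = 10,
                                promoter_fraction = 0.5,
                                nucleus_diameter = 2, bp_per_bead = 1000,
                                step_nm = 100, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  check_iupac(pattern)
  lengths <- rep_len(lengths, n_chrom)
  plen <- nchar(pattern)
  capacity <- sum(lengths %/% (2 * plen + 500))
  if (n_sites > capacity) stop("site count exceeds genome capacity")

  chrom_names <- paste0("chr", seq_len(n_chrom))
  seqs <- lapply(lengths, function(L) {
    sample(c("A", "C", "G", "T"), L, replace = TRUE)
  })
  names(seqs) <- chrom_names

  # distribute sites over chromosomes proportionally to length
  site_chrom <- sample(rep(seq_len(n_chrom),
                           pmax(1, round(n_sites * lengths / sum(lengths)))),
                       n_sites, replace = TRUE)
  sites <- NULL
  ann <- NULL
  gene_i <- 0L
  for (ci in seq_len(n_chrom)) {
    ns <- sum(site_chrom == ci)
    if (ns == 0) next
    # keep planted instances and their promoter genes well separated
    slots <- floor(seq(600, lengths[ci] - plen - 600, length.out = max(ns, 2)))
    slots <- slots[seq_len(ns)]
    for (s0 in slots) {
      inst <- realize_iupac(pattern)
      strand <- sample(c("+", "-"), 1)
      planted <- if (strand == "+") inst else revcomp_chr(inst)
      seqs[[ci]][s0:(s0 + plen - 1)] <- strsplit(planted, "")[[1]]
      is_prom <- stats::runif(1) < promoter_fraction
      if (is_prom) {
        gene_i <- gene_i + 1L
        # gene on the same strand with the site within 500 bp upstream
        if (strand == "+") {
          gstart <- s0 + plen - 1 + sample(10:400, 1)
          gend <- min(gstart + 300, lengths[ci])
        } else {
          gend <- s0 - sample(10:400, 1)
          gstart <- max(gend - 300, 1)
        }
        ann <- rbind(ann, data.frame(
          chrom = chrom_names[ci], start = gstart, end = gend,
          strand = strand, gene_id = sprintf("GENE%03d", gene_i)))
      }
      sites <- rbind(sites, data.frame(
        chrom = chrom_names[ci], start = s0, strand = strand,
        promoter = is_prom))
    }
  }

  # confined random-walk polymer, one bead per bp_per_bead
  r_nuc_nm <- nucleus_diameter * 1000 / 2
  coords <- NULL
  for (ci in seq_len(n_chrom)) {
    n_beads <- max(2L, ceiling(lengths[ci] / bp_per_bead))
    xyz <- matrix(NA_real_, n_beads, 3)
    repeat {
      xyz[1, ] <- stats::runif(3, -r_nuc_nm, r_nuc_nm)
      if (sum(xyz[1, ]^2) < (0.9 * r_nuc_nm)^2) break
    }
    for (b in 2:n_beads) {
      repeat {
        step <- stats::rnorm(3)
        prop <- xyz[b - 1, ] + step_nm * step / sqrt(sum(step^2))
        if (sum(prop^2) < r_nuc_nm^2) break
      }
      xyz[b, ] <- prop
    }
    coords <- rbind(coords, data.frame(
      chrom = chrom_names[ci],
      bp = pmin((seq_len(n_beads) - 1) * bp_per_bead + 1, lengths[ci]),
      x_nm = xyz[, 1], y_nm = xyz[, 2], z_nm = xyz[, 3]))
  }

  seqs <- Biostrings::DNAStringSet(vapply(seqs, paste0, "", collapse = ""))
  list(sequences = seqs, annotation = ann, coords = coords,
       sites = sites %||% data.frame(chrom = character(), start = integer(),
                                     strand = character(),
                                     promoter = logical()))
}

iupac_map <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
               S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
               H = "ACT", V = "ACG", N = "ACGT")

check_iupac <- function(pattern) {
  ch <- strsplit(toupper(pattern), "")[[1]]
  if (length(ch) == 0 || !all(ch %in% names(iupac_map))) {
    stop("invalid IUPAC pattern: ", pattern)
  }
  invisible(ch)
}

# a concrete DNA realization of an IUPAC pattern
realize_iupac <- function(pattern) {
  ch <- check_iupac(pattern)
  paste0(vapply(ch, function(c) {
    opts <- strsplit(iupac_map[[c]], "")[[1]]
    opts[sample.int(length(opts), 1)]
  }, ""), collapse = "")
}

revcomp_chr <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste0(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

#' Write an image stack as multi-page 16-bit TIFF
#'
#' @param stack List of numeric matrices (counts).
#' @param path Output file.
#' @param max_count Full-scale count value mapped to 16-bit maximum.
#' @export
write_stack_tiff <- function(stack, path, max_count = 65535) {
  pages <- lapply(stack, function(m) pmin(pmax(m / max_count, 0), 1))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#'
#' @param path TIFF file.
#' @param max_count Full-scale count value (inverse of [write_stack_tiff()]).
#' @return List of numeric matrices.
#' @export
read_stack_tiff <- function(path, max_count = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p * max_count
  })
}
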