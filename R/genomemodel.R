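#' Scan a genome for IUPAC pattern matches
#'
#' Finds all matches of an IUPAC nucleotide pattern on both strands of each
#' chromosome, deduplicated by (chromosome, start, strand); minus-strand
#' matches are reported by the 1-based start of the matched region on the
#' plus-strand coordinates. If an annotation is supplied, each site is
#' flagged as a promoter site when it lies within 500 bp upstream of an
#' annotated gene start on the same strand.
#'
#' @param sequences A [Biostrings::DNAStringSet] (or path to a FASTA file).
#' @param pattern IUPAC pattern string.
#' @param annotation Optional data frame (`chrom`, `start`, `end`,
#'   `strand`, `gene_id`; 1-based inclusive).
#' @param promoter_bp Upstream window defining a promoter (default 500).
#' @return Data frame of class `binding_sites`: `chrom`, `start`, `end`,
#'   `strand`, `promoter`.
#' @export
scan_sites <- function(sequences, pattern, annotation = NULL,
                       promoter_bp = 500) {
  check_iupac(pattern)
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences)) {
    sequences <- Biostrings::readDNAStringSet(sequences)
  }
  pat <- Biostrings::DNAString(pattern)
  plen <- nchar(pattern)
  out <- list()
  for (ci in seq_along(sequences)) {
    chrom <- names(sequences)[ci] %||% paste0("chr", ci)
    fwd <- Biostrings::matchPattern(pat, sequences[[ci]], fixed = FALSE)
    rev <- Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                    sequences[[ci]], fixed = FALSE)
    rows <- rbind(
      if (length(fwd)) data.frame(chrom = chrom,
                                  start = Biostrings::start(fwd),
                                  strand = "+"),
      if (length(rev)) data.frame(chrom = chrom,
                                  start = Biostrings::start(rev),
                                  strand = "-"))
    if (!is.null(rows)) out[[length(out) + 1]] <- rows
  }
  sites <- if (length(out)) do.call(rbind, out) else {
    data.frame(chrom = character(), start = integer(), strand = character())
  }
  sites <- unique(sites)
  sites$end <- sites$start + plen - 1L
  sites$promoter <- flag_promoters(sites, annotation, promoter_bp)
  sites <- sites[order(sites$chrom, sites$start, sites$strand), ]
  rownames(sites) <- NULL
  class(sites) <- c("binding_sites", class(sites))
  sites
}

flag_promoters <- function(sites, annotation, promoter_bp) {
  if (is.null(annotation) || nrow(sites) == 0) {
    return(rep(FALSE, nrow(sites)))
  }
  vapply(seq_len(nrow(sites)), function(i) {
    g <- annotation[annotation$chrom == sites$chrom[i], , drop = FALSE]
    if (!nrow(g)) return(FALSE)
    any(vapply(seq_len(nrow(g)), function(j) {
      if (g$strand[j] == "+") {
        # upstream window [start - promoter_bp, start - 1]
        sites$end[i] >= g$start[j] - promoter_bp &&
          sites$start[i] <= g$start[j] - 1
      } else {
        sites$start[i] <= g$end[j] + promoter_bp &&
          sites$end[i] >= g$end[j] + 1
      }
    }, TRUE))
  }, TRUE)
}

#' Specification of a nuclear binding model
#'
#' Defines how fluorophore-tagged factor molecules are distributed in the
#' nucleus: bound to DNA sites as monomers or as u-mer clusters, placed on
#' the nuclear-envelope surface (NE variants, emulating molecules in
#' transit), or a per-cell mixture of models. Defaults follow the cluster
#' hypothesis for a nuclear-localized repressor: 190 molecules in
#' DNA-bound foci grouped into 7-mer clusters, 130 molecules near the
#' envelope grouped into 7-mer clusters, and a 75% NE-cluster / 25%
#' DNA-cluster mixture.
#'
#' @param model One of `"monomer"`, `"dna_cluster"`, `"ne_monomer"`,
#'   `"ne_cluster"`, `"mixture"`.
#' @param unit Cluster unit u (molecules per cluster, default 7).
#' @param total_molecules Molecules placed on DNA sites (default 190).
#' @param ne_molecules Molecules placed at the envelope (default 130).
#' @param mixture_weights Named weights for the mixture model (must sum to
#'   1).
#' @return Object of class `binding_model_spec`.
#' @export
binding_model_spec <- function(model = c("monomer", "dna_cluster",
                                         "ne_monomer", "ne_cluster",
                                         "mixture"),
                               unit = 7, total_molecules = 190,
                               ne_molecules = 130,
                               mixture_weights = c(ne_cluster = 0.75,
                                                   dna_cluster = 0.25)) {
  model <- match.arg(model)
  if (unit < 1) stop("unit must be >= 1")
  if (abs(sum(mixture_weights) - 1) > 1e-8) {
    stop("mixture weights must sum to 1")
  }
  structure(list(model = model, unit = unit,
                 total_molecules = total_molecules,
                 ne_molecules = ne_molecules,
                 mixture_weights = mixture_weights),
            class = "binding_model_spec")
}

#' Assign molecules to 3D positions under a binding model
#'
#' Places molecules according to the model: the monomer model assigns one
#' molecule to every promoter site and the remaining molecules to randomly
#' chosen non-promoter sites; the cluster model places `floor(total/u)`
#' clusters of `u` molecules on randomly chosen promoter sites (remainder
#' molecules are dropped and reported); NE variants place molecules (or
#' u-mer clusters) uniformly on the nuclear-envelope sphere; the mixture
#' model draws one sub-model per cell by the configured weights. Site
#' positions in 3D are interpolated linearly in bp between the two nearest
#' modeled loci of the same chromosome.
#'
#' @param sites `binding_sites` data frame (needs `promoter` flags for
#'   DNA models).
#' @param spec A [binding_model_spec()].
#' @param coords 3D model data frame (`chrom`, `bp`, `x_nm`, `y_nm`,
#'   `z_nm`); required for DNA models.
#' @param nucleus_radius_nm Nuclear radius for NE placements (default
#'   1000).
#' @return Data frame of class `binding_configuration` (`x_nm`, `y_nm`,
#'   `z_nm`, `molecules`, `origin`) with attributes `"model"` and
#'   `"remainder"`.
#' @export
assign_binding <- function(sites, spec, coords = NULL,
                           nucleus_radius_nm = 1000) {
  stopifnot(inherits(spec, "binding_model_spec"))
  model <- spec$model
  if (model == "mixture") {
    model <- sample(names(spec$mixture_weights), 1,
                    prob = spec$mixture_weights)
  }
  placements <- switch(model,
    monomer = {
      prom <- sites[sites$promoter, , drop = FALSE]
      rest <- sites[!sites$promoter, , drop = FALSE]
      n_extra <- spec$total_molecules - nrow(prom)
      if (n_extra < 0) {
        prom <- prom[seq_len(spec$total_molecules), , drop = FALSE]
        n_extra <- 0
      }
      if (n_extra > nrow(rest)) stop("not enough sites for requested placements")
      extra <- rest[sample.int(nrow(rest), n_extra), , drop = FALSE]
      placed <- rbind(prom, extra)
      data.frame(site_to_xyz(placed, coords), molecules = 1,
                 origin = "dna")
    },
    dna_cluster = {
      if (spec$total_molecules < spec$unit) {
        stop("total molecules fewer than one cluster unit")
      }
      n_cl <- floor(spec$total_molecules / spec$unit)
      prom <- sites[sites$promoter, , drop = FALSE]
      if (nrow(prom) < 1) stop("not enough sites for requested placements")
      pick <- prom[sample.int(nrow(prom), n_cl,
                              replace = n_cl > nrow(prom)), , drop = FALSE]
      data.frame(site_to_xyz(pick, coords), molecules = spec$unit,
                 origin = "dna")
    },
    ne_monomer = data.frame(sphere_surface(spec$ne_molecules,
                                           nucleus_radius_nm),
                            molecules = 1, origin = "envelope"),
    ne_cluster = {
      if (spec$ne_molecules < spec$unit) {
        stop("NE molecules fewer than one cluster unit")
      }
      n_cl <- floor(spec$ne_molecules / spec$unit)
      data.frame(sphere_surface(n_cl, nucleus_radius_nm),
                 molecules = spec$unit, origin = "envelope")
    })
  total_req <- if (model %in% c("ne_monomer", "ne_cluster")) {
    spec$ne_molecules
  } else spec$total_molecules
  remainder <- total_req - sum(placements$molecules)
  if (remainder > 0) {
    message(remainder, " remainder molecule(s) dropped by the cluster ",
            "assignment policy")
  }
  structure(placements, model = model, remainder = remainder,
            class = c("binding_configuration", class(placements)))
}

sphere_surface <- function(n, r_nm) {
  v <- matrix(stats::rnorm(3 * n), n, 3)
  v <- v / sqrt(rowSums(v^2)) * r_nm
  data.frame(x_nm = v[, 1], y_nm = v[, 2], z_nm = v[, 3])
}

# interpolate site bp positions onto the 3D polymer model
site_to_xyz <- function(sites, coords) {
  if (is.null(coords)) stop("3D coordinates required for DNA binding models")
  out <- matrix(NA_real_, nrow(sites), 3)
  for (i in seq_len(nrow(sites))) {
    cc <- coords[coords$chrom == sites$chrom[i], , drop = FALSE]
    if (!nrow(cc)) stop("chromosome ", sites$chrom[i], " missing from model")
    cc <- cc[order(cc$bp), ]
    bp <- sites$start[i]
    j <- findInterval(bp, cc$bp)
    if (j < 1) {
      out[i, ] <- as.numeric(cc[1, c("x_nm", "y_nm", "z_nm")])
    } else if (j >= nrow(cc)) {
      out[i, ] <- as.numeric(cc[nrow(cc), c("x_nm", "y_nm", "z_nm")])
    } else {
      f <- (bp - cc$bp[j]) / (cc$bp[j + 1] - cc$bp[j])
      out[i, ] <- (1 - f) * as.numeric(cc[j, c("x_nm", "y_nm", "z_nm")]) +
        f * as.numeric(cc[j + 1, c("x_nm", "y_nm", "z_nm")])
    }
  }
  data.frame(x_nm = out[, 1], y_nm = out[, 2], z_nm = out[, 3])
}

#' Render a simulated nuclear image from a binding configuration
#'
#' Applies a rotation (random by default, emulating the unknown
#' orientation of the nucleus relative to the camera), keeps placements
#' within the microscope depth of field about the focal (equatorial)
#' plane, projects them to that plane, renders each placement as a
#' PSF-integrated Gaussian spot of intensity `molecules * I_GFP`, and adds
#' the camera noise model.
#'
#' @param config A `binding_configuration`.
#' @param params A [sim_params()] object.
#' @param rotation 3x3 rotation matrix, or `NULL` for a random projection.
#' @param img_size Image side (px).
#' @param noise Add camera noise?
#' @param depth_of_field Depth of field in um; only placements with
#'   rotated `|z|` below half this depth are rendered (default 1).
#' @return Numeric matrix (one frame) with attribute
#'   `"projected_px"` (data frame x_px, y_px, molecules).
#' @export
simulate_nuclear_image <- function(config, params = sim_params(),
                                   rotation = NULL, img_size = NULL,
                                   noise = TRUE, depth_of_field = 1) {
  px <- params$pixel_size
  r_nuc_px <- params$nucleus_diameter * 1000 / 2 / px
  if (is.null(img_size)) img_size <- ceiling(2 * r_nuc_px) + 24
  c0 <- (img_size + 1) / 2
  R <- rotation %||% random_rotation()
  if (nrow(config) > 0) {
    xyz <- as.matrix(config[, c("x_nm", "y_nm", "z_nm")]) %*% t(R)
    infocus <- abs(xyz[, 3]) <= depth_of_field * 1000 / 2
    xyz <- xyz[infocus, , drop = FALSE]
    config <- config[infocus, , drop = FALSE]
  }
  if (nrow(config) > 0) {
    x <- c0 + xyz[, 1] / px
    y <- c0 + xyz[, 2] / px
    amp <- config$molecules * params$single_brightness
    frame <- render_spots(img_size, img_size, x, y, amp,
                          psf_sigma_px(params))
    proj <- data.frame(x_px = x, y_px = y, molecules = config$molecules)
  } else {
    frame <- matrix(0, img_size, img_size)
    proj <- data.frame(x_px = numeric(), y_px = numeric(),
                       molecules = numeric())
  }
  if (noise) {
    frame <- apply_camera_noise(frame, params$read_noise, params$shot_noise,
                                params$gain, params$offset)
  }
  structure(frame, projected_px = proj)
}

#' Compare a simulated stoichiometry distribution with a reference
#'
#' Evaluates Gaussian KDEs of the simulated and reference stoichiometry
#' samples on a shared grid and reports the coefficient of determination
#' `R^2 = 1 - SS_res/SS_tot` of the simulated density against the
#' reference density. `R^2 = 1` for identical samples; it can be negative
#' for badly mismatched distributions.
#'
#' @param simulated,reference Numeric stoichiometry samples (>= 30 values
#'   each).
#' @param n_grid Shared grid size.
#' @return List of class `model_comparison`: `r_squared`, `grid`,
#'   `sim_density`, `ref_density`.
#' @export
compare_model <- function(simulated, reference, n_grid = 256) {
  simulated <- simulated[is.finite(simulated)]
  reference <- reference[is.finite(reference)]
  if (length(simulated) < 30 || length(reference) < 30) {
    stop("need at least 30 values in each sample")
  }
  if (stats::sd(reference) == 0) stop("degenerate reference: zero variance")
  rng <- range(c(simulated, reference))
  pad <- 0.1 * diff(rng)
  grid <- seq(rng[1] - pad, rng[2] + pad, length.out = n_grid)
  dens <- function(v) {
    d <- stats::density(v, bw = "nrd0", from = grid[1],
                        to = grid[n_grid], n = n_grid)
    d$y
  }
  sim_d <- dens(simulated)
  ref_d <- dens(reference)
  r2 <- 1 - sum((ref_d - sim_d)^2) / sum((ref_d - mean(ref_d))^2)
  structure(list(r_squared = r2, grid = grid, sim_density = sim_d,
                 ref_density = ref_d),
            class = "model_comparison")
}

#' Sliding-window electrostatic charge profile of a protein sequence
#'
#' Assigns charge -1 to residues D and E, +1 to K and R, +0.5 to H and 0
#' to all other residues, then reports the mean charge in a rolling window
#' (default 75 residues) at each window position.
#'
#' @param sequence Amino-acid sequence (single string, one-letter codes).
#' @param window Window length in residues.
#' @return Data frame `position` (window centre) and `charge` (mean
#'   windowed charge).
#' @export
charge_profile <- function(sequence, window = 75) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  valid <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(aa %in% valid)) {
    stop("non-amino-acid character in sequence: ",
         paste(unique(aa[!aa %in% valid]), collapse = ""))
  }
  if (length(aa) < window) stop("sequence shorter than the window")
  q <- numeric(length(aa))
  q[aa %in% c("D", "E")] <- -1
  q[aa %in% c("K", "R")] <- 1
  q[aa == "H"] <- 0.5
  means <- stats::filter(q, rep(1 / window, window), sides = 1)
  pos <- window:length(aa)
  data.frame(position = pos - (window - 1) / 2,
             charge = as.numeric(means[pos]))
}

#' Nearest-neighbour distances between binding sites in 3D
#'
#' For each site with 3D coordinates, the Euclidean nearest-neighbour
#' distance overall, split into nearest same-chromosome and nearest
#' different-chromosome neighbours, and the fraction of sites whose
#' nearest neighbour lies below a threshold (default 50 nm).
#'
#' @param sites Data frame with `chrom`, `x_nm`, `y_nm`, `z_nm` (>= 2
#'   rows).
#' @param threshold_nm Closeness threshold (default 50).
#' @return List: `nn` data frame (`nn_nm`, `nn_same_nm`, `nn_diff_nm`),
#'   `fraction_below`.
#' @export
site_nn_distances <- function(sites, threshold_nm = 50) {
  if (nrow(sites) < 2) stop("need at least 2 sites")
  xyz <- as.matrix(sites[, c("x_nm", "y_nm", "z_nm")])
  dmat <- as.matrix(stats::dist(xyz))
  diag(dmat) <- Inf
  same <- outer(sites$chrom, sites$chrom, "==")
  nn_all <- apply(dmat, 1, min)
  d_same <- dmat; d_same[!same] <- Inf
  d_diff <- dmat; d_diff[same] <- Inf
  nn <- data.frame(nn_nm = nn_all,
                   nn_same_nm = apply(d_same, 1, min),
                   nn_diff_nm = apply(d_diff, 1, min))
  nn$nn_same_nm[!is.finite(nn$nn_same_nm)] <- NA
  nn$nn_diff_nm[!is.finite(nn$nn_diff_nm)] <- NA
  list(nn = nn, fraction_below = mean(nn_all < threshold_nm))
}

#' Write binding sites as BED (0-based half-open) and native CSV
#'
#' @param sites `binding_sites` data frame.
#' @param bed_path,csv_path Output paths (either may be `NULL`).
#' @export
write_sites <- function(sites, bed_path = NULL, csv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = sites$chrom, start = sites$start - 1L,
                      end = sites$end, name = ".", score = 0,
                      strand = sites$strand)
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(sites), csv_path, row.names = FALSE)
  }
  invisible(sites)
}
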