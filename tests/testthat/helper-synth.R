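# Shared fixtures built in code.

# Brownian track with optional localization error, in um.
mk_brownian_track <- function(D, n, dt = 5, sigma = 0) {
  st <- sqrt(2 * D * dt / 1000)
  x <- cumsum(c(0, stats::rnorm(n - 1, 0, st)))
  y <- cumsum(c(0, stats::rnorm(n - 1, 0, st)))
  data.frame(frame = seq_len(n),
             x_um = x + stats::rnorm(n, 0, sigma / 1000),
             y_um = y + stats::rnorm(n, 0, sigma / 1000))
}

# Circle boundary object.
mk_circle_boundary <- function(cx, cy, r, n = 90, label = "nucleus",
                               p = 0.9992) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  smooth_boundary(cbind(cx + r * cos(th), cy + r * sin(th)), p = p,
                  label = label)
}

# Distance of each detection to its nearest true focus (px).
match_detections <- function(det, truth) {
  vapply(seq_len(nrow(det)), function(i) {
    min(sqrt((det$x_px[i] - truth$x_px)^2 + (det$y_px[i] - truth$y_px)^2))
  }, 0)
}

# Single-molecule characteristic intensity as seen by the detector (the
# ROI aperture truncates the PSF, so the effective per-molecule brightness
# must be calibrated through the same detection path).
pipeline_single_brightness <- function(params = sim_params(),
                                       dp = detection_params(),
                                       n_rep = 15) {
  vals <- replicate(n_rep, {
    cfg <- structure(
      data.frame(x_nm = stats::runif(1, -500, 500),
                 y_nm = stats::runif(1, -500, 500), z_nm = 0,
                 molecules = 1, origin = "dna"),
      class = c("binding_configuration", "data.frame"))
    img <- simulate_nuclear_image(cfg, params, rotation = diag(3))
    d <- detect_foci(img, dp)
    if (nrow(d)) max(d$intensity) else NA_real_
  })
  stats::median(vals, na.rm = TRUE)
}

# Stoichiometry sample from rendered nuclear images under a composite
# binding model ("cluster" = DNA 7-mer clusters + NE 7-mer clusters;
# "monomer" = DNA monomers + NE monomers), measured through detection.
sample_model_stoichiometries <- function(kind, sites, coords, I1,
                                         params = sim_params(),
                                         dp = detection_params(),
                                         n_img = 25) {
  out <- numeric(0)
  for (i in seq_len(n_img)) {
    cfg <- if (kind == "cluster") {
      rbind(suppressMessages(assign_binding(
              sites, binding_model_spec("dna_cluster"), coords = coords)),
            suppressMessages(assign_binding(
              sites, binding_model_spec("ne_cluster"))))
    } else {
      rbind(suppressMessages(assign_binding(
              sites, binding_model_spec("monomer"), coords = coords)),
            suppressMessages(assign_binding(
              sites, binding_model_spec("ne_monomer"))))
    }
    det <- detect_foci(simulate_nuclear_image(cfg, params), dp)
    if (nrow(det)) out <- c(out, det$intensity / I1)
  }
  out
}

# Brute-force IUPAC scanner used as an oracle for scan_sites().
iupac_regex <- function(pattern) {
  map <- c(A = "A", C = "C", G = "G", T = "T", R = "[AG]", Y = "[CT]",
           S = "[CG]", W = "[AT]", K = "[GT]", M = "[AC]", B = "[CGT]",
           D = "[AGT]", H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste0(map[strsplit(toupper(pattern), "")[[1]]], collapse = "")
}

revcomp_str <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
            W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
            N = "N")
  paste0(rev(comp[strsplit(toupper(s), "")[[1]]]), collapse = "")
}

brute_force_scan <- function(seq_str, pattern, chrom = "chr1") {
  find_all <- function(rx) {
    m <- gregexpr(paste0("(?=", rx, ")"), seq_str, perl = TRUE)[[1]]
    if (m[1] == -1) integer(0) else as.integer(m)
  }
  fwd <- find_all(iupac_regex(pattern))
  rev <- find_all(iupac_regex(revcomp_str(pattern)))
  out <- rbind(
    if (length(fwd)) data.frame(chrom = chrom, start = fwd, strand = "+"),
    if (length(rev)) data.frame(chrom = chrom, start = rev, strand = "-"))
  if (is.null(out)) {
    return(data.frame(chrom = character(), start = integer(),
                      strand = character()))
  }
  unique(out[order(out$start, out$strand), ])
}

random_dna <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
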