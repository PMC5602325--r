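test_that("scan_sites agrees with a brute-force IUPAC oracle", {
  set.seed(12)
  patterns <- c("TTTWWGCGGRG", "ANNCGT", "ACGT", "YRYR")
  for (pat in patterns) {
    seq_str <- random_dna(8000)
    seqs <- Biostrings::DNAStringSet(c(chr1 = seq_str))
    got <- scan_sites(seqs, pat)
    want <- brute_force_scan(seq_str, pat)
    expect_equal(nrow(got), nrow(want), info = pat)
    expect_equal(got$start, want$start, info = pat)
    expect_equal(got$strand, want$strand, info = pat)
  }
  # palindromic pattern: one report per (position, strand), no duplicates
  seqs <- Biostrings::DNAStringSet(c(chr1 = "AAACGTAAA"))
  pal <- scan_sites(seqs, "ACGT")
  expect_equal(nrow(pal), 2)
  expect_equal(pal$start, c(3L, 3L))
  expect_setequal(pal$strand, c("+", "-"))

  expect_equal(nrow(scan_sites(seqs, "GGGGGG")), 0)
  expect_error(scan_sites(seqs, "AXC"), "IUPAC")
})

test_that("promoter flags follow the 500 bp upstream rule", {
  seqs <- Biostrings::DNAStringSet(c(chr1 = random_dna(3000)))
  ann <- data.frame(chrom = "chr1", start = 1000, end = 1500, strand = "+",
                    gene_id = "G1")
  sites <- data.frame(chrom = "chr1", start = c(600, 100, 1200),
                      strand = "+")
  sites$end <- sites$start + 10
  flags <- slimcluster:::flag_promoters(sites, ann, 500)
  expect_equal(flags, c(TRUE, FALSE, FALSE))
})

test_that("binding models place the expected cluster counts", {
  g <- generate_toy_genome(4, 60000, "TTTWWGCGGRG", n_sites = 250,
                           promoter_fraction = 0.45, seed = 7)
  sites <- scan_sites(g$sequences, "TTTWWGCGGRG", g$annotation)
  expect_gt(sum(sites$promoter), 30)

  set.seed(1)
  dna <- suppressMessages(assign_binding(
    sites, binding_model_spec("dna_cluster"), coords = g$coords))
  expect_equal(nrow(dna), 27)           # floor(190 / 7)
  expect_true(all(dna$molecules == 7))
  expect_equal(sum(dna$molecules) + attr(dna, "remainder"), 190)

  ne <- suppressMessages(assign_binding(sites,
                                        binding_model_spec("ne_cluster")))
  expect_equal(nrow(ne), 18)            # floor(130 / 7)
  r <- sqrt(ne$x_nm^2 + ne$y_nm^2 + ne$z_nm^2)
  expect_equal(r, rep(1000, 18), tolerance = 1e-9)

  # u = 1 cluster placement count equals the monomer count
  u1 <- suppressMessages(assign_binding(
    sites, binding_model_spec("dna_cluster", unit = 1), coords = g$coords))
  expect_equal(nrow(u1), 190)
  expect_true(all(u1$molecules == 1))
  mono <- assign_binding(sites, binding_model_spec("monomer"),
                         coords = g$coords)
  expect_equal(sum(mono$molecules), 190)

  expect_error(assign_binding(sites,
                              binding_model_spec("dna_cluster",
                                                 total_molecules = 3)),
               "fewer than one cluster")

  mixed <- replicate(40, attr(suppressMessages(assign_binding(
    sites, binding_model_spec("mixture"), coords = g$coords)), "model"))
  expect_true(all(mixed %in% c("ne_cluster", "dna_cluster")))
  expect_gt(mean(mixed == "ne_cluster"), 0.5)
})

test_that("nuclear image rendering conserves spot intensity", {
  p <- sim_params()
  cfg <- structure(data.frame(x_nm = 0, y_nm = 0, z_nm = 0, molecules = 7,
                              origin = "dna"),
                   class = c("binding_configuration", "data.frame"))
  img <- simulate_nuclear_image(cfg, p, rotation = diag(3), noise = FALSE)
  expect_equal(sum(img), 7 * 5000, tolerance = 0.01)

  empty <- simulate_nuclear_image(cfg[0, ], p, noise = FALSE)
  expect_true(all(empty == 0))

  # two placements closer than the resolution merge into one focus
  pair <- structure(data.frame(x_nm = c(-50, 50), y_nm = 0, z_nm = 0,
                               molecules = 7, origin = "dna"),
                    class = c("binding_configuration", "data.frame"))
  set.seed(3)
  img2 <- simulate_nuclear_image(pair, p, rotation = diag(3))
  det <- detect_foci(img2, detection_params())
  expect_equal(nrow(det), 1)
  I1 <- pipeline_single_brightness(p)
  expect_lt(abs(det$intensity / I1 - 14) / 14, 0.25)

  # out-of-focus placements are not rendered
  deep <- structure(data.frame(x_nm = 0, y_nm = 0, z_nm = 900,
                               molecules = 7, origin = "dna"),
                    class = c("binding_configuration", "data.frame"))
  img3 <- simulate_nuclear_image(deep, p, rotation = diag(3),
                                 noise = FALSE, depth_of_field = 1)
  expect_true(all(img3 == 0))
})

test_that("model comparison scores identity and mismatch correctly", {
  set.seed(8)
  ref <- rnorm(200, 20, 5)
  expect_equal(compare_model(ref, ref)$r_squared, 1)
  far <- rnorm(200, 200, 5)
  expect_lt(compare_model(far, ref)$r_squared, 0)
  expect_error(compare_model(rnorm(40), rep(3, 40)), "degenerate")
  expect_error(compare_model(rnorm(10), rnorm(40)), "at least 30")
})

test_that("charge profiles use the stated residue weights", {
  polyk <- charge_profile(strrep("K", 100), window = 75)
  expect_equal(polyk$charge, rep(1, nrow(polyk)), tolerance = 1e-9)
  polyd <- charge_profile(strrep("D", 100), window = 75)
  expect_equal(polyd$charge, rep(-1, nrow(polyd)), tolerance = 1e-9)
  dkh <- charge_profile(strrep("DKH", 30), window = 3)
  expect_true(all(abs(dkh$charge - 0.5 / 3) < 1e-9))
  expect_error(charge_profile("ACDEX75", window = 3), "non-amino-acid")
  expect_error(charge_profile("ACD", window = 75), "shorter")
})

test_that("nearest-neighbour site distances split by chromosome", {
  two <- data.frame(chrom = c("a", "a"), x_nm = c(0, 10), y_nm = 0, z_nm = 0)
  nn <- site_nn_distances(two)
  expect_equal(nn$nn$nn_nm, c(10, 10))

  grid <- expand.grid(x_nm = seq(0, 300, 100), y_nm = seq(0, 300, 100))
  grid$z_nm <- 0
  grid$chrom <- "a"
  nng <- site_nn_distances(grid)
  expect_true(all(nng$nn$nn_nm == 100))
  expect_equal(nng$fraction_below, 0)

  single <- data.frame(chrom = "a", x_nm = c(0, 30), y_nm = 0, z_nm = 0)
  nns <- site_nn_distances(single)
  expect_true(all(is.na(nns$nn$nn_diff_nm)))
  expect_equal(nns$fraction_below, 1)  # both below 50 nm
  expect_error(site_nn_distances(two[1, ]), "at least 2")
})

test_that("site export writes BED half-open and CSV 1-based", {
  sites <- data.frame(chrom = "chr1", start = 10L, end = 20L, strand = "+",
                      promoter = TRUE)
  bed <- tempfile(fileext = ".bed")
  csv <- tempfile(fileext = ".csv")
  write_sites(sites, bed, csv)
  b <- read.table(bed, sep = "\t")
  expect_equal(b$V2, 9)
  expect_equal(b$V3, 20)
  expect_equal(read.csv(csv)$start, 10)
})
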