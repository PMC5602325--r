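# slimcluster

Quantitative analysis of transcription-factor clusters from millisecond
Slimfield single-molecule fluorescence microscopy of live yeast cells, with
a full synthetic-data generator for validating every analysis step against
ground truth.

The package implements the analysis chain used to show that a glucose-
responsive repressor operates as clusters of ~7 molecules rather than as
monomers:

- **Synthetic Slimfield data** (`sim_params()`, `generate_cell_stack()`,
  `generate_displacements()`, `generate_bleach_traces()`,
  `generate_frap_curve()`, `generate_stoichiometries()`,
  `generate_toy_genome()`): spherical cell (5 µm) with nucleus (2 µm),
  diffuse fluorophore pools rendered as PSF-blurred projections, diffusing
  multi-fluorophore foci, exponential photobleaching (t_b = 40 ms),
  Poisson + Gaussian camera noise, and toy genomes with planted IUPAC sites
  on a confined random-walk polymer — all with ground truth returned.
- **Segmentation** (`segment_compartment()`, `smooth_boundary()`): iterative
  relative thresholding at 0.3 × mean compartment intensity with sub-pixel
  radial refinement, and periodic smoothing-spline boundaries (p = 0.9992).
- **Focus detection and tracking** (`detect_foci()`, `link_tracks()`,
  `classify_track()`): difference-of-Gaussians seeding, iterative Gaussian
  masking to sub-pixel centroids (~40 nm precision at S ≥ 7),
  characteristic intensity in a 5 px ROI minus the local annulus
  background, SNR > 0.4 acceptance, nearest-neighbour linking within one
  PSF width under factor-two brightness/width gates, and
  nuclear / cytoplasmic / trans-nuclear classification.
- **Stoichiometry** (`estimate_single_brightness()`, `fit_bleach_constant()`,
  `track_stoichiometry()`, `periodicity()`, `copro_pool_counts()`,
  `pool_stoichiometry_bound()`): exp(+t/t_b) photobleach correction,
  S = I₀/I_GFP with the modal single-fluorophore brightness, pairwise-
  difference power-spectrum periodicity (the 7-mer signature), non-negative
  least-squares pool deconvolution, and the pool-monomer bound
  S < n_pool((b + w)/d)³.
- **Mobility** (`msd()`, `fit_D()`, `fit_cdf_mixture()`,
  `fit_gamma_mixture()`, `fit_anomalous()`): time-averaged MSD
  (4Dτ + 4σ²), D from the first four lags, Brownian CDF mixtures with
  model selection (components added only for a > 10% reduced-χ²
  improvement), Gamma-mixture fits to D distributions, and the
  subdiffusion model 4σ² + 4Kτ^α.
- **Kinetics** (`transform_transnuclear()`, `dwell_times()`, `fit_frap()`):
  envelope-relative coordinates about the interpolated crossing point,
  exponential dwell constants at the nuclear envelope, and single-
  exponential FRAP turnover fits C(t) = C(0)(1 − exp(−t/t_R)).
- **Genome models** (`scan_sites()`, `assign_binding()`,
  `simulate_nuclear_image()`, `compare_model()`, `charge_profile()`,
  `site_nn_distances()`): IUPAC scanning on both strands, promoter
  flagging (500 bp upstream), monomer / 7-mer-cluster / nuclear-envelope
  binding configurations on 3D chromosome coordinates, rendered nuclear
  images re-analysed by the same detector, and KDE-based R² model
  comparison.
- **Geometry and colocalization** (`cluster_diameter()`,
  `packing_exponent()`, `overlap_integral()`, `genome_mesh_size()`,
  `subunit_diameter()`, `render_heatmap()`): motion-blur-corrected cluster
  diameters, the d ~ S^a packing law (spherical a = 1/3), the Gaussian
  overlap colocalization score ν with the 0.75 criterion, and DNA mesh
  geometry.
- **Pipeline** (`run_config()`, `run_pipeline()`, `verify_run()`):
  simulate → segment → track → stoichiometry → mobility → kinetics →
  model comparison with a checksummed manifest.

## Worked example

Recover the cluster unit and a FRAP turnover time from synthetic data:

```r
library(slimcluster)

# 7-mer periodicity from noisy stoichiometries
s <- generate_stoichiometries(500, u = 7, k_range = 1:4, noise_sd = 0.7,
                              seed = 42)
periodicity(s)$period
#> [1] 6.963898

# FRAP turnover at the reported nuclear-foci constant
curve <- generate_frap_curve(10, 133, exp(seq(log(1), log(1000),
                                              length.out = 10)),
                             noise_sd = 0.5, seed = 1)
fit_frap(curve)$t_R
#> [1] 127.1858

# analytic genome geometry: the yeast genome as a space-filling tube
genome_mesh_size(12.1e6, 0.34, 2)
#> $tube_length_mm
#> [1] 4.114
#> $tube_diameter_nm
#> [1] 36.00537
```

The periodicity says foci are built in steps of ~7 molecules; the FRAP
constant of ~127 s is the slow turnover of DNA-bound clusters; the 36 nm
tube diameter is the effective DNA mesh size of a 2 µm nucleus packed with
a 4.1 mm genome.

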