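---
title: "Models and methods behind slimcluster"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind slimcluster}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slimcluster)
```

# The measurement problem

Millisecond Slimfield microscopy images single fluorescent-protein fusions
in live yeast at 5 ms per frame and 80 nm per pixel. A transcription
factor tagged this way appears as two components: a diffuse *pool* of
molecules whose nearest-neighbour spacing is below the ~230 nm optical
resolution, and discrete diffraction-limited *foci*. The questions the
package answers are quantitative: how many molecules are in a focus
(stoichiometry), how fast it moves (diffusion analysis), how it crosses
the nuclear envelope, how fast DNA-bound material turns over (FRAP), how
big clusters are, and whether the spatial statistics of nuclear foci are
better explained by monomeric or by clustered binding to promoter sites.

Because no raw imaging data accompany the study conditions, every analysis
is validated on synthetic data generated at those conditions, with ground
truth retained so that recovery can be scored.

# The synthetic forward model

`generate_cell_stack()` renders a spherical cell (diameter 5 µm, default)
with a concentric spherical nucleus (2 µm) at 80 nm/pixel:

* **Pools** are uniform volume densities; a camera sees their 2D
  projection, the chord length `2*sqrt(R^2 - r^2)`, convolved with the
  Gaussian PSF (sigma 230 nm). This is the same forward model the pool
  deconvolution inverts, which is deliberate: it makes pool recovery a
  well-posed linear problem and tests the solver, not the renderer.
* **Foci** are Gaussian spots whose total integrated intensity is
  `S * I_GFP` (default `I_GFP` = 5000 counts). Pixel values come from the
  exact integral of the Gaussian over each pixel, so photon conservation
  holds to the truncation of the tails: with noise off, the summed frame
  intensity equals `(pool + sum(S)) * I_GFP * exp(-t/t_b)`.
* **Diffusion** is simulated as Gaussian steps of per-axis variance
  `2*D*dt`, reflected at compartment boundaries. Trans-nuclear foci move
  on a straight path through the envelope at the diffusive speed, with an
  optional exponentially distributed pause at the crossing; the pause
  starts at a random phase within a frame interval, as a real crossing
  would.
* **Photobleaching** in the image stack is the deterministic envelope
  `exp(-t/t_b)` with `t_b` = 40 ms; the stochastic integer-step process is
  generated separately by `generate_bleach_traces()`, where each of `S`
  fluorophores carries an exponential lifetime with mean `t_b`.
* **Camera noise** is Poisson shot noise on the expected counts plus
  Gaussian read noise (sd 7 counts) on a constant offset (100 counts),
  with gain 1. The real study's camera parameters are not published;
  these are free parameters chosen to give in-vivo-like SNR (a single
  fluorophore detected at SNR ~ 2-3).

What the generator does **not** emulate: optical aberrations, EMCCD gain
registers and excess noise, 3D PSF structure, out-of-focus blur (out-of-
field emitters are simply omitted), cell-to-cell variability, and
autofluorescence texture. Passing tests therefore demonstrate correctness
of the estimators under the stated model, not robustness to every real-
microscope artifact.

The toy genome (`generate_toy_genome()`) plants concrete instances of an
IUPAC pattern in random sequence, annotates genes so that a configurable
fraction of sites fall within 500 bp upstream of a gene start, and lays
each chromosome out as a confined random walk in the nuclear sphere. The
walk uses one bead per kb and 100 nm steps. That step length is a
deliberate design choice: chromatinized DNA has a persistence length of
~50 nm, so ~100 nm Kuhn segments per kb give chromosome territories that
span the nucleus, as in population-consensus 3D chromosome models. With
much shorter steps each chromosome collapses into a ~100 nm ball and all
binding configurations become a single diffraction-limited blob, which
would make any binding-model comparison vacuous.

# Segmentation

The compartment threshold is defined *relative to the compartment itself*:
0.3 times the mean fluorescence inside the current mask. Since the mask
depends on the threshold, the definition is a fixed point; the
implementation bootstraps with an Otsu mask and iterates
threshold-then-largest-component until stable (the bootstrap is a choice;
the fixed point is insensitive to it for blob-like compartments). The
boundary is then refined to sub-pixel precision by interpolating the
threshold crossing along radial rays from the mask centroid. On rendered
uniform spheres with default noise the median boundary error is ~0.25 px,
within the half-pixel target. The procedure is scale-invariant because the
threshold scales with the image.

Boundaries are smoothed with a periodic smoothing spline on radius versus
polar angle. The smoothing parameter follows the penalized least-squares
convention (`p = 1` interpolates); periodicity is enforced by replicating
one period on each side. The default `p = 0.9992` keeps the boundary
within a tenth of a pixel of a true circle while suppressing pixel-level
jitter.

# Detection, tracking, stoichiometry

Candidates are seeded on a difference-of-Gaussians band-pass (sigmas of
half and three PSF widths). The noise floor is estimated from the
*negative* side of the band-passed image — spots contribute only positive
values, so this estimate stays honest even when the frame is densely
covered by signal (a nucleus full of clusters). Local maxima above 3.5
noise-sd are refined by iterative Gaussian masking run on the band-passed
image; running it on the raw frame lets pool-intensity gradients drag
low-stoichiometry centroids by 1-2 px. Accepted foci (SNR > 0.4, with SNR
= intensity per ROI pixel / background sd per pixel) get a radial-Gaussian
sigma fit. The characteristic intensity is the plain ROI sum (radius 5 px)
minus the annulus-median background. That aperture truncates the PSF
(~33% of the light falls outside 5 px and the annulus absorbs part of the
tail), which is why all stoichiometry work calibrates `I_GFP` through the
same detector — the truncation factor then cancels in `S = I0/I_GFP`,
exactly as an in-vivo modal-intensity calibration cancels it in a real
experiment.

Linking is greedy nearest-neighbour between consecutive frames only (no
gap closing), gated at one PSF width and factor-two brightness and width
ratios, resolving ambiguity by minimal displacement. Tracks are classified
nuclear / cytoplasmic / trans-nuclear against the smoothed boundaries.

Stoichiometry weights the intensity at time `t` by `exp(+t/t_b)` and
divides the corrected track mean by `I_GFP`; the corrected mean is the
default `I0` estimator (first-point and fit-intercept variants are
options) because it is unbiased under exponential decay and has the
lowest variance of the three on short tracks. Tracks starting after frame
70 of illumination are excluded.

**Periodicity.** The distribution of pairwise differences of a periodic
stoichiometry sample is a comb at multiples of the unit. The estimator
builds a Gaussian KDE of all pairwise differences, removes the smooth
triangular envelope with a wide running median, and evaluates the
periodogram on a continuous grid of candidate periods (>= 2 molecules, so
DC and sub-unit harmonics are excluded). Significance uses the normalized
spectral coherence — peak power divided by its Cauchy–Schwarz bound — which
is ~0.25-0.35 for genuine combs and < 0.1 for featureless samples; the
default threshold is 0.15. The reported period is refined to the nearest
local maximum of the difference KDE, which removes the small bias the
envelope leaves in the raw spectral peak. These choices were validated on
generated combs with units 3, 5, 7 and 9 and on uniform/normal null
samples.

**Pool deconvolution.** The nuclear and cytoplasmic pools are modelled as
uniform spheres projected through the PSF; each basis image is scaled to
one molecule, and non-negative least squares (with a constant background
column) returns copy numbers directly. In the synthetic forward model the
whole compartment volume is observed, so no depth-of-field correction is
applied by default; for real data a finite `depth_of_field` divides by the
fraction of the compartment volume inside the focal slab.

# Mobility

The MSD uses the time-averaged estimator with `1/(N - 1 - n)`
normalization; `D` is the gradient of a free-intercept line through the
first four lags divided by 4 (the intercept absorbs `4*sigma^2`; a
fixed-intercept mode exists). The CDF of first-step squared displacements
is fitted by weighted least squares with 1, 2, then 3 Brownian
components; weights are the inverse binomial variance of the empirical
CDF. Two guards govern model selection: the >10% reduced-chi-squared
improvement rule, and an identifiability requirement that every accepted
component carries >= 5% weight and differs from its neighbour by at least
a factor 2 in `D`. The second guard exists because empirical-CDF residuals
are strongly correlated (Brownian-bridge-like), so an extra component can
soak up noise and pass the chi-squared rule alone in roughly a third of
single-population runs; components closer than a factor two are not
resolvable by this analysis in any case. The optimizer is multi-started,
including a start at the EM maximum-likelihood solution of the equivalent
exponential mixture, because the least-squares surface has a ridge
trading the slow component's weight against its coefficient.

A caveat quantified during development: with localization precision 40 nm
at 5 ms, an immobile component at `D` = 0.15 µm²/s appears at
`D + sigma^2/dt` = 0.47 µm²/s, only ~4x below a 1.5 µm²/s mobile
component. At 1000 tracks the Cramér–Rao bound on the immobile fraction is
then ~8 percentage points, so single-sample estimates scatter widely no
matter the estimator; recovery checks therefore use the median over
seeded replicates. Pass `sigma` to `fit_cdf_mixture()` to report
noise-corrected coefficients.

The Gamma-mixture fit to per-track `D` values uses the density with shape
`m` (the number of MSD lags per estimate, default 4; `m = 1` is the
exponential) fitted by least squares to a 64-bin histogram — a KDE with a
global bandwidth oversmooths a slow component sitting near zero. The
anomalous model `4*sigma^2 + 4*K*tau^alpha` is fitted to lags <= 30 ms by
nonlinear least squares seeded from the log-log line; the Brownian special
case (`alpha = 1`) is always fitted alongside and its chi-squared
reported.

# Trans-nuclear kinetics and FRAP

The envelope crossing point is interpolated linearly between the first
pair of localizations on opposite sides of the smoothed nuclear boundary;
coordinates are translated there and rotated so `x'` is tangent and `y'`
normal to the envelope (interior `y' < 0`, from the spline derivative).
The transform is rigid by construction. Dwells are contiguous runs with
`|y'|` inside a 40 nm band — the envelope's own width; the band is a
declared choice, exposed as a parameter. Because dwell durations are
observed in whole frames, the exponential constant uses the geometric
(frame-censored) maximum-likelihood estimator
`tau = -dt / log(1 - 1/kbar)`; the naive mean of `k*dt` overestimates a
10 ms constant by ~25% at 5 ms frames. The plain mean is also returned.

FRAP recovery is `C(t) = C0 * (1 - exp(-t/t_R))` fitted by
Levenberg–Marquardt with data-driven starts; sampling times come from the
input, with no uniform-grid assumption, matching stroboscopic acquisition.
`frap_bleach_correct()` applies the same `exp(+t/t_b)` reweighting as the
stoichiometry module using cumulative illumination time.

# Binding models and their comparison

`scan_sites()` delegates IUPAC matching to `Biostrings::matchPattern`
(both strands, deduplicated by chromosome/start/strand); tests hold it to
a hand-written position-by-position oracle. Promoter sites sit within
500 bp upstream of an annotated gene start on the matching strand.

`assign_binding()` realizes the competing hypotheses: monomers on every
promoter site plus the remainder on non-promoter sites; 7-mer clusters
(`floor(total/unit)` of them — 27 for 190 molecules, with the remainder
molecule dropped and reported) on random promoter sites; nuclear-envelope
variants placing molecules or 18 7-mer clusters (130 molecules) uniformly
on the envelope sphere; and a per-cell mixture (default 75% NE-cluster /
25% DNA-cluster). Base-pair positions are interpolated linearly between
the two nearest modelled loci.

`simulate_nuclear_image()` rotates a configuration uniformly at random
(unknown nuclear orientation), keeps placements within a 1 µm depth of
field about the focal plane, and renders them with the same spot model and
noise as the cell simulator. Rendered images are analysed by the *same*
detector as any experimental data, so apparent stoichiometries inherit the
real optical merging of sub-resolution clusters. `compare_model()` scores
a simulated stoichiometry sample against a reference by `R^2` between
Gaussian KDEs on a shared grid. In the end-to-end check, samples drawn
under the composite cluster model score `R^2` ~ 0.8 against an
independently generated cluster reference while the composite monomer
model scores near or below zero, and the ordering holds in effectively
all seeded replicates.

# Geometry

The effective cluster diameter subtracts from the fitted focus width
(twice the Gaussian sigma) both the immobilized single-fluorophore width
(460 nm) and the diffusive motion blur accumulated during one exposure.
The blur enters as the diffusion length `sqrt(4*D*dt)` — the printed raw
form subtracts an area from a length and is dimensionally inconsistent; it
remains available behind `raw_formula = TRUE` for comparison. Non-positive
diameters are reported as unresolvable rather than as errors. The packing
law `d ~ S^a` is fitted on log-log axes; ideal spherical packing gives
`a = 1/3` exactly, a rod `a = 1`, an anchor `a = 0`.

The overlap integral between two fitted Gaussian foci,
`v = exp(-dr^2 / (2*(s1^2 + s2^2)))`, is symmetric, strictly decreasing in
separation, and 1 only for coincident centres; pairs are formed only
within 5 px and called colocalized above 0.75 (both exposed as
parameters). Genome mesh geometry treats the genome as a tube of length
`bp * 0.34 nm` filling the nuclear sphere, giving ~4.1 mm and a ~36 nm
tube diameter for yeast. Heat maps sum one Gaussian per localization,
either on a 1000-px grid with 15-px kernels (foci maps) or at 20 nm
pixels with 40 nm kernels (super-resolution rendering).

# Numerical choices and problem sizes

Exponential and recovery fits use `minpack.lm::nlsLM` with positivity
bounds; mixture fits use transformed parameters (stick-breaking logits for
weights, logs for coefficients) under Nelder–Mead/Brent with multi-start.
Degenerate inputs fail loudly: constant images, non-decaying traces,
monotonically decreasing FRAP samples, zero-variance references, collinear
boundaries.

Test and validation runs are sized for a single CPU: 80-px cell frames,
8-12 frame stacks, 49-px nuclear renders, 1000-displacement mixture fits,
and 25-40 rendered projections per binding-model sample. These sizes were
chosen so each property check completes in seconds while leaving the
statistical conclusions (recovery within the stated tolerances) stable
across seeds; they are smaller than a real 30-cell experiment, and
absolute copy-number tables from the original system are out of scope.

# Known limitations

* Apparent stoichiometries of dense nuclear configurations are dominated
  by optical merging; the model comparison relies on this being applied
  identically to simulation and reference, not on resolving single
  clusters.
* The CDF mixture cannot resolve components closer than ~2x in apparent
  `D`, and immobile-fraction estimates at n = 1000 carry ~10-percentage-
  point sampling noise (see the information-bound discussion above).
* The pool deconvolution assumes spherical compartments and a Gaussian
  PSF; aspherical cells would need their own basis images.
* The toy genome is a geometric stand-in, not chromatin physics; nothing
  about loop structure, territories or tethering is modelled beyond
  confinement.
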