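---
title: "Terrain, thermal inertia and the distribution of dryland biocrusts: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Terrain, thermal inertia and the distribution of dryland biocrusts: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biocrustmap)
```

# The scientific problem

Biological soil crusts (biocrusts) — communities of mosses, lichens,
cyanobacteria, algae and fungi living on the topsoil of plant interspaces —
are a structural component of dryland ecosystems. At landscape scale their
composition tracks microtopography: insolation, exposure and water
redistribution create a mosaic of dry, salt-rich microsites favouring
lichen-dominated crusts and moister, nutrient-richer microsites favouring
mosses. `biocrustmap` implements a complete fine-resolution (UAV-style)
analysis of this control: terrain attributes from a digital terrain model,
radiometrically calibrated multispectral classification of the surface
covers, apparent thermal inertia (ATI) as a soil-moisture proxy from a
pre-dawn/noon thermal pair, and plot- and landscape-level statistics linking
all three.

Because studies of this kind rarely deposit their imagery, the package ships
a first-class synthetic scene generator with a fully known ground truth.
Every stage of the pipeline — and every statistical claim about what the
pipeline recovers — is tested against that ground truth.

# Raster model and file format

Rasters are square-celled, north-up grids (row 1 = northernmost row, values
at cell centres, metres everywhere). Missing cells are carried as an
explicit `NA` mask and only become a sentinel value on disk. All stages
check grid alignment (`assert_aligned()`) and refuse to resample silently.
On disk rasters are ESRI ASCII grids (plain text, one file per band), a
deliberately simple interchange format; the package assumes a single planar
CRS and offers no reprojection, which is adequate for sites of a few
hectares.

# Terrain attributes

* **Pit filling** (`fill_pits()`) is a priority-flood style minimal raise:
  every cell ends with a non-ascending path to the boundary (or to nodata).
  It is implemented as a vectorized Jacobi iteration of
  `W = max(z, min(neighbour W) + eps)`, which converges to the exact spill
  levels. With `eps = 0` a pit is raised exactly to its spill elevation;
  flow routing uses `eps = 1e-6` m so that filled flats acquire a strict
  gradient and the router never sees a tie. Both behaviours are tested.
* **Slope/aspect** use the Zevenbergen–Thorne second-order polynomial
  (central differences of the 3×3 window); edges are padded by linear
  extrapolation, which keeps planes exact to the border. Aspect is the
  downslope compass direction; flat cells get `NA` aspect, and
  **northernness** is `cos(aspect) + 1` in `[0, 2]`.
* **Flow** is Tarboton's D-infinity: the steepest downward slope over the
  eight triangular facets, with flow split between the two bounding grid
  directions in proportion to angular distance. Facets touching off-grid or
  nodata neighbours are skipped; a cell with no downslope facet is an
  outlet if it borders the edge (its accumulation leaves the grid) and an
  error (a pit) otherwise. Accumulation processes cells in decreasing
  elevation — a valid topological order because D-infinity receivers are
  strictly lower than donors — and reports specific catchment area
  (accumulated area / cell width, m). A brute-force recursive accumulation
  serves as an independent oracle in the tests, and total boundary outflow
  is checked against the grid area (mass conservation). A caveat worth
  stating: on a discretized cone the facet-steepest direction is *not*
  exactly radial (deviations up to ~0.12 rad at cardinal cells, with the
  facet-order tie-break picking a consistent side at diagonals); the tests
  assert the discretization bound, not an idealized exactness.
* **TWI** is `ln(A / tan beta)` with `tan beta` clamped at 1e-3 (0.057°) so
  flat cells stay finite; **LSF** is
  `(n + 1)(A / 22.13)^n (sin beta / 0.0896)^m` with `n = 0.4`, `m = 1.3`.
  `A` is specific catchment area in both, matching the D-infinity toolchain
  convention; the raw-area alternative is available by multiplying by cell
  width.
* **PSIR** (potential solar incoming radiation, Wh/m²/yr) integrates a
  uniform clear sky: direct beam `S0 * tau^(1/cos z)` projected on the
  tilted cell, plus an isotropic diffuse fraction weighted by the sky-view
  factor `(1 + cos s)/2`. Defaults: latitude 40.03°N, transmissivity 0.5,
  diffuse proportion 0.3, every 5 days / 0.25 h, 8-direction ray-marched
  horizon shading (nearest direction to the sun azimuth, rays capped at
  100 m). The standard declination/hour-angle formulas position the sun.
  Tested properties: spatial uniformity on flat ground, south > north
  slopes at 40°N, elevation-offset invariance, and the diffuse-only limit
  as transmissivity vanishes. A uniform (not standard-overcast) diffuse sky
  is assumed.

# Radiometry and classification

Raw DN convert to pseudo-radiance as `R = f^2 (P - B) / (A * ISO * t + C)`
— the denominator grouping follows the small-camera calibration literature,
since the compact typeset form is ambiguous — then to reflectance through
the panel coefficient `K = rho_ref / R_ref`. Any measured surface can act
as an empirical-line target (bright biocrust patches included, useful when
a white panel saturates); the per-band least-squares line is exact through
two noiseless targets and idempotent once applied.

`CR_red` interpolates the continuum between the green (550 nm) and red-edge
(735 nm) band centres and divides the red (660 nm) reflectance by it,
clipping at 1 so that absorption-free spectra (bare soil) sit exactly at 1;
the clip plus an epsilon makes the "equal to 1" refinement rule well defined
in floating point. Classification is an RBF-kernel SVM on the four bands
(cost 1, kernel width `1/(4 var)`, fixed for determinism — tuning is not
the point here), refined by two rules: DryVeg pixels with `CR_red < 0.75`
become Moss (dry canopies lack the chlorophyll absorption mosses show), and
BL pixels with `CR_red = 1` become Soil. Accuracy is reported as a
confusion matrix (classified rows × truth columns), overall accuracy and
Cohen's kappa.

# Apparent thermal inertia

`ATI = C (1 - albedo) / deltaT` with `deltaT` the noon minus pre-dawn
surface temperature and albedo the mean of the four band reflectances.
`C = 1.19` is an input constant (a solar-correction factor whose derivation
depends on site and date; it is configuration, not computed), emissivity is
taken as 1 (gypsum soils and biocrusts are near-black bodies in the thermal
window), and cells with `deltaT < 0.1` K or `albedo >= 1` become nodata
rather than unstable ratios. Vegetation is masked out of the ATI map using
the classification before any plot averaging.

# The synthetic scene

The generator emulates a semi-arid gypsum hillslope in the wet season, at
desk scale: the default site is 140 × 140 m at 1 m cells (the multi-seed
checks use 40–60 m scenes and a coarser 30-day/1-h solar sampling; these
sizes are the package's own choices and are stated here once).

* **DTM**: an inclined plane (gradients 0.05, 0.08) plus 12 signed Gaussian
  knolls/hollows of up to 1.5 m — signed so the expected surface equals the
  plane, which the Monte-Carlo test exploits.
* **Moisture**: `m0 + m_north * northernness01 + m_psir * psir01 + noise`
  (defaults 10, +8, −6, 1 %), clipped to the observed field range
  4.44–22.6 %. North-facing, low-insolation cells are wetter.
* **Covers**: vegetation (GreenVeg/DryVeg, together 58 % prior) forms
  clumped patches by thresholding Gaussian-smoothed noise at the
  prior-matching quantile; the five ground covers draw from a multinomial
  whose Moss log-odds rise with standardized moisture (+0.8 per s.d.) and
  lichen-class log-odds fall at half that rate — the moss-wet / lichen-dry
  contrast the statistics should recover. Field plots avoid footprints
  that are entirely vascular vegetation, as a field crew would.
* **Spectra**: a hand-authored endmember table (configuration data, not
  code) satisfying the qualitative ordering of field spectra: BL brightest;
  Moss the darkest biocrust with only DryVeg darker; GreenVeg with the
  deepest `CR_red`; Soil exactly on the continuum. Gaussian noise
  (s.d. 0.012) is added per band; raw DN invert the calibration chain and
  round half-up, so calibration recovers reflectance within one DN step.
* **Thermal pair**: `deltaT = C (1 - albedo) / (a + b * moisture)` with
  `a = 0.02`, `b = 0.003` K⁻¹ per %, pre-dawn baseline 5 °C, and 0.75 K
  Gaussian noise per image (the calibration-level accuracy of uncooled
  thermal cameras). At zero noise the pipeline recovers the true ATI to
  1e-10 and the plot regression reaches r² = 1.
* **Plot table**: 23 plots of 2 × 2 m; soluble salts decrease and organic
  carbon, total P and total N increase with plot northernness, with noise,
  clipped to the observed field ranges.

What the generator does *not* emulate: BRDF and shadowing in the optical
bands, physically based soil heat flux (the ATI identity is imposed, not
derived), spatially structured reflectance noise, and mixed pixels at cover
boundaries. Tests passing on these scenes therefore demonstrate the
*pipeline's* correctness and statistical calibration, not that real imagery
is this easy.

# Statistics

* **Correlation ratio**: terrain attributes are min-max standardized and
  cut at 1/3 and 2/3 into terciles (left-closed bins, maximum mapping to
  H); `eta^2` is the count-weighted between-tercile variance over the total
  variance, identical (to 1e-12, and tested on 1000 random datasets) to the
  R² of a regression on tercile indicators. Table rows with `eta^2 < 0.3`
  are flagged as not represented. Count weighting (not equal category
  weights) is used, matching the statistic's printed definition.
* **Kruskal–Wallis + Dunn**: the omnibus test is `stats::kruskal.test`;
  Dunn's pairwise z uses mean ranks with tie-corrected variance and
  Holm-adjusted two-sided p-values (the adjustment is a configurable
  choice), with a compact letter display.
* **RDA**: responses (biocrust covers) centred, predictors standardized;
  fitted values decomposed by SVD; proportion explained = constrained
  eigenvalue sum over total inertia; Ezekiel-adjusted R². Cross-checked
  against an independent projection+PCA oracle and against `vegan::rda` in
  the tests (vegan is never the implementation). Marginal (type III)
  permutation tests permute residuals of the reduced model, N = 999 by
  default, `p = (count + 1)/(N + 1)`; type-I error is calibrated within
  [0.03, 0.07] at alpha 0.05 in the acceptance suite. VIF screening
  (`1/(1 - R²)`, threshold 10) with exhaustive subset enumeration (≤ 9
  candidates) and adjusted-R² selection.
* **Sampling**: seeded rejection sampling with a spatial hash enforces the
  3 m minimum distance between the 1147 landscape points (the
  semivariogram range of the moisture field is computed alongside as an
  advisory check); covers and attributes are extracted as means over 3 m
  circles.

# Two calibration decisions worth explaining

**The ATI slope check uses the forward regression with robust errors.** The
headline plot-level result is the OLS of moisture on ATI and its r².
For *calibration* (does the recovered slope agree with the generator's
ATI–moisture link?) that direction is the wrong tool: the thermal noise
lives in ATI, so regressing moisture on noisy ATI is attenuation-biased by
construction, and the ATI noise is heteroscedastic (`dATI ~ ATI² dT`, so wet
plots are noisier). The calibration test therefore fits plot ATI on plot
moisture (noise in y only, implied slope `b`) with an HC3
heteroscedasticity-consistent confidence interval, which attains its nominal
coverage.

**Sign structure is assessed in the axis-1/2 plane.** In these scenes Moss
dominates RDA axis 1 and the lichen contrast expresses on axis 2 (the two
axes carry >99 % of constrained inertia); per-axis sign comparisons are
rotation-fragile, so the tests use the 2-D dot product between a response's
scores and a predictor's biplot vector. Moss aligns with ATI and the lichen
classes with PSIR; alignment with LSF is *not* asserted, because the
generator gives lichens no LSF mechanism — an honest statement of what the
synthetic conditions can and cannot demonstrate.

# Reproducing the analysis

The `analysis/` scripts run the whole study in order (simulate → terrain →
classify → ATI → plot statistics → ordination), writing tables under
`results/`; `scripts/acceptance.R --seed <s> --out <json>` recomputes the
headline quantities from scratch in one pass. One seed reproduces every
scene bit-exactly.

# Known limitations

* Pure-R raster engine: adequate to a few hundred thousand cells; no tiling.
* The solar model is a geometric clear-sky integrator; it is not a
  replacement for a full atmospheric radiation model, and horizon shading
  uses the nearest of 8 ray directions.
* The SVM contract fixes hyperparameters rather than tuning them.
* The empirical-line and panel calibrations assume Lambertian targets.
* `C` in the ATI formula is a constant; diurnal harmonic thermal models are
  out of scope.
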