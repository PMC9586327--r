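---
title: "Methods: spine-apparatus morphometry and proximity-proteome statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spine-apparatus morphometry and proximity-proteome statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinescope)
```

# Scope

The spine apparatus (SA) is a specialization of the smooth endoplasmic
reticulum found in a subset of dendritic spines: a stack of two or more
closely apposed, parallel, flat cisterns whose formation requires the
actin-associated protein synaptopodin. `spinescope` implements, at desk
scale, the four computational procedures used to characterise this
organelle and its molecular neighbourhood:

1. **SA morphometry in volume EM** — semiautomated detection and
   plane-by-plane tracking of membrane structures in FIB-SEM-style 3D
   stacks, cistern counting, membrane-contact detection, and a PSD-first
   spine census.
2. **iBioID differential enrichment** — statistics for in vivo
   proximity-biotinylation spectral counts comparing a bait proteome
   (e.g. BioID2–synaptopodin) against a spatial-reference proteome
   (e.g. BioID2–Shank3 fragment), with internal-standard normalization by
   the endogenously biotinylated carboxylases.
3. **Single-cell coexpression** — per-gene Pearson correlation of raw read
   counts with a reference gene across cells, and the analytic t-to-r
   significance threshold.
4. **Spine fluorescence enrichment** — the spine/shaft enrichment factor
   from thresholded spot detection, top-40 spot means, and pooled shaft
   ROIs.

Each stage is paired with a synthetic-data generator with known ground
truth, so the full pipeline is testable without any external data.

# SA morphometry

## Model and procedure

Membranes in heavy-metal-stained EM are dark ridges on a brighter
background. The detection chain is:

* `dog_filter(vol, sigma_small, sigma_large, invert = TRUE)` — a
  difference-of-Gaussians band-pass. Inversion first makes dark membranes
  positive ridges; the DoG then suppresses the constant background
  (`dog(vol + c) = dog(vol)` exactly) and responds maximally at structures
  whose width matches the sigma band. Boundary handling is edge
  replication. The sigmas and the mask threshold are deliberately
  *required* configuration: the source procedure selects them manually,
  and no principled default exists across magnifications.
* `threshold_mask()` — inclusive (`>=`) thresholding into a binary mask.
* `track_structure(mask, seed, min_overlap)` — the continuity-tracking
  step. From a manually seeded 2D segment in one plane, 2D connected
  components (8-neighbourhood) of the mask are accepted in adjacent planes
  when they overlap the current selection by at least `min_overlap`
  voxels. Overlap is evaluated against the selection grown by one voxel
  laterally, so diagonal continuity counts; propagation is bidirectional
  and revisits planes until a fixed point. Two consequences we consider
  essential and test: branching structures are followed completely, and
  with `min_overlap = 1` the result is *exactly* the 3D 26-connected
  component of the mask containing the seed (verified against a
  brute-force graph-labelling oracle). Raising `min_overlap` prunes
  single-voxel bridges, which is the practical use of the knob.
* `refine_object()` — manual additions/removals; removals win on
  conflict, edits are recorded in provenance.

## Cistern classification

`segment_cisterns()` decomposes an ER mask into 3D connected components
and describes each by the eigenvalues of its voxel-coordinate scatter in
nanometres (anisotropic voxels are handled by scaling coordinates with
`voxel_size_nm` before the eigendecomposition). A component is a *flat
cistern* when it is extended in two principal directions (middle principal
SD at least one mean voxel edge — this excludes tubules and single
voxels, whose middle eigenvalue is degenerate) and thin in the third
(`flatness = smallest/middle eigenvalue <= flatness_max`).

`classify_sa()` then applies the SA definition: at least two flat
cisterns, pairwise parallel (angle between normals at most
`parallel_tol_deg`) and closely apposed (surface gap at most
`gap_max_nm`). The defaults are artifact decisions, not measured
constants, because "flat", "parallel" and "closely apposed" are never
quantified in the source procedure:

| parameter | default | rationale |
|---|---|---|
| `flatness_max` | 0.33 | a sheet should be at least ~3x wider than thick |
| `parallel_tol_deg` | 30° | generous; planted stacks are near-0°, crossed sheets near-90° |
| `gap_max_nm` | 80 nm | upper end of reported inter-cistern spacing |
| `contact_dist_nm` | 30 nm | conventional ER–plasma-membrane contact-site distance |

The *qualifying group* is the largest connected group under the pairwise
(parallel AND apposed) relation, not a clique: in a stack, apposition
holds between neighbouring cisterns while the two end cisterns of a tall
stack are legitimately far apart. A single flat cistern gives
`cistern_count = 1` but `is_sa = FALSE`; a tubule contributes 0.

The inter-component gap is approximated as the minimum centre-to-centre
voxel distance minus one mean voxel edge (a surface correction), floored
at zero. `detect_contacts()` uses plain centre-to-centre distances in nm;
with the default 30 nm cut, face-adjacent voxels at 8 nm spacing are
contacts and anything two voxels away along an 8 nm axis still is, while
a 40 nm-spaced axis is not.

`spine_census()` implements the bias-minimising protocol: spines are
identified by their postsynaptic density (PSD) first, and only
PSD-positive spines enter the denominator for the ER/SA fractions.

## What the EM phantom emulates — and what it does not

`generate_em_phantom()` plants spine-like compartments on a regular grid
of boxes: a 1-voxel plasma-membrane shell, a PSD patch, and per planted
fraction an SA (axis-aligned stack of flat cisterns), plain ER (single
cistern or tubule, probability 1/2 for SA-negative spines), a PM-contact
extension and/or a nearby tubulovesicle. Defaults state the world the
procedures were built for: 8 nm isotropic voxels, SA in half the spines
(reported range 40–60%), cistern counts on {2..8} with median 3,
PM-contact fraction 0.83 and tubulovesicle-contact fraction 0.41 (the
reported contact statistics), 1-voxel cisterns with 2-voxel (16 nm) gaps.

The phantom is deliberately *not* photorealistic: membranes are binary
dark voxels plus Gaussian noise; there are no membrane-contrast gradients,
no curvature, no touching organelles from neighbouring spines, and
cisterns are axis-aligned. A green classification test therefore
establishes that the geometry pipeline (components, eigen-shape, gap
logic) is correct, not that the thresholds would transfer unchanged to
real FIB-SEM data — on real data the sigmas, threshold and the three
classification tolerances must be tuned per dataset, which is why they
are all explicit configuration.

# iBioID enrichment

## Statistics

For each protein the enrichment is the ratio of mean counts in bait
versus control samples (absent protein = count 0; positive/0 is flagged
infinite, 0/0 undefined). Significance is a two-sample Student's t test
with pooled variance, two-sided, at `alpha = 0.1`, combined with the
direction gate `ratio > 1` — so proteins enriched near the spatial
reference (PSD components, for a PSD-anchored reference bait) are never
called. The sidedness and variance treatment are not stated in the source
procedure; we chose the textbook pooled two-sided test and let the ratio
gate supply direction. Zero-variance degeneracies: equal means give
`p = 1`; unequal means with zero pooled variance give a `p = 0` sentinel.
No multiple-testing correction is applied, mirroring the stated `P < 0.1`
rule; a Benjamini–Hochberg column is emitted for reference only.

`normalize_by_endogenous()` divides every non-control protein's counts in
a sample by the summed counts of the two endogenously biotinylated
carboxylases (propionyl-CoA carboxylase alpha chain, `Pcca`, and pyruvate
carboxylase, `Pc`) in that sample. Controls are retained and flagged but
excluded from testing output.

## The simulator's noise model

The generator (`generate_proteomics_table()`) draws negative-binomial
counts (`variance = mean + dispersion * mean^2`; `dispersion = 0` is
Poisson) around per-protein lognormal abundances, with the reference
design of 4 bait vs 3 control replicates and a planted enriched fraction
at a chosen log2 fold change. Two per-sample factors model yield
variation:

* `efficiency_range` — the bait-construct biotinylation yield. It
  multiplies exogenous proteins only; the endogenous standards are
  biotinylated by cellular metabolism and do not see it. No internal
  standard can correct this component.
* `recovery_range` — the streptavidin-recovery/loading yield, shared by
  *all* proteins including the standards. This is exactly the component
  internal-standard normalization removes.

This split resolves an internal tension in a single-factor model: a
factor the standards do not see cannot be corrected by dividing by the
standards, while a factor they fully share is corrected essentially
exactly. With both factors the simulator also reproduces the diagnostic
relationship that motivates the normalization — in samples with low
exogenous signal the standards take a relatively larger share of the
counts. The standards themselves are drawn Poisson (no biological
overdispersion): their biotinylation is constitutive, which is precisely
what qualifies them as internal standards; giving them the proteome's
biological dispersion would make the normalizer noisier than the signal
it corrects on well-behaved samples.

Both factor ranges default to `[1, 1]` (no yield variation) so that the
baseline world is clean; tests switch them on explicitly. The t test on
negative-binomial counts is approximate; the suite checks that its null
level at `alpha = 0.1` stays within ±0.04 of nominal for the default
count regime (mean 50, dispersion 0.05, 4 vs 3 replicates).

# Single-cell coexpression

`pearson_vs_reference()` computes, for every gene, the Pearson
correlation between its per-cell raw counts and the reference gene's
counts — no normalization or log transform, matching the source
procedure's use of read counts directly. The computation uses sufficient
statistics (sums, sums of squares, cross-products), so sparse matrices
are never densified; a suite test pins the sparse path to a dense
two-pass oracle at 1e-10 relative error. Genes with zero variance are
flagged undefined and excluded from ranking (the coefficient is undefined
at zero SD, and assigning 0 would silently rank them).

`significance_threshold(n, t)` inverts the t statistic of a correlation
coefficient, `t = r * sqrt((n - 2) / (1 - r^2))`, into
`r_min = t / sqrt(n - 2 + t^2)`. At droplet-atlas scale
(n = 939,489 cells; t = 0.99) this gives about 1e-3 — with that many
cells, essentially any nonzero correlation is distinguishable from zero.
We implement the formula as stated and attach no p-value interpretation
to `t = 0.99`. Correlations are computed jointly across all cells, the
reading consistent with quoting a single n.

The generator induces a chosen post-discretization correlation through a
Gaussian copula with Poisson marginals: a shared standard-normal factor
per cell enters each gene's latent variable with weight rho, and counts
are `qpois(pnorm(z), lambda)`. Discretization attenuates correlation, so
rho is calibrated deterministically per gene by 1D quadrature over the
shared factor (4001-point grid on [-9, 9]; the marginals are exactly
Poisson, so means and SDs are analytic) and monotone root-finding. The
calibration residual is well below the ±0.02 recovery tolerance at 1e5
cells. A target of exactly 1 requires identical marginals and is realised
as an exact copy; targets outside the attainable (Fréchet-bounded) range
for the given means raise a validation error rather than clamping.

# Spine fluorescence enrichment

Per image (neuron) `i`, the enrichment factor is
`EF_i = mu_spine_i / mu_shaft_i`, with `mu_spine` the mean of the
`k = 40` brightest detected spots' mean intensities and `mu_shaft` the
pooled mean of five manually chosen shaft regions. Conventions we fixed
where the source is silent: spots are 8-connected supra-threshold
components with at least 2 px area; with fewer than `k` spots all are
used and a warning records the shortfall; shaft ROIs are pooled with
equal region weighting (area weighting is available by flag); the spot
threshold is required configuration with a 99.5th-percentile directive
available as a convenience. EF is invariant under multiplicative gain;
an additive offset `c` moves it to `(EF * mu_shaft + c) / (mu_shaft + c)`,
which the suite uses as a negative control.

The image phantom renders a horizontal shaft band at a known intensity
and non-overlapping disk spots at `shaft_intensity * target_ef`
(bounded rejection sampling; impossible placements raise an error), plus
additive Gaussian noise at 2% of shaft intensity by default. It does not
model the point-spread function, photobleaching, or spine necks;
recovery tests therefore establish the correctness of the measurement
chain, not robustness to optical blur. `sample_shaft_rois()` stands in
for manual shaft selection by deterministically slicing the band into
five centred rectangles.

# Numerical and reproducibility choices

* All generators run under `withr::with_seed(spec$seed)`: bitwise
  reproducible for a fixed spec and seed, and the caller's RNG state is
  untouched.
* Distances are always computed in nm via `voxel_size_nm`; indices are
  1-based `(plane, row, col)` throughout, following R convention.
* Morphological operations (dilation, flood fill, labelling) are
  implemented as vectorised shift-and-combine over whole arrays, which
  keeps pure-R tracking practical to ~64^3 volumes — the scale of the
  oracle-equivalence guarantee; larger volumes work but slow down
  linearly in voxel count.
* On-disk formats are plain text (TSV with `#` metadata lines,
  MatrixMarket + sidecars, a simple text raster for volumes/images) and
  round-trip at 12 significant digits. No TIFF codec is available to this
  R environment, so the raster format substitutes for the multi-page
  TIFF named in the original tooling.

# Known limitations

* Fully automatic SA discovery (without a manual seed) is out of scope,
  as are mitochondria/PSD-specific detectors beyond mask-role plumbing.
* The spectral-count distribution of real iBioID data is unknown; the
  negative-binomial choice is a stand-in, and conclusions from the
  calibration tests are about the implementation, not the real assay.
* The coexpression module does not download or parse any atlas; the
  DropViz-scale analysis is represented by the generator and by the
  analytic threshold at the published cell count.
* Cross-experiment overlap of significant sets is computed as the two
  directional fractions; reproducing any specific published protein
  catalogue is out of scope (the underlying raw data are not deposited).
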