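---
title: "Whole-bone trabecular morphometry and ontogenetic statistics with trabecula"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-bone trabecular morphometry and ontogenetic statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(trabecula)
```

## The method

`trabecula` implements a holistic (whole-bone) trabecular morphometry
workflow for microCT volumes of small long bones — the motivating system is
the primate third metacarpal across an ontogenetic series — together with
the nonparametric statistics used to compare trabecular architecture
between age groups. The chain is:

1. **Binarisation** of the greyscale stack, either by a global Otsu
   threshold or by two-class clustering of intensities within overlapping
   subwindows with majority voting (`binarize()`), which adapts to local
   intensity drift as windowed-clustering segmentation methods do.
2. **Cortical/trabecular separation** (`separate_cortex()`): the whole-bone
   solid is recovered by morphological closing and cavity filling; the
   compact cortical band is estimated per slice from the bone-occupancy
   profile by depth below the periosteal surface; the *inner mask* is the
   enclosed interior beyond that band and the trabecular phase is the bone
   inside it.
3. **Growth-plate handling**: unfused specimens carry a transverse
   cartilage gap; `split_epiphysis()` detects it as the distal-most run of
   slices whose bone area falls below 5% of the specimen median and splits
   the stack; both parts are then analysed as separate volumes, as is done
   when such specimens are segmented manually.
4. **Region cutting** (`cut_regions()`): the proximal border of the distal
   metaphysis sits at 70% of total proximodistal length from the proximal
   end; the distal border of the base is placed where dorsopalmar breadth
   has fallen to 60% of the maximal base breadth (an automated stand-in for
   a visual criterion, always overridable by explicit slice numbers);
   the epiphysis boundary comes from the growth plate or a user-supplied
   slice. Intervals are 0-based, half-open, and partition the bone extent.
5. **Grid morphometry** (`build_grid()`, `sample_grid()`): a background
   grid (2.5 mm spacing at study scale) is superimposed on the inner mask
   and overlapping spherical VOIs (5 mm diameter) at each node yield
   per-node BV/TV and the mean-intercept-length (MIL) fabric.
   The MIL scan casts parallel line families for a deterministic Fibonacci
   hemisphere of directions; per direction, MIL = total in-mask line length
   / number of marrow-to-bone crossings; the ellipsoid `1/MIL^2(w) = w'Hw`
   is fitted by least squares and the degree of anisotropy is
   `DA = 1 - lambda_min/lambda_max` of the MIL ellipsoid radii, bounded in
   [0, 1] with 0 isotropic.
6. **Thickness metrics** (`local_thickness_map()`, `region_thickness()`):
   sphere-fitting local thickness (maximal inscribed spheres via the
   Euclidean distance transform, distance ridge, and sphere coverage
   propagation) gives Tb.Th on the bone phase and Tb.Sp on the marrow
   phase; `Tb.N = 1/(Tb.Th + Tb.Sp)` by definition.
7. **Whole-bone mapping** (`mesh_inner_region()`, `interpolate_to_mesh()`,
   `mesh_mean()`): the inner region is tetrahedralised on a decimated
   structured lattice (six tetrahedra per cubic cell, centroid-culled),
   node samples are interpolated to element centroids by inverse-distance
   weighting (k = 8, power 2), and region means are element-volume-weighted
   mesh means. `dorsopalmar_index()` quantifies the dorsal/palmar
   concentration of a map over the epiphysis; `export_colormap()` writes
   VTK colour maps with per-specimen or fixed (0–0.45) BV/TV scales.
8. **Ontogenetic statistics** (`run_study()`): a Shapiro–Wilk gate logs why
   the nonparametric path is used; species-pooled Kruskal–Wallis tests
   across the five age categories (Neonate < 7 months, Infant 1 to 2.9 y,
   Infant 2 to 5.9 y, Juvenile to 11.9 y, Adult 12+ y; half-open bins)
   with Nemenyi all-pairs post hoc tests on the studentized range;
   per-category interspecific tests with the Neonate cell merged into
   Infant 1 when too small; Kruskal–Wallis tests of the three inter-region
   ratios (base/metaphysis, base/epiphysis, metaphysis/epiphysis); and two
   PCAs (SVD of the centred, unit-variance-scaled matrix) for
   base+metaphysis (10 variables) and the epiphysis (5 variables),
   complete-case. Significance is α = 0.05 throughout.

## Synthetic data: what it emulates and what it does not

No microCT scans ship with the package; every stage is validated against
generated data with known ground truth.

**Phantoms** (`make_phantom()`) provide closed-form truth: parallel plates
(BV/TV = t/p, Tb.Th = t, Tb.Sp = p − t, Tb.N = 1/p, strongly anisotropic),
square rod lattices (BV/TV = πr²/s²; their Tb.Sp/Tb.N spatial means have
no closed form and are recorded as `NA`), and thresholded Gaussian random
fields (exact fill fraction, statistically isotropic). Plate and rod
patterns are phase-shifted so the volume faces cut mid-structure, keeping
the thickness estimator's boundary convention (faces continue the phase)
unbiased.

**Synthetic metacarpals** (`make_synthetic_metacarpal()`) are scaled-down
(9.6 mm × 2.56 mm at 0.04 mm voxels by default) elongated bones with a
closed cortical shell whose thickness varies along the shaft, trabecular
fill in the base and distal end, a hollow mid-shaft, an unfused
growth-plate gap below the fusion age (126 months, within the 10–11-year
fusion window), and an ossified epiphysis drawn with the per-category
presence probabilities of the study's availability table. The fill is a
parallel-plate lattice with fenestrations (~15% of plate area), anchored
at the end caps and the growth plate so that every plate and marrow slab
inside a measured region is full-sized; plate thickness and spacing per
region follow the age trajectory. The epiphyseal fill carries a linear
dorsopalmar BV/TV gradient: distopalmar concentration in infants shifting
to distodorsal in adults (gradient ±0.5 around the category means), the
simplest spatial model that reproduces the qualitative palmar-to-dorsal
ontogenetic shift. Greyscale rendering blurs the phase labels with a
Gaussian (σ = 0.7 voxel, emulating partial-volume effects) and adds
intensity noise (SD 8 on the 8-bit scale).

The default **age trajectory** (`default_trajectory()`) is qualitative by
design — the study system's per-category values are not published — and
encodes: BV/TV and Tb.Th lowest at birth and increasing with age; Tb.N
decreasing; Tb.Sp near-constant with a slight adult increase; DA
near-constant. Thickness and separation means are multiples of the default
rendering voxel (e.g. Tb.Th 0.12→0.28 mm, Tb.Sp 0.40→0.48 mm) so
voxelisation does not bias category means; between-individual SDs are
0.02 mm (Tb.Th) and 0.04 mm (Tb.Sp). Image-level specimens realise BV/TV,
Tb.Th, Tb.Sp and Tb.N exactly (recorded per specimen as realised ground
truth); DA is only qualitative — the plate fill is strongly anisotropic at
every age — so parameter-recovery checks cover the four closed-form
parameters and treat DA directionally. Table-rendered cohorts
(`make_cohort(render = "table")`) draw the same per-specimen parameters
without rendering voxels, for statistical simulations at scale.

What the generator does **not** emulate: scanner artefacts beyond blur and
noise (no beam hardening, rings, or misalignment), rod-like or mixed
trabecular architectures, sexual dimorphism, bone growth in external size,
remodelling gradients near the growth plate, and realistic DA trajectories.
A green test suite therefore shows that the estimators and statistics are
correct on geometry they were specified for — not that segmentation would
be artefact-free on museum scans.

## Numerical choices

* **Thickness calibration.** The discrete EDT yields the distance to the
  nearest background voxel centre. The local thickness value uses a
  parity-aware medial-surface rule: where a ridge voxel has an equal-radius
  twin across the surface normal the diameter is `2r`, otherwise `2r − 1`
  (voxel units), making slabs of even and odd thickness both exact.
  Sphere diameters are still underestimated by up to a voxel, and volume
  faces are treated as phase continuation.
* **MIL fit.** Directions with no crossings enter the fit with
  `1/MIL² = 0`; fitted eigenvalues below `5e-3` of the largest are clamped
  (rank deficiency: unbounded intercepts, DA → ~0.93–1), while eigenvalues
  below `−5%` of the largest flag the VOI invalid. VOIs need ≥ 10% of the
  sphere inside the inner mask and ≥ 50 bone voxels. Lines shorter than 2
  voxels are ignored.
* **Cortical band.** The occupancy threshold is 0.75 (compact bone vs a
  trabecular fill), the per-slice profile is pooled over ±12 slices (at
  least one trabecular period), one extra voxel of erosion guards against
  the filled solid overhanging the bone surface, and end caps are detected
  by walking in from the piece ends while slice occupancy stays ≥ 0.97.
* **Junction margins.** Regional thickness means exclude voxels within 2
  (bone) or 4 (marrow) voxels of the cortex, where mask cuts and wall
  wedges bias local values; the marrow map runs on the whole medullary
  cavity so slabs are not clipped at the inner-mask edge.
* **Ties and degenerate inputs.** A fully tied sample yields H = 0, p = 1;
  constant PCA columns are dropped with a warning; groups with fewer than
  two observations are flagged `NA` in post hoc matrices; a VOI with no
  mask voxels is an invalid sample, not an error.

## Design choices where the method was genuinely open

* The 5 mm "spherical volumes" are read as sphere *diameter* (configurable).
* Whether thickness metrics are per-VOI or whole-region is ambiguous in
  holistic workflows; they are computed whole-region here, with
  `region_thickness()` callable on any voxel subset.
* The mesh mean is element-volume-weighted (`weighted = FALSE` gives the
  unweighted variant for sensitivity checks).
* The tetrahedral mesh is a structured-lattice (Kuhn) decomposition rather
  than a point-cloud Delaunay run: deterministic, watertight in the bulk,
  and volume-unbiased under centroid culling.
* Age bins follow the continuous stage definitions (2.9/5.9/11.9-year
  uppers), which partition the age line, rather than the coarser labels
  sometimes used alongside them.
* Ratio orientation is fixed (base/metaphysis, base/epiphysis,
  metaphysis/epiphysis); the reverse is the reciprocal.
* The dorsopalmar split plane passes through the region's volume-weighted
  centroid; for a symmetric map both halves are identical and the index
  is 1.
* No multiple-testing correction is applied beyond the Nemenyi family-wise
  control; a Holm option exists on `p.adjust` downstream if wanted.

## Problem sizes

The packaged simulation studies run at miniature scale so the full loop
stays cheap: synthetic bones of 240×64×64 voxels, grid spacing 0.4 mm with
1.0 mm VOIs and 32 MIL directions (`miniature_params()`), cohorts of 10
specimens per age category for image-level recovery, 100 table-level
cohorts for power checks and 500 for null calibration. Study-scale
defaults (2.5 mm grid, 5 mm VOIs, 128 directions) are what `morph_params()`
returns.

## Known limitations

* The cortical-band estimator assumes a shell-like geometry with a
  trabecular interior; it errors (by design) on solid blocks or open
  shells.
* Thickness metrics inherit the half-voxel-scale discretisation limits of
  sphere fitting; at fewer than ~4 voxels per trabecula they are noisy.
* The MIL fabric of a perfectly layered medium is rank-deficient; DA is
  then reported near 1 by the clamping rule rather than exactly 1.
* `split_epiphysis()` needs a genuine transverse gap; fused specimens must
  supply the epiphysis boundary explicitly (as the original workflows did
  from visual inspection).
* Statistical routines assume the cohort table's category structure;
  cells with < 2 observations are reported as untestable rather than
  imputed.
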