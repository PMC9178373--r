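# trabecula

Whole-bone ("holistic") trabecular morphometry for microCT volumes of
small long bones, and the ontogenetic statistics used to compare
trabecular architecture between age groups. The package is aimed at
researchers in skeletal biology and functional morphology who quantify
cancellous bone across development — the motivating system is the primate
third metacarpal from neonate to adult — and at anyone who needs tested,
scriptable implementations of the standard trabecular parameters.

## What it computes

From a greyscale or binary image stack the package derives, per anatomical
region (base, distal metaphysis, epiphysis):

- **BV/TV** — bone volume fraction, by voxel counting in overlapping
  spherical volumes of interest (VOIs) on a background grid over the inner
  (trabecular) mask, interpolated onto a tetrahedral mesh of the region;
- **DA** — degree of anisotropy from the mean-intercept-length (MIL)
  fabric: per direction ω, MIL(ω) = total test-line length / number of
  marrow→bone crossings; the ellipsoid `1/MIL²(ω) = ωᵀHω` is fitted by
  least squares and `DA = 1 − λ_min/λ_max` of its radii, 0 (isotropic) to
  1 (anisotropic);
- **Tb.Th, Tb.Sp** — mean trabecular thickness and separation by the
  sphere-fitting (maximal inscribed sphere) local-thickness method on the
  bone and marrow phases;
- **Tb.N** — trabecular number, `Tb.N = 1/(Tb.Th + Tb.Sp)`;
- whole-bone **colour maps** of these parameters on the mesh (VTK export,
  per-specimen or fixed 0–0.45 BV/TV scale) and a **dorsopalmar
  concentration index** of the epiphysis;
- **age-category statistics**: Kruskal–Wallis across ontogenetic
  categories with Nemenyi post hoc tests, interspecific tests,
  inter-region ratios, and PCAs of the regional variable sets.

Segmentation utilities turn a raw stack into the analysed regions:
binarisation (global Otsu or windowed two-class clustering with majority
voting), cortical-shell/trabecular separation, growth-plate gap detection
for unfused specimens, and 70%-length region cutting.

A first-class synthetic-data module generates phantoms with closed-form
ground truth (plates, rod lattices, isotropic foams) and whole
metacarpal-like volumes with a cortical shell, fenestrated-plate
trabecular fill following an ontogenetic parameter trajectory, an unfused
growth plate below fusion age, and an epiphyseal dorsopalmar BV/TV
gradient that shifts distopalmar→distodorsal with age — so the entire
pipeline is testable without scan data.

## Worked example

```r
library(trabecula)

## a plate phantom with known truth: t = 0.25 mm plates repeating every 1 mm
ph   <- make_phantom(phantom_spec("plate", 0.025, 120,
                                  thickness = 0.25, period = 1.0))
mask <- voxel_volume(array(1L, dim(ph$volume)), 0.025)
rt   <- region_thickness(ph$volume, mask)
fab  <- mil_fabric(ph$volume, mask, node = c(1.5, 1.5, 1.5),
                   voi_diameter = 2.5)
cat(sprintf("BV/TV  %.3f (truth %.2f)\nTb.Th  %.3f mm (truth %.2f)\nTb.Sp  %.3f mm (truth %.2f)\nTb.N   %.3f /mm (truth %.2f)\nDA     %.3f (strongly anisotropic)\n",
            mean(as.vector(ph$volume)), ph$truth$bvtv,
            rt$tb_th, ph$truth$tb_th, rt$tb_sp, ph$truth$tb_sp,
            rt$tb_n, ph$truth$tb_n, fab$da))
```

which prints

```
BV/TV  0.250 (truth 0.25)
Tb.Th  0.250 mm (truth 0.25)
Tb.Sp  0.750 mm (truth 0.75)
Tb.N   1.000 /mm (truth 1.00)
DA     0.929 (strongly anisotropic)
```

i.e. the estimators recover the phantom exactly (thickness metrics to
within a voxel in general; a parallel-plate medium is maximally
anisotropic, reported as DA ≈ 0.93 under the rank-deficiency clamp).

```r
## a synthetic adult metacarpal through the whole pipeline
sp  <- make_synthetic_metacarpal(age_months = 200, seed = 3)
res <- process_specimen(sp, miniature_params())
print(as.data.frame(res$record[, c("region", "bvtv", "da", "tb_th",
                                   "tb_sp", "tb_n")]), digits = 3)
round(res$dorsopalmar_index, 2)
```

```
      region  bvtv    da tb_th tb_sp tb_n
1       base 0.363 0.822 0.270 0.464 1.36
2 metaphysis 0.294 0.766 0.233 0.457 1.45
3  epiphysis 0.330 0.775 0.254 0.518 1.29
[1] 1.05
```

The record gives mesh-mean BV/TV and DA and the sphere-fitting thickness
metrics per region; an index above 1 marks the adult-like distodorsal
BV/TV concentration in the epiphysis (infants show values below 1).

The numbered drivers under `analysis/` run the full study on synthetic
data: phantom validation, cohort simulation, image-to-record recovery,
whole-bone colour maps, and the ontogenetic statistics with figures.
Outputs land under `results/`.

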