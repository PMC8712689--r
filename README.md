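# stemhisto

Quantitative histology of whole maize stem cross-sections from darkfield
and multispectral autofluorescence macro-images.

Maize stems are built from three tissues — a dense outer **rind**,
scattered **vascular bundles**, and thin-walled pith **parenchyma** — whose
proportions and cell-wall chemistry vary between inbred lines and drive
forage digestibility and biomass value. `stemhisto` implements a complete,
label-free image-analysis pipeline for whole cross-sections:

* **Segmentation** — threshold + hole filling for the stem mask, an
  alternating sequential filter (closings/openings of increasing size) to
  contrast dense tissue, size analysis around the mode of the bundle-area
  distribution to split rind from bundles, and Euclidean-distance zonation
  of the parenchyma (< 500 µm near the rind, > 1000 µm middle).
* **Morphometry** — Table-style descriptors: stem area St(A) and perimeter
  St(P), rind area Ri(A) and thickness Ri(T) (binary opening
  granulometry), bundle areas/elongations Vi(A), Vi(E), count and density
  Vb(N) = Vb(A)/V̄i(A), Vb(D) = Vb(N)/St(A), with the estimation formulas
  Ri(A)~ = Ri(T)·St(P) − diffEstMeas and the damaged-rind stem-area
  branch.
* **Cell sizing without segmentation** — grey-level granulometry: closings
  with square structuring elements (18–207 µm by 7.26 µm) sieve the dark
  cell lumens; the normalised increment curve is a size distribution whose
  mean is the grey-level cell diameter.
* **Stereology** — spherical-cell model Cw(D) = 3·t/R·100 (t = 0.5 µm wall
  thickness, R = mean size/2) and a cylinder-internode model turning
  relative areas into relative tissue cell-wall amounts.
* **Pseudospectra** — per-tissue means of the 11 fluorescence channels
  (U1b…GRr), background subtraction, division of parenchyma spectra by the
  cell-wall density, and section normalisation by the mean of the four
  tissue means (removes thickness effects).
* **Statistics** — relative phenolics (closure to 100%), population-SD
  CVs, PCA with correlation-circle loadings, one/two-way Type II ANOVA
  with Tukey compact-letter comparisons, and channel-wise correlation
  profiles between tissue fluorescence and phenolic composition.
* **Synthetic phantoms** — Poisson-disc/Voronoi stem sections with full
  ground truth (masks, descriptors, fluorescence signatures) standing in
  for the study's unreleased imagery.

All morphology primitives (van Herk min/max filtering, exact Euclidean
feature transform, connected components, hole filling) are implemented in
C++ within the package — no external imaging library is needed.

## Worked example

```r
library(stemhisto)

# a synthetic section with known ground truth
ph <- generate_phantom(phantom_params(stem_radius_um = 2300,
                                      rind_thickness_um = 300,
                                      n_bundles = 12, seed = 7))
rois <- segment_stem(ph$darkfield, pixel_size_um = 3.63)
rois
#> roi_set (1318x1318 px, 3.63 um/px)
#>   whole_stem                16.60 mm2
#>   all_tissue                16.60 mm2
#>   rind                       4.06 mm2
#>   bundles_all                1.28 mm2
#>   parenchyma                11.26 mm2
#>   parenchyma_near_rind       5.14 mm2
#>   parenchyma_middle          2.99 mm2
#>   individual bundles: 12

g <- granulometry_stats(graylevel_granulometry(
  ph$darkfield, rois$parenchyma_middle, "closing"))
round(g$mean_size_um, 1)    # 61.5 -> grey-level cell diameter (truth 70 um)
round(cell_wall_density(g$mean_size_um), 2)   # 4.88 % wall volume

# the printed-table twins
round(cell_wall_density(70.0), 2)   # 4.29
round(cell_wall_density(54.9), 2)   # 5.46

comp <- load_composition_table()
rel <- relative_phenolics(comp$kl_pct_cw, comp$pca_pct_cw, comp$fa_pct_cw)
round(cor(rel$kl_rel, rel$pca_rel), 2)   # -0.94 (closure-induced)
```

The segmentation recovers the phantom tissues with Jaccard ≥ 0.90 (rind,
bundles) and ≥ 0.95 (parenchyma); the granulometric cell diameter lands
within ±10 µm of the 70 µm truth (a known −8 µm bias of square-element
sieving on polygonal lumens, discussed in the methods vignette).

## Command line

```sh
Rscript inst/cli/stemhisto.R simulate --out run/ --seed 1
Rscript inst/cli/stemhisto.R segment run/darkfield.tif --modality darkfield --out run/rois
Rscript inst/cli/stemhisto.R morpho run/rois/roiset.json run/darkfield.tif --out run/morpho
Rscript inst/cli/stemhisto.R run-all --out run_all/
```

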