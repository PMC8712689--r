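---
title: "Models, parameters and design choices in stemhisto"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, parameters and design choices in stemhisto}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemhisto)
```

`stemhisto` quantifies the anatomy and cell-wall chemistry of whole maize
stem cross-sections from two kinds of label-free macro-images: darkfield
greyscale mosaics, in which light-scattering cell walls appear bright on a
dark background, and 11-channel multispectral autofluorescence stacks, in
which cell-wall phenolics (lignin, hydroxycinnamic acids) emit under UV
and visible excitation. This vignette explains the models behind each
stage, the tunable parameters and their defaults, what the synthetic
phantoms do and do not emulate, and the numerical choices made where the
underlying method left the design open.

## The segmentation workflow

The seven tissue regions of interest are produced by a fixed sequence:

1. **Whole stem**: automatic (Otsu) or fixed threshold, largest connected
   component, interior hole filling. Darkfield convention throughout:
   foreground brighter than background.
2. **All tissue**: large dark tears (torn parenchyma) are detected after a
   closing larger than the cell size (`hole_closing_um`, default 150 µm)
   has brightened ordinary cell lumens; candidate regions darker than a
   threshold and larger than `min_hole_area_um2` (default 0.01 mm²) are
   removed. The default hole threshold is a fraction (0.35) of the
   in-stem median rather than Otsu, because Otsu on a hole-free section
   would split the histogram arbitrarily and invent holes.
3. **Dense tissue**: an alternating sequential filter — closing then
   opening at each structuring-element size, sizes increasing — suppresses
   the one-pixel-wide parenchyma walls while closing the small lumens of
   rind and bundle texture, so dense tissue keeps its intensity. Default
   half-widths are 1, 2, 3 px at 3.63 µm/px. Otsu on the in-tissue
   histogram then yields the rind+bundle mask.
4. **Rind vs bundles**: the typical bundle area is the mode of the
   component-area distribution, restricted to components whose centroid
   lies more than 1 mm below the stem contour (bundles embedded in or
   touching the rind would bias it). The mode uses a Gaussian kernel
   density with Silverman bandwidth on log-area, falling back to a
   Freedman–Diaconis histogram below 10 objects — a robust choice for the
   few dozen objects of a real section. "External" components (within 2 px
   of the contour) larger than 5× the mode are merged into the rind;
   non-external components within [0.2, 5]× the mode become individualised
   bundles (the lower bound rejects debris); everything dense that is not
   rind is `bundles_all`, including connected clusters.
5. **Parenchyma zones**: parenchyma is the stem minus rind and bundles,
   exactly (the partition invariant is enforced by the `roi_set`
   constructor). Euclidean distance to the rind splits it at < 500 µm
   (near rind) and > 1000 µm (middle); the band in between belongs to
   neither, which is deliberate — the two zones are meant to contrast.

Fluorescence stacks are segmented by the same workflow applied to the
per-pixel sum of the 11 channels.

A section is flagged `rind_damaged` when no external rind fragment is
found or the rind accompanies less than 95% of the contour. The flag
drives the estimation branch of the stem area (below).

## Morphological descriptors and estimation formulas

Areas are pixel counts times the squared pixel size; the stem perimeter is
a four-direction Cauchy–Crofton estimate from intercept counts, which is
within 1% on disks (stems are round; the known −5% bias on exact squares
is irrelevant here and covered by tests). Rind thickness is the mean of
the binary opening granulometry of the rind mask (square elements up to
1456 µm). Two biases matter and are deliberately left to the calibration
step rather than patched locally:

* an axis-aligned square fits a diagonal band of width $t$ only up to side
  $t/\sqrt2$, so opening granulometry of an ideal annulus reads
  ≈ 0.83 t;
* in real sections, bundles still attached to the rind inflate the
  thickness.

The rind-area estimate $\tilde{Ri}(A) = Ri(T)\cdot St(P) - d$ therefore
uses an offset $d$ (`compute_diff_est_meas`) learned as the mean of
$Ri(T)\cdot St(P) - Ri(A)$ over undamaged sections; its sign depends on
which bias dominates (negative on clean synthetic annuli, positive when
attached bundles dominate). For damaged sections the stem area replaces
the measured rind by the estimated one.

Bundle elongation is the minor/major axis ratio of the equivalent ellipse
from second-order moments — unlike a bounding-box width/length it is
rotation-invariant. The bundle count $Vb(N) = Vb(A)/\bar{Vi}(A)$ corrects
for merged clusters: the mean individual area comes from individualised
bundles only, the total area includes clusters.

## Grey-level granulometry

Closing an image with a square of width $k$ removes dark structures that
cannot contain the square, so the summed grey level inside the ROI
increases; the increment between consecutive sizes is the amount of dark
material of that size. The curve of increments over sizes 18–207 µm (step
7.26 µm = 2 px), baseline-corrected and renormalised to 100, is a size
distribution of the cell lumens; its mean is the grey-level cell diameter
and needs no cell segmentation.

Baseline correction subtracts the smallest increment observed over the
largest quartile of sizes (a constant-offset model of the residual
variation contributed by the image background), floors at zero and
renormalises. A constant-offset model is the simplest reading of
"residual size variations caused by the general background"; anything
richer (e.g. fitting a trend) would need evidence the data do not provide.
Degenerate curves (constant images) are flagged and excluded from moment
computation rather than renormalised into noise.

Sizes are converted to the nearest odd pixel width. The rind-thickness
granulometry uses a 14.52 µm step (4 px) rather than 7.26 µm purely for
cost — the published maximum (1456 µm) is kept and the mean of a
distribution 100 µm wide moves by well under one step.

## Stereology: from areas to cell-wall amounts

The internode is treated as a cylinder, so relative volumes equal relative
areas in the section; no axial integration is performed and none is
claimed. Rind and bundles are counted as 100% wall (their lumens are
small); the parenchyma wall amount is its area times the wall density from
the spherical-cell model

$$Cw(D) = \frac{3\,t}{R}\times100,\qquad t = 0.5\ \mu m,\ R = \tfrac{\text{mean size}}{2},$$

which is the surface-to-volume ratio of a thin-walled sphere. The
near-rind area is total parenchyma minus middle parenchyma, so the
500–1000 µm transition band is counted with the near-rind zone. The total
wall amount (rind + bundles + parenchyma walls) normalises the per-tissue
percentages and, divided by the stem area, gives CW(T).

The model is a volume statement; evaluated on a planar phantom it sits a
geometric factor (~3–4) above a literal 2-D census of wall material, which
is exactly what the tests assert. It is a comparison tool between lines,
not an absolute wall assay.

## Pseudospectra

The 11 channels are, in fixed order, U1b U1g U2b U2g U2r BLb BLg BLr GRb
GRg GRr: blue/green(/red) emission under two UV (U1, U2) and two visible
(BL, GR) excitations. U1r never enters the stack (excitation-band
reflection); BL/GR captures are multiplied by a gain of 2 at assembly.
The channels BLb, GRb and GRg cannot physically carry emission (emission
cannot be bluer than the excitation) and are kept as baselines in every
spectrum — the method text is inconsistent about whether the third silent
channel is GRr or GRg, but physics and the definition of the "visible sum"
image (which includes GRr as a signal channel) identify {BLb, GRb, GRg};
the set is nevertheless configurable.

Corrections are applied in a fixed order: (1) subtraction of the
background spectrum (channel-wise mean over signal-free regions — a mask
can be supplied, or the darkest 1% of pixels outside the stem is used in
unattended runs); (2) division of parenchyma spectra by the cell-wall
density, which converts a lumen-diluted tissue mean into an estimate of
wall fluorescence; (3) section normalisation by
$F_n = \tfrac14(\bar{Ri} + \bar{Vb} + \bar{Pr} + \bar{Pm})$, the mean of
the four tissue channel-means, removing the section-thickness intensity
effect. Scaling every channel by a common gain provably leaves the
normalised spectra untouched. Negative post-subtraction values are kept
(clipping would bias channel means); a warning fires below −1% of the
spectrum maximum.

## Statistics

Relative phenolics close to 100% by construction, which *induces*
correlations between them (−0.94 between relative lignin and pCA on the
packaged table); downstream interpretation must account for that, and the
tests pin the induced values. The coefficient of variation uses the
population (divisor-*n*) standard deviation — the convention is forced by
reproducing the published summary values (8.5% for cell wall, 15.56% for
pCA) and is stated on the function. PCA standardises morphological
descriptors (heterogeneous units) but not pseudospectra (baselines must
not be inflated); standardised loadings are also reported as
correlation-circle coordinates with the same ≥ 0.5 display rule used in
the source figures. ANOVA uses Type II sums of squares from nested
least-squares fits because the design is unbalanced (a missing internode,
extra repeats); the implementation is verified to full precision against
an external reference on a frozen fixture. Multiple comparisons use Tukey
HSD on estimated marginal means with a compact letter display; the
adjustment method is a declared default (the source does not state one).
Correlation profiles are per-channel Pearson coefficients across lines
with unadjusted two-sided significance at α = 0.05, mirroring a
per-channel display rather than a family-wise claim.

## The synthetic phantom: what it emulates, what it does not

The generator builds, deterministically from a seed: an annular rind with
small-cell dense texture; non-overlapping elliptical bundles with a bright
sheath; a parenchyma mosaic from Poisson-disc-seeded Voronoi tessellation
(Bridson sampling with a spatially varying radius, two Lloyd iterations)
whose nominal cell diameter shrinks from 70 µm (middle) to 50 µm within
500 µm of the rind; optional elliptical holes and a missing rind arc; a
darkfield rendering (walls bright, lumens dark, Gaussian noise); and an
11-channel fluorescence stack in which *wall pixels* emit the per-tissue
signature (UV-dominant parenchyma, visible-dominant rind/bundles, zero at
baseline channels) times a section gain, over channel-dependent background
offsets — emulating ethanol-washed sections with empty lumens.

Defaults state a realistic silage-stage internode: 1.5 cm² stem, 600 µm
rind (≈ 17% relative rind area, matching the printed four-line table),
77 bundles/cm² of ≈ 0.1 mm², 3.63 µm/px. Scaled-down radii are used in
tests for cost, with cell sizes and distance bands unchanged and stated in
the test comments.

Known, deliberate simplifications:

* walls are 1 px (3.63 µm) thick — an order of magnitude thicker than real
  parenchyma walls — so absolute wall-pixel counts are not comparable to
  the 0.5 µm stereological model (the tests assert bracketing, not
  equality);
* square-element sieving of polygonal lumens reads systematically below
  the nominal seed spacing (≈ −8 µm at 70 µm), a shared property of the
  method on real cells; the ±10 µm recovery criterion accommodates it;
* fluorescence is generated on the darkfield grid (3.63 µm/px), not the
  instrument's 2.78 µm/px — serial-section registration is out of scope
  and a shared grid gives exact ground truth for both modalities;
* no mosaic-stitching artefacts, no photophysics (quenching, bleaching),
  no sub-bundle anatomy.

A green phantom test therefore establishes that the *pipeline* recovers
what the stated world contains, at the stated noise; it does not establish
instrument-level accuracy on real sections.

## Numerical conventions

Images are numeric matrices (row, column), 0-based pixel coordinates in
the C++ core, 8-connectivity for components, edge replication at image
borders for morphology, exact Euclidean distance transforms. Intensities
are non-negative reals; bit depth is an I/O concern (the bundled TIFF
codec reads/writes uint8, uint16 and float32). All randomness flows
through R's RNG, so every generator output is a pure function of its
parameters including the seed.

## Known limitations

* The semi-automated steps of the original workflow (operator-validated
  thresholds, hand-picked background regions) are replaced by automatic
  defaults with explicit override hooks; agreement with operator choices
  on real data cannot be tested here.
* `diffEstMeas` calibration needs at least one undamaged section; a
  cohort of only damaged sections falls back to the uncorrected estimate
  with a flag.
* The bundled TIFF codec is intentionally minimal (no compression, tiles,
  or colour); it exists because the execution environment ships no R TIFF
  reader.
* Printed-table reproduction is exact for the quantities whose inputs are
  printed (the spherical-cell density twins, relative phenolics,
  means/CVs, closure
  correlations); image-derived descriptors of the original study are not
  reproducible because the imagery is not public — phantom recovery is the
  substitute evidence.
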