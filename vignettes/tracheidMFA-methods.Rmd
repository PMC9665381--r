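---
title: "Measuring S2 microfibril angle and tracheid morphology together: models and design"
author: "tracheidMFA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring S2 microfibril angle and tracheid morphology together: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Softwood tracheids carry information at two very different scales. At the
micrometre scale, the transverse section shows the anatomy a quantitative
wood anatomist measures: lumen and cell areas, radial and tangential
diameters, wall thickness, and the arrangement of cells into radial files
(the lineage rows a single cambial initial produces across a growth ring).
At the nanometre scale, the cellulose microfibrils of the dominant S2 wall
layer wind around the cell axis at the microfibril angle (MFA), the single
strongest determinant of wood stiffness. The two scales are usually
measured by different instruments on different samples, which makes their
relationship hard to study cell by cell.

This package implements a microscopy-based route that measures both on the
*same* section: polarized-light micrographs give a per-pixel retardation
map that converts to MFA, fluorescence micrographs give the segmentation
and the morphometry, and an image-registration step joins the two so that
every tracheid ends up with its seven anatomical parameters and its
per-wall mean S2 MFA. A synthetic phantom generator renders both
modalities from a known ground-truth model, so the whole chain is testable
end to end without any microscope.

## From three polarization frames to retardation

One imaging spot is captured three times through a circular polariscope
while the polarizer is rotated to angles $\alpha_k$ (default $0,45,90$
degrees). The frame model is

$$I_k = \frac{I_0}{2}\Big[1 + \sin\delta\,\sin 2(\alpha_k - \varphi)\Big],
\qquad \delta = \frac{2\pi\Gamma}{\lambda},$$

with $\Gamma$ the retardation (nm), $\varphi$ the slow-axis azimuth and
$\lambda$ the working wavelength (546 nm). After per-pixel subtraction of
the background stack (stray light), the three frames are a linear system
in $(I_0/2,\; s\cos 2\varphi,\; s\sin 2\varphi)$ with
$s = (I_0/2)\sin\delta$, solved exactly for any polarizer angles pairwise
distinct modulo 180 (`polInvert()`). Numerical choices:

* **Invalid-pixel floor.** Pixels with $I_0$ below 1% of the stack maximum
  (lumina, mounting medium) are masked invalid rather than inverted;
  dividing by a near-zero $I_0$ only amplifies sensor noise.
* **Quarter-wave ambiguity.** $\sin\delta$ determines $\delta$ only up to
  $\pi - \delta$; retardations above $\lambda/4 \approx 136.5$ nm are not
  unwrapped but clamped and flagged. Under the package's optical constants
  the S2 MFA range of interest (below 45 degrees) stays below the 84.6 nm
  working point, far from the bound; a 90-degree MFA would produce 175 nm
  and is out of the measurable range by design.
* **Azimuth degeneracy.** At $\Gamma = 0$ the azimuth is undefined and is
  reported as NA instead of an arbitrary angle.

The forward model (`polForward()`) is the exact counterpart, and the test
suite treats the noiseless round trip — not fidelity to any particular
instrument — as the correctness criterion for the pair.

## From retardation to MFA

Light propagates along the cell axis through a wall of thickness $t$ whose
cellulose fraction is $f$. Fibrils inclined by $\mu$ from the propagation
direction present the apparent extraordinary index of a uniaxial
indicatrix,

$$n_e'(\mu) = \frac{n_o n_e}{\sqrt{n_e^2\cos^2\mu + n_o^2\sin^2\mu}},
\qquad \Gamma(\mu) = t\,f\,[\,n_e'(\mu) - n_o\,],$$

with $n_o = 1.529$, $n_e = 1.599$ for cellulose, $t = 5000$ nm (a 5 um
section) and $f = 0.5$ (the S2-layer convention for softwoods). The map is
strictly increasing on $[0^\circ, 90^\circ]$, from 0 to
$t f (n_e - n_o) = 175$ nm, and is inverted analytically
(`retardationToMfa()`); the round trip is exact to well below
$10^{-4}$ degrees. Two caveats are inherited from the physics, not the
code: $t$ and $f$ are rarely known exactly for a given section, so
absolute MFA values are semi-quantitative and should be cross-validated
(the `caveMfa()` X-ray route exists for exactly that), and earlywood vs
latewood differences in cellulose content are ignored because they amount
to a few percent at most.

## Separating wall families and the S2 layer

With the section mounted so that the polarizer frame is rotated 45 degrees
from the radial direction (`sampleRotationDeg`, configurable), tangential
walls — the walls separating radially consecutive cells of a file —
concentrate their azimuths near 45 degrees. `classifyWalls()` histograms
the wall-pixel azimuths in 1-degree bins (circularly, period 180), fits a
single Gaussian around the dominant peak (nonlinear least squares
initialized at the mode; a windowed circular standard deviation replaces
the fit when the peak is too narrow for one), and classifies pixels within
$3\sigma$ of the center as tangential, the rest as radial. A fitted
$3\sigma$ spanning the whole circle is rejected with a pointer to the
mounting rotation, since it means no wall family has a consistent azimuth.

Across the thickness of a double wall the MFA profile is
high–low–high–high–low–high: the thin S1 and S3 layers are below the
optical resolution and merge with their neighborhood into local maxima,
while each cell's S2 core is a local-minimum valley. `detectS2()` scans
each wall band one-dimensionally along the direction perpendicular to the
wall plane (along x for tangential walls, along y for radial ones),
reduces local-extremum plateaus to their medial pixel, and returns the
valley pixels as the S2 mask and the ridge pixels as the S1+S3 mask. Two
guards matter in practice:

* a **prominence floor** (1 degree by default): intensity quantization and
  sensor noise fragment flat plateaus into sub-0.1-degree wiggles that
  would otherwise be detected as extrema; the genuine S2/S1+S3 contrast is
  an order of magnitude larger;
* an optional **along-wall running mean** (window 5 recommended for noisy
  data, off by default) that averages parallel to the wall, where the
  profile is constant, and leaves the cross-wall profile that carries the
  signal untouched.

S1+S3 values are retained for display but are an unresolved mixture of
sub-resolution layers; they never feed the downstream statistics.

## Segmentation, radial files, morphometry

The UV-excitation channel shows lignified walls bright (brightest at the
lignin-rich compound middle lamella between cells) and lumina dark; the
green-excitation channel shows only the extractive-rich ray cells.
`maskRays()` thresholds the green mosaic (Otsu) and cleans the mask
morphologically; `segmentCells()` binarizes the walls (Otsu), takes
interior connected lumen regions as seeds, and grows cell territories by
intensity-weighted propagation so boundaries settle on the bright
middle-lamella ridge. Latewood cells whose lumen is too small to seed are
flagged rather than silently lost, and extra seeds can be supplied
programmatically — the package's replacement for the manual boundary
correction an operator would otherwise perform.

`extractRadialFiles()` builds the region adjacency graph of touching
cells and chains each cell to its most probable latewood-ward neighbor:
candidates are adjacent cells whose centroid-to-centroid vector lies
within 25 degrees of the radial axis, and the successor minimizes the
Bray–Curtis dissimilarity of tracheid transverse areas,
$BC(A_1, A_2) = |A_1 - A_2|/(A_1 + A_2)$, with ties broken toward the
straighter connection. Files that span the ring without touching the
mosaic border are marked intact. `measureCells()` then measures areas by
pixel counting, diameters as extents along the scan lines through the
centroid, and tangential wall thickness as half the double-wall span
between consecutive file members along the radial line through both
centroids, assigned to both cells — a definition chosen because it is
reproducible and orientation-consistent.

## Mosaicking and registration

Tiles overlap by about 66%; `pocShift()` estimates integer shifts from the
phase of the normalized cross-power spectrum, and `stitchTiles()` chains
them row-major from the nominal grid, falling back to the nominal stride
(with a flag) when an estimate strays beyond 25% of the tile size.
Sub-pixel shifts are deliberately not estimated — wall thickness is
several pixels at the working magnification. One subtlety: near-periodic
cell lattices alias the correlation peak by one cell pitch, so the peak is
searched inside a window around the mechanically plausible shift; offsets
are estimated once per modality and reused for every channel.

POM-to-FLM registration must absorb a ~4x magnification ratio and a small
mounting rotation. `registerImages()` uses the log-polar magnitude
spectrum (Fourier–Mellin): rotation becomes an angular shift and scale a
log-radial shift of the spectrum, recovered by phase correlation, refined
by a Nelder–Mead search maximizing the spatial correlation peak on
downsampled working copies, with the translation estimated last at full
resolution. The estimator is scale- and rotation-invariant by
construction; it was chosen over keypoint matching because it needs no
feature detector, is a natural extension of the phase-correlation
machinery already present, and meets the same contract (identity on
identical images, agreement with plain phase correlation for pure
translations, scale within 1% and rotation within 0.5 degrees at a 4x
ratio). The `inlierCount` field of the transform is reserved for
keypoint-based estimators and is NA here.

## Tracheidograms and statistics

Per-file parameter sequences are normalized to a common grid of 27 cells
(the study-scale mean file length) by piecewise-linear interpolation —
chosen over splines to preserve monotonicity and endpoints — with NA gaps
of up to two cells bridged and longer gaps propagated. Mean S2 MFA arrays
are smoothed with a Savitzky–Golay filter (window 3, order 1, i.e. a
centered moving mean that reproduces linear trends exactly); morphology
arrays stay raw. Per-cell means require at least 10 S2 pixels per wall
class (`minPixels`), a variance-control floor.

Tangential wall thickness is screened per normalized position with the
modified z-score, $0.6745\,(x - \mathrm{med})/\mathrm{MAD} > 3.5$, the
standard robust cutoff; flags map back to raw cells by nearest scaled
index. Pearson correlations (with listwise deletion) relate each
anatomical parameter to per-wall mean S2 MFA; Shapiro–Wilk and Bartlett
tests gate the distributional assumptions; position effects are tested by
the Steel–Dwass all-pairs comparison: joint mid-ranks per pair, a
tie-corrected variance, and $\sqrt 2\,|t|$ referred to the studentized
range with $k$ groups and infinite degrees of freedom at family level
$\alpha = 0.05$.

The asymptotic reference is a deliberate choice: exact small-sample
Steel–Dwass tables are out of scope, and at the study-scale group size
(16 files per position) the asymptotic error is small. The test suite
still confronts the implementation with a family-wise max-statistic
permutation oracle at a deliberately harsh size (5 groups of 8), where the
asymptotic p-values deviate from the exact permutation law by up to about
0.06 in the mid-range — an $O(1/n)$ effect of the normal approximation,
an order of magnitude below the deviation an incorrect statistic or
variance would produce. The suite also verifies that the family-wise
type-I error on 27 null groups of 16 stays below the nominal 0.05 (the
rank discreteness makes the test conservative there).

## Cave's construction for the X-ray cross-check

`caveMfa()` estimates mean MFA from the azimuthal intensity profile of the
cellulose (200) diffraction arc: baseline (minimum of the tails)
subtraction, Savitzky–Golay smoothing (window 11, order 2), inflection
points from the zero crossings of the second derivative on each flank,
tangents at the inflections extended to the zero baseline, and
$\mathrm{MFA} = 0.6\,T/2$ with $T$ the span between the intercepts. The
method exists in variants differing in whether $0.6T$ uses the full or the
half tangent-intercept width; this package pins the half-width convention
through the Gaussian closed form — for a Gaussian of standard deviation
$s$ the inflections sit at $\pm s$, the tangent construction gives
$T = 4s$ exactly, and the estimate is $1.2\,s$ — which the tests reproduce
to better than 0.1 degrees. Multi-modal profiles are rejected with the
mode positions listed.

## The phantom: what it emulates, and what it does not

`sectionModel()` describes one ring as `nFiles` rows of `cellsPerFile`
rectangular tracheids with rectangular lumina. Defaults emulate one
mature ring of a model softwood at a realistic survey scale:
16 files of 27 cells (432 tracheids), radial diameters falling
logistically from 35 to 12 um across the earlywood–latewood transition,
single-wall thickness rising from 2 to 3.5 um, constant 30 um tangential
diameter, a linear tangential/radial S2 MFA ramp from 20 to 10 degrees, an
S1+S3 edge MFA of 35 degrees, two one-cell-tall ray bands, 0.5 um pixels,
and a 45-degree polarizer-frame rotation so tangential walls peak at 45
degrees. Azimuths get 2 degrees of per-pixel jitter, which is what makes
the Gaussian fit of `classifyWalls()` well-posed.

Two design choices deserve their rationale:

* **Per-file size variation** (`fileDiameterSd = 0.02`,
  `fileTangentialSdUm = 1.5`, drawn once from a model-owned seed so the
  geometry is a property of the model, not of the render seed). Real rings
  always vary between files; a perfectly periodic lattice would also make
  tile registration mathematically ill-posed, because a shift by one cell
  pitch reproduces the scene exactly.
* **Frame rotation instead of raster rotation.** The sample rotation is
  implemented as an offset of the azimuth values (the optical frame
  rotated relative to the anatomical frame) while rasters stay
  axis-aligned with the radial direction along x. The observable the
  rotation exists to produce — the tangential azimuth peak near 45
  degrees — is identical, and the segmentation stages are spared a
  compensating raster rotation.

Rendering: the UV channel is 0.15 background, 0.70 wall, 0.95 middle
lamella (lignin autofluorescence is strongest there, and the bright
boundary is also what lets seeded growing recover the true cell outline);
the green channel is bright only on rays; the polarization frames come
from the forward model applied to the true retardation and azimuth maps,
cut into tiles with 66% overlap and seeded integer jitter, with matching
background tiles. Noise is additive Gaussian clipped to the sensor range —
no shot-noise model, no bordered pits on radial walls, no MFA disturbance
from sectioning damage. Passing the phantom tests therefore demonstrates
the correctness of the algorithms under the stated image-formation model,
not robustness to every artifact of real sections; the pixel-perfect
segmentation the phantom allows, in particular, is a property of its crisp
rendering, and real micrographs will land closer to the flagged-QC path.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to run on
one CPU in minutes: polarimetry round trips on 512x512 fields, the full
study-scale phantom (16x27 cells, ~1000x1600 px) through the complete
pipeline in both noiseless and 1%-noise conditions, a 100000-draw
permutation oracle, and 500 null simulations of the 27x16 design. All
randomness flows through explicit integer seeds (`withSeed()` restores the
RNG state afterwards), and reruns with the same configuration are
byte-identical, CSVs included.

## Known limitations

Absolute MFA is semi-quantitative (section thickness and cellulose
fraction enter multiplicatively); retardations beyond the quarter-wave
bound are flagged, not unwrapped; integer-pixel stitching; the S1+S3 mask
is an unresolved mixture; the phantom's rectangular geometry cannot
represent within-file tangential-diameter variation; and the Steel–Dwass
p-values are asymptotic, which is conservative at the study's group sizes
but visibly approximate below n of about 10.
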