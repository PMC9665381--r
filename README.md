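# tracheidMFA

Simultaneous, per-tracheid measurement of the S2 microfibril angle (MFA)
and transverse cell morphology from transverse sections of softwood,
organized by radial files.

Quantitative wood anatomists and wood-quality researchers usually measure
cell anatomy (microscopy) and MFA (X-ray diffraction) on different
instruments, losing the cell-by-cell link between them. This package
implements a microscopy-only route that recovers both from the *same*
section: polarization micrograph triplets are inverted to retardation and
azimuth maps, converted to MFA through a birefringence model, and split
into radial- and tangential-wall S2 contributions; fluorescence
micrographs drive cell segmentation, ray masking, radial-file tracing and
morphometry; image registration joins the two sides so every tracheid
carries its seven anatomical parameters plus per-wall mean S2 MFA; and
tracheidogram normalization, correlation analysis and Steel–Dwass
all-pairs position tests summarize the intra-annual trends. A synthetic
phantom generator renders all input modalities from a known ground truth,
so the complete pipeline is testable end to end without a microscope.

## The models at the core

**Three-frame polarimetry.** Each spot is imaged at polarizer angles
α<sub>k</sub> ∈ {0°, 45°, 90°}:

    I_k = (I0/2) [ 1 + sin δ · sin 2(α_k − φ) ],   δ = 2πΓ/λ

which, after background subtraction, is solved per pixel in closed form
for the mean intensity I0, retardation Γ and azimuth φ (`polInvert()`).

**Birefringence model.** For fibrils inclined μ from the cell axis in a
section of thickness t and cellulose fraction f,

    Γ(μ) = t · f · [ n_o n_e / sqrt(n_e² cos²μ + n_o² sin²μ) − n_o ]

with n_o = 1.529, n_e = 1.599, t = 5000 nm, f = 0.5; Γ rises strictly
from 0 to 175 nm at 90°, and is inverted analytically
(`retardationToMfa()`).

**Wall families and the S2 layer.** Tangential walls peak near 45° in the
azimuth histogram; a fitted Gaussian's ±3σ band defines them
(`classifyWalls()`). Within each wall band the S2 layer is the
local-minimum valley line of the MFA profile and the merged S1+S3 layers
are the ridges (`detectS2()`).

**Files and morphometry.** Cells are segmented by seeded region growing
on the UV mosaic (`segmentCells()`); radial files are chained on the
region adjacency graph under a 25° angle restriction with the Bray–Curtis
criterion |A1−A2|/(A1+A2) on transverse areas (`extractRadialFiles()`);
`measureCells()` yields the seven anatomical parameters in µm/µm².

**Statistics.** Tracheidograms normalized to 27 positions
(`normalizeFile()`), Savitzky–Golay smoothing (window 3, order 1),
modified-z outlier screening, Pearson correlations, Shapiro–Wilk/Bartlett
gates, and Steel–Dwass all-pairs comparisons via the studentized range
(`steelDwass()`). `caveMfa()` adds the classical X-ray cross-check (Cave's
tangent construction on the (200) azimuthal profile).

## Worked example

Everything below runs from a synthetic phantom — no images needed:

```r
library(tracheidMFA)

model <- sectionModel(nFiles = 8, cellsPerFile = 12, rayAfterFile = 3L)
dir <- file.path(tempdir(), "demo")
ph <- runPhantom(model, dir = dir, seed = 1, tileGrid = c(2, 3), noiseSd = 10)
bundle <- runPipeline(dir, nNormalized = 12, s2SmoothWindow = 5)

length(unique(bundle$files$file[bundle$files$intact]))
#> [1] 8
head(bundle$cells[, c("label", "file", "position", "lumenRadialDiameterUm",
                      "cellWallOccupancy", "meanS2MfaTangentialDeg")], 4)
#>   label file position lumenRadialDiameterUm cellWallOccupancy meanS2MfaTangentialDeg
#> 1     1    1        1                    32         0.2188552               19.80199
#> 2    15    1        2                    32         0.2188552               18.87160
#> 3    23    1        3                    32         0.2188552               18.27445
#> 4    31    1        4                    32         0.2188552               17.36239
```

All 96 phantom tracheids are segmented into 8 intact radial files. Wide
thin-walled earlywood cells (32 µm lumina, occupancy 0.22) carry tangential
S2 MFA near 20°, and the per-cell means track the phantom's built-in
20°→10° ramp. The correlation table reproduces the expected signs — MFA
correlates positively with lumen size and negatively with wall occupancy
and thickness:

```r
subset(bundle$correlations, wall == "tangential" &
       parameter %in% c("lumenRadialDiameterUm", "cellWallOccupancy",
                        "tangentialWallThicknessUm"))
#>                    parameter       wall          r            p  n
#> 13     lumenRadialDiameterUm tangential  0.9020706 4.513483e-36 96
#> 15         cellWallOccupancy tangential -0.8282012 2.265208e-25 96
#> 16 tangentialWallThicknessUm tangential -0.8372892 2.199650e-26 96

round(bundle$bands$meanS2MfaTangentialDeg$mean, 2)
#>  [1] 19.94 19.06 18.20 17.31 16.48 15.60 14.74 13.88 12.94 12.13 11.23 10.49
```

The last line is the mean tangential-wall S2 tracheidogram across files —
the recovered intra-annual MFA trend, within a few tenths of a degree of
the ground truth despite 1% sensor noise.

A thin command-line wrapper is installed with the package:

```sh
Rscript inst/scripts/tracheidmfa.R phantom --dir /tmp/ph --seed 1 --noiseless
Rscript inst/scripts/tracheidmfa.R all --input /tmp/ph --out /tmp/bundle
```

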