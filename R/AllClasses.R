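#' @import methods
NULL

#' Optical configuration for polarized-light MFA imaging
#'
#' Bundles the constants of the birefringence model and of the three-frame
#' acquisition: monochromatic wavelength, the three polarizer angles, the
#' ordinary and extraordinary refractive indices of cellulose, the section
#' thickness and the cellulose volume fraction of the wall.
#'
#' @slot wavelengthNm monochromatic wavelength in nm (default 546).
#' @slot polarizerAnglesDeg the three polarizer angles in degrees, pairwise
#'   distinct modulo 180.
#' @slot nO,nE ordinary and extraordinary refractive indices of cellulose
#'   (defaults 1.529 and 1.599).
#' @slot sectionThicknessNm section thickness in nm (default 5000, i.e. 5 um).
#' @slot celluloseFraction cellulose volume fraction of the wall in (0, 1]
#'   (default 0.5, the S2-layer convention for softwoods).
#' @exportClass OpticsConfig
setClass("OpticsConfig", representation(
  wavelengthNm = "numeric",
  polarizerAnglesDeg = "numeric",
  nO = "numeric",
  nE = "numeric",
  sectionThicknessNm = "numeric",
  celluloseFraction = "numeric"
))

setValidity("OpticsConfig", function(object) {
  msg <- NULL
  if (length(object@wavelengthNm) != 1L || object@wavelengthNm <= 0)
    msg <- c(msg, "wavelengthNm must be a single positive number")
  if (length(object@polarizerAnglesDeg) != 3L)
    msg <- c(msg, "exactly three polarizer angles are required")
  a <- object@polarizerAnglesDeg %% 180
  if (anyDuplicated(round(a, 8)) > 0)
    msg <- c(msg, "polarizer angles must be pairwise distinct modulo 180")
  if (!(object@nE > object@nO && object@nO > 1))
    msg <- c(msg, "need nE > nO > 1")
  if (object@sectionThicknessNm <= 0)
    msg <- c(msg, "sectionThicknessNm must be > 0")
  f <- object@celluloseFraction
  if (!(f > 0 && f <= 1))
    msg <- c(msg, "celluloseFraction must be in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

#' Construct an OpticsConfig
#'
#' @param wavelengthNm wavelength in nm.
#' @param polarizerAnglesDeg three polarizer angles in degrees.
#' @param nO,nE ordinary/extraordinary refractive indices of cellulose.
#' @param sectionThicknessNm section thickness in nm.
#' @param celluloseFraction cellulose volume fraction of the wall.
#' @return An \linkS4class{OpticsConfig}.
#' @examples
#' opticsConfig()
#' @export
opticsConfig <- function(wavelengthNm = 546,
                         polarizerAnglesDeg = c(0, 45, 90),
                         nO = 1.529, nE = 1.599,
                         sectionThicknessNm = 5000,
                         celluloseFraction = 0.5) {
  new("OpticsConfig", wavelengthNm = wavelengthNm,
      polarizerAnglesDeg = polarizerAnglesDeg, nO = nO, nE = nE,
      sectionThicknessNm = sectionThicknessNm,
      celluloseFraction = celluloseFraction)
}

#' Three co-registered polarization frames plus background
#'
#' Holds one imaging spot: three intensity rasters captured at the polarizer
#' angles of the attached \linkS4class{OpticsConfig}, and a matching
#' background stack (no sample in the beam) used for stray-light correction.
#'
#' @slot frames numeric array h x w x 3 of intensities (>= 0).
#' @slot background numeric array h x w x 3, same shape as \code{frames}.
#' @slot anglesDeg the three polarizer angles, degrees.
#' @exportClass PolarizationStack
setClass("PolarizationStack", representation(
  frames = "array",
  background = "array",
  anglesDeg = "numeric"
))

setValidity("PolarizationStack", function(object) {
  msg <- NULL
  d <- dim(object@frames)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "frames must be an h x w x 3 array")
  if (!identical(dim(object@background), d))
    msg <- c(msg, "background must have the same shape as frames")
  if (length(object@anglesDeg) != 3L)
    msg <- c(msg, "three polarizer angles are required")
  if (any(object@frames < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' Construct a PolarizationStack
#'
#' @param frames h x w x 3 intensity array.
#' @param background h x w x 3 background array; defaults to zeros.
#' @param anglesDeg three polarizer angles in degrees.
#' @return A \linkS4class{PolarizationStack}.
#' @export
polarizationStack <- function(frames, background = NULL,
                              anglesDeg = c(0, 45, 90)) {
  if (is.null(background)) background <- array(0, dim(frames))
  new("PolarizationStack", frames = frames, background = background,
      anglesDeg = anglesDeg)
}

#' Per-pixel retardation and azimuth recovered from a polarization triplet
#'
#' @slot retardationNm retardation map in nm (>= 0 where valid).
#' @slot azimuthDeg slow-axis azimuth map in degrees, stored modulo 180
#'   (optic-axis symmetry); NA where the azimuth is undefined (zero
#'   retardation).
#' @slot meanIntensity transmitted mean-intensity map (I0).
#' @slot validMask logical raster: pixel carries a usable solution.
#' @slot clampedMask logical raster: |sin delta| exceeded 1 and the
#'   retardation was clamped to the quarter-wave bound.
#' @exportClass RetardationResult
setClass("RetardationResult", representation(
  retardationNm = "matrix",
  azimuthDeg = "matrix",
  meanIntensity = "matrix",
  validMask = "matrix",
  clampedMask = "matrix"
))

#' Per-pixel MFA map with wall classes and layer masks
#'
#' @slot mfaDeg microfibril angle map in degrees, range [0, 90]; NA off-wall.
#' @slot wallClass integer raster: 0 none, 1 radial wall, 2 tangential wall.
#' @slot s2Mask,s13Mask logical rasters marking the S2 valley lines and the
#'   S1+S3 ridge lines inside wall bands; disjoint by construction.
#' @slot gaussianFit named numeric (mu, sigma, amplitude) of the Gaussian
#'   fitted to the azimuth histogram peak used to define tangential walls.
#' @exportClass MfaResult
setClass("MfaResult", representation(
  mfaDeg = "matrix",
  wallClass = "matrix",
  s2Mask = "matrix",
  s13Mask = "matrix",
  gaussianFit = "numeric"
))

setValidity("MfaResult", function(object) {
  msg <- NULL
  if (any(object@s2Mask & object@s13Mask))
    msg <- c(msg, "s2Mask and s13Mask must be disjoint")
  s <- object@gaussianFit["sigma"]
  if (!is.na(s) && s <= 0) msg <- c(msg, "sigma must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Ground-truth model of a synthetic wood section
#'
#' Describes one annual ring as a grid of rectangular tracheids with
#' rectangular lumina: \code{nFiles} radial files (rows), each of
#' \code{cellsPerFile} cells ordered earlywood to latewood along the image
#' x axis. Per-position vectors give the radial diameter, wall thickness and
#' per-wall S2 MFA of every cell at that position in its file.
#'
#' @slot nFiles number of radial files.
#' @slot cellsPerFile cells per file (study-scale default 27).
#' @slot radialDiameterUm per-position tracheid radial diameters, um.
#' @slot tangentialDiameterUm per-position tracheid tangential diameters, um.
#' @slot wallThicknessUm per-position (single) wall thickness, um.
#' @slot mfaTangentialDeg,mfaRadialDeg per-position S2 MFA of tangential and
#'   radial walls, degrees in [0, 90).
#' @slot s13MfaDeg MFA assigned to the S1+S3 edge pixels of every wall.
#' @slot rayAfterFile file indices after which a ray band is inserted.
#' @slot rayHeightUm height of a ray band, um.
#' @slot pixelSizeUm raster sampling, um per pixel.
#' @slot sampleRotationDeg rotation of the polarizer frame relative to the
#'   radial axis; tangential walls appear at this azimuth.
#' @slot sectionThicknessNm,celluloseFraction optics of the section.
#' @slot azimuthJitterSd per-pixel Gaussian jitter of true azimuths, degrees.
#' @slot fileDiameterSd fractional sd of the per-file radial-diameter scale
#'   (between-file biological variation; also what makes tile registration
#'   well-posed on an otherwise periodic lattice).
#' @slot fileTangentialSdUm sd of the per-file tangential-diameter offset, um.
#' @slot fileSeed integer seed of the per-file variation; part of the model
#'   so the geometry is a function of the model alone, not of the render
#'   seed.
#' @slot marginPx empty margin around the cell block, px.
#' @exportClass SectionModel
setClass("SectionModel", representation(
  nFiles = "integer",
  cellsPerFile = "integer",
  radialDiameterUm = "numeric",
  tangentialDiameterUm = "numeric",
  wallThicknessUm = "numeric",
  mfaTangentialDeg = "numeric",
  mfaRadialDeg = "numeric",
  s13MfaDeg = "numeric",
  rayAfterFile = "integer",
  rayHeightUm = "numeric",
  pixelSizeUm = "numeric",
  sampleRotationDeg = "numeric",
  sectionThicknessNm = "numeric",
  celluloseFraction = "numeric",
  azimuthJitterSd = "numeric",
  fileDiameterSd = "numeric",
  fileTangentialSdUm = "numeric",
  fileSeed = "integer",
  marginPx = "integer"
))

setValidity("SectionModel", function(object) {
  msg <- NULL
  n <- object@cellsPerFile
  for (nm in c("radialDiameterUm", "tangentialDiameterUm", "wallThicknessUm",
               "mfaTangentialDeg", "mfaRadialDeg")) {
    if (length(slot(object, nm)) != n)
      msg <- c(msg, sprintf("%s must have length cellsPerFile", nm))
  }
  if (any(object@radialDiameterUm <= 0) || any(object@tangentialDiameterUm <= 0) ||
      any(object@wallThicknessUm <= 0))
    msg <- c(msg, "diameters and wall thickness must be > 0")
  if (any(2 * object@wallThicknessUm >= pmin(object@radialDiameterUm,
                                             object@tangentialDiameterUm)))
    msg <- c(msg, "lumen must fit inside the cell outline (2*wall < diameter)")
  mfa <- c(object@mfaTangentialDeg, object@mfaRadialDeg, object@s13MfaDeg)
  if (any(mfa < 0 | mfa >= 90))
    msg <- c(msg, "MFA values must lie in [0, 90)")
  if (any(object@rayAfterFile < 1 | object@rayAfterFile >= object@nFiles))
    msg <- c(msg, "rayAfterFile indices must lie in [1, nFiles)")
  if (is.null(msg)) TRUE else msg
})

#' Rasterized phantom with its ground truth
#'
#' Result of \code{\link{buildSection}}: the label image plus per-cell truth
#' recomputed from the rasterized (pixel-quantized) geometry, so stored truth
#' and the label raster agree exactly.
#'
#' @slot labelImage integer raster; 0 background/ray, k the k-th tracheid.
#' @slot wallMask,lumenMask,rayMask logical rasters.
#' @slot mlMask logical raster: outermost wall pixel layer of every cell
#'   (compound middle lamella), the lignin-rich boundary rendered brightest
#'   under UV excitation.
#' @slot wallClassTrue integer raster: 0 none, 1 radial wall, 2 tangential.
#' @slot mfaTrue per-pixel true MFA, degrees (0 off-wall).
#' @slot azimuthTrue per-pixel true azimuth, degrees mod 180 (NA off-wall).
#' @slot cells data.frame of per-cell truth: label, file, position, centroid,
#'   the seven anatomical parameters (um / um^2) and per-wall S2 MFA.
#' @slot model the generating \linkS4class{SectionModel}.
#' @slot seed integer seed used for the azimuth jitter.
#' @exportClass PhantomTruth
setClass("PhantomTruth", representation(
  labelImage = "matrix",
  wallMask = "matrix",
  lumenMask = "matrix",
  rayMask = "matrix",
  mlMask = "matrix",
  wallClassTrue = "matrix",
  mfaTrue = "matrix",
  azimuthTrue = "matrix",
  cells = "data.frame",
  model = "SectionModel",
  seed = "integer"
))

#' Similarity transform between the POM and FLM frames
#'
#' Maps POM pixel coordinates (x, y) into FLM pixel coordinates through
#' \code{matrix} (3 x 3, homogeneous, row vector convention
#' \code{c(x, y, 1) \%*\% t(matrix)}).
#'
#' @slot scale isotropic scale factor (> 0).
#' @slot rotationDeg in-plane rotation, degrees counterclockwise.
#' @slot translation length-2 numeric (tx, ty) in FLM pixels.
#' @slot matrix 3 x 3 homogeneous transform matrix.
#' @slot peak phase-correlation peak of the final alignment, in [0, 1].
#' @slot inlierCount reserved for keypoint-based estimation; NA for the
#'   spectral estimator used here.
#' @exportClass RegistrationTransform
setClass("RegistrationTransform", representation(
  scale = "numeric",
  rotationDeg = "numeric",
  translation = "numeric",
  matrix = "matrix",
  peak = "numeric",
  inlierCount = "numeric"
))

setValidity("RegistrationTransform", function(object) {
  if (object@scale <= 0) return("scale must be > 0")
  if (abs(det(object@matrix)) < 1e-12) return("matrix must be invertible")
  TRUE
})
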