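#' Accessor generics
#'
#' Small accessor family for the raster-bearing classes; use these instead of
#' reaching into slots.
#'
#' @param object one of the package's S4 objects.
#' @return The corresponding raster, table or value.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("retardation", function(object) standardGeneric("retardation"))
#' @rdname accessors
#' @export
setGeneric("azimuth", function(object) standardGeneric("azimuth"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("mfaMap", function(object) standardGeneric("mfaMap"))
#' @rdname accessors
#' @export
setGeneric("wallClass", function(object) standardGeneric("wallClass"))
#' @rdname accessors
#' @export
setGeneric("s2Mask", function(object) standardGeneric("s2Mask"))
#' @rdname accessors
#' @export
setGeneric("s13Mask", function(object) standardGeneric("s13Mask"))
#' @rdname accessors
#' @export
setGeneric("labelImage", function(object) standardGeneric("labelImage"))
#' @rdname accessors
#' @export
setGeneric("cellTable", function(object) standardGeneric("cellTable"))

#' @rdname accessors
setMethod("retardation", "RetardationResult", function(object) object@retardationNm)
#' @rdname accessors
setMethod("azimuth", "RetardationResult", function(object) object@azimuthDeg)
#' @rdname accessors
setMethod("validMask", "RetardationResult", function(object) object@validMask)
#' @rdname accessors
setMethod("mfaMap", "MfaResult", function(object) object@mfaDeg)
#' @rdname accessors
setMethod("wallClass", "MfaResult", function(object) object@wallClass)
#' @rdname accessors
setMethod("s2Mask", "MfaResult", function(object) object@s2Mask)
#' @rdname accessors
setMethod("s13Mask", "MfaResult", function(object) object@s13Mask)
#' @rdname accessors
setMethod("labelImage", "PhantomTruth", function(object) object@labelImage)
#' @rdname accessors
setMethod("cellTable", "PhantomTruth", function(object) object@cells)

setMethod("show", "OpticsConfig", function(object) {
  cat("OpticsConfig: lambda =", object@wavelengthNm, "nm;",
      "polarizer angles =", paste(object@polarizerAnglesDeg, collapse = "/"),
      "deg\n  nO =", object@nO, ", nE =", object@nE,
      "; t =", object@sectionThicknessNm, "nm; cellulose fraction =",
      object@celluloseFraction, "\n")
})

setMethod("show", "PolarizationStack", function(object) {
  d <- dim(object@frames)
  cat("PolarizationStack:", d[1], "x", d[2], "px, angles",
      paste(object@anglesDeg, collapse = "/"), "deg\n")
})

setMethod("show", "RetardationResult", function(object) {
  d <- dim(object@retardationNm)
  v <- object@retardationNm[object@validMask]
  cat("RetardationResult:", d[1], "x", d[2], "px;",
      sprintf("%.1f%% valid;", 100 * mean(object@validMask)),
      if (length(v)) sprintf("retardation %.2f-%.2f nm", min(v), max(v))
      else "no valid pixels", "\n")
})

setMethod("show", "MfaResult", function(object) {
  cat("MfaResult:", sum(object@wallClass == 2L), "tangential-wall px,",
      sum(object@wallClass == 1L), "radial-wall px;",
      sum(object@s2Mask), "S2 px,", sum(object@s13Mask), "S1+S3 px\n")
  gf <- object@gaussianFit
  cat(sprintf("  azimuth peak: mu = %.2f deg, sigma = %.2f deg\n",
              gf["mu"], gf["sigma"]))
})

setMethod("show", "SectionModel", function(object) {
  cat("SectionModel:", object@nFiles, "files x", object@cellsPerFile,
      "cells;", object@pixelSizeUm, "um/px;",
      length(object@rayAfterFile), "ray band(s)\n")
})

setMethod("show", "PhantomTruth", function(object) {
  d <- dim(object@labelImage)
  cat("PhantomTruth:", d[1], "x", d[2], "px,",
      nrow(object@cells), "cells in", object@model@nFiles, "files\n")
})

setMethod("show", "RegistrationTransform", function(object) {
  cat(sprintf(
    "RegistrationTransform: scale %.4f, rotation %.3f deg, t = (%.1f, %.1f), peak %.3f\n",
    object@scale, object@rotationDeg, object@translation[1],
    object@translation[2], object@peak))
})
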