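#' Retardation of a wall with a given microfibril angle
#'
#' Uniaxial-indicatrix model of a transverse section viewed along the cell
#' axis: cellulose fibrils inclined by the MFA \eqn{\mu} from the section
#' normal present the apparent extraordinary index
#' \deqn{n_e'(\mu) = \frac{n_o n_e}{\sqrt{n_e^2\cos^2\mu + n_o^2\sin^2\mu}},}
#' giving the retardation
#' \deqn{\Gamma(\mu) = t \, f \, [\,n_e'(\mu) - n_o\,]}
#' for section thickness \eqn{t} and cellulose volume fraction \eqn{f}.
#' \eqn{\Gamma} is 0 at \eqn{\mu = 0} (fibrils along the propagation
#' direction show no birefringence) and rises strictly monotonically to
#' \eqn{t f (n_e - n_o)} at 90 degrees.
#'
#' @param mfaDeg MFA in degrees, in [0, 90]; vector or raster.
#' @param optics an \linkS4class{OpticsConfig}.
#' @return Retardation in nm, same shape as \code{mfaDeg}.
#' @seealso \code{\link{retardationToMfa}} for the inverse.
#' @examples
#' op <- opticsConfig()
#' mfaToRetardation(c(0, 45, 90), op)
#' @export
mfaToRetardation <- function(mfaDeg, optics) {
  stopifnot(all(mfaDeg >= 0 & mfaDeg <= 90, na.rm = TRUE))
  mu <- deg2rad(mfaDeg)
  nO <- optics@nO; nE <- optics@nE
  nEff <- nO * nE / sqrt(nE^2 * cos(mu)^2 + nO^2 * sin(mu)^2)
  optics@sectionThicknessNm * optics@celluloseFraction * (nEff - nO)
}

#' Convert retardation to microfibril angle
#'
#' Analytic inverse of \code{\link{mfaToRetardation}} (the map is strictly
#' increasing on [0, 90] degrees, so the inverse is unique). Retardations
#' above \eqn{\Gamma(90^\circ)} are clamped to 90 degrees and counted in the
#' \code{"clamped"} attribute of the result.
#'
#' @param retardationNm retardation in nm, >= 0 (NA propagated).
#' @param optics an \linkS4class{OpticsConfig}.
#' @return MFA in degrees, same shape as the input, with attribute
#'   \code{clamped} giving the number of clamped entries.
#' @examples
#' op <- opticsConfig()
#' retardationToMfa(mfaToRetardation(25, op), op)
#' @export
retardationToMfa <- function(retardationNm, optics) {
  if (any(retardationNm < 0, na.rm = TRUE))
    stop("retardation must be non-negative")
  nO <- optics@nO; nE <- optics@nE
  tf <- optics@sectionThicknessNm * optics@celluloseFraction
  nEff <- retardationNm / tf + nO
  gMax <- tf * (nE - nO)
  clamped <- sum(retardationNm > gMax, na.rm = TRUE)
  nEff <- pmin(nEff, nE)
  # nEff^2 = nO^2 nE^2 / (nE^2 cos^2 mu + nO^2 sin^2 mu)  =>  solve sin^2 mu
  sin2 <- (nE^2 - nO^2 * nE^2 / nEff^2) / (nE^2 - nO^2)
  sin2 <- pmin(pmax(sin2, 0), 1)
  out <- rad2deg(asin(sqrt(sin2)))
  if (is.matrix(retardationNm)) out <- matrix(out, nrow(retardationNm))
  attr(out, "clamped") <- clamped
  out
}

#' Classify wall pixels as radial or tangential from the azimuth histogram
#'
#' The azimuths of all wall pixels are histogrammed in 1-degree bins
#' (circular, period 180). Tangential walls concentrate in one peak (near 45
#' degrees under the default mounting, where the polarizer frame is rotated
#' 45 degrees from the radial axis); a single Gaussian is fitted around the
#' dominant peak and pixels within \code{sigmaMult} fitted sigma of its
#' center (circular distance) are classified tangential, the remaining wall
#' pixels radial.
#'
#' @param azimuthDeg azimuth raster, degrees mod 180 (NA allowed off-wall).
#' @param wallMask logical raster of wall pixels; must be nonempty.
#' @param binWidthDeg histogram bin width, degrees (default 1).
#' @param sigmaMult tangential-wall half-width in fitted sigmas (default 3).
#' @return A list with \code{wallClass} (integer raster: 0 none, 1 radial,
#'   2 tangential) and \code{gaussianFit} (named numeric mu, sigma,
#'   amplitude).
#' @details When the histogram peak is too narrow for a stable nonlinear
#'   fit (a near-degenerate, single-valued azimuth population) the circular
#'   standard deviation inside a 15-degree window around the mode is used,
#'   with a floor of half a bin. A flat histogram (no dominant orientation)
#'   is an error: it usually means the section is mounted so that neither
#'   wall family has a consistent azimuth; check the sample rotation.
#' @export
classifyWalls <- function(azimuthDeg, wallMask, binWidthDeg = 1,
                          sigmaMult = 3) {
  stopifnot(identical(dim(azimuthDeg), dim(wallMask)))
  az <- azimuthDeg[wallMask]
  az <- az[is.finite(az)]
  if (length(az) == 0) stop("wallMask selects no finite azimuths")
  breaks <- seq(0, 180, by = binWidthDeg)
  h <- hist(az %% 180, breaks = breaks, plot = FALSE)
  counts <- h$counts
  mids <- h$mids
  if (max(counts) < 2 * stats::median(counts) || max(counts) < 5)
    stop("azimuth histogram has no dominant peak; check sample_rotation")
  mode <- mids[which.max(counts)]
  # recenter circularly around the mode so the peak is not split at 0/180
  x <- mode + circularDiffDeg(mids, mode)
  win <- abs(x - mode) <= 15
  wsum <- sum(counts[win])
  muW <- sum(x[win] * counts[win]) / wsum
  sdW <- sqrt(sum(counts[win] * (x[win] - muW)^2) / wsum)
  fit <- NULL
  if (sdW >= binWidthDeg / 2) {
    df <- data.frame(x = x, y = counts)
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)), data = df,
                        start = list(A = max(counts), mu = muW,
                                     s = max(sdW, binWidthDeg)),
                        lower = c(0, mode - 90, binWidthDeg / 4),
                        upper = c(Inf, mode + 90, 90)),
      error = function(e) NULL)
  }
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    mu <- as.numeric(cf["mu"]) %% 180
    sigma <- abs(as.numeric(cf["s"]))
    amp <- as.numeric(cf["A"])
  } else {
    mu <- muW %% 180
    sigma <- max(sdW, binWidthDeg / 2)
    amp <- max(counts)
  }
  if (sigmaMult * sigma >= 90)
    stop("azimuth peak too broad to separate wall families ",
         "(3 sigma spans the whole circle); check sample_rotation")
  dist <- abs(circularDiffDeg(azimuthDeg, mu))
  wallClass <- matrix(0L, nrow(wallMask), ncol(wallMask))
  tang <- wallMask & is.finite(azimuthDeg) & dist <= sigmaMult * sigma
  wallClass[wallMask] <- 1L
  wallClass[tang] <- 2L
  list(wallClass = wallClass,
       gaussianFit = c(mu = mu, sigma = sigma, amplitude = amp))
}

# Local-extremum plateaus of a 1-D run: returns medial indices of plateaus
# that are strictly below (minima) or strictly above (maxima) all existing
# neighbors; a plateau spanning the whole run is neither. minProm guards
# against quantization/noise wiggle: the run must span at least minProm and
# a minimum (maximum) must sit at least minProm below the run maximum
# (above the run minimum).
runExtrema <- function(v, minProm = 0) {
  r <- rle(v)
  k <- length(r$values)
  if (k == 0) return(list(min = integer(), max = integer()))
  lo <- min(v); hi <- max(v)
  if (k == 1 || hi - lo < minProm)
    return(list(min = integer(), max = integer()))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  mins <- maxs <- integer()
  for (i in seq_len(k)) {
    left <- if (i > 1) r$values[i - 1] else NA_real_
    right <- if (i < k) r$values[i + 1] else NA_real_
    vi <- r$values[i]
    isMin <- (is.na(left) || vi < left) && (is.na(right) || vi < right) &&
      vi <= hi - minProm
    isMax <- (is.na(left) || vi > left) && (is.na(right) || vi > right) &&
      vi >= lo + minProm
    mid <- floor((starts[i] + ends[i]) / 2)
    if (isMin) mins <- c(mins, mid)
    if (isMax) maxs <- c(maxs, mid)
  }
  list(min = mins, max = maxs)
}

#' Isolate S2 and S1+S3 layer pixels inside wall bands
#'
#' Across the thickness of a double wall the MFA profile is
#' high-low-high-high-low-high: the S2 layer of each cell is a local-minimum
#' valley line and the thin S1/S3 layers merge into local-maximum ridge
#' lines. Wall bands are scanned one-dimensionally along the direction
#' perpendicular to the wall plane -- along image x (rows) for tangential
#' walls and along image y (columns) for radial walls -- and
#' local-extremum plateaus are reduced to their medial pixel. Plateaus that
#' span a whole band (uniform MFA) yield neither mask.
#'
#' @param mfaDeg MFA raster, degrees (NA off-wall is fine).
#' @param wallClass integer raster from \code{\link{classifyWalls}}.
#' @param smoothWindow odd integer; optional running-mean smoothing of the
#'   MFA values along the wall direction (i.e. perpendicular to the scan)
#'   before extremum detection, for noise suppression. 1 disables (default).
#' @param minProminenceDeg smallest MFA contrast (degrees) a valley or
#'   ridge must show against its wall band; runs flatter than this yield no
#'   extrema. Guards against quantization and sensor noise creating
#'   spurious extrema on plateaus (the S2/S1+S3 contrast is an order of
#'   magnitude larger).
#' @return A list with logical rasters \code{s2Mask} and \code{s13Mask},
#'   both subsets of \code{wallClass != 0} and mutually disjoint.
#' @export
detectS2 <- function(mfaDeg, wallClass, smoothWindow = 1,
                     minProminenceDeg = 1) {
  stopifnot(identical(dim(mfaDeg), dim(wallClass)))
  nr <- nrow(mfaDeg); nc <- ncol(mfaDeg)
  s2 <- s13 <- matrix(FALSE, nr, nc)
  scanClass <- function(class, alongRows) {
    mask <- wallClass == class & is.finite(mfaDeg)
    val <- mfaDeg
    if (smoothWindow > 1) {
      # smooth along the wall plane: columns for tangential (vertical) walls,
      # rows for radial (horizontal) walls
      if (alongRows) {               # scan rows => wall runs vertically
        for (j in seq_len(nc)) {
          mj <- mask[, j]
          if (any(mj)) val[, j] <- maskedRunningMean(val[, j], mj, smoothWindow)
        }
      } else {
        for (i in seq_len(nr)) {
          mi <- mask[i, ]
          if (any(mi)) val[i, ] <- maskedRunningMean(val[i, ], mi, smoothWindow)
        }
      }
    }
    nLines <- if (alongRows) nr else nc
    for (i in seq_len(nLines)) {
      lineMask <- if (alongRows) mask[i, ] else mask[, i]
      if (!any(lineMask)) next
      lineVal <- if (alongRows) val[i, ] else val[, i]
      runs <- rle(lineMask)
      pos <- cumsum(runs$lengths)
      start <- pos - runs$lengths + 1
      for (k in which(runs$values)) {
        idx <- start[k]:pos[k]
        if (length(idx) < 2) next
        ex <- runExtrema(lineVal[idx], minProm = minProminenceDeg)
        if (alongRows) {
          s2[i, idx[ex$min]] <<- TRUE
          s13[i, idx[ex$max]] <<- TRUE
        } else {
          s2[idx[ex$min], i] <<- TRUE
          s13[idx[ex$max], i] <<- TRUE
        }
      }
    }
  }
  scanClass(2L, alongRows = TRUE)    # tangential walls: scan along x
  scanClass(1L, alongRows = FALSE)   # radial walls: scan along y
  s13[s2] <- FALSE
  list(s2Mask = s2, s13Mask = s13)
}

#' Assemble an MfaResult from its components
#'
#' Convenience wrapper chaining \code{\link{retardationToMfa}},
#' \code{\link{classifyWalls}} and \code{\link{detectS2}} on an inverted
#' polarization result.
#'
#' @param ret a \linkS4class{RetardationResult}.
#' @param optics an \linkS4class{OpticsConfig}.
#' @param wallMask logical raster of wall pixels; when NULL, valid pixels
#'   with retardation above \code{retFloorNm} are used.
#' @param retFloorNm retardation floor for the default wall mask (nm).
#' @param smoothWindow,minProminenceDeg passed to \code{\link{detectS2}}.
#' @return An \linkS4class{MfaResult}.
#' @export
mfaFromRetardation <- function(ret, optics, wallMask = NULL,
                               retFloorNm = 1, smoothWindow = 1,
                               minProminenceDeg = 1) {
  stopifnot(is(ret, "RetardationResult"))
  g <- retardation(ret)
  if (is.null(wallMask))
    wallMask <- validMask(ret) & is.finite(g) & g > retFloorNm
  mfa <- retardationToMfa(ifelse(is.na(g), 0, g), optics)
  mfa <- matrix(as.numeric(mfa), nrow(g))
  mfa[!wallMask] <- NA_real_
  cls <- classifyWalls(azimuth(ret), wallMask)
  masks <- detectS2(mfa, cls$wallClass, smoothWindow = smoothWindow,
                    minProminenceDeg = minProminenceDeg)
  new("MfaResult", mfaDeg = mfa, wallClass = cls$wallClass,
      s2Mask = masks$s2Mask, s13Mask = masks$s13Mask,
      gaussianFit = cls$gaussianFit)
}
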