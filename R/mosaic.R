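#' Integer translation between two images by phase-only correlation
#'
#' Computes the normalized cross-power spectrum of the two images and takes
#' the location of the peak of its inverse transform as the integer shift.
#' The returned shift (dy, dx) satisfies: content at position p in
#' \code{imageA} appears at p + (dy, dx) in \code{imageB} (circularly).
#' Among the aliased candidates (shifts are defined modulo the raster size)
#' the one closest to \code{nominal} is reported.
#'
#' @param imageA,imageB equal-shaped, non-constant numeric matrices.
#' @param nominal length-2 numeric prior shift used to disambiguate the
#'   circular aliasing; defaults to c(0, 0) (smallest-magnitude shift).
#' @param maxDev optional length-2 window half-width: the peak is searched
#'   only among shifts within \code{maxDev} of \code{nominal} (useful on
#'   periodic scenes, where the global peak can sit one lattice period off
#'   the mechanically plausible shift). NULL searches globally.
#' @return named numeric c(dy, dx, peak); peak in [0, 1] is the correlation
#'   peak height, ~1 for an exact circular shift and near 0 for unrelated
#'   images.
#' @examples
#' a <- matrix(stats::rnorm(64 * 64), 64)
#' pocShift(a, a)   # (0, 0) with peak ~ 1
#' @export
pocShift <- function(imageA, imageB, nominal = c(0, 0), maxDev = NULL) {
  stopifnot(identical(dim(imageA), dim(imageB)))
  if (stats::sd(imageA) == 0 || stats::sd(imageB) == 0)
    stop("constant image: phase spectrum undefined")
  nr <- nrow(imageA); nc <- ncol(imageA)
  Fa <- stats::fft(imageA - mean(imageA))
  Fb <- stats::fft(imageB - mean(imageB))
  Q <- Fa * Conj(Fb)
  mod <- Mod(Q)
  mod[mod < .Machine$double.eps] <- 1
  r <- Re(stats::fft(Q / mod, inverse = TRUE)) / length(Q)
  # peak at index p means B is A rolled by -p: shift candidates per axis are
  # the two circular representatives of -p
  allowed <- function(p, n, nom, dev) {
    cand <- cbind((-p) %% n, (-p) %% n - n)
    apply(abs(cand - nom) <= dev, 1, any)
  }
  if (!is.null(maxDev)) {
    py <- 0:(nr - 1); px <- 0:(nc - 1)
    okY <- allowed(py, nr, nominal[1], maxDev[1])
    okX <- allowed(px, nc, nominal[2], maxDev[2])
    r[!okY, ] <- -Inf
    r[, !okX] <- -Inf
  }
  i <- which.max(r)
  p0 <- c(((i - 1) %% nr), ((i - 1) %/% nr))
  pick <- function(p, n, nom) {
    cand <- c((-p) %% n, (-p) %% n - n)
    cand[which.min(abs(cand - nom))]
  }
  c(dy = pick(p0[1], nr, nominal[1]), dx = pick(p0[2], nc, nominal[2]),
    peak = max(r))
}

#' Stitch an overlapping tile grid into one mosaic
#'
#' Tiles are given row-major on a rows x cols grid with a known nominal
#' overlap. The shift of each tile relative to its left (or, for the first
#' column, top) neighbor is measured by \code{\link{pocShift}} seeded with
#' the nominal stride, and offsets are composed greedily row-major from the
#' origin tile. A measured shift deviating from nominal by more than 25% of
#' the tile size is discarded and the nominal stride used, with the tile
#' index flagged. Overlapping pixels are resolved last-write in row-major
#' order.
#'
#' @param tiles row-major list of equal-shaped matrices.
#' @param gridShape c(rows, cols); \code{prod(gridShape)} must equal
#'   \code{length(tiles)}.
#' @param overlap nominal overlap fraction (> 0 when the grid has more than
#'   one tile).
#' @return list: \code{mosaic} (matrix), \code{offsets} (0-based integer
#'   n x 2 dy/dx, normalized to start at 0), \code{flagged} (indices of
#'   tiles that fell back to the nominal stride).
#' @seealso \code{\link{stitchWithOffsets}} to paint further channels with
#'   the same offsets.
#' @export
stitchTiles <- function(tiles, gridShape, overlap) {
  gr <- gridShape[1]; gc <- gridShape[2]
  stopifnot(length(tiles) == gr * gc)
  th <- nrow(tiles[[1]]); tw <- ncol(tiles[[1]])
  if (gr * gc > 1 && overlap <= 0) stop("nominal overlap must be > 0")
  sy <- round(th * (1 - overlap)); sx <- round(tw * (1 - overlap))
  off <- matrix(0, gr * gc, 2)
  flagged <- integer()
  idx <- function(r, c) (r - 1) * gc + c
  for (r in seq_len(gr)) for (c in seq_len(gc)) {
    i <- idx(r, c)
    if (r == 1 && c == 1) next
    if (c > 1) {
      ref <- idx(r, c - 1); nom <- c(0, sx)
    } else {
      ref <- idx(r - 1, c); nom <- c(sy, 0)
    }
    s <- tryCatch(
      pocShift(tiles[[ref]], tiles[[i]], nominal = -nom,
               maxDev = 0.2 * c(th, tw)),
      error = function(e) c(dy = -nom[1], dx = -nom[2], peak = 0))
    rel <- -s[1:2]   # tile content appears shifted by -measured in scene
    if (max(abs(rel - nom) / c(th, tw)) > 0.25) {
      rel <- nom
      flagged <- c(flagged, i)
    }
    off[i, ] <- off[ref, ] + rel
  }
  off[, 1] <- off[, 1] - min(off[, 1])
  off[, 2] <- off[, 2] - min(off[, 2])
  off <- round(off)
  list(mosaic = stitchWithOffsets(tiles, off),
       offsets = matrix(as.integer(off), ncol = 2,
                        dimnames = list(NULL, c("dy", "dx"))),
       flagged = flagged)
}

#' Paint tiles onto a canvas at given offsets
#'
#' Applies offsets (for instance those estimated once by
#' \code{\link{stitchTiles}} on one modality) to any other channel captured
#' on the same grid; overlaps are last-write in list order.
#'
#' @param tiles row-major list of equal-shaped matrices.
#' @param offsets 0-based integer n x 2 (dy, dx) top-left positions.
#' @return The stitched matrix.
#' @export
stitchWithOffsets <- function(tiles, offsets) {
  th <- nrow(tiles[[1]]); tw <- ncol(tiles[[1]])
  H <- max(offsets[, 1]) + th; W <- max(offsets[, 2]) + tw
  mosaic <- matrix(0, H, W)
  for (i in seq_along(tiles)) {
    mosaic[(offsets[i, 1] + 1):(offsets[i, 1] + th),
           (offsets[i, 2] + 1):(offsets[i, 2] + tw)] <- tiles[[i]]
  }
  mosaic
}

# Embed a matrix centered in an N x N canvas with a Hann window applied.
hannEmbed <- function(img, N) {
  img <- img - mean(img)
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(nrow(img)) - 1) / (nrow(img) - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ncol(img)) - 1) / (ncol(img) - 1))
  img <- img * outer(wr, wc)
  out <- matrix(0, N, N)
  r0 <- floor((N - nrow(img)) / 2); c0 <- floor((N - ncol(img)) / 2)
  out[r0 + seq_len(nrow(img)), c0 + seq_len(ncol(img))] <- img
  out
}

# fft magnitude, zero-frequency centered, lightly high-pass filtered.
centeredLogSpectrum <- function(img) {
  N <- nrow(img)
  m <- Mod(stats::fft(img))
  m <- rollMatrix(m, N / 2, N / 2)
  f <- (seq_len(N) - 1 - N / 2) / N
  rad2 <- outer(f^2, f^2, "+")
  hp <- 1 - cos(pi * pmin(sqrt(rad2) / 0.5, 1))^2  # suppress DC region
  log1p(m) * hp
}

# Sample a centered spectrum on a (log-radius x angle) grid; angles cover
# [0, 180) (the magnitude spectrum is centrosymmetric).
logPolarSample <- function(spec, nAngle = 256, nRad = 256) {
  N <- nrow(spec)
  ctr <- N / 2 + 1
  rMax <- N / 2 - 1
  logBase <- exp(log(rMax) / nRad)
  rad <- logBase^(seq_len(nRad))
  ang <- pi * (seq_len(nAngle) - 1) / nAngle
  rr <- outer(rad, sin(ang))   # row offset
  cc <- outer(rad, cos(ang))
  v <- bilinearSample(spec, row = ctr + as.vector(rr),
                      col = ctr + as.vector(cc), fill = 0)
  list(lp = matrix(v, nRad, nAngle), logBase = logBase,
       angleStep = 180 / nAngle)
}

# Phase-correlation peak value between imgMov warped by (scale, rot, t) and
# imgRef; helper for the refinement search.
similarityPeak <- function(imgMov, imgRef, scale, rotationDeg) {
  ctrM <- c(ncol(imgMov), nrow(imgMov)) / 2
  ctrR <- c(ncol(imgRef), nrow(imgRef)) / 2
  M <- similarityMatrix(scale, rotationDeg, centerSrc = ctrM,
                        centerDst = ctrR)
  w <- warpBySimilarity(imgMov, M, dim(imgRef))
  s <- tryCatch(pocShift(w, imgRef), error = function(e) c(0, 0, peak = 0))
  list(peak = s[["peak"]], shift = s[1:2], matrix = M)
}

#' Register a POM mosaic onto an FLM mosaic by a similarity transform
#'
#' Estimates the scale, rotation and translation mapping polarized-light
#' (POM) mosaic coordinates into fluorescence (FLM) mosaic coordinates.
#' Rotation and scale are recovered from the log-polar resampled magnitude
#' spectra of the two images by phase correlation (rotation becomes an
#' angular shift, scale a log-radial shift), refined by a local search
#' maximizing the spatial phase-correlation peak; the residual translation
#' then comes from one final phase correlation. This spectral estimator is
#' scale- and rotation-invariant by construction and needs no keypoints, so
#' \code{inlierCount} is reported as NA.
#'
#' @param pomMosaic,flmMosaic numeric matrices covering a common region
#'   (possibly at different magnification).
#' @param maxScale largest scale ratio searched (either direction).
#' @param minPeak minimum acceptable final phase-correlation peak; below it
#'   the registration is considered failed.
#' @return A \linkS4class{RegistrationTransform} mapping POM (x, y) pixel
#'   coordinates into FLM pixel coordinates.
#' @export
registerImages <- function(pomMosaic, flmMosaic, maxScale = 8,
                           minPeak = 0.02) {
  # pure-translation fast path
  if (identical(dim(pomMosaic), dim(flmMosaic))) {
    s <- tryCatch(pocShift(pomMosaic, flmMosaic),
                  error = function(e) c(dy = 0, dx = 0, peak = 0))
    if (s[["peak"]] > 0.25) {
      M <- similarityMatrix(1, 0, tx = s[["dx"]], ty = s[["dy"]])
      return(new("RegistrationTransform", scale = 1, rotationDeg = 0,
                 translation = c(s[["dx"]], s[["dy"]]), matrix = M,
                 peak = s[["peak"]], inlierCount = NA_real_))
    }
  }
  # rotation/scale search runs on downsampled working copies; only the
  # final translation estimate touches the full-resolution rasters
  fP <- max(1, ceiling(max(dim(pomMosaic)) / 384))
  fF <- max(1, ceiling(max(dim(flmMosaic)) / 384))
  pomW <- blockMean(pomMosaic, fP); flmW <- blockMean(flmMosaic, fF)
  N <- 2^ceiling(log2(max(dim(pomW), dim(flmW), 128)))
  spPom <- centeredLogSpectrum(hannEmbed(pomW, N))
  spFlm <- centeredLogSpectrum(hannEmbed(flmW, N))
  lpP <- logPolarSample(spPom); lpF <- logPolarSample(spFlm)
  pc <- tryCatch(pocShift(lpP$lp, lpF$lp),
                 error = function(e) c(dy = 0, dx = 0, peak = 0))
  # angular axis is dim 2, radial axis dim 1 of the log-polar image;
  # a spatial scale s scales the spectrum by 1/s, so the log-radial shift
  # maps to scale, the angular shift to rotation (sign fixed by the warp
  # refinement below, which also absorbs any residual bias)
  dAng <- pc[["dx"]] * lpP$angleStep
  scale0 <- lpP$logBase^pc[["dy"]]
  cand <- expand.grid(
    scale = unique(c(scale0, 1 / scale0) *
                     rep(c(1, 1 / lpP$logBase^2, lpP$logBase^2), each = 2)),
    rot = c(dAng, -dAng, dAng + 90, dAng - 90))
  cand$rot <- ((cand$rot + 90) %% 180) - 90
  candScaleTrue <- cand$scale * fF / fP
  cand <- cand[candScaleTrue > 1 / maxScale & candScaleTrue < maxScale, ]
  cand <- unique(rbind(cand, data.frame(scale = fP / fF, rot = 0)))
  best <- NULL
  for (i in seq_len(nrow(cand))) {
    r <- similarityPeak(pomW, flmW, cand$scale[i], cand$rot[i])
    if (is.null(best) || r$peak > best$peak) {
      best <- r; best$scale <- cand$scale[i]; best$rot <- cand$rot[i]
    }
  }
  obj <- function(p) {
    -similarityPeak(pomW, flmW, exp(p[1]), p[2])$peak
  }
  opt <- stats::optim(c(log(best$scale), best$rot), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 100, reltol = 1e-6))
  scale <- exp(opt$par[1]) * fF / fP; rot <- opt$par[2]
  fin <- similarityPeak(pomMosaic, flmMosaic, scale, rot)
  if (fin$peak < minPeak)
    stop(sprintf(
      "registration failed: peak %.4f below %.3f (scale %.3f, rot %.2f deg)",
      fin$peak, minPeak, scale, rot))
  ctrM <- c(ncol(pomMosaic), nrow(pomMosaic)) / 2
  ctrR <- c(ncol(flmMosaic), nrow(flmMosaic)) / 2
  M <- similarityMatrix(scale, rot, tx = fin$shift[["dx"]],
                        ty = fin$shift[["dy"]],
                        centerSrc = ctrM, centerDst = ctrR)
  new("RegistrationTransform", scale = scale, rotationDeg = rot,
      translation = c(fin$shift[["dx"]], fin$shift[["dy"]]), matrix = M,
      peak = fin$peak, inlierCount = NA_real_)
}
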