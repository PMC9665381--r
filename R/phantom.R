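# Synthetic section phantom: a known ground-truth ring rendered into the
# same modalities the microscopes produce, so every pipeline stage can be
# validated against analytic truth.

withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv())) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

logisticRamp <- function(t, center, width) 1 / (1 + exp(-(t - center) / width))

#' Construct a SectionModel
#'
#' Builds the ground-truth description of one annual ring. Defaults emulate
#' the study scale of a mature ring of a model softwood: 16 radial files of
#' 27 tracheids, an earlywood plateau of wide thin-walled cells followed by
#' a logistic transition to narrow thick-walled latewood, constant
#' tangential diameter, a linear S2 MFA ramp from 20 to 10 degrees across
#' the ring on both wall families, an S1+S3 edge MFA of 35 degrees, and two
#' one-cell-tall ray bands.
#'
#' @param nFiles number of radial files (rows).
#' @param cellsPerFile tracheids per file, earlywood to latewood.
#' @param radialDiameterUm per-position radial diameters, um (recycled
#'   default: 35 um earlywood to 12 um latewood, logistic transition).
#' @param tangentialDiameterUm per-position tangential diameters, um.
#' @param wallThicknessUm per-position single-wall thickness, um.
#' @param mfaTangentialDeg,mfaRadialDeg per-position S2 MFA, degrees.
#' @param s13MfaDeg MFA of the S1+S3 wall-edge pixels, degrees.
#' @param rayAfterFile file indices after which a ray band is inserted.
#' @param rayHeightUm ray band height, um.
#' @param pixelSizeUm raster sampling, um/px.
#' @param sampleRotationDeg polarizer-frame rotation; tangential walls show
#'   this azimuth (default 45).
#' @param sectionThicknessNm,celluloseFraction optical parameters.
#' @param azimuthJitterSd per-pixel sd of azimuth jitter, degrees.
#' @param fileDiameterSd fractional sd of the per-file radial-diameter
#'   scale factor (clamped at two sd); 0 gives a strictly periodic lattice.
#' @param fileTangentialSdUm sd of the per-file tangential-diameter offset,
#'   um (clamped at two sd).
#' @param fileSeed seed of the per-file variation draws; a model property,
#'   so the rasterized geometry depends on the model alone and the
#'   \code{\link{buildSection}} seed only drives the azimuth jitter.
#' @param marginPx empty margin around the cell block.
#' @return A \linkS4class{SectionModel}.
#' @examples
#' sectionModel(nFiles = 4, cellsPerFile = 8)
#' @export
sectionModel <- function(nFiles = 16, cellsPerFile = 27,
                         radialDiameterUm = NULL,
                         tangentialDiameterUm = 30,
                         wallThicknessUm = NULL,
                         mfaTangentialDeg = NULL,
                         mfaRadialDeg = NULL,
                         s13MfaDeg = 35,
                         rayAfterFile = NULL,
                         rayHeightUm = 15,
                         pixelSizeUm = 0.5,
                         sampleRotationDeg = 45,
                         sectionThicknessNm = 5000,
                         celluloseFraction = 0.5,
                         azimuthJitterSd = 2,
                         fileDiameterSd = 0.02,
                         fileTangentialSdUm = 1.5,
                         fileSeed = 42L,
                         marginPx = 8L) {
  n <- as.integer(cellsPerFile)
  t <- if (n > 1) (seq_len(n) - 1) / (n - 1) else 0
  if (is.null(radialDiameterUm))
    radialDiameterUm <- 35 - 23 * logisticRamp(t, 0.70, 0.08)
  if (is.null(wallThicknessUm))
    wallThicknessUm <- 2 + 1.5 * logisticRamp(t, 0.75, 0.06)
  if (is.null(mfaTangentialDeg))
    mfaTangentialDeg <- 20 - 10 * t
  if (is.null(mfaRadialDeg))
    mfaRadialDeg <- mfaTangentialDeg
  if (is.null(rayAfterFile))
    rayAfterFile <- if (nFiles >= 12) c(5L, 11L) else integer()
  rep_n <- function(x) if (length(x) == 1) rep(x, n) else x
  new("SectionModel",
      nFiles = as.integer(nFiles), cellsPerFile = n,
      radialDiameterUm = rep_n(radialDiameterUm),
      tangentialDiameterUm = rep_n(tangentialDiameterUm),
      wallThicknessUm = rep_n(wallThicknessUm),
      mfaTangentialDeg = rep_n(mfaTangentialDeg),
      mfaRadialDeg = rep_n(mfaRadialDeg),
      s13MfaDeg = s13MfaDeg,
      rayAfterFile = as.integer(rayAfterFile),
      rayHeightUm = rayHeightUm,
      pixelSizeUm = pixelSizeUm,
      sampleRotationDeg = sampleRotationDeg,
      sectionThicknessNm = sectionThicknessNm,
      celluloseFraction = celluloseFraction,
      azimuthJitterSd = azimuthJitterSd,
      fileDiameterSd = fileDiameterSd,
      fileTangentialSdUm = fileTangentialSdUm,
      fileSeed = as.integer(fileSeed),
      marginPx = as.integer(marginPx))
}

#' Rasterize a SectionModel into a phantom with ground truth
#'
#' Cells are rendered as axis-aligned rectangles with rectangular lumina;
#' the geometry is quantized to whole pixels first and all stored truth is
#' recomputed from the quantized geometry, so truth tables and the label
#' raster agree exactly. Wall pixels closer to a vertical cell border than
#' to a horizontal one are tangential class, the rest radial; the outermost
#' and innermost wall pixel layer carries the S1+S3 MFA, the core the
#' position's S2 MFA. True azimuths are the wall-family azimuth (sample
#' rotation for tangential, +90 for radial) plus seeded Gaussian jitter.
#'
#' @param model a valid \linkS4class{SectionModel}.
#' @param seed integer seed for the azimuth jitter (geometry is
#'   deterministic regardless).
#' @return A \linkS4class{PhantomTruth}.
#' @examples
#' tr <- buildSection(sectionModel(nFiles = 2, cellsPerFile = 3,
#'   rayAfterFile = integer()), seed = 1)
#' nrow(cellTable(tr))
#' @export
buildSection <- function(model, seed = 1L) {
  validObject(model)
  ps <- model@pixelSizeUm
  n <- model@cellsPerFile
  nF <- model@nFiles
  clamp2sd <- function(x, s) pmin(pmax(x, -2 * s), 2 * s)
  eF <- uF <- rep(0, nF)
  if (model@fileDiameterSd > 0 || model@fileTangentialSdUm > 0) {
    z <- withSeed(model@fileSeed, stats::rnorm(2 * nF))
    eF <- clamp2sd(z[seq_len(nF)] * model@fileDiameterSd,
                   model@fileDiameterSd)
    uF <- clamp2sd(z[nF + seq_len(nF)] * model@fileTangentialSdUm,
                   model@fileTangentialSdUm)
  }
  # per-file quantized geometry: rows = files, cols = positions
  drPx <- t(vapply(seq_len(nF), function(f)
    as.integer(round(model@radialDiameterUm * (1 + eF[f]) / ps)),
    integer(n)))
  dtPx <- as.integer(round((mean(model@tangentialDiameterUm) + uF) / ps))
  wPx <- pmax(1L, as.integer(round(model@wallThicknessUm / ps)))
  tooSmall <- sweep(pmin(drPx, matrix(dtPx, nF, n)), 2, 2 * wPx, "<=")
  if (any(tooSmall)) {
    idx <- which(tooSmall, arr.ind = TRUE)
    stop("lumen does not fit for cell(s) at file/position ",
         paste(sprintf("%d/%d", idx[, 1], idx[, 2]), collapse = ", "),
         " after pixel quantization")
  }
  rayPx <- max(1L, round(model@rayHeightUm / ps))
  m <- model@marginPx
  W <- 2L * m + max(rowSums(drPx))
  fileTop <- integer(nF)
  y <- m
  rayTop <- integer(0)
  for (f in seq_len(nF)) {
    fileTop[f] <- y
    y <- y + dtPx[f]
    if (f %in% model@rayAfterFile) {
      rayTop <- c(rayTop, y)
      y <- y + rayPx
    }
  }
  H <- y + m
  x0 <- cbind(m, m + t(apply(drPx, 1, cumsum)))[, seq_len(n), drop = FALSE]

  labels <- matrix(0L, H, W)
  wall <- lumen <- ray <- ml <- matrix(FALSE, H, W)
  wcls <- matrix(0L, H, W)
  mfa <- matrix(0, H, W)
  azBase <- matrix(NA_real_, H, W)

  for (rt in rayTop) ray[(rt + 1):(rt + rayPx), ] <- TRUE

  for (f in seq_len(model@nFiles)) {
    for (j in seq_len(n)) {
      lab <- (f - 1L) * n + j
      dr <- drPx[f, j]; dt <- dtPx[f]
      rows <- (fileTop[f] + 1):(fileTop[f] + dt)
      cols <- (x0[f, j] + 1):(x0[f, j] + dr)
      labels[rows, cols] <- lab
      # local distances to outer borders
      i <- seq_len(dt) - 1
      jj <- seq_len(dr) - 1
      dTB <- pmin(i, dt - 1 - i)        # distance to horizontal border
      dLR <- pmin(jj, dr - 1 - jj)      # distance to vertical border
      dTBm <- matrix(dTB, dt, dr)
      dLRm <- matrix(dLR, dt, dr, byrow = TRUE)
      w <- wPx[j]
      isWall <- dLRm < w | dTBm < w
      isTang <- isWall & (dLRm <= dTBm)
      dWall <- ifelse(isTang, dLRm, dTBm)
      isEdge <- isWall & (dWall == 0 | dWall == w - 1)
      cm <- matrix(0, dt, dr)
      cm[isWall & !isTang] <- model@mfaRadialDeg[j]
      cm[isWall & isTang] <- model@mfaTangentialDeg[j]
      cm[isEdge & w >= 3] <- model@s13MfaDeg
      am <- matrix(NA_real_, dt, dr)
      am[isTang] <- model@sampleRotationDeg
      am[isWall & !isTang] <- model@sampleRotationDeg + 90
      wall[rows, cols] <- isWall
      lumen[rows, cols] <- !isWall
      ml[rows, cols] <- dWall == 0 & isWall
      wcls[rows, cols][isTang] <- 2L
      wcls[rows, cols][isWall & !isTang] <- 1L
      mfa[rows, cols] <- cm
      azBase[rows, cols] <- am
    }
  }
  azim <- azBase
  if (model@azimuthJitterSd > 0) {
    idx <- which(!is.na(azBase))
    jit <- withSeed(seed, stats::rnorm(length(idx), 0, model@azimuthJitterSd))
    azim[idx] <- (azBase[idx] + jit) %% 180
  } else azim <- azBase %% 180

  # per-cell truth from the quantized geometry
  pairHalf <- (wPx[-1] + wPx[-n]) / 2          # half double-wall per pair
  thick <- vapply(seq_len(n), function(j) {
    v <- c(if (j > 1) pairHalf[j - 1], if (j < n) pairHalf[j])
    mean(v)
  }, numeric(1)) * ps
  cells <- do.call(rbind, lapply(seq_len(nF), function(f) {
    lumR <- drPx[f, ] - 2 * wPx
    lumT <- dtPx[f] - 2 * wPx
    data.frame(
      position = seq_len(n),
      label = (f - 1L) * n + seq_len(n),
      file = f,
      centroidRow = fileTop[f] + (dtPx[f] + 1) / 2,
      centroidCol = x0[f, ] + (drPx[f, ] + 1) / 2,
      tracheidTransverseAreaUm2 = drPx[f, ] * dtPx[f] * ps^2,
      lumenTransverseAreaUm2 = lumR * lumT * ps^2,
      tracheidRadialDiameterUm = drPx[f, ] * ps,
      lumenRadialDiameterUm = lumR * ps,
      tracheidTangentialDiameterUm = dtPx[f] * ps,
      tangentialWallThicknessUm = thick,
      mfaS2TangentialDeg = model@mfaTangentialDeg,
      mfaS2RadialDeg = model@mfaRadialDeg
    )
  }))
  cells$cellWallAreaUm2 <- cells$tracheidTransverseAreaUm2 -
    cells$lumenTransverseAreaUm2
  cells$cellWallOccupancy <- cells$cellWallAreaUm2 /
    cells$tracheidTransverseAreaUm2
  ord <- c("label", "file", "position", "centroidRow", "centroidCol",
           "tracheidTransverseAreaUm2", "lumenTransverseAreaUm2",
           "cellWallAreaUm2", "cellWallOccupancy",
           "tracheidRadialDiameterUm", "lumenRadialDiameterUm",
           "tracheidTangentialDiameterUm", "tangentialWallThicknessUm",
           "mfaS2RadialDeg", "mfaS2TangentialDeg")
  cells <- cells[order(cells$label), ord]
  rownames(cells) <- NULL
  new("PhantomTruth", labelImage = labels, wallMask = wall,
      lumenMask = lumen, rayMask = ray, mlMask = ml, wallClassTrue = wcls,
      mfaTrue = mfa, azimuthTrue = azim, cells = cells, model = model,
      seed = as.integer(seed))
}

#' Render fluorescence micrographs of a phantom
#'
#' The UV-excitation channel is bright on lignified walls -- brightest on
#' the lignin-rich compound middle lamella between cells -- and dark in
#' lumina and background; the green-excitation channel is bright only on
#' ray bands. Optional Gaussian blur emulates the point-spread function,
#' and additive Gaussian sensor noise (clipped to [0, 1]) is applied per
#' channel.
#'
#' @param truth a \linkS4class{PhantomTruth}.
#' @param noiseSd sd of additive Gaussian noise (intensity units; full
#'   scale is 1).
#' @param blurSigma Gaussian PSF sigma in px (0 = none).
#' @param seed integer seed for the noise.
#' @return list with matrices \code{uv} and \code{green} in [0, 1].
#' @export
renderFluorescence <- function(truth, noiseSd = 0, blurSigma = 0, seed = 1L) {
  uv <- 0.15 + 0.55 * truth@wallMask + 0.25 * truth@mlMask
  green <- 0.75 * truth@rayMask
  if (blurSigma > 0) {
    uv <- as.matrix(EBImage::gblur(uv, sigma = blurSigma))
    green <- as.matrix(EBImage::gblur(green, sigma = blurSigma))
  }
  if (noiseSd > 0) {
    nz <- withSeed(seed, stats::rnorm(2 * length(uv), 0, noiseSd))
    uv <- uv + matrix(nz[seq_along(uv)], nrow(uv))
    green <- green + matrix(nz[length(uv) + seq_along(uv)], nrow(uv))
    uv <- pmin(pmax(uv, 0), 1)
    green <- pmin(pmax(green, 0), 1)
  }
  list(uv = uv, green = green)
}

# Cut a raster into an overlapping tile grid. Returns tiles (row-major
# list), integer offsets (top-left, 0-based, n x 2 as dy dx) and tile dim.
cutTiles <- function(raster, gridShape, overlap = 0.66, jitterPx = 0,
                     seed = 1L) {
  nr <- nrow(raster); nc <- ncol(raster)
  gr <- gridShape[1]; gc <- gridShape[2]
  th <- min(nr, ceiling(nr / (1 + (gr - 1) * (1 - overlap))))
  tw <- min(nc, ceiling(nc / (1 + (gc - 1) * (1 - overlap))))
  sy <- if (gr > 1) floor((nr - th) / (gr - 1)) else 0L
  sx <- if (gc > 1) floor((nc - tw) / (gc - 1)) else 0L
  off <- as.matrix(expand.grid(dx = (0:(gc - 1)) * sx,
                               dy = (0:(gr - 1)) * sy))[, c("dy", "dx")]
  off <- matrix(as.integer(off), ncol = 2,
                dimnames = list(NULL, c("dy", "dx")))
  # row-major ordering (row index fastest within a row of the grid)
  ord <- order(off[, 1], off[, 2])
  off <- off[ord, , drop = FALSE]
  if (jitterPx > 0) {
    jit <- withSeed(seed, matrix(sample(-jitterPx:jitterPx,
                                        2 * nrow(off), replace = TRUE),
                                 ncol = 2))
    jit[1, ] <- 0L
    off[, 1] <- pmin(pmax(off[, 1] + jit[, 1], 0L), nr - th)
    off[, 2] <- pmin(pmax(off[, 2] + jit[, 2], 0L), nc - tw)
  }
  tiles <- lapply(seq_len(nrow(off)), function(i) {
    raster[(off[i, 1] + 1):(off[i, 1] + th),
           (off[i, 2] + 1):(off[i, 2] + tw), drop = FALSE]
  })
  list(tiles = tiles, offsets = off, tileDim = c(th, tw),
       gridShape = c(gr, gc))
}

#' Render polarization micrograph tiles of a phantom
#'
#' Forward-models the three-frame polarization acquisition from the
#' phantom's true MFA and azimuth maps: per-pixel retardation through
#' \code{\link{mfaToRetardation}}, frame intensities through
#' \code{\link{polForward}}, then tiling with the stated overlap (plus
#' optional seeded integer jitter of the tile origins), per-tile additive
#' Gaussian noise, and matching background tiles (no sample: background
#' offset plus noise).
#'
#' @param truth a \linkS4class{PhantomTruth}.
#' @param optics an \linkS4class{OpticsConfig}; defaults to the phantom's
#'   section thickness and cellulose fraction.
#' @param tileGrid NULL for a single full-frame stack, or c(rows, cols).
#' @param overlap nominal tile overlap fraction (default 0.66).
#' @param noiseSd sd of additive Gaussian noise, intensity units.
#' @param meanIntensity transmitted mean intensity I0, arbitrary units.
#' @param background stray-light offset added to every frame.
#' @param jitterPx max absolute integer jitter of tile origins.
#' @param pixelScale integer block-averaging factor applied to the rendered
#'   maps first (coarser sampling), for registration scenarios.
#' @param rotationDeg rigid rotation of the scene (and of the azimuths)
#'   before rendering, degrees CCW, for registration scenarios.
#' @param seed integer seed for jitter and noise.
#' @return list: \code{stacks} (list of \linkS4class{PolarizationStack}),
#'   \code{offsets} (0-based dy/dx of each tile), \code{tileDim},
#'   \code{gridShape}, \code{overlap}, and the clean full-frame
#'   \code{retardation} and \code{azimuth} maps actually rendered.
#' @export
renderPolarization <- function(truth, optics = NULL, tileGrid = NULL,
                               overlap = 0.66, noiseSd = 0,
                               meanIntensity = 1000, background = 50,
                               jitterPx = 0, pixelScale = 1, rotationDeg = 0,
                               seed = 1L) {
  model <- truth@model
  if (is.null(optics))
    optics <- opticsConfig(sectionThicknessNm = model@sectionThicknessNm,
                           celluloseFraction = model@celluloseFraction)
  gamma <- mfaToRetardation(truth@mfaTrue, optics)
  az <- truth@azimuthTrue
  az[is.na(az)] <- 0
  if (rotationDeg != 0) {
    ctr <- c(ncol(gamma), nrow(gamma)) / 2
    M <- similarityMatrix(1, rotationDeg, centerSrc = ctr, centerDst = ctr)
    gamma <- warpBySimilarity(gamma, M, dim(gamma))
    az <- (warpBySimilarity(az, M, dim(az)) + rotationDeg) %% 180
  }
  if (pixelScale > 1) {
    gamma <- blockMean(gamma, pixelScale)
    az <- blockMean(az, pixelScale)
  }
  nAmbig <- sum(gamma > optics@wavelengthNm / 4)
  if (nAmbig > 0)
    warning(nAmbig, " pixel(s) exceed the unambiguous retardation range")
  frames <- polForward(gamma, az, meanIntensity, optics, background)
  if (is.null(tileGrid)) {
    tilesPerFrame <- lapply(1:3, function(k) list(frames[, , k]))
    offsets <- matrix(0L, 1, 2, dimnames = list(NULL, c("dy", "dx")))
    tileDim <- dim(gamma); gridShape <- c(1L, 1L)
  } else {
    c1 <- cutTiles(frames[, , 1], tileGrid, overlap, jitterPx, seed)
    tilesPerFrame <- list(c1$tiles,
                          lapply(seq_len(nrow(c1$offsets)), function(i)
                            frames[(c1$offsets[i, 1] + 1):(c1$offsets[i, 1] + c1$tileDim[1]),
                                   (c1$offsets[i, 2] + 1):(c1$offsets[i, 2] + c1$tileDim[2]), 2]),
                          lapply(seq_len(nrow(c1$offsets)), function(i)
                            frames[(c1$offsets[i, 1] + 1):(c1$offsets[i, 1] + c1$tileDim[1]),
                                   (c1$offsets[i, 2] + 1):(c1$offsets[i, 2] + c1$tileDim[2]), 3]))
    offsets <- c1$offsets; tileDim <- c1$tileDim; gridShape <- c1$gridShape
  }
  nT <- nrow(offsets)
  stacks <- withSeed(seed + 1L, lapply(seq_len(nT), function(i) {
    fr <- array(0, c(tileDim, 3))
    bg <- array(background, c(tileDim, 3))
    for (k in 1:3) {
      tk <- tilesPerFrame[[k]][[i]]
      if (noiseSd > 0)
        tk <- tk + matrix(stats::rnorm(length(tk), 0, noiseSd), nrow(tk))
      fr[, , k] <- pmax(tk, 0)
    }
    if (noiseSd > 0)
      bg <- pmax(bg + array(stats::rnorm(length(bg), 0, noiseSd), dim(bg)), 0)
    polarizationStack(fr, bg, optics@polarizerAnglesDeg)
  }))
  list(stacks = stacks, offsets = offsets, tileDim = tileDim,
       gridShape = gridShape, overlap = overlap, optics = optics,
       retardation = gamma, azimuth = az)
}
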