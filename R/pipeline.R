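# End-to-end orchestration: phantom dataset emission and the full
# tiles-to-statistics pipeline, both as plain functions so every stage stays
# independently callable.

INTENSITY_SCALE <- 65535   # stored TIFF intensities are counts / this
RETARDATION_SCALE <- 256   # stored retardation TIFFs are nm / this

writeGray <- function(m, path, scale = 1) {
  tiff::writeTIFF(pmin(pmax(m / scale, 0), 1), path,
                  bits.per.sample = 16L, compression = "none")
}

#' Emit a phantom dataset to disk
#'
#' Builds a phantom, renders polarization tiles (with matching background
#' tiles), UV and green fluorescence tiles, and writes the directory layout
#' \code{\link{runPipeline}} consumes: per-tile multi-page TIFFs, truth
#' tables (CSV) and a JSON manifest of the layout, optics and seeds.
#'
#' @param model a \linkS4class{SectionModel}.
#' @param dir output directory (created).
#' @param seed integer seed driving all phantom randomness.
#' @param tileGrid POM tile grid c(rows, cols).
#' @param overlap POM nominal tile overlap fraction.
#' @param flmTileGrid fluorescence tile grid; c(1, 1) writes single images.
#' @param flmOverlap fluorescence tile overlap.
#' @param noiseSd additive Gaussian noise sd for the polarization frames
#'   (intensity counts) and, divided by \code{meanIntensity}, for the
#'   fluorescence channels.
#' @param jitterPx integer tile-origin jitter.
#' @param meanIntensity transmitted mean intensity, counts.
#' @param background stray-light offset, counts.
#' @return invisibly, a list with the truth object and the manifest.
#' @export
runPhantom <- function(model = sectionModel(), dir, seed = 1L,
                       tileGrid = c(3, 3), overlap = 0.66,
                       flmTileGrid = c(2, 2), flmOverlap = 0.3,
                       noiseSd = 0, jitterPx = 2, meanIntensity = 1000,
                       background = 50) {
  dir.create(file.path(dir, "pom"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "flm"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), recursive = TRUE, showWarnings = FALSE)
  truth <- buildSection(model, seed = seed)
  pom <- renderPolarization(truth, tileGrid = tileGrid, overlap = overlap,
                            noiseSd = noiseSd, meanIntensity = meanIntensity,
                            background = background, jitterPx = jitterPx,
                            seed = seed)
  for (i in seq_along(pom$stacks)) {
    st <- pom$stacks[[i]]
    tiff::writeTIFF(lapply(1:3, function(k)
      pmin(st@frames[, , k] / INTENSITY_SCALE, 1)),
      file.path(dir, "pom", sprintf("tile_%03d.tif", i)),
      bits.per.sample = 16L, compression = "none")
    tiff::writeTIFF(lapply(1:3, function(k)
      pmin(st@background[, , k] / INTENSITY_SCALE, 1)),
      file.path(dir, "pom", sprintf("background_%03d.tif", i)),
      bits.per.sample = 16L, compression = "none")
  }
  flm <- renderFluorescence(truth, noiseSd = noiseSd / meanIntensity,
                            seed = seed + 1L)
  uvCut <- cutTiles(flm$uv, flmTileGrid, flmOverlap, jitterPx = jitterPx,
                    seed = seed + 2L)
  for (i in seq_along(uvCut$tiles)) {
    writeGray(uvCut$tiles[[i]],
              file.path(dir, "flm", sprintf("uv_%03d.tif", i)))
    gTile <- flm$green[(uvCut$offsets[i, 1] + 1):(uvCut$offsets[i, 1] + uvCut$tileDim[1]),
                       (uvCut$offsets[i, 2] + 1):(uvCut$offsets[i, 2] + uvCut$tileDim[2])]
    writeGray(gTile, file.path(dir, "flm", sprintf("green_%03d.tif", i)))
  }
  utils::write.csv(cellTable(truth), file.path(dir, "truth", "cells.csv"),
                   row.names = FALSE)
  writeGray(truth@labelImage, file.path(dir, "truth", "labels.tif"),
            scale = max(truth@labelImage))
  manifest <- list(
    generator = "tracheidMFA phantom",
    seed = seed,
    pom = list(gridShape = tileGrid, overlap = overlap,
               nTiles = length(pom$stacks), tileDim = pom$tileDim,
               offsets = pom$offsets,
               intensityScale = INTENSITY_SCALE,
               meanIntensity = meanIntensity, background = background,
               noiseSd = noiseSd,
               acquisitionOrder = "row-major raster (not serpentine)"),
    flm = list(gridShape = flmTileGrid, overlap = flmOverlap,
               nTiles = length(uvCut$tiles), tileDim = uvCut$tileDim,
               offsets = uvCut$offsets),
    optics = list(wavelengthNm = pom$optics@wavelengthNm,
                  polarizerAnglesDeg = pom$optics@polarizerAnglesDeg,
                  nO = pom$optics@nO, nE = pom$optics@nE,
                  sectionThicknessNm = pom$optics@sectionThicknessNm,
                  celluloseFraction = pom$optics@celluloseFraction),
    pixelSizeUm = list(pom = model@pixelSizeUm, flm = model@pixelSizeUm),
    model = list(nFiles = model@nFiles, cellsPerFile = model@cellsPerFile)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(truth = truth, manifest = manifest))
}

readStackTiff <- function(path, scale = INTENSITY_SCALE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) p * scale)
}

#' Run the full pipeline on a dataset directory
#'
#' Executes every stage in order: three-frame inversion of each
#' polarization tile, mosaicking (offsets estimated once on the
#' retardation channel and reused for azimuth and mean intensity),
#' fluorescence mosaicking, POM-to-FLM registration, MFA conversion, wall
#' classification, S2 valley detection, ray masking, segmentation, radial
#' file extraction, morphometry, POM/FLM integration, tracheidogram
#' normalization and smoothing, outlier screening, correlation analysis,
#' the distribution checks and the Steel-Dwass position comparison.
#' Stage failures abort with the stage name.
#'
#' @param inputDir dataset directory as written by \code{\link{runPhantom}}
#'   (tiles, backgrounds, fluorescence, manifest.json).
#' @param outDir optional output directory for the result bundle (mosaics
#'   as TIFF, tables as CSV, log as JSON).
#' @param nNormalized tracheidogram grid length (default 27).
#' @param alpha family-wise significance level.
#' @param minS2Pixels minimum S2 pixel count per cell/wall for a defined
#'   mean.
#' @param s2SmoothWindow along-wall smoothing window for valley detection
#'   (odd; 1 = none, use 5 for noisy data).
#' @param steelDwassParams parameters tested across positions.
#' @return invisibly, the bundle: mosaics, masks, tables, transforms, QC.
#' @export
runPipeline <- function(inputDir, outDir = NULL, nNormalized = 27,
                        alpha = 0.05, minS2Pixels = 10, s2SmoothWindow = 1,
                        steelDwassParams = c("cellWallOccupancy",
                                             "lumenRadialDiameterUm",
                                             "tangentialWallThicknessUm",
                                             "meanS2MfaRadialDeg",
                                             "meanS2MfaTangentialDeg")) {
  stage <- "config"
  fail <- function(e) stop("pipeline stage '", stage, "' failed: ",
                           conditionMessage(e), call. = FALSE)
  tryCatch({
    manifestPath <- file.path(inputDir, "manifest.json")
    if (!file.exists(manifestPath)) stop("manifest.json not found")
    man <- jsonlite::read_json(manifestPath, simplifyVector = TRUE)
    optics <- opticsConfig(
      wavelengthNm = man$optics$wavelengthNm,
      polarizerAnglesDeg = man$optics$polarizerAnglesDeg,
      nO = man$optics$nO, nE = man$optics$nE,
      sectionThicknessNm = man$optics$sectionThicknessNm,
      celluloseFraction = man$optics$celluloseFraction)
    nPom <- man$pom$nTiles
    tilePaths <- file.path(inputDir, "pom", sprintf("tile_%03d.tif", 1:nPom))
    bgPaths <- file.path(inputDir, "pom",
                         sprintf("background_%03d.tif", 1:nPom))
    if (!all(file.exists(tilePaths))) stop("missing polarization tiles")
    if (!all(file.exists(bgPaths))) stop("missing background tiles")
    nFlm <- man$flm$nTiles
    uvPaths <- file.path(inputDir, "flm", sprintf("uv_%03d.tif", 1:nFlm))
    grPaths <- file.path(inputDir, "flm", sprintf("green_%03d.tif", 1:nFlm))
    if (!all(file.exists(uvPaths)) || !all(file.exists(grPaths)))
      stop("missing fluorescence images")
    scale <- man$pom$intensityScale
  }, error = fail)

  stage <- "polarimetry"
  tryCatch({
    invTiles <- lapply(seq_len(nPom), function(i) {
      fr <- readStackTiff(tilePaths[i], scale)
      bg <- readStackTiff(bgPaths[i], scale)
      st <- polarizationStack(
        array(unlist(fr), c(dim(fr[[1]]), 3)),
        array(unlist(bg), c(dim(bg[[1]]), 3)),
        optics@polarizerAnglesDeg)
      polInvert(st, optics)
    })
  }, error = fail)

  stage <- "stitch"
  tryCatch({
    retTiles <- lapply(invTiles, retardation)
    retTiles <- lapply(retTiles, function(m) ifelse(is.na(m), 0, m))
    stPom <- stitchTiles(retTiles, man$pom$gridShape, man$pom$overlap)
    azTiles <- lapply(invTiles, function(r) {
      a <- azimuth(r); a[is.na(a)] <- -1; a
    })
    azMosaic <- stitchWithOffsets(azTiles, stPom$offsets)
    azMosaic[azMosaic < 0] <- NA_real_
    i0Mosaic <- stitchWithOffsets(lapply(invTiles, function(r)
      r@meanIntensity), stPom$offsets)
    validMosaic <- stitchWithOffsets(lapply(invTiles, function(r)
      r@validMask * 1), stPom$offsets) > 0.5
    retMosaic <- stPom$mosaic
    uvTiles <- lapply(uvPaths, function(p) tiff::readTIFF(p))
    grTiles <- lapply(grPaths, function(p) tiff::readTIFF(p))
    if (nFlm > 1) {
      stFlm <- stitchTiles(uvTiles, man$flm$gridShape, man$flm$overlap)
      uvMosaic <- stFlm$mosaic
      greenMosaic <- stitchWithOffsets(grTiles, stFlm$offsets)
      flmFlagged <- stFlm$flagged
    } else {
      uvMosaic <- uvTiles[[1]]; greenMosaic <- grTiles[[1]]
      flmFlagged <- integer()
    }
  }, error = fail)

  stage <- "register"
  tryCatch({
    transform <- registerImages(retMosaic, uvMosaic)
  }, error = fail)

  stage <- "mfa"
  tryCatch({
    # wall support comes from the (registered) UV wall binarization, which
    # is robust in lumina where the retardation signal is pure noise
    rngU <- range(uvMosaic)
    thrU <- EBImage::otsu(EBImage::Image((uvMosaic - rngU[1]) / diff(rngU)),
                          range = c(0, 1))
    wallBinFlm <- (uvMosaic - rngU[1]) / diff(rngU) > thrU
    wallMaskPom <- warpBySimilarity(wallBinFlm * 1, solve(transform@matrix),
                                    dim(retMosaic)) > 0.5
    wallMaskPom <- wallMaskPom & validMosaic & is.finite(azMosaic)
    retResult <- new("RetardationResult", retardationNm = retMosaic,
                     azimuthDeg = azMosaic, meanIntensity = i0Mosaic,
                     validMask = validMosaic,
                     clampedMask = matrix(FALSE, nrow(retMosaic),
                                          ncol(retMosaic)))
    mfaRes <- mfaFromRetardation(retResult, optics, wallMask = wallMaskPom,
                                 smoothWindow = s2SmoothWindow)
  }, error = fail)

  stage <- "segment"
  tryCatch({
    rayMask <- maskRays(uvMosaic, greenMosaic)
    seg <- segmentCells(uvMosaic, rayMask)
    if (seg$qc$nCells == 0) stop("no cells segmented")
  }, error = fail)

  stage <- "files"
  tryCatch({
    files <- extractRadialFiles(seg$labels,
                                borderLabels = seg$qc$borderLabels)
  }, error = fail)

  stage <- "measure"
  tryCatch({
    flmPx <- man$pixelSizeUm$flm
    cells <- measureCells(seg$labels, seg$wallBin, flmPx, files = files)
  }, error = fail)

  stage <- "integrate"
  tryCatch({
    cells <- integrateCells(seg$labels, cells, mfaRes, transform,
                            minPixels = minS2Pixels)
  }, error = fail)

  stage <- "tracheidogram"
  tryCatch({
    intactIds <- unique(files$file[files$intact])
    params <- c("tracheidTransverseAreaUm2", "lumenTransverseAreaUm2",
                "cellWallAreaUm2", "cellWallOccupancy",
                "tracheidRadialDiameterUm", "lumenRadialDiameterUm",
                "tracheidTangentialDiameterUm", "tangentialWallThicknessUm",
                "meanS2MfaRadialDeg", "meanS2MfaTangentialDeg")
    norm <- list()
    for (p in params) {
      mat <- t(vapply(intactIds, function(f) {
        d <- cells[!is.na(cells$file) & cells$file == f, ]
        d <- d[order(d$position), ]
        normalizeFile(d[[p]], N = nNormalized)
      }, numeric(nNormalized)))
      rownames(mat) <- intactIds
      # denoising applies to the MFA arrays only; morphology stays raw
      if (grepl("^meanS2", p))
        mat <- t(apply(mat, 1, sgSmooth))
      norm[[p]] <- mat
    }
    keep <- screenOutliers(norm$tangentialWallThicknessUm)
    outliers <- which(!keep, arr.ind = TRUE)
    bands <- lapply(norm, tracheidogramBands)
  }, error = fail)

  stage <- "stats"
  tryCatch({
    # reflect normalized-grid outlier flags back to the raw cells
    if (nrow(outliers)) {
      for (r in seq_len(nrow(outliers))) {
        f <- intactIds[outliers[r, 1]]
        d <- cells[!is.na(cells$file) & cells$file == f, ]
        rawPos <- mapNormalizedToRaw(outliers[r, 2], nrow(d), nNormalized)
        lab <- d$label[d$position == rawPos]
        cells$tangentialWallThicknessUm[cells$label %in% lab] <- NA_real_
      }
    }
    correlations <- mfaCorrelationTable(cells)
    groupsOf <- function(p) {
      lapply(seq_len(nNormalized), function(j) {
        v <- norm[[p]][, j]
        v[is.finite(v)]
      })
    }
    assumptions <- list()
    posTests <- list()
    for (p in intersect(steelDwassParams, names(norm))) {
      gr <- groupsOf(p)
      if (any(vapply(gr, length, 1L) < 2)) next
      assumptions[[p]] <- checkAssumptions(gr)
      posTests[[p]] <- steelDwass(gr, alpha = alpha)
    }
  }, error = fail)

  stage <- "write"
  bundle <- list(
    optics = optics, transform = transform,
    retardationMosaic = retMosaic, azimuthMosaic = azMosaic,
    mfa = mfaRes, uvMosaic = uvMosaic, greenMosaic = greenMosaic,
    rayMask = rayMask, labels = seg$labels, segQC = seg$qc,
    pomOffsets = stPom$offsets, pomFlagged = stPom$flagged,
    flmFlagged = flmFlagged,
    files = files, cells = cells, normalized = norm, bands = bands,
    outliers = outliers, correlations = correlations,
    assumptions = assumptions, steelDwass = posTests)
  if (!is.null(outDir)) tryCatch({
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeGray(ifelse(is.na(retMosaic), 0, retMosaic),
              file.path(outDir, "retardation_nm.tif"), RETARDATION_SCALE)
    writeGray(ifelse(is.na(azMosaic), 0, azMosaic),
              file.path(outDir, "azimuth_deg.tif"), 180)
    writeGray(ifelse(is.na(mfaMap(mfaRes)), 0, mfaMap(mfaRes)),
              file.path(outDir, "mfa_deg.tif"), 90)
    writeGray(wallClass(mfaRes), file.path(outDir, "wall_class.tif"), 2)
    writeGray(s2Mask(mfaRes) * 1, file.path(outDir, "s2_mask.tif"))
    writeGray(seg$labels / max(1, max(seg$labels)),
              file.path(outDir, "labels.tif"))
    utils::write.csv(cells, file.path(outDir, "cells.csv"),
                     row.names = FALSE)
    for (p in names(norm))
      utils::write.csv(norm[[p]],
                       file.path(outDir, paste0("tracheidogram_", p, ".csv")))
    utils::write.csv(correlations, file.path(outDir, "correlations.csv"),
                     row.names = FALSE)
    for (p in names(posTests))
      utils::write.csv(posTests[[p]],
                       file.path(outDir, paste0("steel_dwass_", p, ".csv")),
                       row.names = FALSE)
    log <- list(package = "tracheidMFA",
                version = as.character(utils::packageVersion("tracheidMFA")),
                rVersion = R.version.string,
                date = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                inputDir = normalizePath(inputDir),
                registration = list(scale = transform@scale,
                                    rotationDeg = transform@rotationDeg,
                                    peak = transform@peak),
                qc = list(borderLabels = seg$qc$borderLabels,
                          unassignedPx = seg$qc$unassignedPx,
                          flaggedPomTiles = stPom$flagged,
                          flaggedFlmTiles = flmFlagged,
                          nOutliers = nrow(outliers)))
    jsonlite::write_json(log, file.path(outDir, "run_log.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, error = fail)
  invisible(bundle)
}
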