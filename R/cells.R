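#' Mask ray bands from the green-excitation fluorescence channel
#'
#' Rays deposit extractives that fluoresce under green excitation while
#' tracheid walls stay dark, so an Otsu threshold on the green mosaic
#' followed by a morphological opening and closing isolates the ray bands.
#' The mask is subtracted from the analysis region downstream so that only
#' tracheid anatomy is evaluated.
#'
#' @param uvMosaic UV-excitation mosaic (same shape; reserved for shape
#'   checks).
#' @param greenMosaic green-excitation mosaic.
#' @param brushSize diameter (px) of the disc brush for opening/closing.
#' @return logical raster, TRUE on ray pixels. A constant green channel
#'   yields an empty mask.
#' @export
maskRays <- function(uvMosaic, greenMosaic, brushSize = 5) {
  stopifnot(identical(dim(uvMosaic), dim(greenMosaic)))
  rng <- range(greenMosaic)
  if (diff(rng) < 1e-9)
    return(matrix(FALSE, nrow(greenMosaic), ncol(greenMosaic)))
  g <- (greenMosaic - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(g), range = c(0, 1))
  mask <- g > thr
  br <- EBImage::makeBrush(brushSize, shape = "disc")
  mask <- EBImage::closing(EBImage::opening(mask, br), br)
  matrix(as.logical(mask), nrow(greenMosaic))
}

#' Segment tracheids from the UV-excitation mosaic by seeded region growing
#'
#' Walls are binarized by an Otsu threshold; connected lumen regions (dark,
#' non-ray, not connected to the image border) become seeds, and every
#' tissue pixel is assigned to a seed by intensity-weighted propagation
#' (a watershed-style region growing on the wall intensity), so cell
#' boundaries settle on the bright wall ridge between lumina. Ray pixels
#' are excluded from the result. Latewood tracheids whose lumen falls below
#' the seed size cannot seed a region; such unassigned wall area is
#' reported in the QC slot, and extra seeds can be injected to recover them
#' (replacing the manual correction a microscopist would do).
#'
#' @param uvMosaic UV-excitation mosaic.
#' @param rayMask logical raster from \code{\link{maskRays}}; NULL for none.
#' @param minLumenPx smallest connected lumen area accepted as a seed.
#' @param extraSeeds optional integer matrix of user-supplied seed centers
#'   (rows: y, x) injected as additional seeds.
#' @return list: \code{labels} (integer raster, 0 = background/ray),
#'   \code{qc} (list: \code{borderLabels}, labels touching the mosaic
#'   border; \code{unassignedPx}, tissue pixels no seed could claim;
#'   \code{nCells}).
#' @export
segmentCells <- function(uvMosaic, rayMask = NULL, minLumenPx = 12,
                         extraSeeds = NULL) {
  nr <- nrow(uvMosaic); nc <- ncol(uvMosaic)
  if (is.null(rayMask)) rayMask <- matrix(FALSE, nr, nc)
  rng <- range(uvMosaic)
  if (diff(rng) < 1e-9) {
    warning("blank UV mosaic: no cells segmented")
    return(list(labels = matrix(0L, nr, nc),
                qc = list(borderLabels = integer(), unassignedPx = 0L,
                          nCells = 0L)))
  }
  u <- (uvMosaic - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(u), range = c(0, 1))
  wallBin <- u > thr
  open <- !wallBin & !rayMask
  comp <- EBImage::bwlabel(open)
  comp <- matrix(as.integer(comp), nr, nc)
  # components touching the border are mounting medium / margin, not lumina
  borderComps <- unique(c(comp[1, ], comp[nr, ], comp[, 1], comp[, nc]))
  borderComps <- borderComps[borderComps > 0]
  sizes <- c(0L, tabulate(comp))        # offset so comp == 0 indexes safely
  drop <- comp > 0 & (comp %in% borderComps | sizes[comp + 1L] < minLumenPx)
  seeds <- comp
  seeds[drop] <- 0L
  seeds <- EBImage::bwlabel(seeds > 0)
  seeds <- matrix(as.integer(seeds), nr, nc)
  if (!is.null(extraSeeds) && nrow(extraSeeds) > 0) {
    k <- max(seeds)
    for (i in seq_len(nrow(extraSeeds))) {
      r <- extraSeeds[i, 1]; c <- extraSeeds[i, 2]
      if (seeds[r, c] == 0L) seeds[r, c] <- k + i
    }
  }
  if (max(seeds) == 0L) {
    warning("no lumen seeds found: empty segmentation")
    return(list(labels = matrix(0L, nr, nc),
                qc = list(borderLabels = integer(),
                          unassignedPx = sum(!rayMask & comp == 0),
                          nCells = 0L)))
  }
  tissue <- !rayMask & !(open & comp %in% borderComps)
  lab <- EBImage::propagate(EBImage::Image(u), EBImage::Image(seeds),
                            mask = EBImage::Image(tissue))
  lab <- matrix(as.integer(lab), nr, nc)
  lab[rayMask] <- 0L
  borderLabels <- unique(c(lab[1, ], lab[nr, ], lab[, 1], lab[, nc]))
  borderLabels <- sort(borderLabels[borderLabels > 0])
  unassigned <- sum(tissue & lab == 0L & wallBin)
  list(labels = lab, wallBin = wallBin,
       qc = list(borderLabels = borderLabels,
                 unassignedPx = as.integer(unassigned),
                 nCells = length(setdiff(unique(as.vector(lab)), 0L))))
}

#' Bray-Curtis dissimilarity of two areas
#'
#' \deqn{BC(A_1, A_2) = |A_1 - A_2| / (A_1 + A_2)} -- the morphological
#' similarity criterion used to chain radial-file neighbors; 0 iff equal,
#' < 1 always, symmetric.
#'
#' @param a,b positive areas (vectorized).
#' @return dissimilarity in [0, 1).
#' @examples
#' brayCurtis(100, 300)  # 0.5
#' @export
brayCurtis <- function(a, b) abs(a - b) / (a + b)

# 8-connected adjacency pairs of a label image (unique label pairs).
adjacencyPairs <- function(labels) {
  pair <- function(a, b) {
    keep <- a > 0 & b > 0 & a != b
    cbind(pmin(a[keep], b[keep]), pmax(a[keep], b[keep]))
  }
  nr <- nrow(labels); nc <- ncol(labels)
  p <- rbind(
    pair(labels[-nr, ], labels[-1, ]),
    pair(labels[, -nc], labels[, -1]),
    pair(labels[-nr, -nc], labels[-1, -1]),
    pair(labels[-nr, -1], labels[-1, -nc])
  )
  unique(p)
}

#' Extract radial files from a segmented label image
#'
#' Builds the region adjacency graph of touching cells and chains each cell
#' to its most probable latewood-ward neighbor: among adjacent cells whose
#' centroid-to-centroid vector points within \code{maxAngleDeg} of the
#' radial (horizontal) axis, the successor minimizing the Bray-Curtis
#' dissimilarity of tracheid transverse areas is chosen (ties broken by the
#' straighter connection). Chains are grown from cells with no predecessor.
#' A file is intact when it spans the full ring width and contains no
#' border-flagged cell.
#'
#' @param labels integer label raster (>= 2 cells).
#' @param maxAngleDeg angle restriction between the centroid vector and the
#'   horizontal, degrees (default 25).
#' @param earlywoodLeft logical; TRUE (default) when earlywood is at
#'   smaller x.
#' @param borderLabels labels flagged at segmentation QC; files containing
#'   one are not intact.
#' @return data.frame with one row per chained cell: \code{file},
#'   \code{position} (1 = most earlywood), \code{label}, plus an
#'   \code{intact} flag per file; ordered by file then position.
#' @export
extractRadialFiles <- function(labels, maxAngleDeg = 25,
                               earlywoodLeft = TRUE,
                               borderLabels = integer()) {
  st <- labelStats(labels)
  if (nrow(st) < 2) stop("need at least two labelled cells")
  if (!earlywoodLeft) st$col <- max(st$col) + min(st$col) - st$col
  g <- igraph::graph_from_edgelist(
    matrix(match(adjacencyPairs(labels), st$label), ncol = 2),
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nrow(st) - igraph::vcount(g)))
  succ <- rep(NA_integer_, nrow(st))
  for (i in seq_len(nrow(st))) {
    nb <- as.integer(igraph::neighbors(g, i))
    if (!length(nb)) next
    dx <- st$col[nb] - st$col[i]
    dy <- st$row[nb] - st$row[i]
    ang <- abs(rad2deg(atan2(dy, dx)))
    ok <- dx > 0 & ang <= maxAngleDeg
    if (!any(ok)) next
    nb <- nb[ok]; ang <- ang[ok]
    bc <- brayCurtis(st$n[i], st$n[nb])
    best <- which(bc == min(bc))
    if (length(best) > 1) best <- best[which.min(ang[best])]
    succ[i] <- nb[best]
  }
  hasPred <- rep(FALSE, nrow(st))
  hasPred[stats::na.omit(succ)] <- TRUE
  roots <- which(!hasPred)
  roots <- roots[order(st$row[roots], st$col[roots])]
  xMin <- min(st$col); xMax <- max(st$col)
  linked <- which(!is.na(succ))
  meanSpacing <- if (length(linked))
    stats::median(st$col[succ[linked]] - st$col[linked]) else xMax - xMin
  out <- list(); fid <- 0L
  for (r in roots) {
    chain <- integer(); i <- r
    visited <- logical(nrow(st))
    while (!is.na(i) && !visited[i]) {
      visited[i] <- TRUE
      chain <- c(chain, i)
      i <- succ[i]
    }
    if (!is.na(i) && visited[i]) stop("cyclic chain detected")
    fid <- fid + 1L
    spans <- st$col[chain[1]] <= xMin + 1.5 * meanSpacing &&
      st$col[chain[length(chain)]] >= xMax - 1.5 * meanSpacing
    intact <- spans && !any(st$label[chain] %in% borderLabels)
    out[[fid]] <- data.frame(file = fid, position = seq_along(chain),
                             label = st$label[chain], intact = intact)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Length (px) of the run of TRUE containing (or nearest to) index at in a
# logical vector; returns c(extent, start, end), zeros when empty.
runExtentAt <- function(v, at) {
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  if (!length(runs)) return(c(0, 0, 0))
  inRun <- runs[starts[runs] <= at & ends[runs] >= at]
  k <- if (length(inRun)) inRun[1] else
    runs[which.min(pmin(abs(starts[runs] - at), abs(ends[runs] - at)))]
  c(r$lengths[k], starts[k], ends[k])
}

#' Measure the seven anatomical parameters of every segmented tracheid
#'
#' Areas are pixel counts scaled by the pixel area; radial and tangential
#' diameters are the extents of the cell (and of its lumen) along the
#' horizontal and vertical scan lines through the centroid; the tangential
#' wall thickness is half the double-wall distance between consecutive
#' cells of a file, measured along the radial scan line through both
#' centroids and assigned to both cells (averaged over a cell's two pairs).
#' Cells without file membership get NA thickness.
#'
#' @param labels integer label raster.
#' @param wallMask logical raster of wall pixels (from the binarized UV
#'   mosaic, or the phantom truth).
#' @param pixelSizeUm pixel size, um/px.
#' @param files optional data.frame from \code{\link{extractRadialFiles}};
#'   enables thickness measurement and file/position columns.
#' @return data.frame of cell records (units um and um^2): label, centroid,
#'   the seven parameters, file and position when available.
#' @export
measureCells <- function(labels, wallMask, pixelSizeUm, files = NULL) {
  st <- labelStats(labels)
  ps <- pixelSizeUm
  lumen <- labels > 0 & !wallMask
  out <- data.frame(
    label = st$label,
    centroidRow = st$row, centroidCol = st$col,
    tracheidTransverseAreaUm2 = st$n * ps^2,
    lumenTransverseAreaUm2 = NA_real_, cellWallAreaUm2 = NA_real_,
    cellWallOccupancy = NA_real_,
    tracheidRadialDiameterUm = NA_real_, lumenRadialDiameterUm = NA_real_,
    tracheidTangentialDiameterUm = NA_real_,
    tangentialWallThicknessUm = NA_real_
  )
  lumCount <- tabulate(labels[lumen], nbins = max(st$label))
  out$lumenTransverseAreaUm2 <- lumCount[st$label] * ps^2
  out$cellWallAreaUm2 <- out$tracheidTransverseAreaUm2 -
    out$lumenTransverseAreaUm2
  out$cellWallOccupancy <- out$cellWallAreaUm2 /
    out$tracheidTransverseAreaUm2
  for (i in seq_len(nrow(st))) {
    lb <- st$label[i]
    r <- round(st$row[i]); c <- round(st$col[i])
    rowCells <- labels[r, ] == lb
    colCells <- labels[, c] == lb
    out$tracheidRadialDiameterUm[i] <- runExtentAt(rowCells, c)[1] * ps
    out$tracheidTangentialDiameterUm[i] <- runExtentAt(colCells, r)[1] * ps
    out$lumenRadialDiameterUm[i] <- runExtentAt(lumen[r, ] & rowCells, c)[1] * ps
  }
  if (!is.null(files)) {
    out <- merge(out, files[, c("label", "file", "position")],
                 by = "label", all.x = TRUE)
    thickSum <- numeric(nrow(out)); thickN <- integer(nrow(out))
    fid <- split(seq_len(nrow(files)), files$file)
    rowOf <- match(files$label, out$label)
    for (f in fid) {
      ord <- f[order(files$position[f])]
      for (k in seq_len(length(ord) - 1)) {
        iA <- rowOf[ord[k]]; iB <- rowOf[ord[k + 1]]
        rAB <- round((out$centroidRow[iA] + out$centroidRow[iB]) / 2)
        cA <- round(out$centroidCol[iA]); cB <- round(out$centroidCol[iB])
        if (cA >= cB) next
        lA <- out$label[iA]; lB <- out$label[iB]
        seg <- labels[rAB, cA:cB]
        segWall <- wallMask[rAB, cA:cB]
        segLum <- seg > 0 & !segWall
        # double wall: wall pixels of the pair between the two lumina
        lumA <- which(segLum & seg == lA)
        lumB <- which(segLum & seg == lB)
        if (!length(lumA) || !length(lumB)) next
        between <- (max(lumA) + 1):(min(lumB) - 1)
        between <- between[between >= 1 & between <= length(seg)]
        dw <- sum(segWall[between] & seg[between] %in% c(lA, lB))
        half <- dw / 2 * ps
        thickSum[c(iA, iB)] <- thickSum[c(iA, iB)] + half
        thickN[c(iA, iB)] <- thickN[c(iA, iB)] + 1L
      }
    }
    out$tangentialWallThicknessUm <-
      ifelse(thickN > 0, thickSum / pmax(thickN, 1), NA_real_)
    out <- out[order(is.na(out$file), out$file, out$position), ]
    rownames(out) <- NULL
  }
  out
}
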