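# Shared fixtures: everything is generated in code at test time.

# A small ring phantom: 4 files x 8 cells, no rays, fast to rasterize.
smallModel <- function(nFiles = 4, cellsPerFile = 8, ...) {
  sectionModel(nFiles = nFiles, cellsPerFile = cellsPerFile,
               rayAfterFile = integer(), ...)
}

# A strictly regular lattice (no per-file variation), for analytic checks.
regularModel <- function(nFiles = 2, cellsPerFile = 3,
                         radialDiameterUm = 20, tangentialDiameterUm = 20,
                         wallThicknessUm = 3, pixelSizeUm = 1, ...) {
  sectionModel(nFiles = nFiles, cellsPerFile = cellsPerFile,
               radialDiameterUm = radialDiameterUm,
               tangentialDiameterUm = tangentialDiameterUm,
               wallThicknessUm = wallThicknessUm,
               mfaTangentialDeg = rep(20, cellsPerFile),
               mfaRadialDeg = rep(20, cellsPerFile),
               rayAfterFile = integer(),
               pixelSizeUm = pixelSizeUm,
               fileDiameterSd = 0, fileTangentialSdUm = 0, ...)
}

# Per-true-cell Jaccard index against the best-overlapping predicted label.
jaccardPerCell <- function(truthLabels, predLabels) {
  vapply(sort(unique(truthLabels[truthLabels > 0])), function(l) {
    tm <- truthLabels == l
    cand <- predLabels[tm]
    cand <- cand[cand > 0]
    if (!length(cand)) return(0)
    b <- as.integer(names(which.max(table(cand))))
    pm <- predLabels == b
    sum(tm & pm) / sum(tm | pm)
  }, numeric(1))
}

# Match measured cells to truth rows by nearest centroid.
matchToTruth <- function(cells, truthCells) {
  vapply(seq_len(nrow(cells)), function(i) {
    which.min((truthCells$centroidRow - cells$centroidRow[i])^2 +
                (truthCells$centroidCol - cells$centroidCol[i])^2)
  }, integer(1))
}
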