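test_that("Bray-Curtis dissimilarity behaves like a bounded metric on areas", {
  expect_equal(brayCurtis(100, 100), 0)
  expect_equal(brayCurtis(100, 300), 0.5)
  set.seed(6)
  a <- runif(100, 1, 1000); b <- runif(100, 1, 1000)
  expect_equal(brayCurtis(a, b), brayCurtis(b, a))
  expect_true(all(brayCurtis(a, b) >= 0 & brayCurtis(a, b) < 1))
  expect_true(all((brayCurtis(a, b) == 0) == (a == b)))
})

test_that("ray bands are masked from the green channel and tracheids are spared", {
  tr <- buildSection(sectionModel(nFiles = 12, cellsPerFile = 8,
                                  rayAfterFile = c(4L, 8L)), seed = 1)
  fl <- renderFluorescence(tr)
  ray <- maskRays(fl$uv, fl$green)
  expect_gte(sum(ray & tr@rayMask) / sum(tr@rayMask), 0.95)
  expect_lte(sum(ray & !tr@rayMask) / sum(!tr@rayMask), 0.01)
  # removing the masked signal leaves nothing to mask
  g2 <- fl$green
  g2[ray] <- 0
  expect_equal(sum(maskRays(fl$uv, g2)), 0L)
})

test_that("a constant green channel yields an empty ray mask", {
  z <- matrix(0, 30, 30)
  expect_equal(sum(maskRays(z, z)), 0L)
})

test_that("a blank UV mosaic segments to zero cells with a warning", {
  expect_warning(seg <- segmentCells(matrix(0.2, 40, 40)), "blank")
  expect_equal(seg$qc$nCells, 0L)
})

test_that("noiseless phantom cells are recovered with high overlap", {
  tr <- buildSection(sectionModel(nFiles = 12, cellsPerFile = 10,
                                  rayAfterFile = c(4L, 8L)), seed = 1)
  fl <- renderFluorescence(tr)
  seg <- segmentCells(fl$uv, maskRays(fl$uv, fl$green))
  expect_equal(seg$qc$nCells, nrow(cellTable(tr)))
  jac <- jaccardPerCell(labelImage(tr), seg$labels)
  expect_gte(mean(jac >= 0.8), 0.95)
})

test_that("radial files chain every cell in truth order", {
  tr <- buildSection(smallModel(nFiles = 5, cellsPerFile = 9), seed = 2)
  fl <- renderFluorescence(tr)
  seg <- segmentCells(fl$uv)
  files <- extractRadialFiles(seg$labels,
                              borderLabels = seg$qc$borderLabels)
  expect_equal(length(unique(files$file)), 5L)
  expect_true(all(files$intact))
  # positions advance strictly along x
  cells <- measureCells(seg$labels, seg$wallBin, 0.5, files = files)
  ok <- tapply(seq_len(nrow(cells)), cells$file, function(ix) {
    all(diff(cells$centroidCol[ix][order(cells$position[ix])]) > 0)
  })
  expect_true(all(ok))
})

test_that("file extraction is invariant to label permutation", {
  tr <- buildSection(smallModel(nFiles = 3, cellsPerFile = 6), seed = 2)
  fl <- renderFluorescence(tr)
  seg <- segmentCells(fl$uv)
  f1 <- extractRadialFiles(seg$labels)
  set.seed(99)
  perm <- sample(max(seg$labels))
  relab <- seg$labels
  relab[seg$labels > 0] <- perm[seg$labels[seg$labels > 0]]
  f2 <- extractRadialFiles(relab)
  # same chains after mapping back
  key1 <- tapply(f1$label, f1$file, paste, collapse = ",")
  key2 <- tapply(match(f2$label, perm), f2$file, paste, collapse = ",")
  expect_setequal(unname(key1), unname(key2))
})

test_that("a single row of cells forms one file in x order", {
  tr <- buildSection(regularModel(nFiles = 1, cellsPerFile = 5), seed = 1)
  files <- extractRadialFiles(labelImage(tr))
  expect_equal(length(unique(files$file)), 1L)
  expect_equal(files$label, 1:5)
})

test_that("hand-built cells measure to their textbook values", {
  # 20 x 20 um cell, 3 um wall => 14 x 14 lumen: occupancy 0.51
  lab <- matrix(0L, 30, 30)
  lab[6:25, 6:25] <- 1L
  wall <- matrix(FALSE, 30, 30)
  wall[6:25, 6:25] <- TRUE
  wall[9:22, 9:22] <- FALSE
  m <- measureCells(lab, wall, 1)
  expect_equal(m$tracheidTransverseAreaUm2, 400)
  expect_equal(m$lumenTransverseAreaUm2, 196)
  expect_equal(m$cellWallOccupancy, (400 - 196) / 400)
  expect_equal(m$tracheidRadialDiameterUm, 20)
  expect_equal(m$lumenRadialDiameterUm, 14)
  # lumen-less latewood extreme: occupancy 1
  wall2 <- matrix(FALSE, 30, 30)
  wall2[6:25, 6:25] <- TRUE
  m2 <- measureCells(lab, wall2, 1)
  expect_equal(m2$lumenTransverseAreaUm2, 0)
  expect_equal(m2$cellWallOccupancy, 1)
})

test_that("cell, ray and background areas partition the mosaic", {
  tr <- buildSection(sectionModel(nFiles = 12, cellsPerFile = 8,
                                  rayAfterFile = c(4L, 8L)), seed = 1)
  labs <- labelImage(tr)
  expect_equal(sum(labs > 0) + sum(tr@rayMask) +
                 sum(labs == 0 & !tr@rayMask), length(labs))
  expect_equal(sum(labs > 0 & tr@rayMask), 0L)
})

test_that("phantom morphometry matches truth within five percent per cell", {
  tr <- buildSection(sectionModel(nFiles = 8, cellsPerFile = 10,
                                  rayAfterFile = 4L), seed = 1)
  fl <- renderFluorescence(tr)
  seg <- segmentCells(fl$uv, maskRays(fl$uv, fl$green))
  files <- extractRadialFiles(seg$labels,
                              borderLabels = seg$qc$borderLabels)
  cells <- measureCells(seg$labels, seg$wallBin, tr@model@pixelSizeUm,
                        files = files)
  ct <- cellTable(tr)
  m <- matchToTruth(cells, ct)
  for (col in c("tracheidTransverseAreaUm2", "lumenTransverseAreaUm2",
                "cellWallAreaUm2", "cellWallOccupancy",
                "tracheidRadialDiameterUm", "lumenRadialDiameterUm",
                "tracheidTangentialDiameterUm",
                "tangentialWallThicknessUm")) {
    rel <- abs(cells[[col]] - ct[[col]][m]) / ct[[col]][m]
    expect_lt(max(rel, na.rm = TRUE), 0.05, label = col)
  }
})
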