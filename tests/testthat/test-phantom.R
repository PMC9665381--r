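test_that("identical model and seed give bit-identical phantoms", {
  m <- smallModel()
  a <- buildSection(m, seed = 9)
  b <- buildSection(m, seed = 9)
  expect_identical(labelImage(a), labelImage(b))
  expect_identical(a@azimuthTrue, b@azimuthTrue)
  expect_identical(cellTable(a), cellTable(b))
  c <- buildSection(m, seed = 10)
  expect_identical(labelImage(a), labelImage(c))   # geometry seed-free
  expect_false(identical(a@azimuthTrue, c@azimuthTrue))
})

test_that("a single file of identical square cells rasterizes symmetrically", {
  tr <- buildSection(regularModel(nFiles = 1, cellsPerFile = 3), seed = 1)
  ct <- cellTable(tr)
  expect_equal(nrow(ct), 3L)
  expect_equal(unique(ct$file), 1)
  expect_equal(length(unique(ct$tracheidTransverseAreaUm2)), 1L)
  expect_equal(sort(unique(labelImage(tr)[labelImage(tr) > 0])), 1:3)
})

test_that("the study-scale model yields 432 labelled tracheids", {
  tr <- buildSection(sectionModel(), seed = 1)
  expect_equal(nrow(cellTable(tr)), 432L)
  expect_equal(length(unique(labelImage(tr)[labelImage(tr) > 0])), 432L)
})

test_that("per-cell truth respects its own identities", {
  ct <- cellTable(buildSection(smallModel(), seed = 2))
  expect_equal(ct$cellWallAreaUm2,
               ct$tracheidTransverseAreaUm2 - ct$lumenTransverseAreaUm2)
  expect_true(all(ct$cellWallAreaUm2 >= 0))
  expect_equal(ct$cellWallOccupancy,
               ct$cellWallAreaUm2 / ct$tracheidTransverseAreaUm2)
  expect_true(all(ct$cellWallOccupancy >= 0 & ct$cellWallOccupancy <= 1))
  expect_true(all(ct$lumenRadialDiameterUm <= ct$tracheidRadialDiameterUm))
})

test_that("truth is self-consistent: remeasuring the label raster reproduces it", {
  tr <- buildSection(smallModel(nFiles = 3, cellsPerFile = 6), seed = 4)
  ct <- cellTable(tr)
  files <- data.frame(file = ct$file, position = ct$position,
                      label = ct$label, intact = TRUE)
  meas <- measureCells(labelImage(tr), tr@wallMask,
                       tr@model@pixelSizeUm, files = files)
  m <- match(ct$label, meas$label)
  ps <- tr@model@pixelSizeUm
  # one pixel of discretization slack on lengths, one-pixel rim on areas
  rimUm2 <- 2 * ps * (ct$tracheidRadialDiameterUm +
                        ct$tracheidTangentialDiameterUm)
  for (col in c("tracheidTransverseAreaUm2", "lumenTransverseAreaUm2")) {
    expect_true(all(abs(meas[[col]][m] - ct[[col]]) <= rimUm2), label = col)
  }
  for (col in c("tracheidRadialDiameterUm", "lumenRadialDiameterUm",
                "tracheidTangentialDiameterUm")) {
    expect_true(all(abs(meas[[col]][m] - ct[[col]]) <= ps), label = col)
  }
  expect_lt(max(abs(meas$tangentialWallThicknessUm[m] -
                      ct$tangentialWallThicknessUm), na.rm = TRUE), ps)
})

test_that("geometry that cannot hold a lumen errors with the cell position", {
  m <- regularModel(radialDiameterUm = 8, wallThicknessUm = 3.9)
  expect_error(buildSection(m, seed = 1), "file/position")
})

test_that("fluorescence render honours its contract", {
  tr <- buildSection(smallModel(), seed = 1)          # no rays
  fl <- renderFluorescence(tr)
  expect_true(all(fl$green == 0))
  mid <- (min(fl$uv) + max(fl$uv)) / 2
  expect_identical(fl$uv > mid, tr@wallMask)
  trR <- buildSection(sectionModel(nFiles = 12, cellsPerFile = 8,
                                   rayAfterFile = c(4L, 8L)), seed = 1)
  flR <- renderFluorescence(trR)
  expect_true(all(flR$green[trR@rayMask] > 0.5))
  expect_true(all(flR$green[!trR@rayMask] < 0.1))
})

test_that("rendered noise has the requested dispersion at the million-pixel scale", {
  tr <- buildSection(sectionModel(nFiles = 14, cellsPerFile = 24), seed = 1)
  expect_gte(length(tr@wallMask), 1e6)
  clean <- renderFluorescence(tr)
  noisy <- renderFluorescence(tr, noiseSd = 0.04, seed = 8)
  resid <- (noisy$uv - clean$uv)[clean$uv > 0.1 & clean$uv < 0.9]
  expect_lt(abs(sd(resid) - 0.04) / 0.04, 0.1)
})

test_that("a zero-MFA section renders three identical frames equal to background", {
  m <- regularModel(nFiles = 2, cellsPerFile = 3)
  m@mfaTangentialDeg[] <- 0; m@mfaRadialDeg[] <- 0; m@s13MfaDeg <- 0
  tr <- buildSection(m, seed = 1)
  pom <- renderPolarization(tr, meanIntensity = 1000, background = 40)
  fr <- pom$stacks[[1]]@frames
  for (k in 1:3) expect_equal(fr[, , k], matrix(540, nrow(fr), ncol(fr)))
})

test_that("noiseless render inverts back to the true retardation map", {
  tr <- buildSection(smallModel(), seed = 2)
  pom <- renderPolarization(tr)
  res <- polInvert(pom$stacks[[1]], pom$optics)
  expect_lt(max(abs(retardation(res) - pom$retardation), na.rm = TRUE), 1e-6)
})

test_that("tiles carry their construction offsets and POC recovers them", {
  tr <- buildSection(smallModel(nFiles = 6, cellsPerFile = 12), seed = 2)
  pom <- renderPolarization(tr, tileGrid = c(1, 2), overlap = 0.66)
  off <- pom$offsets
  expect_equal(nrow(off), 2L)
  rel <- off[2, ] - off[1, ]
  s <- pocShift(pom$stacks[[1]]@frames[, , 1], pom$stacks[[2]]@frames[, , 1],
                nominal = -rel, maxDev = c(20, 20))
  expect_equal(unname(-s[1:2]), unname(rel))
})
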