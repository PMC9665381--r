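test_that("normalization is the identity on files already at target length", {
  v <- rnorm(27)
  expect_equal(normalizeFile(v, N = 27), v)
})

test_that("normalization preserves constants, endpoints and linear ramps", {
  expect_equal(normalizeFile(rep(3.5, 14), N = 27), rep(3.5, 27))
  ramp <- seq(2, 10, length.out = 14)
  out <- normalizeFile(ramp, N = 27)
  expect_equal(out, seq(2, 10, length.out = 27))   # linear in, linear out
  expect_equal(out[c(1, 27)], ramp[c(1, 14)])
  v <- rnorm(12)
  out2 <- normalizeFile(v, N = 27)
  expect_gte(min(out2), min(v) - 1e-12)
  expect_lte(max(out2), max(v) + 1e-12)
})

test_that("short NA gaps are bridged and long gaps stay undefined", {
  v <- c(1, 2, NA, 4, 5, 6, 7, 8, 9, 10)
  out <- normalizeFile(v, N = 10)
  expect_equal(out, 1:10)                      # gap of 1 interpolates
  v2 <- c(1, 2, NA, NA, NA, 6, 7, 8, 9, 10)
  out2 <- normalizeFile(v2, N = 10)
  expect_true(all(is.na(out2[3:5])))
  expect_equal(out2[c(1, 2, 6:10)], c(1, 2, 6:10))
  expect_error(normalizeFile(3, N = 27), "two cells")
})

test_that("window-3 order-1 smoothing is the centered moving mean", {
  expect_equal(sgSmooth(c(1, 2, 4))[2], 7 / 3)
  const <- rep(2.2, 9)
  expect_equal(sgSmooth(const), const)
  lin <- seq(1, 5, by = 0.5)
  expect_equal(sgSmooth(lin), lin)             # order-1 reproduces lines
  expect_error(sgSmooth(c(1, 2), window = 3), "shorter")
})

test_that("percentage change tracks the preceding tracheid", {
  expect_equal(percentageChange(c(10, 11)), c(NA, 10))
  expect_equal(percentageChange(rep(4, 5)), c(NA, 0, 0, 0, 0))
  expect_equal(percentageChange(c(4, 2, 3)), c(NA, -50, 50))
  expect_equal(percentageChange(c(0, 5))[2], NA_real_)  # zero predecessor
})

test_that("pointwise bands collapse to zero width on identical files", {
  m <- matrix(rep(seq(20, 10, length.out = 27), each = 5), nrow = 5)
  b <- tracheidogramBands(m)
  expect_equal(b$sd, rep(0, 27))
  expect_equal(b$mean, seq(20, 10, length.out = 27))
  expect_equal(b$n, rep(5L, 27))
})

test_that("integration joins S2 pixels to cells and respects the pixel floor", {
  tr <- buildSection(smallModel(nFiles = 3, cellsPerFile = 6), seed = 2)
  pom <- renderPolarization(tr)
  res <- polInvert(pom$stacks[[1]], pom$optics)
  mfaRes <- mfaFromRetardation(res, pom$optics, wallMask = tr@wallMask)
  fl <- renderFluorescence(tr)
  seg <- segmentCells(fl$uv)
  files <- extractRadialFiles(seg$labels)
  cells <- measureCells(seg$labels, seg$wallBin, 0.5, files = files)
  ic <- integrateCells(seg$labels, cells, mfaRes)
  ct <- cellTable(tr)
  m <- matchToTruth(ic, ct)
  expect_lt(max(abs(ic$meanS2MfaTangentialDeg - ct$mfaS2TangentialDeg[m]),
                na.rm = TRUE), 1)
  expect_true(all(ic$nS2Tangential[!is.na(ic$meanS2MfaTangentialDeg)] >= 10))
  # raising the floor above any count undefines every mean
  ic2 <- integrateCells(seg$labels, cells, mfaRes,
                        minPixels = max(ic$nS2Tangential) + 1)
  expect_true(all(is.na(ic2$meanS2MfaTangentialDeg)))
})

test_that("an empty S2 mask leaves all means undefined", {
  tr <- buildSection(smallModel(nFiles = 2, cellsPerFile = 3), seed = 1)
  mfaRes <- new("MfaResult",
                mfaDeg = matrix(NA_real_, 10, 10),
                wallClass = matrix(0L, 10, 10),
                s2Mask = matrix(FALSE, 10, 10),
                s13Mask = matrix(FALSE, 10, 10),
                gaussianFit = c(mu = 45, sigma = 2, amplitude = 1))
  cells <- data.frame(label = 1:3)
  ic <- integrateCells(matrix(1L, 10, 10), cells, mfaRes)
  expect_true(all(is.na(ic$meanS2MfaTangentialDeg)))
  expect_true(all(is.na(ic$meanS2MfaRadialDeg)))
})

test_that("integration commutes with a pure translation", {
  tr <- buildSection(smallModel(nFiles = 3, cellsPerFile = 6), seed = 2)
  pom <- renderPolarization(tr)
  res <- polInvert(pom$stacks[[1]], pom$optics)
  mfaRes <- mfaFromRetardation(res, pom$optics, wallMask = tr@wallMask)
  fl <- renderFluorescence(tr)
  seg <- segmentCells(fl$uv)
  cells <- data.frame(label = sort(unique(seg$labels[seg$labels > 0])))
  idOut <- integrateCells(seg$labels, cells, mfaRes)
  # shift the FLM frame by (dy, dx) = (7, 11) and register accordingly
  dy <- 7L; dx <- 11L
  big <- matrix(0L, nrow(seg$labels) + dy, ncol(seg$labels) + dx)
  big[(dy + 1):nrow(big), (dx + 1):ncol(big)] <- seg$labels
  tf <- new("RegistrationTransform", scale = 1, rotationDeg = 0,
            translation = c(dx, dy),
            matrix = rbind(c(1, 0, dx), c(0, 1, dy), c(0, 0, 1)),
            peak = 1, inlierCount = NA_real_)
  shifted <- integrateCells(big, cells, mfaRes, transform = tf)
  expect_equal(shifted$meanS2MfaTangentialDeg, idOut$meanS2MfaTangentialDeg)
  expect_equal(shifted$meanS2MfaRadialDeg, idOut$meanS2MfaRadialDeg)
})
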