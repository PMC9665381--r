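test_that("phase correlation identifies the null shift of identical images", {
  set.seed(3)
  a <- matrix(rnorm(64 * 64), 64)
  s <- pocShift(a, a)
  expect_equal(unname(s[1:2]), c(0, 0))
  expect_gt(s[["peak"]], 0.99)
})

test_that("phase correlation recovers a circular roll exactly", {
  set.seed(4)
  a <- matrix(rnorm(80 * 96), 80)
  b <- tracheidMFA:::rollMatrix(a, 17, -5)
  s <- pocShift(a, b)
  expect_equal(unname(s[1:2]), c(17, -5))
  expect_gt(s[["peak"]], 0.99)
})

test_that("unrelated noise images correlate weakly and constants error", {
  set.seed(5)
  a <- matrix(rnorm(96 * 96), 96)
  b <- matrix(rnorm(96 * 96), 96)
  expect_lt(pocShift(a, b)[["peak"]], 0.1)
  expect_error(pocShift(matrix(1, 8, 8), a[1:8, 1:8]), "constant")
})

test_that("the nominal window steers peak choice on periodic scenes", {
  set.seed(8)
  motif <- matrix(runif(16), 4)
  period <- motif[rep(1:4, 8), rep(1:4, 8)]      # strictly 4-periodic scene
  rolled <- tracheidMFA:::rollMatrix(period, 0, 1)
  g <- pocShift(period, rolled)
  expect_true(unname(g[2]) %% 4 == 1)            # global: any alias
  s <- pocShift(period, rolled, nominal = c(0, 1), maxDev = c(1, 1))
  expect_equal(unname(s[2]), 1)                  # windowed: the true shift
})

test_that("a tile grid with jittered origins stitches back to the scene", {
  tr <- buildSection(smallModel(nFiles = 6, cellsPerFile = 12), seed = 2)
  uv <- renderFluorescence(tr)$uv
  cu <- tracheidMFA:::cutTiles(uv, c(3, 4), 0.66, jitterPx = 3, seed = 7)
  st <- stitchTiles(cu$tiles, c(3, 4), 0.66)
  expect_true(all(st$offsets == cu$offsets))
  expect_length(st$flagged, 0)
  # mosaic equals the scene wherever tiles cover it
  cover <- stitchWithOffsets(lapply(cu$tiles, function(t) t * 0 + 1),
                             st$offsets) > 0
  scene <- uv[seq_len(nrow(st$mosaic)), seq_len(ncol(st$mosaic))]
  expect_gte(mean(st$mosaic[cover] == scene[cover]), 0.999)
})

test_that("a 1x1 grid is the identity", {
  m <- matrix(runif(200), 10)
  expect_identical(stitchWithOffsets(list(m), matrix(0L, 1, 2)), m)
})

test_that("registering an image onto itself is the identity transform", {
  tr <- buildSection(smallModel(), seed = 1)
  uv <- renderFluorescence(tr)$uv
  tf <- registerImages(uv, uv)
  expect_equal(tf@scale, 1)
  expect_equal(tf@rotationDeg, 0)
  expect_equal(tf@translation, c(0, 0))
  expect_gt(tf@peak, 0.99)
})

test_that("a pure translation registration agrees with direct phase correlation", {
  tr <- buildSection(smallModel(nFiles = 6, cellsPerFile = 10), seed = 1)
  uv <- renderFluorescence(tr)$uv
  big <- matrix(0.15, nrow(uv) + 40, ncol(uv) + 60)
  big[21:(20 + nrow(uv)), 41:(40 + ncol(uv))] <- uv
  crop <- big[seq_len(nrow(uv)), seq_len(ncol(uv))]
  tf <- registerImages(uv, crop)
  s <- pocShift(uv, crop)
  expect_equal(tf@translation, unname(s[c("dx", "dy")]))
  expect_equal(tf@translation, c(40, 20))
  # transform maps a POM point to its FLM position
  p <- c(100, 80, 1) %*% t(tf@matrix)
  expect_equal(as.numeric(p[1:2]), c(140, 100))
})

test_that("scale and rotation between modalities are recovered within tolerance", {
  tr <- buildSection(sectionModel(nFiles = 8, cellsPerFile = 12,
                                  rayAfterFile = 3L), seed = 1)
  flm <- renderFluorescence(tr)$uv
  pom <- renderPolarization(tr, pixelScale = 4, rotationDeg = 3)
  tf <- registerImages(pom$retardation, flm)
  expect_lt(abs(tf@scale - 4) / 4, 0.01)
  expect_lt(abs(tf@rotationDeg - (-3)), 0.5)
})
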