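op <- opticsConfig()

test_that("retardation model matches the hand-derived constants", {
  expect_equal(mfaToRetardation(0, op), 0, tolerance = 1e-9)
  # Gamma(90) = t f (nE - nO) = 5000 * 0.5 * 0.070
  expect_equal(mfaToRetardation(90, op), 175)
  # Gamma(45) via nE'(45) = nO nE / sqrt((nO^2 + nE^2)/2), worked by hand
  expect_equal(mfaToRetardation(45, op), 84.56368, tolerance = 1e-6)
})

test_that("retardation grows strictly and continuously with MFA", {
  mu <- seq(0, 90, by = 0.25)
  g <- mfaToRetardation(mu, op)
  expect_true(all(diff(g) > 0))
  expect_lt(max(diff(g)), 2)            # no jumps at 0.25 deg steps
})

test_that("MFA conversion round-trips to numerical precision", {
  mu <- seq(5, 85, by = 5)
  back <- retardationToMfa(mfaToRetardation(mu, op), op)
  expect_lt(max(abs(back - mu)), 1e-4)
  mu1 <- seq(1, 89, by = 1)
  expect_lt(max(abs(retardationToMfa(mfaToRetardation(mu1, op), op) - mu1)),
            1e-4)
})

test_that("out-of-range retardation clamps to 90 degrees and negatives error", {
  out <- retardationToMfa(c(10, 200), op)
  expect_equal(as.numeric(out[2]), 90)
  expect_equal(attr(out, "clamped"), 1L)
  expect_error(retardationToMfa(-1, op), "non-negative")
})

test_that("wall classification recovers the 45-degree tangential peak from jittered azimuths", {
  tr <- buildSection(smallModel(azimuthJitterSd = 2), seed = 5)
  cls <- classifyWalls(tr@azimuthTrue, tr@wallMask)
  expect_lt(abs(cls$gaussianFit["mu"] - 45), 0.5)
  tangTrue <- tr@wallClassTrue == 2L
  recall <- sum(cls$wallClass == 2L & tangTrue) / sum(tangTrue)
  expect_gte(recall, 0.99)
  # partition: tangential + radial = wall mask, disjoint
  expect_equal(cls$wallClass > 0L, tr@wallMask)
  expect_equal(sum(cls$wallClass == 1L) + sum(cls$wallClass == 2L),
               sum(tr@wallMask))
})

test_that("wall classification is invariant to pixel ordering and equivariant in azimuth", {
  tr <- buildSection(smallModel(), seed = 5)
  cls <- classifyWalls(tr@azimuthTrue, tr@wallMask)
  rot <- classifyWalls((tr@azimuthTrue + 20) %% 180, tr@wallMask)
  expect_lt(abs(((rot$gaussianFit["mu"] - cls$gaussianFit["mu"] - 20 + 90)
                 %% 180) - 90), 0.2)
})

test_that("a single-valued azimuth population degenerates to all-tangential", {
  az <- matrix(NA_real_, 20, 20)
  wall <- matrix(FALSE, 20, 20)
  wall[5:15, 5:15] <- TRUE
  az[wall] <- 45
  cls <- classifyWalls(az, wall)
  expect_true(all(cls$wallClass[wall] == 2L))
  expect_equal(sum(cls$wallClass == 1L), 0L)
})

test_that("a flat azimuth histogram is an error advising rotation check", {
  set.seed(1)
  az <- matrix(runif(400, 0, 180), 20)
  wall <- matrix(TRUE, 20, 20)
  expect_error(classifyWalls(az, wall), "sample_rotation")
})

test_that("valley detection isolates the S2 midline of a high-low-high wall band", {
  # one vertical tangential wall band, MFA 35-20-35 across its width
  mfa <- matrix(NA_real_, 10, 9)
  wc <- matrix(0L, 10, 9)
  wc[, 4:6] <- 2L
  mfa[, 4] <- 35; mfa[, 5] <- 20; mfa[, 6] <- 35
  d <- detectS2(mfa, wc)
  expect_true(all(d$s2Mask[, 5]))
  expect_true(all(d$s13Mask[, c(4, 6)]))
  expect_false(any(d$s2Mask & d$s13Mask))
  expect_false(any(d$s2Mask[, -5]))
})

test_that("uniform wall bands yield no valley or ridge pixels", {
  mfa <- matrix(NA_real_, 10, 9)
  wc <- matrix(0L, 10, 9)
  wc[, 4:6] <- 2L
  mfa[, 4:6] <- 20
  d <- detectS2(mfa, wc)
  expect_equal(sum(d$s2Mask), 0L)
  expect_equal(sum(d$s13Mask), 0L)
})

test_that("radial wall bands are scanned across rows", {
  mfa <- matrix(NA_real_, 9, 10)
  wc <- matrix(0L, 9, 10)
  wc[4:6, ] <- 1L
  mfa[4, ] <- 35; mfa[5, ] <- 18; mfa[6, ] <- 35
  d <- detectS2(mfa, wc)
  expect_true(all(d$s2Mask[5, ]))
  expect_true(all(d$s13Mask[c(4, 6), ]))
})

test_that("phantom per-cell S2 means recover truth within a degree", {
  tr <- buildSection(smallModel(), seed = 3)
  pom <- renderPolarization(tr)
  res <- polInvert(pom$stacks[[1]], pom$optics)
  mfaRes <- mfaFromRetardation(res, pom$optics, wallMask = tr@wallMask)
  labs <- labelImage(tr)
  ct <- cellTable(tr)
  idx <- which(s2Mask(mfaRes) & wallClass(mfaRes) == 2L & labs > 0)
  mu <- tapply(mfaMap(mfaRes)[idx], labs[idx], mean)
  err <- abs(mu[as.character(ct$label)] - ct$mfaS2TangentialDeg)
  expect_lt(max(err, na.rm = TRUE), 1)
})
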