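test_that("the robust screen flags gross outliers and spares clean positions", {
  m <- matrix(rep(c(2, 2.1, 1.9, 2.05, 2), 3), nrow = 5)
  expect_true(all(screenOutliers(m)))
  m[3, 2] <- 21                                   # 10x the rest
  keep <- screenOutliers(m)
  expect_false(keep[3, 2])
  expect_equal(sum(!keep), 1L)
  # all-equal position: MAD 0 but nothing flagged
  m2 <- matrix(5, 6, 3)
  expect_true(all(screenOutliers(m2)))
  # fewer than four values: no screening
  m3 <- matrix(c(1, 1, 100), 3, 1)
  expect_true(all(screenOutliers(m3)))
})

test_that("normalized positions map back to raw cells bijectively at equal length", {
  expect_equal(mapNormalizedToRaw(1:27, 27, 27), 1:27)
  p <- mapNormalizedToRaw(1:27, 14, 27)
  expect_true(all(p >= 1 & p <= 14))
  expect_equal(p[1], 1)
  expect_equal(p[27], 14)
})

test_that("Pearson correlation matches the covariance formula on a printed toy set", {
  x <- c(1.2, 3.4, 2.2, 5.0, 4.1)
  y <- c(10.0, 14.1, 11.3, 19.9, 16.0)
  rec <- data.frame(p = x, meanS2MfaTangentialDeg = y)
  out <- correlateMfa(rec, "p", wall = "tangential")
  rHand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, rHand, tolerance = 1e-12)
  expect_equal(out$n, 5L)
  # perfect and degenerate cases
  recId <- data.frame(p = 1:10, meanS2MfaTangentialDeg = 1:10)
  expect_equal(correlateMfa(recId, "p")$r, 1)
  recConst <- data.frame(p = rep(1, 5), meanS2MfaTangentialDeg = rnorm(5))
  expect_true(is.na(correlateMfa(recConst, "p")$r))
})

test_that("assumption checks gate the nonparametric route", {
  set.seed(21)
  g <- rnorm(60)
  same <- list(a = g, b = g, c = g)
  chk <- checkAssumptions(same)
  expect_gt(chk$bartlettP, 0.99)
  ties <- list(a = rep(1, 10), b = rnorm(10, 0, 1))
  chk2 <- checkAssumptions(ties)
  expect_true(is.na(chk2$shapiroP[1]))
  expect_true(chk2$degenerate[1])
  mixed <- list(a = rnorm(50, 0, 1), b = rnorm(50, 0, 5))
  expect_lt(checkAssumptions(mixed)$bartlettP, 0.01)
})

test_that("Steel-Dwass finds nothing among identical groups and everything between separated ones", {
  gSame <- replicate(4, rep(c(1, 2, 3, 4), 4), simplify = FALSE)
  rSame <- steelDwass(gSame)
  expect_true(all(rSame$p == 1))
  expect_false(any(rSame$significant))
  # two fully separated groups, n = 10: W = 155, E = 105, V = 175
  rSep <- steelDwass(list(a = 1:10, b = 101:110))
  expect_equal(abs(rSep$statistic), 50 / sqrt(175), tolerance = 1e-12)
  expect_true(rSep$significant)
  expect_lt(rSep$p, 0.05)
})

test_that("Steel-Dwass is invariant under strictly monotone transforms", {
  set.seed(31)
  g <- list(rnorm(9), rnorm(9, 0.7), rnorm(9, 0.3), rnorm(9, 1.1))
  p0 <- steelDwass(g)$p
  expect_equal(steelDwass(lapply(g, exp))$p, p0)
  expect_equal(steelDwass(lapply(g, function(v) 3 * v - 100))$p, p0)
})

test_that("the pairwise matrix is symmetric with an undefined diagonal", {
  set.seed(41)
  g <- list(rnorm(6), rnorm(6), rnorm(6))
  pm <- attr(steelDwass(g), "pMatrix")
  expect_equal(pm, t(pm))
  expect_true(all(is.na(diag(pm))))
  expect_true(all(pm[upper.tri(pm)] >= 0 & pm[upper.tri(pm)] <= 1))
})

test_that("asymptotic p-values track a permutation oracle on a small design", {
  set.seed(17)
  groups <- list(rnorm(12), rnorm(12, 0.9), rnorm(12, 0.45))
  obs <- steelDwass(groups)
  pooled <- unlist(groups)
  idx <- rep(1:3, each = 12)
  pairs <- utils::combn(3, 2)
  B <- 4000
  maxs <- vapply(seq_len(B), function(b) {
    gp <- split(sample(pooled), idx)
    max(apply(pairs, 2, function(pr)
      abs(tracheidMFA:::steelDwassStatistic(gp[[pr[1]]], gp[[pr[2]]]))))
  }, numeric(1))
  pPerm <- vapply(abs(obs$statistic), function(t) mean(maxs >= t),
                  numeric(1))
  expect_lt(max(abs(obs$p - pPerm)), 0.08)
})
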