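#' Robust outlier screen across tracheidogram positions
#'
#' At each normalized position the across-file values are screened with the
#' modified z-score, \eqn{0.6745\,(x - \mathrm{med})/\mathrm{MAD}}; values
#' beyond \code{threshold} (default 3.5) are flagged. Positions with fewer
#' than four finite values are not screened. With a zero MAD (ties at the
#' median) any value off the median has an infinite score and is flagged,
#' while an all-equal position flags nothing.
#'
#' @param fileMatrix numeric matrix, files x normalized positions (as
#'   produced by stacking \code{\link{normalizeFile}} outputs).
#' @param threshold modified z-score cutoff.
#' @return logical keep-mask of the same shape (TRUE = keep).
#' @seealso \code{\link{mapNormalizedToRaw}} to push flags back to raw
#'   cells.
#' @export
screenOutliers <- function(fileMatrix, threshold = 3.5) {
  keep <- matrix(TRUE, nrow(fileMatrix), ncol(fileMatrix))
  for (j in seq_len(ncol(fileMatrix))) {
    x <- fileMatrix[, j]
    ok <- is.finite(x)
    if (sum(ok) < 4) next
    med <- stats::median(x[ok])
    mad0 <- stats::median(abs(x[ok] - med))
    z <- 0.6745 * (x - med) / mad0       # Inf when mad0 == 0 and x != med
    z[x == med] <- 0
    keep[, j] <- !(ok & abs(z) > threshold)
  }
  keep
}

#' Map a normalized-grid position back to a raw cell index
#'
#' The flag raised at normalized position \code{p} (grid length \code{N})
#' of a file with \code{n} raw cells belongs to the raw cell whose scaled
#' index is nearest: \code{round((p-1)(n-1)/(N-1)) + 1}. The mapping is a
#' bijection when \code{n == N}.
#'
#' @param p normalized position(s), 1-based.
#' @param n raw file length.
#' @param N normalized grid length.
#' @return raw cell index (vectorized over \code{p}).
#' @export
mapNormalizedToRaw <- function(p, n, N = 27) {
  round((p - 1) * (n - 1) / (N - 1)) + 1
}

#' Pearson correlation between an anatomical parameter and mean S2 MFA
#'
#' Listwise deletion of incomplete pairs, then the textbook product-moment
#' correlation with its two-sided t-test p-value.
#'
#' @param records integrated cell table (see \code{\link{integrateCells}}).
#' @param parameter column name of the anatomical parameter.
#' @param wall \code{"radial"} or \code{"tangential"}: which wall's mean S2
#'   MFA to correlate against.
#' @return list(r, p, n); r is NA when fewer than 3 complete pairs remain
#'   or a variable is constant.
#' @export
correlateMfa <- function(records, parameter,
                         wall = c("tangential", "radial")) {
  wall <- match.arg(wall)
  mfaCol <- if (wall == "radial") "meanS2MfaRadialDeg" else
    "meanS2MfaTangentialDeg"
  x <- records[[parameter]]
  y <- records[[mfaCol]]
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(r = NA_real_, p = NA_real_, n = n))
  ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Correlation table of all anatomical parameters vs per-wall S2 MFA
#'
#' @param records integrated cell table.
#' @param parameters column names to correlate (default: the seven
#'   anatomical parameters).
#' @return data.frame: parameter, wall, r, p, n.
#' @export
mfaCorrelationTable <- function(records, parameters = c(
  "tracheidTransverseAreaUm2", "tracheidRadialDiameterUm",
  "tracheidTangentialDiameterUm", "lumenTransverseAreaUm2",
  "lumenRadialDiameterUm", "cellWallAreaUm2", "cellWallOccupancy",
  "tangentialWallThicknessUm")) {
  grid <- expand.grid(parameter = parameters,
                      wall = c("radial", "tangential"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i)
    correlateMfa(records, grid$parameter[i], grid$wall[i]))
  data.frame(parameter = grid$parameter, wall = grid$wall,
             r = vapply(res, `[[`, numeric(1), "r"),
             p = vapply(res, `[[`, numeric(1), "p"),
             n = vapply(res, `[[`, numeric(1), "n"))
}

#' Normality and homoscedasticity gate for position groups
#'
#' Shapiro-Wilk per group and Bartlett across groups -- the standard checks
#' run before choosing a nonparametric all-pairs comparison. Degenerate
#' groups (all ties) make Shapiro unavailable; they are reported with NA
#' and flagged.
#'
#' @param groups list of numeric vectors (each n >= 3).
#' @return list: \code{shapiroP} (per group, NA where degenerate),
#'   \code{degenerate} (logical per group), \code{bartlettP}.
#' @export
checkAssumptions <- function(groups) {
  stopifnot(length(groups) >= 2)
  sp <- vapply(groups, function(g) {
    if (length(g) < 3) return(NA_real_)
    tryCatch(stats::shapiro.test(g)$p.value, error = function(e) NA_real_)
  }, numeric(1))
  degen <- vapply(groups, function(g) stats::sd(g) == 0, logical(1))
  bp <- tryCatch(
    stats::bartlett.test(groups)$p.value, error = function(e) NA_real_)
  list(shapiroP = sp, degenerate = degen, bartlettP = bp)
}

# Standardized pairwise rank statistic of the Steel-Dwass family:
# joint mid-ranks of the pair, tie-corrected variance, returns t such that
# sqrt(2)*|t| is referred to the studentized range with k groups, df = Inf.
steelDwassStatistic <- function(xi, xj) {
  ni <- length(xi); nj <- length(xj); N <- ni + nj
  r <- rank(c(xi, xj))
  W <- sum(r[seq_len(ni)])
  E <- ni * (N + 1) / 2
  V <- ni * nj / (N * (N - 1)) * sum((r - (N + 1) / 2)^2)
  if (V <= 0) return(0)
  (W - E) / sqrt(V)
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For every pair of groups the joint mid-ranks give a standardized
#' Wilcoxon statistic with tie-corrected variance; \eqn{\sqrt 2\,|t|} is
#' referred to the studentized range distribution with \code{k} groups and
#' infinite degrees of freedom, controlling the family-wise error at
#' \code{alpha} over all simultaneous pairwise comparisons. An all-tied
#' pair has p = 1.
#'
#' @param groups list of >= 2 numeric vectors, each of length >= 2.
#' @param alpha family-wise significance level (default 0.05).
#' @return data.frame with one row per unordered pair: i, j, statistic
#'   (standardized rank statistic), p, significant; the symmetric p-value
#'   matrix is attached as attribute \code{"pMatrix"}.
#' @examples
#' g <- list(a = rnorm(8), b = rnorm(8, 2), c = rnorm(8))
#' steelDwass(g)
#' @export
steelDwass <- function(groups, alpha = 0.05) {
  k <- length(groups)
  stopifnot(k >= 2, all(vapply(groups, length, 1L) >= 2))
  pairs <- utils::combn(k, 2)
  res <- data.frame(i = pairs[1, ], j = pairs[2, ], statistic = NA_real_,
                    p = NA_real_, significant = NA)
  for (m in seq_len(ncol(pairs))) {
    t <- steelDwassStatistic(groups[[pairs[1, m]]], groups[[pairs[2, m]]])
    p <- if (t == 0 && stats::sd(c(groups[[pairs[1, m]]],
                                   groups[[pairs[2, m]]])) == 0) 1 else
      stats::ptukey(sqrt(2) * abs(t), nmeans = k, df = Inf,
                    lower.tail = FALSE)
    res$statistic[m] <- t
    res$p[m] <- p
    res$significant[m] <- p < alpha
  }
  pm <- matrix(NA_real_, k, k)
  pm[cbind(res$i, res$j)] <- res$p
  pm[cbind(res$j, res$i)] <- res$p
  nm <- names(groups)
  if (!is.null(nm)) dimnames(pm) <- list(nm, nm)
  attr(res, "pMatrix") <- pm
  res
}
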