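#' Attach per-wall mean S2 MFA to segmented cells
#'
#' Every S2-valley pixel of the MFA result is mapped from the POM frame into
#' the FLM frame through the registration transform, assigned to the
#' enclosing segmented cell and to its wall class, and per-cell per-class
#' means are computed. Means resting on fewer than \code{minPixels} pixels
#' are left NA (variance control).
#'
#' @param labels FLM-frame integer label raster.
#' @param cells data.frame of cell records (one row per label), e.g. from
#'   \code{\link{measureCells}}.
#' @param mfa an \linkS4class{MfaResult} in the POM frame.
#' @param transform a \linkS4class{RegistrationTransform} mapping POM to FLM
#'   pixel coordinates; NULL means the frames already coincide.
#' @param minPixels minimum S2 pixel count per cell and wall class.
#' @return \code{cells} with columns \code{meanS2MfaRadialDeg},
#'   \code{meanS2MfaTangentialDeg}, \code{nS2Radial}, \code{nS2Tangential}.
#' @export
integrateCells <- function(labels, cells, mfa, transform = NULL,
                           minPixels = 10) {
  stopifnot(is(mfa, "MfaResult"))
  idx <- which(s2Mask(mfa))
  out <- cells
  out$meanS2MfaRadialDeg <- NA_real_
  out$meanS2MfaTangentialDeg <- NA_real_
  out$nS2Radial <- 0L
  out$nS2Tangential <- 0L
  if (!length(idx)) return(out)
  nrP <- nrow(mfaMap(mfa))
  py <- ((idx - 1) %% nrP) + 1
  px <- ((idx - 1) %/% nrP) + 1
  if (!is.null(transform)) {
    xy <- cbind(px, py, 1) %*% t(transform@matrix)
    fx <- round(xy[, 1]); fy <- round(xy[, 2])
  } else {
    fx <- px; fy <- py
  }
  ok <- fy >= 1 & fy <= nrow(labels) & fx >= 1 & fx <= ncol(labels)
  lab <- integer(length(idx))
  lab[ok] <- labels[cbind(fy[ok], fx[ok])]
  cls <- wallClass(mfa)[idx]
  val <- mfaMap(mfa)[idx]
  keep <- ok & lab > 0 & cls > 0 & is.finite(val)
  if (!any(keep)) return(out)
  agg <- stats::aggregate(val[keep],
                          by = list(label = lab[keep], class = cls[keep]),
                          FUN = function(v) c(mean(v), length(v)))
  m <- match(agg$label, out$label)
  for (i in seq_len(nrow(agg))) {
    if (is.na(m[i])) next
    mu <- agg$x[i, 1]; n <- agg$x[i, 2]
    if (agg$class[i] == 1L) {
      out$nS2Radial[m[i]] <- n
      if (n >= minPixels) out$meanS2MfaRadialDeg[m[i]] <- mu
    } else {
      out$nS2Tangential[m[i]] <- n
      if (n >= minPixels) out$meanS2MfaTangentialDeg[m[i]] <- mu
    }
  }
  out
}

#' Normalize a radial-file value sequence to a common cell count
#'
#' Piecewise-linear interpolation of the per-cell sequence from its native
#' index grid (scaled to [0, 1]) onto \code{N} equispaced positions, so
#' files of different lengths can be averaged position by position
#' (the tracheidogram convention). NA runs of up to \code{maxGap} cells are
#' bridged by the interpolation; positions falling inside longer NA runs
#' stay NA.
#'
#' @param values per-cell values, earlywood first (length >= 2).
#' @param N target grid length (default 27, the study's mean tracheid
#'   count per file).
#' @param maxGap longest internal NA run that may be interpolated across.
#' @return numeric vector of length \code{N}.
#' @examples
#' normalizeFile(seq(0, 1, length.out = 14), N = 27)
#' @export
normalizeFile <- function(values, N = 27, maxGap = 2) {
  n <- length(values)
  if (n < 2) stop("need at least two cells per file")
  good <- is.finite(values)
  if (sum(good) < 2) return(rep(NA_real_, N))
  t0 <- seq(0, 1, length.out = n)
  tOut <- seq(0, 1, length.out = N)
  out <- stats::approx(t0[good], values[good], xout = tOut, rule = 1)$y
  r <- rle(!good)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (k in which(r$values & r$lengths > maxGap)) {
    lo <- if (starts[k] > 1) t0[starts[k] - 1] else -Inf
    hi <- if (ends[k] < n) t0[ends[k] + 1] else Inf
    out[tOut > lo & tOut < hi] <- NA_real_
  }
  # endpoints of an all-defined sequence are preserved exactly
  if (good[1]) out[1] <- values[1]
  if (good[n]) out[N] <- values[n]
  out
}

#' Savitzky-Golay smoothing of a tracheidogram array
#'
#' Thin wrapper around \code{signal::sgolayfilt} with the denoising
#' defaults used for mean-MFA file arrays: window 3, polynomial order 1
#' (a centered moving mean that reproduces linear trends exactly). Edges
#' are handled by the filter's polynomial startup frames. Internal NA runs
#' are left in place; each complete run at least one window long is
#' smoothed separately.
#'
#' @param values numeric vector.
#' @param window odd filter length (default 3).
#' @param order polynomial order < window (default 1).
#' @return smoothed vector, same length.
#' @examples
#' sgSmooth(c(1, 2, 4))[2]  # 7/3
#' @export
sgSmooth <- function(values, window = 3, order = 1) {
  stopifnot(window %% 2 == 1, order < window)
  if (length(values) < window) stop("array shorter than the filter window")
  good <- is.finite(values)
  if (all(good))
    return(signal::sgolayfilt(values, p = order, n = window))
  out <- values
  r <- rle(good)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  for (k in which(r$values & r$lengths >= window)) {
    seg <- starts[k]:ends[k]
    out[seg] <- signal::sgolayfilt(values[seg], p = order, n = window)
  }
  out
}

#' Percentage change from the preceding tracheid
#'
#' \code{out[i] = 100 (v[i] - v[i-1]) / v[i-1]}; the first element is NA,
#' as is any element whose predecessor is zero or undefined.
#'
#' @param values numeric vector (length >= 2).
#' @return numeric vector, same length.
#' @examples
#' percentageChange(c(4, 2, 3))  # NA -50 50
#' @export
percentageChange <- function(values) {
  stopifnot(length(values) >= 2)
  prev <- values[-length(values)]
  d <- 100 * (values[-1] - prev) / prev
  d[!is.finite(d) | prev == 0] <- NA_real_
  c(NA_real_, d)
}

#' Pointwise mean and dispersion bands over normalized files
#'
#' Stacks per-file normalized arrays and returns, per grid position, the
#' across-file mean, standard deviation and standard error (NA-aware).
#'
#' @param fileMatrix numeric matrix, files x positions.
#' @return data.frame: position, mean, sd, se, n.
#' @export
tracheidogramBands <- function(fileMatrix) {
  n <- colSums(is.finite(fileMatrix))
  mu <- colMeans(fileMatrix, na.rm = TRUE)
  sd <- apply(fileMatrix, 2, stats::sd, na.rm = TRUE)
  data.frame(position = seq_len(ncol(fileMatrix)), mean = mu, sd = sd,
             se = sd / sqrt(pmax(n, 1)), n = n)
}
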