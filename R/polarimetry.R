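#' Forward model of the three-frame polarization acquisition
#'
#' Renders the three intensity frames a circular polariscope with a rotating
#' polarizer records from a birefringent specimen:
#' \deqn{I_k = \frac{I_0}{2}\left[1 + \sin\delta \,
#'   \sin 2(\alpha_k - \varphi)\right], \qquad
#'   \delta = \frac{2\pi\Gamma}{\lambda},}
#' with \eqn{\Gamma} the retardation (nm), \eqn{\varphi} the slow-axis
#' azimuth, and \eqn{\alpha_k} the k-th polarizer angle. A per-frame
#' background offset (stray light) is added on top.
#'
#' @param retardationNm retardation raster in nm; the model is unambiguous
#'   for \eqn{\Gamma \le \lambda/4}.
#' @param azimuthDeg azimuth raster, degrees (mod 180).
#' @param meanIntensity transmitted mean intensity \eqn{I_0} (scalar or
#'   raster).
#' @param optics an \linkS4class{OpticsConfig}.
#' @param background scalar, raster or h x w x 3 array added per frame.
#' @return h x w x 3 array of frame intensities.
#' @seealso \code{\link{polInvert}} for the closed-form inverse.
#' @examples
#' op <- opticsConfig()
#' fr <- polForward(matrix(84.5, 8, 8), matrix(30, 8, 8), 1000, op)
#' dim(fr)
#' @export
polForward <- function(retardationNm, azimuthDeg, meanIntensity, optics,
                       background = 0) {
  retardationNm <- as.matrix(retardationNm)
  azimuthDeg <- as.matrix(azimuthDeg)
  d <- dim(retardationNm)
  if (length(meanIntensity) == 1)
    meanIntensity <- matrix(meanIntensity, d[1], d[2])
  delta <- 2 * pi * retardationNm / optics@wavelengthNm
  out <- array(0, c(d, 3))
  bg <- background
  if (length(bg) == 1) bg <- array(bg, c(d, 3))
  if (length(dim(bg)) == 2) bg <- array(bg, c(d, 3))
  for (k in 1:3) {
    a <- deg2rad(optics@polarizerAnglesDeg[k])
    out[, , k] <- meanIntensity / 2 *
      (1 + sin(delta) * sin(2 * (a - deg2rad(azimuthDeg)))) + bg[, , k]
  }
  out
}

#' Invert a polarization triplet to retardation and azimuth maps
#'
#' Closed-form per-pixel solution of the three-frame model of
#' \code{\link{polForward}} after background subtraction. Writing
#' \eqn{I_k = c + s\,[\sin 2\alpha_k \cos 2\varphi - \cos 2\alpha_k
#' \sin 2\varphi]} with \eqn{c = I_0/2} and \eqn{s = (I_0/2)\sin\delta},
#' the three frames form a linear system in
#' \eqn{(c,\; s\cos 2\varphi,\; s\sin 2\varphi)} that is solved exactly for
#' any three polarizer angles pairwise distinct modulo 180. Then
#' \eqn{\sin\delta = \sqrt{u_2^2+u_3^2}/c} and
#' \eqn{2\varphi = \mathrm{atan2}(u_3, u_2)}.
#'
#' Pixels with \eqn{I_0} below \code{i0Floor} times the stack maximum are
#' masked invalid (lumina, mounting medium). Pixels where noise pushes
#' \eqn{|\sin\delta|} above 1 are clamped to the quarter-wave retardation
#' \eqn{\lambda/4} and flagged in \code{clampedMask}; retardations above that
#' bound are not unwrapped. The azimuth is undefined (NA) where the
#' retardation vanishes.
#'
#' @param stack a \linkS4class{PolarizationStack}.
#' @param optics an \linkS4class{OpticsConfig} (supplies wavelength; the
#'   polarizer angles of the stack are used).
#' @param i0Floor invalid-pixel floor as a fraction of the maximum
#'   background-corrected mean intensity (default 0.01).
#' @return A \linkS4class{RetardationResult}.
#' @examples
#' op <- opticsConfig()
#' fr <- polForward(matrix(50, 16, 16), matrix(70, 16, 16), 1000, op)
#' res <- polInvert(polarizationStack(fr), op)
#' range(retardation(res))
#' @export
polInvert <- function(stack, optics, i0Floor = 0.01) {
  validObject(stack)
  f <- stack@frames - stack@background
  d <- dim(f)[1:2]
  a <- deg2rad(stack@anglesDeg)
  A <- cbind(1, sin(2 * a), -cos(2 * a))
  Ainv <- solve(A)
  F <- matrix(f, prod(d), 3)
  U <- F %*% t(Ainv)                    # columns: c, s*cos2phi, s*sin2phi
  i0 <- 2 * U[, 1]
  floorVal <- i0Floor * max(i0, 0, na.rm = TRUE)
  valid <- is.finite(i0) & i0 > floorVal
  s <- sqrt(U[, 2]^2 + U[, 3]^2)
  sinDelta <- ifelse(valid & U[, 1] > 0, s / U[, 1], NA_real_)
  clamped <- valid & !is.na(sinDelta) & sinDelta > 1
  sinDelta <- pmin(sinDelta, 1)
  gamma <- optics@wavelengthNm / (2 * pi) * asin(sinDelta)
  phi <- (rad2deg(atan2(U[, 3], U[, 2])) / 2) %% 180
  phi[!valid | is.na(sinDelta) | sinDelta < 1e-12] <- NA_real_
  gamma[!valid] <- NA_real_
  new("RetardationResult",
      retardationNm = matrix(gamma, d[1], d[2]),
      azimuthDeg = matrix(phi, d[1], d[2]),
      meanIntensity = matrix(i0, d[1], d[2]),
      validMask = matrix(valid, d[1], d[2]),
      clampedMask = matrix(clamped, d[1], d[2]))
}
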