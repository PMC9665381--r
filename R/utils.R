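# Shared raster and angle helpers (internal).

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Signed circular difference a - b reduced to (-period/2, period/2].
circularDiffDeg <- function(a, b, period = 180) {
  d <- (a - b) %% period
  ifelse(d > period / 2, d - period, d)
}

# Circular (wrapped) roll of a matrix by integer (dy, dx): content at (i, j)
# moves to (i + dy, j + dx) modulo the raster size.
rollMatrix <- function(m, dy, dx) {
  nr <- nrow(m); nc <- ncol(m)
  i <- ((seq_len(nr) - 1 - dy) %% nr) + 1
  j <- ((seq_len(nc) - 1 - dx) %% nc) + 1
  m[i, j, drop = FALSE]
}

# Vectorized bilinear sampling of matrix img at fractional (row, col)
# positions; coordinates outside the raster return `fill`.
bilinearSample <- function(img, row, col, fill = 0) {
  nr <- nrow(img); nc <- ncol(img)
  r0 <- floor(row); c0 <- floor(col)
  fr <- row - r0; fc <- col - c0
  ok <- r0 >= 1 & c0 >= 1 & r0 <= nr - 1 & c0 <= nc - 1
  # clamp to keep indices legal; masked out below
  r0c <- pmin(pmax(r0, 1), nr - 1); c0c <- pmin(pmax(c0, 1), nc - 1)
  i00 <- cbind(r0c, c0c); i10 <- cbind(r0c + 1, c0c)
  i01 <- cbind(r0c, c0c + 1); i11 <- cbind(r0c + 1, c0c + 1)
  v <- (1 - fr) * (1 - fc) * img[i00] + fr * (1 - fc) * img[i10] +
    (1 - fr) * fc * img[i01] + fr * fc * img[i11]
  v[!ok] <- fill
  v
}

# Apply the inverse of a similarity (POM -> FLM style) to fill an output
# raster of size outDim (nr, nc): out[r, c] = img(inverse-mapped position).
# mat is the 3x3 homogeneous forward matrix acting on (x, y, 1) row vectors.
warpBySimilarity <- function(img, mat, outDim, fill = 0) {
  inv <- solve(mat)
  nr <- outDim[1]; nc <- outDim[2]
  xy <- cbind(rep(seq_len(nc), each = nr), rep(seq_len(nr), times = nc), 1)
  src <- xy %*% t(inv)
  matrix(bilinearSample(img, row = src[, 2], col = src[, 1], fill = fill),
         nr, nc)
}

# Build a 3x3 similarity matrix: scale s, rotation theta (deg, CCW in x-y),
# mapping about image centers plus translation (tx, ty) in target pixels.
similarityMatrix <- function(scale, rotationDeg, tx = 0, ty = 0,
                             centerSrc = c(0, 0), centerDst = c(0, 0)) {
  th <- deg2rad(rotationDeg)
  R <- scale * matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2,
                      byrow = TRUE)
  t0 <- centerDst + c(tx, ty) - as.vector(R %*% centerSrc)
  rbind(cbind(R, t0), c(0, 0, 1))
}

# Block-mean downsampling by an integer factor (trims remainder rows/cols).
blockMean <- function(m, factor) {
  if (factor == 1) return(m)
  nr <- (nrow(m) %/% factor) * factor
  nc <- (ncol(m) %/% factor) * factor
  m <- m[seq_len(nr), seq_len(nc), drop = FALSE]
  a <- array(m, c(factor, nr %/% factor, factor, nc %/% factor))
  colMeans(aperm(a, c(1, 3, 2, 4)), dims = 2)
}

# Running mean of a vector with NA-aware masking: values where mask is FALSE
# contribute nothing; window must be odd.
maskedRunningMean <- function(v, mask, window) {
  if (window <= 1) return(v)
  stopifnot(window %% 2 == 1)
  x <- ifelse(mask, v, 0)
  w <- as.numeric(mask)
  k <- rep(1, window)
  pad <- (window - 1) / 2
  s <- stats::filter(c(rep(0, pad), x, rep(0, pad)), k, sides = 2)
  n <- stats::filter(c(rep(0, pad), w, rep(0, pad)), k, sides = 2)
  s <- s[(pad + 1):(pad + length(v))]
  n <- n[(pad + 1):(pad + length(v))]
  out <- ifelse(n > 0, s / n, NA_real_)
  out[!mask] <- v[!mask]
  as.numeric(out)
}

# Centroids and pixel counts of a label image; returns data.frame ordered by
# label with columns label, n, row, col.
labelStats <- function(labels) {
  idx <- which(labels > 0)
  if (length(idx) == 0)
    return(data.frame(label = integer(), n = integer(),
                      row = numeric(), col = numeric()))
  lab <- labels[idx]
  rows <- ((idx - 1) %% nrow(labels)) + 1
  cols <- ((idx - 1) %/% nrow(labels)) + 1
  n <- tabulate(lab)
  keep <- which(n > 0)
  data.frame(
    label = keep,
    n = n[keep],
    row = as.numeric(rowsum(rows, lab)[, 1] / n[keep]),
    col = as.numeric(rowsum(cols, lab)[, 1] / n[keep])
  )
}
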