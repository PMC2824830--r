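## Small 3-vector helpers used throughout. Atom tables store coordinates in
## plain x/y/z columns; these helpers operate on n x 3 matrices.

.vnorm <- function(v) sqrt(sum(v * v))

.unit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalise a (near-)zero vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.deg <- function(rad) rad * 180 / pi
.rad <- function(deg) deg * pi / 180

## rotation about z / x by theta (radians)
.rotZ <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

.rotX <- function(theta) {
  c <- cos(theta); s <- sin(theta)
  matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, 3, byrow = TRUE)
}

## coordinates of an atom data.frame as n x 3 matrix
.xyz <- function(atoms) cbind(atoms$x, atoms$y, atoms$z)

## apply rigid (or improper) transform rot %*% x + trans to an atom table
.transformAtoms <- function(atoms, rot, trans = c(0, 0, 0)) {
  m <- .xyz(atoms) %*% t(rot)
  atoms$x <- m[, 1] + trans[1]
  atoms$y <- m[, 2] + trans[2]
  atoms$z <- m[, 3] + trans[3]
  atoms
}

## minimum cross-distance between two coordinate matrices (n x 3, m x 3)
.minCrossDist <- function(a, b) {
  ## dist^2 = |a|^2 + |b|^2 - 2 a.b, computed blockwise to bound memory
  na <- nrow(a)
  best <- Inf
  step <- max(1L, floor(2e6 / max(1L, nrow(b))))
  i <- 1L
  while (i <= na) {
    j <- min(na, i + step - 1L)
    blk <- a[i:j, , drop = FALSE]
    d2 <- outer(rowSums(blk^2), rowSums(b^2), "+") - 2 * blk %*% t(b)
    best <- min(best, min(d2))
    i <- j + 1L
  }
  sqrt(max(best, 0))
}

## distances from one point to rows of a matrix
.distToPoint <- function(m, p) {
  sqrt((m[, 1] - p[1])^2 + (m[, 2] - p[2])^2 + (m[, 3] - p[3])^2)
}

## best-fit plane normal of a point cloud (unit vector, arbitrary sign)
.planeNormal <- function(m) {
  ctr <- colMeans(m)
  s <- svd(sweep(m, 2, ctr))
  s$v[, 3]
}
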