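.norm2 <- function(v) sqrt(sum(v^2))

.unit <- function(v) {
  n <- .norm2(v)
  if (n < 1e-12) geometryError("cannot normalize a zero vector")
  v / n
}

# deterministic vector perpendicular to d: cross with the world axis least
# aligned with d
.anyPerp <- function(d) {
  ax <- diag(3)[, which.min(abs(d))]
  .unit(c(d[2] * ax[3] - d[3] * ax[2],
          d[3] * ax[1] - d[1] * ax[3],
          d[1] * ax[2] - d[2] * ax[1]))
}

#' Fit a straight axis through an SSE's C-alpha coordinates
#'
#' Total-least-squares line (first principal component through the centroid).
#' The returned endpoints are the projections of the first and last C-alpha
#' onto the line; the direction always points N to C (from the first towards
#' the last residue).
#'
#' @param coords m x 3 matrix of the element's C-alpha coordinates in
#'   residue order, m >= 3.
#' @return List with \code{start}, \code{end} (3-vectors) and \code{dir}
#'   (unit 3-vector).
#' @examples
#' fitAxis(cbind(0:3, 0, 0))$end  # (3, 0, 0)
#' @export
fitAxis <- function(coords) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3L) geometryError("axis fit needs >= 3 points")
  ctr <- colMeans(coords)
  cc <- sweep(coords, 2, ctr)
  if (max(abs(cc)) < 1e-9)
    geometryError("axis fit degenerate: all points coincide")
  sv <- svd(cc, nu = 0, nv = 1)
  d <- sv$v[, 1]
  # orient N -> C
  if (sum((coords[nrow(coords), ] - coords[1L, ]) * d) < 0) d <- -d
  t1 <- sum((coords[1L, ] - ctr) * d)
  t2 <- sum((coords[nrow(coords), ] - ctr) * d)
  list(start = ctr + t1 * d, end = ctr + t2 * d, dir = d)
}

#' Least-squares rigid superposition of two point sets
#'
#' Kabsch algorithm via singular value decomposition: finds the proper
#' rotation (det = +1) and translation minimizing the RMSD of
#' \code{R \%*\% mov + t} onto \code{ref}.
#'
#' @param ref,mov n x 3 matrices of paired coordinates, n >= 3.
#' @return List with \code{R} (3 x 3 rotation), \code{t} (3-vector) and
#'   \code{rmsd} (Angstrom).
#' @examples
#' p <- matrix(rnorm(30), 10)
#' s <- superpose(p, p)
#' s$rmsd  # 0
#' @export
superpose <- function(ref, mov) {
  ref <- as.matrix(ref); mov <- as.matrix(mov)
  if (nrow(ref) != nrow(mov)) usageError("point sets differ in length")
  if (nrow(ref) < 3L) geometryError("superposition needs >= 3 points")
  cr <- colMeans(ref); cm <- colMeans(mov)
  X <- sweep(mov, 2, cm); Y <- sweep(ref, 2, cr)
  if (max(abs(X)) < 1e-9 || max(abs(Y)) < 1e-9)
    geometryError("superposition degenerate: coincident points")
  H <- crossprod(X, Y)                       # 3x3
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (d == 0) d <- 1
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cr - as.vector(R %*% cm)
  fitted <- sweep(mov %*% t(R), 2, tvec, "+")
  list(R = R, t = tvec, rmsd = sqrt(mean(rowSums((fitted - ref)^2))))
}

# apply a superposition to an n x 3 matrix or a 3-vector
.applyRigid <- function(x, fit) {
  if (is.matrix(x)) sweep(x %*% t(fit$R), 2, fit$t, "+")
  else as.vector(fit$R %*% x) + fit$t
}

#' Best-fit plane frame of a 3D point set
#'
#' Principal-axes frame of the points: origin at the centroid, in-plane x
#' along the first principal axis, in-plane y along the second. The x sign is
#' chosen so the first point has nonnegative x; the y sign so the first point
#' with |y| above tolerance has nonnegative y (both for determinism).
#'
#' @param pts n x 3 matrix.
#' @return List with \code{origin}, \code{ex}, \code{ey} (3-vectors) and
#'   \code{xy} (n x 2 in-plane coordinates of the input points).
#' @export
planeFrame <- function(pts) {
  pts <- as.matrix(pts)
  origin <- colMeans(pts)
  cc <- sweep(pts, 2, origin)
  if (nrow(pts) == 1L || max(abs(cc)) < 1e-12) {
    ex <- c(1, 0, 0); ey <- c(0, 1, 0)
  } else {
    sv <- svd(cc, nu = 0, nv = min(3L, ncol(cc)))
    ex <- sv$v[, 1]
    ey <- if (ncol(sv$v) >= 2) sv$v[, 2] else .anyPerp(ex)
  }
  x <- as.vector(cc %*% ex)
  if (length(x) && x[1] < 0) { ex <- -ex; x <- -x }
  y <- as.vector(cc %*% ey)
  iy <- which(abs(y) > 1e-9)
  if (length(iy) && y[iy[1]] < 0) { ey <- -ey; y <- -y }
  list(origin = origin, ex = ex, ey = ey, xy = cbind(x, y))
}

# wrap an angle into [-pi, pi)
.wrapAngle <- function(a) {
  a <- (a + pi) %% (2 * pi) - pi
  a[a >= pi] <- a[a >= pi] - 2 * pi
  a
}

#' Circular mean of angles
#'
#' Mean direction of angles in radians (period 2 pi), wrapped to [-pi, pi).
#' The mean of -170 and +170 degrees is 180 degrees, not 0.
#'
#' @param a numeric vector of angles (radians).
#' @return Length-1 numeric.
#' @export
circularMean <- function(a) .wrapAngle(atan2(mean(sin(a)), mean(cos(a))))
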