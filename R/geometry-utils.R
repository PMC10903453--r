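# Low-level vector geometry shared across the package. Points are plain
# numeric length-3 vectors or n x 3 matrices, lengths in nanometres.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (!is.finite(n) || n < 1e-12) {
    abort_geometry("cannot normalise a zero-length vector")
  }
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L]
  )
}

# Row-wise cross product of two n x 3 matrices.
cross3_rows <- function(a, b) {
  cbind(
    a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
    a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
    a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L]
  )
}

clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

# Angle between two vectors in degrees, in [0, 180].
angle_between_deg <- function(a, b) {
  na <- vec_norm(a)
  nb <- vec_norm(b)
  if (na < 1e-12 || nb < 1e-12) abort_geometry("angle undefined for zero-length vector")
  rad2deg(acos(clamp(sum(a * b) / (na * nb), -1, 1)))
}

# Rodrigues rotation of vector(s) v about a unit axis by angle (radians).
rotate_about <- function(v, axis, angle_rad) {
  k <- unit_vec(axis)
  if (is.matrix(v)) {
    kv <- cross3_rows(matrix(k, nrow(v), 3L, byrow = TRUE), v)
    kdv <- as.numeric(v %*% k)
    v * cos(angle_rad) + kv * sin(angle_rad) +
      outer(kdv, k) * (1 - cos(angle_rad))
  } else {
    v * cos(angle_rad) + cross3(k, v) * sin(angle_rad) +
      k * sum(k * v) * (1 - cos(angle_rad))
  }
}

# Least-squares plane through a cloud of points (n x 3). Returns the unit
# normal (sign arbitrary) and the centroid.
fit_plane <- function(pts) {
  if (nrow(pts) < 3L) abort_support("plane fit needs at least 3 points")
  ctr <- colMeans(pts)
  x <- sweep(pts, 2L, ctr)
  sv <- svd(x, nu = 0L)
  list(normal = sv$v[, 3L], centre = ctr)
}

# Minimum distance from each point (n x 3) to a polyline (m x 3).
dist_to_polyline <- function(pts, polyline) {
  if (!is.matrix(pts)) pts <- matrix(pts, ncol = 3L)
  m <- nrow(polyline)
  if (m == 1L) {
    d <- sweep(pts, 2L, polyline[1L, ])
    return(sqrt(rowSums(d * d)))
  }
  best <- rep(Inf, nrow(pts))
  for (i in seq_len(m - 1L)) {
    a <- polyline[i, ]
    b <- polyline[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab * ab)
    ap <- sweep(pts, 2L, a)
    t <- if (len2 < 1e-18) rep(0, nrow(pts)) else clamp(as.numeric(ap %*% ab) / len2, 0, 1)
    d <- ap - outer(t, ab)
    best <- pmin(best, rowSums(d * d))
  }
  sqrt(best)
}

# Moeller-Trumbore intersection of a single ray with all triangles of a mesh.
# Returns the parametric distances t (> eps) of the hits, NA for misses.
ray_triangle_hits <- function(orig, dir, vertices, faces, eps = 1e-7) {
  v0 <- vertices[faces[, 1L], , drop = FALSE]
  e1 <- vertices[faces[, 2L], , drop = FALSE] - v0
  e2 <- vertices[faces[, 3L], , drop = FALSE] - v0
  h <- cbind(
    dir[2L] * e2[, 3L] - dir[3L] * e2[, 2L],
    dir[3L] * e2[, 1L] - dir[1L] * e2[, 3L],
    dir[1L] * e2[, 2L] - dir[2L] * e2[, 1L]
  )
  a <- rowSums(e1 * h)
  t <- rep(NA_real_, nrow(faces))
  ok <- abs(a) > 1e-12
  if (!any(ok)) return(t)
  f <- 1 / a[ok]
  s <- sweep(v0[ok, , drop = FALSE], 2L, orig, FUN = function(x, y) y - x)
  u <- f * rowSums(s * h[ok, , drop = FALSE])
  q <- cross3_rows(s, e1[ok, , drop = FALSE])
  v <- f * as.numeric(q %*% dir)
  tt <- f * rowSums(e2[ok, , drop = FALSE] * q)
  tol <- 1e-9
  hit <- u >= -tol & v >= -tol & (u + v) <= 1 + tol & tt > eps
  tt[!hit] <- NA_real_
  t[ok] <- tt
  t
}
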