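# Analytic fixture meshes built in code: cube, icosphere, slab, open
# plane and an exact wedge. Used as closed-form oracles for the
# morphometric operators.

helper_signed_volume <- function(v, f) {
  v1 <- v[f[, 1], , drop = FALSE]
  v2 <- v[f[, 2], , drop = FALSE]
  v3 <- v[f[, 3], , drop = FALSE]
  cr <- cbind(
    v2[, 2] * v3[, 3] - v2[, 3] * v3[, 2],
    v2[, 3] * v3[, 1] - v2[, 1] * v3[, 3],
    v2[, 1] * v3[, 2] - v2[, 2] * v3[, 1]
  )
  sum(rowSums(v1 * cr)) / 6
}

unit_cube_vertices <- function() {
  rbind(
    c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0),
    c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1)
  )
}

cube_mesh <- function(edge = 1, centre = c(0, 0, 0)) {
  v <- unit_cube_vertices() * edge
  v <- sweep(v, 2, centre - edge / 2, `+`)
  f <- rbind(
    c(1, 3, 2), c(1, 4, 3),      # bottom (-z)
    c(5, 6, 7), c(5, 7, 8),      # top (+z)
    c(1, 2, 6), c(1, 6, 5),      # front (-y)
    c(2, 3, 7), c(2, 7, 6),      # right (+x)
    c(3, 4, 8), c(3, 8, 7),      # back (+y)
    c(4, 1, 5), c(4, 5, 8)       # left (-x)
  )
  tri_mesh(v, f)
}

# Axis-aligned box with independent side lengths (slab when one is small).
box_mesh <- function(lx, ly, lz, centre = c(0, 0, 0)) {
  m <- cube_mesh(1, centre = c(0.5, 0.5, 0.5))   # unit cube on [0,1]^3
  v <- sweep(m$vertices, 2, c(lx, ly, lz), `*`)
  v <- sweep(v, 2, centre - c(lx, ly, lz) / 2, `+`)
  tri_mesh(v, m$faces)
}

# Finely triangulated axis-aligned slab so that area-weighted sampling has
# faces everywhere (the plain box has only 2 triangles per side).
slab_mesh <- function(lx, ly, thickness, n = 10) {
  xs <- seq(-lx / 2, lx / 2, length.out = n + 1)
  ys <- seq(-ly / 2, ly / 2, length.out = n + 1)
  nv <- (n + 1)^2
  gv <- as.matrix(expand.grid(x = xs, y = ys))
  idx <- function(i, j) (j - 1) * (n + 1) + i
  quads <- do.call(rbind, lapply(seq_len(n), function(j) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1), idx(i, j + 1))
    }))
  }))
  top_v <- cbind(gv, thickness / 2)
  bot_v <- cbind(gv, -thickness / 2)
  v <- rbind(top_v, bot_v)
  f_top <- rbind(quads[, c(1, 2, 3)], quads[, c(1, 3, 4)])
  f_bot <- rbind(quads[, c(1, 3, 2)], quads[, c(1, 4, 3)]) + nv
  # Side walls stitched from the boundary loop.
  bnd <- c(idx(seq_len(n), 1), idx(n + 1, seq_len(n)),
           idx(rev(seq_len(n) + 1), n + 1), idx(1, rev(seq_len(n) + 1)))
  f_side <- do.call(rbind, lapply(seq_along(bnd), function(k) {
    a <- bnd[k]
    b <- bnd[if (k == length(bnd)) 1 else k + 1]
    rbind(c(a, b + nv, b), c(a, a + nv, b + nv))
  }))
  m <- tri_mesh(v, rbind(f_top, f_bot, f_side))
  if (helper_signed_volume(m$vertices, m$faces) < 0) {
    m$faces <- m$faces[, c(1, 3, 2)]
  }
  m
}

icosphere <- function(radius = 1, subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1)
  )
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  for (s in seq_len(subdiv)) {
    mid_cache <- new.env()
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      if (!is.null(mid_cache[[key]])) return(mid_cache[[key]])
      v <<- rbind(v, (v[a, ] + v[b, ]) / 2)
      mid_cache[[key]] <- nrow(v)
      nrow(v)
    }
    f <- do.call(rbind, lapply(seq_len(nrow(f)), function(i) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      rbind(c(a, ab, ca), c(b, bc, ab), c(cc, ca, bc), c(ab, bc, ca))
    }))
  }
  v <- v / sqrt(rowSums(v * v)) * radius
  if (helper_signed_volume(v, f) < 0) f <- f[, c(1, 3, 2)]
  tri_mesh(v, f)
}

# Open planar grid mesh at z = 0 (not watertight; for wedge-angle tests).
plane_mesh <- function(half = 10, n = 20) {
  xs <- seq(-half, half, length.out = n + 1)
  gv <- as.matrix(expand.grid(x = xs, y = xs))
  v <- cbind(gv, 0)
  idx <- function(i, j) (j - 1) * (n + 1) + i
  f <- do.call(rbind, lapply(seq_len(n), function(j) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      rbind(
        c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
        c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
      )
    }))
  }))
  tri_mesh(v, f)
}

# Two open flank strips meeting along the y-axis ridge at x = 0, with an
# exact interior angle (degrees): the analytic wedge.
wedge_mesh <- function(angle_deg, length = 30, flank = 20, n = 20) {
  alpha <- angle_deg * pi / 360
  ts <- seq(0, flank, length.out = n + 1)[-1]
  ys <- seq(-length / 2, length / 2, length.out = n + 1)
  build_flank <- function(sign_z) {
    prof <- cbind(-ts * cos(alpha), ts * sin(alpha) * sign_z)
    prof <- rbind(c(0, 0), prof)
    np <- nrow(prof)
    v <- cbind(
      rep(prof[, 1], times = length(ys)),
      rep(ys, each = np),
      rep(prof[, 2], times = length(ys))
    )
    idx <- function(i, j) (j - 1) * np + i
    f <- do.call(rbind, lapply(seq_len(length(ys) - 1), function(j) {
      do.call(rbind, lapply(seq_len(np - 1), function(i) {
        rbind(
          c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1)),
          c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
        )
      }))
    }))
    list(v = v, f = f)
  }
  up <- build_flank(1)
  dn <- build_flank(-1)
  v <- rbind(up$v, dn$v)
  f <- rbind(up$f, dn$f + nrow(up$v))
  tri_mesh(v, f)
}

# Random rigid transform (rotation matrix + translation), seeded.
random_rigid <- function(seed) {
  withr::with_seed(seed, {
    a <- matrix(rnorm(9), 3)
    q <- qr.Q(qr(a))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    list(rotation = q, translation = rnorm(3, 0, 50))
  })
}

# Apply a rigid transform to a pose table.
transform_poses <- function(poses, rotation, translation) {
  out <- poses
  point_stems <- c("centre", "base_a", "base_b")
  dir_stems <- c("axis_a", "axis_b", "ridge_tangent", "normal")
  for (stem in c(point_stems, dir_stems)) {
    cols <- paste0(stem, c("_x", "_y", "_z"))
    m <- as.matrix(poses[cols]) %*% t(rotation)
    if (stem %in% point_stems) m <- sweep(m, 2, translation, `+`)
    out[cols] <- m
  }
  out
}
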