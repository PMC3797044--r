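# Shared geometry helpers: affines are 4x4 voxel->world or world->world maps,
# voxel indices are 0-based, world coordinates are in mm (RAS).

#' Build a diagonal voxel-to-world affine
#'
#' World coordinates are `index * voxel_size` (0-based indices, RAS, origin at
#' the corner voxel center).
#'
#' @param voxel_size Voxel edge length(s) in mm (scalar or length 3).
#' @return A 4x4 affine matrix.
#' @export
diag_affine <- function(voxel_size) {
  vs <- rep(voxel_size, length.out = 3)
  a <- diag(c(vs, 1))
  a
}

#' Map 0-based voxel indices to world mm
#' @param ijk Numeric matrix (n x 3) or length-3 vector of voxel coordinates.
#' @param affine 4x4 voxel-to-world affine.
#' @return Matrix (n x 3) of world coordinates.
#' @export
voxel_to_world <- function(ijk, affine) {
  ijk <- rbind2mat(ijk)
  t(affine %*% rbind(t(ijk), 1))[, 1:3, drop = FALSE]
}

#' Map world mm to continuous 0-based voxel coordinates
#' @param xyz Numeric matrix (n x 3) or length-3 vector of world coordinates.
#' @param affine 4x4 voxel-to-world affine.
#' @return Matrix (n x 3) of voxel coordinates.
#' @export
world_to_voxel <- function(xyz, affine) {
  xyz <- rbind2mat(xyz)
  t(solve(affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

rbind2mat <- function(x) {
  if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
}

#' Trilinear interpolation of a 3D volume
#'
#' Coordinates are continuous 0-based voxel indices; points are clamped to the
#' volume bounding box, `NA` values in the volume propagate.
#'
#' @param vol 3D numeric array.
#' @param pts Matrix (n x 3) of voxel coordinates.
#' @return Numeric vector of interpolated values.
#' @export
trilinear <- function(vol, pts) {
  pts <- rbind2mat(pts)
  d <- dim(vol)
  x <- pmin(pmax(pts[, 1], 0), d[1] - 1)
  y <- pmin(pmax(pts[, 2], 0), d[2] - 1)
  z <- pmin(pmax(pts[, 3], 0), d[3] - 1)
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  x1 <- pmin(x0 + 1, d[1] - 1)
  y1 <- pmin(y0 + 1, d[2] - 1)
  z1 <- pmin(z0 + 1, d[3] - 1)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  idx <- function(i, j, k) vol[cbind(i + 1, j + 1, k + 1)]
  v000 <- idx(x0, y0, z0); v100 <- idx(x1, y0, z0)
  v010 <- idx(x0, y1, z0); v110 <- idx(x1, y1, z0)
  v001 <- idx(x0, y0, z1); v101 <- idx(x1, y0, z1)
  v011 <- idx(x0, y1, z1); v111 <- idx(x1, y1, z1)
  (v000 * (1 - fx) + v100 * fx) * (1 - fy) * (1 - fz) +
    (v010 * (1 - fx) + v110 * fx) * fy * (1 - fz) +
    (v001 * (1 - fx) + v101 * fx) * (1 - fy) * fz +
    (v011 * (1 - fx) + v111 * fx) * fy * fz
}

normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  n[n == 0] <- 1
  m / n
}

# Rotation matrix from XYZ Euler angles (radians)
euler_rotation <- function(rx, ry, rz) {
  Rx <- rbind(c(1, 0, 0), c(0, cos(rx), -sin(rx)), c(0, sin(rx), cos(rx)))
  Ry <- rbind(c(cos(ry), 0, sin(ry)), c(0, 1, 0), c(-sin(ry), 0, cos(ry)))
  Rz <- rbind(c(cos(rz), -sin(rz), 0), c(sin(rz), cos(rz), 0), c(0, 0, 1))
  Rz %*% Ry %*% Rx
}

# Random rotation matrix (uniform via QR of Gaussian matrix)
random_rotation <- function() {
  qrd <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qrd)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Triangulated unit sphere mesh (subdivided icosahedron)
#'
#' Antipodally symmetric mesh used for ODF evaluation and peak extraction.
#'
#' @param subdiv Number of recursive subdivisions (0 gives the icosahedron;
#'   3 gives 642 vertices, about 8 degrees vertex spacing).
#' @return List with `vertices` (n x 3 unit vectors), `faces` (m x 3,
#'   1-based), and `neighbors` (adjacency list per vertex).
#' @export
icosphere <- function(subdiv = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- normalize_rows(v)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    mid_cache <- new.env(hash = TRUE)
    verts <- v
    midpoint <- function(a, b) {
      k <- key(a, b)
      if (!is.null(mid_cache[[k]])) return(mid_cache[[k]])
      m <- verts[a, ] + verts[b, ]
      m <- m / sqrt(sum(m^2))
      verts <<- rbind(verts, m)
      mid_cache[[k]] <- nrow(verts)
      nrow(verts)
    }
    nf <- matrix(0L, nrow = 4 * nrow(f), ncol = 3)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c); ca <- midpoint(c, a)
      nf[(i - 1) * 4 + 1:4, ] <- rbind(
        c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    v <- verts
    f <- nf
  }
  nb <- vector("list", nrow(v))
  for (i in seq_len(nrow(f))) {
    a <- f[i, 1]; b <- f[i, 2]; c <- f[i, 3]
    nb[[a]] <- c(nb[[a]], b, c)
    nb[[b]] <- c(nb[[b]], a, c)
    nb[[c]] <- c(nb[[c]], a, b)
  }
  nb <- lapply(nb, unique)
  list(vertices = v, faces = f, neighbors = nb)
}
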