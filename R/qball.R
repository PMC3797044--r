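# Analytic Q-ball ODF reconstruction: regularized real spherical-harmonic fit
# of the single-shell signal, Funk-Radon transform applied per harmonic order.

# index table for an even-order real SH basis
sh_index_table <- function(lmax) {
  out <- NULL
  for (l in seq(0, lmax, by = 2))
    out <- rbind(out, cbind(l = l, m = -l:l))
  as.data.frame(out)
}

#' Real even-order spherical-harmonic basis
#'
#' Orthonormal real basis built from associated Legendre functions:
#' `m = 0` terms are zonal, `m > 0` use `cos(m phi)`, `m < 0` use
#' `sin(|m| phi)`, each with unit L2 norm on the sphere. Only even orders are
#' included (diffusion signals are antipodally symmetric).
#'
#' @param dirs Matrix (n x 3) of unit vectors.
#' @param lmax Maximum (even) harmonic order.
#' @return Matrix n x R with R = (lmax+1)(lmax+2)/2.
#' @export
real_sh_basis <- function(dirs, lmax) {
  dirs <- rbind2mat(dirs)
  if (lmax %% 2 != 0) stop("harmonic order must be even")
  theta <- acos(pmin(pmax(dirs[, 3], -1), 1))
  phi <- atan2(dirs[, 2], dirs[, 1])
  ct <- cos(theta)
  n <- nrow(dirs)
  tab <- sh_index_table(lmax)
  B <- matrix(0, n, nrow(tab))
  for (l in seq(0, lmax, by = 2)) {
    P <- pracma::legendre(l, ct) # (l+1) x n, rows m = 0..l, CS phase included
    if (l == 0) P <- matrix(P, nrow = 1)
    for (m in -l:l) {
      j <- which(tab$l == l & tab$m == m)
      am <- abs(m)
      norm <- sqrt((2 * l + 1) / (4 * pi) *
                   factorial(l - am) / factorial(l + am))
      base <- norm * P[am + 1, ]
      B[, j] <- if (m == 0) base
                else if (m > 0) sqrt(2) * base * cos(m * phi)
                else sqrt(2) * base * sin(am * phi)
    }
  }
  B
}

# Legendre polynomial at zero, even l: (-1)^(l/2) (l-1)!! / l!!
legendre_p0 <- function(l) {
  if (l == 0) return(1)
  (-1)^(l / 2) * prod(seq(1, l - 1, by = 2)) / prod(seq(2, l, by = 2))
}

#' Analytic Q-ball ODF reconstruction
#'
#' Least-squares spherical-harmonic fit of the normalized single-shell signal
#' with Laplace-Beltrami regularization, followed by the Funk-Radon transform
#' (per-order scaling by `2 pi P_l(0)`). ODF amplitudes are min-max
#' normalized at evaluation time (see [odf_peaks()]).
#'
#' @param dwi A `dwi_volume` with a single non-zero shell.
#' @param order Even harmonic order (default 6).
#' @param reg Laplace-Beltrami regularization weight (default 0.006).
#' @return Object of class `odf_field` with coefficient array
#'   `coef` (x, y, z, R), `order`, `reg`, `mask`, `affine`.
#' @export
qball_odf <- function(dwi, order = 6, reg = 0.006) {
  stopifnot(inherits(dwi, "dwi_volume"))
  if (order %% 2 != 0) stop("harmonic order must be even")
  b <- dwi$scheme$bvalues
  shells <- unique(round(b[b > 0]))
  if (length(shells) > 1)
    stop("Q-ball requires a single shell; found b = ",
         paste(shells, collapse = ", "))
  dwi_idx <- which(b > 0)
  ncoef <- (order + 1) * (order + 2) / 2
  if (ncoef > length(dwi_idx))
    stop("harmonic order ", order, " needs ", ncoef,
         " directions but only ", length(dwi_idx), " are available")
  dirs <- dwi$scheme$directions[dwi_idx, , drop = FALSE]
  B <- real_sh_basis(dirs, order)
  tab <- sh_index_table(order)
  L <- diag((tab$l * (tab$l + 1))^2)
  Minv <- solve(crossprod(B) + reg * L, t(B)) # R x ndir

  shape <- dim(dwi$signal)[1:3]
  nv <- prod(shape)
  S <- matrix(dwi$signal, nv, dim(dwi$signal)[4])
  s0 <- rowMeans(S[, b == 0, drop = FALSE])
  s0[s0 <= 0] <- NA
  E <- S[, dwi_idx, drop = FALSE] / s0
  E[!is.finite(E)] <- 0
  C <- E %*% t(Minv)
  # Funk-Radon transform, diagonal per order
  frt <- 2 * pi * vapply(tab$l, legendre_p0, numeric(1))
  C <- sweep(C, 2, frt, "*")
  C[!dwi$mask, ] <- 0
  structure(list(coef = array(C, c(shape, ncoef)), order = order, reg = reg,
                 mask = dwi$mask, affine = dwi$affine,
                 voxel_size = dwi$voxel_size),
            class = "odf_field")
}

#' Extract ODF peaks on a sphere mesh
#'
#' Per masked voxel the ODF is evaluated on an antipodally symmetric
#' triangulated sphere, min-max normalized, and local mesh maxima above
#' `rel_threshold` times the global maximum are retained, deduplicated within
#' `min_separation` degrees; antipodal pairs are collapsed to one
#' representative with a canonical sign (largest-magnitude component
#' positive). Voxels whose ODF is constant (isotropic) yield no peaks.
#'
#' @param odf An `odf_field`.
#' @param mesh Sphere mesh from [icosphere()].
#' @param min_separation Minimum angular separation between peaks, degrees.
#' @param rel_threshold Relative amplitude threshold in (0, 1].
#' @param max_peaks Maximum number of peaks stored per voxel.
#' @return Object of class `peak_field` with `peaks` array
#'   (x, y, z, max_peaks, 3), `n_peaks` count array, `mask`, `affine`.
#' @export
odf_peaks <- function(odf, mesh = icosphere(3), min_separation = 25,
                      rel_threshold = 0.5, max_peaks = 4) {
  stopifnot(inherits(odf, "odf_field"))
  V <- mesh$vertices
  Bm <- real_sh_basis(V, odf$order)
  shape <- dim(odf$coef)[1:3]
  nv <- prod(shape)
  C <- matrix(odf$coef, nv, dim(odf$coef)[4])
  vox <- which(odf$mask)
  cos_sep <- cos(min_separation * pi / 180)

  # neighbor index matrix; short rows padded by recycling their neighbors
  maxnb <- max(lengths(mesh$neighbors))
  nbmat <- matrix(1L, nrow(V), maxnb)
  for (i in seq_len(nrow(V)))
    nbmat[i, ] <- rep(mesh$neighbors[[i]], length.out = maxnb)

  peaks <- array(NA_real_, c(nv, max_peaks, 3))
  npk <- integer(nv)
  chunk <- 2000L
  for (start in seq(1, length(vox), by = chunk)) {
    idx <- vox[start:min(start + chunk - 1, length(vox))]
    A <- C[idx, , drop = FALSE] %*% t(Bm) # voxels x vertices
    rng_lo <- apply(A, 1, min)
    rng_hi <- apply(A, 1, max)
    rng <- rng_hi - rng_lo
    flat <- rng <= 1e-6 * pmax(abs(rng_hi), 1e-12)
    An <- (A - rng_lo) / ifelse(rng > 0, rng, 1)
    nbmax <- A[, nbmat[, 1]]
    for (c2 in 2:maxnb) nbmax <- pmax(nbmax, A[, nbmat[, c2]])
    is_peak <- (A > nbmax) & (An >= rel_threshold)
    is_peak[flat, ] <- FALSE
    for (r in seq_len(nrow(A))) {
      cand <- which(is_peak[r, ])
      if (length(cand) == 0) next
      cand <- cand[order(A[r, cand], decreasing = TRUE)]
      acc <- matrix(numeric(0), 0, 3)
      for (cv in cand) {
        dir <- V[cv, ]
        if (nrow(acc) > 0 && any(abs(acc %*% dir) > cos_sep)) next
        mx <- which.max(abs(dir))
        if (dir[mx] < 0) dir <- -dir
        acc <- rbind(acc, dir)
        if (nrow(acc) == max_peaks) break
      }
      v <- idx[r]
      npk[v] <- nrow(acc)
      if (nrow(acc) > 0) peaks[v, seq_len(nrow(acc)), ] <- acc
    }
  }
  structure(list(peaks = array(peaks, c(shape, max_peaks, 3)),
                 n_peaks = array(npk, shape), mask = odf$mask,
                 max_peaks = max_peaks, affine = odf$affine,
                 voxel_size = odf$voxel_size),
            class = "peak_field")
}

#' Peak field from a tensor principal eigenvector
#'
#' Wraps the tensor's first eigenvector as a one-peak-per-voxel field so the
#' tracker can consume either tensors or ODF peaks.
#'
#' @param tf A `tensor_field`.
#' @param fa_min Voxels with FA below this carry no direction (default 0,
#'   i.e. every masked voxel carries its eigenvector).
#' @return A `peak_field` with one peak per masked voxel.
#' @export
tensor_peaks <- function(tf, fa_min = 0) {
  stopifnot(inherits(tf, "tensor_field"))
  shape <- dim(tf$evals)[1:3]
  nv <- prod(shape)
  sm <- scalar_maps(tf)
  e1 <- matrix(array(tf$evecs, c(nv, 9))[, 1:3], nv, 3)
  ok <- as.vector(tf$mask) & as.vector(sm$fa) >= fa_min &
    rowSums(e1^2) > 0
  peaks <- array(NA_real_, c(nv, 1, 3))
  peaks[ok, 1, ] <- normalize_rows(e1[ok, , drop = FALSE])
  structure(list(peaks = array(peaks, c(shape, 1, 3)),
                 n_peaks = array(as.integer(ok), shape), mask = tf$mask,
                 max_peaks = 1L, affine = tf$affine,
                 voxel_size = tf$voxel_size),
            class = "peak_field")
}
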