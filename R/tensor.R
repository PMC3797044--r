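# Diffusion tensor estimation and scalar maps (FA, Westin shape coefficients).

#' Fit the diffusion tensor per voxel
#'
#' Weighted log-linear least squares of `ln S = ln S0 - b g' D g` per masked
#' voxel, with weights `S^2` (the standard first-order variance correction for
#' the log transform). Non-positive samples are excluded from the fit; voxels
#' with fewer than 7 usable samples (6 tensor components + log S0) yield a
#' zero tensor and are flagged.
#'
#' @param dwi A `dwi_volume`.
#' @return Object of class `tensor_field` with lower-triangular tensor array
#'   `D` (x, y, z, 6; order Dxx, Dxy, Dyy, Dxz, Dyz, Dzz, mm^2/s),
#'   eigenvalue array `evals` (x, y, z, 3; descending, negatives clamped to 0
#'   and flagged in `clamped`), eigenvector array `evecs` (x, y, z, 3, 3;
#'   `evecs[..., , k]` is the k-th eigenvector), `mask` and `flags`.
#' @export
fit_tensor <- function(dwi) {
  stopifnot(inherits(dwi, "dwi_volume"))
  shape <- dim(dwi$signal)[1:3]
  ngrad <- dim(dwi$signal)[4]
  scheme <- dwi$scheme
  if (sum(scheme$bvalues > 0) < 6)
    stop("tensor fit needs at least 6 diffusion-weighted directions")
  g <- scheme$directions
  b <- scheme$bvalues
  # design: ln S0, then -b * (gx^2, 2 gx gy, gy^2, 2 gx gz, 2 gy gz, gz^2)
  X <- cbind(1,
             -b * g[, 1]^2, -b * 2 * g[, 1] * g[, 2], -b * g[, 2]^2,
             -b * 2 * g[, 1] * g[, 3], -b * 2 * g[, 2] * g[, 3], -b * g[, 3]^2)
  p <- ncol(X)
  S <- matrix(dwi$signal, nrow = prod(shape), ncol = ngrad)
  vox <- which(dwi$mask)
  S <- S[vox, , drop = FALSE]
  usable <- S > 0
  W <- S^2 * usable
  Y <- suppressWarnings(log(S))
  Y[!usable] <- 0

  # normal equations per voxel via matrix contraction over gradients
  pair_i <- rep(seq_len(p), times = p)
  pair_j <- rep(seq_len(p), each = p)
  XP <- X[, pair_i] * X[, pair_j]            # ngrad x p^2
  XtWX <- W %*% XP                           # nvox x p^2
  XtWy <- (W * Y) %*% X                      # nvox x p

  nv <- length(vox)
  D6 <- matrix(0, nv, 6)
  flags <- integer(nv)
  enough <- rowSums(usable) >= p
  for (k in seq_len(nv)) {
    if (!enough[k]) { flags[k] <- 1L; next }
    A <- matrix(XtWX[k, ], p, p)
    beta <- tryCatch(solve(A, XtWy[k, ]), error = function(e) NULL)
    if (is.null(beta)) { flags[k] <- 1L; next }
    D6[k, ] <- beta[2:7]
  }

  evals <- matrix(0, nv, 3)
  evecs <- array(0, c(nv, 3, 3))
  clamped <- logical(nv)
  for (k in seq_len(nv)) {
    d <- D6[k, ]
    Dm <- matrix(c(d[1], d[2], d[4],
                   d[2], d[3], d[5],
                   d[4], d[5], d[6]), 3, 3)
    e <- eigen(Dm, symmetric = TRUE)
    ev <- e$values
    if (any(ev < 0)) { clamped[k] <- TRUE; ev <- pmax(ev, 0) }
    evals[k, ] <- ev
    evecs[k, , ] <- e$vectors
  }

  full <- function(m, nc) {
    out <- matrix(0, prod(shape), nc)
    out[vox, ] <- m
    out
  }
  Darr <- array(full(D6, 6), c(shape, 6))
  evarr <- array(full(evals, 3), c(shape, 3))
  ecarr <- array(0, c(prod(shape), 3, 3))
  ecarr[vox, , ] <- evecs
  ecarr <- array(ecarr, c(shape, 3, 3))
  flag_arr <- array(0L, shape); flag_arr[vox] <- flags
  clamp_arr <- array(FALSE, shape); clamp_arr[vox] <- clamped
  structure(list(D = Darr, evals = evarr, evecs = ecarr, mask = dwi$mask,
                 flags = flag_arr, clamped = clamp_arr,
                 affine = dwi$affine, voxel_size = dwi$voxel_size),
            class = "tensor_field")
}

#' Construct a tensor field directly from eigen-systems
#'
#' Mainly used to build synthetic fields in analyses and tests.
#'
#' @param evals Array (x, y, z, 3) of eigenvalues, descending.
#' @param evecs Array (x, y, z, 3, 3) of eigenvectors (columns).
#' @param affine 4x4 voxel-to-world affine.
#' @param mask Optional logical 3D mask.
#' @return A `tensor_field`.
#' @export
tensor_field <- function(evals, evecs, affine = diag_affine(1), mask = NULL) {
  shape <- dim(evals)[1:3]
  if (is.null(mask)) mask <- array(TRUE, shape)
  nv <- prod(shape)
  ev <- matrix(evals, nv, 3)
  ec <- array(evecs, c(nv, 3, 3))
  D6 <- matrix(0, nv, 6)
  for (k in seq_len(nv)) {
    V <- ec[k, , ]
    Dm <- V %*% diag(ev[k, ]) %*% t(V)
    D6[k, ] <- Dm[c(1, 2, 5, 3, 6, 9)]
  }
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(D = array(D6, c(shape, 6)), evals = evals, evecs = evecs,
                 mask = mask, flags = array(0L, shape),
                 clamped = array(FALSE, shape), affine = affine,
                 voxel_size = vs),
            class = "tensor_field")
}

#' Scalar maps from a tensor field
#'
#' Fractional anisotropy, trace-normalized Westin shape coefficients and mean
#' diffusivity:
#' \deqn{FA = \sqrt{3/2}\,\sqrt{\sum_i(\lambda_i-\bar\lambda)^2} / \sqrt{\sum_i \lambda_i^2}}
#' \deqn{c_l = (\lambda_1-\lambda_2)/\sum\lambda,\;
#'       c_p = 2(\lambda_2-\lambda_3)/\sum\lambda,\;
#'       c_s = 3\lambda_3/\sum\lambda}
#' so that `cl + cp + cs = 1` wherever the trace is positive. The all-zero
#' tensor is assigned FA = cl = cp = cs = 0 by convention and flagged.
#'
#' @param tf A `tensor_field`.
#' @return Object of class `scalar_maps` with 3D maps `fa`, `cl`, `cp`, `cs`,
#'   `md` (mm^2/s) plus `degenerate` flag map, `mask`, `affine`.
#' @export
scalar_maps <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  shape <- dim(tf$evals)[1:3]
  ev <- matrix(tf$evals, prod(shape), 3)
  l1 <- ev[, 1]; l2 <- ev[, 2]; l3 <- ev[, 3]
  tr <- l1 + l2 + l3
  md <- tr / 3
  dev2 <- (l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2
  ss <- l1^2 + l2^2 + l3^2
  fa <- ifelse(ss > 0, sqrt(1.5 * dev2 / ss), 0)
  cl <- ifelse(tr > 0, (l1 - l2) / tr, 0)
  cp <- ifelse(tr > 0, 2 * (l2 - l3) / tr, 0)
  cs <- ifelse(tr > 0, 3 * l3 / tr, 0)
  degen <- tr <= 0
  shape3 <- function(x) array(x, shape)
  structure(list(fa = shape3(fa), cl = shape3(cl), cp = shape3(cp),
                 cs = shape3(cs), md = shape3(md),
                 degenerate = shape3(degen), mask = tf$mask,
                 affine = tf$affine, voxel_size = tf$voxel_size),
            class = "scalar_maps")
}
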