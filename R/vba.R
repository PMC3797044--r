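# Voxel-based analysis: affine FA registration, tensor reorientation (PPD),
# edge-preserving local MMSE smoothing, voxelwise group and rank-correlation
# statistics, multi-template consensus.

# parameters: translation (3, mm), rotation (3, rad), log-scale (3), shear (3)
params_to_affine <- function(p, center_fixed, center_moving) {
  R <- euler_rotation(p[4], p[5], p[6])
  S <- diag(exp(p[7:9]))
  Sh <- diag(3)
  Sh[1, 2] <- p[10]; Sh[1, 3] <- p[11]; Sh[2, 3] <- p[12]
  A <- R %*% S %*% Sh
  off <- center_moving + p[1:3] - A %*% center_fixed
  rbind(cbind(A, off), c(0, 0, 0, 1))
}

resample_vol <- function(moving, moving_affine, fixed_dim, fixed_affine,
                         world_map) {
  grid <- as.matrix(expand.grid(0:(fixed_dim[1] - 1), 0:(fixed_dim[2] - 1),
                                0:(fixed_dim[3] - 1)))
  wf <- voxel_to_world(grid, fixed_affine)
  wm <- t(world_map %*% rbind(t(wf), 1))[, 1:3, drop = FALSE]
  vm <- world_to_voxel(wm, moving_affine)
  array(trilinear(moving, vm), dim = fixed_dim)
}

downsample2 <- function(vol) {
  d <- dim(vol)
  d2 <- pmax(1L, d %/% 2L)
  idx <- function(n, n2) pmin(rep(seq_len(n2), each = 2), n2)[seq_len(2 * n2)]
  out <- array(0, d2)
  cnt <- array(0, d2)
  xi <- pmin((0:(d[1] - 1)) %/% 2 + 1, d2[1])
  yi <- pmin((0:(d[2] - 1)) %/% 2 + 1, d2[2])
  zi <- pmin((0:(d[3] - 1)) %/% 2 + 1, d2[3])
  for (k in seq_len(d[3])) {
    sl <- vol[, , k]
    agg <- rowsum(sl, xi, reorder = TRUE)
    agg <- t(rowsum(t(agg), yi, reorder = TRUE))
    out[, , zi[k]] <- out[, , zi[k]] + agg
    cnt[, , zi[k]] <- cnt[, , zi[k]] + tabulate(xi, d2[1]) %o% tabulate(yi, d2[2])
  }
  out / cnt
}

ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 10) return(0)
  suppressWarnings(cc <- cor(a[ok], b[ok]))
  if (is.na(cc)) 0 else cc
}

#' Affine registration of two FA maps
#'
#' Twelve-parameter affine (translation, rotation, scale, shear) maximizing
#' normalized cross-correlation, multi-resolution (half, then full
#' resolution), Nelder-Mead. The returned transform maps fixed-world
#' coordinates to moving-world coordinates (the pull-back used for
#' resampling). If optimization fails to improve on the identity the identity
#' is returned with a warning.
#'
#' @param moving,fixed 3D FA arrays.
#' @param moving_affine,fixed_affine Voxel-to-world affines.
#' @param maxit Nelder-Mead iteration cap per level.
#' @return List of class `affine_transform`: `matrix` (4x4 fixed-world to
#'   moving-world), `params`, `ncc`, `identity_ncc`.
#' @export
register_affine <- function(moving, fixed,
                            moving_affine = diag_affine(1),
                            fixed_affine = diag_affine(1),
                            maxit = 500) {
  fd <- dim(fixed)
  cf <- voxel_to_world((fd - 1) / 2, fixed_affine)[1, ]
  cm <- voxel_to_world((dim(moving) - 1) / 2, moving_affine)[1, ]
  vs <- sqrt(colSums(fixed_affine[1:3, 1:3]^2))

  objective <- function(psub, idx, pfull, fx, fx_affine) {
    p <- pfull
    p[idx] <- psub
    A <- params_to_affine(p, cf, cm)
    res <- resample_vol(moving, moving_affine, dim(fx), fx_affine, A)
    -ncc(as.vector(res), as.vector(fx))
  }
  p0 <- rep(0, 12)
  scale <- c(rep(max(vs), 3), rep(0.05, 3), rep(0.05, 3), rep(0.05, 3))
  rigid <- 1:6

  # coarse level, rigid parameters only (avoids the rotation-scale
  # trade-off while far from the optimum)
  fx2 <- downsample2(fixed)
  fx2_affine <- fixed_affine %*% diag(c(2, 2, 2, 1))
  opt <- optim(p0[rigid], objective, idx = rigid, pfull = p0, fx = fx2,
               fx_affine = fx2_affine, method = "Nelder-Mead",
               control = list(maxit = maxit, parscale = scale[rigid]))
  p <- p0; p[rigid] <- opt$par
  # fine level: rigid simplex, then full-affine quasi-Newton refinement
  opt <- optim(p[rigid], objective, idx = rigid, pfull = p, fx = fixed,
               fx_affine = fixed_affine, method = "Nelder-Mead",
               control = list(maxit = maxit, parscale = scale[rigid] / 4))
  p[rigid] <- opt$par
  opt <- optim(p[rigid], objective, idx = rigid, pfull = p, fx = fixed,
               fx_affine = fixed_affine, method = "BFGS",
               control = list(maxit = 100, reltol = 1e-12,
                              parscale = scale[rigid] / 4))
  p[rigid] <- opt$par
  opt <- optim(p, objective, idx = 1:12, pfull = p, fx = fixed,
               fx_affine = fixed_affine, method = "BFGS",
               control = list(maxit = 100, reltol = 1e-12,
                              parscale = scale / 4))
  opt$par <- { p[1:12] <- opt$par; p }
  id_ncc <- -objective(p0, 1:12, p0, fixed, fixed_affine)
  fit_ncc <- -opt$value
  if (fit_ncc < id_ncc) {
    # already perfectly aligned inputs leave nothing to improve; only a
    # genuine failure warrants the warning
    if (id_ncc < 1 - 1e-9)
      warning("registration failed to improve on the identity; returning identity")
    return(structure(list(matrix = diag(4), params = p0, ncc = id_ncc,
                          identity_ncc = id_ncc),
                     class = "affine_transform"))
  }
  structure(list(matrix = params_to_affine(opt$par, cf, cm), params = opt$par,
                 ncc = fit_ncc, identity_ncc = id_ncc),
            class = "affine_transform")
}

#' Identity transform
#' @return An `affine_transform` with the identity matrix.
#' @export
identity_transform <- function() {
  structure(list(matrix = diag(4), params = rep(0, 12), ncc = 1,
                 identity_ncc = 1),
            class = "affine_transform")
}

#' Resample a scalar volume through an affine transform
#'
#' @param vol Moving 3D array.
#' @param transform An `affine_transform` (fixed world to moving world) or a
#'   4x4 matrix.
#' @param fixed_dim,fixed_affine Target grid.
#' @param moving_affine Moving voxel-to-world affine.
#' @param nearest Use nearest-neighbor lookup (for masks/labels).
#' @return Resampled 3D array on the fixed grid.
#' @export
apply_transform <- function(vol, transform, fixed_dim, fixed_affine,
                            moving_affine = fixed_affine, nearest = FALSE) {
  M <- if (inherits(transform, "affine_transform")) transform$matrix
       else transform
  if (!nearest)
    return(resample_vol(vol, moving_affine, fixed_dim, fixed_affine, M))
  grid <- as.matrix(expand.grid(0:(fixed_dim[1] - 1), 0:(fixed_dim[2] - 1),
                                0:(fixed_dim[3] - 1)))
  wf <- voxel_to_world(grid, fixed_affine)
  wm <- t(M %*% rbind(t(wf), 1))[, 1:3, drop = FALSE]
  vm <- round(world_to_voxel(wm, moving_affine))
  d <- dim(vol)
  inside <- vm[, 1] >= 0 & vm[, 1] < d[1] & vm[, 2] >= 0 & vm[, 2] < d[2] &
            vm[, 3] >= 0 & vm[, 3] < d[3]
  out <- rep(vol[1] * 0, nrow(vm))
  out[inside] <- vol[vm[inside, , drop = FALSE] + 1L]
  array(out, fixed_dim)
}

#' Preservation-of-principal-direction tensor reorientation
#'
#' Applies the PPD rule under the linear part `F` of a spatial transform:
#' the first eigenvector is mapped by `F` and renormalized, the second is
#' mapped and re-orthogonalized against the new first, the third completes
#' the right-handed frame; eigenvalues are preserved. A singular local map
#' leaves the voxel unrotated and flags it.
#'
#' @param tf A `tensor_field`.
#' @param transform An `affine_transform` or 4x4/3x3 matrix whose linear part
#'   carries the spatial map applied to the image.
#' @return A `tensor_field` with rotated eigenvectors.
#' @export
reorient_ppd <- function(tf, transform) {
  stopifnot(inherits(tf, "tensor_field"))
  M <- if (inherits(transform, "affine_transform")) transform$matrix
       else transform
  F <- if (all(dim(M) == c(4, 4))) M[1:3, 1:3] else M
  if (abs(det(F)) < 1e-12) {
    warning("singular linear map; tensors left unrotated")
    return(tf)
  }
  shape <- dim(tf$evals)[1:3]
  nv <- prod(shape)
  ec <- array(tf$evecs, c(nv, 3, 3))
  vox <- which(tf$mask & matrix(tf$evals, nv, 3)[, 1] > 0)
  for (k in vox) {
    e1 <- F %*% ec[k, , 1]
    n1 <- sqrt(sum(e1^2))
    if (n1 < 1e-12) next
    e1 <- e1 / n1
    e2 <- F %*% ec[k, , 2]
    e2 <- e2 - sum(e2 * e1) * e1
    n2 <- sqrt(sum(e2^2))
    if (n2 < 1e-12) next
    e2 <- e2 / n2
    e3 <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    ec[k, , 1] <- e1; ec[k, , 2] <- e2; ec[k, , 3] <- e3
  }
  tensor_field(tf$evals, array(ec, c(shape, 3, 3)), tf$affine, tf$mask)
}

#' Edge-preserving local MMSE (Wiener-type) smoothing
#'
#' Per voxel the output is `mean + max(0, 1 - noise_var/local_var) * (value -
#' mean)` over a 3x3x3 neighborhood whose weights are attenuated across
#' high-gradient edges of the edge map (`exp(-(delta_edge)^2 / (2 h^2))`).
#' Output values never leave the input range (the estimate is a convex
#' combination of the voxel and its local mean).
#'
#' @param vol 3D scalar map.
#' @param edge Edge map guiding the attenuation (defaults to `vol` itself).
#' @param iterations Number of passes (default 1).
#' @param noise_var Noise variance; `NULL` estimates it as the median local
#'   variance (uniform-weight) over the volume.
#' @param edge_scale Attenuation scale `h` on edge-map units; `NULL` uses
#'   half the edge map's SD.
#' @return Smoothed 3D array.
#' @export
smooth_aniso <- function(vol, edge = vol, iterations = 1, noise_var = NULL,
                         edge_scale = NULL) {
  d <- dim(vol)
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  shift <- function(a, o) {
    out <- array(NA_real_, d)
    src <- list(max(1, 1 - o[1]):min(d[1], d[1] - o[1]),
                max(1, 1 - o[2]):min(d[2], d[2] - o[2]),
                max(1, 1 - o[3]):min(d[3], d[3] - o[3]))
    dst <- list(src[[1]] + o[1], src[[2]] + o[2], src[[3]] + o[3])
    out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
    out
  }
  if (is.null(edge_scale)) {
    es <- sd(edge, na.rm = TRUE) / 2
    if (!is.finite(es) || es == 0) es <- 1
  } else es <- edge_scale
  for (it in seq_len(iterations)) {
    sw <- array(0, d); swv <- array(0, d); swv2 <- array(0, d)
    for (i in seq_len(nrow(offs))) {
      o <- offs[i, ]
      vk <- shift(vol, o)
      ek <- shift(edge, o)
      w <- exp(-((ek - edge)^2) / (2 * es^2))
      w[is.na(w) | is.na(vk)] <- 0
      vk[is.na(vk)] <- 0
      sw <- sw + w
      swv <- swv + w * vk
      swv2 <- swv2 + w * vk^2
    }
    mu <- swv / sw
    lv <- pmax(swv2 / sw - mu^2, 0)
    if (is.null(noise_var)) {
      nv <- median(lv, na.rm = TRUE)
      if (!is.finite(nv)) nv <- 0
    } else nv <- noise_var
    alpha <- pmax(0, 1 - nv / pmax(lv, .Machine$double.eps))
    alpha[lv <= nv] <- 0
    vol <- mu + alpha * (vol - mu)
  }
  vol
}

# stack list of 3D arrays / 4D array into subjects x voxels matrix
stack_maps <- function(maps) {
  if (is.list(maps)) {
    d <- dim(maps[[1]])
    Y <- t(vapply(maps, as.vector, numeric(prod(d))))
    list(Y = Y, dim = d)
  } else {
    d <- dim(maps)
    list(Y = t(matrix(maps, prod(d[1:3]), d[4])), dim = d[1:3])
  }
}

#' Voxelwise gender-adjusted group comparison (t-map)
#'
#' Per masked voxel fits `value ~ group + gender` and reports the t statistic
#' and two-sided p of the group contrast, signed as control minus case
#' (positive t where cases are reduced). The significance mask applies the
#' uncorrected threshold `p_threshold`.
#'
#' @param maps List of 3D subject maps (or 4D array, subject last).
#' @param group Factor with levels `control`, `case`.
#' @param gender Optional covariate factor; dropped with a warning if
#'   confounded with group.
#' @param p_threshold Uncorrected voxelwise threshold (default 0.01).
#' @param mask Optional logical 3D mask.
#' @return Object of class `stat_map` with `stat`, `p`, `sig`, `threshold`,
#'   `df`, `covariates`, `type = "t"`.
#' @export
group_tmap <- function(maps, group, gender = NULL, p_threshold = 0.01,
                       mask = NULL) {
  sm <- stack_maps(maps)
  Y <- sm$Y
  n <- nrow(Y)
  group <- factor(group, levels = c("control", "case"))
  if (any(table(group) < 3)) stop("need at least 3 subjects per group")
  covs <- "group"
  X <- model.matrix(~group)
  if (!is.null(gender)) {
    X2 <- model.matrix(~ group + factor(gender))
    if (qr(X2)$rank == ncol(X2)) {
      X <- X2
      covs <- c("group", "gender")
    } else warning("gender is confounded with group; covariate dropped")
  }
  if (is.null(mask)) mask <- array(TRUE, sm$dim)
  vox <- which(as.vector(mask))
  Yv <- Y[, vox, drop = FALSE]
  XtXi <- solve(crossprod(X))
  beta <- XtXi %*% crossprod(X, Yv)
  res <- Yv - X %*% beta
  df <- n - ncol(X)
  sigma2 <- colSums(res^2) / df
  cgg <- XtXi[2, 2]
  se <- sqrt(sigma2 * cgg)
  tstat <- ifelse(se > 0, -beta[2, ] / se, 0) # control - case
  p <- 2 * pt(-abs(tstat), df)
  full <- function(x, fill = NA_real_) {
    out <- array(fill, sm$dim); out[vox] <- x; out
  }
  structure(list(stat = full(tstat), p = full(p),
                 sig = full(p < p_threshold, FALSE) & mask,
                 threshold = p_threshold, df = df, covariates = covs,
                 type = "t"),
            class = "stat_map")
}

#' Voxelwise Spearman correlation map
#'
#' Per masked voxel computes the Spearman correlation between the scalar and
#' the outcome; with a gender covariate, ranks of both are residualized on
#' gender first (partial rank correlation). The display mask combines
#' `p < p_threshold` and `|rho| > rho_threshold`.
#'
#' @param maps List of 3D subject maps (or 4D array).
#' @param outcome Numeric outcome per subject (must be non-constant).
#' @param gender Optional covariate factor.
#' @param p_threshold Voxelwise p threshold (default 0.001).
#' @param rho_threshold Display threshold on `|rho|` (default 0.2).
#' @param mask Optional logical 3D mask.
#' @return A `stat_map` with `type = "spearman"`.
#' @export
spearman_map <- function(maps, outcome, gender = NULL, p_threshold = 0.001,
                         rho_threshold = 0.2, mask = NULL) {
  sm <- stack_maps(maps)
  Y <- sm$Y
  n <- nrow(Y)
  if (!all(is.finite(outcome))) stop("outcome must be finite for all subjects")
  if (length(unique(outcome)) < 2) stop("constant outcome: correlation undefined")
  if (is.null(mask)) mask <- array(TRUE, sm$dim)
  vox <- which(as.vector(mask))
  R <- apply(Y[, vox, drop = FALSE], 2, rank)
  ry <- rank(outcome)
  if (!is.null(gender)) {
    G <- model.matrix(~ factor(gender))
    P <- diag(n) - G %*% solve(crossprod(G)) %*% t(G)
    R <- P %*% R
    ry <- as.vector(P %*% ry)
  } else {
    R <- sweep(R, 2, colMeans(R))
    ry <- ry - mean(ry)
  }
  num <- as.vector(crossprod(R, ry))
  den <- sqrt(colSums(R^2) * sum(ry^2))
  rho <- ifelse(den > 0, num / den, 0)
  rho <- pmin(pmax(rho, -1), 1)
  dfree <- n - 2 - if (is.null(gender)) 0 else 1
  tt <- rho * sqrt(dfree / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), dfree)
  p[abs(rho) >= 1] <- 0
  full <- function(x, fill = NA_real_) {
    out <- array(fill, sm$dim); out[vox] <- x; out
  }
  structure(list(stat = full(rho), p = full(p),
                 sig = full(p < p_threshold & abs(rho) > rho_threshold, FALSE) & mask,
                 threshold = p_threshold, rho_threshold = rho_threshold,
                 df = dfree, covariates = if (is.null(gender)) "none" else "gender",
                 type = "spearman"),
            class = "stat_map")
}

#' Multi-template consensus of voxel-based group comparisons
#'
#' Repeats the register-smooth-test chain once with each listed subject as
#' the template, maps each template's significance mask into the frame of the
#' first template, and intersects: only voxels significant under every
#' template survive.
#'
#' @param fa_maps List of subject FA maps (3D arrays on a shared grid size).
#' @param group,gender As in [group_tmap()].
#' @param templates Indices of subjects used as templates (at least 2).
#' @param registration `"identity"` (subjects already share a frame; the
#'   phantom-cohort default) or `"affine"` ([register_affine()] per subject).
#' @param smooth Apply [smooth_aniso()] to each registered map.
#' @param p_threshold Voxelwise threshold (default 0.01).
#' @param affine Shared voxel-to-world affine.
#' @param mask Optional logical mask.
#' @return List of class `consensus` with `consensus` (logical 3D mask in
#'   the first template's frame), `per_template` masks, `templates`.
#' @export
template_consensus <- function(fa_maps, group, gender = NULL,
                               templates = seq_along(fa_maps),
                               registration = c("identity", "affine"),
                               smooth = TRUE, p_threshold = 0.01,
                               affine = diag_affine(1), mask = NULL) {
  registration <- match.arg(registration)
  if (length(templates) < 2) stop("need at least 2 templates")
  d <- dim(fa_maps[[1]])
  masks <- vector("list", length(templates))
  to_first <- vector("list", length(templates))
  for (ti in seq_along(templates)) {
    k <- templates[ti]
    result <- tryCatch({
      reg_maps <- lapply(seq_along(fa_maps), function(i) {
        if (registration == "identity" || i == k) return(fa_maps[[i]])
        tr <- register_affine(fa_maps[[i]], fa_maps[[k]], affine, affine)
        apply_transform(fa_maps[[i]], tr, d, affine, affine)
      })
      if (smooth)
        reg_maps <- lapply(reg_maps, smooth_aniso, edge = fa_maps[[k]])
      stm <- group_tmap(reg_maps, group, gender, p_threshold, mask)
      stm$sig
    }, error = function(e)
      stop("VBA failed for template ", k, ": ", conditionMessage(e),
           call. = FALSE))
    masks[[ti]] <- result
    to_first[[ti]] <- if (registration == "identity" || ti == 1) result else {
      tr <- register_affine(fa_maps[[k]], fa_maps[[templates[1]]],
                            affine, affine)
      apply_transform(result * 1, tr, d, affine, affine, nearest = TRUE) > 0
    }
  }
  consensus <- Reduce(`&`, to_first)
  structure(list(consensus = consensus, per_template = masks,
                 templates = templates, p_threshold = p_threshold),
            class = "consensus")
}
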