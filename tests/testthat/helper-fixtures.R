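# Shared fixtures, built in code at load time.

# full acquisition scheme (126 directions, b = 3000) and a lighter one
scheme_full <- default_scheme()
scheme_lite <- default_scheme(30)

# a single-bundle phantom whose one fat bundle fills the grid along +y
single_bundle_spec <- function(shape = c(8, 8, 6), evals = c(1.7, 0.3, 0.3) * 1e-3,
                               frac = 1, sigma = 0, seed = 1) {
  vs <- 0.7
  phantom_spec(shape = shape, voxel_size = vs,
               bundles = list(list(name = "b",
                                   centerline = rbind(c(0, vs, 2.1),
                                                      c(0, (shape[2] - 2) * vs, 2.1)),
                                   radius = 100, evals = evals, frac = frac)),
               regions = list(), sigma = sigma, seed = seed)
}

# synthetic uniform-direction tensor field (slab), FA ~ 0.8
uniform_tensor_field <- function(shape = c(20, 5, 5), dir = c(1, 0, 0),
                                 evals = c(1.7, 0.3, 0.3) * 1e-3,
                                 voxel_size = 0.7) {
  dir <- dir / sqrt(sum(dir^2))
  a <- if (abs(dir[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- c(dir[2] * a[3] - dir[3] * a[2], dir[3] * a[1] - dir[1] * a[3],
         dir[1] * a[2] - dir[2] * a[1])
  u <- u / sqrt(sum(u^2))
  v <- c(dir[2] * u[3] - dir[3] * u[2], dir[3] * u[1] - dir[1] * u[3],
         dir[1] * u[2] - dir[2] * u[1])
  nv <- prod(shape)
  ev <- array(rep(evals, each = nv), c(shape, 3))
  ec <- array(0, c(shape, 3, 3))
  for (i in 1:3) {
    ec[, , , i, 1] <- dir[i]
    ec[, , , i, 2] <- u[i]
    ec[, , , i, 3] <- v[i]
  }
  tensor_field(ev, ec, diag_affine(voxel_size))
}

# DWI signal of a single tensor D at a scheme, as a tiny 4D volume
tensor_signal_volume <- function(D, scheme, shape = c(2, 2, 1), s0 = 100) {
  g <- scheme$directions
  quad <- rowSums((g %*% D) * g)
  att <- s0 * exp(-scheme$bvalues * quad)
  arr <- array(rep(att, each = prod(shape)), c(shape, scheme$n))
  dwi_volume(arr, scheme, diag_affine(0.7))
}

# smooth multi-blob image for registration tests
blob_image <- function(d = c(24, 24, 16), n_blobs = 6, seed = 1) {
  set.seed(seed)
  base <- array(0, d)
  g <- as.matrix(expand.grid(0:(d[1] - 1), 0:(d[2] - 1), 0:(d[3] - 1)))
  for (k in seq_len(n_blobs)) {
    c0 <- c(runif(1, 6, d[1] - 6), runif(1, 6, d[2] - 6), runif(1, 4, d[3] - 4))
    base <- base + array(exp(-rowSums(sweep(g, 2, c0)^2) / (2 * 9)), d)
  }
  base
}

# independent dense-resampling membership oracle: walks each streamline at a
# fine step, collects (region, hemisphere) labels by nearest voxel, and
# evaluates the AND/OR network logic from scratch
oracle_network_membership <- function(t, atlas, spec, side, fine = 10) {
  if (is.character(spec)) spec <- builtin_network(spec)
  vapply(t$streamlines, function(sl) {
    pts <- sl
    if (nrow(sl) > 1) {
      dense <- lapply(seq_len(nrow(sl) - 1), function(i) {
        f <- seq(0, 1, length.out = fine + 1)[-(fine + 1)]
        outer(1 - f, sl[i, ]) + outer(f, sl[i + 1, ])
      })
      pts <- rbind(do.call(rbind, dense), sl[nrow(sl), ])
    }
    vox <- round(world_to_voxel(pts, atlas$affine))
    d <- dim(atlas$labels)
    keep <- vox[, 1] >= 0 & vox[, 1] < d[1] & vox[, 2] >= 0 & vox[, 2] < d[2] &
            vox[, 3] >= 0 & vox[, 3] < d[3]
    ids <- unique(atlas$labels[vox[keep, , drop = FALSE] + 1L])
    ids <- ids[ids > 0]
    tab <- atlas$table[match(ids, atlas$table$id), ]
    if (side != "global") tab <- tab[tab$hemisphere == side, , drop = FALSE]
    regs <- unique(tab$region)
    all(spec$required %in% regs) && any(spec$optional %in% regs)
  }, logical(1))
}
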