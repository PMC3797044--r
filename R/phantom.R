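# Multi-tensor DWI phantoms with a paired-region atlas and known ground truth.

REGION_NAMES <- c("prefrontal cortex", "cingulate cortex", "temporal cortex",
                  "caudate", "putamen", "thalamus", "amygdala", "hippocampus",
                  "hippocampal formation")

#' Default phantom layout: bundles and paired region boxes
#'
#' Three straight bundles per hemisphere run along +y at fixed (x, z):
#' an "anxiety" bundle traversing amygdala, hippocampal formation and
#' cingulate cortex; a "memory" bundle traversing hippocampal formation,
#' hippocampus, temporal and prefrontal cortices; and a "free" bundle
#' traversing only the striatum (caudate + putamen), belonging to neither
#' network. Thalamus is placed off every bundle as a distractor. Regions are
#' axis-aligned boxes with explicit left/right labels; only the traversal
#' logic, not anatomy, is modeled.
#'
#' @param shape Grid shape in voxels (length 3).
#' @param voxel_size Isotropic voxel size in mm.
#' @param radius Bundle radius in mm.
#' @param evals Bundle tensor eigenvalues in mm^2/s (length 3, descending).
#' @param frac Bundle volume fraction per voxel.
#' @return List with `bundles` (per-bundle name, centerline mm, radius,
#'   eigenvalues, fraction) and `regions` (per-region name, hemisphere,
#'   box in mm: 3 x 2 matrix of lower/upper corners).
#' @export
phantom_layout <- function(shape = c(40, 40, 20), voxel_size = 0.7,
                           radius = 1.5 * voxel_size,
                           evals = c(1.7, 0.3, 0.3) * 1e-3, frac = 0.85) {
  vs <- voxel_size
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  xc <- c(left = 0.25 * (nx - 1), right = 0.75 * (nx - 1))
  zlow <- 0.35 * (nz - 1)
  zhigh <- 0.7 * (nz - 1)
  dx <- max(3, round(nx / 10))
  yspan <- c(2, ny - 3) * vs
  line_y <- function(x, z) rbind(c(x, yspan[1], z), c(x, yspan[2], z)) # mm
  bundles <- list()
  regions <- list()
  ybox <- function(f0, f1) c(f0, f1) * (ny - 1) * vs
  for (h in c("left", "right")) {
    xa <- (xc[[h]] - dx) * vs
    xm <- (xc[[h]] + dx) * vs
    xn <- xc[[h]] * vs
    bundles[[paste0("anxiety_", h)]] <- list(
      name = paste0("anxiety_", h), centerline = line_y(xa, zlow * vs),
      radius = radius, evals = evals, frac = frac)
    bundles[[paste0("memory_", h)]] <- list(
      name = paste0("memory_", h), centerline = line_y(xm, zlow * vs),
      radius = radius, evals = evals, frac = frac)
    bundles[[paste0("free_", h)]] <- list(
      name = paste0("free_", h), centerline = line_y(xn, zhigh * vs),
      radius = radius, evals = evals, frac = frac)
    box <- function(x, yfrac, z, halfw = 2 * vs) {
      rbind(x = c(x - halfw, x + halfw),
            y = ybox(yfrac[1], yfrac[2]),
            z = c(z - halfw, z + halfw))
    }
    add_region <- function(name, x, yfrac, z) {
      regions[[length(regions) + 1]] <<- list(
        name = name, hemisphere = h, box = box(x, yfrac, z))
    }
    # on the anxiety bundle
    add_region("amygdala", xa, c(0.08, 0.22), zlow * vs)
    add_region("hippocampal formation", xa, c(0.30, 0.44), zlow * vs)
    add_region("cingulate cortex", xa, c(0.52, 0.66), zlow * vs)
    # on the memory bundle (second hippocampal-formation box: one label,
    # two components, so both networks' required sets are satisfiable)
    add_region("hippocampal formation", xm, c(0.08, 0.22), zlow * vs)
    add_region("hippocampus", xm, c(0.30, 0.44), zlow * vs)
    add_region("temporal cortex", xm, c(0.52, 0.66), zlow * vs)
    add_region("prefrontal cortex", xm, c(0.74, 0.88), zlow * vs)
    # on the free bundle: striatum plus the thalamus distractor, so that no
    # network-required region sits on it (it stays outside both networks)
    add_region("thalamus", xn, c(0.08, 0.22), zhigh * vs)
    add_region("putamen", xn, c(0.30, 0.44), zhigh * vs)
    add_region("caudate", xn, c(0.52, 0.66), zhigh * vs)
  }
  # merge duplicate (name, hemisphere) boxes into box lists
  merged <- list()
  for (r in regions) {
    k <- paste0(r$name, "|", r$hemisphere)
    if (is.null(merged[[k]]))
      merged[[k]] <- list(name = r$name, hemisphere = r$hemisphere,
                          boxes = list(r$box))
    else merged[[k]]$boxes <- c(merged[[k]]$boxes, list(r$box))
  }
  list(bundles = bundles, regions = unname(merged))
}

#' Specify a DWI phantom
#'
#' @param shape Grid shape in voxels.
#' @param voxel_size Isotropic voxel size, mm (0.7 by default, the ex-vivo
#'   acquisition resolution the phantom emulates).
#' @param bundles List of bundles (see [phantom_layout()]); each has a
#'   `centerline` polyline in mm, `radius` mm, tensor `evals` mm^2/s and a
#'   volume fraction `frac`.
#' @param regions Region box list as produced by [phantom_layout()], used to
#'   build the label atlas; may be empty.
#' @param background_adc Isotropic diffusivity of the background compartment,
#'   mm^2/s.
#' @param s0 Non-diffusion-weighted signal amplitude.
#' @param sigma Rician noise level in signal units (0 = noiseless).
#' @param seed Integer seed for noise and dropout.
#' @param dropout Named numeric vector: per-bundle fraction of member voxels
#'   demoted to background (bundle thinning).
#' @param lambda1_scale List with `regions` (names) and `factor`: bundle-voxel
#'   principal eigenvalue is multiplied by `factor` inside those atlas
#'   regions (used to plant anisotropy effects).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(40, 40, 20), voxel_size = 0.7,
                         bundles = NULL, regions = NULL,
                         background_adc = 0.7e-3, s0 = 100, sigma = 0,
                         seed = 1L, dropout = NULL, lambda1_scale = NULL) {
  if (is.null(bundles) || is.null(regions)) {
    lay <- phantom_layout(shape, voxel_size)
    if (is.null(bundles)) bundles <- lay$bundles
    if (is.null(regions)) regions <- lay$regions
  }
  for (b in bundles) {
    if (any(b$evals <= 0)) stop("bundle eigenvalues must be positive")
    if (b$frac <= 0 || b$frac > 1) stop("bundle volume fraction must be in (0,1]")
  }
  if (background_adc <= 0) stop("background diffusivity must be positive")
  structure(list(shape = as.integer(shape), voxel_size = voxel_size,
                 bundles = bundles, regions = regions,
                 background_adc = background_adc, s0 = s0, sigma = sigma,
                 seed = as.integer(seed),
                 dropout = dropout, lambda1_scale = lambda1_scale),
            class = "phantom_spec")
}

# distance from points (n x 3) to a polyline (k x 3); returns list(dist, seg
# tangent index)
polyline_distance <- function(pts, line) {
  n <- nrow(pts)
  best <- rep(Inf, n)
  tangent_idx <- rep(1L, n)
  nseg <- nrow(line) - 1
  for (s in seq_len(nseg)) {
    a <- line[s, ]; b <- line[s + 1, ]
    ab <- b - a
    len2 <- sum(ab^2)
    ap <- sweep(pts, 2, a)
    t <- pmin(pmax((ap %*% ab)[, 1] / len2, 0), 1)
    proj <- outer(t, ab)
    d <- sqrt(rowSums((ap - proj)^2))
    upd <- d < best
    best[upd] <- d[upd]
    tangent_idx[upd] <- s
  }
  tang <- normalize_rows(line[-1, , drop = FALSE] - line[-nrow(line), , drop = FALSE])
  list(dist = best, tangent = tang[tangent_idx, , drop = FALSE])
}

# orthonormal complement of unit rows t: returns list(u, v)
orthonormal_complement <- function(t) {
  a <- matrix(rep(c(1, 0, 0), each = nrow(t)), ncol = 3)
  swap <- abs(t[, 1]) > 0.9
  a[swap, ] <- matrix(rep(c(0, 1, 0), each = sum(swap)), ncol = 3)
  u <- cbind(t[, 2] * a[, 3] - t[, 3] * a[, 2],
             t[, 3] * a[, 1] - t[, 1] * a[, 3],
             t[, 1] * a[, 2] - t[, 2] * a[, 1])
  u <- normalize_rows(u)
  v <- cbind(t[, 2] * u[, 3] - t[, 3] * u[, 2],
             t[, 3] * u[, 1] - t[, 1] * u[, 3],
             t[, 1] * u[, 2] - t[, 2] * u[, 1])
  list(u = u, v = v)
}

#' Build the label atlas for a phantom specification
#'
#' @param spec A [phantom_spec()].
#' @return A `region_atlas` (see [region_atlas()]).
#' @export
phantom_atlas <- function(spec) {
  shape <- spec$shape
  affine <- diag_affine(spec$voxel_size)
  grid <- as.matrix(expand.grid(x = 0:(shape[1] - 1), y = 0:(shape[2] - 1),
                                z = 0:(shape[3] - 1)))
  world <- grid * spec$voxel_size
  labels <- array(0L, dim = shape)
  tab <- data.frame(id = integer(), region = character(),
                    hemisphere = character(), stringsAsFactors = FALSE)
  id <- 0L
  for (r in spec$regions) {
    id <- id + 1L
    inside <- rep(FALSE, nrow(world))
    for (bx in r$boxes) {
      inside <- inside |
        (world[, 1] >= bx[1, 1] & world[, 1] <= bx[1, 2] &
         world[, 2] >= bx[2, 1] & world[, 2] <= bx[2, 2] &
         world[, 3] >= bx[3, 1] & world[, 3] <= bx[3, 2])
    }
    labels[inside] <- id
    tab <- rbind(tab, data.frame(id = id, region = r$name,
                                 hemisphere = r$hemisphere,
                                 stringsAsFactors = FALSE))
  }
  region_atlas(labels, tab, affine)
}

#' Generate a synthetic DWI volume with known ground truth
#'
#' Per voxel and gradient the signal follows the multi-tensor forward model
#' `S(g) = S0 (sum_i f_i exp(-b g' D_i g) + f_bg exp(-b d_bg))`, followed by
#' Rician corruption `|S + n1 + i n2|` with `n1, n2 ~ N(0, sigma^2)`.
#'
#' @param spec A [phantom_spec()].
#' @param scheme A [gradient_scheme()].
#' @return List of class `phantom` with `dwi` (a `dwi_volume`), `atlas`
#'   (a `region_atlas`) and `truth` (per-bundle voxel membership, tangents,
#'   eigenvalues after any planted modification, per-bundle region
#'   traversals, and the voxels carrying a planted eigenvalue effect).
#' @export
make_phantom <- function(spec, scheme) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(scheme, "gradient_scheme"))
  shape <- spec$shape
  nvox <- prod(shape)
  ngrad <- scheme$n
  affine <- diag_affine(spec$voxel_size)
  grid <- as.matrix(expand.grid(x = 0:(shape[1] - 1), y = 0:(shape[2] - 1),
                                z = 0:(shape[3] - 1)))
  world <- grid * spec$voxel_size
  atlas <- phantom_atlas(spec)

  set.seed(spec$seed)
  # bundle membership; thinning demotes the outermost fraction of member
  # voxels (by centerline distance) to background, modeling a uniformly
  # narrower bundle
  members <- list()
  for (b in spec$bundles) {
    pd <- polyline_distance(world, b$centerline)
    inb <- pd$dist <= b$radius
    drop_frac <- if (is.null(spec$dropout)) NA_real_
                 else unname(spec$dropout[b$name])
    if (isTRUE(drop_frac > 0)) {
      idx <- which(inb)
      ndrop <- round(drop_frac * length(idx))
      if (ndrop > 0) {
        ord <- idx[order(pd$dist[idx], idx, decreasing = TRUE)]
        inb[ord[seq_len(ndrop)]] <- FALSE
      }
    }
    members[[b$name]] <- list(mask = inb, tangent = pd$tangent[inb, , drop = FALSE])
  }
  frac_tot <- rep(0, nvox)
  for (b in spec$bundles) frac_tot <- frac_tot + b$frac * members[[b$name]]$mask
  if (any(frac_tot > 1 + 1e-12))
    stop("overlapping bundles: volume fractions exceed 1 in ",
         sum(frac_tot > 1 + 1e-12), " voxel(s)")

  bvals <- scheme$bvalues
  dirs <- scheme$directions
  # background compartment
  att_bg <- exp(-bvals * spec$background_adc)
  signal <- (1 - frac_tot) %o% att_bg
  # per-bundle anisotropic compartments
  truth_bundles <- list()
  for (b in spec$bundles) {
    m <- members[[b$name]]$mask
    ev <- matrix(b$evals, nrow = sum(m), ncol = 3, byrow = TRUE)
    if (!is.null(spec$lambda1_scale) &&
        length(spec$lambda1_scale$regions) > 0 &&
        spec$lambda1_scale$factor != 1) {
      lab <- atlas$labels[m]
      hit <- lab > 0 &
        atlas$table$region[match(lab, atlas$table$id)] %in% spec$lambda1_scale$regions
      ev[hit, 1] <- ev[hit, 1] * spec$lambda1_scale$factor
    } else hit <- rep(FALSE, sum(m))
    tg <- members[[b$name]]$tangent
    if (sum(m) > 0) {
      uv <- orthonormal_complement(tg)
      ct <- tg %*% t(dirs)
      cu <- uv$u %*% t(dirs)
      cv <- uv$v %*% t(dirs)
      quad <- ev[, 1] * ct^2 + ev[, 2] * cu^2 + ev[, 3] * cv^2
      att <- exp(-sweep(quad, 2, bvals, "*"))
      signal[m, ] <- signal[m, , drop = FALSE] + b$frac * att
    }
    truth_bundles[[b$name]] <- list(
      voxels = which(m), tangent = tg, evals = ev, frac = b$frac,
      effect_voxels = which(m)[hit])
  }
  signal <- spec$s0 * signal
  if (spec$sigma > 0) {
    n1 <- matrix(rnorm(length(signal), 0, spec$sigma), nrow = nvox)
    n2 <- matrix(rnorm(length(signal), 0, spec$sigma), nrow = nvox)
    signal <- sqrt((signal + n1)^2 + n2^2)
  }
  dim(signal) <- c(shape, ngrad)
  mask <- array(TRUE, dim = shape)
  dwi <- dwi_volume(signal, scheme, affine, mask)

  traversals <- lapply(truth_bundles, function(tb) {
    lab <- unique(atlas$labels[tb$voxels])
    lab <- lab[lab > 0]
    atlas$table[match(lab, atlas$table$id), c("region", "hemisphere")]
  })
  structure(list(dwi = dwi, atlas = atlas,
                 truth = list(bundles = truth_bundles,
                              traversals = traversals,
                              background_adc = spec$background_adc,
                              spec = spec)),
            class = "phantom")
}

#' Container for a 4D diffusion-weighted volume
#'
#' @param signal 4D array (x, y, z, gradient), non-negative.
#' @param scheme Matching [gradient_scheme()].
#' @param affine 4x4 voxel-to-world affine.
#' @param mask Logical 3D brain mask (defaults to all `TRUE`).
#' @return Object of class `dwi_volume`.
#' @export
dwi_volume <- function(signal, scheme, affine = diag_affine(1), mask = NULL) {
  d <- dim(signal)
  if (length(d) != 4) stop("signal must be a 4D array")
  if (d[4] != scheme$n)
    stop("signal has ", d[4], " volumes but scheme has ", scheme$n,
         " gradients")
  if (is.null(mask)) mask <- array(TRUE, dim = d[1:3])
  if (!all(dim(mask) == d[1:3])) stop("mask shape does not match signal")
  if (min(signal, na.rm = TRUE) < 0) stop("signal must be non-negative")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  structure(list(signal = signal, scheme = scheme, affine = affine,
                 mask = mask, voxel_size = vs),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$signal)
  cat("DWI volume:", paste(d[1:3], collapse = " x "), "voxels x", d[4],
      "gradients, voxel size", paste(signif(x$voxel_size, 3), collapse = " x "),
      "mm\n")
  invisible(x)
}
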