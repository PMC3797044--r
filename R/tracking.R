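# Deterministic whole-brain streamline tractography.

#' Deterministic streamline tractography
#'
#' Seeds one streamline at the center of every masked voxel whose FA is at
#' least `seed_fa`, integrates bidirectionally with fixed-step second-order
#' Runge-Kutta over trilinearly interpolated peak directions (sign-aligned to
#' the previous step; at crossings the peak with the smallest angle to the
#' previous direction is chosen), and terminates on FA below `stop_fa`,
#' turning angle above `max_angle`, or leaving the volume. Streamlines
#' shorter than `min_length` are discarded.
#'
#' @param source Direction source: a `tensor_field` (tracks the principal
#'   eigenvector) or a `peak_field` from [odf_peaks()] (the pipeline
#'   default).
#' @param maps A `scalar_maps` on the same grid (FA is used for seeding and
#'   termination).
#' @param step Step size in mm (default 0.35, half the reference voxel).
#' @param seed_fa,stop_fa Seed and termination FA thresholds (defaults 0.2
#'   and 0.15).
#' @param max_angle Maximum turning angle per step, degrees (default 60).
#' @param min_length Minimum retained streamline length, mm (default 2.1).
#' @param max_steps Safety cap on steps per direction.
#' @return Object of class `tractogram`: `streamlines` (list of n x 3 world
#'   mm matrices), `seed_voxel` (0-based seed indices), `step`, `params`.
#' @export
track <- function(source, maps, step = 0.35, seed_fa = 0.2, stop_fa = 0.15,
                  max_angle = 60, min_length = 2.1, max_steps = 2000) {
  if (inherits(source, "tensor_field")) source <- tensor_peaks(source)
  stopifnot(inherits(source, "peak_field"), inherits(maps, "scalar_maps"))
  if (!all(dim(maps$fa) == dim(source$n_peaks)))
    stop("FA map and direction source must share a grid")
  if (step <= 0) stop("step must be positive")
  if (seed_fa < 0 || seed_fa > 1 || stop_fa < 0 || stop_fa > 1)
    stop("FA thresholds must lie in [0,1]")
  if (max_angle <= 0 || max_angle > 180) stop("max_angle must be in (0,180]")
  vs <- source$voxel_size
  if (diff(range(vs)) > 1e-6 * mean(vs))
    stop("tracking assumes isotropic voxels")
  step_vox <- step / vs[1]

  shape <- dim(maps$fa)
  seeds_lin <- which(source$mask & maps$fa >= seed_fa & source$n_peaks > 0)
  if (length(seeds_lin) == 0) {
    return(structure(list(streamlines = list(), seed_voxel = matrix(0L, 0, 3),
                          step = step,
                          params = list(step = step, seed_fa = seed_fa,
                                        stop_fa = stop_fa,
                                        max_angle = max_angle,
                                        min_length = min_length)),
                     class = "tractogram"))
  }
  seeds <- arrayInd(seeds_lin, shape) - 1L
  min_points <- as.integer(ceiling(min_length / step)) + 1L

  pk <- source$peaks
  pk[is.na(pk)] <- 0
  res <- cpp_track(as.numeric(pk), as.integer(source$n_peaks),
                   as.numeric(maps$fa), as.integer(shape),
                   seeds, step_vox, max_angle, stop_fa,
                   as.integer(max_steps), min_points)
  affine <- source$affine
  sl <- lapply(res$streamlines, function(m) voxel_to_world(m, affine))
  structure(list(streamlines = sl,
                 seed_voxel = seeds[res$seed_index, , drop = FALSE],
                 step = step,
                 params = list(step = step, seed_fa = seed_fa,
                               stop_fa = stop_fa, max_angle = max_angle,
                               min_length = min_length)),
            class = "tractogram")
}

#' Number of retained streamlines
#' @param t A `tractogram`.
#' @return Integer count.
#' @export
total_fiber_count <- function(t) {
  stopifnot(inherits(t, "tractogram"))
  length(t$streamlines)
}

#' Concatenate tractograms
#' @param ... `tractogram` objects sharing generation parameters.
#' @return A `tractogram` whose fiber count is the sum of the inputs'.
#' @export
concat_tractograms <- function(...) {
  ts <- list(...)
  stopifnot(all(vapply(ts, inherits, logical(1), "tractogram")))
  structure(list(streamlines = do.call(c, lapply(ts, `[[`, "streamlines")),
                 seed_voxel = do.call(rbind, lapply(ts, `[[`, "seed_voxel")),
                 step = ts[[1]]$step, params = ts[[1]]$params),
            class = "tractogram")
}

#' Subset a tractogram
#' @param t A `tractogram`.
#' @param idx Indices of streamlines to keep.
#' @return A `tractogram`.
#' @export
subset_tractogram <- function(t, idx) {
  structure(list(streamlines = t$streamlines[idx],
                 seed_voxel = t$seed_voxel[idx, , drop = FALSE],
                 step = t$step, params = t$params),
            class = "tractogram")
}

#' @export
print.tractogram <- function(x, ...) {
  n <- length(x$streamlines)
  cat("Tractogram:", n, "streamlines")
  if (n > 0) {
    len <- vapply(x$streamlines, function(m) (nrow(m) - 1) * x$step, numeric(1))
    cat(", length", signif(min(len), 3), "-", signif(max(len), 3), "mm")
  }
  cat(" (step", x$step, "mm)\n")
  invisible(x)
}

#' Total streamline length
#' @param t A `tractogram`.
#' @return Numeric vector of per-streamline lengths in mm.
#' @export
streamline_lengths <- function(t) {
  vapply(t$streamlines, function(m) (nrow(m) - 1) * t$step, numeric(1))
}
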