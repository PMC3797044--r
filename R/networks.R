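# Region atlases and region-logic fiber networks: a streamline belongs to a
# network when it traverses ALL required regions and AT LEAST ONE optional
# region, optionally restricted to one hemisphere.

#' Construct a region atlas
#'
#' @param labels Integer 3D label volume (0 = unlabeled).
#' @param table Data frame with columns `id`, `region`, `hemisphere`
#'   (`left`, `right` or `midline`); region names must come from the fixed
#'   grey-matter vocabulary used by the built-in networks.
#' @param affine 4x4 voxel-to-world affine.
#' @return Object of class `region_atlas`.
#' @export
region_atlas <- function(labels, table, affine = diag_affine(1)) {
  storage.mode(labels) <- "integer"
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids > 0]
  missing_ids <- setdiff(ids, table$id)
  if (length(missing_ids) > 0)
    stop("label volume contains ids absent from the table: ",
         paste(missing_ids, collapse = ", "))
  bad <- setdiff(table$region, REGION_NAMES)
  if (length(bad) > 0)
    stop("unknown region name(s): ", paste(bad, collapse = ", "))
  if (!all(table$hemisphere %in% c("left", "right", "midline")))
    stop("hemisphere must be left, right or midline")
  structure(list(labels = labels, table = table, affine = affine),
            class = "region_atlas")
}

#' Define a fiber network by traversal logic
#'
#' @param name Network name.
#' @param required Region names every member fiber must traverse (logical
#'   AND).
#' @param optional Region names of which at least one must be traversed
#'   (logical OR). Must be disjoint from `required`; both non-empty.
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(name, required, optional) {
  if (length(required) == 0 || length(optional) == 0)
    stop("required and optional region sets must be non-empty")
  if (length(intersect(required, optional)) > 0)
    stop("required and optional sets must be disjoint")
  structure(list(name = name, required = required, optional = optional),
            class = "network_spec")
}

#' Built-in network definitions
#'
#' The anxiety/attention network keeps fibers passing through the amygdala
#' and the hippocampal formation plus at least one of striatum (caudate or
#' putamen), thalamus, prefrontal, temporal or cingulate cortex. The
#' short-term memory network keeps fibers passing through the hippocampal
#' formation plus at least one of hippocampus, thalamus, prefrontal or
#' temporal cortex.
#'
#' @param name `"anxiety"` or `"memory"`.
#' @return A [network_spec()].
#' @export
builtin_network <- function(name = c("anxiety", "memory")) {
  name <- match.arg(name)
  if (name == "anxiety")
    network_spec("anxiety",
                 required = c("amygdala", "hippocampal formation"),
                 optional = c("caudate", "putamen", "thalamus",
                              "prefrontal cortex", "temporal cortex",
                              "cingulate cortex"))
  else
    network_spec("memory",
                 required = "hippocampal formation",
                 optional = c("hippocampus", "thalamus",
                              "prefrontal cortex", "temporal cortex"))
}

# labels hit by a streamline: each segment is resampled at one tenth of the
# inter-point spacing, then world points -> nearest voxel -> label ids (the
# same definition as the brute-force voxel-trace oracle)
densify_polyline <- function(points, factor = 10) {
  n <- nrow(points)
  if (n < 2 || factor <= 1) return(points)
  a <- points[-n, , drop = FALSE]
  b <- points[-1, , drop = FALSE]
  out <- vector("list", factor)
  f <- seq(0, 1, length.out = factor + 1)[-(factor + 1)]
  for (i in seq_len(factor))
    out[[i]] <- (1 - f[i]) * a + f[i] * b
  rbind(do.call(rbind, out), points[n, , drop = FALSE])
}

streamline_labels <- function(points, atlas) {
  points <- densify_polyline(points)
  vox <- round(world_to_voxel(points, atlas$affine))
  d <- dim(atlas$labels)
  inside <- vox[, 1] >= 0 & vox[, 1] < d[1] &
            vox[, 2] >= 0 & vox[, 2] < d[2] &
            vox[, 3] >= 0 & vox[, 3] < d[3]
  if (!any(inside)) return(integer(0))
  v <- vox[inside, , drop = FALSE]
  unique(atlas$labels[v + 1L])
}

# (region, hemisphere) pairs traversed by a streamline
streamline_regions <- function(points, atlas) {
  ids <- streamline_labels(points, atlas)
  ids <- ids[ids > 0]
  atlas$table[match(ids, atlas$table$id), c("region", "hemisphere")]
}

#' Does a streamline pass through a region?
#'
#' A streamline passes through a region when any point of the polyline,
#' resampled at one tenth of its inter-point spacing and mapped to the
#' nearest voxel, carries a matching label; the resampling guards against
#' region corners crossed between tracking steps. Points outside the volume
#' are unlabeled.
#'
#' @param streamline Matrix (n x 3) of world-mm points.
#' @param atlas A [region_atlas()].
#' @param region Region name.
#' @param hemisphere `"either"` (default), `"left"` or `"right"`.
#' @return Logical.
#' @export
passes_through <- function(streamline, atlas, region,
                           hemisphere = c("either", "left", "right")) {
  hemisphere <- match.arg(hemisphere)
  if (!region %in% atlas$table$region)
    stop("region '", region, "' is not present in the atlas")
  hit <- streamline_regions(streamline, atlas)
  if (nrow(hit) == 0) return(FALSE)
  ok <- hit$region == region
  if (hemisphere != "either") ok <- ok & hit$hemisphere == hemisphere
  any(ok)
}

#' Extract the sub-tractogram satisfying a network's traversal logic
#'
#' Retains streamlines traversing every required region and at least one
#' optional region. For `side = "left"`/`"right"` only labels of that
#' hemisphere count; for `"global"` either hemisphere counts. Each
#' streamline is counted once.
#'
#' @param t A `tractogram`.
#' @param atlas A [region_atlas()].
#' @param spec A [network_spec()] or a built-in name (`"anxiety"`,
#'   `"memory"`).
#' @param side `"global"`, `"left"` or `"right"`.
#' @return A `tractogram` restricted to member streamlines, with attribute
#'   `member_index` giving their indices in `t`.
#' @export
extract_network <- function(t, atlas, spec, side = c("global", "left", "right")) {
  side <- match.arg(side)
  if (is.character(spec)) spec <- builtin_network(spec)
  stopifnot(inherits(t, "tractogram"), inherits(atlas, "region_atlas"),
            inherits(spec, "network_spec"))
  absent <- setdiff(c(spec$required, spec$optional), atlas$table$region)
  if (length(absent) > 0)
    stop("network '", spec$name, "' names region(s) absent from the atlas: ",
         paste(absent, collapse = ", "))
  keep <- vapply(t$streamlines, function(sl) {
    hit <- streamline_regions(sl, atlas)
    if (nrow(hit) == 0) return(FALSE)
    if (side != "global") hit <- hit[hit$hemisphere == side, , drop = FALSE]
    regs <- unique(hit$region)
    all(spec$required %in% regs) && any(spec$optional %in% regs)
  }, logical(1))
  out <- subset_tractogram(t, which(keep))
  attr(out, "member_index") <- which(keep)
  attr(out, "network") <- spec$name
  attr(out, "side") <- side
  out
}

#' Network fiber ratio
#'
#' Number of fibers in the network divided by the total number of fibers in
#' the brain.
#'
#' @param network Sub-tractogram from [extract_network()].
#' @param whole Whole-brain `tractogram`.
#' @return Fraction in `[0, 1]`.
#' @export
fiber_ratio <- function(network, whole) {
  nw <- total_fiber_count(whole)
  if (nw == 0) stop("whole-brain tractogram is empty; fiber ratio undefined")
  total_fiber_count(network) / nw
}

#' Mean FA along network fibers
#'
#' FA is sampled by trilinear interpolation at every point of every member
#' streamline and pooled across points (not per-streamline means).
#'
#' @param network Sub-tractogram from [extract_network()].
#' @param maps A `scalar_maps`.
#' @return Pooled mean FA, or `NA` (with a warning) for an empty network.
#' @export
network_mean_fa <- function(network, maps) {
  stopifnot(inherits(maps, "scalar_maps"))
  if (total_fiber_count(network) == 0) {
    warning("empty network: mean FA is missing")
    return(NA_real_)
  }
  pts <- do.call(rbind, network$streamlines)
  vox <- world_to_voxel(pts, maps$affine)
  mean(trilinear(maps$fa, vox))
}
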