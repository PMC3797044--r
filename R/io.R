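# NIfTI + gradient-table + atlas I/O.

as_nifti_image <- function(arr, affine) {
  img <- RNifti::asNifti(arr)
  img <- RNifti::`sform<-`(img, structure(affine, code = 2L))
  img
}

#' Write a DWI volume to NIfTI + bval/bvec
#'
#' @param dwi A `dwi_volume`.
#' @param prefix Output path prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.bval`, `<prefix>.bvec`.
#' @return The NIfTI path, invisibly.
#' @export
write_dwi <- function(dwi, prefix) {
  stopifnot(inherits(dwi, "dwi_volume"))
  path <- paste0(prefix, ".nii.gz")
  RNifti::writeNifti(as_nifti_image(dwi$signal, dwi$affine), path)
  write_bval_bvec(dwi$scheme, paste0(prefix, ".bval"), paste0(prefix, ".bvec"))
  invisible(path)
}

#' Read a DWI volume from NIfTI + bval/bvec
#'
#' Volumes are paired to gradients positionally; the gradient count must
#' equal the fourth dimension and the scheme must contain a b=0 volume.
#'
#' @param nifti_path Path to a 4D NIfTI.
#' @param bval_path,bvec_path FSL-dialect gradient table paths.
#' @param mask Optional logical 3D mask.
#' @return A `dwi_volume`.
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path, mask = NULL) {
  img <- RNifti::readNifti(nifti_path)
  arr <- unclass(img)
  attributes(arr) <- list(dim = dim(img))
  if (length(dim(arr)) != 4) stop("expected a 4D DWI volume")
  scheme <- read_bval_bvec(bval_path, bvec_path)
  if (scheme$n != dim(arr)[4])
    stop("gradient count (", scheme$n, ") does not match volume count (",
         dim(arr)[4], ")")
  affine <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  affine <- matrix(as.numeric(affine), 4, 4)
  dwi_volume(arr, scheme, affine, mask)
}

#' Write a 3D scalar map to NIfTI
#' @param vol 3D array.
#' @param affine 4x4 voxel-to-world affine.
#' @param path Output `.nii.gz` path.
#' @export
write_scalar_nifti <- function(vol, affine, path) {
  RNifti::writeNifti(as_nifti_image(vol, affine), path)
  invisible(path)
}

#' Read a 3D scalar NIfTI
#' @param path NIfTI path.
#' @return List with `data` (3D array) and `affine`.
#' @export
read_scalar_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- unclass(img)
  attributes(arr) <- list(dim = dim(img))
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  list(data = arr, affine = affine)
}

#' Write the lower-triangular tensor components to NIfTI
#'
#' Component order Dxx, Dxy, Dyy, Dxz, Dyz, Dzz along the fourth dimension.
#'
#' @param tf A `tensor_field`.
#' @param path Output `.nii.gz` path.
#' @export
write_tensor_nifti <- function(tf, path) {
  stopifnot(inherits(tf, "tensor_field"))
  RNifti::writeNifti(as_nifti_image(tf$D, tf$affine), path)
  invisible(path)
}

#' Write a region atlas (NIfTI labels + JSON table)
#' @param atlas A `region_atlas`.
#' @param prefix Output prefix; writes `<prefix>.nii.gz`,
#'   `<prefix>.labels.json`.
#' @export
write_atlas <- function(atlas, prefix) {
  stopifnot(inherits(atlas, "region_atlas"))
  RNifti::writeNifti(as_nifti_image(atlas$labels, atlas$affine),
                     paste0(prefix, ".nii.gz"))
  jsonlite::write_json(atlas$table, paste0(prefix, ".labels.json"),
                       dataframe = "rows")
  invisible(prefix)
}

#' Read a region atlas (NIfTI labels + JSON table)
#' @param prefix Prefix used by [write_atlas()].
#' @return A `region_atlas`.
#' @export
read_atlas <- function(prefix) {
  img <- RNifti::readNifti(paste0(prefix, ".nii.gz"))
  arr <- unclass(img)
  attributes(arr) <- list(dim = dim(img))
  storage.mode(arr) <- "integer"
  tab <- jsonlite::read_json(paste0(prefix, ".labels.json"),
                             simplifyVector = TRUE)
  affine <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  region_atlas(arr, tab, affine)
}
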