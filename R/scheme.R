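# Gradient schemes (FSL bval/bvec dialect)

#' Construct a diffusion gradient scheme
#'
#' @param bvalues Numeric vector of b-values in s/mm^2, one per volume.
#' @param directions Matrix (n x 3) of gradient directions; rows for b>0
#'   volumes must be unit vectors (tolerance 1e-6), b=0 rows may be zero.
#' @return Object of class `gradient_scheme` with elements `bvalues`,
#'   `directions`, `n`.
#' @export
gradient_scheme <- function(bvalues, directions) {
  directions <- rbind2mat(directions)
  if (length(bvalues) != nrow(directions))
    stop("bvalues (", length(bvalues), ") and directions (", nrow(directions),
         ") counts differ")
  if (!any(bvalues == 0))
    stop("gradient scheme must contain at least one b=0 volume")
  dwi <- bvalues > 0
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm[dwi] - 1) > 1e-6))
    stop("b>0 directions must be unit vectors (max |norm-1| = ",
         format(max(abs(nrm[dwi] - 1))), ")")
  structure(list(bvalues = as.numeric(bvalues), directions = directions,
                 n = length(bvalues)),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  shells <- sort(unique(round(x$bvalues[x$bvalues > 0])))
  cat("Gradient scheme:", x$n, "volumes,", sum(x$bvalues == 0), "b=0,",
      sum(x$bvalues > 0), "diffusion-weighted (b =",
      paste(shells, collapse = ", "), "s/mm^2)\n")
  invisible(x)
}

#' Near-uniform unit directions on the sphere (Fibonacci spiral)
#'
#' Deterministic full-sphere point set with good angular uniformity, used for
#' the default high-angular-resolution acquisition scheme.
#'
#' @param n Number of directions.
#' @return Matrix (n x 3) of unit vectors.
#' @export
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  polar <- acos(1 - 2 * i / n)
  azim <- pi * (1 + sqrt(5)) * i
  cbind(sin(polar) * cos(azim), sin(polar) * sin(azim), cos(polar))
}

#' Default single-shell acquisition scheme
#'
#' One b=0 volume followed by `n_dirs` directions at the given shell, matching
#' a high-angular-resolution ex-vivo protocol (126 directions at
#' b = 3000 s/mm^2 by default).
#'
#' @param n_dirs Number of diffusion-weighted directions.
#' @param bvalue Shell b-value in s/mm^2.
#' @return A [gradient_scheme()].
#' @export
default_scheme <- function(n_dirs = 126, bvalue = 3000) {
  gradient_scheme(c(0, rep(bvalue, n_dirs)),
                  rbind(c(0, 0, 0), fibonacci_directions(n_dirs)))
}

#' Read FSL-dialect bval/bvec files
#'
#' `bvec` files with 3 rows x N columns or N rows x 3 columns are both
#' accepted and canonicalized to N x 3; directions are re-normalized to unit
#' length for b>0 volumes.
#'
#' @param bval_path,bvec_path Paths to whitespace-separated text files.
#' @return A [gradient_scheme()].
#' @export
read_bval_bvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bv <- as.matrix(read.table(bvec_path))
  if (nrow(bv) == 3 && ncol(bv) != 3) bv <- t(bv)
  if (nrow(bv) == 3 && ncol(bv) == 3) bv <- t(bv) # 3x3: FSL rows convention
  if (ncol(bv) != 3)
    stop("bvec file must have 3 rows or 3 columns, got ", nrow(bv), "x", ncol(bv))
  if (nrow(bv) != length(bvals))
    stop("bvec direction count (", nrow(bv), ") does not match bval count (",
         length(bvals), ")")
  dimnames(bv) <- NULL
  nrm <- sqrt(rowSums(bv^2))
  fix <- bvals > 0 & nrm > 0
  bv[fix, ] <- bv[fix, , drop = FALSE] / nrm[fix]
  gradient_scheme(bvals, bv)
}

#' Write FSL-dialect bval/bvec files
#' @param scheme A [gradient_scheme()].
#' @param bval_path,bvec_path Output paths (bval: one row; bvec: three rows).
#' @export
write_bval_bvec <- function(scheme, bval_path, bvec_path) {
  cat(paste(scheme$bvalues, collapse = " "), "\n", file = bval_path, sep = "")
  write.table(t(scheme$directions), bvec_path, row.names = FALSE,
              col.names = FALSE)
  invisible(c(bval_path, bvec_path))
}
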