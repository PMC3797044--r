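# TCK streamline format (MRtrix): text header terminated by END, then
# little-endian float32 triplets in world mm; NaN triplet separates
# streamlines, Inf triplet terminates the stream.

#' Write a tractogram to TCK
#'
#' @param t A `tractogram`.
#' @param path Output path (conventionally `.tck`); a JSON sidecar with the
#'   generation parameters is written next to it.
#' @param sidecar Write the parameter sidecar (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_tck <- function(t, path, sidecar = TRUE) {
  stopifnot(inherits(t, "tractogram"))
  header <- paste0(
    "mrtrix tracks\ndatatype: Float32LE\ncount: ",
    length(t$streamlines), "\n")
  # offset must be known before writing; compute with placeholder length
  make_header <- function(off) paste0(header, "file: . ", off, "\nEND\n")
  off <- nchar(make_header(0), type = "bytes")
  # widen offset until self-consistent
  repeat {
    off2 <- nchar(make_header(off), type = "bytes")
    if (off2 == off) break
    off <- off2
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(make_header(off), con, eos = NULL)
  for (m in t$streamlines) {
    writeBin(as.numeric(t(m)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  if (sidecar) {
    jsonlite::write_json(t$params, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a TCK tractogram
#'
#' @param path Path to a TCK file.
#' @return A `tractogram` (generation parameters restored from the JSON
#'   sidecar when present).
#' @export
read_tck <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  lines <- character()
  repeat {
    ln <- readLines(con, n = 1)
    if (length(ln) == 0) stop("unterminated TCK header")
    if (ln == "END") break
    lines <- c(lines, ln)
  }
  if (!grepl("^mrtrix tracks", lines[1])) stop("not a TCK file: ", path)
  dt <- sub("^datatype:\\s*", "", grep("^datatype:", lines, value = TRUE))
  if (length(dt) != 1 || dt != "Float32LE")
    stop("unsupported TCK datatype: ", dt)
  file_line <- grep("^file:", lines, value = TRUE)
  off <- as.integer(sub("^file:\\s*\\.\\s*", "", file_line))
  seek(con, off)
  raw_n <- file.info(path)$size - off
  vals <- readBin(con, "numeric", n = raw_n / 4, size = 4, endian = "little")
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  is_nan <- rowSums(is.na(m)) > 0
  is_inf <- is.infinite(m[, 1])
  stops <- which(is_nan | is_inf)
  starts <- c(1, stops[-length(stops)] + 1)
  sl <- list()
  for (i in seq_along(stops)) {
    if (is_inf[stops[i]]) break
    rng <- starts[i]:(stops[i] - 1)
    if (length(rng) >= 1 && stops[i] > starts[i])
      sl[[length(sl) + 1]] <- m[rng, , drop = FALSE]
  }
  params <- NULL
  sc <- paste0(path, ".json")
  if (file.exists(sc)) params <- jsonlite::read_json(sc, simplifyVector = TRUE)
  step <- if (!is.null(params$step)) params$step else {
    if (length(sl) > 0 && nrow(sl[[1]]) > 1)
      sqrt(sum((sl[[1]][2, ] - sl[[1]][1, ])^2)) else NA_real_
  }
  structure(list(streamlines = sl,
                 seed_voxel = matrix(NA_integer_, length(sl), 3),
                 step = step, params = params),
            class = "tractogram")
}
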