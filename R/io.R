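# Stack I/O (float32 TIFF and raw) and run configuration.

# Minimal multi-page float32 TIFF writer (little-endian, uncompressed,
# one strip per page, SampleFormat = IEEE float). Written by hand because
# the available libtiff binding clamps floating-point data to [0, 1] on
# write; reading goes through tiff::readTIFF, against which this writer is
# round-trip verified.
write_tiff_float32 <- function(images, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) writeBin(as.integer(v), con, size = 4, endian = "little")
  n_tags <- 10L
  ifd_size <- 2L + n_tags * 12L + 4L
  npix <- vapply(images, length, integer(1))
  data_off <- integer(length(images))
  ifd_off <- integer(length(images))
  pos <- 8L
  for (j in seq_along(images)) {
    data_off[j] <- pos
    pos <- pos + npix[j] * 4L
    ifd_off[j] <- pos
    pos <- pos + ifd_size
  }
  writeBin(charToRaw("II"), con)
  w16(42L)
  w32(ifd_off[1])
  tag <- function(id, type, value) { w16(id); w16(type); w32(1L); w32(value) }
  for (j in seq_along(images)) {
    img <- images[[j]]
    writeBin(as.numeric(t(img)), con, size = 4, endian = "little")  # row-major
    w16(n_tags)
    tag(256L, 4L, ncol(img))           # ImageWidth
    tag(257L, 4L, nrow(img))           # ImageLength
    tag(258L, 3L, 32L)                 # BitsPerSample
    tag(259L, 3L, 1L)                  # Compression: none
    tag(262L, 3L, 1L)                  # Photometric: BlackIsZero
    tag(273L, 4L, data_off[j])         # StripOffsets
    tag(277L, 3L, 1L)                  # SamplesPerPixel
    tag(278L, 4L, nrow(img))           # RowsPerStrip
    tag(279L, 4L, npix[j] * 4L)        # StripByteCounts
    tag(339L, 3L, 3L)                  # SampleFormat: IEEE float
    w32(if (j < length(images)) ifd_off[j + 1] else 0L)  # next IFD
  }
  invisible(path)
}

guess_format <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "raw"
}

#' Read and write image stacks (float32 TIFF or raw)
#'
#' `read_stack()` reads a single- or multi-page TIFF (pages become stack
#' slices in page order) or a raw little-endian float32 file (column-major,
#' explicit `shape` required). `write_stack()` writes the same formats in
#' float32, so one write/read round trip is lossless at float32 precision
#' (and bit-exact for data already representable in float32). The format is
#' chosen from the file extension unless given explicitly.
#'
#' @param path file path.
#' @param format `"auto"`, `"tiff"` or `"raw"`.
#' @param shape for raw files: image shape `c(H, W)` or stack shape
#'   `c(H, W, J)`.
#' @return `read_stack`: a list of `H x W` matrices (always a list, also
#'   for single-page files).
#' @export
read_stack <- function(path, format = c("auto", "tiff", "raw"), shape = NULL) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  if (format == "tiff") {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1L]   # drop extra channels
      matrix(as.numeric(p), nrow(p), ncol(p))
    })
  } else {
    if (is.null(shape)) stop("raw format requires an explicit 'shape'")
    shape <- as.integer(shape)
    if (length(shape) == 2L) shape <- c(shape, 1L)
    expect <- prod(shape) * 4L
    actual <- file.size(path)
    if (actual != expect)
      stop(sprintf("raw file size mismatch: expected %d bytes for shape %s, found %d",
                   expect, paste(shape, collapse = "x"), actual))
    con <- file(path, "rb")
    on.exit(close(con))
    lapply(seq_len(shape[3]), function(j) {
      matrix(readBin(con, "double", n = shape[1] * shape[2], size = 4,
                     endian = "little"),
             shape[1], shape[2])
    })
  }
}

#' @rdname read_stack
#' @param stack a matrix, a list of matrices, or a 3D array (slices along
#'   the third dimension).
#' @export
write_stack <- function(stack, path, format = c("auto", "tiff", "raw")) {
  format <- match.arg(format)
  if (format == "auto") format <- guess_format(path)
  if (is.matrix(stack)) stack <- list(stack)
  if (is.array(stack) && length(dim(stack)) == 3L)
    stack <- lapply(seq_len(dim(stack)[3]), function(j) stack[, , j])
  stopifnot(is.list(stack), length(stack) >= 1L)
  for (im in stack) assert_image(im)
  if (format == "tiff") {
    write_tiff_float32(stack, path)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    for (im in stack)
      writeBin(as.numeric(im), con, size = 4, endian = "little")
  }
  invisible(path)
}

#' Resolve a run configuration from defaults, file and overrides
#'
#' Merges three layers of parameters with precedence
#' `cli_overrides > file_config > defaults`. Keys not present in `defaults`
#' are rejected with an error listing the valid keys; calling with only
#' `defaults` returns them verbatim. The resolved configuration can be
#' written next to outputs with [write_config_sidecar()] so every run is
#' re-runnable from its sidecar.
#'
#' @param defaults named list of all valid parameters with default values.
#' @param file_config named list loaded from a configuration file.
#' @param overrides named list of command-line overrides.
#' @return merged named list of class `"run_config"`.
#' @export
resolve_config <- function(defaults, file_config = list(), overrides = list()) {
  stopifnot(is.list(defaults), is.list(file_config), is.list(overrides))
  valid <- names(defaults)
  for (layer in list(file_config, overrides)) {
    unknown <- setdiff(names(layer), valid)
    if (length(unknown) > 0L)
      stop(sprintf("unknown parameter(s) %s; valid parameters are: %s",
                   paste0("'", unknown, "'", collapse = ", "),
                   paste(valid, collapse = ", ")))
  }
  out <- defaults
  out[names(file_config)] <- file_config
  out[names(overrides)] <- overrides
  structure(out, class = c("run_config", "list"))
}

#' @rdname resolve_config
#' @param config a resolved `"run_config"`.
#' @param path sidecar file path (JSON).
#' @export
write_config_sidecar <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

read_config_file <- function(path) {
  if (is.null(path) || identical(path, "")) return(list())
  as.list(jsonlite::read_json(path, simplifyVector = TRUE))
}
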