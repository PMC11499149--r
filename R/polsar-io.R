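#' @include AllClasses.R utils.R
NULL

# Flat-binary raster container: band-sequential, little-endian payload with a
# JSON sidecar header at <path>.json. Complex rasters are stored as re/im
# pairs (complex64 = float32 pairs by default, complex128 = float64 pairs);
# real rasters as float64; integer rasters as int32. Row-major pixel order,
# pixel (1,1) top-left.

headerPath <- function(path) paste0(path, ".json")

writeHeader <- function(path, header) {
  jsonlite::write_json(header, headerPath(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

readHeader <- function(path) {
  hp <- headerPath(path)
  if (!file.exists(hp))
    stop("missing sidecar header: ", hp, call. = FALSE)
  jsonlite::read_json(hp, simplifyVector = TRUE)
}

checkPayload <- function(path, expectedBytes) {
  if (!file.exists(path))
    stop(sprintf("missing payload file '%s' (expected %d bytes)",
                 path, expectedBytes), call. = FALSE)
  sz <- file.info(path)$size
  if (sz != expectedBytes)
    stop(sprintf(
      "header/payload mismatch for '%s': header implies %d bytes, file has %d",
      path, expectedBytes, sz), call. = FALSE)
}

complexBytes <- function(dtype) switch(dtype, complex64 = 8L, complex128 = 16L,
  stop("unknown complex dtype: ", dtype, call. = FALSE))

writeComplexBands <- function(con, bands, dtype) {
  size <- complexBytes(dtype) / 2L
  for (b in bands) {
    v <- as.complex(t(b))  # row-major on disk
    inter <- as.numeric(rbind(Re(v), Im(v)))
    writeBin(inter, con, size = size, endian = "little")
  }
}

readComplexBand <- function(con, rows, cols, dtype) {
  size <- complexBytes(dtype) / 2L
  raw <- readBin(con, "numeric", n = 2L * rows * cols, size = size,
                 endian = "little")
  if (length(raw) != 2L * rows * cols)
    stop("truncated payload while reading band", call. = FALSE)
  v <- complex(real = raw[c(TRUE, FALSE)], imaginary = raw[c(FALSE, TRUE)])
  t(matrix(v, cols, rows))
}

#' Write a quad-pol scattering image
#'
#' Band-sequential little-endian flat binary (channel order HH, HV, VH, VV)
#' with a JSON sidecar header at \code{<path>.json} declaring rows, cols,
#' dtype, channel order, interleave, byte order and the date tag.
#'
#' @param img a \linkS4class{ScatteringImage}.
#' @param path payload file path.
#' @param dtype \code{"complex64"} (float32 pairs, default) or
#'   \code{"complex128"} (float64 pairs, lossless for R doubles).
#' @return \code{path}, invisibly.
#' @export
writeScatteringImage <- function(img, path, dtype = c("complex64",
                                                      "complex128")) {
  dtype <- match.arg(dtype)
  d <- dim(img@shh)
  header <- list(format = "genpol-scattering", rows = d[1], cols = d[2],
                 dtype = dtype, channels = c("HH", "HV", "VH", "VV"),
                 interleave = "bsq", byte_order = "little",
                 date_tag = img@dateTag)
  if (!is.null(img@pixelSpacing)) header$pixel_spacing <- img@pixelSpacing
  con <- file(path, "wb")
  on.exit(close(con))
  writeComplexBands(con, list(img@shh, img@shv, img@svh, img@svv), dtype)
  writeHeader(path, header)
  invisible(path)
}

#' Read a quad-pol scattering image
#'
#' Validates the sidecar header and the payload byte count before reading;
#' a truncated or oversized payload raises a format error naming the
#' expected byte count.
#'
#' @param path payload file path (header expected at \code{<path>.json}).
#' @return a \linkS4class{ScatteringImage}.
#' @export
readScatteringImage <- function(path) {
  h <- readHeader(path)
  for (fld in c("rows", "cols", "dtype", "channels"))
    if (is.null(h[[fld]]))
      stop("sidecar header lacks field '", fld, "'", call. = FALSE)
  rows <- as.integer(h$rows); cols <- as.integer(h$cols)
  checkPayload(path, 4L * rows * cols * complexBytes(h$dtype))
  con <- file(path, "rb")
  on.exit(close(con))
  bands <- lapply(1:4, function(i) readComplexBand(con, rows, cols, h$dtype))
  names(bands) <- tolower(h$channels)
  new("ScatteringImage", shh = bands$hh, shv = bands$hv, svh = bands$vh,
      svv = bands$vv, dateTag = if (is.null(h$date_tag)) "" else h$date_tag,
      pixelSpacing = if (is.null(h$pixel_spacing)) NULL
                     else as.numeric(h$pixel_spacing))
}

#' Write a parameter raster
#'
#' Float64 values (NaN outside the valid mask) followed by the mask as
#' uint8, plus a JSON header carrying the name and units. Round trips are
#' bit-exact. NaN inside the valid mask is a validation error; an all-invalid
#' raster is written with a warning.
#'
#' @param r a \linkS4class{ParamRaster}.
#' @param path payload file path.
#' @return \code{path}, invisibly.
#' @export
writeParamRaster <- function(r, path) {
  validObject(r)
  if (!any(r@validMask))
    warning("parameter raster '", r@name, "' has zero valid pixels")
  d <- dim(r@values)
  header <- list(format = "genpol-param", rows = d[1], cols = d[2],
                 dtype = "float64", name = r@name, units = r@units,
                 interleave = "bsq", byte_order = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.numeric(t(r@values)), con, size = 8L, endian = "little")
  writeBin(as.integer(t(r@validMask)), con, size = 1L, endian = "little")
  writeHeader(path, header)
  invisible(path)
}

#' Read a parameter raster
#' @param path payload file path.
#' @return a \linkS4class{ParamRaster}.
#' @export
readParamRaster <- function(path) {
  h <- readHeader(path)
  rows <- as.integer(h$rows); cols <- as.integer(h$cols)
  n <- rows * cols
  checkPayload(path, 8L * n + n)
  con <- file(path, "rb")
  on.exit(close(con))
  vals <- t(matrix(readBin(con, "numeric", n = n, size = 8L,
                           endian = "little"), cols, rows))
  mask <- t(matrix(as.logical(readBin(con, "integer", n = n, size = 1L,
                                      signed = FALSE, endian = "little")),
                   cols, rows))
  new("ParamRaster", values = vals, name = h$name, units = h$units,
      validMask = mask)
}

#' Write a label mask
#'
#' Int32 class labels then int32 parcel ids, with class names and the
#' per-parcel train/verify table in the JSON header.
#'
#' @param mask a \linkS4class{LabelMask}.
#' @param path payload file path.
#' @return \code{path}, invisibly.
#' @export
writeLabelMask <- function(mask, path) {
  validObject(mask)
  d <- dim(mask@labels)
  header <- list(format = "genpol-labels", rows = d[1], cols = d[2],
                 dtype = "int32", class_names = mask@classNames,
                 parcel_info = mask@parcelInfo,
                 interleave = "bsq", byte_order = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.integer(t(mask@labels)), con, size = 4L, endian = "little")
  writeBin(as.integer(t(mask@parcels)), con, size = 4L, endian = "little")
  writeHeader(path, header)
  invisible(path)
}

#' Load a label mask
#'
#' Resolves the per-parcel train/verify split from the header and validates
#' that no label exceeds the class table.
#'
#' @param path payload file path.
#' @return a \linkS4class{LabelMask}.
#' @export
loadLabelMask <- function(path) {
  h <- readHeader(path)
  rows <- as.integer(h$rows); cols <- as.integer(h$cols)
  n <- rows * cols
  checkPayload(path, 2L * 4L * n)
  con <- file(path, "rb")
  on.exit(close(con))
  labels <- t(matrix(readBin(con, "integer", n = n, size = 4L,
                             endian = "little"), cols, rows))
  parcels <- t(matrix(readBin(con, "integer", n = n, size = 4L,
                              endian = "little"), cols, rows))
  classNames <- as.character(h$class_names)
  if (any(labels > length(classNames)))
    stop("label exceeds class-table length", call. = FALSE)
  pinfo <- as.data.frame(h$parcel_info)
  mask <- new("LabelMask", labels = labels, classNames = classNames,
              parcels = parcels, parcelInfo = pinfo)
  counts <- table(factor(labels[labels > 0], levels = seq_along(classNames),
                         labels = classNames))
  message("loaded label mask: ",
          paste(sprintf("%s=%d", names(counts), counts), collapse = ", "))
  mask
}

#' Validate a genpol flat-binary container
#'
#' Checks header presence, required fields and the header/payload byte
#' count for any of the package's raster containers.
#'
#' @param path payload file path.
#' @return the parsed header, invisibly; errors describe the defect.
#' @export
validateContainer <- function(path) {
  h <- readHeader(path)
  n <- as.integer(h$rows) * as.integer(h$cols)
  expected <- switch(h$format,
    "genpol-scattering" = 4L * n * complexBytes(h$dtype),
    "genpol-param" = 8L * n + n,
    "genpol-labels" = 8L * n,
    stop("unknown container format: ", h$format, call. = FALSE))
  checkPayload(path, expected)
  invisible(h)
}
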