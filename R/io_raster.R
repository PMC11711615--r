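# Minimal single-strip uncompressed GeoTIFF writer/reader (8-bit unsigned,
# little-endian) and BIL+HDR binary raster I/O. Class, confidence-category
# and inter-model-variability layers are small integers, so 8 bits with a
# reserved nodata code losslessly encode every product; the continuous
# percent-confidence layer travels in NetCDF.

tif_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2L, endian = "little")
tif_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4L, endian = "little")
tif_dbl <- function(x) writeBin(as.double(x), raw(), size = 8L, endian = "little")

#' Write an integer raster as a minimal GeoTIFF
#'
#' Single-strip, uncompressed, 8-bit unsigned grayscale with GeoTIFF
#' georeferencing (geographic WGS84, pixel-is-area, cell size and
#' upper-left corner from the grid) and a GDAL-style nodata tag.
#'
#' @param path output `.tif` path.
#' @param codes integer matrix `nlat x nlon` (row 1 = northernmost), values
#'   0-255; `NA` written as `nodata`.
#' @param lat,lon cell-center coordinates (lat descending).
#' @param nodata nodata code (default 0).
#' @return `path`, invisibly.
#' @export
write_geotiff_raw <- function(path, codes, lat, lon, nodata = 0L) {
  h <- nrow(codes); w <- ncol(codes)
  vals <- as.integer(t(codes))            # row-major pixel order
  vals[is.na(vals)] <- as.integer(nodata)
  if (any(vals < 0 | vals > 255)) stop("values must fit 8-bit unsigned")
  xres <- if (w > 1) abs(lon[2] - lon[1]) else 1
  yres <- if (h > 1) abs(lat[2] - lat[1]) else 1
  west <- min(lon) - xres / 2
  north <- max(lat) + yres / 2

  strip_offset <- 8L
  nbytes <- w * h
  ifd_offset <- strip_offset + nbytes + (nbytes %% 2L)

  ext <- list()  # external value blocks, appended after the IFD
  entries <- list()
  add <- function(tag, type, count, value4) {
    entries[[length(entries) + 1L]] <<- c(tif_u16(tag), tif_u16(type),
                                          tif_u32(count), value4)
  }
  add_ext <- function(tag, type, count, bytes) {
    ext[[length(ext) + 1L]] <<- list(tag = tag, type = type, count = count,
                                     bytes = bytes)
    add(tag, type, count, tif_u32(0L))  # offset patched below
  }
  short_val <- function(x) c(tif_u16(x), tif_u16(0L))
  add(256L, 4L, 1L, tif_u32(w))                       # ImageWidth
  add(257L, 4L, 1L, tif_u32(h))                       # ImageLength
  add(258L, 3L, 1L, short_val(8L))                    # BitsPerSample
  add(259L, 3L, 1L, short_val(1L))                    # Compression: none
  add(262L, 3L, 1L, short_val(1L))                    # BlackIsZero
  add(273L, 4L, 1L, tif_u32(strip_offset))            # StripOffsets
  add(277L, 3L, 1L, short_val(1L))                    # SamplesPerPixel
  add(278L, 4L, 1L, tif_u32(h))                       # RowsPerStrip
  add(279L, 4L, 1L, tif_u32(nbytes))                  # StripByteCounts
  add_ext(282L, 5L, 1L, c(tif_u32(72L), tif_u32(1L))) # XResolution
  add_ext(283L, 5L, 1L, c(tif_u32(72L), tif_u32(1L))) # YResolution
  add(296L, 3L, 1L, short_val(2L))                    # ResolutionUnit: inch
  add(339L, 3L, 1L, short_val(1L))                    # SampleFormat: uint
  add_ext(33550L, 12L, 3L, tif_dbl(c(xres, yres, 0)))            # pixel scale
  add_ext(33922L, 12L, 6L, tif_dbl(c(0, 0, 0, west, north, 0)))  # tiepoint
  add_ext(34735L, 3L, 16L, tif_u16(c(1, 1, 0, 3,
                                     1024, 0, 1, 2,    # model type: geographic
                                     1025, 0, 1, 1,    # raster type: area
                                     2048, 0, 1, 4326)))  # GCS WGS84
  nod <- c(charToRaw(as.character(as.integer(nodata))), as.raw(0L))
  if (length(nod) <= 4L) {
    add(42113L, 2L, length(nod), c(nod, raw(4L - length(nod))))
  } else add_ext(42113L, 2L, length(nod), nod)

  n_ent <- length(entries)
  ifd_size <- 2L + 12L * n_ent + 4L
  # patch external offsets
  pos <- ifd_offset + ifd_size
  for (e in ext) {
    i <- which(vapply(entries, function(en)
      identical(en[1:2], tif_u16(e$tag)), TRUE))
    entries[[i]][9:12] <- tif_u32(pos)
    pos <- pos + length(e$bytes) + length(e$bytes) %% 2L
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), tif_u16(42L), tif_u32(ifd_offset)), con)
  writeBin(as.raw(vals), con)
  if (nbytes %% 2L) writeBin(raw(1L), con)
  writeBin(tif_u16(n_ent), con)
  for (e in entries) writeBin(e, con)
  writeBin(tif_u32(0L), con)
  for (e in ext) {
    writeBin(e$bytes, con)
    if (length(e$bytes) %% 2L) writeBin(raw(1L), con)
  }
  invisible(path)
}

#' Read a minimal GeoTIFF written by [write_geotiff_raw()]
#'
#' @param path `.tif` file (single-strip uncompressed 8-bit, either byte
#'   order).
#' @param nodata code decoded to `NA` (default 0).
#' @return List with `codes` (integer matrix), `pixel_scale`, `tiepoint`,
#'   `nodata`.
#' @export
read_geotiff_raw <- function(path, nodata = 0L) {
  con <- file(path, "rb")
  on.exit(close(con))
  order_bytes <- rawToChar(readBin(con, "raw", 2L))
  endian <- if (order_bytes == "II") "little"
  else if (order_bytes == "MM") "big" else stop("not a TIFF file")
  r16 <- function() readBin(con, "integer", 1L, size = 2L, signed = FALSE,
                            endian = endian)
  r32 <- function() readBin(con, "integer", 1L, size = 4L, endian = endian)
  if (r16() != 42L) stop("not a TIFF file")
  seek(con, r32())
  n <- r16()
  tags <- list()
  for (i in seq_len(n)) {
    tag <- r16(); type <- r16(); count <- r32()
    val_pos <- seek(con)
    value <- if (type == 3L && count <= 2L) {
      v <- vapply(seq_len(count), function(j) r16(), 0L); v
    } else if (type %in% c(4L, 2L) && count <= 4L) {
      r32()
    } else {
      off <- r32()
      here <- seek(con, off)
      v <- switch(as.character(type),
        "2" = rawToChar(readBin(con, "raw", count)),
        "3" = readBin(con, "integer", count, size = 2L, signed = FALSE,
                      endian = endian),
        "4" = readBin(con, "integer", count, size = 4L, endian = endian),
        "5" = readBin(con, "integer", 2L * count, size = 4L, endian = endian),
        "12" = readBin(con, "double", count, size = 8L, endian = endian),
        stop("unsupported TIFF type ", type))
      seek(con, here)
      v
    }
    seek(con, val_pos + 4L)
    tags[[as.character(tag)]] <- value
  }
  w <- tags[["256"]]; h <- tags[["257"]]
  if (!identical(tags[["259"]][1], 1L)) stop("compressed TIFF not supported")
  seek(con, tags[["273"]][1])
  vals <- as.integer(readBin(con, "raw", w * h))
  codes <- matrix(vals, h, w, byrow = TRUE)
  codes[codes == nodata] <- NA_integer_
  list(codes = codes, pixel_scale = tags[["33550"]],
       tiepoint = tags[["33922"]], nodata = nodata)
}

#' Write an integer raster as BIL + HDR (+ legend)
#'
#' Band-interleaved-by-line binary raster: one 8-bit unsigned band,
#' little-endian, rows from north to south, with an ASCII `.hdr` sidecar
#' giving dimensions, byte order, cell size and nodata code.
#'
#' @inheritParams write_geotiff_raw
#' @param path output `.bil` path; the `.hdr` goes alongside.
#' @return `path`, invisibly.
#' @export
write_bil_raw <- function(path, codes, lat, lon, nodata = 0L) {
  h <- nrow(codes); w <- ncol(codes)
  vals <- as.integer(t(codes))
  vals[is.na(vals)] <- as.integer(nodata)
  if (any(vals < 0 | vals > 255)) stop("values must fit 8-bit unsigned")
  con <- file(path, "wb")
  writeBin(as.raw(vals), con)
  close(con)
  xres <- if (w > 1) abs(lon[2] - lon[1]) else 1
  yres <- if (h > 1) abs(lat[2] - lat[1]) else 1
  hdr <- c(
    "BYTEORDER      I",
    "LAYOUT         BIL",
    sprintf("NROWS          %d", h),
    sprintf("NCOLS          %d", w),
    "NBANDS         1",
    "NBITS          8",
    sprintf("BANDROWBYTES   %d", w),
    sprintf("TOTALROWBYTES  %d", w),
    sprintf("ULXMAP         %.6f", min(lon)),
    sprintf("ULYMAP         %.6f", max(lat)),
    sprintf("XDIM           %.6f", xres),
    sprintf("YDIM           %.6f", yres),
    sprintf("NODATA         %d", as.integer(nodata)))
  writeLines(hdr, sub("\\.bil$", ".hdr", path))
  invisible(path)
}

#' Read a BIL + HDR raster written by [write_bil_raw()]
#'
#' @param path `.bil` file with its `.hdr` sidecar.
#' @return List with `codes` (integer matrix, nodata as `NA`) and `header`
#'   (named character vector).
#' @export
read_bil_raw <- function(path) {
  hdr_lines <- readLines(sub("\\.bil$", ".hdr", path))
  kv <- do.call(rbind, strsplit(trimws(hdr_lines), "\\s+"))
  header <- stats::setNames(kv[, 2], toupper(kv[, 1]))
  h <- as.integer(header[["NROWS"]]); w <- as.integer(header[["NCOLS"]])
  if (!identical(as.integer(header[["NBITS"]]), 8L))
    stop("only 8-bit BIL supported")
  vals <- as.integer(readBin(path, "raw", n = w * h))
  if (length(vals) != w * h) stop("BIL size does not match header dimensions")
  codes <- matrix(vals, h, w, byrow = TRUE)
  nodata <- suppressWarnings(as.integer(header[["NODATA"]]))
  if (!is.na(nodata)) codes[codes == nodata] <- NA_integer_
  list(codes = codes, header = header)
}
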