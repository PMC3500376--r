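#' Read a raster from disk
#'
#' @param path file path.
#' @param dialect `"esri_ascii"` or `"geotiff"`.
#' @param kind layer kind to stamp on the result (not stored in either format).
#' @return a [raster_layer()].
#' @export
read_raster <- function(path, dialect = c("esri_ascii", "geotiff"),
                        kind = "continuous") {
  dialect <- match.arg(dialect)
  switch(dialect,
         esri_ascii = read_esri_ascii(path, kind),
         geotiff = read_geotiff(path, kind))
}

#' Write a raster to disk
#'
#' Round-trips value-identically (including the nodata mask and grid
#' geometry) through [read_raster()] for both dialects.
#'
#' @param layer a [raster_layer()].
#' @param path file path.
#' @param dialect `"esri_ascii"` or `"geotiff"`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(layer, path, dialect = c("esri_ascii", "geotiff")) {
  dialect <- match.arg(dialect)
  switch(dialect,
         esri_ascii = write_esri_ascii(layer, path),
         geotiff = write_geotiff(layer, path))
  invisible(path)
}

# --- ESRI ASCII grid -------------------------------------------------------

read_esri_ascii <- function(path, kind = "continuous") {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (i <= length(lines) &&
         grepl("^\\s*[A-Za-z_]+\\s+-?[0-9.eE+-]+\\s*$", lines[i])) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(parts[1])]] <- as.numeric(parts[2])
    i <- i + 1
  }
  req <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")
  if (!all(req %in% names(hdr)))
    stop("not an ESRI ASCII grid: missing header field(s) ",
         paste(setdiff(req, names(hdr)), collapse = ", "))
  nodata <- if (!is.null(hdr$nodata_value)) hdr$nodata_value else -9999
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  rows <- lines[i:length(lines)]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) != nr) stop("expected ", nr, " data rows, found ", length(rows))
  vals <- lapply(rows, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(lengths(vals) != nc)) stop("ragged rows in ASCII grid")
  m <- do.call(rbind, vals)
  m[m == nodata] <- NA_real_
  spec <- grid_spec(nr, nc, hdr$cellsize,
                    origin_x = hdr$xllcorner,
                    origin_y = hdr$yllcorner + nr * hdr$cellsize,
                    nodata = nodata)
  raster_layer(m, spec, kind)
}

write_esri_ascii <- function(layer, path) {
  sp <- layer$spec
  m <- layer$values
  m[is.na(m)] <- sp$nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste("ncols", sp$ncols),
    paste("nrows", sp$nrows),
    paste("xllcorner", format(sp$origin_x, digits = 17)),
    paste("yllcorner", format(sp$origin_y - sp$nrows * sp$cellsize, digits = 17)),
    paste("cellsize", format(sp$cellsize, digits = 17)),
    paste("NODATA_value", format(sp$nodata, digits = 17))
  ), con)
  writeLines(apply(m, 1, function(r) paste(format(r, digits = 17, trim = TRUE),
                                           collapse = " ")), con)
  invisible(path)
}

# --- minimal GeoTIFF -------------------------------------------------------
# Single-band float64, uncompressed, one strip, little-endian, with the
# ModelPixelScale / ModelTiepoint / GDAL_NODATA tags. No package in this
# stack reads or writes GeoTIFF, so the subset we emit is implemented
# directly; the reader accepts exactly this subset and errors loudly on
# anything fancier.

TIFF_TAGS <- c(ImageWidth = 256L, ImageLength = 257L, BitsPerSample = 258L,
               Compression = 259L, Photometric = 262L, StripOffsets = 273L,
               SamplesPerPixel = 277L, RowsPerStrip = 278L,
               StripByteCounts = 279L, SampleFormat = 339L,
               ModelPixelScale = 33550L, ModelTiepoint = 33922L,
               GDALNodata = 42113L)

write_geotiff <- function(layer, path) {
  sp <- layer$spec
  m <- layer$values
  m[is.na(m)] <- sp$nodata
  # pixel data: row-major (TIFF scanlines), float64 LE
  pix <- writeBin(as.vector(t(m)), raw(), size = 8, endian = "little")
  nodata_str <- c(charToRaw(format(sp$nodata, digits = 17)), as.raw(0))
  scale <- c(sp$cellsize, sp$cellsize, 0)
  tiepoint <- c(0, 0, 0, sp$origin_x, sp$origin_y, 0)

  u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")
  f64 <- function(x) writeBin(as.numeric(x), raw(), size = 8, endian = "little")

  # layout: 8-byte header | pixel data | scale (24) | tiepoint (48) |
  #         nodata string | IFD
  off_pix <- 8L
  off_scale <- off_pix + length(pix)
  off_tie <- off_scale + 24L
  off_nodata <- off_tie + 48L
  off_ifd <- off_nodata + length(nodata_str)
  if (off_ifd %% 2 == 1) { nodata_str <- c(nodata_str, as.raw(0)); off_ifd <- off_ifd + 1L }

  entry <- function(tag, type, count, value_raw) {
    # value_raw must be exactly 4 bytes (value or offset)
    c(u16(tag), u16(type), u32(count), value_raw)
  }
  TYPE_SHORT <- 3L; TYPE_LONG <- 4L; TYPE_ASCII <- 2L; TYPE_DOUBLE <- 12L
  entries <- list(
    entry(256, TYPE_LONG, 1, u32(sp$ncols)),
    entry(257, TYPE_LONG, 1, u32(sp$nrows)),
    entry(258, TYPE_SHORT, 1, c(u16(64), u16(0))),
    entry(259, TYPE_SHORT, 1, c(u16(1), u16(0))),
    entry(262, TYPE_SHORT, 1, c(u16(1), u16(0))),
    entry(273, TYPE_LONG, 1, u32(off_pix)),
    entry(277, TYPE_SHORT, 1, c(u16(1), u16(0))),
    entry(278, TYPE_LONG, 1, u32(sp$nrows)),
    entry(279, TYPE_LONG, 1, u32(length(pix))),
    entry(339, TYPE_SHORT, 1, c(u16(3), u16(0))),
    entry(33550, TYPE_DOUBLE, 3, u32(off_scale)),
    entry(33922, TYPE_DOUBLE, 6, u32(off_tie)),
    entry(42113, TYPE_ASCII, length(nodata_str), u32(off_nodata))
  )
  ifd <- c(u16(length(entries)), do.call(c, entries), u32(0))
  header <- c(charToRaw("II"), u16(42), u32(off_ifd))
  writeBin(c(header, pix, f64(scale), f64(tiepoint), nodata_str, ifd),
           path)
  invisible(path)
}

read_geotiff <- function(path, kind = "continuous") {
  raw_all <- readBin(path, "raw", file.info(path)$size)
  rd_u16 <- function(off) readBin(raw_all[(off + 1):(off + 2)], "integer",
                                  size = 2, signed = FALSE, endian = "little")
  rd_u32 <- function(off) readBin(raw_all[(off + 1):(off + 4)], "integer",
                                  size = 4, endian = "little")
  rd_f64 <- function(off, n) readBin(raw_all[(off + 1):(off + 8 * n)],
                                     "numeric", n = n, size = 8,
                                     endian = "little")
  if (rawToChar(raw_all[1:2]) != "II" || rd_u16(2) != 42L)
    stop("not a little-endian TIFF")
  ifd_off <- rd_u32(4)
  n_entries <- rd_u16(ifd_off)
  tags <- list()
  for (k in seq_len(n_entries)) {
    e <- ifd_off + 2 + (k - 1) * 12
    tags[[as.character(rd_u16(e))]] <-
      list(type = rd_u16(e + 2), count = rd_u32(e + 4), val = rd_u32(e + 8),
           val16 = rd_u16(e + 8), off = e + 8)
  }
  need <- function(tag) {
    t <- tags[[as.character(tag)]]
    if (is.null(t)) stop("GeoTIFF missing required tag ", tag)
    t
  }
  getv <- function(tag) {
    t <- need(tag)
    if (t$type == 3) t$val16 else t$val
  }
  if (getv(259) != 1) stop("compressed TIFF not supported")
  if (getv(258) != 64 || need(339)$val16 != 3)
    stop("only float64 sample format supported")
  nc <- getv(256); nr <- getv(257)
  strip_off <- getv(273); strip_len <- getv(279)
  if (strip_len != nr * nc * 8) stop("multi-strip TIFF not supported")
  vals <- rd_f64(strip_off, nr * nc)
  m <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)
  scale <- rd_f64(need(33550)$val, 3)
  if (abs(scale[1] - scale[2]) > 1e-9) stop("non-square cells not supported")
  tie <- rd_f64(need(33922)$val, 6)
  nodata <- NA_real_
  nt <- tags[["42113"]]
  if (!is.null(nt)) {
    bytes <- raw_all[(nt$val + 1):(nt$val + nt$count)]
    bytes <- bytes[bytes != as.raw(0)]
    nodata <- as.numeric(rawToChar(bytes))
  }
  if (!is.na(nodata)) m[m == nodata] <- NA_real_
  spec <- grid_spec(nr, nc, scale[1], origin_x = tie[4], origin_y = tie[5],
                    nodata = if (is.na(nodata)) -9999 else nodata)
  raster_layer(m, spec, kind)
}
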