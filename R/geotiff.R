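# Minimal single-band GeoTIFF codec.
#
# No GeoTIFF-capable package is available to this package, and plain TIFF
# writers are limited to 32-bit samples, which cannot carry index values in
# [0, 100] at six-decimal precision. Files are written uncompressed,
# little-endian, one 64-bit IEEE float sample per pixel, single strip, with
# ModelPixelScale / ModelTiepoint / GeoKeyDirectory georeferencing and the
# GDAL nodata tag. The reader additionally accepts float32 and 8/16/32-bit
# unsigned integer samples and multi-strip layouts, but not compression,
# tiling, multiple bands, or big-endian files.

TIFF_TYPE_SIZE <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `11` = 4L, `12` = 8L)

u16le <- function(x) as.raw(rbind(x %% 256L, (x %/% 256L) %% 256L))
u32le <- function(x) {
  x <- as.numeric(x)
  as.raw(rbind(x %% 256, (x %/% 256) %% 256, (x %/% 65536) %% 256,
               (x %/% 16777216) %% 256))
}
f64le <- function(x) writeBin(as.double(x), raw(), size = 8L, endian = "little")

# One 12-byte IFD entry. 'value' is either an inline value or an offset.
tiff_entry <- function(tag, type, count, value, inline_type = NULL) {
  out <- c(u16le(tag), u16le(type), u32le(count))
  if (!is.null(inline_type)) {
    if (inline_type == "short") {
      out <- c(out, u16le(value), u16le(0L))
    } else {
      out <- c(out, u32le(value))
    }
  } else {
    out <- c(out, u32le(value))
  }
  out
}

epsg_code <- function(crs_id) {
  if (grepl("^EPSG:[0-9]+$", crs_id)) return(as.integer(sub("^EPSG:", "", crs_id)))
  if (crs_id %in% c("GCS_WGS_1984", "WGS84", "WGS 84")) return(4326L)
  32767L  # user-defined; the citation string carries the identifier
}

#' Write one single-band GeoTIFF
#'
#' Low-level writer used by [write_cube()]. Values are stored as 64-bit
#' floats, uncompressed, little-endian, with the grid's georeferencing and
#' the nodata code in the standard tags.
#'
#' @param path Output file path.
#' @param values Numeric matrix (`n_rows` x `n_cols`), row 1 = north. Cells
#'   to be treated as missing must already hold `nodata`.
#' @param grid A [grid_spec()]; `pixel_size_y` must be negative (north-up).
#' @param nodata Nodata code recorded in the file. Default -9999.
#' @return `path`, invisibly.
#' @export
write_geotiff <- function(path, values, grid, nodata = -9999) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols)
    stop("matrix dimensions do not match the grid")
  if (grid$pixel_size_y >= 0)
    stop("GeoTIFF export requires a north-up grid (pixel_size_y < 0)")
  nr <- grid$n_rows; nc <- grid$n_cols

  data <- f64le(as.vector(t(values)))           # row-major pixel order
  data_len <- length(data)

  scale_raw <- f64le(c(grid$pixel_size_x, abs(grid$pixel_size_y), 0))
  tie_raw <- f64le(c(0, 0, 0, grid$origin_x, grid$origin_y, 0))
  citation <- paste0(grid$crs_id, "|")
  ascii_raw <- c(charToRaw(citation), as.raw(0L))
  if (length(ascii_raw) %% 2L) ascii_raw <- c(ascii_raw, as.raw(0L))
  geokeys <- c(1L, 1L, 0L, 4L,
               1024L, 0L, 1L, 2L,          # model type: geographic
               1025L, 0L, 1L, 1L,          # raster type: pixel-is-area
               1026L, 34737L, nchar(citation), 0L,
               2048L, 0L, 1L, epsg_code(grid$crs_id))
  geokey_raw <- u16le(geokeys)
  nodata_str <- sprintf("%g", nodata)
  nodata_raw <- c(charToRaw(nodata_str), as.raw(0L))
  if (length(nodata_raw) %% 2L) nodata_raw <- c(nodata_raw, as.raw(0L))

  ifd_off <- 8 + data_len
  n_entries <- 16L
  ifd_len <- 2L + n_entries * 12L + 4L
  scale_off <- ifd_off + ifd_len
  tie_off <- scale_off + length(scale_raw)
  geokey_off <- tie_off + length(tie_raw)
  ascii_off <- geokey_off + length(geokey_raw)
  nodata_off <- ascii_off + length(ascii_raw)

  entries <- c(
    tiff_entry(256L, 4L, 1L, nc),                 # ImageWidth
    tiff_entry(257L, 4L, 1L, nr),                 # ImageLength
    tiff_entry(258L, 3L, 1L, 64L, "short"),       # BitsPerSample
    tiff_entry(259L, 3L, 1L, 1L, "short"),        # Compression: none
    tiff_entry(262L, 3L, 1L, 1L, "short"),        # Photometric: min-is-black
    tiff_entry(273L, 4L, 1L, 8L),                 # StripOffsets
    tiff_entry(277L, 3L, 1L, 1L, "short"),        # SamplesPerPixel
    tiff_entry(278L, 4L, 1L, nr),                 # RowsPerStrip
    tiff_entry(279L, 4L, 1L, data_len),           # StripByteCounts
    tiff_entry(284L, 3L, 1L, 1L, "short"),        # PlanarConfiguration
    tiff_entry(339L, 3L, 1L, 3L, "short"),        # SampleFormat: IEEE float
    tiff_entry(33550L, 12L, 3L, scale_off),       # ModelPixelScale
    tiff_entry(33922L, 12L, 6L, tie_off),         # ModelTiepoint
    tiff_entry(34735L, 3L, length(geokeys), geokey_off),
    tiff_entry(34737L, 2L, length(ascii_raw), ascii_off),
    tiff_entry(42113L, 2L, length(nodata_raw), nodata_off)
  )
  buf <- c(charToRaw("II"), u16le(42L), u32le(ifd_off),
           data,
           u16le(n_entries), entries, u32le(0L),
           scale_raw, tie_raw, geokey_raw, ascii_raw, nodata_raw)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(buf, con)
  invisible(path)
}

rd_u16 <- function(buf, pos, n = 1L)
  readBin(buf[pos:(pos + 2L * n - 1L)], "integer", n = n, size = 2L,
          signed = FALSE, endian = "little")
rd_u32 <- function(buf, pos, n = 1L) {
  v <- readBin(buf[pos:(pos + 4L * n - 1L)], "integer", n = n, size = 4L,
               endian = "little")
  v <- as.numeric(v)
  ifelse(v < 0, v + 4294967296, v)
}

# Raw bytes of one tag's value, following the inline/offset rule.
tag_bytes <- function(buf, entry) {
  size <- TIFF_TYPE_SIZE[as.character(entry$type)]
  if (is.na(size)) stop("unsupported TIFF data type ", entry$type)
  nbytes <- size * entry$count
  if (nbytes <= 4L) {
    entry$value_raw[seq_len(nbytes)]
  } else {
    off <- rd_u32(entry$value_raw, 1L)
    buf[(off + 1):(off + nbytes)]
  }
}

tag_numeric <- function(buf, entry) {
  b <- tag_bytes(buf, entry)
  switch(as.character(entry$type),
    `1` = as.integer(b),
    `3` = rd_u16(b, 1L, entry$count),
    `4` = rd_u32(b, 1L, entry$count),
    `11` = readBin(b, "double", n = entry$count, size = 4L, endian = "little"),
    `12` = readBin(b, "double", n = entry$count, size = 8L, endian = "little"),
    stop("tag is not numeric"))
}

tag_string <- function(buf, entry) {
  b <- tag_bytes(buf, entry)
  b <- b[b != as.raw(0L)]
  rawToChar(b)
}

#' Read one single-band GeoTIFF
#'
#' Low-level reader used by [read_cube()]. Accepts the subset of TIFF this
#' package writes, plus float32 and 8/16/32-bit unsigned integer samples and
#' multi-strip files. Compressed, tiled, multi-band, or big-endian files are
#' rejected.
#'
#' @param path File path.
#' @return A list with `values` (numeric matrix, row 1 = north), `grid`
#'   (a [grid_spec()]), and `nodata` (numeric, `NA` if the file declares
#'   none).
#' @export
read_geotiff <- function(path) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  buf <- readBin(path, "raw", n = file.size(path))
  if (length(buf) < 8L) stop("'", path, "' is not a TIFF file")
  if (rawToChar(buf[1:2]) == "MM")
    stop("'", path, "': big-endian TIFF is not supported")
  if (rawToChar(buf[1:2]) != "II" || rd_u16(buf, 3L) != 42L)
    stop("'", path, "' is not a TIFF file")
  ifd_off <- rd_u32(buf, 5L)
  n <- rd_u16(buf, ifd_off + 1L)
  entries <- list()
  for (i in seq_len(n)) {
    p <- ifd_off + 2L + (i - 1L) * 12L + 1L
    entries[[as.character(rd_u16(buf, p))]] <- list(
      type = rd_u16(buf, p + 2L),
      count = rd_u32(buf, p + 4L),
      value_raw = buf[(p + 8L):(p + 11L)]
    )
  }
  need <- function(tag, default = NULL) {
    e <- entries[[as.character(tag)]]
    if (is.null(e)) {
      if (is.null(default)) stop("'", path, "': missing required TIFF tag ", tag)
      return(default)
    }
    tag_numeric(buf, e)
  }
  nc <- need(256L); nr <- need(257L)
  bits <- need(258L, 1L); comp <- need(259L, 1L)
  spp <- need(277L, 1L); fmt <- need(339L, 1L)
  if (comp != 1L) stop("'", path, "': compressed TIFF is not supported")
  if (spp != 1L) stop("'", path, "': only single-band rasters are supported")
  if (!is.null(entries[["322"]])) stop("'", path, "': tiled TIFF is not supported")
  strip_off <- need(273L); strip_cnt <- need(279L)
  data <- do.call(c, lapply(seq_along(strip_off), function(i)
    buf[(strip_off[i] + 1):(strip_off[i] + strip_cnt[i])]))
  npix <- nr * nc
  vals <- if (fmt == 3L && bits == 64L) {
    readBin(data, "double", n = npix, size = 8L, endian = "little")
  } else if (fmt == 3L && bits == 32L) {
    readBin(data, "double", n = npix, size = 4L, endian = "little")
  } else if (fmt %in% c(1L, 4L) && bits %in% c(8L, 16L)) {
    as.numeric(readBin(data, "integer", n = npix, size = bits / 8L,
                       signed = FALSE, endian = "little"))
  } else if (fmt %in% c(1L, 4L) && bits == 32L) {
    as.numeric(readBin(data, "integer", n = npix, size = 4L, endian = "little"))
  } else if (fmt == 2L && bits %in% c(8L, 16L, 32L)) {
    as.numeric(readBin(data, "integer", n = npix, size = bits / 8L,
                       signed = TRUE, endian = "little"))
  } else {
    stop("'", path, "': unsupported sample format (", fmt, "/", bits, " bits)")
  }
  values <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)

  crs <- NA_character_
  if (!is.null(entries[["34737"]])) {
    s <- tag_string(buf, entries[["34737"]])
    s <- sub("\\|+$", "", s)
    if (nzchar(s)) crs <- s
  }
  if (is.na(crs) && !is.null(entries[["34735"]])) {
    keys <- tag_numeric(buf, entries[["34735"]])
    km <- matrix(keys[-(1:4)], ncol = 4L, byrow = TRUE)
    g <- km[km[, 1L] == 2048L, , drop = FALSE]
    if (nrow(g) == 1L && g[1L, 4L] != 32767L) crs <- paste0("EPSG:", g[1L, 4L])
  }
  if (is.na(crs)) crs <- "unknown"

  if (!is.null(entries[["33550"]]) && !is.null(entries[["33922"]])) {
    sc <- tag_numeric(buf, entries[["33550"]])
    tp <- tag_numeric(buf, entries[["33922"]])
    grid <- grid_spec(nr, nc,
                      origin_x = tp[4L] - tp[1L] * sc[1L],
                      origin_y = tp[5L] + tp[2L] * sc[2L],
                      pixel_size_x = sc[1L], pixel_size_y = -sc[2L],
                      crs_id = crs)
  } else {
    warning("'", path, "' carries no georeferencing tags; assuming a unit grid")
    grid <- grid_spec(nr, nc, crs_id = crs)
  }
  nodata <- NA_real_
  if (!is.null(entries[["42113"]])) {
    nd <- suppressWarnings(as.numeric(tag_string(buf, entries[["42113"]])))
    if (!is.na(nd)) nodata <- nd
  }
  list(values = values, grid = grid, nodata = nodata)
}

#' Read a gridded time series from per-step GeoTIFF files
#'
#' Builds a [raster_cube()] from one single-band GeoTIFF per time step.
#' Cells equal to `background_value` (the conventional -9999 background) or
#' to the file's own declared nodata code, or non-finite, are masked
#' invalid; they are never used by any downstream computation.
#'
#' @param paths Ordered character vector of file paths, one per time step.
#' @param time_labels Time labels matching `paths` (see [raster_cube()]).
#' @param background_value Sentinel marking missing cells. Default -9999.
#' @return A [raster_cube()].
#' @export
read_cube <- function(paths, time_labels, background_value = -9999) {
  if (length(paths) < 1L) stop("no input files")
  times <- as_time_table(time_labels)
  if (length(paths) != nrow(times))
    stop("number of files (", length(paths),
         ") does not match number of time labels (", nrow(times), ")")
  first <- read_geotiff(paths[[1L]])
  grid <- first$grid
  nt <- length(paths)
  values <- array(NA_real_, c(nt, grid$n_rows, grid$n_cols))
  valid <- array(FALSE, dim(values))
  for (i in seq_len(nt)) {
    r <- if (i == 1L) first else read_geotiff(paths[[i]])
    if (!grid_equal(r$grid, grid))
      stop("grid of '", paths[[i]], "' does not match grid of '", paths[[1L]], "'")
    v <- r$values
    ok <- is.finite(v) & v != background_value
    if (!is.na(r$nodata)) ok <- ok & v != r$nodata
    values[i, , ] <- v
    valid[i, , ] <- ok
  }
  values[!valid] <- NA_real_
  raster_cube(values, times, grid, valid)
}

#' Write a cube as one GeoTIFF per time step
#'
#' Files are named by substituting `{year}`, `{month}`, `{week}`, and
#' `{index}` in `name_pattern`; the default follows the `VHIopt_year.tif`
#' convention of annual VHI products. Values are rounded to six decimal
#' places; invalid cells are written as `nodata`. A read-back with
#' [read_cube()] reproduces values to six decimals and the valid mask
#' exactly.
#'
#' @param cube A [raster_cube()].
#' @param out_dir Output directory (created if absent).
#' @param name_pattern Filename pattern. Default `"VHIopt_{year}.tif"`.
#' @param nodata Nodata code written to invalid cells. Default -9999.
#' @return Character vector of the files written.
#' @export
write_cube <- function(cube, out_dir, name_pattern = "VHIopt_{year}.tif",
                       nodata = -9999) {
  stopifnot(inherits(cube, "raster_cube"))
  nt <- nrow(cube$times)
  if (nt < 1L) stop("empty cube")
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory '", out_dir, "'")
  names <- vapply(seq_len(nt), function(i) {
    s <- name_pattern
    s <- gsub("{year}", cube$times$year[i], s, fixed = TRUE)
    if ("month" %in% names(cube$times))
      s <- gsub("{month}", sprintf("%02d", cube$times$month[i]), s, fixed = TRUE)
    if ("week" %in% names(cube$times))
      s <- gsub("{week}", sprintf("%02d", cube$times$week[i]), s, fixed = TRUE)
    gsub("{index}", i, s, fixed = TRUE)
  }, "")
  if (anyDuplicated(names))
    stop("name pattern '", name_pattern, "' produces duplicate file names; ",
         "include {month}, {week}, or {index}")
  paths <- file.path(out_dir, names)
  for (i in seq_len(nt)) {
    m <- round(cube$values[i, , ], 6L)
    m[!cube$valid[i, , ]] <- nodata
    dim(m) <- c(cube$grid$n_rows, cube$grid$n_cols)
    write_geotiff(paths[i], m, cube$grid, nodata = nodata)
  }
  paths
}
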