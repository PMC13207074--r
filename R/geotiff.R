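# Minimal GeoTIFF codec: uncompressed baseline TIFF with the GeoTIFF
# georeferencing tags (ModelPixelScale, ModelTiepoint, GeoKeyDirectory),
# GDAL_NODATA and an optional JSON ImageDescription.  Supports the sample
# layouts this package writes (float32 / int32 / uint8, pixel-interleaved)
# plus the common integer widths on read.  Little-endian on write; both
# byte orders on read.

.tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `5` = 8L,
                     `6` = 1L, `7` = 1L, `8` = 2L, `9` = 4L, `10` = 8L,
                     `11` = 4L, `12` = 8L)

#' Write a raster to a GeoTIFF file
#'
#' Writes a single- or multi-band raster as an uncompressed, little-endian,
#' pixel-interleaved GeoTIFF with geographic (WGS84) georeferencing taken
#' from `grid`.  `NA` cells are stored as the nodata value (IEEE NaN for
#' `float32` by default) and recorded in the `GDAL_NODATA` tag.
#'
#' @param x Matrix (`n_rows x n_cols`) or 3-D array
#'   (`n_rows x n_cols x n_bands`); rows north to south.
#' @param grid [geo_grid()] describing the raster's placement.
#' @param path Output file path.
#' @param type Sample type: `"float32"`, `"int32"` or `"uint8"`.
#' @param nodata Nodata value; defaults to NaN for `float32`, -9999 for
#'   `int32`, 255 for `uint8`.
#' @param description Optional list of metadata, stored as JSON in the
#'   TIFF ImageDescription tag (e.g. acquisition date, scale factor).
#' @return `path`, invisibly.
#' @seealso [read_geotiff()]
#' @export
write_geotiff <- function(x, grid, path, type = c("float32", "int32", "uint8"),
                          nodata = NULL, description = NULL) {
  type <- match.arg(type)
  stopifnot(inherits(grid, "geo_grid"))
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (length(dim(x)) != 3L) stop("x must be a matrix or 3-D array")
  check_raster_dims(x, grid, "x")
  nb <- dim(x)[3L]

  if (is.null(nodata))
    nodata <- switch(type, float32 = NaN, int32 = -9999, uint8 = 255)
  vals <- as.vector(aperm(x, c(3L, 2L, 1L)))  # band-fastest, then col, row
  if (type == "float32") {
    vals[is.na(vals)] <- NaN
  } else {
    vals[is.na(vals)] <- nodata
    vals <- as.integer(round(vals))
    if (type == "uint8" && (any(vals < 0L) || any(vals > 255L)))
      stop("uint8 values must lie in [0, 255]")
  }

  bps <- if (type == "uint8") 8L else 32L
  fmt <- switch(type, float32 = 3L, int32 = 2L, uint8 = 1L)
  strip_bytes <- grid$n_rows * grid$n_cols * nb * (bps %/% 8L)

  desc <- NULL
  if (!is.null(description))
    desc <- as.character(jsonlite::toJSON(description, auto_unbox = TRUE,
                                          digits = NA))
  nodata_str <- if (is.nan(nodata)) "nan" else
    format(nodata, scientific = FALSE, trim = TRUE)
  geokeys <- as.integer(c(1, 1, 0, 3,        # version, revision, n keys
                          1024, 0, 1, 2,     # model type: geographic
                          1025, 0, 1, 1,     # raster type: pixel is area
                          2048, 0, 1, 4326)) # geographic CRS: WGS84

  # entries: list(tag, type, values); ASCII passed as a string
  ent <- list(
    list(256L, 4L, grid$n_cols),
    list(257L, 4L, grid$n_rows),
    list(258L, 3L, rep(bps, nb)),
    list(259L, 3L, 1L),
    list(262L, 3L, 1L))
  if (!is.null(desc)) ent <- c(ent, list(list(270L, 2L, desc)))
  ent <- c(ent, list(
    list(273L, 4L, NA),  # strip offset patched below
    list(277L, 3L, nb),
    list(278L, 4L, grid$n_rows),
    list(279L, 4L, strip_bytes),
    list(284L, 3L, 1L),
    list(339L, 3L, rep(fmt, nb)),
    list(33550L, 12L, c(grid$cell_size_deg, grid$cell_size_deg, 0)),
    list(33922L, 12L, c(0, 0, 0, grid$origin_lon, grid$origin_lat, 0)),
    list(34735L, 3L, geokeys),
    list(42113L, 2L, nodata_str)))

  payload_bytes <- function(e) {
    if (e[[2L]] == 2L) nchar(e[[3L]], type = "bytes") + 1L
    else length(e[[3L]]) * .tiff_type_size[[as.character(e[[2L]])]]
  }
  n_ent <- length(ent)
  ifd_off <- 8L
  overflow_off <- ifd_off + 2L + 12L * n_ent + 4L
  off <- overflow_off
  for (i in seq_along(ent)) {
    nb_i <- payload_bytes(ent[[i]])
    ent[[i]]$off <- if (nb_i > 4L) off else NA_integer_
    if (nb_i > 4L) off <- off + nb_i + (nb_i %% 2L)
  }
  strip_off <- off
  ent[[which(vapply(ent, function(e) e[[1L]], 0L) == 273L)]][[3L]] <- strip_off

  con <- file(path, "wb")
  on.exit(close(con))
  wb <- function(v, size) writeBin(v, con, size = size, endian = "little")
  wb(charToRaw("II"), 1L); wb(42L, 2L); wb(ifd_off, 4L)
  wb(n_ent, 2L)
  for (e in ent) {
    wb(e[[1L]], 2L); wb(e[[2L]], 2L)
    cnt <- if (e[[2L]] == 2L) nchar(e[[3L]], type = "bytes") + 1L
           else length(e[[3L]])
    wb(as.integer(cnt), 4L)
    if (!is.na(e$off)) {
      wb(as.integer(e$off), 4L)
    } else {  # inline, left-justified in the 4-byte slot
      sz <- .tiff_type_size[[as.character(e[[2L]])]]
      if (e[[2L]] == 3L) {
        v <- as.integer(e[[3L]])
        wb(v, 2L)
        wb(raw(4L - 2L * length(v)), 1L)
      } else if (e[[2L]] == 4L) {
        wb(as.integer(e[[3L]]), 4L)
      } else if (e[[2L]] == 2L) {
        r <- c(charToRaw(e[[3L]]), as.raw(0L))
        wb(c(r, raw(4L - length(r))), 1L)
      } else stop("unhandled inline type")
    }
  }
  wb(0L, 4L)  # no next IFD
  for (e in ent) {
    if (is.na(e$off)) next
    if (e[[2L]] == 2L) {
      r <- c(charToRaw(e[[3L]]), as.raw(0L))
    } else if (e[[2L]] == 3L) {
      r <- writeBin(as.integer(e[[3L]]), raw(), size = 2L, endian = "little")
    } else if (e[[2L]] == 12L) {
      r <- writeBin(as.numeric(e[[3L]]), raw(), size = 8L, endian = "little")
    } else {
      r <- writeBin(as.integer(e[[3L]]), raw(), size = 4L, endian = "little")
    }
    if (length(r) %% 2L) r <- c(r, raw(1L))
    writeBin(r, con)
  }
  if (type == "float32") wb(as.numeric(vals), 4L)
  else if (type == "int32") wb(as.integer(vals), 4L)
  else wb(as.integer(vals), 1L)
  invisible(path)
}

#' Read a GeoTIFF file
#'
#' Reads an uncompressed strip-based GeoTIFF (either byte order; 8/16/32-bit
#' integer or 32-bit float samples, pixel-interleaved), returning the raster
#' with nodata cells as `NA` and the georeferencing parsed into a
#' [geo_grid()].  Cells must be square in degrees.
#'
#' @param path File path.
#' @return A list with `values` (3-D array `n_rows x n_cols x n_bands`),
#'   `grid` ([geo_grid()]), `n_bands`, `nodata` (as stored, or `NULL`) and
#'   `description` (parsed JSON list, raw string, or `NULL`).
#' @seealso [write_geotiff()]
#' @export
read_geotiff <- function(path) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file: ", path)
  endian <- if (rawToChar(raw[1:2]) == "II") "little"
            else if (rawToChar(raw[1:2]) == "MM") "big"
            else stop("not a TIFF file: ", path)
  rd <- function(off, what, n, size, signed = TRUE)
    readBin(raw[(off + 1L):length(raw)], what, n = n, size = size,
            signed = signed, endian = endian)
  if (rd(2L, "integer", 1L, 2L) != 42L) stop("not a baseline TIFF: ", path)
  ifd <- rd(4L, "integer", 1L, 4L)
  n_ent <- rd(ifd, "integer", 1L, 2L)

  tags <- list()
  for (i in seq_len(n_ent)) {
    eo <- ifd + 2L + (i - 1L) * 12L
    tag <- rd(eo, "integer", 1L, 2L, signed = FALSE)
    typ <- rd(eo + 2L, "integer", 1L, 2L, signed = FALSE)
    cnt <- rd(eo + 4L, "integer", 1L, 4L)
    sz <- .tiff_type_size[[as.character(typ)]]
    if (is.null(sz)) next
    voff <- if (sz * cnt > 4L) rd(eo + 8L, "integer", 1L, 4L) else eo + 8L
    val <- switch(as.character(typ),
      `1` = rd(voff, "integer", cnt, 1L, signed = FALSE),
      `2` = {
        chars <- rd(voff, "raw", cnt, 1L)
        rawToChar(chars[chars != as.raw(0L)])
      },
      `3` = rd(voff, "integer", cnt, 2L, signed = FALSE),
      `4` = rd(voff, "integer", cnt, 4L),
      `11` = rd(voff, "numeric", cnt, 4L),
      `12` = rd(voff, "numeric", cnt, 8L),
      NULL)
    if (!is.null(val)) tags[[as.character(tag)]] <- val
  }
  need <- function(tag) {
    v <- tags[[as.character(tag)]]
    if (is.null(v)) stop("required TIFF tag ", tag, " missing in ", path)
    v
  }
  w <- need(256L); h <- need(257L)
  comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]]
  if (comp != 1L) stop("only uncompressed TIFFs are supported (tag 259 = ",
                       comp, ")")
  nb <- if (is.null(tags[["277"]])) 1L else tags[["277"]]
  bps <- need(258L)[1L]
  fmt <- if (is.null(tags[["339"]])) 1L else tags[["339"]][1L]
  planar <- if (is.null(tags[["284"]])) 1L else tags[["284"]]
  if (planar != 1L) stop("only pixel-interleaved (chunky) TIFFs supported")
  offs <- need(273L); cnts <- need(279L)

  data <- unlist(lapply(seq_along(offs), function(i)
    rd(offs[i], "raw", cnts[i], 1L)), use.names = FALSE)
  npix <- as.numeric(w) * h * nb
  vals <- if (fmt == 3L) {
    if (bps != 32L) stop("only 32-bit float samples supported")
    readBin(data, "numeric", n = npix, size = 4L, endian = endian)
  } else if (bps == 8L) {
    readBin(data, "integer", n = npix, size = 1L, signed = (fmt == 2L),
            endian = endian)
  } else if (bps == 16L) {
    readBin(data, "integer", n = npix, size = 2L, signed = (fmt == 2L),
            endian = endian)
  } else if (bps == 32L) {
    readBin(data, "integer", n = npix, size = 4L, endian = endian)
  } else stop("unsupported sample layout: ", bps, "-bit, format ", fmt)
  arr <- aperm(array(as.numeric(vals), dim = c(nb, w, h)), c(3L, 2L, 1L))

  nodata <- NULL
  if (!is.null(tags[["42113"]])) {
    ns <- trimws(tags[["42113"]])
    nodata <- if (tolower(ns) == "nan") NaN else as.numeric(ns)
    arr[if (is.nan(nodata)) is.nan(arr) else arr == nodata] <- NA
  } else if (fmt == 3L) {
    arr[is.nan(arr)] <- NA
  }

  scale <- tags[["33550"]]; tie <- tags[["33922"]]
  if (is.null(scale) || is.null(tie))
    stop("file lacks GeoTIFF georeferencing tags: ", path)
  if (abs(scale[1L] - scale[2L]) > 1e-9 * max(scale[1:2]))
    stop(sprintf("non-square cells (%g x %g deg) are not supported",
                 scale[1L], scale[2L]))
  origin_lon <- tie[4L] - tie[1L] * scale[1L]
  origin_lat <- tie[5L] + tie[2L] * scale[2L]
  grid <- geo_grid(h, w, scale[1L], origin_lon, origin_lat)

  desc <- tags[["270"]]
  if (!is.null(desc) && startsWith(trimws(desc), "{"))
    desc <- tryCatch(jsonlite::fromJSON(desc), error = function(e) desc)

  list(values = arr, grid = grid, n_bands = nb, nodata = nodata,
       description = desc)
}
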