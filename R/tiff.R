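# Minimal baseline TIFF 6.0 reader/writer.
#
# No TIFF-capable R package is available in the target environment, so the
# package carries its own reader/writer for the subset of TIFF this pipeline
# needs: uncompressed, chunky (PlanarConfiguration 1), 8- or 16-bit unsigned
# grayscale (plus 8-bit RGB for QC overlays), multi-page, either byte order,
# one or more strips per page. Anything else is rejected loudly; conversion
# from vendor formats is upstream of this tool.

.tiff_type_size <- c(1L, 1L, 2L, 4L, 8L, 1L, 1L, 2L, 4L, 8L, 4L, 8L)

#' Read a multi-page TIFF file
#'
#' Decodes an uncompressed grayscale (or RGB) TIFF into a list of integer
#' matrices, one per page, along with the metadata needed downstream:
#' bit depth, physical pixel size (from the resolution tags, when present)
#' and the ImageDescription string.
#'
#' @param path Path to a TIFF file.
#' @return A list with elements `pages` (list of integer matrices, row =
#'   image y, col = image x; RGB pages are H x W x 3 arrays),
#'   `bits_per_sample`, `pixel_size_um` (numeric or `NA`), `description`
#'   (character or `NA`).
#' @export
read_tiff <- function(path) {
  if (!file.exists(path)) stop("cannot read TIFF: file not found: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 8L) stop("not a TIFF file (truncated): ", path)
  order_tag <- rawToChar(raw[1:2])
  endian <- switch(order_tag, II = "little", MM = "big",
                   stop("not a TIFF file (bad byte-order mark): ", path))
  rd_int <- function(off, size, n = 1L, signed = FALSE) {
    readBin(raw[(off + 1L):(off + size * n)], "integer",
            n = n, size = size, endian = endian,
            signed = signed || size == 4L)
  }
  if (rd_int(2L, 2L) != 42L) stop("not a classic TIFF file: ", path)

  read_values <- function(tag_type, count, entry_off) {
    size <- .tiff_type_size[tag_type]
    nbytes <- size * count
    off <- if (nbytes <= 4L) entry_off + 8L else rd_int(entry_off + 8L, 4L)
    if (tag_type == 2L) {            # ASCII
      bytes <- raw[(off + 1L):(off + count)]
      return(rawToChar(bytes[bytes != as.raw(0L)]))
    }
    if (tag_type == 5L)              # RATIONAL: numerator / denominator pairs
      return(rd_int(off, 4L, 2L * count))
    rd_int(off, size, count)
  }

  pages <- list()
  bits <- NA_integer_
  px_um <- NA_real_
  descr <- NA_character_
  ifd_off <- rd_int(4L, 4L)
  while (ifd_off != 0L) {
    n_entries <- rd_int(ifd_off, 2L)
    tags <- list()
    for (k in seq_len(n_entries)) {
      eoff <- ifd_off + 2L + 12L * (k - 1L)
      tag <- rd_int(eoff, 2L)
      type <- rd_int(eoff + 2L, 2L)
      count <- rd_int(eoff + 4L, 4L)
      if (type >= 1L && type <= 12L)
        tags[[as.character(tag)]] <- read_values(type, count, eoff)
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    w <- g(256); h <- g(257)
    if (is.null(w) || is.null(h)) stop("TIFF page missing dimensions: ", path)
    comp <- g(259, 1L)
    if (comp != 1L)
      stop("unsupported TIFF compression (", comp, "); only uncompressed ",
           "TIFF is readable: ", path)
    spp <- g(277, 1L)
    bps <- g(258, 1L)[1]
    if (!bps %in% c(8L, 16L))
      stop("unsupported TIFF bit depth: ", bps)
    if (g(284, 1L) != 1L) stop("unsupported TIFF planar configuration")
    sf <- g(339, 1L)[1]
    if (sf != 1L) stop("unsupported TIFF sample format (expected unsigned)")
    bits <- bps
    if (!is.na(d <- g(270, NA_character_)[1])) descr <- d
    xres <- g(282)
    runit <- g(296, 2L)
    if (!is.null(xres) && xres[2] > 0L && xres[1] > 0L) {
      per_unit <- xres[1] / xres[2]
      um_per_unit <- switch(as.character(runit), "2" = 25400, "3" = 10000, NA)
      if (!is.na(um_per_unit)) px_um <- um_per_unit / per_unit
    }
    offsets <- g(273); counts <- g(279)
    if (is.null(offsets) || is.null(counts))
      stop("TIFF page missing strip layout: ", path)
    data <- raw(0)
    for (s in seq_along(offsets))
      data <- c(data, raw[(offsets[s] + 1L):(offsets[s] + counts[s])])
    n_px <- as.numeric(w) * h * spp
    vals <- readBin(data, "integer", n = n_px, size = bps / 8L,
                    endian = endian, signed = FALSE)
    if (spp == 1L) {
      page <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    } else if (spp == 3L) {
      page <- array(0L, dim = c(h, w, 3L))
      for (ch in 1:3)
        page[, , ch] <- matrix(vals[seq(ch, n_px, by = 3L)],
                               nrow = h, ncol = w, byrow = TRUE)
    } else stop("unsupported TIFF samples per pixel: ", spp)
    pages[[length(pages) + 1L]] <- page
    ifd_off <- rd_int(ifd_off + 2L + 12L * n_entries, 4L)
  }
  if (length(pages) == 0L) stop("TIFF file contains no images: ", path)
  list(pages = pages, bits_per_sample = bits, pixel_size_um = px_um,
       description = descr)
}

#' Write a multi-page TIFF file
#'
#' Writes uncompressed little-endian TIFF. Grayscale pages are integer
#' matrices; RGB pages (used for QC overlays) are H x W x 3 arrays and are
#' always written 8-bit.
#'
#' @param pages A matrix/array or a list of them, one per page.
#' @param path Output path.
#' @param bits_per_sample 8 or 16 (grayscale only).
#' @param pixel_size_um Physical pixel edge length in micrometers; written
#'   as centimeter-unit resolution tags when not `NULL`/`NA`.
#' @param description Optional ImageDescription string (first page only).
#' @return `path`, invisibly.
#' @export
write_tiff <- function(pages, path, bits_per_sample = 16L,
                       pixel_size_um = NULL, description = NULL) {
  if (!is.list(pages)) pages <- list(pages)
  stopifnot(length(pages) >= 1L, bits_per_sample %in% c(8L, 16L))
  if (!is.null(pixel_size_um) && is.na(pixel_size_um)) pixel_size_um <- NULL

  u16 <- function(x) writeBin(as.integer(x), con, size = 2L, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4L, endian = "little")

  is_rgb <- vapply(pages, function(p) length(dim(p)) == 3L, logical(1))
  page_dims <- lapply(pages, dim)
  bps <- ifelse(is_rgb, 8L, as.integer(bits_per_sample))
  spp <- ifelse(is_rgb, 3L, 1L)
  data_sizes <- as.integer(vapply(seq_along(pages), function(k) {
    d <- page_dims[[k]]
    as.numeric(d[1]) * d[2] * spp[k] * (bps[k] / 8)
  }, numeric(1)))
  pad <- data_sizes %% 2L
  data_offsets <- 8L + cumsum(c(0L, (data_sizes + pad)[-length(pages)]))

  extra_off <- 8L + sum(data_sizes + pad)
  descr_bytes <- if (!is.null(description)) {
    b <- c(charToRaw(description), as.raw(0L))
    if (length(b) %% 2L == 1L) b <- c(b, as.raw(0L))
    b
  } else raw(0)
  descr_off <- extra_off
  res_off <- descr_off + length(descr_bytes)     # one shared RATIONAL
  have_res <- !is.null(pixel_size_um)
  rgb_bps_off <- res_off + (if (have_res) 8L else 0L)  # 3 SHORTs for RGB pages
  any_rgb <- any(is_rgb)
  ifd0_off <- rgb_bps_off + (if (any_rgb) 6L else 0L)

  n_tags <- function(k) {
    6L +                                    # width,length,bps,comp,photo,spp
      3L +                                  # strip offsets/bytecounts, rps
      1L +                                  # planar config
      1L +                                  # sample format
      (if (k == 1L && !is.null(description)) 1L else 0L) +
      (if (have_res) 3L else 0L)
  }
  ifd_sizes <- vapply(seq_along(pages), function(k) 2L + 12L * n_tags(k) + 4L,
                      integer(1))
  ifd_offsets <- ifd0_off + cumsum(c(0L, ifd_sizes[-length(pages)]))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con); u16(42L); u32(ifd0_off)
  for (k in seq_along(pages)) {
    p <- pages[[k]]
    maxv <- 2^bps[k] - 1
    v <- as.integer(round(pmin(pmax(p, 0), maxv)))
    d <- page_dims[[k]]
    if (is_rgb[k]) {
      arr <- array(v, dim = d)
      inter <- integer(data_sizes[k])       # interleave RGB, row-major
      for (ch in 1:3)
        inter[seq(ch, length(inter), by = 3L)] <- as.vector(t(arr[, , ch]))
      writeBin(inter, con, size = 1L, endian = "little")
    } else {
      writeBin(as.vector(t(matrix(v, d[1], d[2]))), con,
               size = bps[k] / 8L, endian = "little")
    }
    if (pad[k] == 1L) writeBin(as.raw(0L), con)
  }
  if (length(descr_bytes)) writeBin(descr_bytes, con)
  if (have_res) {
    # pixels per centimeter as RATIONAL
    u32(round(1e7 / pixel_size_um)); u32(1000L)
  }
  if (any_rgb) u16(c(8L, 8L, 8L))

  for (k in seq_along(pages)) {
    d <- page_dims[[k]]
    entry <- function(tag, type, count, value, is_offset = FALSE) {
      u16(tag); u16(type); u32(count)
      if (is_offset) { u32(value); return(invisible()) }
      if (type == 3L) { u16(value); u16(0L) } else u32(value)
    }
    u16(n_tags(k))
    entry(256L, 4L, 1L, d[2])                       # ImageWidth
    entry(257L, 4L, 1L, d[1])                       # ImageLength
    if (is_rgb[k]) entry(258L, 3L, 3L, rgb_bps_off, is_offset = TRUE)
    else entry(258L, 3L, 1L, bps[k])                # BitsPerSample
    entry(259L, 3L, 1L, 1L)                         # Compression = none
    entry(262L, 3L, 1L, if (is_rgb[k]) 2L else 1L)  # Photometric
    if (k == 1L && !is.null(description))
      entry(270L, 2L, length(descr_bytes), descr_off, is_offset = TRUE)
    entry(273L, 4L, 1L, data_offsets[k])            # StripOffsets
    entry(277L, 3L, 1L, spp[k])                     # SamplesPerPixel
    entry(278L, 4L, 1L, d[1])                       # RowsPerStrip
    entry(279L, 4L, 1L, data_sizes[k])              # StripByteCounts
    if (have_res) {
      entry(282L, 5L, 1L, res_off, is_offset = TRUE)
      entry(283L, 5L, 1L, res_off, is_offset = TRUE)
    }
    entry(284L, 3L, 1L, 1L)                         # PlanarConfiguration
    if (have_res) entry(296L, 3L, 1L, 3L)           # ResolutionUnit = cm
    entry(339L, 3L, 1L, 1L)                         # SampleFormat = uint
    u32(if (k < length(pages)) ifd_offsets[k + 1L] else 0L)
  }
  invisible(path)
}
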