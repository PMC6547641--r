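# Multichannel image container, TIFF ingest, maximum-intensity projection
# and CSV export.
#
# Coordinate convention (fixed for the whole package): arrays are indexed
# [y, x] with the origin at the top-left pixel, 1-based, and pixel centers
# at integer coordinates. All centroid and moment arithmetic uses these
# pixel-center coordinates.

.rdi_roles <- c("nucleus", "cell", "rna_localized", "rna_control")

.validate_roles <- function(channel_roles) {
  if (!is.character(channel_roles) || length(channel_roles) < 3L)
    stop("channel_roles must be a character vector of >= 3 roles")
  bad <- setdiff(channel_roles, .rdi_roles)
  if (length(bad))
    stop("unknown channel role(s): ", paste(bad, collapse = ", "))
  if (sum(channel_roles == "nucleus") != 1L)
    stop("exactly one channel must have role 'nucleus'")
  if (sum(channel_roles == "cell") != 1L)
    stop("exactly one channel must have role 'cell'")
  n_rna <- sum(startsWith(channel_roles, "rna_"))
  if (n_rna < 1L || n_rna > 2L)
    stop("one or two channels must have an RNA role ",
         "('rna_localized'/'rna_control')")
  invisible(channel_roles)
}

#' Construct a multichannel microscopy image
#'
#' The in-memory container for a (possibly z-stacked) multichannel
#' fluorescence image. One channel must carry the nuclear stain, one the
#' whole-cell stain, and one or two channels the RNA signal.
#'
#' @param pixels Numeric array of dimension `c(H, W, Z, C)` (single-plane
#'   images use `Z = 1`); non-negative integer intensities.
#' @param channel_roles Character vector of length `C`; each element one of
#'   `"nucleus"`, `"cell"`, `"rna_localized"`, `"rna_control"`.
#' @param bit_depth Detector bit depth; intensities must fit in
#'   `[0, 2^bit_depth - 1]`.
#' @param pixel_size_um Physical pixel edge in micrometers, or `NA` (areas
#'   are then reported in pixel units).
#' @param source_id Identifier carried through to result rows.
#' @return An object of class `mc_image`.
#' @export
mc_image <- function(pixels, channel_roles, bit_depth = 16L,
                     pixel_size_um = NA_real_, source_id = "image") {
  if (length(dim(pixels)) != 4L)
    stop("pixels must be a 4-D array (y, x, z, channel)")
  .validate_roles(channel_roles)
  if (dim(pixels)[4] != length(channel_roles))
    stop("channel count (", dim(pixels)[4], ") does not match the role ",
         "mapping (", length(channel_roles), " roles)")
  if (min(pixels) < 0 || max(pixels) > 2^bit_depth - 1)
    stop("intensities outside [0, 2^bit_depth - 1]")
  structure(list(pixels = pixels, channel_roles = channel_roles,
                 bit_depth = as.integer(bit_depth),
                 pixel_size_um = as.numeric(pixel_size_um),
                 source_id = source_id),
            class = "mc_image")
}

#' @export
print.mc_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<mc_image> %s: %d x %d px, %d z-plane(s), %d channel(s), %d-bit\n",
              x$source_id, d[1], d[2], d[3], d[4], x$bit_depth))
  cat("  roles:", paste(x$channel_roles, collapse = ", "), "\n")
  cat("  pixel size:",
      if (is.na(x$pixel_size_um)) "unknown (pixel units)"
      else paste0(x$pixel_size_um, " um"), "\n")
  invisible(x)
}

#' Read a multichannel TIFF image
#'
#' Reads a multi-page TIFF (plain or OME-style; uncompressed) and arranges
#' its pages into a z-stacked multichannel image. The page count must be
#' `length(channel_roles) * Z` for some integer `Z >= 1`. When the file was
#' written by [write_image()] the page layout, bit depth and pixel size are
#' recovered from the embedded description; the `page_order` argument
#' overrides the layout for third-party files.
#'
#' @param path TIFF file path.
#' @param channel_roles Role of each channel, in channel order (see
#'   [mc_image()]). Channel roles are always explicit, never guessed from
#'   channel order.
#' @param page_order `"channel_fastest"` (page = channels within each
#'   z-plane, the ImageJ hyperstack order) or `"z_fastest"`.
#' @param pixel_size_um Override for the physical pixel size; `NULL` uses
#'   file metadata. When neither is available a warning is issued and areas
#'   are reported in pixel units.
#' @param bit_depth Override for the detector bit depth; `NULL` uses file
#'   metadata, falling back to the TIFF storage depth.
#' @return An [mc_image()].
#' @export
read_image <- function(path, channel_roles,
                       page_order = c("channel_fastest", "z_fastest"),
                       pixel_size_um = NULL, bit_depth = NULL) {
  page_order <- match.arg(page_order)
  .validate_roles(channel_roles)
  tf <- read_tiff(path)
  meta <- NULL
  if (!is.na(tf$description))
    meta <- tryCatch(jsonlite::fromJSON(tf$description),
                     error = function(e) NULL)
  nC <- length(channel_roles)
  if (!is.null(meta$channels) && meta$channels != nC)
    stop("file declares ", meta$channels, " channels but the role mapping ",
         "has ", nC)
  n_pages <- length(tf$pages)
  if (n_pages %% nC != 0L)
    stop("page count (", n_pages, ") is not a multiple of the channel ",
         "count (", nC, ")")
  nz <- n_pages %/% nC
  if (!is.null(meta$page_order)) page_order <- meta$page_order
  d <- dim(tf$pages[[1]])
  pix <- array(0, dim = c(d[1], d[2], nz, nC))
  for (p in seq_len(n_pages)) {
    if (page_order == "channel_fastest") {
      ch <- (p - 1L) %% nC + 1L
      z <- (p - 1L) %/% nC + 1L
    } else {
      z <- (p - 1L) %% nz + 1L
      ch <- (p - 1L) %/% nz + 1L
    }
    if (!identical(dim(tf$pages[[p]]), d))
      stop("TIFF pages differ in extent")
    pix[, , z, ch] <- tf$pages[[p]]
  }
  bd <- if (!is.null(bit_depth)) bit_depth
        else if (!is.null(meta$bit_depth)) meta$bit_depth
        else tf$bits_per_sample
  px <- if (!is.null(pixel_size_um)) pixel_size_um
        else if (is.numeric(meta$pixel_size_um) &&
                 length(meta$pixel_size_um) == 1L) meta$pixel_size_um
        else tf$pixel_size_um
  if (is.na(px))
    warning("no pixel-size metadata in ", basename(path),
            "; areas will be reported in pixel units")
  sid <- sub("\\.[^.]*$", "", basename(path))
  mc_image(pix, channel_roles, bit_depth = bd, pixel_size_um = px,
           source_id = sid)
}

#' Write a multichannel image as TIFF
#'
#' Inverse of [read_image()]: pages are written channel-fastest with a JSON
#' description recording layout, bit depth and pixel size.
#'
#' @param img An [mc_image()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "mc_image"))
  d <- dim(img$pixels)
  pages <- vector("list", d[3] * d[4])
  for (z in seq_len(d[3]))
    for (ch in seq_len(d[4]))
      pages[[(z - 1L) * d[4] + ch]] <- img$pixels[, , z, ch]
  meta <- list(software = "rdindex", page_order = "channel_fastest",
               channels = d[4], z = d[3], channel_roles = img$channel_roles,
               bit_depth = img$bit_depth)
  if (!is.na(img$pixel_size_um)) meta$pixel_size_um <- img$pixel_size_um
  descr <- jsonlite::toJSON(meta, auto_unbox = TRUE)
  store <- if (img$bit_depth > 8L) 16L else 8L
  write_tiff(pages, path, bits_per_sample = store,
             pixel_size_um = if (is.na(img$pixel_size_um)) NULL
                             else img$pixel_size_um,
             description = as.character(descr))
}

#' Maximum-intensity z-projection
#'
#' Collapses a z-stack to one 2-D image per channel by taking, for every
#' (y, x), the maximum intensity over z. For a single-plane image this is
#' the identity. All index computation downstream operates on projections.
#'
#' @param img An [mc_image()].
#' @return An object of class `proj_image`: list with `pixels` (array
#'   `H x W x C`), plus the metadata of the source image.
#' @export
max_project <- function(img) {
  stopifnot(inherits(img, "mc_image"))
  d <- dim(img$pixels)
  out <- array(0, dim = c(d[1], d[2], d[4]))
  for (ch in seq_len(d[4])) {
    m <- img$pixels[, , 1, ch]
    for (z in seq_len(d[3])[-1]) m <- pmax(m, img$pixels[, , z, ch])
    out[, , ch] <- m
  }
  structure(list(pixels = out, channel_roles = img$channel_roles,
                 bit_depth = img$bit_depth,
                 pixel_size_um = img$pixel_size_um,
                 source_id = img$source_id),
            class = "proj_image")
}

#' Extract one channel of a projected image by role
#'
#' @param proj A `proj_image`.
#' @param role One of the channel roles present in the image.
#' @return A 2-D intensity matrix.
#' @export
channel <- function(proj, role) {
  stopifnot(inherits(proj, "proj_image"))
  i <- which(proj$channel_roles == role)
  if (length(i) != 1L)
    stop("image has ", length(i), " channels with role '", role, "'")
  proj$pixels[, , i]
}

#' Write analysis results to CSV
#'
#' One row per cell per RNA channel, RFC-4180 with a header line, numeric
#' values at full double precision (>= 6 significant digits). Row order is
#' preserved.
#'
#' @param rows A data frame of result rows (see [compute_rdi()]), or a list
#'   of such data frames to be row-bound.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path) {
  if (is.data.frame(rows)) df <- rows
  else if (length(rows) == 0L) df <- empty_results()
  else df <- do.call(rbind, rows)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "NA")
  invisible(path)
}

#' Empty results table (header schema)
#' @return A zero-row data frame with the result columns.
#' @export
empty_results <- function() {
  data.frame(source_id = character(0), cell_id = character(0),
             rna_role = character(0), area_px = integer(0),
             area_um2 = numeric(0), pdi = numeric(0), pi = numeric(0),
             di = numeric(0), mean_intensity = numeric(0),
             background_threshold = numeric(0),
             background_mode = character(0), status = character(0),
             stringsAsFactors = FALSE)
}
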