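# RNA distribution metrics.
#
# Everything here operates on a 2-D projected RNA channel, a cell mask and
# a nuclear mask. The three indexes are intensity-weighted spatial
# statistics:
#
#   PI  = |RNA centroid - cell centroid| / Rg_cell
#   DI  = mu2(RNA about RNA centroid) / mu2(uniform about cell centroid)
#   PDI = mu2(RNA about nucleus centroid) / mu2(uniform about nucleus centroid)
#
# where mu2(field about c) = sum_ij r_ij^2 I_ij / sum_ij I_ij, r_ij the
# Euclidean distance of pixel (i,j) to c, and the "uniform" reference
# assigns equal intensity to every cell-mask pixel. A diffuse RNA therefore
# has DI = PDI = 1 exactly; concentration anywhere gives DI < 1;
# perinuclear signal gives PDI < 1 and peripheral signal PDI > 1. The
# reference for both DI and PDI is computed through the same code path as
# the numerator, so the uniform anchors hold to machine precision.

.rdi_degenerate <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("rdi_degenerate_field",
                                          "rdi_error")))
}

#' Background-handled RNA intensity field
#'
#' Applies the user-chosen background handling to a raw RNA channel and
#' restricts it to the cell mask. Two modes exist because background can be
#' treated either way in practice:
#' \describe{
#'   \item{`threshold` (default)}{pixels with raw intensity `<= threshold`
#'     are zeroed; surviving pixels keep their raw value;}
#'   \item{`subtract`}{`threshold` is subtracted from every pixel and the
#'     result clipped at zero.}
#' }
#' Pixels outside the cell mask are always zero. If nothing survives the
#' field is flagged degenerate; index computations on it raise an error and
#' batch runs report a flagged row instead of numbers.
#'
#' @param raw_channel 2-D intensity matrix (projected RNA channel).
#' @param cell A cell [binary_mask()].
#' @param threshold Non-negative background level in intensity units.
#' @param mode `"threshold"` or `"subtract"`.
#' @return An object of class `intensity_field`.
#' @export
apply_background <- function(raw_channel, cell, threshold = 0,
                             mode = c("threshold", "subtract")) {
  mode <- match.arg(mode)
  stopifnot(is.matrix(raw_channel), inherits(cell, "binary_mask"),
            threshold >= 0)
  if (!identical(dim(raw_channel), dim(cell$pixels)))
    stop("RNA channel and cell mask differ in extent")
  vals <- if (mode == "threshold") {
    ifelse(raw_channel > threshold, raw_channel, 0)
  } else {
    pmax(raw_channel - threshold, 0)
  }
  vals <- vals * cell$pixels
  structure(list(values = vals, support = cell$pixels,
                 background_threshold = threshold, background_mode = mode,
                 degenerate = !any(vals > 0)),
            class = "intensity_field")
}

# wrap a plain matrix (already masked) as a field; internal
.as_field <- function(values, support = values > 0) {
  structure(list(values = values, support = support,
                 background_threshold = 0, background_mode = "threshold",
                 degenerate = !any(values > 0)),
            class = "intensity_field")
}

# equal intensity on every cell-mask pixel: the hypothetical uniform
# distribution used as the DI / PDI reference
.uniform_field <- function(cell) .as_field(cell$pixels * 1.0, cell$pixels)

.check_field <- function(field) {
  stopifnot(inherits(field, "intensity_field"))
  if (field$degenerate || sum(field$values) <= 0)
    .rdi_degenerate("degenerate intensity field: total intensity is zero ",
                    "(background threshold at or above the maximum in-cell ",
                    "intensity?)")
  invisible(field)
}

#' Intensity-weighted RNA centroid
#'
#' @param field An [apply_background()] result.
#' @return Named numeric `c(x =, y =)` in pixel-center coordinates.
#' @export
rna_centroid <- function(field) {
  .check_field(field)
  I <- field$values
  w <- sum(I)
  c(x = sum(col(I) * I) / w, y = sum(row(I) * I) / w)
}

#' Intensity-weighted second moment about a point
#'
#' `mu2 = sum_ij r_ij^2 I_ij / sum_ij I_ij`, with `r_ij` the Euclidean
#' distance of pixel (i, j) to `center`.
#'
#' @param field An intensity field.
#' @param center Numeric `c(x, y)`.
#' @return Non-negative scalar (square pixels).
#' @export
second_moment <- function(field, center) {
  .check_field(field)
  I <- field$values
  r2 <- (col(I) - center[[1]])^2 + (row(I) - center[[2]])^2
  sum(r2 * I) / sum(I)
}

#' Cell geometry summary
#'
#' Unweighted centroids of the cell and nucleus masks, the cell's radius of
#' gyration (root-mean-square distance of all cell-mask pixels to the cell
#' centroid) and its area.
#'
#' @param cell Cell [binary_mask()].
#' @param nucleus Nucleus [binary_mask()] (may be `NULL` if only cell
#'   geometry is needed).
#' @param pixel_size_um Micrometers per pixel edge, or `NA`.
#' @return An object of class `cell_geometry`: list with `cell_centroid`,
#'   `nucleus_centroid`, `radius_of_gyration`, `area_px`, `area_um2`.
#' @export
cell_geometry <- function(cell, nucleus = NULL, pixel_size_um = NA_real_) {
  stopifnot(inherits(cell, "binary_mask"))
  if (!any(cell$pixels)) stop("empty cell mask")
  xs <- col(cell$pixels)[cell$pixels]
  ys <- row(cell$pixels)[cell$pixels]
  cc <- c(x = mean(xs), y = mean(ys))
  rg <- sqrt(mean((xs - cc[["x"]])^2 + (ys - cc[["y"]])^2))
  nc_ <- NULL
  if (!is.null(nucleus)) {
    stopifnot(inherits(nucleus, "binary_mask"))
    if (!any(nucleus$pixels)) stop("empty nucleus mask")
    nxs <- col(nucleus$pixels)[nucleus$pixels]
    nys <- row(nucleus$pixels)[nucleus$pixels]
    nc_ <- c(x = mean(nxs), y = mean(nys))
  }
  structure(list(cell_centroid = cc, nucleus_centroid = nc_,
                 radius_of_gyration = rg, area_px = length(xs),
                 area_um2 = if (is.na(pixel_size_um)) NA_real_
                            else length(xs) * pixel_size_um^2),
            class = "cell_geometry")
}

#' Polarization index
#'
#' Displacement of the RNA centroid from the cell centroid, normalized by
#' the cell's radius of gyration. Zero for any distribution whose centroid
#' coincides with the cell centroid; grows with polarization and with the
#' distance of the RNA mass from the cell centroid.
#'
#' @param field An intensity field.
#' @param geom A [cell_geometry()].
#' @return Non-negative scalar.
#' @export
polarization_index <- function(field, geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  rc <- rna_centroid(field)
  sqrt((rc[["x"]] - geom$cell_centroid[["x"]])^2 +
         (rc[["y"]] - geom$cell_centroid[["y"]])^2) / geom$radius_of_gyration
}

#' Dispersion index
#'
#' Second moment of the RNA about its own centroid, divided by the second
#' moment of the hypothetical uniform distribution over the cell mask about
#' the cell-mask centroid. 1 for diffuse RNA, < 1 for RNA concentrated
#' anywhere in the cell, > 1 for peripherally distributed RNA (the latter
#' is affected by polarization; see [peripheral_distribution_index()]).
#'
#' @param field An intensity field.
#' @param cell Cell [binary_mask()].
#' @return Positive scalar.
#' @export
dispersion_index <- function(field, cell) {
  num <- second_moment(field, rna_centroid(field))
  ref <- .uniform_field(cell)
  den <- second_moment(ref, rna_centroid(ref))
  num / den
}

#' Peripheral distribution index
#'
#' Same construction as the dispersion index, but both the RNA moment and
#' the uniform reference moment are taken about the nucleus centroid. This
#' makes the index sensitive to the distance of the RNA from the nucleus
#' but invariant to polarization: relocating RNA mass at fixed distance
#' from the nucleus centroid does not change it. 1 for diffuse RNA
#' (exactly, wherever the nucleus sits), < 1 for perinuclear, > 1 for
#' peripheral RNA.
#'
#' @param field An intensity field.
#' @param cell Cell [binary_mask()].
#' @param geom A [cell_geometry()] carrying the nucleus centroid.
#' @return Positive scalar.
#' @export
peripheral_distribution_index <- function(field, cell, geom) {
  stopifnot(inherits(geom, "cell_geometry"))
  if (is.null(geom$nucleus_centroid))
    stop("PDI requires a nucleus centroid; supply a nucleus mask to ",
         "cell_geometry()")
  nc_ <- geom$nucleus_centroid
  num <- second_moment(field, nc_)
  den <- second_moment(.uniform_field(cell), nc_)
  num / den
}

#' Mean RNA intensity over the cell
#'
#' Total raw RNA signal inside the cell mask divided by the cell area in
#' pixels — the average RNA signal across the cell. Computed on the raw,
#' un-thresholded channel.
#'
#' @param raw_channel 2-D intensity matrix.
#' @param cell Cell [binary_mask()].
#' @return Non-negative scalar.
#' @export
mean_rna_intensity <- function(raw_channel, cell) {
  stopifnot(is.matrix(raw_channel), inherits(cell, "binary_mask"))
  n <- sum(cell$pixels)
  if (n == 0L) stop("empty cell mask")
  sum(raw_channel * cell$pixels) / n
}

#' Compute all RNA distribution metrics for one cell
#'
#' Runs background handling and the three indexes for every RNA channel of
#' a projected image, given the cell and nucleus masks. Degenerate fields
#' (nothing above background) produce a flagged row with `NA` indexes
#' rather than an error, so batch runs never abort on one empty cell.
#'
#' @param proj A `proj_image` (see [max_project()]).
#' @param cell Cell [binary_mask()].
#' @param nucleus Nucleus [binary_mask()].
#' @param background_thresholds Named numeric: background level per RNA
#'   role (unnamed scalar = same for all RNA channels).
#' @param background_mode `"threshold"` or `"subtract"` (see
#'   [apply_background()]).
#' @param cell_id Identifier for the analysed cell.
#' @return Data frame, one row per RNA channel, columns as in
#'   [empty_results()].
#' @export
compute_rdi <- function(proj, cell, nucleus, background_thresholds = 0,
                        background_mode = c("threshold", "subtract"),
                        cell_id = "cell1") {
  stopifnot(inherits(proj, "proj_image"))
  background_mode <- match.arg(background_mode)
  geom <- cell_geometry(cell, nucleus, proj$pixel_size_um)
  rna_roles <- proj$channel_roles[startsWith(proj$channel_roles, "rna_")]
  rows <- lapply(rna_roles, function(role) {
    raw <- channel(proj, role)
    thr <- if (!is.null(names(background_thresholds)) &&
               role %in% names(background_thresholds))
      background_thresholds[[role]]
    else unname(background_thresholds[1])
    field <- apply_background(raw, cell, thr, background_mode)
    mi <- mean_rna_intensity(raw, cell)
    res <- tryCatch(list(
      pdi = peripheral_distribution_index(field, cell, geom),
      pi = polarization_index(field, geom),
      di = dispersion_index(field, cell),
      status = "ok"
    ), rdi_degenerate_field = function(e)
      list(pdi = NA_real_, pi = NA_real_, di = NA_real_,
           status = "degenerate_field"))
    data.frame(source_id = proj$source_id, cell_id = cell_id,
               rna_role = role, area_px = geom$area_px,
               area_um2 = geom$area_um2, pdi = res$pdi, pi = res$pi,
               di = res$di, mean_intensity = mi,
               background_threshold = thr, background_mode = background_mode,
               status = res$status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Background threshold sweep
#'
#' Recomputes the indexes over a grid of background thresholds for one RNA
#' channel — the response curve used to choose an appropriate background
#' level: with too little noise removal the indexes are dominated by the
#' (roughly uniform) background and PDI sits near 1; raising the threshold
#' moves PDI towards the value reflecting the real signal, where the curve
#' plateaus.
#'
#' @param raw_channel 2-D intensity matrix (projected RNA channel).
#' @param cell,nucleus Cell and nucleus [binary_mask()]s.
#' @param thresholds Numeric vector of background levels to evaluate.
#' @param mode Background mode, as in [apply_background()].
#' @return Data frame with columns `threshold`, `pdi`, `pi`, `di`,
#'   `n_pixels` (pixels surviving background handling). Degenerate
#'   thresholds yield `NA` index values.
#' @export
threshold_sweep <- function(raw_channel, cell, nucleus, thresholds,
                            mode = c("threshold", "subtract")) {
  mode <- match.arg(mode)
  geom <- cell_geometry(cell, nucleus)
  out <- lapply(thresholds, function(thr) {
    field <- apply_background(raw_channel, cell, thr, mode)
    vals <- tryCatch(list(
      pdi = peripheral_distribution_index(field, cell, geom),
      pi = polarization_index(field, geom),
      di = dispersion_index(field, cell)
    ), rdi_degenerate_field = function(e)
      list(pdi = NA_real_, pi = NA_real_, di = NA_real_))
    data.frame(threshold = thr, pdi = vals$pdi, pi = vals$pi, di = vals$di,
               n_pixels = sum(field$values > 0))
  })
  do.call(rbind, out)
}
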