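# Cell and nucleus segmentation.
#
# Cell mask: (optional Wiener / unsharp pre-processing) -> Sobel gradient ->
# threshold -> 1-px dilation -> flood fill -> keep the largest component.
# Nuclear mask: Wiener -> Otsu -> restrict to the cell mask -> flood fill.
# Masks are editable with polygon operations (draw / limit / expand) and
# extra dilation; every edit is recorded so an analysis can be replayed
# from its configuration.

#' Segmentation parameters
#'
#' Every tunable of automatic mask generation. The defaults reproduce the
#' fully automatic path: edge-threshold multiplier 0.5, one 1-pixel
#' dilation, no pre-processing.
#'
#' @param edge_threshold_multiplier Multiplier applied to the automatic
#'   base edge threshold (default 0.5; smaller finds more edges).
#' @param dilation_iterations Number of 1-pixel dilations of the binary
#'   edge image before flood fill (default 1).
#' @param wiener_iterations Adaptive-denoise passes applied to the cell
#'   channel before edge detection (default 0).
#' @param sharpen_iterations Unsharp-mask passes applied to the cell
#'   channel before edge detection (default 0).
#' @param edge_threshold_constant Internal RMS scale of the automatic base
#'   threshold (see [auto_edge_threshold()]).
#' @param unsharp_amount,unsharp_sigma Unsharp-mask parameters.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(edge_threshold_multiplier = 0.5,
                                dilation_iterations = 1L,
                                wiener_iterations = 0L,
                                sharpen_iterations = 0L,
                                edge_threshold_constant = 4,
                                unsharp_amount = 1,
                                unsharp_sigma = 1) {
  stopifnot(edge_threshold_multiplier > 0, dilation_iterations >= 0,
            wiener_iterations >= 0, sharpen_iterations >= 0,
            edge_threshold_constant > 0)
  structure(list(edge_threshold_multiplier = edge_threshold_multiplier,
                 dilation_iterations = as.integer(dilation_iterations),
                 wiener_iterations = as.integer(wiener_iterations),
                 sharpen_iterations = as.integer(sharpen_iterations),
                 edge_threshold_constant = edge_threshold_constant,
                 unsharp_amount = unsharp_amount,
                 unsharp_sigma = unsharp_sigma),
            class = "segmentation_params")
}

#' Binary mask container
#'
#' @param pixels Logical matrix.
#' @param kind `"cell"` or `"nucleus"`.
#' @param provenance `"auto"` (fresh from segmentation) or `"edited"`.
#' @param edit_log List of edit records applied so far.
#' @return An object of class `binary_mask`.
#' @export
binary_mask <- function(pixels, kind = c("cell", "nucleus"),
                        provenance = c("auto", "edited"), edit_log = list()) {
  kind <- match.arg(kind)
  provenance <- match.arg(provenance)
  stopifnot(is.matrix(pixels), is.logical(pixels))
  structure(list(pixels = pixels, kind = kind, provenance = provenance,
                 edit_log = edit_log),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %s (%s): %d x %d, %d px set, %d edit(s)\n",
              x$kind, x$provenance, nrow(x$pixels), ncol(x$pixels),
              sum(x$pixels), length(x$edit_log)))
  invisible(x)
}

.segmentation_failure <- function(msg, ...) {
  stop(errorCondition(msg, ..., class = c("rdi_segmentation_failure",
                                          "rdi_error")))
}

# keep the largest 8-connected component of a logical matrix
.largest_component <- function(m) {
  lab <- cpp_label_components(m, 8L)
  sizes <- tabulate(lab[lab > 0L])
  if (length(sizes) == 0L) return(m)
  lab == which.max(sizes)
}

#' Automatic cell mask
#'
#' Segments the single cell of interest from the whole-cell stain channel:
#' optional denoise/sharpen pre-processing, Sobel edge detection,
#' thresholding at `auto_edge_threshold() * multiplier`, 1-pixel dilation
#' of the edge image to close small gaps, flood fill of the interior, and
#' retention of the connected component covering the largest area. The
#' result is a single 8-connected, hole-free component.
#'
#' @param cell_channel 2-D intensity matrix (whole-cell stain, projected).
#' @param params A [segmentation_params()].
#' @return A cell [binary_mask()] with provenance `"auto"`.
#' @export
cell_mask <- function(cell_channel, params = segmentation_params()) {
  stopifnot(is.matrix(cell_channel), inherits(params, "segmentation_params"))
  work <- cell_channel
  for (i in seq_len(params$wiener_iterations)) work <- wiener_denoise(work)
  for (i in seq_len(params$sharpen_iterations))
    work <- unsharp_mask(work, amount = params$unsharp_amount,
                         sigma = params$unsharp_sigma,
                         max_value = max(cell_channel))
  grad <- tryCatch(sobel_gradient(work), error = function(e) stop(e))
  if (all(grad == 0))
    .segmentation_failure("cell segmentation failed: image has no edges",
                          gradient = grad)
  thr <- auto_edge_threshold(grad, params$edge_threshold_constant) *
    params$edge_threshold_multiplier
  edges <- grad > thr
  if (!any(edges))
    .segmentation_failure("cell segmentation failed: no edge pixels above ",
                          "threshold", gradient = grad, threshold = thr)
  dil <- cpp_dilate3x3(edges, params$dilation_iterations)
  filled <- cpp_fill_holes(dil)
  biggest <- .largest_component(filled)
  biggest <- cpp_fill_holes(biggest)
  binary_mask(biggest, kind = "cell", provenance = "auto")
}

#' Automatic nuclear mask
#'
#' Segments the nucleus from the nuclear-stain channel: adaptive (Wiener)
#' denoising, automatic Otsu threshold, restriction to the cell mask
#' (removing any nuclei that belong to neighbouring cells), and flood fill.
#' The nuclear mask is always contained in its cell mask.
#'
#' @param nucleus_channel 2-D intensity matrix (nuclear stain, projected).
#' @param cell A cell [binary_mask()].
#' @return A nucleus [binary_mask()].
#' @export
nuclear_mask <- function(nucleus_channel, cell) {
  stopifnot(is.matrix(nucleus_channel), inherits(cell, "binary_mask"))
  if (!identical(dim(nucleus_channel), dim(cell$pixels)))
    stop("nucleus channel and cell mask differ in extent")
  den <- wiener_denoise(nucleus_channel)
  thr <- otsu_threshold(den)
  nuc <- (den > thr) & cell$pixels
  if (!any(nuc))
    .segmentation_failure("nuclear segmentation failed: no nuclear signal ",
                          "inside the cell mask", threshold = thr)
  nuc <- cpp_fill_holes(nuc) & cell$pixels
  binary_mask(nuc, kind = "nucleus", provenance = "auto")
}

# ---- polygon editing ---------------------------------------------------

# segment intersection test for the simple-polygon check
.segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c)
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
     ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
}

.polygon_is_simple <- function(v) {
  n <- nrow(v)
  if (n < 3L) return(FALSE)
  nxt <- c(seq_len(n)[-1], 1L)
  for (i in seq_len(n - 2L))
    for (j in seq(i + 2L, n)) {
      if (i == 1L && j == n) next   # closing edge is adjacent to the first
      if (.segments_intersect(v[i, ], v[nxt[i], ], v[j, ], v[nxt[j], ]))
        return(FALSE)
    }
  TRUE
}

# even-odd scanline rasterization; vertices are (x, y) in pixel-center
# coordinates (x = column, y = row, 1-based)
.rasterize_polygon <- function(vertices, nr, nc) {
  v <- as.matrix(vertices)
  out <- matrix(FALSE, nr, nc)
  n <- nrow(v)
  nxt <- c(seq_len(n)[-1], 1L)
  eps <- 1e-9
  for (y in seq_len(nr)) {
    y1 <- v[, 2]; y2 <- v[nxt, 2]
    cross <- (y1 <= y & y2 > y) | (y2 <= y & y1 > y)
    if (!any(cross)) next
    x1 <- v[cross, 1]; x2 <- v[nxt, 1][cross]
    ya <- y1[cross]; yb <- y2[cross]
    xs <- sort(x1 + (y - ya) * (x2 - x1) / (yb - ya))
    for (k in seq(1L, length(xs) - 1L, by = 2L)) {
      j1 <- ceiling(xs[k] - eps); j2 <- floor(xs[k + 1L] + eps)
      j1 <- max(1L, j1); j2 <- min(nc, j2)
      if (j1 <= j2) out[y, j1:j2] <- TRUE
    }
  }
  out
}

#' Edit a binary mask
#'
#' Programmatic counterpart of the interactive mask-editing tools. Modes:
#' \describe{
#'   \item{`draw`}{replace the mask entirely with the rasterized filled
#'     polygon;}
#'   \item{`limit`}{intersect the mask with the polygon — anything outside
#'     the polygon is excluded;}
#'   \item{`expand`}{union the mask with the polygon — additional area is
#'     included;}
#'   \item{`dilate`}{grow the mask by one pixel in all directions (no
#'     polygon required); apply repeatedly for more dilation.}
#' }
#' The edit is appended to the mask's `edit_log` and its provenance
#' becomes `"edited"`. If a cell mask is edited, any nuclear mask derived
#' from it must be recomputed afterwards.
#'
#' @param mask A [binary_mask()].
#' @param mode One of `"draw"`, `"limit"`, `"expand"`, `"dilate"`.
#' @param vertices For the polygon modes, an n x 2 matrix (or list of
#'   `c(x, y)` pairs) of vertices of a simple closed polygon, in pixel
#'   coordinates (x = column, y = row).
#' @return The edited [binary_mask()].
#' @export
edit_mask <- function(mask, mode = c("draw", "limit", "expand", "dilate"),
                      vertices = NULL) {
  stopifnot(inherits(mask, "binary_mask"))
  mode <- match.arg(mode)
  nr <- nrow(mask$pixels); nc <- ncol(mask$pixels)
  poly <- NULL
  if (mode != "dilate") {
    if (is.null(vertices)) stop("mode '", mode, "' requires polygon vertices")
    v <- if (is.list(vertices)) do.call(rbind, vertices) else as.matrix(vertices)
    if (ncol(v) != 2L || nrow(v) < 3L)
      stop("vertices must be an n x 2 (x, y) matrix with n >= 3")
    if (!.polygon_is_simple(v))
      stop("polygon is self-intersecting; supply a simple closed polygon")
    poly <- .rasterize_polygon(v, nr, nc)
  }
  new_pixels <- switch(mode,
    draw = poly,
    limit = mask$pixels & poly,
    expand = mask$pixels | poly,
    dilate = cpp_dilate3x3(mask$pixels, 1L))
  if (mode == "limit" && !any(new_pixels))
    .segmentation_failure("limit polygon excludes the entire mask")
  rec <- list(mode = mode,
              vertices = if (mode == "dilate") NULL else
                unname(as.matrix(if (is.list(vertices))
                  do.call(rbind, vertices) else vertices)))
  binary_mask(new_pixels, kind = mask$kind, provenance = "edited",
              edit_log = c(mask$edit_log, list(rec)))
}

#' Apply a list of edit records to a mask
#'
#' Replays edits (as stored in a run configuration or decision file) in the
#' order given.
#'
#' @param mask A [binary_mask()].
#' @param edits List of records, each a list with `mode` and optionally
#'   `vertices`.
#' @return The edited mask.
#' @export
apply_edits <- function(mask, edits) {
  for (e in edits)
    mask <- edit_mask(mask, mode = e$mode, vertices = e$vertices)
  mask
}
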