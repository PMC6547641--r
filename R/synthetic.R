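# Synthetic image generator.
#
# Produces fully specified 4-channel test images — a cell-shaped region
# containing a nucleus-shaped subregion, with RNA intensity laid down
# under controlled distribution classes (uniform, perinuclear, peripheral
# rim, polarized, clustered) — together with a ground-truth record holding
# the generating masks, centroids and closed-form expected index values
# where they exist. Identical spec + seed gives bit-identical images.
#
# Stated world (defaults): 512 x 512 frame, 12-bit intensities, disk cell
# of radius 150 px with a 40 px nucleus offset 30 px from the cell center,
# 0.16 um pixels (a 63x confocal objective), nuclear stain at ~75% and
# cell stain at ~40% of the dynamic range.

.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# squared distance of every pixel center to (cx, cy)
.dist2_from <- function(nr, nc, cx, cy) {
  outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+")
}

.shape_mask <- function(shape, center, nr, nc) {
  type <- shape$type
  if (type == "disk") {
    .dist2_from(nr, nc, center[1], center[2]) <= shape$radius^2
  } else if (type == "ellipse") {
    dx2 <- outer(rep(1, nr), (seq_len(nc) - center[1])^2 / shape$a^2)
    dy2 <- outer((seq_len(nr) - center[2])^2 / shape$b^2, rep(1, nc))
    dx2 + dy2 <= 1
  } else if (type == "polygon") {
    .rasterize_polygon(shape$vertices, nr, nc)
  } else stop("unknown shape type: ", type)
}

#' Specification of a synthetic test cell
#'
#' @param image_size `c(H, W)` in pixels.
#' @param cell_shape Shape list: `list(type = "disk", radius = )`,
#'   `list(type = "ellipse", a = , b = )` or
#'   `list(type = "polygon", vertices = )` (n x 2 (x, y) matrix).
#' @param cell_center `c(x, y)`; default the image center.
#' @param nucleus_shape Shape list for the nucleus.
#' @param nucleus_offset `c(dx, dy)` of the nucleus center from the cell
#'   center, in pixels.
#' @param rna_class RNA distribution class:
#'   `list(type = "uniform")`,
#'   `list(type = "perinuclear", sigma = )`,
#'   `list(type = "peripheral_rim", inner_frac = )`,
#'   `list(type = "polarized", direction = , displacement_frac = , sigma = )`,
#'   or `list(type = "clustered", n_clusters = , cluster_sigma = )`.
#' @param control_class Distribution class for the second (control) RNA
#'   channel; default `list(type = "uniform")`.
#' @param total_intensity Target summed RNA intensity per channel before
#'   quantization.
#' @param noise `list(type = "none")`,
#'   `list(type = "uniform", level = )` (i.i.d. uniform floor on
#'   `[0, level]` over the whole frame) or
#'   `list(type = "gaussian", sigma = )`.
#' @param bit_depth Detector bit depth (default 12).
#' @param pixel_size_um Pixel edge in micrometers (default 0.16).
#' @param n_z Number of z-planes; planes carry the 2-D design scaled by a
#'   z-profile that peaks at 1, so the maximum projection recovers the
#'   design exactly.
#' @param seed Integer RNG seed; identical spec + seed is bit-identical.
#' @return An object of class `synthetic_cell_spec`.
#' @export
synthetic_cell_spec <- function(image_size = c(512L, 512L),
                                cell_shape = list(type = "disk", radius = 150),
                                cell_center = NULL,
                                nucleus_shape = list(type = "disk", radius = 40),
                                nucleus_offset = c(30, 0),
                                rna_class = list(type = "uniform"),
                                control_class = list(type = "uniform"),
                                total_intensity = 2e7,
                                noise = list(type = "none"),
                                bit_depth = 12L,
                                pixel_size_um = 0.16,
                                n_z = 1L,
                                seed = 1L) {
  if (is.null(cell_center))
    cell_center <- c((image_size[2] + 1) / 2, (image_size[1] + 1) / 2)
  structure(list(image_size = as.integer(image_size), cell_shape = cell_shape,
                 cell_center = cell_center, nucleus_shape = nucleus_shape,
                 nucleus_offset = nucleus_offset, rna_class = rna_class,
                 control_class = control_class,
                 total_intensity = total_intensity, noise = noise,
                 bit_depth = as.integer(bit_depth),
                 pixel_size_um = pixel_size_um, n_z = as.integer(n_z),
                 seed = as.integer(seed)),
            class = "synthetic_cell_spec")
}

# lay down one RNA channel (real-valued, pre-noise, pre-quantization)
.render_rna <- function(class, cell_px, cell_center, nucleus_center, nr, nc,
                        total_intensity) {
  area <- sum(cell_px)
  r_eq <- sqrt(area / pi)              # equivalent disk radius
  type <- class$type
  base <- if (type == "uniform") {
    cell_px * 1.0
  } else if (type == "perinuclear") {
    sigma <- if (is.null(class$sigma)) 40 else class$sigma
    d2 <- .dist2_from(nr, nc, nucleus_center[1], nucleus_center[2])
    exp(-d2 / (2 * sigma^2)) * cell_px
  } else if (type == "peripheral_rim") {
    inner_frac <- if (is.null(class$inner_frac)) 0.8 else class$inner_frac
    k <- max(1L, round((1 - inner_frac) * r_eq))
    (cell_px & !cpp_erode3x3(cell_px, k)) * 1.0
  } else if (type == "polarized") {
    dir <- if (is.null(class$direction)) 0 else class$direction
    dfrac <- if (is.null(class$displacement_frac)) 0.5
             else class$displacement_frac
    sigma <- if (is.null(class$sigma)) r_eq / 6 else class$sigma
    cx <- cell_center[1] + dfrac * r_eq * cos(dir)
    cy <- cell_center[2] + dfrac * r_eq * sin(dir)
    d2 <- .dist2_from(nr, nc, cx, cy)
    exp(-d2 / (2 * sigma^2)) * cell_px
  } else if (type == "clustered") {
    n_cl <- if (is.null(class$n_clusters)) 5L else class$n_clusters
    csig <- if (is.null(class$cluster_sigma)) 6 else class$cluster_sigma
    interior <- cpp_erode3x3(cell_px, max(1L, ceiling(2 * csig)))
    cand <- which(interior)
    if (length(cand) < n_cl) stop("cell too small for requested clusters")
    pick <- sample(cand, n_cl)
    out <- matrix(0, nr, nc)
    for (p in pick) {
      py <- (p - 1L) %% nr + 1L
      px <- (p - 1L) %/% nr + 1L
      out <- out + exp(-.dist2_from(nr, nc, px, py) / (2 * csig^2))
    }
    out * cell_px
  } else stop("unknown RNA class: ", type)
  s <- sum(base)
  if (s <= 0) stop("RNA class rendered an empty field")
  if (type %in% c("uniform", "peripheral_rim")) {
    # keep the field exactly constant on its support after quantization
    lvl <- max(1, round(total_intensity / sum(base > 0)))
    base * lvl
  } else {
    base * (total_intensity / s)
  }
}

#' Generate a synthetic multichannel image with ground truth
#'
#' Renders the four channels (nuclear stain, whole-cell stain, localized
#' RNA, control RNA) described by a [synthetic_cell_spec()], applies noise
#' and quantization, and returns both the image and a truth record with
#' the generating masks, centroids, radius of gyration and — where a
#' closed form exists — expected index values.
#'
#' @param spec A [synthetic_cell_spec()].
#' @param source_id Identifier stamped on the image.
#' @return List with `image` (an [mc_image()]) and `truth` (list:
#'   `cell_mask`, `nucleus_mask` (logical matrices), `cell_centroid`,
#'   `nucleus_centroid`, `radius_of_gyration`, `area_px`, `expected`
#'   (named list of closed-form index values, possibly empty), `seed`).
#' @export
generate_synthetic_cell <- function(spec, source_id = "synthetic") {
  stopifnot(inherits(spec, "synthetic_cell_spec"))
  nr <- spec$image_size[1]; nc <- spec$image_size[2]
  cc <- spec$cell_center
  ncen <- cc + spec$nucleus_offset
  cell_px <- .shape_mask(spec$cell_shape, cc, nr, nc)
  nuc_px <- .shape_mask(spec$nucleus_shape, ncen, nr, nc)
  if (!any(nuc_px) || any(nuc_px & !cell_px))
    stop("infeasible geometry: nucleus is not strictly inside the cell")
  maxv <- 2^spec$bit_depth - 1

  img <- .with_seed(spec$seed, {
    rna1 <- .render_rna(spec$rna_class, cell_px, cc, ncen, nr, nc,
                        spec$total_intensity)
    rna2 <- .render_rna(spec$control_class, cell_px, cc, ncen, nr, nc,
                        spec$total_intensity)
    nuc_ch <- nuc_px * (0.75 * maxv)
    cell_ch <- cell_px * (0.40 * maxv)
    chans <- list(nuc_ch, cell_ch, rna1, rna2)
    if (spec$noise$type == "uniform") {
      chans <- lapply(chans, function(m)
        m + matrix(stats::runif(nr * nc, 0, spec$noise$level), nr, nc))
    } else if (spec$noise$type == "gaussian") {
      chans <- lapply(chans, function(m)
        m + matrix(stats::rnorm(nr * nc, 0, spec$noise$sigma), nr, nc))
    } else if (spec$noise$type != "none") {
      stop("unknown noise type: ", spec$noise$type)
    }
    # z-profile peaks at 1 so the max projection recovers the 2-D design
    zw <- if (spec$n_z == 1L) 1
          else exp(-((seq_len(spec$n_z) - (spec$n_z + 1) / 2)^2) /
                     (2 * (spec$n_z / 4)^2))
    zw <- zw / max(zw)
    pix <- array(0, dim = c(nr, nc, spec$n_z, 4L))
    for (z in seq_len(spec$n_z))
      for (ch in 1:4)
        pix[, , z, ch] <- pmin(pmax(round(chans[[ch]] * zw[z]), 0), maxv)
    pix
  })

  xs <- col(cell_px)[cell_px]; ys <- row(cell_px)[cell_px]
  true_cc <- c(x = mean(xs), y = mean(ys))
  rg <- sqrt(mean((xs - true_cc[["x"]])^2 + (ys - true_cc[["y"]])^2))
  nxs <- col(nuc_px)[nuc_px]; nys <- row(nuc_px)[nuc_px]
  expected <- list()
  if (spec$rna_class$type == "uniform" && spec$noise$type == "none")
    expected <- list(di = 1, pdi = 1, pi = 0)
  if (spec$rna_class$type == "polarized" && spec$noise$type == "none" &&
      spec$cell_shape$type == "disk") {
    dfrac <- if (is.null(spec$rna_class$displacement_frac)) 0.5
             else spec$rna_class$displacement_frac
    # blob centroid at d * R from the center of a disk with Rg = R / sqrt(2)
    expected <- list(pi = dfrac * sqrt(2))
  }
  truth <- list(cell_mask = cell_px, nucleus_mask = nuc_px,
                cell_centroid = true_cc,
                nucleus_centroid = c(x = mean(nxs), y = mean(nys)),
                radius_of_gyration = rg, area_px = length(xs),
                rna_class = spec$rna_class$type, expected = expected,
                seed = spec$seed)
  image <- mc_image(img, c("nucleus", "cell", "rna_localized", "rna_control"),
                    bit_depth = spec$bit_depth,
                    pixel_size_um = spec$pixel_size_um,
                    source_id = source_id)
  list(image = image, truth = truth)
}

#' Render a field of unit-mass Gaussian spots
#'
#' Supports the intensity-versus-spot equivalence checks and sparse-signal
#' simulations: each spot is a discrete Gaussian kernel normalized to unit
#' total mass, centered (sub-pixel) at the given coordinate.
#'
#' @param coords n x 2 matrix of (x, y) spot centers (must lie inside
#'   `cell_px` when a mask is given).
#' @param psf_sigma Gaussian width in pixels.
#' @param image_size `c(H, W)`.
#' @param cell_px Optional logical mask; coordinates outside it are an
#'   error.
#' @param amplitude Scale applied to every unit-mass spot.
#' @return List with `channel` (H x W matrix) and `coords` (the input, for
#'   the coordinate-based oracle).
#' @export
spot_field <- function(coords, psf_sigma, image_size, cell_px = NULL,
                       amplitude = 1) {
  coords <- as.matrix(coords)
  nr <- image_size[1]; nc <- image_size[2]
  if (!is.null(cell_px)) {
    ok <- cell_px[cbind(pmin(pmax(round(coords[, 2]), 1L), nr),
                        pmin(pmax(round(coords[, 1]), 1L), nc))]
    if (!all(ok)) stop("spot coordinates outside the cell mask")
  }
  out <- matrix(0, nr, nc)
  r <- ceiling(4 * psf_sigma)
  for (k in seq_len(nrow(coords))) {
    x0 <- coords[k, 1]; y0 <- coords[k, 2]
    ys <- max(1L, floor(y0 - r)):min(nr, ceiling(y0 + r))
    xs <- max(1L, floor(x0 - r)):min(nc, ceiling(x0 + r))
    kern <- outer(exp(-(ys - y0)^2 / (2 * psf_sigma^2)),
                  exp(-(xs - x0)^2 / (2 * psf_sigma^2)))
    out[ys, xs] <- out[ys, xs] + amplitude * kern / sum(kern)
  }
  list(channel = out, coords = coords)
}

#' Write a packaged fixture set
#'
#' Generates a small deterministic set of synthetic images covering the
#' distribution classes, writes them as TIFF plus a JSON truth summary,
#' and returns the file listing. Used by the `make-fixtures` CLI
#' subcommand and by tutorials; the test suite builds its fixtures in code.
#'
#' @param dir Output directory (created if needed).
#' @param seed Base RNG seed.
#' @param image_size Frame size for the fixtures; geometry scales with it.
#'   The default is the full acquisition-scale world (512 px frame, cell
#'   radius 150 px); smaller frames shrink the cell proportionally, which
#'   increases the relative weight of the ~2 px outward boundary bias of
#'   edge-based segmentation.
#' @return Data frame with `source_id`, `path`, `rna_class`.
#' @export
make_fixture_set <- function(dir, seed = 1L, image_size = c(512L, 512L)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  classes <- list(
    uniform = list(type = "uniform"),
    perinuclear = list(type = "perinuclear", sigma = 20),
    peripheral = list(type = "peripheral_rim", inner_frac = 0.8),
    polarized = list(type = "polarized", direction = 0,
                     displacement_frac = 0.5),
    clustered = list(type = "clustered", n_clusters = 4L, cluster_sigma = 4)
  )
  scale <- image_size[1] / 512
  rows <- list(); truths <- list()
  for (i in seq_along(classes)) {
    id <- paste0("fixture_", names(classes)[i])
    spec <- synthetic_cell_spec(
      image_size = image_size,
      cell_shape = list(type = "disk", radius = 150 * scale),
      nucleus_shape = list(type = "disk", radius = 40 * scale),
      nucleus_offset = c(30 * scale, 0),
      rna_class = classes[[i]], seed = seed + i)
    g <- generate_synthetic_cell(spec, source_id = id)
    path <- file.path(dir, paste0(id, ".tif"))
    write_image(g$image, path)
    rows[[i]] <- data.frame(source_id = id, path = path,
                            rna_class = names(classes)[i],
                            stringsAsFactors = FALSE)
    truths[[id]] <- list(
      rna_class = names(classes)[i],
      cell_centroid = unname(g$truth$cell_centroid),
      nucleus_centroid = unname(g$truth$nucleus_centroid),
      radius_of_gyration = g$truth$radius_of_gyration,
      area_px = g$truth$area_px, expected = g$truth$expected,
      seed = spec$seed)
  }
  jsonlite::write_json(truths, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  do.call(rbind, rows)
}
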