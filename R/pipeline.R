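# Batch orchestration: read -> project -> segment -> (replay edits) ->
# metrics -> CSV, with QC overlays and a log. The interactive accept /
# edit loop of the original workflow is a two-pass design here: an
# automatic run writes overlays, the user records accept/edit decisions in
# a JSON file keyed by source_id, and a re-run replays those decisions —
# so a completed, human-reviewed analysis is reproducible from artifacts
# on disk.

#' Run configuration
#'
#' @param inputs Character vector of TIFF paths and/or globs.
#' @param channel_roles Channel role mapping (see [mc_image()]).
#' @param params [segmentation_params()] defaults for every image.
#' @param background_thresholds Named numeric per RNA role, or a scalar.
#' @param background_mode `"threshold"` or `"subtract"`.
#' @param decisions Per-image review decisions: a named list keyed by
#'   source_id (or path to a JSON file of the same shape). Each entry is
#'   `list(action = "accept")` or
#'   `list(action = "edit", edits = list(list(mode =, vertices =), ...))`.
#'   Images without an entry are auto-accepted.
#' @param output_dir Directory for `results.csv`, overlays and the log.
#' @param overlay Write per-image QC overlay TIFFs (cell outline red,
#'   nuclear outline white over the chosen channel).
#' @param overlay_channel Role of the channel under the overlay outlines.
#' @param page_order,pixel_size_um Passed to [read_image()].
#' @param log_level `"info"` or `"quiet"`.
#' @return An object of class `run_config`.
#' @export
run_config <- function(inputs, channel_roles,
                       params = segmentation_params(),
                       background_thresholds = 0,
                       background_mode = c("threshold", "subtract"),
                       decisions = NULL,
                       output_dir = ".",
                       overlay = FALSE,
                       overlay_channel = "cell",
                       page_order = "channel_fastest",
                       pixel_size_um = NULL,
                       log_level = c("info", "quiet")) {
  background_mode <- match.arg(background_mode)
  log_level <- match.arg(log_level)
  .validate_roles(channel_roles)
  if (is.character(decisions) && length(decisions) == 1L)
    decisions <- .read_decisions(decisions)
  if (!is.null(decisions)) .validate_decisions(decisions)
  structure(list(inputs = inputs, channel_roles = channel_roles,
                 params = params,
                 background_thresholds = background_thresholds,
                 background_mode = background_mode, decisions = decisions,
                 output_dir = output_dir, overlay = overlay,
                 overlay_channel = overlay_channel, page_order = page_order,
                 pixel_size_um = pixel_size_um, log_level = log_level),
            class = "run_config")
}

#' Read a run configuration from JSON
#'
#' @param path JSON file with fields named as in [run_config()];
#'   `segmentation_params` entries are passed through to
#'   [segmentation_params()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  params <- do.call(segmentation_params,
                    if (is.null(j$segmentation_params)) list()
                    else j$segmentation_params)
  thr <- if (is.null(j$background_thresholds)) 0
         else unlist(j$background_thresholds)
  run_config(inputs = unlist(j$inputs),
             channel_roles = unlist(j$channel_roles), params = params,
             background_thresholds = thr,
             background_mode = if (is.null(j$background_mode)) "threshold"
                               else j$background_mode,
             decisions = j$decisions,
             output_dir = if (is.null(j$output_dir)) "." else j$output_dir,
             overlay = isTRUE(j$overlay),
             overlay_channel = if (is.null(j$overlay_channel)) "cell"
                               else j$overlay_channel,
             page_order = if (is.null(j$page_order)) "channel_fastest"
                          else j$page_order,
             pixel_size_um = j$pixel_size_um)
}

.read_decisions <- function(path) {
  if (!file.exists(path)) stop("decision file not found: ", path)
  jsonlite::fromJSON(path, simplifyVector = TRUE,
                     simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
}

.validate_decisions <- function(decisions) {
  if (!is.list(decisions) ||
      (length(decisions) > 0L && is.null(names(decisions))))
    stop("malformed decision file: must be an object keyed by source_id")
  for (id in names(decisions)) {
    d <- decisions[[id]]
    if (is.null(d$action) || !d$action %in% c("accept", "edit"))
      stop("malformed decision for '", id,
           "': action must be 'accept' or 'edit'")
    if (d$action == "edit" && (is.null(d$edits) || !is.list(d$edits)))
      stop("malformed decision for '", id, "': 'edit' needs an edits list")
  }
  invisible(decisions)
}

#' Apply a review decision to computed masks
#'
#' Auto-accepts when no decision exists for the image. An `edit` decision
#' replays its polygon/dilation edits on the cell mask in the order listed
#' and recomputes the nuclear mask from the edited cell mask (nuclear
#' boundaries are always derived after cell-mask editing).
#'
#' @param proj Projected image.
#' @param cell,nucleus Automatic masks.
#' @param decisions Decision list (see [run_config()]).
#' @return List with `cell`, `nucleus`, `decision` (`"auto_accept"`,
#'   `"accept"` or `"edit"`).
#' @export
review_masks <- function(proj, cell, nucleus, decisions = NULL) {
  d <- decisions[[proj$source_id]]
  if (is.null(d))
    return(list(cell = cell, nucleus = nucleus, decision = "auto_accept"))
  if (d$action == "accept")
    return(list(cell = cell, nucleus = nucleus, decision = "accept"))
  edits <- lapply(d$edits, function(e)
    list(mode = e$mode,
         vertices = if (is.null(e$vertices)) NULL
                    else do.call(rbind, lapply(e$vertices, unlist))))
  cell2 <- apply_edits(cell, edits)
  nucleus2 <- nuclear_mask(channel(proj, "nucleus"), cell2)
  list(cell = cell2, nucleus = nucleus2, decision = "edit")
}

# mask outline: pixels in the mask whose 3x3 neighbourhood leaves it
.mask_outline <- function(px) px & !cpp_erode3x3(px, 1L)

#' Write a QC overlay image
#'
#' Renders the chosen channel in grayscale with the cell outline in red
#' and the nuclear outline in white, as an 8-bit RGB TIFF.
#'
#' @param proj Projected image.
#' @param cell,nucleus Masks to outline.
#' @param path Output path.
#' @param channel_role Channel shown under the outlines.
#' @return `path`, invisibly.
#' @export
write_overlay <- function(proj, cell, nucleus, path, channel_role = "cell") {
  base <- channel(proj, channel_role)
  g <- round(255 * base / max(1, max(base)))
  rgb <- array(0L, dim = c(nrow(g), ncol(g), 3L))
  for (ch in 1:3) rgb[, , ch] <- g
  co <- .mask_outline(cell$pixels)
  no <- .mask_outline(nucleus$pixels)
  r <- rgb[, , 1]; gg <- rgb[, , 2]; b <- rgb[, , 3]
  r[co] <- 255L; gg[co] <- 0L; b[co] <- 0L
  r[no] <- 255L; gg[no] <- 255L; b[no] <- 255L
  rgb[, , 1] <- r; rgb[, , 2] <- gg; rgb[, , 3] <- b
  write_tiff(list(rgb), path)
}

.log_msg <- function(con, level, ...) {
  msg <- paste0(..., collapse = "")
  if (level != "quiet") message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full analysis pipeline over a batch of images
#'
#' For every readable input image: maximum-intensity projection, automatic
#' cell and nuclear segmentation, replay of any review decision, and index
#' computation for each RNA channel. Failures (unreadable file,
#' segmentation failure, degenerate field) are logged and reported as
#' flagged rows — one failure never aborts the batch. Results are written
#' to `results.csv` in the output directory; a rerun with an identical
#' configuration reproduces the CSV byte-identically.
#'
#' @param config A [run_config()] or path to a JSON configuration.
#' @return Invisibly, a list with `results` (data frame), `csv_path`,
#'   `n_failed`.
#' @export
rdi_run <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  paths <- unique(unlist(lapply(config$inputs, function(p)
    if (grepl("[*?]", p)) Sys.glob(p) else p)))
  paths <- paths[order(basename(paths))]
  if (length(paths) == 0L) stop("run error: no input images matched")
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$output_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  if (!is.null(config$decisions)) {
    ids <- vapply(paths, function(p) sub("\\.[^.]*$", "", basename(p)), "")
    unknown <- setdiff(names(config$decisions), ids)
    if (length(unknown))
      stop("decision file references unknown source_id(s): ",
           paste(unknown, collapse = ", "))
  }
  rows <- list(); n_failed <- 0L
  for (p in paths) {
    sid <- sub("\\.[^.]*$", "", basename(p))
    row <- tryCatch({
      img <- read_image(p, config$channel_roles,
                        page_order = config$page_order,
                        pixel_size_um = config$pixel_size_um)
      proj <- max_project(img)
      cm <- cell_mask(channel(proj, "cell"), config$params)
      nm <- nuclear_mask(channel(proj, "nucleus"), cm)
      rv <- review_masks(proj, cm, nm, config$decisions)
      if (isTRUE(config$overlay))
        write_overlay(proj, rv$cell, rv$nucleus,
                      file.path(config$output_dir,
                                paste0("overlay_", sid, ".tif")),
                      config$overlay_channel)
      res <- compute_rdi(proj, rv$cell, rv$nucleus,
                         background_thresholds = config$background_thresholds,
                         background_mode = config$background_mode)
      .log_msg(log_con, config$log_level, "ok: ", sid,
               " (decision: ", rv$decision, ")")
      res
    }, error = function(e) {
      n_failed <<- n_failed + 1L
      status <- if (inherits(e, "rdi_segmentation_failure"))
        "segmentation_failure" else "read_error"
      .log_msg(log_con, config$log_level, "FAILED: ", sid, " [", status,
               "] ", conditionMessage(e))
      roles <- config$channel_roles[startsWith(config$channel_roles, "rna_")]
      data.frame(source_id = sid, cell_id = "cell1", rna_role = roles,
                 area_px = NA_integer_, area_um2 = NA_real_, pdi = NA_real_,
                 pi = NA_real_, di = NA_real_, mean_intensity = NA_real_,
                 background_threshold = NA_real_,
                 background_mode = config$background_mode, status = status,
                 stringsAsFactors = FALSE)
    })
    rows[[length(rows) + 1L]] <- row
  }
  results <- do.call(rbind, rows)
  csv_path <- file.path(config$output_dir, "results.csv")
  write_results(results, csv_path)
  .log_msg(log_con, config$log_level, "wrote ", nrow(results), " rows to ",
           csv_path, " (", n_failed, " image(s) failed)")
  invisible(list(results = results, csv_path = csv_path,
                 n_failed = n_failed))
}

# ---- command-line entry point ------------------------------------------

.cli_args_to_list <- function(args) {
  out <- list()
  for (a in args) {
    m <- regmatches(a, regexec("^--([^=]+)=(.*)$", a))[[1]]
    if (length(m) == 3L) out[[gsub("-", "_", m[2])]] <- m[3]
    else if (startsWith(a, "--")) out[[gsub("-", "_", sub("^--", "", a))]] <- TRUE
    else out$positional <- c(out$positional, a)
  }
  out
}

#' Command-line interface
#'
#' Entry point used by `inst/cli/rdindex.R`
#' (`Rscript .../rdindex.R <subcommand> ...`). Subcommands:
#' \describe{
#'   \item{`analyze --config=conf.json`}{run the batch pipeline;}
#'   \item{`sweep-threshold --config=conf.json --max=600 --step=50
#'     --role=rna_localized`}{write the PDI-versus-threshold response curve
#'     for every input image to `threshold_sweep.csv`;}
#'   \item{`make-fixtures --dir=out [--seed=1]`}{write the synthetic
#'     fixture set;}
#'   \item{`overlay --config=conf.json`}{run segmentation only and write
#'     QC overlays.}
#' }
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the subcommand's result.
#' @export
rdi_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0L)
    stop("usage: rdindex.R <analyze|sweep-threshold|make-fixtures|overlay> ",
         "[--config=...] [--dir=...] [--seed=...]")
  sub <- args[1]
  opt <- .cli_args_to_list(args[-1])
  if (sub == "analyze") {
    invisible(rdi_run(opt$config))
  } else if (sub == "make-fixtures") {
    seed <- if (is.null(opt$seed)) 1L else as.integer(opt$seed)
    invisible(make_fixture_set(opt$dir, seed = seed))
  } else if (sub == "overlay") {
    config <- read_run_config(opt$config)
    config$overlay <- TRUE
    invisible(rdi_run(config))
  } else if (sub == "sweep-threshold") {
    config <- read_run_config(opt$config)
    role <- if (is.null(opt$role)) "rna_localized" else opt$role
    upper <- if (is.null(opt$max)) 600 else as.numeric(opt$max)
    step <- if (is.null(opt$step)) 50 else as.numeric(opt$step)
    thresholds <- seq(0, upper, by = step)
    paths <- unique(unlist(lapply(config$inputs, function(p)
      if (grepl("[*?]", p)) Sys.glob(p) else p)))
    out <- lapply(paths, function(p) {
      img <- read_image(p, config$channel_roles,
                        page_order = config$page_order,
                        pixel_size_um = config$pixel_size_um)
      proj <- max_project(img)
      cm <- cell_mask(channel(proj, "cell"), config$params)
      nm <- nuclear_mask(channel(proj, "nucleus"), cm)
      sw <- threshold_sweep(channel(proj, role), cm, nm, thresholds,
                            mode = config$background_mode)
      cbind(source_id = proj$source_id, sw)
    })
    df <- do.call(rbind, out)
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    csv <- file.path(config$output_dir, "threshold_sweep.csv")
    utils::write.csv(df, csv, row.names = FALSE)
    invisible(df)
  } else {
    stop("unknown subcommand: ", sub)
  }
}
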