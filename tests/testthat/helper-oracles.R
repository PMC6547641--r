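# Shared fixture builders and independent brute-force oracles.
# The oracles are deliberately literal (explicit per-pixel loops, no shared
# code with the package internals) so they can stand as a second route for
# the moment, threshold and gradient computations.

disk_px <- function(nr, nc, cx, cy, r) {
  outer((seq_len(nr) - cy)^2, (seq_len(nc) - cx)^2, "+") <= r^2
}

iou <- function(a, b) sum(a & b) / sum(a | b)

# explicit summation oracle for the intensity-weighted centroid
bf_centroid <- function(I) {
  sx <- 0; sy <- 0; w <- 0
  for (i in seq_len(nrow(I)))
    for (j in seq_len(ncol(I))) {
      sx <- sx + j * I[i, j]
      sy <- sy + i * I[i, j]
      w <- w + I[i, j]
    }
  c(x = sx / w, y = sy / w)
}

# explicit summation oracle for the second moment about (cx, cy)
bf_mu2 <- function(I, cx, cy) {
  s <- 0; w <- 0
  for (i in seq_len(nrow(I)))
    for (j in seq_len(ncol(I))) {
      s <- s + ((j - cx)^2 + (i - cy)^2) * I[i, j]
      w <- w + I[i, j]
    }
  s / w
}

# direct 3x3 Sobel arithmetic with replicated borders
bf_sobel <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3, byrow = TRUE)
  ky <- t(kx)
  at <- function(i, j) m[min(max(i, 1), nr), min(max(j, 1), nc)]
  out <- matrix(0, nr, nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc)) {
      gx <- 0; gy <- 0
      for (di in -1:1)
        for (dj in -1:1) {
          gx <- gx + kx[di + 2, dj + 2] * at(i + di, j + dj)
          gy <- gy + ky[di + 2, dj + 2] * at(i + di, j + dj)
        }
      out[i, j] <- sqrt(gx^2 + gy^2)
    }
  out
}

# exhaustive scan over all candidate integer thresholds, maximizing the
# between-class variance directly from its definition
bf_otsu <- function(v) {
  v <- round(as.vector(v))
  cands <- sort(unique(v))
  cands <- cands[-length(cands)]
  best <- -Inf; best_t <- NA
  for (t in cands) {
    lo <- v[v <= t]; hi <- v[v > t]
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    if (w0 == 0 || w1 == 0) next
    bcv <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; best_t <- t }
  }
  best_t
}

# indexes computed from a spot coordinate list (no pixels involved):
# each coordinate carries equal mass
coord_metrics <- function(coords, cell_px, nuc_centroid) {
  cx <- mean(coords[, 1]); cy <- mean(coords[, 2])
  mu2_rna <- mean((coords[, 1] - cx)^2 + (coords[, 2] - cy)^2)
  xs <- col(cell_px)[cell_px]; ys <- row(cell_px)[cell_px]
  mcx <- mean(xs); mcy <- mean(ys)
  mu2_uni_cc <- mean((xs - mcx)^2 + (ys - mcy)^2)
  mu2_rna_nc <- mean((coords[, 1] - nuc_centroid[1])^2 +
                       (coords[, 2] - nuc_centroid[2])^2)
  mu2_uni_nc <- mean((xs - nuc_centroid[1])^2 + (ys - nuc_centroid[2])^2)
  list(di = mu2_rna / mu2_uni_cc, pdi = mu2_rna_nc / mu2_uni_nc,
       pi = sqrt((cx - mcx)^2 + (cy - mcy)^2) / sqrt(mu2_uni_cc))
}

# a small standard test cell: 256x256, disk cell r = 75, nucleus r = 20
# offset (15, 0); returns masks, geometry and raw helpers
std_cell <- function(nr = 256L, nc = 256L, r_cell = 75, r_nuc = 20,
                     offset = c(15, 0)) {
  cx <- (nc + 1) / 2; cy <- (nr + 1) / 2
  cell <- binary_mask(disk_px(nr, nc, cx, cy, r_cell), "cell")
  nuc <- binary_mask(disk_px(nr, nc, cx + offset[1], cy + offset[2], r_nuc),
                     "nucleus")
  list(cell = cell, nucleus = nuc, geom = cell_geometry(cell, nuc),
       cx = cx, cy = cy, r_cell = r_cell)
}

# write a small synthetic image to a temp TIFF and return its path
write_synthetic_tiff <- function(dir, id, seed = 1L, rna_class = list(type = "uniform"),
                                 image_size = c(128L, 128L)) {
  spec <- synthetic_cell_spec(
    image_size = image_size,
    cell_shape = list(type = "disk", radius = 40),
    nucleus_shape = list(type = "disk", radius = 10),
    nucleus_offset = c(8, 0), rna_class = rna_class, seed = seed)
  g <- generate_synthetic_cell(spec, source_id = id)
  path <- file.path(dir, paste0(id, ".tif"))
  write_image(g$image, path)
  list(path = path, truth = g$truth, image = g$image)
}
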