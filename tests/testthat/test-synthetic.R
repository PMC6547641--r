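# Synthetic image generator: determinism, geometry contracts, spot fields
# and agreement between intensity-based and coordinate-based indexes.

test_that("identical spec + seed is bit-identical; geometry is validated", {
  spec <- synthetic_cell_spec(image_size = c(96L, 96L),
                              cell_shape = list(type = "disk", radius = 30),
                              nucleus_shape = list(type = "disk", radius = 8),
                              nucleus_offset = c(6, 0),
                              noise = list(type = "gaussian", sigma = 20),
                              seed = 99)
  a <- generate_synthetic_cell(spec)
  b <- generate_synthetic_cell(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  spec2 <- spec; spec2$seed <- 100L
  c <- generate_synthetic_cell(spec2)
  expect_false(identical(a$image$pixels, c$image$pixels))

  bad <- synthetic_cell_spec(image_size = c(96L, 96L),
                             cell_shape = list(type = "disk", radius = 20),
                             nucleus_shape = list(type = "disk", radius = 10),
                             nucleus_offset = c(18, 0))
  expect_error(generate_synthetic_cell(bad), "not strictly inside")
})

test_that("generator truth records carry closed-form expectations", {
  u <- generate_synthetic_cell(synthetic_cell_spec(
    image_size = c(128L, 128L),
    cell_shape = list(type = "disk", radius = 40),
    nucleus_shape = list(type = "disk", radius = 10),
    nucleus_offset = c(8, 0), seed = 5))
  expect_equal(u$truth$expected, list(di = 1, pdi = 1, pi = 0))

  p <- generate_synthetic_cell(synthetic_cell_spec(
    image_size = c(256L, 256L),
    cell_shape = list(type = "disk", radius = 75),
    nucleus_shape = list(type = "disk", radius = 20),
    nucleus_offset = c(15, 0),
    rna_class = list(type = "polarized", direction = 0,
                     displacement_frac = 0.4, sigma = 6), seed = 5))
  # displacement d * R in a disk with Rg = R/sqrt(2) gives PI = d * sqrt(2)
  expect_equal(p$truth$expected$pi, 0.4 * sqrt(2))
  proj <- max_project(p$image)
  f <- apply_background(channel(proj, "rna_localized"),
                        binary_mask(p$truth$cell_mask, "cell"), 0)
  geom <- cell_geometry(binary_mask(p$truth$cell_mask, "cell"),
                        binary_mask(p$truth$nucleus_mask, "nucleus"))
  expect_equal(polarization_index(f, geom), p$truth$expected$pi,
               tolerance = 0.05)
})

test_that("distribution classes produce the expected index ordering", {
  base <- function(class, seed = 31) synthetic_cell_spec(
    image_size = c(256L, 256L),
    cell_shape = list(type = "disk", radius = 75),
    nucleus_shape = list(type = "disk", radius = 20),
    nucleus_offset = c(15, 0), rna_class = class, seed = seed)
  idx <- function(class) {
    g <- generate_synthetic_cell(base(class))
    proj <- max_project(g$image)
    cm <- binary_mask(g$truth$cell_mask, "cell")
    nm <- binary_mask(g$truth$nucleus_mask, "nucleus")
    geom <- cell_geometry(cm, nm)
    f <- apply_background(channel(proj, "rna_localized"), cm, 0)
    c(pdi = peripheral_distribution_index(f, cm, geom),
      di = dispersion_index(f, cm),
      pi = polarization_index(f, geom))
  }
  peri <- idx(list(type = "perinuclear", sigma = 15))
  rim <- idx(list(type = "peripheral_rim", inner_frac = 0.8))
  clus <- idx(list(type = "clustered", n_clusters = 3L, cluster_sigma = 5))
  expect_lt(peri[["pdi"]], 1)
  expect_gt(rim[["pdi"]], 1)
  expect_gt(rim[["di"]], 1)
  expect_lt(clus[["di"]], 1)
})

test_that("ellipse and polygon cell shapes render and stay feasible", {
  e <- generate_synthetic_cell(synthetic_cell_spec(
    image_size = c(128L, 128L),
    cell_shape = list(type = "ellipse", a = 50, b = 30),
    nucleus_shape = list(type = "disk", radius = 10),
    nucleus_offset = c(10, 0), seed = 3))
  expect_gt(sum(e$truth$cell_mask), pi * 50 * 30 * 0.95)
  v <- rbind(c(20, 20), c(108, 30), c(100, 100), c(30, 108))
  p <- generate_synthetic_cell(synthetic_cell_spec(
    image_size = c(128L, 128L),
    cell_shape = list(type = "polygon", vertices = v),
    cell_center = c(64, 64),
    nucleus_shape = list(type = "disk", radius = 10),
    nucleus_offset = c(0, 0), seed = 3))
  expect_true(all(p$truth$cell_mask[p$truth$nucleus_mask]))
})

test_that("spot fields: unit mass, point-mass centroid, coordinate oracle", {
  s <- std_cell()
  one <- spot_field(rbind(c(100, 120)), psf_sigma = 1.5,
                    image_size = c(256L, 256L), cell_px = s$cell$pixels)
  expect_equal(sum(one$channel), 1, tolerance = 1e-6)

  # sigma -> 0 limit: centroid of n spots equals the coordinate mean
  pts <- rbind(c(110, 130), c(150, 120), c(130, 150))
  tight <- spot_field(pts, psf_sigma = 0.05, image_size = c(256L, 256L))
  f <- rdindex:::.as_field(tight$channel)
  expect_equal(unname(rna_centroid(f)), colMeans(pts), tolerance = 1e-6)

  expect_error(spot_field(rbind(c(2, 2)), 1, c(256L, 256L), s$cell$pixels),
               "outside the cell mask")

  # 200 seeded spots: intensity-based vs coordinate-based indexes within 1%
  set.seed(17)
  n <- 200
  repeat {
    rr <- 70 * sqrt(stats::runif(n)); th <- stats::runif(n, 0, 2 * pi)
    xs <- s$cx + rr * cos(th); ys <- s$cy + rr * sin(th)
    inside <- s$cell$pixels[cbind(round(ys), round(xs))]
    if (all(inside)) break
  }
  coords <- cbind(xs, ys)
  sf <- spot_field(coords, psf_sigma = 1, image_size = c(256L, 256L),
                   cell_px = s$cell$pixels)
  f <- rdindex:::.as_field(sf$channel)
  oracle <- coord_metrics(coords, s$cell$pixels, s$geom$nucleus_centroid)
  expect_equal(dispersion_index(f, s$cell), oracle$di, tolerance = 0.01)
  expect_equal(peripheral_distribution_index(f, s$cell, s$geom), oracle$pdi,
               tolerance = 0.01)
})

test_that("fixture set writes images + truth and keeps mask invariants", {
  dir <- tempfile(); dir.create(dir)
  listing <- make_fixture_set(dir, seed = 1L, image_size = c(192L, 192L))
  expect_identical(nrow(listing), 5L)
  expect_true(all(file.exists(listing$path)))
  truth <- jsonlite::fromJSON(file.path(dir, "truth.json"),
                              simplifyVector = TRUE)
  expect_setequal(names(truth), listing$source_id)
  roles <- c("nucleus", "cell", "rna_localized", "rna_control")
  # reduced scale for speed; the strict IoU recovery gate runs at full
  # acquisition scale in the acceptance suite
  for (p in listing$path) {
    g <- read_image(p, roles)
    proj <- max_project(g)
    cm <- cell_mask(channel(proj, "cell"))
    nm <- nuclear_mask(channel(proj, "nucleus"), cm)
    expect_identical(rdindex:::cpp_fill_holes(cm$pixels), cm$pixels)
    expect_true(all(cm$pixels[nm$pixels]))
  }
})
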