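# Index computations: exact anchors, closed forms, brute-force oracles and
# the invariances that make PI / DI / PDI interpretable.

test_that("background handling: threshold mode, subtract mode, degeneracy", {
  s <- std_cell(64, 64, r_cell = 20, r_nuc = 6, offset = c(4, 0))
  raw <- matrix(50, 64, 64)
  raw[s$cell$pixels] <- 100
  raw[1, 1] <- 50

  f0 <- apply_background(raw, s$cell, 0)
  expect_equal(f0$values, raw * s$cell$pixels)

  f60 <- apply_background(raw, s$cell, 60)
  expect_true(all(f60$values[f60$values > 0] == 100))
  expect_identical(sum(f60$values > 0), sum(s$cell$pixels))

  fsub <- apply_background(raw, s$cell, 60, mode = "subtract")
  expect_true(all(fsub$values[s$cell$pixels] == 40))

  fdeg <- apply_background(raw, s$cell, 200)
  expect_true(fdeg$degenerate)
  expect_error(rna_centroid(fdeg), class = "rdi_degenerate_field")
})

test_that("centroid and second moment match explicit summation oracles", {
  # point mass and symmetric pair
  I <- matrix(0, 32, 32); I[20, 10] <- 5
  f <- rdindex:::.as_field(I)
  expect_equal(rna_centroid(f), c(x = 10, y = 20))
  expect_equal(second_moment(f, c(10, 20)), 0)

  I2 <- matrix(0, 32, 32); I2[16, 5] <- 2; I2[16, 15] <- 2
  f2 <- rdindex:::.as_field(I2)
  expect_equal(rna_centroid(f2), c(x = 10, y = 16))
  expect_equal(second_moment(f2, c(10, 16)), 25)  # two pixels at r = 5

  # seeded random 64x64 fields against the brute-force double loop
  for (seed in 1:3) {
    set.seed(seed)
    I <- matrix(stats::runif(64 * 64), 64, 64)
    f <- rdindex:::.as_field(I)
    expect_equal(rna_centroid(f), bf_centroid(I), tolerance = 1e-12)
    expect_equal(second_moment(f, c(20.5, 40.25)),
                 bf_mu2(I, 20.5, 40.25), tolerance = 1e-12)
  }
})

test_that("uniform field gives DI = 1, PDI = 1 and PI ~ 0 exactly", {
  s <- std_cell()
  f <- rdindex:::.uniform_field(s$cell)
  expect_equal(dispersion_index(f, s$cell), 1, tolerance = 1e-12)
  expect_equal(peripheral_distribution_index(f, s$cell, s$geom), 1,
               tolerance = 1e-12)
  expect_lt(polarization_index(f, s$geom), 0.02)
  # scaling every intensity leaves the indexes untouched
  f7 <- rdindex:::.as_field(f$values * 7)
  expect_equal(dispersion_index(f7, s$cell), 1, tolerance = 1e-12)
})

test_that("PI closed form: point mass in a disk (Rg = R / sqrt(2))", {
  s <- std_cell(192, 192, r_cell = 60, r_nuc = 15, offset = c(0, 0))
  I <- matrix(0, 192, 192)
  I[96, 126] <- 10                      # ~29.5 px right of the centroid
  f <- rdindex:::.as_field(I)
  d <- sqrt((126 - s$geom$cell_centroid[["x"]])^2 +
              (96 - s$geom$cell_centroid[["y"]])^2)
  expect_equal(polarization_index(f, s$geom), d / (60 / sqrt(2)),
               tolerance = 0.01)
})

test_that("DI and PDI order concentrated, diffuse and peripheral fields", {
  s <- std_cell()
  nr <- 256; nc <- 256
  ncx <- s$geom$nucleus_centroid[["x"]]; ncy <- s$geom$nucleus_centroid[["y"]]

  central <- exp(-outer((1:nr - s$cy)^2, (1:nc - s$cx)^2, "+") / (2 * 10^2)) *
    s$cell$pixels
  perinuc <- exp(-outer((1:nr - ncy)^2, (1:nc - ncx)^2, "+") / (2 * 12^2)) *
    s$cell$pixels
  d_cc <- sqrt(outer((1:nr - s$cy)^2, (1:nc - s$cx)^2, "+"))
  rim <- (d_cc >= 65 & d_cc <= 74 & s$cell$pixels) * 1.0

  expect_lt(dispersion_index(rdindex:::.as_field(central), s$cell), 1)
  expect_gt(dispersion_index(rdindex:::.as_field(rim), s$cell), 1)
  expect_lt(peripheral_distribution_index(rdindex:::.as_field(perinuc),
                                          s$cell, s$geom), 1)
  expect_gt(peripheral_distribution_index(rdindex:::.as_field(rim),
                                          s$cell, s$geom), 1)
})

test_that("translating image, masks and field together changes nothing", {
  small <- std_cell(128, 128, r_cell = 30, r_nuc = 8, offset = c(6, 0))
  set.seed(4)
  I <- matrix(stats::runif(128 * 128), 128, 128) * small$cell$pixels
  shift <- function(m, dy, dx) {
    out <- matrix(0, 200, 200)
    out[(1:128) + dy, (1:128) + dx] <- m
    out
  }
  f1 <- rdindex:::.as_field(I)
  r1 <- list(pi = polarization_index(f1, small$geom),
             di = dispersion_index(f1, small$cell),
             pdi = peripheral_distribution_index(f1, small$cell, small$geom))
  cell2 <- binary_mask(shift(small$cell$pixels, 31, 17) > 0, "cell")
  nuc2 <- binary_mask(shift(small$nucleus$pixels, 31, 17) > 0, "nucleus")
  geom2 <- cell_geometry(cell2, nuc2)
  f2 <- rdindex:::.as_field(shift(I, 31, 17))
  expect_equal(polarization_index(f2, geom2), r1$pi, tolerance = 1e-10)
  expect_equal(dispersion_index(f2, cell2), r1$di, tolerance = 1e-10)
  expect_equal(peripheral_distribution_index(f2, cell2, geom2), r1$pdi,
               tolerance = 1e-10)
})

test_that("PDI is invariant to polarization of a peripheral arc; PI is not", {
  s <- std_cell()
  ncx <- s$geom$nucleus_centroid[["x"]]; ncy <- s$geom$nucleus_centroid[["y"]]
  d_nc <- sqrt(outer((1:256 - ncy)^2, (1:256 - ncx)^2, "+"))
  ang <- atan2(outer(1:256 - ncy, rep(1, 256)),
               outer(rep(1, 256), 1:256 - ncx))
  annulus <- d_nc >= 50 & d_nc <= 58 & s$cell$pixels
  arc_right <- (annulus & abs(ang) < pi / 4) * 1.0
  arc_left <- (annulus & abs(abs(ang) - pi) < pi / 4) * 1.0

  fr <- rdindex:::.as_field(arc_right); fl <- rdindex:::.as_field(arc_left)
  pdi_r <- peripheral_distribution_index(fr, s$cell, s$geom)
  pdi_l <- peripheral_distribution_index(fl, s$cell, s$geom)
  pi_r <- polarization_index(fr, s$geom)
  pi_l <- polarization_index(fl, s$geom)
  expect_lt(abs(pdi_r - pdi_l) / pdi_r, 0.02)
  expect_gt(abs(pi_r - pi_l), 0.3)
})

test_that("mean RNA intensity is the masked raw mean", {
  s <- std_cell(64, 64, r_cell = 20, r_nuc = 6, offset = c(4, 0))
  const <- matrix(0, 64, 64); const[s$cell$pixels] <- 42
  expect_equal(mean_rna_intensity(const, s$cell), 42)
  outside <- matrix(1000, 64, 64); outside[s$cell$pixels] <- 0
  expect_equal(mean_rna_intensity(outside, s$cell), 0)
  set.seed(2)
  r <- matrix(stats::runif(64 * 64, 0, 100), 64, 64)
  expect_equal(mean_rna_intensity(r, s$cell),
               sum(r[s$cell$pixels]) / sum(s$cell$pixels), tolerance = 1e-12)
})

test_that("cell geometry: square, disk Rg, physical area", {
  sq <- matrix(FALSE, 32, 32); sq[11:20, 6:15] <- TRUE
  g <- cell_geometry(binary_mask(sq, "cell"))
  expect_identical(g$area_px, 100L)
  expect_equal(g$cell_centroid, c(x = 10.5, y = 15.5))

  d <- binary_mask(disk_px(256, 256, 128.5, 128.5, 100), "cell")
  gd <- cell_geometry(d)
  expect_equal(gd$radius_of_gyration, 100 / sqrt(2), tolerance = 0.01)

  sq50 <- matrix(FALSE, 64, 64); sq50[1:50, 1:50] <- TRUE
  g50 <- cell_geometry(binary_mask(sq50, "cell"), pixel_size_um = 0.2)
  expect_identical(g50$area_px, 2500L)
  expect_equal(g50$area_um2, 100.0)
  expect_error(cell_geometry(binary_mask(matrix(FALSE, 4, 4), "cell")),
               "empty")
})

test_that("compute_rdi assembles rows and flags degenerate channels", {
  spec <- synthetic_cell_spec(image_size = c(160L, 160L),
                              cell_shape = list(type = "disk", radius = 45),
                              nucleus_shape = list(type = "disk", radius = 12),
                              nucleus_offset = c(9, 0), seed = 21)
  g <- generate_synthetic_cell(spec, source_id = "unit")
  proj <- max_project(g$image)
  cm <- binary_mask(g$truth$cell_mask, "cell")
  nm <- binary_mask(g$truth$nucleus_mask, "nucleus")
  res <- compute_rdi(proj, cm, nm)
  expect_identical(nrow(res), 2L)
  expect_setequal(res$rna_role, c("rna_localized", "rna_control"))
  expect_true(all(res$status == "ok"))
  expect_equal(res$di, c(1, 1), tolerance = 1e-9)
  expect_equal(res$pdi, c(1, 1), tolerance = 1e-9)
  expect_equal(res$area_um2, rep(g$truth$area_px * 0.16^2, 2))

  # a threshold above the dynamic range flags the row instead of erroring
  res2 <- compute_rdi(proj, cm, nm, background_thresholds = 1e6)
  expect_true(all(res2$status == "degenerate_field"))
  expect_true(all(is.na(res2$pdi)))
  expect_false(anyNA(res2$mean_intensity))   # raw mean is still defined
})

test_that("threshold sweep returns the response curve frame", {
  s <- std_cell(128, 128, r_cell = 40, r_nuc = 10, offset = c(8, 0))
  set.seed(12)
  raw <- matrix(stats::runif(128 * 128, 0, 100), 128, 128)
  sw <- threshold_sweep(raw, s$cell, s$nucleus, thresholds = c(0, 50, 150))
  expect_identical(nrow(sw), 3L)
  expect_true(all(diff(sw$n_pixels) <= 0))
  expect_true(is.na(sw$pdi[3]))              # everything below 150 -> flagged
  expect_equal(sw$pdi[1], 1, tolerance = 0.05)  # uniform noise is diffuse
})
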