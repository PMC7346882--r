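test_that("a rectangular slab splits at mid-depth within one pixel row", {
  map <- slab_map(220L, 140L, border = 10L)
  bnd <- boundary_from_side(map, "top")
  reg <- partition_epi_endo(map, bnd)
  n_epi <- sum(reg == 1L); n_endo <- sum(reg == 2L)
  expect_lte(abs(n_epi - n_endo), 120L)  # one row stratum of the 120-px slab
  # epicardial pixels are the shallow half
  rows_epi <- range(which(apply(unclass(reg) == 1L, 1, any)))
  rows_endo <- range(which(apply(unclass(reg) == 2L, 1, any)))
  expect_lt(rows_epi[2], rows_endo[2])
  expect_lt(rows_epi[1], rows_endo[1])
})

test_that("curved walls split into equal areas within 1%", {
  # annular wall segment: outer boundary is the epicardial surface
  nr <- 300L; nc <- 300L
  cls <- psr_classes()
  lab <- matrix(cls[["background"]], nr, nc)
  ctr <- c(300, 150); R1 <- 120; R2 <- 260
  for (r in 1:nr) for (cl in 1:nc) {
    d <- sqrt((r - ctr[1])^2 + (cl - ctr[2])^2)
    if (d >= R1 && d <= R2) lab[r, cl] <- cls[["myocyte"]]
  }
  map <- class_map(lab, 2)
  tis <- lab == cls[["myocyte"]]
  bnd <- matrix(FALSE, nr, nc)
  for (r in 1:nr) for (cl in 1:nc)
    if (tis[r, cl] &&
        sqrt((r - ctr[1])^2 + (cl - ctr[2])^2) >= R2 - 1) bnd[r, cl] <- TRUE
  reg <- partition_epi_endo(map, bnd)
  imbalance <- abs(sum(reg == 1L) - sum(reg == 2L)) / sum(tis)
  expect_lte(imbalance, 0.01)
})

test_that("with a left boundary the epicardial half is the left columns", {
  cls <- psr_classes()
  map <- class_map(matrix(cls[["myocyte"]], 60, 80), 2)
  bnd <- matrix(FALSE, 60, 80); bnd[, 1] <- TRUE
  reg <- partition_epi_endo(map, bnd)
  col_class <- apply(unclass(reg), 2, function(x) unique(x))
  expect_true(all(vapply(col_class, length, integer(1)) == 1L))
  cut <- max(which(vapply(col_class, `[`, 0L, 1) == 1L))
  expect_true(all(unclass(reg)[, 1:cut] == 1L))
  expect_true(all(unclass(reg)[, (cut + 1L):80] == 2L))
  expect_lte(abs(sum(reg == 1L) - sum(reg == 2L)), 60L)
})

test_that("septal samples get a whole-only mask and free walls need a boundary", {
  map <- slab_map(80L, 80L)
  reg <- partition_epi_endo(map, septal = TRUE)
  expect_identical(attr(reg, "method"), "whole_only")
  expect_identical(sum(reg == 3L), sum(class_counts(map)[["myocyte"]]))
  expect_error(partition_epi_endo(map), "boundary")
})

test_that("composition percentages follow their arithmetic definition", {
  map <- toy_class_map(c(collagen = 20L, fat = 10L, myocyte = 70L))
  rec <- compute_composition(map, heart_id = "H1", location = "LV_ant")
  expect_equal(rec$collagen_pct, 20)
  expect_equal(rec$fat_pct, 10)
  expect_equal(rec$myocyte_pct, 70)
  expect_equal(rec$tissue_area_mm2, 100 * 100^2 * 1e-6)
  expect_identical(rec$group, "LV")

  # perivascular pixels leave both numerator and denominator
  map2 <- toy_class_map(c(collagen = 10L, fat = 10L, myocyte = 70L,
                          excluded_perivascular = 10L))
  rec2 <- compute_composition(map2)
  expect_equal(rec2$collagen_pct, 100 * 10 / 90, tolerance = 1e-12)
  expect_equal(rec2$fat_pct, 100 * 10 / 90, tolerance = 1e-12)
  expect_equal(rec2$myocyte_pct, 100 * 70 / 90, tolerance = 1e-12)
  expect_equal(rec2$collagen_pct + rec2$fat_pct + rec2$myocyte_pct, 100,
               tolerance = 1e-6)
})

test_that("pooled epicardial+endocardial records reproduce the total exactly", {
  syn <- generate_slide(slide_spec(width_px = 256, height_px = 256,
                                   collagen_frac = 0.12, fat_frac = 0.06,
                                   n_vessels = 1, rng_seed = 19L))
  res <- process_slide(syn$slide, heart_id = "H1", location = "RV",
                       boundary = syn$truth$epicardial_boundary)
  rec <- res$records
  halves <- rec[rec$region != "total", ]
  halves$region <- "total"
  pooled <- aggregate_composition(halves)
  total <- rec[rec$region == "total", ]
  expect_identical(pooled$analyzable_px, total$analyzable_px)
  expect_equal(pooled$collagen_pct, total$collagen_pct, tolerance = 1e-12)
  expect_equal(pooled$fat_pct, total$fat_pct, tolerance = 1e-12)
})

test_that("zero analyzable tissue fails explicitly", {
  cls <- psr_classes()
  map <- class_map(matrix(cls[["background"]], 20, 20), 2)
  expect_error(compute_composition(map), "zero analyzable")
})

test_that("partition is deterministic", {
  syn <- generate_slide(slide_spec(width_px = 128, height_px = 128,
                                   collagen_frac = 0.1, fat_frac = 0.05,
                                   n_vessels = 1, rng_seed = 29L))
  map <- detect_fat(classify_pixels(syn$slide))
  b <- syn$truth$epicardial_boundary
  expect_identical(unclass(partition_epi_endo(map, b)),
                   unclass(partition_epi_endo(map, b)))
})
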