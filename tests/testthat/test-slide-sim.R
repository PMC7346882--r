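test_that("slide generation is deterministic under a fixed seed", {
  sp <- slide_spec(width_px = 128, height_px = 128, collagen_frac = 0.1,
                   fat_frac = 0.05, n_vessels = 1, rng_seed = 9L)
  a <- generate_slide(sp)
  b <- generate_slide(sp)
  expect_identical(a$slide$pixels, b$slide$pixels)
  expect_identical(a$truth$class_mask$labels, b$truth$class_mask$labels)
  expect_identical(a$truth$lumen_mask, b$truth$lumen_mask)
})

test_that("ground-truth fractions equal independent mask pixel counts", {
  syn <- generate_slide(slide_spec(width_px = 256, height_px = 256,
                                   collagen_frac = 0.12, fat_frac = 0.07,
                                   n_vessels = 2, rng_seed = 4L))
  lab <- syn$truth$class_mask$labels
  cls <- psr_classes()
  n_tissue <- sum(lab %in% cls[c("collagen", "fat", "myocyte")])
  counted <- c(collagen = sum(lab == cls[["collagen"]]),
               fat = sum(lab == cls[["fat"]]),
               myocyte = sum(lab == cls[["myocyte"]])) / n_tissue
  expect_equal(syn$truth$true_fracs, counted, tolerance = 0)
  expect_equal(sum(syn$truth$true_fracs), 1, tolerance = 1e-9)
})

test_that("requested fractions are realized within placement tolerance", {
  syn0 <- generate_slide(slide_spec(width_px = 256, height_px = 256,
                                    collagen_frac = 0.15, fat_frac = 0,
                                    n_vessels = 0, rng_seed = 2L))
  expect_identical(unname(syn0$truth$true_fracs[["fat"]]), 0)
  expect_lt(abs(syn0$truth$true_fracs[["collagen"]] - 0.15), 0.02)

  syn1 <- generate_slide(slide_spec(width_px = 256, height_px = 256,
                                    collagen_frac = 0.152, fat_frac = 0.05,
                                    n_vessels = 2, rng_seed = 3L))
  expect_lt(abs(syn1$truth$true_fracs[["collagen"]] - 0.152), 0.02)
})

test_that("masks are mutually consistent and structures stay off the border", {
  syn <- generate_slide(slide_spec(width_px = 192, height_px = 192,
                                   collagen_frac = 0.1, fat_frac = 0.08,
                                   n_vessels = 2, rng_seed = 6L))
  lab <- syn$truth$class_mask$labels
  cls <- psr_classes()
  expect_true(all(lab[syn$truth$lumen_mask] == cls[["background"]]))
  expect_true(all(lab[syn$truth$perivascular_mask] == cls[["collagen"]]))
  fat <- lab == cls[["fat"]]
  expect_false(any(fat[1, ]) || any(fat[nrow(fat), ]) ||
                 any(fat[, 1]) || any(fat[, ncol(fat)]))
  # enclosed: every fat component is surrounded by tissue, not background
  edge_touch <- fat[2, ] | fat[nrow(fat) - 1L, ] | fat[, 2] | fat[, ncol(fat) - 1L]
  expect_false(any(edge_touch))
})

test_that("unattainable geometry fails explicitly instead of truncating", {
  expect_error(generate_slide(slide_spec(width_px = 64, height_px = 64,
                                         collagen_frac = 0.05,
                                         fat_frac = 0.6, n_vessels = 0,
                                         rng_seed = 1L)),
               "unattainable")
})

test_that("invalid slide specs are rejected", {
  expect_error(slide_spec(collagen_frac = 0.7, fat_frac = 0.4), "< 1")
  expect_error(slide_spec(width_px = 32), "64")
  expect_error(slide_spec(fat_frac = 1), "fat_frac")
})

test_that("slide images round-trip through TIFF and PNG", {
  syn <- generate_slide(slide_spec(width_px = 96, height_px = 96,
                                   collagen_frac = 0.1, fat_frac = 0,
                                   n_vessels = 0, rng_seed = 5L))
  for (ext in c("tif", "png")) {
    f <- tempfile(fileext = paste0(".", ext))
    write_slide(syn$slide, f)
    back <- read_slide(f)
    expect_equal(back$um_per_px, syn$slide$um_per_px)
    expect_equal(back$pixels, syn$slide$pixels, tolerance = 1 / 254)
  }
})
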