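test_that("a uniform stain-coloured image is labelled entirely one class", {
  img <- array(rep(c(0.71, 0.12, 0.16), each = 64 * 64), c(64, 64, 3))
  map <- classify_pixels(img, um_per_px = 2)
  expect_identical(unname(class_counts(map)[["collagen"]]), 64L * 64L)
})

test_that("classification recovers generator truth away from class boundaries", {
  syn <- generate_slide(slide_spec(width_px = 384, height_px = 384,
                                   collagen_frac = 0.15, fat_frac = 0.08,
                                   n_vessels = 2, rng_seed = 21L))
  map <- classify_pixels(syn$slide)
  truth <- syn$truth$class_mask$labels
  cls <- psr_classes()
  # provisional truth: fat vacuoles are still background at this stage
  truth[truth == cls[["fat"]]] <- cls[["background"]]
  # non-boundary pixels: 4-neighbourhood all same true class
  nr <- nrow(truth); nc <- ncol(truth)
  interior <- matrix(FALSE, nr, nc)
  interior[2:(nr - 1), 2:(nc - 1)] <-
    truth[2:(nr - 1), 2:(nc - 1)] == truth[1:(nr - 2), 2:(nc - 1)] &
    truth[2:(nr - 1), 2:(nc - 1)] == truth[3:nr, 2:(nc - 1)] &
    truth[2:(nr - 1), 2:(nc - 1)] == truth[2:(nr - 1), 1:(nc - 2)] &
    truth[2:(nr - 1), 2:(nc - 1)] == truth[2:(nr - 1), 3:nc]
  agreement <- mean((map$labels == truth)[interior])
  expect_gte(agreement, 0.99)
})

test_that("pixel assignment matches an exhaustive band-plus-nearest oracle", {
  # mixed colours: some inside a band, several inside none (greys, dark and
  # desaturated mixes) that must fall through to nearest-centre assignment
  cols <- rbind(c(0.55, 0.05, 0.08), c(0.40, 0.30, 0.28), c(0.05, 0.05, 0.05),
                c(0.55, 0.52, 0.50), c(0.30, 0.25, 0.60), c(0.20, 0.45, 0.25),
                c(0.45, 0.40, 0.35), c(0.45, 0.10, 0.40), c(0.70, 0.68, 0.40),
                c(0.12, 0.30, 0.45))
  img <- array(NA_real_, c(1, 10, 3))
  for (i in 1:10) img[1, i, ] <- cols[i, ]
  bands <- default_color_bands()
  map <- classify_pixels(img, bands, um_per_px = 1)

  # exhaustive per-pixel oracle: priority band membership, then nearest centre
  cls <- psr_classes()
  in_band <- function(hsv, b) {
    h_ok <- if (b$h[1] > b$h[2]) hsv[1] >= b$h[1] || hsv[1] <= b$h[2]
            else hsv[1] >= b$h[1] && hsv[1] <= b$h[2]
    h_ok && hsv[2] >= b$s[1] && hsv[2] <= b$s[2] &&
      hsv[3] >= b$v[1] && hsv[3] <= b$v[2]
  }
  expected <- integer(10)
  n_fallthrough <- 0L
  for (i in 1:10) {
    hsv <- as.vector(grDevices::rgb2hsv(cols[i, 1], cols[i, 2], cols[i, 3],
                                        maxColorValue = 1))
    best_class <- NA_character_
    for (nm in bands$priority)
      if (is.na(best_class) && in_band(hsv, bands$bands[[nm]])) best_class <- nm
    if (is.na(best_class)) {
      n_fallthrough <- n_fallthrough + 1L
      best <- Inf
      for (nm in bands$priority) {
        ct <- bands$centers[[nm]]
        hd <- abs(hsv[1] - ct[1]); hd <- min(hd, 1 - hd)
        d2 <- (2 * hd)^2 + (hsv[2] - ct[2])^2 + (hsv[3] - ct[3])^2
        if (d2 < best) { best <- d2; best_class <- nm }
      }
    }
    expected[i] <- cls[[best_class]]
  }
  expect_gte(n_fallthrough, 5L)  # the nearest-centre branch is exercised
  expect_identical(as.vector(map$labels), expected)
})

test_that("classification is deterministic and preserves the pixel count", {
  syn <- generate_slide(slide_spec(width_px = 128, height_px = 128,
                                   collagen_frac = 0.1, fat_frac = 0.05,
                                   n_vessels = 1, rng_seed = 8L))
  m1 <- classify_pixels(syn$slide)
  m2 <- classify_pixels(syn$slide)
  expect_identical(m1$labels, m2$labels)
  expect_identical(sum(class_counts(m1)), 128L * 128L)
  m3 <- detect_fat(m1)
  expect_identical(sum(class_counts(m3)), 128L * 128L)
})

test_that("enlarging a class's band never shrinks that class", {
  syn <- generate_slide(slide_spec(width_px = 128, height_px = 128,
                                   collagen_frac = 0.12, fat_frac = 0,
                                   n_vessels = 0, rng_seed = 13L))
  narrow <- default_color_bands()
  wide <- narrow
  wide$bands$collagen$h <- c(0.80, 0.15)
  wide$bands$collagen$s <- c(0.10, 1)
  n_narrow <- class_counts(classify_pixels(syn$slide, narrow))[["collagen"]]
  n_wide <- class_counts(classify_pixels(syn$slide, wide))[["collagen"]]
  expect_gte(n_wide, n_narrow)
})

test_that("malformed images are rejected explicitly", {
  expect_error(classify_pixels(array(0, c(4, 4, 2)), um_per_px = 1), "RGB")
  expect_error(classify_pixels(array(0, c(0, 4, 3)), um_per_px = 1), "empty")
  img <- array(0.5, c(4, 4, 3))
  expect_error(classify_pixels(img), "um_per_px")
})
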