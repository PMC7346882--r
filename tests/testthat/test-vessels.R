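test_that("maps without enclosed background yield no candidates", {
  lum <- detect_lumens(slab_map(100L, 100L))
  expect_identical(nrow(lum), 0L)
  # excluding with an empty candidate set is a no-op
  map <- slab_map(100L, 100L)
  expect_identical(exclude_perivascular(map, lum)$labels, map$labels)
})

test_that("vessel lumens are found among fat vacuoles after arbitration", {
  syn <- generate_slide(slide_spec(width_px = 512, height_px = 512,
                                   collagen_frac = 0.10, fat_frac = 0.08,
                                   n_vessels = 5, rng_seed = 31L))
  map <- detect_fat(classify_pixels(syn$slide))
  lum <- detect_lumens(map)
  expect_identical(sum(lum$accepted), 5L)
  # candidates are ordered by centroid row then column
  expect_identical(order(lum$centroid_row, lum$centroid_col),
                   seq_len(nrow(lum)))
})

test_that("non-elliptical enclosed regions are listed but rejected", {
  map <- slab_map(200L, 200L)
  cls <- psr_classes()
  # enclosed L-shaped unstained region, large enough to be a candidate
  map$labels[60:140, 60:75] <- cls[["background"]]
  map$labels[125:140, 60:140] <- cls[["background"]]
  lum <- detect_lumens(map)
  expect_identical(nrow(lum), 1L)
  expect_lt(lum$score, 0.4)
  expect_false(lum$accepted)
})

test_that("raising the score threshold never accepts more lumens", {
  syn <- generate_slide(slide_spec(width_px = 384, height_px = 384,
                                   collagen_frac = 0.1, fat_frac = 0.05,
                                   n_vessels = 3, rng_seed = 17L))
  map <- detect_fat(classify_pixels(syn$slide))
  accepted <- vapply(c(0.2, 0.4, 0.6, 0.8, 0.99), function(th)
    sum(detect_lumens(map, exclusion_params(score_threshold = th))$accepted),
    numeric(1))
  expect_true(all(diff(accepted) <= 0))
})

test_that("perivascular exclusion removes the cuff and nothing else", {
  syn <- generate_slide(slide_spec(width_px = 512, height_px = 512,
                                   collagen_frac = 0.12, fat_frac = 0.05,
                                   n_vessels = 3,
                                   vessel_lumen_radius_px = c(12, 14),
                                   perivascular_cuff_px = 6, rng_seed = 23L))
  map <- detect_fat(classify_pixels(syn$slide))
  before <- class_counts(map)
  lum <- detect_lumens(map)
  out <- exclude_perivascular(map, lum)
  after <- class_counts(out)
  cls <- psr_classes()
  pv <- syn$truth$perivascular_mask
  excl <- out$labels == cls[["excluded_perivascular"]]
  expect_gte(sum(excl & pv) / sum(pv), 0.95)
  n_interstitial <- sum(syn$truth$class_mask$labels == cls[["collagen"]] & !pv)
  expect_lt(sum(excl & !pv) / n_interstitial, 0.01)
  # myocyte and fat pixel counts are never changed by exclusion
  expect_identical(after[["myocyte"]], before[["myocyte"]])
  expect_identical(after[["fat"]], before[["fat"]])
  expect_identical(sum(after), sum(before))
})

test_that("lumens with no adjacent collagen exclude only themselves", {
  map <- slab_map(200L, 200L)
  cls <- psr_classes()
  # bare elliptical lumen directly in myocyte
  for (r in 1:200) for (cl in 1:200)
    if (((r - 100) / 25)^2 + ((cl - 100) / 18)^2 <= 1)
      map$labels[r, cl] <- cls[["background"]]
  lum <- detect_lumens(map)
  expect_true(all(lum$accepted))
  out <- exclude_perivascular(map, lum)
  expect_identical(unname(class_counts(out)[["excluded_perivascular"]]), 0L)
  expect_identical(unname(class_counts(out)[["excluded_lumen"]]),
                   unname(lum$area_px[1]))
})

test_that("overlapping vessel reaches union without double counting", {
  map <- slab_map(260L, 260L, border = 12L)
  map <- paint_vessel(map, 110, 110, 16, 5)
  map <- paint_vessel(map, 110, 170, 16, 5)
  lum <- detect_lumens(map)
  expect_identical(sum(lum$accepted), 2L)
  out <- exclude_perivascular(map, lum)
  cnt <- class_counts(out)
  expect_identical(sum(cnt), 260L * 260L)
  expect_identical(unname(cnt[["collagen"]]), 0L)  # both cuffs fully excluded
})

test_that("exclusion parameters validate their invariants", {
  expect_error(exclusion_params(score_threshold = 1.01), "score_threshold")
  expect_error(exclusion_params(cuff_reach_factor = 0), "cuff_reach")
})
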