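#' Colour model for synthetic PSR slides
#'
#' Per-class RGB centres (in `[0, 1]`) and Gaussian spreads used by
#' [generate_slide()]. Collagen is strong red, myocytes orange-yellow;
#' fat vacuoles, vessel lumens and slide background share one near-white
#' distribution, as on a real PSR slide where all three are unstained.
#'
#' @param collagen,myocyte,white Length-3 RGB centres.
#' @param sd_stain Gaussian SD of stained-class pixels.
#' @param sd_white Gaussian SD of unstained (near-white) pixels.
#' @return A list of class `slide_colors`.
#' @export
slide_colors <- function(collagen = c(0.71, 0.12, 0.16),
                         myocyte = c(0.90, 0.63, 0.24),
                         white = c(0.96, 0.96, 0.96),
                         sd_stain = 0.03, sd_white = 0.02) {
  for (x in list(collagen, myocyte, white))
    if (length(x) != 3L || any(x < 0) || any(x > 1))
      stop("colour centres must be length-3 RGB in [0, 1]")
  if (sd_stain < 0 || sd_white < 0) stop("colour SDs must be >= 0")
  structure(list(collagen = collagen, myocyte = myocyte, white = white,
                 sd_stain = sd_stain, sd_white = sd_white),
            class = "slide_colors")
}

#' Specification of a synthetic PSR slide
#'
#' Describes one synthetic ventricular-myocardium section: a rectangular
#' tissue slab on a near-white background, with elliptical vessel lumens
#' wrapped in perivascular collagen cuffs, enclosed fat vacuoles, and
#' scattered interstitial collagen making up the requested tissue fractions.
#'
#' @param width_px,height_px Image size in pixels (>= 64).
#' @param um_per_px Pixel calibration, micrometres per pixel. The default
#'   (2 um/px) emulates the downsampled overview resolution at which
#'   whole-section morphometry is typically run.
#' @param collagen_frac Target collagen fraction of tissue pixels, in (0, 1);
#'   includes perivascular cuffs.
#' @param fat_frac Target fat fraction of tissue pixels, in `[0, 1)`.
#' @param n_vessels Number of vessels (elliptical lumen + collagen cuff).
#' @param vessel_lumen_radius_px Range `c(lo, hi)` for the lumen semi-major
#'   axis in pixels.
#' @param perivascular_cuff_px Cuff thickness in pixels.
#' @param fat_vacuole_radius_px Range `c(lo, hi)` for vacuole radii in pixels.
#' @param epicardial_side Which tissue edge is the epicardial surface:
#'   `"top"`, `"bottom"`, `"left"` or `"right"`.
#' @param border_px Width of the near-white border around the tissue slab.
#' @param colors A [slide_colors] object.
#' @param rng_seed Integer seed; the same seed reproduces the slide
#'   bit for bit.
#' @return A validated list of class `slide_spec`.
#' @export
slide_spec <- function(width_px = 768, height_px = 768, um_per_px = 2,
                       collagen_frac = 0.10, fat_frac = 0.05, n_vessels = 3,
                       vessel_lumen_radius_px = c(14, 24),
                       perivascular_cuff_px = 6,
                       fat_vacuole_radius_px = c(4, 9),
                       epicardial_side = c("top", "bottom", "left", "right"),
                       border_px = 16, colors = slide_colors(),
                       rng_seed = 1L) {
  epicardial_side <- match.arg(epicardial_side)
  spec <- list(width_px = as.integer(width_px),
               height_px = as.integer(height_px),
               um_per_px = um_per_px, collagen_frac = collagen_frac,
               fat_frac = fat_frac, n_vessels = as.integer(n_vessels),
               vessel_lumen_radius_px = vessel_lumen_radius_px,
               perivascular_cuff_px = perivascular_cuff_px,
               fat_vacuole_radius_px = fat_vacuole_radius_px,
               epicardial_side = epicardial_side,
               border_px = as.integer(border_px), colors = colors,
               rng_seed = as.integer(rng_seed))
  validate_slide_spec(spec)
  structure(spec, class = "slide_spec")
}

validate_slide_spec <- function(s) {
  if (s$width_px < 64L || s$height_px < 64L)
    stop("slide must be at least 64 x 64 px")
  if (s$um_per_px <= 0) stop("um_per_px must be positive")
  if (s$collagen_frac <= 0 || s$collagen_frac >= 1)
    stop("collagen_frac must be in (0, 1)")
  if (s$fat_frac < 0 || s$fat_frac >= 1)
    stop("fat_frac must be in [0, 1)")
  if (s$collagen_frac + s$fat_frac >= 1)
    stop("collagen_frac + fat_frac must be < 1")
  rng_ok <- function(r) length(r) == 2L && all(r > 0) && r[1] <= r[2]
  if (!rng_ok(s$vessel_lumen_radius_px))
    stop("vessel_lumen_radius_px must be c(lo, hi) with 0 < lo <= hi")
  if (!rng_ok(s$fat_vacuole_radius_px))
    stop("fat_vacuole_radius_px must be c(lo, hi) with 0 < lo <= hi")
  if (s$perivascular_cuff_px <= 0) stop("perivascular_cuff_px must be > 0")
  if (s$n_vessels < 0) stop("n_vessels must be >= 0")
  if (s$border_px < 2L) stop("border_px must be >= 2")
  if (!inherits(s$colors, "slide_colors")) stop("colors must be slide_colors()")
  invisible(s)
}

# linear indices of pixels within `radius` of (r0, c0), clipped to the grid
disk_idx <- function(nr, nc, r0, c0, radius) {
  rs <- max(1L, floor(r0 - radius)):min(nr, ceiling(r0 + radius))
  cs <- max(1L, floor(c0 - radius)):min(nc, ceiling(c0 + radius))
  rr <- rep.int(rs, length(cs))
  cc <- rep(cs, each = length(rs))
  keep <- (rr - r0)^2 + (cc - c0)^2 <= radius^2
  (cc[keep] - 1L) * nr + rr[keep]
}

# linear indices of pixels inside an ellipse (pixel-centre test)
ellipse_idx <- function(nr, nc, r0, c0, a, b, theta) {
  ext <- max(a, b)
  rs <- max(1L, floor(r0 - ext)):min(nr, ceiling(r0 + ext))
  cs <- max(1L, floor(c0 - ext)):min(nc, ceiling(c0 + ext))
  rr <- rep.int(rs, length(cs)) - r0
  cc <- rep(cs, each = length(rs)) - c0
  # x along columns, y along rows; theta measured from the column axis
  u <- cc * cos(theta) + rr * sin(theta)
  w <- -cc * sin(theta) + rr * cos(theta)
  keep <- (u / a)^2 + (w / b)^2 <= 1
  ((rep(cs, each = length(rs)) - 1L) * nr + rep.int(rs, length(cs)))[keep]
}

#' Generate a synthetic PSR slide with ground truth
#'
#' Draws a PSR-like section: a rectangular tissue slab of myocytes on a
#' near-white background, `n_vessels` elliptical lumens each wrapped in a
#' perivascular collagen cuff, enclosed near-white fat vacuoles, and
#' interstitial collagen specks placed until the realized collagen pixel
#' count matches the requested fraction. Every pixel's colour is then drawn
#' from its class's distribution ([slide_colors]).
#'
#' Geometry rules: vacuoles and vessels never touch the tissue edge (fat is
#' disambiguated from background by enclosure, and cuffs must be complete),
#' and interstitial collagen is kept clear of the cuffs so perivascular and
#' interstitial collagen are distinct structures, as on a real section.
#'
#' @param spec A [slide_spec].
#' @return A list of class `synthetic_slide` with elements
#'   \describe{
#'     \item{slide}{`slide_image`: RGB pixel array plus `um_per_px`.}
#'     \item{truth}{`slide_truth`: `class_mask` (a [class_map] of true labels,
#'       lumens labelled background), logical `lumen_mask` and
#'       `perivascular_mask`, logical `epicardial_boundary`, and `true_fracs`
#'       — realized collagen/fat/myocyte fractions of tissue pixels, which
#'       always sum to 1.}
#'   }
#' @export
generate_slide <- function(spec) {
  validate_slide_spec(spec)
  with_seed(spec$rng_seed, {
    nr <- spec$height_px; nc <- spec$width_px
    cls <- psr_classes()
    bd <- spec$border_px
    lab <- matrix(cls[["background"]], nr, nc)
    t_rows <- (bd + 1L):(nr - bd); t_cols <- (bd + 1L):(nc - bd)
    lab[t_rows, t_cols] <- cls[["myocyte"]]

    lumen_mask <- matrix(FALSE, nr, nc)
    cuff_mask <- matrix(FALSE, nr, nc)
    occupied <- matrix(TRUE, nr, nc)       # border + placed structures + gap
    occupied[t_rows, t_cols] <- FALSE

    # --- vessels: elliptical lumen + constant-thickness collagen cuff ------
    cuff <- spec$perivascular_cuff_px
    lumen_info <- vector("list", spec$n_vessels)
    if (spec$n_vessels > 0L) {
      for (i in seq_len(spec$n_vessels)) {
        placed <- FALSE
        for (try in seq_len(400L)) {
          a <- stats::runif(1, spec$vessel_lumen_radius_px[1],
                            spec$vessel_lumen_radius_px[2])
          b <- a * stats::runif(1, 0.72, 1)
          th <- stats::runif(1, 0, pi)
          ext <- a + cuff + 3
          lo_r <- bd + ext + 1; hi_r <- nr - bd - ext
          lo_c <- bd + ext + 1; hi_c <- nc - bd - ext
          if (lo_r >= hi_r || lo_c >= hi_c) break
          r0 <- stats::runif(1, lo_r, hi_r); c0 <- stats::runif(1, lo_c, hi_c)
          foot <- disk_idx(nr, nc, r0, c0, ext)
          if (any(occupied[foot])) next
          li <- ellipse_idx(nr, nc, r0, c0, a, b, th)
          ci <- setdiff(ellipse_idx(nr, nc, r0, c0, a + cuff, b + cuff, th), li)
          lab[li] <- cls[["background"]]; lumen_mask[li] <- TRUE
          lab[ci] <- cls[["collagen"]]; cuff_mask[ci] <- TRUE
          occupied[disk_idx(nr, nc, r0, c0, ext + 2)] <- TRUE
          lumen_info[[i]] <- list(center = c(r0, c0), a = a, b = b, theta = th)
          placed <- TRUE
          break
        }
        if (!placed)
          stop("could not place ", spec$n_vessels, " vessels: geometry too crowded")
      }
    }

    n_tissue <- sum(lab == cls[["myocyte"]] | lab == cls[["collagen"]])

    # --- fat vacuoles: enclosed near-white discs ---------------------------
    target_fat <- round(spec$fat_frac * n_tissue)
    min_vac <- floor(pi * spec$fat_vacuole_radius_px[1]^2 * 0.7)
    n_fat <- 0L
    misses <- 0L
    while (target_fat - n_fat >= min_vac) {
      rad <- stats::runif(1, spec$fat_vacuole_radius_px[1],
                          spec$fat_vacuole_radius_px[2])
      # never overshoot the target by more than one smallest vacuole
      rad <- min(rad, sqrt((target_fat - n_fat) / pi) + 1)
      r0 <- stats::runif(1, bd + rad + 2, nr - bd - rad - 1)
      c0 <- stats::runif(1, bd + rad + 2, nc - bd - rad - 1)
      foot <- disk_idx(nr, nc, r0, c0, rad + 2)
      if (any(occupied[foot])) {
        misses <- misses + 1L
        if (misses > 2000L)
          stop("requested fat_frac unattainable at this geometry ",
               "(vacuole packing limit reached)")
        next
      }
      di <- disk_idx(nr, nc, r0, c0, rad)
      lab[di] <- cls[["fat"]]
      occupied[foot] <- TRUE
      n_fat <- n_fat + length(di)
      misses <- 0L
    }

    # --- interstitial collagen: small specks away from the cuffs -----------
    target_col <- round(spec$collagen_frac * n_tissue)
    n_col <- sum(cuff_mask)
    if (n_col > target_col)
      stop("perivascular cuffs alone exceed the requested collagen_frac; ",
           "reduce n_vessels/cuff thickness or raise collagen_frac")
    # keep specks off the cuffs (gap 2 px) so interstitial collagen is never
    # geodesically connected to a vessel
    near_cuff <- cuff_mask
    if (any(cuff_mask)) near_cuff <- dilate8(dilate8(cuff_mask))
    eligible <- lab == cls[["myocyte"]] & !near_cuff
    eligible_idx <- which(eligible)
    while (n_col < target_col) {
      if (!length(eligible_idx))
        stop("requested collagen_frac unattainable: no room left for ",
             "interstitial collagen")
      ctr <- eligible_idx[stats::runif(1, 1, length(eligible_idx) + 1)]
      r0 <- (ctr - 1L) %% nr + 1L; c0 <- (ctr - 1L) %/% nr + 1L
      rad <- stats::runif(1, 1, 3)
      di <- disk_idx(nr, nc, r0, c0, rad)
      di <- di[eligible[di]]
      need <- target_col - n_col
      if (length(di) > need) di <- di[seq_len(need)]
      lab[di] <- cls[["collagen"]]
      eligible[di] <- FALSE
      n_col <- n_col + length(di)
      if (n_col >= target_col || length(di) == 0L)
        eligible_idx <- which(eligible)
    }

    # --- colours ------------------------------------------------------------
    col <- spec$colors
    px <- matrix(0, nr * nc, 3L)
    white_px <- lab == cls[["background"]] | lab == cls[["fat"]]
    for (ch in 1:3) {
      v <- numeric(nr * nc)
      v[white_px] <- stats::rnorm(sum(white_px), col$white[ch], col$sd_white)
      sel <- lab == cls[["collagen"]]
      v[sel] <- stats::rnorm(sum(sel), col$collagen[ch], col$sd_stain)
      sel <- lab == cls[["myocyte"]]
      v[sel] <- stats::rnorm(sum(sel), col$myocyte[ch], col$sd_stain)
      px[, ch] <- pmin(pmax(v, 0), 1)
    }
    img <- array(px, dim = c(nr, nc, 3L))

    # --- epicardial boundary annotation -------------------------------------
    boundary <- matrix(FALSE, nr, nc)
    switch(spec$epicardial_side,
           top = { boundary[t_rows[1], t_cols] <- TRUE },
           bottom = { boundary[t_rows[length(t_rows)], t_cols] <- TRUE },
           left = { boundary[t_rows, t_cols[1]] <- TRUE },
           right = { boundary[t_rows, t_cols[length(t_cols)]] <- TRUE })

    n_tissue_final <- sum(lab == cls[["collagen"]] | lab == cls[["fat"]] |
                            lab == cls[["myocyte"]])
    true_fracs <- c(collagen = sum(lab == cls[["collagen"]]),
                    fat = sum(lab == cls[["fat"]]),
                    myocyte = sum(lab == cls[["myocyte"]])) / n_tissue_final

    structure(list(
      slide = structure(list(pixels = img, um_per_px = spec$um_per_px),
                        class = "slide_image"),
      truth = structure(list(class_mask = class_map(lab, spec$um_per_px),
                             lumen_mask = lumen_mask,
                             perivascular_mask = cuff_mask,
                             epicardial_boundary = boundary,
                             lumens = lumen_info[!vapply(lumen_info, is.null,
                                                         logical(1))],
                             true_fracs = true_fracs),
                        class = "slide_truth"),
      spec = spec
    ), class = "synthetic_slide")
  })
}

#' @export
print.slide_image <- function(x, ...) {
  cat(sprintf("<slide_image> %d x %d px RGB @ %.4g um/px\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$um_per_px))
  invisible(x)
}

#' @export
print.synthetic_slide <- function(x, ...) {
  print(x$slide)
  cat("true fractions:",
      paste(sprintf("%s %.3f", names(x$truth$true_fracs), x$truth$true_fracs),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a slide image to disk
#'
#' 8-bit RGB, TIFF or PNG by file extension. The calibration is stored in a
#' JSON sidecar (`<path>.json`) so a round trip through [read_slide()]
#' preserves it.
#'
#' @param slide A `slide_image`.
#' @param path Output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_slide <- function(slide, path) {
  stopifnot(inherits(slide, "slide_image"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(slide$pixels, path, bits.per.sample = 8L)
  } else if (ext == "png") {
    png::writePNG(slide$pixels, path)
  } else stop("unsupported slide format: .", ext)
  jsonlite::write_json(list(um_per_px = slide$um_per_px),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a slide image written by [write_slide()] (or any RGB TIFF/PNG)
#'
#' @param path Image path.
#' @param um_per_px Calibration override; required if no JSON sidecar exists.
#' @return A `slide_image`.
#' @export
read_slide <- function(path, um_per_px = NULL) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) tiff::readTIFF(path)
         else if (ext == "png") png::readPNG(path)
         else stop("unsupported slide format: .", ext)
  if (length(dim(img)) == 3L && dim(img)[3] > 3L) img <- img[, , 1:3]
  if (is.null(um_per_px)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("no calibration: supply um_per_px or a ", basename(sidecar), " sidecar")
    um_per_px <- jsonlite::read_json(sidecar)$um_per_px
  }
  structure(list(pixels = img, um_per_px = um_per_px), class = "slide_image")
}
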