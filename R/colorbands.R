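#' Colour-band thresholds for PSR pixel classification
#'
#' Defines, per provisional class (`background`, `collagen`, `myocyte`), an
#' inclusion box in a working colour space, a priority order used when a pixel
#' falls inside several boxes, and a class centre used to resolve pixels that
#' fall inside none (nearest centre wins, so the map always partitions the
#' image). Fat is not a colour class: unstained fat vacuoles share the
#' near-white band with background and are resolved geometrically later by
#' [detect_fat()].
#'
#' In the default `hsv` space each band is a list with elements `h`, `s`, `v`,
#' each a `c(lo, hi)` range in `[0, 1]`; a hue range with `lo > hi` wraps
#' around the red point (e.g. `c(0.92, 0.07)`). In the `rgb` dialect the
#' elements are `r`, `g`, `b` ranges in `[0, 1]`.
#'
#' PSR renders collagen fibres strong red, counterstained myocytes
#' orange-yellow, and unstained structures (fat, lumens, slide background)
#' near white, which is what the default bands encode. The defaults are tuned
#' on the synthetic fixtures of [generate_slide()]; real slides require
#' explicit calibration by the user because vendor thresholds are not
#' published.
#'
#' @param bands Named list of per-class band boxes (see Details).
#' @param centers Named list of per-class centres in the working space
#'   (length-3 numeric, ordered as the space's channels).
#' @param priority Character vector: permutation of the class names, first
#'   match wins on overlap.
#' @param space `"hsv"` (default) or `"rgb"`.
#' @return An object of class `color_bands`.
#' @seealso [default_color_bands()], [classify_pixels()]
#' @export
color_bands <- function(bands, centers, priority, space = c("hsv", "rgb")) {
  space <- match.arg(space)
  chans <- if (space == "hsv") c("h", "s", "v") else c("r", "g", "b")
  cls <- c("background", "collagen", "myocyte")
  if (!setequal(names(bands), cls)) stop("bands must cover exactly: ",
                                         paste(cls, collapse = ", "))
  if (!setequal(priority, cls)) stop("priority must be a permutation of the classes")
  if (!setequal(names(centers), cls)) stop("centers must cover every class")
  for (b in bands) {
    if (!setequal(names(b), chans)) stop("each band needs ranges for: ",
                                         paste(chans, collapse = ", "))
    for (r in b) {
      if (length(r) != 2L || any(!is.finite(r)) || any(r < 0) || any(r > 1))
        stop("band ranges must be c(lo, hi) within [0, 1]")
    }
  }
  for (ct in centers) {
    if (length(ct) != 3L || any(!is.finite(ct))) stop("centers must be length-3 numeric")
  }
  structure(list(bands = bands, centers = centers,
                 priority = priority, space = space),
            class = "color_bands")
}

#' Default colour bands for synthetic PSR slides
#'
#' Near-white pixels (low saturation, high value) are provisional background;
#' saturated red hues are collagen; saturated orange-yellow hues are myocyte.
#'
#' @return A [color_bands] object in HSV space.
#' @export
default_color_bands <- function() {
  color_bands(
    bands = list(
      background = list(h = c(0, 1), s = c(0, 0.25), v = c(0.75, 1)),
      collagen   = list(h = c(0.90, 0.055), s = c(0.30, 1), v = c(0.15, 1)),
      myocyte    = list(h = c(0.055, 0.25), s = c(0.30, 1), v = c(0.15, 1))
    ),
    centers = list(
      background = c(0.10, 0.03, 0.96),
      collagen   = c(0.985, 0.83, 0.71),
      myocyte    = c(0.098, 0.74, 0.90)
    ),
    priority = c("background", "collagen", "myocyte"),
    space = "hsv"
  )
}

#' @export
print.color_bands <- function(x, ...) {
  cat(sprintf("<color_bands> space=%s priority=%s\n", x$space,
              paste(x$priority, collapse = " > ")))
  invisible(x)
}

# TRUE where `val` lies in range `r`; hue ranges may wrap (lo > hi)
in_range <- function(val, r, circular = FALSE) {
  if (circular && r[1] > r[2]) val >= r[1] | val <= r[2]
  else val >= r[1] & val <= r[2]
}

# squared distance to a class centre; hue axis is circular, weighted x2 so a
# half-turn of hue counts as much as a full swing of saturation or value
center_dist2 <- function(chan, center, space) {
  if (space == "hsv") {
    hd <- abs(chan[, 1] - center[1]); hd <- pmin(hd, 1 - hd)
    (2 * hd)^2 + (chan[, 2] - center[2])^2 + (chan[, 3] - center[3])^2
  } else {
    (chan[, 1] - center[1])^2 + (chan[, 2] - center[2])^2 +
      (chan[, 3] - center[3])^2
  }
}

#' Classify slide pixels by colour-band thresholds
#'
#' Produces the provisional per-pixel class map: near-white pixels are labelled
#' background (enclosed fat vacuoles are recovered from background later by
#' [detect_fat()]), red-band pixels collagen, orange/yellow-band pixels
#' myocyte. Overlaps are resolved by the band priority order; pixels matching
#' no band are assigned to the nearest class centre in the working colour
#' space, so every pixel receives exactly one label.
#'
#' @param img RGB image array (`rows x cols x 3`, values in `[0, 1]`) or a
#'   `slide_image` from [generate_slide()]/[read_slide()].
#' @param bands A [color_bands] object.
#' @param um_per_px Pixel calibration in micrometres; taken from `img` if it
#'   is a `slide_image`.
#' @return A [class_map] with labels in `{background, collagen, myocyte}`.
#' @export
classify_pixels <- function(img, bands = default_color_bands(),
                            um_per_px = NULL) {
  if (inherits(img, "slide_image")) {
    if (is.null(um_per_px)) um_per_px <- img$um_per_px
    img <- img$pixels
  }
  if (is.null(um_per_px)) stop("`um_per_px` is required when `img` is a bare array")
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("`img` must be an RGB array with dim c(rows, cols, 3)")
  if (any(dim(img)[1:2] == 0L)) stop("`img` is empty")
  stopifnot(inherits(bands, "color_bands"))

  nr <- dim(img)[1]; nc <- dim(img)[2]
  rgbm <- matrix(pmin(pmax(as.vector(img), 0), 1), ncol = 3L)
  chan <- if (bands$space == "hsv") {
    t(grDevices::rgb2hsv(t(rgbm), maxColorValue = 1))
  } else rgbm
  chan_names <- if (bands$space == "hsv") c("h", "s", "v") else c("r", "g", "b")

  cls <- psr_classes()
  lab <- rep.int(NA_integer_, nr * nc)
  # priority order: first band that matches claims the pixel
  for (class_name in bands$priority) {
    b <- bands$bands[[class_name]]
    hit <- rep.int(TRUE, nr * nc)
    for (j in seq_along(chan_names)) {
      circ <- bands$space == "hsv" && chan_names[j] == "h"
      hit <- hit & in_range(chan[, j], b[[chan_names[j]]], circular = circ)
    }
    take <- is.na(lab) & hit
    lab[take] <- cls[[class_name]]
  }
  # out-of-band pixels: nearest class centre in the working space
  rest <- which(is.na(lab))
  if (length(rest)) {
    d <- vapply(bands$priority, function(class_name) {
      center_dist2(chan[rest, , drop = FALSE],
                   bands$centers[[class_name]], bands$space)
    }, numeric(length(rest)))
    d <- matrix(d, nrow = length(rest))
    lab[rest] <- cls[bands$priority[max.col(-d, ties.method = "first")]]
  }
  class_map(matrix(lab, nr, nc), um_per_px)
}
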