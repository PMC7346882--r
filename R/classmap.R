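#' Pixel class labels
#'
#' Integer codes used in a [class_map] label field. Tissue classes are
#' `collagen`, `fat` and `myocyte`; `background` covers unstained pixels that
#' are not enclosed vacuoles (slide background, clefts, unresolved lumens);
#' `excluded_lumen` and `excluded_perivascular` mark vessel lumens and their
#' perivascular collagen cuffs, which are removed from analyzable tissue.
#'
#' @return Named integer vector of the six label codes.
#' @export
psr_classes <- function() {
  c(background = 0L, collagen = 1L, fat = 2L, myocyte = 3L,
    excluded_lumen = 4L, excluded_perivascular = 5L)
}

#' Construct a per-pixel class map
#'
#' A `class_map` is an integer matrix of [psr_classes()] codes with a pixel
#' calibration attached. It is the common currency between classification,
#' vessel exclusion, regional partition and quantification.
#'
#' @param labels Integer matrix of label codes (rows = image rows).
#' @param um_per_px Pixel edge length in micrometres.
#' @return An object of class `class_map`.
#' @export
class_map <- function(labels, um_per_px) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (!all(labels %in% psr_classes()))
    stop("`labels` contains codes outside psr_classes()")
  if (!is.numeric(um_per_px) || length(um_per_px) != 1L || um_per_px <= 0)
    stop("`um_per_px` must be a single positive number")
  structure(list(labels = labels, um_per_px = as.numeric(um_per_px)),
            class = "class_map")
}

#' @export
print.class_map <- function(x, ...) {
  cat(sprintf("<class_map> %d x %d px @ %.4g um/px\n",
              nrow(x$labels), ncol(x$labels), x$um_per_px))
  print(class_counts(x))
  invisible(x)
}

#' @export
dim.class_map <- function(x) dim(x$labels)

#' Count pixels per class label
#'
#' Always returns all six classes (zero counts included) so that label
#' accounting can be checked stage by stage: the counts sum to the total
#' pixel number after every operation.
#'
#' @param map A [class_map].
#' @return Named integer vector over the six classes.
#' @export
class_counts <- function(map) {
  stopifnot(inherits(map, "class_map"))
  cls <- psr_classes()
  cnt <- tabulate(map$labels + 1L, nbins = length(cls))
  names(cnt) <- names(cls)
  cnt
}

# logical mask of tissue pixels (collagen/fat/myocyte); lumens and cuffs are
# not analyzable tissue
tissue_mask <- function(map) {
  cls <- psr_classes()
  map$labels == cls[["collagen"]] | map$labels == cls[["fat"]] |
    map$labels == cls[["myocyte"]]
}

#' Write a class map as a label PNG with a JSON legend
#'
#' The label image is an 8-bit single-channel PNG holding the raw class codes
#' (0..5); the legend maps each code to its class name and records the pixel
#' calibration.
#'
#' @param map A [class_map].
#' @param png_path Output path for the label PNG.
#' @param legend_path Output path for the JSON legend; defaults to the PNG
#'   path with extension `.json`.
#' @return `png_path`, invisibly.
#' @export
write_class_map <- function(map, png_path,
                            legend_path = sub("\\.png$", ".json", png_path)) {
  stopifnot(inherits(map, "class_map"))
  png::writePNG(map$labels / 255, png_path)
  legend <- list(classes = as.list(psr_classes()),
                 um_per_px = map$um_per_px)
  jsonlite::write_json(legend, legend_path, auto_unbox = TRUE, digits = NA)
  invisible(png_path)
}

#' Read a class map written by [write_class_map()]
#'
#' @param png_path Label PNG path.
#' @param legend_path JSON legend path.
#' @return A [class_map].
#' @export
read_class_map <- function(png_path,
                           legend_path = sub("\\.png$", ".json", png_path)) {
  raw <- png::readPNG(png_path)
  if (length(dim(raw)) == 3L) raw <- raw[, , 1L]
  legend <- jsonlite::read_json(legend_path, simplifyVector = TRUE)
  class_map(round(raw * 255), legend$um_per_px)
}
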