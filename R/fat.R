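#' Morphological parameters for fat-vacuole detection
#'
#' Fat shares the near-white colour of slide background, so it is defined
#' geometrically: an unstained region is a fat vacuole only if it is enclosed
#' by tissue (not connected to the image border), its area lies in a
#' plausible adipocyte range, and it is compact (solidity after morphological
#' closing at least `min_solidity`). Areas are in square micrometres so the
#' same parameters work across calibrations.
#'
#' @param min_area,max_area Component area bounds, um^2. Defaults suit
#'   adipocyte-scale vacuoles at overview resolution (about 2 um/px).
#' @param min_solidity Minimum solidity (pixel count / convex-hull area) in
#'   (0, 1].
#' @param closing_radius_px Radius of the morphological closing applied to a
#'   candidate component before the solidity test; 0 disables closing.
#' @return A list of class `fat_morph_params`.
#' @export
fat_morph_params <- function(min_area = 60, max_area = 1100,
                             min_solidity = 0.85, closing_radius_px = 1L) {
  if (!(min_area < max_area)) stop("min_area must be < max_area")
  if (min_solidity <= 0 || min_solidity > 1)
    stop("min_solidity must be in (0, 1]")
  if (closing_radius_px < 0) stop("closing_radius_px must be >= 0")
  structure(list(min_area = min_area, max_area = max_area,
                 min_solidity = min_solidity,
                 closing_radius_px = as.integer(closing_radius_px)),
            class = "fat_morph_params")
}

# solidity of a pixel set: count / convex hull (shoelace) area of the pixel
# centres; degenerate hulls (points, lines) count as fully solid
pixel_solidity <- function(pts) {
  if (nrow(pts) < 4L) return(1)
  h <- grDevices::chull(pts[, 2], pts[, 1])
  hx <- pts[h, 2]; hy <- pts[h, 1]
  area <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
  if (area < 1e-9) return(1)
  min(nrow(pts) / area, 1)
}

#' Relabel enclosed unstained vacuoles as fat
#'
#' Scans the provisional background label for connected components that do
#' not touch the image border, fall inside the configured area window, and
#' are compact after closing, and relabels them as fat. Border-connected
#' near-white regions (slide background, open clefts) stay background, and
#' large enclosed regions are left for lumen detection. Zero detected fat is
#' a valid outcome.
#'
#' @param map A provisional [class_map] from [classify_pixels()].
#' @param params A [fat_morph_params].
#' @return The updated [class_map].
#' @export
detect_fat <- function(map, params = fat_morph_params()) {
  stopifnot(inherits(map, "class_map"), inherits(params, "fat_morph_params"))
  cls <- psr_classes()
  bg <- map$labels == cls[["background"]]
  if (!any(bg)) return(map)
  cc <- EBImage::bwlabel(bg)
  ids <- setdiff(seq_len(max(cc)), border_labels(cc))
  if (!length(ids)) return(map)
  px_area <- map$um_per_px^2
  lo <- params$min_area / px_area; hi <- params$max_area / px_area
  pix <- split(which(cc > 0), cc[cc > 0])
  for (id in ids) {
    idx <- pix[[as.character(id)]]
    n <- length(idx)
    if (n < lo || n > hi) next
    pts <- cbind((idx - 1L) %% nrow(cc) + 1L, (idx - 1L) %/% nrow(cc) + 1L)
    if (params$closing_radius_px > 0L) {
      cpts <- close_component(pts, params$closing_radius_px)
    } else cpts <- pts
    if (pixel_solidity(cpts) < params$min_solidity) next
    map$labels[idx] <- cls[["fat"]]
  }
  map
}

# morphological closing of a component, computed on a padded local window;
# returns the closed component's pixel coordinates (window-local shape only —
# used for the solidity measurement, never for relabelling)
close_component <- function(pts, radius) {
  pad <- radius + 1L
  r0 <- min(pts[, 1]) - pad; c0 <- min(pts[, 2]) - pad
  m <- matrix(FALSE, max(pts[, 1]) - r0 + pad + 1L,
              max(pts[, 2]) - c0 + pad + 1L)
  m[cbind(pts[, 1] - r0, pts[, 2] - c0)] <- TRUE
  brush <- EBImage::makeBrush(2L * radius + 1L, shape = "disc")
  closed <- EBImage::closing(m + 0, brush) > 0.5
  idx <- which(closed)
  cbind((idx - 1L) %% nrow(closed) + 1L + r0,
        (idx - 1L) %/% nrow(closed) + 1L + c0)
}
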