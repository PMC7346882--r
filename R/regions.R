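#' Partition free-wall tissue into equal-area epicardial and endocardial halves
#'
#' Every analyzable-tissue pixel is assigned its Euclidean distance to the
#' annotated epicardial surface; pixels are then ranked by distance and split
#' at the median rank so each half carries 50% of the tissue area. The cut is
#' placed between distance strata (pixels sharing one distance value are
#' never divided), so the two halves differ by at most one stratum. The
#' nearer half is epicardial. Septal samples have no epicardial surface and
#' receive a `whole_only` mask.
#'
#' @param map A [class_map] (fat detected and vessels excluded).
#' @param boundary Logical matrix marking the epicardial surface pixels, the
#'   same size as the map. May be `NULL` for septal samples.
#' @param septal Logical; `TRUE` for septal samples (no partition).
#' @return An integer matrix of class `region_mask`: 0 = not analyzable
#'   tissue, 1 = epicardial, 2 = endocardial, 3 = whole_only; the partition
#'   method is recorded in `attr(, "method")`.
#' @export
partition_epi_endo <- function(map, boundary = NULL, septal = FALSE) {
  stopifnot(inherits(map, "class_map"))
  tis <- tissue_mask(map)
  if (!any(tis)) stop("no analyzable tissue to partition")
  rm <- matrix(0L, nrow(map$labels), ncol(map$labels))
  if (septal) {
    rm[tis] <- 3L
    return(structure(rm, method = "whole_only", class = "region_mask"))
  }
  if (is.null(boundary))
    stop("free-wall sample needs an epicardial boundary annotation")
  if (!is.logical(boundary) || !identical(dim(boundary), dim(map$labels)))
    stop("boundary must be a logical matrix matching the map dimensions")
  if (!any(boundary)) stop("boundary annotation is empty")
  # distance of every pixel to the nearest boundary pixel
  d <- EBImage::distmap(matrix(as.numeric(!boundary),
                               nrow(boundary), ncol(boundary)),
                        metric = "euclidean")
  if (!is.matrix(d)) d <- EBImage::imageData(d)
  dt <- d[tis]
  n <- length(dt)
  # cut between distance strata, as close to n/2 as strata allow
  tab <- table(dt)
  cum <- cumsum(as.integer(tab))
  k <- which.min(abs(cum - n / 2))
  cut_val <- as.numeric(names(tab))[k]
  epi <- tis & d <= cut_val
  rm[epi] <- 1L
  rm[tis & !epi] <- 2L
  structure(rm, method = "equal_area_distance_rank", class = "region_mask")
}

#' Epicardial boundary mask from a named image side
#'
#' Convenience annotation for slab-like sections: marks the outermost tissue
#' pixel of every image column (or row) on the given side.
#'
#' @param map A [class_map].
#' @param side `"top"`, `"bottom"`, `"left"` or `"right"`.
#' @return Logical matrix usable as `boundary` in [partition_epi_endo()].
#' @export
boundary_from_side <- function(map, side = c("top", "bottom", "left", "right")) {
  side <- match.arg(side)
  tis <- tissue_mask(map)
  out <- matrix(FALSE, nrow(tis), ncol(tis))
  if (side %in% c("top", "bottom")) {
    for (j in seq_len(ncol(tis))) {
      rows <- which(tis[, j])
      if (!length(rows)) next
      out[if (side == "top") min(rows) else max(rows), j] <- TRUE
    }
  } else {
    for (i in seq_len(nrow(tis))) {
      cols <- which(tis[i, ])
      if (!length(cols)) next
      out[i, if (side == "left") min(cols) else max(cols)] <- TRUE
    }
  }
  out
}

#' Read an epicardial boundary annotation from a mask PNG
#'
#' Any pixel above 0.5 in the first channel marks the boundary.
#'
#' @param path PNG path.
#' @return Logical matrix.
#' @export
read_boundary_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img > 0.5
}
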