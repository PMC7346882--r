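#' Moment-matched ellipse of a pixel region
#'
#' Fits the ellipse sharing the region's centroid and second-order central
#' moments: semi-axes `a = 2*sqrt(l1)`, `b = 2*sqrt(l2)` from the
#' eigenvalues of the pixel-coordinate covariance matrix, orientation from
#' the principal eigenvector. For a region that is itself a filled ellipse
#' the fit reproduces it (same area, centroid and moments); for arbitrary
#' regions the moments, not the area, are matched — the standard regionprops
#' convention.
#'
#' @param region Logical matrix (pixel mask) or a two-column integer matrix
#'   of (row, col) pixel coordinates.
#' @return List of class `ellipse_params`: `center` (row, col), `semi_major`,
#'   `semi_minor`, `orientation` (radians from the column axis, in `[0, pi)`).
#' @export
fit_ellipse <- function(region) {
  pts <- region_coords(region)
  if (nrow(pts) == 0L) stop("region is empty")
  y <- pts[, 1]; x <- pts[, 2]            # y = rows, x = columns
  my <- mean(y); mx <- mean(x)
  vxx <- mean((x - mx)^2); vyy <- mean((y - my)^2)
  vxy <- mean((x - mx) * (y - my))
  tr <- vxx + vyy
  dt <- sqrt(((vxx - vyy) / 2)^2 + vxy^2)
  l1 <- tr / 2 + dt; l2 <- tr / 2 - dt
  if (l2 <= 1e-12)
    stop("degenerate region: pixels are collinear, no ellipse fit")
  theta <- 0.5 * atan2(2 * vxy, vxx - vyy)
  if (theta < 0) theta <- theta + pi
  structure(list(center = c(my, mx),
                 semi_major = 2 * sqrt(l1), semi_minor = 2 * sqrt(l2),
                 orientation = theta %% pi),
            class = "ellipse_params")
}

#' @export
print.ellipse_params <- function(x, ...) {
  cat(sprintf(
    "<ellipse> center (%.1f, %.1f) a=%.2f b=%.2f theta=%.1f deg\n",
    x$center[1], x$center[2], x$semi_major, x$semi_minor,
    x$orientation * 180 / pi))
  invisible(x)
}

# normalize a region to a 2-column (row, col) coordinate matrix
region_coords <- function(region) {
  if (is.logical(region) && is.matrix(region)) {
    idx <- which(region)
    cbind(row = (idx - 1L) %% nrow(region) + 1L,
          col = (idx - 1L) %/% nrow(region) + 1L)
  } else if (is.matrix(region) && ncol(region) == 2L) {
    storage.mode(region) <- "double"
    region
  } else stop("region must be a logical mask or a 2-column coordinate matrix")
}

#' Elliptical shape score of a pixel region
#'
#' The score used for automated vessel-lumen detection: the
#' intersection-over-union between the region and its moment-matched filled
#' ellipse ([fit_ellipse()]), rasterized at pixel centres. It lies in
#' `[0, 1]`, equals 1 exactly when the region is the rasterization of its own
#' moment ellipse, is invariant under translation and 90-degree rotation, and
#' degrades as the region departs from elliptical shape. Regions whose pixels
#' are collinear score 0 by convention. Lumen candidates scoring at or above
#' the acceptance threshold (0.4 by default) are treated as vessel lumens.
#'
#' This is a reconstruction of the shape criterion: the score formula used by
#' the proprietary software behind the original analyses is unpublished, so
#' this package defines it operationally as IoU against the moment ellipse.
#'
#' @param region Logical mask or 2-column (row, col) coordinate matrix.
#' @return Numeric score in `[0, 1]`.
#' @export
elliptical_score <- function(region) {
  pts <- region_coords(region)
  if (nrow(pts) == 0L) stop("region is empty")
  fit <- tryCatch(fit_ellipse(pts), error = function(e) NULL)
  if (is.null(fit)) return(0)
  ell <- ellipse_pixels(fit)
  key_p <- pts[, 1] * 1e6 + pts[, 2]
  key_e <- ell[, 1] * 1e6 + ell[, 2]
  inter <- sum(key_p %in% key_e)
  inter / (nrow(pts) + nrow(ell) - inter)
}

# integer pixel centres inside an ellipse_params (no grid clipping)
ellipse_pixels <- function(fit) {
  a <- fit$semi_major; b <- fit$semi_minor; th <- fit$orientation
  ext <- max(a, b)
  rs <- floor(fit$center[1] - ext):ceiling(fit$center[1] + ext)
  cs <- floor(fit$center[2] - ext):ceiling(fit$center[2] + ext)
  rr <- rep.int(rs, length(cs)) - fit$center[1]
  cc <- rep(cs, each = length(rs)) - fit$center[2]
  u <- cc * cos(th) + rr * sin(th)
  w <- -cc * sin(th) + rr * cos(th)
  keep <- (u / a)^2 + (w / b)^2 <= 1
  cbind(row = rep.int(rs, length(cs))[keep],
        col = rep(cs, each = length(rs))[keep])
}
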