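# Independent oracles and fixture builders shared across the test files.
# The elliptical-score oracle below recomputes everything from first
# principles (explicit moment sums, closed-form eigen decomposition, pixel
# enumeration with set operations) and shares no helper with the package.

# brute-force intersection-over-union of a region with its moment ellipse
oracle_elliptical_score <- function(mask) {
  idx <- which(mask)
  ys <- (idx - 1L) %% nrow(mask) + 1L
  xs <- (idx - 1L) %/% nrow(mask) + 1L
  n <- length(idx)
  mx <- sum(xs) / n; my <- sum(ys) / n
  sxx <- sum((xs - mx)^2) / n
  syy <- sum((ys - my)^2) / n
  sxy <- sum((xs - mx) * (ys - my)) / n
  # closed-form eigenvalues of the 2x2 covariance
  half_tr <- (sxx + syy) / 2
  root <- sqrt(((sxx - syy) / 2)^2 + sxy^2)
  l1 <- half_tr + root; l2 <- half_tr - root
  if (l2 <= 1e-12) return(0)
  a <- 2 * sqrt(l1); b <- 2 * sqrt(l2)
  th <- 0.5 * atan2(2 * sxy, sxx - syy)
  # enumerate every pixel centre in a window covering region and ellipse
  ext <- ceiling(max(a, b)) + 2L
  rr <- floor(min(ys, my - ext)):ceiling(max(ys, my + ext))
  cc <- floor(min(xs, mx - ext)):ceiling(max(xs, mx + ext))
  region_keys <- paste(ys, xs)
  ell_keys <- character(0)
  for (r in rr) for (cl in cc) {
    dx <- cl - mx; dy <- r - my
    u <- dx * cos(th) + dy * sin(th)
    w <- -dx * sin(th) + dy * cos(th)
    if ((u / a)^2 + (w / b)^2 <= 1) ell_keys <- c(ell_keys, paste(r, cl))
  }
  inter <- length(intersect(region_keys, ell_keys))
  inter / length(union(region_keys, ell_keys))
}

# --- region builders (logical masks on generous canvases) -------------------

mask_canvas <- function(nr, nc) matrix(FALSE, nr, nc)

make_disk_mask <- function(radius, pad = 6L) {
  n <- 2L * (radius + pad) + 1L
  ctr <- radius + pad + 1L
  m <- mask_canvas(n, n)
  for (r in 1:n) for (cl in 1:n)
    if ((r - ctr)^2 + (cl - ctr)^2 <= radius^2) m[r, cl] <- TRUE
  m
}

make_rect_mask <- function(w, h, pad = 6L) {
  m <- mask_canvas(h + 2L * pad, w + 2L * pad)
  m[(pad + 1L):(pad + h), (pad + 1L):(pad + w)] <- TRUE
  m
}

make_ellipse_mask <- function(a, b, theta = 0, pad = 6L) {
  ext <- ceiling(max(a, b)) + pad
  n <- 2L * ext + 1L
  ctr <- ext + 1L
  m <- mask_canvas(n, n)
  for (r in 1:n) for (cl in 1:n) {
    dx <- cl - ctr; dy <- r - ctr
    u <- dx * cos(theta) + dy * sin(theta)
    w <- -dx * sin(theta) + dy * cos(theta)
    if ((u / a)^2 + (w / b)^2 <= 1) m[r, cl] <- TRUE
  }
  m
}

make_L_mask <- function(arm = 40L, thick = 3L, pad = 6L) {
  n <- arm + 2L * pad
  m <- mask_canvas(n, n)
  m[(pad + 1L):(pad + arm), (pad + 1L):(pad + thick)] <- TRUE
  m[(pad + arm - thick + 1L):(pad + arm), (pad + 1L):(pad + arm)] <- TRUE
  m
}

make_notched_disk_mask <- function(radius = 15L, pad = 6L) {
  m <- make_disk_mask(radius, pad)
  ctr <- radius + pad + 1L
  m[1:ctr, ctr:ncol(m)] <- FALSE   # remove one quadrant
  m
}

# --- class-map builders ------------------------------------------------------

# toy map from given class counts laid out left to right on a grid
toy_class_map <- function(counts, nr = 10L, um_per_px = 100) {
  stopifnot(sum(counts) == nr * nr)
  lab <- matrix(rep(psr_classes()[names(counts)], counts), nr, nr)
  class_map(lab, um_per_px)
}

# myocyte slab with border background; optional structures painted on top
slab_map <- function(nr = 200L, nc = 200L, border = 10L, um_per_px = 2) {
  cls <- psr_classes()
  lab <- matrix(cls[["background"]], nr, nc)
  lab[(border + 1L):(nr - border), (border + 1L):(nc - border)] <-
    cls[["myocyte"]]
  class_map(lab, um_per_px)
}

paint_disk <- function(map, r0, c0, radius, class_name) {
  cls <- psr_classes()
  nr <- nrow(map$labels)
  for (r in floor(r0 - radius):ceiling(r0 + radius))
    for (cl in floor(c0 - radius):ceiling(c0 + radius))
      if ((r - r0)^2 + (cl - c0)^2 <= radius^2)
        map$labels[r, cl] <- cls[[class_name]]
  map
}

# a vessel: background lumen disk wrapped in a collagen cuff ring
paint_vessel <- function(map, r0, c0, lumen_radius, cuff_px) {
  map <- paint_disk(map, r0, c0, lumen_radius + cuff_px, "collagen")
  paint_disk(map, r0, c0, lumen_radius, "background")
}
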