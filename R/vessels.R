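#' Parameters for vessel-lumen detection and perivascular exclusion
#'
#' @param score_threshold Minimum [elliptical_score()] for a candidate to be
#'   accepted as a vessel lumen; default 0.4.
#' @param min_lumen_area Minimum candidate area in um^2; enclosed unstained
#'   regions smaller than this are never considered lumens (they are fat or
#'   clefts).
#' @param cuff_reach_factor Perivascular collagen is excluded up to this
#'   multiple of the lumen's equivalent radius (`sqrt(area/pi)`) from the
#'   lumen, measured geodesically within the collagen label. Scaling the
#'   reach with lumen size keeps the exclusion proportionate across the wide
#'   range of vessel calibers seen in sections. Default 2.
#' @return A list of class `exclusion_params`.
#' @export
exclusion_params <- function(score_threshold = 0.4, min_lumen_area = 1600,
                             cuff_reach_factor = 2.0) {
  if (score_threshold <= 0 || score_threshold > 1)
    stop("score_threshold must be in (0, 1]")
  if (min_lumen_area < 0) stop("min_lumen_area must be >= 0")
  if (cuff_reach_factor <= 0) stop("cuff_reach_factor must be > 0")
  structure(list(score_threshold = score_threshold,
                 min_lumen_area = min_lumen_area,
                 cuff_reach_factor = cuff_reach_factor),
            class = "exclusion_params")
}

#' Detect vessel-lumen candidates by elliptical score
#'
#' Candidates are the enclosed background-labelled connected components of at
#' least `min_lumen_area` remaining after fat detection ([detect_fat()] runs
#' first, so small round vacuoles have already been claimed as fat). Each
#' candidate is scored with [elliptical_score()] and accepted when the score
#' reaches `score_threshold`. Candidates are ordered by centroid (row, then
#' column) for reproducible output.
#'
#' @param map A [class_map] after fat detection.
#' @param params An [exclusion_params].
#' @return A data.frame of class `lumen_candidates` with one row per
#'   candidate: `centroid_row`, `centroid_col`, `area_px`, `area_um2`,
#'   `score`, `accepted`; the candidate pixel sets (linear indices into the
#'   label matrix) are in `attr(, "regions")`.
#' @export
detect_lumens <- function(map, params = exclusion_params()) {
  stopifnot(inherits(map, "class_map"), inherits(params, "exclusion_params"))
  cls <- psr_classes()
  bg <- map$labels == cls[["background"]]
  empty <- structure(
    data.frame(centroid_row = numeric(0), centroid_col = numeric(0),
               area_px = integer(0), area_um2 = numeric(0),
               score = numeric(0), accepted = logical(0)),
    regions = list(), class = c("lumen_candidates", "data.frame"))
  if (!any(bg)) return(empty)
  cc <- EBImage::bwlabel(bg)
  ids <- setdiff(seq_len(max(cc)), border_labels(cc))
  if (!length(ids)) return(empty)
  px_area <- map$um_per_px^2
  min_px <- params$min_lumen_area / px_area
  pix <- split(which(cc > 0), cc[cc > 0])
  nr <- nrow(map$labels)
  rows <- lapply(ids, function(id) {
    idx <- pix[[as.character(id)]]
    if (length(idx) < min_px) return(NULL)
    pts <- cbind((idx - 1L) %% nr + 1L, (idx - 1L) %/% nr + 1L)
    sc <- elliptical_score(pts)
    list(centroid_row = mean(pts[, 1]), centroid_col = mean(pts[, 2]),
         area_px = length(idx), area_um2 = length(idx) * px_area,
         score = sc, accepted = sc >= params$score_threshold, idx = idx)
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(empty)
  df <- do.call(rbind, lapply(rows, function(r)
    data.frame(centroid_row = r$centroid_row, centroid_col = r$centroid_col,
               area_px = r$area_px, area_um2 = r$area_um2,
               score = r$score, accepted = r$accepted)))
  ord <- order(df$centroid_row, df$centroid_col)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, regions = lapply(rows, `[[`, "idx")[ord],
            class = c("lumen_candidates", "data.frame"))
}

#' Exclude vessel lumens and their perivascular collagen cuffs
#'
#' Accepted lumens are relabelled `excluded_lumen`. Collagen pixels reachable
#' from the lumen by geodesic dilation *within the collagen label* — so the
#' exclusion follows the cuff and never jumps across myocytes — are relabelled
#' `excluded_perivascular`, up to a geodesic distance of
#' `cuff_reach_factor * sqrt(lumen area / pi)` (8-connected steps). Myocyte
#' and fat pixels are never relabelled, and overlapping reaches of nearby
#' vessels simply union (labels stay exclusive).
#'
#' @param map A [class_map] after fat detection.
#' @param lumens A `lumen_candidates` from [detect_lumens()]; only accepted
#'   rows are used.
#' @param params An [exclusion_params].
#' @return The updated [class_map].
#' @export
exclude_perivascular <- function(map, lumens, params = exclusion_params()) {
  stopifnot(inherits(map, "class_map"), inherits(lumens, "lumen_candidates"))
  cls <- psr_classes()
  regions <- attr(lumens, "regions")
  nr <- nrow(map$labels); nc <- ncol(map$labels)
  for (i in seq_len(nrow(lumens))) {
    if (!lumens$accepted[i]) next
    idx <- regions[[i]]
    reach <- ceiling(params$cuff_reach_factor *
                       sqrt(lumens$area_px[i] / pi))
    pr <- (idx - 1L) %% nr + 1L; pc <- (idx - 1L) %/% nr + 1L
    r1 <- max(1L, min(pr) - reach - 1L); r2 <- min(nr, max(pr) + reach + 1L)
    c1 <- max(1L, min(pc) - reach - 1L); c2 <- min(nc, max(pc) + reach + 1L)
    win <- map$labels[r1:r2, c1:c2]
    seed <- matrix(FALSE, nrow(win), ncol(win))
    seed[cbind(pr - r1 + 1L, pc - c1 + 1L)] <- TRUE
    mask <- seed | win == cls[["collagen"]]
    for (step in seq_len(reach)) {
      grown <- dilate8(seed) & mask
      if (identical(grown, seed)) break
      seed <- grown
    }
    cuff <- seed & win == cls[["collagen"]]
    win[cuff] <- cls[["excluded_perivascular"]]
    map$labels[r1:r2, c1:c2] <- win
    map$labels[idx] <- cls[["excluded_lumen"]]
  }
  map
}

#' Write lumen candidates to CSV
#'
#' @param lumens A `lumen_candidates`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_lumen_candidates <- function(lumens, path) {
  utils::write.csv(as.data.frame(lumens), path, row.names = FALSE)
  invisible(path)
}
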