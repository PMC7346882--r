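#' Analysis grouping of sampled locations
#'
#' Sections are sampled at six ventricular locations; for analysis the right
#' ventricular outflow tract and right ventricular free-wall samples are
#' grouped as RV, and the anterior/posterior septal and left ventricular
#' samples as IVS and LV.
#'
#' @param location Character vector of location labels.
#' @return Character vector of group labels (`RV`, `IVS`, `LV`).
#' @export
location_group <- function(location) {
  groups <- c(RVOT = "RV", RV = "RV", RV_ant = "RV", RV_lat = "RV",
              RV_post = "RV", IVS = "IVS", IVS_ant = "IVS", IVS_post = "IVS",
              LV = "LV", LV_ant = "LV", LV_post = "LV")
  unknown <- setdiff(unique(location), names(groups))
  if (length(unknown))
    stop("unknown location label(s): ", paste(unknown, collapse = ", "))
  unname(groups[location])
}

#' Whether a location lies in the interventricular septum
#'
#' Septal samples have no epicardial surface, so no epi/endo partition.
#'
#' @param location Character vector of location labels.
#' @return Logical vector.
#' @export
is_septal <- function(location) location_group(location) == "IVS"

# one composition row over the analyzable pixels selected by `sel`
composition_row <- function(map, sel, region) {
  cls <- psr_classes()
  lab <- map$labels[sel]
  n_col <- sum(lab == cls[["collagen"]])
  n_fat <- sum(lab == cls[["fat"]])
  n_myo <- sum(lab == cls[["myocyte"]])
  n <- n_col + n_fat + n_myo
  if (n == 0L) stop("zero analyzable tissue in region '", region, "'")
  data.frame(region = region,
             collagen_px = n_col, fat_px = n_fat, myocyte_px = n_myo,
             analyzable_px = n,
             collagen_pct = 100 * n_col / n,
             fat_pct = 100 * n_fat / n,
             myocyte_pct = 100 * n_myo / n,
             tissue_area_mm2 = n * map$um_per_px^2 * 1e-6)
}

#' Compute tissue composition percentages per region
#'
#' Percentages are of *analyzable* tissue: collagen, fat and myocyte pixels,
#' after excluded lumens and perivascular cuffs have been removed from both
#' numerator and denominator (keeping cuffs in the denominator would silently
#' deflate all three percentages). A `total` record is always produced;
#' `epicardial` and `endocardial` records are added when a partitioned
#' [region_mask][partition_epi_endo()] is supplied. Pixel counts are carried
#' in the output so records can be pooled exactly with
#' [aggregate_composition()] (e.g. merging the right ventricular free-wall
#' samples before analysis).
#'
#' @param map A finalized [class_map] (fat detected, vessels excluded).
#' @param regions Optional `region_mask` from [partition_epi_endo()].
#' @param heart_id,location Sample identifiers; `location` must be one of the
#'   labels known to [location_group()].
#' @param covariates Optional named list (e.g. `sex`, `age`, `bmi`) appended
#'   as columns.
#' @return A data.frame of class `composition_records`, one row per region.
#' @export
compute_composition <- function(map, regions = NULL, heart_id = "heart1",
                                location = "RV", covariates = NULL) {
  stopifnot(inherits(map, "class_map"))
  tis <- tissue_mask(map)
  if (!any(tis)) stop("zero analyzable tissue in slide")
  rows <- list(composition_row(map, tis, "total"))
  if (!is.null(regions)) {
    stopifnot(inherits(regions, "region_mask"))
    if (attr(regions, "method") != "whole_only") {
      rows <- c(rows,
                list(composition_row(map, regions == 1L & tis, "epicardial"),
                     composition_row(map, regions == 2L & tis, "endocardial")))
    }
  }
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(heart_id = heart_id, location = location,
                          group = location_group(location)),
               out)
  for (nm in names(covariates)) out[[nm]] <- covariates[[nm]]
  class(out) <- c("composition_records", "data.frame")
  out
}

#' Pool composition records by summing pixel counts
#'
#' Recomputes percentages from summed pixel counts, so pooling the epicardial
#' and endocardial records of one slide reproduces its total record exactly,
#' and pooling the right ventricular free-wall samples of one heart yields
#' the combined-RV record used for analysis.
#'
#' @param records A `composition_records` data.frame (rows may come from
#'   several slides).
#' @param by Character vector of grouping columns, default
#'   `c("heart_id", "group", "region")`.
#' @return A pooled `composition_records` data.frame.
#' @export
aggregate_composition <- function(records,
                                  by = c("heart_id", "group", "region")) {
  stopifnot(is.data.frame(records))
  need <- c(by, "collagen_px", "fat_px", "myocyte_px", "analyzable_px",
            "tissue_area_mm2")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  key <- interaction(records[by], drop = TRUE, lex.order = TRUE)
  agg <- function(v) tapply(v, key, sum)
  out <- unique(records[by])
  out <- out[order(interaction(out[by], drop = TRUE, lex.order = TRUE)), ,
             drop = FALSE]
  out$collagen_px <- as.vector(agg(records$collagen_px))
  out$fat_px <- as.vector(agg(records$fat_px))
  out$myocyte_px <- as.vector(agg(records$myocyte_px))
  out$analyzable_px <- as.vector(agg(records$analyzable_px))
  out$collagen_pct <- 100 * out$collagen_px / out$analyzable_px
  out$fat_pct <- 100 * out$fat_px / out$analyzable_px
  out$myocyte_pct <- 100 * out$myocyte_px / out$analyzable_px
  out$tissue_area_mm2 <- as.vector(agg(records$tissue_area_mm2))
  # carry per-heart covariates through when they are constant within groups
  for (nm in intersect(c("sex", "age", "bmi"), names(records))) {
    v <- tapply(records[[nm]], key, function(x)
      if (length(unique(x)) == 1L) x[1] else NA)
    out[[nm]] <- if (is.factor(records[[nm]]) || is.character(records[[nm]]))
      as.character(v) else as.numeric(v)
  }
  rownames(out) <- NULL
  class(out) <- c("composition_records", "data.frame")
  out
}

#' Reshape composition records to the long study-table schema
#'
#' One row per (heart, location/group, region, component) with `value_pct`,
#' the schema shared with [generate_study()] and accepted by
#' [fit_composition_mlm()].
#'
#' @param records A `composition_records` data.frame.
#' @param location_col Column to report as `location` (default `"group"`).
#' @return A long-format data.frame.
#' @export
composition_to_long <- function(records, location_col = "group") {
  comps <- c(collagen = "collagen_pct", fat = "fat_pct", myocyte = "myocyte_pct")
  out <- do.call(rbind, lapply(names(comps), function(comp) {
    data.frame(heart_id = records$heart_id,
               location = records[[location_col]],
               region = records$region,
               component = comp,
               value_pct = records[[comps[[comp]]]])
  }))
  for (nm in intersect(c("sex", "age", "bmi"), names(records)))
    out[[nm]] <- rep(records[[nm]], length(comps))
  rownames(out) <- NULL
  out
}
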