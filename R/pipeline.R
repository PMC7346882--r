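#' Run the full pipeline on one slide
#'
#' classify -> fat detection -> lumen detection -> perivascular exclusion ->
#' regional partition -> composition. Each stage's pixel accounting is kept
#' so label conservation can be audited.
#'
#' @param slide A `slide_image` or a path readable by [read_slide()].
#' @param config A `pipeline_config`.
#' @param heart_id,location Sample identifiers.
#' @param boundary Epicardial boundary: logical matrix, a side name
#'   (`"top"`, ...) resolved with [boundary_from_side()], or `NULL`.
#'   Required for free-wall locations; ignored for septal ones.
#' @param covariates Optional named list passed to [compute_composition()].
#' @return List of class `slide_result`: `map` (final [class_map]), `lumens`,
#'   `regions`, `records`, `accounting` (per-stage class counts).
#' @export
process_slide <- function(slide, config = pipeline_config(),
                          heart_id = "heart1", location = "RV",
                          boundary = NULL, covariates = NULL) {
  validate_pipeline_config(config)
  if (is.character(slide)) slide <- read_slide(slide, um_per_px = config$um_per_px)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("slide %s/%s, stage %s: %s", heart_id, location, name,
                   conditionMessage(e)), call. = FALSE))
  }
  acct <- list()
  map <- stage("classify", classify_pixels(slide, config$color_bands))
  acct$classify <- class_counts(map)
  map <- stage("fat", detect_fat(map, config$fat))
  acct$fat <- class_counts(map)
  lumens <- stage("lumens", detect_lumens(map, config$exclusion))
  map <- stage("exclude", exclude_perivascular(map, lumens, config$exclusion))
  acct$exclude <- class_counts(map)
  septal <- is_septal(location)
  if (!septal && is.character(boundary))
    boundary <- boundary_from_side(map, boundary)
  regions <- stage("partition",
                   partition_epi_endo(map, boundary = boundary,
                                      septal = septal))
  records <- stage("composition",
                   compute_composition(map, regions, heart_id = heart_id,
                                       location = location,
                                       covariates = covariates))
  structure(list(map = map, lumens = lumens, regions = regions,
                 records = records, accounting = acct),
            class = "slide_result")
}

#' Run the slide-to-statistics pipeline on a set of slides
#'
#' Processes every slide with [process_slide()], pools records per heart and
#' analysis group (merging the right ventricular free-wall samples), fits the
#' multilevel model per component, and derives geometric-mean predictions and
#' the configured ratio contrasts. Deterministic: identical config and
#' inputs give identical outputs, and the report records the config hash,
#' seed, per-stage pixel accounting and every lumen candidate.
#'
#' @param config A `pipeline_config`; validated before any image is read.
#' @param slides List of slide entries; each a list with elements `slide`
#'   (a `slide_image` or path), `heart_id`, `location`, optional `boundary`
#'   (matrix or side name) and optional covariates `sex`, `age`, `bmi`.
#' @param out_dir Optional output directory; when given, composition,
#'   predictions, ratios and candidate CSVs plus `report.json` and per-slide
#'   label PNGs are written there.
#' @return List of class `pipeline_result`: `records` (per-slide),
#'   `pooled`, `table` (long format), `fits`, `predictions`, `ratios`,
#'   `report`.
#' @export
run_pipeline <- function(config, slides, out_dir = NULL) {
  validate_pipeline_config(config)
  if (!length(slides)) stop("no slides supplied")
  for (i in seq_along(slides)) {
    s <- slides[[i]]
    if (is.null(s$heart_id) || is.null(s$location))
      stop("slide entry ", i, " lacks heart_id/location")
    if (!is_septal(s$location) && is.null(s$boundary))
      stop("free-wall slide ", s$heart_id, "/", s$location,
           " lacks an epicardial boundary annotation")
  }

  results <- lapply(slides, function(s) {
    cov <- s[intersect(c("sex", "age", "bmi"), names(s))]
    process_slide(s$slide, config, heart_id = s$heart_id,
                  location = s$location, boundary = s$boundary,
                  covariates = if (length(cov)) cov else NULL)
  })
  records <- do.call(rbind, lapply(results, `[[`, "records"))
  pooled <- aggregate_composition(records)
  table <- composition_to_long(pooled)

  fits <- list(); predictions <- NULL; ratios <- NULL
  for (comp in intersect(c("collagen", "fat", "myocyte"),
                         unique(table$component))) {
    fit <- withCallingHandlers(
      fit_composition_mlm(table, comp,
                          covariates = config$stats$covariates,
                          zero_action = config$stats$zero_action,
                          reml = config$stats$reml),
      warning = function(w) invokeRestart("muffleWarning"))
    fits[[comp]] <- fit
    predictions <- rbind(predictions, predict_geometric_means(fit))
    for (ct in config$stats$contrasts) {
      if (all(ct %in% fit$cells$cell))
        ratios <- rbind(ratios, contrast_ratio(fit, ct[1], ct[2]))
    }
  }

  report <- list(
    config_hash = config_hash(config),
    rng_seed = config$rng_seed,
    n_slides = length(slides),
    slides = lapply(seq_along(slides), function(i) list(
      heart_id = slides[[i]]$heart_id, location = slides[[i]]$location,
      accounting = lapply(results[[i]]$accounting, as.list),
      n_lumen_candidates = nrow(results[[i]]$lumens),
      n_lumens_accepted = sum(results[[i]]$lumens$accepted))))

  out <- structure(list(records = records, pooled = pooled, table = table,
                        fits = fits, predictions = predictions,
                        ratios = ratios, report = report,
                        results = results),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(out, slides, out_dir)
  out
}

write_pipeline_result <- function(out, slides, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(out$records, file.path(out_dir, "composition.csv"),
                   row.names = FALSE)
  utils::write.csv(out$pooled, file.path(out_dir, "composition_pooled.csv"),
                   row.names = FALSE)
  utils::write.csv(out$table, file.path(out_dir, "study_table.csv"),
                   row.names = FALSE)
  utils::write.csv(out$predictions, file.path(out_dir, "predictions.csv"),
                   row.names = FALSE)
  if (!is.null(out$ratios))
    utils::write.csv(out$ratios, file.path(out_dir, "ratios.csv"),
                     row.names = FALSE)
  cand <- do.call(rbind, lapply(seq_along(out$results), function(i)
    if (nrow(out$results[[i]]$lumens))
      cbind(heart_id = slides[[i]]$heart_id,
            location = slides[[i]]$location,
            as.data.frame(out$results[[i]]$lumens))))
  if (!is.null(cand))
    utils::write.csv(cand, file.path(out_dir, "lumen_candidates.csv"),
                     row.names = FALSE)
  jsonlite::write_json(out$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (i in seq_along(out$results))
    write_class_map(out$results[[i]]$map,
                    file.path(out_dir, sprintf("classmap_%s_%s.png",
                                               slides[[i]]$heart_id,
                                               slides[[i]]$location)))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d slides, %d pooled records\n",
              x$report$n_slides, nrow(x$pooled)))
  if (!is.null(x$ratios)) print(x$ratios, digits = 3)
  invisible(x)
}

#' Write the documented synthetic fixture set
#'
#' Builds the small reference fixture used by the test suite: three hearts,
#' each with an RV free-wall, a septal and an LV free-wall slide (256 px,
#' composition targets taken from [reference_composition()] totals), plus a
#' simulated 29-heart study table, and a manifest of MD5 checksums of the
#' text outputs (CSV/JSON; image bytes depend on the compression library and
#' are not manifested).
#'
#' @param dir Output directory.
#' @param seed Integer seed; the default seed reproduces the committed
#'   manifest byte for byte.
#' @return Invisibly, the manifest data.frame (`file`, `md5`).
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ref <- reference_composition()
  tot <- function(comp, loc)
    ref$geometric_mean[ref$component == comp & ref$location == loc &
                         ref$region == "total"] / 100
  locs <- c(RV = "RV", IVS = "IVS_ant", LV = "LV_ant")
  truths <- list()
  for (h in 1:3) {
    for (g in names(locs)) {
      spec <- slide_spec(width_px = 256, height_px = 256,
                         collagen_frac = tot("collagen", g),
                         fat_frac = tot("fat", g),
                         n_vessels = 1L,
                         vessel_lumen_radius_px = c(12, 16),
                         perivascular_cuff_px = 4,
                         rng_seed = seed + 97L * h + 7L * match(g, names(locs)))
      syn <- generate_slide(spec)
      stem <- sprintf("H%02d_%s", h, locs[[g]])
      write_slide(syn$slide, file.path(dir, paste0(stem, ".png")))
      png::writePNG(syn$truth$epicardial_boundary * 1,
                    file.path(dir, paste0(stem, "_boundary.png")))
      truths[[stem]] <- as.list(round(syn$truth$true_fracs, 6))
    }
  }
  jsonlite::write_json(truths, file.path(dir, "slide_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_study_csv(generate_study(study_spec(rng_seed = seed)),
                  file.path(dir, "study.csv"))
  write_pipeline_config(pipeline_config(rng_seed = seed),
                        file.path(dir, "config.yaml"))
  text_files <- sort(c("slide_truth.json", "study.csv", "config.yaml"))
  manifest <- data.frame(file = text_files,
                         md5 = unname(tools::md5sum(file.path(dir, text_files))))
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
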