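#' Pipeline configuration
#'
#' Bundles every tunable of the slide-to-statistics pipeline: colour bands,
#' fat morphology, vessel-exclusion parameters, pixel calibration, statistics
#' options and the seed. Section provenance (nominal section thickness,
#' scan magnification) is carried as metadata only — it does not enter any
#' computation.
#'
#' @param color_bands A [color_bands] object.
#' @param fat A [fat_morph_params].
#' @param exclusion An [exclusion_params].
#' @param um_per_px Pixel calibration of the input slides.
#' @param stats List: `covariates` (character or NULL), `zero_action`
#'   (`"replace"`/`"error"`), `reml` (logical), `contrasts` (list of
#'   `c(cell_a, cell_b)` pairs).
#' @param metadata Provenance list (free-form scalars).
#' @param rng_seed Integer seed for any stochastic step.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(color_bands = default_color_bands(),
                            fat = fat_morph_params(),
                            exclusion = exclusion_params(),
                            um_per_px = 2,
                            stats = list(covariates = NULL,
                                         zero_action = "replace",
                                         reml = TRUE,
                                         contrasts = list(
                                           c("RV:total", "IVS:total"),
                                           c("RV:total", "LV:total"))),
                            metadata = list(section_thickness_um = 5,
                                            magnification = "20x"),
                            rng_seed = 1L) {
  cfg <- structure(list(color_bands = color_bands, fat = fat,
                        exclusion = exclusion, um_per_px = um_per_px,
                        stats = stats, metadata = metadata,
                        rng_seed = as.integer(rng_seed)),
                   class = "pipeline_config")
  validate_pipeline_config(cfg)
}

#' Validate a pipeline configuration
#'
#' Re-runs every owning type's validation (colour bands, fat morphology,
#' exclusion parameters, stats options). Called by [run_pipeline()] before
#' any image is read, so an invalid configuration fails fast.
#'
#' @param cfg A `pipeline_config`.
#' @return `cfg`, invisibly, or an error.
#' @export
validate_pipeline_config <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) stop("not a pipeline_config")
  with(cfg$color_bands, color_bands(bands, centers, priority, space))
  with(cfg$fat, fat_morph_params(min_area, max_area, min_solidity,
                                 closing_radius_px))
  with(cfg$exclusion, exclusion_params(score_threshold, min_lumen_area,
                                       cuff_reach_factor))
  if (cfg$um_per_px <= 0) stop("um_per_px must be positive")
  if (!cfg$stats$zero_action %in% c("replace", "error"))
    stop("stats$zero_action must be 'replace' or 'error'")
  if (!is.logical(cfg$stats$reml)) stop("stats$reml must be logical")
  for (ct in cfg$stats$contrasts)
    if (length(ct) != 2L) stop("each contrast must be c(cell_a, cell_b)")
  invisible(cfg)
}

# strip classes recursively so yaml serializes plain lists
strip_s3 <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_s3)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Write / read a pipeline configuration as YAML
#'
#' The YAML file round-trips: reading it back reconstructs an equivalent
#' validated `pipeline_config`.
#'
#' @param cfg A `pipeline_config`.
#' @param path YAML file path.
#' @return `path` (write) or the `pipeline_config` (read).
#' @export
write_pipeline_config <- function(cfg, path) {
  validate_pipeline_config(cfg)
  writeLines(yaml::as.yaml(strip_s3(unclass(cfg)), precision = 15), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cb <- y$color_bands
  pipeline_config(
    color_bands = color_bands(cb$bands, cb$centers,
                              unlist(cb$priority), cb$space),
    fat = do.call(fat_morph_params, y$fat),
    exclusion = do.call(exclusion_params, y$exclusion),
    um_per_px = y$um_per_px,
    stats = list(covariates = if (length(y$stats$covariates))
                   unlist(y$stats$covariates) else NULL,
                 zero_action = y$stats$zero_action,
                 reml = y$stats$reml,
                 contrasts = lapply(y$stats$contrasts, unlist)),
    metadata = y$metadata,
    rng_seed = y$rng_seed)
}

#' Hash of a pipeline configuration
#'
#' MD5 of the canonical YAML serialization; recorded in every pipeline
#' report so outputs from different configurations are distinguishable.
#'
#' @param cfg A `pipeline_config`.
#' @return Character MD5 hash.
#' @export
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_pipeline_config(cfg, f)
  unname(tools::md5sum(f))
}
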