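#' Reference tissue composition of normal ventricular myocardium
#'
#' Geometric-mean collagen, fat and myocyte percentages of analyzable tissue
#' area in structurally normal adult hearts, by location (RV, IVS, LV) and
#' region (total; epicardial/endocardial for the free walls — the septum has
#' no epicardial surface). These reference values are the default simulation
#' truth for [study_spec()].
#'
#' @return data.frame with columns `component`, `location`, `region`,
#'   `geometric_mean` (percent of analyzable tissue area).
#' @export
reference_composition <- function() {
  df <- rbind(
    data.frame(component = "collagen",
               location = c("RV", "IVS", "LV", "RV", "LV", "RV", "LV"),
               region = c("total", "total", "total", "epicardial",
                          "epicardial", "endocardial", "endocardial"),
               geometric_mean = c(15.2, 8.6, 9.5, 15.9, 9.1, 13.5, 9.5)),
    data.frame(component = "fat",
               location = c("RV", "IVS", "LV", "RV", "LV", "RV", "LV"),
               region = c("total", "total", "total", "epicardial",
                          "epicardial", "endocardial", "endocardial"),
               geometric_mean = c(12.3, 1.5, 4.7, 20.1, 7.2, 4.5, 2.1)),
    data.frame(component = "myocyte",
               location = c("RV", "IVS", "LV", "RV", "LV", "RV", "LV"),
               region = c("total", "total", "total", "epicardial",
                          "epicardial", "endocardial", "endocardial"),
               geometric_mean = c(65.9, 88.6, 81.2, 52.1, 74.3, 79.5, 86.8)))
  rownames(df) <- NULL
  df
}

#' Specification of a simulated clustered composition study
#'
#' Describes a study of `n_hearts` hearts with several sampling locations per
#' heart: per-cell log-scale means, one shared random intercept per heart,
#' and log-scale residual noise, so every value is log-normal and values from
#' the same heart are correlated. Heart-level covariates (sex, age, BMI) are
#' drawn per heart and can carry optional log-scale effects.
#'
#' @param n_hearts Number of hearts (>= 2).
#' @param fixed_log_means data.frame with columns `component`, `location`,
#'   `region`, `log_mean`. Default: `log()` of [reference_composition()].
#' @param heart_sd SD of the per-heart random intercept (log scale).
#' @param residual_sd Residual SD (log scale).
#' @param covariate_effects Optional named list with any of `sex_female`,
#'   `age`, `bmi`: log-scale coefficients (age and BMI act on centered
#'   values, sex on the female indicator).
#' @param female_frac Fraction of female hearts; exactly
#'   `round(n_hearts * female_frac)` hearts (at least 1) are drawn female so
#'   the sex column is never constant by accident.
#' @param age_mean,age_sd,bmi_mean,bmi_sd Covariate distributions (years;
#'   kg/m^2). Defaults reflect a young-adult non-cardiac-death population.
#' @param rng_seed Integer seed.
#' @return A validated list of class `study_spec`.
#' @export
study_spec <- function(n_hearts = 29L, fixed_log_means = NULL,
                       heart_sd = 0.3, residual_sd = 0.2,
                       covariate_effects = NULL, female_frac = 4 / 29,
                       age_mean = 32.1, age_sd = 9.9,
                       bmi_mean = 28.7, bmi_sd = 7.3, rng_seed = 1L) {
  if (is.null(fixed_log_means)) {
    fixed_log_means <- reference_composition()
    fixed_log_means$log_mean <- log(fixed_log_means$geometric_mean)
    fixed_log_means$geometric_mean <- NULL
  }
  need <- c("component", "location", "region", "log_mean")
  if (!all(need %in% names(fixed_log_means)))
    stop("fixed_log_means needs columns: ", paste(need, collapse = ", "))
  if (n_hearts < 2L) stop("n_hearts must be >= 2")
  if (heart_sd < 0 || residual_sd < 0) stop("SDs must be >= 0")
  if (female_frac < 0 || female_frac > 1) stop("female_frac must be in [0, 1]")
  ok_eff <- c("sex_female", "age", "bmi")
  if (!is.null(covariate_effects) &&
      !all(names(covariate_effects) %in% ok_eff))
    stop("covariate_effects names must be among: ",
         paste(ok_eff, collapse = ", "))
  structure(list(n_hearts = as.integer(n_hearts),
                 fixed_log_means = fixed_log_means, heart_sd = heart_sd,
                 residual_sd = residual_sd,
                 covariate_effects = covariate_effects,
                 female_frac = female_frac, age_mean = age_mean,
                 age_sd = age_sd, bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 rng_seed = as.integer(rng_seed)),
            class = "study_spec")
}

#' Simulate a clustered composition study table
#'
#' One row per (heart, location, region, component):
#' `value_pct = exp(log_mean + heart_intercept + covariate terms + residual)`.
#' The heart intercept is shared across all rows of a heart, inducing the
#' within-heart correlation a multilevel model must account for. All values
#' are positive by construction and log-normal within a cell.
#'
#' @param spec A [study_spec].
#' @return Long-format data.frame: `heart_id`, `location`, `region`,
#'   `component`, `value_pct`, `sex`, `age`, `bmi`.
#' @export
generate_study <- function(spec) {
  stopifnot(inherits(spec, "study_spec"))
  with_seed(spec$rng_seed, {
    n <- spec$n_hearts
    heart_id <- sprintf("H%02d", seq_len(n))
    b <- stats::rnorm(n, 0, spec$heart_sd)
    n_f <- max(1L, min(n - 1L, round(n * spec$female_frac)))
    sex <- rep("male", n)
    sex[sample.int(n, n_f)] <- "female"
    age <- stats::rnorm(n, spec$age_mean, spec$age_sd)
    bmi <- stats::rnorm(n, spec$bmi_mean, spec$bmi_sd)

    cells <- spec$fixed_log_means
    out <- do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(heart_id = heart_id[i], location = cells$location,
                 region = cells$region, component = cells$component,
                 log_mean = cells$log_mean, b = b[i], sex = sex[i],
                 age = age[i], bmi = bmi[i])
    }))
    eff <- spec$covariate_effects
    shift <- rep(0, nrow(out))
    if (!is.null(eff$sex_female)) shift <- shift +
        eff$sex_female * (out$sex == "female")
    if (!is.null(eff$age)) shift <- shift + eff$age * (out$age - spec$age_mean)
    if (!is.null(eff$bmi)) shift <- shift + eff$bmi * (out$bmi - spec$bmi_mean)
    eps <- stats::rnorm(nrow(out), 0, spec$residual_sd)
    out$value_pct <- exp(out$log_mean + out$b + shift + eps)
    out$log_mean <- NULL
    out$b <- NULL
    out[c("heart_id", "location", "region", "component", "value_pct",
          "sex", "age", "bmi")]
  })
}

#' Write / read the long composition study table
#'
#' CSV schema shared by [generate_study()], [composition_to_long()] and
#' [fit_composition_mlm()]: `heart_id, location, region, component,
#' value_pct, sex, age, bmi`.
#'
#' @param table Long-format data.frame.
#' @param path CSV path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_study_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_study_csv
#' @export
read_study_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
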