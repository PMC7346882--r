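#' Fit a multilevel model to log-transformed composition percentages
#'
#' Fits, for one tissue component, a linear mixed model on `log(value_pct)`
#' with cell-mean fixed effects for every observed (location, region) cell,
#' optional heart-level covariates (sex, age, BMI), and a random intercept
#' per heart to account for the clustered structure (several samples per
#' heart). Estimation is REML by default, via \pkg{lme4}. Back-transformed
#' cell estimates are geometric means ([predict_geometric_means()]); cell
#' differences exponentiate to geometric-mean ratios ([contrast_ratio()]).
#'
#' Continuous covariates are centered at their sample means and `sex` is
#' coded with `male` as reference, so cell estimates remain interpretable as
#' log geometric means at reference covariate values.
#'
#' Zero percentages (possible for fat in the septum) have no log. With
#' `zero_action = "replace"` they are replaced by half the smallest positive
#' value of that component, with a warning; `"error"` fails instead, naming
#' the offending rows. Negative values always fail.
#'
#' @param table Long-format study table (see [generate_study()]): columns
#'   `heart_id`, `location`, `region`, `component`, `value_pct`, plus any
#'   covariate columns.
#' @param component Which component to model: `"collagen"`, `"fat"` or
#'   `"myocyte"`.
#' @param covariates Optional character vector among `"sex"`, `"age"`,
#'   `"bmi"`.
#' @param zero_action `"replace"` (default) or `"error"`.
#' @param reml Logical; REML (default) or ML.
#' @return An object of class `psr_mlm`; see [predict_geometric_means()],
#'   [contrast_ratio()], [covariate_tests()], and the `print`, `summary`,
#'   `coef`, `vcov`, `predict` methods.
#' @export
fit_composition_mlm <- function(table, component,
                                covariates = NULL,
                                zero_action = c("replace", "error"),
                                reml = TRUE) {
  zero_action <- match.arg(zero_action)
  need <- c("heart_id", "location", "region", "component", "value_pct")
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("table lacks columns: ", paste(miss, collapse = ", "))
  d <- table[table$component == component, , drop = FALSE]
  if (!nrow(d)) stop("no rows for component '", component, "'")
  if (length(unique(d$heart_id)) < 2L) stop("need at least 2 hearts")
  if (any(d$value_pct < 0))
    stop("negative value_pct in rows: ",
         paste(utils::head(which(d$value_pct < 0), 10), collapse = ", "))
  zero_replacement <- NA_real_
  if (any(d$value_pct == 0)) {
    bad <- which(d$value_pct == 0)
    if (zero_action == "error")
      stop("zero value_pct (no log) in rows: ",
           paste(utils::head(bad, 10), collapse = ", "))
    pos <- d$value_pct[d$value_pct > 0]
    if (!length(pos)) stop("all values are zero for component '", component, "'")
    zero_replacement <- min(pos) / 2
    warning(sprintf(
      "replaced %d zero value(s) of %s with half the smallest positive value (%g)",
      length(bad), component, zero_replacement))
    d$value_pct[bad] <- zero_replacement
  }

  d$cell <- factor(paste(d$location, d$region, sep = ":"))
  d$heart_id <- factor(d$heart_id)
  d$.logv <- log(d$value_pct)

  centers <- list()
  fx_terms <- "0 + cell"
  for (cv in covariates) {
    if (!cv %in% names(d)) stop("covariate column missing: ", cv)
    if (length(unique(d[[cv]])) < 2L)
      stop("collinear fixed effects: covariate '", cv, "' is constant")
    if (cv == "sex") {
      lv <- unique(d$sex)
      ref <- if ("male" %in% lv) "male" else sort(lv)[1]
      d$sex <- factor(d$sex, levels = c(ref, setdiff(sort(lv), ref)))
    } else {
      centers[[cv]] <- mean(d[[cv]])
      d[[cv]] <- d[[cv]] - centers[[cv]]
    }
    fx_terms <- paste(fx_terms, "+", cv)
  }
  fixed_formula <- stats::as.formula(paste(".logv ~", fx_terms))

  # rank check before fitting: collinear covariates are an explicit failure
  X <- stats::model.matrix(fixed_formula, data = d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("collinear fixed effects (constant or aliased): ",
         paste(dropped, collapse = ", "))
  }

  form <- stats::update.formula(fixed_formula, . ~ . + (1 | heart_id))
  fit <- suppressWarnings(lme4::lmer(form, data = d, REML = reml))
  singular <- lme4::isSingular(fit)
  if (singular)
    message("multilevel fit is singular (heart-level variance at boundary)")

  fe <- lme4::fixef(fit)
  vc <- as.matrix(stats::vcov(fit))
  vcs <- lme4::VarCorr(fit)
  cell_names <- sub("^cell", "", grep("^cell", names(fe), value = TRUE))
  cell_idx <- grep("^cell", names(fe))
  est <- fe[cell_idx]
  names(est) <- cell_names
  cov_idx <- setdiff(seq_along(fe), cell_idx)
  parts <- do.call(rbind, strsplit(cell_names, ":", fixed = TRUE))

  structure(list(
    component = component,
    estimates = est,
    cells = data.frame(cell = cell_names, location = parts[, 1],
                       region = parts[, 2]),
    covariate_estimates = fe[cov_idx],
    beta = fe,
    vcov = vc,
    par_names = names(fe),
    cell_par = paste0("cell", cell_names),
    heart_var = as.numeric(vcs$heart_id[1, 1]),
    resid_var = attr(vcs, "sc")^2,
    n_obs = nrow(d),
    n_hearts = nlevels(d$heart_id),
    estimation = if (reml) "REML" else "ML",
    singular = singular,
    covariates = covariates,
    centers = centers,
    zero_replacement = zero_replacement,
    lmer_fit = fit
  ), class = "psr_mlm")
}

#' Assemble a `psr_mlm` from known cell estimates
#'
#' Low-level constructor for worked examples and degenerate checks: builds a
#' fit object directly from log-scale cell estimates (names `location:region`)
#' and an optional fixed-effect covariance matrix (default zero, i.e. the
#' estimates are treated as known constants).
#'
#' @param estimates Named numeric vector of log-scale cell means.
#' @param vcov Covariance matrix of the estimates (default zero matrix).
#' @param component Component label.
#' @param heart_var,resid_var Variance components (default 0).
#' @return A `psr_mlm`.
#' @export
composition_fit <- function(estimates, vcov = NULL, component = "collagen",
                            heart_var = 0, resid_var = 0) {
  if (is.null(names(estimates)) || any(!nzchar(names(estimates))))
    stop("estimates must be named 'location:region'")
  if (is.null(vcov))
    vcov <- matrix(0, length(estimates), length(estimates))
  vcov <- as.matrix(vcov)
  if (!isSymmetric(unname(vcov), tol = 1e-8) ||
      any(eigen(vcov, symmetric = TRUE, only.values = TRUE)$values < -1e-8))
    stop("vcov must be symmetric positive semi-definite")
  nm <- names(estimates)
  parts <- strsplit(nm, ":", fixed = TRUE)
  loc <- vapply(parts, `[`, "", 1)
  reg <- vapply(parts, function(p) if (length(p) > 1) p[2] else "total", "")
  dimnames(vcov) <- list(paste0("cell", nm), paste0("cell", nm))
  structure(list(component = component, estimates = estimates,
                 cells = data.frame(cell = nm, location = loc, region = reg),
                 covariate_estimates = numeric(0),
                 beta = stats::setNames(as.numeric(estimates),
                                        paste0("cell", nm)),
                 vcov = vcov,
                 par_names = paste0("cell", nm),
                 cell_par = paste0("cell", nm),
                 heart_var = heart_var, resid_var = resid_var,
                 n_obs = NA_integer_, n_hearts = NA_integer_,
                 estimation = "fixed", singular = FALSE,
                 covariates = NULL, centers = list(),
                 zero_replacement = NA_real_, lmer_fit = NULL),
            class = "psr_mlm")
}

#' @export
print.psr_mlm <- function(x, ...) {
  cat(sprintf("<psr_mlm> %s | %s | %s obs, %s hearts\n", x$component,
              x$estimation, x$n_obs, x$n_hearts))
  cat(sprintf("  heart var %.4g, residual var %.4g%s\n", x$heart_var,
              x$resid_var, if (x$singular) " (singular)" else ""))
  gm <- exp(x$estimates)
  cat("  geometric means (%):\n")
  print(round(gm, 2))
  if (length(x$covariate_estimates)) {
    cat("  covariate effects (log scale):\n")
    print(round(x$covariate_estimates, 4))
  }
  invisible(x)
}

#' @export
coef.psr_mlm <- function(object, ...) {
  c(object$estimates, object$covariate_estimates)
}

#' @export
vcov.psr_mlm <- function(object, ...) object$vcov

#' @export
summary.psr_mlm <- function(object, ...) {
  out <- list(fit = object,
              predictions = predict_geometric_means(object),
              covariate_tests = if (length(object$covariate_estimates))
                covariate_tests(object) else NULL)
  class(out) <- "summary.psr_mlm"
  out
}

#' @export
print.summary.psr_mlm <- function(x, ...) {
  print(x$fit)
  cat("\nGeometric-mean predictions (95% CI):\n")
  print(x$predictions, digits = 3)
  if (!is.null(x$covariate_tests)) {
    cat("\nCovariate Wald tests (log scale):\n")
    print(x$covariate_tests, digits = 3)
  }
  invisible(x)
}

#' @export
predict.psr_mlm <- function(object, ...) predict_geometric_means(object, ...)

# SE of a linear combination l'beta of the fixed effects
lincomb_se <- function(fit, l) {
  as.numeric(sqrt(t(l) %*% fit$vcov %*% l))
}

# contrast vector selecting one cell, covariates at reference (centered
# continuous covariates contribute `at` minus their center)
cell_contrast <- function(fit, cell, at = NULL) {
  l <- numeric(length(fit$par_names))
  names(l) <- fit$par_names
  l[paste0("cell", cell)] <- 1
  for (nm in names(fit$covariate_estimates)) {
    base <- sub("^(sex|age|bmi).*", "\\1", nm)
    if (!is.null(at[[nm]])) {
      l[nm] <- at[[nm]] - (fit$centers[[base]] %||% 0)
    }
  }
  l
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Geometric-mean predictions with confidence intervals
#'
#' Back-transforms each cell's log-scale estimate to the original percentage
#' scale: `geometric_mean = exp(estimate)` with a Wald interval
#' `exp(estimate +/- z * SE)`. When the fit includes covariates, predictions
#' are at reference covariate values (male; age and BMI at their sample
#' means) unless `at` supplies other values on the original covariate scale.
#'
#' @param fit A `psr_mlm`.
#' @param level Confidence level (default 0.95).
#' @param at Optional named list of covariate values for the prediction
#'   point, e.g. `list(sexfemale = 1)` for the female stratum.
#' @return data.frame of class `prediction_table`: `component`, `location`,
#'   `region`, `geometric_mean`, `ci_low`, `ci_high` (all in %).
#' @export
predict_geometric_means <- function(fit, level = 0.95, at = NULL) {
  stopifnot(inherits(fit, "psr_mlm"))
  z <- stats::qnorm(1 - (1 - level) / 2)
  rows <- lapply(seq_len(nrow(fit$cells)), function(i) {
    l <- cell_contrast(fit, fit$cells$cell[i], at = at)
    est <- sum(l * fit$beta[fit$par_names])
    se <- lincomb_se(fit, l)
    data.frame(component = fit$component,
               location = fit$cells$location[i],
               region = fit$cells$region[i],
               geometric_mean = exp(est),
               ci_low = exp(est - z * se), ci_high = exp(est + z * se))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("prediction_table", "data.frame")
  out
}

#' Geometric-mean ratio between two cells
#'
#' The between-location (or between-region) contrast on the original scale:
#' `ratio = exp(est_a - est_b)`, Wald interval from the covariance of the two
#' cell estimates, two-sided Wald p-value. Requesting a cell against itself
#' returns the degenerate ratio 1 with p = 1.
#'
#' @param fit A `psr_mlm`.
#' @param cell_a,cell_b Cell names as `location:region` (e.g. `"RV:total"`).
#' @param level Confidence level.
#' @return One-row data.frame of class `ratio_estimate`: `component`,
#'   `numerator`, `denominator`, `ratio`, `ci_low`, `ci_high`, `p_value`.
#' @export
contrast_ratio <- function(fit, cell_a, cell_b, level = 0.95) {
  stopifnot(inherits(fit, "psr_mlm"))
  for (cell in c(cell_a, cell_b))
    if (!cell %in% fit$cells$cell)
      stop("cell '", cell, "' not in fit; available: ",
           paste(fit$cells$cell, collapse = ", "))
  z <- stats::qnorm(1 - (1 - level) / 2)
  if (identical(cell_a, cell_b)) {
    out <- data.frame(component = fit$component, numerator = cell_a,
                      denominator = cell_b, ratio = 1, ci_low = 1,
                      ci_high = 1, p_value = 1)
    class(out) <- c("ratio_estimate", "data.frame")
    return(out)
  }
  l <- numeric(length(fit$par_names))
  names(l) <- fit$par_names
  l[paste0("cell", cell_a)] <- 1
  l[paste0("cell", cell_b)] <- -1
  diff <- fit$estimates[[cell_a]] - fit$estimates[[cell_b]]
  se <- lincomb_se(fit, l)
  p <- if (se == 0) as.numeric(diff == 0) else
    2 * stats::pnorm(-abs(diff / se))
  out <- data.frame(component = fit$component, numerator = cell_a,
                    denominator = cell_b, ratio = exp(diff),
                    ci_low = exp(diff - z * se),
                    ci_high = exp(diff + z * se), p_value = p)
  class(out) <- c("ratio_estimate", "data.frame")
  out
}

#' Wald tests for covariate effects
#'
#' One row per covariate coefficient in the fit: log-scale estimate, SE,
#' z statistic and two-sided p-value.
#'
#' @param fit A `psr_mlm` fitted with covariates.
#' @return data.frame: `covariate`, `estimate`, `se`, `z`, `p_value`.
#' @export
covariate_tests <- function(fit) {
  stopifnot(inherits(fit, "psr_mlm"))
  if (!length(fit$covariate_estimates))
    stop("fit has no covariates; refit with `covariates = ...`")
  nm <- names(fit$covariate_estimates)
  se <- sqrt(diag(fit$vcov)[nm])
  z <- fit$covariate_estimates / se
  data.frame(covariate = nm, estimate = as.numeric(fit$covariate_estimates),
             se = as.numeric(se), z = as.numeric(z),
             p_value = 2 * stats::pnorm(-abs(as.numeric(z))),
             row.names = NULL)
}
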