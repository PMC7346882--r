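test_that("noise-free data recover the generator log-means exactly", {
  sp <- study_spec(n_hearts = 6, heart_sd = 0, residual_sd = 0, rng_seed = 2L)
  tab <- generate_study(sp)
  ref <- reference_composition()
  for (comp in c("collagen", "fat")) {
    fit <- suppressMessages(fit_composition_mlm(tab, comp))
    rc <- ref[ref$component == comp, ]
    truth <- stats::setNames(log(rc$geometric_mean),
                             paste(rc$location, rc$region, sep = ":"))
    expect_equal(fit$estimates[names(truth)], truth, tolerance = 1e-8)
    # exp/log round trip through the prediction table
    pred <- predict_geometric_means(fit)
    got <- stats::setNames(pred$geometric_mean,
                           paste(pred$location, pred$region, sep = ":"))
    expect_equal(got[names(truth)], exp(truth), tolerance = 1e-8)
  }
})

test_that("the random intercept absorbs between-heart variance", {
  sp <- study_spec(n_hearts = 25, heart_sd = 0.5, residual_sd = 0.15,
                   rng_seed = 42L)
  tab <- generate_study(sp)
  fit <- fit_composition_mlm(tab, "collagen")
  d <- tab[tab$component == "collagen", ]
  d$cell <- paste(d$location, d$region, sep = ":")
  flat <- stats::lm(log(value_pct) ~ 0 + cell, data = d)
  expect_gt(summary(flat)$sigma^2, fit$resid_var)
  expect_gt(fit$heart_var, 0)
})

test_that("ratio contrasts are exp of estimate differences", {
  sp <- study_spec(rng_seed = 12L)
  fit <- fit_composition_mlm(generate_study(sp), "collagen")
  rt <- contrast_ratio(fit, "RV:total", "IVS:total")
  expect_equal(rt$ratio,
               exp(fit$estimates[["RV:total"]] - fit$estimates[["IVS:total"]]),
               tolerance = 1e-12)
  pred <- predict_geometric_means(fit)
  gm <- stats::setNames(pred$geometric_mean,
                        paste(pred$location, pred$region, sep = ":"))
  expect_equal(rt$ratio, unname(gm["RV:total"] / gm["IVS:total"]),
               tolerance = 1e-12)
  expect_true(rt$ci_low <= rt$ratio && rt$ratio <= rt$ci_high)
  same <- contrast_ratio(fit, "RV:total", "RV:total")
  expect_identical(same$ratio, 1)
  expect_identical(same$p_value, 1)
})

test_that("fixed cell estimates give degenerate predictions and ratios", {
  fit <- composition_fit(c("RV:total" = log(15.2), "IVS:total" = log(8.6)))
  pred <- predict_geometric_means(fit)
  rv <- pred[pred$location == "RV", ]
  expect_equal(rv$geometric_mean, 15.2, tolerance = 1e-12)
  expect_equal(rv$ci_low, 15.2, tolerance = 1e-12)
  expect_equal(rv$ci_high, 15.2, tolerance = 1e-12)
  expect_equal(round(contrast_ratio(fit, "RV:total", "IVS:total")$ratio, 2),
               1.77)
})

test_that("larger cell estimates give larger geometric means", {
  f1 <- composition_fit(c("RV:total" = log(10)))
  f2 <- composition_fit(c("RV:total" = log(10) + 0.2))
  expect_gt(predict_geometric_means(f2)$geometric_mean,
            predict_geometric_means(f1)$geometric_mean)
})

test_that("zeros are replaced by half the minimum positive value, or fail", {
  sp <- study_spec(n_hearts = 5, rng_seed = 8L)
  tab <- generate_study(sp)
  idx <- which(tab$component == "fat")[1:2]
  tab$value_pct[idx] <- 0
  expect_warning(fit <- fit_composition_mlm(tab, "fat"), "half the smallest")
  pos <- tab$value_pct[tab$component == "fat" & tab$value_pct > 0]
  expect_equal(fit$zero_replacement, min(pos) / 2, tolerance = 1e-12)
  expect_error(fit_composition_mlm(tab, "fat", zero_action = "error"), "zero")
  tab$value_pct[idx[1]] <- -1
  expect_error(fit_composition_mlm(tab, "fat"), "negative")
})

test_that("constant covariates fail with an explicit collinearity error", {
  sp <- study_spec(n_hearts = 10, rng_seed = 9L)
  tab <- generate_study(sp)
  tab$bmi <- 25
  expect_error(fit_composition_mlm(tab, "collagen", covariates = "bmi"),
               "collinear")
})

test_that("covariate Wald tests detect a real sex effect more often than null", {
  spec_eff <- study_spec(n_hearts = 29,
                         covariate_effects = list(sex_female = log(1.4)))
  hits_eff <- simulate_covariate_type1(spec_eff, "collagen",
                                       covariates = "sex", n_rep = 40,
                                       seed = 400)
  spec_null <- study_spec(n_hearts = 29)
  hits_null <- simulate_covariate_type1(spec_null, "collagen",
                                        covariates = "sex", n_rep = 40,
                                        seed = 500)
  expect_gt(mean(hits_eff$p_value < 0.05), mean(hits_null$p_value < 0.05))
})

test_that("scaling one heart moves its intercept, not the cell means", {
  sp <- study_spec(n_hearts = 12, heart_sd = 0.2, residual_sd = 0,
                   rng_seed = 77L)
  tab <- generate_study(sp)
  fit0 <- suppressMessages(fit_composition_mlm(tab, "collagen"))
  tab2 <- tab
  h1 <- tab2$heart_id == "H01"
  tab2$value_pct[h1] <- tab2$value_pct[h1] * 2
  fit2 <- suppressMessages(fit_composition_mlm(tab2, "collagen"))
  # one of 12 intercepts absorbs log(2): cells shift by log(2)/12 at most
  expect_equal(unname(fit2$estimates - fit0$estimates),
               rep(log(2) / 12, length(fit0$estimates)), tolerance = 1e-4)
  b0 <- lme4::ranef(fit0$lmer_fit)$heart_id
  b2 <- lme4::ranef(fit2$lmer_fit)$heart_id
  expect_gt(b2["H01", 1] - b0["H01", 1], 0.5)
})
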