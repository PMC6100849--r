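test_that("noise-free data on the published line are recovered exactly", {
  pr <- make_profiles_on_line(seq(60, 400, length.out = 20), -2.549, 1.8213)
  fit <- fit_spread(pr)
  expect_equal(fit$intercept, -2.549, tolerance = 1e-9)
  expect_equal(fit$slope, 1.8213, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  expect_error(fit_spread(pr[1:2, ]), ">= 3")
  same <- pr; same$art <- 100
  expect_error(fit_spread(same), "zero variance")
})

test_that("r-squared matches an independent two-pass sums-of-squares oracle", {
  set.seed(42)
  art <- runif(80, 60, 400)
  pr <- make_profiles_on_line(art, -2.549, 1.8213, offset = rnorm(80, 0, 0.3))
  fit <- fit_spread(pr)
  x <- log10(pr$art); y <- log10(pr$n_localities)
  yhat <- fit$intercept + fit$slope * x
  r2_oracle <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  expect_equal(fit$r2, r2_oracle, tolerance = 1e-12)
  # residuals of the fit sum to zero
  expect_lt(abs(sum(residuals(fit))), 1e-9)
})

test_that("confidence bands equal the textbook mean-response interval", {
  set.seed(7)
  pr <- make_profiles_on_line(runif(10, 60, 300), -1, 1.5,
                              offset = rnorm(10, 0, 0.2))
  fit <- fit_spread(pr)
  xs <- log10(c(65, 120, 250))
  band <- confidence_band(fit, xs, level = 0.95)
  # independent recomputation through predict.lm
  lmfit <- lm(log10(n_localities) ~ log10(art), data = pr)
  ref <- predict(lmfit, newdata = data.frame(art = 10^xs),
                 interval = "confidence", level = 0.95)
  expect_equal(band$fit, unname(ref[, "fit"]), tolerance = 1e-10)
  expect_equal(band$lower, unname(ref[, "lwr"]), tolerance = 1e-10)
  expect_equal(band$upper, unname(ref[, "upr"]), tolerance = 1e-10)

  # width minimized at the x mean; widths shrink as n grows
  wide <- confidence_band(fit, seq(1.5, 2.6, by = 0.01))
  expect_equal(wide$x[which.min(wide$upper - wide$lower)], fit$x_mean,
               tolerance = 0.01)
  big <- make_profiles_on_line(runif(4000, 60, 300), -1, 1.5,
                               offset = rnorm(4000, 0, 0.2))
  fit_big <- fit_spread(big)
  wb <- confidence_band(fit_big, fit_big$x_mean)
  expect_lt(wb$upper - wb$lower,
            (band$upper - band$lower)[which.min(abs(xs - fit$x_mean))])
})

test_that("classification labels partition species and respect the lag gate", {
  art <- seq(30, 400, length.out = 40)
  pr <- make_profiles_on_line(art, -2.549, 1.8213,
                              offset = rnorm(40, 0, 0.1))
  fit <- fit_spread(pr)
  # a species exactly on the fitted line is EXPECTED with residual 0
  on_line <- pr[1, ]
  on_line$art <- 150
  on_line$n_localities <- 10^(fit$intercept + fit$slope * log10(150))
  cls1 <- classify_spread(on_line, fit, lag_threshold = 54)
  expect_equal(cls1$label, "EXPECTED")
  expect_equal(cls1$residual, 0, tolerance = 1e-12)

  # planted +1 log10 outlier beyond the lag is ML
  out <- on_line
  out$n_localities <- out$n_localities * 10
  expect_equal(classify_spread(out, fit, 54)$label, "ML")

  cls <- classify_spread(pr, fit, lag_threshold = 54)
  expect_setequal(unique(cls$label),
                  intersect(c("ML", "FL", "EXPECTED", "PRE_LAG"), cls$label))
  expect_equal(nrow(cls), nrow(pr))
  expect_true(all((cls$label == "PRE_LAG") == (pr$art <= 54)))

  # widening the band never moves a species out of EXPECTED
  cls90 <- classify_spread(pr, fit, 54, level = 0.90)
  cls99 <- classify_spread(pr, fit, 54, level = 0.99)
  was_expected <- cls90$label == "EXPECTED"
  expect_true(all(cls99$label[was_expected] %in% c("EXPECTED", "PRE_LAG")))
})

test_that("mean slope recovery is unbiased over replicate synthetic worlds", {
  # calibration design: arrivals 1500-1940 (all past lag, counts clear of
  # the integer floor), near-immediate detection, no planted outliers
  slopes <- vapply(1:60, function(s) {
    cfg <- synthetic_config(n_species = 250, era = c(1500, 1940), beta1 = 1.8,
                            sigma = 0.3, outlier_fraction = 0,
                            detection_scale = 5, herb_fraction = 1, seed = s)
    dd <- deduplicate_specimens(generate_dataset(cfg)$specimens)
    coef(fit_spread(species_profiles(dd, function(y) 0)))[["slope"]]
  }, numeric(1))
  expect_lt(abs(mean(slopes) - 1.8), 0.04)
  # per-replicate recovery at the calibrated band
  expect_gte(mean(abs(slopes - 1.8) < 0.16), 0.85)
})
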