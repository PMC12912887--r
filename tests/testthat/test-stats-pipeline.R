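test_that("transform selection tracks the scale the data were generated on", {
  set.seed(51)
  des <- one_background_design(fish_per_cell = 8, seed = 51)
  tab <- generate_cone_catch_table(des, null_profiles())

  # gaussian identity-scale response with a wide relative spread, so log
  # and sqrt visibly distort the residuals: identity wins
  dat <- tab[!tab$is_background, ]
  dat$resp <- pmax(20 + as.numeric(factor(dat$population)) * 2 +
                     rnorm(nrow(dat), 0, 10), 0.5)
  pick <- choose_transform(dat, "resp")
  expect_equal(pick$transform, "identity")
  expect_true(all(pick$W <= 1))

  # exp(normal) response: log should win in nearly every replicate
  wins <- vapply(1:10, function(i) {
    d <- dat
    set.seed(100 + i)
    d$resp <- exp(1 + as.numeric(factor(d$population)) * 0.5 +
                    rnorm(nrow(d), 0, 0.8))
    choose_transform(d, "resp")$transform == "log"
  }, logical(1))
  expect_gte(mean(wins), 0.9)

  dat$resp <- 1
  expect_error(choose_transform(dat, "resp"), "constant")
  dat$resp <- c(-1, rep(1, nrow(dat) - 1))
  expect_message(choose_transform(dat, "resp", c("identity", "log")),
                 "log transform skipped")
})

test_that("a saturated zero-noise toy is reproduced exactly by the fit", {
  # 2 populations x 2 times, no noise, no covariate effects: fixed effects
  # must reproduce the cell means exactly
  cells <- expand.grid(fish = 1:6, time_min = c(0, 1))
  cells$population <- rep(c("A", "B"), each = 3, length.out = nrow(cells))
  cells$fish_id <- paste0(cells$population, cells$fish)
  cells$sex <- rep_len(c("F", "M"), nrow(cells))
  cells$length_cm <- 3 + cells$fish * 0.1
  mu <- c(A_0 = 1, A_1 = 2, B_0 = 1.5, B_1 = 1.6)
  cells$y <- mu[paste(cells$population, cells$time_min, sep = "_")]
  # zero residual variance makes the optimizer grumble; the estimates are
  # still exact
  fit <- suppressWarnings(suppressMessages(fit_colour_lmm(cells, "y")))
  emm <- as.data.frame(emmeans::emmeans(fit, ~ time | population,
                                        lmer.df = "satterthwaite"))
  got <- setNames(emm$emmean, paste(emm$population, emm$time, sep = "_"))
  expect_equal(got[names(mu)], mu, tolerance = 1e-8)
})

test_that("variance components are attributed correctly", {
  # fish_sd = 0: random-intercept variance collapses toward zero and the
  # residual SD estimates the generator's noise
  des <- one_background_design(fish_per_cell = 10, seed = 52)
  profs <- null_profiles(fish_sd = 0,
                         resid_sd = c(luminance = 0.02, hue = 0.002,
                                      saturation = 0.005))
  tab <- add_colour_metrics(generate_cone_catch_table(des, profs))
  fit <- fit_colour_lmm(tab, "luminance")
  vc <- as.data.frame(lme4::VarCorr(fit))
  ri <- vc$sdcor[vc$grp == "fish_id"]
  res <- vc$sdcor[vc$grp == "Residual"]
  expect_lt(ri, 0.01)
  expect_equal(res, 0.02, tolerance = 0.25)

  # and the converse: real fish-level variance shows up in the intercept
  profs2 <- null_profiles(fish_sd = c(luminance = 0.08, hue = 0.004,
                                      saturation = 0.01),
                          resid_sd = c(luminance = 0.02, hue = 0.002,
                                       saturation = 0.005))
  tab2 <- add_colour_metrics(generate_cone_catch_table(des, profs2))
  vc2 <- as.data.frame(lme4::VarCorr(fit_colour_lmm(tab2, "luminance")))
  expect_equal(vc2$sdcor[vc2$grp == "fish_id"], 0.08, tolerance = 0.4)
})

test_that("interaction test has the factorial dimensions and df methods agree", {
  des <- one_background_design(fish_per_cell = 5, seed = 53)
  tab <- generate_cone_catch_table(des, default_population_profiles())
  fit <- fit_colour_lmm(tab, "q_dbl")
  sat <- test_interaction(fit)
  bw <- test_interaction(fit, ddf = "between-within")
  expect_equal(sat$num_df, 9)
  expect_equal(bw$num_df, 9)
  # balanced design: 80 rows - 20 fish - 12 within-fish params
  expect_equal(bw$den_df, 48)
  expect_equal(sat$den_df, bw$den_df, tolerance = 0.5)
  expect_equal(sat$F, bw$F, tolerance = 1e-6)
  expect_lt(sat$p, 0.05)  # populations genuinely differ under the defaults

  one_pop <- tab[tab$population == "Gizan", ]
  expect_error(fit_colour_lmm(one_pop, "q_dbl"), "singular design")
})

test_that("within-population time contrasts have the right family structure", {
  des <- one_background_design(fish_per_cell = 5, seed = 54)
  tab <- add_colour_metrics(generate_cone_catch_table(
    des, default_population_profiles()))
  fit <- fit_colour_lmm(tab, "luminance")
  ct <- time_contrasts_within_population(fit)
  expect_equal(nrow(ct), 4 * choose(4, 2))
  expect_true(all(ct$family_size == 6))
  # Tukey adjustment never decreases a p-value
  expect_true(all(ct$p_value >= ct$p_unadjusted - 1e-12))
  expect_true(all(ct$p_value >= 0 & ct$p_value <= 1))

  # identity transform: the regrid path equals link-scale contrasts exactly
  ct_link <- time_contrasts_within_population(fit, regrid = FALSE)
  expect_equal(ct$estimate, ct_link$estimate, tolerance = 1e-10)
  expect_equal(ct$p_value, ct_link$p_value, tolerance = 1e-10)

  # the conservative full-family option keeps the same estimates but can
  # only raise adjusted p-values
  ct_all <- time_contrasts_within_population(fit, family = "all")
  expect_equal(nrow(ct_all), nrow(ct))
  key <- paste(ct$population, ct$contrast)
  key_all <- paste(ct_all$population, ct_all$contrast)
  expect_setequal(key_all, key)
  m <- match(key, key_all)
  expect_equal(ct_all$estimate[m], ct$estimate, tolerance = 1e-10)
  expect_true(all(ct_all$p_value[m] >= ct$p_value - 1e-12))
  expect_true(all(ct_all$family_size == choose(16, 2)))
})

test_that("log-scale fits report contrasts on the response scale", {
  des <- one_background_design(fish_per_cell = 5, seed = 55)
  tab <- add_colour_metrics(generate_cone_catch_table(
    des, default_population_profiles()))
  fit <- fit_colour_lmm(tab, "luminance", transform = "log")
  ct <- time_contrasts_within_population(fit)
  emm <- as.data.frame(emmeans::emmeans(fit, ~ time | population,
                                        lmer.df = "satterthwaite"))
  # response-scale estimate of a pair = difference of back-transformed means
  first <- ct[ct$population == emm$population[1] &
                ct$contrast == "time0 - time1", ]
  means <- emm[emm$population == emm$population[1], ]
  expect_equal(first$estimate,
               exp(means$emmean[means$time == 0]) -
                 exp(means$emmean[means$time == 1]),
               tolerance = 1e-8)
  # adjusted p monotone in |t| within a family
  fam <- ct[ct$population == ct$population[1], ]
  o <- order(abs(fam$t_ratio))
  expect_true(all(diff(fam$p_value[o]) <= 1e-10))
})

test_that("AIC ranking follows the likelihood and finds real covariates", {
  des <- one_background_design(fish_per_cell = 10, seed = 56)
  profs <- null_profiles(sex_effect = c(luminance = 0.1, hue = 0,
                                        saturation = 0))
  tab <- add_colour_metrics(generate_cone_catch_table(des, profs))
  rhs_full <- "time * population + length_cm + sex + (1 | fish_id)"
  rhs_nosex <- "time * population + length_cm + (1 | fish_id)"
  out <- compare_models_aic(tab, "luminance", c(rhs_full, rhs_nosex))
  expect_equal(out$AIC, -2 * out$logLik + 2 * out$k, tolerance = 1e-8)
  expect_equal(out$model[1], rhs_full)  # the sex effect is real and large
  expect_gt(out$delta_AIC[2], 2)

  dup <- compare_models_aic(tab, "luminance", c(rhs_full, rhs_full))
  expect_equal(dup$AIC[1], dup$AIC[2], tolerance = 1e-10)
  expect_equal(dup$delta_AIC[2], 0, tolerance = 1e-10)
})
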