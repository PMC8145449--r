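test_that("BH step-up acceptance matches the hand-applied rule", {
  # thresholds i*q/m = {0.0125, 0.025, 0.0375, 0.05}; largest i with
  # p(i) <= i*q/m is i = 2 (0.04 > 0.0375), so only the first two pass
  expect_identical(bh_select(c(0.001, 0.02, 0.04, 0.9), q = 0.05),
                   c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(bh_select(rep(1, 5), q = 0.05), rep(FALSE, 5))
  # m = 1 reduces to p <= q
  expect_true(bh_select(0.04, q = 0.05))
  expect_false(bh_select(0.06, q = 0.05))
})

test_that("univariate screening computes LRT p-values and the BH set", {
  cfg <- generator_config(seed = 31, n_rows = 40, n_cols = 40,
                          n_predictors = 4,
                          true_coefficients = c(env01 = 1.5))
  land <- generate_landscape(cfg)
  occ <- generate_species(land, cfg)
  scr <- univariate_screen(occ, land, q = 0.05)
  expect_true("env01" %in% scr$accepted)
  # cross-check one LRT p-value against stats::anova on the same fit
  df <- as.data.frame(land)
  df$y <- occ$presence
  fit <- glm(y ~ env01, binomial, df)
  p_ref <- anova(fit, test = "Chisq")["env01", "Pr(>Chi)"]
  expect_equal(scr$table$p_value[scr$table$predictor == "env01"], p_ref,
               tolerance = 1e-10)
  expect_identical(scr$table$accepted, bh_select(scr$table$p_value, 0.05))
})

test_that("screening rejects single-class species", {
  land <- generate_landscape(generator_config(seed = 1, n_rows = 5,
                                              n_cols = 5,
                                              n_predictors = 1))
  all1 <- species_occurrence(rep(1, 25), land)
  expect_error(univariate_screen(all1, land), "degenerate response")
})

test_that("stepwise AIC finds the informative predictor among noise", {
  cfg <- generator_config(seed = 17, n_rows = 55, n_cols = 55,
                          n_predictors = 6,
                          true_coefficients = c(env01 = 1.2))
  land <- generate_landscape(cfg)
  occ <- generate_species(land, cfg)
  model <- stepwise_aic(occ, land, sprintf("env%02d", 1:6))
  expect_true("env01" %in% model$variables)
  null_aic <- fit_model(occ, land)$aic
  expect_lte(model$aic, null_aic)
})

test_that("stepwise returns intercept-only when no move improves AIC", {
  # a pure-noise predictor on a small sample: adding it costs ~2 AIC
  cfg <- generator_config(seed = 4, n_rows = 8, n_cols = 8,
                          n_predictors = 1, target_prevalence = 0.4)
  land <- generate_landscape(cfg)
  occ <- generate_species(land, cfg)
  add_aic <- fit_model(occ, land, "env01")$aic
  null_aic <- fit_model(occ, land)$aic
  expect_gt(add_aic, null_aic)  # fixture sanity: the move is not improving
  model <- stepwise_aic(occ, land, "env01")
  expect_length(model$variables, 0)
  expect_equal(model$aic, null_aic)
})

test_that("exact stepwise ties resolve lexicographically", {
  cfg <- generator_config(seed = 13, n_rows = 30, n_cols = 30,
                          n_predictors = 2,
                          true_coefficients = c(env02 = 1.5))
  land <- generate_landscape(cfg)
  # env00 is a bit-identical copy of env02: both additions give equal AIC
  land$predictors$env00 <- land$predictors$env02
  occ <- generate_species(land, cfg)
  model <- stepwise_aic(occ, land, c("env02", "env00"))
  expect_identical(model$variables, "env00")
})

test_that("trimming keeps exactly one of two collinear copies", {
  cfg <- generator_config(seed = 23, n_rows = 45, n_cols = 45,
                          n_predictors = 2,
                          true_coefficients = c(env01 = 1.5))
  land <- generate_landscape(cfg)
  # near-duplicate of the informative predictor
  near <- land$predictors$env01 +
    matrix(rnorm(45 * 45, sd = 0.02), 45, 45)
  land$predictors$env01b <- (near - mean(near[land$valid])) /
    sd(near[land$valid])
  occ <- generate_species(land, cfg)
  joint <- fit_model(occ, land, c("env01", "env01b"))
  expect_true(any(joint$coefficient_p >= 0.05))  # collinearity fixture holds
  trimmed <- trim_model(joint, alpha = 0.05)
  expect_length(trimmed$variables, 1)
  expect_true(all(trimmed$coefficient_p < 0.05))
})

test_that("trimming is a fixed point on an already-significant model", {
  cfg <- generator_config(seed = 29, n_rows = 40, n_cols = 40,
                          n_predictors = 2,
                          true_coefficients = c(env01 = 1.5, env02 = -1))
  land <- generate_landscape(cfg)
  occ <- generate_species(land, cfg)
  model <- fit_model(occ, land, c("env01", "env02"))
  expect_true(all(model$coefficient_p < 0.05))
  trimmed <- trim_model(model, 0.05)
  expect_identical(trimmed$variables, model$variables)
  expect_equal(trimmed$coefficients, model$coefficients)
})

test_that("perfect separation is flagged and stabilized by ridge", {
  x <- matrix(c(rep(-1, 30) + seq(-0.5, 0.5, length.out = 30),
                rep(1, 30) + seq(-0.5, 0.5, length.out = 30)), 6, 10)
  x <- (x - mean(x)) / sd(x)
  land <- toy_landscape(env01 = x)
  occ <- species_occurrence(as.integer(as.vector(x) > 0), land)
  model <- fit_model(occ, land, "env01")
  expect_true(model$separation)
  expect_identical(model$engine, "ridge")
  expect_true(all(is.finite(coef(model))))
  expect_true(all(is.finite(model$coefficient_p)))
})

test_that("favorability_fit attaches co-monotone P and F surfaces", {
  cfg <- generator_config(seed = 37, n_rows = 30, n_cols = 35,
                          n_predictors = 4,
                          true_coefficients = c(env01 = 1.5, env03 = -0.8))
  land <- generate_landscape(cfg)
  occ <- generate_species(land, cfg)
  fit <- favorability_fit(occ, land)
  expect_s3_class(fit, "favorability_model")
  expect_length(fit$favorability, sum(land$valid))
  expect_identical(order(fit$favorability), order(fit$fitted_probability))
  expect_equal(
    fit$favorability,
    favorability(fit$fitted_probability, fit$n1, fit$n0))
  # the favorability surface crosses 0.5 exactly at P = prevalence
  prev <- fit$n1 / (fit$n1 + fit$n0)
  expect_equal(favorability(prev, fit$n1, fit$n0), 0.5)
  # methods behave
  expect_length(coef(fit), length(fit$variables) + 1)
  expect_equal(predict(fit, land, type = "probability"),
               fit$fitted_probability)
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_identical(dim(sims), c(sum(land$valid), 2L))
  expect_true(all(unlist(sims) %in% 0:1))
  expect_length(residuals(fit), sum(land$valid))
})
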