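# Small but realistic two-part fixture reused across this file.
tp_fixture <- local({
  ct <- generate_country_table(10, seed = 301)
  pars <- true_params(
    covariates = c("has_partner", "female", "age_c"),
    beta_need = c(-1.0, -0.1, 0.3, 0.04),
    beta_use = cbind(informal = c(-0.6, 0.8, -0.2, 0.02),
                     formal = c(-1.1, -0.9, 0.3, 0.04),
                     mixed = c(-1.6, 0.4, 0.1, 0.03)),
    sigma_need = 0.3, sigma_use = c(0.4, 0.5, 0.4))
  pop <- generate_population(ct, pars, 600, seed = 302)
  sp1 <- binary_mixed_spec(fixed_effects = pars$covariates)
  sp2 <- multinomial_mixed_spec(fixed_effects = pars$covariates,
                                quadrature_nodes_per_dim = 5)
  fit <- fit_two_part(pop$data, sp1, sp2, "iadl1", compute_vcov = FALSE)
  list(pop = pop, pars = pars, sp1 = sp1, sp2 = sp2, fit = fit)
})

test_that("Part II sample is exactly the needer subsample", {
  d <- tp_fixture$pop$data
  expect_identical(tp_fixture$fit$part2$n_obs, sum(derive_need(d, "iadl1")))
  expect_identical(tp_fixture$fit$part1$n_obs, nrow(d))
  expect_identical(tp_fixture$fit$need_definition, "iadl1")
})

test_that("hurdle violations and empty hurdles are rejected", {
  d <- tp_fixture$pop$data
  d$iadl_count[d$care_use != "none"][1:3] <- 0L
  expect_error(fit_two_part(d, tp_fixture$sp1, tp_fixture$sp2, "iadl1"),
               "hurdle violation.*person_id")

  # needers all have exactly 1 IADL limitation -> iadl2 empties the hurdle
  d2 <- tp_fixture$pop$data
  d2$iadl_count[d2$iadl_count >= 1L] <- 1L
  expect_error(suppressWarnings(
    fit_two_part(d2, tp_fixture$sp1, tp_fixture$sp2, "iadl2")))
})

test_that("needer share matches the generator's expected prevalence", {
  d <- tp_fixture$pop$data
  pars <- tp_fixture$pars
  # generator-based oracle: fresh large draw of the same design
  big <- generate_population(generate_country_table(200, seed = 303), pars,
                             500, seed = 304)
  p_expect <- mean(big$data$need)
  se <- sqrt(p_expect * (1 - p_expect) / nrow(d)) +
    sd(tapply(big$data$need, big$data$country_id, mean)) / sqrt(10)
  expect_lt(abs(mean(d$need) - p_expect), 3 * se)
})

test_that("unconditional probabilities obey the hurdle product identity", {
  fit <- tp_fixture$fit
  d <- tp_fixture$pop$data[1:400, ]
  P <- predict_unconditional(fit, d)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  pn <- predict_need(fit$part1, d)
  pc <- predict_conditional(fit$part2, d)
  for (k in c("informal", "formal", "mixed"))
    expect_equal(P[, k], pn * pc[, k], tolerance = 1e-12)
  expect_equal(P[, "no_care"], 1 - pn + pn * pc[, "none"], tolerance = 1e-12)

  # a closed hurdle forces (1, 0, 0, 0)
  fit0 <- tp_fixture$fit
  fit0$part1$beta_hat["(Intercept)"] <- -60
  P0 <- predict_unconditional(fit0, d[1:5, ])
  expect_equal(unname(P0[, "no_care"]), rep(1, 5), tolerance = 1e-12)
  expect_true(all(P0[, c("informal", "formal", "mixed")] < 1e-12))
})

test_that("hand-constructed product: P(need)=0.4, P(informal|need)=0.5", {
  # constant-probability fit built by hand
  sp1 <- binary_mixed_spec(fixed_effects = character(0))
  sp2 <- multinomial_mixed_spec(fixed_effects = character(0))
  fit <- structure(list(
    part1 = structure(list(beta_hat = c("(Intercept)" = qlogis(0.4)),
                           sigma_hat = 0, spec = sp1),
                      class = "binary_mixed_fit"),
    part2 = structure(list(
      beta_hat = matrix(c(log(0.5 / 0.3), log(0.15 / 0.3), log(0.05 / 0.3)),
                        1, 3, dimnames = list("(Intercept)", CARE4[-1])),
      sigma_hat = c(informal = 0, formal = 0, mixed = 0), spec = sp2),
      class = "mnl_mixed_fit"),
    need_definition = "iadl1"), class = "twopart_fit")
  d <- data.frame(country_id = 1, x = 0)
  P <- predict_unconditional(fit, d)
  expect_equal(unname(P[1, "informal"]), 0.4 * 0.5, tolerance = 1e-12)
  expect_equal(unname(P[1, "no_care"]), 1 - 0.4 + 0.4 * 0.3,
               tolerance = 1e-12)
})

test_that("AME identities: null effect, two-pass difference, coarse step", {
  fit <- tp_fixture$fit
  d <- tp_fixture$pop$data
  # a covariate absent from the truth and (nearly) null in the fit:
  # use a synthetic null fit with female's coefficients zeroed
  fit0 <- fit
  fit0$part1$beta_hat["female"] <- 0
  fit0$part2$beta_hat["female", ] <- 0
  expect_lt(abs(ame(fit0, d, "female", "informal")), 1e-8)

  # binary AME equals the two-pass counterfactual mean difference exactly
  for (col in c("need", "informal", "formal_given_need")) {
    hi <- d; hi$has_partner <- 1
    lo <- d; lo$has_partner <- 0
    direct <- mean(ltchurdle:::predict_column(fit, hi, col) -
                     ltchurdle:::predict_column(fit, lo, col))
    expect_identical(ame(fit, d, "has_partner", col), direct)
  }

  # continuous AME stable between the default and a coarse step
  a_fine <- ame(fit, d, "age_c", "informal")
  a_coarse <- ame(fit, d, "age_c", "informal", step_scale = 1e-3)
  expect_lt(abs(a_fine - a_coarse), 1e-4)
  expect_error(ame(fit, d, "age_c", "noclm"), "column")
  expect_error(ame(fit, d, "zzz", "informal"), "not in the model")
})

test_that("chain decomposition holds for covariates entering only Part II", {
  # build a fit where has_partner affects Part II only
  fit <- tp_fixture$fit
  fit$part1$beta_hat["has_partner"] <- 0
  d <- tp_fixture$pop$data[1:1500, ]
  pn <- predict_need(fit$part1, d)
  hi <- d; hi$has_partner <- 1
  lo <- d; lo$has_partner <- 0
  for (k in c("informal", "mixed")) {
    lhs <- ame(fit, d, "has_partner", k)
    dcond <- predict_conditional(fit$part2, hi)[, k] -
      predict_conditional(fit$part2, lo)[, k]
    expect_equal(lhs, mean(pn * dcond), tolerance = 1e-8)
  }
})

test_that("collapsed any-care AME equals the sum of parts plus cross-term", {
  fit <- tp_fixture$fit
  d <- tp_fixture$pop$data[1:1500, ]
  a_use <- ame(fit, d, "has_partner", "use")
  parts <- sum(ame(fit, d, "has_partner", "informal"),
               ame(fit, d, "has_partner", "formal"),
               ame(fit, d, "has_partner", "mixed"))
  expect_equal(a_use, parts, tolerance = 1e-10)
  # and 'use' + its complement through 'none|need' reproduces the need AME
  hi <- d; hi$has_partner <- 1
  lo <- d; lo$has_partner <- 0
  pn_hi <- predict_need(fit$part1, hi); pn_lo <- predict_need(fit$part1, lo)
  none_hi <- predict_conditional(fit$part2, hi)[, "none"]
  none_lo <- predict_conditional(fit$part2, lo)[, "none"]
  cross <- mean(pn_hi * none_hi - pn_lo * none_lo)
  expect_equal(ame(fit, d, "has_partner", "need"), a_use + cross,
               tolerance = 1e-10)
})

test_that("grouped dummies zero their siblings; age_joint is coherent", {
  ct <- generate_country_table(6, seed = 311)
  pop <- generate_population(ct, share_like_params(), 900, seed = 312)
  d <- pop$data
  covs <- c("wealth_q2", "wealth_q3", "wealth_q4", "wealth_q5",
            "has_partner", "age_c", "age2_c")
  sp1 <- binary_mixed_spec(fixed_effects = covs)
  sp2 <- multinomial_mixed_spec(fixed_effects = covs,
                                quadrature_nodes_per_dim = 5)
  fit <- suppressWarnings(fit_two_part(d, sp1, sp2, "iadl1",
                                       compute_vcov = FALSE))
  # moving to q3 must zero q2/q4/q5 in the counterfactual
  hi <- d; hi$wealth_q2 <- 0; hi$wealth_q4 <- 0; hi$wealth_q5 <- 0
  hi$wealth_q3 <- 1
  lo <- d; lo$wealth_q2 <- 0; lo$wealth_q3 <- 0; lo$wealth_q4 <- 0
  lo$wealth_q5 <- 0
  direct <- mean(ltchurdle:::predict_column(fit, hi, "need") -
                   ltchurdle:::predict_column(fit, lo, "need"))
  expect_identical(ame(fit, d, "wealth_q3", "need"), direct)

  aj <- ame(fit, d, "age_joint", "need")
  expect_true(is.finite(aj))
  # joint effect = age_c AME + age2_c AME weighted by d(age2)/d(age) locally
  a1 <- ame(fit, d, "age_c", "need")
  expect_false(isTRUE(all.equal(aj, a1)))  # quadratic term contributes
})

test_that("McFadden pseudo R2 and increments behave", {
  expect_equal(mcfadden_r2(-500, -1000), 0.5)
  expect_equal(mcfadden_r2(-1000, -1000), 0)
  expect_error(mcfadden_r2(-500, 10), "negative")
  expect_equal(incremental_r2(-400, -450, -1000), 0.05)
  f <- tp_fixture$fit
  expect_equal(mcfadden_r2(f$part1, f$part1), 0)
})

test_that("bootstrap margins: metadata, determinism, degenerate covariate", {
  ct <- generate_country_table(6, seed = 321)
  pars <- true_params(covariates = c("has_partner", "female"),
                      beta_need = c(-0.8, -0.2, 0.3),
                      beta_use = cbind(informal = c(-0.5, 0.8, -0.2),
                                       formal = c(-1.0, -0.8, 0.3),
                                       mixed = c(-1.4, 0.3, 0.1)),
                      sigma_need = 0.3, sigma_use = c(0.3, 0.3, 0.3))
  pop <- generate_population(ct, pars, 400, seed = 322)
  d <- pop$data
  d$constant_cov <- 1
  sp1 <- binary_mixed_spec(fixed_effects = c("has_partner", "female"))
  sp2 <- multinomial_mixed_spec(fixed_effects = c("has_partner", "female"),
                                quadrature_nodes_per_dim = 3)
  amt <- bootstrap_margins(d, sp1, sp2, "iadl1", B = 5, seed = 31,
                           covariates = c("has_partner", "female"),
                           columns = c("need", "informal"))
  expect_s3_class(amt, "ame_table")
  expect_identical(attr(amt, "B"), 5)
  expect_identical(attr(amt, "ci_method"), "basic")
  expect_true(all(c("estimate", "se", "ci_lo", "ci_hi", "stars") %in%
                    names(amt)))
  expect_true(all(amt$se >= 0))

  amt2 <- bootstrap_margins(d, sp1, sp2, "iadl1", B = 5, seed = 31,
                            covariates = c("has_partner", "female"),
                            columns = c("need", "informal"))
  expect_identical(as.data.frame(amt), as.data.frame(amt2))

  expect_error(bootstrap_margins(d, sp1, sp2, "iadl1", B = 1, seed = 1),
               "B must be")

  # percentile CIs and cluster resampling run and stay ordered
  amt3 <- bootstrap_margins(d, sp1, sp2, "iadl1", B = 4, seed = 32,
                            ci_method = "percentile", resample = "cluster",
                            covariates = "has_partner", columns = "need")
  expect_true(all(amt3$ci_lo <= amt3$ci_hi))
})
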