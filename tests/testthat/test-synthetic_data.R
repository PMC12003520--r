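test_that("country table respects its sampling laws and degenerate configs", {
  ct <- generate_country_table(18, seed = 3)
  expect_equal(nrow(ct), 18L)
  expect_setequal(names(ct), c("country_id", "means_testing", "cash_for_care",
                               "ltc_beds", "replacement_rate",
                               "cpi_personal_care", "gdp_per_capita",
                               "female_lfp"))
  expect_false(any(duplicated(ct$country_id)))
  expect_true(all(ct$ltc_beds >= 0))
  expect_true(all(ct$means_testing %in% 0:1 & ct$cash_for_care %in% 0:1))

  # zero-variance config returns the configured means exactly
  degen <- list(means_testing = list(law = "constant", value = 1),
                cash_for_care = list(law = "constant", value = 0),
                ltc_beds = list(law = "constant", value = 44.9),
                replacement_rate = list(law = "constant", value = 64.1),
                cpi_personal_care = list(law = "constant", value = 102.8),
                gdp_per_capita = list(law = "constant", value = 107.3),
                female_lfp = list(law = "constant", value = 70.7))
  one <- generate_country_table(1, config = degen, seed = 9)
  expect_equal(one$ltc_beds, 44.9)
  expect_equal(one$replacement_rate, 64.1)
  expect_equal(one$means_testing, 1L)

  expect_error(generate_country_table(0), "n_countries")

  # law of large numbers: truncation at 0 is immaterial at these settings
  big <- generate_country_table(10000, seed = 5)
  se <- 10 / sqrt(10000)
  expect_lt(abs(mean(big$ltc_beds) - 44.9), 3 * se)
})

make_null_params <- function(sigma_need = 0, sigma_use = c(0, 0, 0),
                             b0_need = 0) {
  true_params(covariates = c("female", "age_c"),
              beta_need = c(b0_need, 0, 0),
              beta_use = matrix(0, 3, 3),
              sigma_need = sigma_need, sigma_use = sigma_use)
}

test_that("population under the symmetric null has 50% need, uniform types", {
  ct <- generate_country_table(10, seed = 21)
  pop <- generate_population(ct, make_null_params(), 1000, seed = 22)
  d <- pop$data
  expect_equal(nrow(d), 10000L)
  se_need <- sqrt(0.25 / nrow(d))
  expect_lt(abs(mean(d$need) - 0.5), 3 * se_need)
  shares <- prop.table(table(d$care_use[d$need == 1]))
  se_cat <- sqrt(0.25 * 0.75 / sum(d$need))
  for (k in CARE4) expect_lt(abs(shares[[k]] - 0.25), 3 * se_cat)
})

test_that("saturating negative need intercept closes the hurdle entirely", {
  ct <- generate_country_table(5, seed = 31)
  pop <- generate_population(ct, make_null_params(b0_need = -50), 200,
                             seed = 32)
  expect_true(all(pop$data$need == 0L))
  expect_true(all(pop$data$care_use == "none"))
  expect_true(all(pop$data$iadl_count == 0L))
})

test_that("hurdle consistency: zero latent need implies care_use none", {
  pop <- generate_population(generate_country_table(8, seed = 41),
                             share_like_params(), 500, seed = 42)
  d <- pop$data
  expect_true(all(d$care_use[d$need == 0L] == "none"))
  # generating definition reproduces the latent indicator exactly
  expect_identical(derive_need(d, "iadl1"), d$need)
  # counts only where needed
  expect_true(all(d$iadl_count[d$need == 1L] >= 1L))
  expect_true(all(d$adl_count[d$need == 0L] == 0L))
})

test_that("identical seed and config give byte-identical output", {
  ct <- generate_country_table(6, seed = 51)
  p1 <- generate_population(ct, share_like_params(), 300, seed = 52)
  p2 <- generate_population(ct, share_like_params(), 300, seed = 52)
  expect_identical(p1$data, p2$data)
  expect_identical(p1$params$u_need, p2$params$u_need)
  ct2 <- generate_country_table(6, seed = 51)
  expect_identical(ct, ct2)
})

test_that("zero random-intercept SDs make countries exchangeable for need", {
  # chi-squared test of need-by-country should reject at the nominal rate
  pars <- true_params(covariates = c("female", "age_c"),
                      beta_need = c(qlogis(0.3), 0, 0),
                      beta_use = matrix(0, 3, 3),
                      sigma_need = 0, sigma_use = c(0, 0, 0))
  ct <- generate_country_table(20, seed = 61)
  rejections <- 0L
  for (r in 1:20) {
    pop <- generate_population(ct, pars, 500, seed = 600 + r)
    tab <- table(pop$data$country_id, pop$data$need)
    if (suppressWarnings(stats::chisq.test(tab)$p.value) < 0.05)
      rejections <- rejections + 1L
  }
  # Binomial(20, 0.05): > 4 rejections has probability < 0.3%
  expect_lte(rejections, 4L)
})

test_that("true_params validates conformability and JSON round-trips", {
  expect_error(true_params(covariates = c("a", "b"),
                           beta_need = c(0, 0),
                           beta_use = matrix(0, 3, 3),
                           sigma_need = 0.1, sigma_use = c(0.1, 0.1, 0.1)),
               "beta_need has length 2")
  expect_error(true_params(covariates = "a",
                           beta_need = c(0, 0),
                           beta_use = matrix(0, 3, 3),
                           sigma_need = 0.1, sigma_use = c(0.1, 0.1, 0.1)),
               "beta_use must be 2 x 3")
  expect_error(true_params(covariates = "a",
                           beta_need = c(0, 0),
                           beta_use = matrix(0, 2, 3),
                           sigma_need = -1, sigma_use = c(0.1, 0.1, 0.1)),
               "non-negative")
  pp <- share_like_params()
  tmp <- tempfile(fileext = ".json")
  write_true_params(pp, tmp)
  qq <- read_true_params(tmp)
  expect_equal(pp$beta_need, qq$beta_need)
  expect_equal(pp$beta_use, qq$beta_use)
  expect_equal(pp$sigma_use, qq$sigma_use)
})

test_that("gamma-weight option produces positive unit-mean-ish weights", {
  pop <- generate_population(generate_country_table(4, seed = 71),
                             make_null_params(), 500,
                             covariate_config = list(weights = list(law = "gamma")),
                             seed = 72)
  w <- pop$data$weight
  expect_true(all(w > 0))
  expect_lt(abs(mean(w) - 1), 0.1)
  expect_gt(sd(w), 0.2)
})
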