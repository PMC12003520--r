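spec2x <- multinomial_mixed_spec(fixed_effects = "x1")

test_that("uniform categorical baseline and pooled reduction are exact", {
  dm <- data.frame(country_id = c(1, 1, 2, 2), need = 1L,
                   care_use = CARE4, x1 = 0)
  pr0 <- list(beta = matrix(0, 2, 3), sigma = c(0, 0, 0))
  expect_equal(suppressWarnings(loglik_multinomial(dm, pr0, spec2x)),
               4 * log(0.25), tolerance = 1e-12)

  B <- rbind(c(-1, -1.5, -2), c(0.5, -0.3, 0.2))
  d <- gen_mnl_data(4, 100, B, c(0, 0, 0), seed = 201)
  # term-by-term softmax log-density, independent arithmetic
  S <- cbind(0, cbind(1, d$x1) %*% B)
  P <- exp(S) / rowSums(exp(S))
  yi <- match(d$care_use, CARE4)
  expect_equal(loglik_multinomial(d, list(beta = B, sigma = c(0, 0, 0)),
                                  spec2x),
               sum(log(P[cbind(seq_len(nrow(d)), yi)])), tolerance = 1e-9)

  expect_error(loglik_multinomial(d, list(beta = B, sigma = c(-0.1, 0, 0)),
                                  spec2x), "sigma")
  d$need[3] <- 0L
  expect_error(loglik_multinomial(d, list(beta = B, sigma = c(0, 0, 0)),
                                  spec2x), "hurdle")
})

test_that("3-D AGHQ matches dense midpoint integration and is node-stable", {
  B <- rbind(c(-0.8, -1.2, -1.6), c(0.5, -0.3, 0.2))
  sg <- c(0.5, 0.5, 0.5)
  d <- gen_mnl_data(4, 15, B, sg, seed = 211)
  la <- loglik_multinomial(d, list(beta = B, sigma = sg), spec2x)
  lg <- oracle_mnl_grid(d, "x1", B, sg, M = 101)   # fine check at unit scale
  expect_lt(abs(la - lg) / abs(lg), 1e-4)          # grid error dominates

  sp11 <- multinomial_mixed_spec(fixed_effects = "x1",
                                 quadrature_nodes_per_dim = 11)
  l11 <- loglik_multinomial(d, list(beta = B, sigma = sg), sp11)
  expect_lt(abs(la - l11) / abs(la), 1e-5)
})

test_that("reparameterization identity: shift x, adjust intercepts", {
  B <- rbind(c(-0.8, -1.2, -1.6), c(0.5, -0.3, 0.2))
  sg <- c(0.4, 0.5, 0.3)
  d <- gen_mnl_data(5, 30, B, sg, seed = 221)
  l0 <- loglik_multinomial(d, list(beta = B, sigma = sg), spec2x)
  cshift <- 1.7
  d2 <- d
  d2$x1 <- d$x1 + cshift
  B2 <- B
  B2[1, ] <- B[1, ] - B[2, ] * cshift
  expect_equal(loglik_multinomial(d2, list(beta = B2, sigma = sg), spec2x),
               l0, tolerance = 1e-8)
})

test_that("sigma = 0 data reproduce the pooled multinomial-logit MLE", {
  B <- rbind(c(-1, -1.4, -1.8), c(0.5, -0.4, 0.3), c(0.7, -0.5, 0.4))
  d <- gen_mnl_data(40, 300, B, c(0, 0, 0), seed = 231)
  sp <- multinomial_mixed_spec(fixed_effects = c("x1", "x2"))
  fit <- fit_multinomial(d, sp, compute_vcov = FALSE)
  ref <- nnet::multinom(factor(care_use, levels = CARE4) ~ x1 + x2,
                        d, trace = FALSE, reltol = 1e-14)
  expect_lt(max(abs(fit$beta_hat - t(coef(ref)))), 1e-3)
  expect_true(all(fit$sigma_hat < 0.05))
})

test_that("degenerate outcomes raise diagnostic errors", {
  d <- gen_mnl_data(4, 40, rbind(c(-1, -1, -1), c(0, 0, 0)), c(0, 0, 0),
                    seed = 241)
  d$care_use <- "none"
  expect_error(fit_multinomial(d, spec2x), "never observed")
  d2 <- gen_mnl_data(1, 80, rbind(c(-1, -1, -1), c(0, 0, 0)), c(0, 0, 0),
                     seed = 242)
  expect_error(fit_multinomial(d2, spec2x), "2 clusters")
})

test_that("conditional probabilities: trivial, normalized, match MC oracle", {
  d <- gen_mnl_data(3, 20, rbind(c(-0.5, -1, -1.5), c(0.4, -0.2, 0.3)),
                    c(0.4, 0.6, 0.5), seed = 251)
  fit0 <- structure(list(beta_hat = matrix(0, 2, 2 + 1,
                                           dimnames = list(c("(Intercept)", "x1"),
                                                           CARE4[-1])),
                         sigma_hat = c(informal = 0, formal = 0, mixed = 0),
                         spec = spec2x),
                    class = "mnl_mixed_fit")
  P0 <- predict_conditional(fit0, d)
  expect_true(all(abs(P0 - 0.25) < 1e-12))

  fit <- fit_multinomial(d, spec2x, compute_vcov = FALSE)
  P <- predict_conditional(fit, d, "marginal")
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
  expect_true(all(P > 0 & P < 1))

  d10 <- d[1:10, ]
  Eta <- cbind(1, d10$x1) %*% fit$beta_hat
  mc <- mc_mnl_marginal(Eta, fit$sigma_hat, ndraw = 1e6, seed = 6)
  # MC SE of a softmax mean is below sqrt(.25/ndraw) per cell
  expect_lt(max(abs(predict_conditional(fit, d10, "marginal") - mc)),
            3 * sqrt(0.25 / 1e6) + 2e-4)
  expect_error(predict_conditional(fit, d, "nonsense"))
})

test_that("shared random structure is a labelled 1-D alternative", {
  B <- rbind(c(-0.9, -1.3, -1.7), c(0.4, -0.3, 0.2))
  set.seed(261)
  J <- 12; nj <- 80; n <- J * nj
  d <- data.frame(country_id = rep(1:J, each = nj), need = 1L, x1 = rnorm(n))
  u <- rnorm(J, 0, 0.5)
  S <- cbind(0, sweep(cbind(1, d$x1) %*% B, 1, -u[d$country_id]))
  P <- exp(S) / rowSums(exp(S))
  d$care_use <- CARE4[apply(P, 1, function(p) sample(4, 1, prob = p))]
  sps <- multinomial_mixed_spec(fixed_effects = "x1",
                                random_structure = "shared",
                                quadrature_nodes_per_dim = 15)
  fit <- fit_multinomial(d, sps, compute_vcov = FALSE)
  expect_identical(names(fit$sigma_hat), "shared")
  expect_identical(fit$spec$random_structure, "shared")
  expect_lt(abs(fit$sigma_hat - 0.5), 0.25)
  P4 <- predict_conditional(fit, d[1:5, ])
  expect_lt(max(abs(rowSums(P4) - 1)), 1e-12)
})
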