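# Independent oracles and small data generators shared across the suite.
# Oracles deliberately avoid the package's quadrature code paths: dense
# deterministic integration grids and plain Monte-Carlo averages.

CARE4 <- c("none", "informal", "formal", "mixed")

## ---- data generators -------------------------------------------------------

# binary-response clustered data from explicit parameters
gen_binary_data <- function(J, nj, beta, sigma, seed, x_fn = NULL) {
  set.seed(seed)
  n <- J * nj
  d <- data.frame(country_id = rep(seq_len(J), each = nj))
  if (is.null(x_fn)) {
    d$x1 <- rnorm(n)
    d$x2 <- rbinom(n, 1, 0.5)
    d$x3 <- rnorm(n)
  } else d <- cbind(d, x_fn(n))
  xcols <- setdiff(names(d), "country_id")
  X <- cbind(1, as.matrix(d[xcols[seq_len(length(beta) - 1)]]))
  u <- rnorm(J, 0, sigma)
  d$need <- rbinom(n, 1, plogis(drop(X %*% beta) + u[d$country_id]))
  d
}

# needer-only multinomial data from explicit parameters
gen_mnl_data <- function(J, nj, B, sig, seed) {
  set.seed(seed)
  n <- J * nj
  d <- data.frame(country_id = rep(seq_len(J), each = nj), need = 1L,
                  x1 = rnorm(n), x2 = rbinom(n, 1, 0.5), x3 = rnorm(n))
  X <- cbind(1, as.matrix(d[, c("x1", "x2", "x3")[seq_len(nrow(B) - 1)],
                            drop = FALSE]))
  U <- matrix(rnorm(3 * J, 0, rep(sig, each = J)), J)
  S <- cbind(0, X %*% B + U[d$country_id, ])
  P <- exp(S - apply(S, 1, max))
  P <- P / rowSums(P)
  cum <- t(apply(P, 1, cumsum))
  d$care_use <- CARE4[1L + rowSums(runif(n) > cum[, 1:3, drop = FALSE])]
  d
}

## ---- dense-grid integration oracles ----------------------------------------

# 1-D trapezoidal integration of the binary cluster likelihood
oracle_binary_grid <- function(data, xcols, beta, sigma, npts = 20001) {
  u <- seq(-10 * sigma, 10 * sigma, length.out = npts)
  du <- u[2] - u[1]
  X <- cbind(1, as.matrix(data[xcols]))
  eta <- drop(X %*% beta)
  tot <- 0
  for (j in unique(data$country_id)) {
    sel <- data$country_id == j
    lp <- outer(eta[sel], u, "+")
    ll <- colSums(stats::dbinom(data$need[sel], 1, plogis(lp), log = TRUE))
    f <- exp(ll) * dnorm(u, 0, sigma)
    tot <- tot + log(sum((f[-1] + f[-npts]) / 2) * du)
  }
  tot
}

# 3-D midpoint integration of the multinomial cluster likelihood on
# [-6 sigma, 6 sigma]^3 with M^3 cells (per-category sigma)
oracle_mnl_grid <- function(data, xcols, B, sg, M = 201) {
  mid <- function(s) seq(-6 * s, 6 * s, length.out = M + 1)[-(M + 1)] +
    6 * s / M
  u1 <- mid(sg[1]); u2 <- mid(sg[2]); u3 <- mid(sg[3])
  X <- cbind(1, as.matrix(data[xcols]))
  Eta <- X %*% B
  yi <- match(data$care_use, CARE4) - 1L
  lphi <- outer(outer(dnorm(u1, 0, sg[1], log = TRUE),
                      dnorm(u2, 0, sg[2], log = TRUE), "+"),
                dnorm(u3, 0, sg[3], log = TRUE), "+")
  ones <- rep(1, M)
  tot <- 0
  for (j in unique(data$country_id)) {
    sel <- which(data$country_id == j)
    acc <- array(0, dim = c(M, M, M))
    for (i in sel) {
      den <- 1 + outer(outer(exp(Eta[i, 1] + u1), ones), ones) +
        outer(outer(ones, exp(Eta[i, 2] + u2)), ones) +
        outer(outer(ones, ones), exp(Eta[i, 3] + u3))
      acc <- acc - log(den)
      if (yi[i] == 1) acc <- acc + Eta[i, 1] + outer(outer(u1, 0 * ones, "+"), 0 * ones, "+")
      if (yi[i] == 2) acc <- acc + Eta[i, 2] + outer(outer(0 * ones, u2, "+"), 0 * ones, "+")
      if (yi[i] == 3) acc <- acc + Eta[i, 3] + outer(outer(0 * ones, 0 * ones, "+"), u3, "+")
    }
    tot <- tot + log(sum(exp(acc + lphi)) *
                       (12 * sg[1] / M) * (12 * sg[2] / M) * (12 * sg[3] / M))
  }
  tot
}

## ---- Monte-Carlo prediction oracles ----------------------------------------

# E_u logistic(eta + u), u ~ N(0, sigma^2), by plain Monte Carlo
mc_binary_marginal <- function(eta, sigma, ndraw = 1e6, seed = 1) {
  set.seed(seed)
  u <- rnorm(ndraw, 0, sigma)
  vapply(eta, function(e) mean(plogis(e + u)), numeric(1))
}

# E_u softmax over (0, eta_k + u_k), u_k ~ N(0, sigma_k^2) independent
mc_mnl_marginal <- function(Eta, sig, ndraw = 1e6, seed = 1) {
  set.seed(seed)
  U <- cbind(rnorm(ndraw, 0, sig[1]), rnorm(ndraw, 0, sig[2]),
             rnorm(ndraw, 0, sig[3]))
  out <- matrix(0, nrow(Eta), 4)
  for (i in seq_len(nrow(Eta))) {
    S <- cbind(0, sweep(U, 2, Eta[i, ], "+"))
    E <- exp(S - apply(S, 1, max))
    out[i, ] <- colMeans(E / rowSums(E))
  }
  colnames(out) <- CARE4
  out
}

## ---- generator-truth AME oracle --------------------------------------------

# Population AMEs of binary design columns on need and unconditional
# care-type probabilities, under TrueParams, by Monte-Carlo over fresh
# covariate draws; expectations over the random intercepts use the package's
# closed quadrature kernels on counterfactual designs (the covariate part is
# the MC element). One MC population serves all requested covariates.
# Returns a columns x covariates matrix.
true_ame_oracle <- function(params, covariates, columns, n_mc = 1e6,
                            seed = 7, nodes = 24, nodes3 = 6) {
  set.seed(seed)
  # many virtual countries so country-covariate laws are integrated too
  ct <- generate_country_table(500L, seed = seed + 1)
  cfg <- default_covariate_config()
  n <- n_mc
  d <- data.frame(country_id = rep(ct$country_id, length.out = n))
  d$age <- ltchurdle:::rtnorm(n, cfg$age$mean, cfg$age$sd, cfg$age$min,
                              cfg$age$max)
  d$female <- rbinom(n, 1, cfg$female$p)
  d$wealth_quintile <- sample.int(5, n, TRUE)
  d$education <- sample(c("primary", "secondary", "tertiary"), n, TRUE,
                        prob = cfg$education$p)
  d$has_partner <- rbinom(n, 1, cfg$has_partner$p)
  d$has_children <- rbinom(n, 1, cfg$has_children$p)
  d <- expand_covariates(d, ct)
  d <- d[intersect(c("country_id", params$covariates), names(d))]

  gh1 <- ltchurdle:::gh_rule(nodes)
  gh3 <- ltchurdle:::gh_rule(nodes3)
  meta <- ltchurdle:::covariate_meta(params$covariates)
  predict_true <- function(dd) {
    X <- cbind(1, as.matrix(dd[params$covariates]))
    pn <- as.numeric(ltchurdle:::.cpp_predict_binary_marg(
      drop(X %*% params$beta_need), params$sigma_need, gh1$z, gh1$w))
    P <- ltchurdle:::.cpp_predict_mnl_marg(X %*% params$beta_use,
                                           params$sigma_use, gh3$z, gh3$w,
                                           FALSE)
    cbind(need = pn, informal = pn * P[, 2], formal = pn * P[, 3],
          mixed = pn * P[, 4])
  }
  out <- matrix(NA_real_, length(columns), length(covariates),
                dimnames = list(columns, covariates))
  for (cv in covariates) {
    pair <- ltchurdle:::counterfactual_pair(d, cv, meta)
    dif <- colMeans(predict_true(pair$hi) - predict_true(pair$lo))
    out[, cv] <- dif[columns]
  }
  out
}

# Generator-truth AMEs CONDITIONAL on a realized study population: fresh
# individual draws are assigned to the population's realized countries (their
# covariates and drawn random intercepts), so probabilities are exact softmax
# evaluations with no integration. This is the estimand the fitted pipeline
# targets; comparing to the law-level oracle would additionally require
# country-level resampling, which the within-country bootstrap by design
# does not propagate.
true_ame_oracle_conditional <- function(pop, covariates, columns,
                                        n_mc = 1e6, seed = 7) {
  set.seed(seed)
  params <- pop$params
  ct <- pop$country_table
  J <- nrow(ct)
  cfg <- default_covariate_config()
  n <- n_mc
  d <- data.frame(country_id = rep(ct$country_id, length.out = n))
  d$age <- ltchurdle:::rtnorm(n, cfg$age$mean, cfg$age$sd, cfg$age$min,
                              cfg$age$max)
  d$female <- rbinom(n, 1, cfg$female$p)
  d$wealth_quintile <- sample.int(5, n, TRUE)
  d$education <- sample(c("primary", "secondary", "tertiary"), n, TRUE,
                        prob = cfg$education$p)
  d$has_partner <- rbinom(n, 1, cfg$has_partner$p)
  d$has_children <- rbinom(n, 1, cfg$has_children$p)
  d <- expand_covariates(d, ct)
  jidx <- match(d$country_id, ct$country_id)
  meta <- ltchurdle:::covariate_meta(params$covariates)

  predict_true <- function(dd) {
    X <- cbind(1, as.matrix(dd[params$covariates]))
    pn <- plogis(drop(X %*% params$beta_need) + params$u_need[jidx])
    S <- X %*% params$beta_use + params$u_use[jidx, , drop = FALSE]
    E <- exp(cbind(0, S))
    P <- E / rowSums(E)
    cbind(need = pn, informal = pn * P[, 2], formal = pn * P[, 3],
          mixed = pn * P[, 4])
  }
  out <- matrix(NA_real_, length(columns), length(covariates),
                dimnames = list(columns, covariates))
  for (cv in covariates) {
    pair <- ltchurdle:::counterfactual_pair(d, cv, meta)
    dif <- colMeans(predict_true(pair$hi) - predict_true(pair$lo))
    out[, cv] <- dif[columns]
  }
  out
}
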