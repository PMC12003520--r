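# Part I: country-random-intercept binary logit for care need, estimated by
# maximum likelihood with (adaptive) Gauss-Hermite quadrature.

gh_rule <- function(n) {
  r <- pracma::gaussHermite(n)
  list(z = r$x, w = r$w)
}

# Hessian by central finite differences of an analytic gradient.
fd_hessian <- function(par, grad_fn, h = 1e-5) {
  p <- length(par)
  H <- matrix(0, p, p)
  for (k in seq_len(p)) {
    hp <- hm <- par
    hk <- h * max(1, abs(par[k]))
    hp[k] <- par[k] + hk
    hm[k] <- par[k] - hk
    H[, k] <- (grad_fn(hp) - grad_fn(hm)) / (2 * hk)
  }
  (H + t(H)) / 2
}

check_separation <- function(beta, names, bound = 30) {
  bad <- which(abs(beta) > bound)
  if (length(bad))
    stop("apparent separation: coefficient(s) diverging for ",
         paste(names[bad], collapse = ", "),
         " (|beta| > ", bound, ")", call. = FALSE)
}

#' Specification of the Part I random-intercept binary logit
#'
#' @param response Name of the 0/1 response column (default `"need"`).
#' @param fixed_effects Ordered character vector of design column names; an
#'   intercept is always prepended.
#' @param cluster Name of the cluster (country) id column.
#' @param quadrature_nodes Gauss-Hermite nodes (default 15).
#' @param adaptive Centre and scale the nodes at each cluster's posterior
#'   mode (default `TRUE`); `FALSE` gives plain GHQ.
#' @param max_iter Maximum BFGS iterations.
#' @param gradient_tolerance Convergence declared when the largest absolute
#'   score is below `gradient_tolerance * (1 + |loglik|)`.
#' @return Object of class `binary_mixed_spec`.
#' @export
binary_mixed_spec <- function(response = "need", fixed_effects,
                              cluster = "country_id", quadrature_nodes = 15,
                              adaptive = TRUE, max_iter = 200,
                              gradient_tolerance = 1e-5) {
  stopifnot(quadrature_nodes >= 1)
  structure(list(response = response, fixed_effects = fixed_effects,
                 cluster = cluster, quadrature_nodes = as.integer(quadrature_nodes),
                 adaptive = isTRUE(adaptive), max_iter = as.integer(max_iter),
                 gradient_tolerance = gradient_tolerance),
            class = "binary_mixed_spec")
}

prepare_binary <- function(dataset, spec) {
  for (nm in c(spec$response, spec$cluster))
    if (!nm %in% names(dataset))
      stop("column '", nm, "' not found in dataset", call. = FALSE)
  y <- dataset[[spec$response]]
  if (!all(y %in% 0:1))
    stop("response '", spec$response, "' must be binary 0/1", call. = FALSE)
  X <- build_design(dataset, spec$fixed_effects, check_rank = TRUE)
  ci <- cluster_index(dataset[[spec$cluster]])
  list(y = as.numeric(y[ci$order]), X = X[ci$order, , drop = FALSE], ci = ci)
}

#' Marginal log-likelihood of the Part I model
#'
#' Sum over clusters of the log of the Bernoulli-logit cluster contribution
#' integrated over the N(0, sigma^2) random intercept, approximated by
#' (adaptive) Gauss-Hermite quadrature. `sigma = 0` evaluates the pooled
#' logit log-likelihood exactly, with no quadrature.
#'
#' @param dataset Data frame with response, covariates and cluster columns.
#' @param beta Coefficient vector, intercept first.
#' @param sigma Random-intercept SD (>= 0).
#' @param spec A [binary_mixed_spec()].
#' @return The marginal log-likelihood (scalar).
#' @export
loglik_binary <- function(dataset, beta, sigma, spec) {
  if (sigma < 0) stop("sigma must be >= 0", call. = FALSE)
  d <- prepare_binary(dataset, spec)
  if (length(beta) != ncol(d$X))
    stop("beta has length ", length(beta), " but the design has ",
         ncol(d$X), " columns", call. = FALSE)
  gh <- gh_rule(spec$quadrature_nodes)
  .cpp_binary_loglik(d$y, d$X, d$ci$start, d$ci$size, beta, sigma,
                     gh$z, gh$w, spec$adaptive, FALSE)$loglik
}

#' Fit the Part I random-intercept binary logit
#'
#' Maximizes the AGHQ marginal likelihood over `(beta, log sigma)` by BFGS
#' with analytic gradients, starting from the pooled-logit estimate and
#' `sigma = 0.3`. The covariance matrix is the inverse observed information
#' at the optimum (finite differences of the analytic gradient); it is meant
#' for diagnostics and starting values — inference on margins uses the
#' bootstrap.
#'
#' @param dataset Data frame.
#' @param spec A [binary_mixed_spec()].
#' @param start Optional warm start, `list(beta =, sigma =)`.
#' @param fix_sigma Optionally hold the random-intercept SD fixed at this
#'   value and maximize over `beta` only (``fix_sigma = 0`` gives the exact
#'   pooled-logit reduction).
#' @param compute_vcov Set `FALSE` to skip the observed-information matrix
#'   (used inside the bootstrap).
#' @return Object of class `binary_mixed_fit` with elements `beta_hat`,
#'   `sigma_hat`, `loglik`, `vcov` (for `(beta, log sigma)`), `converged`,
#'   `boundary` (sigma at the zero boundary), `n_obs`, `n_clusters`, `spec`.
#' @export
fit_binary <- function(dataset, spec, start = NULL, fix_sigma = NULL,
                       compute_vcov = TRUE) {
  d <- prepare_binary(dataset, spec)
  if (length(d$ci$size) < 2)
    stop("at least 2 clusters are required", call. = FALSE)
  if (length(unique(d$y)) < 2)
    stop("response '", spec$response, "' takes a single value; ",
         "both classes are required", call. = FALSE)
  gh <- gh_rule(spec$quadrature_nodes)
  p <- ncol(d$X)
  cn <- colnames(d$X)

  # optimize in a column-equilibrated design space; report original scale
  scl <- design_scales(d$X)
  Xs <- sweep(d$X, 2, scl, "/")

  free_sigma <- is.null(fix_sigma)
  if (is.null(start)) {
    g0 <- suppressWarnings(glm.fit(Xs, d$y, family = binomial()))
    par0 <- c(g0$coefficients, if (free_sigma) log(0.3))
  } else {
    par0 <- c(start$beta * scl,
              if (free_sigma) log(max(start$sigma, 1e-3)))
  }

  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    sg <- if (free_sigma) exp(par[p + 1L]) else fix_sigma
    r <- .cpp_binary_loglik(d$y, Xs, d$ci$start, d$ci$size,
                            par[seq_len(p)], sg,
                            gh$z, gh$w, spec$adaptive, TRUE)
    cache$par <- par
    cache$res <- r
    r
  }
  fn <- function(par) -evaluate(par)$loglik
  gr <- function(par) {
    r <- evaluate(par)
    -c(r$grad_beta, if (free_sigma) r$grad_logsigma)
  }
  # interior-optimality score; a boundary-zero sigma has a non-vanishing
  # (downhill) log-sigma score and is exempted, as usual for boundary MLEs
  conv_score <- function(par) {
    g <- gr(par)
    if (free_sigma && exp(par[p + 1L]) < 1e-3 && g[p + 1L] > 0)
      g[p + 1L] <- 0
    max(abs(g))
  }
  opt <- optim(par0, fn, gr, method = "BFGS",
               control = list(maxit = spec$max_iter, reltol = 1e-9))
  stationary <- FALSE
  for (restart in 1:3) {
    # a fresh BFGS (reset Hessian) from the terminal point polishes the
    # score when reltol stopped early on an ill-conditioned ridge
    if (conv_score(opt$par) <
          spec$gradient_tolerance * (1 + abs(opt$value))) break
    prev <- opt$value
    opt <- optim(opt$par, fn, gr, method = "BFGS",
                 control = list(maxit = spec$max_iter, reltol = 1e-9))
    if (prev - opt$value < 1e-7 * (1 + abs(opt$value))) {
      # flat likelihood (weakly identified corner): no further improvement
      # is attainable, accept the point as the (possibly flat) optimum
      stationary <- TRUE
      break
    }
  }
  beta <- setNames(opt$par[seq_len(p)] / scl, cn)
  check_separation(opt$par[seq_len(p)], cn)
  ll <- -opt$value
  g_final <- conv_score(opt$par)
  converged <- opt$convergence == 0 &&
    (stationary || g_final < spec$gradient_tolerance * (1 + abs(ll)))
  if (!converged)
    warning("fit_binary did not meet the gradient tolerance (max score ",
            format(g_final, digits = 3), ")", call. = FALSE)
  sigma <- if (free_sigma) exp(opt$par[p + 1L]) else fix_sigma
  boundary <- sigma < 1e-4

  vc <- matrix(NA_real_, p + 1L, p + 1L)
  if (compute_vcov) {
    H <- fd_hessian(opt$par, function(q) gr(q))   # hessian of -loglik (scaled)
    vc <- tryCatch({
      Tm <- diag(c(1 / scl, if (free_sigma) 1))
      full <- matrix(NA_real_, p + 1L, p + 1L)
      blk <- Tm %*% solve(H) %*% Tm
      full[seq_len(nrow(blk)), seq_len(nrow(blk))] <- blk
      full
    }, error = function(e) {
      warning("observed information is singular; vcov set to NA", call. = FALSE)
      matrix(NA_real_, p + 1L, p + 1L)
    })
  }
  dimnames(vc) <- list(c(cn, "log_sigma"), c(cn, "log_sigma"))

  structure(list(beta_hat = beta, sigma_hat = sigma, loglik = ll,
                 vcov = vc, converged = converged, boundary = boundary,
                 n_obs = length(d$y), n_clusters = length(d$ci$size),
                 spec = spec, optim_counts = opt$counts),
            class = "binary_mixed_fit")
}

#' Predicted need probabilities
#'
#' `marginal` integrates the logistic over the estimated random-intercept
#' law (population-averaged probability); `conditional_zero` evaluates at
#' `u = 0` (median country).
#'
#' @param fit A `binary_mixed_fit`.
#' @param dataset Data frame with the fit's covariates.
#' @param mode `"marginal"` or `"conditional_zero"`.
#' @param nodes Gauss-Hermite nodes for the marginal integral.
#' @return Probability vector in (0, 1), one element per row.
#' @export
predict_need <- function(fit, dataset, mode = c("marginal", "conditional_zero"),
                         nodes = 30) {
  mode <- match.arg(mode)
  X <- build_design(dataset, fit$spec$fixed_effects)
  eta <- drop(X %*% fit$beta_hat)
  if (mode == "conditional_zero") return(plogis(eta))
  gh <- gh_rule(nodes)
  as.numeric(.cpp_predict_binary_marg(eta, fit$sigma_hat, gh$z, gh$w))
}

#' @export
print.binary_mixed_fit <- function(x, ...) {
  cat("Random-intercept binary logit (AGHQ,",
      x$spec$quadrature_nodes, "nodes)\n")
  cat("  n =", x$n_obs, " clusters =", x$n_clusters,
      " loglik =", format(x$loglik, digits = 8), "\n")
  cat("  sigma =", format(x$sigma_hat, digits = 4),
      if (x$boundary) "(boundary zero)" else "", "\n")
  print(round(x$beta_hat, 4))
  invisible(x)
}
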