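# Part II: country-random-intercept multinomial logit for care type
# conditional on need (reference category "none"), estimated by maximum
# likelihood with adaptive tensor-product Gauss-Hermite quadrature.

#' Specification of the Part II random-intercept multinomial logit
#'
#' @param category_labels The four care categories, reference first.
#' @param fixed_effects Ordered design column names; intercept prepended.
#' @param cluster Cluster (country) id column.
#' @param random_structure `"per_category_independent"` (one independent
#'   random intercept per non-reference care type per country; 3-D
#'   tensor-product quadrature) or `"shared"` (a single common intercept
#'   added to all three non-reference scores; 1-D quadrature).
#' @param quadrature_nodes_per_dim Nodes per integration dimension
#'   (default 7).
#' @param adaptive Adaptive (posterior-mode-centred) quadrature.
#' @param max_iter,gradient_tolerance As in [binary_mixed_spec()].
#' @return Object of class `multinomial_mixed_spec`.
#' @export
multinomial_mixed_spec <- function(category_labels = CARE_LEVELS,
                                   fixed_effects,
                                   cluster = "country_id",
                                   random_structure = c("per_category_independent",
                                                        "shared"),
                                   quadrature_nodes_per_dim = 7,
                                   adaptive = TRUE, max_iter = 500,
                                   gradient_tolerance = 1e-5) {
  random_structure <- match.arg(random_structure)
  if (length(category_labels) != 4L || category_labels[1] != "none")
    stop("category_labels must be the four care categories with 'none' first",
         call. = FALSE)
  stopifnot(quadrature_nodes_per_dim >= 1)
  structure(list(category_labels = category_labels,
                 fixed_effects = fixed_effects, cluster = cluster,
                 random_structure = random_structure,
                 quadrature_nodes_per_dim = as.integer(quadrature_nodes_per_dim),
                 adaptive = isTRUE(adaptive), max_iter = as.integer(max_iter),
                 gradient_tolerance = gradient_tolerance),
            class = "multinomial_mixed_spec")
}

prepare_mnl <- function(dataset, spec, require_need = TRUE) {
  for (nm in c("care_use", spec$cluster))
    if (!nm %in% names(dataset))
      stop("column '", nm, "' not found in dataset", call. = FALSE)
  if (require_need) {
    if (!"need" %in% names(dataset))
      stop("dataset must carry the derived 'need' indicator", call. = FALSE)
    if (any(dataset$need != 1L))
      stop("hurdle violation: ", sum(dataset$need != 1L),
           " record(s) without need in the Part II sample", call. = FALSE)
  }
  bad <- setdiff(unique(dataset$care_use), spec$category_labels)
  if (length(bad))
    stop("unknown care_use labels: ", paste(bad, collapse = ", "), call. = FALSE)
  y <- match(dataset$care_use, spec$category_labels) - 1L   # 0 = reference
  X <- build_design(dataset, spec$fixed_effects, check_rank = TRUE)
  ci <- cluster_index(dataset[[spec$cluster]])
  list(y = as.integer(y[ci$order]), X = X[ci$order, , drop = FALSE], ci = ci)
}

mnl_sigma_vec <- function(sigma, spec) {
  if (spec$random_structure == "shared") {
    if (length(sigma) != 1L) stop("shared structure takes one SD", call. = FALSE)
    c(sigma, 0, 0)
  } else {
    if (length(sigma) != 3L) stop("three per-category SDs required", call. = FALSE)
    as.numeric(sigma)
  }
}

#' Marginal log-likelihood of the Part II model
#'
#' Each cluster's product of categorical likelihoods is integrated over the
#' random-intercept law: a 3-D tensor-product adaptive Gauss-Hermite grid
#' under `per_category_independent`, 1-D under `shared`. All SDs equal to 0
#' gives the pooled multinomial-logit log-likelihood exactly.
#'
#' @param dataset Needer subsample (every row must have `need == 1`).
#' @param params List with `beta` (p x 3 matrix, columns informal/formal/
#'   mixed) and `sigma` (length 3, or length 1 for `shared`).
#' @param spec A [multinomial_mixed_spec()].
#' @return The marginal log-likelihood (scalar).
#' @export
loglik_multinomial <- function(dataset, params, spec) {
  sig <- mnl_sigma_vec(params$sigma, spec)
  if (any(sig < 0)) stop("sigma must be >= 0", call. = FALSE)
  d <- prepare_mnl(dataset, spec)
  B <- as.matrix(params$beta)
  if (nrow(B) != ncol(d$X) || ncol(B) != 3L)
    stop("beta must be ", ncol(d$X), " x 3 (got ", nrow(B), " x ", ncol(B),
         ")", call. = FALSE)
  gh <- gh_rule(spec$quadrature_nodes_per_dim)
  .cpp_mnl_loglik(d$y, d$X, d$ci$start, d$ci$size, B, sig, gh$z, gh$w,
                  spec$adaptive, spec$random_structure == "shared",
                  FALSE)$loglik
}

#' Fit the Part II random-intercept multinomial logit
#'
#' MLE over all non-reference category coefficient vectors and log-SDs by
#' BFGS with analytic gradients, from pooled multinomial-logit starting
#' values (via `nnet::multinom`) and SDs of 0.3.
#'
#' @inheritParams fit_binary
#' @param spec A [multinomial_mixed_spec()].
#' @param fix_sigma Optionally hold the random-intercept SDs fixed (length 3,
#'   or 1 for `shared`); all zero gives the exact pooled reduction.
#' @return Object of class `mnl_mixed_fit`: `beta_hat` (p x 3), `sigma_hat`
#'   (per category, or single shared), `loglik`, `vcov`, `converged`,
#'   `boundary`, `n_obs`, `n_clusters`, `spec`.
#' @export
fit_multinomial <- function(dataset, spec, start = NULL, fix_sigma = NULL,
                            compute_vcov = TRUE) {
  d <- prepare_mnl(dataset, spec)
  if (length(d$ci$size) < 2)
    stop("at least 2 clusters are required", call. = FALSE)
  obs <- table(factor(spec$category_labels[d$y + 1L],
                      levels = spec$category_labels))
  if (any(obs == 0))
    stop("care category never observed: ",
         paste(names(obs)[obs == 0], collapse = ", "), call. = FALSE)

  p <- ncol(d$X)
  cn <- colnames(d$X)
  nsig <- if (spec$random_structure == "shared") 1L else 3L
  gh <- gh_rule(spec$quadrature_nodes_per_dim)
  shared <- spec$random_structure == "shared"

  # optimize in a column-equilibrated design space; report original scale
  scl <- design_scales(d$X)
  Xs <- sweep(d$X, 2, scl, "/")

  free_sigma <- is.null(fix_sigma)
  if (is.null(start)) {
    yf <- factor(spec$category_labels[d$y + 1L], levels = spec$category_labels)
    mn <- nnet::multinom(yf ~ Xs - 1, trace = FALSE, maxit = 300)
    B0 <- t(coef(mn))   # p x 3, columns informal/formal/mixed
    par0 <- c(as.vector(B0), if (free_sigma) rep(log(0.3), nsig))
  } else {
    par0 <- c(as.vector(as.matrix(start$beta) * scl),
              if (free_sigma) log(pmax(start$sigma, 1e-3)))
  }

  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    B <- matrix(par[seq_len(3L * p)], p, 3L)
    sig <- if (free_sigma)
      mnl_sigma_vec(exp(par[3L * p + seq_len(nsig)]), spec)
    else mnl_sigma_vec(fix_sigma, spec)
    r <- .cpp_mnl_loglik(d$y, Xs, d$ci$start, d$ci$size, B, sig,
                         gh$z, gh$w, spec$adaptive, shared, TRUE)
    cache$par <- par
    cache$res <- r
    r
  }
  fn <- function(par) -evaluate(par)$loglik
  gr <- function(par) {
    r <- evaluate(par)
    gs <- if (shared) r$grad_logsigma[1] else r$grad_logsigma
    -c(as.vector(r$grad_beta), if (free_sigma) gs)
  }
  # interior-optimality score with boundary-zero sigma coordinates exempted
  conv_score <- function(par) {
    g <- gr(par)
    if (free_sigma)
      for (k in seq_len(nsig)) {
        j <- 3L * p + k
        if (exp(par[j]) < 1e-3 && g[j] > 0) g[j] <- 0
      }
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
  B <- matrix(opt$par[seq_len(3L * p)] / scl, p, 3L,
              dimnames = list(cn, spec$category_labels[-1]))
  for (k in 1:3)
    check_separation(matrix(opt$par[seq_len(3L * p)], p, 3L)[, k],
                     paste0(spec$category_labels[-1][k], ":", cn))
  ll <- -opt$value
  g_final <- conv_score(opt$par)
  converged <- opt$convergence == 0 &&
    (stationary || g_final < spec$gradient_tolerance * (1 + abs(ll)))
  if (!converged)
    warning("fit_multinomial did not meet the gradient tolerance (max score ",
            format(g_final, digits = 3), ")", call. = FALSE)
  sigma <- if (free_sigma) exp(opt$par[3L * p + seq_len(nsig)]) else
    rep_len(fix_sigma, nsig)
  names(sigma) <- if (shared) "shared" else spec$category_labels[-1]
  boundary <- sigma < 1e-4

  npar <- 3L * p + nsig
  vc <- matrix(NA_real_, npar, npar)
  if (compute_vcov) {
    H <- fd_hessian(opt$par, function(q) gr(q))
    vc <- tryCatch({
      Tm <- diag(c(rep(1 / scl, 3L), if (free_sigma) rep(1, nsig)))
      blk <- Tm %*% solve(H) %*% Tm
      full <- matrix(NA_real_, npar, npar)
      full[seq_len(nrow(blk)), seq_len(nrow(blk))] <- blk
      full
    }, error = function(e) {
      warning("observed information is singular; vcov set to NA", call. = FALSE)
      matrix(NA_real_, npar, npar)
    })
  }
  pn <- c(paste(rep(spec$category_labels[-1], each = p), cn, sep = ":"),
          paste0("log_sigma_", names(sigma)))
  dimnames(vc) <- list(pn, pn)

  structure(list(beta_hat = B, sigma_hat = sigma, loglik = ll, vcov = vc,
                 converged = converged, boundary = boundary,
                 n_obs = length(d$y), n_clusters = length(d$ci$size),
                 spec = spec, optim_counts = opt$counts),
            class = "mnl_mixed_fit")
}

#' Predicted conditional care-type probabilities
#'
#' Four-column probability table over (none, informal, formal, mixed), rows
#' summing to 1. `marginal` integrates the softmax over the estimated
#' random-intercept law by tensor-product Gauss-Hermite quadrature;
#' `conditional_zero` evaluates at u = 0.
#'
#' @param fit A `mnl_mixed_fit`.
#' @param dataset Data frame with the fit's covariates.
#' @param mode `"marginal"` or `"conditional_zero"`.
#' @param nodes_per_dim Quadrature nodes per dimension for `marginal`.
#' @return Numeric matrix, n x 4, columns named by category.
#' @export
predict_conditional <- function(fit, dataset,
                                mode = c("marginal", "conditional_zero"),
                                nodes_per_dim = 8) {
  mode <- match.arg(mode)
  X <- build_design(dataset, fit$spec$fixed_effects)
  Eta <- X %*% fit$beta_hat
  shared <- fit$spec$random_structure == "shared"
  sig <- if (mode == "conditional_zero") c(0, 0, 0) else
    mnl_sigma_vec(fit$sigma_hat, fit$spec)
  gh <- gh_rule(nodes_per_dim)
  P <- .cpp_predict_mnl_marg(Eta, sig, gh$z, gh$w, shared)
  colnames(P) <- fit$spec$category_labels
  P
}

#' @export
print.mnl_mixed_fit <- function(x, ...) {
  cat("Random-intercept multinomial logit (reference 'none';",
      x$spec$random_structure, "random intercepts; AGHQ",
      x$spec$quadrature_nodes_per_dim, "nodes/dim)\n")
  cat("  n =", x$n_obs, " clusters =", x$n_clusters,
      " loglik =", format(x$loglik, digits = 8), "\n")
  cat("  sigma:", paste(names(x$sigma_hat), format(x$sigma_hat, digits = 4),
                        sep = "=", collapse = ", "), "\n")
  print(round(x$beta_hat, 4))
  invisible(x)
}
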