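# Two-part (hurdle) combination: Part I need probability times Part II
# conditional care-type probability, average marginal effects for the seven
# output columns, bootstrap uncertainty, and fit statistics.

AME_COLUMNS <- c("need", "informal_given_need", "formal_given_need",
                 "mixed_given_need", "informal", "formal", "mixed")
AME_COLUMNS_COLLAPSED <- c("need", "use_given_need", "use")

#' Fit the two-part model
#'
#' Part I (binary random-intercept logit) on the full sample with the need
#' indicator derived from `need_definition`; Part II (multinomial
#' random-intercept logit) on the needer subsample. The hurdle assumption —
#' care use implies need — is enforced: records without derived need but
#' with `care_use != "none"` raise an error listing the offending ids.
#'
#' @param dataset Individual-level data frame with expanded design columns
#'   (see [expand_covariates()]).
#' @param spec1 A [binary_mixed_spec()]; its `response` is replaced by the
#'   derived need indicator.
#' @param spec2 A [multinomial_mixed_spec()].
#' @param need_definition Need definition passed to [derive_need()].
#' @param min_needers Warn when fewer needers than this remain for Part II.
#' @param start Optional warm starts,
#'   `list(part1 = list(beta, sigma), part2 = list(beta, sigma))`.
#' @param compute_vcov Passed to both part fitters.
#' @param fingerprint Attach a hash of the dataset (skipped inside the
#'   bootstrap, where it would re-serialize the data every replicate).
#' @return Object of class `twopart_fit` with `part1`, `part2`,
#'   `need_definition`, `n_needers`, `data_hash`.
#' @export
fit_two_part <- function(dataset, spec1, spec2, need_definition = "iadl1",
                         min_needers = 200, start = NULL,
                         compute_vcov = TRUE, fingerprint = TRUE) {
  dataset$need <- derive_need(dataset, need_definition)
  viol <- which(dataset$need == 0L & dataset$care_use != "none")
  if (length(viol))
    stop("hurdle violation under need definition '", need_definition, "': ",
         length(viol), " record(s) use care without derived need; person_id: ",
         paste(head(dataset$person_id[viol], 20), collapse = ", "),
         call. = FALSE)
  n_needers <- sum(dataset$need)
  if (n_needers < min_needers)
    warning("only ", n_needers, " needers available for Part II (minimum ",
            min_needers, ")", call. = FALSE)
  if (n_needers == 0L)
    stop("no records satisfy need definition '", need_definition, "'",
         call. = FALSE)
  spec1$response <- "need"
  part1 <- fit_binary(dataset, spec1, start = start$part1,
                      compute_vcov = compute_vcov)
  part2 <- fit_multinomial(dataset[dataset$need == 1L, , drop = FALSE], spec2,
                           start = start$part2, compute_vcov = compute_vcov)
  structure(list(part1 = part1, part2 = part2,
                 need_definition = need_definition,
                 n_needers = n_needers,
                 data_hash = if (fingerprint) rlang::hash(dataset) else NA_character_),
            class = "twopart_fit")
}

#' Unconditional care-use probabilities
#'
#' The hurdle product: `P(type k) = P(need) * P(k | need)` for the three
#' care types and `P(no_care) = 1 - P(need) + P(need) * P(none | need)`.
#' Rows sum to 1 by construction.
#'
#' @param fit A `twopart_fit`.
#' @param dataset Data frame with the design columns.
#' @param mode Random-effect treatment for both parts: `"marginal"`
#'   (population-averaged, the default) or `"conditional_zero"`.
#' @return Numeric matrix, n x 4, columns `no_care`, `informal`, `formal`,
#'   `mixed`.
#' @export
predict_unconditional <- function(fit, dataset,
                                  mode = c("marginal", "conditional_zero")) {
  mode <- match.arg(mode)
  pn <- predict_need(fit$part1, dataset, mode)
  pc <- predict_conditional(fit$part2, dataset, mode)
  out <- cbind(no_care = 1 - pn + pn * pc[, "none"],
               informal = pn * pc[, "informal"],
               formal = pn * pc[, "formal"],
               mixed = pn * pc[, "mixed"])
  out
}

# Predicted probability for one output column. `nodes` controls the
# quadrature sizes of the marginal integrals (binary / per MNL dimension).
predict_column <- function(fit, dataset, column, mode = "marginal",
                           nodes = c(binary = 30, mnl = 8)) {
  if (!column %in% c(AME_COLUMNS, AME_COLUMNS_COLLAPSED))
    stop("unknown output column '", column, "'", call. = FALSE)
  if (column == "need")
    return(predict_need(fit$part1, dataset, mode, nodes = nodes[["binary"]]))
  if (grepl("_given_need$", column)) {
    pc <- predict_conditional(fit$part2, dataset, mode,
                              nodes_per_dim = nodes[["mnl"]])
    k <- sub("_given_need$", "", column)
    return(if (k == "use") 1 - pc[, "none"] else pc[, k])
  }
  pn <- predict_need(fit$part1, dataset, mode, nodes = nodes[["binary"]])
  pc <- predict_conditional(fit$part2, dataset, mode,
                            nodes_per_dim = nodes[["mnl"]])
  if (column == "use") return(pn * (1 - pc[, "none"]))
  pn * pc[, column]
}

# --- covariate metadata -----------------------------------------------------
# Dummy groups are mutually exclusive sets sharing one reference level; the
# age square is tied to age for the coherent joint perturbation.
covariate_meta <- function(design_names) {
  groups <- list()
  w <- grep("^wealth_q[2-5]$", design_names, value = TRUE)
  if (length(w)) groups$wealth <- w
  e <- intersect(c("edu_secondary", "edu_tertiary"), design_names)
  if (length(e)) groups$education <- e
  list(groups = groups,
       age_pair = all(c("age_c", "age2_c") %in% design_names))
}

# Counterfactual datasets (hi, lo) for one covariate, or NULL for continuous.
counterfactual_pair <- function(dataset, covariate, meta) {
  x <- dataset[[covariate]]
  grp <- NULL
  for (g in meta$groups) if (covariate %in% g) grp <- g
  binaryish <- all(x %in% 0:1)
  if (!binaryish && is.null(grp)) return(NULL)
  hi <- lo <- dataset
  if (!is.null(grp)) for (g in grp) hi[[g]] <- lo[[g]] <- 0
  hi[[covariate]] <- 1
  lo[[covariate]] <- if (is.null(grp)) 0 else lo[[covariate]]
  list(hi = hi, lo = lo)
}

#' Average marginal effect of one covariate on one output column
#'
#' Binary and grouped-dummy covariates: the mean over all records of the
#' difference in predicted probability with the covariate at its level
#' versus the reference (other dummies of the same group zeroed), all else
#' observed. Continuous covariates: the mean central-difference numerical
#' derivative with step `step_scale * sd(x)`. The special name `"age_joint"`
#' perturbs age and its square coherently (diagnostic complement to the
#' separate `age_c` and `age2_c` rows).
#'
#' @param fit A `twopart_fit`.
#' @param dataset Data frame with the design columns.
#' @param covariate A design column name, or `"age_joint"`.
#' @param column One of `r paste0('\x60', AME_COLUMNS, '\x60', collapse = ", ")`,
#'   or collapsed `use_given_need` / `use`.
#' @param mode Prediction mode, see [predict_unconditional()].
#' @param step_scale Relative step of the central difference.
#' @param nodes Quadrature sizes of the marginal prediction integrals,
#'   `c(binary =, mnl =)`.
#' @return The average marginal effect (scalar).
#' @export
ame <- function(fit, dataset, covariate, column, mode = "marginal",
                step_scale = 1e-5, nodes = c(binary = 30, mnl = 8)) {
  design <- union(fit$part1$spec$fixed_effects, fit$part2$spec$fixed_effects)
  meta <- covariate_meta(design)
  if (identical(covariate, "age_joint")) {
    if (!meta$age_pair)
      stop("age_joint requires both age_c and age2_c in the design",
           call. = FALSE)
    h <- step_scale * max(sd(dataset$age_c), 1)
    hi <- lo <- dataset
    hi$age_c <- dataset$age_c + h
    hi$age2_c <- hi$age_c^2
    lo$age_c <- dataset$age_c - h
    lo$age2_c <- lo$age_c^2
    return(mean(predict_column(fit, hi, column, mode, nodes) -
                  predict_column(fit, lo, column, mode, nodes)) / (2 * h))
  }
  if (!covariate %in% design)
    stop("covariate '", covariate, "' is not in the model design",
         call. = FALSE)
  pair <- counterfactual_pair(dataset, covariate, meta)
  if (!is.null(pair))
    return(mean(predict_column(fit, pair$hi, column, mode, nodes) -
                  predict_column(fit, pair$lo, column, mode, nodes)))
  h <- step_scale * max(sd(dataset[[covariate]]), 1e-8)
  hi <- lo <- dataset
  hi[[covariate]] <- dataset[[covariate]] + h
  lo[[covariate]] <- dataset[[covariate]] - h
  mean(predict_column(fit, hi, column, mode, nodes) -
         predict_column(fit, lo, column, mode, nodes)) / (2 * h)
}

# All requested output columns at once, sharing the two part predictions.
column_table <- function(fit, dataset, columns, mode = "marginal",
                         nodes = c(binary = 30, mnl = 8)) {
  pn <- NULL
  pc <- NULL
  need_pn <- any(!grepl("_given_need$", columns))
  need_pc <- any(columns != "need")
  if (need_pn)
    pn <- predict_need(fit$part1, dataset, mode, nodes = nodes[["binary"]])
  if (need_pc)
    pc <- predict_conditional(fit$part2, dataset, mode,
                              nodes_per_dim = nodes[["mnl"]])
  out <- matrix(NA_real_, nrow(dataset), length(columns),
                dimnames = list(NULL, columns))
  for (cl in columns) {
    out[, cl] <- if (cl == "need") pn
    else if (cl == "use_given_need") 1 - pc[, "none"]
    else if (grepl("_given_need$", cl)) pc[, sub("_given_need$", "", cl)]
    else if (cl == "use") pn * (1 - pc[, "none"])
    else pn * pc[, cl]
  }
  out
}

# Point-estimate AME table (no uncertainty): covariates x columns. Binary
# and grouped-dummy covariates share one hi/lo counterfactual prediction
# across all columns; continuous covariates fall back to ame().
ame_point_table <- function(fit, dataset, covariates, columns,
                            mode = "marginal",
                            nodes = c(binary = 30, mnl = 8)) {
  design <- union(fit$part1$spec$fixed_effects, fit$part2$spec$fixed_effects)
  meta <- covariate_meta(design)
  out <- matrix(NA_real_, length(covariates), length(columns),
                dimnames = list(covariates, columns))
  for (cv in covariates) {
    pair <- if (cv %in% design) counterfactual_pair(dataset, cv, meta)
    if (is.null(pair)) {
      for (cl in columns)
        out[cv, cl] <- ame(fit, dataset, cv, cl, mode, nodes = nodes)
    } else {
      dif <- column_table(fit, pair$hi, columns, mode, nodes) -
        column_table(fit, pair$lo, columns, mode, nodes)
      out[cv, ] <- colMeans(dif)
    }
  }
  out
}

stars_from_p <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.10, "*", "")))
}

#' Bootstrap average marginal effects with confidence intervals
#'
#' Resamples individuals with replacement — by default within each country,
#' preserving country sample sizes — refits both parts per replicate (warm
#' started at the full-sample estimates), recomputes every requested AME
#' cell, and reports the replicate SD as the bootstrap SE together with
#' basic ("inverted") or percentile confidence intervals. Significance stars
#' use the normal approximation `z = estimate / SE` at the 10%/5%/1%
#' thresholds. Replicates whose refit fails or does not converge are dropped
#' and counted; more than 20% failures is an error.
#'
#' @param dataset Individual-level data frame with design columns.
#' @param spec1,spec2 Part specifications.
#' @param need_definition Passed to [fit_two_part()].
#' @param B Number of bootstrap replicates (>= 2; default 100).
#' @param seed Integer seed; the replicate stream is deterministic given it.
#' @param ci_method `"basic"` (reverse percentile, the default reading of
#'   "inverted" intervals) or `"percentile"`.
#' @param level Confidence level (default 0.95).
#' @param resample `"within_country"` (default) or `"cluster"` (resample
#'   whole countries with replacement).
#' @param covariates Design columns to report (default: every fixed effect).
#' @param columns Output columns (default: the seven-column layout; use
#'   `c("need", "use_given_need", "use")` for the collapsed layout).
#' @param mode Prediction mode for the margins.
#' @param nodes Quadrature sizes of the prediction integrals, as in [ame()].
#' @return Object of class `ame_table`: a data frame with one row per
#'   (covariate, column) cell — `estimate`, `se`, `ci_lo`, `ci_hi`, `stars`
#'   — and metadata attributes (`B`, `B_failed`, `seed`, `ci_method`,
#'   `level`, `resample`, `mode`, `need_definition`).
#' @export
bootstrap_margins <- function(dataset, spec1, spec2,
                              need_definition = "iadl1", B = 100, seed = 1L,
                              ci_method = c("basic", "percentile"),
                              level = 0.95,
                              resample = c("within_country", "cluster"),
                              covariates = NULL, columns = AME_COLUMNS,
                              mode = "marginal",
                              nodes = c(binary = 30, mnl = 8)) {
  ci_method <- match.arg(ci_method)
  resample <- match.arg(resample)
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  if (is.null(covariates))
    covariates <- union(spec1$fixed_effects, spec2$fixed_effects)

  full <- fit_two_part(dataset, spec1, spec2, need_definition,
                       compute_vcov = FALSE)
  est <- ame_point_table(full, dataset, covariates, columns, mode, nodes)
  warm <- list(part1 = list(beta = full$part1$beta_hat,
                            sigma = full$part1$sigma_hat),
               part2 = list(beta = full$part2$beta_hat,
                            sigma = full$part2$sigma_hat))

  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, B)
  by_country <- split(seq_len(nrow(dataset)), dataset$country_id)
  reps <- array(NA_real_, c(length(covariates), length(columns), B))
  failed <- 0L
  for (b in seq_len(B)) {
    set.seed(rep_seeds[b])
    idx <- if (resample == "within_country") {
      unlist(lapply(by_country, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]),
        use.names = FALSE)
    } else {
      picked <- sample(names(by_country), length(by_country), replace = TRUE)
      unlist(lapply(seq_along(picked), function(j) {
        ii <- by_country[[picked[j]]]
        ii
      }), use.names = FALSE)
    }
    db <- dataset[idx, , drop = FALSE]
    if (resample == "cluster") {
      # relabel so repeated draws of one country act as distinct clusters
      sizes <- vapply(by_country[picked], length, integer(1))
      db$country_id <- rep(seq_along(picked), sizes)
    }
    db$person_id <- seq_len(nrow(db))
    rb <- tryCatch({
      fb <- suppressWarnings(
        fit_two_part(db, spec1, spec2, need_definition, min_needers = 0,
                     start = warm, compute_vcov = FALSE,
                     fingerprint = FALSE))
      if (!fb$part1$converged || !fb$part2$converged) stop("no convergence")
      ame_point_table(fb, db, covariates, columns, mode, nodes)
    }, error = function(e) NULL)
    if (is.null(rb)) failed <- failed + 1L else reps[, , b] <- rb
  }
  if (failed > 0.2 * B)
    stop("bootstrap failed in ", failed, " of ", B, " replicates; ",
         "check convergence diagnostics of the full-sample fit",
         call. = FALSE)

  a <- (1 - level) / 2
  cells <- expand.grid(covariate = covariates, column = columns,
                       stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(r) {
    i <- match(cells$covariate[r], covariates)
    j <- match(cells$column[r], columns)
    th <- est[i, j]
    draws <- reps[i, j, ]
    draws <- draws[!is.na(draws)]
    se <- sd(draws)
    q <- quantile(draws, c(a, 1 - a), names = FALSE, type = 7)
    ci <- if (ci_method == "basic") c(2 * th - q[2], 2 * th - q[1]) else q
    p <- if (se > 0) 2 * pnorm(-abs(th / se)) else as.numeric(th != 0)
    data.frame(covariate = cells$covariate[r], column = cells$column[r],
               estimate = th, se = se, ci_lo = ci[1], ci_hi = ci[2],
               stars = stars_from_p(p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  structure(out, class = c("ame_table", "data.frame"),
            B = B, B_failed = failed, seed = seed, ci_method = ci_method,
            level = level, resample = resample, mode = mode,
            need_definition = need_definition)
}

#' @export
print.ame_table <- function(x, digits = 3, ...) {
  cat("Average marginal effects (bootstrap B =", attr(x, "B"),
      "failed =", attr(x, "B_failed"),
      "| CI:", attr(x, "ci_method"), attr(x, "level") * 100, "% |",
      attr(x, "resample"), "resampling | need:",
      attr(x, "need_definition"), ")\n")
  wide <- format_ame_table(x, digits = digits)
  print(wide, right = TRUE)
  invisible(x)
}

#' Format an AME table in the wide published layout
#'
#' One row per covariate, one column per output column, cells
#' `estimate (SE) stars`.
#'
#' @param x An `ame_table`.
#' @param digits Digits for estimates and SEs.
#' @return A character data frame.
#' @export
format_ame_table <- function(x, digits = 3) {
  covs <- unique(x$covariate)
  cols <- unique(x$column)
  wide <- data.frame(row.names = covs)
  for (cl in cols) {
    sub <- x[x$column == cl, ]
    wide[[cl]] <- sprintf("%s (%s)%s",
                          formatC(sub$estimate[match(covs, sub$covariate)],
                                  digits = digits, format = "f"),
                          formatC(sub$se[match(covs, sub$covariate)],
                                  digits = digits, format = "f"),
                          sub$stars[match(covs, sub$covariate)])
  }
  wide
}

#' McFadden pseudo R-squared
#'
#' `1 - loglik / null_loglik`, where the null model is intercept plus random
#' intercept only, fitted on the identical sample. `incremental_r2` is the
#' gain of the full model over a reduced model (typically dropping the
#' country-level covariate block) against the same null.
#'
#' @param fit_loglik,null_loglik,full,reduced,null Log-likelihoods (scalars)
#'   or fitted objects with a `loglik` element.
#' @return Pseudo R-squared (scalar).
#' @export
mcfadden_r2 <- function(fit_loglik, null_loglik) {
  ll <- extract_ll(fit_loglik)
  l0 <- extract_ll(null_loglik)
  if (l0 >= 0)
    stop("null log-likelihood must be negative for nondegenerate data",
         call. = FALSE)
  1 - ll / l0
}

#' @rdname mcfadden_r2
#' @export
incremental_r2 <- function(full, reduced, null) {
  mcfadden_r2(full, null) - mcfadden_r2(reduced, null)
}

extract_ll <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  if (!is.null(x$loglik)) return(x$loglik)
  stop("cannot extract a log-likelihood from object of class ",
       paste(class(x), collapse = "/"), call. = FALSE)
}

#' @export
print.twopart_fit <- function(x, ...) {
  cat("Two-part hurdle fit (need definition:", x$need_definition, ")\n")
  cat("  Part I: n =", x$part1$n_obs, " loglik =",
      format(x$part1$loglik, digits = 8), "\n")
  cat("  Part II: n =", x$part2$n_obs, "needers, loglik =",
      format(x$part2$loglik, digits = 8), "\n")
  invisible(x)
}
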