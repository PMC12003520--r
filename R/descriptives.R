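# Weighted descriptive table by care-use category, with significance stars
# against the "no care" reference column.

wmean <- function(x, w) sum(w * x) / sum(w)
wvar <- function(x, w) {
  m <- wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}
kish_ess <- function(w) sum(w)^2 / sum(w^2)

# Weighted two-sample z-test with Kish effective sample sizes.
wz_test <- function(x1, w1, x0, w0) {
  if (length(x1) < 2 || length(x0) < 2) return(NA_real_)
  v1 <- wvar(x1, w1); v0 <- wvar(x0, w0)
  se <- sqrt(v1 / kish_ess(w1) + v0 / kish_ess(w0))
  if (!is.finite(se) || se == 0) return(NA_real_)
  2 * pnorm(-abs((wmean(x1, w1) - wmean(x0, w0)) / se))
}

table_one_rows <- function(data) {
  pct <- function(x) list(values = as.numeric(x) * 100, type = "pct")
  cont <- function(x) list(values = as.numeric(x), type = "mean")
  rows <- list(
    "IADL: at least 1 (%)" = pct(data$iadl_count >= 1),
    "IADL: at least 2 (%)" = pct(data$iadl_count >= 2),
    "ADL: at least 1 (%)" = pct(data$adl_count >= 1),
    "ADL: at least 2 (%)" = pct(data$adl_count >= 2),
    "2nd wealth quintile (%)" = pct(data$wealth_quintile == 2),
    "3rd wealth quintile (%)" = pct(data$wealth_quintile == 3),
    "4th wealth quintile (%)" = pct(data$wealth_quintile == 4),
    "5th wealth quintile (%)" = pct(data$wealth_quintile == 5),
    "Has a spouse/partner (%)" = pct(data$has_partner == 1),
    "Has children (%)" = pct(data$has_children == 1),
    "Secondary education (%)" = pct(data$education == "secondary"),
    "Tertiary education (%)" = pct(data$education == "tertiary"),
    "Age (years)" = cont(data$age),
    "Female (%)" = pct(data$female == 1))
  cty <- list(
    "Means testing (%)" = function(d) pct(d$means_testing == 1),
    "Cash-for-care benefits (%)" = function(d) pct(d$cash_for_care == 1),
    "LTC beds (p. 1,000)" = function(d) cont(d$ltc_beds),
    "Replacement rate (%)" = function(d) cont(d$replacement_rate),
    "Consumer price index (personal care)" = function(d) cont(d$cpi_personal_care),
    "GDP p. capita (in PPS)" = function(d) cont(d$gdp_per_capita),
    "Female labor market part. (%)" = function(d) cont(d$female_lfp))
  for (nm in names(cty))
    if (all(c("means_testing", "ltc_beds") %in% names(data)))
      rows[[nm]] <- cty[[nm]](data)
  rows
}

#' Weighted descriptive statistics by care-use category
#'
#' Weighted means (continuous rows) and weighted percents (binary rows) for
#' the no care / informal / formal / mixed columns and the total column,
#' with two-sided weighted z-tests (Kish effective sample size) of each care
#' column against the "no care" reference; stars at p < 0.10 / 0.05 / 0.01.
#'
#' @param dataset Individual-level data frame.
#' @param country_table Optional country table joined by `country_id` so the
#'   country-covariate rows can be reported.
#' @param weights_on Use the `weight` column (`TRUE`, default) or equal
#'   weights.
#' @return Object of class `descriptives_table`: a data frame with columns
#'   `no_care`, `informal`, `formal`, `mixed`, `total` and star columns for
#'   the three non-reference categories.
#' @export
table_one <- function(dataset, country_table = NULL, weights_on = TRUE) {
  if (!is.null(country_table))
    dataset <- merge(dataset,
                     country_table[, setdiff(names(country_table),
                                             setdiff(names(dataset), "country_id")),
                                   drop = FALSE],
                     by = "country_id", sort = FALSE)
  if (any(dataset$weight <= 0)) stop("weights must be positive", call. = FALSE)
  w <- if (weights_on) dataset$weight else rep(1, nrow(dataset))
  groups <- c(no_care = "none", informal = "informal", formal = "formal",
              mixed = "mixed")
  idx <- lapply(groups, function(g) which(dataset$care_use == g))
  empty <- names(idx)[vapply(idx, length, integer(1)) == 0]
  if (length(empty))
    warning("care category with 0 records: ",
            paste(empty, collapse = ", "), "; column emitted as NA",
            call. = FALSE)
  rows <- table_one_rows(dataset)

  out <- data.frame(row.names = names(rows))
  stars <- matrix("", length(rows), 3,
                  dimnames = list(names(rows),
                                  c("informal", "formal", "mixed")))
  for (g in names(groups)) {
    ii <- idx[[g]]
    out[[g]] <- vapply(rows, function(r)
      if (length(ii)) wmean(r$values[ii], w[ii]) else NA_real_, numeric(1))
  }
  out$total <- vapply(rows, function(r) wmean(r$values, w), numeric(1))
  i0 <- idx$no_care
  for (g in c("informal", "formal", "mixed")) {
    ii <- idx[[g]]
    pv <- vapply(rows, function(r)
      if (length(ii)) wz_test(r$values[ii], w[ii], r$values[i0], w[i0])
      else NA_real_, numeric(1))
    stars[, g] <- ifelse(is.na(pv), "", stars_from_p(pv))
  }
  out$stars_informal <- stars[, "informal"]
  out$stars_formal <- stars[, "formal"]
  out$stars_mixed <- stars[, "mixed"]
  attr(out, "n") <- c(vapply(idx, length, integer(1)),
                      total = nrow(dataset))
  attr(out, "weights_on") <- weights_on
  class(out) <- c("descriptives_table", "data.frame")
  out
}

#' @export
print.descriptives_table <- function(x, ...) {
  n <- attr(x, "n")
  num <- x[, c("no_care", "informal", "formal", "mixed", "total")]
  disp <- data.frame(
    `no care` = sprintf("%.1f", num$no_care),
    informal = paste0(sprintf("%.1f", num$informal), x$stars_informal),
    formal = paste0(sprintf("%.1f", num$formal), x$stars_formal),
    mixed = paste0(sprintf("%.1f", num$mixed), x$stars_mixed),
    total = sprintf("%.1f", num$total),
    check.names = FALSE, row.names = rownames(x))
  cat("Weighted descriptives by type of care use",
      if (attr(x, "weights_on")) "(survey weights)" else "(unweighted)", "\n")
  print(disp, right = TRUE)
  cat("N:", paste(names(n), n, sep = "=", collapse = "  "),
      "\nStars vs 'no care': *p<0.10 **p<0.05 ***p<0.01\n")
  invisible(x)
}
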