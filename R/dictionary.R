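# Data dictionary: canonical column names, categorical codings, and the
# expansion of raw survey columns into numeric design columns.

CARE_LEVELS <- c("none", "informal", "formal", "mixed")
EDU_LEVELS <- c("primary", "secondary", "tertiary")
GALI_LEVELS <- c("none", "mild", "severe")

IND_REQUIRED <- c("person_id", "country_id", "age", "female",
                  "wealth_quintile", "education", "has_partner",
                  "has_children", "iadl_count", "adl_count", "gali",
                  "care_use", "weight")
CTY_REQUIRED <- c("country_id", "means_testing", "cash_for_care", "ltc_beds",
                  "replacement_rate", "cpi_personal_care", "gdp_per_capita",
                  "female_lfp")

# Centring constants for country-level covariates (sample-wide reference
# values of the emulated survey); centring leaves slopes and marginal effects
# unchanged but keeps the optimizer well conditioned.
DICTIONARY_CENTERS <- c(age = 65, ltc_beds = 44.9, replacement_rate = 64.1,
                        cpi_personal_care = 102.8, gdp_per_capita = 107.3,
                        female_lfp = 70.7)

#' Standard design columns of the two-part model
#'
#' Individual-level block: wealth-quintile dummies (reference: 1st quintile),
#' education dummies (reference: primary), partner/children indicators,
#' centred age in years and its square, female indicator. Country-level
#' block: means-testing and cash-for-care indicators and centred macro/policy
#' covariates.
#'
#' @param block `"all"`, `"individual"` or `"country"`.
#' @return Character vector of design column names (intercept excluded).
#' @export
standard_covariates <- function(block = c("all", "individual", "country")) {
  block <- match.arg(block)
  ind <- c("wealth_q2", "wealth_q3", "wealth_q4", "wealth_q5",
           "edu_secondary", "edu_tertiary", "has_partner", "has_children",
           "age_c", "age2_c", "female")
  cty <- c("means_testing", "cash_for_care", "ltc_beds_c",
           "replacement_rate_c", "cpi_personal_care_c", "gdp_per_capita_c",
           "female_lfp_c")
  switch(block, all = c(ind, cty), individual = ind, country = cty)
}

#' Expand raw survey columns into numeric design columns
#'
#' Adds dummy and centred columns per the data dictionary:
#' `wealth_q2`..`wealth_q5`, `edu_secondary`, `edu_tertiary`,
#' `age_c = age - 65`, `age2_c = age_c^2`, and `<country covariate>_c`
#' centred at the reference values in `DICTIONARY_CENTERS`. Columns already
#' present are left untouched.
#'
#' @param data Individual-level data frame (see [validate_dataset()]),
#'   optionally already joined to the country table.
#' @param country_table Optional country table to join by `country_id` first.
#' @return `data` with the numeric design columns appended.
#' @export
expand_covariates <- function(data, country_table = NULL) {
  if (!is.null(country_table)) {
    keep <- setdiff(names(country_table), setdiff(names(data), "country_id"))
    data <- merge(data, country_table[, keep, drop = FALSE],
                  by = "country_id", sort = FALSE)
  }
  add <- function(nm, val) {
    if (!nm %in% names(data)) data[[nm]] <<- val
    invisible(NULL)
  }
  if ("wealth_quintile" %in% names(data))
    for (q in 2:5) add(paste0("wealth_q", q), as.numeric(data$wealth_quintile == q))
  if ("education" %in% names(data)) {
    add("edu_secondary", as.numeric(data$education == "secondary"))
    add("edu_tertiary", as.numeric(data$education == "tertiary"))
  }
  if ("age" %in% names(data)) {
    add("age_c", data$age - DICTIONARY_CENTERS[["age"]])
    add("age2_c", (data$age - DICTIONARY_CENTERS[["age"]])^2)
  }
  for (nm in setdiff(names(DICTIONARY_CENTERS), "age"))
    if (nm %in% names(data)) add(paste0(nm, "_c"), data[[nm]] - DICTIONARY_CENTERS[[nm]])
  data
}

# Design matrix with leading intercept, from an ordered covariate list.
build_design <- function(data, covariates, check_rank = FALSE) {
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols))
    stop("design columns not found in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  X <- cbind("(Intercept)" = rep(1, nrow(data)))
  if (length(covariates)) {
    M <- as.matrix(as.data.frame(lapply(data[covariates], as.numeric)))
    colnames(M) <- covariates
    X <- cbind(X, M)
  }
  if (anyNA(X)) stop("missing values in design columns; complete cases are required",
                     call. = FALSE)
  if (check_rank) {
    # rank check on a column-equilibrated copy (scale-invariant)
    scl <- pmax(apply(abs(X), 2, max), 1e-12)
    qrX <- qr(sweep(X, 2, scl, "/"))
    if (qrX$rank < ncol(X))
      warning("design matrix is rank deficient (rank ", qrX$rank, " < ",
              ncol(X), " columns)", call. = FALSE)
  }
  X
}

# column scales for internal optimizer equilibration
design_scales <- function(X) {
  scl <- apply(abs(X), 2, max)
  scl[scl == 0 | !is.finite(scl)] <- 1
  scl[1] <- 1
  scl
}

# Cluster bookkeeping: order rows by cluster, 0-based offsets for the C++ core.
cluster_index <- function(cluster_values) {
  ord <- order(cluster_values)
  cl <- cluster_values[ord]
  runs <- rle(as.character(cl))
  sizes <- runs$lengths
  starts <- cumsum(c(0L, sizes[-length(sizes)]))
  list(order = ord, start = as.integer(starts), size = as.integer(sizes),
       labels = runs$values)
}

#' Derive the binary care-need indicator
#'
#' Need definitions: `iadl1`/`iadl2` — at least 1 / 2 limitations with
#' instrumental activities of daily living; `adl1`/`adl2` — same for ADL;
#' `gali_any` — any global activity limitation (mild or severe);
#' `gali_severe` — severe limitation only.
#'
#' @param data Data frame with `iadl_count`, `adl_count`, `gali` as required
#'   by the chosen definition.
#' @param definition One of `"iadl1"`, `"iadl2"`, `"adl1"`, `"adl2"`,
#'   `"gali_any"`, `"gali_severe"`.
#' @return Integer 0/1 vector, one element per row.
#' @export
derive_need <- function(data, definition = c("iadl1", "iadl2", "adl1", "adl2",
                                             "gali_any", "gali_severe")) {
  definition <- match.arg(definition)
  field <- switch(definition,
                  iadl1 = , iadl2 = "iadl_count",
                  adl1 = , adl2 = "adl_count",
                  gali_any = , gali_severe = "gali")
  if (!field %in% names(data))
    stop("need definition '", definition, "' requires column '", field,
         "', which is missing", call. = FALSE)
  out <- switch(definition,
                iadl1 = data$iadl_count >= 1,
                iadl2 = data$iadl_count >= 2,
                adl1 = data$adl_count >= 1,
                adl2 = data$adl_count >= 2,
                gali_any = data$gali %in% c("mild", "severe"),
                gali_severe = data$gali == "severe")
  as.integer(out)
}

#' Validate an individual-level dataset against the data dictionary
#'
#' Structural problems (missing required columns, individuals whose
#' `country_id` has no row in the country table) stop with an error. Value
#' problems are collected into a machine-readable report: category labels,
#' value ranges, duplicate person ids, and hurdle consistency (care reported
#' with zero derived need under the active definition).
#'
#' @param individual Individual-level data frame.
#' @param country_table Country-level data frame.
#' @param need_definition Active need definition for the hurdle check.
#' @return List with `ok` (logical) and `checks`, a data frame with one row
#'   per check (`check`, `ok`, `n_bad`, `detail`).
#' @export
validate_dataset <- function(individual, country_table,
                             need_definition = "iadl1") {
  miss <- setdiff(IND_REQUIRED, names(individual))
  if (length(miss))
    stop("individual table is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  missc <- setdiff(CTY_REQUIRED, names(country_table))
  if (length(missc))
    stop("country table is missing required columns: ",
         paste(missc, collapse = ", "), call. = FALSE)
  orphans <- setdiff(unique(individual$country_id), country_table$country_id)
  if (length(orphans))
    stop("country_id values with no row in the country table: ",
         paste(sort(orphans), collapse = ", "), call. = FALSE)

  checks <- list()
  note <- function(check, bad, detail = "") {
    n_bad <- if (is.logical(bad)) sum(bad, na.rm = TRUE) else length(bad)
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, ok = n_bad == 0L, n_bad = n_bad,
      detail = if (n_bad > 0L) detail else "", stringsAsFactors = FALSE)
  }
  note("care_use_labels", !individual$care_use %in% CARE_LEVELS,
       "care_use outside {none, informal, formal, mixed}")
  note("education_labels", !individual$education %in% EDU_LEVELS,
       "education outside {primary, secondary, tertiary}")
  note("gali_labels", !individual$gali %in% GALI_LEVELS,
       "gali outside {none, mild, severe}")
  note("counts_nonnegative",
       individual$iadl_count < 0 | individual$adl_count < 0,
       "negative limitation counts")
  note("wealth_quintile_range", !individual$wealth_quintile %in% 1:5,
       "wealth_quintile outside 1..5")
  note("weights_positive", !(individual$weight > 0), "non-positive weights")
  note("binary_indicators",
       !individual$female %in% 0:1 | !individual$has_partner %in% 0:1 |
         !individual$has_children %in% 0:1,
       "female/has_partner/has_children not in {0,1}")
  dup <- duplicated(individual$person_id)
  note("unique_person_id", dup,
       paste("duplicated person_id:",
             paste(head(unique(individual$person_id[dup]), 10), collapse = ", ")))
  cbin <- !(country_table$means_testing %in% 0:1 &
              country_table$cash_for_care %in% 0:1) |
    country_table$ltc_beds < 0
  note("country_ranges", cbin, "country binary flags not 0/1 or ltc_beds < 0")
  need <- derive_need(individual, need_definition)
  viol <- need == 0L & individual$care_use != "none"
  note("hurdle_consistency", viol,
       paste("care reported with zero derived need; person_id:",
             paste(head(individual$person_id[viol], 10), collapse = ", ")))
  checks <- do.call(rbind, checks)
  list(ok = all(checks$ok), checks = checks)
}
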