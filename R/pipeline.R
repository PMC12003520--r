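# Run configuration, serialization helpers, and the end-to-end pipeline:
# generate (or read) -> validate -> descriptives -> two-part fit ->
# pseudo R-squared report -> bootstrapped margins, optionally stratified by
# sex and with the collapsed (binary-use) layout.

#' Build a run configuration
#'
#' Defaults reproduce the packaged SHARE-like study conditions at a reduced
#' bootstrap size. All fields can be overridden via `...` or loaded from
#' YAML with [read_run_config()].
#'
#' @param ... Named overrides of the default fields.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    # either generator settings...
    generator = list(n_countries = 18, n_per_country = 1950,
                     params = "share_like"),
    # ...or input paths (individual_csv, country_csv) taking precedence
    individual_csv = NULL,
    country_csv = NULL,
    need_definition = "iadl1",
    part1_covariates = standard_covariates(),
    part2_covariates = standard_covariates(),
    quadrature = list(nodes = 15, nodes_per_dim = 5, adaptive = TRUE,
                      random_structure = "per_category_independent"),
    bootstrap = list(B = 100, ci_method = "basic", level = 0.95,
                     resample = "within_country"),
    prediction_mode = "marginal",
    strata = "none",              # "none" or "sex"
    emit_collapsed = FALSE,       # also emit the collapsed (adl1) layout
    collapsed_need_definition = "adl1",
    ame_covariates = NULL,        # default: all fixed effects
    seed = 1L,
    outdir = NULL)
  override <- list(...)
  for (nm in names(override)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(override[[nm]]))
      modifyList(cfg[[nm]], override[[nm]]) else override[[nm]]
  }
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg A `run_config`.
#' @return `read_run_config` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Serialize a fitted part to JSON
#'
#' @param fit A `binary_mixed_fit` or `mnl_mixed_fit`.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(class = class(fit)[1],
              beta_hat = if (is.matrix(fit$beta_hat))
                as.data.frame(fit$beta_hat) else as.list(fit$beta_hat),
              sigma_hat = as.list(fit$sigma_hat),
              loglik = fit$loglik, converged = fit$converged,
              boundary = fit$boundary, n_obs = fit$n_obs,
              n_clusters = fit$n_clusters,
              random_structure = fit$spec$random_structure)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

pipeline_log <- function(stage, t0) {
  message(sprintf("[ltchurdle] %-12s %6.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

fit_r2_report <- function(dataset, cfg, need_definition, spec1, spec2) {
  # null (intercept + random intercept), reduced (individual block only),
  # and full fits on the identical samples
  dataset$need <- derive_need(dataset, need_definition)
  needers <- dataset[dataset$need == 1L, , drop = FALSE]
  ind_only <- intersect(cfg$part1_covariates, standard_covariates("individual"))
  sp1 <- function(fx) { s <- spec1; s$fixed_effects <- fx; s$response <- "need"; s }
  sp2 <- function(fx) { s <- spec2; s$fixed_effects <- fx; s }
  f_full1 <- fit_binary(dataset, sp1(cfg$part1_covariates), compute_vcov = FALSE)
  f_red1 <- fit_binary(dataset, sp1(ind_only), compute_vcov = FALSE)
  f_null1 <- fit_binary(dataset, sp1(character(0)), compute_vcov = FALSE)
  f_full2 <- fit_multinomial(needers, sp2(cfg$part2_covariates), compute_vcov = FALSE)
  f_red2 <- fit_multinomial(needers, sp2(intersect(cfg$part2_covariates,
                                                   standard_covariates("individual"))),
                            compute_vcov = FALSE)
  f_null2 <- fit_multinomial(needers, sp2(character(0)), compute_vcov = FALSE)
  list(part1 = list(
         r2_full = mcfadden_r2(f_full1, f_null1),
         r2_reduced = mcfadden_r2(f_red1, f_null1),
         r2_incremental_country = incremental_r2(f_full1, f_red1, f_null1)),
       part2 = list(
         r2_full = mcfadden_r2(f_full2, f_null2),
         r2_reduced = mcfadden_r2(f_red2, f_null2),
         r2_incremental_country = incremental_r2(f_full2, f_red2, f_null2)),
       loglik = list(part1_full = f_full1$loglik, part1_null = f_null1$loglik,
                     part2_full = f_full2$loglik, part2_null = f_null2$loglik))
}

run_chain <- function(dataset, country_table, cfg, label, outdir, t0) {
  spec1 <- binary_mixed_spec(
    fixed_effects = cfg$part1_covariates,
    quadrature_nodes = cfg$quadrature$nodes,
    adaptive = cfg$quadrature$adaptive)
  spec2 <- multinomial_mixed_spec(
    fixed_effects = cfg$part2_covariates,
    random_structure = cfg$quadrature$random_structure,
    quadrature_nodes_per_dim = cfg$quadrature$nodes_per_dim,
    adaptive = cfg$quadrature$adaptive)
  tag <- if (nzchar(label)) paste0("_", label) else ""

  fit <- fit_two_part(dataset, spec1, spec2, cfg$need_definition,
                      compute_vcov = FALSE)
  write_fit_json(fit$part1, file.path(outdir, paste0("fit_part1", tag, ".json")))
  write_fit_json(fit$part2, file.path(outdir, paste0("fit_part2", tag, ".json")))
  pipeline_log(paste0("fit", tag), t0)

  r2 <- fit_r2_report(dataset, cfg, cfg$need_definition, spec1, spec2)
  jsonlite::write_json(r2, file.path(outdir, paste0("pseudo_r2", tag, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(paste0("pseudo_r2", tag), t0)

  amt <- bootstrap_margins(
    dataset, spec1, spec2, cfg$need_definition,
    B = cfg$bootstrap$B, seed = cfg$seed,
    ci_method = cfg$bootstrap$ci_method, level = cfg$bootstrap$level,
    resample = cfg$bootstrap$resample, covariates = cfg$ame_covariates,
    mode = cfg$prediction_mode)
  write.csv(as.data.frame(amt),
            file.path(outdir, paste0("ame_table", tag, ".csv")),
            row.names = FALSE)
  writeLines(utils::capture.output(print(amt)),
             file.path(outdir, paste0("ame_table", tag, ".txt")))
  pipeline_log(paste0("margins", tag), t0)

  collapsed <- NULL
  if (isTRUE(cfg$emit_collapsed)) {
    collapsed <- bootstrap_margins(
      dataset, spec1, spec2, cfg$collapsed_need_definition,
      B = cfg$bootstrap$B, seed = cfg$seed,
      ci_method = cfg$bootstrap$ci_method, level = cfg$bootstrap$level,
      resample = cfg$bootstrap$resample, covariates = cfg$ame_covariates,
      columns = AME_COLUMNS_COLLAPSED, mode = cfg$prediction_mode)
    write.csv(as.data.frame(collapsed),
              file.path(outdir, paste0("ame_table_collapsed", tag, ".csv")),
              row.names = FALSE)
    pipeline_log(paste0("collapsed", tag), t0)
  }
  list(fit = fit, r2 = r2, margins = amt, margins_collapsed = collapsed)
}

#' Run the full analysis pipeline
#'
#' Chains generate (or read) -> validate -> weighted descriptives ->
#' two-part fit -> McFadden pseudo R-squared report -> bootstrapped average
#' marginal effects, writing every artifact (CSV/JSON/text) plus a metadata
#' sidecar with the config hash and seeds into `cfg$outdir`. With
#' `strata = "sex"` the full chain additionally runs per subsample and a
#' combined comparison file is written.
#'
#' @param cfg A [run_config()].
#' @return Invisible list with the in-memory artifacts (`data`,
#'   `country_table`, `validation`, `table1`, plus per-stratum chains).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  outdir <- cfg$outdir %||% tempfile("ltchurdle_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())

  if (!is.null(cfg$individual_csv)) {
    dataset <- read.csv(cfg$individual_csv, stringsAsFactors = FALSE)
    country_table <- read.csv(cfg$country_csv, stringsAsFactors = FALSE)
    params <- NULL
  } else {
    params <- if (identical(cfg$generator$params, "share_like"))
      share_like_params() else read_true_params(cfg$generator$params)
    ct <- generate_country_table(cfg$generator$n_countries, seed = cfg$seed)
    pop <- generate_population(ct, params, cfg$generator$n_per_country,
                               seed = cfg$seed + 1L)
    dataset <- pop$data
    country_table <- pop$country_table
    write_population_csv(pop, outdir)
  }
  dataset <- expand_covariates(dataset, country_table)
  dataset <- dataset[complete.cases(
    dataset[, intersect(names(dataset),
                        c(IND_REQUIRED, cfg$part1_covariates,
                          cfg$part2_covariates))]), ]
  pipeline_log("data", t0)

  val <- validate_dataset(dataset, country_table, cfg$need_definition)
  write.csv(val$checks, file.path(outdir, "validation.csv"), row.names = FALSE)
  if (!val$ok)
    warning("validation reported issues; see validation.csv", call. = FALSE)
  pipeline_log("validate", t0)

  t1 <- table_one(dataset, country_table)
  write.csv(cbind(row = rownames(t1), as.data.frame(t1)),
            file.path(outdir, "table1.csv"), row.names = FALSE)
  writeLines(utils::capture.output(print(t1)),
             file.path(outdir, "table1.txt"))
  pipeline_log("table1", t0)

  chains <- list(all = run_chain(dataset, country_table, cfg, "", outdir, t0))
  if (identical(cfg$strata, "sex")) {
    for (s in c("women", "men")) {
      sub <- dataset[dataset$female == (s == "women"), , drop = FALSE]
      sub_cfg <- cfg
      # female is constant within stratum; drop it from both designs
      sub_cfg$part1_covariates <- setdiff(cfg$part1_covariates, "female")
      sub_cfg$part2_covariates <- setdiff(cfg$part2_covariates, "female")
      if (!is.null(sub_cfg$ame_covariates))
        sub_cfg$ame_covariates <- setdiff(sub_cfg$ame_covariates, "female")
      chains[[s]] <- run_chain(sub, country_table, sub_cfg, s, outdir, t0)
    }
    comp <- merge(as.data.frame(chains$women$margins)[, 1:4],
                  as.data.frame(chains$men$margins)[, 1:4],
                  by = c("covariate", "column"),
                  suffixes = c("_women", "_men"))
    write.csv(comp, file.path(outdir, "margins_sex_comparison.csv"),
              row.names = FALSE)
  }

  meta <- list(config = unclass(cfg), config_hash = rlang::hash(unclass(cfg)),
               seed = cfg$seed, outdir = outdir,
               timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
               package_version = as.character(utils::packageVersion("ltchurdle")))
  jsonlite::write_json(meta, file.path(outdir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log("done", t0)
  invisible(c(list(data = dataset, country_table = country_table,
                   params = params, validation = val, table1 = t1,
                   outdir = outdir), chains))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
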