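# End-to-end orchestration: normalize -> classify -> gate -> fit -> pool ->
# report, driven by a config list or YAML file.

#' Default pipeline configuration
#'
#' @param input_dir directory holding `tumor.tsv`, `normal.tsv`,
#'   `clinical.tsv`, `therapy.tsv` (the formats written by
#'   [write_cohort()]).
#' @param outdir output directory for result tables.
#' @param ... overrides for any config key.
#' @return Named list of pipeline settings.
#' @export
pipeline_config <- function(input_dir = NULL, outdir = NULL, ...) {
  cfg <- list(
    input_dir = input_dir,
    tumor_file = NULL, normal_file = NULL, clinical_file = NULL,
    therapy_file = NULL,
    kb_file = example_kb_path(), name_map_file = example_name_map_path(),
    rules = RULE_NAMES, thr_high = 2, thr_low = -2,
    endpoints = "os", covariates = c("age", "stage", "grade"),
    window_days = 548L, time_dependent = FALSE, strict_names = FALSE,
    meta = TRUE, lrt = TRUE,
    sweep_thresholds = NULL, sweep_rule = "tem",
    cv = NULL,  # e.g. list(k = 5, repeats = 50, rules = c("export","tem"))
    seed = 1L, outdir = outdir)
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  for (f in c("tumor", "normal", "clinical", "therapy")) {
    key <- paste0(f, "_file")
    if (is.null(cfg[[key]]) && !is.null(cfg$input_dir))
      cfg[[key]] <- file.path(cfg$input_dir, paste0(f, ".tsv"))
  }
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror [pipeline_config()]; unknown keys are an error so typos do
#' not silently fall back to defaults.
#'
#' @param path YAML file path.
#' @param ... overrides applied after reading (CLI flags beat config keys).
#' @export
read_run_config <- function(path, ...) {
  raw <- yaml::read_yaml(path)
  known <- names(pipeline_config())
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  do.call(pipeline_config, c(raw, list(...)))
}

#' Run the full therapy-efficacy analysis
#'
#' Executes the pipeline on one cohort: build the composite normal
#' reference, Z-score the tumors, evaluate every configured rule over the
#' eligible therapies, classify patients, fit gated per-cancer and
#' stratified pan-cancer Cox models (univariate and covariate-adjusted) per
#' endpoint, pool per-cancer estimates by random-effects meta-analysis, and
#' optionally run the likelihood-ratio test, threshold sweep, and repeated
#' cross-validation. When `config$outdir` is set, all result tables, the
#' gate report, an exclusion log and a copy of the configuration are
#' written there, so a run is reproducible from its config and seed.
#'
#' @param config list from [pipeline_config()] / [read_run_config()], or a
#'   path to a YAML config file.
#' @return List: `summary` (one row per rule x endpoint x model with group
#'   sizes, prevalence, HR, CI, p), `risk` (per-rule risk tables),
#'   `per_cancer`, `meta`, `lrt`, `sweep`, `cv`, `gate_report`, `log`.
#' @export
run_tem_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  set.seed(config$seed)
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))

  kb <- read_kb(config$kb_file)
  name_map <- read_name_map(config$name_map_file)
  tumor <- read_expression_matrix(config$tumor_file)
  normal <- read_expression_matrix(config$normal_file)
  clinical <- utils::read.delim(config$clinical_file, stringsAsFactors = FALSE)
  records <- utils::read.delim(config$therapy_file, stringsAsFactors = FALSE)

  ref <- build_reference(normal)
  z <- zscore(tumor, ref)
  note("reference: %d genes from %d normals (%d callable)",
       nrow(ref), attr(ref, "n_normals"), sum(ref$callable))

  n_missing_start <- sum(is.na(records$start_day))
  if (n_missing_start)
    note("excluded %d therapy record(s) with missing start day",
         n_missing_start)

  rules <- default_rules(config$thr_high, config$thr_low)[config$rules]
  calls <- expression_calls(z, config$thr_high, config$thr_low)

  risk_tables <- list(); verdict_tables <- list()
  for (rn in names(rules)) {
    verdicts <- withCallingHandlers(
      evaluate_cohort(records, calls, kb, rules[[rn]], name_map,
                      config$window_days,
                      unknown = if (config$strict_names) "error" else "skip"),
      warning = function(w) {
        note("[%s] %s", rn, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    verdict_tables[[rn]] <- verdicts
    risk_tables[[rn]] <- classify_patients(verdicts,
                                           patients = clinical$patient_id)
  }

  summary_rows <- list(); per_cancer <- list(); meta <- list()
  lrt_res <- list(); gate_rows <- list()
  for (ep in config$endpoints) {
    for (rn in names(rules)) {
      cohort <- risk_cohort(clinical, risk_tables[[rn]],
                            exclude_types = rules[[rn]]$excluded_cancer_types)
      n_high <- sum(cohort$risk == "high"); n_low <- sum(cohort$risk == "low")
      pc <- per_cancer_survival(cohort, endpoint = ep)
      per_cancer[[paste(ep, rn, sep = ".")]] <- pc
      gate_rows[[paste(ep, rn, sep = ".")]] <-
        cbind(endpoint = ep, rule = rn, pc$gate_report)
      if (config$meta && !is.null(pc$effects) && nrow(pc$effects) >= 1) {
        ok <- pc$effects$converged
        if (any(ok))
          meta[[paste(ep, rn, sep = ".")]] <- pool_hr(
            pc$effects$hr[ok], pc$effects$ci_low[ok], pc$effects$ci_high[ok],
            labels = pc$effects$cancer_type[ok],
            n_low = pc$effects$n_low[ok], n_high = pc$effects$n_high[ok])
      }
      for (model in c("univariate", "multivariate")) {
        covs <- if (model == "multivariate") config$covariates else character()
        eff <- suppressMessages(
          fit_risk_cox(cohort, endpoint = ep, covariates = covs,
                       stratify_by = "cancer_type",
                       time_dependent = config$time_dependent))
        skipped <- inherits(eff, "gate_skip")
        summary_rows[[length(summary_rows) + 1L]] <- data.frame(
          rule = rn, endpoint = ep, model = model,
          n_low = n_low, n_high = n_high,
          pct_high = prevalence(n_high, n_low + n_high),
          hr = if (skipped) NA_real_ else eff$hr,
          ci_low = if (skipped) NA_real_ else eff$ci_low,
          ci_high = if (skipped) NA_real_ else eff$ci_high,
          p = if (skipped) NA_real_ else eff$p,
          skipped = skipped, stringsAsFactors = FALSE)
        if (!skipped && model == "multivariate" && config$lrt) {
          base <- suppressMessages(fit_base_cox(cohort, ep, config$covariates,
                                                "cancer_type"))
          if (!is.null(base))
            lrt_res[[paste(ep, rn, sep = ".")]] <- lrt(base, eff$fit)
        }
      }
    }
  }
  summary <- do.call(rbind, summary_rows)

  sweep <- NULL
  if (!is.null(config$sweep_thresholds))
    sweep <- threshold_sweep(z, records, clinical, kb, name_map,
                             rule_name = config$sweep_rule,
                             thresholds = config$sweep_thresholds,
                             endpoint = config$endpoints[1],
                             window_days = config$window_days)

  cv <- NULL
  if (!is.null(config$cv)) {
    cv_rules <- config$cv$rules %||% names(rules)
    cv <- cross_validate(
      clinical, risk_tables[cv_rules], k = config$cv$k %||% 5L,
      repeats = config$cv$repeats %||% 50L, seed = config$seed,
      endpoint = config$endpoints[1],
      exclude_types = lapply(rules[cv_rules],
                             function(r) r$excluded_cancer_types))
  }

  gate_report <- do.call(rbind, gate_rows)
  res <- list(summary = summary, risk = risk_tables,
              verdicts = verdict_tables, per_cancer = per_cancer,
              meta = meta, lrt = lrt_res, sweep = sweep, cv = cv,
              gate_report = gate_report, log = log, config = config)
  if (!is.null(config$outdir)) write_pipeline_outputs(res, config$outdir)
  invisible(res)
}

fit_base_cox <- function(cohort, endpoint, covariates, stratify_by) {
  need <- c(paste0(endpoint, c("_time", "_event")), covariates, stratify_by)
  cohort <- cohort[stats::complete.cases(cohort[, need, drop = FALSE]), ,
                   drop = FALSE]
  rhs <- c(covariates, sprintf("strata(%s)", stratify_by))
  fml <- stats::reformulate(
    rhs, response = sprintf("Surv(%s_time, %s_event)", endpoint, endpoint))
  tryCatch(survival::coxph(fml, data = cohort, ties = "efron"),
           error = function(e) NULL)
}

write_pipeline_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name) {
    if (!is.null(df) && nrow(df))
      utils::write.table(df, file.path(outdir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
  }
  wt(res$summary, "summary.tsv")
  wt(res$gate_report, "gate_report.tsv")
  for (rn in names(res$risk))
    wt(cbind(rule = rn, res$risk[[rn]]), sprintf("risk_%s.tsv", rn))
  for (rn in names(res$verdicts))
    wt(res$verdicts[[rn]], sprintf("verdicts_%s.tsv", rn))
  if (length(res$meta)) {
    meta_df <- do.call(rbind, lapply(names(res$meta), function(nm) {
      m <- res$meta[[nm]]
      data.frame(analysis = nm, pooled_hr = m$pooled_hr, ci_low = m$ci_low,
                 ci_high = m$ci_high, p = m$p, tau2 = m$tau2, q = m$q,
                 k = m$k, stringsAsFactors = FALSE)
    }))
    wt(meta_df, "meta.tsv")
    for (nm in names(res$meta))
      wt(forest_data(res$meta[[nm]]), sprintf("forest_%s.tsv", nm))
  }
  if (!is.null(res$sweep)) wt(res$sweep, "threshold_sweep.tsv")
  if (!is.null(res$cv)) {
    wt(res$cv$summary, "cv_summary.tsv")
    wt(res$cv$details, "cv_details.tsv")
  }
  if (length(res$log))
    writeLines(res$log, file.path(outdir, "log.txt"))
  cfg <- res$config
  cfg$kb <- NULL
  yaml::write_yaml(cfg[!vapply(cfg, is.function, logical(1))],
                   file.path(outdir, "config.yaml"))
  invisible(outdir)
}
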