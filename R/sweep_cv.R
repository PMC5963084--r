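# Threshold sweeps and repeated cross-validation of rule-based risk
# classifications.

#' Join clinical data to a risk table
#'
#' @param clinical clinical table with `patient_id` (one row per patient).
#' @param risk output of [classify_patients()].
#' @param exclude_types cancer types to drop (a rule's
#'   `excluded_cancer_types`).
#' @param drop_unevaluable drop patients with no evaluable eligible therapy?
#' @return `clinical` with `risk` and `transition_day` columns added.
#' @export
risk_cohort <- function(clinical, risk, exclude_types = character(),
                        drop_unevaluable = FALSE) {
  stopifnot(!anyDuplicated(clinical$patient_id))
  i <- match(clinical$patient_id, risk$patient_id)
  out <- clinical
  out$risk <- ifelse(is.na(i), "low", risk$status[i])
  out$transition_day <- risk$transition_day[i]
  out$evaluable <- !is.na(i) & risk$evaluable[i]
  if (drop_unevaluable) out <- out[out$evaluable, , drop = FALSE]
  if (length(exclude_types))
    out <- out[!out$cancer_type %in% exclude_types, , drop = FALSE]
  out
}

#' Sweep the expression-call threshold for one rule
#'
#' Re-runs call -> classify -> gate -> stratified pan-cancer Cox at each
#' symmetric Z threshold, exposing the trade-off between the number of
#' flagged patients and the hazard-ratio magnitude. The flagged count is
#' non-increasing in the threshold; thresholds whose cohort fails the gates
#' are reported as skipped rather than erroring.
#'
#' @param z Z-score matrix ([zscore()]).
#' @param records therapy records.
#' @param clinical clinical table.
#' @param kb,name_map knowledge base and name map.
#' @param rule_name rule to sweep (default `"tem"`).
#' @param thresholds positive ascending Z thresholds (calls use `+t`/`-t`).
#' @param endpoint,covariates,time_dependent passed to [fit_risk_cox()].
#' @param window_days eligibility window.
#' @return Data frame `threshold`, `n_flagged`, `hr`, `ci_low`, `ci_high`,
#'   `p`, `skipped`, `reasons`.
#' @export
threshold_sweep <- function(z, records, clinical, kb, name_map,
                            rule_name = "tem",
                            thresholds = c(1.5, 2, 2.5, 3),
                            endpoint = "os", covariates = character(),
                            time_dependent = FALSE, window_days = 548L) {
  stopifnot(all(thresholds > 0), !is.unsorted(thresholds))
  rows <- lapply(thresholds, function(thr) {
    rule <- rule_spec(rule_name, thr_high = thr, thr_low = -thr)
    calls <- expression_calls(z, thr_high = thr, thr_low = -thr)
    verdicts <- suppressWarnings(
      evaluate_cohort(records, calls, kb, rule, name_map, window_days))
    risk <- classify_patients(verdicts, patients = clinical$patient_id)
    cohort <- risk_cohort(clinical, risk,
                          exclude_types = rule$excluded_cancer_types)
    n_flagged <- sum(cohort$risk == "high")
    eff <- fit_risk_cox(cohort, endpoint = endpoint, covariates = covariates,
                        stratify_by = "cancer_type",
                        time_dependent = time_dependent)
    if (inherits(eff, "gate_skip"))
      data.frame(threshold = thr, n_flagged = n_flagged, hr = NA_real_,
                 ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                 skipped = TRUE, reasons = paste(eff$reasons, collapse = ";"),
                 stringsAsFactors = FALSE)
    else
      data.frame(threshold = thr, n_flagged = n_flagged, hr = eff$hr,
                 ci_low = eff$ci_low, ci_high = eff$ci_high, p = eff$p,
                 skipped = FALSE, reasons = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Stratified fold assignment: within each cancer_type x event stratum,
# patients are shuffled and dealt round-robin into k folds.
assign_folds <- function(strata, k) {
  fold <- integer(length(strata))
  for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Repeated k-fold cross-validation of rule risk associations
#'
#' Assesses the variability of each rule's hazard-ratio estimate under
#' cohort resampling. Folds are stratified by cancer type and event status;
#' per repeat and fold, a stratified Cox model is fitted on the k-1
#' training folds when the gates pass. A rule is "included" in a model when
#' its training cohort passed the gates, the fit converged, and the
#' high-risk group was non-empty. Identical seeds give identical fold
#' assignments and summaries.
#'
#' @param clinical clinical table.
#' @param risk_tables named list of [classify_patients()] outputs, one per
#'   rule.
#' @param k number of folds (default 5).
#' @param repeats number of repeats (default 50).
#' @param seed integer seed controlling fold assignment.
#' @param endpoint,covariates,time_dependent passed to [fit_risk_cox()].
#' @param exclude_types named list of per-rule cancer-type exclusions.
#' @return List with `summary` (per rule: `n_models`, `inclusion`,
#'   `median_hr`, `sd_hr`, `mad_hr`) and `details` (per rule x repeat x
#'   fold).
#' @export
cross_validate <- function(clinical, risk_tables, k = 5L, repeats = 50L,
                           seed = 1L, endpoint = "os",
                           covariates = character(), time_dependent = FALSE,
                           exclude_types = list()) {
  stopifnot(k >= 2L, repeats >= 1L)
  rules <- names(risk_tables)
  ev <- clinical[[paste0(endpoint, "_event")]]
  strata <- paste(clinical$cancer_type, ev)
  set.seed(seed)
  folds <- vapply(seq_len(repeats), function(r) assign_folds(strata, k),
                  integer(nrow(clinical)))
  details <- list()
  for (rule in rules) {
    cohort <- risk_cohort(clinical, risk_tables[[rule]],
                          exclude_types = exclude_types[[rule]] %||% character())
    keep <- match(cohort$patient_id, clinical$patient_id)
    for (r in seq_len(repeats)) for (f in seq_len(k)) {
      train <- cohort[folds[keep, r] != f, , drop = FALSE]
      eff <- suppressMessages(
        fit_risk_cox(train, endpoint = endpoint, covariates = covariates,
                     stratify_by = "cancer_type",
                     time_dependent = time_dependent))
      skipped <- inherits(eff, "gate_skip")
      details[[length(details) + 1L]] <- data.frame(
        rule = rule, repeat_ = r, fold = f,
        included = !skipped && eff$converged && eff$n_high > 0L,
        hr = if (skipped) NA_real_ else eff$hr,
        stringsAsFactors = FALSE)
    }
  }
  details <- do.call(rbind, details)
  summary <- do.call(rbind, lapply(rules, function(rule) {
    d <- details[details$rule == rule, , drop = FALSE]
    hrs <- d$hr[d$included]
    data.frame(rule = rule, n_models = nrow(d),
               inclusion = mean(d$included),
               median_hr = if (length(hrs)) stats::median(hrs) else NA_real_,
               sd_hr = if (length(hrs) > 1) stats::sd(hrs) else NA_real_,
               mad_hr = if (length(hrs)) stats::mad(hrs) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(summary = summary, details = details)
}
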