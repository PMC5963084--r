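# Survival validation: gated Cox models, likelihood-ratio tests, KM and
# covariate-adjusted KM curves.

#' Minimum-size gates for survival model fitting
#'
#' A Cox model is fitted only when the cohort passes all three gates: at
#' least `min_per_group` patients in each risk group, at least `min_events`
#' observed events, and at least `min_total` patients.
#'
#' @param data data frame with the endpoint's event column and a `risk`
#'   column (`"low"`/`"high"`).
#' @param endpoint `"os"` or `"efs"`.
#' @param min_per_group,min_events,min_total gate thresholds.
#' @return List: `pass` (logical), `reasons` (character vector of failed
#'   gates, e.g. `"min_events"`), `n_low`, `n_high`, `n_events`, `n_total`.
#' @export
check_gates <- function(data, endpoint = c("os", "efs"), min_per_group = 5L,
                        min_events = 10L, min_total = 20L) {
  endpoint <- match.arg(endpoint)
  ev <- data[[paste0(endpoint, "_event")]]
  n_low <- sum(data$risk == "low")
  n_high <- sum(data$risk == "high")
  n_events <- sum(ev, na.rm = TRUE)
  n_total <- nrow(data)
  reasons <- c(
    if (min(n_low, n_high) < min_per_group) "min_per_group",
    if (n_events < min_events) "min_events",
    if (n_total < min_total) "min_total")
  list(pass = length(reasons) == 0L, reasons = reasons %||% character(),
       n_low = n_low, n_high = n_high, n_events = n_events, n_total = n_total)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Build counting-process rows for the time-dependent risk encoding:
# patients are at risk as "low" until their transition day, "high" after.
encode_time_dependent <- function(data, endpoint) {
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  rows <- lapply(seq_len(nrow(data)), function(i) {
    r <- data[i, , drop = FALSE]
    td <- r$transition_day
    if (is.na(td) || r$risk == "low" || td <= 0 || td >= r[[tcol]]) {
      r$tstart <- 0; r$tstop <- r[[tcol]]; r$ev <- r[[ecol]]
      r$risk_td <- r$risk
      return(r)
    }
    pre <- r; pre$tstart <- 0; pre$tstop <- td; pre$ev <- 0L; pre$risk_td <- "low"
    post <- r; post$tstart <- td; post$tstop <- r[[tcol]]; post$ev <- r[[ecol]]
    post$risk_td <- "high"
    rbind(pre, post)
  })
  do.call(rbind, rows)
}

#' Fit a gated Cox proportional-hazards model for risk status
#'
#' Fits `Surv(time, event) ~ risk [+ covariates] [+ strata(cancer_type)]`
#' with the Efron tie approximation and reports the hazard ratio of
#' high-risk relative to low-risk patients (HR > 1 means worse survival for
#' the high-risk group). Rows with missing covariates are dropped
#' (complete-case) with a message. If the gates of [check_gates()] fail,
#' no model is fitted and a `gate_skip` object records the reasons.
#'
#' Risk status is a time-fixed baseline covariate by default;
#' `time_dependent = TRUE` switches to a counting-process encoding in which
#' patients contribute low-risk person-time before their transition day.
#'
#' @param data data frame with `risk` (`"low"`/`"high"`), `transition_day`,
#'   `<endpoint>_time`, `<endpoint>_event`, plus any covariate columns and
#'   `cancer_type` if stratifying.
#' @param endpoint `"os"` (overall) or `"efs"` (event-free) survival.
#' @param covariates character vector of adjustment covariate columns
#'   (empty for a univariate model).
#' @param stratify_by optional column name whose levels get separate
#'   baseline hazards (pan-cancer models stratify by `"cancer_type"`).
#' @param time_dependent use the start-stop risk encoding?
#' @param ... gate thresholds passed to [check_gates()].
#' @return A `survival_effect`: `hr`, `ci_low`, `ci_high`, `p`, `n_low`,
#'   `n_high`, `n_events`, `n_used`, `model` (`"univariate"`/
#'   `"multivariate"`), `endpoint`, `converged`, `loglik`, `fit` (the
#'   underlying `coxph`); or a `gate_skip` with the failure reasons.
#' @export
fit_risk_cox <- function(data, endpoint = c("os", "efs"),
                         covariates = character(), stratify_by = NULL,
                         time_dependent = FALSE, ...) {
  endpoint <- match.arg(endpoint)
  stopifnot("risk" %in% names(data))
  need <- c(paste0(endpoint, c("_time", "_event")), covariates, stratify_by)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  cc <- stats::complete.cases(data[, need, drop = FALSE])
  if (!all(cc))
    message(sprintf("dropped %d row(s) with missing covariates", sum(!cc)))
  data <- data[cc, , drop = FALSE]
  gates <- check_gates(data, endpoint, ...)
  if (!gates$pass)
    return(structure(c(gates, list(endpoint = endpoint)), class = "gate_skip"))
  data$risk <- factor(data$risk, levels = c("low", "high"))
  rhs <- c("risk", covariates,
           if (!is.null(stratify_by)) sprintf("strata(%s)", stratify_by))
  if (time_dependent) {
    data <- encode_time_dependent(data, endpoint)
    data$risk <- factor(data$risk_td, levels = c("low", "high"))
    fml <- stats::reformulate(rhs, response = "Surv(tstart, tstop, ev)")
  } else {
    fml <- stats::reformulate(
      rhs, response = sprintf("Surv(%s_time, %s_event)", endpoint, endpoint))
  }
  fit <- survival::coxph(fml, data = data, ties = "efron",
                         x = FALSE, model = TRUE)
  sm <- summary(fit)
  i <- grep("^riskhigh$", rownames(sm$coefficients))
  if (length(i) != 1L)
    stop("risk coefficient not found in Cox fit", call. = FALSE)
  converged <- is.finite(sm$coefficients[i, "se(coef)"]) &&
    sm$coefficients[i, "se(coef)"] < 1e3
  structure(list(
    hr = unname(sm$coefficients[i, "exp(coef)"]),
    ci_low = unname(sm$conf.int[i, "lower .95"]),
    ci_high = unname(sm$conf.int[i, "upper .95"]),
    p = unname(sm$coefficients[i, "Pr(>|z|)"]),
    n_low = gates$n_low, n_high = gates$n_high, n_events = gates$n_events,
    n_used = nrow(data),
    model = if (length(covariates)) "multivariate" else "univariate",
    endpoint = endpoint, converged = converged,
    loglik = fit$loglik[length(fit$loglik)], fit = fit),
    class = "survival_effect")
}

#' @export
print.survival_effect <- function(x, ...) {
  cat(sprintf("%s %s Cox model: HR = %.2f [%.2f, %.2f], p = %.2g (%d low / %d high, %d events)\n",
              toupper(x$endpoint), x$model, x$hr, x$ci_low, x$ci_high, x$p,
              x$n_low, x$n_high, x$n_events))
  invisible(x)
}

#' @export
print.gate_skip <- function(x, ...) {
  cat(sprintf("model skipped (gates failed: %s); %d low / %d high, %d events\n",
              paste(x$reasons, collapse = ", "), x$n_low, x$n_high, x$n_events))
  invisible(x)
}

#' Likelihood-ratio test between nested Cox models
#'
#' `chi2 = 2 * (loglik_augmented - loglik_base)`, with degrees of freedom
#' equal to the difference in estimated (non-aliased) parameters, compared
#' to the chi-square upper tail. Both fits must be on identical rows.
#'
#' @param base,augmented `coxph` fits or `survival_effect` objects whose
#'   models are nested.
#' @return List `chi2`, `df`, `p`.
#' @export
lrt <- function(base, augmented) {
  getfit <- function(x) if (inherits(x, "survival_effect")) x$fit else x
  fb <- getfit(base); fa <- getfit(augmented)
  stopifnot(inherits(fb, "coxph"), inherits(fa, "coxph"))
  if (fb$n != fa$n)
    stop("models fitted on different rows (n = ", fb$n, " vs ", fa$n, ")",
         call. = FALSE)
  npar <- function(f) sum(!is.na(stats::coef(f)))
  df <- npar(fa) - npar(fb)
  if (df < 0) stop("augmented model has fewer parameters than base",
                   call. = FALSE)
  chi2 <- max(0, 2 * (fa$loglik[length(fa$loglik)] -
                        fb$loglik[length(fb$loglik)]))
  p <- if (df == 0) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Kaplan-Meier curves per group
#'
#' Product-limit estimates with 95% confidence bands; steps occur only at
#' event times. Empty groups are omitted with a warning.
#'
#' @param time,event numeric survival times and 0/1 event indicators.
#' @param group grouping vector (e.g. risk status).
#' @return Data frame `group`, `time`, `n_risk`, `n_event`, `surv`,
#'   `ci_low`, `ci_high`.
#' @export
km_curve <- function(time, event, group) {
  group <- as.factor(group)
  empty <- levels(group)[tabulate(group, nbins = nlevels(group)) == 0L]
  if (length(empty)) {
    warning("omitting empty group(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
    group <- droplevels(group)
  }
  sf <- survival::survfit(survival::Surv(time, event) ~ group, conf.type = "log")
  strata <- if (is.null(sf$strata)) stats::setNames(length(sf$time), levels(group))
            else sf$strata
  data.frame(
    group = rep(sub("^group=", "", names(strata)), strata),
    time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
    surv = sf$surv, ci_low = sf$lower, ci_high = sf$upper,
    stringsAsFactors = FALSE)
}

#' Covariate-adjusted survival curves at a reference profile
#'
#' Model-based survival curves from a fitted multivariate Cox model, with
#' every covariate fixed at the supplied profile (e.g. a uniform cohort of
#' 50-year-olds with stage-3 grade-3 disease) and one curve per risk group.
#' This removes the covariate imbalance that distorts raw KM comparisons of
#' observational risk groups.
#'
#' @param effect a `survival_effect` from [fit_risk_cox()] (multivariate).
#' @param profile one-row data frame of covariate values; must cover every
#'   covariate in the model apart from `risk`.
#' @param risk_levels risk groups to predict for.
#' @return Data frame `group`, `time`, `surv`, `ci_low`, `ci_high`.
#' @export
adjusted_km <- function(effect, profile, risk_levels = c("low", "high")) {
  stopifnot(inherits(effect, "survival_effect"), nrow(profile) == 1L)
  fit <- effect$fit
  vars <- setdiff(all.vars(stats::delete.response(stats::terms(fit))), "risk")
  miss <- setdiff(vars, names(profile))
  if (length(miss))
    stop("profile is missing model covariate(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(profile), vars)
  if (length(extra))
    stop("profile names covariate(s) absent from the model: ",
         paste(extra, collapse = ", "), call. = FALSE)
  nd <- profile[rep(1L, length(risk_levels)), , drop = FALSE]
  nd$risk <- factor(risk_levels, levels = c("low", "high"))
  sf <- survival::survfit(fit, newdata = nd)
  surv <- if (is.matrix(sf$surv)) sf$surv else matrix(sf$surv, ncol = 1L)
  lo <- if (is.matrix(sf$lower)) sf$lower else matrix(sf$lower, ncol = 1L)
  hi <- if (is.matrix(sf$upper)) sf$upper else matrix(sf$upper, ncol = 1L)
  do.call(rbind, lapply(seq_along(risk_levels), function(j) {
    data.frame(group = risk_levels[j], time = sf$time, surv = surv[, j],
               ci_low = lo[, j], ci_high = hi[, j], stringsAsFactors = FALSE)
  }))
}

#' Per-cancer survival models with gating
#'
#' Fits one gated Cox model per cancer type and collects estimates and gate
#' failures.
#'
#' @inheritParams fit_risk_cox
#' @param covariates either a character vector applied to every cancer type
#'   or a named list of per-type covariate vectors.
#' @return List with `effects` (data frame: cancer_type, n_low, n_high,
#'   n_events, hr, ci_low, ci_high, p, fitted) and `gate_report` (data
#'   frame of per-type gate outcomes), plus `fits` (named list of
#'   `survival_effect`s for fitted types).
#' @export
per_cancer_survival <- function(data, endpoint = c("os", "efs"),
                                covariates = character(),
                                time_dependent = FALSE, ...) {
  endpoint <- match.arg(endpoint)
  types <- sort(unique(data$cancer_type))
  fits <- list(); rows <- list(); gates <- list()
  for (ct in types) {
    covs <- if (is.list(covariates)) covariates[[ct]] %||% character()
            else covariates
    res <- fit_risk_cox(data[data$cancer_type == ct, , drop = FALSE],
                        endpoint = endpoint, covariates = covs,
                        time_dependent = time_dependent, ...)
    skipped <- inherits(res, "gate_skip")
    gates[[ct]] <- data.frame(
      cancer_type = ct, pass = !skipped,
      reasons = if (skipped) paste(res$reasons, collapse = ";") else "",
      n_low = res$n_low, n_high = res$n_high, n_events = res$n_events,
      stringsAsFactors = FALSE)
    if (!skipped) {
      fits[[ct]] <- res
      rows[[ct]] <- data.frame(
        cancer_type = ct, n_low = res$n_low, n_high = res$n_high,
        n_events = res$n_events, hr = res$hr, ci_low = res$ci_low,
        ci_high = res$ci_high, p = res$p, converged = res$converged,
        stringsAsFactors = FALSE)
    }
  }
  list(effects = do.call(rbind, rows) %||% data.frame(),
       gate_report = do.call(rbind, gates), fits = fits)
}
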