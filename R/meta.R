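# DerSimonian-Laird random-effects pooling of per-cancer hazard ratios.

#' Random-effects meta-analysis of hazard ratios
#'
#' Pools per-stratum (per-cancer) hazard ratios into a single estimate,
#' treating each stratum as an observation of a common underlying log
#' hazard ratio with between-stratum variance `tau2`. Standard errors are
#' back-calculated from the 95% confidence bounds assuming symmetric normal
#' (Wald) intervals on the log scale:
#' `se_i = (log(ci_high_i) - log(ci_low_i)) / (2 * 1.959964)`.
#'
#' With `y_i = log(hr_i)` and fixed-effect weights `w_i = 1 / se_i^2`,
#' Cochran's heterogeneity statistic is `Q = sum(w_i * (y_i - y_fixed)^2)`
#' and the DerSimonian-Laird between-stratum variance is
#' `tau2 = max(0, (Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))`.
#' Random-effects weights `1 / (se_i^2 + tau2)` give the pooled log hazard
#' ratio, its standard error, a Wald confidence interval and a two-sided
#' normal p-value. When `tau2 = 0` the result coincides exactly with the
#' inverse-variance fixed-effect estimate; a single stratum is returned
#' unchanged.
#'
#' Group sizes, when supplied, are carried through for display (forest-plot
#' marker scaling) but do not enter the weights.
#'
#' @param hr,ci_low,ci_high per-stratum hazard ratios and 95% CI bounds
#'   (`0 < ci_low <= hr <= ci_high`).
#' @param labels optional stratum labels (cancer types).
#' @param n_low,n_high optional per-stratum group sizes.
#' @param conf_level confidence level of the supplied and reported
#'   intervals.
#' @return A `meta_result`: `pooled_hr`, `ci_low`, `ci_high`, `p`, `tau2`,
#'   `q`, `k`, and `studies` (per-stratum data frame with `yi`, `sei`,
#'   `weight`).
#' @export
pool_hr <- function(hr, ci_low, ci_high, labels = NULL, n_low = NULL,
                    n_high = NULL, conf_level = 0.95) {
  k <- length(hr)
  if (k == 0L) stop("no studies to pool", call. = FALSE)
  stopifnot(length(ci_low) == k, length(ci_high) == k)
  labels <- labels %||% paste0("study", seq_len(k))
  if (any(!(ci_low > 0 & ci_low <= hr & hr <= ci_high)))
    stop("invalid CI for study ",
         labels[which(!(ci_low > 0 & ci_low <= hr & hr <= ci_high))[1]],
         call. = FALSE)
  zcrit <- stats::qnorm(1 - (1 - conf_level) / 2)
  yi <- log(hr)
  sei <- (log(ci_high) - log(ci_low)) / (2 * zcrit)
  if (any(sei <= 0))
    stop("zero standard error for study ", labels[which(sei <= 0)[1]],
         call. = FALSE)
  wi <- 1 / sei^2
  y_fixed <- sum(wi * yi) / sum(wi)
  q <- sum(wi * (yi - y_fixed)^2)
  denom <- sum(wi) - sum(wi^2) / sum(wi)
  tau2 <- if (k == 1L || denom <= 0) 0 else max(0, (q - (k - 1)) / denom)
  wstar <- 1 / (sei^2 + tau2)
  y_pool <- sum(wstar * yi) / sum(wstar)
  se_pool <- sqrt(1 / sum(wstar))
  structure(list(
    pooled_hr = exp(y_pool),
    ci_low = exp(y_pool - zcrit * se_pool),
    ci_high = exp(y_pool + zcrit * se_pool),
    p = 2 * stats::pnorm(-abs(y_pool / se_pool)),
    tau2 = tau2, q = q, k = k, se = se_pool,
    studies = data.frame(label = labels, hr = hr, ci_low = ci_low,
                         ci_high = ci_high, yi = yi, sei = sei,
                         weight = wstar / sum(wstar),
                         n_low = n_low %||% NA_integer_,
                         n_high = n_high %||% NA_integer_,
                         stringsAsFactors = FALSE)),
    class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("Random-effects pooled HR = %.2f [%.2f, %.2f], p = %.2g (k = %d, tau2 = %.3g, Q = %.2f)\n",
              x$pooled_hr, x$ci_low, x$ci_high, x$p, x$k, x$tau2, x$q))
  invisible(x)
}

#' Compare meta-analytic and stratified-Cox pan-cancer estimates
#'
#' Both estimators target the common pan-cancer log hazard ratio; this
#' reports their log-HR ratio and whether the confidence intervals overlap.
#' No pass/fail threshold is imposed -- disagreement under heterogeneity is
#' informative, not an error.
#'
#' @param meta a `meta_result`.
#' @param stratified a `survival_effect` from the cancer-type-stratified
#'   pan-cancer Cox model on the same cohort and rule.
#' @return List `log_hr_meta`, `log_hr_cox`, `log_hr_ratio`, `ci_overlap`.
#' @export
compare_pooling <- function(meta, stratified) {
  stopifnot(inherits(meta, "meta_result"),
            inherits(stratified, "survival_effect"))
  lm_ <- log(meta$pooled_hr); lc <- log(stratified$hr)
  list(log_hr_meta = lm_, log_hr_cox = lc,
       log_hr_ratio = if (abs(lc) > .Machine$double.eps^0.5) lm_ / lc else NA_real_,
       ci_overlap = max(meta$ci_low, stratified$ci_low) <=
         min(meta$ci_high, stratified$ci_high))
}

#' Forest-plot data table for a meta-analysis
#'
#' @param meta a `meta_result`.
#' @return Data frame `label`, `hr`, `ci_low`, `ci_high`, `weight`,
#'   `marker_size` (scaled by number of high-risk patients when known,
#'   otherwise by weight), with a final row for the pooled estimate.
#' @export
forest_data <- function(meta) {
  stopifnot(inherits(meta, "meta_result"))
  st <- meta$studies
  size <- if (all(is.na(st$n_high))) st$weight else st$n_high / max(st$n_high)
  rbind(
    data.frame(label = st$label, hr = st$hr, ci_low = st$ci_low,
               ci_high = st$ci_high, weight = st$weight, marker_size = size,
               stringsAsFactors = FALSE),
    data.frame(label = "pooled", hr = meta$pooled_hr, ci_low = meta$ci_low,
               ci_high = meta$ci_high, weight = 1, marker_size = 1,
               stringsAsFactors = FALSE))
}
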