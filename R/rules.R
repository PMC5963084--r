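# Rule engine: evaluate administered therapies against expression calls and
# classify patients as high-/low-risk.

RULE_NAMES <- c("export", "import", "metabolism_any", "metabolism_2",
                "target_any", "target_2", "any_hit", "any_pk_hit", "tem")

#' Specify a therapy-efficacy rule
#'
#' A rule names which pharmacokinetic features render an administered
#' therapy predictably ineffective:
#' \describe{
#'   \item{export}{any drug-export gene called high}
#'   \item{import}{any drug-import gene called low}
#'   \item{metabolism_any}{any metabolism hit (degrading enzyme high, or
#'     prodrug-activating enzyme low)}
#'   \item{metabolism_2}{at least `min_metabolism_genes` distinct
#'     metabolism-hit genes}
#'   \item{target_any, target_2}{at least 1 / `min_target_genes` target
#'     genes called low}
#'   \item{any_hit}{any single-feature rule fires}
#'   \item{any_pk_hit}{any transport (import/export) or metabolism feature
#'     fires}
#'   \item{tem}{the therapy-efficacy model: any export gene high, or at
#'     least `min_metabolism_genes` distinct drug-degrading enzymes high.
#'     By default prodrug-activator lows do not count towards the two-gene
#'     criterion (`tem_count_activators = FALSE`); the full metabolism
#'     feature (used by `metabolism_any`/`metabolism_2`) counts both.}
#' }
#'
#' `excluded_cancer_types` marks cancer types to drop from pan-cancer
#' pooling for this rule (used where a rule's mechanism is confounded in a
#' tissue, e.g. metabolism rules in breast cancer where taxane-metabolizing
#' aromatase is itself the target of co-administered anti-hormone therapy).
#'
#' @param name one of the rule names above.
#' @param thr_high,thr_low inclusive Z thresholds for high/low calls.
#' @param min_metabolism_genes distinct metabolism genes required by
#'   `metabolism_2` and `tem` (default 2).
#' @param min_target_genes distinct target genes required by `target_2`.
#' @param tem_count_activators should activator-low hits count towards the
#'   TEM two-gene metabolism criterion?
#' @param excluded_cancer_types character vector of cancer types excluded
#'   from pan-cancer pooling under this rule.
#' @return An object of class `rule_spec`.
#' @export
rule_spec <- function(name, thr_high = 2, thr_low = -2,
                      min_metabolism_genes = 2L, min_target_genes = 2L,
                      tem_count_activators = FALSE,
                      excluded_cancer_types = character()) {
  name <- match.arg(name, RULE_NAMES)
  stopifnot(thr_high > 0, thr_low < 0,
            min_metabolism_genes >= 1L, min_target_genes >= 1L)
  structure(list(name = name, thr_high = thr_high, thr_low = thr_low,
                 min_metabolism_genes = as.integer(min_metabolism_genes),
                 min_target_genes = as.integer(min_target_genes),
                 tem_count_activators = isTRUE(tem_count_activators),
                 excluded_cancer_types = excluded_cancer_types),
            class = "rule_spec")
}

#' The default rule set
#'
#' All nine named rules at Z thresholds of +/-2, with metabolism-based
#' single-feature rules excluding BRCA from pan-cancer pooling (see
#' [rule_spec()]).
#'
#' @param thr_high,thr_low inclusive Z thresholds.
#' @return Named list of `rule_spec` objects.
#' @export
default_rules <- function(thr_high = 2, thr_low = -2) {
  out <- lapply(RULE_NAMES, function(nm) {
    excl <- if (nm %in% c("metabolism_any", "metabolism_2")) "BRCA" else character()
    rule_spec(nm, thr_high = thr_high, thr_low = thr_low,
              excluded_cancer_types = excl)
  })
  stats::setNames(out, RULE_NAMES)
}

#' Restrict therapy records to the first-line eligibility window
#'
#' Because tumor profiling is done on pre-treatment tissue, only therapies
#' started early enough to approximate first-line treatment are evaluated:
#' records with a known start day within `window_days` of diagnosis
#' (default 548 days, i.e. 1.5 years) are kept. Records with a missing
#' start day are excluded with a warning.
#'
#' @param records data frame with columns `patient_id`, `raw_name`,
#'   `start_day`.
#' @param window_days eligibility window in days since diagnosis.
#' @return The eligible subset of `records`.
#' @export
eligible_therapies <- function(records, window_days = 548L) {
  stopifnot(all(c("patient_id", "start_day") %in% names(records)))
  missing_start <- is.na(records$start_day)
  if (any(missing_start))
    warning(sprintf("excluded %d therapy record(s) with missing start day",
                    sum(missing_start)), call. = FALSE)
  keep <- !missing_start & records$start_day <= window_days &
    records$start_day >= 0
  records[keep, , drop = FALSE]
}

empty_hits <- function(with_role = FALSE) {
  if (with_role)
    data.frame(gene = character(), role = character(), z = numeric(),
               level = character(), stringsAsFactors = FALSE)
  else
    data.frame(gene = character(), z = numeric(), level = character(),
               stringsAsFactors = FALSE)
}

#' Feature hits for one drug against one patient's expression calls
#'
#' Applies the three tumor-genomics features to the genes the knowledge
#' base annotates to `drug`:
#' \enumerate{
#'   \item transport: export genes called high; import genes called low;
#'   \item metabolism: drug-degrading enzymes called high, plus
#'     prodrug-activating enzymes called low (distinguished by `role`);
#'   \item target: target genes called low.
#' }
#' A drug absent from the knowledge base returns four empty evidence sets.
#'
#' @param drug generic drug name.
#' @param zcalls data frame with columns `gene`, `z`, `level` for one
#'   patient (e.g. one sample's rows of [expression_calls()]).
#' @param kb a `pk_kb`.
#' @return List with data frames `export`, `import`, `metabolism` (with a
#'   `role` column), `target`.
#' @export
feature_hits <- function(drug, zcalls, kb) {
  stopifnot(all(c("gene", "z", "level") %in% names(zcalls)))
  pick <- function(genes, lev) {
    rows <- zcalls[zcalls$gene %in% genes & zcalls$level == lev,
                   c("gene", "z", "level"), drop = FALSE]
    rows <- rows[order(rows$gene), , drop = FALSE]
    rownames(rows) <- NULL
    rows
  }
  exp_hit <- pick(genes_for(kb, drug, "export"), "high")
  imp_hit <- pick(genes_for(kb, drug, "import"), "low")
  met_high <- pick(genes_for(kb, drug, "metabolize"), "high")
  act_low <- pick(genes_for(kb, drug, "activate"), "low")
  met <- rbind(
    if (nrow(met_high)) cbind(met_high[, "gene", drop = FALSE],
                              role = "metabolize", met_high[, c("z", "level")]),
    if (nrow(act_low)) cbind(act_low[, "gene", drop = FALSE],
                             role = "activate", act_low[, c("z", "level")]))
  if (is.null(met)) met <- empty_hits(with_role = TRUE)
  rownames(met) <- NULL
  list(export = exp_hit, import = imp_hit, metabolism = met,
       target = pick(genes_for(kb, drug, "target"), "low"))
}

rule_predicate <- function(hits, rule) {
  n_exp <- nrow(hits$export)
  n_imp <- nrow(hits$import)
  n_met <- length(unique(hits$metabolism$gene))
  n_met_degrade <- length(unique(
    hits$metabolism$gene[hits$metabolism$role == "metabolize"]))
  n_tgt <- length(unique(hits$target$gene))
  switch(rule$name,
    export = n_exp >= 1L,
    import = n_imp >= 1L,
    metabolism_any = n_met >= 1L,
    metabolism_2 = n_met >= rule$min_metabolism_genes,
    target_any = n_tgt >= 1L,
    target_2 = n_tgt >= rule$min_target_genes,
    any_hit = n_exp >= 1L || n_imp >= 1L || n_met >= 1L || n_tgt >= 1L,
    any_pk_hit = n_exp >= 1L || n_imp >= 1L || n_met >= 1L,
    tem = n_exp >= 1L ||
      (if (rule$tem_count_activators) n_met else n_met_degrade) >=
        rule$min_metabolism_genes)
}

#' Evaluate one drug under one rule
#'
#' @inheritParams feature_hits
#' @param rule a [rule_spec()].
#' @return List of class `therapy_verdict`: `drug`, `rule`, `ineffective`,
#'   and `evidence` (data frame `gene`, `role`, `z`, `level` of every
#'   feature hit for the drug, whether or not the rule consulted it).
#' @export
evaluate_therapy <- function(drug, zcalls, kb, rule) {
  stopifnot(inherits(rule, "rule_spec"))
  hits <- feature_hits(drug, zcalls, kb)
  ev <- rbind(
    if (nrow(hits$export)) cbind(hits$export[, "gene", drop = FALSE],
                                 role = "export", hits$export[, c("z", "level")]),
    if (nrow(hits$import)) cbind(hits$import[, "gene", drop = FALSE],
                                 role = "import", hits$import[, c("z", "level")]),
    hits$metabolism,
    if (nrow(hits$target)) cbind(hits$target[, "gene", drop = FALSE],
                                 role = "target", hits$target[, c("z", "level")]))
  if (is.null(ev)) ev <- empty_hits(with_role = TRUE)
  rownames(ev) <- NULL
  structure(list(drug = fold_name(drug), rule = rule$name,
                 ineffective = rule_predicate(hits, rule), evidence = ev),
            class = "therapy_verdict")
}

# Normalize raw names once; returns list(raw -> character vector of generics
# or NULL if unknown/skipped). Non-drug tokens are kept; the evaluator skips
# them because they have no KB annotation.
normalize_records <- function(records, name_map, kb,
                              unknown = c("skip", "error")) {
  unknown <- match.arg(unknown)
  raw_names <- unique(records$raw_name)
  lut <- stats::setNames(vector("list", length(raw_names)), raw_names)
  n_unknown <- 0L
  for (rn in raw_names) {
    lut[[rn]] <- tryCatch(normalize_therapy(rn, name_map, kb),
      pktem_unknown_therapy = function(e) {
        if (unknown == "error") stop(e)
        n_unknown <<- n_unknown + 1L
        NULL
      })
  }
  if (n_unknown > 0L)
    warning(sprintf("skipped %d unknown therapy name(s)", n_unknown),
            call. = FALSE)
  lut
}

#' Evaluate a cohort's eligible therapies under one rule
#'
#' Normalizes raw therapy names, restricts to the first-line window,
#' evaluates each component drug of each eligible record, and returns
#' per-(patient, record, drug) verdicts. A record is ineffective if any of
#' its component drugs is; non-drug tokens (e.g. radiotherapy) and drugs
#' without knowledge-base annotation contribute no evidence.
#'
#' @param records therapy records: `patient_id`, `raw_name`, `start_day`.
#' @param calls long-format expression calls ([expression_calls()]) whose
#'   `sample` matches `patient_id`.
#' @param kb a `pk_kb`.
#' @param rule a [rule_spec()].
#' @param name_map a `therapy_name_map`.
#' @param window_days first-line eligibility window (days).
#' @param unknown `"skip"` (default) or `"error"` for unmapped raw names.
#' @return Data frame with one row per (patient, record, drug):
#'   `patient_id`, `raw_name`, `start_day`, `drug`, `rule`, `ineffective`,
#'   `evidence` (semicolon-joined `GENE:role:Z:call`).
#' @export
evaluate_cohort <- function(records, calls, kb, rule, name_map,
                            window_days = 548L, unknown = c("skip", "error")) {
  stopifnot(inherits(kb, "pk_kb"), inherits(rule, "rule_spec"))
  lut <- normalize_records(records, name_map, kb, unknown)
  elig <- eligible_therapies(records, window_days)

  # expand eligible records to one row per component drug
  drugs_per_rec <- lut[elig$raw_name]
  nd <- lengths(drugs_per_rec)
  res <- data.frame(
    patient_id = rep(elig$patient_id, nd),
    raw_name = rep(elig$raw_name, nd),
    start_day = rep(elig$start_day, nd),
    drug = unlist(drugs_per_rec, use.names = FALSE) %||% character(),
    stringsAsFactors = FALSE)
  res$rule <- rep(rule$name, nrow(res))

  # all feature hits in the cohort at once: non-normal calls are sparse, so
  # join them against the relation table and keep role-consistent rows
  nn <- calls[calls$level != "normal", c("sample", "gene", "z", "level"),
              drop = FALSE]
  hits <- merge(nn, kb$relations[, c("drug", "gene", "role")], by = "gene")
  keep <- (hits$role == "export" & hits$level == "high") |
    (hits$role == "import" & hits$level == "low") |
    (hits$role == "metabolize" & hits$level == "high") |
    (hits$role == "activate" & hits$level == "low") |
    (hits$role == "target" & hits$level == "low")
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$sample, hits$drug, hits$role, hits$gene), ,
               drop = FALSE]
  hkey <- paste(hits$sample, hits$drug)

  cnt <- function(sel) {
    n <- tapply(hits$gene[sel], hkey[sel],
                function(g) length(unique(g)))
    i <- match(paste(res$patient_id, res$drug), names(n))
    ifelse(is.na(i), 0L, as.integer(n[i]))
  }
  n_exp <- cnt(hits$role == "export")
  n_imp <- cnt(hits$role == "import")
  n_met <- cnt(hits$role %in% c("metabolize", "activate"))
  n_met_degrade <- cnt(hits$role == "metabolize")
  n_tgt <- cnt(hits$role == "target")

  res$ineffective <- switch(rule$name,
    export = n_exp >= 1L,
    import = n_imp >= 1L,
    metabolism_any = n_met >= 1L,
    metabolism_2 = n_met >= rule$min_metabolism_genes,
    target_any = n_tgt >= 1L,
    target_2 = n_tgt >= rule$min_target_genes,
    any_hit = n_exp >= 1L | n_imp >= 1L | n_met >= 1L | n_tgt >= 1L,
    any_pk_hit = n_exp >= 1L | n_imp >= 1L | n_met >= 1L,
    tem = n_exp >= 1L |
      (if (rule$tem_count_activators) n_met else n_met_degrade) >=
        rule$min_metabolism_genes)

  ev <- tapply(sprintf("%s:%s:%.2f:%s", hits$gene, hits$role, hits$z,
                       hits$level), hkey, paste, collapse = ";")
  i <- match(paste(res$patient_id, res$drug), names(ev))
  res$evidence <- ifelse(is.na(i), "", as.character(ev[i]))
  rownames(res) <- NULL
  res
}

#' Classify patients as high-/low-risk from therapy verdicts
#'
#' A patient is low-risk until they receive a predicted-ineffective eligible
#' therapy; the transition day is the earliest start day among ineffective
#' eligible therapies. Patients in `patients` with no evaluable eligible
#' therapy are low-risk but flagged `evaluable = FALSE` so callers can
#' exclude them.
#'
#' @param verdicts verdict table from [evaluate_cohort()] (eligible records
#'   only).
#' @param patients character vector of all patient IDs in the cohort
#'   (defaults to those appearing in `verdicts`).
#' @return Data frame `patient_id`, `status` (`"low"`/`"high"`),
#'   `transition_day` (`NA` when low), `evaluable`.
#' @export
classify_patients <- function(verdicts, patients = unique(verdicts$patient_id)) {
  ineff <- verdicts[verdicts$ineffective, , drop = FALSE]
  tday <- tapply(ineff$start_day, ineff$patient_id, min)
  out <- data.frame(patient_id = patients, stringsAsFactors = FALSE)
  out$transition_day <- as.numeric(tday[out$patient_id])
  out$status <- ifelse(is.na(out$transition_day), "low", "high")
  out$evaluable <- out$patient_id %in% verdicts$patient_id
  out[, c("patient_id", "status", "transition_day", "evaluable")]
}

#' Percentage of flagged patients
#'
#' @param flagged number flagged high-risk.
#' @param total cohort size (> 0).
#' @return `100 * flagged / total`, rounded to one decimal.
#' @export
prevalence <- function(flagged, total) {
  stopifnot(length(flagged) == 1L, length(total) == 1L)
  if (total <= 0) stop("total must be positive", call. = FALSE)
  if (flagged < 0 || flagged > total)
    stop("flagged must be between 0 and total", call. = FALSE)
  round(100 * flagged / total, 1)
}

#' Write a risk table as TSV
#'
#' Columns `patient_id`, `rule`, `status`, `transition_day` (and any
#' extras present, e.g. `evaluable`).
#'
#' @param risk risk table ([classify_patients()] output plus a `rule`
#'   column).
#' @param path file path.
#' @export
write_risk_table <- function(risk, path) {
  utils::write.table(risk, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
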