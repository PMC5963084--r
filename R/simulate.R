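# Synthetic cohort generator: expression, regimens, clinical covariates and
# survival with planted pharmacokinetic alterations and known ground truth.

default_regimen_pools <- function() {
  list(
    GBM  = c("carboplatin", "cisplatin", "erlotinib"),
    BRCA = c("doxorubicin", "paclitaxel", "fluorouracil", "methotrexate",
             "tamoxifen", "anastrozole", "trastuzumab"),
    OV   = c("carboplatin", "paclitaxel", "doxorubicin", "gemcitabine",
             "docetaxel"),
    KIRC = c("gemcitabine", "fluorouracil", "erlotinib"),
    LUAD = c("docetaxel", "paclitaxel", "carboplatin", "cisplatin",
             "erlotinib"),
    UCEC = c("carboplatin", "paclitaxel", "gemcitabine", "doxorubicin",
             "topotecan"),
    HNSC = c("carboplatin", "paclitaxel", "cetuximab", "fluorouracil",
             "docetaxel"),
    LUSC = c("docetaxel", "paclitaxel", "gemcitabine", "carboplatin",
             "cisplatin"))
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the structure of a pan-cancer pre-treatment cohort:
#' eight cancer types totalling 2868 tumors with 295 pooled normal samples;
#' heavy-majority-unaltered pharmacokinetic gene expression with planted
#' activations at the prevalences reported for such cohorts (about 5% of
#' patients receiving a therapy rendered ineffective by exporter or
#' two-gene metabolism activation); regimens drawn from the knowledge base
#' per cancer type with start days within 900 days of diagnosis; and
#' exponential survival whose hazard is multiplied by `exp(log_hr)`
#' (default log 1.47) for patients who received a planted-ineffective
#' therapy.
#'
#' Expression model: each gene has a level `mu` (log-uniform over
#' `meanlog_range`) and a relative spread `a` (`amplitude_range`); samples
#' take `mu * (1 +/- a*D)` with the relative deviation `D` drawn from a
#' bounded, symmetric spike-and-shell mixture. The mixture is chosen so
#' that the composite reference's median absolute deviation (about
#' `0.82*a*mu`) comfortably exceeds half the maximum deviation (`a*mu`):
#' unaltered samples cannot reach `|Z| = 1.5` when the reference pools a
#' few hundred normals, so calls are a pure readout of planted alterations
#' and separability is robust to arbitrary per-type sample counts. Planted
#' alterations shift the patient's value by `shift_high`/`shift_low` times
#' the gene's composite-reference scale (low shifts floor at zero,
#' expression being non-negative), landing planted `|Z|` in roughly
#' `[2.8, 5.2]`.
#'
#' @param seed integer seed; the same seed yields byte-identical cohorts.
#' @param n_tumors named integer vector of tumors per cancer type.
#' @param n_normals named integer vector of normal samples per cancer type.
#' @param kb a `pk_kb` (default: the bundled example knowledge base).
#' @param regimen_pools named list of candidate drugs per cancer type; every
#'   drug must be in `kb`.
#' @param n_noise_genes unannotated filler genes.
#' @param prob_export,prob_metab2 per-patient probabilities of planting an
#'   exporter-high / two-metabolizing-genes-high alteration on an eligible
#'   administered drug (these two mechanisms define the planted high-risk
#'   label).
#' @param prob_metab1,prob_import,prob_target per-patient probabilities of
#'   the remaining single-feature plantings.
#' @param shift_high,shift_low planted shifts in units of the gene's
#'   composite-reference scale.
#' @param meanlog_range range of per-gene log expression levels.
#' @param amplitude_range range of the per-gene relative spread `a` of the
#'   bounded two-shell expression model (see Details above).
#' @param therapy_count_range records per patient (uniform integer range).
#' @param start_day_max latest therapy start day.
#' @param window_days eligibility window used when placing planted
#'   therapies.
#' @param alias_prob probability a record uses a raw alias/brand name
#'   instead of the generic.
#' @param radiotherapy_prob probability of an extra radiotherapy record.
#' @param log_hr true log hazard ratio applied to planted high-risk
#'   patients.
#' @param time_dependent_effect apply the hazard multiplier only from the
#'   planted therapy's start day (default: from day 0).
#' @param baseline_rate named per-type exponential event rates (per day).
#' @param horizon administrative censoring horizon (days).
#' @param censor_min_frac censoring times are uniform on
#'   `[censor_min_frac * horizon, horizon]`.
#' @param beta_age,beta_stage,beta_grade covariate log-hazard effects (age
#'   centred at 60, stage/grade at 2.5).
#' @param or_stage,or_grade odds ratios tilting planted high-risk patients
#'   towards stage 3-4 / grade 3-4.
#' @param age_mean named per-type mean age; `age_sd` common SD.
#' @param prob_late_stage,prob_late_grade baseline probabilities of stage
#'   3-4 and grade 3-4.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_tumors = c(GBM = 134L, BRCA = 815L, OV = 262L,
                                    KIRC = 480L, LUAD = 329L, UCEC = 333L,
                                    HNSC = 303L, LUSC = 212L),
                       n_normals = c(GBM = 5L, BRCA = 100L, OV = 5L,
                                     KIRC = 65L, LUAD = 35L, UCEC = 25L,
                                     HNSC = 35L, LUSC = 25L),
                       kb = NULL, regimen_pools = NULL, n_noise_genes = 40L,
                       prob_export = 0.036, prob_metab2 = 0.016,
                       prob_metab1 = 0.06, prob_import = 0.028,
                       prob_target = 0.027,
                       shift_high = 4, shift_low = -4,
                       meanlog_range = c(2, 8),
                       amplitude_range = c(0.3, 0.5),
                       therapy_count_range = c(1L, 3L),
                       start_day_max = 900L, window_days = 548L,
                       alias_prob = 0.25, radiotherapy_prob = 0.1,
                       log_hr = log(1.47), time_dependent_effect = FALSE,
                       baseline_rate = c(GBM = 1/700, BRCA = 1/8300,
                                         OV = 1/2500, KIRC = 1/4900,
                                         LUAD = 1/3000, UCEC = 1/7600,
                                         HNSC = 1/3500, LUSC = 1/2800),
                       horizon = 3650, censor_min_frac = 0.2,
                       beta_age = 0.02, beta_stage = 0.2, beta_grade = 0.1,
                       or_stage = 1.6, or_grade = 1.4,
                       age_mean = c(GBM = 61, BRCA = 58, OV = 58, KIRC = 61,
                                    LUAD = 67, UCEC = 63, HNSC = 61,
                                    LUSC = 68.5),
                       age_sd = 11,
                       prob_late_stage = 0.45, prob_late_grade = 0.45) {
  kb <- kb %||% read_kb(example_kb_path())
  types <- names(n_tumors)
  stopifnot(!is.null(types), all(nzchar(types)), all(n_tumors >= 0),
            all(n_normals >= 0), sum(n_normals) > 0)
  regimen_pools <- regimen_pools %||% default_regimen_pools()[types]
  regimen_pools <- regimen_pools[types]
  if (any(vapply(regimen_pools, is.null, logical(1))))
    stop("no regimen pool for cancer type(s): ",
         paste(types[vapply(regimen_pools, is.null, logical(1))],
               collapse = ", "), call. = FALSE)
  absent <- setdiff(unlist(regimen_pools), kb_drugs(kb))
  if (length(absent))
    stop("regimen pool drug(s) absent from the knowledge base: ",
         paste(absent, collapse = ", "), call. = FALSE)
  probs <- c(prob_export, prob_metab2, prob_metab1, prob_import, prob_target,
             alias_prob, radiotherapy_prob, censor_min_frac,
             prob_late_stage, prob_late_grade)
  stopifnot(all(probs >= 0 & probs <= 1), all(baseline_rate[types] > 0),
            horizon > 0, shift_high > 0, shift_low < 0,
            all(names(n_normals) == types))
  structure(list(
    seed = as.integer(seed), n_tumors = n_tumors, n_normals = n_normals,
    kb = kb, regimen_pools = regimen_pools,
    n_noise_genes = as.integer(n_noise_genes),
    prob_export = prob_export, prob_metab2 = prob_metab2,
    prob_metab1 = prob_metab1, prob_import = prob_import,
    prob_target = prob_target, shift_high = shift_high,
    shift_low = shift_low, meanlog_range = meanlog_range,
    amplitude_range = amplitude_range,
    therapy_count_range = therapy_count_range,
    start_day_max = as.integer(start_day_max),
    window_days = as.integer(window_days), alias_prob = alias_prob,
    radiotherapy_prob = radiotherapy_prob, log_hr = log_hr,
    time_dependent_effect = isTRUE(time_dependent_effect),
    baseline_rate = baseline_rate[types], horizon = horizon,
    censor_min_frac = censor_min_frac, beta_age = beta_age,
    beta_stage = beta_stage, beta_grade = beta_grade,
    or_stage = or_stage, or_grade = or_grade, age_mean = age_mean[types],
    age_sd = age_sd, prob_late_stage = prob_late_stage,
    prob_late_grade = prob_late_grade), class = "sim_config")
}

# drugs in the KB (optionally restricted to `pool`) that have >= n genes of
# the given role
drugs_with_role <- function(kb, role, n = 1L, pool = NULL) {
  drugs <- pool %||% kb_drugs(kb)
  drugs[vapply(drugs, function(d) length(genes_for(kb, d, role)) >= n,
               logical(1))]
}

# invert the bundled name map: aliases that resolve to exactly this drug
single_drug_aliases <- function(name_map) {
  inv <- list()
  for (nm in names(name_map)) {
    v <- name_map[[nm]]
    if (length(v) == 1L) inv[[v]] <- c(inv[[v]], nm)
  }
  inv
}

tilt_binary <- function(p0, or, tilt) {
  odds <- p0 / (1 - p0) * ifelse(tilt, or, 1)
  odds / (1 + odds)
}

#' Generate a synthetic cohort
#'
#' Deterministic given `config$seed`. Planted alterations are realized by
#' shifting the chosen gene's tumor expression relative to the composite
#' reference built from the generated normal samples; survival times are
#' exponential with the hazard multiplied by `exp(log_hr)` for planted
#' high-risk patients. Ground truth is returned alongside the data and is
#' never encoded in the analysis inputs themselves.
#'
#' @param config a [sim_config()].
#' @return List of class `sim_cohort`: `tumor` and `normal` expression
#'   matrices, `clinical` (with OS and EFS endpoints), `therapy` records,
#'   `manifest` (sample type and cancer type per sample), and `truth`
#'   (per-patient planted labels and the planted alteration list).
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  kb <- config$kb
  types <- names(config$n_tumors)
  name_map <- read_name_map(example_name_map_path())
  aliases <- single_drug_aliases(name_map)

  kb_genes <- sort(unique(kb$relations$gene))
  genes <- c(kb_genes,
             if (config$n_noise_genes > 0)
               sprintf("NOISE%03d", seq_len(config$n_noise_genes)))
  ng <- length(genes)
  nt <- length(types)

  # Per-gene expression model: gene level mu_g, relative amplitude a_g.
  # Samples are mu * (1 +/- a*D) with the relative deviation D drawn from a
  # spike-and-shell mixture (25% U(0,0.08), 5% U(0.08,0.75), 70% U(0.75,1)).
  # The spike at zero anchors the sample median at mu; the shell puts the
  # median absolute deviation at ~0.82*a*mu, well above half the maximum
  # deviation (a*mu), so unaltered samples stay below |Z| ~ 1.25 and calls
  # at any threshold of 1.5 or more are a pure readout of planted shifts,
  # whatever the per-type sample counts.
  mu <- exp(stats::runif(ng, config$meanlog_range[1], config$meanlog_range[2]))
  amp <- stats::runif(ng, config$amplitude_range[1], config$amplitude_range[2])

  draw_block <- function(type, n, prefix) {
    u <- matrix(stats::runif(ng * n), ng, n)
    d <- ifelse(u < 0.25, stats::runif(ng * n, 0, 0.08),
         ifelse(u < 0.30, stats::runif(ng * n, 0.08, 0.75),
                stats::runif(ng * n, 0.75, 1)))
    sgn <- matrix(sample(c(-1, 1), ng * n, replace = TRUE), ng, n)
    m <- mu * (1 + sgn * d * amp)
    colnames(m) <- sprintf("%s_%s_%03d", prefix, type, seq_len(n))
    m
  }
  normal <- do.call(cbind, lapply(types, function(ct)
    draw_block(ct, config$n_normals[ct], "N")))
  tumor <- do.call(cbind, lapply(types, function(ct)
    draw_block(ct, config$n_tumors[ct], "P")))
  rownames(normal) <- rownames(tumor) <- genes
  patients <- colnames(tumor)
  np <- length(patients)
  patient_type <- rep(types, config$n_tumors)

  # composite reference of the generated normals, used to express planted
  # shifts in reference-scale units
  ref_m <- apply(normal, 1L, stats::median)
  ref_s <- vapply(seq_len(ng), function(i)
    stats::median(abs(normal[i, ] - ref_m[i])), numeric(1))
  names(ref_s) <- genes

  # regimens: per patient 1-3 single-drug records, occasional radiotherapy
  drugs_of <- vector("list", np)
  starts_of <- vector("list", np)
  for (i in seq_len(np)) {
    pool <- config$regimen_pools[[patient_type[i]]]
    nrec <- sample(seq(config$therapy_count_range[1],
                       config$therapy_count_range[2]), 1L)
    drugs <- sample(pool, min(nrec, length(pool)))
    starts <- sample(0:config$start_day_max, length(drugs), replace = TRUE)
    drugs_of[[i]] <- drugs; starts_of[[i]] <- starts
  }

  # planted alterations
  mech <- data.frame(
    mechanism = c("export", "metab2", "metab1", "import", "target"),
    role = c("export", "metabolize", "metabolize", "import", "target"),
    n_genes = c(1L, 2L, 1L, 1L, 1L),
    high = c(TRUE, TRUE, TRUE, FALSE, FALSE),
    prob = c(config$prob_export, config$prob_metab2, config$prob_metab1,
             config$prob_import, config$prob_target),
    stringsAsFactors = FALSE)
  p_pat <- character(); p_mech <- character(); p_drug <- character()
  p_gene <- character(); p_start <- numeric()
  tem_truth <- logical(np)
  transition_truth <- rep(NA_real_, np)
  role_gene_count <- local({
    rel <- kb$relations
    tab <- table(paste(rel$drug, rel$role))
    function(d, role) {
      n <- tab[paste(d, role)]
      ifelse(is.na(n), 0L, as.integer(n))
    }
  })
  for (i in seq_len(np)) {
    for (mi in seq_len(nrow(mech))) {
      if (stats::runif(1) >= mech$prob[mi]) next
      role <- mech$role[mi]; ngene <- mech$n_genes[mi]
      # pick an administered drug with enough genes of this role, preferring
      # one already started inside the eligibility window
      cand <- drugs_of[[i]][role_gene_count(drugs_of[[i]], role) >= ngene]
      cand_elig <- cand[starts_of[[i]][match(cand, drugs_of[[i]])] <=
                          config$window_days]
      if (length(cand_elig)) {
        drug <- cand_elig[sample.int(length(cand_elig), 1L)]
        start <- starts_of[[i]][match(drug, drugs_of[[i]])]
      } else {
        pool <- drugs_with_role(kb, role, ngene,
                                config$regimen_pools[[patient_type[i]]])
        if (!length(pool)) pool <- drugs_with_role(kb, role, ngene)
        if (!length(pool)) next
        drug <- pool[sample.int(length(pool), 1L)]
        start <- sample(0:config$window_days, 1L)
        drugs_of[[i]] <- c(drugs_of[[i]], drug)
        starts_of[[i]] <- c(starts_of[[i]], start)
      }
      gs <- genes_for(kb, drug, role)
      gs <- gs[sample.int(length(gs), ngene)]
      shift <- if (mech$high[mi]) config$shift_high else config$shift_low
      for (g in gs) {
        if (ref_s[g] <= 0) next
        tumor[g, i] <- max(0, tumor[g, i] + shift * ref_s[g])
      }
      p_pat <- c(p_pat, patients[i]); p_mech <- c(p_mech, mech$mechanism[mi])
      p_drug <- c(p_drug, drug); p_gene <- c(p_gene, paste(gs, collapse = ";"))
      p_start <- c(p_start, start)
      if (mech$mechanism[mi] %in% c("export", "metab2")) {
        tem_truth[i] <- TRUE
        transition_truth[i] <- min(transition_truth[i], start, na.rm = TRUE)
      }
    }
  }

  # raw therapy names: mostly generics (case-varied), sometimes aliases
  nrec <- lengths(drugs_of)
  r_pat <- rep(patients, nrec)
  r_raw <- unlist(drugs_of, use.names = FALSE)
  r_start <- unlist(starts_of, use.names = FALSE)
  use_alias <- stats::runif(length(r_raw)) < config$alias_prob &
    r_raw %in% names(aliases)
  r_raw[use_alias] <- vapply(r_raw[use_alias], function(d) {
    al <- aliases[[d]]
    al[sample.int(length(al), 1L)]
  }, character(1))
  capitalize <- !use_alias & stats::runif(length(r_raw)) < 0.5
  r_raw[capitalize] <- paste0(toupper(substr(r_raw[capitalize], 1, 1)),
                              substr(r_raw[capitalize], 2, 1000L))
  rt <- stats::runif(np) < config$radiotherapy_prob
  therapy <- data.frame(
    patient_id = c(r_pat, patients[rt]),
    raw_name = c(r_raw, rep("radiation", sum(rt))),
    start_day = c(r_start,
                  sample(0:config$start_day_max, sum(rt), replace = TRUE)),
    stringsAsFactors = FALSE)
  therapy <- therapy[order(match(therapy$patient_id, patients),
                           therapy$start_day), , drop = FALSE]
  rownames(therapy) <- NULL

  # clinical covariates, tilted for planted high-risk patients
  age <- stats::rnorm(np, config$age_mean[patient_type], config$age_sd)
  sex <- sample(c("female", "male"), np, replace = TRUE)
  late_stage <- stats::rbinom(np, 1L, tilt_binary(config$prob_late_stage,
                                                  config$or_stage, tem_truth))
  late_grade <- stats::rbinom(np, 1L, tilt_binary(config$prob_late_grade,
                                                  config$or_grade, tem_truth))
  stage <- ifelse(late_stage == 1L, sample(3:4, np, TRUE, c(2, 1) / 3),
                  sample(1:2, np, TRUE, c(5, 4) / 9))
  grade <- ifelse(late_grade == 1L, sample(3:4, np, TRUE, c(2, 1) / 3),
                  sample(1:2, np, TRUE, c(5, 4) / 9))

  eta <- config$beta_age * (age - 60) + config$beta_stage * (stage - 2.5) +
    config$beta_grade * (grade - 2.5)
  rate0 <- config$baseline_rate[patient_type] * exp(eta)
  td <- ifelse(tem_truth, transition_truth, Inf)
  draw_event_time <- function(rate_mult) {
    # piecewise-exponential inversion when the planted effect starts at the
    # transition day; plain exponential otherwise
    e <- stats::rexp(np)
    r1 <- rate0 * rate_mult
    r2 <- rate0 * rate_mult * exp(ifelse(tem_truth, config$log_hr, 0))
    if (!config$time_dependent_effect) return(e / r2)
    t1 <- e / r1
    ifelse(t1 <= td | !tem_truth, t1, td + (e - r1 * td) / r2)
  }
  t_os <- draw_event_time(1)
  t_prog <- draw_event_time(0.5)
  cens <- stats::runif(np, config$censor_min_frac * config$horizon,
                       config$horizon)
  os_time <- pmin(t_os, cens)
  efs_raw <- pmin(t_os, t_prog)
  clinical <- data.frame(
    patient_id = patients, cancer_type = patient_type, age = age, sex = sex,
    stage = stage, grade = grade,
    os_time = os_time, os_event = as.integer(t_os <= cens),
    efs_time = pmin(efs_raw, cens), efs_event = as.integer(efs_raw <= cens),
    stringsAsFactors = FALSE)
  rownames(clinical) <- NULL

  manifest <- data.frame(
    sample_id = c(patients, colnames(normal)),
    sample_type = rep(c("tumor", "normal"), c(np, ncol(normal))),
    cancer_type = c(patient_type, rep(types, config$n_normals)),
    stringsAsFactors = FALSE)

  truth <- list(
    patients = data.frame(patient_id = patients, cancer_type = patient_type,
                          planted_high_risk = tem_truth,
                          transition_day = ifelse(tem_truth,
                                                  transition_truth, NA_real_),
                          stringsAsFactors = FALSE),
    alterations = data.frame(
      patient_id = p_pat, mechanism = p_mech, drug = p_drug, gene = p_gene,
      start_day = p_start, stringsAsFactors = FALSE),
    log_hr = config$log_hr)

  structure(list(tumor = tumor, normal = normal, clinical = clinical,
                 therapy = therapy, manifest = manifest, truth = truth,
                 config = config), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d tumors / %d normals, %d genes, %d therapy records; %d planted high-risk patients (%.1f%%)\n",
              ncol(x$tumor), ncol(x$normal), nrow(x$tumor), nrow(x$therapy),
              sum(x$truth$patients$planted_high_risk),
              100 * mean(x$truth$patients$planted_high_risk)))
  invisible(x)
}

#' Write a synthetic cohort to a directory in the pipeline's file formats
#'
#' Emits `tumor.tsv`, `normal.tsv`, `clinical.tsv`, `therapy.tsv`,
#' `manifest.tsv` and the ground truth (`truth_patients.tsv`,
#' `truth_alterations.tsv`). Same seed, same bytes.
#'
#' @param sim a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  write_expression_matrix(sim$tumor, file.path(dir, "tumor.tsv"))
  write_expression_matrix(sim$normal, file.path(dir, "normal.tsv"))
  wt(sim$clinical, "clinical.tsv")
  wt(sim$therapy, "therapy.tsv")
  wt(sim$manifest, "manifest.tsv")
  wt(sim$truth$patients, "truth_patients.tsv")
  wt(sim$truth$alterations, "truth_alterations.tsv")
  invisible(dir)
}
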