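# Shared fixtures: a tiny hand-written KB, a scaled-down simulated cohort,
# and independent brute-force oracles used to cross-check the implementation.

tiny_kb <- function() {
  as_pk_kb(data.frame(
    drug = c("paclitaxel", "paclitaxel", "paclitaxel", "paclitaxel",
             "gemcitabine", "gemcitabine", "carboplatin", "carboplatin"),
    gene = c("ABCC1", "CYP3A4", "NR1I2", "MAP2",
             "NT5C", "CMPK1", "SLC31A1", "HMGB1"),
    role = c("export", "metabolize", "metabolize", "target",
             "metabolize", "activate", "import", "target"),
    stringsAsFactors = FALSE))
}

# zcalls data frame for one patient from named Z-scores
zcalls_of <- function(z, thr_high = 2, thr_low = -2) {
  data.frame(gene = names(z), z = unname(z),
             level = call_level(unname(z), thr_high, thr_low),
             stringsAsFactors = FALSE)
}

# small cohort: same structure as the defaults, an order of magnitude fewer
# patients, so whole-pipeline tests stay fast
small_sim_config <- function(seed, n_per_type = 40L, ...) {
  types <- c("GBM", "BRCA", "OV", "KIRC", "LUAD", "UCEC", "HNSC", "LUSC")
  sim_config(seed = seed,
             n_tumors = stats::setNames(rep(n_per_type, length(types)), types),
             n_normals = stats::setNames(rep(37L, length(types)), types),
             ...)
}

# run normalize -> call -> evaluate -> classify on a simulated cohort
classify_sim <- function(sim, rule, thr_high = 2, thr_low = -2) {
  ref <- build_reference(sim$normal)
  z <- zscore(sim$tumor, ref)
  calls <- expression_calls(z, thr_high, thr_low)
  kb <- read_kb(example_kb_path())
  nm <- read_name_map(example_name_map_path())
  verdicts <- suppressWarnings(
    evaluate_cohort(sim$therapy, calls, kb, rule, nm))
  risk <- classify_patients(verdicts, patients = sim$clinical$patient_id)
  list(risk = risk, verdicts = verdicts, z = z, calls = calls)
}

# brute-force robust Z-scores straight from the definition
oracle_zscore <- function(tumors, normals) {
  out <- matrix(NA_real_, nrow(tumors), ncol(tumors),
                dimnames = dimnames(tumors))
  for (g in rownames(tumors)) {
    v <- normals[g, ]
    m <- stats::median(v, na.rm = TRUE)
    s <- stats::median(abs(v - m), na.rm = TRUE)
    if (!is.finite(s) || s <= 0) next
    out[g, ] <- (tumors[g, ] - m) / s
  }
  out
}

# brute-force product-limit estimator
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  data.frame(time = tt, surv = vapply(tt, function(t0) {
    d <- sum(time == t0 & event == 1)
    n <- sum(time >= t0)
    s <<- s * (1 - d / n)
    s
  }, numeric(1)))
}

# simple exponential survival frame with two labelled groups
null_surv_frame <- function(n_per_group, rate = 1 / 1000, hr = 1,
                            cens_rate = 1 / 2000) {
  n <- 2L * n_per_group
  risk <- rep(c("low", "high"), each = n_per_group)
  t_ev <- stats::rexp(n, rate * ifelse(risk == "high", hr, 1))
  t_c <- stats::rexp(n, cens_rate)
  data.frame(risk = risk, transition_day = ifelse(risk == "high", 0, NA),
             os_time = pmin(t_ev, t_c), os_event = as.integer(t_ev <= t_c),
             stringsAsFactors = FALSE)
}
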