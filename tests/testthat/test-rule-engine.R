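kb_full <- read_kb(example_kb_path())
nm_full <- read_name_map(example_name_map_path())

test_that("feature_hits sorts evidence into the three mechanism features", {
  # exporter elevation for a taxane
  h <- feature_hits("paclitaxel", zcalls_of(c(ABCC2 = 4.77)), kb_full)
  expect_equal(h$export$gene, "ABCC2")
  expect_equal(nrow(h$import) + nrow(h$metabolism) + nrow(h$target), 0L)
  # three concurrently elevated degrading enzymes shared by two drugs
  zc <- zcalls_of(c(NT5C = 3.84, UPB1 = 3.87, DPYS = 2.33))
  for (drug in c("gemcitabine", "fluorouracil")) {
    h <- feature_hits(drug, zc, kb_full)
    expect_setequal(h$metabolism$gene, c("NT5C", "UPB1", "DPYS"))
    expect_true(all(h$metabolism$role == "metabolize"))
  }
  # influx transporter loss for a platinum drug
  h <- feature_hits("carboplatin", zcalls_of(c(SLC31A1 = -2.67)), kb_full)
  expect_equal(h$import$gene, "SLC31A1")
  # prodrug activator loss is a metabolism hit with its own role
  h <- feature_hits("gemcitabine", zcalls_of(c(CMPK1 = -4.12)), kb_full)
  expect_equal(h$metabolism$gene, "CMPK1")
  expect_equal(h$metabolism$role, "activate")
  # unannotated drug or token: all evidence sets empty
  for (d in c("radiotherapy", "leucovorin"))
    expect_true(all(vapply(feature_hits(d, zc, kb_full), nrow,
                           integer(1)) == 0L))
})

test_that("rule predicates respect their gene-count boundaries", {
  one_met <- zcalls_of(c(CYP3A4 = 2.5))
  two_met <- zcalls_of(c(CYP3A4 = 2.5, CYP2C8 = 3.1))
  act_plus_met <- zcalls_of(c(NT5C = 2.5, CMPK1 = -2.5))
  tgt_only <- zcalls_of(c(TOP2B = -4.39, MAP2 = -5.04))
  ev <- function(zc, rule, drug = "paclitaxel")
    evaluate_therapy(drug, zc, kb_full, rule_spec(rule))$ineffective
  # one degrading enzyme: not enough for the efficacy model, enough for
  # metabolism_any
  expect_false(ev(one_met, "tem"))
  expect_true(ev(one_met, "metabolism_any"))
  expect_false(ev(one_met, "metabolism_2"))
  expect_true(ev(two_met, "tem"))
  expect_true(ev(two_met, "metabolism_2"))
  # target-only profile: flagged by any_hit, not by the PK-based rules
  expect_true(ev(tgt_only, "any_hit", drug = "doxorubicin"))
  expect_false(ev(tgt_only, "any_pk_hit", drug = "doxorubicin"))
  expect_false(ev(tgt_only, "tem", drug = "doxorubicin"))
  # activator-low + one degrading enzyme: two metabolism genes for the
  # metabolism feature, but the efficacy model counts degrading enzymes only
  expect_true(ev(act_plus_met, "metabolism_2", drug = "gemcitabine"))
  expect_false(ev(act_plus_met, "tem", drug = "gemcitabine"))
  tem_act <- rule_spec("tem", tem_count_activators = TRUE)
  expect_true(evaluate_therapy("gemcitabine", act_plus_met, kb_full,
                               tem_act)$ineffective)
  # export always suffices for the efficacy model
  expect_true(ev(zcalls_of(c(ABCC1 = 2.01)), "tem"))
})

test_that("verdict evidence lists only genes annotated to the drug", {
  zc <- zcalls_of(c(ABCC1 = 3, SLC31A1 = -3, NOISE1 = 5))
  v <- evaluate_therapy("paclitaxel", zc, kb_full, rule_spec("any_hit"))
  expect_true(all(v$evidence$gene %in%
                    kb_full$relations$gene[kb_full$relations$drug ==
                                             "paclitaxel"]))
  expect_false("NOISE1" %in% v$evidence$gene)
  expect_false("SLC31A1" %in% v$evidence$gene)
})

test_that("eligibility keeps the first-line window and drops unknown starts", {
  rec <- data.frame(patient_id = c("p1", "p1", "p2"),
                    raw_name = c("Taxol", "Taxol", "Taxol"),
                    start_day = c(100, 600, NA))
  expect_warning(kept <- eligible_therapies(rec), "missing start day")
  expect_equal(kept$start_day, 100)
  expect_equal(kept$patient_id, "p1")
})

test_that("patients classify from their earliest ineffective eligible therapy", {
  v <- data.frame(patient_id = c("p1", "p1", "p2"),
                  start_day = c(200, 90, 10),
                  ineffective = c(TRUE, TRUE, FALSE))
  rk <- classify_patients(v, patients = c("p1", "p2", "p3"))
  expect_equal(rk$status, c("high", "low", "low"))
  expect_equal(rk$transition_day[1], 90)
  expect_true(is.na(rk$transition_day[2]))
  expect_equal(rk$evaluable, c(TRUE, TRUE, FALSE))
})

test_that("an ineffective therapy outside the window leaves the patient low-risk", {
  # composition of eligibility and classification, checked by enumeration:
  # the only flagged record starts after the window
  zc_all <- data.frame(sample = "p1", gene = "ABCC1", z = 5, level = "high",
                       callable = TRUE)
  rec <- data.frame(patient_id = "p1", raw_name = "Taxol", start_day = 600)
  v <- evaluate_cohort(rec, zc_all, kb_full, rule_spec("tem"), nm_full)
  expect_equal(nrow(v), 0L)
  rk <- classify_patients(v, patients = "p1")
  expect_equal(rk$status, "low")
})

test_that("prevalence reports one-decimal percentages and guards its domain", {
  expect_equal(prevalence(0, 100), 0)
  expect_equal(prevalence(1, 3), 33.3)
  expect_error(prevalence(1, 0), "positive")
  expect_error(prevalence(5, 3), "between")
})

test_that("the cohort evaluator agrees with per-drug evaluation and ignores record order", {
  sim <- simulate_cohort(small_sim_config(31))
  res <- classify_sim(sim, rule_spec("any_hit"))
  # per-drug reference path on every (patient, drug) pair of the verdict
  calls_by <- split(res$calls[, c("gene", "z", "level")], res$calls$sample)
  v <- res$verdicts
  idx <- sample(seq_len(nrow(v)), min(200, nrow(v)))
  for (i in idx) {
    ref <- evaluate_therapy(v$drug[i], calls_by[[v$patient_id[i]]], kb_full,
                            rule_spec("any_hit"))
    expect_identical(v$ineffective[i], ref$ineffective)
    expect_setequal(strsplit(v$evidence[i], ";")[[1]],
                    sprintf("%s:%s:%.2f:%s", ref$evidence$gene,
                            ref$evidence$role, ref$evidence$z,
                            ref$evidence$level))
  }
  # permuting therapy record order changes nothing
  set.seed(1)
  shuffled <- sim$therapy[sample(nrow(sim$therapy)), ]
  v2 <- suppressWarnings(
    evaluate_cohort(shuffled, res$calls, kb_full, rule_spec("any_hit"),
                    nm_full))
  rk1 <- classify_patients(v, patients = sim$clinical$patient_id)
  rk2 <- classify_patients(v2, patients = sim$clinical$patient_id)
  expect_identical(rk1, rk2)
})

test_that("rule dominance holds: tem within any_pk_hit within any_hit", {
  for (seed in c(5, 6)) {
    sim <- simulate_cohort(small_sim_config(seed))
    high <- lapply(c("tem", "any_pk_hit", "any_hit"), function(rn) {
      rk <- classify_sim(sim, rule_spec(rn))$risk
      rk$patient_id[rk$status == "high"]
    })
    expect_true(all(high[[1]] %in% high[[2]]))
    expect_true(all(high[[2]] %in% high[[3]]))
  }
})

test_that("raising the call threshold never flags more therapies or patients", {
  sim <- simulate_cohort(small_sim_config(17))
  counts <- vapply(c(1.5, 2, 2.5, 3), function(thr) {
    rk <- classify_sim(sim, rule_spec("tem", thr_high = thr,
                                      thr_low = -thr),
                       thr_high = thr, thr_low = -thr)$risk
    sum(rk$status == "high")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("unknown therapy names skip with a warning, or abort in strict mode", {
  zc_all <- data.frame(sample = "p1", gene = "ABCC1", z = 5, level = "high",
                       callable = TRUE)
  rec <- data.frame(patient_id = "p1", raw_name = c("Taxol", "mystery-mix"),
                    start_day = c(10, 20))
  expect_warning(
    v <- evaluate_cohort(rec, zc_all, kb_full, rule_spec("tem"), nm_full),
    "unknown therapy")
  expect_equal(unique(v$drug), "paclitaxel")
  expect_error(
    evaluate_cohort(rec, zc_all, kb_full, rule_spec("tem"), nm_full,
                    unknown = "error"),
    "mystery-mix")
})
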