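test_that("gates block fitting and record their reasons", {
  set.seed(1)
  d <- null_surv_frame(50)
  d$os_event <- 0L
  d$os_event[1:9] <- 1L  # 9 events: below the 10-event gate
  res <- fit_risk_cox(d)
  expect_s3_class(res, "gate_skip")
  expect_true("min_events" %in% res$reasons)
  expect_null(res$hr)
  d2 <- null_surv_frame(3)   # 3 per group and 6 total
  g <- check_gates(d2)
  expect_false(g$pass)
  expect_true(all(c("min_per_group", "min_total") %in% g$reasons))
})

test_that("a null cohort fits near HR 1 with nominal CI coverage", {
  set.seed(202)
  hrs <- numeric(20); covers <- logical(20)
  for (i in 1:20) {
    d <- null_surv_frame(500)
    eff <- fit_risk_cox(d)
    hrs[i] <- eff$hr
    covers[i] <- eff$ci_low <= 1 && 1 <= eff$ci_high
  }
  expect_true(all(hrs > 0.8 & hrs < 1.25))
  expect_gte(mean(covers), 0.9)
})

test_that("a planted hazard ratio is recovered within its confidence interval", {
  set.seed(77)
  beta <- log(1.5)
  cover <- vapply(1:40, function(i) {
    d <- null_surv_frame(1000, hr = exp(beta))
    eff <- fit_risk_cox(d)
    log(eff$ci_low) <= beta && beta <= log(eff$ci_high)
  }, logical(1))
  expect_gte(mean(cover), 0.85)  # ~95% nominal, 40 replicates
})

test_that("the time-dependent encoding splits person-time at the transition day", {
  d <- data.frame(risk = c("high", "high", "low"),
                  transition_day = c(100, 0, NA),
                  os_time = c(300, 200, 400), os_event = c(1L, 1L, 0L))
  enc <- pktem:::encode_time_dependent(d, "os")
  expect_equal(nrow(enc), 4L)  # first patient contributes two intervals
  p1 <- enc[enc$os_time == 300, ]
  expect_equal(p1$tstart, c(0, 100))
  expect_equal(p1$tstop, c(100, 300))
  expect_equal(p1$ev, c(0L, 1L))
  expect_equal(p1$risk_td, c("low", "high"))
})

test_that("likelihood-ratio tests compare nested fits correctly", {
  set.seed(9)
  d <- null_surv_frame(150)
  d$x1 <- rnorm(nrow(d))
  d$const <- 1
  base <- fit_risk_cox(d)$fit
  aug_const <- survival::coxph(
    survival::Surv(os_time, os_event) ~ risk + const, data = d)
  res <- lrt(base, aug_const)
  expect_equal(res$chi2, 0, tolerance = 1e-8)
  expect_equal(res$df, 0L)
  expect_equal(res$p, 1)
  aug2 <- survival::coxph(
    survival::Surv(os_time, os_event) ~ risk + x1 + const, data = d)
  expect_equal(lrt(base, aug2)$df, 1L)  # df = number of added parameters
  d2 <- d[-1, ]
  aug3 <- survival::coxph(survival::Surv(os_time, os_event) ~ risk,
                          data = d2)
  expect_error(lrt(base, aug3), "different rows")
})

test_that("LRT p-values are roughly uniform under a null covariate", {
  set.seed(123)
  ps <- vapply(1:400, function(i) {
    d <- null_surv_frame(60)
    d$x <- rnorm(nrow(d))
    b <- survival::coxph(survival::Surv(os_time, os_event) ~ risk, data = d)
    a <- survival::coxph(survival::Surv(os_time, os_event) ~ risk + x,
                         data = d)
    lrt(b, a)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("KM curves match the closed form and the product-limit oracle", {
  # all censored: survival stays at 1
  km <- km_curve(c(5, 10, 15), c(0, 0, 0), rep("a", 3))
  expect_true(all(km$surv == 1))
  # single event among n: S(t1) = 1 - 1/n
  km <- km_curve(c(3, 8, 9, 12), c(1, 0, 0, 0), rep("a", 4))
  expect_equal(km$surv[km$time == 3], 1 - 1 / 4)
  # brute-force product-limit agreement on small random samples
  set.seed(5)
  for (i in 1:10) {
    n <- sample(8:20, 1)
    time <- sample(1:40, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7)
    km <- km_curve(time, event, rep("a", n))
    orc <- oracle_km(time, event)
    got <- km$surv[match(orc$time, km$time)]
    expect_equal(got, orc$surv, tolerance = 1e-12)
  }
  expect_warning(km_curve(1:4, c(1, 1, 0, 1),
                          factor(rep("a", 4), levels = c("a", "b"))),
                 "empty")
})

test_that("adjusted survival curves obey the proportional-hazards identity", {
  set.seed(31)
  d <- null_surv_frame(400, hr = 1.8)
  d$age <- rnorm(nrow(d), 60, 10)
  d$stage <- sample(1:4, nrow(d), replace = TRUE)
  eff <- fit_risk_cox(d, covariates = c("age", "stage"))
  prof <- data.frame(age = 50, stage = 3)
  adj <- adjusted_km(eff, prof)
  lo <- adj[adj$group == "low", ]; hi <- adj[adj$group == "high", ]
  # ratio of cumulative hazards between the two risk curves is the fitted HR
  keep <- lo$surv < 0.999 & lo$surv > 0.01
  ratio <- log(hi$surv[keep]) / log(lo$surv[keep])
  expect_equal(ratio, rep(eff$hr, sum(keep)), tolerance = 1e-6)
  # a worse stage profile lowers predicted survival everywhere
  stage_coef <- stats::coef(eff$fit)[["stage"]]
  prof_hi <- data.frame(age = 50, stage = 3)
  prof_lo <- data.frame(age = 50, stage = 1)
  s_hi <- adjusted_km(eff, prof_hi, risk_levels = "low")$surv
  s_lo <- adjusted_km(eff, prof_lo, risk_levels = "low")$surv
  if (stage_coef > 0) expect_true(all(s_hi <= s_lo + 1e-12))
  # profile validation
  expect_error(adjusted_km(eff, data.frame(age = 50)), "missing")
  expect_error(adjusted_km(eff, data.frame(age = 50, stage = 3, junk = 1)),
               "absent")
})

test_that("EFS and OS fits agree when their events and times coincide", {
  set.seed(55)
  d <- null_surv_frame(300, hr = 1.6)
  d$efs_time <- d$os_time
  d$efs_event <- d$os_event
  a <- fit_risk_cox(d, endpoint = "os")
  b <- fit_risk_cox(d, endpoint = "efs")
  expect_equal(a$hr, b$hr)
  expect_equal(a$p, b$p)
})

test_that("per-cancer fitting gates each cancer type separately", {
  set.seed(14)
  big <- null_surv_frame(200, hr = 1.5)
  big$cancer_type <- "AAA"
  tiny <- null_surv_frame(4)  # fails min_per_group and min_total
  tiny$cancer_type <- "BBB"
  res <- per_cancer_survival(rbind(big, tiny))
  expect_equal(res$effects$cancer_type, "AAA")
  gr <- res$gate_report
  expect_false(gr$pass[gr$cancer_type == "BBB"])
  expect_match(gr$reasons[gr$cancer_type == "BBB"], "min_per_group")
  expect_identical(names(res$fits), "AAA")
})
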