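test_that("cohort rules apply closed pediatric interval and strict adult age", {
  # ages straddling every boundary: [6, 18] closed for exposure, > 18 strict
  # for the diagnosis
  pts <- make_patients(
    exposure_ages = list(p1 = 10, p2 = 20, p3 = 5.9, p4 = 6.0, p5 = 18.0,
                         p6 = 18.1, p7 = 12),
    diagnosis_ages = list(p1 = 25, p2 = 25, p3 = 25, p4 = 25, p5 = 25,
                          p6 = 25, p7 = 18.0, p8 = 19))
  a <- build_cohorts(pts, "RX", "DX")
  arm <- stats::setNames(a$arm, a$person_id)
  expect_identical(unname(arm[c("p1", "p4", "p5")]),
                   rep("target", 3))                      # in-window exposures
  expect_identical(unname(arm[c("p2", "p3", "p6", "p8")]),
                   rep("comparator", 4))                  # outside the window
  expect_identical(unname(arm["p7"]), "excluded")         # dx at exactly 18
  expect_equal(a$index_age[a$person_id == "p1"], 25)
  expect_error(build_cohorts(pts, character(0), "DX"), "nonempty")
})

test_that("index age is the first qualifying adult diagnosis", {
  pts <- make_patients(exposure_ages = list(p1 = 10),
                       diagnosis_ages = list(p1 = c(17, 22, 20, 30), p2 = 22))
  a <- build_cohorts(pts, "RX", "DX")
  expect_equal(a$index_age[a$person_id == "p1"], 20)
  # every patient excluded in one arm -> infeasible
  solo <- make_patients(exposure_ages = list(p1 = 10),
                        diagnosis_ages = list(p1 = 22))
  expect_error(build_cohorts(solo, "RX", "DX"), "infeasible")
})

test_that("outcome extraction honours the 3-day diagnosis lag", {
  lag3 <- 3 / 365.25
  visits <- data.frame(
    person_id = c("p1", "p2", "p3", "p4", "p5", "p6"),
    visit_type = c("inpatient", "inpatient", "inpatient", "outpatient",
                   "inpatient", "inpatient"),
    age = c(26, 26, 26, 26, 24, 26),
    stringsAsFactors = FALSE)
  # p1: same-day diagnosis -> event; p2: 4 days later -> censored;
  # p3: diagnosis 1 day BEFORE the visit -> censored; p4: outpatient -> no;
  # p5: inpatient with no linked diagnosis -> no; p6: lag boundary -> event
  extra_dx <- data.frame(
    person_id = c("p1", "p2", "p3", "p6"),
    concept_id = "DX",
    age = c(26, 26 + 4 / 365.25, 26 - 1 / 365.25, 26 + lag3),
    stringsAsFactors = FALSE)
  pts <- make_patients(
    exposure_ages = list(p1 = 10, p2 = 10, p3 = 10),
    diagnosis_ages = list(p1 = 22, p2 = 22, p3 = 22, p4 = 22, p5 = 22,
                          p6 = 22),
    visits = visits, extra_dx = extra_dx, obs_end = 40)
  a <- build_cohorts(pts, "RX", "DX")
  rows <- extract_outcomes(pts, a, "DX")
  ev <- stats::setNames(rows$event, rows$person_id)
  expect_identical(unname(ev[c("p1", "p6")]), c(TRUE, TRUE))
  expect_identical(unname(ev[c("p2", "p3", "p4", "p5")]), rep(FALSE, 4))
  expect_equal(rows$time[rows$person_id == "p1"], 4)      # 26 - 22
  expect_equal(rows$time[rows$person_id == "p2"], 18)     # censored at 40
})

test_that("propensity AUC matches the concordant-pair oracle", {
  set.seed(50)
  rows <- data.frame(exposure = rbinom(50, 1, 0.4),
                     z1 = rnorm(50), z2 = rnorm(50))
  rows$z1 <- rows$z1 + rows$exposure  # some signal
  ps <- fit_propensity(rows, covariates = c("z1", "z2"))
  s1 <- ps$scores[rows$exposure == 1]
  s0 <- ps$scores[rows$exposure == 0]
  conc <- 0
  for (a in s1) for (b in s0) conc <- conc + (a > b) + 0.5 * (a == b)
  expect_equal(ps$auc, conc / (length(s1) * length(s0)))
})

test_that("propensity AUC reflects covariate signal strength", {
  set.seed(51)
  n <- 5000
  none <- data.frame(exposure = rbinom(n, 1, 0.3), z = rnorm(n))
  expect_lt(abs(fit_propensity(none, "z")$auc - 0.5), 0.03)

  perfect <- data.frame(exposure = rep(c(1, 0), each = 200),
                        z = rep(c(1, 0), each = 200))
  ps <- fit_propensity(perfect, "z")
  expect_gt(ps$auc, 0.99)
  expect_true(all(ps$scores > 0 & ps$scores < 1))

  expect_error(fit_propensity(data.frame(exposure = rep(1, 10), z = rnorm(10)),
                              "z"), "arm")
  expect_error(fit_propensity(none, character(0)), "covariate")
})

test_that("stabilized IPW weights satisfy the identity cases", {
  e <- rep(c(1, 0), each = 10)
  expect_equal(ipw_weights(rep(0.5, 20), e), rep(1, 20))
  set.seed(52)
  s <- runif(20, 0.2, 0.8)
  expect_equal(ipw_weights(rep(mean(e), 20), e), rep(1, 20))
  expect_error(ipw_weights(c(0, s[-1]), e), "strictly")
  # ATT: exposed weight 1
  watt <- ipw_weights(s, e, scheme = "ATT", truncate_quantile = 1)
  expect_equal(watt[e == 1], rep(1, 10))
  expect_equal(watt[e == 0], (s / (1 - s))[e == 0])
})

test_that("IPW restores covariate balance in a confounded cohort", {
  worked <- vapply(1:10, function(s) {
    cfg <- cohort_sim_config(n_patients = 3000, seed = 700 + s)
    pt <- gen_patient_table(cfg)
    a <- build_cohorts(pt, "RX_ADRB2_AGONIST", "DX_SCHIZOPHRENIA")
    rows <- extract_outcomes(pt, a, "DX_SCHIZOPHRENIA")
    ps <- fit_propensity(rows)
    w <- ipw_weights(ps$scores, rows$exposure)
    bal <- covariate_balance(rows, weights = w)
    abs(bal$smd_before) > 0.2 && abs(bal$smd_after) < 0.1
  }, logical(1))
  expect_true(all(worked))
})

test_that("greedy caliper matching follows the hand-traced algorithm", {
  # logits placed by hand; caliper = 0.2 * sd(logit), ratio 2
  scores <- plogis(c(2.0, 1.0, -1.0,               # targets T1 T2 T3
                     1.95, 1.90, 1.2, 0.95, 0.90, -3.0))  # comparators C1..C6
  expo <- c(1, 1, 1, 0, 0, 0, 0, 0, 0)
  ids <- c("T1", "T2", "T3", "C1", "C2", "C3", "C4", "C5", "C6")
  cal <- 0.2 * stats::sd(qlogis(scores))  # = 0.337
  expect_gt(cal, 0.3); expect_lt(cal, 0.4)
  # trace: T1 (logit 2.0) takes C1 (1.95), C2 (1.90); C3 at |0.8| outside.
  # T2 (1.0) takes C4 (0.95), C5 (0.90); C3 at |0.2| inside but farther than
  # C4/C5? |1.2-1.0| = 0.2 < |0.95-1.0| = 0.05? no: 0.05 < 0.2, C4 and C5
  # are nearer; ratio 2 fills with C4, C5. T3 (-1.0): nearest remaining are
  # C3 (1.2) and C6 (-3.0), both outside the caliper -> unmatched.
  mm <- match_cohorts(scores, expo, ids = ids, caliper_sd = 0.2,
                      max_ratio = 2)
  expect_identical(sort(mm$pairs$comparator_id[mm$pairs$target_id == "T1"]),
                   c("C1", "C2"))
  expect_identical(sort(mm$pairs$comparator_id[mm$pairs$target_id == "T2"]),
                   c("C4", "C5"))
  expect_identical(mm$n_unmatched_targets, 1L)
  expect_false("T3" %in% mm$pairs$target_id)
})

test_that("identical scores match every target at full ratio", {
  scores <- rep(0.4, 12)
  expo <- rep(c(1, 0), times = c(3, 9))
  mm <- match_cohorts(scores, expo, max_ratio = 3)
  expect_identical(nrow(mm$pairs), 9L)
  expect_identical(mm$n_unmatched_targets, 0L)
  expect_error(match_cohorts(c(0.9, 0.1), c(1, 0), caliper_sd = 0.0001),
               "infeasible")
})

test_that("covariate balance matches the closed-form binary SMD", {
  rows <- data.frame(person_id = 1:200,
                     exposure = rep(c(1, 0), each = 100),
                     z = c(rep(1, 60), rep(0, 40), rep(1, 40), rep(0, 60)),
                     weight = 1)
  bal <- covariate_balance(rows, "z")
  expect_equal(bal$smd_before, 0.2 / sqrt((0.24 + 0.24) / 2), tolerance = 1e-12)
  # identical arms: zero
  rows0 <- data.frame(person_id = 1:40, exposure = rep(c(1, 0), each = 20),
                      z = rep(rep(c(3, 7), 10), 2))
  bal0 <- covariate_balance(rows0, "z")
  expect_equal(bal0$smd_before, 0)
  # constant covariate reports 0, not NaN
  rowsc <- data.frame(person_id = 1:20, exposure = rep(c(1, 0), 10), z = 5)
  expect_equal(covariate_balance(rowsc, "z")$smd_before, 0)
})

test_that("cox fitter handles exchangeable arms and small-sample oracle", {
  # identical event-time multisets in both arms: beta = 0
  rows <- data.frame(time = rep(c(1, 2, 3, 4), 2), event = TRUE,
                     exposure = rep(c(1, 0), each = 4))
  f <- fit_cox(rows)
  expect_equal(f$hr, 1, tolerance = 1e-9)

  # 4-patient fixture vs brute-force grid over the partial likelihood
  rows4 <- data.frame(time = c(1, 2, 3, 4), event = TRUE,
                      exposure = c(1, 0, 1, 0))
  f4 <- fit_cox(rows4)
  grid <- seq(-3, 3, by = 1e-4)
  lpl <- vapply(grid, function(b) {
    r <- exp(b * rows4$exposure)
    sum(b * rows4$exposure - log(rev(cumsum(rev(r)))))
  }, numeric(1))
  expect_lt(abs(log(f4$hr) - grid[which.max(lpl)]), 1e-4)
})

test_that("newton estimates match the grid argmax on random small fixtures", {
  set.seed(60)
  for (i in 1:8) {
    n <- sample(5:8, 1)
    rows <- data.frame(time = sample(seq(1, 40), n),  # unique -> no ties
                       event = c(TRUE, TRUE, runif(n - 2) < 0.7),
                       exposure = c(1, 0, rbinom(n - 2, 1, 0.5)))
    est <- tryCatch(fit_cox(rows), error = function(e) NULL)
    if (is.null(est)) next  # monotone likelihood fixtures are rejected
    grid <- seq(-3, 3, by = 1e-3)
    ord <- order(rows$time)
    tt <- rows$time[ord]; ee <- rows$event[ord]; xx <- rows$exposure[ord]
    lpl <- vapply(grid, function(b) {
      r <- exp(b * xx)
      sum((b * xx - log(rev(cumsum(rev(r)))))[ee])
    }, numeric(1))
    if (abs(grid[which.max(lpl)]) > 2.9) next  # near-divergent, skip fixture
    expect_lt(abs(log(est$hr) - grid[which.max(lpl)]), 2e-3)
  }
})

test_that("cox fit is invariant to time units and label inversion maps hr to 1/hr", {
  set.seed(61)
  n <- 400
  rows <- data.frame(time = rexp(n, 0.2), event = runif(n) < 0.7,
                     exposure = rbinom(n, 1, 0.5))
  f <- fit_cox(rows)
  rows_m <- rows; rows_m$time <- rows_m$time * 24 * 60
  fm <- fit_cox(rows_m)
  expect_equal(f$hr, fm$hr, tolerance = 1e-10)
  expect_equal(f$ci_low, fm$ci_low, tolerance = 1e-10)

  flip <- rows; flip$exposure <- 1 - flip$exposure
  ff <- fit_cox(flip)
  expect_equal(log(ff$hr), -log(f$hr), tolerance = 1e-8)
  expect_equal(ff$ci_low, 1 / f$ci_high, tolerance = 1e-8)
})

test_that("unit weights reproduce the unweighted fit exactly", {
  set.seed(62)
  n <- 300
  rows <- data.frame(time = rexp(n), event = runif(n) < 0.5,
                     exposure = rbinom(n, 1, 0.4))
  f1 <- fit_cox(rows)
  rows$weight <- 1
  f2 <- fit_cox(rows, robust = FALSE)
  expect_equal(f1$hr, f2$hr, tolerance = 1e-12)
  expect_equal(f1$log_hr_se, f2$log_hr_se, tolerance = 1e-12)
})

test_that("cox estimates agree with survival::coxph including robust weights", {
  library(survival)
  set.seed(63)
  n <- 1500
  rows <- data.frame(time = round(rexp(n, 0.3), 1) + 0.05,  # heavy ties
                     event = runif(n) < 0.6,
                     exposure = rbinom(n, 1, 0.35),
                     z = rnorm(n))
  rows$time <- rows$time * exp(-0.3 * rows$exposure)
  f <- fit_cox(rows, covariates = "z")
  cp <- coxph(Surv(time, event) ~ exposure + z, data = rows, ties = "breslow")
  expect_equal(unname(f$beta), unname(coef(cp)), tolerance = 1e-7)
  expect_equal(f$log_hr_se, sqrt(vcov(cp)[1, 1]), tolerance = 1e-7)

  rows$weight <- runif(n, 0.5, 2)
  fw <- fit_cox(rows, covariates = "z")
  cpw <- coxph(Surv(time, event) ~ exposure + z, data = rows,
               weights = weight, ties = "breslow", robust = TRUE)
  expect_equal(unname(fw$beta), unname(coef(cpw)), tolerance = 1e-7)
  expect_equal(fw$log_hr_se, sqrt(vcov(cpw)[1, 1]), tolerance = 1e-6)
})

test_that("cox fitter rejects degenerate designs", {
  rows <- data.frame(time = 1:6, event = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                     exposure = c(1, 1, 1, 0, 0, 0))
  expect_error(fit_cox(rows), "one exposure arm")
  expect_error(fit_cox(data.frame(time = c(-1, 2), event = TRUE,
                                  exposure = c(1, 0))), "positive")
})

test_that("null simulation keeps nominal CI coverage", {
  covered <- vapply(1:100, function(s) {
    cfg <- cohort_sim_config(n_patients = 2000, true_hr = 1,
                             confounders = NULL, exposure_intercept = -0.5,
                             seed = 9000 + s)
    pt <- gen_patient_table(cfg)
    a <- build_cohorts(pt, "RX_ADRB2_AGONIST", "DX_SCHIZOPHRENIA")
    rows <- extract_outcomes(pt, a, "DX_SCHIZOPHRENIA")
    f <- fit_cox(rows)
    f$ci_low <= 1 && 1 <= f$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.90)
})

test_that("the full study wrapper returns a coherent report", {
  pt <- gen_patient_table(cohort_sim_config(n_patients = 4000, seed = 77))
  rep <- run_cohort_study(pt, "RX_ADRB2_AGONIST", "DX_SCHIZOPHRENIA")
  expect_named(rep, c("estimates", "propensity", "balance", "attrition"))
  expect_s3_class(rep$estimates$ipw, "hazard_estimate")
  expect_true(rep$estimates$ipw$robust)
  expect_false(rep$estimates$crude$robust)
  expect_gt(rep$propensity$auc, 0.5)
  expect_true(all(abs(rep$balance$ipw$smd_after) <
                    abs(rep$balance$ipw$smd_before)))
  expect_identical(rep$attrition$n_total, 4000L)
  out <- capture.output(print(rep$estimates$ipw))
  expect_match(out[1], "IPW")
})
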