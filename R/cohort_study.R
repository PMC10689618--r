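# Observational cohort emulation: cohort construction from event tables,
# outcome extraction, propensity scores, IPW, caliper matching and balance
# diagnostics.

#' Assign patients to target / comparator cohorts
#'
#' Target: at least one exposure-concept record at an age inside the closed
#' pediatric window AND at least one disease-concept diagnosis strictly
#' after `diagnosis_age_min`. Comparator: the adult diagnosis without any
#' pediatric-window exposure record. Everyone else is excluded. The index
#' age is the first qualifying adult diagnosis.
#'
#' @param patients Patient table list as produced by [gen_patient_table()]
#'   (elements persons, exposures, diagnoses, visits).
#' @param exposure_concepts,disease_concepts Character vectors of concept
#'   ids defining exposure and disease.
#' @param exposure_age_range Closed age interval for pediatric exposure
#'   (default `c(6, 18)`).
#' @param diagnosis_age_min Diagnoses must occur strictly after this age
#'   (default 18).
#' @return data.frame with one row per person: person_id, arm
#'   ("target" / "comparator" / "excluded"), index_age (NA when excluded).
#' @export
build_cohorts <- function(patients, exposure_concepts, disease_concepts,
                          exposure_age_range = c(6, 18),
                          diagnosis_age_min = 18) {
  if (!length(exposure_concepts) || !length(disease_concepts)) {
    stop("concept sets must be nonempty")
  }
  pid <- patients$persons$person_id
  ex <- patients$exposures
  ped <- unique(ex$person_id[ex$concept_id %in% exposure_concepts &
                               ex$age >= exposure_age_range[1] &
                               ex$age <= exposure_age_range[2]])
  dx <- patients$diagnoses
  dx <- dx[dx$concept_id %in% disease_concepts & dx$age > diagnosis_age_min, ]
  idx <- tapply(dx$age, dx$person_id, min)
  has_dx <- pid %in% names(idx)
  has_ped <- pid %in% ped
  arm <- ifelse(!has_dx, "excluded",
                ifelse(has_ped, "target", "comparator"))
  out <- data.frame(person_id = pid, arm = arm,
                    index_age = as.numeric(idx[pid]),
                    stringsAsFactors = FALSE)
  out$index_age[out$arm == "excluded"] <- NA_real_
  if (!any(out$arm == "target") || !any(out$arm == "comparator")) {
    stop("study infeasible: target n = ", sum(out$arm == "target"),
         ", comparator n = ", sum(out$arm == "comparator"))
  }
  rownames(out) <- NULL
  out
}

#' Extract survival rows (time-at-risk, event flag) per included patient
#'
#' The outcome is the first inpatient visit after the index age that has a
#' disease-concept diagnosis dated on the visit day or up to `lag_days`
#' after it. Patients without a qualifying visit are censored at the end of
#' their observation window. Rows with non-positive time-at-risk are dropped
#' (count reported via attribute `"n_dropped"`).
#'
#' @inheritParams build_cohorts
#' @param assignment Output of [build_cohorts()].
#' @param lag_days Diagnosis-after-visit allowance in days (default 3).
#' @return data.frame: person_id, time (years), event, exposure (1 =
#'   target), covariate columns from `persons`, weight (1).
#' @export
extract_outcomes <- function(patients, assignment, disease_concepts,
                             lag_days = 3) {
  inc <- assignment[assignment$arm != "excluded", ]
  lag <- lag_days / 365.25
  v <- patients$visits
  v <- v[v$visit_type == "inpatient" & v$person_id %in% inc$person_id, ]
  d <- patients$diagnoses
  d <- d[d$concept_id %in% disease_concepts, c("person_id", "age")]
  names(d)[2] <- "dx_age"
  pairs <- merge(v, d, by = "person_id")
  pairs <- pairs[pairs$dx_age >= pairs$age & pairs$dx_age <= pairs$age + lag, ]
  pairs$index_age <- inc$index_age[match(pairs$person_id, inc$person_id)]
  pairs <- pairs[pairs$age > pairs$index_age, ]
  ev_age <- tapply(pairs$age, pairs$person_id, min)

  out <- inc
  out$event <- out$person_id %in% names(ev_age)
  obs_end <- patients$persons$obs_end_age[
    match(out$person_id, patients$persons$person_id)]
  end_age <- ifelse(out$event, as.numeric(ev_age[out$person_id]), obs_end)
  out$time <- end_age - out$index_age
  out$exposure <- as.integer(out$arm == "target")
  covs <- setdiff(names(patients$persons),
                  c("person_id", "obs_start_age", "obs_end_age"))
  for (cv in covs) {
    out[[cv]] <- patients$persons[[cv]][
      match(out$person_id, patients$persons$person_id)]
  }
  out$weight <- 1
  dropped <- sum(out$time <= 0)
  out <- out[out$time > 0, c("person_id", "time", "event", "exposure",
                             covs, "weight")]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  attr(out, "covariates") <- covs
  out
}

#' Fit a propensity model for exposure
#'
#' Ridge (L2) logistic regression of exposure on the covariates, with
#' scores clipped to `[1e-6, 1 - 1e-6]` and AUC computed from the rank
#' statistic (Mann-Whitney).
#'
#' @param rows Survival rows from [extract_outcomes()] (or any data.frame
#'   with an `exposure` column and covariate columns).
#' @param covariates Covariate column names; default the `"covariates"`
#'   attribute of `rows`.
#' @param c_strength Inverse regularization strength (default 1).
#' @return List of class `propensity_result`: scores, coefficients
#'   (intercept + covariates), auc, covariates.
#' @export
fit_propensity <- function(rows, covariates = NULL, c_strength = 1) {
  covariates <- covariates %||% attr(rows, "covariates")
  if (is.null(covariates) || !length(covariates)) {
    stop("need at least one covariate")
  }
  y <- as.integer(rows$exposure)
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    stop("need at least 2 patients in each exposure arm")
  }
  x <- as.matrix(rows[, covariates, drop = FALSE])
  storage.mode(x) <- "double"
  rl <- ridge_logistic(x, y, c_strength)
  scores <- expit(rl$intercept + drop(x %*% rl$beta))
  scores <- pmin(pmax(scores, 1e-6), 1 - 1e-6)
  r <- rank(scores)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  structure(list(scores = scores,
                 coefficients = c(intercept = rl$intercept, rl$beta),
                 auc = auc, covariates = covariates),
            class = "propensity_result")
}

#' Stabilized inverse-probability-of-treatment weights
#'
#' ATE weights: exposed `P(exposed) / score`, unexposed
#' `(1 - P(exposed)) / (1 - score)`; ATT weights: exposed 1, unexposed
#' `score / (1 - score)`. Weights above the `truncate_quantile` quantile are
#' capped there.
#'
#' @param scores Propensity scores in (0, 1).
#' @param exposure 0/1 exposure indicator.
#' @param scheme `"ATE"` (stabilized, default) or `"ATT"`.
#' @param truncate_quantile Upper truncation quantile (default 0.99; `1`
#'   disables truncation).
#' @return Positive weight vector.
#' @export
ipw_weights <- function(scores, exposure, scheme = c("ATE", "ATT"),
                        truncate_quantile = 0.99) {
  scheme <- match.arg(scheme)
  if (any(scores <= 0 | scores >= 1)) stop("scores must lie strictly in (0, 1)")
  e <- as.logical(exposure)
  w <- if (scheme == "ATE") {
    p1 <- mean(e)
    ifelse(e, p1 / scores, (1 - p1) / (1 - scores))
  } else {
    ifelse(e, 1, scores / (1 - scores))
  }
  if (truncate_quantile < 1) {
    cap <- stats::quantile(w, truncate_quantile, names = FALSE)
    w <- pmin(w, cap)
  }
  w
}

#' Greedy variable-ratio nearest-neighbor matching on the propensity logit
#'
#' Targets are processed in descending propensity order; each receives up to
#' `max_ratio` nearest unused comparators whose logit score lies within the
#' caliper (`caliper_sd` standard deviations of the logit scores, boundary
#' inclusive). Matching is without replacement. Targets with no comparator
#' in the caliper are dropped and counted.
#'
#' @param scores Propensity scores in (0, 1).
#' @param exposure 0/1 exposure indicator.
#' @param ids Person ids aligned with `scores` (default positional).
#' @param caliper_sd Caliper width in SDs of the logit score (default 0.2).
#' @param max_ratio Maximum comparators per target (default 20).
#' @return List: pairs (data.frame target_id, comparator_id), matched_ids,
#'   n_unmatched_targets, caliper (logit units).
#' @export
match_cohorts <- function(scores, exposure, ids = seq_along(scores),
                          caliper_sd = 0.2, max_ratio = 20) {
  e <- as.logical(exposure)
  if (!any(e) || !all(c(TRUE, FALSE) %in% e)) stop("both arms must be nonempty")
  lg <- logit(pmin(pmax(scores, 1e-12), 1 - 1e-12))
  caliper <- caliper_sd * stats::sd(lg)
  tol <- 1e-9 * (1 + max(abs(lg)))  # boundary-inclusive comparisons
  t_idx <- which(e)[order(-scores[e])]
  c_idx <- which(!e)
  c_ord <- c_idx[order(lg[c_idx])]
  c_lg <- lg[c_ord]
  avail <- rep(TRUE, length(c_ord))
  pairs_t <- list(); pairs_c <- list()
  for (ti in t_idx) {
    lo <- findInterval(lg[ti] - caliper - tol, c_lg) + 1L
    hi <- findInterval(lg[ti] + caliper + tol, c_lg)
    if (hi < lo) next
    win <- lo:hi
    win <- win[avail[win]]
    if (!length(win)) next
    dd <- abs(c_lg[win] - lg[ti])
    take <- win[order(dd)][seq_len(min(max_ratio, length(win)))]
    avail[take] <- FALSE
    pairs_t[[length(pairs_t) + 1L]] <- rep(ids[ti], length(take))
    pairs_c[[length(pairs_c) + 1L]] <- ids[c_ord[take]]
  }
  if (!length(pairs_t)) stop("study infeasible: no target could be matched")
  pairs <- data.frame(target_id = unlist(pairs_t),
                      comparator_id = unlist(pairs_c),
                      stringsAsFactors = FALSE)
  matched_targets <- unique(pairs$target_id)
  list(pairs = pairs,
       matched_ids = c(matched_targets, pairs$comparator_id),
       n_unmatched_targets = sum(e) - length(matched_targets),
       caliper = caliper)
}

# Weighted mean / population variance.
wmean <- function(x, w) sum(w * x) / sum(w)
wvar <- function(x, w) {
  m <- wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

#' Standardized mean differences before and after adjustment
#'
#' SMD per covariate: `(mean_T - mean_C) / sqrt((var_T + var_C) / 2)` with
#' weighted means and (population) variances. "Before" uses unit weights on
#' all rows; "after" uses the supplied weights and/or the matched subset.
#' Constant covariates (zero pooled SD) report SMD 0.
#'
#' @param rows Survival rows with exposure and covariate columns.
#' @param covariates Covariate column names; default the `"covariates"`
#'   attribute of `rows`.
#' @param weights Adjustment weights aligned with `rows` (default 1).
#' @param subset Optional person_id vector (e.g. `match_cohorts()$matched_ids`)
#'   restricting the "after" population.
#' @return data.frame: covariate, smd_before, smd_after.
#' @export
covariate_balance <- function(rows, covariates = NULL, weights = NULL,
                              subset = NULL) {
  covariates <- covariates %||% attr(rows, "covariates")
  if (is.null(covariates) || !length(covariates)) {
    stop("need at least one covariate")
  }
  weights <- weights %||% rep(1, nrow(rows))
  keep <- if (is.null(subset)) rep(TRUE, nrow(rows))
          else rows$person_id %in% subset
  smd <- function(x, e, w) {
    mt <- wmean(x[e], w[e]); mc <- wmean(x[!e], w[!e])
    sd_pool <- sqrt((wvar(x[e], w[e]) + wvar(x[!e], w[!e])) / 2)
    if (sd_pool == 0) 0 else (mt - mc) / sd_pool
  }
  e_all <- rows$exposure == 1
  out <- data.frame(covariate = covariates,
                    smd_before = NA_real_, smd_after = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(covariates)) {
    x <- as.numeric(rows[[covariates[i]]])
    out$smd_before[i] <- smd(x, e_all, rep(1, nrow(rows)))
    out$smd_after[i] <- smd(x[keep], e_all[keep], weights[keep])
  }
  out
}

#' Run the full observational study emulation
#'
#' Builds cohorts, extracts outcomes, fits the propensity model, and
#' estimates the exposure hazard ratio crude, IPW-weighted and/or in the
#' matched subpopulation, with covariate balance diagnostics.
#'
#' @inheritParams build_cohorts
#' @inheritParams extract_outcomes
#' @param design `"both"`, `"ipw"` or `"matched"`.
#' @param covariates Covariate columns for the propensity model (default all
#'   person covariates).
#' @param caliper_sd,max_ratio Matching controls (see [match_cohorts()]).
#' @return List report: per-method `hazard_estimate`s under `estimates`,
#'   `propensity` summary, `balance` tables, and `attrition` counts.
#' @export
run_cohort_study <- function(patients, exposure_concepts, disease_concepts,
                             design = c("both", "ipw", "matched"),
                             covariates = NULL, lag_days = 3,
                             exposure_age_range = c(6, 18),
                             diagnosis_age_min = 18,
                             caliper_sd = 0.2, max_ratio = 20) {
  design <- match.arg(design)
  assignment <- build_cohorts(patients, exposure_concepts, disease_concepts,
                              exposure_age_range, diagnosis_age_min)
  rows <- extract_outcomes(patients, assignment, disease_concepts, lag_days)
  ps <- fit_propensity(rows, covariates)
  estimates <- list(crude = fit_cox(rows, method = "crude"))
  balance <- list()
  attrition <- list(n_total = nrow(assignment),
                    n_excluded = sum(assignment$arm == "excluded"),
                    n_target = sum(rows$exposure == 1),
                    n_comparator = sum(rows$exposure == 0),
                    n_dropped_nonpositive_time = attr(rows, "n_dropped"))
  if (design %in% c("both", "ipw")) {
    w <- ipw_weights(ps$scores, rows$exposure)
    rw <- rows; rw$weight <- w
    estimates$ipw <- fit_cox(rw, method = "IPW")
    balance$ipw <- covariate_balance(rows, ps$covariates, weights = w)
  }
  if (design %in% c("both", "matched")) {
    mm <- match_cohorts(ps$scores, rows$exposure, ids = rows$person_id,
                        caliper_sd = caliper_sd, max_ratio = max_ratio)
    rm_ <- rows[rows$person_id %in% mm$matched_ids, ]
    estimates$matched <- fit_cox(rm_, method = "matched")
    balance$matched <- covariate_balance(rows, ps$covariates,
                                         subset = mm$matched_ids)
    attrition$n_matched_target <- estimates$matched$n_target
    attrition$n_matched_comparator <- estimates$matched$n_comparator
    attrition$n_unmatched_targets <- mm$n_unmatched_targets
  }
  list(estimates = estimates,
       propensity = list(auc = ps$auc, coefficients = ps$coefficients),
       balance = balance,
       attrition = attrition)
}
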