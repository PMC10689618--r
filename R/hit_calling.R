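# Compound-level classification of dose series, four-parameter logistic
# dose-response fitting and time-course AUC normalization.

.call_levels <- c("increase", "increase_gt20", "decrease", "decrease_gt20",
                  "no_effect", "toxic")

#' Classify one compound's dose series
#'
#' Only points at concentrations strictly above the dose gate (default 5 uM)
#' are considered. Toxicity takes precedence: any toxic qualifying point
#' makes the call `toxic`. Otherwise a non-toxic qualifying point with
#' normalized response below `decrease_cut_pct` (70) calls `decrease` and
#' above `increase_cut_pct` (130) calls `increase`; when the only crossings
#' sit above `high_dose_um` (20 uM) the call becomes `decrease_gt20` /
#' `increase_gt20`; responses within the band at all qualifying doses call
#' `no_effect`. If crossings occur in both directions the direction of the
#' highest crossing dose wins and `conflict` is set.
#'
#' @param series data.frame with columns concentration_um, pct_phagocytosis,
#'   toxic, sorted by concentration (strictly increasing).
#' @param thresholds A [screen_thresholds()].
#' @param compound_id Optional id echoed into the result.
#' @return One-row data.frame: compound_id, call, supporting_doses
#'   (";"-joined), conflict, note.
#' @export
classify_compound <- function(series, thresholds = screen_thresholds(),
                              compound_id = NA_character_) {
  if (nrow(series) < 1) stop("series needs at least one point")
  if (is.unsorted(series$concentration_um, strictly = TRUE)) {
    stop("concentrations must be strictly increasing")
  }
  res <- function(call, doses = numeric(0), conflict = FALSE, note = "") {
    data.frame(compound_id = compound_id, call = call,
               supporting_doses = paste(doses, collapse = ";"),
               conflict = conflict, note = note, stringsAsFactors = FALSE)
  }
  qual <- series[series$concentration_um > thresholds$dose_gate_um, ]
  if (nrow(qual) == 0) return(res("no_effect", note = "no-qualifying-dose"))
  if (any(qual$toxic, na.rm = TRUE)) {
    # record a suppressed direction if any qualifying point (toxic wells
    # included: cell death and a response crossing co-occur) crossed a cut
    suppressed <- any(qual$pct_phagocytosis < thresholds$decrease_cut_pct |
                        qual$pct_phagocytosis > thresholds$increase_cut_pct)
    return(res("toxic",
               doses = qual$concentration_um[qual$toxic %in% TRUE],
               conflict = isTRUE(suppressed),
               note = if (isTRUE(suppressed)) "effect-crossing-suppressed-by-toxicity" else ""))
  }
  dn <- qual$pct_phagocytosis < thresholds$decrease_cut_pct
  up <- qual$pct_phagocytosis > thresholds$increase_cut_pct
  if (!any(dn) && !any(up)) return(res("no_effect"))
  conflict <- any(dn) && any(up)
  if (conflict) {
    top_cross <- max(qual$concentration_um[dn | up])
    dir_dn <- dn[qual$concentration_um == top_cross][1]
  } else {
    dir_dn <- any(dn)
  }
  cross <- if (dir_dn) dn else up
  doses <- qual$concentration_um[cross]
  within <- any(doses <= thresholds$high_dose_um)
  call <- if (dir_dn) {
    if (within) "decrease" else "decrease_gt20"
  } else {
    if (within) "increase" else "increase_gt20"
  }
  res(call, doses = doses, conflict = conflict)
}

#' Classify every compound in a normalized screen
#'
#' Builds one dose series per compound from the normalized data wells and
#' applies [classify_compound()]. The screen is singlicate: duplicate
#' (compound, concentration) rows raise an error unless
#' `aggregate = "median"`, which takes the median response (a dose is toxic
#' when any replicate well is toxic).
#'
#' @param normalized Output of [normalize_screen()].
#' @param thresholds A [screen_thresholds()].
#' @param aggregate `"error"` (default) or `"median"`.
#' @param fit_curves If TRUE, attach a 4PL fit per compound (columns
#'   ec50_um, bottom, top, hill_slope, converged).
#' @return List with `calls` (one row per compound) and `counts` (named
#'   integer vector over the six call categories).
#' @export
classify_screen <- function(normalized, thresholds = screen_thresholds(),
                            aggregate = c("error", "median"),
                            fit_curves = FALSE) {
  aggregate <- match.arg(aggregate)
  d <- normalized[normalized$role == "data" & !is.na(normalized$compound_id), ]
  if (anyDuplicated(d[, c("compound_id", "concentration_um")])) {
    if (aggregate == "error") {
      stop("duplicate (compound, dose) rows; screen is singlicate ",
           "(use aggregate = \"median\" to collapse replicates)")
    }
    d <- do.call(rbind, lapply(
      split(d, list(d$compound_id, d$concentration_um), drop = TRUE),
      function(g) data.frame(
        compound_id = g$compound_id[1],
        concentration_um = g$concentration_um[1],
        pct_phagocytosis = stats::median(g$pct_phagocytosis),
        toxic = any(g$toxic), stringsAsFactors = FALSE)))
  }
  calls <- do.call(rbind, lapply(split(d, d$compound_id), function(g) {
    g <- g[order(g$concentration_um), ]
    cc <- classify_compound(
      g[, c("concentration_um", "pct_phagocytosis", "toxic")],
      thresholds, compound_id = g$compound_id[1])
    if (fit_curves) {
      fit <- tryCatch(fit_dose_response(g), error = function(e) NULL)
      cc$ec50_um <- if (is.null(fit)) NA_real_ else fit$ec50_um
      cc$bottom <- if (is.null(fit)) NA_real_ else fit$bottom
      cc$top <- if (is.null(fit)) NA_real_ else fit$top
      cc$hill_slope <- if (is.null(fit)) NA_real_ else fit$hill_slope
      cc$converged <- if (is.null(fit)) FALSE else fit$converged
    }
    cc
  }))
  calls <- calls[order(calls$compound_id), ]
  rownames(calls) <- NULL
  counts <- table(factor(calls$call, levels = .call_levels))
  list(calls = calls, counts = c(counts))
}

# 4PL response at dose c: bottom + (top - bottom) / (1 + (c / ec50)^slope).
# slope > 0 gives a curve decreasing in dose.
four_pl <- function(conc, bottom, top, ec50, slope) {
  bottom + (top - bottom) / (1 + (conc / ec50)^slope)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least squares on log10 dose via Levenberg-Marquardt, with starting values
#' from the data (bottom/top from the extreme responses, EC50 at the dose
#' nearest the half-maximal response, slope sign from the response
#' direction) plus a small multi-start over slope. EC50 is constrained to
#' `[min_dose / 100, max_dose * 100]`. The fit never raises on optimizer
#' failure: `converged = FALSE` is returned instead. Flat series
#' (`top ~ bottom`) are reported with `converged = FALSE` since the EC50 is
#' unidentifiable.
#'
#' With few singlicate points all four parameters are rarely jointly
#' identifiable: shallow-slope fits with extreme plateaus can beat the truth
#' on squared error. When responses are on a normalized scale whose
#' zero-dose asymptote is known (percent of plate median: 100), passing
#' `baseline` anchors that asymptote and fits the three remaining
#' parameters (effect plateau, EC50, slope magnitude), optionally inside
#' `plateau_bounds` / `slope_bounds`. This is the recommended mode for
#' 5-point screen series.
#'
#' @param series data.frame with columns concentration_um, pct_phagocytosis
#'   and optionally toxic (toxic points are dropped).
#' @param baseline Known response at vanishing dose (e.g. 100 on the
#'   percent-of-median scale), or `NULL` (default) for the free
#'   four-parameter fit.
#' @param plateau_bounds Bounds for the effect plateau in anchored mode
#'   (default `c(0, 300)` percent).
#' @param slope_bounds Bounds for the Hill slope magnitude in anchored mode
#'   (default `c(0.3, 5)`).
#' @return List of class `hill_fit`: bottom, top, ec50_um, hill_slope, sse,
#'   converged.
#' @export
fit_dose_response <- function(series, baseline = NULL,
                              plateau_bounds = c(0, 300),
                              slope_bounds = c(0.3, 5)) {
  if (!is.null(series$toxic)) series <- series[!series$toxic %in% TRUE, ]
  conc <- series$concentration_um
  pct <- series$pct_phagocytosis
  keep <- is.finite(conc) & is.finite(pct) & conc > 0
  conc <- conc[keep]; pct <- pct[keep]
  if (length(conc) < 4) stop("insufficient data: need >= 4 usable points")
  lo_ec <- min(conc) / 100
  hi_ec <- max(conc) * 100

  result <- function(b, t, e, s, sse, conv) {
    structure(list(bottom = b, top = t, ec50_um = e, hill_slope = s,
                   sse = sse, converged = conv), class = "hill_fit")
  }
  if (diff(range(pct)) < 1e-8) {
    return(result(pct[1], pct[1], NA_real_, NA_real_, 0, FALSE))
  }

  if (!is.null(baseline)) {
    # anchored mode: response = E + (baseline - E) / (1 + (c/ec50)^s), s > 0
    le0 <- log10(sqrt(min(conc) * max(conc)))
    best <- NULL
    for (s0 in c(0.5, 1, 2)) {
      for (E0 in c(max(plateau_bounds[1], min(pct)),
                   min(plateau_bounds[2], max(pct)))) {
        fit <- tryCatch(
          minpack.lm::nlsLM(
            pct ~ E + (baseline - E) / (1 + 10^(s * (log10(conc) - le))),
            start = list(E = E0, le = le0, s = s0),
            lower = c(E = plateau_bounds[1], le = log10(lo_ec),
                      s = slope_bounds[1]),
            upper = c(E = plateau_bounds[2], le = log10(hi_ec),
                      s = slope_bounds[2]),
            control = minpack.lm::nls.lm.control(maxiter = 200)),
          error = function(e) NULL)
        if (is.null(fit)) next
        sse <- sum(stats::residuals(fit)^2)
        if (is.null(best) || sse < best$sse) {
          best <- list(cf = stats::coef(fit), sse = sse)
        }
      }
    }
    if (is.null(best)) {
      return(result(min(pct), max(pct), NA_real_, NA_real_, Inf, FALSE))
    }
    E <- unname(best$cf["E"]); ec <- unname(10^best$cf["le"])
    s <- unname(best$cf["s"])
    degenerate <- abs(E - baseline) < 1e-6 * max(1, abs(baseline))
    return(if (E <= baseline) {
      result(E, baseline, ec, s, best$sse, !degenerate)
    } else {
      result(baseline, E, ec, -s, best$sse, !degenerate)
    })
  }

  mid <- (min(pct) + max(pct)) / 2
  ec_start <- conc[which.min(abs(pct - mid))]
  dir_dn <- pct[which.max(conc)] < pct[which.min(conc)]
  starts <- list(
    c(b = min(pct), t = max(pct), le = log10(ec_start), s = if (dir_dn) 1 else -1),
    c(b = min(pct), t = max(pct), le = log10(ec_start), s = if (dir_dn) 2 else -2),
    c(b = min(pct), t = max(pct), le = log10(sqrt(min(conc) * max(conc))),
      s = if (dir_dn) 0.5 else -0.5)
  )
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        pct ~ b + (t - b) / (1 + 10^(s * (log10(conc) - le))),
        start = as.list(st),
        lower = c(b = -Inf, t = -Inf, le = log10(lo_ec), s = -Inf),
        upper = c(b = Inf, t = Inf, le = log10(hi_ec), s = Inf),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    sse <- sum(stats::residuals(fit)^2)
    if (is.null(best) || sse < best$sse) {
      cf <- stats::coef(fit)
      best <- list(cf = cf, sse = sse)
    }
  }
  if (is.null(best)) {
    return(result(min(pct), max(pct), NA_real_, NA_real_, Inf, FALSE))
  }
  cf <- best$cf
  degenerate <- abs(cf["t"] - cf["b"]) < 1e-6 * max(1, abs(cf["t"]))
  result(unname(cf["b"]), unname(cf["t"]), unname(10^cf["le"]),
         unname(cf["s"]), best$sse, !degenerate)
}

#' Percent AUC of a treated time course relative to vehicle
#'
#' Trapezoidal area under the signal-vs-time curve, expressed as a percent
#' of the vehicle AUC. The two series must share the same time grid.
#'
#' @param tc data.frame with columns hour, signal (treated series).
#' @param vehicle data.frame with columns hour, signal (dose-0 series).
#' @return Scalar percent AUC.
#' @export
timecourse_auc <- function(tc, vehicle) {
  if (nrow(tc) != nrow(vehicle) ||
      any(abs(tc$hour - vehicle$hour) > 1e-9 * pmax(1, abs(tc$hour)))) {
    stop("treated and vehicle series must share the same time grid")
  }
  if (is.unsorted(tc$hour, strictly = TRUE)) {
    stop("times must be strictly increasing")
  }
  auc_t <- pracma::trapz(tc$hour, tc$signal)
  auc_v <- pracma::trapz(vehicle$hour, vehicle$signal)
  if (auc_v == 0) stop("vehicle AUC is zero; percent AUC undefined")
  100 * auc_t / auc_v
}
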