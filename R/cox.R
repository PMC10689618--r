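# Weighted Cox proportional-hazards fitter: Breslow tie handling,
# Newton-Raphson on the partial likelihood, model-based or robust
# (sandwich, score-residual) variance.

# Partial likelihood, gradient and information at `beta` for sorted data.
# x: n x p matrix sorted by ascending time; ft: index of the first row of
# each tie group (risk sets are closed under ties).
cox_quantities <- function(beta, time, event, x, w, ft) {
  eta <- drop(x %*% beta)
  r <- w * exp(eta)
  # reverse cumulative sums give risk-set aggregates at each row's time
  rc <- function(v) rev(cumsum(rev(v)))
  S0 <- rc(r)[ft]
  p <- ncol(x)
  S1 <- matrix(0, length(time), p)
  for (j in seq_len(p)) S1[, j] <- rc(r * x[, j])[ft]
  xbar <- S1 / S0
  ev <- which(event)
  loglik <- sum(w[ev] * (eta[ev] - log(S0[ev])))
  grad <- colSums(w[ev] * (x[ev, , drop = FALSE] - xbar[ev, , drop = FALSE]))
  info <- matrix(0, p, p)
  for (j in seq_len(p)) {
    for (k in j:p) {
      S2jk <- rc(r * x[, j] * x[, k])[ft]
      v <- sum(w[ev] * (S2jk[ev] / S0[ev] - xbar[ev, j] * xbar[ev, k]))
      info[j, k] <- v; info[k, j] <- v
    }
  }
  list(loglik = loglik, grad = grad, info = info,
       S0 = S0, xbar = xbar, eta = eta)
}

#' Fit a weighted Cox proportional-hazards model
#'
#' Maximizes the (weighted) Cox partial likelihood by Newton-Raphson with
#' step halving, using Breslow handling of tied event times, until the
#' gradient max-norm falls below `tol` scaled by the magnitude of the log
#' partial likelihood. The first column of the design is
#' the exposure of interest and is summarized as a hazard ratio with a 95%
#' confidence interval; the variance is model-based (inverse information)
#' for unit weights and a robust score-residual sandwich otherwise (or when
#' `robust = TRUE`).
#'
#' @param rows data.frame with columns time (> 0), event (logical/0-1),
#'   exposure (0/1), optional covariate columns and optional weight
#'   (default 1).
#' @param covariates Character vector of covariate columns to adjust for
#'   (default none: univariable exposure model).
#' @param robust Force robust variance on/off; default: robust iff any
#'   weight differs from 1.
#' @param ties Tie handling; only `"breslow"` is implemented.
#' @param max_iter,tol Newton-Raphson controls.
#' @param method Label echoed into the result (e.g. "IPW", "matched").
#' @return Object of class `hazard_estimate`: hr, ci_low, ci_high,
#'   log_hr_se, beta, vcov, loglik, n_target, n_comparator, n_events,
#'   iterations, converged, robust, method.
#' @export
fit_cox <- function(rows, covariates = character(0), robust = NULL,
                    ties = "breslow", max_iter = 100, tol = 1e-8,
                    method = "unweighted") {
  ties <- match.arg(ties)
  if (any(rows$time <= 0)) stop("times must be positive")
  w <- rows$weight %||% rep(1, nrow(rows))
  if (any(w <= 0)) stop("weights must be positive")
  event <- as.logical(rows$event)
  exposure <- as.numeric(rows$exposure)
  if (sum(event & exposure == 1) == 0 || sum(event & exposure == 0) == 0) {
    stop("infinite estimate: no events in one exposure arm ",
         "(monotone partial likelihood)")
  }
  x <- cbind(exposure = exposure)
  for (cv in covariates) x <- cbind(x, rows[[cv]])
  colnames(x) <- c("exposure", covariates)

  ord <- order(rows$time)
  time <- rows$time[ord]; event <- event[ord]
  x <- x[ord, , drop = FALSE]; w <- w[ord]
  ft <- match(time, time)  # first row of each tie group

  p <- ncol(x)
  beta <- rep(0, p)
  q <- cox_quantities(beta, time, event, x, w, ft)
  # gradient tolerance scaled by the partial-likelihood magnitude: an
  # absolute cutoff is unreachable in double precision once |logPL| is large
  gtol <- function(q) tol * (1 + abs(q$loglik))
  converged <- FALSE; it <- 0
  while (it < max_iter) {
    it <- it + 1
    if (max(abs(q$grad)) < gtol(q)) { converged <- TRUE; break }
    step <- solve(q$info, q$grad)
    alpha <- 1
    repeat {
      cand <- beta + alpha * step
      qc <- cox_quantities(cand, time, event, x, w, ft)
      if (is.finite(qc$loglik) && qc$loglik >= q$loglik) break
      alpha <- alpha / 2
      if (alpha < 1e-8) break
    }
    if (alpha < 1e-8 && (!is.finite(qc$loglik) || qc$loglik <= q$loglik)) {
      # no ascent direction left at machine precision: at the optimum if the
      # gradient is small on the likelihood scale, stuck otherwise
      if (max(abs(q$grad)) < 1e-4 * (1 + abs(q$loglik))) {
        converged <- TRUE; break
      }
      stop("Cox fit stalled before reaching the gradient tolerance ",
           "(max gradient ", format(max(abs(q$grad))), ")")
    }
    if (max(abs(cand)) > 50) {
      stop("infinite estimate: coefficient diverging (monotone likelihood)")
    }
    beta <- cand; q <- qc
  }
  if (!converged && max(abs(q$grad)) < gtol(q)) converged <- TRUE
  if (!converged) {
    stop("Cox fit did not converge in ", max_iter,
         " iterations (max gradient ", format(max(abs(q$grad))), ")")
  }

  use_robust <- if (is.null(robust)) any(w != 1) else isTRUE(robust)
  inv_info <- solve(q$info)
  if (use_robust) {
    # score residuals U_i (unweighted), sandwich B = sum (w_i U_i)(w_i U_i)'
    lt <- findInterval(time, time)  # last row of each tie group
    ev_c0 <- cumsum(ifelse(event, w / q$S0, 0))[lt]
    U <- matrix(0, length(time), p)
    expeta <- exp(q$eta)
    for (j in seq_len(p)) {
      ev_c1 <- cumsum(ifelse(event, w * q$xbar[, j] / q$S0, 0))[lt]
      U[, j] <- ifelse(event, x[, j] - q$xbar[, j], 0) -
        expeta * (x[, j] * ev_c0 - ev_c1)
    }
    Uw <- U * w
    vcov <- inv_info %*% crossprod(Uw) %*% inv_info
  } else {
    vcov <- inv_info
  }
  se1 <- sqrt(vcov[1, 1])
  structure(list(
    hr = exp(beta[1]),
    ci_low = exp(beta[1] - stats::qnorm(0.975) * se1),
    ci_high = exp(beta[1] + stats::qnorm(0.975) * se1),
    log_hr_se = se1,
    beta = stats::setNames(beta, colnames(x)),
    vcov = vcov,
    loglik = q$loglik,
    n_target = sum(exposure == 1),
    n_comparator = sum(exposure == 0),
    n_events = sum(event),
    iterations = it,
    converged = converged,
    robust = use_robust,
    method = method), class = "hazard_estimate")
}

#' @export
print.hazard_estimate <- function(x, ...) {
  cat(sprintf("Cox hazard ratio (%s%s): HR = %.3f (95%% CI %.3f-%.3f)\n",
              x$method, if (x$robust) ", robust SE" else "",
              x$hr, x$ci_low, x$ci_high))
  cat(sprintf("  n = %d target / %d comparator, %d events, %d iterations\n",
              x$n_target, x$n_comparator, x$n_events, x$iterations))
  invisible(x)
}
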