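#' Kaplan-Meier product-limit estimate
#'
#' Survival curve over the distinct event times; times at which only
#' censoring occurs do not produce a step.
#'
#' @param time Non-negative follow-up times (months).
#' @param event 0/1 event indicators (1 = death observed).
#' @return A data frame of class `"km_curve"` with columns `time`
#'   (sorted distinct event times), `n_risk`, `n_event` and `survival`
#'   (the step value just after each event time; the curve starts at 1).
#' @export
km_estimate <- function(time, event) {
  check_surv(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none", se.fit = FALSE)
  keep <- fit$n.event > 0
  out <- data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
                    n_event = fit$n.event[keep], survival = fit$surv[keep])
  class(out) <- c("km_curve", "data.frame")
  out
}

check_surv <- function(time, event, group = NULL) {
  if (!length(time)) stop("empty survival data")
  if (length(time) != length(event)) stop("'time' and 'event' lengths differ")
  if (any(!is.finite(time)) || any(time < 0)) stop("negative or non-finite time")
  if (!all(event %in% c(0, 1))) stop("'event' must be 0/1")
  if (!is.null(group)) {
    if (length(group) != length(time)) stop("'group' length differs")
    if (length(unique(group)) != 2L) stop("exactly two groups required")
  }
  invisible(TRUE)
}

#' Two-group log-rank test
#'
#' Standard (rho = 0) log-rank test of the separation between the two
#' Kaplan-Meier curves: `chi_sq = (sum(O - E))^2 / sum(V)` over the pooled
#' event times, referred to a chi-square with 1 df.
#'
#' @param time,event As in [km_estimate()].
#' @param group Two-level group labels.
#' @return List with `chi_sq`, `p`, and the per-group observed/expected
#'   event counts (`observed`, `expected`).
#' @export
logrank_test <- function(time, event, group) {
  check_surv(time, event, group)
  if (sum(event) < 1) stop("at least one event is required")
  sd <- survival::survdiff(survival::Surv(time, event) ~ g,
                           data = data.frame(time = time, event = event,
                                             g = factor(group)))
  list(chi_sq = as.numeric(sd$chisq),
       p = stats::pchisq(as.numeric(sd$chisq), df = 1, lower.tail = FALSE),
       observed = as.numeric(sd$obs), expected = as.numeric(sd$exp))
}

#' Cox proportional-hazards fit
#'
#' Maximizes the Cox partial likelihood (Newton-Raphson, tight convergence
#' tolerance, up to 50 iterations) with the chosen correction for tied
#' event times. Standard errors come from the inverse observed information;
#' `ci95 = exp(beta +/- 1.96 * se)` exactly.
#'
#' @param time,event As in [km_estimate()].
#' @param covariates Numeric vector or matrix (subjects in rows).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return List of class `"cox_fit"`: `beta`, `hr`, `se`, `ci95` (matrix
#'   with columns `lo`, `hi`), `p_wald`, `log_partial_likelihood`,
#'   `score_stat` (global score test statistic at beta = 0), `ties`,
#'   and `flagged` (`TRUE` when a coefficient ran to the monotone-likelihood
#'   boundary and was capped).
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  check_surv(time, event)
  if (sum(event) < 1) stop("at least one event is required")
  x <- as.matrix(covariates)
  if (nrow(x) != length(time)) stop("covariate rows must match number of subjects")
  if (any(!is.finite(x))) stop("non-finite covariate value")
  if (any(apply(x, 2L, function(v) length(unique(v))) < 2L)) {
    stop("degenerate covariate (constant across subjects)")
  }
  flagged <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(time, event) ~ x, ties = ties,
                    control = survival::coxph.control(iter.max = 50, eps = 1e-9)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be", conditionMessage(w))) {
        flagged <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(stats::vcov(fit))))
  if (flagged) {
    cap <- 20  # |beta| cap under monotone likelihood (HR ~ 5e8)
    beta <- pmin(pmax(beta, -cap), cap)
  }
  ci <- cbind(lo = exp(beta - 1.96 * se), hi = exp(beta + 1.96 * se))
  structure(list(beta = beta, hr = exp(beta), se = se, ci95 = ci,
                 p_wald = unname(2 * stats::pnorm(-abs(beta / se))),
                 log_partial_likelihood = fit$loglik[2L],
                 log_partial_likelihood_null = fit$loglik[1L],
                 score_stat = unname(fit$score), ties = ties,
                 flagged = flagged),
            class = "cox_fit")
}

# Fast Cox fit on a single covariate via survival::coxph.fit (no formula
# machinery); used inside the screening / resampling loops.
cox_quick <- function(time, event, x, ties = "efron") {
  fit <- survival::coxph.fit(x = matrix(as.numeric(x), ncol = 1L),
                             y = survival::Surv(time, event),
                             strata = NULL, offset = NULL, init = 0,
                             control = survival::coxph.control(iter.max = 50, eps = 1e-9),
                             weights = NULL, method = ties, rownames = NULL)
  beta <- as.numeric(fit$coefficients)
  se <- sqrt(as.numeric(fit$var))
  if (!is.finite(beta)) beta <- sign(beta) * 20
  c(beta = beta, se = se)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; output order matches input.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
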