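#' Median split of a per-sample score
#'
#' High group = score strictly above the median; ties at the median go to the
#' low group, so the split is deterministic.
#'
#' @param score named numeric vector, >= 4 samples.
#' @return logical vector (TRUE = high) with the input names.
#' @export
median_split <- function(score) {
  if (length(score) < 4) stop("need >= 4 samples")
  if (stats::sd(score) == 0) stop("constant score cannot be split")
  score > stats::median(score)
}

#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator with right censoring, one step function per group.
#'
#' @param time survival times (days).
#' @param event 0/1 event indicators (1 = death).
#' @param groups group labels (each group >= 2 samples).
#' @return named list per group: data.frame with `time`, `n_risk`, `n_event`,
#'   `surv`.
#' @export
km_estimate <- function(time, event, groups = rep(1, length(time))) {
  g <- factor(groups)
  if (any(table(g) < 2)) stop("each group needs >= 2 samples")
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  strata <- if (is.null(fit$strata)) stats::setNames(length(fit$time),
                                                     levels(g)[1])
            else fit$strata
  idx <- rep(seq_along(strata), strata)
  out <- list()
  for (i in seq_along(strata)) {
    sel <- idx == i
    nm <- sub("^g=", "", names(strata)[i])
    out[[nm]] <- data.frame(time = fit$time[sel], n_risk = fit$n.risk[sel],
                            n_event = fit$n.event[sel], surv = fit$surv[sel])
  }
  out
}

#' Univariate Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Breslow tie handling; hazard ratio with Wald
#' 95% CI and p-value from the observed information. Monotone-likelihood
#' (perfect separation) fits are flagged and returned with infinite CI
#' bounds.
#'
#' @param covariate numeric (or 2-level) per-sample covariate.
#' @param time,event survival outcome (days, 0/1).
#' @param conf_level CI level (default 0.95).
#' @return list of class `cox_result`: `beta`, `hr`, `ci_low`, `ci_high`,
#'   `wald_p`, `n`, `n_events`, `separation` flag.
#' @export
cox_univariate <- function(covariate, time, event, conf_level = 0.95) {
  if (sum(event) < 2) stop("need >= 2 events")
  x <- if (is.numeric(covariate)) covariate
       else as.numeric(factor(covariate)) - 1
  if (stats::sd(x) == 0) stop("constant covariate")
  fit <- suppressWarnings(
    survival::coxph(survival::Surv(time, event) ~ x, ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9,
                                                      iter.max = 50)))
  beta <- unname(stats::coef(fit))
  se <- sqrt(diag(stats::vcov(fit)))[1]
  sep <- !is.finite(se) || abs(beta) > 15 || se > 100
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  res <- list(beta = beta, hr = exp(beta),
              ci_low = if (sep) 0 else exp(beta - z * se),
              ci_high = if (sep) Inf else exp(beta + z * se),
              wald_p = if (sep) NA_real_
                       else 2 * stats::pnorm(-abs(beta / se)),
              se = se, n = length(time), n_events = sum(event),
              separation = sep)
  class(res) <- "cox_result"
  res
}

#' @export
print.cox_result <- function(x, ...) {
  cat(sprintf("HR = %.3f (%.2f-%.2f), Wald p = %.3g, n = %d (%d events)%s\n",
              x$hr, x$ci_low, x$ci_high, x$wald_p, x$n, x$n_events,
              if (x$separation) " [monotone likelihood]" else ""))
  invisible(x)
}

#' Median-split survival analysis of a score
#'
#' The Fig.-4-style analysis: split samples at the median of a score (e.g. a
#' module eigengene or a single gene), estimate KM curves per tier and the
#' Wald hazard ratio of high vs low.
#'
#' @param score named per-sample score.
#' @param time,event survival outcome aligned with `score`.
#' @return list with `groups`, `km` (per-tier step functions) and `cox`
#'   (a `cox_result` for high vs low).
#' @export
survival_by_split <- function(score, time, event) {
  hi <- median_split(score)
  grp <- ifelse(hi, "high", "low")
  list(groups = grp,
       km = km_estimate(time, event, grp),
       cox = cox_univariate(as.numeric(hi), time, event))
}
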