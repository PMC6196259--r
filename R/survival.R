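#' Split a quantity into high and low categories
#'
#' Dichotomizes per-sample values at the cohort median (default) or mean.
#' Samples strictly above the threshold are "high"; samples at or below it
#' are "low" (boundary ties stay low, so the split is deterministic). With
#' an even number of distinct values and a median split, the groups are
#' exactly balanced.
#'
#' @param values Per-sample numeric vector (names kept); at least 2
#'   distinct finite values.
#' @param method \code{"median"} (default) or \code{"mean"}.
#' @return List of class \code{dichotomy}: \code{label} (factor low/high),
#'   \code{threshold}, \code{method}.
#' @export
dichotomize <- function(values, method = c("median", "mean")) {
  method <- match.arg(method)
  v <- values[is.finite(values)]
  if (length(unique(v)) < 2)
    stop("dichotomize: all values equal; no high/low split exists")
  thr <- if (method == "median") stats::median(v) else mean(v)
  label <- factor(ifelse(values > thr, "high", "low"), levels = c("low", "high"))
  names(label) <- names(values)
  structure(list(label = label, threshold = thr, method = method),
            class = "dichotomy")
}

#' Kaplan-Meier estimate of freedom from recurrence
#'
#' Product-limit estimator of the survival (recurrence-free) function.
#' Censored observations reduce the risk set without producing a step.
#'
#' @param times Follow-up times in months, nonnegative.
#' @param events Event indicators (1 = recurrence observed, 0 = censored).
#' @return List of class \code{km_curve}: \code{time} (event-time grid),
#'   \code{surv}, \code{n_risk}, \code{n_event}, plus the underlying
#'   \code{survfit} object.
#' @export
km_estimate <- function(times, events) {
  if (any(times < 0)) stop("km_estimate: negative follow-up time")
  if (!all(events %in% c(0, 1))) stop("km_estimate: events must be 0/1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1, conf.type = "log")
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, fit = fit),
            class = "km_curve")
}

#' Survival probability at given times from a KM curve
#'
#' Step-function evaluation of the product-limit estimate, with Greenwood
#' standard errors and log-scale confidence intervals.
#'
#' @param curve A \code{km_curve}.
#' @param at Times (months) at which to evaluate.
#' @return Data frame: time, surv, lower, upper.
#' @export
km_at <- function(curve, at) {
  s <- summary(curve$fit, times = at, extend = TRUE)
  data.frame(time = s$time, surv = s$surv, lower = s$lower, upper = s$upper)
}

#' k-group log-rank test
#'
#' Standard log-rank chi-square across k groups (df = k - 1). For two
#' groups, also reports a signed direction: positive when the second group
#' level has more events than expected.
#'
#' @param groups Group label per sample (>= 2 nonempty groups).
#' @param times Follow-up times in months.
#' @param events Event indicators 0/1.
#' @return List: \code{chi2}, \code{df}, \code{p}, and for two groups
#'   \code{direction} (+1/-1/0).
#' @export
logrank <- function(groups, times, events) {
  g <- factor(groups)
  if (nlevels(g) < 2) stop("logrank: need at least 2 groups")
  if (any(table(g) == 0)) stop("logrank: empty group")
  if (sum(events) < 1) stop("logrank: no events observed")
  sd <- survival::survdiff(survival::Surv(times, events) ~ g)
  df <- nlevels(g) - 1L
  p <- stats::pchisq(sd$chisq, df = df, lower.tail = FALSE)
  out <- list(chi2 = unname(sd$chisq), df = df, p = p)
  if (nlevels(g) == 2) out$direction <- sign(sd$obs[2] - sd$exp[2])
  out
}

#' Univariate Cox proportional-hazards screen across genes
#'
#' Fits one Cox model per gene (Efron tie handling) of the recurrence
#' outcome on that gene's expression and reports the coefficient, the score
#' (log-rank-type) statistic and its p-value. Genes with degenerate
#' covariates or non-converging fits are flagged, never silently dropped.
#'
#' @param expr Genes x samples matrix (any monotone scale).
#' @param times Follow-up times per sample (months).
#' @param events Event indicators 0/1.
#' @return Data frame: gene, coef, score_chi2, p, flag ("" when clean).
#' @export
cox_screen <- function(expr, times, events) {
  if (ncol(expr) != length(times) || length(times) != length(events))
    stop("cox_screen: expr columns, times and events must align")
  if (sum(events) < 10)
    warning("cox_screen: fewer than 10 events; per-gene estimates unstable")
  srv <- survival::Surv(times, events)
  one <- function(x) {
    if (!all(is.finite(x))) return(c(NA, NA, NA, 1))
    if (stats::sd(x) == 0) return(c(NA, NA, NA, 2))
    fit <- tryCatch(
      survival::coxph(srv ~ x, ties = "efron",
                      control = survival::coxph.control(iter.max = 50)),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$coefficients))
      return(c(NA, NA, NA, 3))
    sc <- fit$score
    c(fit$coefficients[[1]], sc, stats::pchisq(sc, 1, lower.tail = FALSE), 0)
  }
  res <- t(apply(expr, 1, one))
  flags <- c("", "non-finite covariate", "constant covariate", "non-convergence")
  data.frame(gene = rownames(expr), coef = res[, 1], score_chi2 = res[, 2],
             p = res[, 3], flag = flags[res[, 4] + 1],
             row.names = NULL, stringsAsFactors = FALSE)
}
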