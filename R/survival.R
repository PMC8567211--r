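## Survival machinery: thin, contract-enforcing surfaces over the survival
## package. Endpoint conventions follow standard leukaemia trial reporting:
## relapse rate is presented as 1 - Kaplan-Meier of time-to-relapse with
## censoring at death in remission (not a competing-risks cumulative
## incidence); ties are handled by the Efron approximation; rate confidence
## intervals use the log(-log) transform so bounds stay in [0, 1].

#' Kaplan-Meier product-limit fit
#'
#' @param times event/censoring times in years, >= 0.
#' @param indicators event indicators (1 = event, 0 = censored).
#' @return object of class `heh_km`: list with `time`, `surv`, `lower`,
#'   `upper` (pointwise 95% log-log bounds), `n_risk`, `n_event`, `n` and
#'   the underlying `survfit` object as `fit`.
#' @export
km_fit <- function(times, indicators) {
  if (length(times) != length(indicators))
    stop("times and indicators must have the same length", call. = FALSE)
  stopifnot(length(times) >= 1, all(times >= 0), all(indicators %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, indicators) ~ 1,
                           conf.type = "log-log")
  structure(list(time = fit$time, surv = fit$surv,
                 lower = fit$lower, upper = fit$upper,
                 n_risk = fit$n.risk, n_event = fit$n.event,
                 n = length(times), fit = fit),
            class = "heh_km")
}

#' @export
print.heh_km <- function(x, ...) {
  cat("<heh_km> n =", x$n, ", events =", sum(x$n_event),
      ", last follow-up =", round(max(x$time), 3), "\n")
  invisible(x)
}

#' Survival (or failure) rate at a fixed horizon
#'
#' Step-function convention: the last estimate at or before the horizon is
#' used; a horizon beyond the last follow-up carries the last estimate
#' forward with a warning, and a horizon before the first observed time
#' returns a degenerate estimate (survival 1) with a warning.
#'
#' @param curve an `heh_km` object.
#' @param horizon time in years, > 0.
#' @param as_failure if `TRUE`, report `1 - S(horizon)` (e.g. a relapse
#'   rate) with the interval transformed accordingly.
#' @return list with `rate` and `ci` (length-2 95% interval).
#' @export
rate_at <- function(curve, horizon, as_failure = FALSE) {
  stopifnot(inherits(curve, "heh_km"), horizon > 0)
  if (horizon < min(curve$fit$time)) {
    warning("horizon precedes the first observed time; returning degenerate estimate",
            call. = FALSE)
    est <- 1; lo <- 1; up <- 1
  } else {
    if (horizon > max(curve$fit$time))
      warning("horizon beyond last follow-up; last estimate carried forward",
              call. = FALSE)
    s <- summary(curve$fit, times = horizon, extend = TRUE)
    est <- s$surv; lo <- s$lower; up <- s$upper
    if (is.na(lo)) { lo <- est; up <- est }
  }
  if (as_failure) list(rate = 1 - est, ci = c(1 - up, 1 - lo))
  else list(rate = est, ci = c(lo, up))
}

#' Log-rank test between groups
#'
#' @param times,indicators as in [km_fit()].
#' @param group group labels (>= 2 non-empty groups; >= 1 event overall).
#' @return list with `chi2`, `df` and two-sided `p`.
#' @export
logrank <- function(times, indicators, group) {
  stopifnot(length(times) == length(indicators),
            length(times) == length(group))
  group <- as.factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2) stop("need at least two non-empty groups", call. = FALSE)
  if (any(table(group) == 0)) stop("a group has zero subjects", call. = FALSE)
  if (sum(indicators) < 1) stop("need at least one event", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(times, indicators) ~ group)
  df <- nlevels(group) - 1L
  list(chi2 = as.numeric(sd$chisq), df = df,
       p = stats::pchisq(as.numeric(sd$chisq), df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximisation with the Efron tie correction; Wald 95%
#' confidence intervals and two-sided p-values per covariate. In
#' `"univariate"` mode each covariate is fitted in its own model.
#'
#' @param times,indicators as in [km_fit()].
#' @param covariates data.frame or matrix of numeric covariates; no
#'   covariate may be constant.
#' @param mode `"multivariate"` (one joint model) or `"univariate"`.
#' @return data.frame with one row per covariate: `term`, `coef`, `hr`,
#'   `lcl`, `ucl`, `p`, `n_events`, `log_partial_likelihood`.
#' @export
cox_fit <- function(times, indicators, covariates,
                    mode = c("multivariate", "univariate")) {
  mode <- match.arg(mode)
  X <- as.data.frame(covariates)
  stopifnot(length(times) == length(indicators), nrow(X) == length(times))
  const <- vapply(X, function(v) length(unique(v[!is.na(v)])) < 2, logical(1))
  if (any(const))
    stop("constant covariate(s): ", paste(names(X)[const], collapse = ", "),
         call. = FALSE)
  if (sum(indicators) < ncol(X))
    stop("fewer events than covariates", call. = FALSE)
  fit_one <- function(Xs) {
    dat <- cbind(data.frame(.t = times, .s = indicators), Xs)
    fit <- withCallingHandlers(
      survival::coxph(survival::Surv(.t, .s) ~ ., data = dat, ties = "efron"),
      warning = function(w) {
        if (grepl("converge|infinite|beta may be infinite", conditionMessage(w)))
          stop("Cox model failed: ", conditionMessage(w),
               " (after ", survival::coxph.control()$iter.max, " max iterations);",
               " consider exact/penalised methods for separated data",
               call. = FALSE)
        invokeRestart("muffleWarning")
      })
    if (any(is.na(stats::coef(fit))) || any(abs(stats::coef(fit)) > 15))
      stop("apparent complete separation; consider exact/penalised methods",
           call. = FALSE)
    s <- summary(fit)
    data.frame(term = rownames(s$coefficients),
               coef = s$coefficients[, "coef"],
               hr = s$coefficients[, "exp(coef)"],
               lcl = s$conf.int[, "lower .95"],
               ucl = s$conf.int[, "upper .95"],
               p = s$coefficients[, "Pr(>|z|)"],
               n_events = fit$nevent,
               log_partial_likelihood = fit$loglik[2],
               row.names = NULL, stringsAsFactors = FALSE)
  }
  if (mode == "multivariate") fit_one(X)
  else do.call(rbind, lapply(names(X), function(nm) fit_one(X[, nm, drop = FALSE])))
}

#' Harrell's concordance index
#'
#' Probability that, over usable (comparable) pairs, the subject with the
#' higher predicted risk has the earlier event; ties in the prediction are
#' credited 0.5.
#'
#' @param predicted_risk numeric risk scores (higher = worse).
#' @param times,indicators as in [km_fit()].
#' @return C-index in `[0, 1]`.
#' @export
concordance_index <- function(predicted_risk, times, indicators) {
  stopifnot(length(predicted_risk) == length(times),
            length(times) == length(indicators))
  y <- survival::Surv(times, indicators)
  cf <- survival::concordancefit(y, as.numeric(predicted_risk), reverse = TRUE)
  npairs <- sum(cf$count[c("concordant", "discordant", "tied.x")])
  if (is.na(npairs) || npairs == 0)
    stop("no usable pairs for concordance", call. = FALSE)
  as.numeric(cf$concordance)
}
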