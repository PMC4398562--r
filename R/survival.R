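## Survival machinery used to score classifications: Kaplan-Meier curves,
## log-rank tests, Cox proportional-hazards fits (via the survival package),
## and the uni- vs bivariate hazard-ratio independence check.

#' Kaplan-Meier product-limit estimator
#'
#' Wraps \code{survival::survfit}. The median survival is the earliest
#' time at which the estimated curve drops to 0.5 or below; when the curve
#' never reaches 0.5 the median is undefined and returned as \code{NA}
#' with \code{medianDefined = FALSE}.
#'
#' @param time nonnegative survival times (months)
#' @param event logical/0-1 event indicators (TRUE = death observed)
#' @return list with \code{time}, \code{surv} (step-function values after
#'   each distinct event time), \code{median}, \code{medianDefined}, and
#'   the underlying \code{survfit} object
#' @examples
#' kaplanMeier(c(1, 2, 3), c(1, 1, 1))$median   # 2
#' @export
kaplanMeier <- function(time, event) {
  if (length(time) == 0L) stop("empty survival data")
  if (any(time < 0)) stop("negative survival times")
  event <- as.integer(event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  med <- if (any(fit$surv <= 0.5)) fit$time[which(fit$surv <= 0.5)[1L]]
         else NA_real_
  list(time = fit$time, surv = fit$surv,
       median = med, medianDefined = !is.na(med), fit = fit)
}

#' Log-rank test
#'
#' Standard observed-vs-expected log-rank chi-square across k groups
#' (k - 1 degrees of freedom), via \code{survival::survdiff}.
#'
#' @param time,event as in [kaplanMeier()]
#' @param group group labels (2 or more nonempty levels)
#' @return list with \code{chisq}, \code{df}, \code{p.value}
#' @export
logrankTest <- function(time, event, group) {
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2L || any(table(group) == 0L))
    stop("log-rank test needs at least 2 nonempty groups")
  if (any(time < 0)) stop("negative survival times")
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  df <- nlevels(group) - 1L
  list(chisq = sd$chisq, df = df,
       p.value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood fit with Breslow tie handling via
#' \code{survival::coxph}. Reports hazard ratios with Wald confidence
#' intervals. Non-convergence and complete separation (divergent
#' coefficients) are explicit errors.
#'
#' @param time,event as in [kaplanMeier()]
#' @param X data.frame or matrix of covariates (no constant columns)
#' @param conf.level Wald CI level
#' @return data.frame with one row per coefficient: \code{coef} (log HR),
#'   \code{hr}, \code{se}, \code{lower}, \code{upper}, \code{p.value}
#' @export
coxFit <- function(time, event, X, conf.level = 0.95) {
  X <- as.data.frame(X)
  if (sum(event) == 0L) stop("no events observed: Cox fit undefined")
  const <- vapply(X, function(col) length(unique(col)) < 2L, logical(1))
  if (any(const))
    stop("constant covariate(s): ", paste(names(X)[const], collapse = ", "))
  dat <- cbind(data.frame(.time = time, .event = as.integer(event)), X)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(X)), collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(fml, data = dat, ties = "breslow",
                    control = survival::coxph.control(iter.max = 100)),
    warning = function(w) {
      if (grepl("infinite|did not converge|beta may be infinite",
                conditionMessage(w)))
        stop("Cox fit failed: ", conditionMessage(w), call. = FALSE)
      invokeRestart("muffleWarning")
    })
  if (any(!is.finite(stats::coef(fit))) || any(abs(stats::coef(fit)) > 15))
    stop("Cox fit failed: divergent coefficient (complete separation?)")
  s <- summary(fit, conf.int = conf.level)
  z <- stats::qnorm(1 - (1 - conf.level) / 2)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  data.frame(
    covariate = names(co), coef = unname(co), hr = exp(unname(co)),
    se = unname(se),
    lower = exp(unname(co) - z * unname(se)),
    upper = exp(unname(co) + z * unname(se)),
    p.value = unname(s$coefficients[, "Pr(>|z|)"]),
    row.names = NULL)
}

#' Independence of predictors: uni- vs bivariate hazard ratios
#'
#' Two predictors are treated as independent when each covariate's
#' log hazard ratio from the joint (bivariate) fit stays within a relative
#' tolerance of its univariate value:
#' \code{|log HR_bi - log HR_uni| <= tol * |log HR_uni|}. This
#' operationalizes "the hazard ratios do not differ significantly"; the
#' tolerance (default 0.25) is a package configuration.
#'
#' @param uni data.frame from [coxFit()] with one covariate per fit
#'   (rows stacked), or named numeric vector of univariate log HRs
#' @param bi data.frame from a joint [coxFit()], or named numeric vector
#'   of bivariate log HRs
#' @param tol relative tolerance on the log hazard ratio
#' @return named logical vector, one entry per covariate
#' @export
independenceCheck <- function(uni, bi, tol = 0.25) {
  getLogHR <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$coef, x$covariate)
    else x
  }
  u <- getLogHR(uni); b <- getLogHR(bi)
  if (!setequal(names(u), names(b)))
    stop("covariate sets differ between the univariate and bivariate fits")
  b <- b[names(u)]
  abs(b - u) <= tol * abs(u)
}
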