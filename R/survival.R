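# Survival statistics: Kaplan-Meier, log-rank, Cox proportional hazards.
# Estimation delegates to the survival package; this layer adds the
# validation, shapes and conventions used throughout the pipeline
# (deaths-precede-censorings at ties, Efron tie handling, 95% Wald CIs).

.check_surv <- function(time, event) {
  if (any(!is.finite(time)) || any(time <= 0))
    stop("survival times must be positive and finite")
  if (!all(event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (event)")
}

#' Kaplan-Meier product-limit estimate
#'
#' @param time positive event/censoring times (months)
#' @param event 0 = censored, 1 = event
#' @return data.frame with one row per distinct event time: \code{time},
#'   \code{at_risk}, \code{deaths}, \code{survival} (the product-limit
#'   estimate, non-increasing, S(0) = 1 implicitly)
#' @examples
#' kmEstimate(c(5, 8, 12), c(1, 0, 1))
#' @export
kmEstimate <- function(time, event) {
  .check_surv(time, event)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep], at_risk = fit$n.risk[keep],
             deaths = fit$n.event[keep], survival = fit$surv[keep])
}

#' Log-rank test
#'
#' Standard observed-minus-expected log-rank statistic with hypergeometric
#' variance; df = number of groups - 1; p from the upper chi-square tail.
#'
#' @param time,event as in \code{\link{kmEstimate}}
#' @param group group membership (>= 2 non-empty groups)
#' @return list with \code{chi2}, \code{df}, \code{p.value},
#'   \code{observed}, \code{expected}
#' @export
logrankTest <- function(time, event, group) {
  .check_surv(time, event)
  group <- as.factor(droplevels(as.factor(group)))
  if (nlevels(group) < 2L) stop("need >= 2 non-empty groups")
  sd_fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- nlevels(group) - 1L
  chi2 <- sd_fit$chisq
  list(chi2 = unname(chi2), df = df,
       p.value = unname(pchisq(chi2, df, lower.tail = FALSE)),
       observed = sd_fit$obs, expected = sd_fit$exp)
}

#' Cox proportional-hazards fit
#'
#' Univariate (one model per covariate) or multivariate (joint) Cox
#' regression with Efron (default) or Breslow tie handling. Hazard ratios
#' are reported with 95\% Wald confidence intervals
#' \code{exp(beta +/- 1.96 se)}. A monotone partial likelihood (perfect
#' separation) is surfaced as a warning and flagged in the result.
#'
#' @param data data.frame holding survival columns and covariates
#' @param covariates character vector of covariate column names (categorical
#'   covariates are used as factors as supplied)
#' @param timeCol,eventCol names of the time and event columns
#' @param mode "multivariate" (joint fit) or "univariate" (one covariate at
#'   a time)
#' @param ties "efron" or "breslow"
#' @return data.frame per fitted term: covariate, term, beta, HR, ci_low,
#'   ci_high, z, p, plus attributes \code{ties}, \code{loglik},
#'   \code{converged}, \code{separation}
#' @export
coxFit <- function(data, covariates, timeCol = "time_months",
                   eventCol = "event",
                   mode = c("multivariate", "univariate"),
                   ties = c("efron", "breslow")) {
  mode <- match.arg(mode)
  ties <- match.arg(ties)
  if (!all(c(timeCol, eventCol) %in% colnames(data)))
    stop("missing time/event columns: ", timeCol, ", ", eventCol)
  missing_cov <- setdiff(covariates, colnames(data))
  if (length(missing_cov))
    stop("covariates not in data: ", paste(missing_cov, collapse = ", "))
  .check_surv(data[[timeCol]], data[[eventCol]])
  if (sum(data[[eventCol]]) < 1L) stop("need at least one event")
  for (v in covariates)
    if (length(unique(data[[v]])) < 2L)
      stop("constant covariate: ", v)

  fit_one <- function(covs) {
    fml <- stats::as.formula(paste0(
      "survival::Surv(", timeCol, ", ", eventCol, ") ~ ",
      paste(sprintf("`%s`", covs), collapse = " + ")))
    separation <- FALSE
    fit <- withCallingHandlers(
      survival::coxph(fml, data = data, ties = ties),
      warning = function(w) {
        if (grepl("infinite|did not converge", conditionMessage(w))) {
          separation <<- TRUE
          warning("possible monotone likelihood (separation) for ",
                  paste(covs, collapse = "+"), call. = FALSE)
          invokeRestart("muffleWarning")
        }
      })
    s <- summary(fit)
    beta <- s$coefficients[, "coef"]
    se <- s$coefficients[, "se(coef)"]
    out <- data.frame(covariate = rep(paste(covs, collapse = "+"),
                               length(beta)),
               term = rownames(s$coefficients),
               beta = unname(beta), HR = unname(exp(beta)),
               ci_low = unname(exp(beta - 1.96 * se)),
               ci_high = unname(exp(beta + 1.96 * se)),
               z = unname(s$coefficients[, "z"]),
               p = unname(s$coefficients[, ncol(s$coefficients)]),
               separation = separation,
               stringsAsFactors = FALSE, row.names = NULL)
    attr(out, "loglik") <- fit$loglik[2]
    out
  }

  if (mode == "univariate") {
    out <- do.call(rbind, lapply(covariates, fit_one))
    attr(out, "loglik") <- NA_real_
  } else {
    out <- fit_one(covariates)
  }
  attr(out, "ties") <- ties
  attr(out, "mode") <- mode
  out
}
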