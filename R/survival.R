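#' Kaplan-Meier survival estimate per group
#'
#' Product-limit estimator; censored times reduce the at-risk count
#' without creating steps. Without censoring the estimate equals the
#' empirical survival function at every event time.
#'
#' @param time positive follow-up times.
#' @param event binary event indicator (1 death, 0 censored).
#' @param group group label per subject (e.g. dormancy category).
#' @return `data.frame` with columns `group`, `time`, `nRisk`, `nEvent`,
#'   `surv`; the underlying [survival::survfit] object is attached as
#'   attribute `fit`.
#' @export
kmEstimate <- function(time, event, group = rep("all", length(time))) {
  if (any(time <= 0)) stop("times must be positive")
  if (!all(event %in% c(0, 1))) stop("event must be binary 0/1")
  g <- as.factor(group)
  if (any(table(g) == 0L)) stop("empty group")
  fit <- survival::survfit(survival::Surv(time, event) ~ g)
  if (length(levels(g)) == 1L) {
    out <- data.frame(group = levels(g), time = fit$time, nRisk = fit$n.risk,
                      nEvent = fit$n.event, surv = fit$surv)
  } else {
    out <- data.frame(
      group = rep(sub("^g=", "", names(fit$strata)), fit$strata),
      time = fit$time, nRisk = fit$n.risk, nEvent = fit$n.event,
      surv = fit$surv)
  }
  attr(out, "fit") <- fit
  out
}

#' Log-rank test across groups
#'
#' Standard K-group log-rank chi-square with `K - 1` degrees of freedom.
#'
#' @inheritParams kmEstimate
#' @return A list: `statistic`, `df`, `p`.
#' @export
logrankTest <- function(time, event, group) {
  g <- as.factor(group)
  if (nlevels(droplevels(g)) < 2L) stop("need at least 2 groups")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ g)
  df <- length(sd_$n) - 1L
  list(statistic = unname(sd_$chisq), df = df,
       p = pchisq(sd_$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards ratios with staged covariate adjustment
#'
#' Fits one Cox model per covariate set (partial likelihood, Efron tie
#' handling by default) with the dormancy category as the exposure,
#' reference level `NO`, and reports the log hazard ratio with 95%
#' confidence interval per category and covariate set. Non-convergence is
#' reported per model rather than fatal.
#'
#' @param time,event as in [kmEstimate()].
#' @param category dormancy category per subject (factor; relevelled to
#'   reference `"NO"` when present).
#' @param covariates `data.frame` of candidate covariates (e.g. age,
#'   gender, study, stage), one row per subject.
#' @param covariateSets list of character vectors naming covariates for
#'   each staged model; the default progression is `{}` then
#'   `{age, gender}`, `{age, gender, study}`, `{age, gender, stage}`,
#'   `{age, gender, study, stage}` intersected with available columns.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return `data.frame`: `covariates`, `term`, `logHR`, `lo`, `hi`, `p`,
#'   `converged`.
#' @export
coxHR <- function(time, event, category, covariates = NULL,
                  covariateSets = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  cat_ <- as.factor(category)
  if ("NO" %in% levels(cat_)) cat_ <- stats::relevel(cat_, ref = "NO")
  df <- data.frame(time = time, event = event, category = cat_)
  if (!is.null(covariates)) df <- cbind(df, covariates)
  if (is.null(covariateSets)) {
    av <- colnames(covariates)
    covariateSets <- Filter(function(s) all(s %in% av), list(
      character(0), c("age", "gender"), c("age", "gender", "study"),
      c("age", "gender", "stage"), c("age", "gender", "study", "stage")))
    if (!length(covariateSets)) covariateSets <- list(character(0))
  }
  res <- lapply(covariateSets, function(cv) {
    rhs <- paste(c("category", cv), collapse = " + ")
    label <- if (length(cv)) paste(cv, collapse = "+") else "(none)"
    fit <- tryCatch(
      survival::coxph(stats::as.formula(
        paste("survival::Surv(time, event) ~", rhs)), data = df,
        ties = ties),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) {
      fit <- tryCatch(suppressWarnings(
        survival::coxph(stats::as.formula(
          paste("survival::Surv(time, event) ~", rhs)), data = df,
          ties = ties)), error = function(e) NULL)
      if (is.null(fit))
        return(data.frame(covariates = label, term = NA_character_,
                          logHR = NA_real_, lo = NA_real_, hi = NA_real_,
                          p = NA_real_, converged = FALSE,
                          stringsAsFactors = FALSE))
    }
    sm <- summary(fit)
    terms <- grep("^category", rownames(sm$coefficients), value = TRUE)
    data.frame(covariates = label, term = sub("^category", "", terms),
               logHR = sm$coefficients[terms, "coef"],
               lo = log(sm$conf.int[terms, "lower .95"]),
               hi = log(sm$conf.int[terms, "upper .95"]),
               p = sm$coefficients[terms, "Pr(>|z|)"],
               converged = TRUE, row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
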