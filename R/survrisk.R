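#' Read clinical survival data from TSV
#'
#' Expects columns `patient`, `time`, `event`, then one column per
#' expression covariate.
#'
#' @param path File path.
#' @return A `data.frame` validated for positive times and 0/1 events.
#' @export
read_survival <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_survival(df)
  df
}

validate_survival <- function(df) {
  stopifnot(is.data.frame(df),
            all(c("patient", "time", "event") %in% names(df)))
  if (any(df$time <= 0)) {
    stop_input("non-positive follow-up time at row(s): ",
               paste(utils::head(which(df$time <= 0), 5), collapse = ", "))
  }
  if (!all(df$event %in% c(0, 1))) stop_input("event must be 0 or 1")
  if (anyNA(df)) stop_input("missing values in survival data")
  invisible(df)
}

surv_covariates <- function(data, covariates = NULL) {
  cand <- setdiff(names(data), c("patient", "time", "event"))
  if (is.null(covariates)) covariates <- cand
  missing <- setdiff(covariates, cand)
  if (length(missing) > 0) {
    stop_input("covariate(s) absent from the data: ",
               paste(missing, collapse = ", "))
  }
  covariates
}

#' Fit a multivariate Cox proportional-hazards model
#'
#' Maximizes the Efron-corrected partial likelihood by Newton-Raphson (via
#' `survival::coxph`). Non-convergence is flagged on the returned object
#' rather than silently ignored.
#'
#' @param data Survival `data.frame` with `patient`, `time`, `event` and
#'   expression covariate columns.
#' @param covariates Character vector of covariate column names; default
#'   all non-clinical columns.
#' @return An object of class `cox_model`: list with `covariates`, `beta`,
#'   `se`, `converged`, `iterations`, and the underlying `fit`.
#' @export
cox_fit <- function(data, covariates = NULL) {
  validate_survival(data)
  covariates <- surv_covariates(data, covariates)
  if (sum(data$event) < 1) stop_input("no events in the data")
  const <- vapply(covariates,
                  function(v) stats::var(data[[v]]) == 0, logical(1))
  if (any(const)) {
    stop_input("constant covariate(s) carry no information: ",
               paste(covariates[const], collapse = ", "))
  }
  X <- as.matrix(data[, covariates, drop = FALSE])
  qrX <- qr(scale(X, scale = FALSE))
  if (qrX$rank < ncol(X)) stop_input("covariates are collinear")
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(sprintf("`%s`", covariates),
                                     collapse = " + ")))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(f, data = data, ties = "efron"),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    })
  beta <- stats::setNames(unname(stats::coef(fit)), covariates)
  if (any(!is.finite(beta))) converged <- FALSE
  structure(list(covariates = covariates, beta = beta,
                 se = stats::setNames(sqrt(diag(stats::vcov(fit))), covariates),
                 converged = converged, iterations = fit$iter, fit = fit),
            class = "cox_model")
}

#' @export
print.cox_model <- function(x, ...) {
  cat(sprintf("cox_model: %d covariate(s), %s in %d iteration(s)\n",
              length(x$covariates),
              if (x$converged) "converged" else "NOT converged",
              x$iterations))
  print(data.frame(beta = x$beta, se = x$se, hr = exp(x$beta)))
  invisible(x)
}

#' Per-patient prognostic index
#'
#' The linear predictor `PI_i = sum_g beta_g x_ig` of a fitted Cox model,
#' uncentered.
#'
#' @param model A [cox_fit()] result, or a named numeric vector of
#'   coefficients.
#' @param data Survival `data.frame` containing the model covariates.
#' @return Numeric vector of prognostic indices, one per patient.
#' @export
prognostic_index <- function(model, data) {
  beta <- if (inherits(model, "cox_model")) model$beta else model
  stopifnot(is.numeric(beta), !is.null(names(beta)))
  missing <- setdiff(names(beta), names(data))
  if (length(missing) > 0) {
    stop_input("covariate(s) absent from the data: ",
               paste(missing, collapse = ", "))
  }
  X <- as.matrix(data[, names(beta), drop = FALSE])
  drop(X %*% beta)
}

#' Kaplan-Meier survival curve
#'
#' Product-limit estimate of the survival function.
#'
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @return A `data.frame` of the step function: `time`, `n_risk`,
#'   `n_event`, `surv`. `S(0) = 1` is implicit; the curve is
#'   right-continuous and nonincreasing.
#' @export
km_curve <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  data.frame(time = sf$time, n_risk = sf$n.risk, n_event = sf$n.event,
             surv = sf$surv)
}

#' Two-group log-rank test
#'
#' Standard (observed - expected)^2 / variance log-rank statistic summed
#' over distinct event times, referred to chi-square with 1 df.
#'
#' @param time,event Survival outcome for all subjects.
#' @param group Two-level group label per subject.
#' @return List with `chi2`, `p`, and the per-group observed/expected
#'   event counts.
#' @export
log_rank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) != 2) stop_input("need exactly two non-empty groups")
  if (sum(event) < 1) stop_input("no events in the data")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  list(chi2 = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
       observed = unname(sd$obs), expected = unname(sd$exp))
}

#' Prognostic-index risk partition and risk-group testing
#'
#' Splits the cohort into low- and high-risk groups at the median
#' prognostic index (high PI = high risk), then quantifies the contrast:
#' hazard ratio from a univariate Cox fit on the group indicator (with the
#' multivariate-model-implied ratio `exp(mean PI_high - mean PI_low)`
#' reported alongside), the log-rank test between the groups, and a Welch
#' t-test per covariate comparing expression between risk groups.
#'
#' @param model A [cox_fit()] result.
#' @param data Survival `data.frame` (>= 4 patients).
#' @param alpha Significance level for the reported flags; default 0.05.
#' @param split `"median"` (default) or a numeric quantile in (0, 1).
#' @return An object of class `risk_partition`: list with `partition`
#'   (`data.frame`: patient, pi, group), `hazard_ratio`, `hr_model`,
#'   `hr_ci`, `log_rank_chi2`, `log_rank_p`, `significant`,
#'   `covariate_tests` (`data.frame` with Welch t and p per covariate),
#'   and `alpha`.
#' @export
partition_and_test <- function(model, data, alpha = 0.05, split = "median") {
  validate_survival(data)
  if (nrow(data) < 4) stop_input("need at least 4 patients")
  pi <- prognostic_index(model, data)
  q <- if (identical(split, "median")) 0.5 else {
    stopifnot(is.numeric(split), split > 0, split < 1)
    split
  }
  cut <- stats::quantile(pi, q, names = FALSE)
  grp <- ifelse(pi > cut, "high", "low")
  if (length(unique(grp)) < 2) {
    stop_input("prognostic index cannot be split (all values on one side)")
  }
  lr <- log_rank(data$time, data$event, grp)
  ind <- as.integer(grp == "high")
  gfit <- survival::coxph(survival::Surv(data$time, data$event) ~ ind,
                          ties = "efron")
  hr <- unname(exp(stats::coef(gfit)))
  ci <- unname(exp(stats::confint(gfit)))
  hr_model <- exp(mean(pi[grp == "high"]) - mean(pi[grp == "low"]))
  tests <- do.call(rbind, lapply(model$covariates, function(v) {
    tt <- tryCatch(
      stats::t.test(data[[v]][grp == "high"], data[[v]][grp == "low"]),
      error = function(e) NULL)   # e.g. a covariate constant within groups
    data.frame(covariate = v,
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               significant = if (is.null(tt)) NA else tt$p.value < alpha,
               stringsAsFactors = FALSE)
  }))
  structure(list(partition = data.frame(patient = data$patient, pi = pi,
                                        group = grp,
                                        stringsAsFactors = FALSE),
                 hazard_ratio = hr, hr_model = hr_model, hr_ci = ci,
                 log_rank_chi2 = lr$chi2, log_rank_p = lr$p,
                 significant = lr$p < alpha,
                 covariate_tests = tests, alpha = alpha),
            class = "risk_partition")
}

#' @export
print.risk_partition <- function(x, ...) {
  tab <- table(x$partition$group)
  cat(sprintf("risk_partition: %d low / %d high risk\n",
              tab[["low"]], tab[["high"]]))
  cat(sprintf("  group hazard ratio %.3f (95%% CI %.3f-%.3f); model-implied %.3f\n",
              x$hazard_ratio, x$hr_ci[1], x$hr_ci[2], x$hr_model))
  cat(sprintf("  log-rank chi2 %.3f, p = %.3g (%ssignificant at %.2g)\n",
              x$log_rank_chi2, x$log_rank_p,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}
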