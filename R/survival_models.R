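#' Fit a Cox proportional-hazards model
#'
#' Thin, validated interface over [survival::coxph()] with Efron tie
#' handling (Breslow optional). Rows with missing covariate values are
#' dropped with a logged count. Reports Wald statistics, the log partial
#' likelihood and `AIC = -2 logPL + 2 k`. Non-convergence and monotone
#' likelihoods are reported via `converged = FALSE` rather than an error.
#'
#' @param data data.frame with columns `time` (>= 0), `event` (0/1) and
#'   the covariates.
#' @param covariates character vector of covariate column names.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_fit`: list with `coefficients` (data.frame
#'   `term`, `coef`, `hr`, `ci_low`, `ci_high`, `se`, `z`, `p`),
#'   `log_partial_likelihood`, `aic`, `n_used`, `n_events`, `n_dropped`,
#'   `score_test`, `converged`.
#' @export
fit_cox <- function(data, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c("time", "event") %in% names(data)))
  missing_cov <- setdiff(covariates, names(data))
  if (length(missing_cov)) {
    stop("covariate(s) not in data: ", paste(missing_cov, collapse = ", "))
  }
  if (any(data$time < 0, na.rm = TRUE)) stop("negative survival time")
  if (!all(data$event %in% c(0, 1))) stop("event must be 0/1")
  d <- data[, c("time", "event", covariates), drop = FALSE]
  complete <- stats::complete.cases(d)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    message("fit_cox: dropped ", n_dropped, " row(s) with missing values")
  }
  d <- d[complete, , drop = FALSE]
  if (sum(d$event) < 1) stop("no events in data")
  x <- as.matrix(d[, covariates, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant covariate(s): ",
         paste(covariates[sds == 0], collapse = ", "))
  }
  if (qr(cbind(1, x))$rank < ncol(x) + 1L) {
    stop("collinear design among covariates: ",
         paste(covariates, collapse = ", "))
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(time, event) ~",
    paste(sprintf("`%s`", covariates), collapse = " + ")
  ))
  converged <- TRUE
  fit <- withCallingHandlers(
    survival::coxph(fml, data = d, ties = ties,
                    control = survival::coxph.control(eps = 1e-10,
                                                      iter.max = 100)),
    warning = function(w) {
      if (grepl("converge|infinite|beta may be infinite", conditionMessage(w))) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)
  z975 <- 1.959964
  beta <- unname(stats::coef(fit))
  se <- unname(sqrt(diag(stats::vcov(fit))))
  coefs <- data.frame(
    term = covariates,
    coef = beta,
    hr = exp(beta),
    ci_low = exp(beta - z975 * se),
    ci_high = exp(beta + z975 * se),
    se = se,
    z = beta / se,
    p = 2 * stats::pnorm(-abs(beta / se)),
    stringsAsFactors = FALSE
  )
  logpl <- fit$loglik[2]
  out <- list(
    coefficients = coefs,
    log_partial_likelihood = logpl,
    aic = -2 * logpl + 2 * length(covariates),
    n_used = fit$n,
    n_events = fit$nevent,
    n_dropped = n_dropped,
    score_test = unname(fit$score),
    converged = converged,
    ties = ties
  )
  class(out) <- "cox_fit"
  out
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat("Cox PH fit (", x$ties, " ties): n = ", x$n_used, ", events = ",
      x$n_events, if (!x$converged) "  [NOT CONVERGED]", "\n", sep = "")
  print(format(x$coefficients, digits = digits), row.names = FALSE)
  cat("logPL =", format(x$log_partial_likelihood, digits = digits),
      " AIC =", format(x$aic, digits = digits), "\n")
  invisible(x)
}

#' Univariate Cox regression over a feature matrix
#'
#' Fits each column of `feature_matrix` as a single-covariate Cox model
#' against the survival columns in `data`. Failing features are skipped
#' with a warning, never abort the sweep. Results are sorted by Wald p.
#'
#' @param data data.frame with `time` and `event`, row order matching
#'   `feature_matrix`.
#' @param feature_matrix samples x features numeric matrix.
#' @param ties tie handling passed to [fit_cox()].
#' @return data.frame with one row per successfully fitted feature:
#'   `feature`, `coef`, `hr`, `ci_low`, `ci_high`, `p`; attribute `fits`
#'   holds the full `cox_fit` objects (named by feature).
#' @export
univariate_cox <- function(data, feature_matrix, ties = "efron") {
  stopifnot(nrow(data) == nrow(feature_matrix))
  fits <- list()
  failed <- character()
  for (f in colnames(feature_matrix)) {
    d <- data.frame(time = data$time, event = data$event,
                    x = feature_matrix[, f])
    names(d)[3] <- f
    fit <- tryCatch(fit_cox(d, f, ties = ties), error = function(e) NULL)
    if (is.null(fit)) failed <- c(failed, f) else fits[[f]] <- fit
  }
  if (length(failed)) {
    warning("univariate_cox: failed for feature(s): ",
            paste(failed, collapse = ", "))
  }
  res <- do.call(rbind, lapply(names(fits), function(f) {
    cf <- fits[[f]]$coefficients
    data.frame(feature = f, coef = cf$coef, hr = cf$hr,
               ci_low = cf$ci_low, ci_high = cf$ci_high, p = cf$p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res)) {
    res <- data.frame(feature = character(), coef = numeric(),
                      hr = numeric(), ci_low = numeric(),
                      ci_high = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  }
  res <- res[order(res$p), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "fits") <- fits
  res
}

#' Kaplan-Meier product-limit curve
#'
#' @param data data.frame with `time` and `event`.
#' @return object of class `km_curve`: list with `time` (ordered distinct
#'   observed times), `surv` (S(t), right-continuous), `n_risk`,
#'   `n_event`, `median` (the smallest time with S(t) <= 0.5, NA when S
#'   never reaches 0.5), `n`.
#' @export
km_curve <- function(data) {
  stopifnot(nrow(data) >= 1)
  if (any(data$time < 0)) stop("negative survival time")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  # median := smallest t with S(t) <= 0.5 (NA when S never reaches 0.5)
  med <- if (any(fit$surv <= 0.5)) min(fit$time[fit$surv <= 0.5]) else
    NA_real_
  out <- list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
              n_event = fit$n.event, median = med, n = fit$n)
  class(out) <- "km_curve"
  out
}

#' Evaluate a Kaplan-Meier curve at a time point
#'
#' Right-continuous step-function evaluation; S(t) = 1 before the first
#' observed time.
#'
#' @param curve a `km_curve`.
#' @param t non-negative time (days); vectorized.
#' @return survival probability/ies at `t`.
#' @export
km_survival_at <- function(curve, t) {
  if (any(t < 0)) stop("negative time")
  vapply(t, function(ti) {
    idx <- which(curve$time <= ti)
    if (!length(idx)) 1 else curve$surv[max(idx)]
  }, numeric(1))
}

#' Log-rank test for survival differences between groups
#'
#' Mantel-Haenszel log-rank chi-square with k - 1 degrees of freedom.
#'
#' @param data data.frame with `time` and `event`.
#' @param group_labels vector of group labels, one per row of `data`; at
#'   least two non-empty groups.
#' @return list with `chi_square`, `df`, `p`.
#' @export
logrank_test <- function(data, group_labels) {
  stopifnot(nrow(data) == length(group_labels))
  groups <- unique(group_labels[!is.na(group_labels)])
  if (length(groups) < 2) stop("need at least two non-empty groups")
  d <- data.frame(time = data$time, event = data$event,
                  group = group_labels)
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  df <- length(sd_$n) - 1L
  list(chi_square = unname(sd_$chisq), df = df,
       p = stats::pchisq(unname(sd_$chisq), df, lower.tail = FALSE))
}
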