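#' Split a cohort into training and testing halves
#'
#' Seeded uniform permutation; the first `ceiling(n/2)` permuted samples
#' form the training set. The two halves are disjoint and exhaustive.
#'
#' @param samples character vector of sample ids (n >= 2).
#' @param seed integer seed.
#' @return list with `train` and `test` (ids in original cohort order).
#' @export
split_train_test <- function(samples, seed) {
  n <- length(samples)
  stopifnot(n >= 2)
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  k <- ceiling(n / 2)
  list(train = samples[sort(perm[seq_len(k)])],
       test = samples[sort(perm[-seq_len(k)])])
}

#' Univariate Cox screen of candidate lncRNAs
#'
#' Keeps the candidates whose single-covariate Cox Wald p is below `alpha`.
#'
#' @param candidates character vector of lncRNA ids (columns of `expr`).
#' @param surv data.frame with `time` and `event`, rows aligned with
#'   `expr`.
#' @param expr samples x lncRNAs expression matrix.
#' @param alpha screening significance level.
#' @return character vector of surviving ids (sorted by p); attribute
#'   `table` holds the full univariate results.
#' @export
univariate_screen <- function(candidates, surv, expr, alpha = 0.05) {
  stopifnot(length(candidates) > 0)
  missing <- setdiff(candidates, colnames(expr))
  if (length(missing)) {
    stop("candidate(s) missing from expression: ",
         paste(missing, collapse = ", "))
  }
  tab <- univariate_cox(surv, expr[, candidates, drop = FALSE])
  keep <- tab$feature[tab$p < alpha]
  attr(keep, "table") <- tab
  keep
}

cox_aic <- function(surv, expr, features, ties = "efron") {
  if (!length(features)) {
    fit <- survival::coxph(survival::Surv(time, event) ~ 1, data = surv)
    return(-2 * fit$loglik[1])
  }
  d <- data.frame(time = surv$time, event = surv$event,
                  expr[, features, drop = FALSE], check.names = FALSE)
  fit_cox(d, features, ties = ties)$aic
}

#' Bidirectional stepwise Cox model selection by AIC
#'
#' Starts from the full model of screened features (directions `"both"`
#' and `"backward"`) or the empty model (`"forward"`). At each step every
#' allowed single-feature removal and addition is scored by the AIC of the
#' resulting multivariate Cox fit; the best move is applied only when it
#' strictly lowers the current AIC. Ties are broken by preferring removal
#' over addition, then by lexicographic feature id. Moves whose fit fails
#' are unavailable (logged via message).
#'
#' @param screened character vector of screened feature ids.
#' @param surv data.frame with `time` and `event`, rows aligned with
#'   `expr`.
#' @param expr expression matrix containing the screened features.
#' @param direction `"both"`, `"backward"` or `"forward"`.
#' @return character vector of selected ids (sorted); attribute `path`
#'   records the visited models and AICs.
#' @export
stepwise_select <- function(screened, surv, expr,
                            direction = c("both", "backward", "forward")) {
  direction <- match.arg(direction)
  stopifnot(length(screened) > 0)
  screened <- sort(unique(screened))
  current <- if (direction == "forward") character() else screened
  aic_of <- function(features) {
    tryCatch(cox_aic(surv, expr, features),
             error = function(e) {
               message("stepwise_select: move unavailable (",
                       conditionMessage(e), ")")
               NA_real_
             })
  }
  cur_aic <- aic_of(current)
  if (is.na(cur_aic)) stop("initial stepwise model failed to fit")
  path <- list(list(features = current, aic = cur_aic))
  repeat {
    moves <- list()
    if (direction %in% c("both", "backward") && length(current) > 1) {
      for (f in current) {
        moves[[length(moves) + 1L]] <-
          list(type = "drop", feature = f, features = setdiff(current, f))
      }
    }
    if (direction %in% c("both", "forward")) {
      for (f in setdiff(screened, current)) {
        moves[[length(moves) + 1L]] <-
          list(type = "add", feature = f, features = sort(c(current, f)))
      }
    }
    if (!length(moves)) break
    aics <- vapply(moves, function(m) aic_of(m$features), numeric(1))
    ok <- !is.na(aics)
    if (!any(ok)) break
    moves <- moves[ok]; aics <- aics[ok]
    type_rank <- vapply(moves, function(m) m$type == "add", logical(1))
    feats <- vapply(moves, function(m) m$feature, character(1))
    best <- order(aics, type_rank, feats)[1]
    if (aics[best] < cur_aic) {
      current <- moves[[best]]$features
      cur_aic <- aics[best]
      path[[length(path) + 1L]] <- list(features = current, aic = cur_aic)
    } else break
  }
  out <- sort(current)
  attr(out, "path") <- path
  out
}

#' Build a lncRNA risk signature
#'
#' Fits the selected features jointly in a multivariate Cox model on the
#' training cohort; the signature's weights are the multivariate
#' coefficients and its cutoff is the median training risk score
#' (`score = sum(coef_j * expression_j)`).
#'
#' @param selected character vector of feature ids.
#' @param surv training survival data.frame (`time`, `event`), rows
#'   aligned with `expr`.
#' @param expr training expression matrix.
#' @param provenance optional list stored with the signature (cohort id,
#'   alpha, selection path, ...).
#' @return object of class `cerna_signature`: list with `features`,
#'   `coefficients` (named), `cutoff`, `fit` (the `cox_fit`),
#'   `provenance`.
#' @export
build_signature <- function(selected, surv, expr, provenance = list()) {
  stopifnot(length(selected) > 0)
  d <- data.frame(time = surv$time, event = surv$event,
                  expr[, selected, drop = FALSE], check.names = FALSE)
  fit <- fit_cox(d, selected)
  if (!fit$converged) {
    stop("multivariate Cox fit did not converge for features: ",
         paste(selected, collapse = ", "))
  }
  coefs <- stats::setNames(fit$coefficients$coef, fit$coefficients$term)
  scores <- as.vector(expr[, selected, drop = FALSE] %*% coefs)
  sig <- list(features = selected, coefficients = coefs,
              cutoff = stats::median(scores), fit = fit,
              provenance = c(provenance, list(n_train = nrow(expr))))
  class(sig) <- "cerna_signature"
  sig
}

#' @export
print.cerna_signature <- function(x, digits = 3, ...) {
  cat("lncRNA risk signature (", length(x$features), " features )\n",
      sep = "")
  cat("  score =",
      paste(sprintf("(%s * %s)", format(x$coefficients, digits = digits),
                    x$features), collapse = " + "), "\n")
  cat("  cutoff (training median):", format(x$cutoff, digits = digits),
      "\n")
  invisible(x)
}

#' Score samples and assign risk groups
#'
#' `score = sum_j coefficient_j * expression_j`; a sample is high-risk iff
#' its score is strictly greater than the signature's stored cutoff.
#'
#' @param sig a `cerna_signature` (or any list with `features`,
#'   `coefficients`, `cutoff`).
#' @param expr samples x features expression matrix containing all
#'   signature features.
#' @return data.frame with `sample_id`, `score`, `group` ("high"/"low").
#' @export
risk_score <- function(sig, expr) {
  missing <- setdiff(sig$features, colnames(expr))
  if (length(missing)) {
    stop("signature feature(s) missing from expression: ",
         paste(missing, collapse = ", "))
  }
  score <- as.vector(expr[, sig$features, drop = FALSE] %*%
                       sig$coefficients[sig$features])
  data.frame(
    sample_id = if (is.null(rownames(expr))) {
      as.character(seq_len(nrow(expr)))
    } else rownames(expr),
    score = score,
    group = ifelse(score > sig$cutoff, "high", "low"),
    stringsAsFactors = FALSE
  )
}

eval_endpoint <- function(clinical, risk, time_col, event_col) {
  d <- data.frame(time = clinical[[time_col]],
                  event = clinical[[event_col]])
  ok <- stats::complete.cases(d)
  d <- d[ok, , drop = FALSE]
  grp <- risk$group[ok]
  lr <- logrank_test(d, grp)
  km <- lapply(split(d, grp), km_curve)
  list(
    logrank = lr,
    km = km,
    median = vapply(km, function(k) k$median, numeric(1)),
    rate_5y = vapply(km, function(k) km_survival_at(k, 1825), numeric(1))
  )
}

#' Apply a signature to a cohort and evaluate survival separation
#'
#' Scores the cohort with the stored coefficients and cutoff (never
#' re-derived), then compares high- vs low-risk groups by log-rank test
#' and Kaplan-Meier curves for overall survival and, when present,
#' disease-free survival, reporting per-group median survival and 5-year
#' (1825-day) rates.
#'
#' @param sig a `cerna_signature`.
#' @param expr cohort expression matrix.
#' @param clinical cohort clinical table (columns `os_time_days`,
#'   `os_event`, optionally `dfs_time_days`, `dfs_event`), rows aligned
#'   with `expr`.
#' @return list with `risk` (the [risk_score()] table), `group_sizes`,
#'   `os` and (optionally) `dfs` bundles (log-rank result, per-group KM
#'   curves, medians, 5-year rates).
#' @export
apply_and_evaluate <- function(sig, expr, clinical) {
  stopifnot(nrow(expr) == nrow(clinical))
  risk <- risk_score(sig, expr)
  out <- list(
    risk = risk,
    group_sizes = table(factor(risk$group, levels = c("high", "low"))),
    os = eval_endpoint(clinical, risk, "os_time_days", "os_event")
  )
  if (all(c("dfs_time_days", "dfs_event") %in% names(clinical)) &&
      any(stats::complete.cases(clinical[, c("dfs_time_days",
                                             "dfs_event")]))) {
    out$dfs <- eval_endpoint(clinical, risk, "dfs_time_days", "dfs_event")
  }
  out
}

encode_clinical <- function(clinical, risk) {
  enc_bin <- function(values, high_levels, low_levels, what) {
    bad <- which(!values %in% c(high_levels, low_levels) & !is.na(values))
    if (length(bad)) {
      stop("unencodable ", what, " value(s) in row(s): ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
    as.integer(values %in% high_levels)
  }
  data.frame(
    time = clinical$os_time_days,
    event = clinical$os_event,
    risk_high = as.integer(risk$group == "high"),
    age_gt60 = as.integer(clinical$age_years > 60),
    stage_34 = enc_bin(clinical$stage, c("III", "IV"), c("I", "II"),
                       "stage"),
    grade_34 = enc_bin(clinical$grade, c("G3", "G4"), c("G1", "G2"),
                       "grade"),
    response_cr = enc_bin(clinical$response, "CR", "non-CR", "response")
  )
}

#' Univariate and multivariate Cox analysis of risk group and clinical
#' factors
#'
#' Encodes the covariates as binary contrasts (risk high vs low, age > 60
#' vs <= 60, stage III/IV vs I/II, grade G3/G4 vs G1/G2, response CR vs
#' non-CR) and reports each covariate's univariate fit alongside the joint
#' multivariate fit on overall survival.
#'
#' @param clinical clinical table (synthetic-cohort format).
#' @param risk [risk_score()] table aligned with `clinical`.
#' @param covariates subset of the encoded covariates to analyse.
#' @return data.frame with one row per covariate: `variable`,
#'   `comparison`, univariate `hr`/`ci_low`/`ci_high`/`p` and multivariate
#'   `hr_adj`/`ci_low_adj`/`ci_high_adj`/`p_adj`.
#' @export
multivariate_clinical_cox <- function(clinical, risk,
                                      covariates = c("risk_high",
                                                     "age_gt60",
                                                     "stage_34",
                                                     "grade_34",
                                                     "response_cr")) {
  stopifnot(nrow(clinical) == nrow(risk))
  d <- encode_clinical(clinical, risk)
  comparisons <- c(risk_high = "High/Low", age_gt60 = ">60/<=60",
                   stage_34 = "III,IV/I,II", grade_34 = "G3,G4/G1,G2",
                   response_cr = "CR/non-CR")
  uni <- lapply(covariates, function(v) fit_cox(d, v)$coefficients)
  multi <- if (length(covariates) > 1) {
    fit_cox(d, covariates)$coefficients
  } else uni[[1]]
  out <- do.call(rbind, lapply(seq_along(covariates), function(i) {
    u <- uni[[i]]
    m <- multi[multi$term == covariates[i], ]
    data.frame(
      variable = covariates[i],
      comparison = unname(comparisons[covariates[i]]),
      hr = u$hr, ci_low = u$ci_low, ci_high = u$ci_high, p = u$p,
      hr_adj = m$hr, ci_low_adj = m$ci_low, ci_high_adj = m$ci_high,
      p_adj = m$p, stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out
}

#' Serialize / restore a signature as JSON
#'
#' @param sig a `cerna_signature`.
#' @param path JSON file path.
#' @return `write_signature` returns the path invisibly; `read_signature`
#'   a `cerna_signature` (without the fitted model object).
#' @export
write_signature <- function(sig, path) {
  jsonlite::write_json(
    list(features = sig$features,
         coefficients = as.list(sig$coefficients),
         cutoff = sig$cutoff,
         provenance = sig$provenance),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  sig <- list(features = raw$features,
              coefficients = unlist(raw$coefficients),
              cutoff = raw$cutoff,
              provenance = raw$provenance)
  class(sig) <- "cerna_signature"
  sig
}
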