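#' Pearson chi-square test on a 2x2 contingency table
#'
#' @param table 2x2 non-negative integer matrix (rows: risk group;
#'   columns: CR / non-CR).
#' @param yates apply the Yates continuity correction (off by default).
#' @return list with `statistic`, `p`, `df = 1`.
#' @export
chi_square_2x2 <- function(table, yates = FALSE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (sum(table) == 0) stop("empty table")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero row or column margin: expected counts undefined")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = yates))
  list(statistic = unname(ct$statistic), p = ct$p.value, df = 1L)
}

#' Complete-response rates by risk group
#'
#' @param clinical clinical table with a `response` column
#'   (CR / non-CR); samples with missing response are excluded (count
#'   reported).
#' @param risk [risk_score()] table aligned with `clinical`.
#' @param yates passed to [chi_square_2x2()].
#' @return list with `rates` (named per group), `table` (2x2 counts,
#'   rows high/low, cols CR/non-CR), `test` (chi-square result or NULL
#'   when degenerate), `n_missing`.
#' @export
cr_rate_by_group <- function(clinical, risk, yates = FALSE) {
  stopifnot(nrow(clinical) == nrow(risk))
  ok <- !is.na(clinical$response)
  n_missing <- sum(!ok)
  resp <- clinical$response[ok]
  grp <- risk$group[ok]
  for (g in c("high", "low")) {
    if (!sum(grp == g)) stop("no evaluable samples in group: ", g)
  }
  tab <- table(factor(grp, levels = c("high", "low")),
               factor(resp == "CR", levels = c(TRUE, FALSE),
                      labels = c("CR", "non-CR")))
  rates <- tab[, "CR"] / rowSums(tab)
  test <- tryCatch(chi_square_2x2(unclass(tab), yates = yates),
                   error = function(e) {
                     warning("chi-square unavailable: ",
                             conditionMessage(e))
                     NULL
                   })
  list(rates = rates, table = tab, test = test, n_missing = n_missing)
}

#' Correlation between binned risk score and CR proportion
#'
#' Samples are cut into `n_bins` score-quantile bins; the per-bin CR
#' proportion is correlated (Pearson) with the per-bin mean score.
#'
#' @param scores numeric risk scores.
#' @param responses character vector, "CR" / "non-CR", aligned with
#'   `scores`.
#' @param n_bins number of quantile bins (>= 3).
#' @return list with `r`, `p`, and the per-bin table (`mean_score`,
#'   `cr_rate`, `n`).
#' @export
binned_cr_correlation <- function(scores, responses, n_bins = 4) {
  stopifnot(length(scores) == length(responses), n_bins >= 3)
  ok <- !is.na(scores) & !is.na(responses)
  scores <- scores[ok]; responses <- responses[ok]
  breaks <- unique(stats::quantile(scores, probs = seq(0, 1,
                                                       length.out = n_bins + 1)))
  if (length(breaks) < n_bins + 1) {
    stop("empty score bin (tied quantiles); try fewer bins")
  }
  bins <- cut(scores, breaks = breaks, include.lowest = TRUE)
  counts <- table(bins)
  if (length(counts) < n_bins || any(counts == 0)) {
    stop("empty score bin; try fewer bins")
  }
  tab <- data.frame(
    mean_score = tapply(scores, bins, mean),
    cr_rate = tapply(responses == "CR", bins, mean),
    n = as.vector(counts)
  )
  ct <- pearson_test(tab$mean_score, tab$cr_rate)
  list(r = ct$r, p = ct$p, bins = tab)
}

#' Survival separation restricted to complete responders
#'
#' Subsets the cohort to `response == "CR"` and compares high- vs
#' low-risk overall survival by log-rank test and Kaplan-Meier curves.
#'
#' @param clinical clinical table.
#' @param risk [risk_score()] table aligned with `clinical`.
#' @return list with `logrank`, `km` (per group), `median` (per group),
#'   `n` (CR samples used).
#' @export
cr_restricted_survival <- function(clinical, risk) {
  stopifnot(nrow(clinical) == nrow(risk))
  keep <- !is.na(clinical$response) & clinical$response == "CR"
  d <- data.frame(time = clinical$os_time_days[keep],
                  event = clinical$os_event[keep])
  grp <- risk$group[keep]
  for (g in c("high", "low")) {
    if (!sum(grp == g)) stop("no CR samples in group: ", g)
  }
  km <- lapply(split(d, grp), km_curve)
  list(logrank = logrank_test(d, grp), km = km,
       median = vapply(km, function(k) k$median, numeric(1)),
       n = sum(keep))
}

#' Three-way survival comparison: mutant vs high-risk vs low-risk
#' wild-type
#'
#' Groups samples into driver-gene mutants and risk-stratified wild-type
#' samples, then runs the omnibus 3-group log-rank test (2 df) plus the
#' three pairwise tests (uncorrected by default; Benjamini-Hochberg
#' optional).
#'
#' @param clinical clinical table with `mutation_status`
#'   ("mutant"/"wild-type").
#' @param risk [risk_score()] table aligned with `clinical` (used for
#'   wild-type samples).
#' @param bh_adjust apply BH correction to the pairwise p-values.
#' @return list with `groups` (per-sample labels), `omnibus`
#'   (log-rank, df = 2), `pairwise` (data.frame `group1`, `group2`,
#'   `chi_square`, `p`, optionally `q`).
#' @export
three_group_comparison <- function(clinical, risk, bh_adjust = FALSE) {
  stopifnot(nrow(clinical) == nrow(risk))
  lab <- ifelse(clinical$mutation_status == "mutant", "mutant",
                paste0(risk$group, "-risk wild-type"))
  counts <- table(lab)
  expected <- c("mutant", "high-risk wild-type", "low-risk wild-type")
  empty <- setdiff(expected, names(counts))
  if (length(empty)) {
    stop("empty categor(ies): ", paste(empty, collapse = ", "))
  }
  d <- data.frame(time = clinical$os_time_days, event = clinical$os_event)
  omnibus <- logrank_test(d, lab)
  pairs <- utils::combn(sort(expected), 2, simplify = FALSE)
  pw <- do.call(rbind, lapply(pairs, function(pr) {
    keep <- lab %in% pr
    lr <- logrank_test(d[keep, , drop = FALSE], lab[keep])
    data.frame(group1 = pr[1], group2 = pr[2],
               chi_square = lr$chi_square, p = lr$p,
               stringsAsFactors = FALSE)
  }))
  if (bh_adjust) pw$q <- stats::p.adjust(pw$p, method = "BH")
  list(groups = lab, omnibus = omnibus, pairwise = pw)
}

#' Top co-expressed mRNAs for a risk score
#'
#' Ranks mRNAs by the absolute Pearson correlation of their expression
#' with the per-sample risk score (descending; ties broken by id) and
#' returns the top `k`. Constant mRNA columns are skipped with a warning.
#'
#' @param mrna_matrix samples x mRNAs matrix.
#' @param scores per-sample risk scores aligned with the matrix rows.
#' @param k number of mRNAs to return.
#' @return data.frame `mrna_id`, `r`, `abs_r`, `p`, ranked.
#' @export
top_coexpressed <- function(mrna_matrix, scores, k = 100) {
  stopifnot(nrow(mrna_matrix) == length(scores))
  ids <- colnames(mrna_matrix)
  const <- apply(mrna_matrix, 2, stats::sd) == 0
  if (any(const)) {
    warning("skipped constant mRNA column(s): ",
            paste(ids[const], collapse = ", "))
  }
  ids <- ids[!const]
  if (k > length(ids)) stop("k exceeds the number of usable mRNAs")
  res <- do.call(rbind, lapply(ids, function(id) {
    ct <- pearson_test(mrna_matrix[, id], scores)
    data.frame(mrna_id = id, r = ct$r, abs_r = abs(ct$r), p = ct$p,
               stringsAsFactors = FALSE)
  }))
  res <- res[order(-res$abs_r, res$mrna_id), , drop = FALSE]
  rownames(res) <- NULL
  utils::head(res, k)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, the upper-tail hypergeometric probability of
#' observing at least the realised overlap between the query and the set
#' within the universe; Benjamini-Hochberg q-values across the tested
#' sets.
#'
#' @param query character vector of gene ids; ids outside the universe
#'   are dropped with a warning.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param universe character vector defining the background.
#' @return data.frame per set: `set`, `k` (overlap), `K` (set size in
#'   universe), `n` (query size), `N` (universe size), `p`, `q`; sorted
#'   by p.
#' @export
ora <- function(query, sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning("dropped ", length(outside), " query id(s) outside universe")
  }
  query <- unique(intersect(query, universe))
  n <- length(query)
  N <- length(universe)
  res <- do.call(rbind, lapply(names(sets), function(s) {
    set <- intersect(unique(sets[[s]]), universe)
    K <- length(set)
    k <- length(intersect(query, set))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = s, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  }))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  res
}
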