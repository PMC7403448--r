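#!/usr/bin/env Rscript
# Stage 3: lncRNA risk signature.
#
# Splits the cohort 50/50 into training and testing halves, screens the
# network lncRNAs by univariate Cox (p < 0.05), selects an optimal subset
# by bidirectional stepwise AIC, fits the multivariate signature, and
# evaluates high/low-risk separation (median training score as cutoff,
# transferred verbatim to the test half). Writes results/signature/.

suppressPackageStartupMessages(library(cernasig))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 2 && args[1] == "--seed") args[2]
                   else 1)

expr <- read_expression_tsv("results/cohort/expression_lncrnas.tsv")
clinical <- read_clinical("results/cohort/clinical.tsv")
triples <- utils::read.delim("results/network/triples.tsv",
                             stringsAsFactors = FALSE)
candidates <- sort(unique(triples$lncrna_id))
cat("candidate network lncRNAs:", length(candidates), "\n")

sp <- split_train_test(rownames(expr), seed = seed)
tr <- match(sp$train, rownames(expr))
te <- match(sp$test, rownames(expr))
surv_tr <- data.frame(time = clinical$os_time_days[tr],
                      event = clinical$os_event[tr])

screened <- univariate_screen(candidates, surv_tr,
                              expr[tr, , drop = FALSE])
cat("screened (univariate p < 0.05):", paste(screened, collapse = ", "),
    "\n")
stopifnot(length(screened) > 0)
selected <- stepwise_select(as.character(screened), surv_tr,
                            expr[tr, , drop = FALSE])
sig <- build_signature(as.character(selected), surv_tr,
                       expr[tr, , drop = FALSE],
                       provenance = list(cohort = "synthetic-default",
                                         seed = seed))
print(sig)

dir.create("results/signature", showWarnings = FALSE, recursive = TRUE)
write_signature(sig, "results/signature/signature.json")

rows <- list()
for (nm in c("train", "test", "combined")) {
  idx <- switch(nm, train = tr, test = te, combined = seq_len(nrow(expr)))
  ev <- apply_and_evaluate(sig, expr[idx, , drop = FALSE],
                           clinical[idx, , drop = FALSE])
  cat(sprintf(
    "%s: n(high)=%d n(low)=%d | OS log-rank p=%.3g | medians %s | 5y %s\n",
    nm, ev$group_sizes["high"], ev$group_sizes["low"], ev$os$logrank$p,
    paste(names(ev$os$median), round(ev$os$median), collapse = " "),
    paste(names(ev$os$rate_5y), round(ev$os$rate_5y, 2), collapse = " ")))
  rows[[nm]] <- data.frame(
    cohort = nm, n_high = ev$group_sizes["high"],
    n_low = ev$group_sizes["low"], os_logrank_p = ev$os$logrank$p,
    os_median_high = ev$os$median["high"],
    os_median_low = ev$os$median["low"],
    os_5y_high = ev$os$rate_5y["high"], os_5y_low = ev$os$rate_5y["low"],
    dfs_logrank_p = if (is.null(ev$dfs)) NA else ev$dfs$logrank$p)
  if (nm == "combined") {
    utils::write.table(ev$risk, "results/signature/risk_assignments.tsv",
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cox_tab <- multivariate_clinical_cox(clinical, ev$risk)
    utils::write.table(cox_tab, "results/signature/clinical_cox.tsv",
                       sep = "\t", quote = FALSE, row.names = FALSE)
    adj <- cox_tab[cox_tab$variable == "risk_high", ]
    cat(sprintf(
      "risk group adjusted for age/stage/grade/response: HR %.2f (%.2f-%.2f), p=%.3g\n",
      adj$hr_adj, adj$ci_low_adj, adj$ci_high_adj, adj$p_adj))
  }
}
utils::write.table(do.call(rbind, rows), "results/signature/evaluation.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/signature/\n")
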