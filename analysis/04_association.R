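#!/usr/bin/env Rscript
# Stage 4: chemo-response and co-expression analyses.
#
# Using the combined-cohort risk assignments from stage 3: CR rates per
# risk group with a chi-square test, the binned risk-vs-CR correlation,
# survival separation restricted to complete responders, the three-way
# mutant / high-risk / low-risk comparison, and the top risk-score-
# correlated mRNAs with a hypergeometric enrichment example. Writes
# results/association/.

suppressPackageStartupMessages(library(cernasig))

clinical <- read_clinical("results/cohort/clinical.tsv")
risk <- utils::read.delim("results/signature/risk_assignments.tsv",
                          stringsAsFactors = FALSE)
mrnas <- read_expression_tsv("results/cohort/expression_mrnas.tsv")
dir.create("results/association", showWarnings = FALSE, recursive = TRUE)

cr <- cr_rate_by_group(clinical, risk)
cat(sprintf("CR rate low-risk %.0f%% vs high-risk %.0f%% (chi-square p=%.3g)\n",
            100 * cr$rates["low"], 100 * cr$rates["high"], cr$test$p))

bc <- binned_cr_correlation(risk$score, clinical$response)
cat(sprintf("binned CR correlation: r=%.2f p=%.3g (%d bins)\n",
            bc$r, bc$p, nrow(bc$bins)))

crs <- cr_restricted_survival(clinical, risk)
cat(sprintf(
  "among complete responders: log-rank p=%.3g, medians high=%.0f low=%.0f\n",
  crs$logrank$p, crs$median["high"], crs$median["low"]))

tg <- three_group_comparison(clinical, risk)
cat(sprintf("mutant vs risk-stratified wild-type: omnibus p=%.3g\n",
            tg$omnibus$p))
utils::write.table(tg$pairwise, "results/association/three_group.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

top <- top_coexpressed(mrnas, risk$score, k = 20)
cat("top co-expressed mRNAs:", paste(utils::head(top$mrna_id, 5),
                                     collapse = ", "), "...\n")
utils::write.table(top, "results/association/top_coexpressed.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)

# enrichment example: are the lncRNA-linked mRNAs over-represented among
# the top correlates? (the generator links mrna001-mrna005)
sets <- list(lncRNA_linked = sprintf("mrna%03d", 1:5),
             decoy = sprintf("mrna%03d", 50:69))
enr <- ora(top$mrna_id, sets, universe = colnames(mrnas))
print(enr)
utils::write.table(enr, "results/association/enrichment.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote results/association/\n")
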