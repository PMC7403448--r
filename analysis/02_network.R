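#!/usr/bin/env Rscript
# Stage 2: gene-directed ceRNA network.
#
# Reads the cohort written by 01_simulate.R, applies the three screening
# gates (positive gene-lncRNA correlation at p < 0.05; at least one shared
# regulating miRNA; negative miRNA-gene and miRNA-lncRNA correlation at
# p < 0.05) and assembles the surviving triples into a network. Writes
# results/network/.

suppressPackageStartupMessages(library(cernasig))

expr <- list(
  genes = read_expression_tsv("results/cohort/expression_genes.tsv"),
  mirnas = read_expression_tsv("results/cohort/expression_mirnas.tsv"),
  lncrnas = read_expression_tsv("results/cohort/expression_lncrnas.tsv")
)
target_map <- read_target_map("results/cohort/target_map.tsv")

triples <- identify_triples(expr, target_map, colnames(expr$genes))
net <- build_network(triples)
print(net)
for (g in names(net$summary$triples_per_gene)) {
  cat("  ", g, ":", net$summary$triples_per_gene[[g]], "triples\n")
}

write_network(net, "results/network")
cat("wrote results/network/\n")
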