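#' Pearson correlation with two-sided t-test
#'
#' Sample Pearson coefficient with the usual t-transform p-value,
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3, finite, non-constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: constant input vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Screen lncRNAs positively co-expressed with a driver gene
#'
#' Keeps lncRNAs whose Pearson correlation with the gene is positive with
#' p below `alpha`. Constant lncRNA columns have undefined correlation and
#' are skipped with a warning.
#'
#' @param gene_expr numeric vector, the driver gene's expression.
#' @param lncrna_matrix samples x lncRNAs matrix, sample-aligned with
#'   `gene_expr`.
#' @param alpha significance level for the positive-correlation gate.
#' @return data.frame with columns `lncrna_id`, `r`, `p`, `n`, one row per
#'   surviving lncRNA (possibly zero rows).
#' @export
screen_positive_pairs <- function(gene_expr, lncrna_matrix, alpha = 0.05) {
  if (length(gene_expr) != nrow(lncrna_matrix)) {
    stop("gene expression and lncRNA matrix have no aligned samples")
  }
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  keep <- list()
  skipped <- character()
  for (id in colnames(lncrna_matrix)) {
    v <- lncrna_matrix[, id]
    if (stats::sd(v) == 0) {
      skipped <- c(skipped, id)
      next
    }
    res <- pearson_test(gene_expr, v)
    if (res$r > 0 && res$p < alpha) {
      keep[[id]] <- data.frame(lncrna_id = id, r = res$r, p = res$p,
                               n = res$n, stringsAsFactors = FALSE)
    }
  }
  if (length(skipped)) {
    warning("skipped constant lncRNA column(s): ",
            paste(skipped, collapse = ", "))
  }
  out <- if (length(keep)) do.call(rbind, keep) else {
    data.frame(lncrna_id = character(), r = numeric(), p = numeric(),
               n = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' miRNAs regulating both a gene and a lncRNA
#'
#' @param target_map a `target_map` data.frame.
#' @param gene_id,lncrna_id target ids; an absent target yields the empty
#'   set.
#' @return character vector of shared miRNA ids (sorted).
#' @export
shared_mirnas <- function(target_map, gene_id, lncrna_id) {
  reg_g <- target_map$mirna_id[target_map$target_id == gene_id]
  reg_l <- target_map$mirna_id[target_map$target_id == lncrna_id]
  sort(intersect(reg_g, reg_l))
}

#' Identify gene-directed ceRNA triples
#'
#' For each driver gene: (1) keep lncRNAs positively correlated with the
#' gene at `alpha`; (2) keep gene-lncRNA pairs sharing at least
#' `min_shared` regulating miRNAs in the validated-target map; (3) for each
#' shared miRNA, emit the triple when the miRNA is negatively correlated
#' with both the gene and the lncRNA (with p < `alpha` on both when
#' `require_negative_p` is set). Output rows are sorted
#' (gene, miRNA, lncRNA) lexicographically.
#'
#' @param expr list with sample-aligned matrices `genes`, `mirnas`,
#'   `lncrnas` (samples x features).
#' @param target_map a `target_map`.
#' @param gene_ids driver genes to direct the network at; must be columns
#'   of `expr$genes`.
#' @param alpha significance level for both correlation gates.
#' @param min_shared minimum number of shared regulating miRNAs for a
#'   candidate gene-lncRNA pair.
#' @param require_negative_p if `TRUE` the two negative correlations must
#'   also reach p < `alpha`; if `FALSE` the sign alone is gated.
#' @return data.frame of triples with the correlation evidence: columns
#'   `gene_id`, `mirna_id`, `lncrna_id`, `r_gl`, `p_gl`, `r_mg`, `p_mg`,
#'   `r_ml`, `p_ml`.
#' @export
identify_triples <- function(expr, target_map, gene_ids,
                             alpha = 0.05, min_shared = 1L,
                             require_negative_p = TRUE) {
  missing <- setdiff(gene_ids, colnames(expr$genes))
  if (length(missing)) {
    stop("gene(s) missing from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  stopifnot(nrow(expr$genes) == nrow(expr$mirnas),
            nrow(expr$genes) == nrow(expr$lncrnas))
  rows <- list()
  for (g in gene_ids) {
    gv <- expr$genes[, g]
    pos <- screen_positive_pairs(gv, expr$lncrnas, alpha = alpha)
    for (i in seq_len(nrow(pos))) {
      l <- pos$lncrna_id[i]
      shared <- shared_mirnas(target_map, g, l)
      if (length(shared) < min_shared) next
      for (m in shared) {
        if (!m %in% colnames(expr$mirnas)) next
        mv <- expr$mirnas[, m]
        if (stats::sd(mv) == 0) next
        mg <- pearson_test(mv, gv)
        ml <- pearson_test(mv, expr$lncrnas[, l])
        ok <- mg$r < 0 && ml$r < 0
        if (ok && require_negative_p) ok <- mg$p < alpha && ml$p < alpha
        if (ok) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = g, mirna_id = m, lncrna_id = l,
            r_gl = pos$r[i], p_gl = pos$p[i],
            r_mg = mg$r, p_mg = mg$p, r_ml = ml$r, p_ml = ml$p,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(gene_id = character(), mirna_id = character(),
               lncrna_id = character(), r_gl = numeric(), p_gl = numeric(),
               r_mg = numeric(), p_mg = numeric(), r_ml = numeric(),
               p_ml = numeric(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$gene_id, out$mirna_id, out$lncrna_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble ceRNA triples into a network
#'
#' Nodes are the distinct genes, miRNAs and lncRNAs appearing in the
#' triples; edges are the unique gene-miRNA and miRNA-lncRNA pairs the
#' triples induce.
#'
#' @param triples data.frame from [identify_triples()].
#' @return object of class `cerna_network`: list with `nodes` (data.frame
#'   `id`, `class`), `edges` (data.frame `source`, `target`,
#'   `source_class`, `target_class`), `triples`, and `summary` (node/edge
#'   counts, per-class counts, triples per gene).
#' @export
build_network <- function(triples) {
  genes <- sort(unique(triples$gene_id))
  mirnas <- sort(unique(triples$mirna_id))
  lncrnas <- sort(unique(triples$lncrna_id))
  nodes <- data.frame(
    id = c(genes, mirnas, lncrnas),
    class = rep(c("gene", "mirna", "lncrna"),
                c(length(genes), length(mirnas), length(lncrnas))),
    stringsAsFactors = FALSE
  )
  gm <- unique(triples[, c("gene_id", "mirna_id")])
  ml <- unique(triples[, c("mirna_id", "lncrna_id")])
  edges <- rbind(
    if (nrow(gm)) data.frame(source = gm$gene_id, target = gm$mirna_id,
                             source_class = "gene", target_class = "mirna",
                             stringsAsFactors = FALSE),
    if (nrow(ml)) data.frame(source = ml$mirna_id, target = ml$lncrna_id,
                             source_class = "mirna",
                             target_class = "lncrna",
                             stringsAsFactors = FALSE)
  )
  if (is.null(edges)) {
    edges <- data.frame(source = character(), target = character(),
                        source_class = character(),
                        target_class = character(), stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  net <- list(
    nodes = nodes, edges = edges, triples = triples,
    summary = list(
      n_nodes = nrow(nodes), n_edges = nrow(edges),
      n_genes = length(genes), n_mirnas = length(mirnas),
      n_lncrnas = length(lncrnas), n_triples = nrow(triples),
      triples_per_gene = if (nrow(triples)) {
        as.list(table(triples$gene_id))
      } else list()
    )
  )
  class(net) <- "cerna_network"
  net
}

#' @export
print.cerna_network <- function(x, ...) {
  s <- x$summary
  cat("ceRNA network:", s$n_nodes, "nodes (", s$n_genes, "genes,",
      s$n_mirnas, "miRNAs,", s$n_lncrnas, "lncRNAs ),",
      s$n_edges, "edges,", s$n_triples, "triples\n")
  invisible(x)
}

#' Write triples and network edge list as TSV
#'
#' @param network a `cerna_network`.
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
write_network <- function(network, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p1 <- file.path(dir, "triples.tsv")
  utils::write.table(network$triples, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  p2 <- file.path(dir, "network_edges.tsv")
  utils::write.table(network$edges, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(p1, p2))
}
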