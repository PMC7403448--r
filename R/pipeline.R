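#' Run the full ceRNA-network / risk-signature analysis
#'
#' Orchestrates every stage from one configuration: cohort input (files or
#' the synthetic generator) -> triple identification -> network assembly ->
#' train/test split -> univariate screen -> stepwise AIC selection ->
#' multivariate signature -> evaluation on training, testing and combined
#' cohorts -> clinical Cox adjustment -> chemo-response associations ->
#' co-expression and optional over-representation analysis. Every random
#' decision derives from `config$seed`.
#'
#' @param config list with components:
#'   * `simulate`: a [sim_config()] (synthetic cohort), or `NULL` and
#'     instead `paths`: list of TSV paths `expr_genes`, `expr_mirnas`,
#'     `expr_lncrnas`, optional `expr_mrnas`, `targets`, `clinical`;
#'   * `gene_ids`: driver genes (default: all columns of the gene matrix);
#'   * `alpha`, `min_shared`, `require_negative_p`: triple gates;
#'   * `screen_alpha`: univariate screening level (default 0.05);
#'   * `stepwise_direction`: passed to [stepwise_select()];
#'   * `n_bins`: for [binned_cr_correlation()];
#'   * `top_k`: co-expressed mRNAs to rank (default 100, capped);
#'   * `gene_sets`: optional named list or GMT path for [ora()];
#'   * `seed`: mandatory integer;
#'   * `out_dir`: optional output directory for the JSON report and stage
#'     TSVs.
#' @return a `run_report` list; `status` is `"ok"` or names the degenerate
#'   early exit (`"no_triples"`, `"no_screened_candidates"`).
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop("config$seed is mandatory")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  alpha <- config$alpha %||% 0.05
  min_shared <- config$min_shared %||% 1L
  require_negative_p <- config$require_negative_p %||% TRUE
  screen_alpha <- config$screen_alpha %||% 0.05
  direction <- config$stepwise_direction %||% "both"
  n_bins <- config$n_bins %||% 4

  cohort <- stage("input", {
    if (!is.null(config$simulate)) {
      cfg <- config$simulate
      cfg$seed <- as.integer(config$seed)
      simulate_cohort(validate_sim_config(cfg))
    } else {
      p <- config$paths
      expr <- list(genes = read_expression_tsv(p$expr_genes),
                   mirnas = read_expression_tsv(p$expr_mirnas),
                   lncrnas = read_expression_tsv(p$expr_lncrnas))
      if (!is.null(p$expr_mrnas)) {
        expr$mrnas <- read_expression_tsv(p$expr_mrnas)
      }
      list(expression = expr, target_map = read_target_map(p$targets),
           clinical = read_clinical(p$clinical))
    }
  })
  expr <- cohort$expression
  clinical <- cohort$clinical
  gene_ids <- config$gene_ids %||% colnames(expr$genes)

  report <- list(report_version = "1.0", seed = as.integer(config$seed),
                 status = "ok",
                 params = list(alpha = alpha, min_shared = min_shared,
                               require_negative_p = require_negative_p,
                               screen_alpha = screen_alpha,
                               stepwise_direction = direction))

  triples <- stage("identify_triples",
                   identify_triples(expr, cohort$target_map, gene_ids,
                                    alpha = alpha, min_shared = min_shared,
                                    require_negative_p = require_negative_p))
  network <- stage("build_network", build_network(triples))
  report$network <- network$summary
  if (nrow(triples) == 0) {
    report$status <- "no_triples"
    report$message <- "no ceRNA triples passed the screening gates"
    return(finish_report(report, network, NULL, NULL, config))
  }

  samples <- rownames(expr$lncrnas)
  split <- stage("split_train_test", split_train_test(samples,
                                                     config$seed))
  tr_idx <- match(split$train, samples)
  te_idx <- match(split$test, samples)
  surv_of <- function(idx) data.frame(time = clinical$os_time_days[idx],
                                      event = clinical$os_event[idx])
  candidates <- sort(unique(triples$lncrna_id))
  screened <- stage("univariate_screen",
                    univariate_screen(candidates, surv_of(tr_idx),
                                      expr$lncrnas[tr_idx, , drop = FALSE],
                                      alpha = screen_alpha))
  report$screened <- as.character(screened)
  if (!length(screened)) {
    report$status <- "no_screened_candidates"
    report$message <- "no network lncRNA passed the univariate screen"
    return(finish_report(report, network, NULL, NULL, config))
  }

  selected <- stage("stepwise_select",
                    stepwise_select(as.character(screened), surv_of(tr_idx),
                                    expr$lncrnas[tr_idx, , drop = FALSE],
                                    direction = direction))
  sig <- stage("build_signature",
               build_signature(as.character(selected), surv_of(tr_idx),
                               expr$lncrnas[tr_idx, , drop = FALSE],
                               provenance = list(alpha = screen_alpha,
                                                 seed = config$seed)))
  report$signature <- list(features = sig$features,
                           coefficients = as.list(sig$coefficients),
                           cutoff = sig$cutoff)

  eval_cohort <- function(idx) {
    apply_and_evaluate(sig, expr$lncrnas[idx, , drop = FALSE],
                       clinical[idx, , drop = FALSE])
  }
  evaluations <- stage("apply_and_evaluate", list(
    train = eval_cohort(tr_idx),
    test = eval_cohort(te_idx),
    combined = eval_cohort(seq_along(samples))
  ))
  report$evaluation <- lapply(evaluations, summarize_evaluation)

  risk_full <- evaluations$combined$risk
  report$clinical_cox <- stage("multivariate_clinical_cox",
                               multivariate_clinical_cox(clinical,
                                                         risk_full))

  report$association <- stage("association", {
    out <- list()
    cr <- tryCatch(cr_rate_by_group(clinical, risk_full),
                   error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(cr)) {
      out$cr_rates <- as.list(cr$rates)
      out$cr_chi_square_p <- if (is.null(cr$test)) NA else cr$test$p
    }
    bc <- tryCatch(binned_cr_correlation(risk_full$score,
                                         clinical$response,
                                         n_bins = n_bins),
                   error = function(e) NULL)
    if (!is.null(bc)) out$binned_cr <- list(r = bc$r, p = bc$p)
    crs <- tryCatch(cr_restricted_survival(clinical, risk_full),
                    error = function(e) NULL)
    if (!is.null(crs)) {
      out$cr_restricted <- list(p = crs$logrank$p,
                                median = as.list(crs$median))
    }
    tg <- tryCatch(three_group_comparison(clinical, risk_full),
                   error = function(e) NULL)
    if (!is.null(tg)) {
      out$three_group <- list(omnibus_p = tg$omnibus$p,
                              pairwise = tg$pairwise)
    }
    out
  })

  coexpr <- NULL
  if (!is.null(expr$mrnas)) {
    k <- min(config$top_k %||% 100L, ncol(expr$mrnas))
    coexpr <- stage("top_coexpressed",
                    top_coexpressed(expr$mrnas, risk_full$score, k = k))
    report$top_coexpressed <- coexpr$mrna_id
    gene_sets <- config$gene_sets
    if (!is.null(gene_sets)) {
      if (is.character(gene_sets)) gene_sets <- read_gmt(gene_sets)
      report$ora <- stage("ora", ora(coexpr$mrna_id, gene_sets,
                                     universe = colnames(expr$mrnas)))
    }
  }
  finish_report(report, network, evaluations, risk_full, config,
                coexpr = coexpr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

summarize_evaluation <- function(ev) {
  lr <- function(e) list(chi_square = e$logrank$chi_square,
                         p = e$logrank$p,
                         median = as.list(e$median),
                         rate_5y = as.list(e$rate_5y))
  out <- list(group_sizes = as.list(ev$group_sizes), os = lr(ev$os))
  if (!is.null(ev$dfs)) out$dfs <- lr(ev$dfs)
  out
}

finish_report <- function(report, network, evaluations, risk_full, config,
                          coexpr = NULL) {
  class(report) <- "run_report"
  if (!is.null(config$out_dir)) {
    dir <- config$out_dir
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_network(network, dir)
    if (!is.null(risk_full)) {
      utils::write.table(risk_full, file.path(dir, "risk_assignments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(report$clinical_cox)) {
      utils::write.table(report$clinical_cox,
                         file.path(dir, "clinical_cox.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(coexpr)) {
      utils::write.table(coexpr, file.path(dir, "top_coexpressed.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    jsonlite::write_json(unclass(report), file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         dataframe = "rows")
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Pipeline run (seed ", x$seed, "): status ", x$status, "\n",
      sep = "")
  cat("  network: ", x$network$n_triples, " triples, ",
      x$network$n_nodes, " nodes, ", x$network$n_edges, " edges\n",
      sep = "")
  if (!is.null(x$signature)) {
    cat("  signature:", paste(x$signature$features, collapse = ", "),
        "| cutoff", format(x$signature$cutoff, digits = 3), "\n")
    cat("  held-out OS log-rank p:",
        format(x$evaluation$test$os$p, digits = 3), "\n")
  }
  invisible(x)
}
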