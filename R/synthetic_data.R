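#' Simulation configuration for a synthetic ceRNA cohort
#'
#' Describes a cohort with planted ceRNA structure and planted prognostic
#' lncRNAs. Planted triples share a latent miRNA repressor: the miRNA is
#' standard normal and both its gene and lncRNA targets load on it with
#' weight `-repression_strength`, which induces positive gene-lncRNA
#' co-expression and negative miRNA-target co-expression with closed-form
#' expected correlations (see the package vignette).
#'
#' @param n_samples number of samples.
#' @param n_mirnas,n_lncrnas,n_genes,n_mrnas feature counts per class.
#'   `n_genes` are the driver genes the network is directed at; `n_mrnas`
#'   are background mRNAs used only by co-expression / enrichment analyses.
#' @param planted_triples list of length-3 character vectors
#'   `c(gene, mirna, lncrna)` naming features by id (ids are
#'   `gene1..`, `mir001..`, `lnc001..`, `mrna001..`).
#' @param repression_strength loading `a` of targets on their planted latent
#'   miRNA; expected gene-lncRNA correlation is `a^2 / (a^2 + noise_sd^2)`.
#' @param noise_sd standard deviation of the independent expression noise.
#' @param target_map_density probability of a non-planted regulator-target
#'   association in the simulated validated-target map.
#' @param prognostic_lncrnas named numeric vector of true log-hazard
#'   coefficients, names are lncRNA ids; may be empty (global null).
#' @param baseline_hazard baseline event rate (events/day).
#' @param censor_window upper bound of the uniform censoring time (days).
#' @param cr_intercept,cr_slope logistic model for complete response:
#'   `P(CR) = plogis(cr_intercept + cr_slope * linear_predictor)` where the
#'   linear predictor is the planted log-hazard `sum(beta_j * x_j)`.
#' @param mutation_prob probability that a sample carries a driver-gene
#'   mutation (mutation status is independent of everything else).
#' @param age_gt60_prob,stage_high_prob,grade_high_prob clinical category
#'   skews: probability of age > 60, stage III/IV, grade G3/G4.
#' @param mrna_linked_lncrnas character vector of lncRNA ids that the first
#'   `length(mrna_linked_lncrnas)` background mRNAs load on (weight
#'   `mrna_loading`), so co-expression analyses have planted structure.
#' @param mrna_loading loading of linked mRNAs on their lncRNA.
#' @param seed integer seed; the single source of randomness. Sub-stage
#'   streams (target map, expression, clinical) are derived from it
#'   deterministically.
#'
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 242L,
                       n_mirnas = 10L,
                       n_lncrnas = 60L,
                       n_genes = 2L,
                       n_mrnas = 0L,
                       planted_triples = list(
                         c("gene1", "mir001", "lnc001"),
                         c("gene1", "mir002", "lnc002"),
                         c("gene2", "mir003", "lnc003"),
                         c("gene2", "mir004", "lnc004")
                       ),
                       repression_strength = 0.8,
                       noise_sd = 1.0,
                       target_map_density = 0.1,
                       prognostic_lncrnas = c(lnc001 = 0.6, lnc002 = -0.5,
                                              lnc003 = 0.45),
                       baseline_hazard = 5e-4,
                       censor_window = 3650,
                       cr_intercept = 0.5,
                       cr_slope = -1.0,
                       mutation_prob = 0.47,
                       age_gt60_prob = 0.5,
                       stage_high_prob = 0.9,
                       grade_high_prob = 0.85,
                       mrna_linked_lncrnas = character(),
                       mrna_loading = 0.7,
                       seed = 1L) {
  cfg <- list(
    n_samples = as.integer(n_samples), n_mirnas = as.integer(n_mirnas),
    n_lncrnas = as.integer(n_lncrnas), n_genes = as.integer(n_genes),
    n_mrnas = as.integer(n_mrnas),
    planted_triples = planted_triples,
    repression_strength = repression_strength, noise_sd = noise_sd,
    target_map_density = target_map_density,
    prognostic_lncrnas = prognostic_lncrnas,
    baseline_hazard = baseline_hazard, censor_window = censor_window,
    cr_intercept = cr_intercept, cr_slope = cr_slope,
    mutation_prob = mutation_prob,
    age_gt60_prob = age_gt60_prob, stage_high_prob = stage_high_prob,
    grade_high_prob = grade_high_prob,
    mrna_linked_lncrnas = as.character(mrna_linked_lncrnas),
    mrna_loading = mrna_loading,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c(n_samples = cfg$n_samples, n_mirnas = cfg$n_mirnas,
              n_lncrnas = cfg$n_lncrnas, n_genes = cfg$n_genes)
  if (any(counts <= 0L)) {
    stop("counts must be positive: ",
         paste(names(counts)[counts <= 0L], collapse = ", "))
  }
  if (cfg$n_mrnas < 0L) stop("n_mrnas must be >= 0")
  if (cfg$repression_strength < 0) stop("repression_strength must be >= 0")
  if (cfg$noise_sd <= 0) stop("noise_sd must be > 0")
  if (cfg$target_map_density < 0 || cfg$target_map_density > 1) {
    stop("target_map_density must lie in [0, 1]")
  }
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be > 0")
  if (cfg$censor_window <= 0) stop("censor_window must be > 0")
  ids <- feature_ids(cfg)
  for (tr in cfg$planted_triples) {
    if (length(tr) != 3L) stop("each planted triple must have 3 ids")
    if (!(tr[1] %in% ids$genes && tr[2] %in% ids$mirnas &&
          tr[3] %in% ids$lncrnas)) {
      stop("planted triple references unknown feature ids: ",
           paste(tr, collapse = ", "))
    }
  }
  bad <- setdiff(names(cfg$prognostic_lncrnas), ids$lncrnas)
  if (length(bad)) {
    stop("prognostic_lncrnas reference unknown lncRNAs: ",
         paste(bad, collapse = ", "))
  }
  bad <- setdiff(cfg$mrna_linked_lncrnas, ids$lncrnas)
  if (length(bad)) {
    stop("mrna_linked_lncrnas reference unknown lncRNAs: ",
         paste(bad, collapse = ", "))
  }
  if (length(cfg$mrna_linked_lncrnas) > cfg$n_mrnas) {
    stop("more linked mRNAs requested than n_mrnas")
  }
  invisible(cfg)
}

# Per-stage RNG streams: consecutive cohort seeds must not share a stream,
# so stages use seed * 10 + offset (folded into the signed-int range).
sub_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 10 + stage) %% 2147483647)
}

feature_ids <- function(cfg) {
  list(
    genes = paste0("gene", seq_len(cfg$n_genes)),
    mirnas = sprintf("mir%03d", seq_len(cfg$n_mirnas)),
    lncrnas = sprintf("lnc%03d", seq_len(cfg$n_lncrnas)),
    mrnas = if (cfg$n_mrnas > 0L) sprintf("mrna%03d", seq_len(cfg$n_mrnas))
            else character(),
    samples = sprintf("s%04d", seq_len(cfg$n_samples))
  )
}

#' Simulate a validated miRNA-target association map
#'
#' Every planted triple `(g, m, l)` contributes the associations `m -> g`
#' and `m -> l`; every other miRNA x gene and miRNA x lncRNA pair receives
#' an association independently with probability `target_map_density`.
#' Random pairs are drawn in a fixed order (genes before lncRNAs, pairs in
#' column-major order of the miRNA x target grid), so the draw stream is
#' replayable from the seed.
#'
#' @param config a [sim_config()].
#' @return a `target_map` data.frame with columns `mirna_id`, `target_id`,
#'   `target_class` (`"gene"` or `"lncrna"`); no duplicated
#'   (mirna_id, target_id) pair.
#' @export
generate_target_map <- function(config) {
  validate_sim_config(config)
  ids <- feature_ids(config)
  set.seed(sub_seed(config$seed, 0L))
  random_block <- function(targets, class) {
    grid <- expand.grid(mirna_id = ids$mirnas, target_id = targets,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    keep <- stats::runif(nrow(grid)) < config$target_map_density
    if (!any(keep)) return(NULL)
    cbind(grid[keep, , drop = FALSE], target_class = class)
  }
  blocks <- list(random_block(ids$genes, "gene"),
                 random_block(ids$lncrnas, "lncrna"))
  planted <- NULL
  if (length(config$planted_triples)) {
    tr <- do.call(rbind, config$planted_triples)
    planted <- rbind(
      data.frame(mirna_id = tr[, 2], target_id = tr[, 1],
                 target_class = "gene", stringsAsFactors = FALSE),
      data.frame(mirna_id = tr[, 2], target_id = tr[, 3],
                 target_class = "lncrna", stringsAsFactors = FALSE)
    )
  }
  map <- do.call(rbind, c(list(planted), blocks))
  if (is.null(map)) {
    map <- data.frame(mirna_id = character(), target_id = character(),
                      target_class = character(), stringsAsFactors = FALSE)
  }
  map <- map[!duplicated(map[, c("mirna_id", "target_id")]), , drop = FALSE]
  map <- map[order(map$mirna_id, map$target_id), , drop = FALSE]
  rownames(map) <- NULL
  as_target_map(map)
}

#' Simulate expression matrices with planted ceRNA structure
#'
#' miRNAs are iid standard normal. A feature targeted by a planted triple
#' equals `-a * m + noise` where `m` is the triple's miRNA expression and
#' `a` the repression strength; features in several triples sum their
#' loadings. All other features are pure noise with sd `noise_sd`.
#' Background mRNAs listed via `mrna_linked_lncrnas` additionally load on
#' their lncRNA.
#'
#' @param config a [sim_config()].
#' @return list of matrices `genes`, `mirnas`, `lncrnas` and (if
#'   `n_mrnas > 0`) `mrnas`; samples x features, shared ordered rownames.
#' @export
generate_expression <- function(config) {
  validate_sim_config(config)
  ids <- feature_ids(config)
  n <- config$n_samples
  a <- config$repression_strength
  set.seed(sub_seed(config$seed, 1L))
  mk <- function(cols, sd = config$noise_sd) {
    m <- matrix(stats::rnorm(n * length(cols), sd = sd), nrow = n,
                dimnames = list(ids$samples, cols))
    m
  }
  mirnas <- mk(ids$mirnas, sd = 1)
  genes <- mk(ids$genes)
  lncrnas <- mk(ids$lncrnas)
  # unique (target, miRNA) loadings from the planted triples
  if (length(config$planted_triples)) {
    tr <- do.call(rbind, config$planted_triples)
    gm <- unique(tr[, c(1, 2), drop = FALSE])
    for (i in seq_len(nrow(gm))) {
      genes[, gm[i, 1]] <- genes[, gm[i, 1]] - a * mirnas[, gm[i, 2]]
    }
    lm_ <- unique(tr[, c(3, 2), drop = FALSE])
    for (i in seq_len(nrow(lm_))) {
      lncrnas[, lm_[i, 1]] <- lncrnas[, lm_[i, 1]] - a * mirnas[, lm_[i, 2]]
    }
  }
  out <- list(genes = genes, mirnas = mirnas, lncrnas = lncrnas)
  if (config$n_mrnas > 0L) {
    mrnas <- mk(ids$mrnas)
    for (i in seq_along(config$mrna_linked_lncrnas)) {
      mrnas[, i] <- mrnas[, i] +
        config$mrna_loading * lncrnas[, config$mrna_linked_lncrnas[i]]
    }
    out$mrnas <- mrnas
  }
  out
}

#' Simulate the clinical table for a synthetic cohort
#'
#' Event times are exponential with per-sample hazard
#' `baseline_hazard * exp(lp)` where `lp = sum(beta_j * x_j)` over the
#' planted prognostic lncRNAs; censoring is uniform on `(0, censor_window]`.
#' Disease-free survival uses a hazard 1.5x the overall-survival hazard with
#' its own censoring draw. Complete response is Bernoulli with logistic
#' probability in `lp`; clinical categories follow the configured skews.
#'
#' @param config a [sim_config()].
#' @param lncrna_expression samples x lncRNAs matrix (from
#'   [generate_expression()]).
#' @return data.frame with columns `sample_id`, `os_time_days`, `os_event`,
#'   `dfs_time_days`, `dfs_event`, `age_years`, `stage`, `grade`,
#'   `response`, `mutation_status`.
#' @export
generate_clinical <- function(config, lncrna_expression) {
  validate_sim_config(config)
  n <- config$n_samples
  beta <- config$prognostic_lncrnas
  if (length(beta)) {
    missing <- setdiff(names(beta), colnames(lncrna_expression))
    if (length(missing)) {
      stop("prognostic lncRNAs absent from expression: ",
           paste(missing, collapse = ", "))
    }
    lp <- as.vector(lncrna_expression[, names(beta), drop = FALSE] %*% beta)
  } else {
    lp <- rep(0, n)
  }
  if (any(!is.finite(lp))) stop("non-finite linear predictor")
  set.seed(sub_seed(config$seed, 2L))
  draw_surv <- function(hazard_scale) {
    ev <- stats::rexp(n, rate = config$baseline_hazard * hazard_scale *
                        exp(lp))
    cs <- stats::runif(n, 0, config$censor_window)
    list(time = pmin(ev, cs), event = as.integer(ev <= cs))
  }
  os <- draw_surv(1)
  dfs <- draw_surv(1.5)
  age <- ifelse(stats::runif(n) < config$age_gt60_prob,
                sample(61:80, n, replace = TRUE),
                sample(40:60, n, replace = TRUE))
  stage <- ifelse(stats::runif(n) < config$stage_high_prob,
                  sample(c("III", "IV"), n, replace = TRUE),
                  sample(c("I", "II"), n, replace = TRUE))
  grade <- ifelse(stats::runif(n) < config$grade_high_prob,
                  sample(c("G3", "G4"), n, replace = TRUE),
                  sample(c("G1", "G2"), n, replace = TRUE))
  p_cr <- stats::plogis(config$cr_intercept + config$cr_slope * lp)
  response <- ifelse(stats::runif(n) < p_cr, "CR", "non-CR")
  mutation <- ifelse(stats::runif(n) < config$mutation_prob,
                     "mutant", "wild-type")
  data.frame(
    sample_id = rownames(lncrna_expression),
    os_time_days = os$time, os_event = os$event,
    dfs_time_days = dfs$time, dfs_event = dfs$event,
    age_years = age, stage = stage, grade = grade,
    response = response, mutation_status = mutation,
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete synthetic cohort
#'
#' Runs [generate_target_map()], [generate_expression()] and
#' [generate_clinical()] from one configuration and bundles the results
#' together with the planted ground truth.
#'
#' @param config a [sim_config()].
#' @return an object of class `synthetic_cohort`: list with `expression`
#'   (matrices), `target_map`, `clinical`, and `truth` (the planted triples
#'   and prognostic coefficients, echoed verbatim from the config).
#' @export
simulate_cohort <- function(config) {
  validate_sim_config(config)
  expr <- generate_expression(config)
  cohort <- list(
    expression = expr,
    target_map = generate_target_map(config),
    clinical = generate_clinical(config, expr$lncrnas),
    truth = list(planted_triples = config$planted_triples,
                 prognostic_lncrnas = config$prognostic_lncrnas),
    config = config
  )
  class(cohort) <- "synthetic_cohort"
  cohort
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$config
  cat("Synthetic ceRNA cohort:", cfg$n_samples, "samples;",
      cfg$n_genes, "driver genes,", cfg$n_mirnas, "miRNAs,",
      cfg$n_lncrnas, "lncRNAs,", cfg$n_mrnas, "mRNAs\n")
  cat("  planted triples:", length(cfg$planted_triples),
      "| prognostic lncRNAs:", length(cfg$prognostic_lncrnas),
      "| target map:", nrow(x$target_map), "associations\n")
  invisible(x)
}

#' Write a synthetic cohort to tab-separated files
#'
#' Expression matrices are written with a leading `sample_id` column and a
#' header row of feature ids; the target map and clinical table use the
#' formats read back by [read_target_map()] and [read_clinical()].
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in names(cohort$expression)) {
    p <- file.path(dir, paste0("expression_", nm, ".tsv"))
    write_expression_tsv(cohort$expression[[nm]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "target_map.tsv")
  utils::write.table(cohort$target_map, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "clinical.tsv")
  utils::write.table(cohort$clinical, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(paths, p))
}
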