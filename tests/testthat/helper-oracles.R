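`%+%` <- function(a, b) paste0(a, b)

# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and cor.test / coxph) wherever they check them.

# Pearson r and two-sided t-transform p from the covariance formula.
oracle_pearson <- function(x, y) {
  n <- length(x)
  xc <- x - mean(x); yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2), n = n)
}

# Column-wise correlations of each column of X against each column of Y,
# via the same hand formula (vectorized); returns list(r, p) matrices.
oracle_corr_mat <- function(X, Y) {
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  r <- crossprod(Xc, Yc) / sqrt(outer(colSums(Xc^2), colSums(Yc^2)))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

# Exhaustive triple enumeration applying the three screening gates to every
# (gene, miRNA, lncRNA) combination, using the hand-formula correlations.
brute_force_triples <- function(expr, target_map, gene_ids, alpha = 0.05,
                                min_shared = 1L, require_negative_p = TRUE) {
  gl <- oracle_corr_mat(expr$genes, expr$lncrnas)
  mg <- oracle_corr_mat(expr$mirnas, expr$genes)
  ml <- oracle_corr_mat(expr$mirnas, expr$lncrnas)
  regulators <- function(target) {
    sort(target_map$mirna_id[target_map$target_id == target])
  }
  rows <- list()
  for (g in sort(gene_ids)) {
    for (l in sort(colnames(expr$lncrnas))) {
      if (!(gl$r[g, l] > 0 && gl$p[g, l] < alpha)) next
      shared <- intersect(regulators(g), regulators(l))
      if (length(shared) < min_shared) next
      for (m in shared) {
        if (!m %in% colnames(expr$mirnas)) next
        ok <- mg$r[m, g] < 0 && ml$r[m, l] < 0
        if (ok && require_negative_p) {
          ok <- mg$p[m, g] < alpha && ml$p[m, l] < alpha
        }
        if (ok) {
          rows[[length(rows) + 1L]] <- data.frame(
            gene_id = g, mirna_id = m, lncrna_id = l,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(gene_id = character(), mirna_id = character(),
               lncrna_id = character(), stringsAsFactors = FALSE)
  }
  out <- out[order(out$gene_id, out$mirna_id, out$lncrna_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# A random screening instance: iid normal expression, Bernoulli target map.
random_instance <- function(seed, n_genes = 3, n_mirnas = 8, n_lncrnas = 20,
                            n = 100, density = 0.15) {
  set.seed(seed)
  ids <- list(g = paste0("g", seq_len(n_genes)),
              m = sprintf("m%02d", seq_len(n_mirnas)),
              l = sprintf("l%02d", seq_len(n_lncrnas)))
  samples <- sprintf("s%03d", seq_len(n))
  mk <- function(cols) matrix(rnorm(n * length(cols)), nrow = n,
                              dimnames = list(samples, cols))
  expr <- list(genes = mk(ids$g), mirnas = mk(ids$m), lncrnas = mk(ids$l))
  grid <- expand.grid(mirna_id = ids$m, target_id = c(ids$g, ids$l),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$target_class <- ifelse(grid$target_id %in% ids$g, "gene", "lncrna")
  map <- grid[runif(nrow(grid)) < density, , drop = FALSE]
  rownames(map) <- NULL
  class(map) <- c("target_map", "data.frame")
  list(expr = expr, map = map, gene_ids = ids$g)
}

# Efron-approximation log partial likelihood for one covariate.
efron_logpl <- function(beta, time, event, x) {
  eta <- beta * x
  w <- exp(eta)
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    sum_d <- sum(w[D])
    sum_r <- sum(w[R])
    ll <- ll + sum(eta[D])
    for (j in seq_len(d) - 1) ll <- ll - log(sum_r - (j / d) * sum_d)
  }
  ll
}

# Product-limit survival table built by direct tabulation.
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  surv <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# Exponential two-group survival data with a given true hazard ratio.
two_group_surv <- function(n_per_group, hr, base_rate = 0.001,
                           censor = Inf) {
  grp <- rep(0:1, each = n_per_group)
  ev <- rexp(2 * n_per_group, rate = base_rate * hr^grp)
  cs <- if (is.finite(censor)) runif(2 * n_per_group, 0, censor) else Inf
  data.frame(time = pmin(ev, cs), event = as.integer(ev <= cs),
             group = grp)
}

# Survival data with continuous covariates and planted log-hazards.
planted_surv <- function(n, beta, x = NULL, base_rate = 5e-4,
                         censor = 3650) {
  p <- length(beta)
  if (is.null(x)) {
    x <- matrix(rnorm(n * p), nrow = n,
                dimnames = list(NULL, names(beta)))
  }
  lp <- as.vector(x %*% beta)
  ev <- rexp(n, rate = base_rate * exp(lp))
  cs <- runif(n, 0, censor)
  list(surv = data.frame(time = pmin(ev, cs),
                         event = as.integer(ev <= cs)),
       x = x)
}

# AIC of a multivariate Cox fit on a feature subset (exhaustive-oracle use).
subset_aic <- function(features, surv, expr) {
  d <- data.frame(time = surv$time, event = surv$event,
                  expr[, features, drop = FALSE], check.names = FALSE)
  fit <- survival::coxph(
    stats::as.formula(paste("survival::Surv(time, event) ~",
                            paste(sprintf("`%s`", features),
                                  collapse = " + "))),
    data = d, ties = "efron")
  -2 * fit$loglik[2] + 2 * length(features)
}

# Default-style cohort for the signature stage: iid lncRNAs, planted
# prognostic effects, no ceRNA structure.
signature_cohort <- function(seed, n = 400, n_lncrnas = 30, beta = NULL) {
  cfg <- sim_config(n_samples = n, n_lncrnas = n_lncrnas, n_mirnas = 3,
                    planted_triples = list(),
                    prognostic_lncrnas = if (is.null(beta)) {
                      stats::setNames(numeric(0), character(0))
                    } else beta,
                    target_map_density = 0, seed = seed)
  simulate_cohort(cfg)
}
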