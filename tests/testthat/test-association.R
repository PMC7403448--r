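test_that("chi-square on 2x2 tables matches the textbook formula", {
  even <- matrix(c(10, 10, 10, 10), 2)
  res <- chi_square_2x2(even)
  expect_equal(res$statistic, 0, tolerance = 1e-12)
  expect_equal(res$p, 1, tolerance = 1e-12)
  # perfect association: E = 10 everywhere, sum((O-E)^2/E) = 40
  res <- chi_square_2x2(matrix(c(20, 0, 0, 20), 2))
  expect_equal(res$statistic, 40, tolerance = 1e-12)
  # random tables vs hand evaluation
  set.seed(14)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 15) + 1, 2)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    want <- sum((tab - E)^2 / E)
    expect_equal(chi_square_2x2(tab)$statistic, want, tolerance = 1e-10)
    expect_equal(chi_square_2x2(tab)$p,
                 pchisq(want, 1, lower.tail = FALSE), tolerance = 1e-10)
  }
  expect_error(chi_square_2x2(matrix(c(0, 0, 5, 5), 2)), "margin")
})

test_that("Yates correction shrinks the statistic", {
  tab <- matrix(c(12, 5, 6, 14), 2)
  expect_lt(chi_square_2x2(tab, yates = TRUE)$statistic,
            chi_square_2x2(tab, yates = FALSE)$statistic)
})

make_risk <- function(groups) {
  data.frame(sample_id = paste0("s", seq_along(groups)),
             score = ifelse(groups == "high", 1, -1), group = groups,
             stringsAsFactors = FALSE)
}

make_clinical <- function(response, time = NULL, event = NULL,
                          mutation = "wild-type") {
  n <- length(response)
  data.frame(sample_id = paste0("s", 1:n),
             os_time_days = if (is.null(time)) rep(100, n) else time,
             os_event = if (is.null(event)) rep(1, n) else event,
             dfs_time_days = rep(50, n), dfs_event = rep(1, n),
             age_years = 55, stage = "III", grade = "G3",
             response = response,
             mutation_status = rep_len(mutation, n),
             stringsAsFactors = FALSE)
}

test_that("CR rates per risk group are plain proportions", {
  grp <- rep(c("low", "high"), each = 10)
  resp <- c(rep("CR", 7), rep("non-CR", 3), rep("CR", 5), rep("non-CR", 5))
  out <- cr_rate_by_group(make_clinical(resp), make_risk(grp))
  expect_equal(unname(out$rates["low"]), 0.70)
  expect_equal(unname(out$rates["high"]), 0.50)
  expect_equal(sum(out$table), 20)
  # all-CR cohort: rates are 1 and the test degenerates cleanly
  expect_warning(
    out <- cr_rate_by_group(make_clinical(rep("CR", 20)), make_risk(grp)),
    "chi-square unavailable")
  expect_equal(unname(out$rates), c(1, 1))
  expect_null(out$test)
  expect_error(cr_rate_by_group(make_clinical(resp),
                                make_risk(rep("low", 20))),
               "group: high")
})

test_that("low-risk cohorts achieve CR more often when the planted slope "
          %+% "is negative", {
  wins <- vapply(1:20, function(s) {
    cfg <- sim_config(n_samples = 400, n_lncrnas = 5, n_mirnas = 2,
                      planted_triples = list(),
                      prognostic_lncrnas = c(lnc001 = 0.8),
                      cr_slope = -1, target_map_density = 0,
                      seed = 8800 + s)
    cohort <- simulate_cohort(cfg)
    sig <- list(features = "lnc001", coefficients = c(lnc001 = 0.8),
                cutoff = 0)
    risk <- risk_score(sig, cohort$expression$lncrnas)
    out <- cr_rate_by_group(cohort$clinical, risk)
    out$rates["low"] > out$rates["high"]
  }, logical(1))
  expect_gte(mean(wins), 0.9)
})

test_that("binned CR correlation reproduces a brute-force binning "
          %+% "oracle and tracks direction", {
  set.seed(90)
  scores <- rnorm(200)
  resp <- ifelse(runif(200) < plogis(0.5 - 2 * scores), "CR", "non-CR")
  out <- binned_cr_correlation(scores, resp, n_bins = 4)
  expect_lt(out$r, 0)
  # oracle: quartile binning + hand pearson
  q <- quantile(scores, probs = seq(0, 1, 0.25))
  bins <- cut(scores, breaks = q, include.lowest = TRUE)
  mean_s <- tapply(scores, bins, mean)
  cr_rate <- tapply(resp == "CR", bins, mean)
  want <- oracle_pearson(as.vector(mean_s), as.vector(cr_rate))
  expect_equal(out$r, want$r, tolerance = 1e-10)
  expect_equal(out$p, want$p, tolerance = 1e-10)
  expect_error(binned_cr_correlation(rep(1, 30),
                                     rep(c("CR", "non-CR"), 15)),
               "bin")
})

test_that("binned CR correlation is centred on zero under a null slope", {
  rs <- vapply(1:40, function(s) {
    set.seed(9100 + s)
    scores <- rnorm(200)
    resp <- ifelse(runif(200) < 0.6, "CR", "non-CR")
    binned_cr_correlation(scores, resp)$r
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.2)
})

test_that("CR-restricted survival compares only complete responders", {
  set.seed(17)
  base_t <- rexp(30, 0.01)
  cl <- make_clinical(rep(c("CR", "non-CR"), 15),
                      time = rep(base_t, 2)[1:30],
                      event = rep(1, 30))
  # identical duplicated CR groups: exact null
  cr_idx <- which(cl$response == "CR")
  cl2 <- rbind(cl[cr_idx, ], cl[cr_idx, ])
  grp <- rep(c("high", "low"), each = length(cr_idx))
  out <- cr_restricted_survival(cl2, make_risk(grp))
  expect_equal(out$logrank$chi_square, 0, tolerance = 1e-10)
  expect_equal(out$logrank$p, 1, tolerance = 1e-10)
  expect_equal(out$n, nrow(cl2))
  expect_error(
    cr_restricted_survival(make_clinical(rep("non-CR", 10)),
                           make_risk(rep(c("high", "low"), 5))),
    "no CR samples")
})

test_that("three-group comparison: omnibus df, planted separation, "
          %+% "pairwise consistency", {
  set.seed(26)
  n <- 240
  status <- rep(c("mutant", "wild-type"), c(80, 160))
  grp <- c(rep("low", 80), rep(c("high", "low"), each = 80))
  # mutants and low-risk share a hazard; high-risk wild-type is worse
  rate <- ifelse(status == "wild-type" & grp == "high", 0.004, 0.001)
  ev <- rexp(n, rate)
  cl <- make_clinical(rep("CR", n), time = pmin(ev, 2000),
                      event = as.integer(ev <= 2000), mutation = status)
  risk <- make_risk(grp)
  out <- three_group_comparison(cl, risk)
  expect_equal(out$omnibus$df, 2)
  expect_lt(out$omnibus$p, 0.01)
  pw <- out$pairwise
  vs_high <- pw$p[pw$group1 == "high-risk wild-type"]
  expect_true(all(vs_high < 0.05))
  equal_pair <- pw$p[pw$group1 == "low-risk wild-type" &
                       pw$group2 == "mutant"]
  expect_gt(equal_pair, 0.05)
  # each pairwise row equals a direct two-group log-rank on that subset
  lab <- out$groups
  for (i in seq_len(nrow(pw))) {
    keep <- lab %in% c(pw$group1[i], pw$group2[i])
    direct <- logrank_test(data.frame(time = cl$os_time_days,
                                      event = cl$os_event)[keep, ],
                           lab[keep])
    expect_equal(pw$chi_square[i], direct$chi_square, tolerance = 1e-10)
  }
  # BH flag adds monotone q-values
  out_bh <- three_group_comparison(cl, risk, bh_adjust = TRUE)
  expect_true(all(out_bh$pairwise$q >= out_bh$pairwise$p - 1e-12))
  expect_error(three_group_comparison(
    make_clinical(rep("CR", 10), mutation = "mutant"),
    make_risk(rep("high", 10))), "empty categor")
})

test_that("top co-expressed mRNAs are ranked by |r| with deterministic "
          %+% "ties", {
  set.seed(41)
  n <- 80
  scores <- rnorm(n)
  m <- cbind(hit = scores, anti = -scores + rnorm(n, sd = 0.2),
             noise1 = rnorm(n), noise2 = rnorm(n), flat = rep(1, n))
  expect_warning(top <- top_coexpressed(m, scores, k = 2), "flat")
  expect_identical(top$mrna_id[1], "hit")
  expect_equal(top$r[1], 1, tolerance = 1e-12)
  # k = all usable columns, brute-force oracle ordering
  expect_warning(all_ranked <- top_coexpressed(m, scores, k = 4), "flat")
  want <- vapply(c("hit", "anti", "noise1", "noise2"), function(id) {
    abs(oracle_pearson(m[, id], scores)$r)
  }, numeric(1))
  expect_identical(all_ranked$mrna_id,
                   names(sort(want, decreasing = TRUE)))
  expect_error(suppressWarnings(top_coexpressed(m, scores, k = 10)),
               "exceeds")
})

test_that("over-representation analysis matches the closed-form "
          %+% "hypergeometric", {
  universe <- paste0("g", 1:20)
  sets <- list(hit = paste0("g", 1:5), other = paste0("g", 6:10))
  # query = universe: overlap is the whole set, upper tail at max, p = 1
  res <- ora(universe, sets, universe)
  expect_equal(res$p, c(1, 1))
  expect_equal(res$k, res$K)
  # perfect 5-of-5 overlap: p = 1 / choose(20, 5)
  res <- ora(paste0("g", 1:5), sets["hit"], universe)
  expect_equal(res$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(res$p, 1 / 15504, tolerance = 1e-9)
  # overlap bounded by set and query sizes
  expect_true(all(res$k <= pmin(res$K, res$n)))
  expect_warning(ora(c("g1", "zzz"), sets, universe), "outside universe")
  expect_error(ora("g1", sets, character(0)), "empty universe")
})

test_that("BH adjustment is monotone, bounded by 1, and flat on uniform "
          %+% "input", {
  set.seed(5)
  sets <- lapply(1:6, function(i) paste0("g", sample(1:40, 8)))
  names(sets) <- paste0("s", 1:6)
  res <- ora(paste0("g", 1:10), sets, paste0("g", 1:40))
  expect_true(all(res$q <= 1 + 1e-12))
  expect_true(all(res$q >= res$p - 1e-12))
  expect_true(all(diff(res$q) >= -1e-12))  # sorted by p => monotone q
  # equal raw p-values keep q = p under BH
  p <- rep(0.03, 5)
  expect_equal(p.adjust(p, "BH"), p)
  same_sets <- rep(list(paste0("g", 1:4)), 3)
  names(same_sets) <- paste0("dup", 1:3)
  res <- ora(paste0("g", 1:4), same_sets, paste0("g", 1:30))
  expect_equal(res$q, res$p, tolerance = 1e-12)
})

test_that("GMT files round-trip into named gene-set lists", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\t-\tg2\tg4"), path)
  sets <- read_gmt(path)
  expect_identical(names(sets), c("setA", "setB"))
  expect_identical(sets$setA, c("g1", "g2", "g3"))
  writeLines("broken\tonly-desc", path)
  expect_error(read_gmt(path), "malformed")
})
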