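# Statistical layer versus independent from-scratch oracles.

test_that("Student t matches the incomplete-beta oracle to 1e-12", {
  set.seed(101)
  for (i in 1:300) {
    x <- rnorm(sample(3:10, 1), sd = runif(1, 0.5, 2))
    y <- rnorm(sample(3:10, 1), mean = runif(1, -1, 1))
    got <- two_group_ttest(x, y)
    want <- oracle_t2(x, y)
    expect_equal(got$statistic, unname(want["t"]), tolerance = 1e-12)
    expect_equal(got$p_raw, unname(want["p"]), tolerance = 1e-12)
    expect_equal(got$estimate, mean(x) - mean(y))
  }
  # paired test equals the one-sample t on differences
  x <- rnorm(8); y <- rnorm(8)
  got <- two_group_ttest(x, y, paired = TRUE)
  d <- x - y
  t_or <- mean(d) / (sd(d) / sqrt(8))
  expect_equal(got$statistic, t_or, tolerance = 1e-12)
  expect_equal(got$p_raw, stats::pbeta(7 / (7 + t_or^2), 3.5, 0.5),
               tolerance = 1e-12)
})

test_that("degenerate t inputs are flagged, not propagated as NaN", {
  got <- two_group_ttest(c(1, 2, 3), c(1, 2, 3), paired = TRUE)
  expect_equal(got$statistic, 0)
  expect_equal(got$p_raw, 1)
  expect_true(got$degenerate)
  got2 <- two_group_ttest(c(2, 2), c(2, 2))
  expect_equal(got2$p_raw, 1)
  got3 <- two_group_ttest(c(3, 3), c(1, 1))
  expect_equal(got3$p_raw, 0)
  expect_true(got3$degenerate)
  expect_error(two_group_ttest(1, c(1, 2)), "at least 2")
})

test_that("one-way ANOVA matches its oracle and the F = t^2 identity", {
  set.seed(102)
  for (i in 1:200) {
    groups <- lapply(seq_len(sample(2:5, 1)), function(j)
      rnorm(sample(3:8, 1), mean = runif(1, -1, 1)))
    got <- anova_oneway(groups)
    want <- oracle_f(groups)
    expect_equal(got$statistic, unname(want["f"]), tolerance = 1e-12)
    expect_equal(got$p_raw, unname(want["p"]), tolerance = 1e-12)
  }
  x <- rnorm(8); y <- rnorm(8)
  expect_equal(anova_oneway(list(x, y))$statistic,
               two_group_ttest(x, y)$statistic^2, tolerance = 1e-12)
  same <- anova_oneway(list(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_raw, 1)
})

test_that("BH adjustment equals the step-up oracle exactly", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  set.seed(103)
  for (i in 1:200) {
    p <- runif(sample(1:40, 1))
    expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-12)
  }
  # NA entries are excluded from the family count m
  p <- c(0.01, NA, 0.02, 0.04)
  expect_equal(bh_adjust(p), c(0.03, NA, 0.03, 0.04))
  # families are adjusted independently
  fam <- c(1, 1, 2, 2)
  p2 <- c(0.01, 0.04, 0.01, 0.04)
  expect_equal(bh_adjust(p2, fam), c(0.02, 0.04, 0.02, 0.04))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Pearson correlations match the from-scratch oracle", {
  set.seed(104)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    ids <- sprintf("A%02d", seq_len(n))
    out <- correlate_outcomes(
      data.frame(animal_id = ids, feature_id = "f", value = x),
      data.frame(animal_id = ids, y = y))
    want <- oracle_pearson(x, y)
    expect_equal(out$r, unname(want["r"]), tolerance = 1e-12)
    expect_equal(out$p_raw, unname(want["p"]), tolerance = 1e-12)
  }
})

test_that("volcano classification applies the published cutoffs", {
  expect_equal(volcano_classify(0.2, 0.01), "up")
  expect_equal(volcano_classify(0.05, 0.01), "ns")   # 0.05 is not > 0.1
  expect_equal(volcano_classify(-0.3, 0.2), "ns")    # p fails
  expect_equal(volcano_classify(-0.3, 0.01), "down")
  expect_equal(volcano_classify(0.1, 0.01), "ns")    # boundary excluded
  expect_true(is.na(volcano_classify(NA, 0.01)))
  expect_equal(volcano_classify(c(0.2, -0.2), c(0.01, 0.01)),
               c("up", "down"))
})

test_that("combined-rank selection matches brute-force enumeration", {
  feats <- data.frame(id = sprintf("f%02d", 1:10),
                      p_raw = c(0.5, 0.01, 0.2, 0.03, 0.8, 0.04, 0.6,
                                0.02, 0.9, 0.05),
                      change = c(0.1, 1.2, 0.4, 0.9, 0.05, 0.7, 0.2,
                                 1.0, 0.01, 0.6))
  out <- rank_top_features(feats, fraction = 0.2)
  expect_equal(sum(out$selected), 2)
  expect_true(all(c("f02", "f08") %in% out$id[out$selected]))

  set.seed(105)
  for (i in 1:50) {
    n <- sample(5:40, 1)
    tab <- data.frame(id = sprintf("g%03d", seq_len(n)),
                      p_raw = round(runif(n), 2),       # forces ties
                      change = round(rnorm(n), 1))
    frac <- runif(1, 0.1, 0.9)
    out <- rank_top_features(tab, frac)
    # brute force: pairwise-count mid-ranks, then the documented tie-break
    rp <- vapply(seq_len(n), function(j)
      sum(tab$p_raw < tab$p_raw[j]) +
        (sum(tab$p_raw == tab$p_raw[j]) + 1) / 2, 0)
    rm_ <- vapply(seq_len(n), function(j)
      sum(abs(tab$change) > abs(tab$change[j])) +
        (sum(abs(tab$change) == abs(tab$change[j])) + 1) / 2, 0)
    comb <- rp + rm_
    pick <- order(comb, -abs(tab$change), tab$id)[seq_len(ceiling(frac * n))]
    expect_identical(which(out$selected), sort(pick))
    expect_equal(out$combined, comb)
  }
  # a feature dominating both ranks is always selected
  dom <- data.frame(id = c("a", "b", "c", "d", "e"),
                    p_raw = c(1e-6, 0.3, 0.4, 0.5, 0.6),
                    change = c(3, 0.1, 0.2, 0.1, 0.3))
  expect_true(rank_top_features(dom, 0.2)$selected[1])
  expect_error(rank_top_features(dom, 0), "fraction")
})

test_that("group Z-scores use the grand mean and documented SD conventions", {
  same <- group_zscores(list(g1 = c(1, 2), g2 = c(1, 2)))
  expect_equal(unname(same), c(0, 0))
  z <- group_zscores(list(g1 = c(0, 0), g2 = c(1, 1)))
  expect_equal(unname(z), c(-1, 1))   # grand mean 0.5, population SD 0.5
  zs <- group_zscores(list(g1 = c(0, 0), g2 = c(1, 1)), sd_type = "sample")
  expect_equal(unname(zs), c(-0.5, 0.5) / sd(c(0, 0, 1, 1)))
  set.seed(9)
  gs <- list(a = rnorm(5), b = rnorm(5), c = rnorm(5))
  expect_equal(sum(group_zscores(gs)), 0, tolerance = 1e-12)
  flat <- group_zscores(list(g1 = c(2, 2), g2 = c(2, 2)))
  expect_true(all(is.na(flat)))
})

test_that("log2 ratios versus mock handle edge cases", {
  expect_equal(log2_vs_mock(5, 5), 0)
  expect_equal(log2_vs_mock(10, 5), 1)
  expect_true(is.na(log2_vs_mock(5, 0)))
  expect_true(is.na(log2_vs_mock(0, 5)))
  expect_equal(log2_vs_mock(c(5, 10), c(5, 5)), c(0, 1))
})

test_that("outcome correlations flag degeneracies and control FDR per family", {
  ft <- data.frame(animal_id = sprintf("A%02d", 1:6),
                   feature_id = "lin", value = 1:6, family = "freq")
  oc <- data.frame(animal_id = sprintf("A%02d", 1:6),
                   outcome_lin = 2 * (1:6) + 3, outcome_const = rep(1, 6))
  out <- correlate_outcomes(ft, oc)
  expect_equal(out$r[out$outcome == "outcome_lin"], 1)
  expect_true(out$missing[out$outcome == "outcome_const"])
  expect_true(is.na(out$r[out$outcome == "outcome_const"]))
  expect_true(all(out$p_adj >= out$p_raw, na.rm = TRUE))
  expect_true(out$hatch[out$missing])

  # a true correlation of 0.8 at n=24 lands inside its Fisher interval
  tr <- make_truth(default_config(n_animals = 8), seed = 12)
  sev <- tr$animals$severity
  set.seed(77)
  feat <- 0.8 * scale(sev)[, 1] + sqrt(1 - 0.64) * rnorm(24)
  ft2 <- data.frame(animal_id = tr$animals$animal_id, feature_id = "sev",
                    value = feat, family = "freq")
  oc2 <- data.frame(animal_id = tr$animals$animal_id,
                    severity = sev)
  r_hat <- correlate_outcomes(ft2, oc2)$r[1]
  ci <- tanh(atanh(0.8) + c(-1, 1) * 1.96 / sqrt(24 - 3))
  expect_gt(r_hat, ci[1])
  expect_lt(r_hat, ci[2])
})

test_that("within-group correlation mode appends per-group rows", {
  set.seed(11)
  ft <- data.frame(animal_id = sprintf("A%02d", 1:12),
                   feature_id = "f", value = rnorm(12), family = "freq",
                   group = rep(c("mock", "mRNA"), each = 6))
  oc <- data.frame(animal_id = sprintf("A%02d", 1:12), y = rnorm(12))
  out <- correlate_outcomes(ft, oc, by_group = TRUE)
  expect_equal(sum(is.na(out$group)), 1)         # pooled row
  expect_setequal(na.omit(out$group), c("mock", "mRNA"))
  expect_true(all(is.na(out$p_adj[!is.na(out$group)])))  # BH on pooled only
})
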