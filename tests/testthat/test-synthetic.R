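# Generator: determinism, invariants, mixture fidelity and outcome links.

test_that("truth construction is deterministic and validates its config", {
  cfg <- default_config(n_animals = 2)
  expect_identical(make_truth(cfg, seed = 5), make_truth(cfg, seed = 5))

  bad <- cfg
  bad$pop_freqs$PBMC$mock <- bad$pop_freqs$PBMC$mock * 0 + 1.2 / 13
  bad$pop_freqs$PBMC$mock[1] <- 1.2 - sum(bad$pop_freqs$PBMC$mock[-1])
  expect_error(make_truth(bad, seed = 1), "configuration error")

  bad2 <- cfg
  bad2$groups["mock"] <- -1
  expect_error(make_truth(bad2, seed = 1), "configuration error")

  bad3 <- cfg
  bad3$stim_effects["CD4T", "pErk12", "UNSTIM"] <- 0.5
  expect_error(make_truth(bad3, seed = 1), "UNSTIM")
})

test_that("truth invariants hold and study effects are encoded", {
  tr <- make_truth(default_config(n_animals = 4), seed = 11)
  for (a in tr$animals$animal_id) for (tis in tr$config$tissues) {
    f <- tr$animal_freqs[a, tis, ]
    expect_true(all(f >= 0 & f <= 1))
    expect_lte(sum(f), 1)
  }
  expect_true(all(tr$stim_effects[, , "UNSTIM"] == 0))
  tt <- seq(0, tr$config$acquisition$window, length.out = 50)
  expect_true(all(drift_multiplier <- cytopipe:::drift_multiplier(tr, tt) > 0))
  # encoded group-level composition differences (Fig-2-style pattern)
  expect_gt(tr$pop_freqs$PBMC$mock[["CD8Tact"]],
            tr$pop_freqs$PBMC$mRNA[["CD8Tact"]])
  expect_lt(tr$pop_freqs$PBMC$mock[["pDC"]], tr$pop_freqs$PBMC$mRNA[["pDC"]])
  expect_gt(tr$pop_freqs$LN$mock[["intMC"]], tr$pop_freqs$LN$mRNA[["intMC"]])
  expect_gt(tr$pop_freqs$LN$mock[["B"]], tr$pop_freqs$LN$protein[["B"]])
})

test_that("sample simulation is deterministic with valid structure", {
  tr <- tiny_truth()
  m <- sample_meta("A01", "PBMC", "UNSTIM", first_code(tr))
  ev1 <- simulate_sample(tr, m, n_events = 1000, bead_fraction = 0.05)
  ev2 <- simulate_sample(tr, m, n_events = 1000, bead_fraction = 0.05)
  expect_identical(ev1$exprs, ev2$exprs)
  expect_identical(ev1$truth_labels, ev2$truth_labels)
  expect_true(all(diff(ev1$exprs[, "Time"]) > 0))
  expect_true(all(ev1$exprs >= 0))

  ev0 <- simulate_sample(tr, m, n_events = 500, bead_fraction = 0)
  expect_false(any(ev0$truth_labels$is_bead))

  expect_error(simulate_sample(tr, sample_meta("nope", "PBMC", "UNSTIM")),
               "unknown animal")
  bad_meta <- m
  bad_meta$favourite_colour <- "green"
  expect_error(simulate_sample(tr, bad_meta, 100), "unknown meta field")
  expect_error(simulate_sample(tr, m, n_events = 100, bead_fraction = 0.5),
               "bead_fraction")
})

test_that("empirical mixture proportions match truth fractions", {
  tr <- flat_truth()
  m <- sample_meta("A02", "LN", "UNSTIM", first_code(tr))
  ev <- simulate_sample(tr, m, n_events = 100000, bead_fraction = 0)
  tab <- table(ev$truth_labels$population)
  n <- n_events(ev)
  for (pop in tr$populations) {
    p <- tr$animal_freqs["A02", "LN", pop]
    se <- sqrt(p * (1 - p) / n)
    expect_lt(abs(tab[[pop]] / n - p), 4 * se)
  }
})

test_that("per-channel medians match generator locations (resampling oracle)", {
  tr <- flat_truth()
  m <- sample_meta("A01", "PBMC", "UNSTIM", first_code(tr))
  ev <- simulate_sample(tr, m, n_events = 50000, bead_fraction = 0)
  idx <- which(ev$truth_labels$population == "CD4T")
  for (marker in c("CD45", "CD4", "CD8", "pErk12")) {
    ch <- ev$panel$channel[ev$panel$marker == marker]
    med <- asinh(stats::median(ev$exprs[idx, ch]) / 5)
    loc <- tr$marker_loc["CD4T", marker]
    sdv <- tr$marker_sd["CD4T", marker]
    # oracle: direct draws from the stated arcsinh-scale distribution
    set.seed(99)
    oracle <- stats::median(pmax(0, stats::rnorm(length(idx), loc, sdv)))
    mc_tol <- 4 * 1.2533 * sdv / sqrt(length(idx))
    expect_lt(abs(med - oracle), 2 * mc_tol)
    expect_lt(abs(med - loc), 4 * mc_tol + 1e-3)
  }
})

test_that("doublets carry the union of two barcode codes", {
  tr <- tiny_truth()
  code_a <- c(1L, 1L, 0L, 1L, 0L, 0L)
  code_b <- c(0L, 1L, 1L, 0L, 1L, 0L)
  ma <- sample_meta("A01", "PBMC", "UNSTIM", code_a)
  mb <- sample_meta("A02", "PBMC", "UNSTIM", code_b)
  dd <- simulate_doublet_events(tr, ma, mb, n = 200)
  bc_ch <- dd$panel$channel[dd$panel$role == "barcode"]
  z <- asinh(dd$exprs[, bc_ch] / 5)
  high <- rowSums(z > 2.25)
  expect_true(all(high == sum(code_a | code_b)))
  expect_true(all(high > tr$config$barcode$k))
  expect_true(all(dd$truth_labels$is_doublet))

  empty <- simulate_doublet_events(tr, ma, mb, n = 0)
  expect_equal(n_events(empty), 0)
  expect_error(simulate_doublet_events(tr, ma, ma, n = 10), "distinct")
})

test_that("CBC records satisfy the mononuclear-count invariant in bulk", {
  cfg <- default_config(n_animals = 334)
  tr <- make_truth(cfg, seed = 21)
  cbc <- simulate_cbc(tr)
  expect_equal(nrow(cbc), 1002)
  expect_true(all(cbc$wbc >= cbc$neutrophils + cbc$eosinophils))
  expect_true(all(cbc$neutrophils >= 0 & cbc$eosinophils >= 0))
  expect_identical(cbc, simulate_cbc(tr))
})

test_that("outcomes follow the severity model and clip to clinical ranges", {
  cfg <- default_config(n_animals = 8)
  cfg$severity$sd <- 0
  for (nm in names(cfg$outcome_links)) cfg$outcome_links[[nm]]$sd <- 0
  tr <- make_truth(cfg, seed = 4)
  oc <- simulate_outcomes(tr, c("A01", "A02"))  # same group, equal severity
  expect_equal(oc$viral_rna_log10[1], oc$viral_rna_log10[2])
  expect_equal(oc$pathology_score[1], oc$pathology_score[2])

  tr2 <- make_truth(default_config(n_animals = 8), seed = 4)
  oc2 <- simulate_outcomes(tr2)
  expect_true(all(oc2$pathology_score >= 0 & oc2$pathology_score <= 4))
  expect_true(all(oc2$radiograph_score >= 0 & oc2$radiograph_score <= 3))
  g <- tr2$animals$group
  expect_gt(mean(oc2$viral_rna_log10[g == "mock"]),
            mean(oc2$viral_rna_log10[g == "protein"]))
  expect_error(simulate_outcomes(tr2, "A99"), "unknown animal")
})

test_that("zero severity-pathology slope yields null correlation (permutation)", {
  cfg <- default_config(n_animals = 8)
  cfg$outcome_links$pathology$slope <- 0
  tr <- make_truth(cfg, seed = 17)
  oc <- simulate_outcomes(tr)
  r_obs <- cor(tr$animals$severity, oc$pathology_score)
  set.seed(42)
  r_perm <- replicate(2000, cor(sample(tr$animals$severity),
                                oc$pathology_score))
  p_perm <- mean(abs(r_perm) >= abs(r_obs))
  expect_gt(p_perm, 0.05)
})

test_that("drift shows up in bead medians by the injected ratio", {
  tr <- make_truth(default_config(n_animals = 2, drift_range = 2), seed = 9)
  m <- sample_meta("A01", "PBMC", "UNSTIM", first_code(tr))
  ev <- simulate_sample(tr, m, n_events = 40000, bead_fraction = 0.1)
  be <- ev$exprs[ev$truth_labels$is_bead, ]
  q <- stats::quantile(be[, "Time"], c(0, 0.25, 0.75, 1))
  early <- be[, "Time"] <= q[2]
  late <- be[, "Time"] >= q[3]
  for (ch in c("Ce140Di", "Lu175Di")) {
    ratio <- stats::median(be[early, ch]) / stats::median(be[late, ch])
    expected <- cytopipe:::drift_multiplier(tr, mean(be[early, "Time"])) /
      cytopipe:::drift_multiplier(tr, mean(be[late, "Time"]))
    expect_lt(abs(ratio / expected - 1), 0.1)
  }
})
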