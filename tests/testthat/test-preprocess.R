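# Bead identification, normalization, barcode assignment, Mahalanobis
# filtering and the debarcode partition.

test_that("bead identification is exact against the truth sidecar", {
  tr <- tiny_truth()
  m <- sample_meta("A01", "PBMC", "UNSTIM", first_code(tr))
  ev <- simulate_sample(tr, m, n_events = 10000, bead_fraction = 0.05)
  mask <- identify_beads(ev)
  expect_equal(mask, ev$truth_labels$is_bead)

  ev0 <- simulate_sample(tr, m, n_events = 3000, bead_fraction = 0)
  expect_warning(mask0 <- identify_beads(ev0), "no bead mode")
  expect_false(any(mask0))

  evb <- simulate_sample(tr, m, n_events = 2000, bead_fraction = 0.05)
  all_beads <- subset_events(evb, evb$truth_labels$is_bead)
  expect_true(all(identify_beads(all_beads)))

  expect_error(identify_beads(ev, bead_channels = character(0)),
               "at least one bead channel")
  expect_error(identify_beads(ev, bead_channels = "NotAChannel"),
               "not in events")
})

test_that("normalization is the identity without drift and inverts injected drift", {
  tr <- flat_truth()  # drift range 1
  m <- sample_meta("A01", "PBMC", "UNSTIM", first_code(tr))
  ev <- simulate_sample(tr, m, n_events = 30000, bead_fraction = 0.1)
  beads <- subset_events(ev, identify_beads(ev))
  f <- fit_normalization(beads, window_size = 500)
  expect_true(all(abs(f$multipliers - 1) < 0.03))

  # inject a known multiplicative drift g(t) on one channel; with the
  # undrifted medians as reference the fitted multiplier must be ~1/g
  g <- function(t) 1 / (1 + t / 600)      # 2-fold decline
  ref <- apply(beads$exprs[, colnames(f$multipliers)], 2, median)
  drifted <- beads
  drifted$exprs[, "Ce140Di"] <- drifted$exprs[, "Ce140Di"] *
    g(drifted$exprs[, "Time"])
  f2 <- fit_normalization(drifted, window_size = 500, reference = ref)
  expect_true(all(abs(f2$multipliers[, "Ce140Di"] * g(f2$knots) - 1) < 0.05))

  # two batches whose bead medians differ 2-fold: shared reference makes
  # the multipliers differ by the same factor
  batch2 <- beads
  batch2$exprs[, "Ce142Di"] <- batch2$exprs[, "Ce142Di"] * 2
  fa <- fit_normalization(beads, window_size = 500, reference = ref)
  fb <- fit_normalization(batch2, window_size = 500, reference = ref)
  ratio <- fa$multipliers[, "Ce142Di"] / fb$multipliers[, "Ce142Di"]
  expect_true(all(abs(ratio / 2 - 1) < 0.05))
})

test_that("applying normalization is idempotent and validates factors", {
  tr <- make_truth(default_config(n_animals = 2, drift_range = 2), seed = 6)
  m <- sample_meta("A01", "PBMC", "UNSTIM", first_code(tr))
  ev <- simulate_sample(tr, m, n_events = 30000, bead_fraction = 0.1)
  mask <- identify_beads(ev)
  f <- fit_normalization(subset_events(ev, mask), window_size = 500)
  nev <- apply_normalization(ev, f)
  expect_equal(nev$exprs[, "Time"], ev$exprs[, "Time"])
  f2 <- fit_normalization(subset_events(nev, mask), window_size = 500)
  expect_true(all(abs(f2$multipliers - 1) < 0.05))

  # unit factors leave events untouched
  fid <- f
  fid$multipliers[] <- 1
  fid$global[] <- 1
  same <- apply_normalization(ev, fid)
  expect_equal(same$exprs, ev$exprs)

  fneg <- f
  fneg$multipliers[1, 1] <- -1
  expect_error(apply_normalization(ev, fneg), "strictly positive")
  expect_error(fit_normalization(subset_events(ev, mask),
                                 window_size = 1e6), "window_size")
})

test_that("barcode assignment recovers codes with near-unit separation", {
  b <- small_batch()
  cells <- subset_events(b$events, !b$events$truth_labels$is_bead)
  asg <- assign_barcodes(cells, b$scheme)
  tl <- cells$truth_labels
  singlet <- !tl$is_doublet
  hit <- !is.na(asg$sample_id)
  # every assignment that is made is correct
  expect_true(all(asg$sample_id[hit] == tl$sample_id[hit]))
  expect_gt(mean(hit[singlet]), 0.97)
  expect_gt(median(asg$separation[singlet]), 0.4)
  # doublets: >k channels high forces near-zero separation or a bad code
  expect_true(all(is.na(asg$sample_id[tl$is_doublet])))
  expect_lt(median(asg$separation[tl$is_doublet]), 0.1)

  expect_error(barcode_scheme("s1", n = 3, k = 3), "k < n")
  expect_error(assign_barcodes(cells, barcode_scheme("s1", n = 4, k = 2)),
               "barcode channels")
})

test_that("assignments are equivariant to per-channel rescaling and yields are monotone", {
  b <- small_batch()
  cells <- subset_events(b$events, !b$events$truth_labels$is_bead)
  asg <- assign_barcodes(cells, b$scheme)
  scaled <- cells
  bc1 <- scaled$panel$channel[scaled$panel$role == "barcode"][1]
  scaled$exprs[, bc1] <- scaled$exprs[, bc1] * 3
  asg2 <- assign_barcodes(scaled, b$scheme)
  agree <- (is.na(asg$sample_id) & is.na(asg2$sample_id)) |
    (!is.na(asg$sample_id) & !is.na(asg2$sample_id) &
       asg$sample_id == asg2$sample_id)
  expect_gt(mean(agree), 0.999)

  counts <- vapply(c(0.1, 0.3, 0.5), function(cut)
    sum(!is.na(assign_barcodes(cells, b$scheme, cut)$sample_id)), 0)
  expect_true(all(diff(counts) <= 0))
  dist_counts <- vapply(c(50, 30, 10), function(md)
    sum(!is.na(mahalanobis_filter(cells, asg, max_dist = md)$sample_id)), 0)
  expect_true(all(diff(dist_counts) <= 0))
})

test_that("Mahalanobis filter keeps centroids and removes outliers by convention", {
  # crafted assignment: 500 events N(mu, I) in rescaled barcode space
  set.seed(8)
  n <- 500
  mu <- rep(0.5, 6)
  r <- matrix(rnorm(n * 6, mu, 1), n, 6, byrow = FALSE)
  r[1, ] <- mu                      # exact centroid
  r[2, ] <- mu + c(5, 0, 0, 0, 0, 0) / sqrt(1)   # ~5 units out
  asg <- structure(
    data.frame(sample_id = rep("s1", n), separation = 1,
               mahalanobis = NA_real_, reason = "assigned"),
    class = c("barcode_assignment", "data.frame"), rescaled = r)
  dummy <- matrix(0, n, 1)
  # plain-distance convention, threshold 3: the 5-unit event is removed
  out <- mahalanobis_filter(dummy, asg, max_dist = 3, squared = FALSE)
  expect_lt(out$mahalanobis[1], 0.5)
  expect_equal(out$sample_id[1], "s1")
  expect_gt(out$mahalanobis[2], 3)
  expect_true(is.na(out$sample_id[2]))
  expect_equal(out$reason[2], "distance")
  # squared convention with the default threshold keeps it (5^2 < 30)
  out2 <- mahalanobis_filter(dummy, asg, max_dist = 30, squared = TRUE)
  expect_false(is.na(out2$sample_id[2]))
})

test_that("Mahalanobis filter removes shifted contaminants, sparing genuine events", {
  set.seed(31)
  n_good <- 2000; n_bad <- 100
  mu_a <- c(1, 1, 1, 0, 0, 0) * 0.9        # sample's own code centroid
  mu_b <- c(1, 0, 0, 1, 1, 0) * 0.9        # another code, diffusely stained
  r <- rbind(matrix(rnorm(n_good * 6, rep(mu_a, each = n_good), 0.05),
                    n_good, 6),
             matrix(rnorm(n_bad * 6, rep(mu_b, each = n_bad), 0.3),
                    n_bad, 6))
  truth_bad <- rep(c(FALSE, TRUE), c(n_good, n_bad))
  asg <- structure(
    data.frame(sample_id = "s1", separation = 1, mahalanobis = NA_real_,
               reason = "assigned")[rep(1, n_good + n_bad), ],
    class = c("barcode_assignment", "data.frame"), rescaled = r)
  out <- mahalanobis_filter(matrix(0, n_good + n_bad, 1), asg)
  removed <- is.na(out$sample_id)
  expect_gte(mean(removed[truth_bad]), 0.90)
  expect_lte(mean(removed[!truth_bad]), 0.02)
})

test_that("debarcoding partitions events with a conserved yield report", {
  b <- small_batch()
  cells <- subset_events(b$events, !b$events$truth_labels$is_bead)
  deb <- debarcode(cells, b$scheme)
  sizes <- vapply(deb$samples, n_events, 0)
  expect_equal(sum(sizes) + length(deb$unassigned), n_events(cells))
  expect_equal(sum(sizes), sum(!is.na(deb$assignment$sample_id)))
  expect_true(all(sizes > 0))
  expect_equal(sum(deb$yield$fraction), 1)
  # per-sample truth sidecars ride along and agree
  for (sid in names(deb$samples)[1:3])
    expect_true(all(deb$samples[[sid]]$truth_labels$sample_id == sid))

  # a batch of only doublets is fully rejected in the separated regime
  cfg <- default_config(n_animals = 2, drift_range = 1)
  cfg$barcode$sd <- 0.1
  tr <- make_truth(cfg, seed = 13)
  dd <- simulate_doublet_events(tr,
                                sample_meta("A01", "PBMC", "UNSTIM",
                                            b$scheme$codes[1, ]),
                                sample_meta("A02", "PBMC", "UNSTIM",
                                            b$scheme$codes[2, ]), n = 500)
  deb2 <- suppressWarnings(debarcode(dd, b$scheme))
  expect_equal(length(deb2$unassigned), 500)
  expect_true(all(vapply(deb2$samples, n_events, 0) == 0))
})
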