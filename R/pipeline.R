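# Pipeline orchestration: simulate -> normalize -> debarcode -> gate ->
# featurize -> test -> report, deterministic under a single seed.

#' Pipeline run configuration
#'
#' Bundles the experiment design, analysis thresholds and gate tree for a
#' full reproducible run. The configuration round-trips through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param seed integer seed driving every random draw of the run.
#' @param n_animals animals per treatment group.
#' @param n_events cell events per sample.
#' @param bead_fraction fraction of batch events that are normalization
#'   beads.
#' @param doublet_fraction fraction of cell events added as doublets.
#' @param drift_range sensitivity drift dynamic range (1 = none).
#' @param effect_scale scale of the vaccination effects (0 = null).
#' @param separation_cutoff debarcoding separation cutoff (rescaled units).
#' @param max_dist Mahalanobis threshold (squared-distance convention).
#' @param min_cells minimum events for a signaling median.
#' @param volcano_p,volcano_diff volcano significance / change cutoffs.
#' @param top_fraction combined-rank selection fraction.
#' @param sd_type Z-score SD convention (`"population"` or `"sample"`).
#' @param gate_cutoff default gate threshold on the arcsinh scale.
#' @return list of class `run_config` (includes the gate tree node list
#'   under `$gate`).
#' @export
pipeline_config <- function(seed = 1, n_animals = 8, n_events = 2000,
                            bead_fraction = 0.05, doublet_fraction = 0.02,
                            drift_range = 2, effect_scale = 1,
                            separation_cutoff = 0.3, max_dist = 30,
                            min_cells = 20, volcano_p = 0.05,
                            volcano_diff = 0.1, top_fraction = 0.2,
                            sd_type = "population", gate_cutoff = 2.25) {
  cfg <- list(seed = as.integer(seed), n_animals = n_animals,
              n_events = n_events, bead_fraction = bead_fraction,
              doublet_fraction = doublet_fraction,
              drift_range = drift_range, effect_scale = effect_scale,
              separation_cutoff = separation_cutoff, max_dist = max_dist,
              min_cells = min_cells, volcano_p = volcano_p,
              volcano_diff = volcano_diff, top_fraction = top_fraction,
              sd_type = sd_type, gate_cutoff = gate_cutoff,
              gate = default_gate_config(gate_cutoff))
  class(cfg) <- c("run_config", "list")
  validate_run_config(cfg)
}

#' @noRd
validate_run_config <- function(config) {
  if (is.null(config[["gate"]])) cp_stop("run config is missing the gate tree")
  if (is.null(config$seed)) cp_stop("run config is missing a seed")
  with_ranges <- list(bead_fraction = c(0, 0.2), doublet_fraction = c(0, 0.2),
                      separation_cutoff = c(0, 1), top_fraction = c(1e-9, 1),
                      volcano_p = c(0, 1))
  for (nm in names(with_ranges)) {
    v <- config[[nm]]
    if (is.null(v) || v < with_ranges[[nm]][1] || v > with_ranges[[nm]][2])
      cp_stop("run config field '%s' out of range", nm)
  }
  if (config$n_events < 1 || config$n_animals < 1)
    cp_stop("run config requires n_events >= 1 and n_animals >= 1")
  invisible(config)
}

#' Write / read a run configuration as YAML
#'
#' @param config a `run_config`.
#' @param path YAML file path.
#' @return `read_run_config` returns the `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("run_config", "list")
  validate_run_config(cfg)
}

# Sample roster and batch layout: one sample per (animal, tissue, stim),
# chunked into pooled barcode batches of at most 16.
#' @noRd
plan_batches <- function(truth, batch_size = 16) {
  an <- truth$animals
  grid <- expand.grid(animal_id = an$animal_id,
                      tissue = truth$config$tissues,
                      stim = truth$config$stims,
                      stringsAsFactors = FALSE)
  grid$group <- an$group[match(grid$animal_id, an$animal_id)]
  grid <- grid[order(grid$tissue, grid$stim, grid$animal_id), ]
  grid$key <- paste(grid$animal_id, grid$tissue, grid$stim, sep = "_")
  grid$batch <- sprintf("batch%02d",
                        (seq_len(nrow(grid)) - 1) %/% batch_size + 1)
  grid
}

#' Run the full analysis pipeline on a simulated experiment
#'
#' Simulates pooled barcoded batches under the configured study design,
#' then runs every analysis stage: bead identification, cross-batch bead
#' normalization, debarcoding with Mahalanobis filtering, hierarchical
#' gating, feature extraction (frequencies, pseudo-absolute counts,
#' signaling responses) and the statistical layer (group tests, volcano,
#' combined-rank selection, ANOVA Z-scores, log2 ratios, outcome
#' correlations). Deterministic given the config seed.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional directory; when given, all result CSVs and the
#'   run manifest are written there.
#' @return list with the feature tables, statistics tables, yield report
#'   and `manifest` (config hash, per-stage event accounting, file
#'   checksums), invisibly when `outdir` is given.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  validate_run_config(config)
  truth <- make_truth(default_config(config$n_animals, config$n_events,
                                     config$drift_range,
                                     config$effect_scale),
                      seed = config$seed)
  tree <- build_gate_tree(config[["gate"]], truth$panel)
  plan <- plan_batches(truth)
  batches <- split(plan, plan$batch)
  manifest_counts <- list()

  # -- simulate all batches
  sim <- lapply(names(batches), function(b) {
    pl <- batches[[b]]
    scheme <- barcode_scheme(pl$key)
    metas <- lapply(seq_len(nrow(pl)), function(i)
      sample_meta(pl$animal_id[i], pl$tissue[i], pl$stim[i],
                  scheme$codes[pl$key[i], ], batch_id = b))
    ev <- simulate_batch(truth, metas, n_events = config$n_events,
                         bead_fraction = config$bead_fraction,
                         doublet_fraction = config$doublet_fraction)
    list(events = ev, scheme = scheme, plan = pl)
  })
  names(sim) <- names(batches)

  # -- beads and cross-batch normalization reference
  bead_masks <- lapply(sim, function(b) identify_beads(b$events))
  panel <- truth$panel
  bead_ch <- panel$channel[panel$role == "bead"]
  all_beads <- do.call(rbind, lapply(names(sim), function(b)
    sim[[b]]$events$exprs[bead_masks[[b]], bead_ch, drop = FALSE]))
  reference <- apply(all_beads, 2, stats::median)

  # -- per batch: normalize, strip beads, debarcode
  gated <- list()
  yields <- list()
  for (b in names(sim)) {
    ev <- sim[[b]]$events
    beads <- bead_masks[[b]]
    bead_ev <- ev$exprs[beads, , drop = FALSE]
    factors <- fit_normalization(bead_ev,
                                 window_size = min(500, max(20,
                                   floor(sum(beads) / 4))),
                                 channels = bead_ch, reference = reference)
    ev <- apply_normalization(ev, factors)
    cells <- subset_events(ev, !beads)
    deb <- debarcode(cells, sim[[b]]$scheme,
                     separation_cutoff = config$separation_cutoff,
                     max_dist = config$max_dist)
    yields[[b]] <- cbind(batch = b, deb$yield)
    manifest_counts[[b]] <- c(total = n_events(sim[[b]]$events),
                              beads = sum(beads),
                              assigned = sum(!is.na(deb$assignment$sample_id)),
                              unassigned = length(deb$unassigned))
    pl <- sim[[b]]$plan
    for (i in seq_len(nrow(pl))) {
      key <- pl$key[i]
      sev <- deb$samples[[key]]
      gated[[key]] <- list(
        meta = list(animal_id = pl$animal_id[i], group = pl$group[i],
                    tissue = pl$tissue[i], stim = pl$stim[i]),
        gate = apply_gates(sev, tree), events = sev)
    }
  }
  sim <- NULL  # release raw event memory

  # -- features
  freq <- compute_frequencies(gated)
  cbc <- simulate_cbc(truth)
  pseudo <- pseudo_absolute_counts(freq, cbc)
  sig <- signaling_features(gated, min_cells = config$min_cells)
  resp <- signaling_responses(sig)
  outcomes <- simulate_outcomes(truth)

  # -- statistics
  freq_tests <- frequency_group_tests(freq)
  ratios <- log2_ratio_table(freq)
  volcano <- volcano_table(resp, p_cutoff = config$volcano_p,
                           diff_cutoff = config$volcano_diff)
  top <- rank_top_features(volcano, fraction = config$top_fraction,
                           by = c("tissue", "stim"))
  zsc <- signaling_group_stats(resp, top[top$selected, , drop = FALSE],
                               sd_type = config$sd_type)
  corr <- outcome_correlation_table(freq, resp,
                                    top[top$selected, , drop = FALSE],
                                    outcomes)

  results <- list(frequencies = freq, pseudo_counts = pseudo,
                  signaling = sig, responses = resp,
                  group_tests = freq_tests, log2_ratios = ratios,
                  volcano = volcano, top_features = top, zscores = zsc,
                  outcome_correlations = corr,
                  yield = do.call(rbind, yields), outcomes = outcomes,
                  cbc = cbc)

  cfg_hash <- substr(tools::md5sum(
    write_run_config(config, tempfile(fileext = ".yaml")))[[1]], 1, 12)
  counts <- do.call(rbind, manifest_counts)
  if (!all(counts[, "total"] ==
             counts[, "beads"] + counts[, "assigned"] +
             counts[, "unassigned"]))
    cp_stop("manifest conservation check failed")
  manifest <- list(config_hash = unname(cfg_hash),
                   stage_counts = as.data.frame(counts),
                   n_samples = length(gated))
  results$manifest <- manifest
  if (!is.null(outdir)) {
    files <- report(results, outdir)
    manifest$files <- files
    results$manifest <- manifest
    jsonlite::write_json(
      list(config_hash = manifest$config_hash,
           stage_counts = manifest$stage_counts,
           n_samples = manifest$n_samples,
           files = as.list(files)),
      file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA)
    return(invisible(results))
  }
  results
}

# ---- statistics table builders used by the pipeline ----

#' Group comparisons of population frequencies
#'
#' Unstimulated-condition frequencies only: per tissue and population,
#' Student t of each vaccine group versus mock plus one-way ANOVA across
#' all groups; BH adjustment within a tissue across populations x
#' pairwise comparisons.
#'
#' @param freq_table output of [compute_frequencies()].
#' @param control control group label.
#' @return data.frame with estimates, raw and adjusted p-values.
#' @export
frequency_group_tests <- function(freq_table, control = "mock") {
  ft <- freq_table[freq_table$stim == "UNSTIM", , drop = FALSE]
  groups <- setdiff(unique(ft$group), control)
  rows <- list()
  for (tis in unique(ft$tissue)) {
    for (pop in unique(ft$population)) {
      sub <- ft[ft$tissue == tis & ft$population == pop, ]
      x0 <- sub$frequency[sub$group == control]
      gs <- split(sub$frequency, sub$group)
      an <- anova_oneway(gs)
      rows[[length(rows) + 1]] <- data.frame(
        tissue = tis, population = pop, comparison = "ANOVA",
        estimate = NA_real_, statistic = an$statistic, p_raw = an$p_raw,
        degenerate = an$degenerate)
      for (g in groups) {
        tt <- two_group_ttest(sub$frequency[sub$group == g], x0)
        rows[[length(rows) + 1]] <- data.frame(
          tissue = tis, population = pop,
          comparison = paste0(g, "_vs_", control), estimate = tt$estimate,
          statistic = tt$statistic, p_raw = tt$p_raw,
          degenerate = tt$degenerate)
      }
    }
  }
  out <- do.call(rbind, rows)
  pair <- out$comparison != "ANOVA"
  out$p_adj <- NA_real_
  out$p_adj[pair] <- bh_adjust(out$p_raw[pair], out$tissue[pair])
  out$p_adj[!pair] <- bh_adjust(out$p_raw[!pair], out$tissue[!pair])
  rownames(out) <- NULL
  out
}

#' log2 frequency ratios of vaccine groups versus mock
#'
#' @param freq_table output of [compute_frequencies()].
#' @param control control group label.
#' @return data.frame (`tissue`, `population`, `group`, `log2_ratio`);
#'   the control group's ratio is 0 by definition.
#' @export
log2_ratio_table <- function(freq_table, control = "mock") {
  ft <- freq_table[freq_table$stim == "UNSTIM", , drop = FALSE]
  agg <- stats::aggregate(frequency ~ tissue + population + group,
                          data = ft, FUN = mean)
  rows <- list()
  for (tis in unique(agg$tissue)) for (pop in unique(agg$population)) {
    sub <- agg[agg$tissue == tis & agg$population == pop, ]
    m0 <- sub$frequency[sub$group == control]
    for (g in unique(sub$group)) {
      v <- if (g == control) 0 else
        log2_vs_mock(sub$frequency[sub$group == g], m0)
      rows[[length(rows) + 1]] <- data.frame(
        tissue = tis, population = pop, group = g, log2_ratio = v)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Volcano table of stimulation responses
#'
#' Pooled over all treatment groups: per (tissue, stim, population,
#' marker), paired t-test of stimulated versus unstimulated arcsinh
#' medians across animals, the mean arcsinh change, and the volcano class
#' from the uncorrected p-value.
#'
#' @param responses output of [signaling_responses()].
#' @param p_cutoff,diff_cutoff volcano thresholds.
#' @return data.frame with one row per feature (`id` =
#'   population_marker).
#' @export
volcano_table <- function(responses, p_cutoff = 0.05, diff_cutoff = 0.1) {
  keys <- unique(responses[c("tissue", "stim", "population", "marker")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- responses[responses$tissue == keys$tissue[i] &
                       responses$stim == keys$stim[i] &
                       responses$population == keys$population[i] &
                       responses$marker == keys$marker[i], ]
    r <- sub$response[!is.na(sub$response)]
    if (length(r) < 2) {
      est <- if (length(r)) mean(r) else NA_real_
      p <- NA_real_
    } else if (stats::var(r) == 0) {
      est <- mean(r)
      p <- if (est == 0) 1 else 0
    } else {
      tt <- stats::t.test(r)
      est <- mean(r)
      p <- tt$p.value
    }
    data.frame(tissue = keys$tissue[i], stim = keys$stim[i],
               population = keys$population[i], marker = keys$marker[i],
               id = paste(keys$population[i], keys$marker[i], sep = "_"),
               n = length(r), change = est, p_raw = p)
  })
  out <- do.call(rbind, rows)
  out$class <- volcano_classify(out$change, out$p_raw, p_cutoff, diff_cutoff)
  rownames(out) <- NULL
  out
}

#' ANOVA and Z-scores for selected signaling features
#'
#' For each selected (tissue, stim, population, marker) feature: one-way
#' ANOVA of the per-animal responses across treatment groups with BH
#' adjustment within (tissue, stim), and per-group Z-scores against the
#' grand mean of all animal values.
#'
#' @param responses output of [signaling_responses()].
#' @param selected selected rows of the volcano/ranking table.
#' @param sd_type Z-score SD convention.
#' @return data.frame with one row per (feature, group).
#' @export
signaling_group_stats <- function(responses, selected,
                                  sd_type = "population") {
  rows <- list()
  for (i in seq_len(nrow(selected))) {
    sub <- responses[responses$tissue == selected$tissue[i] &
                       responses$stim == selected$stim[i] &
                       responses$population == selected$population[i] &
                       responses$marker == selected$marker[i] &
                       !is.na(responses$response), ]
    gs <- split(sub$response, sub$group)
    gs <- gs[lengths(gs) >= 2]
    if (length(gs) < 2) next
    an <- anova_oneway(gs)
    z <- group_zscores(gs, sd_type)
    rows[[length(rows) + 1]] <- data.frame(
      tissue = selected$tissue[i], stim = selected$stim[i],
      population = selected$population[i], marker = selected$marker[i],
      id = selected$id[i], group = names(z), zscore = unname(z),
      f_statistic = an$statistic, p_raw = an$p_raw)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(tissue = character(0), stim = character(0),
                      population = character(0), marker = character(0),
                      id = character(0), group = character(0),
                      zscore = numeric(0), f_statistic = numeric(0),
                      p_raw = numeric(0), p_adj = numeric(0)))
  first <- !duplicated(out[c("tissue", "stim", "id")])
  adj1 <- bh_adjust(out$p_raw[first],
                    paste(out$tissue[first], out$stim[first]))
  key <- paste(out$tissue, out$stim, out$id)
  out$p_adj <- adj1[match(key, key[first])]
  rownames(out) <- NULL
  out
}

#' Feature-versus-outcome correlation table
#'
#' Pools unstimulated population frequencies and the selected signaling
#' responses into one animal-level feature table and correlates each
#' feature with every clinical outcome (Pearson, BH per tissue x feature
#' family x outcome).
#'
#' @param freq_table,responses,selected,outcomes pipeline tables.
#' @return output of [correlate_outcomes()].
#' @export
outcome_correlation_table <- function(freq_table, responses, selected,
                                      outcomes) {
  fr <- freq_table[freq_table$stim == "UNSTIM", ]
  feat_f <- data.frame(animal_id = fr$animal_id, group = fr$group,
                       feature_id = paste(fr$tissue, fr$population, "freq",
                                          sep = "_"),
                       value = fr$frequency,
                       family = paste0("freq_", fr$tissue))
  sel_key <- paste(selected$tissue, selected$stim, selected$population,
                   selected$marker)
  rs <- responses[paste(responses$tissue, responses$stim,
                        responses$population, responses$marker) %in%
                    sel_key, ]
  feat_s <- data.frame(animal_id = rs$animal_id, group = rs$group,
                       feature_id = paste(rs$tissue, rs$stim, rs$population,
                                          rs$marker, sep = "_"),
                       value = rs$response,
                       family = paste0("signal_", rs$tissue))
  correlate_outcomes(rbind(feat_f, feat_s), outcomes)
}

#' Write pipeline result tables to CSV
#'
#' Always writes valid CSVs (headers even when empty).
#'
#' @param results list from [run_pipeline()].
#' @param outdir output directory (created if needed).
#' @return named vector of md5 checksums of the written files.
#' @export
report <- function(results, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("frequencies", "pseudo_counts", "responses", "group_tests",
              "log2_ratios", "volcano", "top_features", "zscores",
              "outcome_correlations", "yield")
  files <- character(0)
  for (nm in tables) {
    tab <- results[[nm]]
    if (is.null(tab)) next
    path <- file.path(outdir, paste0(nm, ".csv"))
    utils::write.csv(tab, path, row.names = FALSE)
    files[paste0(nm, ".csv")] <- unname(tools::md5sum(path))
  }
  files
}
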