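# Synthetic acquisition: event-level simulation of barcoded, bead-spiked
# samples, cell-cell doublets, CBC records and clinical outcomes.

#' Construct sample metadata
#'
#' @param animal_id animal identifier present in the truth object.
#' @param tissue,stim tissue and stimulation condition labels.
#' @param barcode_code integer 0/1 vector with exactly k ones (a row of a
#'   [barcode_scheme()] code matrix), or NULL for an unbarcoded acquisition.
#' @param batch_id pooled-batch identifier.
#' @return list of class `sample_meta`.
#' @export
sample_meta <- function(animal_id, tissue, stim, barcode_code = NULL,
                        batch_id = "batch1") {
  structure(list(animal_id = animal_id, tissue = tissue, stim = stim,
                 barcode_code = barcode_code, batch_id = batch_id),
            class = "sample_meta")
}

#' @noRd
validate_meta <- function(truth, meta) {
  allowed <- c("animal_id", "group", "tissue", "stim", "barcode_code",
               "batch_id")
  extra <- setdiff(names(meta), allowed)
  if (length(extra))
    cp_stop("unknown meta field(s): %s", paste(extra, collapse = ", "))
  i <- match(meta$animal_id, truth$animals$animal_id)
  if (is.na(i)) cp_stop("unknown animal '%s'", meta$animal_id)
  if (!meta$tissue %in% truth$config$tissues)
    cp_stop("unknown tissue '%s'", meta$tissue)
  if (!meta$stim %in% truth$config$stims)
    cp_stop("unknown stim '%s'", meta$stim)
  if (!is.null(meta$group) && meta$group != truth$animals$group[i])
    cp_stop("meta group '%s' does not match animal '%s'", meta$group,
            meta$animal_id)
  invisible(meta)
}

#' @noRd
new_cyto_events <- function(exprs, panel, meta = NULL, truth_labels = NULL) {
  structure(list(exprs = exprs, panel = panel, meta = meta,
                 truth_labels = truth_labels), class = "cyto_events")
}

#' @export
print.cyto_events <- function(x, ...) {
  cat(sprintf("cyto_events: %d events x %d channels%s\n", nrow(x$exprs),
              ncol(x$exprs),
              if (!is.null(x$truth_labels)) " (with truth sidecar)" else ""))
  invisible(x)
}

#' Number of events in an event matrix
#' @param x a `cyto_events` object.
#' @export
n_events <- function(x) nrow(x$exprs)

# Draw raw (untransformed, pre-drift) values for n cell events of given
# population labels under one sample's stimulation condition and barcode.
#' @noRd
sim_cell_raw <- function(truth, n, pop_labels, eff, code) {
  panel <- truth$panel
  markers <- colnames(truth$marker_loc)
  sig <- panel$marker[panel$role == "signaling"]
  mu <- truth$marker_loc[pop_labels, , drop = FALSE]
  mu[, sig] <- mu[, sig] + eff[pop_labels, sig, drop = FALSE]
  sdm <- truth$marker_sd[pop_labels, , drop = FALSE]
  z <- mu + matrix(stats::rnorm(n * length(markers)), n) * sdm
  bc <- truth$config$barcode
  nbc <- bc$n
  if (is.null(code)) code <- rep(0L, nbc)
  zb <- matrix(bc$lo + (bc$hi - bc$lo) * rep(code, each = n), n, nbc) +
    matrix(stats::rnorm(n * nbc, 0, bc$sd), n)
  bead_cfg <- truth$config$beads
  n_beadch <- sum(panel$role == "bead")
  zd <- matrix(stats::rnorm(n * n_beadch, 0, bead_cfg$off_sd), n)
  raw <- cbind(arcsinh_inverse(z, truth$cofactor),
               arcsinh_inverse(zb, truth$cofactor),
               arcsinh_inverse(zd, truth$cofactor))
  colnames(raw) <- c(panel$channel[panel$role %in% c("phenotype", "signaling")],
                     panel$channel[panel$role == "barcode"],
                     panel$channel[panel$role == "bead"])
  raw
}

# Raw values for n normalization-bead events: bead signature on the five
# bead channels, near-zero everywhere else.
#' @noRd
sim_bead_raw <- function(truth, n) {
  panel <- truth$panel
  bead_cfg <- truth$config$beads
  meas <- panel$channel[panel$role != "time"]
  raw <- matrix(0, n, length(meas), dimnames = list(NULL, meas))
  is_bead_ch <- meas %in% panel$channel[panel$role == "bead"]
  raw[, !is_bead_ch] <- arcsinh_inverse(
    matrix(stats::rnorm(n * sum(!is_bead_ch), 0, bead_cfg$off_sd), n),
    truth$cofactor)
  raw[, is_bead_ch] <- arcsinh_inverse(
    matrix(stats::rnorm(n * sum(is_bead_ch), bead_cfg$loc, bead_cfg$sd), n),
    truth$cofactor)
  raw
}

#' @noRd
draw_populations <- function(truth, animal_id, tissue, n) {
  f <- truth$animal_freqs[animal_id, tissue, ]
  probs <- c(f, other = 1 - sum(f))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# Assemble raw event rows into a timed, drift-affected acquisition.
#' @noRd
finalize_acquisition <- function(truth, raw, labels, meta) {
  n <- nrow(raw)
  perm <- sample.int(n)
  raw <- raw[perm, , drop = FALSE]
  rownames(raw) <- NULL   # population labels must never ride on the matrix
  labels <- labels[perm, , drop = FALSE]
  t <- sort(stats::runif(n, 0, truth$config$acquisition$window))
  raw <- raw * drift_multiplier(truth, t)
  exprs <- cbind(raw, Time = t)
  # column order follows the panel
  exprs <- exprs[, truth$panel$channel, drop = FALSE]
  rownames(labels) <- NULL
  new_cyto_events(exprs, truth$panel, meta, labels)
}

#' Simulate a single-sample acquisition
#'
#' Draws `n_events` events from the animal's population mixture for the
#' sample's tissue, applies the stimulation shifts of the sample's
#' condition to the signaling channels, writes the sample's barcode code
#' onto the palladium channels, intersperses `bead_fraction` normalization
#' bead events, assigns strictly increasing acquisition times and applies
#' the multiplicative sensitivity drift. True per-event labels (population,
#' bead status) are returned in the `truth_labels` sidecar, never in the
#' channel data.
#'
#' @param truth a `cyto_truth` object.
#' @param meta a [sample_meta()].
#' @param n_events total events to draw (cells + beads), >= 1.
#' @param bead_fraction fraction of events that are normalization beads,
#'   in [0, 0.2].
#' @param seed integer seed; default is derived deterministically from the
#'   truth seed and the sample metadata.
#' @return a `cyto_events` object.
#' @export
simulate_sample <- function(truth, meta, n_events = NULL, bead_fraction = 0.05,
                            seed = NULL) {
  stopifnot(inherits(truth, "cyto_truth"))
  validate_meta(truth, meta)
  n_events <- n_events %||% truth$config$acquisition$n_events
  if (n_events < 1) cp_stop("n_events must be >= 1")
  if (bead_fraction < 0 || bead_fraction > 0.2)
    cp_stop("bead_fraction must lie in [0, 0.2]")
  seed <- seed %||% derive_seed(truth$seed, "sample", meta$animal_id,
                                meta$tissue, meta$stim, n_events)
  sample_id <- paste(meta$animal_id, meta$tissue, meta$stim, sep = "_")
  with_seed(seed, {
    n_bead <- round(n_events * bead_fraction)
    n_cell <- n_events - n_bead
    pops <- draw_populations(truth, meta$animal_id, meta$tissue, n_cell)
    eff <- effective_stim_effects(truth, meta$animal_id, meta$tissue,
                                  meta$stim)
    raw <- rbind(sim_cell_raw(truth, n_cell, pops, eff, meta$barcode_code),
                 sim_bead_raw(truth, n_bead))
    labels <- data.frame(
      sample_id = c(rep(sample_id, n_cell), rep(NA_character_, n_bead)),
      population = c(pops, rep(NA_character_, n_bead)),
      is_bead = rep(c(FALSE, TRUE), c(n_cell, n_bead)),
      is_doublet = FALSE)
    finalize_acquisition(truth, raw, labels, meta)
  })
}

#' Simulate cell-cell doublet events
#'
#' Each doublet is the channel-wise raw-intensity sum of two independent
#' single-cell events carrying two distinct barcode codes, so more than k
#' barcode channels are high and a k-of-n debarcoder must reject it.
#'
#' @param truth a `cyto_truth` object.
#' @param meta_a,meta_b metadata of the two contributing samples; their
#'   barcode codes must differ.
#' @param n number of doublet events (0 allowed).
#' @param seed integer seed (default derived from truth).
#' @return a `cyto_events` object with `is_doublet = TRUE` sidecar labels.
#' @export
simulate_doublet_events <- function(truth, meta_a, meta_b, n, seed = NULL) {
  validate_meta(truth, meta_a)
  validate_meta(truth, meta_b)
  if (identical(meta_a$barcode_code, meta_b$barcode_code))
    cp_stop("doublet samples must carry distinct barcode codes")
  seed <- seed %||% derive_seed(truth$seed, "doublet", meta_a$animal_id,
                                meta_b$animal_id, n)
  panel <- truth$panel
  meas <- panel$channel[panel$role != "time"]
  with_seed(seed, {
    if (n == 0) {
      exprs <- matrix(numeric(0), 0, nrow(panel),
                      dimnames = list(NULL, panel$channel))
      return(new_cyto_events(exprs, panel, meta_a,
                             data.frame(sample_id = character(0),
                                        population = character(0),
                                        is_bead = logical(0),
                                        is_doublet = logical(0))))
    }
    raw_pair <- function(meta) {
      pops <- draw_populations(truth, meta$animal_id, meta$tissue, n)
      eff <- effective_stim_effects(truth, meta$animal_id, meta$tissue,
                                    meta$stim)
      sim_cell_raw(truth, n, pops, eff, meta$barcode_code)
    }
    raw <- raw_pair(meta_a)[, meas] + raw_pair(meta_b)[, meas]
    labels <- data.frame(sample_id = NA_character_,
                         population = NA_character_,
                         is_bead = FALSE, is_doublet = TRUE)[rep(1, n), ]
    finalize_acquisition(truth, raw, labels, meta_a)
  })
}

#' Simulate a pooled barcoded batch
#'
#' Pools up to `choose(n, k)` barcoded samples into one acquisition stream
#' with spiked normalization beads and cell-cell doublets, a common
#' acquisition time axis and shared sensitivity drift — the raw input the
#' normalization + debarcoding stages expect.
#'
#' @param truth a `cyto_truth` object.
#' @param metas list of [sample_meta()] with distinct barcode codes and
#'   unique (animal, tissue, stim) keys.
#' @param n_events events per sample (cells).
#' @param bead_fraction fraction of total events that are beads.
#' @param doublet_fraction fraction of total cell events added as doublets.
#' @param seed integer seed (default derived from truth and batch id).
#' @return a `cyto_events` object with per-event truth sidecar
#'   (`sample_id`, `population`, `is_bead`, `is_doublet`).
#' @export
simulate_batch <- function(truth, metas, n_events = 5000,
                           bead_fraction = 0.05, doublet_fraction = 0.02,
                           seed = NULL) {
  stopifnot(length(metas) >= 1)
  for (m in metas) validate_meta(truth, m)
  keys <- vapply(metas, function(m)
    paste(m$animal_id, m$tissue, m$stim, sep = "_"), "")
  if (anyDuplicated(keys))
    cp_stop("duplicate (animal, tissue, stim) within batch")
  codes <- vapply(metas, function(m) paste(m$barcode_code, collapse = ""), "")
  if (anyDuplicated(codes)) cp_stop("duplicate barcode codes within batch")
  batch_id <- metas[[1]]$batch_id
  seed <- seed %||% derive_seed(truth$seed, "batch", batch_id, n_events)
  with_seed(seed, {
    raws <- vector("list", length(metas))
    labs <- vector("list", length(metas))
    for (i in seq_along(metas)) {
      m <- metas[[i]]
      pops <- draw_populations(truth, m$animal_id, m$tissue, n_events)
      eff <- effective_stim_effects(truth, m$animal_id, m$tissue, m$stim)
      raws[[i]] <- sim_cell_raw(truth, n_events, pops, eff, m$barcode_code)
      labs[[i]] <- data.frame(sample_id = keys[i], population = pops,
                              is_bead = FALSE, is_doublet = FALSE)
    }
    n_cells <- n_events * length(metas)
    n_beads <- round(bead_fraction * n_cells)
    n_doub <- round(doublet_fraction * n_cells)
    raw <- do.call(rbind, raws)
    labels <- do.call(rbind, labs)
    if (n_beads > 0) {
      raw <- rbind(raw, sim_bead_raw(truth, n_beads))
      labels <- rbind(labels, data.frame(
        sample_id = NA_character_, population = NA_character_,
        is_bead = TRUE, is_doublet = FALSE)[rep(1, n_beads), ])
    }
    if (n_doub > 0 && length(metas) >= 2) {
      ia <- sample.int(length(metas), n_doub, replace = TRUE)
      shift <- sample.int(length(metas) - 1, n_doub, replace = TRUE)
      ib <- 1 + (ia - 1 + shift) %% length(metas)
      meas <- truth$panel$channel[truth$panel$role != "time"]
      draw_one <- function(idx) {
        m <- metas[[idx]]
        pop <- draw_populations(truth, m$animal_id, m$tissue, 1)
        eff <- effective_stim_effects(truth, m$animal_id, m$tissue, m$stim)
        sim_cell_raw(truth, 1, pop, eff, m$barcode_code)[, meas]
      }
      doub <- t(vapply(seq_len(n_doub),
                       function(j) draw_one(ia[j]) + draw_one(ib[j]),
                       numeric(length(meas))))
      colnames(doub) <- meas
      raw <- rbind(raw, doub)
      labels <- rbind(labels, data.frame(
        sample_id = NA_character_, population = NA_character_,
        is_bead = FALSE, is_doublet = TRUE)[rep(1, n_doub), ])
    }
    finalize_acquisition(truth, raw, labels,
                         list(batch_id = batch_id, keys = keys))
  })
}

#' Simulate complete blood count records
#'
#' CBC values are drawn so that the invariant
#' `wbc >= neutrophils + eosinophils >= 0` holds by construction (counts are
#' fractions of the drawn WBC).
#'
#' @param truth a `cyto_truth` object.
#' @param animal_id one or more animal ids; default all animals.
#' @return data.frame with columns `animal_id`, `wbc`, `neutrophils`,
#'   `eosinophils` (cells/uL).
#' @export
simulate_cbc <- function(truth, animal_id = truth$animals$animal_id) {
  idx <- match(animal_id, truth$animals$animal_id)
  if (anyNA(idx)) cp_stop("unknown animal '%s'", animal_id[is.na(idx)][1])
  cfg <- truth$config$cbc
  rows <- lapply(animal_id, function(a) {
    with_seed(derive_seed(truth$seed, "cbc", a), {
      wbc <- max(2000, stats::rnorm(1, cfg$wbc_mean, cfg$wbc_sd))
      nf <- min(0.90, max(0.05, stats::rnorm(1, cfg$neut_frac, cfg$neut_sd)))
      ef <- min(0.08, max(0, stats::rnorm(1, cfg$eos_frac, cfg$eos_sd)))
      data.frame(animal_id = a, wbc = wbc, neutrophils = wbc * nf,
                 eosinophils = wbc * ef)
    })
  })
  do.call(rbind, rows)
}

#' Simulate clinical outcome records
#'
#' Outcomes are linear functions of the animal's latent severity plus
#' Gaussian noise, clipped to their clinical ranges: lung viral RNA
#' (log10 copies / 30 mg tissue), lung pathology score (0-4) and lung
#' radiograph score (0-3). The mock group has higher mean severity by
#' construction, so outcomes separate by group.
#'
#' @inheritParams simulate_cbc
#' @return data.frame with columns `animal_id`, `viral_rna_log10`,
#'   `pathology_score`, `radiograph_score`.
#' @export
simulate_outcomes <- function(truth, animal_id = truth$animals$animal_id) {
  idx <- match(animal_id, truth$animals$animal_id)
  if (anyNA(idx)) cp_stop("unknown animal '%s'", animal_id[is.na(idx)][1])
  links <- truth$config$outcome_links
  rows <- lapply(seq_along(animal_id), function(j) {
    a <- animal_id[j]
    sev <- truth$animals$severity[idx[j]]
    with_seed(derive_seed(truth$seed, "outcome", a), {
      val <- vapply(links, function(lk) {
        v <- lk$intercept + lk$slope * sev +
          if (lk$sd > 0) stats::rnorm(1, 0, lk$sd) else 0
        min(lk$range[2], max(lk$range[1], v))
      }, 0)
      data.frame(animal_id = a, viral_rna_log10 = val[["viral_rna"]],
                 pathology_score = val[["pathology"]],
                 radiograph_score = val[["radiograph"]])
    })
  })
  do.call(rbind, rows)
}
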