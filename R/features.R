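# Feature extraction: population frequencies (% of mononuclear cells),
# CBC-anchored pseudo-absolute counts, arcsinh-median signaling levels and
# stimulation responses.

# A "gated sample" is list(meta = list(animal_id, group, tissue, stim),
# gate = gate_result). The pipeline produces these; tests can build them
# directly.

#' Population frequencies as percent of mononuclear cells
#'
#' `value = 100 * population count / mononuclear total` per sample.
#' Samples with zero mononuclear events are excluded with a warning.
#'
#' @param gated_samples list of gated samples (see Details in
#'   [signaling_features()]).
#' @return data.frame (`animal_id`, `group`, `tissue`, `stim`,
#'   `population`, `frequency` in percent).
#' @export
compute_frequencies <- function(gated_samples) {
  rows <- lapply(gated_samples, function(s) {
    if (s$gate$mononuclear_total == 0) {
      cp_warn("sample %s/%s/%s has zero mononuclear events; excluded",
              s$meta$animal_id, s$meta$tissue, s$meta$stim)
      return(NULL)
    }
    data.frame(animal_id = s$meta$animal_id, group = s$meta$group,
               tissue = s$meta$tissue, stim = s$meta$stim,
               population = names(s$gate$counts),
               frequency = 100 * as.numeric(s$gate$counts) /
                 s$gate$mononuclear_total)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' CBC-anchored pseudo-absolute counts (cells/uL of blood)
#'
#' The CBC mononuclear count is `wbc - (neutrophils + eosinophils)` and is
#' assumed to correspond to the CD45+CD66- mononuclear fraction; each
#' population's pseudo-absolute count is that value times the population
#' frequency. Computed for PBMC samples in the unstimulated condition
#' only. Animals without a CBC record get flagged missing rows.
#'
#' @param freq_table output of [compute_frequencies()].
#' @param cbc data.frame (`animal_id`, `wbc`, `neutrophils`,
#'   `eosinophils`).
#' @return data.frame (`animal_id`, `group`, `population`, `cells_per_ul`,
#'   `missing`).
#' @export
pseudo_absolute_counts <- function(freq_table, cbc) {
  ft <- freq_table[freq_table$tissue == "PBMC" &
                     freq_table$stim == "UNSTIM", , drop = FALSE]
  i <- match(ft$animal_id, cbc$animal_id)
  mono <- cbc$wbc[i] - (cbc$neutrophils[i] + cbc$eosinophils[i])
  if (any(mono < 0, na.rm = TRUE))
    cp_stop("CBC invariant violated: wbc < neutrophils + eosinophils for %s",
            paste(unique(ft$animal_id[which(mono < 0)]), collapse = ", "))
  out <- data.frame(animal_id = ft$animal_id, group = ft$group,
                    population = ft$population,
                    cells_per_ul = mono * ft$frequency / 100,
                    missing = is.na(i))
  rownames(out) <- NULL
  out
}

#' Correct parent frequencies for reported nested subpopulations
#'
#' For every reported parent with reported children, the corrected parent
#' frequency is the parent minus the sum of its reported children (e.g.
#' total B cells minus IgM+ B cells); children are unchanged. Violated
#' containment (children summing above the parent) is an error.
#'
#' @param freq_table output of [compute_frequencies()].
#' @param tree the `gate_tree` that produced the counts.
#' @return `freq_table` with corrected parent values.
#' @export
nested_corrected_frequencies <- function(freq_table, tree) {
  out <- freq_table
  parents <- unique(vapply(tree$reported, function(nm)
    reported_parent(tree, nm), ""))
  parents <- setdiff(parents, "")
  key <- interaction(out$animal_id, out$tissue, out$stim, drop = TRUE)
  for (p in parents) {
    kids <- tree$reported[vapply(tree$reported, function(nm)
      identical(reported_parent(tree, nm), p), TRUE)]
    for (k in levels(key)) {
      rows <- key == k
      pv <- out$frequency[rows & out$population == p]
      kv <- sum(out$frequency[rows & out$population %in% kids])
      if (!length(pv)) next
      if (kv > pv + 1e-9)
        cp_stop("containment violated: children of '%s' sum to %.3f > %.3f",
                p, kv, pv)
      out$frequency[rows & out$population == p] <- pv - kv
    }
  }
  out
}

#' Median arcsinh-transformed signal for a gated population
#'
#' @param events `cyto_events` or matrix.
#' @param population_mask logical event mask (population membership).
#' @param marker signaling marker short name (or channel name).
#' @param cofactor arcsinh cofactor (default 5).
#' @param min_cells minimum events for a stable median; below it the value
#'   is flagged missing (NA).
#' @return median of `arcsinh(x/cofactor)` over the masked events, or NA.
#' @export
arcsinh_median <- function(events, population_mask, marker, cofactor = 5,
                           min_cells = 20) {
  stopifnot(cofactor > 0)
  exprs <- get_exprs(events)
  ch <- if (marker %in% colnames(exprs)) marker else
    marker_to_channel(get_panel(events), marker)
  if (sum(population_mask) < min_cells) return(NA_real_)
  stats::median(arcsinh_transform(exprs[population_mask, ch], cofactor))
}

#' Per-sample signaling medians for all populations and markers
#'
#' @param gated_samples list of entries `list(meta, gate, events)` where
#'   `meta` carries `animal_id`, `group`, `tissue`, `stim`; `gate` is an
#'   [apply_gates()] result; `events` the sample's `cyto_events`.
#' @param markers signaling marker names (default: panel role
#'   `"signaling"`).
#' @param cofactor,min_cells see [arcsinh_median()].
#' @return long data.frame (`animal_id`, `group`, `tissue`, `stim`,
#'   `population`, `marker`, `median`, `n_cells`); `median` is NA when the
#'   population has fewer than `min_cells` events.
#' @export
signaling_features <- function(gated_samples, markers = NULL, cofactor = 5,
                               min_cells = 20) {
  rows <- lapply(gated_samples, function(s) {
    panel <- s$events$panel
    mk <- markers %||% panel$marker[panel$role == "signaling"]
    chans <- marker_to_channel(panel, mk)
    pops <- s$gate$tree$reported
    z <- arcsinh_transform(s$events$exprs[, chans, drop = FALSE], cofactor)
    res <- lapply(pops, function(p) {
      mask <- s$gate$membership[, p]
      n <- sum(mask)
      med <- if (n >= min_cells)
        apply(z[mask, , drop = FALSE], 2, stats::median)
      else rep(NA_real_, length(mk))
      data.frame(animal_id = s$meta$animal_id, group = s$meta$group,
                 tissue = s$meta$tissue, stim = s$meta$stim,
                 population = p, marker = mk, median = unname(med),
                 n_cells = n)
    })
    do.call(rbind, res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stimulation response on the arcsinh scale
#'
#' `stim - unstim` difference of matched medians; missing if either side
#' is missing.
#'
#' @param stim_median,unstim_median numeric vectors (recycled).
#' @return numeric vector of responses.
#' @export
stim_response <- function(stim_median, unstim_median) {
  stim_median - unstim_median
}

#' Stimulation responses for a signaling feature table
#'
#' Joins each stimulated row of a [signaling_features()] table with the
#' matched unstimulated row for the same (animal, tissue, population,
#' marker) and computes the arcsinh response.
#'
#' @param sig_table output of [signaling_features()].
#' @param unstim label of the unstimulated condition.
#' @return data.frame of stimulated rows with a `response` column (NA when
#'   either side is missing).
#' @export
signaling_responses <- function(sig_table, unstim = "UNSTIM") {
  base <- sig_table[sig_table$stim == unstim, , drop = FALSE]
  out <- sig_table[sig_table$stim != unstim, , drop = FALSE]
  key <- function(d) paste(d$animal_id, d$tissue, d$population, d$marker,
                           sep = "\r")
  i <- match(key(out), key(base))
  out$response <- stim_response(out$median, base$median[i])
  rownames(out) <- NULL
  out
}
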