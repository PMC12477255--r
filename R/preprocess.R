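# Preprocessing: bead identification, bead-standard sensitivity
# normalization (sliding-window medians), k-of-n barcode assignment with
# separation cutoff, and Mahalanobis purity filtering.

#' @noRd
get_exprs <- function(events) {
  if (inherits(events, "cyto_events")) events$exprs else events
}

#' Subset a cyto_events object by event index or mask
#'
#' Keeps the panel, metadata and truth sidecar aligned with the retained
#' events.
#'
#' @param events a `cyto_events` object.
#' @param i logical mask or integer index over events.
#' @return a `cyto_events` object.
#' @export
subset_events <- function(events, i) {
  stopifnot(inherits(events, "cyto_events"))
  new_cyto_events(events$exprs[i, , drop = FALSE], events$panel,
                  events$meta,
                  if (!is.null(events$truth_labels))
                    events$truth_labels[i, , drop = FALSE])
}

#' @noRd
get_panel <- function(events, panel = NULL) {
  if (!is.null(panel)) return(panel)
  if (inherits(events, "cyto_events")) return(events$panel)
  cp_stop("a panel is required when events are a bare matrix")
}

# Otsu threshold (maximal between-class variance) on a numeric vector.
#' @noRd
otsu_threshold <- function(z, n_bins = 256) {
  r <- range(z)
  if (diff(r) == 0) return(NA_real_)
  h <- tabulate(pmin(n_bins, 1L + floor((z - r[1]) / diff(r) * n_bins)),
                n_bins)
  mids <- r[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(r)
  w <- cumsum(h)
  m <- cumsum(h * mids)
  w1 <- w[-n_bins]; w2 <- w[n_bins] - w1
  ok <- w1 > 0 & w2 > 0
  if (!any(ok)) return(NA_real_)
  mu1 <- m[-n_bins] / w1
  mu2 <- (m[n_bins] - m[-n_bins]) / w2
  bc <- w1 * w2 * (mu1 - mu2)^2
  bc[!ok] <- -Inf
  mids[which.max(bc)]
}

#' Identify normalization-bead events
#'
#' An event is flagged as a bead iff it exceeds the data-driven threshold
#' on every bead channel. Per channel the threshold is the valley between
#' the background and bead intensity modes (maximal between-class variance
#' on the arcsinh scale); a channel whose events are all in a single high
#' mode counts as all-above-threshold, and when no clear bead mode exists
#' a fallback quantile of the positive events is tried. If some bead
#' channel shows no bead signal at all, an empty mask is returned with a
#' warning.
#'
#' @param events `cyto_events` or numeric matrix.
#' @param bead_channels channel names; default: panel channels with role
#'   `"bead"`.
#' @param min_quantile fallback quantile of positive events used when no
#'   valley is found.
#' @param cofactor arcsinh cofactor.
#' @return logical mask, one entry per event.
#' @export
identify_beads <- function(events, bead_channels = NULL, min_quantile = 0.98,
                           cofactor = 5) {
  exprs <- get_exprs(events)
  if (is.null(bead_channels)) {
    panel <- get_panel(events)
    bead_channels <- panel$channel[panel$role == "bead"]
  }
  if (length(bead_channels) < 1) cp_stop("at least one bead channel required")
  missing_ch <- setdiff(bead_channels, colnames(exprs))
  if (length(missing_ch))
    cp_stop("bead channel(s) not in events: %s",
            paste(missing_ch, collapse = ", "))
  n <- nrow(exprs)
  if (n == 0) return(logical(0))
  # a bead mode must sit well above background on the arcsinh scale
  hi_level <- 2
  mask <- rep(TRUE, n)
  for (ch in bead_channels) {
    z <- arcsinh_transform(exprs[, ch], cofactor)
    t <- otsu_threshold(z)
    ok_split <- FALSE
    if (!is.na(t)) {
      hi <- z > t
      if (sum(hi) > 0 && sum(!hi) > 0 &&
          (mean(z[hi]) - mean(z[!hi])) >= 1 && stats::median(z[hi]) >= hi_level)
        ok_split <- TRUE
    }
    if (!ok_split) {
      if (stats::median(z) >= hi_level) {
        hi <- rep(TRUE, n)      # single high mode: whole channel is bead-like
      } else {
        pos <- z[exprs[, ch] > 0]
        t <- if (length(pos)) stats::quantile(pos, min_quantile) else Inf
        hi <- z > t
        if (!any(hi) || stats::median(z[hi]) < hi_level) {
          cp_warn("no bead mode detected on channel %s; returning empty mask",
                  ch)
          return(rep(FALSE, n))
        }
      }
    }
    mask <- mask & hi
  }
  mask
}

#' Fit bead-standard normalization factors
#'
#' Implements sliding-window median bead normalization: bead events are
#' sorted by acquisition time, the per-channel median is computed in
#' overlapping windows of `window_size` beads, and the correction
#' multiplier at each window knot is `reference / local median`. Between
#' knots the multiplier is linearly interpolated; beyond the first/last
#' knot it is held flat. The reference defaults to the global bead median
#' of this run; pass the medians of all pooled batches to normalize across
#' batches.
#'
#' @param bead_events `cyto_events` or matrix containing only bead events,
#'   with a `Time` column.
#' @param window_size beads per window (default 500).
#' @param channels channels to fit (default: bead channels of the panel).
#' @param reference optional named per-channel reference medians.
#' @return object of class `norm_factors`: `knots` (times), `multipliers`
#'   (knots x channels), `global` (geometric-mean multiplier applied to
#'   channels without their own fit), `reference`.
#' @export
fit_normalization <- function(bead_events, window_size = 500,
                              channels = NULL, reference = NULL) {
  exprs <- get_exprs(bead_events)
  if (is.null(channels)) {
    panel <- get_panel(bead_events)
    channels <- panel$channel[panel$role == "bead"]
  }
  if (!"Time" %in% colnames(exprs)) cp_stop("bead events lack a Time channel")
  if (nrow(exprs) < window_size)
    cp_stop("need at least window_size (%d) bead events, got %d",
            window_size, nrow(exprs))
  exprs <- exprs[order(exprs[, "Time"]), , drop = FALSE]
  n <- nrow(exprs)
  step <- max(1, floor(window_size / 2))
  starts <- unique(c(seq(1, n - window_size + 1, by = step),
                     n - window_size + 1))
  knots <- numeric(length(starts))
  med <- matrix(0, length(starts), length(channels),
                dimnames = list(NULL, channels))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + window_size - 1)
    knots[i] <- stats::median(exprs[idx, "Time"])
    med[i, ] <- apply(exprs[idx, channels, drop = FALSE], 2, stats::median)
  }
  if (any(med == 0)) {
    bad <- which(med == 0, arr.ind = TRUE)[1, ]
    cp_stop("local bead median is zero for channel %s in window %d",
            channels[bad[2]], bad[1])
  }
  if (is.null(reference)) {
    reference <- apply(exprs[, channels, drop = FALSE], 2, stats::median)
  } else {
    if (!all(channels %in% names(reference)))
      cp_stop("reference must name every fitted channel")
    reference <- reference[channels]
  }
  mult <- sweep(1 / med, 2, reference, `*`)
  keep <- !duplicated(knots)
  knots <- knots[keep]
  mult <- mult[keep, , drop = FALSE]
  o <- order(knots)
  structure(list(knots = knots[o],
                 multipliers = mult[o, , drop = FALSE],
                 global = exp(rowMeans(log(mult[o, , drop = FALSE]))),
                 reference = reference),
            class = "norm_factors")
}

#' @export
print.norm_factors <- function(x, ...) {
  cat(sprintf("norm_factors: %d knots over [%.1f, %.1f]s, %d channels\n",
              length(x$knots), min(x$knots), max(x$knots),
              ncol(x$multipliers)))
  invisible(x)
}

#' Apply normalization factors to an event stream
#'
#' Every measurement channel is multiplied by its time-interpolated
#' correction: channels with their own fitted multiplier use it, all
#' remaining channels use the global (geometric-mean) sensitivity
#' correction. The time channel is untouched.
#'
#' @param events `cyto_events` or matrix with a `Time` column.
#' @param factors a `norm_factors` object.
#' @return same type as `events`, corrected.
#' @export
apply_normalization <- function(events, factors) {
  stopifnot(inherits(factors, "norm_factors"))
  if (any(factors$multipliers <= 0) || any(factors$global <= 0))
    cp_stop("normalization multipliers must be strictly positive")
  if (is.unsorted(factors$knots, strictly = TRUE))
    cp_stop("normalization knots must be strictly increasing")
  exprs <- get_exprs(events)
  if (!"Time" %in% colnames(exprs)) cp_stop("events lack a Time channel")
  fitted_ch <- colnames(factors$multipliers)
  if (!all(fitted_ch %in% colnames(exprs)))
    cp_stop("channel mismatch: fitted channel(s) %s absent from events",
            paste(setdiff(fitted_ch, colnames(exprs)), collapse = ", "))
  t <- exprs[, "Time"]
  interp <- function(y) {
    if (length(factors$knots) == 1) rep(y, length(t))
    else stats::approx(factors$knots, y, xout = t, rule = 2)$y
  }
  g <- interp(factors$global)
  for (ch in setdiff(colnames(exprs), "Time")) {
    m <- if (ch %in% fitted_ch) interp(factors$multipliers[, ch]) else g
    exprs[, ch] <- exprs[, ch] * m
  }
  if (inherits(events, "cyto_events")) {
    events$exprs <- exprs
    events
  } else exprs
}

# Percentile-rescale barcode channels to [0, 1] within the run. Rescaling
# happens on the arcsinh scale (like the intensities the code levels are
# defined on), which makes the separation statistic insensitive to the
# multiplicative spread of raw ion counts.
#' @noRd
rescale_barcode <- function(exprs, channels, probs = c(0.01, 0.99),
                            cofactor = 5) {
  r <- matrix(0, nrow(exprs), length(channels),
              dimnames = list(NULL, channels))
  z <- arcsinh_transform(exprs[, channels, drop = FALSE], cofactor)
  q <- apply(z, 2, stats::quantile, probs = probs, names = FALSE)
  # midpoint of the joint intensity range, for degenerate channels
  mid <- (min(q[1, ]) + max(q[2, ])) / 2
  for (j in seq_along(channels)) {
    spread <- q[2, j] - q[1, j]
    if (spread >= 1) {
      r[, j] <- pmin(1, pmax(0, (z[, j] - q[1, j]) / spread))
    } else {
      # channel without high/low structure in this run (e.g. a code
      # position used by no pooled sample): constant, never stretched noise
      r[, j] <- as.numeric(stats::median(z[, j]) > mid)
    }
  }
  r
}

#' Assign events to samples by k-of-n barcode code
#'
#' Per event: (1) each barcode channel is rescaled to [0, 1] by its 1st-99th
#' percentile range within the run; (2) the separation is the difference
#' between the k-th and (k+1)-th highest rescaled intensities; (3) the
#' preliminary code flags the k highest channels and is looked up in the
#' scheme. Events whose code is not in the scheme (`"bad_code"`, e.g.
#' doublets, which light up more than k channels and therefore separate
#' poorly) or whose separation falls below `separation_cutoff`
#' (`"low_separation"`) are left unassigned.
#'
#' @param events `cyto_events` or matrix.
#' @param scheme a [barcode_scheme()].
#' @param separation_cutoff minimum separation on rescaled units.
#' @param barcode_channels channel names (default: panel role `"barcode"`).
#' @return object of class `barcode_assignment`: data.frame with columns
#'   `sample_id` (NA when unassigned), `separation`, `mahalanobis` (NA
#'   until filtering), `reason` (`"assigned"`, `"low_separation"`,
#'   `"bad_code"`, later `"distance"`); the rescaled barcode matrix is kept
#'   as an attribute for the Mahalanobis filter.
#' @export
assign_barcodes <- function(events, scheme, separation_cutoff = 0.3,
                            barcode_channels = NULL) {
  stopifnot(inherits(scheme, "barcode_scheme"))
  exprs <- get_exprs(events)
  if (is.null(barcode_channels)) {
    panel <- get_panel(events)
    barcode_channels <- panel$channel[panel$role == "barcode"]
  }
  if (length(barcode_channels) != scheme$n)
    cp_stop("scheme expects %d barcode channels, %d supplied", scheme$n,
            length(barcode_channels))
  n <- nrow(exprs)
  k <- scheme$k
  r <- rescale_barcode(exprs, barcode_channels)
  # vectorized selection of the k+1 largest values per event
  work <- r
  topvals <- matrix(0, n, k + 1)
  member <- matrix(FALSE, n, scheme$n)
  if (n > 0) {
    for (i in seq_len(k + 1)) {
      j <- max.col(work, ties.method = "first")
      idx <- cbind(seq_len(n), j)
      topvals[, i] <- work[idx]
      if (i <= k) member[idx] <- TRUE
      work[idx] <- -Inf
    }
  }
  separation <- if (n > 0) topvals[, k] - topvals[, k + 1] else numeric(0)
  code_str <- apply(member, 1, function(b) paste(as.integer(b), collapse = ""))
  scheme_str <- apply(scheme$codes, 1, paste, collapse = "")
  hit <- match(code_str, scheme_str)
  sample_id <- rownames(scheme$codes)[hit]
  reason <- rep("assigned", n)
  reason[is.na(hit)] <- "bad_code"
  low <- !is.na(hit) & separation < separation_cutoff
  reason[low] <- "low_separation"
  sample_id[reason != "assigned"] <- NA_character_
  out <- data.frame(sample_id = if (n) sample_id else character(0),
                    separation = separation,
                    mahalanobis = rep(NA_real_, n),
                    reason = if (n) reason else character(0))
  structure(out, class = c("barcode_assignment", "data.frame"),
            rescaled = r, scheme = scheme,
            separation_cutoff = separation_cutoff)
}

#' Mahalanobis purity filter on barcode assignments
#'
#' For each assigned sample the mean and covariance of the rescaled
#' barcode channels are estimated from that sample's events (single pass);
#' events farther than `max_dist` from their sample centroid are set to
#' unassigned with reason `"distance"`. The default convention is the
#' squared Mahalanobis distance (`squared = TRUE`, threshold 30); set
#' `squared = FALSE` to threshold the plain distance.
#'
#' @param events event matrix the assignment came from (unused beyond
#'   sanity checks; distances are computed on the stored rescaled matrix).
#' @param assignment a `barcode_assignment`.
#' @param max_dist distance threshold.
#' @param squared whether `max_dist` applies to squared distances.
#' @return updated `barcode_assignment` with distances recorded.
#' @export
mahalanobis_filter <- function(events, assignment, max_dist = 30,
                               squared = TRUE) {
  stopifnot(inherits(assignment, "barcode_assignment"))
  r <- attr(assignment, "rescaled")
  if (nrow(r) != nrow(assignment))
    cp_stop("assignment does not match events")
  p <- ncol(r)
  for (sid in unique(assignment$sample_id[!is.na(assignment$sample_id)])) {
    idx <- which(!is.na(assignment$sample_id) & assignment$sample_id == sid)
    if (length(idx) < p + 1) {
      cp_warn("sample %s has %d events (< %d); Mahalanobis filter skipped",
              sid, length(idx), p + 1)
      next
    }
    x <- r[idx, , drop = FALSE]
    mu <- colMeans(x)
    S <- stats::cov(x)
    ev <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
    if (ev < 1e-12) {
      eps <- 1e-6 * mean(diag(S))
      if (eps <= 0) eps <- 1e-12
      S <- S + diag(eps, p)
      cp_warn("singular barcode covariance for sample %s; regularized", sid)
    }
    d2 <- stats::mahalanobis(x, mu, S)
    d <- if (squared) d2 else sqrt(d2)
    assignment$mahalanobis[idx] <- d
    drop <- idx[d > max_dist]
    assignment$sample_id[drop] <- NA_character_
    assignment$reason[drop] <- "distance"
  }
  assignment
}

#' Debarcode a pooled event stream
#'
#' Composes [assign_barcodes()] and [mahalanobis_filter()] and splits the
#' input into disjoint per-sample event matrices plus an unassigned pool,
#' with a yield report counting events by outcome.
#'
#' @param events `cyto_events` (pooled batch).
#' @param scheme a [barcode_scheme()].
#' @param separation_cutoff,max_dist,squared see [assign_barcodes()] and
#'   [mahalanobis_filter()].
#' @param apply_mahalanobis logical; apply the purity filter.
#' @return list with `samples` (named list of `cyto_events`, truth sidecar
#'   rows carried along when present), `assignment`, `yield` (data.frame of
#'   per-reason counts and fractions) and `unassigned` (row indices).
#' @export
debarcode <- function(events, scheme, separation_cutoff = 0.3,
                      max_dist = 30, squared = TRUE,
                      apply_mahalanobis = TRUE) {
  asg <- assign_barcodes(events, scheme, separation_cutoff)
  if (apply_mahalanobis)
    asg <- mahalanobis_filter(events, asg, max_dist, squared)
  exprs <- get_exprs(events)
  panel <- get_panel(events)
  labels <- if (inherits(events, "cyto_events")) events$truth_labels else NULL
  samples <- list()
  for (sid in rownames(attr(asg, "scheme")$codes)) {
    idx <- which(!is.na(asg$sample_id) & asg$sample_id == sid)
    samples[[sid]] <- new_cyto_events(
      exprs[idx, , drop = FALSE], panel, list(sample_id = sid),
      if (!is.null(labels)) labels[idx, , drop = FALSE])
  }
  tab <- table(factor(asg$reason, levels = c("assigned", "low_separation",
                                             "bad_code", "distance")))
  yield <- data.frame(reason = names(tab), events = as.integer(tab),
                      fraction = as.integer(tab) / max(1, nrow(asg)))
  list(samples = samples, assignment = asg, yield = yield,
       unassigned = which(is.na(asg$sample_id)))
}
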