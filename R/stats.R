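# Statistical layer: group tests with BH correction, volcano
# classification, combined-rank feature selection, group Z-scores, log2
# ratios versus control and clinical-outcome correlations.

#' Two-group Student t-test
#'
#' Two-sided equal-variance Student t for unpaired data; one-sample t on
#' the differences for paired data. Degenerate inputs (zero variance) are
#' flagged: zero variance with zero mean difference gives t = 0, p = 1.
#'
#' @param x,y numeric vectors (>= 2 values each; equal length if paired).
#' @param paired logical.
#' @return data.frame row: `estimate` (mean(x) - mean(y)), `statistic`,
#'   `df`, `p_raw`, `degenerate`.
#' @export
two_group_ttest <- function(x, y, paired = FALSE) {
  if (paired && length(x) != length(y))
    cp_stop("paired test requires equal-length vectors")
  if (length(x) < 2 || length(y) < 2)
    cp_stop("need at least 2 values per group")
  est <- mean(x) - mean(y)
  degenerate <- if (paired) stats::var(x - y) == 0 else
    (stats::var(x) == 0 && stats::var(y) == 0)
  if (degenerate) {
    if (est == 0)
      return(data.frame(estimate = 0, statistic = 0,
                        df = if (paired) length(x) - 1
                             else length(x) + length(y) - 2,
                        p_raw = 1, degenerate = TRUE))
    return(data.frame(estimate = est, statistic = sign(est) * Inf,
                      df = if (paired) length(x) - 1
                           else length(x) + length(y) - 2,
                      p_raw = 0, degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = paired, var.equal = TRUE)
  data.frame(estimate = est, statistic = unname(tt$statistic),
             df = unname(tt$parameter), p_raw = tt$p.value,
             degenerate = FALSE)
}

#' One-way ANOVA
#'
#' Classic fixed-effects one-way F test across groups. Identical values in
#' every group give F = 0, p = 1 (flagged degenerate); zero within-group
#' variance with differing means gives F = Inf, p = 0.
#'
#' @param groups named list of numeric vectors (>= 2 groups of >= 2).
#' @return data.frame row: `statistic` (F), `df1`, `df2`, `p_raw`,
#'   `degenerate`.
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2 || any(lengths(groups) < 2))
    cp_stop("need >= 2 groups with >= 2 values each")
  v <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  df1 <- nlevels(g) - 1
  df2 <- length(v) - nlevels(g)
  within0 <- all(vapply(groups, function(x) stats::var(x) == 0, TRUE))
  if (within0) {
    means <- vapply(groups, mean, 0)
    if (max(means) == min(means))
      return(data.frame(statistic = 0, df1 = df1, df2 = df2, p_raw = 1,
                        degenerate = TRUE))
    return(data.frame(statistic = Inf, df1 = df1, df2 = df2, p_raw = 0,
                      degenerate = TRUE))
  }
  ow <- stats::oneway.test(v ~ g, var.equal = TRUE)
  data.frame(statistic = unname(ow$statistic), df1 = df1, df2 = df2,
             p_raw = ow$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg adjustment within declared families
#'
#' Step-up FDR adjustment. Missing p-values (flagged-degenerate or
#' unavailable statistics) propagate as NA and do not count toward a
#' family's hypothesis count m.
#'
#' @param p_values numeric vector in [0, 1] (NA allowed).
#' @param family optional vector of family ids; adjustment is applied
#'   within each family separately.
#' @return adjusted p-values, same order as input.
#' @export
bh_adjust <- function(p_values, family = NULL) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    cp_stop("p-values must lie in [0, 1]")
  adj <- rep(NA_real_, length(p_values))
  fam <- if (is.null(family)) rep(1L, length(p_values)) else family
  for (f in unique(fam)) {
    idx <- which(fam == f & !is.na(p_values))
    if (length(idx))
      adj[idx] <- stats::p.adjust(p_values[idx], method = "BH")
  }
  adj
}

#' Volcano classification of stimulation-response features
#'
#' A feature is `"up"` iff its uncorrected p-value is below `p_cutoff` and
#' its mean arcsinh change exceeds `diff_cutoff`; `"down"` iff the p-value
#' passes and the change is below `-diff_cutoff`; otherwise `"ns"`.
#'
#' @param mean_diff mean post-stimulation arcsinh change.
#' @param p_raw uncorrected (paired t-test) p-value.
#' @param p_cutoff,diff_cutoff thresholds (defaults 0.05 and 0.1).
#' @return character vector in {"up", "down", "ns"} (NA inputs give NA).
#' @export
volcano_classify <- function(mean_diff, p_raw, p_cutoff = 0.05,
                             diff_cutoff = 0.1) {
  out <- ifelse(is.na(mean_diff) | is.na(p_raw), NA_character_,
                ifelse(p_raw < p_cutoff & mean_diff > diff_cutoff, "up",
                       ifelse(p_raw < p_cutoff & mean_diff < -diff_cutoff,
                              "down", "ns")))
  out
}

#' Combined-rank selection of top responding features
#'
#' Ranks features by p-value (ascending) and by magnitude of mean change
#' (descending), sums the two ranks and selects the
#' `ceiling(fraction * N)` features with the smallest combined rank,
#' separately within each combination of the `by` columns. Ties are broken
#' deterministically: smaller combined rank, then larger |change|, then
#' lexicographic feature id.
#'
#' @param features data.frame with columns `id`, `p_raw`, `change` (plus
#'   any `by` columns).
#' @param fraction fraction of features to keep, in (0, 1].
#' @param by character vector of stratification columns (e.g. tissue and
#'   stimulation), or NULL for a single stratum.
#' @return `features` with added `rank_p`, `rank_change`, `combined`,
#'   `selected`.
#' @export
rank_top_features <- function(features, fraction = 0.2, by = NULL) {
  if (fraction <= 0 || fraction > 1) cp_stop("fraction must be in (0, 1]")
  out <- features
  out$rank_p <- NA_real_
  out$rank_change <- NA_real_
  out$combined <- NA_real_
  out$selected <- FALSE
  strata <- if (is.null(by)) rep(1L, nrow(out)) else
    interaction(out[by], drop = TRUE)
  for (s in unique(strata)) {
    idx <- which(strata == s)
    rp <- rank(out$p_raw[idx], ties.method = "average")
    rm_ <- rank(-abs(out$change[idx]), ties.method = "average")
    comb <- rp + rm_
    n_sel <- ceiling(fraction * length(idx))
    ord <- order(comb, -abs(out$change[idx]), out$id[idx])
    out$rank_p[idx] <- rp
    out$rank_change[idx] <- rm_
    out$combined[idx] <- comb
    out$selected[idx[ord[seq_len(n_sel)]]] <- TRUE
  }
  out
}

#' Group Z-scores against the grand mean
#'
#' For each group, the number of standard deviations by which the group
#' mean differs from the grand mean of all animal-level values. The
#' default SD convention is the population SD of all values
#' (denominator n); `sd_type = "sample"` switches to the n-1 convention.
#'
#' @param values_by_group named list of numeric vectors.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return named numeric vector of Z-scores (NA when the pooled SD is 0).
#' @export
group_zscores <- function(values_by_group,
                          sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  v <- unlist(values_by_group, use.names = FALSE)
  grand <- mean(v)
  s <- if (sd_type == "population")
    sqrt(mean((v - grand)^2)) else stats::sd(v)
  means <- vapply(values_by_group, mean, 0)
  if (is.na(s) || s == 0)
    return(stats::setNames(rep(NA_real_, length(means)),
                           names(values_by_group)))
  (means - grand) / s
}

#' log2 ratio of a group mean versus the control (mock) mean
#'
#' @param group_mean,mock_mean positive means; nonpositive or missing
#'   inputs give NA (flagged undefined).
#' @return `log2(group_mean / mock_mean)`.
#' @export
log2_vs_mock <- function(group_mean, mock_mean) {
  ifelse(is.na(group_mean) | is.na(mock_mean) |
           group_mean <= 0 | mock_mean <= 0,
         NA_real_, log2(group_mean / mock_mean))
}

#' Pearson correlations between features and clinical outcomes
#'
#' For every (feature, outcome) pair, Pearson r and p across animals —
#' pooled over treatment groups by default, optionally also within each
#' group. BH adjustment is applied within each (family, outcome) family;
#' the `hatch` flag marks adjusted p above 0.05. Pairs with fewer than
#' `min_n` complete observations or zero variance on either side are
#' flagged missing.
#'
#' @param feature_table long data.frame with columns `animal_id`,
#'   `feature_id`, `value`, and optionally `family` and `group`.
#' @param outcomes data.frame with `animal_id` and one column per outcome.
#' @param by_group also compute within-group correlations (rows with a
#'   non-NA `group` column appended; BH is applied to the pooled rows
#'   only).
#' @param min_n minimum paired observations (default 3).
#' @return data.frame (`feature_id`, `outcome`, `family`, `group`, `n`,
#'   `r`, `p_raw`, `p_adj`, `hatch`, `missing`).
#' @export
correlate_outcomes <- function(feature_table, outcomes, by_group = FALSE,
                               min_n = 3) {
  stopifnot(all(c("animal_id", "feature_id", "value") %in%
                  names(feature_table)))
  fam <- feature_table$family %||% rep("all", nrow(feature_table))
  feature_table$family <- fam
  outcome_names <- setdiff(names(outcomes), "animal_id")
  one <- function(sub, grp) {
    rows <- lapply(outcome_names, function(oc) {
      i <- match(sub$animal_id, outcomes$animal_id)
      y <- outcomes[[oc]][i]
      ok <- !is.na(sub$value) & !is.na(y)
      x <- sub$value[ok]; yy <- y[ok]
      if (sum(ok) < min_n || stats::sd(x) == 0 || stats::sd(yy) == 0) {
        data.frame(feature_id = sub$feature_id[1], outcome = oc,
                   family = sub$family[1], group = grp, n = sum(ok),
                   r = NA_real_, p_raw = NA_real_, missing = TRUE)
      } else {
        ct <- stats::cor.test(x, yy, method = "pearson")
        data.frame(feature_id = sub$feature_id[1], outcome = oc,
                   family = sub$family[1], group = grp, n = sum(ok),
                   r = unname(ct$estimate), p_raw = ct$p.value,
                   missing = FALSE)
      }
    })
    do.call(rbind, rows)
  }
  res <- lapply(split(feature_table, feature_table$feature_id),
                one, grp = NA_character_)
  out <- do.call(rbind, res)
  if (by_group && "group" %in% names(feature_table)) {
    res_g <- lapply(split(feature_table,
                          list(feature_table$feature_id,
                               feature_table$group), drop = TRUE),
                    function(sub) one(sub, grp = sub$group[1]))
    out <- rbind(out, do.call(rbind, res_g))
  }
  pooled <- is.na(out$group)
  out$p_adj <- NA_real_
  out$p_adj[pooled] <- bh_adjust(out$p_raw[pooled],
                                 paste(out$family[pooled],
                                       out$outcome[pooled]))
  out$hatch <- is.na(out$p_adj) | out$p_adj > 0.05
  rownames(out) <- NULL
  out
}
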