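# Experiment ground truth: study design, population mixtures, marker model,
# stimulation effects, drift and severity links.

POPULATIONS <- c("CD4T", "CD8T", "CD8Tact", "DNT", "B", "BIgM", "NK56",
                 "NK16", "pDC", "mDC", "cMC", "intMC", "ncMC")

# Parent links among reported populations (activated CD8 within CD8 T,
# IgM+ B within B); all other populations sit directly under the
# mononuclear root.
POP_PARENT <- c(CD8Tact = "CD8T", BIgM = "B")

# Phenotype markers expressed ("high") per generator component. "other"
# is the unannotated mononuclear remainder (CD45+ only).
POP_PROFILES <- list(
  CD4T    = c("CD45", "CD3", "CD4"),
  CD8T    = c("CD45", "CD3", "CD8"),
  CD8Tact = c("CD45", "CD3", "CD8", "HLADR", "Ki67"),
  DNT     = c("CD45", "CD3"),
  B       = c("CD45", "CD20", "HLADR"),
  BIgM    = c("CD45", "CD20", "HLADR", "IgM"),
  NK56    = c("CD45", "CD56"),
  NK16    = c("CD45", "CD16"),
  pDC     = c("CD45", "CD123", "HLADR"),
  mDC     = c("CD45", "CD11c", "HLADR"),
  cMC     = c("CD45", "CD14", "CD11b", "CD11c", "HLADR"),
  intMC   = c("CD45", "CD14", "CD16", "CD11b", "HLADR"),
  ncMC    = c("CD45", "CD16", "CD11b", "CD11c", "HLADR"),
  other   = c("CD45")
)

# Mononuclear composition (fractions of CD45+CD66- events) per tissue and
# group. Vaccinated groups share a base composition; the mock (unvaccinated)
# group carries the challenge-response differences: more activated CD8 T and
# fewer pDC in blood, more intermediate monocytes and B / IgM+ B cells in
# the lung-draining lymph node.
default_pop_freqs <- function() {
  pbmc_base <- c(CD4T = 0.24, CD8T = 0.14, CD8Tact = 0.015, DNT = 0.02,
                 B = 0.08, BIgM = 0.03, NK56 = 0.04, NK16 = 0.05,
                 pDC = 0.020, mDC = 0.015, cMC = 0.12, intMC = 0.035,
                 ncMC = 0.03)
  ln_base <- c(CD4T = 0.28, CD8T = 0.12, CD8Tact = 0.010, DNT = 0.02,
               B = 0.16, BIgM = 0.08, NK56 = 0.015, NK16 = 0.01,
               pDC = 0.015, mDC = 0.012, cMC = 0.03, intMC = 0.015,
               ncMC = 0.008)
  pbmc_mock <- pbmc_base
  pbmc_mock[["CD8Tact"]] <- 0.045
  pbmc_mock[["pDC"]] <- 0.008
  ln_mock <- ln_base
  ln_mock[["B"]] <- 0.22
  ln_mock[["BIgM"]] <- 0.13
  ln_mock[["intMC"]] <- 0.035
  list(PBMC = list(mock = pbmc_mock, mRNA = pbmc_base, protein = pbmc_base),
       LN   = list(mock = ln_mock,   mRNA = ln_base,   protein = ln_base))
}

# Baseline stimulation-induced shifts (arcsinh scale) per population x
# signaling marker x stimulus. PMA/ionomycin drives broad MAPK/mTOR/CREB
# activation strongest in T cells, B cells and monocytes with IkB loss in
# B cells and monocytes; R848 (TLR7/8) acts mainly on pDC, mDC, monocytes
# and B cells. Unstimulated shifts are identically zero.
default_stim_effects <- function(populations = POPULATIONS) {
  markers <- c("pSTAT1", "pSTAT3", "pSTAT4", "pSTAT5", "pSTAT6", "pErk12",
               "pMAPKAPK2", "pCREB", "IkBa", "pTBK1", "pS6", "pZap70Syk",
               "p4EBP1", "pPLCg2", "pP38")
  pops <- c(populations, "other")
  eff <- array(0, dim = c(length(pops), length(markers), 3),
               dimnames = list(pops, markers, c("UNSTIM", "PMAI", "R848")))
  tcells <- intersect(c("CD4T", "CD8T", "CD8Tact", "DNT"), pops)
  bcells <- intersect(c("B", "BIgM"), pops)
  mono <- intersect(c("cMC", "intMC", "ncMC"), pops)
  nk <- intersect(c("NK56", "NK16"), pops)
  dc <- intersect(c("pDC", "mDC"), pops)
  lym_my <- c(tcells, bcells, mono)
  set_eff <- function(p, m, s, v) eff[p, m, s] <<- v
  set_eff(lym_my, "pErk12", "PMAI", 1.2)
  set_eff(lym_my, "pS6", "PMAI", 1.0)
  set_eff(lym_my, "pP38", "PMAI", 0.9)
  set_eff(lym_my, "pMAPKAPK2", "PMAI", 0.8)
  set_eff(lym_my, "pCREB", "PMAI", 0.7)
  set_eff(lym_my, "pPLCg2", "PMAI", 0.5)
  set_eff(c(tcells, bcells), "pZap70Syk", "PMAI", 0.4)
  set_eff(c(bcells, mono), "IkBa", "PMAI", -0.8)
  set_eff(nk, "pErk12", "PMAI", 0.8)
  set_eff(nk, "pS6", "PMAI", 0.6)
  set_eff(nk, "pP38", "PMAI", 0.5)
  set_eff("NK56", "pCREB", "PMAI", 0.6)
  set_eff(dc, "pErk12", "PMAI", 0.6)
  set_eff(dc, "pS6", "PMAI", 0.5)
  set_eff("pDC", "pErk12", "R848", 0.9)
  set_eff("pDC", "pS6", "R848", 0.7)
  set_eff("pDC", "pP38", "R848", 0.6)
  set_eff("pDC", "pMAPKAPK2", "R848", 0.5)
  set_eff("pDC", "IkBa", "R848", -0.7)
  set_eff(c("mDC", mono), "pErk12", "R848", 0.6)
  set_eff(c("mDC", mono), "pS6", "R848", 0.5)
  set_eff(c("mDC", mono), "pP38", "R848", 0.5)
  set_eff(c("mDC", mono), "IkBa", "R848", -0.5)
  set_eff(bcells, "IkBa", "R848", -0.6)
  set_eff(bcells, "pErk12", "R848", 0.3)
  eff
}

#' Default experiment configuration
#'
#' Encodes the study conditions the generator emulates: three treatment
#' groups (mock / mRNA / protein vaccine, n animals each), two tissues
#' (PBMC and lung-draining lymph node), three 15-minute ex vivo stimulation
#' conditions (PBS control, PMA/ionomycin, R848), 13 annotated mononuclear
#' populations with tissue- and group-specific composition, 15 signaling
#' markers with stimulation-induced arcsinh-scale shifts, palladium
#' 3-of-6 barcoding, spiked five-element normalization beads, smooth
#' acquisition-time sensitivity drift, and a latent per-animal severity
#' that links designated features to clinical outcomes.
#'
#' @param n_animals animals per group (study design: 8).
#' @param n_events default events per sample acquisition.
#' @param drift_range max/min dynamic range of the sensitivity drift over
#'   the acquisition window (1 = no drift; default 2).
#' @param effect_scale multiplier on the mock-vs-vaccinated composition
#'   differences (1 = study-sized effects, 0 = null experiment).
#' @return nested configuration list understood by [make_truth()].
#' @export
default_config <- function(n_animals = 8, n_events = 50000, drift_range = 2,
                           effect_scale = 1) {
  freqs <- default_pop_freqs()
  if (effect_scale != 1) {
    for (tis in names(freqs)) {
      base <- freqs[[tis]][["mRNA"]]
      freqs[[tis]][["mock"]] <- base + effect_scale *
        (freqs[[tis]][["mock"]] - base)
    }
  }
  list(
    groups = c(mock = n_animals, mRNA = n_animals, protein = n_animals),
    tissues = c("PBMC", "LN"),
    stims = c("UNSTIM", "PMAI", "R848"),
    populations = POPULATIONS,
    pop_freqs = freqs,
    marker_levels = list(hi = 4.0, lo = 0.5, sd = 0.3),
    signaling_baseline = list(loc = 1.0, sd = 0.35),
    stim_effects = default_stim_effects(),
    sigma_animal = 0.10,
    severity = list(means = c(mock = 2.5, mRNA = 1.2, protein = 0.8),
                    sd = 0.5, reference = 1.5),
    # Latent-severity links into composition (per tissue/population) and
    # into stimulation responses (per tissue/population/marker/stim);
    # slopes are per severity unit. effect_scale = 0 removes them too.
    freq_links = data.frame(
      tissue = c("PBMC", "PBMC", "LN", "LN", "LN"),
      population = c("CD8Tact", "pDC", "intMC", "B", "BIgM"),
      beta = effect_scale * c(0.35, -0.30, 0.30, 0.12, 0.18)),
    signaling_links = data.frame(
      tissue = c("LN", "LN", "PBMC", "PBMC", "PBMC"),
      population = c("BIgM", "BIgM", "NK56", "pDC", "pDC"),
      marker = c("IkBa", "IkBa", "pCREB", "pErk12", "pErk12"),
      stim = c("PMAI", "R848", "PMAI", "PMAI", "R848"),
      beta = effect_scale * c(-0.25, -0.20, 0.20, 0.15, -0.15)),
    barcode = list(n = 6, k = 3, hi = 4.0, lo = 0.5, sd = 0.3),
    beads = list(loc = 5.0, sd = 0.15, off_sd = 0.10, fraction = 0.05),
    drift = list(range = drift_range),
    acquisition = list(window = 600, n_events = n_events),
    outcome_links = list(
      viral_rna  = list(intercept = 2.0, slope = 1.6, sd = 0.50,
                        range = c(0, 11)),
      pathology  = list(intercept = 0.0, slope = 0.75, sd = 0.35,
                        range = c(0, 4)),
      radiograph = list(intercept = 0.0, slope = 0.55, sd = 0.35,
                        range = c(0, 3))),
    cbc = list(wbc_mean = 9000, wbc_sd = 1500,
               neut_frac = 0.45, neut_sd = 0.05,
               eos_frac = 0.02, eos_sd = 0.005),
    cofactor = 5
  )
}

validate_config <- function(config) {
  if (any(config$groups < 0) || any(config$groups != round(config$groups)))
    cp_stop("configuration error: group sizes must be nonnegative integers")
  pops <- config$populations
  for (tis in config$tissues) {
    for (grp in names(config$groups)) {
      f <- config$pop_freqs[[tis]][[grp]]
      if (is.null(f) || !all(pops %in% names(f)))
        cp_stop("configuration error: missing population fractions for %s/%s",
                tis, grp)
      f <- f[pops]
      if (any(f < 0) || any(f > 1) || sum(f) > 1)
        cp_stop(paste0("configuration error: population fractions for %s/%s ",
                       "must lie in [0,1] and sum to at most 1 (sum = %.3f)"),
                tis, grp, sum(f))
    }
  }
  if (!identical(unname(config$stim_effects[, , "UNSTIM"]),
                 unname(config$stim_effects[, , "UNSTIM"] * 0)))
    cp_stop("configuration error: UNSTIM stimulation effects must be zero")
  if (config$drift$range < 1)
    cp_stop("configuration error: drift range must be >= 1")
  invisible(config)
}

#' Build experiment ground truth
#'
#' Deterministically expands a configuration into a fully specified
#' experiment: the animal roster with latent severities, per-animal
#' population compositions (group composition perturbed by lognormal
#' between-animal variation and by the severity links), the marker
#' location/scale model on the arcsinh scale, stimulation effects, and the
#' acquisition drift model. All downstream simulation draws are pure
#' functions of this object.
#'
#' @param config configuration list from [default_config()].
#' @param seed integer seed; the same (config, seed) always yields an
#'   identical truth object.
#' @return object of class `cyto_truth`.
#' @export
make_truth <- function(config = default_config(), seed = 1) {
  validate_config(config)
  panel <- default_panel()
  pops_all <- c(config$populations, "other")
  markers <- panel$marker[panel$role %in% c("phenotype", "signaling")]
  lv <- config$marker_levels
  loc <- matrix(lv$lo, nrow = length(pops_all), ncol = length(markers),
                dimnames = list(pops_all, markers))
  sdm <- matrix(lv$sd, nrow = length(pops_all), ncol = length(markers),
                dimnames = list(pops_all, markers))
  sig_markers <- panel$marker[panel$role == "signaling"]
  loc[, sig_markers] <- config$signaling_baseline$loc
  sdm[, sig_markers] <- config$signaling_baseline$sd
  for (p in names(POP_PROFILES))
    loc[p, POP_PROFILES[[p]]] <- lv$hi

  truth <- with_seed(seed, {
    groups <- rep(names(config$groups), config$groups)
    n <- length(groups)
    animals <- data.frame(
      animal_id = sprintf("A%02d", seq_len(n)),
      group = groups,
      severity = stats::rnorm(n, config$severity$means[groups],
                              config$severity$sd))
    sev_ref <- config$severity$reference
    freqs <- array(0, dim = c(n, length(config$tissues),
                              length(config$populations)),
                   dimnames = list(animals$animal_id, config$tissues,
                                   config$populations))
    for (i in seq_len(n)) {
      for (tis in config$tissues) {
        f <- config$pop_freqs[[tis]][[groups[i]]][config$populations]
        beta <- stats::setNames(rep(0, length(f)), names(f))
        lk <- config$freq_links[config$freq_links$tissue == tis, ]
        beta[lk$population] <- lk$beta
        f <- f * exp(beta * (animals$severity[i] - sev_ref) +
                       stats::rnorm(length(f), 0, config$sigma_animal))
        if (sum(f) > 0.98) f <- f * 0.98 / sum(f)
        freqs[i, tis, ] <- f
      }
    }
    list(animals = animals, animal_freqs = freqs)
  })

  structure(list(
    seed = seed, config = config, panel = panel,
    populations = config$populations, pop_parent = POP_PARENT,
    pop_freqs = config$pop_freqs,
    animals = truth$animals, animal_freqs = truth$animal_freqs,
    marker_loc = loc, marker_sd = sdm,
    stim_effects = config$stim_effects,
    drift = config$drift, cofactor = config$cofactor
  ), class = "cyto_truth")
}

#' @export
print.cyto_truth <- function(x, ...) {
  cat(sprintf(paste0("cyto_truth: %d animals (%s), tissues %s, stims %s,\n",
                     "  %d populations + other, drift range %.2f, seed %d\n"),
              nrow(x$animals),
              paste(sprintf("%s=%d", names(x$config$groups), x$config$groups),
                    collapse = ", "),
              paste(x$config$tissues, collapse = "/"),
              paste(x$config$stims, collapse = "/"),
              length(x$populations), x$drift$range, x$seed))
  invisible(x)
}

# Multiplicative sensitivity at time t (shared across channels): smooth
# monotone decline from 1 at t=0 to 1/range at the end of the window.
#' @noRd
drift_multiplier <- function(truth, t) {
  u <- pmin(1, pmax(0, t / truth$config$acquisition$window))
  1 / (1 + (truth$drift$range - 1) * u)
}

# Effective stimulation-effect matrix (pop x signaling marker) for one
# sample, including severity-linked per-animal adjustments.
#' @noRd
effective_stim_effects <- function(truth, animal_id, tissue, stim) {
  eff <- truth$stim_effects[, , stim]
  if (stim == "UNSTIM") return(eff)
  lk <- truth$config$signaling_links
  lk <- lk[lk$tissue == tissue & lk$stim == stim, , drop = FALSE]
  if (nrow(lk)) {
    sev <- truth$animals$severity[match(animal_id, truth$animals$animal_id)]
    dev <- sev - truth$config$severity$reference
    for (j in seq_len(nrow(lk)))
      eff[lk$population[j], lk$marker[j]] <-
        eff[lk$population[j], lk$marker[j]] + lk$beta[j] * dev
  }
  eff
}
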