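# Synthetic antibody panel and palladium barcode scheme definitions.

#' Default synthetic mass cytometry panel
#'
#' A 42-channel panel emulating a cross-species immune profiling design:
#' 15 phenotyping markers, 15 phospho/total signaling markers, 6 palladium
#' barcode channels, 5 dedicated normalization-bead channels and the
#' acquisition time channel. Bead metals are disjoint from marker metals in
#' the synthetic panel, so bead identification is unambiguous by design.
#'
#' @return data.frame with columns `channel` (metal channel name), `marker`
#'   (short marker name, equal to `channel` for beads/barcodes/time) and
#'   `role` (one of `"phenotype"`, `"signaling"`, `"barcode"`, `"bead"`,
#'   `"time"`).
#' @export
default_panel <- function() {
  pheno <- c(CD45 = "Y89Di",   CD66 = "Gd158Di", CD3 = "Gd157Di",
             CD4 = "Gd156Di",  CD8 = "Gd155Di",  CD14 = "Nd144Di",
             CD16 = "Tb159Di", CD20 = "Dy161Di", IgM = "Yb174Di",
             CD56 = "Er167Di", CD11b = "Eu153Di", CD11c = "Nd146Di",
             CD123 = "Nd148Di", HLADR = "Yb176Di", Ki67 = "Er168Di")
  signaling <- c(pSTAT1 = "Nd143Di", pSTAT3 = "Nd145Di", pSTAT4 = "Sm147Di",
                 pSTAT5 = "Sm149Di", pSTAT6 = "Nd150Di", pErk12 = "Er166Di",
                 pMAPKAPK2 = "Dy162Di", pCREB = "Dy163Di", IkBa = "Dy164Di",
                 pTBK1 = "Sm152Di", pS6 = "Sm154Di", pZap70Syk = "Yb171Di",
                 p4EBP1 = "Yb172Di", pPLCg2 = "Yb173Di", pP38 = "Er170Di")
  barcode <- paste0("Pd", c(102, 104, 105, 106, 108, 110), "Di")
  bead <- c("Ce140Di", "Ce142Di", "Ho165Di", "Tm169Di", "Lu175Di")
  rbind(
    data.frame(channel = unname(pheno), marker = names(pheno),
               role = "phenotype"),
    data.frame(channel = unname(signaling), marker = names(signaling),
               role = "signaling"),
    data.frame(channel = barcode, marker = paste0("BC", seq_along(barcode)),
               role = "barcode"),
    data.frame(channel = bead, marker = paste0("Bead", seq_along(bead)),
               role = "bead"),
    data.frame(channel = "Time", marker = "Time", role = "time")
  )
}

#' @noRd
panel_channels <- function(panel, role) panel$channel[panel$role %in% role]

# Map marker short names to channel names; errors on unknown markers.
#' @noRd
marker_to_channel <- function(panel, markers) {
  idx <- match(markers, panel$marker)
  if (anyNA(idx))
    cp_stop("unknown marker(s): %s", paste(markers[is.na(idx)], collapse = ", "))
  panel$channel[idx]
}

#' k-of-n barcode scheme
#'
#' Enumerates all `choose(n, k)` binary codes with exactly `k` ones over `n`
#' barcode channels and assigns the first `n_samples` codes to sample slots.
#' The default 6-choose-3 palladium design yields 20 codes, of which 16 are
#' used per pooled batch.
#'
#' @param sample_ids character vector of sample identifiers (<= choose(n,k)).
#' @param n number of barcode channels.
#' @param k number of "high" channels per code.
#' @return object of class `barcode_scheme`: list with `codes` (0/1 matrix,
#'   one row per sample, rownames = sample ids), `n`, `k`.
#' @export
barcode_scheme <- function(sample_ids, n = 6, k = 3) {
  if (k >= n) cp_stop("barcode scheme requires k < n (got k=%d, n=%d)", k, n)
  combos <- utils::combn(n, k)
  if (length(sample_ids) > ncol(combos))
    cp_stop("%d samples exceed the %d available %d-of-%d codes",
            length(sample_ids), ncol(combos), k, n)
  if (anyDuplicated(sample_ids)) cp_stop("duplicate sample ids in scheme")
  codes <- matrix(0L, nrow = length(sample_ids), ncol = n,
                  dimnames = list(sample_ids, NULL))
  for (i in seq_along(sample_ids)) codes[i, combos[, i]] <- 1L
  if (anyDuplicated(apply(codes, 1, paste, collapse = "")))
    cp_stop("duplicate codes in scheme")
  structure(list(codes = codes, n = n, k = k), class = "barcode_scheme")
}

#' @export
print.barcode_scheme <- function(x, ...) {
  cat(sprintf("%d-of-%d barcode scheme: %d samples\n", x$k, x$n,
              nrow(x$codes)))
  invisible(x)
}
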