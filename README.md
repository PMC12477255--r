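# cytopipe

Analysis pipeline for multiplexed mass cytometry (CyTOF) immune
profiling of vaccine challenge experiments — from raw barcoded event
streams to the statistics behind group-comparison and outcome-correlation
figures — together with a ground-truth synthetic-data generator that makes
every stage testable without instrument data.

## The problem

In a typical non-human primate challenge study, PBMC and lymph-node cells
from three treatment groups (unvaccinated mock control, mRNA vaccine,
protein vaccine; n = 8 animals each) are stimulated ex vivo (PBS control,
PMA/ionomycin, or the TLR7/8 agonist R848), barcoded with palladium
isotopes in pools of 16, spiked with five-element normalization beads and
acquired on a CyTOF instrument. Turning those pooled streams into
statements like *"activated CD8+ T cells are elevated in unvaccinated
blood and correlate with lung pathology"* requires a chain of
computational steps, each of which this package implements and tests:

1. **Bead normalization** — instrument sensitivity drifts over an
   acquisition; bead events identified on five dedicated channels are
   summarised by sliding-window medians (500 beads/window) and each
   channel is multiplied by `reference median / local median`,
   interpolated over time (cross-batch references supported).
2. **Debarcoding** — each event's 6 palladium channels are rescaled to
   [0, 1] by their within-run 1st–99th percentile range on the arcsinh
   scale; the top-k (k = 3) channels give the code, the gap between the
   k-th and (k+1)-th value gives a separation statistic (cutoff 0.3), and
   a per-sample Mahalanobis filter (squared distance, cutoff 30) removes
   impure events. Cell-cell doublets light up more than k channels and
   are rejected by construction.
3. **Hierarchical gating** — a configuration-driven gate tree rooted at
   CD45+CD66− annotates 13 mononuclear populations (CD4 T, CD8 T,
   activated HLA-DR+Ki67+ CD8 T, CD3+CD4−CD8− T, B, IgM+ B, CD56+CD16−
   and CD16+ NK, pDC, mDC, classical/intermediate/non-classical
   monocytes).
4. **Features** — population frequencies as % of mononuclear cells
   (unstimulated condition), pseudo-absolute counts as
   `frequency × (WBC − neutrophils − eosinophils)` from CBC data
   (cells/µL, PBMC only), and per-population medians of `asinh(x/5)`
   signaling intensity with stimulated-minus-unstimulated responses.
5. **Statistics** — equal-variance Student t (vaccine vs mock) and one-way
   ANOVA with Benjamini–Hochberg correction within declared families;
   volcano classification (uncorrected p < 0.05, |Δarcsinh| > 0.1);
   combined p-value/magnitude ranking selecting the top 20% of responding
   features per tissue × stimulation; group Z-scores against the grand
   mean; log2 ratios versus mock; Pearson correlations of features with
   lung viral RNA, pathology and radiograph scores.

The synthetic generator (`make_truth()`, `simulate_batch()`, …) emulates
the full design — mixtures over the 13 populations with group- and
tissue-specific composition, arcsinh-Gaussian marker model, injected
stimulation shifts, sensitivity drift, beads, doublets, CBC and clinical
outcomes linked to a latent per-animal severity — and emits per-event
truth labels in a sidecar table only, so recovery can be scored without
letting the pipeline peek.

## Worked example

```r
library(cytopipe)

cfg <- pipeline_config(seed = 42, n_animals = 4, n_events = 2000)
res <- run_pipeline(cfg)        # simulate -> normalize -> debarcode ->
                                # gate -> featurize -> test

gt <- res$group_tests
sig <- gt[!is.na(gt$p_adj) & gt$p_adj < 0.05 & gt$comparison != "ANOVA", ]
sig[order(sig$p_adj)[1:8], c("tissue", "population", "comparison",
                             "estimate", "p_raw", "p_adj")]
#>  tissue population      comparison estimate    p_raw    p_adj
#>      LN          B protein_vs_mock   -17.96 2.37e-06 6.16e-05
#>      LN          B    mRNA_vs_mock   -16.17 1.24e-05 8.03e-05
#>      LN       BIgM    mRNA_vs_mock    -8.01 9.88e-06 8.03e-05
#>      LN       BIgM protein_vs_mock    -9.02 6.82e-06 8.03e-05
#>    PBMC    CD8Tact    mRNA_vs_mock    -5.34 1.40e-05 1.95e-04
#>    PBMC    CD8Tact protein_vs_mock    -5.77 1.50e-05 1.95e-04
#>      LN      intMC    mRNA_vs_mock    -3.65 1.40e-04 7.28e-04
#>      LN      intMC protein_vs_mock    -3.20 3.09e-04 1.34e-03
```

`estimate` is the vaccine-minus-mock difference in % of mononuclear
cells: unvaccinated animals carry more B cells, IgM+ B cells and
intermediate monocytes in the lymph node and more activated CD8 T cells
in blood, and the BH-adjusted p-values call all of them. The
outcome-correlation table ranks features against clinical severity:

```r
oc <- res$outcome_correlations
oc <- oc[is.na(oc$group) & !oc$missing, ]
head(oc[order(-abs(oc$r)),
        c("feature_id", "outcome", "n", "r", "p_adj")], 5)
#>                 feature_id          outcome  n      r    p_adj
#>         PBMC_R848_pDC_pP38 radiograph_score  5  0.950 0.256697
#>  LN_R848_CD8Tact_pZap70Syk  viral_rna_log10  4 -0.948 0.527234
#>             LN_R848_B_IkBa  viral_rna_log10 12 -0.926 0.001179
#>          PBMC_CD8Tact_freq  pathology_score 12  0.921 0.000279
#>        LN_PMAI_CD8Tact_pS6  viral_rna_log10  4 -0.915 0.574476
```

The two correlations that survive BH adjustment at full n are exactly the
seeded severity links: stimulation-induced IκB loss in lymph-node B cells
tracks viral RNA, and the activated-CD8 frequency in blood tracks
pathology score. (Small-n rows with large r but large adjusted p are
features measurable in only a few animals; they are reported, flagged and
hatched, never silently dropped.)

`run_pipeline(cfg, outdir = "results")` additionally writes every table
(`frequencies.csv`, `group_tests.csv`, `volcano.csv`, `top_features.csv`,
`zscores.csv`, `log2_ratios.csv`, `outcome_correlations.csv`,
`yield.csv`, …) plus a `manifest.json` with a config hash, per-stage event
accounting and file checksums. A thin CLI wraps the same functions:

```sh
exec/cytopipe full-run --seed 1 --n-animals 8 --n-events 2000 --outdir results
exec/cytopipe simulate --seed 1 --outdir sim
exec/cytopipe normalize --in sim/batch01.fcs --out normed.fcs
exec/cytopipe debarcode --in normed.fcs --scheme sim/batch01_scheme.yaml --outdir deb
exec/cytopipe gate --in deb/A01_PBMC_UNSTIM.fcs --out counts.csv
```

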