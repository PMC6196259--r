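# immuneRecur

Links the intra-tumoral immune microenvironment of early-stage (IA/IB)
lung adenocarcinoma to post-resection recurrence. About a fifth to a
quarter of completely resected stage-I patients relapse, and stage alone
does not say who. This package implements, as a tested and reusable R
pipeline, an analysis in which the *composition* of the immune infiltrate
— estimated from bulk tumor transcriptomes — stratifies recurrence risk.

It is aimed at computational biologists working with bulk expression
cohorts (microarray or similar) alongside time-to-recurrence clinical
data, and at anyone who wants a fully synthetic, ground-truthed testbed
for this class of analysis.

## What it does

1. **Preprocessing** — per-array quality filtering (GNUSE-style scores,
   cutoff 1.25, boundary inclusive), quantile normalization,
   empirical-Bayes (ComBat-style) batch adjustment for merging datasets,
   and a variability filter for near-constant genes.
2. **Immune deconvolution** — CIBERSORT-style estimation of the relative
   leukocyte-RNA fractions of 22 immune cell types: per sample, a
   linear-kernel nu-support-vector regression of the mixture on an
   LM22-like signature matrix over nu ∈ {0.25, 0.5, 0.75}, RMSE model
   selection, simplex projection, and permutation significance (1000
   permutations). A non-negative least-squares oracle cross-checks it.
3. **Composite phenotypes** — total B/T/NK cells, non-Treg CD4+ T cells,
   the monocyte-macrophage system, lymphocyte vs non-lymphocyte mass and
   the associated ratios, plus cohort correlation tables
   (recurrence/stage) and Kruskal-Wallis/Dunn group comparisons.
4. **Gene prioritization** — per-gene Welch tests (nominal p < 0.05),
   a univariate Cox screen, Markov-clustering modules on the |r| > 0.30
   correlation graph (inflation 2.5), and a GSEA-style signal-to-noise
   ranked list with bottom-5% tail flags and a weighted KS enrichment
   score.
5. **The net prognostic score** — each of plasma cells, non-Treg CD4+
   T cells (positive factors), Tregs and the monocyte-macrophage system
   (negative factors) is dichotomized at the cohort median; the score

   net = (Treg call + monomac call) − (plasma call + non-Treg CD4 call) ∈ {−2 … 2}

   stratifies patients into five groups a (best) … e (worst), evaluated
   by Kaplan-Meier freedom from recurrence and log-rank tests, alongside
   the pairwise 2×2 phenotypes.
6. **Synthetic cohorts** — `sim_config()` / `simulate_cohort()` generate
   multi-batch expression with group-dependent Dirichlet cell fractions
   and proportional-hazards recurrence times driven by the latent immune
   score, with full ground truth for recovery testing.

## Worked example

```r
library(immuneRecur)

cfg    <- sim_config(seed = 1)          # 280 patients, 3 batches, 22 cell types
sig    <- make_signature(cfg)
cohort <- simulate_cohort(cfg, sig)

dec <- deconvolve(cohort$expression, sig, permutations = 0)
dec
#> deconvolution of 280 samples into 22 cell types
#>   mean RMSE: 0.792  mean r: 0.837

comp <- build_composites(dec)
ct   <- correlation_table(rbind(dec$fractions, comp), cohort$clinical)
ct[ct$cell_type %in% c("T regs", "Plasma cells",
                       "Monocyte-macrophage system", "Total nonTreg CD4"), 1:3]
#>                   cell_type r_recurrence p_recurrence
#>                Plasma cells        -0.17       0.0055
#>                      T regs         0.16       0.0084
#>           Total nonTreg CD4        -0.11       0.0656
#>  Monocyte-macrophage system         0.18       0.0021

st <- score_patients(dec)
table(st$stratum)
#>  a  b  c  d  e
#> 26 65 94 73 22

ss <- stratum_survival(st, cohort$clinical, at_months = 80)
ss$freedom_at
#>   stratum  n events surv lower upper
#> 1       a 26      3 0.93  0.80  1.00
#> 2       b 65     13 0.82  0.71  0.93
#> 3       c 94     25 0.78  0.68  0.89
#> 4       d 73     31 0.58  0.46  0.72
#> 5       e 22     12 0.49  0.30  0.83
```

Reading the output: deconvolved Treg and monocyte-macrophage fractions
correlate positively with recurrence, plasma cells negatively — the
pattern the score exploits — and freedom from recurrence at 80 months
falls monotonically from 93% in stratum a (net score −2: high plasma
cells and non-Treg CD4, low Tregs and monocyte-macrophages) to 49% in
stratum e (net +2), with a 5-group log-rank chi² of 27.2 (p = 1.8e-05).

## The analysis workflow

The `analysis/` directory holds the end-to-end study as numbered thin
drivers over the package functions, writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # synthetic cohort + ground truth
Rscript analysis/02_preprocess.R        # QC, quantile norm, batch adjust, filter
Rscript analysis/03_deconvolve.R        # 22-type fractions, 1000 permutations
Rscript analysis/04_composition.R       # composites + correlation table
Rscript analysis/05_gene_select.R       # Welch/Cox/modules/GSEA candidates
Rscript analysis/06_prognostic_score.R  # net score, strata, KM / log-rank
```

`run_pipeline(pipeline_config(...), out_dir)` runs the same stages as one
call with a provenance manifest; configurations can be read from flat
YAML via `read_pipeline_config()`.

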