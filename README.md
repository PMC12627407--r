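# ctcfloops

Predict CTCF-mediated chromatin loops from genomic and epigenomic
features, and score how the loop landscape differs between conditions.

CTCF loops are chromatin interactions anchored by two CTCF-bound sites,
typically with convergent motif orientation and cohesin (RAD21) at the
loop base. `ctcfloops` frames loop formation as a supervised
classification problem over interval features and provides the full
pipeline around it:

- **IO** for the field's formats: ChIA-PET/Hi-C loop calls (bedpe with
  PET counts and FDR), ENCODE narrowPeak ChIP-seq/DNase peaks, FIMO
  motif-scan tables (MA0139.1 CTCF hits), and GTF gene models.
- **Candidate construction**: loops with `< 2` PETs or FDR `> 0.05` are
  removed; each surviving loop gets three evaluation windows — a
  1000-bp window around each anchor and the interloop region — and only
  spans between 2 kb and 2 Mb are kept.
- **High-confidence labeling**: a loop is positive when its anchor
  motifs are convergent (`+` upstream, `-` downstream), both are
  occupied by CTCF, and RAD21 colocalises with the loop. RAD21 is used
  for labeling only and is barred from the feature matrix. Negatives
  are span-matched pairs of unbound CTCF motifs without RAD21.
- **Classification**: an XGBoost classifier (300 trees, depth 4,
  learning rate 0.1) over anchor FIMO scores, loop span and per-window
  presence flags of CTCF and histone marks, with stratified 2/3–1/3
  splitting, precision/recall/F, ROC-AUC and PR-AUC reporting, and
  normalised gain importances.
- **Binding prediction**: an auxiliary random-forest CTCF-binding
  predictor over 20 × 25-bp binned track matrices around each motif,
  whose probabilities can replace (or augment) CTCF ChIP features when
  ChIP-seq is unavailable.
- **Discordance**: for a case condition versus a panel of controls, the
  discordant loop score `D = (s_control − s_case)²` classifies loops as
  *lost* (high control score, case score `< 0.0005`) or *gained* (the
  reverse, case score `> 0.999`); each discordant loop is annotated
  with the gene of longest overlap and genes are ranked by summed `D`.
- **Synthetic studies**: a generator that emits multi-sample fixture
  sets (FIMO TSV, narrowPeak tracks, bedpe loops, GTF genes, ground
  truth) with a planted feature→loop dependency, so the whole pipeline
  is exercisable and testable without downloads.

Everything is tidyverse-shaped: data frames in, tibbles out, `tidy()` /
`glance()` on fitted models and evaluation reports, `autoplot()` for
ROC curves and importance rankings.

## Worked example

Simulate a three-control study, train on one sample and evaluate on
another:

```r
library(ctcfloops)

study_dir <- file.path(tempdir(), "demo")
cfg <- loop_study_config(n_true_loops = 300, n_background_motifs = 2000,
                         chrom_length = 1.5e7, seed = 7)
study <- simulate_loop_study(study_dir, cfg)

res <- run_loop_workflow(study_dir, train_samples = "control1",
                         test_sample = "control2", seed = 7)
res$eval
#> <eval_report: n=600  precision=0.993  recall=1.000  F=0.997  ROC-AUC=0.997  PR-AUC=0.993>
head(tidy(res$model), 5)
#> # A tibble: 5 × 2
#>   feature             importance
#>   <chr>                    <dbl>
#> 1 presence_ctcf_start          1
#> 2 start_motif_score            0
#> 3 end_motif_score              0
#> 4 loop_span                    0
#> 5 presence_ctcf_end            0
```

The evaluation report says that on 600 held-out candidates (300 true
loops, 300 sampled unbound motif pairs) the classifier reaches an
F-score of 0.997, and the importance table shows it leans almost
entirely on CTCF occupancy at the start anchor — in this fixture CTCF
occupancy is planted as a deterministic consequence of loop status, so
one perfectly informative flag is all the booster needs.

The control-versus-case comparison runs the same way:

```r
dw <- run_discordance_workflow(study_dir,
                               control_samples = c("control1", "control2",
                                                   "control3"),
                               case_sample = "case1", seed = 7)
dw$ranking      # genes ranked by summed discordant loop score
plot_discordance(dw$records)
```

A worked discordant score: a loop scored 1.0 across controls and
8.93e-5 in the case gives `D = (1.0 − 8.93e-5)² = 0.999821` — a lost
loop; `discordant_score(0, 0.999782) = 0.999564` marks a strongly
gained one.

## Command line

A thin CLI over the same functions is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/ctcfloops.R", package="ctcfloops"))') \
    simulate --out study/ --seed 3
# then: label / train / predict / evaluate / bind / discord
```

Every run writes a `provenance.json` (arguments, seed, package
version) next to its outputs.

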