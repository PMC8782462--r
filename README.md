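# intronTFA

Transcription factor (TF) activity inference from intronic RNA-seq reads.

## The idea

Mature mRNA integrates transcription over the transcript half-life
(decay rate γ = ln2 / t½), so regulon-expression scores built on exonic
reads lag and smooth the underlying TF activity — severely for stable
transcripts. Intronic reads come almost entirely from unspliced pre-mRNA,
which is removed by splicing within minutes (β = ln10 / t_spl, t_spl ≈
5–10 min), so intron-level expression tracks transcription nearly
instantaneously. The estimator at the core of the package is simply

> intron-based TFA(sample) = mean over the TF's regulon targets of the
> intron-level CPM, where CPM uses the shared intron+exon library total
> and intronless genes are excluded,

together with exon-based and total-read-based counterparts for
comparison. A kinetic simulator justifies the estimator: target genes
follow du/dt = α·TFⁿ/(TFⁿ+K_dⁿ) − βu, ds/dt = βu − γs, driven by an
oscillatory TF (basal-to-peak cosine, optionally noisy), integrated
deterministically (`deSolve`) or stochastically (tau-leap with Poisson
event counts). Downstream tools cover fixed-period cosinor rhythmicity
and peak phase, exon-vs-intron phase differences, correlation with
measured activity surrogates on an interpolation grid, random-regulon
null calibration, ChIP-peak regulon refinement, half-life sub-regulons,
replicate robustness, and correlation-distance TF module clustering.

All inputs are plain TSV/BED tables (paired intron/exon counts,
DoRothEA-style regulons, half-life, TSS, peaks); a fixture generator
produces complete synthetic datasets with planted ground truth, so every
stage is testable without downloads.

## Worked example

Generate a synthetic circadian dataset (6 TFs: two modules of two
rhythmic TFs peaking at 6 h and 18 h, plus two flat TFs; 8 targets each;
samples every 2 h with 4 replicates), then estimate activities and test
rhythmicity:

```r
library(intronTFA)

fx <- generate_fixture(fixture_config(seed = 3), dir = "fixture")
res <- run_pipeline(list(counts    = "fixture/counts.tsv",
                         sample_info = "fixture/samples.tsv",
                         regulons  = "fixture/regulons.tsv",
                         surrogate = "fixture/surrogate.tsv"),
                    out_dir = "results")
res$rhythm[, c("tf", "p_intron", "p_exon", "class",
               "phase_intron", "phase_diff")]
```

```
   tf     p_intron       p_exon  class phase_intron phase_diff
1 TF1 2.168595e-05 2.485046e-08 class1     6.088047  3.7584937
2 TF2 3.736326e-06 6.648303e-09 class1     6.054597  3.8431811
3 TF3 1.701160e-05 3.972983e-09 class1    18.096421  3.8340783
4 TF4 2.082638e-05 9.103145e-09 class1    18.144709  3.6996398
5 TF5 4.004647e-01 9.998086e-01   none    10.481156 -1.2420253
6 TF6 5.228129e-01 9.933153e-01   none    13.080695 -0.5533528
```

The four planted rhythmic TFs are recovered as class 1 (rhythmic in both
layers) with intron-based peak phases within ~0.1 h of the planted 6 h /
18 h, while the flat TFs are called non-rhythmic. `phase_diff` is the
exon-minus-intron peak time wrapped into (−12, 12]: the positive ~3.8 h
values show the exon-based activity lagging the intron-based one, as the
half-life low-pass predicts. The surrogate correlations
(`res$correlations`, against TF1's planted activity) make the same point:
for the TFs sharing TF1's phase, intron-based TFA correlates at
r ≈ 0.96–0.98 versus r ≈ 0.52–0.53 for exon-based (the antiphase module
mirrors this at r ≈ −0.96 vs −0.51), and the module clustering
(`res$modules`) separates the 6 h-peak TFs from the 18 h-peak TFs.

The simulator view, on a reduced ensemble (10 cells, 2 genes per
half-life bin; the acceptance runs use 100 cells and 6 genes per bin):

```r
b <- ensemble_benchmark(rep(c(20, 100, 1000), each = 2),
                        n_cells = 10, seed = 42)
b$by_halflife
```

```
  half_life    corr_u    corr_s n_genes
1        20 0.9653456 0.8565350       2
2       100 0.8957642 0.3430350       2
3      1000 0.9359892 0.1351507       2
```

corr(s, TF) collapses as the half-life grows; corr(u, TF) does not.

A thin CLI over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/introntfa.R", package="intronTFA"))')" \
    fixture --seed 3 --out fixture
```

with subcommands `simulate`, `quantify`, `regulon`, `tfa`, `rhythm`,
`correlate`, `cluster`, `fixture`, `run`.

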