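# gravirebound

Rapid stimuli — a few minutes of hypergravity, heat, or another acute
stress — reshape the transcriptome faster than mRNA pools can turn over.
Bulk RNA-seq taken at such short time points mixes two signals: newly made
precursor (unspliced, intron-bearing) transcripts and the standing pool of
mature (spliced) mRNA. `gravirebound` is an R package for analysing this
regime: it quantifies reads into spliced/unspliced/ambiguous layers,
tests differential expression per layer under shared normalization,
classifies the *rebound* behaviour of genes across adjacent time
contrasts, tests whether regulated genes distribute over chromosomes and
cytobands as uniform placement predicts, analyses differential exon usage
and its transcript biotypes, computes the protein coding counts ratio
(PCCR), and runs Fisher and preranked gene-set enrichment. A mechanistic
synthetic-data generator with known ground truth drives validation end to
end.

It is written for transcriptomics researchers studying fast
stress-response time courses (the motivating design is a 3-condition
layout — control, 3 min and 15 min of stimulus, four replicates each) and
for methodologists who want a self-contained, oracle-tested
implementation of the layered analysis stack.

## The models at the core

**Kinetics.** Each gene follows the standard two-stage cascade
(transcription → splicing → degradation):

    du/dt = α − βu,        ds/dt = βu − γs

with piecewise-constant rates: a step in α (transcription) or γ
(degradation of spliced mRNA) at stimulus onset, optionally reverting or
overshooting at a rebound time. Unspliced abundance *u* anticipates
future spliced abundance *s* — the premise that makes the layer split
informative. The simulator solves this in closed form (including the
β = γ degenerate case) and NB-samples counts per layer.

**Layer classification.** A read pair is `spliced` when an alignment gap
matches an annotated intron exactly and the blocks are exonic in the same
transcript; `unspliced` when any base overlaps sequence intronic in every
isoform of its gene; intronless genes are spliced by definition;
everything else is `ambiguous`.

**Differential expression.** Median-of-ratios size factors are computed
once from the total layer (spliced + unspliced + ambiguous) and reused
for every layer, so the layers stay comparable. Per gene and contrast a
two-group negative-binomial Wald test is used (moment dispersion with a
trend fitted across genes), with BH adjustment over observable genes.

**Rebound.** Genes are called up/down/ns per contrast
(FDR < 0.05, sign of log2 fold change); transition tables, refined
15-min categories (inner/outer grey, recovered, overshoot, continued)
and the Spearman anticorrelation of fold changes between adjacent
contrasts quantify the temporal inversion.

**PCCR.** Per gene and condition, PCCR = coding / (coding + noncoding)
transcript counts, noncoding = retained intron + ORF-lacking + NMD; a
change beyond one percent point between conditions classifies the gene
as increased/decreased.

## Worked example

```r
library(gravirebound)
library(dplyr)

ann   <- synthetic_annotation(n_genes = 1000, seed = 7, n_chroms = 8)
truth <- simulate_ground_truth(ann, seed = 8)     # known response classes
lc    <- simulate_layered_counts(simulation_design(), truth, seed = 9)
lc
#> <layered_counts> 1000 genes x 12 samples; layers: spliced, unspliced, ambiguous

de <- de_layers(lc, layers = c("total", "spliced", "unspliced"))
deA <- filter(de, layer == "total", contrast == "hypg3-Ctrl")
deB <- filter(de, layer == "total", contrast == "hypg15-hypg3")
rebound_correlation(deA, deB)
#>      rho n_genes frac_same_direction degenerate
#> 1 -0.523    1000              0.0581 FALSE

refine_grey_categories(call_regulation(deA), call_regulation(deB),
                       call_regulation(filter(de, layer == "total",
                                              contrast == "hypg15-Ctrl"))) |>
  count(direction_3min, category)
#>   direction_3min category       n
#> 1 down           inner_grey    45
#> 2 down           overshoot     59
#> 3 down           recovered     10
#> 4 up             continued     10
#> 5 up             inner_grey    35
#> 6 up             overshoot     95
#> 7 up             recovered      8

glance(compute_pccr(simulate_transcript_counts(truth, seed = 10)))
#>   n_genes n_increased n_decreased n_constant n_undefined
#> 1    1000         111          91        798         0
```

Reading: fold changes of the two adjacent contrasts anticorrelate
(Spearman −0.52 over all 1000 genes; restricted to differentially
expressed genes the anticorrelation is much stronger), only 5.8% of
genes regulated in both contrasts keep their direction, and most genes
regulated at 3 min have crossed past baseline ("overshoot") or sit in the
grey categories by 15 min — the rebound signature the simulator planted
and the pipeline recovers. The PCCR table recovers the simulated coding
fraction shifts (about 10% of genes each way).

A one-command synthetic run of the whole pipeline (counting from SAM,
per-layer DE, dynamics, regional tests, exon usage, biotypes, PCCR,
enrichment; every table plus an MD5 manifest):

```r
run_demo("demo_out", seed = 1)
```

or from a shell: `Rscript inst/scripts/gravirebound.R demo --out demo_out --seed 1`.

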