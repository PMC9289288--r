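---
title: "Layered RNA-seq analysis of rapid transcriptional rebound"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered RNA-seq analysis of rapid transcriptional rebound}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its methods: the kinetic model
behind the synthetic data, the layer-classification rules, the
statistical machinery, the parameters that matter and why their defaults
are what they are, and the limits of what the validation can show.

## The problem

Minutes-scale stimuli perturb transcription faster than mRNA pools can
re-equilibrate. A polyA bulk RNA-seq library taken 3 or 15 minutes after
stimulus onset therefore carries two distinguishable populations of
reads: junction/exonic reads from the standing pool of mature mRNA, and
intron-overlapping reads from freshly transcribed precursors. Because
precursors are spliced into the mature pool, the unspliced signal
anticipates the spliced signal; and because degradation acts only on
spliced molecules, a change confined to the spliced layer while the
unspliced layer is flat points to post-transcriptional regulation rather
than a change in transcription. The package's analyses are all built on
this asymmetry.

## Kinetic model and the synthetic-data generator

Each gene follows the linear cascade

$$\frac{du}{dt} = \alpha - \beta u, \qquad
  \frac{ds}{dt} = \beta u - \gamma s,$$

with transcription rate $\alpha$ (molecules/min), splicing rate $\beta$
(1/min) and spliced-degradation rate $\gamma$ (1/min), all
piecewise-constant. Before the stimulus the gene sits at steady state
($u = \alpha/\beta$, $s = \alpha/\gamma$). At $t = 0$ one rate steps by a
fold factor; optionally, at a rebound time it changes again to a multiple
of baseline. `solve_kinetics()` evaluates the closed-form solution
segment by segment; when $|\beta - \gamma|$ is below $10^{-9}$ of their
magnitude the $t\,e^{-\beta t}$ limit form replaces the generic solution
to avoid catastrophic cancellation. The closed form is verified against
`deSolve` numeric integration (segment-wise, so the integrator never
steps across a rate discontinuity) to a relative error below $10^{-6}$
over a grid of more than 100 parameter combinations including the
degenerate case.

Response classes are realised mechanistically, not by injecting fold
changes into count means:

* `transcriptional_up` — sustained $\alpha$ step (default fold 3);
* `post_transcriptional_down` — sustained $\gamma$ step-up (default
  fold 2): spliced abundance falls while expected unspliced abundance is
  untouched, the degradation signature;
* `rebound_up_then_down` / `rebound_down_then_up` — $\alpha$ steps that
  revert *past* baseline at 5 min (default post-rebound level 0.5× resp.
  2× baseline), producing a genuine temporal inversion for the dynamics
  stage to rediscover;
* `null` — no perturbation.

Defaults and the reasoning behind them:

* **Design**: three conditions (control; 3 min; 15 min of stimulus), four
  replicates each — the sampling layout of the motivating experiments.
* **Baseline rates**: $\beta = 1.5$/min, $\gamma = 0.5$/min,
  $\alpha \sim$ log-normal(median 150, sdlog 0.7). These deliberately
  describe *fast-turnover* genes (spliced half-life ≈ 1.4 min): only such
  genes can show count-level changes within 3 min at all, and they are
  the population the analysis is about. Baseline spliced abundance is
  then ≈ 300 counts at unit depth, with a realistic right-skewed spread.
* **polyA capture of unspliced molecules**: 0.15. PolyA enrichment
  depletes precursors; no measured value is available, so a single
  multiplicative factor is used, putting median unspliced counts ≈ 15 —
  detectable but clearly sparser than spliced, as in real libraries.
* **NB dispersion**: 0.05 with per-gene log-normal jitter (sdlog 0.3) —
  typical for a tight cell-culture experiment.
* **Ambiguous layer**: 10% of spliced in expectation; depth factors
  log-normal (sdlog 0.1).
* **PCCR generator**: per-gene per-condition totals log-normal around
  20 000 counts (condition-pooled over four replicates; the PCCR
  statistic is intended for well-quantified genes — at these depths the
  binomial noise of the coding fraction is ≈ 0.3 percent points, safely
  under the 1-point classification threshold). Shifted genes move 5
  percent points of coding mass at 3 min and recover half by 15 min.

All sampling is reproducible: seeds are explicit arguments, and the
generator restores the caller's RNG state.

What the generator does **not** emulate: positional read biases and
mappability, isoform-level expression correlation, batch structure,
library-preparation artefacts, multi-mapping reads, and expression
changes driven by chromatin context. Passing the recovery tests
therefore shows that the pipeline's inference is correct *given its
model assumptions*, not that those assumptions hold for any particular
real library.

## Layer classification

Rules, applied per read pair against the assigned gene (span containment
by exactly one gene; pairs touching several genes are unassigned):

1. **spliced** — some mate's alignment gap(s) coincide exactly (both
   boundaries) with annotated intron(s) of one transcript and all that
   mate's blocks lie within exons of the same transcript;
2. **unspliced** — any aligned base overlaps a position intronic in
   *every* transcript of the gene (the constitutive-intron region);
   this rule outranks rule 1 for a pair, so one precursor-evidence mate
   vetoes a junction mate;
3. **spliced by definition** — genes without any intron;
4. **ambiguous** — everything else, including gaps that match an intron
   at only one boundary (a deliberately conservative choice).

Secondary, supplementary and duplicate alignments are dropped (one vote
per fragment); a pair with an unmapped mate is classified by the mapped
mate. Strand is ignored: the interval logic does not need library
strandedness (a flag-level strand filter can be applied upstream if
desired). The classifier is validated on generated SAM fixtures whose
pairs are constructed to have unambiguous truth; agreement is exact by
construction and checked for every record.

## Differential expression

Size factors are median-of-ratios on the **total** layer and shared by
all layers — keeping spliced and unspliced tests on identical
normalization is what makes cross-layer comparisons meaningful.

Per-gene dispersion is method-of-moments (pooled within-condition),
shrunk toward a trend fitted across genes by loess of the *raw* moment
values on log mean. Fitting the trend on the raw scale matters: genewise
moments at $n = 4$ are extremely noisy, and a log-scale fit of the
positive values alone is biased low. The final estimate is the
equal-weight blend of trend and the positive part of the genewise value,
floored at $10^{-8}$.

The contrast is a two-group NB Wald test with the dispersion held fixed:
group means are fitted by Fisher scoring on *normalized* counts with unit
exposures. Working on normalized counts makes every statistic an exact
function of counts/size-factor — so rescaling any sample's counts
together with its size factor changes nothing, exactly, and swapping the
groups negates the fold change with identical p-values. (A raw-count NB
fit with offsets satisfies these invariances only approximately.) The
efficiency cost of ignoring the per-sample Poisson-term differences is
negligible at the design's depth spread (sdlog 0.1). Genes whose mean
normalized count over the contrast's samples is below 5 are
non-observable: no FDR is assigned and they are excluded from the BH
family. Fold-change shrinkage is deliberately absent — downstream calls
are sign + FDR based.

Null calibration is checked by simulation: at the study design (2000
genes, 4 vs 4, dispersion 0.05) the fraction of null p-values below 0.05
must land in [0.03, 0.07].

## Temporal dynamics

Calls are up / down / ns per contrast (FDR < 0.05 and sign of lfc; an
exact zero lfc is ns — direction undefined). Transition tables
cross-tabulate calls between adjacent contrasts over genes observable in
both; the cells partition that universe. The refined 15-min categories
follow, for a gene regulated at 3 min, from the triple of calls
(3 min vs control, 15 vs 3, 15 vs control): crossing past baseline is
`overshoot`; persisting in direction is `continued`; flat between 3 and
15 min but still displaced from control is `inner_grey`; moving back but
still displaced is `outer_grey`; indistinguishable from control is
`recovered`.

The rebound statistic is the Spearman correlation of fold changes
between adjacent contrasts. Its default universe is all genes observable
in both contrasts; a DEG-restricted mode (significant in at least one
contrast) is provided. The two universes measure different things, and
the difference is structural: the two contrasts share the 3-min samples,
so even pure-noise fold changes correlate at about $-0.5$, and a mixture
with, say, 25% strongly rebounding genes cannot fall much below
$\approx -0.78$ on the all-gene universe no matter how strong the
effects are (rank arithmetic: the null block keeps internal correlation
$-0.5$ while the responsive genes occupy anti-aligned extreme ranks).
The DEG-restricted universe isolates the regulated genes' behaviour and
is where strong anticorrelation (≲ −0.85) is expected and found in the
recovery tests.

`cross_dataset_coherence()` generalizes the transition machinery to a
series of call tables ordered by exposure time, restricted to genes
detected in all datasets, with per-step directional coherence and the
recurrently regulated subset (non-ns in at least 3/5 of the series by
default).

## Genomic distribution

Under uniform placement, a region's expected DEG count is its detected
genes times the global DEG fraction; the expected upregulated count
among a region's DEGs is the region's DEG count times the global up
fraction. Both identities conserve totals exactly, on every input — this
is asserted, not approximated. Two two-sided Fisher tests per region
(DEG enrichment; up/down skew) are BH-adjusted within their families;
regions with no detected gene are dropped before adjustment (untestable
rows would only dilute the family). Direction of deviation is annotated
separately from the p-value because the tests are two-sided. Spearman
correlations between expected and actual vectors summarize how closely
placement follows uniformity. The same machinery runs at chromosome and
cytoband level; cytoband assignment takes the band containing a gene's
strand-aware 5' end (the natural anchor when a gene spans a boundary).

## Differential exon usage and biotypes

Exons of a gene's transcripts are flattened into disjoint bins at all
boundaries, with parent-transcript sets recorded. Bin counting assigns a
pair to every bin any of its blocks overlaps (integer counting; a
junction pair legitimately supports both flanking bins — fractional
schemes were rejected for determinism). The usage test models the bin
count as NB with the per-sample gene total as exposure, i.e. it tests
the bin's *proportion*; gene-level expression changes cancel by
construction (doubling one condition's counts moves usage not at all).
Here the offsets are genuine exposures, so raw counts are used — the
scale-invariance argument of the DE test does not apply. Genes with one
bin carry no test. Per-gene significance is the Šidák-aggregated minimum
bin p ($1 - (1 - p_{\min})^k$ over $k$ observable bins), BH-adjusted
across genes — simpler than DEXSeq's per-gene q machinery but with the
same call semantics, and validated on simulated usage shifts.

Significant bins map to all their parent transcripts, deduplicated per
direction (a transcript hit by bins of both signs appears once in each
direction). Biotype tallies and the biotype–DEG association follow; the
association's 2×2 (up/down × this-biotype/other-biotypes) counts
gene–biotype pairs by default because a gene hosting DU transcripts of
two biotypes genuinely belongs to both groups; an exclusive-gene mode is
provided since the alternative reading is defensible. Groups with fewer
than 20 DEGs are excluded before FDR adjustment.

## PCCR

PCCR = coding / (coding + noncoding) transcript counts per gene and
condition, noncoding = retained intron + ORF-lacking + NMD. lncRNA is
excluded from both pools by default — that is the ratio's defining
formula — with `include_lncrna = TRUE` to fold it into the noncoding
pool, since the broader narrative reading groups it with the noncoding
classes; both definitions are first-class. Classification uses a strict
one-percent-point threshold on the raw (unrounded) ratio difference;
ties are `constant`; an empty pool in either compared condition makes
the gene `undefined` and excludes it downstream. PCCR is exactly
invariant to condition-wise depth rescaling and classification is
antisymmetric under condition swap — both asserted as identities.

## Enrichment

Overrepresentation is a two-sided Fisher test on set membership after
intersecting sets with the detected universe. Preranked enrichment ranks
genes by a statistic (ties broken by gene id for determinism) and
computes the weighted running-sum score (weight $|stat|$, exponent 1).
The null is gene-label permutation; when the number of distinct same-size
subsets does not exceed the permutation budget the null is enumerated
*exhaustively*, making small-universe p-values exact — this is also how
the implementation is validated. The p-value is one-sided among nulls
sharing the observed score's sign; the normalized score divides by the
mean absolute null score of that sign (this differs from FGSEA's
convention; the sign-conditional form is kept because it pairs naturally
with the sign-conditional p-value). Sets larger than 400 genes are
excluded before testing. The smallest achievable sampled p is
$1/(n_{perm}+1)$ — a documented floor; very small p-values need a larger
budget, and no multilevel estimator is attempted. The packaged
55-gene cytoskeletal–nuclear mechanical-axis set (lamins, actins,
tubulins, LINC complex, nuclear pore complex and associated factors) is
a reconstruction from the named families, completed from the standard
human nucleoporin complement.

## Pipeline

`run_pipeline()` drives all stages from one config (YAML-loadable; all
thresholds surfaced: call FDR 0.05, PCCR threshold 0.01, biotype group
minimum 20, set-size cap 400). Outputs are plain TSV plus a manifest
with MD5 checksums; under fixed seeds a rerun is byte-identical, which
the tests assert. `run_demo()` is the one-command synthetic end-to-end
run; `inst/scripts/gravirebound.R` is a thin shell wrapper over these
functions.

## Problem sizes and numerical choices

The validation suite works at sizes chosen to make every stochastic
check stable while keeping a full run in minutes on one CPU: 2000-gene
simulations for calibration/recovery checks, 10 000 labelled read pairs
for the classifier fixture, 100 replicate placement simulations for the
regional tests, 200 random rankings for permutation-uniformity, and a
~100-point parameter grid for the kinetics oracle. Tolerances: kinetics
$10^{-6}$ relative against the integrator; statistical-primitive oracles
to floating-point accuracy; exact (`identical`) assertions for the
conservation and antisymmetry identities.

## Known limitations

* The DE stage is a deliberately self-contained NB Wald stand-in; it
  does not reproduce DESeq2's Cox–Reid dispersion, LFC shrinkage,
  outlier handling or independent-filtering threshold optimization, and
  only two-group contrasts are supported.
* Layer classification assumes the annotation is complete: reads from
  unannotated isoforms inflate the unspliced/ambiguous layers.
* Detection power at 3 minutes is information-limited for modest fold
  changes at four replicates and dispersion 0.05; a twofold degradation
  step is recovered in roughly three quarters to four fifths of
  fast-turnover genes — this is a property of the design, not of the
  estimator, which sits close to the Fisher-information bound.
* The permutation-null enrichment cannot certify p-values below its
  permutation floor.
* The generator's simplifications listed above bound what green tests
  imply about real libraries.
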