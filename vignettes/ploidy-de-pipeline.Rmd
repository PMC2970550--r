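---
title: "Replicate-overlap differential expression and promoter motif enrichment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Replicate-overlap differential expression and promoter motif enrichment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidyseq)
```

## The model

ploidyseq implements a differential-expression procedure for the setting
where two conditions — here haploid (1n) and tetraploid (4n) yeast — are
compared across replicate *pairs* rather than within-condition replicates.
There is therefore no per-gene dispersion to estimate; instead the method
treats each sample's counts as a multinomial draw over the transcriptome and
asks, gene by gene, whether one sample's count is plausible under the other
sample's frequency.

For gene $g$ with counts $k_h$, $k_t$ and library totals $N_h$, $N_t$, the
frequencies are $f_h = k_h / N_h$ and $f_t = k_t / N_t$. The tetraploid
observation is tested against $X \sim \mathrm{Binomial}(N_t, f_h)$ with the
one-sided tail in the observed direction: the cumulative mass function
$P(X \le k_t)$ when $f_t \le f_h$, and $P(X \ge k_t)$ otherwise. The
reciprocal p-value tests $k_h$ against $\mathrm{Binomial}(N_h, f_t)$ in the
mirrored direction. A gene is a per-pair candidate when **both** p-values
fall below $\alpha = 0.001$ — the only reading under which computing both
tails has any effect. Degenerate frequencies use the conventions
$P(X \le k \mid f{=}0) = 1$ and $P(X \ge k \mid f{=}0) = 0$ for $k > 0$, so
a gene silent in one ploidy and read in the other is maximally significant
in exactly one direction.

Candidates are ranked by frequency fold change $f_t / f_h$ (repressed
ascending, induced descending; ties broken lexicographically by gene id),
and the final differential set is the overlap of equal numbers of
top-ranking candidates from the two replicate pairs. The top-N is chosen
adaptively: over a grid of candidate values, the largest N is kept whose
overlap remains hypergeometrically significant at $p < 10^{-10}$ against
random sampling from the expressed-gene background. This replicate-overlap
step, not the per-gene $\alpha$, is what controls false positives (see
*Known limitations*).

## Statistical properties, honestly stated

The binomial test conditions on the other sample's **estimated** frequency
as if it were the true parameter. Under a resampled null in which both
samples are independent multinomial draws from the same profile, the count
difference has roughly twice the variance the test assumes, so the realized
per-pair pass rate at $\alpha = 0.001$ is about
$P(|Z| > z_{0.001}/\sqrt{2}) \approx 0.03$ for well-expressed genes — far
above $2\alpha$, and essentially independent of depth. The test suite and
the acceptance script measure exactly this. The procedure's real guarantee
is joint: false candidates are not *shared* between independent replicate
pairs, so the adaptive overlap step returns an empty final list under the
null (verified by simulation in the tests). Users should treat per-pair
candidate lists as enriched-but-contaminated and only interpret the overlap
set.

Sensitivity is excellent in the regime the design targets: planted fold
changes of 4 (either direction) on genes with expected count ≥ 100 per
sample are recovered by the caller with sensitivity indistinguishable from 1
in the packaged simulations (200 seeded runs).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 0.001 | per-tail binomial threshold, applied to both reciprocal p-values |
| `min_count` | 15 reads | expressed threshold; a gene counts as expressed when it reaches this in **at least one** sample |
| `p_max` | 1e-10 | maximal hypergeometric overlap p for the adaptive top-N |
| `top_n_grid` | multiples of 5 | candidate top-N values |
| `pseudocount` | 0.5 | substituted for zero counts in fold-change ranking only, never in p-values |
| cutoff grid | 0.30–1.00 by 0.05 | motif match cutoffs as fractions of the matrix maximum score |
| motif filters | p ≤ 0.005, set freq ≥ 0.25, fold ≥ 1.5 | all inclusive |

The at-least-one reading of the expressed rule is deliberate: genes silenced
in one ploidy but expressed in the other (e.g. haploid-specific mating
genes) are exactly the genes the analysis must keep.

## Promoter definition and motif scanning

A gene's promoter spans 50 bp downstream of the annotated coding start plus
upstream sequence to the nearest edge of the closest annotated feature lying
strictly upstream (any feature type: ORF, Ty, tRNA, ...), capped at 5 kb;
features overlapping the coding start are skipped when resolving that
boundary, minus-strand genes are mirrored, and regions clip at contig
edges.

Motifs are width-by-4 log-likelihood matrices: a window's score is the sum
of per-position entries, zero means "matches the background model", and the
maximum score (sum of per-position maxima, required positive) is the
consensus score. A promoter's score is the best window on **either strand**
— regulatory motifs are orientation-ambiguous and the public matrix
compendia are strand-agnostic, so double-stranded scanning is the
defensible default. Ambiguous bases (N) score the per-position minimum,
which cannot create spurious matches. Probability-form matrices are
converted with $\log_2(p'/b)$ against a configurable background (uniform
0.25 by default), with a small pseudo-probability (0.01) mixed in so absent
bases score large-but-finite negatives; a background-equal row converts to
zeros, preserving the zero-equals-background property.

For each gene list the scanner evaluates all fifteen cutoffs
$c \in \{0.30, \dots, 1.00\}$, computes set and background match
frequencies, takes the one-sided binomial enrichment p-value at the
background rate, and reports the cutoff minimizing p (ties toward the
smaller cutoff), retaining the whole grid curve. Because the minimum is
taken over a grid, the reported p is optimistically biased; the three-way
filter and the planted/null simulations in the test suite are the guard
against over-reading it.

## The synthetic-data generator

The generator exists so that every stage is testable without downloads, and
its defaults encode the study conditions the pipeline was built for: 6,000
genes, 9 million reads per sample, two replicate pairs, a log-normal
frequency profile (`freq_log_sd = 1`; the transcriptome shape is not
prescribed anywhere, and log-normal is the conventional heavy-tailed
choice), planted folds of 4–8 (reciprocal for repressed genes), and
intergenic gaps of 200–6,000 bp so both the feature-bounded and the
5 kb-capped promoter cases occur.

Counts are drawn multinomially per sample — not as per-gene independent
binomials — so library totals are exact, matching their use as the frequency
denominator. Planted differential genes are drawn from the expression band
of 1–10× the detectability floor (expected count 100 per sample by
default): planting large folds on the most abundant transcripts would move a
visible fraction of library mass, and after renormalization every other
gene would drift in frequency, which is not the situation the method
addresses (real differential sets are a negligible mass fraction). Motif
sites are planted by overwriting the consensus string (no indels, so all
coordinates stay stable) at a uniform position in the promoter, on a random
strand; the toy genome also plants one feature overlapping a gene's coding
start so the promoter skip rule is exercised.

What the generator does **not** emulate: read-level artifacts (sequencing
error, mappability, GC bias), biological overdispersion between replicate
cultures, correlated gene programs, or realistic motif information content.
Passing tests therefore demonstrate the correctness of the procedure's
logic and its statistical behaviour under its own model assumptions, not
performance on real libraries.

One global seed determines everything; sub-generators derive independent
streams from it, and regenerated datasets (and all files written by
`cmd_simulate`) are byte-identical for a fixed configuration.

## Numerical and design choices

- Binomial and hypergeometric tails go through R's regularized
  incomplete-beta implementations (`pbinom`, `phyper`), which are log-space
  stable at library scale ($N$ up to $10^8$); the test suite checks them
  against exact-summation and subset-enumeration oracles at small sizes.
- Fractional counts from 1/n multimap weighting are floored to integers
  before the binomial model (the model is defined on integers); fold
  changes use the raw fractional counts.
- Multimap hits are assigned to the feature containing the hit midpoint,
  strand-agnostically; when overlapping features both contain a midpoint
  the lexicographically smallest feature id wins, so no read ever
  contributes more than total weight 1.
- All coordinates are 1-based closed intervals throughout, the
  R/Bioconductor and GFF3 convention, so no internal conversion layer
  exists to get wrong.
- Repressed and induced genes are ranked, overlapped and reported as
  separate lists; the library totals ("all uniquely mapped reads") are taken
  literally as the frequency denominator and are carried in the count-table
  headers rather than recomputed from ORF sums.
- Promoter extraction has a single-gene reference implementation and a
  vectorized batch implementation; a test asserts their agreement on random
  genomes.

## Problem sizes used in the packaged checks

The test suite and acceptance script run the null simulation at 10,000
genes × 1e6 reads, planted-fold sensitivity over 200 seeded simulations
(1,000 genes each), and planted-motif recovery end to end over 40 planted
plus 40 null genomes of 5,000 genes (60-gene target sets, 50% planting
against a 5% background rate). The study-scale synthetic run in the
acceptance script uses the full 6,000 genes × 9e6 reads with 35 repressed
and 30 induced planted genes. These sizes were chosen to estimate each rate
with useful resolution while keeping a complete run in the minutes range on
one core.

## Known limitations

- The per-pair binomial test is anti-conservative under a resampled null
  (see above); at least two replicate pairs are required and only the
  overlap set is interpretable.
- No dispersion modelling, shrinkage, or FDR control across genes: the
  design substitutes a fixed α plus replicate overlap.
- GO term sets are consumed as flat, pre-propagated assignments; ontology
  DAG propagation and evidence-code filtering are out of scope.
- Alignment is external: the counts module consumes gene-level counts or a
  BED-like hit table, not SAM/BAM.
- The motif background model is uniform by default; the published matrix
  compendia do not restate theirs, so this is a configurable stand-in.
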