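---
title: "Methods: discovering and characterizing unannotated miRNAs with knmir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and characterizing unannotated miRNAs with knmir}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knmir)
```

## The problem

Small RNA-seq of tumour cohorts routinely contains read stacks at loci that
no miRNA annotation covers.  Some of these are genuine miRNAs — hairpin
precursors processed by Drosha/Dicer into a defined mature strand — and a
subset of them is differentially expressed between tumour and normal tissue,
associated with patient survival, or both.  knmir implements, end to end,
the analysis that takes aligned small-RNA reads to a characterized panel of
previously unannotated miRNAs: locus discovery, a filter cascade, TMM
quantification with expression gates, paired differential expression,
tertile survival analysis, seed-weighted target prediction with a
scrambled-sequence null, and pathway over-representation.

Everything runs on synthetic data with planted ground truth, so every stage
is verifiable: the generator controls effect sizes, noise, and the planted
loci/sites, and the test suite measures recovery against that truth.

## Synthetic data: what is emulated, and what is not

`sim_config()` fixes the study conditions.  The defaults describe a
desk-scale paired cohort: 30 planted hairpin loci and 20 structureless
decoys in a random genome; 50 reads per locus; 30 tumour/normal pairs;
negative-binomial counts with dispersion 0.1 (variance $\mu + \phi\mu^2$,
the standard RNA-seq noise model); exponential survival with a baseline
hazard of 1/1000 per day and a hazard ratio of 3 for the top expression
tertile of two designated loci; 30% censoring; and 200 synthetic 3'UTRs.

Choices worth making explicit:

* **Dicer-like processing** is operationalized as 5'-end homogeneity: 85% of
  a hairpin's reads start exactly at the mature 5' end, 10% form a minor
  star-arm stack, and the rest carry 1-2 nt of jitter, so the modal 5' end
  holds at least 80% of locus reads.  Decoy loci get the same depth as a
  smear with heterogeneous 5' ends.  Real data adds isomiR 3' heterogeneity,
  adapter artefacts and sequencing error, none of which are modelled — so a
  passing recovery test shows the *statistical* machinery works, not that
  real-library artefacts are handled.
* **Planted hairpins** are perfect inverted repeats (22-nt mature arm, 8-12
  nt loop, exact reverse-complement star arm).  Genuine precursors carry
  bulges and wobbles; the folding score threshold is therefore easier to
  meet here than in real data.
* **Survival times** are exponential; censoring is administrative at the
  $1-\text{censor\_rate}$ quantile of the baseline time distribution, so
  the realised censoring fraction matches the configured rate for
  baseline-hazard patients.
* **Target sites** are exact reverse complements of the full miRNA, drawn
  from a shared pool of `n_target_pool` UTRs so that distinct miRNAs share
  target genes (as miRNA families do) and the "targeted by at least 10% of
  miRNAs" aggregation rule has something to aggregate.  Real sites are
  mostly seed-matched with imperfect 3' pairing; recovery of perfect sites
  is deliberately the easy case that pins the machinery, not an estimate of
  real-data sensitivity.

## Locus discovery

`stack_reads()` merges same-strand reads whose gap is at most `max_gap`
(default 30 nt, comfortably above the loop span so both hairpin arms join
one locus, and far below inter-locus spacing); loci longer than
`max_precursor_length` (120 nt) are split at the deepest coverage valley.

`fold_hairpin()` maximizes summed pair weights (G–C = 3, A–U = 2, G–U = 1)
over nested structures with hairpin loops of at least `min_loop = 3` nt by
Nussinov-style dynamic programming with full traceback.  This weighted
pairing score stands in for a thermodynamic free energy: it preserves the
ordering "more and stronger pairs = more stable" while remaining exactly
testable against exhaustive enumeration (the suite checks DP = brute force
on hundreds of short sequences).  Traceback is deterministic: position *i*
pairs with the smallest admissible partner achieving the optimum, else
stays unpaired.

`randfold_pvalue()` scores folding stability against dinucleotide-preserving
shuffles (Altschul–Erickson Eulerian-walk shuffles, exact dinucleotide
composition): $p = (c+1)/(n+1)$ with $c$ the number of shuffles scoring at
least the observed score.  Two properties matter:

* The attainable minimum is $1/(n+1)$; with the default 99 shuffles a
  planted hairpin reaches $p = 0.01$.
* Because the pairing score is an integer with a concentrated null
  distribution (for a 70-mer, the modal score carries roughly a fifth of
  the shuffle mass), the $\geq$-tie rule makes these p-values noticeably
  *conservative*: on random sequences the mean p is about 0.6 rather than
  0.5, and the empirical CDF sits below the uniform diagonal.  They remain
  valid for filtering at $p < 0.05$ (validity $P(p \le t) \le t$ is what a
  filter needs, and is asserted in the tests), but they are not uniform the
  way continuous-energy shuffle p-values are.  This is an inherent property
  of a discrete score, not a tunable.

`score_candidate()` recognizes the Dicer signature: the mature arm is the
maximal read stack (modal 5' end, modal length), the star arm is the region
base-paired to it extended by the canonical 2-nt 3' overhang, and the
signature score is (fraction of reads consistent with the mature/star/loop
partition, within 2 nt) x (modal-5' fraction).  A candidate is emitted when
at least half the mature positions are paired and the signature reaches
`min_signature = 0.6`.  The cutoff is a package default — the upstream
literature does not publish one — and is deliberately configurable; at the
generator's conditions it separates planted stacks (signature about 0.85)
from smears (below 0.05) with a wide margin.

## The filter cascade

`apply_filter_cascade()` applies, in a fixed order, with every transition
recorded in an auditable `filter_report`:

1. read support: locus reads >= 10;
2. decoy overlap: any (>= 1 bp, strand-blind) overlap with provided
   rRNA/tRNA intervals rejects the candidate — any BED of decoy intervals
   is accepted;
3. folding p-value < 0.05 (strict);
4. duplicate removal: identical *mature* sequences collapse to the
   highest-signature locus;
5. homology screen: best E-value against the known-miRNA set below 0.1
   means "previously annotated", and the candidate is dropped;
6. GC outliers: mature-sequence GC content beyond 2 *population* standard
   deviations from the current set's mean, single pass.

The order is pinned by a test in which swapping steps 4 and 5 would change
the outcome.  GC is computed on the mature sequence (the quantity that
identifies the miRNA); duplicate identity likewise keys on the mature
sequence.

The homology screen replaces an external BLASTN call: Smith–Waterman local
alignment (match +1, mismatch −2, gap open −5, gap extend −2, via
Biostrings) plus ungapped Karlin–Altschul statistics,
$E = K m n e^{-\lambda S}$.  $\lambda$ solves
$\sum_{ij} p_i p_j e^{\lambda s_{ij}} = 1$ under uniform base composition;
$K$ uses the standard lattice series
$K = \lambda e^{-2\sigma} / (A\,(1 - e^{-\lambda d}))$ evaluated by exact
convolution of the score walk.  For the default scores this reproduces the
published ungapped BLASTN constant ($\lambda = 1.33$, $K = 0.621$) to four
significant digits, which the tests anchor.  A 22-nt exact match scores
$E \approx 10^{-9}$ against a $10^5$-nt database — orders of magnitude
below the 0.1 threshold — so the screen's decisions are insensitive to the
few-percent accuracy of $K$.

Retained candidates get identifiers `Knm<chrom>_<serial>`, the serial being
the 1-based rank in (chromosome, start)-sorted order over the genome-wide
set.

## Quantification, TMM, and expression gates

`count_matrix()` assigns a read to a locus when at least 50% of the read's
length overlaps it on the same strand (ties to the lower-start locus);
assigned + unassigned = total, checked by a brute-force oracle.

`tmm_factors()` implements trimmed-mean-of-M-values normalization from its
definition: reference = sample whose 75th-percentile count fraction is
closest to the mean of those fractions; per sample, over loci nonzero in
both, $M = \log_2\frac{y_k/N_k}{y_r/N_r}$,
$A = \tfrac12 \log_2\left(\frac{y_k}{N_k}\cdot\frac{y_r}{N_r}\right)$;
two-sided trims of 30% on M and 5% on A (the method's canonical defaults;
rank-based, like the reference implementation); inverse
delta-method-variance weights
$w^{-1} = \frac{N_k-y_k}{N_k y_k} + \frac{N_r-y_r}{N_r y_r}$; factor
$= 2^{\sum wM/\sum w}$; factors rescaled to geometric mean 1.  The suite
checks exactness on degenerate designs, agreement to $10^{-10}$ with an
independent straight-line recomputation, and agreement with
`edgeR::calcNormFactors` to 2% on a well-behaved fixture.  Normalized
values are TMM-scaled counts per million: value
$= 10^6\, y / (N f)$, so each column sums to $10^6/f$.  The published
"TMM > 0.1" gates are interpreted on this CPM scale.

Three gates are provided: summed raw reads >= 10; normalized value > 0.1
(strict) in at least one sample; and normalized value > 0.1 in at least
$\lceil 0.10\, n \rceil$ samples — ceiling rounding, so 71 samples require
8.

## Differential expression

`paired_de()` runs a paired Student t-test per locus on the per-pair
differences of normalized values (the cohort is paired; an unpaired Welch
variant sits behind `method = "welch"`, and `log2_values = TRUE` tests
log-scale values).  Fold change is the mean over pairs of
$(T + \varepsilon)/(N + \varepsilon)$ with pseudo-expression
$\varepsilon = 0.01$, guarding near-total-loss loci.  Identical
tumour/normal columns give $t = 0, p = 1$; zero variance around a nonzero
difference yields `NaN` with a warning and is excluded from the BH
denominator.  BH adjustment delegates to `stats::p.adjust`, the canonical
implementation of the step-up rule.  `hier_cluster()` is average-linkage
agglomeration on $1 - r$ (Pearson), via `stats::hclust`, with merge heights
verified against a naive $O(n^3)$ recomputation.

At the generator's conditions (counts around 200, dispersion 0.1, 30
pairs), a planted 4-fold change is detected essentially always, and
all-null cohorts hold the nominal 5% type-I error — the suite measures
both, pooling 200 replicates for calibration.

## Survival analysis

`tertile_groups()` sorts patients from high to low expression (stable ties
by patient id); the top and bottom $\lfloor n/3 \rfloor$ form the high and
low groups, and the remainder stays in mid, keeping the extreme groups
balanced.  The comparison is high vs low with mid excluded
(`high_vs_rest` is available but off by default).

`weighted_logrank()` implements the weighted log-rank family from its
definition, with the hypergeometric variance and tied event times grouped:
$U = \sum_j w_j (d_{1j} - d_j n_{1j}/n_j)$,
$V = \sum_j w_j^2\, d_j \frac{n_{1j}}{n_j}\left(1-\frac{n_{1j}}{n_j}\right)\frac{n_j-d_j}{n_j-1}$,
$U^2/V \sim \chi^2_1$; $w_j = n_j$ gives Gehan–Breslow–Wilcoxon (early
differences up-weighted), $w_j = 1$ the log-rank.  Terms with $n_j = 1$
contribute nothing to $V$.  The chi-square p agrees with a
20,000-permutation null within Monte-Carlo error, the log-rank weighting
agrees with `survival::survdiff`, and the GBW's early-difference advantage
is checked as a trend on piecewise-hazard simulations.

## Target prediction

`duplex_align()` is a Smith–Waterman-style local alignment in which the
miRNA is read antiparallel to the UTR and positions score by base-pairing
ability: complement +5, G:U wobble +1, mismatch −3, gap open −9, gap
extend −4 — the classic parameterization for this task — with pair scores
at miRNA seed positions 2–8 multiplied by 4.  All non-overlapping local
maxima are returned.  A perfect 22-nt site scores
$15\times5 + 7\times20 = 215$, safely above the published acceptance
threshold of 140.

`duplex_energy()` sums nearest-neighbor stacking free energies over
consecutive pair steps plus 4.09 kcal/mol duplex initiation; interior
loops and bulges cost a flat +3.0 kcal/mol each.  The Watson–Crick step
table carries the ten standard Turner/Xia parameters; steps involving a
G:U wobble use a flat −0.5 kcal/mol.  That wobble simplification is
deliberate: a handful of published wobble stacks are destabilizing, and a
uniformly negative table preserves the invariant that extending a duplex
never raises its energy — an invariant the tests assert over the whole
table.  Predictions require score >= 140 *and* energy <= −20 kcal/mol.

`scramble_null_filter()` re-runs the full predictor for five uniform
random permutations of each miRNA (the scramble is a plain permutation,
not dinucleotide-preserving — it emulates a scrambled-oligo control, and a
swap to `dinucleotide_shuffle()` is a one-liner for users who want
composition-matched nulls); any gene predicted for a scramble kills the
true prediction for that gene (`mode = "overlap"` restricts the kill to
coordinate-overlapping sites).  `aggregate_targets()` keeps genes targeted
by at least $\lceil 0.10\, n_{\text{miRNA}} \rceil$ distinct miRNAs.

## Pathway enrichment

`enrich_pathways()` is an explicit upper-tail hypergeometric test of the
aggregated target genes against user-supplied gene sets (GMT), BH-corrected,
with the universe defaulting to the union of pathway genes.  The worked
configuration — universe 10, pathway 5, query 5, overlap 5 — gives exactly
$1/\binom{10}{5} = 1/252$, and the closed form matches $10^5$-draw
Monte-Carlo sampling on randomized configurations.

## The pipeline driver

`run_pipeline()` executes simulate → discover → filter →
quantify/normalize/gate → de → survival → targets → enrich, logging every
threshold applied, writing plain-text outputs per stage, and deriving one
RNG stream per stochastic stage from the single configured seed, so a rerun
with the same configuration is byte-identical.  The bundled
`inst/extdata/demo_config.yaml` runs the whole pipeline in well under a
minute on one CPU.

## Problem sizes and numerical choices

The test suite and the acceptance script use: 200 random sequences of
length <= 12 against the exhaustive folding oracle; 500 random 70-mers with
99 shuffles for p-value calibration; a constructed 50-pass +
10-per-step-fail cascade fixture; 100-locus, 30-pair cohorts (10 planted
log2FC = 2) for DE recovery plus 200 all-null replicates for calibration;
a 40-patient fixture against a 20,000-permutation null and 500 replicates
at hazard ratio 1 for survival; 10 miRNAs x 200 UTRs (seed 23) for target
recovery; and 20 random configurations x $10^5$ draws for the enrichment
Monte-Carlo.  These sizes make every stochastic check reproducible in
seconds to a couple of minutes while leaving the binomial/Monte-Carlo error
bands tight enough to be informative.

Numerical points: the folding DP breaks ties deterministically; TMM trims
are rank-based so trimmed counts are integers; the E-value's $K$ is
computed once per scoring scheme; tertile ties break on patient id;
weighted-log-rank variance terms with one subject at risk are dropped; and
all coordinates are 0-based half-open (BED convention) everywhere.

## Known limitations

* The folding surrogate has no thermodynamic units; its shuffle p-values
  are conservative (see above) and its "free energy" ordering is coarser
  than a nearest-neighbor folder's.
* The generator does not model sequencing error, adapters, isomiR 3'
  heterogeneity, GC bias, or batch structure; recovery rates on synthetic
  data are upper bounds for real libraries.
* Survival handling is two-group weighted log-rank only — no proportional
  hazards modelling, no covariates.
* The enrichment test is a plain hypergeometric over user-supplied sets;
  curated multi-source pathway memberships are out of scope, so enriched
  pathway *counts* are not comparable to analyses run against such
  resources.
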