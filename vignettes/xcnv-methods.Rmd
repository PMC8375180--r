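---
title: "Methods: CNV unification, feature engineering and MVP scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CNV unification, feature engineering and MVP scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xcnv)
```

## The problem

Copy-number variants (CNVs) — deletions (losses) and duplications (gains) of
genomic segments — are a major source of human genetic variation, and a
fraction of them cause disease. Two practical obstacles stand between raw CNV
call sets and a clinically usable pathogenicity estimate. First, the same
underlying event is reported with different breakpoints by different
platforms and calling pipelines, so population databases are full of
redundant near-duplicate records; any allele-frequency estimate computed on
the raw records is wrong. Second, pathogenicity is not a property of any
single annotation: length, dosage type, population frequency, per-base
deleteriousness and conservation, regulatory context and gene-level
haploinsufficiency all carry signal. `xcnv` implements a complete pipeline
for both problems: breakpoint-tolerant unification of redundant calls, a
fixed 30-column annotation feature matrix, a gradient-boosted classifier
whose probabilistic output is the meta-voting prediction (MVP) score, and a
five-tier classification of that score.

## CNV unification by iterative maximal cliques

Coordinates are 1-based inclusive throughout (`length = end − start + 1`);
BED input is converted on read. For two calls $i, j$ on the same chromosome
the breakpoint distance is the Chebyshev distance

$$D_{i,j} = \max(|S_i - S_j|,\; |E_i - E_j|)$$

on the (start, end) pairs. A genomic window $GW = 100$ bp defines binary
similarity: calls with $D_{i,j} < GW$ are indistinguishable (similarity 1),
calls with $D_{i,j} > GW$ are distinct. The boundary $D = GW$ is not covered
by that dichotomy; we score it 0 (distinct), reading the window as the
smallest distance at which two CNVs can be told apart.

Similar calls are joined into an undirected graph and each connected
component is decomposed by iteratively removing a maximum clique until no
node remains; each removed clique is one unified CNV. Cliques (rather than,
say, connected components) matter because similarity is not transitive: a
chain of calls can drift arbitrarily far while staying pairwise-connected,
and a clique guarantees *every* pair is within the window. Three choices
here were genuinely open and are fixed as follows:

* **Gains and losses never merge.** A duplication and a deletion with
  identical breakpoints are biologically distinct events, so graph edges
  require equal `cnv_type`.
* **Tie-breaking.** Equal-size maximum cliques are resolved toward the
  lexicographically smallest sorted member-id tuple, making the partition
  deterministic regardless of enumeration order (clique enumeration itself
  is delegated to igraph, whose internal order is not contractual).
* **Representative coordinates.** The unified interval takes the
  per-coordinate median of member starts and ends (rounding half up), which
  is robust to a single outlier breakpoint in a clique.

Graph construction sorts calls per chromosome and type and only compares
pairs whose starts differ by less than $GW$ — a necessary condition for
similarity — avoiding the quadratic all-pairs scan; a test asserts equality
with the naive graph. A brute-force subset-enumeration oracle checks the
clique partition on random graphs of up to 12 nodes.

## Population allele frequency

Unified CNVs carry per-ethnic-group carrier counts: distinct samples
(records without a sample id count singly) per group, over nine group codes
(AFR, AMR, ASJ, EAS, FIN, NFE, SAS, OTH, UKN; unknown groups map to UKN
rather than being dropped). The allele frequency of a group is carrier
frequency — the fraction of the group's samples carrying the CNV — not an
allele-count frequency; the package does not model diploid genotypes.

A query CNV is assigned a population AF by matching it against a reference
database of unified CNVs at **70% reciprocal overlap** (RO): the overlap
width divided by each interval's own length must both reach 0.7. Matching is
restricted to the query's own CNV type; among qualifying entries the best-RO
match wins, with ties resolved toward the higher AF so results are
deterministic. A query with no qualifying match gets AF 0 — an unobserved
CNV is treated as rare rather than unknown. In the feature matrix the AF is
split into a gain-PAF and a loss-PAF column (the value lands in the column
of the query's own type, 0 in the other), so the model can learn different
frequency-pathogenicity relationships for the two dosage directions.

## The 30-feature matrix

Four groups, 30 named columns in fixed order:

| group | n | columns |
|---|---|---|
| universal | 4 | length (bp), type (gain = 1 / loss = 0), gain-PAF, loss-PAF |
| coding | 13 | FATHMM, LR, LRT, MutationAssessor, MutationTaster, PolyPhen2, RadialSVM, SIFT, VEST3 aggregates; pLI, Episcore, GHIS gene scores; overlapped protein-coding gene count |
| noncoding | 8 | CDTS 1% and 5% constrained fractions; PLS, pELS, dELS, CTCF-bound, CTCF-only, DNase-H3K4me3 overlap fractions |
| genome-wide | 5 | CADD, GERP, phyloP 100-way, phyloP 46-way, SiPhy 29-way aggregates |

The thirteenth coding column is a configurable slot: only twelve coding
sources are canonical, and the schema is data (`xcnv_feature_schema()`), so
an alternative column set can be swapped in; the default is the count of
overlapped protein-coding genes, which is the simplest gene-level burden
measure.

Aggregation rules, with the reasoning where the choice was open:

* **Per-position tracks** (SNV deleteriousness, conservation, CADD):
  the sum of scores at positions inside the CNV divided by the *covered*
  length — the number of scored positions — i.e. the mean over annotated
  bases. Dividing by total CNV length instead (available as
  `denominator = "total"`) would conflate sparse annotation coverage with
  low deleteriousness: a 1 Mb CNV with ten scored bases would look benign
  regardless of those bases' scores. CNVs overlapping no scored position are
  *missing*, not zero.
* **Gene scores** (pLI, Episcore, GHIS): reduced over overlapping genes by
  `max` by default — the most haploinsufficiency-intolerant gene dominates
  the CNV's clinical interpretation — with `mean` available.
* **Regulatory regions** (six cCRE classes): covered base pairs of the CNV
  divided by CNV length, a fraction in [0, 1] that is invariant to how the
  region set is split into intervals. The inverse ratio (CNV length over
  regulatory length), which is unbounded and grows as regulatory content
  shrinks, is retained as `mode = "length_ratio"` for comparability with the
  literal published formula, which we read as a typographical inversion.
* **CDTS**: the fraction of the CNV's scored positions lying below the
  genome-wide 1% (respectively 5%) percentile of the context-dependent
  tolerance score — the share of bases in the most variation-depleted tail.
  The percentile thresholds are inputs (they are properties of the
  genome-wide score distribution, not of the query batch), and the 1% and
  5% versions are two separate columns.
* **Missingness**: cells with no covering annotation are imputed with the
  per-column minimum over the *training* matrix — the least-deleterious
  observed value, consistent with treating absence of annotation as absence
  of evidence for damage. Prediction batches are imputed with the stored
  training minima, never their own; imputation is idempotent and a column
  with no observed training value is a named error.

## Classifier, MVP score and five-tier cutoffs

CNVs longer than 10 Mb are excluded before modelling (they are
overwhelmingly pathogenic and are flagged as such rather than scored), and
training CNVs sharing ≥ 50% reciprocal overlap with any validation CNV are
dropped (type-agnostically — the conservative direction) to prevent
information leakage.

The classifier is XGBoost. Two hyperparameters are tuned — booster
(`gbtree`, `dart`, `gblinear`) and objective (binary logistic, logistic
regression, squared error, squared log error) — by repeated stratified
k-fold cross-validation (the reference schedule is 100 repetitions of
10-fold; tests and the acceptance script use 5 × 5 to keep runtimes
desk-scale). Folds are stratified by label, which stabilizes AUC at small n.
For each combination the per-repeat mean held-out AUC is recorded and the
combination with the highest median is selected; ties break by declared
order (gbtree before dart before gblinear, binary logistic first). The
squared-log-error objective can fail to train when intermediate predictions
leave its domain; such combinations are dropped with a warning rather than
poisoning the search. Remaining tree hyperparameters (depth 6, eta 0.3, 100
rounds at fit time, no early stopping) are fixed documented defaults; the
search is deliberately limited to the two parameters above.

The fitted model's probabilistic output is the **MVP score** in [0, 1],
higher = more pathogenic. Regression objectives produce unbounded raw
outputs, which are clamped with a warning — relevant only during tuning
since the selected objective in practice is logistic. AUC is computed as the
Mann–Whitney rank statistic (ties counted ½), which is threshold-free and
invariant under monotone transforms; a quadratic pairwise-comparison oracle
and pROC serve as independent cross-checks in the tests.

Four cutoffs split the MVP range into the five ACMG-style tiers. For each
ordered boundary (benign | likely benign | uncertain | likely pathogenic |
pathogenic), classes above the boundary are positives and the threshold
minimizing |sensitivity − specificity| over the observed score values is
chosen, ties toward the smaller (more sensitive) threshold. The four
boundaries are derived independently, so monotonicity is not guaranteed; a
violation is corrected by isotonic regression with a warning. Interval
closure at the published cutoffs (0.14 / 0.16 / 0.46 / 0.76) follows the
"below … / more than …" phrasing: benign strictly below the first cutoff,
pathogenic strictly above the last, interior boundaries half-open.

Evaluation reports MCC (0 with a flag when its denominator vanishes, where
the statistic is undefined), accuracy, F1, Fowlkes–Mallows, sensitivity and
specificity, overall and stratified by CNV type and by length bins 0–10 kb,
10–100 kb, 100 kb–1 Mb and 1–10 Mb (left-open, right-closed, so the bins
tile 0–10 Mb). Five-tier predictions collapse to binary with
pathogenic/likely-pathogenic as positives and uncertain excluded.

## The synthetic-data generator

The generator exists so every stage is exercisable without external
downloads; its defaults are the package's study conditions, chosen once:

* three 30 Mb chromosomes; 200 samples across the nine groups (largest:
  NFE 60, SAS 30, UKN 30 — unknown-ancestry samples are a large share of
  real CNV repositories);
* 500 true CNV events (2000 in the end-to-end benchmark), lengths
  log-uniform on 1 kb–1 Mb, gains and losses 1:1, breakpoints ≥ 500 bp
  apart so distinct events stay distinguishable;
* each event carried by 1–5 samples, re-emitted with Normal(0, 20 bp)
  rounded breakpoint jitter — well inside the 100 bp window, so replicate
  groups form cliques; the Gaussian tail still occasionally splits a clique,
  which is why count-recovery is asserted within 2% at sd 20 and exactly at
  sd 10;
* per-CNV, per-source latent means drive all annotation: track scores
  scatter around them (sd 0.5) at ~12 sparse positions per covered CNV, gene
  scores are logistic transforms, cCRE coverage fractions follow them, CDTS
  carries their negation (lower tolerance = more constrained); 90% coverage
  leaves genuine missing cells to exercise imputation;
* labels come from a latent linear score — effect sizes β on standardized
  true feature values plus Normal(0, 0.5) noise — cut at the 30/40/60/70%
  quantiles into the five tiers. The ordinal-band construction mirrors the
  assumption behind the cutpoint procedure (an ordered 1-D severity scale),
  and the recorded band edges are the ground truth for cutoff-recovery
  tests. Setting β to zero makes labels independent of all annotation, the
  null case for calibration tests.

What the generator deliberately does **not** emulate: linkage and
recombination structure, platform-specific breakpoint error profiles
(jitter is i.i.d. Gaussian), correlated annotation tracks (real
conservation scores are strongly inter-correlated), selection-driven
frequency-pathogenicity coupling (replication counts are independent of the
latent score), and real class imbalance. Passing tests therefore demonstrate
that the machinery is correct and recovers known signal under controlled
conditions — not that real-data discrimination reaches any particular level,
which depends on the real annotation resources.

## Numerical and degenerate-input conventions

Boundary distance equal to the genomic window is "not similar"; RO
thresholds use ≥; a single-base interval has length 1 and overlaps itself by
1 bp; `cut`-style length bins are right-closed; median coordinates round
half up; cutoff candidates are the observed scores only; MCC at zero
denominator is 0 with a flag; empty strata are flagged rather than silently
dropped; empty input files produce empty record sets with a warning.

## Problem sizes used by the shipped checks

The test suite runs the clique oracle on 200 random ≤ 12-node graphs, the
confusion-metric grid exhaustively on entries 0–20, the AUC oracle on 100
random 50-point instances, and the end-to-end benchmark on ten seeds at
2000 true CNVs (strong signal) plus five seeds at 1000 (null). The
acceptance script runs one full study at 2000 true CNVs with a 5 × 5 CV
hyperparameter search. These sizes were chosen as the smallest at which the
statistical assertions are stable.

## Known limitations

Multi-allelic copy-number states (CN0/CN1/CN3+…) are out of scope — typing
is binary gain/loss. No liftover: all inputs must share one assembly.
AF is carrier frequency, not allele-dosage frequency. The reference CNV
database interface is structural: the package does not download or
reprocess public repositories. Cutoffs derived on small or
weakly-separated score sets can collapse to nearly equal values after
isotonic correction; the warning should be taken seriously in that case.
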