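---
title: "Dictionary-weighted cluster annotation: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dictionary-weighted cluster annotation: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpcam)
```

## The problem

After clustering a single-cell RNA-seq experiment, each cluster must be
assigned a biological cell-type label. In disease contexts such as
pulmonary fibrosis, reference-dataset methods are sensitive to which
reference they are given, while marker-based methods depend on the
quality of the marker list. `fpcam` implements a marker-based,
cluster-level annotator in which the marker list is a *voting
dictionary*: each (cell type, gene) pair carries a vote count recording
how many curated literature sources list the gene as a marker for that
type, and the per-type weights derived from those votes drive a
similarity score between clusters and cell types.

## The model

**Dictionary weights.** For cell type $m$ with retained marker genes
$g$, the weight is

$$M_{mg} = \frac{V_{mg}}{\sum_{g'} V_{mg'}},$$

the gene's votes over the total votes of the type, so each type's
weights sum to 1. In the packaged basal-resting example, TP63 holds 4 of
21 votes and so gets weight $4/21 \approx 0.1905$; a gene listed by a
single source gets $1/21$. When a dictionary is built from per-study
tables (`build_votes_from_sources()`), a gene receives one vote per
listing source and only the ten most-voted genes per type are retained,
ties broken by the best rank the gene attained in any source, then by
symbol.

**Expression proportions.** The cluster-level input is a long-format
marker table in the Seurat `FindAllMarkers` convention. After the
adjusted-p screen ($p_{adj} < 0.05$ by default) the chosen statistic
(default `avg_log2FC`) is arranged into a gene $\times$ cluster matrix
$A$, and converted to proportions

$$E_{gj} = \frac{A_{gj}}{\sum_{j'} A_{gj'}},$$

each gene's value divided by that gene's total across clusters. Nonzero
gene rows of $E$ are row-stochastic; a gene reported in only one
cluster contributes its full mass there.

**Similarity and label assignment.** The score of cluster $j$ against
cell type $m$ sums over genes present in both inputs:

$$S_{jm} = \sum_{g \in \text{markers}(m)} E_{gj} \, M_{mg},$$

with disjoint gene sets giving $S_{jm} = 0$. Per cluster, with
$S_{\max}$ the row maximum, $S_{\text{sec}}$ the second-highest value
(multiset semantics) and $S_{\text{med}}$ the median over the full row,

$$\lambda_1 = S_{\max} - S_{\text{med}}, \qquad
  \lambda_2 = S_{\text{sec}} - S_{\text{med}}.$$

The cluster takes the argmax type as its primary label when
$\lambda_1 > 0$ and is otherwise `Unannotated` (a zero or negative gap
carries no signal; since the maximum can never be below the median this
happens exactly when the row maximum equals its median). When
$S_{\max} - S_{\text{sec}} > \varepsilon$ (default
$\varepsilon = 10^{-5}$) and $\lambda_2 > 0$, the type attaining
$S_{\text{sec}}$ is attached as a secondary label, giving a one- or
two-label annotation per cluster.

**Evaluation harness.** Given several annotators' per-cluster labels, a
pseudo-reference is formed per cluster by the Boyer–Moore majority-vote
pass over the primary labels (annotators taken in the order supplied),
followed by a verification count; without a strict majority the
plurality label wins with lexicographic tie-break, and such clusters are
logged. An annotator's accuracy is its matching clusters over the number
of reference clusters; the range statistic
$R = |\mathrm{Acc}_1 - \mathrm{Acc}_2|$ summarizes a model's stability
across two reference files.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 0.00001 | gap (score units) between top and second score that triggers the secondary-label rule |
| `p_adj_threshold` | 0.05 | adjusted-p screen on the marker table |
| `value_column` | `avg_log2FC` | statistic fed into $A$; `pct.1` or a mean-expression column may be substituted |
| `normalize_axis` | `gene` | `gene` divides by per-gene totals across clusters (the model); `cluster` divides by per-cluster totals, for sensitivity checks |
| `lambda2_trigger` | `secmax` | `secmax` fires on $S_{\max}-S_{\text{sec}}>\varepsilon$; `median` on $S_{\max}-S_{\text{med}}>\varepsilon$ |
| `case_fold` | `TRUE` | upper-case gene symbols so human and mouse spellings merge |

Similarity scores are unitless products of two proportions; with
realistic dictionaries of hundreds of genes they are numerically small
(order $10^{-3}$ and below), which is why the secondary trigger default
is as small as $10^{-5}$.

## Design choices where the design was open

- **Value column.** Upstream differential expression does not dictate
  which statistic measures "expression level" per (gene, cluster). The
  default is `avg_log2FC`, the only per-gene-per-cluster magnitude the
  standard `FindAllMarkers(only.pos = TRUE)` call emits, and it is
  nonnegative under that call; negative values (possible with other
  columns) are clipped to zero and counted.
- **Normalization axis.** The proportion formula divides per gene
  across clusters, and that is the default; the per-cluster variant is
  exposed but not default because it makes scores depend on how many
  markers a cluster happens to report.
- **Secondary trigger.** A *large* gap between the top two scores
  triggering a *second* label is counterintuitive, but it is the rule
  implemented (`secmax`); the alternative reading (`median`) is one
  config key away for comparison studies.
- **Median over the full row, maximum included.** With a tied maximum
  in a 3-entry row the median equals the maximum and $\lambda_1 = 0$;
  this is accepted as a property of the rule rather than special-cased.
- **Ties.** Argmax ties break lexicographically and are counted in the
  run manifest, keeping outputs deterministic.
- **Duplicate dictionary rows** (e.g. created by case-folding) merge by
  summing votes, with a warning; per-type totals are then recomputed so
  weights always sum to one.
- **Accuracy denominator.** A mismatch is counted once (not as a
  false positive and a false negative simultaneously), making accuracy
  matches/clusters; reference clusters an annotator skipped, or left
  `Unannotated`, count as misses. By default a cluster with two labels
  matches if either label equals the reference (`match_mode =
  "either"`); `"primary"` restricts to the first label.
- **Majority voting.** Boyer–Moore guarantees only strict majorities,
  so the verified candidate falls back to plurality with a
  deterministic lexicographic tie-break, covering both the strict and
  the "highest vote" readings.

## The synthetic benchmark

`synthetic_spec()` plants ground truth end to end: a dictionary of
`n_cell_types` types with 10 genes each (votes drawn from 1..6 with a
profile skewed toward single votes, mimicking real curation where only
a few canonical markers are widely cited), a marker table in which each
cluster expresses its assigned type's markers with values proportional
to the dictionary weights, and a panel of annotators that reproduce the
truth with probability $1 -$ error rate. Three stress knobs:

- `marker_overlap` — fraction of genes shared between adjacent types
  (default 0); raises type confusability.
- `noise_sd` — multiplicative log-normal noise on expression values
  (default 0.3), chosen as a simple positive-valued perturbation that
  stresses the proportion normalization; the model itself assumes no
  particular noise law.
- `dropout` — probability a true marker row is missing from the table
  (default 0.1), emulating markers that fail the upstream screen. The
  top-weight gene of each cluster is always kept so clusters remain
  observable.

The `"paper_scale"` preset (75 types, 29 clusters, 6 sources, overlap
0.1) exercises sparsity at the scale of a realistic curated dictionary.
What the generator does **not** emulate: per-cell counts, library-size
effects, batch structure, correlated markers, or hierarchically related
cell subtypes. Passing the planted-recovery tests therefore shows the
scoring pipeline is implemented correctly and degrades gracefully, not
that any particular real dataset will be annotated at a given accuracy.

## Numerical notes and degenerate inputs

- All-zero gene rows of $A$ yield all-zero rows of $E$ (no NaN); a
  cluster sharing no genes with the dictionary scores 0 everywhere and
  comes out `Unannotated`, with a warning when the overlap is empty
  globally.
- Proportions are scale-invariant per gene row, so the choice of units
  in the value column does not move row-normalized scores.
- A length-1 score row defines $\lambda_1 = 0$ (median = the value) and
  never gets a secondary label.
- Dictionary percents are written as reduced fractions ("4/21") so the
  dictionary file round-trips exactly through integer vote counts.

## Verification problem sizes

The test suite checks the similarity kernel against an exhaustive
double-loop oracle on randomized fixtures up to 50 genes × 10 clusters
× 10 types over 100 seeds; full-pipeline recovery on a 6-type, 8-cluster
benchmark over 50 seeds per noise level (exact recovery at zero
noise/overlap, non-increasing mean recovery in noise); Boyer–Moore
against exhaustive counting on 1,000 random vote vectors; and a
500-seed, six-annotator panel at error 0.1 whose mean accuracy must sit
within three standard errors of 0.9. These sizes keep each property
statistically meaningful while the whole suite runs in well under a
minute.

## Known limitations

- Annotation is per cluster, not per cell, and inherits the upstream
  clustering: a cluster mixing two cell types gets at most two labels.
- Scores are not calibrated probabilities; $\lambda_1$ orders
  candidates within a cluster but is not comparable across datasets.
- Label matching in evaluation is plain string equality after trimming
  and case-folding; no ontology mapping is attempted, so synonymous
  labels from different annotators count as disagreements.
- The dictionary is only as good as its curation; genes absent from it
  are invisible to the score.
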