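---
title: "Cross-species candidate-gene prioritization for ovarian cancer: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-species candidate-gene prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovcand)
```

## The scientific problem

Ovulation subjects the ovarian surface epithelium (OSE) to repeated
cycles of rupture, inflammation and proliferative repair, and this
"incessant ovulation" is one proposed route to serous ovarian cancer.
If that is right, genes whose expression is regulated in normal OSE
across the rodent estrous cycle — particularly around the
peri-ovulatory hormone surge at proestrus evening (PE) and the
post-ovulatory estrus morning (EM) — are natural candidates for genes
that become dysregulated in the human disease. `ovcand` implements
this cross-species prioritization as a reusable, fully tested
pipeline: murine estrous-regulated genes are mapped to human
orthologs, intersected with genes called dysregulated in human ovarian
cancer expression datasets, and the resulting candidates are triaged
against copy-number, somatic-mutation, immunohistochemistry (IHC) and
survival evidence.

No raw data from the motivating study are redistributable, so the
package pairs the pipeline with a synthetic-data generator that plants
known truth at the study's design parameters, plus small transcriptions
of the study's printed evidence tables for replaying the integration
rules exactly.

## Differential expression: the SAM statistic

Dysregulation calls on a two-class (tumor vs normal) log2 expression
matrix use the significance-analysis-of-microarrays relative
difference

$$d_g = \frac{\bar{x}_{g,2} - \bar{x}_{g,1}}{s_g + s_0},$$

where $s_g$ is the gene-wise pooled standard error of the mean
difference and $s_0$ a "fudge factor" that prevents genes with tiny
variance from dominating the ranking. $s_0$ is chosen by percentile
search: candidates are 0 and the 5th–100th percentiles of $s$ in steps
of 5; for each candidate, genes are binned into windows by percentile
of $s$, and the candidate minimizing the coefficient of variation of
the window-wise median absolute deviations of $d$ is kept. This makes
the spread of $d$ approximately independent of $s$.

The null distribution is obtained by permuting group labels. When the
number of distinct label assignments is small (at most the requested
number of permutations, or at most 10,000), all assignments are
enumerated exhaustively, which makes the 2v2 test cases exactly
reproducible against a brute-force oracle. The q-value at rank $i$ (by
decreasing $|d|$) is the median across permutations of the number of
null $|d^*|$ at or above the rank-$i$ threshold, divided by $i$,
capped at 1 and monotonized by a running maximum from the top rank
down. The running maximum is the conservative direction: a gene can
never receive a smaller q than a more extreme gene.

A gene is called dysregulated when `q < 0.05` **and** its linear fold
change exceeds 2 (or falls below 1/2). Inputs are log2 scale, so fold
change is computed as $2^{\bar{x}_2 - \bar{x}_1}$ — the ratio of
anti-logged group means. The threshold scale is a recorded convention
(the motivating analysis states "fold change >2" without a scale);
both thresholds and the permutation count are arguments of
`call_de()`, and the permutation seed is required rather than
defaulted so runs are always reproducible.

## Harmonization

Mouse genes are mapped through an ortholog table (mouse Entrez, mouse
symbol, human Entrez, HUGO symbol), Entrez ID first and
case-insensitive symbol second. One-to-many orthologs are *kept* and
flagged rather than dropped: discarding them silently would lose
candidates, and downstream consumers can restrict to 1:1 if desired.
Unmapped genes are returned in a separate report with a reason code,
never dropped. `normalize_symbols()` resolves aliases to canonical
HUGO symbols case-insensitively and idempotently; ambiguous aliases
(one alias, two canonical targets) are an error because they would
make the join key ill-defined. After mapping, lists are deduplicated
to one record per HUGO symbol, which is the join key for every
evidence layer.

## Overlap and enrichment

`count_support()` aggregates per-dataset calls into one row per gene
with a support count and a consensus direction ("inconsistent" when
both directions occur). Datasets that reported upregulated genes only
are declared as such; down calls cannot originate there, and a gene
seen only in up-only datasets can never be labelled down-consistent.
Ranking is by support count, then by fold change in a designated
reference dataset (qualitative entries like ">3" sort after all
numeric values), then alphabetically — a total order independent of
input row order.

Overlap enrichment uses the Pearson chi-square (no continuity
correction) on the 2×2 in/out table over a stated gene universe, with
an exact hypergeometric upper tail always reported as cross-check, and
the chi-square suppressed when any expected cell falls below 1. The
universe is deliberately an explicit argument: the motivating study
never stated its universe, and the choice is decisive. With a 905-gene
signature, 7285 dysregulated genes and an observed overlap of 338, the
expected overlap is $905 \cdot 7285 / N$; at $N = 18000$ that is 366 —
*more* than observed — while the printed significance is only
recovered for universes above roughly 24,000 genes. The tests
exercise the printed counts with a 25,000-gene universe (a plausible
union of unique genes across five array platforms) and document the
sensitivity here rather than hiding it.

## Copy-number evidence

Per-sample log2 copy-number ratios are thresholded strictly: a sample
counts as gained when its ratio exceeds 0.3, lost below −0.3; a gene
is called gained/lost when strictly more than 30% of samples qualify
(a gene at exactly 30% is neutral, following the printed strict
inequalities). A gene may alternatively qualify through membership in
a reported peak region of recurrent aberration, because the source
datasets report peak-region genes as a parallel route and their
printed integer percentages are rounded summaries — replaying a
printed "29%" through the raw frequency rule would misclassify a
peak-region gene. Consensus requires the same non-neutral direction in
both of exactly two sources; single-source genes are excluded with a
reason code and opposite calls are flagged discordant.

Concordance with expression is the gain-and-up / loss-and-down rule,
with a chi-square (plus Fisher exact cross-check) on the 2×2
{gain,loss}×{up,down} table. Region summaries group genes by the
chromosome-arm prefix of their cytoband ("8q24.3" → "8q"; bands
without a parseable arm, such as a bare "19", go to a "remainder"
group, as do arms with fewer than 3 genes), and report how many
patients carry the aberration in at least one versus all genes of the
group.

## Mutation triage

Genes qualify for catalog interrogation when dysregulated in the same
direction in at least three datasets, or when present in a consensus
cancer-gene list or a kinase driver-mutation list. Catalog records are
"n mutated / N screened" per tissue. Classification distinguishes
three mutually exclusive classes: genes with any ovarian screening
record (including 0/N — screened in ovary and reported there, which
the source tables list under their ovarian-cancer heading even at zero
hits), genes with records only in other tissues, and genes absent from
the catalog entirely. "No record" is deliberately distinct from "0/N".
Fusion annotations ("ALK; haematopoietic and soft tissue") are parsed
into partner and site, with the site text kept verbatim.

## IHC histoscores

The histoscore is $(3 \cdot \%\text{strong} + 2 \cdot \%\text{moderate}
+ 1 \cdot \%\text{weak}) / 100 \in [0, 3]$. The banding statement
"between 0 and 1 weak, 1 and 2 moderate, 2 and 3 strong" leaves the
boundaries ambiguous; the package adopts half-open-from-the-left bins
$(0,1], (1,2], (2,3]$ with 0 mapped to weak, which is exhaustive and
exclusive over the range. Within-patient compartments (OSE, inclusion
cysts, fallopian tube epithelium) are compared with paired two-tailed
t-tests over complete pairs; comparisons involving the
separate-patient cancer group use a one-way ANOVA with Fisher's LSD
post hoc — pairwise t-tests on the pooled ANOVA mean square error with
$N - k$ degrees of freedom, unadjusted for multiplicity, which is the
classical definition of the procedure. Degenerate paired inputs
(constant non-zero difference) are flagged rather than returned as a
spurious infinite t.

## Survival

Kaplan–Meier curves and the two-group log-rank test are delegated to
the `survival` package behind a record-level interface; the median is
read off the curve as the smallest time with survival at or below 0.5
("not reached" when the curve never crosses it), and hand-computed
product-limit and O−E/V oracles in the test suite verify the wrapper
end to end. `dichotomize_at_median()` splits a cohort at the median
score; patients exactly at the median go to the low stratum (the tie
rule is logged and configurable only by pre-shifting scores — it is a
convention, not a tuning knob).

## The synthetic-data generator

Defaults encode the emulated study design: a five-dataset roster with
5868/3479/1084/86/69 planted dysregulated genes, a 905-gene estrous
signature (55% PE), a planted overlap of 338, ten samples per class,
a 96-patient cohort with exponential survival at stratum medians of 22
and 42 months, gain/loss planting probabilities of 0.40/0.35 per
sample around the >0.3/<−0.3 thresholds, and 2% unmapped plus 3%
one-to-many ortholog rows to exercise the harmonization edge cases.
Where the study states no value, choices are standard for normalized
array data: i.i.d. Gaussian noise on the log2 scale (SD 0.5), a log2
effect of 2 (fourfold) for planted genes, a baseline intensity of
N(7, 1), and exponential survival because its closed-form median
(median = ln 2 / rate) gives exact oracles. The universe default of
18,000 genes is the order of a single expression platform.

Planted overlap genes are always members of the largest dataset's
truth set and of smaller datasets by chance, so each is dysregulated
in at least one dataset while support counts vary realistically;
non-planted estrous genes are excluded from all truth sets so the
realized overlap is the planted one plus SAM false positives only.

What the generator does *not* emulate: probe-level effects and
normalization artifacts, correlated noise between genes, batch
structure across datasets, segmental (spatially correlated)
copy-number profiles, inter-core IHC variability, and non-exponential
survival. Passing tests therefore demonstrate that the integration
logic is correct under the stated model, not that the pipeline is
robust to every pathology of real array data.

## Problem sizes and numerical choices

Tests and the acceptance script run the full pipeline on a
down-scaled study — a 3,000-gene universe, 120 estrous genes, dataset
truth sizes 400/250/120/40/30, planted overlap 40, ten samples per
class, 100 permutations — which preserves the ratios of the full
design while keeping a complete run in a few seconds; at a fourfold
log2 effect over 0.5-SD noise the pipeline recovers 100% of the
planted overlap at every seed tried, comfortably above the 95%
recovery the package asserts. SAM falls back to exhaustive
enumeration whenever the assignment count allows, which removes
permutation noise from the small calibration studies. Replays of the
printed evidence tables are exact integer checks: 2 genes called in
all five datasets and 14 in four; 25 overlap genes supported by three
datasets; 39 dual-source, expression-concordant copy-number genes (27
gained/up, 12 lost/down); 25 triaged mutation genes of which 7 carry
ovarian screening records and 4 carry fusion annotations.

## Known limitations

- The enrichment test cannot reproduce the motivating study's exact
  significance because the universe it used is unstated; the package
  makes the universe explicit and documents the sensitivity above.
- Pathway/ontology over-representation against commercial databases,
  GISTIC peak detection, literature-hit counting and probe-level
  preprocessing are out of scope; peak-region membership and
  literature counts are consumed as annotations.
- SAM here is the unpaired two-class variant only.
- The qualitative fold-change entries of the printed tables (">3",
  "up") are ordered after numeric values in ranking; they carry no
  magnitude information.
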