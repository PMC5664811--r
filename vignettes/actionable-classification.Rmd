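---
title: "Actionable-gene molecular classification from panel sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Actionable-gene molecular classification from panel sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panelclass)
```

## The problem

Gastric cancer is molecularly heterogeneous, and targeted panel sequencing
of a few hundred cancer genes is the practical instrument for profiling it
in the clinic. `panelclass` implements the analysis layer that sits on top
of such a panel: given per-tumor variant calls, gene-level copy-number fold
changes, viral read fractions and microsatellite indel counts, it assigns
each tumor a TCGA molecular subtype (EBV, MSI, CIN or GS), flags
hypermutated tumors with a cutoff derived from the data, and groups the
remaining tumors into clusters defined by shared alterations of actionable
genes — genes paired with an FDA-approved targeted therapy — so that each
cluster suggests a therapy hypothesis.

Everything runs on plain TSV tables and a seeded synthetic-cohort
generator, so the full pipeline is testable end to end without any external
download.

## Biomarker definitions

**Tumor mutational burden (TMB).** The rate of peptide-changing SNVs per
megabase of captured region. Only SNVs with allele fraction ≥ `af_min`
(default 0.10) and high or moderate putative impact count; indels and
silent/low-impact variants never do. The denominator `roi_size_mb` is a
required configuration value (default 1.7 Mb): the captured ROI size of a
commercial panel is proprietary and the package does not pretend to know
it, so reported TMB values scale with this setting.

**Microsatellite instability.** Upstream pipelines count somatic indels
inside a catalog of tandem-repeat loci; the package consumes that count and
calls MSI-high when it reaches `msi_threshold` (inclusive). No published
cutoff exists for this locus panel, so the default of 20 indels is a
package calibration chosen so the generator's MSI-H and MSS arms (Poisson
means 45 and 3) separate with essentially no overlap. Deriving the locus
catalog itself would need a reference genome and is out of scope.

**Viral status.** A tumor is positive for HPV-16, HPV-18 or EBV when the
percentage of total reads mapping to the viral genome reaches 0.02, 0.01
or 0.0005 % respectively. Comparisons are inclusive (≥); the empirical
cutoffs are not documented as strict, and inclusivity keeps boundary
behavior predictable. Both choices are configurable.

**Copy number.** Gene-level read-depth fold changes call a gain above
2.5-fold and a loss below 0.75-fold (both strict, partitioning the positive
axis into exactly three intervals). The SCNA locus count of a tumor is the
number of distinct genes called gain or loss.

## Subtype decision tree and the hypermutation cutoff

Subtypes are assigned with precedence EBV > MSI > CIN/GS: EBV positivity
wins outright, then MSI-H, and the remainder split on SCNA burden with
SCNA-high (≥ `scna_cutoff` loci, default 4) giving CIN and the rest GS.
Every tumor receives exactly one subtype.

The SCNA-high cutoff can also be derived from the data
(`derive_scna_cutoff()`): each candidate k is scored by the product of two
two-tailed Fisher p-values — (SCNA ≥ k) against TP53 mutation and
(SCNA < k) against diffuse Lauren histology, the CIN and GS hallmarks — and
the smallest product wins, ties toward smaller k. The original selection
procedure behind the published 4-locus cutoff is not described in enough
detail to reproduce mechanically; this p-value-product scan is the
package's operationalization, and the cutoff can always be pinned
(`scna_cutoff = 4`). On cohorts where almost no tumor sits exactly at the
boundary (the default generator leaves a sparse band at 3 loci), the scan
may return either edge of the empty band — adjacent candidates produce
near-identical partitions and the product is then decided by noise. The
scan table is attached to the result for inspection.

The hypermutation cutoff is the minimum TMB among MSI-H tumors
(`derive_hypermutation_cutoff()`), and the flag is inclusive
(`tmb >= cutoff`). Inclusivity is deliberate: the MSI-H tumor defining the
minimum is itself hypermutated, and with a strict reading the reported
composition — every MSI tumor hypermutated, joined by some EBV/CIN/GS
tumors — could not hold. A strict mode exists for sensitivity analysis.

## Co-alteration clustering

For the non-hypermutated tumors (hypermutated profiles carry so many
mutations that they would swamp any similarity signal), the package builds
the N × N matrix whose entry c_ij counts genes altered in both tumor i and
tumor j, over a chosen gene set (the 69 actionable genes by default).
"Altered" means a peptide-changing mutation *or* a copy-number gain/loss:
the clusters of interest are defined by ERBB2 amplification and CDKN2A/B
deletion as much as by mutations, so a mutation-only predicate would be
inconsistent with its own cluster labels. The predicate is injectable for
sensitivity analysis.

Each entry is replaced by 1/(c_ij + 1), mapping counts into (0, 1] with
value 1 exactly when nothing is shared. The transform is applied verbatim,
diagonal included (c_ii is the tumor's own altered-gene count); it is a
*decreasing* function of similarity, and the package deliberately does not
"fix" it into a conventional similarity — rows of this normalized matrix
are the feature vectors, and tumors with similar sharing patterns have
nearby rows. Rows are clustered with Euclidean distance and Ward linkage.
`hclust` method `"ward.D2"` is used: it implements Ward's minimum-variance
criterion correctly for unsquared Euclidean input (the historical `ward.D`
expects squared distances). Clustering the condensed 1/(c+1) matrix
directly as a distance was considered and rejected: row vectors carry each
tumor's full sharing profile, while the condensed form reduces each pair to
a single number and recovers planted structure noticeably worse.

k is pinnable (default 6, the published cluster count) or selected by
internal validation (`select_k()`): connectivity, average silhouette width
and Dunn index are computed per candidate k from their standard
definitions, and the k maximizing average silhouette wins (ties toward
smaller k). Silhouette is the primary criterion because it is the only one
of the three with a natural scale-free optimum; the full table is returned
so users can weigh the other two. The silhouette implementation is
cross-checked against `cluster::silhouette` in the test suite.

Clusters are labelled by their characteristic gene: among genes altered in
at least half of a cluster's tumors, the one with the smallest two-tailed
Fisher p-value (cluster vs rest) wins; a cluster with no such gene is
`"unassigned"` — the "minor alterations" group.

## Cohort statistics

Frequency tables report, per gene, the percentage of tumors with at least
one alteration of the class (mutation, amplification, deletion), rounded
to one decimal with halves away from zero; subtype shares are printed as
whole percents. Associations between a grouping (clusters, subtypes,
hypermutation) and clinicopathological features use the two-tailed Fisher
exact test for categorical features (multi-level features are dichotomized
one level at a time — whether the original analysis used r×2 tables is
unstated) and the Mann-Whitney U test for continuous ones, group against
all remaining tumors; the hypermutated contrast supports a non-hypermutated
reference set. Raw p-values carry the significance flag at P < 0.05 — the
analysis this package mirrors applies no multiple-testing correction — and
a Benjamini-Hochberg column is emitted alongside, clearly separated, for
responsible reuse. The Mann-Whitney implementation enumerates exactly when
the smaller sample has ≤ 8 observations and no ties are present, and
otherwise uses the tie-corrected normal approximation; the switch point is
a package choice.

## What the synthetic generator emulates

`paper_default_spec()` encodes the study conditions: 207 tumors; subtype
mixture 4/8/58/30 % (EBV/MSI/CIN/GS); 32 hypermutated tumors (the whole
17-tumor MSI arm plus 15 designated others); TMB of the MSI-H arm on
18.5–66.9 counts/Mb versus 3.1–27.7 for MSS; five planted actionable-gene
clusters of sizes 25 (ERBB2), 10 (CDKN2A/B), 10 (KRAS), 9 (BRCA2) and
12 (ATM) over the 175 non-hypermutated tumors; and per-gene alteration
probabilities from the published frequency table (TP53 0.531, ARID1A
0.159, ERBB2-AMP 0.121, ...).

Design choices worth knowing about:

* **Mutation counts, not rates, are drawn** — discrete uniform over the
  count range implied by each arm's TMB interval (a triangular option
  peaked at the arm medians 31.5/11.2 exists). Rounding a continuous rate
  draw can push the realized MSI-H minimum below the intended floor
  (round(18.5 × 1.7)/1.7 = 18.24); drawing counts keeps every tumor on its
  designated side of the hypermutation boundary. Because exactly 32 tumors
  are designated hypermutated, the MSS arm is realized piecewise: designated
  tumors on [cutoff, 27.7], the rest below the cutoff. A single uniform over
  the full MSS range would scatter far more than 15 MSS tumors above 18.5
  and the fixed hypermutated composition could not hold.
* **Label events are planted as driver events.** A planted tumor carries
  its cluster's label event with probability `within_prob` (0.9); tumors of
  the background cluster carry one label event with probability
  `background_prob` (0.05) each, mutually exclusively — the familiar driver
  mutual-exclusivity pattern, and the reason the published clusters are
  disjoint. CDKN2A and CDKN2B are deleted together as a single 9p21 event;
  independent per-gene deletion would split the cluster into
  non-overlapping CDKN2A-only and CDKN2B-only profiles no method could
  join.
* **Ground-truth clusters follow realized alterations.** Clusters are
  defined by observed alterations (the ERBB2 cluster *is* the set of
  ERBB2-altered tumors), so a background tumor that happens to receive an
  ERBB2 amplification genuinely belongs to the ERBB2 cluster, and the
  truth table records it there, with precedence ERBB2 > CDKN2A/B > KRAS >
  BRCA2 > ATM mirroring the order in which the dendrogram splits.
* **Actionable mutations concentrate in the hypermutated arm.** Non-label
  actionable genes are drawn at 0.35× their cohort frequency in
  non-hypermutated tumors and 4.5× in hypermutated ones (the
  mixture-weighted mean stays ≈ 1, preserving cohort-wide frequencies).
  This mirrors the clinical observation that mutation-class actionable
  genes (PIK3CA, RNF43, ...) are heavily enriched in hypermutated tumors —
  and it matters for the clustering pool: at full cohort rates inside the
  175-tumor pool, a gene mutated in 8 % of tumors forms an accidental
  co-alteration cluster the size of a planted one.
* **Filler mutations avoid frequency-modeled genes.** TMB filler and noise
  draws land on panel genes without a modeled frequency (including the
  clearly marked `SYNGENExxx` placeholders of the synthetic panel), so the
  frequency table stays governed by the declared probabilities. TP53 is
  additionally enriched in CIN (×1.3) and depleted in GS (×0.35), the
  coupling the SCNA-cutoff derivation relies on; the multipliers are a
  qualitative synthetic device, not estimates.
* **The panel is a synthetic stand-in.** The real 435-gene content is
  proprietary; `synthetic_panel()` uses real symbols for every gene with a
  published frequency plus 69 real FDA-target genes, and filler symbols for
  the rest, with the 435/69 structure and a 1.7 Mb ROI.

What the generator does **not** emulate: positional information (the model
is strictly gene-level), mutational signatures, subclonal allele-fraction
structure, correlated SCNA segments beyond the 9p21 pair, HPV-positive
tumors (emitted only as sub-cutoff noise; the classifier never consumes
HPV flags), and survival or treatment-response outcomes. Passing tests on
synthetic cohorts therefore demonstrates that the pipeline recovers the
structure it assumes — not that real cohorts contain that structure.

## Numerical and degenerate-input choices

* Percent rounding is half-away-from-zero (`round_half_away()`); base R's
  banker's rounding would print some published-style values differently.
  One printed share (119/207 = 57.49 %, shown as 58 %) is reproducible
  only as the whole-percent rounding of its one-decimal form.
* Boundary comparisons: TMB AF filter, MSI threshold, viral cutoffs and
  the hypermutation flag are inclusive; copy-number thresholds are strict.
* `fisher_two_tailed()` and `mann_whitney()` cap at 1 (floating-point sums
  inside the exact tests can exceed 1 by an ulp).
* Ward agglomeration and `cutree` are deterministic for a given input;
  equal-height merges resolve by `hclust`'s observation order, so repeated
  runs are identical but cluster *indices* are arbitrary — comparisons use
  the adjusted Rand index.
* `select_k()` refuses a matrix whose rows are all identical (silhouette
  undefined) and `derive_scna_cutoff()` refuses a cohort no candidate
  cutoff can split.
* Tumors missing from auxiliary tables get zero/empty defaults with a
  warning; a duplicated id in the clinical table is an error; calls on
  genes outside the panel are dropped with a warning (calling is
  restricted to the captured ROI by construction).

## Problem sizes used by the test suite

Unit tests run on cohorts of 1–60 tumors built in code. Property suites
use: the full enumeration of 2×2 tables with grand total ≤ 30 against a
hypergeometric oracle; complete rank-split enumeration for Mann-Whitney at
sample sizes ≤ 8; 1,000 random cohorts for the hypermutation-cutoff
minimum; and 20 seeded default-spec cohorts (207 tumors, 175 in the
clustering pool) for planted-cluster recovery, where Ward clustering at
k = 6 is required to reach an adjusted Rand index ≥ 0.9 against the
generator's truth and to recover all five cluster labels.

## Limitations

The package starts from called variants: alignment, variant calling,
segmentation and annotation are upstream and out of scope, as are fusion
detection, drug matching and variant-level curation. TMB values depend on
the configured ROI size, and the MSI threshold is a calibration, not a
published constant. The clustering method is faithful to its source —
including the unusual similarity normalization — rather than optimal; for
k far from the planted structure, silhouette-based selection on weak data
can prefer coarse partitions.
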