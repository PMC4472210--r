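---
title: "Methods: expression-guided drug prediction and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: expression-guided drug prediction and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`txpredict` turns one tumor expression profile and a normal-tissue
reference into a ranked drug-prediction report, applies molecular tumor
board decision rules to produce a treatment plan, and quantifies the
reproducibility of the whole chain across replicate biopsy sections and
measurement platforms. This vignette is the package's account of the
science: the model and its assumptions, the parameters that matter, what
the synthetic-data generator does and does not emulate, and the
numerical choices made where the design was genuinely open.

## 1. Relative expression against a whole-body normal reference

Every downstream engine consumes per-gene Z-scores

$$ z_g = \frac{\log_2(x_g + c) - \mu_g}{\sigma_g}, $$

where $x_g$ is the tumor's linear-scale expression (microarray intensity
or FPKM-like), and $\mu_g, \sigma_g$ are the mean and standard deviation
of log2 expression over a panel of normal tissues (45 by default). A
whole-body panel is used deliberately: its wide tissue-to-tissue
variance keeps genes that are strongly expressed somewhere in the body
from looking tumor-specific, which both sharpens the overexpression
signal and steers predictions away from targets with likely on-target
toxicity.

Choices made here, and why:

* **Pseudocount** `c = 1` (default). The reference is modeled in log2
  space while input files are linear; the pseudocount guards zeros in
  FPKM-like data. Whether the original clinical system Z-scored on the
  log scale is not derivable from its public description; the log2
  choice is a design decision of this package, not an inference.
* **Zero-scale genes are excluded, not clipped.** A Z-score is undefined
  when $\sigma_g = 0$; exclusions are recorded on the reference and
  surfaced in the per-profile coverage report, so the omission is
  auditable.
* **Gene universes are intersected**; genes present on only one side are
  dropped and counted, never imputed.

Thresholded derivatives feed the engines: the up/down differential sets
($z \ge +1.5$ / $z \le -1.5$, capped at 500 genes each, ties broken by
lexicographic gene id so the output is a pure function of the profile)
and the overexpressed target set ($z \ge +3$, inclusive).

## 2. The five scoring engines

Each engine emits per-drug evidence rows (method, direction, evidence
points, optional p-value). Evidence scales are a package convention
chosen so every method contributes on a comparable 0–10 scale and
aggregate scores can meaningfully cross a reproducibility threshold of
10:

| method | gate | evidence |
|---|---|---|
| biomarker rules | rule predicate fires on marker z | \|z\| of marker |
| target expression | inhibitor action on a gene with z >= +3 | max qualifying z |
| hidden-node network | inhibitor action on a BH-significant node | −log10(q), capped at 10 |
| connectivity | mean score < 0 and permutation p <= 0.05 | −score × 10 |
| sensitivity signatures (PAGE) | combined statistic > 0 | combined, capped at 10 |

**Biomarker rules** are Z-predicates (direction over/under plus a
threshold) attached to a drug and a prediction of *sensitivity or
resistance*. Resistance is first-class: it is reported and flagged, and
handled by demotion rather than subtraction (section 3).

**Hidden nodes.** The network engine identifies key regulators of the
observed transcriptional profile from a directed protein–protein
interaction network. For each node and radius $L$ (default 2), the
driver neighborhood is everything reachable from the node within $L$
directed steps (divergence of influence) and the effector neighborhood
everything that reaches it (convergence). Enrichment of differentially
expressed genes in a neighborhood is the exact hypergeometric upper
tail over the node universe, Benjamini–Hochberg corrected across all
(node, role) tests, significant at $q \le 0.05$. The production systems
this emulates are proprietary; this surrogate keeps the published idea's
core — a regulator can be topologically significant while not being
differentially expressed itself — with an exact, testable statistic.

**Connectivity scoring** uses the canonical Connectivity-Map KS form:
for a tag set of size $t$ at sorted positions $V$ in an $n$-gene
drug-perturbation ranking, $a = \max_j (j/t - V_j/n)$,
$b = \max_j (V_j/n - (j-1)/t)$, $ks = a$ if $a > b$ else $-b$; the raw
score is $ks_{up} - ks_{down}$ when the two statistics have opposite
signs and 0 otherwise, halved to lie in $[-1, 1]$. Negative scores mean
the drug's transcriptional effect reverses the tumor signature.
Significance is a same-size random-tag permutation null with add-one
smoothing. Multiple cell contexts of one drug are **averaged** — the
combination rule is not pinned down by the clinical system's
description, and averaging is the simplest symmetric choice; it is
flagged here as such. The permutation stream is seeded per drug from
(seed, drug id), so partial or parallel evaluation reproduces exactly.

**Sensitivity signatures.** From a cell-line panel with baseline
expression and per-drug IC50, a gene joins a drug's up-in-sensitive set
when the Pearson correlation between its expression and potency
($-\log_{10} IC_{50}$) is at least `r_thr = 0.5` in at least
`min_contexts = 2` independent cell contexts (and the down set
symmetrically). Only the two-context replication requirement is anchored
in the workflow this reimplements; the correlation threshold is a
package default. Scoring uses the PAGE statistic
$z_{set} = (S_m - \mu)\sqrt{m}/\delta$ against the full Z-profile, which
is approximately N(0,1) under the null (verified to mean 0 ± 0.1 and SD
1 ± 0.1 over 1000 random sets in the test suite); the combined statistic
is $z_{up} - z_{down}$ with a missing set contributing 0.

## 3. Report aggregation and tumor-board rules

The aggregate score is the weighted sum of sensitive-direction evidence
(default weights 1). Two deliberate asymmetries:

* **Resistance never subtracts.** A drug with resistance evidence keeps
  its sensitivity score but carries a flag with provenance, and is
  demoted below unflagged drugs during selection. The alternative
  (vetoing or subtracting) destroys information the board may need; the
  flag-and-demote rule preserves it while keeping the score a pure
  sensitivity sum.
* **Ranks are a total order**: descending score with lexicographic
  drug-id tie-break, rank = position (1 = best, no gaps), so ranking is
  deterministic and reproducible.

The board filter excludes drugs lacking FDA approval or pediatric
dosing, demotes previously failed drugs unless a synergy override is on
record, and selects up to four agents. A switchable diversity heuristic
skips a drug whose targets are all covered by already-chosen drugs when
an uncovered-target drug sits within the next three positions; the
clinical analogue was expert judgment, so the heuristic is an artifact
decision and off-by-one-flag. Drug-interaction checking is a pluggable
interface; without a checker the plan honestly records
`"not evaluated"` rather than implying approval. Combination-dosing
provenance (peer-reviewed combination, component precedent, MTD with
pharmacy reduction) is a label, never dose arithmetic.

## 4. Study gates and ledger arithmetic

The QC gates copy the clinical protocol's printed boundary semantics
exactly, even though they are inconsistent between RNA ratios (strictly
greater than 1.8) and cDNA ratios (at least 1.8): fidelity over
tidiness. RIN must exceed 6.5 strictly; cDNA yield of 5 µg/30 µL passes.
Pathology passes at ≥ 75% viable tumor and < 20% necrosis. Percents are
rounded half away from zero to whole percents, which is the convention
that reproduces 1/14 → 7%, 8/14 → 57%, 5/14 → 36% and 9/14 → 64%.
Milestone dates are ISO-8601 or integer day offsets; feasibility
requires every milestone, treatment start within 21 days of biopsy
(inclusive), and one completed cycle. Time-to-event summaries are plain
order statistics with censoring flags — no survival-curve estimate is
attached, because no per-patient event times exist to validate one
against.

## 5. Concordance statistics

**PERMANOVA.** With squared distances $d_{ij}^2$,
$SS_T = \frac{1}{N}\sum_{i<j} d_{ij}^2$,
$SS_W = \sum_g \frac{1}{n_g}\sum_{i<j \in g} d_{ij}^2$,
$SS_A = SS_T - SS_W$, and pseudo-F
$= \frac{SS_A/(g-1)}{SS_W/(N-g)}$. The permutation p-value uses add-one
smoothing, so 999 permutations give a floor of exactly 0.001. The
partition identity $SS_A + SS_W = SS_T$ and agreement with an
independent implementation (vegan's `adonis2`) are tested; a permutation
matrix can be passed in place of a count for exhaustive enumeration on
small designs. Default distance is Euclidean on log2 values; the
clinical analysis did not name its metric, so one-minus-Pearson is
provided as the common alternative. One caveat the test design works
around: with $g$ groups of $m$ replicates, a random label permutation
reproduces the replicate partition with probability $g!(m!)^g/N!$ and
then ties the observed pseudo-F exactly, so very small designs (4 × 3)
occasionally return 0.002 rather than the floor; six biopsies make this
probability negligible.

**Drug-set reproducibility** is a reconstruction — only the averaging
structure ("over patients, replicates, and drugs") of the original
estimator is public. Per patient, the drug universe is the union of
drugs reaching the threshold in any replicate; each (drug, replicate
pair) contributes 1 when both replicates agree at threshold; the mean is
taken over drugs and pairs, then over patients. The estimator is
validated by its bounds (identical replicates → 1, disjoint → 0) and by
monotone nesting, not against the original study value: the published
overall average (0.68) depends on unreleased tumor data and is
explicitly out of reach at desk scale. A Jaccard distance on
above-threshold drug sets is provided for running the same permutation
MANOVA on drug lists.

**Cross-platform concordance** reports per-sample-pair log2 fold-change
slope and correlation, per-gene cross-sample correlation between
platforms, and (given replicate grouping) per-gene within-biopsy SD per
platform.

## 6. What the synthetic-data generator emulates

The generator exists so every analysis runs under conditions with the
structure the methods assume:

* **Normal reference**: per-gene baselines Uniform(6, 12) log2, per-gene
  tissue dispersion Uniform(1, 2) log2 units over 45 tissues. The wide
  dispersion is the model of a whole-body panel (tissue-specific genes
  vary hugely across body sites) and is what makes a "+k reference SD"
  planting recoverable: the patient-level deviation (SD 1.0 log2) is
  then at most one reference SD, so a +5σ planting stays above the +3
  rule with high probability.
* **Tumors**: reference mean plus patient-specific Gaussian deviations
  (`between_biopsy_sd`, default 1.0 log2); planted drug-target genes
  shifted by `planted_shift_sd` (default 5) reference SDs, drawn from
  inhibitor-target genes of the generated knowledge base so "truly
  beneficial drug" (inhibitor of a planted gene) is a recoverable ground
  truth.
* **Replicate sections**: shared biopsy truth plus independent noise of
  SD `within_biopsy_sd` (default 0.1 log2), an order of magnitude below
  the between-biopsy SD — the regime in which the replicate PERMANOVA
  and reproducibility analyses are meaningful.
* **Dual platforms**: two noisy measurements of the same log2 truth; the
  RNA-seq-like platform applies an affine distortion (gain 0.97, offset
  0.5 log2). The offset cancels in fold changes and the gain keeps the
  fold-change slope within 0.1 of unity, which makes cross-platform
  agreement a nontrivial test rather than an identity.
* **Knowledge base**: 108 drugs, all FDA-approved with pediatric dosing,
  1–3 targets each, 85% inhibitor actions; Z-predicate biomarker rules
  (80% sensitivity, 20% resistance); perturbation rankings in which a
  drug pushes its inhibitor targets toward the bottom (so beneficial
  drugs show inverse connectivity); a two-context, 8-lines-per-context
  sensitivity panel whose potency is coupled to target expression
  (slope 0.7 per SD, noise 0.3 log10 units); and a scale-free directed
  interaction network (preferential attachment, edges oriented hub →
  periphery).

Expression is simulated in log2 space and exported linear, because
preprocessing owns the log transform — input files mirror instrument
scale. The default universe is 2,000 genes, gene-level: desk-scale
runtimes, with probe-set summarization and probe→gene mapping out of
scope.

What it does **not** emulate — and therefore what passing tests do not
show about real data: probe-level microarray artifacts, sequencing reads
and coverage bias, RNA degradation, batch effects, non-Gaussian
expression heterogeneity, correlated gene modules, and any biological
fidelity of the drug/target/rule content. Tests on this generator
validate the *estimators and decision logic*, not clinical performance.

## 7. Determinism, degenerate inputs, problem sizes

All generator and permutation streams derive 32-bit sub-seeds from a
single base seed plus a stream label, so identical configurations are
bitwise reproducible and per-drug permutation nulls do not depend on
evaluation order. Ties are broken lexicographically everywhere a sort
feeds output. Degenerate inputs fail loudly with classed conditions:
empty gene-universe intersections, groups of size one, fewer than three
cell lines per context, milestone-order violations, empty reports after
exclusion. Zero-reach network nodes get p = 1 rather than NaN; KS tag
sets empty after intersection raise an undefined-score error rather than
returning 0.

Test and validation problem sizes are chosen for desk-scale runtimes
(full suite around two minutes): 300–2,000 genes, 10–45 tissues, 20–108
drugs, permutation counts 99–999, Monte-Carlo calibrations at 1,000
replicates. The null calibration of the PERMANOVA rejection rate uses
199 permutations per dataset, where the 5% level is exactly attainable
under exchangeability.

## 8. Known limitations

* The hidden-node engine is a principled surrogate for proprietary
  topology algorithms; radius-bounded reachability with hypergeometric
  enrichment captures convergence/divergence semantics but not the
  original systems' edge weighting or curation.
* The efficacy-score scale is this package's construction (comparable
  0–10 per method, additive); the clinical system's scale was never
  published, so the reproducibility threshold of 10 is meaningful only
  relative to this convention.
* The reproducibility estimator and the drug-list distance are labeled
  reconstructions and are swappable.
* Biomarker rules are Z-predicates by construction; curated clinical
  rule bases are richer (mutations, fusions, protein markers).
* No literature/clinical-trial evidence retrieval, no dose arithmetic,
  no imaging response computation: response classifications and dosing
  provenance are inputs.
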