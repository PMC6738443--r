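---
title: "Mining disease modules and their regulators from case-control transcriptomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining disease modules and their regulators from case-control transcriptomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

modregnet implements a module-centred analysis of case-control expression
data: genes that change expression between conditions are assembled into a
scored interaction network, cohesive modules are mined from that network,
and each module is then tested for functional enrichment and for targeting
by upstream regulators (non-coding RNAs and transcription factors). Hub
genes are ranked by a composite W statistic and re-tested in an independent
cohort with ROC curves. This vignette explains each model, the parameters
that matter, and the design decisions behind the implementation; every
number it mentions is recomputed by the test suite or by
`scripts/acceptance.R`, never copied in.

## The pipeline at a glance

```{r, eval = FALSE}
library(modregnet)
man <- run_pipeline(outdir = "run1", seed = 1)
```

`run_pipeline()` executes, in order: simulation (or loading) of the inputs,
quantile normalization, moderated-t differential expression with two-way
clustering of the top DEGs, GSEA of the case/control contrast,
construction of the DEG interaction network with W-score hub ranking,
cohesiveness-guided module mining, hypergeometric module enrichment,
regulator-module association with a TF-target correlation filter, assembly
of the integrated regulator-gene-pathway network, and validation of the hub
panel in a second cohort. Every stage writes a plain TSV and the manifest
records an MD5 for each output, so `rerun_pipeline()` reproduces a run
bit-for-bit from its manifest.

## Differential expression

Expression values are log2 intensities. Samples are first quantile
normalized (every column is mapped onto the per-rank cross-sample means;
the operation is idempotent). The per-gene case-vs-control contrast is then
tested with a moderated t statistic: per-gene variances are shrunk toward a
common prior estimated by empirical Bayes, and the moderated t has
`df_residual + df_prior` degrees of freedom. For small cohorts (the default
study shape is 7 cases vs 6 controls, so 11 residual df) this moderation is
what makes per-gene testing usable at all; it also keeps the statistic
finite for near-constant genes. `fit_differential(moderated = FALSE)`
computes the ordinary pooled two-sample t — the prior-df-to-zero limit —
which the tests use as a closed-form oracle.

Genes are called differentially expressed at **unadjusted** p < 0.05
(`select_degs()`). With roughly a dozen samples an FDR threshold is very
conservative and discards most of the signal a network analysis needs; the
BH-adjusted p is still reported per gene so users can filter on it. logFC
is defined as case minus control in log2 units. "Most up/down-regulated"
for the top-k cluster view means largest |logFC| among significant genes;
the two-way clustering uses Euclidean distance with average linkage (the
linkage is our choice; complete or Ward would change leaf orders but not
the case/control split the heatmap shows on planted data).

## GSEA

The case/control contrast is ranked by the signal-to-noise metric
(mean difference over the sum of group standard deviations, each sd floored
at max(0.2·|mean|, 0.2), the reference implementation's default). The
enrichment score of a gene set is the signed maximum deviation of the
weighted hit/miss running sum; with weight exponent 0 it reduces to the
classic Kolmogorov-Smirnov form, and both forms are pinned to a
step-by-step oracle at 1e-12 in the tests. Significance is a nominal
permutation p with the add-one correction restricted to same-sign null
scores, so it is never exactly zero. Phenotype relabeling is the default
null (13 samples admit C(13,7) = 1716 distinct relabelings, comfortably
more than the default 1000 permutations); when a smaller cohort makes
relabelings scarce the test falls back to size-matched random gene sets
and says so. The permutation count and type are implementation defaults,
stated here because the convention varies between tools; no normalized ES
or FDR across sets is computed since downstream filtering uses the nominal
p only.

## The DEG network and the W hub score

Scored interactions (STRING-like, scores in [0, 1]) are restricted to pairs
of DEGs with score at least 0.4 — the usual medium-confidence convention,
exposed as `min_score`. Duplicate and reversed pairs collapse to the
maximum score; isolated genes are dropped. Each node gets

W = |logFC| · (−log10 p) · degree,

a composite that is zero when any ingredient carries no information and is
monotone in each factor. Degree is the unweighted incident-edge count,
computed after score filtering (the natural reading: the network whose
hubs are ranked is the network that was built). Hubs are the top-10 W
values with deterministic tie-breaks (degree, then gene id).

## Cohesiveness-guided module mining

A module candidate V is scored by the ClusterONE objective
f(V) = w_in / (w_in + w_bound + penalty), where w_in is the total edge
weight inside V and w_bound the weight crossing its boundary. The penalty
(default 2) represents unobserved connections and keeps tiny sets from
scoring perfectly. `grow_module()` performs a greedy local search —
repeatedly the single best node addition or removal that strictly
increases f, ties broken toward the lexicographically smallest id — so
every reported module is a verified local maximum (the tests re-check this
by brute force). `detect_modules()` seeds growth from nodes in descending
degree order, skipping nodes already inside an accepted module; grown
candidates must have at least `min_size = 3` members and internal edge
density at least 0.5, and pairs with match coefficient
ω(A,B) = |A∩B|²/(|A||B|) ≥ 0.8 are merged (the union is rescored) until no
pair qualifies. One behaviour is worth documenting: grown sets that fail
the size/density filter do not claim coverage — on graphs with a dense
background a growth seeded at a background hub can absorb a large sparse
blob, and if that blob consumed its nodes the genuine modules behind it
would never be seeded. All four parameters follow the published ClusterONE
conventions and are exposed as arguments.

## Enrichment and regulator inference

Module-term over-representation uses the hypergeometric upper tail
P(X ≥ k) over a background universe; the kernel is shared with the
regulator test and agrees with exhaustive enumeration to 1e-10 for every
configuration with N ≤ 30. The default background is every gene with at
least one annotation in the loaded collection (pass `background =` to use
the network genes instead). Terms with zero overlap are not tested, which
affects the BH denominator; BH runs within each module and category, GO
categories at p < 0.01 and q < 0.01, pathways at p < 0.05 and q < 0.2.

A regulator is associated with a module when its filtered targets
(interaction score ≥ 0.5) overlap the module in **more than 2 genes** (a
strict quantity > 2, i.e. at least 3) **and** the hypergeometric p is
below 0.01. The joint rule is what controls false positives: in the tests
1000 random regulators pass at ≤ 2% while planted regulators with 5
module targets among 45 all pass. The background for this test defaults to
the interaction-network genes — the population a module could plausibly
have been drawn from. TF-module edges must additionally survive a Pearson
correlation filter between the TF's and the target's expression (two-sided
p < 0.05 via the t transform on n − 2 df); ncRNA edges are not
correlation-filtered because ncRNA expression is not measured on the
arrays. The surviving regulator→gene and gene→pathway edges form the
integrated network, with gene nodes carrying their DE direction.

## Validation and ROC

Hub genes and module TFs are re-tested in a second cohort with the same
moderated t, and a gene is "consistent" when it is significant at 0.05
with the same direction as in discovery (the same test is reused
deliberately, for internal consistency). Per-gene diagnostic ability is
the ROC AUC with the orientation fixed as "higher expression predicts
case": the Mann-Whitney rank statistic with ties half-counted, which the
tests verify equals the trapezoid area under the threshold-sweep curve to
1e-12 and matches pROC. An AUC below 0.5 is reported as-is;
`auto_direction = TRUE` restores the max(auc, 1 − auc) convention. For
down-regulated markers the meaningful quantity is 1 − AUC, which the
acceptance script applies when reporting the top hub.

## The synthetic-data generator

Every stage is exercised on data with planted truth, generated by
`simulate_study()`:

* **Expression** — baseline per-gene means N(7, 1) on the log2 scale
  (chosen to resemble normalized microarray intensities), 7 cases vs 6
  controls mirroring the discovery-cohort shape, 10% of genes shifted by
  ±2 log2 units in cases, N(0, 0.5) noise. An `effect_size = 0`
  configuration is the null used for calibration tests.
* **Interactions** — a planted-partition graph: five modules of 8-12 genes
  with within-module edge probability 0.9 and scores U(0.7, 1), background
  probability 0.01 with scores U(0.15, 0.7). Modules are drawn
  preferentially from the planted DE genes so the DEG-restricted network
  retains them; they are disjoint by default (`module_overlap` plants
  controlled sharing, since the miner permits overlap).
* **Regulators** — one planted regulator per module (classes alternate
  ncRNA/TF; a planted TF is itself a module gene so its expression is
  observable and correlates with its targets through the group effect),
  guaranteed 5 targets inside its module at scores ≥ 0.5, plus decoys and
  fully random null regulators.
* **Gene sets** — one planted term per module covering ≥ 60% of it, padded
  to a size in [15, 200], plus random terms in the same size range.

A fixed seed makes every table bit-identical across runs. What passing
tests on these data do **not** show: real microarray intensities are not
Gaussian with homogeneous noise, real interactomes have heavy-tailed
degree distributions and correlated annotation structure, and real
regulator databases are biased toward well-studied genes. The synthetic
benchmarks demonstrate correctness and calibration of the machinery, not
biological performance.

## Problem sizes and numerical choices

The shipped tests run the DE calibration at 10,000 genes, module recovery
at 200 genes with five planted modules of 8 (p_in 0.9, p_out 0.05), GSEA
calibration with 500 random sets at 200 permutations spread over five
independent null cohorts, and the end-to-end pipeline at 1,000 genes —
sizes at which every check completes in seconds to a couple of minutes on
one core while leaving the Monte-Carlo error well inside the asserted
bands. Greedy growth treats an improvement below 1e-12 as a tie to
guarantee termination in floating point; p-values of exactly zero are
floored at the smallest positive double before entering −log10; zero
variance makes a correlation undefined and the record is flagged rather
than guessed.

## Known limitations

The miner's greedy search finds local maxima only, and on graphs whose
background density approaches the within-module density, planted-module
recovery degrades — by design, since the signal itself vanishes.
Regulator direction (activation vs inhibition) is not inferred; the
hypergeometric association is symmetric in sign. The GSEA nominal p is not
multiplicity-adjusted across gene sets. Validation reuses the discovery
test rather than an independent statistic, so "consistency" measures
replication of the same contrast, not robustness across methods.
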