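---
title: "Multi-organ disease models and connective pathway analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-organ disease models and connective pathway analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcdmTools)
```

## The problem this package addresses

Immune-mediated inflammatory diseases change gene expression in many organs
at once, not only in the clinically obvious one. Given per-(organ, cell type)
differential-expression tables, a ligand-to-target prior, and pathway gene
sets, `mcdmTools` organizes those changes into a hierarchy of models:

1. **MCDMs** (multicellular disease models): per organ, a directed multigraph
   whose nodes are cell types and whose edges are upstream regulators (URs) —
   ligands expressed by a sender cell type whose known downstream targets are
   over-represented among a receiver cell type's differentially expressed
   genes (DEGs).
2. **MO-MCDM**: the multi-organ version, restricted to URs annotated as
   located in extracellular space, because only those can plausibly travel
   between organs through blood.
3. **Connective pathway analysis (CPA)**: enriched pathways are clustered by
   the genes they share into *programs* and *subprograms*, each labeled
   activated / inhibited / no-direction / not-significant per group of
   datasets; the fraction of pathways that flip between groups (the
   *opposing fraction*) quantifies on/off switching, e.g. between inflamed
   and non-inflamed organ sites.
4. **UR-to-program mapping and takeover screening**: URs are linked to the
   programs they plausibly drive by meta-combined enrichment, and, in
   treatment cohorts, backup ("takeover") URs that explain non-response are
   screened with three explicit criteria.
5. **Reference-based cell typing** supplies the per-cell-type grouping for
   single-cell inputs.

Every stage can be exercised against a synthetic-data module that plants
known structure, so the whole pipeline is testable without any external
download.

## Statistical core

**Set enrichment.** All enrichment is the right-tailed Fisher exact test: for
a query set $q$, target set $t$ and background of size $N$, the p-value is
the hypergeometric tail $P(X \ge |q \cap t|)$. The sample odds ratio gets a
0.5 Haldane correction only when a table cell is zero; the p-value never
does. The choice of background follows the analysis: all genes measured in a
dataset (pathway enrichment), all DEGs of a dataset (GWAS enrichment), all
genes or pathways entering CPA (UR-program mapping, treatment effects).

**Directional activation.** Commercial knowledge bases emit a causal
activation z-score; this package uses an open consistency score in its
place. For pathway genes that are DEGs and carry a direction annotation
(signed-GMT dialect `SYMBOL:+1|-1`),

$$z = \frac{N_\text{consistent} - N_\text{inconsistent}}
          {\sqrt{N_\text{consistent} + N_\text{inconsistent}}},$$

undefined when no signed DEG overlaps. It is bounded by $\pm\sqrt{N}$ and
flips sign when all DEG signs flip. It is a stand-in, not a reimplementation
of any proprietary engine; on real collections its values will differ from
published ones.

**Meta-combination and multiplicity.** Evidence across cell types or
datasets is combined with Fisher's method ($X^2 = -2\sum\ln p_i$ on $2k$
degrees of freedom). BH is used for discovery-style families, Holm for the
small families of pairwise severity tests. Pathway *significance* inside CPA
uses raw $p < 0.05$, matching how canonical-pathway calls are usually made;
FDR applies where the downstream analyses state it (UR-program mapping,
treatment analysis).

**Activation labels.** Per (pathway, group): among the group's datasets with
$p < \alpha$, count $z>0$, $z<0$, and undefined-$z$ calls. Majority wins;
equal nonzero counts or only undefined-$z$ significances give
`no_direction`; no significant dataset gives `not_significant`. A pathway is
*opposing* between two groups when it is activated in one and inhibited in
the other, or significant in exactly one.

## Interaction inference

Expressed genes of a population are those with mean back-transformed
expression $10^x - 1 \ge 10^{-5}$ (the function warns when the result falls
outside the 5,000–10,000 band expected at full scale — synthetic runs at desk
scale trip this warning by design). Ligand activity against a receiver is
the Pearson correlation between the ligand's regulatory-potential vector and
the receiver's 0/1 DEG membership over the candidate universe (receiver
expressed genes ∩ prior gene space); only activity > 0 makes an edge. Edge
targets are the receiver DEGs among the ligand's `top_k = 200`
highest-potential links, boundary ties included. URs are ranked by total
downstream targets (distinct per receiver, summed over receivers), then by
number of distinct receivers, then lexicographically — a deterministic total
order.

Autocrine self-pairs are retained inside organs and excluded from the
MO-MCDM, which is defined by blood transport between organs. Organ
prioritization ranks organs by the median DEG count across bootstrap rounds
(the study design resamples 40 cells per group, ten rounds); the statistic is
configurable to the mean because the original comparison rule is not fully
specified.

## Cell typing

Cells passing QC (≥ 10,000 reads, 400–6,000 transcripts, ≥ 200 genes,
mitochondrial fraction < 20%; genes detected in ≥ 10% of retained cells) are
matched to bulk reference profiles: for each reference, the cell with the
highest Spearman correlation is found, an isotonic (non-decreasing)
regression maps reference values to the natural log of that cell's
expression, and the rounded exponents of the fit become a pseudo-reference
profile on the single-cell scale. Cells and pseudo-references are embedded
together and clustered by Leiden on a k = 30 nearest-neighbor graph, starting
at resolution 0.5 and escalating by 0.1 (cap 5.0) until every cluster's
purity — the fraction of its cells sharing the modal best-match reference —
reaches 70%; all cells of a cluster get the modal label.

Design choices made where the procedure was genuinely open:

* The published workflow uses a denoising autoencoder for its
  32-dimensional latent space. The embedding here is pluggable with a
  truncated PCA default, because the typing logic (matching, monotone
  projection, purity escalation) is embedding-agnostic and a trained
  external component cannot be shipped.
* Per-cell best-reference matches are computed once on expression and reused
  at every resolution (recompute-per-resolution is not specified and would
  not change matches, which do not depend on the clustering).
* Reference points join the k-NN graph with unit weight but do not count
  toward the purity denominator.
* Isotonic regression uses `stats::isoreg`; the fit is a function of the
  reference value, so tied inputs share one fitted value. Back-transformation
  of the log10 layer uses a pseudocount of 1 before taking the natural log.
* Resolution escalation step 0.1 and cap 5.0 give a deterministic, bounded
  search; the Leiden seed is fixed and exposed.

## Connective pathway analysis

Pathways are restricted to genes differentially expressed in at least one of
the group's datasets, pairwise Jaccard similarities are computed on those
restricted sets, and 1 − J feeds Ward clustering under the squared-distance
("ward.D2") update, the convention whose parameter semantics match standard
practice for precomputed non-Euclidean distances. The top cut (default
k = 2) defines programs, labeled `P1, P2, ...` by decreasing size. Each
program's members are re-clustered with the same linkage and cut into
subprograms (`SPi.j`); this equals a subtree cut whenever programs are well
separated and is deterministic regardless. Merge ties follow `hclust`'s
index-based order. The number of subprogram cuts is a per-program
configuration parameter (default 10 at full scale; small synthetic trees use
smaller values).

## Takeover (backup-UR) screening

Given a treatment cohort (responders/non-responders, before/after treatment,
vs controls) and an anchor UR (the drug target; a parameter, nothing is
hard-coded to any gene), a candidate UR is *prioritized* when its downstream
targets are enriched among the anchor's targets in at least one
program/subprogram (FDR < 0.05) and all three criteria hold:

1. its activation z-score has the same nonzero sign in responders and
   non-responders before treatment;
2. its own fold change moves further in that direction in non-responders vs
   control than in responders vs control (strict inequality by default; a
   `weak` option also accepts a crossing from negative to ≥ 0 for
   activators, mirrored for inhibitors, since the published wording admits
   both readings);
3. its fold change in treated non-responders vs treated responders is
   significant (FDR < 0.05) and in the z-score's direction.

z = 0 fails criterion 1 under the strict reading of "similarly positive or
negative". URs missing any statistic are excluded with a reason code rather
than silently failing a criterion.

## What the synthetic generators emulate

`generatePathwayDB()` plants programs by construction: every pathway of a
program carries the program's core genes (`within_share` of its genes), every
pathway carries a small global shared set (`between_share`), and the rest is
private, so requested sharing fractions are exact rather than merely expected.
Each gene receives a ±1 activation-direction sign.

`generatePrior()` assigns each UR a home program and draws its targets
core-first from that program, because gene sharing across a program's
pathways is precisely the footprint of shared upstream regulation — this is
what makes planted URs recoverable by enrichment. `generateDegTables()`
turns UR activity into DEGs whose fold-change sign is the UR direction times
the gene's annotated sign (an active-up UR moves each target in its annotated
direction); planted DEGs are dropped at `fn_rate` and false positives appear
at `fp_rate`. Synthesized p-values follow Beta(0.01, 1) truncated below 0.05
for DEGs and Uniform(0.05, 1) for nulls, with FDR columns drawn consistently
(adjusted ≥ raw, planted DEGs below the 0.05 cut): only the ordering and the
0.05 cut matter downstream. `generateExpression()` draws negative-binomial
counts with variance $\mu + \alpha\mu^2$ and type means perturbed by a
log-normal factor of log-sd `separation`.

The default scenario (`defaultPipelineConfig()`) uses 2 programs × 10
pathways × 50 genes with within/between sharing 0.5/0.05, 8 URs with 120
targets each over the ~500-gene universe, `fp_rate` 0.01 and `fn_rate` 0.1.
The per-UR DEG fraction (~25% of measured genes) mirrors the inflamed-tissue
cohorts this kind of analysis is applied to, where DEG lists routinely exceed
a quarter of the measured probes — that is also why a 5,000-row DEG cap
exists at full scale. One UR is active only in the "inflamed" arm and one in
both arms, producing a program that switches off between arms and one that
does not.

What the generators deliberately do **not** emulate: batch effects, doublets,
ambient RNA, correlated genes within pathways beyond co-regulation by the
planted URs, ortholog mapping between species (a single gene namespace is
assumed throughout), and any real knowledge-base content. Passing tests
therefore demonstrate that the algorithms recover the structure they are
specified to recover under clean, calibrated noise — not that any specific
biological claim holds on real data.

## Numerical choices and degenerate inputs

* Zero-variance vectors make Pearson/Spearman correlations undefined: those
  ligand or reference pairs are skipped with a warning, and an error is
  raised only when nothing remains.
* `combineFisher()` clamps p = 0 to the smallest positive double with a
  warning; empty p-lists are an error.
* Empty query sets give p = 1 by convention (warning); empty backgrounds are
  errors.
* DEG-cap ties at the boundary break by larger |logFC|, then gene id.
* All generators take an explicit integer seed and reproduce their output
  bit-identically; the pipeline manifest records a parameter hash so reruns
  are verifiable.

## Problem sizes

The shipped tests and the acceptance script run everything at desk scale —
a few hundred genes, a handful of cell types, 2 × 10 pathways, 400 cells for
the typing scenario, 200 replicates for the BH calibration — chosen so that
planted effects are comfortably above sampling noise while each scenario
completes in seconds. The same functions operate unchanged on full-scale
inputs read from GMT / TSV / MTX files.

## A worked example

```{r example, eval = FALSE}
library(mcdmTools)
res <- runPipeline(defaultPipelineConfig(seed = 1))
res$urRanking          # URs ordered by downstream reach
res$opposingFractions  # per-program on/off switching between arms
programs(res$tree)     # pathway -> program assignment
```

## Known limitations

* The activation z-score is a consistency score, not a causal-network
  computation; labels on real data will differ from those produced by
  proprietary engines, and the enrichment background differs from any
  engine's internal universe, so published pathway counts are not
  reproducible by design.
* Subprogram cuts are user-chosen counts, not model-selected.
* The DE stand-in (`simpleDE`) is a rank-sum test on normalized values;
  serious single-cell DE should come from a dedicated engine upstream.
* Receptor expression on the receiver side is not modeled; an edge asserts
  target-set enrichment, not a verified signaling path.
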