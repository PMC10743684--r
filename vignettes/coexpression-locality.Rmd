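---
title: "Chromosomal locality of co-expression and TF motif usage: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chromosomal locality of co-expression and TF motif usage: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coexloc)
```

## The question

Gene co-expression networks (GCNs) inferred from tumor transcriptomes show a
striking structural change relative to healthy tissue: most strong
co-expression edges connect genes on the *same* chromosome, while long-range
(inter-chromosomal) co-expression largely disappears. One candidate
explanation is transcription-factor (TF) regulation: if each tight cluster of
co-expressed genes were driven by its own small set of TFs, motif usage could
account for the pattern. `coexloc` implements the full analysis needed to ask
that question — network inference, community detection, per-community motif
enrichment, regulatory-network assembly, and the comparative statistics — on
either real count matrices or synthetic data with planted, known structure.

## The pipeline

1. **Quality control.** Genes with mean raw count < 10, or zero counts in
   more than 50% of samples, are removed (both thresholds strict). Samples
   whose mean expression lies strictly outside the grand mean ± 2 standard
   deviations of the per-sample means are removed in a single pass; the SD
   uses the population denominator `n`, a convention we fix for
   reproducibility. The order — gene filters, then the sample filter, then
   normalization — is fixed; gene-first is our documented choice where the
   convention is otherwise unstated.
2. **Normalization.** Counts-per-million followed by `log2(x + 1)`. Because
   the MI estimator below works on equal-frequency bins, any monotone
   per-sample scaling leaves the network invariant; CPM/log2 is used so that
   written artifacts are on a familiar scale.
3. **Network inference.** Pairwise mutual information (MI) for all gene
   pairs, ARACNe-style data-processing-inequality (DPI) pruning, then a
   top-*k* edge cut.
4. **Communities.** Louvain modularity optimization with seeded restarts;
   the largest 20 communities (by member count) proceed to enrichment.
5. **Enrichment and GRN.** One upper-tail hypergeometric test per
   (TF, community) pair with nonzero overlap, a single Benjamini–Hochberg
   family per phenotype, significance at q < 0.05, and a directed TF→target
   network built from the significant pairs.
6. **Comparison.** Topology counts, per-TF target distributions, exact
   Venn-region counts of TF and target sets, star structures, unique-TF
   subnetworks, per-target regulator counts with chromosome coverage, and a
   motif k-mer census (default: the heptamer `CCGGAAG`).

## The MI estimator

For vectors $x, y$ of $n$ samples we form equal-frequency bins (default
$B = \lfloor\sqrt{n}\rfloor$) with boundaries at order statistics, and return
the plug-in estimate in bits,

$$\hat I(X;Y) = \sum_{a,b} \hat p_{ab} \log_2
  \frac{\hat p_{ab}}{\hat p_{a\cdot}\,\hat p_{\cdot b}}.$$

Boundaries at order statistics make the discretization exactly invariant
under strictly monotone transforms and under permutation of samples, and
tied values always share a bin — important for count data, where naive rank
binning would split ties arbitrarily and break permutation invariance. When
all values are distinct and $B \mid n$ the bins are exactly equal and
$\hat I(X;X) = \log_2 B$. The plug-in estimate has the usual positive bias at
finite $n$; that bias is shared by all pairs and is irrelevant to a rank
(top-*k*) edge cut, which is why no bias correction is applied.

## DPI pruning and the top-k cut

For every triangle whose three MI values exceed a working floor (default 0),
the edge $(i,j)$ is removed when
$I_{ij} < \min(I_{ik}, I_{jk})\,(1-\tau)$. Removals are decided against the
*original* matrix and applied simultaneously, so the result does not depend
on any processing order. The function default is $\tau = 0$, the strictest
reading of the rule; the packaged *run* configuration uses $\tau = 0.15$,
the conventional ARACNe tolerance. The distinction matters at desk scale: a
planted module of mutually co-expressed genes has nearly equal MI on all its
internal edges, and at $\tau = 0$ sampling noise alone decides which of them
is "weakest" in each triangle, thinning near-cliques to spanning-tree-like
remnants. A 15% tolerance retains edges within estimation noise of the
triangle minimum and preserves module cliques, which is what the community
stage should see.

The top-*k* cut keeps the $k$ largest surviving MI values (ties at the
cutoff broken lexicographically by gene pair, so runs are reproducible). At
study scale the convention is $k = 100{,}000$; the packaged desk-scale
default is $k = 2500$, chosen to be of the same order as the number of
planted within-module pairs ($16 \times \binom{20}{2} = 3040$) so that the
retained network can represent the planted structure without drowning it in
noise edges. A cut in the low hundreds at these sizes would fragment the
modules.

## Louvain with seeded restarts

Louvain is order-sensitive, so `louvain_communities()` runs `n_restarts`
passes, each on a node ordering shuffled by a seed derived from the master
seed, scores each partition with the weighted modularity

$$Q = \sum_c \left[\frac{w_c}{W} - \gamma\left(\frac{s_c}{2W}\right)^2\right],$$

and keeps the best (ties to the first restart that attained it). Resolution
$\gamma$ defaults to 1. Community ids are renumbered `0..C-1` by decreasing
size, ties by smallest member gene id, so downstream joins are stable.
Isolated nodes form singleton communities and do not change $Q$.

## Enrichment conventions

The universe is the intersection of the network's community genes with the
union of motif-database candidate targets: only genes that could in
principle be called either way enter the null. The alternative (an explicit
universe) is exposed as an argument. All (TF, community) tests of a
phenotype form one BH family; correcting per community would use a smaller
family and overstate significance. GRN edges use the
community ∩ motif-target intersection rule by default, so each edge asserts
motif evidence; the whole-community reading is available as
`edge_rule = "whole-community"`. The k-mer census uses literal substring
matching by default — the convention under which `NRSCGGAAGNN` does *not*
contain `CCGGAAG` — with IUPAC-degeneracy matching as an option.

## The synthetic generator

`generate_dataset()` plants everything the pipeline is supposed to find.
Genes are assigned round-robin to chromosomes. Each of `n_modules` modules
of `module_size` genes receives one standard-normal latent factor per
sample; member counts are negative binomial with
$\log \mu = \beta_0 + \beta z_m$ and shared dispersion $\phi$
(variance $\mu + \phi\mu^2$). In the **cis** regime, modules are sampled
within one chromosome (cancer-like, chromosome-confined co-expression); in
**trans**, membership ignores chromosomes (healthy-like). True TFs receive a
planted module as regulon with a `target_noise` fraction swapped for random
outside genes; decoy TFs receive size-matched uniform target sets, giving
the enrichment stage a measurable false-discovery surface.

Defaults are the packaged study conditions: 400 genes, 10 chromosomes, 16
modules of 20, 150 samples, $\beta = 1.5$, $\beta_0 = 5$ (mean ≈ 148
counts, comfortably above the QC filters), $\phi = 0.15$ (moderate RNA-seq
overdispersion), 10 true TFs at 10% target noise, 50 decoys. At these
settings within-module correlation is strong (≈ 0.9 on log counts), which
is deliberate: the acceptance question is whether each stage transmits a
clearly planted signal, not whether the estimator is minimax at weak signal.
The generator does **not** emulate batch effects, GC or gene-length bias,
library-size heterogeneity beyond Poisson–gamma noise, or overlapping
regulons — so passing tests certify the pipeline's correctness and
regime-discrimination, not robustness to those real-data artifacts.

Module recovery is scored by the adjusted Rand index between recovered top
communities and planted modules, computed over genes that belong to a
planted module and appear in the network (the standard planted-partition
benchmark).

## Numerical and degenerate-input conventions

* Constant gene profiles discretize to a single bin, have zero entropy, and
  contribute MI 0 with a warning.
* Tiny negative MI values from floating cancellation are clamped to 0.
* `k = 0` overlaps yield hypergeometric p exactly 1; a community equal to
  the whole universe likewise.
* Ties: top-*k* cutoff and top-community cut both break ties
  lexicographically; Louvain restarts break Q ties by first occurrence.
* All randomness flows from explicit seeds through named substreams
  (`derive_seed`), and library code restores the caller's RNG state.

## Problem sizes used by the test and acceptance runs

Unit tests run on 20–80-gene fixtures. The end-to-end checks use the
packaged default conditions above (three seeds per regime for locality and
recovery; five seeds for regulon recovery), which we consider the smallest
configuration at which all stages operate in their intended regime: two
modules per chromosome, enough samples for a 12-bin MI estimate, and a
decoy-to-true TF ratio of 5:1.

## Known limitations

* The MI estimator is the plug-in histogram estimate; no kernel or k-NN
  estimators, and no permutation-based significance thresholds (the edge
  cut is a rank cut by design).
* Louvain only (no Leiden refinement, consensus clustering, or hierarchy).
* The motif database is a flat (TF, motif, target-set) table; no position
  weight matrices and no sequence scanning — enrichment is set-based.
* Chromosome labels are opaque; genomic distance within a chromosome is
  never used.
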