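# coexloc

Cancer gene co-expression networks lose long-range structure: in tumor
transcriptomes, the strongest co-expression edges overwhelmingly connect
genes on the *same* chromosome, while in healthy tissue co-expression spans
chromosomes freely. `coexloc` is an R package for testing whether
transcription-factor (TF) motif usage can account for that pattern. It is
aimed at computational biologists who want a fully reproducible,
desk-scale version of the analysis: every stage is a tested function, and a
synthetic-data generator with planted structure makes every claim
verifiable without access to large tumor cohorts or licensed motif
databases.

## What it computes

Starting from a gene × sample count matrix, a gene→chromosome annotation,
and a motif database of (TF, IUPAC motif, candidate targets) records:

1. **QC** — remove genes with mean count < 10 or zeros in > 50% of samples;
   remove samples whose mean expression falls outside the grand mean ± 2 SD
   of per-sample means; normalize to log2(CPM + 1).
2. **Co-expression network** — plug-in mutual information
   *Î(X;Y) = Σ p̂ log₂(p̂ / p̂ₓ p̂ᵧ)* on equal-frequency bins
   (B = ⌊√n⌋), ARACNe-style DPI pruning (edge (i,j) removed when
   *I₍ᵢⱼ₎ < min(I₍ᵢₖ₎, I₍ⱼₖ₎)(1 − τ)* in some triangle), and a top-k edge
   cut.
3. **Communities** — Louvain maximization of weighted modularity
   *Q = Σ_c [w_c/W − γ(s_c/2W)²]* with seeded restarts; the 20 largest
   communities are kept.
4. **Motif enrichment / GRN** — per (TF, community) upper-tail
   hypergeometric test, one Benjamini–Hochberg family per phenotype,
   q < 0.05; significant TFs are linked to the motif-supported genes of
   their communities to form a directed TF→target network.
5. **Comparative statistics** — intra- vs inter-chromosomal edge fractions,
   community chromosome homogeneity, GRN topology counts, per-TF target
   distributions, exact Venn-region counts of TF/target sets, star-like
   structures, unique-TF subnetworks, and a motif k-mer census (default:
   the heptamer `CCGGAAG`).

The synthetic generator plants chromosome-confined ("cis", cancer-like) or
chromosome-spanning ("trans", healthy-like) co-expression modules through
negative-binomial counts driven by per-module latent factors, plus true
regulons and decoy TFs, so sensitivity and false-discovery proportion are
measurable against ground truth.

## Worked example

```r
library(coexloc)

ds   <- generate_dataset(synthetic_config(regime = "cis", seed = 1))
norm <- preprocess_counts(ds$expression)$matrix
net  <- infer_gcn(norm, dpi_tolerance = 0.15, top_k = 2500)
locality_stats(net, ds$annotation)
#> Locality: 2500/2500 annotated edges intra-chromosomal (fraction 1.000)

part <- louvain_communities(net, seed = 1, n_restarts = 5)
part
#> Community partition: 16 communities over 320 nodes, Q = 0.9352 (resolution 1)
#>   largest sizes: 20, 20, 20, 20, 20

comms <- top_communities(part, 20)
enr   <- enrich_communities(comms, ds$motif_db)
build_grn(enr, comms, ds$motif_db, phenotype = "cis_demo")
#> Regulatory network 'cis_demo': 10 TFs -> 180 targets, 180 edges

module_recovery_ari(comms, ds$truth)
#> [1] 1
```

Under cis wiring every strong edge is intra-chromosomal (fraction 1.000)
and the 16 planted modules are recovered exactly (ARI 1); the ten planted
TFs — and none of the fifty decoys — come out significant. Rerunning with
`regime = "trans"` drops the intra-chromosomal fraction to roughly 0.1
(the chance level for 10 chromosomes) while community recovery and TF
enrichment are unchanged: motif-driven regulation is compatible with either
wiring, which is exactly the contrast the pipeline is designed to expose.

A two-phenotype end-to-end run, writing every artifact plus a manifest:

```r
run_pipeline(coexloc_config(output_dir = "run1"))
```

A thin CLI with subcommands `run`, `simulate`, `preprocess`, `gcn`,
`communities` and `enrich` is installed under `inst/cli/coexloc`.

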