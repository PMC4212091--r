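# mapbias

Allelic mapping bias detection and correction for RNA-seq, with a
simulation-verified cis-eQTL pipeline.

## The problem

Aligning RNA-seq reads to a reference genome penalizes reads that carry
non-reference alleles: at a variant site, an ALT-carrying read differs from
the reference by at least one edit, and wherever the flanking sequence is
repetitive it mismaps or multimaps more often than its REF counterpart.
Exon quantifications at such loci become genotype-dependent for purely
technical reasons, and cis-eQTL scans report them as associations.

`mapbias` implements the simulation-based diagnosis and cure:

* **Exhaustive haplotype-aware read simulation** — for every panel variant,
  every potential read start site and every locally observed haplotype
  combination, build the read (genome single-end, spliced-transcript
  single-end, or paired-end with a fixed inner insert) and map it back.
* **Bias catalog** — per variant, the mapping rates of REF and ALT reads
  (`delta = rate_ref - rate_alt`; flagged when `|delta| > 5%`, direction
  REF or ALT), and the deduplicated list of biased start sites.
* **Filtering** — remove every alignment whose start site is biased, for
  every individual regardless of genotype.
* **Before/after cis-eQTL mapping** — Spearman rank correlation, gene-level
  permutation P values with a shared permutation order, BH at 10% FDR with
  the unfiltered threshold reused verbatim; genes classified as
  common / lost / gained, with `Δlog10 P` drop flags and variant-overlap /
  TSS-matched enrichment diagnostics.
* **Synthetic data as a first-class module** — genomes with segmental
  duplications and provably biased planted loci, phased panels (SNPs and
  indels, MAF ≥ 1%), multi-exon gene models, and negative-binomial RNA-seq
  cohorts with planted true eQTLs and mapping-bias-only false eQTLs plus a
  truth table.

The gene-level statistic is the best `|rho|` over a gene's exons and
cis-variants; its empirical P value is
`(1 + #{permuted best ≥ observed}) / (n_perm + 1)`.

## Worked example

```r
library(mapbias)

cfg <- sim_config(rng_seed = 1, genome_len = 60000, n_individuals = 60)
sim <- make_reference_panel(cfg, n_snps = 120, n_indels = 20) |>
  make_gene_models(n_genes = 12) |>
  plant_eqtl_truth(n_true = 5, n_bias = 3)
sim
#> <mb_sim> 61494 bp over 4 contig(s); 143 variants (123 SNP / 20 indel); 60 individuals
#>   12 gene models
#>   truth: BIAS_FALSE_EQTL=3, NULL=4, TRUE_EQTL=5

catalog <- build_bias_catalog(sim, "genome_se")
catalog
#> <mb_bias_catalog> mode=genome_se; 16802 reads over 143 variants; 10 flagged (|delta| > 0.05); 212 biased start sites

cohort <- simulate_rnaseq_cohort(sim, depth = 300)
res <- eqtl_before_after(cohort, catalog, sim$panel$variants,
                         eqtl_config(n_perm = 500, rng_seed = 1),
                         drop_threshold = 2)
res$comparison
#> <mb_eqtl_comparison> COMMON=6, GAINED=0, LOST=3, NEVER=3; 3 large drop(s)
```

The flagged set contains the three planted bias SNPs (ALT mapping rate 0,
direction REF) plus a handful of indel loci whose alternate reads realign a
few bases off their origin — the strict positional policy counts those as
biased too, mirroring how heavily indels are affected in practice. The
three LOST genes are exactly the three planted false eQTLs: their best
nominal P collapses by more than two orders of magnitude once reads at
biased start sites are removed. All five TRUE_EQTL genes stay COMMON (the
sixth COMMON gene is a NULL gene that cleared the FDR threshold in both
analyses).
`autoplot(catalog)` shows the reference-allele-ratio distribution;
`autoplot(res$comparison)` the before/after P-value scatter colored by
class.

See the methods vignette (`vignettes/mapbias-methods.Rmd`) for the model,
the mapper's location semantics, all tunable parameters and the
simulator's deliberate simplifications.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs the complete synthetic study from scratch with the installed
package — panel and gene-model generation, truth planting, bias-catalog
construction, cohort simulation, filtering, and the before/after eQTL
comparison — printing the headline summaries and writing the JSON report
to `--out`.
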