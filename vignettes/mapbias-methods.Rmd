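---
title: "Detecting and correcting allelic mapping bias in RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and correcting allelic mapping bias in RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mapbias)
library(dplyr)
```

## The problem

RNA-seq reads are aligned to a reference genome that carries, at every
polymorphic site, one of the two alleles an individual may have. A read
carrying the non-reference (ALT) allele differs from the reference by at
least one edit, so whenever the surrounding sequence is even slightly
repetitive, ALT reads have a lower probability of aligning uniquely and
correctly than REF reads from the same position. The consequence is not
subtle: expression estimates at variant-containing exons become
genotype-dependent for purely technical reasons, and a cis-eQTL scan will
happily report those artifacts as associations.

`mapbias` implements the simulation-based remedy end to end:

1. **Enumerate** every potential read overlapping every panel variant, in
   every locally observed haplotype (`build_simulated_reads()`).
2. **Map** those reads back to the reference and judge per-read correctness
   (`map_reads()`, `judge_correctness()`).
3. **Catalog** start sites and variants where REF and ALT reads do not map
   equally (`build_bias_catalog()`).
4. **Filter** real (here: simulated) alignments at biased start sites, for
   every individual regardless of genotype (`filter_alignments()`).
5. **Quantify** exons and **re-map cis-eQTLs** before and after filtering
   with an identical permutation design, then classify each gene as
   common / lost / gained (`eqtl_before_after()`).

Because the real inputs of such a study (a human reference, a phased
population panel, hundreds of RNA-seq libraries) are cluster-scale, the
package ships a first-class synthetic-data generator whose outputs have the
statistical structure the analysis assumes — including loci *guaranteed* to
be biased, and planted true and false eQTLs with a machine-readable truth
table. Every claim the test suite makes is computed against those
constructions.

## The read simulation

For each variant, the candidate start sites are all positions `s` whose
window `[s, s + read_len - 1]` intersects the variant footprint; a
mid-contig SNP has exactly `read_len` of them. At each start, the *local
haplotypes* are the distinct restrictions of the observed panel chromosomes
to the variants inside the window, plus the all-reference string; each is
simulated once, in equal proportions, regardless of population frequency —
the bias of a locus is a property of its sequence, not of allele
frequencies. Reads are built from the haplotype-substituted sequence, with
three frames:

* `genome_se` — single-end over the genome;
* `transcript_se` — single-end over spliced transcripts (variants fully
  inside exons; reads may span junctions and their origins are recorded as
  genomic projections);
* `genome_pe` — paired-end with a fixed *inner* mate distance
  (`inner_insert`, default 60 bases, i.e. 160-base fragments for 50-base
  reads). Haplotypes are enumerated jointly over the whole fragment: one
  chromosome per fragment. The alternative reading of "insert size" as the
  full fragment length is one configuration value away.

Only the forward strand is simulated: end-to-end alignment of a read and
its reverse complement is symmetric, so reverse-strand reads would double
the work without adding information. Window starts that fall on a base
deleted by the haplotype are skipped — no read starts there on that
chromosome. For indels, windows are anchored in haplotype coordinates and
the recorded origin is the reference coordinate of the first aligned base
under left-normalized projection.

## The built-in mapper and what "mapped equally" means

The built-in engine finds, for every read, *all* end-to-end alignments
within edit distance `k` (default 3 for 50-base reads, approximating a BWA
default tolerance), using pigeonhole seeding with banded
edit-distance verification; an exhaustive whole-genome scan with the same
scoring — but no shared search logic — serves as its oracle in the tests.
Ties are enumerated exhaustively, never sampled; multi-location reads get
`mapq = 0`, unique ones `mapq = 37`.

One numerical subtlety deserves a paragraph, because it changes the
definition of "a location". Under unit-cost edit distance, a substitution
can be re-expressed as a pair of gaps at a start shifted by up to `2k`
bases, with the same total cost; an indel near a read end can likewise be
re-expressed as a shifted start with a few substitutions. A naive "count
tied best hits" rule would therefore call an isolated SNP read
"multi-mapping" against its own locus. Real aligners do not do this — their
scoring separates mismatches from gaps — so the built-in mapper merges best
hits whose starts lie within `2k` of each other into a single location
spanning `[pos, pos_max]`, and a read is judged *correct* when its unique
best location's span contains the recorded origin (within `pos_tolerance`).
Genuinely duplicated loci lie far apart and remain distinct.

Even with that merging, an isolated ALT *indel* read can legitimately
realign a few bases away from its origin (the bases before a deletion are
re-read as part of the shifted flank), sometimes uniquely and with a lower
distance than the true gapped alignment. Under the strict policy
(`pos_tolerance = 0`) a fraction of isolated indels is therefore flagged
reference-biased on a perfectly clean genome — which is faithful to how
real aligners treat indels, and is exactly why indel bias rates dwarf SNP
bias rates in practice. The package's specificity tests that assert "zero
flagged variants on a duplication-free genome" run at `pos_tolerance = 8`
(about the maximum indel length plus `2k`), which isolates duplication-driven
bias from this indel realignment ambiguity; isolated SNPs are never flagged
at any tolerance.

## The bias catalog and its directions

Per start site, a record is *biased* when reads from different local
haplotypes at that site do not share one correctness value. Per variant,
reads are pooled over all windows: `rate_ref` and `rate_alt` are the
mapping-correctness rates of REF- and ALT-carrying reads, `delta =
rate_ref - rate_alt`, and the variant is flagged when `|delta|` strictly
exceeds `bias_threshold` (default 0.05 — the ">5% difference in mapping
rate" rule; "strict" was chosen where the convention was ambiguous).
`ref_ratio`, the share of reference alleles among correctly mapped reads,
is kept separate from `delta` and drives the cross-catalog rank
correlations.

For a variant without flanking variants inside any window, REF reads are
exact substrings of the reference: if a REF read fails, an exact duplicate
exists elsewhere, and the corresponding ALT read then ties across the same
loci and fails too. Reference-favoring bias is therefore the *only*
possible direction for flankless variants — a theorem the acceptance suite
checks across random panels. ALT-favored bias arises only through the
*secondary effect*: when the REF allele of variant A rides on the same
chromosomes as the mismapping ALT allele of a flanking variant B,
`link_variants()` plus `plant_biased_duplication()` reproduce it on demand.
A corollary worth stating: planting an *exact* REF-allele copy of a locus
makes both alleles multimap symmetrically (`delta = 0`) — it cannot, by
itself, produce ALT-favored bias under a symmetric mapper.

`plant_biased_duplication()` constructs provably biased loci by writing
`n_copies` (default 2) ALT-carrying copies of a SNP's flanking window onto
a decoy contig: every ALT read then has two exact matches away from home
while REF reads stay unique. The default copy extent (`read_len - 1` per
flank) is the narrowest that captures all single-end windows; paired-end
fragments anchor their second mate outside such a copy and rescue the pair,
which is how the package reproduces the observation that paired-end data
suffer less SNP bias than single-end data. Widening `copy_flank` beyond the
fragment span makes a locus biased for both.

## The synthetic cohort

`simulate_rnaseq_cohort()` draws per-gene, per-individual fragment counts
from a negative binomial (dispersion 0.1, the conventional bulk RNA-seq
value; unstated in the problem the package models), multiplies the mean by
`effect_size` per ALT allele for TRUE_EQTL genes, and samples read start
positions uniformly over each individual's two haplotype exon sequences.
All reads are then mapped with the built-in engine, so ALT reads over
planted-bias loci genuinely multimap and vanish from unique-read
quantification — the false-eQTL mechanism is mechanistic, not painted on.
Fragment counts per individual are conserved exactly; the `true_counts`
matrix records the pre-mapping truth.

Simplifications, deliberately accepted: reads are single-end and
exon-contained (the built-in mapper is unspliced; junction reads would add
only genotype-independent depth loss), variants that only partially overlap
an exon are left unsubstituted, and MAFs are uniform rather than
human-spectrum (the enumeration weights haplotypes equally anyway). Default
exon lengths are 110–200 bases, near the human median — short enough that
the `read_len` biased start sites of a planted mid-exon SNP are a large
fraction of the exon, which is what makes a planted artifact detectable at
cohort sizes of 60–100. A green end-to-end test therefore establishes that
the pipeline removes *mechanistically planted* mapping artifacts while
keeping genuine genotype effects; it does not establish anything about
splice-junction bias, sequencing error (not simulated, by design), or
population LD structure.

## eQTL mapping and the before/after comparison

Associations are Spearman rank correlations (midrank ties) between
normalized exon values and genotype dosages of variants within
`cis_window` (default 1 Mb) of the TSS. The gene-level statistic is the
best association across the gene's exons and cis variants; its empirical P
is `(1 + #{permuted best >= observed}) / (n_perm + 1)` over `n_perm`
permutations of individual labels, with one permutation order shared by all
genes in a run — so the filtered re-analysis is strictly comparable.
Significance is Benjamini–Hochberg on empirical P at 10% FDR; the realized
threshold is recorded and *reused verbatim* for the filtered data, which is
what makes "lost" and "gained" well defined. Exon presence filtering
(`> 0` reads in strictly more than 90% of individuals) and depth
normalization precede mapping; since the association is rank-based, any
strictly monotone per-individual transform leaves results unchanged (and a
test says so).

`classify_eqtl_changes()` reports `dlogp = log10 p_before - log10 p_after`
on the gene-best *nominal* P — the empirical P is floored at
`1/(n_perm + 1)` and cannot express a 20-order-of-magnitude collapse. The
full-scale convention for "a clear false positive" is a drop of more than
20 in log10 P at a cohort of ~185 individuals and genome-wide depth; the
synthetic fixtures run at n = 60–100 with a handful of cis variants, where
the attainable -log10 P is bounded by roughly 12–15 and the noise floor of
a best-of-~500-pairs scan is near 3. The package keeps 20 as the default
`drop_threshold` and the fixtures use 2 — two orders of magnitude, the same
qualitative "the signal did not survive" statement at fixture scale. This
value was fixed from the power arithmetic above before the end-to-end tests
were run, and is not tuned.

Enrichment diagnostics mirror the downstream analyses: the share of
best-associated exons containing a panel variant, contrasted between lost
and common/gained genes by two-sided Fisher exact test; and the
mapping-bias level of best eQTL variants against a TSS-distance-matched
null sample (ten equal-occupancy bins by default; distance is to the
nearest TSS for both sets so that matching is exact), compared by Fisher
on flagged proportions and Mann–Whitney on the full `|delta|`
distributions.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(rng_seed = 1, genome_len = 60000, n_individuals = 60)
sim <- make_reference_panel(cfg, n_snps = 120, n_indels = 20) |>
  make_gene_models(n_genes = 12) |>
  plant_eqtl_truth(n_true = 5, n_bias = 3)

catalog <- build_bias_catalog(sim, "genome_se")
glance(catalog)

cohort <- simulate_rnaseq_cohort(sim, depth = 300)
res <- eqtl_before_after(cohort, catalog, sim$panel$variants,
                         eqtl_config(n_perm = 500, rng_seed = 1),
                         drop_threshold = 2)
res$comparison
autoplot(res$comparison)
```

## Numerical choices and degenerate inputs

* Variant flagging is strictly greater-than the threshold, with a `1e-12`
  float guard.
* Gene-best ties are broken deterministically by (variant position, exon
  start).
* Monomorphic variants and constant exons are dropped per gene; genes with
  no testable pair are reported untested (`NA` P values).
* An empty biased-site set makes filtering an identity copy, with a
  warning; degenerate contingency tables report Fisher P = 1, with a
  warning; TSS bins without null candidates fall back to sampling with
  replacement, with a warning.
* All generators are deterministic given their seeds; identical seeds give
  byte-identical FASTA/VCF outputs.

## Known limitations

The built-in mapper scores unit-cost edits, so its indel handling is
cruder than an affine-gap aligner's; the external-engine adapter exists
precisely so a production aligner (e.g. BWA, driven through a command
template) can stand in, and a test holds the two engines to a rank
correlation of at least 0.9 on a planted fixture. Transcript-frame reads
are judged against a joint genome+transcriptome index with projection and
deduplication, not against a genuinely spliced aligner. The cohort
simulator does not model junction reads, sequencing errors, base-quality
or GC effects, or realistic LD; it models exactly the causal chain the
filtering method is meant to break.
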