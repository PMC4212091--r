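test_that("panel generation conserves counts, frequencies and determinism", {
  cfg <- sim_config(rng_seed = 1, genome_len = 100000, n_individuals = 20)
  sim <- make_reference_panel(cfg, n_snps = 200, n_indels = 20)
  expect_equal(nrow(sim$panel$variants), 220L)
  expect_equal(sum(sim$panel$variants$vclass == "SNP"), 200L)
  expect_true(all(sim$panel$variants$maf >= cfg$maf_min))
  # every variant segregates
  expect_true(all(colSums(sim$panel$haplotypes) >= 1))
  expect_true(all(colSums(sim$panel$haplotypes) <= nrow(sim$panel$haplotypes) - 1))
  # indels are VCF-padded: ref and alt share their first base
  ind <- sim$panel$variants[sim$panel$variants$vclass == "INDEL", ]
  expect_true(all(substr(ind$ref_seq, 1, 1) == substr(ind$alt_seq, 1, 1)))

  # same seed, run twice: byte-identical FASTA and VCF
  sim2 <- make_reference_panel(cfg, n_snps = 200, n_indels = 20)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  v1 <- tempfile(fileext = ".vcf"); v2 <- tempfile(fileext = ".vcf")
  write_reference_fasta(sim$reference, f1)
  write_reference_fasta(sim2$reference, f2)
  write_panel_vcf(sim, v1); write_panel_vcf(sim2, v2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(readLines(v1), readLines(v2))
  unlink(c(f1, f2, v1, v2))

  expect_error(make_reference_panel(cfg, 0, 0), "at least one")
  expect_error(
    make_reference_panel(cfg, 10, 0, dup_spec = list(c(60000, 2))),
    "genome_len / 2", fixed = TRUE)
})

test_that("requested segmental duplications are present as exact repeats", {
  cfg <- sim_config(rng_seed = 4, genome_len = 30000, n_individuals = 10)
  sim <- make_reference_panel(cfg, n_snps = 10, n_indels = 0,
                              dup_spec = list(c(500, 2)))
  g <- sim$reference[[1]]
  # brute-force scan: a 200-mer probe inside the duplicated segment occurs
  # exactly twice (probe stride 100 guarantees at least one probe lands
  # fully inside the 500 bp duplication)
  found <- FALSE
  for (s in seq(1, nchar(g) - 199, by = 100)) {
    probe <- substr(g, s, s + 199)
    hits <- gregexpr(probe, g, fixed = TRUE)[[1]]
    if (length(hits) == 2L) { found <- TRUE; break }
  }
  expect_true(found)
})

test_that("planted duplication biases exactly the planted SNP", {
  cfg <- sim_config(rng_seed = 2, genome_len = 20000, n_individuals = 15)
  sim <- make_reference_panel(cfg, n_snps = 12, n_indels = 0,
                              min_spacing = 70L)
  vid <- sim$panel$variants$variant_id[6]
  sim <- plant_biased_duplication(sim, vid, rng_seed = 7)
  expect_true(sim$panel$variants$planted_bias[
    sim$panel$variants$variant_id == vid])
  ct <- build_bias_catalog(sim, "genome_se", pos_tolerance = 8L)
  row <- ct$variants[ct$variants$variant_id == vid, ]
  expect_equal(row$rate_alt, 0)
  expect_equal(row$rate_ref, 1)
  expect_identical(row$direction, "REF")
  # no other variant flagged; biased sites are the read_len starts at the SNP
  expect_identical(ct$variants$variant_id[ct$variants$flagged], vid)
  expect_equal(nrow(ct$biased_sites), cfg$read_len)
  pos <- sim$panel$variants$pos[sim$panel$variants$variant_id == vid]
  expect_setequal(ct$biased_sites$start, seq(pos - cfg$read_len + 1L, pos))
})

test_that("planting is rejected at indels and over genes", {
  cfg <- sim_config(rng_seed = 3, genome_len = 20000, n_individuals = 10)
  sim <- make_reference_panel(cfg, n_snps = 5, n_indels = 5)
  ind <- sim$panel$variants$variant_id[sim$panel$variants$vclass == "INDEL"][1]
  expect_error(plant_biased_duplication(sim, ind), "SNP")
  sim <- make_gene_models(sim, n_genes = 2)
  snp <- sim$panel$variants$variant_id[sim$panel$variants$vclass == "SNP"][1]
  gene_start <- min(sim$transcripts$start)
  expect_error(
    plant_biased_duplication(sim, snp,
                             at = list(contig = "chr1", pos = gene_start)),
    "overlap an existing gene")
})

test_that("cohort simulation is deterministic, conserves depth, and plants effects", {
  sim <- small_study(seed = 2, n_individuals = 100, genome_len = 40000,
                     n_genes = 8, n_true = 3, n_bias = 2, n_snps = 80,
                     n_indels = 10)
  co <- simulate_rnaseq_cohort(sim, depth = 200)
  co2 <- simulate_rnaseq_cohort(sim, depth = 200)
  expect_identical(co$alignments, co2$alignments)
  # fragment conservation: rows per individual equal the drawn counts exactly
  per_ind <- table(co$alignments$individual)
  expect_equal(as.integer(per_ind[colnames(co$true_counts)]),
               unname(colSums(co$true_counts)))

  tr <- sim$truth[sim$truth$effect_class == "TRUE_EQTL", ]
  dos <- co$genotypes[tr$eqtl_variant[1], ]
  cnt <- co$true_counts[tr$gene_id[1], ]
  ratio <- mean(cnt[dos == 2]) / mean(cnt[dos == 0])
  expect_gt(ratio, 3.2)   # effect 2 per allele => ~4-fold between homozygotes
  expect_lt(ratio, 5.0)

  # bias genes have no genotype effect on *true* fragment counts
  bs <- sim$truth[sim$truth$effect_class == "BIAS_FALSE_EQTL", ]
  dos_b <- co$genotypes[bs$eqtl_variant[1], ]
  cnt_b <- co$true_counts[bs$gene_id[1], ]
  expect_gt(suppressWarnings(
    stats::kruskal.test(cnt_b, factor(dos_b))$p.value), 1e-4)

  cfg_small <- sim_config(rng_seed = 1, n_individuals = 5)
  sim_small <- sim
  sim_small$config <- cfg_small
  expect_error(simulate_rnaseq_cohort(sim_small, depth = 10),
               "at least 10 individuals")
})

test_that("null-gene genotype association P values are uniform over replicates", {
  # one NULL gene per replicate cohort; association of quantified expression
  # with a random cis variant's dosage should carry no signal
  p <- numeric(100)
  for (r in seq_len(100)) {
    cfg <- sim_config(rng_seed = 9000 + r, genome_len = 8000,
                      n_individuals = 50)
    sim <- make_reference_panel(cfg, n_snps = 12, n_indels = 0)
    sim <- make_gene_models(sim, n_genes = 1)
    sim <- plant_eqtl_truth(sim, n_true = 0, n_bias = 0)
    co <- simulate_rnaseq_cohort(sim, depth = 80)
    counts <- quantify_exons(co$alignments, co$exons,
                             individuals = colnames(co$genotypes))
    expr <- colSums(counts)
    v <- sample(rownames(co$genotypes), 1)
    p[r] <- suppressWarnings(
      cor.test(expr, co$genotypes[v, ], method = "spearman")$p.value)
  }
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
})
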