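test_that("window enumeration matches interval arithmetic and brute force", {
  v <- tibble::tibble(variant_id = "v1", pos = 100L, ref_seq = "A")
  w <- enumerate_read_windows(v, 50L, 10000L)
  expect_equal(w$origin_start, 51:100)           # L windows over a SNP

  v$pos <- 10L
  w <- enumerate_read_windows(v, 50L, 10000L)
  expect_equal(w$origin_start, 1:10)             # edge truncation

  vdel <- tibble::tibble(variant_id = "d1", pos = 100L, ref_seq = "ATT")
  w <- enumerate_read_windows(vdel, 50L, 10000L)
  # brute-force intersection over all starts
  brute <- Filter(function(s) s + 49L >= 100L && s <= 102L, 1:9951)
  expect_equal(w$origin_start, brute)
  expect_equal(nrow(w), 52L)

  expect_equal(nrow(enumerate_read_windows(v, 50L, 30L)), 0L)
})

test_that("local haplotypes are the observed restrictions plus all-ref", {
  cfg <- sim_config(rng_seed = 5, genome_len = 5000, n_individuals = 10)
  sim <- make_reference_panel(cfg, n_snps = 8, n_indels = 0)
  v <- sim$panel$variants
  lh <- local_haplotypes(sim$panel, "chr1", v$pos[1] - 10L, v$pos[1] + 10L)
  expect_setequal(lh$signature, c("R", "A"))

  # two variants observed only as RR / AA: RA and AR must be absent
  hap <- matrix(0L, nrow = 20, ncol = 2,
                dimnames = list(NULL, c("x1", "x2")))
  hap[1:6, ] <- 1L
  panel <- list(variants = tibble::tibble(
    variant_id = c("x1", "x2"), contig = "chr1", pos = c(100L, 110L),
    ref_seq = c("A", "C"), alt_seq = c("G", "T"), maf = c(0.3, 0.3),
    vclass = "SNP"), haplotypes = hap, sample_ids = sprintf("I%02d", 1:10))
  lh <- local_haplotypes(panel, "chr1", 90L, 139L)
  expect_setequal(lh$signature, c("RR", "AA"))

  # three variants, random panel: equals brute-force column restriction
  sim3 <- make_reference_panel(
    sim_config(rng_seed = 6, genome_len = 3000, n_individuals = 15),
    n_snps = 3, n_indels = 0)
  vs <- sim3$panel$variants
  win <- c(min(vs$pos) - 5L, max(vs$pos) + 5L)
  lh <- local_haplotypes(sim3$panel, "chr1", win[1], win[2])
  inw <- vs$pos >= win[1] & vs$pos <= win[2]
  brute <- unique(apply(sim3$panel$haplotypes[, vs$variant_id[inw],
                                              drop = FALSE], 1,
                        function(r) paste(c("R", "A")[r + 1], collapse = "")))
  expect_setequal(setdiff(lh$signature, strrep("R", sum(inw))), brute[
    brute != strrep("R", sum(inw))])
})

test_that("an isolated mid-contig SNP yields exactly read_len x 2 reads", {
  cfg <- sim_config(rng_seed = 8, genome_len = 4000, n_individuals = 10)
  sim <- make_reference_panel(cfg, n_snps = 1, n_indels = 0)
  reads <- build_simulated_reads(sim, "genome_se")
  expect_equal(nrow(reads), 2L * cfg$read_len)
  expect_equal(sum(reads$focal_allele == "R"), cfg$read_len)
  expect_false(any(duplicated(reads$read_id)))
  # every sequence equals the naive substitution oracle
  v <- sim$panel$variants
  for (i in seq_len(nrow(reads))) {
    alt <- reads$focal_allele[i] == "A"
    expect_identical(reads$sequence[i],
                     naive_read(sim$reference[[1]], reads$origin_start[i],
                                cfg$read_len, v, alt))
  }
})

test_that("simulated read sets equal brute-force enumeration with indels", {
  for (seed in c(21, 22)) {
    cfg <- sim_config(rng_seed = seed, genome_len = 5000, n_individuals = 8)
    sim <- make_reference_panel(cfg, n_snps = 8, n_indels = 6)
    impl <- build_simulated_reads(sim, "genome_se")
    brute <- brute_enum_se(sim)
    expect_identical(read_set_key(impl), read_set_key(brute))
  }
})

test_that("transcript reads span junctions with correct genomic projection", {
  # toy 2-exon gene with a SNP 10 bp from the 3' end of exon 1
  cfg <- sim_config(rng_seed = 31, genome_len = 3000, n_individuals = 10)
  sim <- make_reference_panel(cfg, n_snps = 1, n_indels = 0)
  pos <- sim$panel$variants$pos[1]
  sim$transcripts <- tibble::tibble(
    gene_id = "g1", transcript_id = "g1.t1", contig = "chr1", strand = "+",
    exon_rank = 1:2, start = c(pos - 150L, pos + 211L),
    end = c(pos + 10L, pos + 500L))
  reads <- build_simulated_reads(sim, "transcript_se")
  expect_equal(nrow(reads), 2L * cfg$read_len)  # SNP fully inside exon 1
  # junction-spanning reads: those starting within 39 bp of the exon-1 end
  jr <- reads[reads$origin_start > pos - 39L, ]
  expect_gt(nrow(jr), 0)
  fr <- mapbias:::transcript_frame(sim$reference, sim$transcripts)
  for (i in seq_len(nrow(jr))) {
    # manual projection: transcript substring must match the spliced sequence
    txs <- jr$origin_tx_start[i]
    expect_identical(jr$origin_start[i], fr$gmap[txs])
    if (jr$focal_allele[i] == "R")
      expect_identical(jr$sequence[i],
                       substr(fr$seq, txs, txs + cfg$read_len - 1L))
  }
  # and they are judged correct under the joint genome+transcriptome index
  ct <- build_bias_catalog(sim, "transcript_se")
  expect_equal(ct$variants$rate_ref, 1)
  expect_equal(ct$variants$rate_alt, 1)
})

test_that("paired-end fragments share one haplotype and skip contig ends", {
  cfg <- sim_config(rng_seed = 41, genome_len = 2000, n_individuals = 10)
  sim <- make_reference_panel(cfg, n_snps = 1, n_indels = 0)
  reads <- build_simulated_reads(sim, "genome_pe")
  v <- sim$panel$variants
  span <- 2L * cfg$read_len + cfg$inner_insert
  # mate-2 window contains no variant: identical mate-2 sequence per window
  m2 <- split(reads$mate_sequence, reads$origin_start)
  expect_true(all(vapply(m2, function(x) length(unique(x)) == 1L, TRUE)))
  # mate-2 origin = mate-1 origin + read_len + inner_insert (no indels here)
  expect_equal(reads$mate_origin_start,
               reads$origin_start + cfg$read_len + cfg$inner_insert)
  # fragments running past the contig end are skipped and counted
  n_windows <- nrow(enumerate_read_windows(v, cfg$read_len, 2000L))
  n_fit <- sum(enumerate_read_windows(v, cfg$read_len, 2000L)$origin_start +
                 span - 1L <= 2000L)
  expect_equal(length(unique(reads$origin_start)), n_fit)
  expect_equal(attr(reads, "skipped"), n_windows - n_fit)
})
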