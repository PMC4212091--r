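test_that("built-in mapper handles exact, duplicated and mutated reads", {
  withr::with_seed(3, {
    g <- paste(sample(c("A", "C", "G", "T"), 6000, replace = TRUE),
               collapse = "")
  })
  ref <- c(chr1 = g)
  # exact unique 50-mer maps at its origin with a single best hit
  a <- map_reads(substr(g, 1001, 1050), ref)
  expect_true(a$mapped)
  expect_equal(a$pos, 1001L)
  expect_equal(a$n_best_hits, 1L)
  expect_equal(a$mapq, 37L)

  # a segment duplicated exactly twice: n_best_hits = 2, mapq = 0
  g2 <- g
  substr(g2, 3001, 3100) <- substr(g2, 1001, 1100)
  b <- map_reads(substr(g2, 1010, 1059), c(chr1 = g2))
  expect_equal(b$n_best_hits, 2L)
  expect_equal(b$mapq, 0L)
  expect_equal(b$pos, 1010L)   # leftmost best hit reported

  # read absent from the genome (distance > k) is unmapped
  c1 <- map_reads(strrep("ACGT", 13) |> substr(1, 50), ref)
  expect_false(c1$mapped)
  expect_equal(c1$n_best_hits, 0L)
})

test_that("seeded engine equals the exhaustive scan on mutated reads", {
  withr::with_seed(9, {
    g <- paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE),
               collapse = "")
    starts <- sample(19000, 150)
    reads <- substring(g, starts, starts + 49)
    mutate1 <- function(r) {
      op <- sample(c("sub", "del", "ins"), 1)
      i <- sample(45, 1) + 2
      if (op == "sub") substr(r, i, i) <- sample(c("A", "C", "G", "T"), 1)
      if (op == "del") r <- paste0(substr(r, 1, i - 1), substr(r, i + 1, 50), "A")
      if (op == "ins") r <- substr(paste0(substr(r, 1, i),
                                          sample(c("A", "C", "G", "T"), 1),
                                          substr(r, i + 1, 50)), 1, 50)
      r
    }
    reads <- c(reads, vapply(reads[1:75], mutate1, ""))
  })
  ref <- c(chr1 = g)
  a <- map_reads(reads, ref, engine = "builtin", report_hits = TRUE)
  b <- map_reads(reads, ref, engine = "exhaustive", report_hits = TRUE)
  expect_identical(a, b)
  expect_identical(attr(a, "hits"), attr(b, "hits"))
})

test_that("built-in mapping is reflexive on unique exact substrings", {
  withr::with_seed(12, {
    g <- paste(sample(c("A", "C", "G", "T"), 30000, replace = TRUE),
               collapse = "")
    starts <- sample(29000, 300)
  })
  reads <- tibble::tibble(read_id = paste0("r", starts),
                          sequence = substring(g, starts, starts + 49))
  a <- map_reads(reads, c(chr1 = g))
  expect_true(all(a$mapped & a$n_best_hits == 1L & a$pos == starts))
})

test_that("correctness judgment applies the positional policy", {
  sim_reads <- tibble::tibble(read_id = c("a", "b", "c", "d"),
                              origin_contig = "chr1",
                              origin_start = c(100L, 100L, 100L, 100L))
  aln <- tibble::tibble(
    read_id = c("a", "b", "c", "d"),
    mapped = c(TRUE, TRUE, TRUE, FALSE),
    contig = c("chr1", "chr1", "chr1", NA),
    pos = c(100L, 101L, 100L, NA), pos_max = c(100L, 101L, 100L, NA),
    strand = c("+", "+", "+", NA), mapq = c(37L, 37L, 0L, 0L),
    n_best_hits = c(1L, 1L, 2L, 0L), best_dist = c(0L, 1L, 0L, NA))
  j0 <- judge_correctness(sim_reads, aln, pos_tolerance = 0L)
  expect_equal(j0$correct, c(TRUE, FALSE, FALSE, FALSE))
  j1 <- judge_correctness(sim_reads, aln, pos_tolerance = 1L)
  expect_equal(j1$correct, c(TRUE, TRUE, FALSE, FALSE))  # 1 bp shift tolerated
})

test_that("external BWA engine agrees directionally with the built-in mapper", {
  skip_if(Sys.which("bwa") == "", "bwa not on PATH")
  cfg <- sim_config(rng_seed = 13, genome_len = 20000, n_individuals = 12)
  sim <- make_reference_panel(cfg, n_snps = 25, n_indels = 5)
  snps <- sim$panel$variants$variant_id[sim$panel$variants$vclass == "SNP"]
  for (vid in snps[c(3, 9, 15)])
    sim <- plant_biased_duplication(sim, vid, rng_seed = 99)
  cmd <- paste("bwa index {ref} 2>/dev/null &&",
               "bwa aln {ref} {reads} 2>/dev/null > {reads}.sai &&",
               "bwa samse {ref} {reads}.sai {reads} 2>/dev/null")
  ct_b <- build_bias_catalog(sim, "genome_se", engine = "builtin")
  ct_e <- build_bias_catalog(sim, "genome_se", engine = "external",
                             external_cmd = cmd)
  cmp <- compare_catalogs(ct_b, ct_e)
  rho <- cmp$rho[cmp$stratum == "ALL"]
  expect_gte(rho, 0.9)
  # the planted SNPs are flagged by both engines
  pl <- sim$panel$variants$variant_id[sim$panel$variants$planted_bias]
  expect_true(all(pl %in% ct_e$variants$variant_id[ct_e$variants$flagged]))
})
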