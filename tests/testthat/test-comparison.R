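called_fixture <- function(p_emp, p_nom, sig, genes = NULL) {
  genes <- genes %||% sprintf("g%03d", seq_along(p_emp))
  fit <- structure(list(
    genes = tibble::tibble(
      gene_id = genes, exon = paste0(genes, "_e1"),
      variant = paste0(genes, "_v1"), rho = 0.5,
      p_nominal = p_nom, p_empirical = p_emp, n_exons = 1L, n_variants = 5L,
      significant = sig),
    threshold = max(c(0, p_emp[sig])), n = 100L,
    config = eqtl_config(rng_seed = 1L)), class = "mb_eqtl_fit")
  fit
}

test_that("eQTL change classes partition genes and track large drops", {
  before <- called_fixture(c(0.001, 0.001, 0.001, 0.5),
                           c(1e-30, 1e-8, 1e-6, 0.2),
                           c(TRUE, TRUE, TRUE, FALSE))
  after <- called_fixture(c(0.001, 0.6, 0.001, 0.001),
                          c(1e-28, 1e-3, 1e-7, 1e-5),
                          c(TRUE, FALSE, TRUE, TRUE))
  cmp <- classify_eqtl_changes(before, after, drop_threshold = 4)
  expect_equal(cmp$genes$class, c("COMMON", "LOST", "COMMON", "GAINED"))
  expect_equal(sum(cmp$counts$n), nrow(cmp$genes))    # exact partition
  expect_equal(cmp$genes$large_drop, c(FALSE, TRUE, FALSE, FALSE))

  idm <- classify_eqtl_changes(before, before, drop_threshold = 4)
  expect_equal(sum(idm$genes$class == "LOST"), 0L)
  expect_equal(sum(idm$genes$class == "GAINED"), 0L)
  expect_true(all(idm$genes$dlogp == 0))

  other <- called_fixture(0.5, 0.5, FALSE, genes = "zzz")
  expect_error(classify_eqtl_changes(before, other), "disjoint")
})

test_that("Fisher exact matches exhaustive hypergeometric enumeration", {
  expect_equal(fisher.test(matrix(c(8, 2, 2, 8), 2))$p.value,
               fisher_enum_p(8, 2, 2, 8), tolerance = 1e-9)
  expect_equal(round(fisher_enum_p(8, 2, 2, 8), 3), 0.023)
})

test_that("variant-overlap enrichment contrasts exon classes", {
  before <- called_fixture(rep(0.001, 8), rep(1e-6, 8), rep(TRUE, 8))
  after <- called_fixture(c(rep(0.6, 4), rep(0.001, 4)),
                          c(rep(0.05, 4), rep(1e-6, 4)),
                          c(rep(FALSE, 4), rep(TRUE, 4)))
  cmp <- classify_eqtl_changes(before, after)
  exons <- tibble::tibble(
    exon_id = paste0(sprintf("g%03d", 1:8), "_e1"),
    gene_id = sprintf("g%03d", 1:8), contig = "chr1", strand = "+",
    start = seq(1000L, by = 1000L, length.out = 8),
    end = seq(1200L, by = 1000L, length.out = 8))
  # variants inside the exons of the four LOST genes only
  variants <- tibble::tibble(
    variant_id = paste0("v", 1:4), contig = "chr1",
    pos = exons$start[1:4] + 50L, ref_seq = "A", alt_seq = "C",
    maf = 0.3, vclass = "SNP")
  enr <- variant_overlap_enrichment(cmp, exons, variants,
                                    classes = c("LOST", "COMMON"))
  p <- enr$proportions
  expect_equal(p$prop_with_variant[p$class == "LOST"], 1)
  expect_equal(p$prop_with_variant[p$class == "COMMON"], 0)
  expect_equal(enr$fisher_p, fisher_enum_p(4, 0, 0, 4), tolerance = 1e-9)

  # identical proportions in both classes: P = 1
  variants2 <- tibble::tibble(
    variant_id = paste0("w", 1:8), contig = "chr1",
    pos = exons$start + 50L, ref_seq = "A", alt_seq = "C", maf = 0.3,
    vclass = "SNP")
  expect_warning(
    enr2 <- variant_overlap_enrichment(cmp, exons, variants2,
                                       classes = c("LOST", "COMMON")),
    "degenerate")
  expect_equal(enr2$fisher_p, 1)
})

test_that("Mann-Whitney agrees with brute-force rank-sum over pairs", {
  withr::with_seed(51, {
    x <- sample(1:20, 40, replace = TRUE)
    y <- sample(3:25, 35, replace = TRUE)
  })
  w <- suppressWarnings(wilcox.test(x, y))
  expect_equal(unname(w$statistic), brute_u(x, y))
  # untied small vectors: exact P against enumeration through wilcox.test
  x2 <- c(1.2, 3.4, 2.2, 8.1); y2 <- c(0.4, 5.5, 6.6, 7.7, 9.9)
  expect_equal(unname(wilcox.test(x2, y2)$statistic), brute_u(x2, y2))
})

test_that("TSS-matched null sampling matches distances and detects enrichment", {
  # catalog where half the variants are flagged; eQTL set = flagged ones
  withr::with_seed(52, {
    nv <- 60
    variants <- tibble::tibble(
      variant_id = paste0("v", 1:nv), contig = "chr1",
      pos = sample.int(2e6, nv), ref_seq = "A", alt_seq = "C", maf = 0.3,
      vclass = "SNP")
    tss <- tibble::tibble(gene_id = paste0("g", 1:20), contig = "chr1",
                          strand = "+", tss = sample.int(2e6, 20))
  })
  catalog <- tibble::tibble(
    variant_id = variants$variant_id, vclass = "SNP",
    delta = c(rep(0.8, 20), rep(0.001, 40)),
    ref_ratio = 0.5, flagged = c(rep(TRUE, 20), rep(FALSE, 40)))
  eqtl <- tibble::tibble(gene_id = tss$gene_id,
                         variant_id = variants$variant_id[1:20])
  enr <- suppressWarnings(
    tss_matched_bias_enrichment(eqtl, variants, tss, catalog,
                                n_bins = 5, rng_seed = 3))
  expect_lt(enr$fisher_p, 0.01)   # planted extreme enrichment

  # identity: the null candidates are exactly the eQTL set
  cat_id <- catalog[1:20, ]
  enr_id <- suppressWarnings(
    tss_matched_bias_enrichment(eqtl, variants, tss, cat_id,
                                n_bins = 5, rng_seed = 3))
  expect_equal(enr_id$fisher_p, 1)
  expect_equal(enr_id$mannwhitney_p, 1)
  # matched set has the eQTL set's size (histogram matched bin-for-bin)
  expect_equal(length(enr_id$matched), nrow(eqtl))
  expect_setequal(enr_id$matched, eqtl$variant_id)
})

test_that("the before/after pipeline removes planted false eQTLs end to end", {
  sim <- small_study(seed = 11)
  cohort <- simulate_rnaseq_cohort(sim, depth = 300)
  catalog <- build_bias_catalog(sim, "genome_se")
  res <- eqtl_before_after(cohort, catalog, sim$panel$variants,
                           eqtl_config(cis_window = 1e6, n_perm = 300,
                                       rng_seed = 5),
                           drop_threshold = 2)
  tt <- dplyr::left_join(res$comparison$genes, sim$truth, by = "gene_id")
  bias <- tt[tt$effect_class == "BIAS_FALSE_EQTL", ]
  true <- tt[tt$effect_class == "TRUE_EQTL", ]
  expect_true(all(true$class == "COMMON"))
  expect_gte(sum(bias$class == "LOST"), 2L)
  # classes partition the tested set
  expect_equal(sum(res$comparison$counts$n), nrow(res$comparison$genes))
  # filtering removed reads from every individual (bias loci are common)
  expect_true(all(res$filter_stats$n_removed > 0))
})
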