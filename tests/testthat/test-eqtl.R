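test_that("Spearman machinery matches independent midrank computation", {
  withr::with_seed(41, {
    x <- sample(1:5, 60, replace = TRUE)    # heavy ties
    y <- x + sample(0:3, 60, replace = TRUE)
  })
  sx <- mapbias:::scale_ranks(matrix(x, ncol = 1))
  sy <- mapbias:::scale_ranks(matrix(y, ncol = 1))
  rho <- crossprod(sx$x, sy$x)[1, 1]
  expect_equal(rho, brute_spearman(x, y), tolerance = 1e-12)
  expect_equal(rho, suppressWarnings(cor(x, y, method = "spearman")),
               tolerance = 1e-12)

  # perfect monotone association
  expect_equal(brute_spearman(c(0, 1, 2, 0, 1, 2), c(1, 2, 3, 1, 2, 3)), 1)
})

test_that("gene-level mapping finds planted signals with valid empirical P", {
  st <- matrix_study(n_genes = 12, n = 80, seed = 42,
                     effect = c(rep(2, 3), rep(1, 9)))
  fit <- map_cis_eqtls(st$expr, st$exons, st$genotypes, st$variants,
                       eqtl_config(n_perm = 500, rng_seed = 9))
  g <- fit$genes
  # planted genes hit their causal variant (first variant of the gene)
  expect_true(all(g$variant[1:3] == paste0(g$gene_id[1:3], "_v1")))
  expect_true(all(g$p_empirical[1:3] == 1 / 501))
  # empirical P floor and range
  expect_true(all(g$p_empirical >= 1 / 501 & g$p_empirical <= 1))
  # same seed reproduces exactly
  fit2 <- map_cis_eqtls(st$expr, st$exons, st$genotypes, st$variants,
                        eqtl_config(n_perm = 500, rng_seed = 9))
  expect_identical(fit$genes, fit2$genes)

  called <- call_eqtl_genes(fit)
  expect_true(all(called$genes$significant[1:3]))
  # threshold reuse reproduces the same calls
  again <- call_eqtl_genes(fit, threshold = called$threshold)
  expect_identical(called$genes$significant, again$genes$significant)
})

test_that("rank-based association is invariant to monotone transforms", {
  st <- matrix_study(n_genes = 6, n = 60, seed = 43,
                     effect = c(2, rep(1, 5)))
  cfg <- eqtl_config(n_perm = 200, rng_seed = 3)
  f1 <- map_cis_eqtls(st$expr, st$exons, st$genotypes, st$variants, cfg)
  f2 <- map_cis_eqtls(log2(st$expr + 1), st$exons, st$genotypes,
                      st$variants, cfg)
  expect_equal(f1$genes$rho, f2$genes$rho, tolerance = 1e-12)
  expect_equal(f1$genes$p_empirical, f2$genes$p_empirical)
})

test_that("permutation P behaves at the floor and near the median", {
  # if the observed statistic beats every permutation, p = 1/(n_perm+1);
  # a null gene's p is far from the floor
  st <- matrix_study(n_genes = 2, n = 100, seed = 44, effect = c(4, 1))
  fit <- map_cis_eqtls(st$expr, st$exons, st$genotypes, st$variants,
                       eqtl_config(n_perm = 1000, rng_seed = 1))
  expect_equal(fit$genes$p_empirical[1], 1 / 1001)
  expect_gt(fit$genes$p_empirical[2], 0.02)

  # untested gene: monomorphic variants are skipped
  st$genotypes[paste0("g002_v", 1:5), ] <- 0L
  fit3 <- map_cis_eqtls(st$expr, st$exons, st$genotypes, st$variants,
                        eqtl_config(n_perm = 200, rng_seed = 1))
  expect_true(is.na(fit3$genes$p_empirical[2]))
  expect_equal(fit3$genes$n_variants[2], 0L)
})

test_that("deterministic tie-breaking picks smallest variant position", {
  # two variants in perfect LD: identical P, tie broken by position
  withr::with_seed(45, {
    n <- 60
    g1 <- rbinom(n, 2, 0.4)
    expr <- matrix(rnbinom(n, mu = 50 * 2^g1, size = 10), nrow = 1,
                   dimnames = list("gX_e1", sprintf("I%03d", 1:n)))
  })
  geno <- rbind(vA = g1, vB = g1)
  colnames(geno) <- colnames(expr)
  exons <- tibble::tibble(exon_id = "gX_e1", gene_id = "gX", contig = "chr1",
                          strand = "+", start = 1000L, end = 1200L)
  variants <- tibble::tibble(variant_id = c("vA", "vB"), contig = "chr1",
                             pos = c(2000L, 1500L), ref_seq = "A",
                             alt_seq = "C", maf = 0.4, vclass = "SNP")
  fit <- map_cis_eqtls(expr, exons, geno, variants,
                       eqtl_config(n_perm = 100, rng_seed = 2))
  expect_identical(fit$genes$variant, "vB")   # smaller position wins
})

test_that("tidy and glance expose fit results", {
  st <- matrix_study(n_genes = 4, n = 50, seed = 46)
  fit <- call_eqtl_genes(map_cis_eqtls(st$expr, st$exons, st$genotypes,
                                       st$variants,
                                       eqtl_config(n_perm = 100,
                                                   rng_seed = 1)))
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 4L)
  expect_equal(glance(fit)$n_tested, 4L)
})
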