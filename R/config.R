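#' Simulation configuration
#'
#' Bundles the knobs shared by the synthetic-data generator and the
#' haplotype-aware read simulator. Defaults follow the read geometry used
#' throughout the package's reference analysis: 50 bp reads, a 60 bp inner
#' mate distance for paired-end simulation, and a 1% minor-allele-frequency
#' floor for the variant panel.
#'
#' @param read_len Read length in bases (>= 20).
#' @param inner_insert Unsequenced gap between paired mates, in bases. The
#'   simulated fragment spans `2 * read_len + inner_insert` reference bases.
#' @param maf_min Minor allele frequency floor for panel variants, in (0, 0.5).
#' @param rng_seed Integer seed; every stochastic operation that receives this
#'   config is byte-reproducible given the same seed.
#' @param genome_len Length of the synthetic reference contig, in bases.
#' @param n_individuals Number of diploid individuals in the panel.
#' @param edit_k Maximum edit distance accepted by the built-in mapper
#'   (default 3 for 50 bp reads, approximating BWA's default tolerance).
#' @param dispersion Negative-binomial dispersion of simulated exon counts.
#'
#' @return A list of class `mb_config`.
#' @export
#' @examples
#' cfg <- sim_config(rng_seed = 1, genome_len = 20000, n_individuals = 20)
sim_config <- function(read_len = 50L, inner_insert = 60L, maf_min = 0.01,
                       rng_seed = 1L, genome_len = 100000L,
                       n_individuals = 50L, edit_k = 3L, dispersion = 0.1) {
  read_len <- as.integer(read_len)
  inner_insert <- as.integer(inner_insert)
  if (read_len < 20L) abort("read_len must be >= 20")
  if (inner_insert < 0L) abort("inner_insert must be >= 0")
  if (!(maf_min > 0 && maf_min < 0.5)) abort("maf_min must be in (0, 0.5)")
  if (n_individuals < 1L) abort("n_individuals must be positive")
  structure(
    list(read_len = read_len, inner_insert = inner_insert, maf_min = maf_min,
         rng_seed = as.integer(rng_seed), genome_len = as.integer(genome_len),
         n_individuals = as.integer(n_individuals), edit_k = as.integer(edit_k),
         dispersion = dispersion),
    class = "mb_config")
}

#' cis-eQTL mapping configuration
#'
#' @param cis_window Bases up/downstream of the gene TSS searched for
#'   cis-variants (default 1 Mb each side).
#' @param n_perm Number of label permutations behind the gene-level empirical
#'   P value (>= 100).
#' @param fdr Target false discovery rate for calling eQTL genes.
#' @param rng_seed Seed for the permutation order (shared by all genes in a
#'   run so that before/after analyses are strictly comparable).
#'
#' @return A list of class `mb_eqtl_config`.
#' @export
eqtl_config <- function(cis_window = 1e6, n_perm = 1000L, fdr = 0.10,
                        rng_seed = 1L) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 100L) abort("n_perm must be >= 100")
  if (!(fdr > 0 && fdr < 1)) abort("fdr must be in (0, 1)")
  structure(
    list(cis_window = cis_window, n_perm = n_perm, fdr = fdr,
         rng_seed = as.integer(rng_seed)),
    class = "mb_eqtl_config")
}
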