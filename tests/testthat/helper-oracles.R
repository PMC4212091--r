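# Independent brute-force oracles. These deliberately re-derive results by a
# different mechanism than the package (character-vector splicing, full
# enumeration, closed-form formulas) so agreement is informative.

# Read starting at reference position s on a haplotype, built by splicing
# character vectors right-to-left. Returns NA if the start base is deleted on
# that haplotype or the sequence runs off the contig.
naive_read <- function(refseq, s, L, vars, alt) {
  slen <- nchar(refseq)
  lo <- min(c(s, vars$pos[alt]))
  chars <- strsplit(substr(refseq, lo, min(lo + 4L * L, slen)), "")[[1]]
  posv <- seq.int(lo, lo + length(chars) - 1L)
  vs <- vars[alt, , drop = FALSE]
  vs <- vs[order(-vs$pos), , drop = FALSE]
  for (i in seq_len(nrow(vs))) {
    p <- vs$pos[i]
    nr <- nchar(vs$ref_seq[i])
    idx <- which(posv >= p & posv <= p + nr - 1L)
    if (!length(idx)) next
    repl <- strsplit(vs$alt_seq[i], "")[[1]]
    before <- seq_len(min(idx) - 1L)
    after <- if (max(idx) < length(chars))
      seq.int(max(idx) + 1L, length(chars)) else integer(0)
    na_pad <- max(0L, length(repl) - nr)
    newpos <- c(p + seq_len(min(length(repl), nr)) - 1L,
                rep(NA_integer_, na_pad))
    chars <- c(chars[before], repl, chars[after])
    posv <- c(posv[before], newpos, posv[after])
  }
  at <- which(!is.na(posv) & posv == s)
  if (!length(at)) return(NA_character_)   # start deleted on this haplotype
  if (at + L - 1L > length(chars)) return(NA_character_)
  paste(chars[at:(at + L - 1L)], collapse = "")
}

# Full brute-force single-end enumeration over a panel: every variant, every
# window start (checked by direct interval intersection), every distinct
# observed local haplotype (plus all-reference).
brute_enum_se <- function(sim) {
  cfg <- sim$config
  L <- cfg$read_len
  vt <- sim$panel$variants
  hap <- sim$panel$haplotypes
  out <- list()
  for (vi in seq_len(nrow(vt))) {
    ctg <- vt$contig[vi]
    refseq <- sim$reference[[ctg]]
    slen <- nchar(refseq)
    fp <- c(vt$pos[vi], vt$pos[vi] + nchar(vt$ref_seq[vi]) - 1L)
    for (s in seq_len(max(0L, slen - L + 1L))) {
      if (s + L - 1L < fp[1] || s > fp[2]) next
      wend <- s + L - 1L
      in_win <- which(vt$contig == ctg & vt$pos <= wend &
                        vt$pos + nchar(vt$ref_seq) - 1L >= s)
      sub <- hap[, vt$variant_id[in_win], drop = FALSE]
      sigs <- unique(c(strrep("0", length(in_win)),
                       apply(sub, 1L, paste0, collapse = "")))
      for (sg in sort(sigs)) {
        alt <- strsplit(sg, "")[[1]] == "1"
        rd <- naive_read(refseq, s, L, vt[in_win, , drop = FALSE], alt)
        if (is.na(rd)) next
        out[[length(out) + 1L]] <- data.frame(
          focal_variant = vt$variant_id[vi], origin_contig = ctg,
          origin_start = s, hap_signature = chartr("01", "RA", sg),
          focal_allele = if (alt[match(vi, in_win)]) "A" else "R",
          sequence = rd)
      }
    }
  }
  do.call(rbind, out)
}

# Canonical string form of a simulated-read set, for set comparison.
read_set_key <- function(df) {
  sort(paste(df$focal_variant, df$origin_contig, df$origin_start,
             df$hap_signature, df$focal_allele, df$sequence, sep = "|"))
}

# Two-sided Fisher exact P by direct hypergeometric enumeration.
fisher_enum_p <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  x <- max(0L, k - n):min(k, m)
  probs <- dhyper(x, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Mann-Whitney U by counting over all pairs (ties counted half).
brute_u <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Spearman rho with midranks from the explicit Pearson-on-ranks formula.
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Small standard study used by several tests: genome, genes, planted truth.
small_study <- function(seed = 11, n_individuals = 60, genome_len = 60000,
                        n_genes = 12, n_true = 5, n_bias = 3,
                        n_snps = 120, n_indels = 20) {
  cfg <- sim_config(rng_seed = seed, genome_len = genome_len,
                    n_individuals = n_individuals)
  sim <- make_reference_panel(cfg, n_snps = n_snps, n_indels = n_indels)
  sim <- make_gene_models(sim, n_genes = n_genes)
  plant_eqtl_truth(sim, n_true = n_true, n_bias = n_bias)
}

# Matrix-level eQTL fixture: one exon per gene, genes 3 Mb apart so each
# gene's cis window holds only its own variants. effect = fold change per ALT
# allele applied to the negative-binomial mean of the first variant.
matrix_study <- function(n_genes, n, q = 5L, seed = 1L, effect = rep(1, n_genes),
                         maf_range = c(0.2, 0.5), mu = 100, dispersion = 0.1) {
  withr::with_seed(seed, {
    inds <- sprintf("I%03d", seq_len(n))
    genes <- sprintf("g%03d", seq_len(n_genes))
    exons <- tibble::tibble(
      exon_id = paste0(genes, "_e1"), gene_id = genes, contig = "chr1",
      strand = "+", start = 3e6 * seq_len(n_genes),
      end = 3e6 * seq_len(n_genes) + 200)
    vids <- paste0(rep(genes, each = q), "_v", seq_len(q))
    variants <- tibble::tibble(
      variant_id = vids, contig = "chr1",
      pos = rep(exons$start, each = q) + seq_len(q) * 1000,
      ref_seq = "A", alt_seq = "C",
      maf = runif(n_genes * q, maf_range[1], maf_range[2]), vclass = "SNP")
    geno <- matrix(rbinom(length(vids) * n, 2L, rep(variants$maf, n)),
                   nrow = length(vids), dimnames = list(vids, inds))
    expr <- matrix(0, nrow = n_genes, ncol = n,
                   dimnames = list(exons$exon_id, inds))
    for (g in seq_len(n_genes)) {
      m <- mu * effect[g]^geno[(g - 1L) * q + 1L, ]
      expr[g, ] <- rnbinom(n, mu = m, size = 1 / dispersion)
    }
  })
  list(expr = expr, exons = exons, genotypes = geno, variants = variants)
}
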