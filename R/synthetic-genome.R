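#' Generate a synthetic reference genome and phased variant panel
#'
#' Builds a random ACGT genome (optionally containing exact segmental
#' duplications, the raw material of allelic mapping bias), places SNP and
#' short-indel variants uniformly outside read-length margins, and phases
#' random haplotypes for a diploid cohort. Minor allele frequencies are drawn
#' uniformly on `[maf_min, 0.5]`: downstream read simulation enumerates
#' observed haplotypes in equal proportions regardless of frequency, so a
#' realistic frequency spectrum would add nothing.
#'
#' @param config A [sim_config()].
#' @param n_snps,n_indels Number of SNPs / indels to place (`n_snps + n_indels
#'   >= 1`). Indels are VCF-padded (ref and alt share their first base) and
#'   left-normalized, 1-3 bp.
#' @param dup_spec List of `c(length, count)` pairs; each produces `count`
#'   identical copies of a random donor segment of `length` bases (the donor
#'   plus `count - 1` overwritten targets). Lengths must be below half the
#'   genome length.
#' @param contig Name of the single reference contig.
#' @param min_spacing Minimum distance between variant positions (default 8,
#'   keeping footprints disjoint while allowing linked flanking variants
#'   inside one read length; raise above `read_len` to build panels of fully
#'   isolated variants).
#'
#' @return An object of class `mb_sim`: a list with elements `reference`
#'   (named character vector of contig sequences), `panel` (variant table,
#'   phased haplotype matrix and sample ids), `transcripts`, `truth`, and
#'   `config`. Deterministic given `config$rng_seed`.
#' @export
#' @examples
#' sim <- make_reference_panel(sim_config(rng_seed = 1, genome_len = 20000,
#'                                        n_individuals = 20), 50, 5)
make_reference_panel <- function(config, n_snps, n_indels = 0L,
                                 dup_spec = list(), contig = "chr1",
                                 min_spacing = 8L) {
  stopifnot(inherits(config, "mb_config"))
  n_snps <- as.integer(n_snps); n_indels <- as.integer(n_indels)
  if (n_snps + n_indels < 1L) abort("at least one variant is required")
  glen <- config$genome_len
  for (d in dup_spec) {
    if (d[[1]] >= glen / 2) abort("duplication length must be < genome_len / 2")
  }
  local_seed(config$rng_seed)

  genome <- random_dna(glen)
  occupied <- matrix(numeric(0), ncol = 2)
  claim <- function(s, e) occupied <<- rbind(occupied, c(s, e))
  overlaps <- function(s, e) {
    nrow(occupied) > 0 && any(occupied[, 1] <= e & occupied[, 2] >= s)
  }
  for (d in dup_spec) {
    len <- as.integer(d[[1]]); count <- as.integer(d[[2]])
    if (count < 2L) abort("dup_spec count must be >= 2 (total copy number)")
    donor <- sample.int(glen - len + 1L, 1L)
    claim(donor, donor + len - 1L)
    seg <- str_sub(genome, donor, donor + len - 1L)
    placed <- 0L
    tries <- 0L
    while (placed < count - 1L) {
      tries <- tries + 1L
      if (tries > 10000L) abort("could not place duplications; genome too small")
      s <- sample.int(glen - len + 1L, 1L)
      if (overlaps(s, s + len - 1L)) next
      str_sub(genome, s, s + len - 1L) <- seg
      claim(s, s + len - 1L)
      placed <- placed + 1L
    }
  }

  # uniform variant placement with disjoint footprints (>= 8 bp apart so a
  # deletion never swallows a neighbour, while still allowing linked flanking
  # variants well inside one read length)
  margin <- config$read_len
  n_var <- n_snps + n_indels
  positions <- integer(0)
  tries <- 0L
  while (length(positions) < n_var) {
    tries <- tries + 1L
    if (tries > 100000L) abort("could not place variants; genome too small")
    p <- sample.int(glen - 2L * margin - 10L, 1L) + margin
    if (length(positions) && any(abs(positions - p) < min_spacing)) next
    positions <- c(positions, p)
  }
  is_snp <- sample(rep(c(TRUE, FALSE), c(n_snps, n_indels)))
  ref_seq <- character(n_var); alt_seq <- character(n_var)
  for (i in seq_len(n_var)) {
    base <- str_sub(genome, positions[i], positions[i])
    if (is_snp[i]) {
      ref_seq[i] <- base
      alt_seq[i] <- sample(setdiff(c("A", "C", "G", "T"), base), 1L)
    } else if (runif(1) < 0.5) {  # deletion of 1-3 bp
      size <- sample.int(3L, 1L)
      ref_seq[i] <- str_sub(genome, positions[i], positions[i] + size)
      alt_seq[i] <- base
    } else {                      # insertion of 1-3 bp
      size <- sample.int(3L, 1L)
      ref_seq[i] <- base
      alt_seq[i] <- paste0(base, random_dna(size))
    }
  }
  ord <- order(positions)
  variants <- tibble(
    variant_id = sprintf("v%05d", seq_len(n_var)),
    contig = contig,
    pos = positions[ord],
    ref_seq = ref_seq[ord],
    alt_seq = alt_seq[ord],
    maf = runif(n_var, config$maf_min, 0.5),
    vclass = ifelse(is_snp[ord], "SNP", "INDEL"),
    planted_bias = FALSE)

  n_hap <- 2L * config$n_individuals
  haplotypes <- matrix(0L, nrow = n_hap, ncol = n_var,
                       dimnames = list(NULL, variants$variant_id))
  for (j in seq_len(n_var)) {
    col <- rbinom(n_hap, 1L, variants$maf[j])
    tries <- 0L
    while (length(unique(col)) == 1L && tries < 100L) {
      col <- rbinom(n_hap, 1L, variants$maf[j])
      tries <- tries + 1L
    }
    if (length(unique(col)) == 1L) {  # force segregation
      col[sample.int(n_hap, 1L)] <- 1L - col[1L]
    }
    haplotypes[, j] <- col
  }
  sample_ids <- sprintf("I%03d", seq_len(config$n_individuals))
  rownames(haplotypes) <- paste0(rep(sample_ids, each = 2L), c("_h1", "_h2"))

  panel <- structure(list(variants = variants, haplotypes = haplotypes,
                          sample_ids = sample_ids),
                     class = "mb_panel")
  structure(list(reference = setNames(genome, contig), panel = panel,
                 transcripts = NULL, truth = NULL, config = config),
            class = "mb_sim")
}

#' @export
print.mb_sim <- function(x, ...) {
  cat("<mb_sim> ", sum(nchar(x$reference)), " bp over ",
      length(x$reference), " contig(s); ",
      nrow(x$panel$variants), " variants (",
      sum(x$panel$variants$vclass == "SNP"), " SNP / ",
      sum(x$panel$variants$vclass == "INDEL"), " indel); ",
      length(x$panel$sample_ids), " individuals\n", sep = "")
  if (!is.null(x$transcripts))
    cat("  ", length(unique(x$transcripts$gene_id)), " gene models\n", sep = "")
  if (!is.null(x$truth))
    cat("  truth: ", paste(capture_classes(x$truth), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

capture_classes <- function(truth) {
  tb <- table(truth$effect_class)
  paste0(names(tb), "=", as.integer(tb))
}

#' Force complete linkage between two panel variants
#'
#' Rewrites the haplotype column of `var_b` as a deterministic function of
#' `var_a`: `"coupling"` puts the two ALT alleles on the same chromosomes,
#' `"repulsion"` puts the ALT of `var_b` on every chromosome carrying the REF
#' of `var_a`. Used to construct the secondary-effect fixtures where the
#' reference allele of one variant is linked to a mis-mapping alternate allele
#' of a flanking variant.
#'
#' @param sim An `mb_sim`.
#' @param var_a,var_b Variant ids.
#' @param phase `"coupling"` or `"repulsion"`.
#' @return The modified `mb_sim` (observed MAF of `var_b` is refreshed).
#' @export
link_variants <- function(sim, var_a, var_b,
                          phase = c("repulsion", "coupling")) {
  phase <- match.arg(phase)
  hap <- sim$panel$haplotypes
  a <- hap[, var_a]
  hap[, var_b] <- if (phase == "coupling") a else 1L - a
  sim$panel$haplotypes <- hap
  f <- mean(hap[, var_b])
  sim$panel$variants$maf[sim$panel$variants$variant_id == var_b] <-
    min(f, 1 - f)
  sim
}

#' Plant a bias-inducing segmental duplication at a SNP
#'
#' Copies the `read_len - 1` flanks around a SNP, substitutes the chosen
#' allele into the copy, and writes `n_copies` copies (separated by random
#' spacers) onto a decoy contig. With the default `allele = "alt"`, every
#' simulated read carrying the ALT allele then has `n_copies` exact genomic
#' matches away from its origin while REF reads remain uniquely mappable at
#' the locus: the locus is provably reference-biased. `allele = "ref"`
#' constructs the mirror image (bias in favor of the non-reference allele).
#'
#' @param sim An `mb_sim`.
#' @param variant_id A SNP in a unique region of the panel.
#' @param allele Which allele the planted copies carry.
#' @param n_copies Number of planted copies (default 2, so biased-allele reads
#'   multimap rather than merely mismap).
#' @param at Optional `list(contig =, pos =)` to overwrite the copy into an
#'   existing contig instead of a decoy; rejected if it would overlap a gene.
#' @param copy_flank Bases copied on each side of the SNP (default
#'   `read_len - 1`, the narrowest copy that captures every single-end read
#'   window; with the default, paired-end fragments anchor mate 2 outside the
#'   copy and rescue the pair, so widen to at least `2 * read_len +
#'   inner_insert` to make the locus biased for paired-end reads too).
#' @param rng_seed Optional seed for the random spacers; defaults to the
#'   current RNG state (callers running under a seeded pipeline stay
#'   deterministic).
#' @return The modified `mb_sim`, with `planted_bias = TRUE` on the variant.
#' @export
plant_biased_duplication <- function(sim, variant_id,
                                     allele = c("alt", "ref"), n_copies = 2L,
                                     at = NULL, copy_flank = NULL,
                                     rng_seed = NULL) {
  allele <- match.arg(allele)
  if (!is.null(rng_seed)) local_seed(rng_seed)
  v <- sim$panel$variants[sim$panel$variants$variant_id == variant_id, ]
  if (nrow(v) != 1L) abort("unknown variant_id")
  if (v$vclass != "SNP") abort("biased duplications can only be planted at SNPs")
  L <- sim$config$read_len
  copy_flank <- copy_flank %||% (L - 1L)
  ref <- sim$reference[[v$contig]]
  wstart <- max(1L, v$pos - copy_flank)
  wend <- min(nchar(ref), v$pos + copy_flank)
  copy <- str_sub(ref, wstart, wend)
  if (allele == "alt") str_sub(copy, v$pos - wstart + 1L, v$pos - wstart + 1L) <-
      v$alt_seq
  if (is.null(at)) {
    spacer <- function() random_dna(2L * L)
    decoy <- paste0(spacer(),
                    paste(vapply(seq_len(n_copies),
                                 function(i) paste0(copy, spacer()), ""),
                          collapse = ""))
    sim$reference[paste0("decoy_", variant_id)] <- decoy
  } else {
    tgt_start <- at$pos
    tgt_end <- at$pos + nchar(copy) * n_copies - 1L
    if (!is.null(sim$transcripts)) {
      spans <- sim$transcripts |>
        group_by(.data$gene_id) |>
        summarise(contig = .data$contig[1], start = min(.data$start),
                  end = max(.data$end), .groups = "drop")
      hit <- spans$contig == at$contig & spans$start <= tgt_end &
        spans$end >= tgt_start
      if (any(hit)) abort("insertion site would overlap an existing gene")
    }
    seqs <- paste(rep(copy, n_copies), collapse = "")
    str_sub(sim$reference[[at$contig]], tgt_start, tgt_start + nchar(seqs) - 1L) <-
      seqs
  }
  sim$panel$variants$planted_bias[
    sim$panel$variants$variant_id == variant_id] <- TRUE
  sim
}

#' Lay out multi-exon gene models on the synthetic genome
#'
#' Places non-overlapping genes sequentially along the contig with random
#' exon counts, exon lengths and intron lengths, alternating random strands.
#' Exons are long enough (by default) to contain a full read window on either
#' side of a mid-exon variant.
#'
#' @param sim An `mb_sim`.
#' @param n_genes Number of genes.
#' @param n_exons,exon_len,intron_len,gap Integer ranges `c(min, max)` sampled
#'   uniformly per gene / exon. Default exon lengths (110-200 bp, near the
#'   human median) keep a planted mid-exon biased SNP's `read_len` start
#'   windows a substantial fraction of the exon, so mapping bias measurably
#'   distorts its quantification.
#' @param rng_seed Seed (default `config$rng_seed + 1000`).
#' @return The `mb_sim` with a `transcripts` tibble: one row per exon with
#'   `gene_id`, `transcript_id`, `contig`, `strand`, `exon_rank`, `start`,
#'   `end` (1-based closed intervals).
#' @export
make_gene_models <- function(sim, n_genes, n_exons = c(2L, 4L),
                             exon_len = c(110L, 200L),
                             intron_len = c(100L, 300L),
                             gap = c(300L, 800L), rng_seed = NULL) {
  cfg <- sim$config
  local_seed(rng_seed %||% (cfg$rng_seed + 1000L))
  contig <- names(sim$reference)[1]
  glen <- nchar(sim$reference[[1]])
  rows <- list()
  cursor <- cfg$read_len + 50L
  runi <- function(r) if (r[1] == r[2]) r[1] else sample(seq.int(r[1], r[2]), 1L)
  for (g in seq_len(n_genes)) {
    cursor <- cursor + runi(gap)
    ne <- runi(n_exons)
    strand <- sample(c("+", "-"), 1L)
    starts <- integer(ne); ends <- integer(ne)
    p <- cursor
    for (e in seq_len(ne)) {
      len <- runi(exon_len)
      starts[e] <- p
      ends[e] <- p + len - 1L
      p <- ends[e] + runi(intron_len) + 1L
    }
    if (ends[ne] > glen - cfg$read_len - 50L)
      abort("genome too short for the requested gene models")
    gid <- sprintf("g%03d", g)
    rows[[g]] <- tibble(gene_id = gid, transcript_id = paste0(gid, ".t1"),
                        contig = contig, strand = strand,
                        exon_rank = seq_len(ne), start = starts, end = ends)
    cursor <- ends[ne]
  }
  sim$transcripts <- list_rbind(rows)
  sim
}

#' Transcription start sites of gene models
#'
#' @param transcripts Exon table as produced by [make_gene_models()].
#' @return Tibble with one row per gene: `gene_id`, `contig`, `strand`, `tss`
#'   (the 5'-most genomic position respecting strand).
#' @export
gene_tss <- function(transcripts) {
  transcripts |>
    group_by(.data$gene_id) |>
    summarise(contig = .data$contig[1], strand = .data$strand[1],
              tss = if (.data$strand[1] == "+") min(.data$start) else
                max(.data$end),
              .groups = "drop")
}

# Add one synthetic SNP to the panel (used when truth planting needs a variant
# at a specific spot). Genotypes are drawn at the given MAF and forced to
# segregate; the haplotype matrix is kept in variant order.
add_snp <- function(sim, contig, pos, maf) {
  ref <- str_sub(sim$reference[[contig]], pos, pos)
  alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
  variants <- sim$panel$variants
  if (any(variants$contig == contig & abs(variants$pos - pos) < 8L))
    abort("new SNP would collide with an existing variant")
  vid <- sprintf("v%05d", nrow(variants) + 1L)
  variants <- bind_rows(variants,
                        tibble(variant_id = vid, contig = contig, pos = pos,
                               ref_seq = ref, alt_seq = alt, maf = maf,
                               vclass = "SNP", planted_bias = FALSE)) |>
    arrange(.data$contig, .data$pos)
  n_hap <- nrow(sim$panel$haplotypes)
  col <- rbinom(n_hap, 1L, maf)
  while (length(unique(col)) == 1L) col <- rbinom(n_hap, 1L, maf)
  hap <- cbind(sim$panel$haplotypes, col)
  colnames(hap)[ncol(hap)] <- vid
  sim$panel$haplotypes <- hap[, variants$variant_id, drop = FALSE]
  sim$panel$variants <- variants
  list(sim = sim, variant_id = vid)
}

#' Plant true and mapping-bias-driven false eQTLs
#'
#' Assigns each gene one of three classes and wires the genome accordingly.
#' `TRUE_EQTL` genes get a cis SNP whose ALT allele multiplies expression by
#' `effect_size`; `BIAS_FALSE_EQTL` genes get a mid-exon SNP at which a biased
#' duplication is planted ([plant_biased_duplication()]) while expression
#' stays genotype-independent (`effect_size = 1`), so any association found at
#' them is a pure mapping artifact; remaining genes are `NULL` controls.
#' Where a gene lacks a suitable SNP (MAF >= `min_maf`, mid-exon for bias
#' genes), one is synthesized into the panel.
#'
#' @param sim An `mb_sim` with gene models.
#' @param n_true,n_bias Number of genes per planted class.
#' @param effect_size Expression fold-change per ALT allele for TRUE_EQTL
#'   genes.
#' @param min_maf Minimum MAF of planted eQTL variants (default 0.2 so both
#'   homozygote classes are populated at cohort sizes around 100).
#' @param rng_seed Seed (default `config$rng_seed + 2000`).
#' @return The `mb_sim` with a `truth` tibble (`gene_id`, `effect_class`,
#'   `eqtl_variant`, `effect_size`) and the panel/reference updated.
#' @export
plant_eqtl_truth <- function(sim, n_true, n_bias, effect_size = 2,
                             min_maf = 0.2, rng_seed = NULL) {
  stopifnot(!is.null(sim$transcripts))
  cfg <- sim$config
  local_seed(rng_seed %||% (cfg$rng_seed + 2000L))
  genes <- unique(sim$transcripts$gene_id)
  if (n_true + n_bias > length(genes))
    abort("more planted genes requested than gene models available")
  shuffled <- sample(genes)
  class_of <- setNames(rep("NULL", length(genes)), shuffled)
  class_of[seq_len(n_bias)] <- "BIAS_FALSE_EQTL"
  class_of[n_bias + seq_len(n_true)] <- "TRUE_EQTL"
  L <- cfg$read_len
  used <- character(0)
  truth <- vector("list", length(genes))
  for (i in seq_along(shuffled)) {
    gid <- shuffled[i]
    cls <- class_of[[i]]
    exons <- sim$transcripts[sim$transcripts$gene_id == gid, ]
    span <- c(min(exons$start), max(exons$end))
    vid <- NA_character_
    if (cls == "BIAS_FALSE_EQTL") {
      # host the artifact in the gene's shortest exon that can hold a
      # mid-exon SNP: the read_len biased start sites are then the largest
      # possible fraction of the exon and the planted artifact is a real
      # false eQTL, not a marginal one
      elig <- exons[exons$end - exons$start + 1L >= 2L * L + 10L, ]
      if (!nrow(elig)) abort("no exon long enough to host a biased SNP")
      ex <- elig[which.min(elig$end - elig$start), ]
      vt <- sim$panel$variants
      in_host <- vt$vclass == "SNP" & vt$maf >= min_maf & !vt$planted_bias &
        !(vt$variant_id %in% used) & vt$contig == ex$contig &
        vt$pos >= ex$start + L - 1L & vt$pos <= ex$end - L + 1L
      if (any(in_host)) {
        vid <- vt$variant_id[in_host][[1]]
      } else {
        pos <- free_position(sim, ex$contig, floor((ex$start + ex$end) / 2),
                             ex$start + L - 1L, ex$end - L + 1L)
        res <- add_snp(sim, ex$contig, pos, runif(1, min_maf, 0.45))
        sim <- res$sim; vid <- res$variant_id
      }
      sim <- plant_biased_duplication(sim, vid, allele = "alt", n_copies = 2L)
    } else if (cls == "TRUE_EQTL") {
      vt <- sim$panel$variants
      near <- vt$contig == exons$contig[1] & vt$pos >= span[1] - 2000L &
        vt$pos <= span[2] + 2000L
      exonic <- purrr::map_lgl(vt$pos, function(p)
        any(p >= exons$start & p <= exons$end))
      ok <- vt$vclass == "SNP" & vt$maf >= min_maf & !vt$planted_bias &
        !(vt$variant_id %in% used) & near
      cand <- vt$variant_id[ok & !exonic]
      if (!length(cand)) cand <- vt$variant_id[ok]
      if (length(cand)) {
        vid <- cand[[1]]
      } else {
        pos <- free_position(sim, exons$contig[1],
                             max(1L, span[1] - 500L),
                             max(1L, span[1] - 1500L), span[1] - 100L)
        res <- add_snp(sim, exons$contig[1], pos, runif(1, min_maf, 0.45))
        sim <- res$sim; vid <- res$variant_id
      }
    }
    if (!is.na(vid)) used <- c(used, vid)
    truth[[i]] <- tibble(gene_id = gid, effect_class = cls,
                         eqtl_variant = vid,
                         effect_size = if (cls == "TRUE_EQTL") effect_size else 1)
  }
  sim$truth <- list_rbind(truth) |> arrange(.data$gene_id)
  sim
}

# Find a position near `want` inside [lo, hi] at least 8 bp from every
# existing variant footprint.
free_position <- function(sim, contig, want, lo, hi) {
  vt <- sim$panel$variants[sim$panel$variants$contig == contig, ]
  cand <- seq.int(lo, hi)
  cand <- cand[order(abs(cand - want))]
  for (p in cand) {
    if (!any(abs(vt$pos - p) < 8L)) return(p)
  }
  abort("no free position for a synthesized variant")
}

#' Genotype dosage matrix from a phased panel
#'
#' @param panel The `panel` element of an `mb_sim`.
#' @return Integer matrix, variants x individuals, with entries 0/1/2 counting
#'   ALT alleles.
#' @export
genotype_dosage <- function(panel) {
  hap <- panel$haplotypes
  n <- length(panel$sample_ids)
  dos <- t(hap[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
             hap[seq(2L, 2L * n, by = 2L), , drop = FALSE])
  colnames(dos) <- panel$sample_ids
  dos
}
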