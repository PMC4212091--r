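#' Simulate an RNA-seq cohort with planted eQTL structure
#'
#' Draws per-gene, per-individual fragment counts from a negative binomial,
#' multiplies the mean by `effect_size` per ALT allele for TRUE_EQTL genes
#' (BIAS_FALSE_EQTL and NULL genes get genotype-independent means), samples
#' read start positions uniformly over each individual's two haplotype exon
#' sequences, and maps every read back to the reference with the built-in
#' mapper. Reads from ALT haplotypes over planted-bias loci therefore multimap
#' or mismap exactly as they would in a real alignment — the mechanism that
#' turns a mapping artifact into a false eQTL.
#'
#' Reads are single-end, exon-contained (no junction reads: the built-in
#' mapper is unspliced, and junction reads would only add genotype-independent
#' depth loss). Variants only partially overlapping an exon are left
#' unsubstituted.
#'
#' @param sim An `mb_sim` with gene models and a truth table
#'   ([plant_eqtl_truth()]).
#' @param depth Mean fragment count per gene per individual (negative binomial
#'   mean before genotype effects).
#' @param dispersion Negative-binomial dispersion (default from the config).
#' @param cis_window Sanity bound: every planted eQTL variant must lie within
#'   this distance of its gene's TSS.
#' @param rng_seed Seed (default `config$rng_seed + 3000`).
#' @return An `mb_cohort`: list with `alignments` (tibble: `individual`,
#'   `read_id`, `gene_id`, `true_pos`, `mapped`, `contig`, `pos`, `strand`,
#'   `mapq`, `n_best_hits`, coordinate-sorted within individual),
#'   `true_counts` (genes x individuals true fragment counts), `genotypes`
#'   (variants x individuals dosages), `exons`, `truth`, `config`.
#' @export
simulate_rnaseq_cohort <- function(sim, depth = 300, dispersion = NULL,
                                   cis_window = 1e6, rng_seed = NULL) {
  cfg <- sim$config
  if (cfg$n_individuals < 10L)
    abort("at least 10 individuals are required for eQTL use")
  if (is.null(sim$truth)) abort("plant_eqtl_truth() must be run first")
  dispersion <- dispersion %||% cfg$dispersion
  L <- cfg$read_len
  exons <- exon_table(sim$transcripts)
  tss <- gene_tss(sim$transcripts)
  vt <- sim$panel$variants
  planted <- sim$truth |> filter(!is.na(.data$eqtl_variant)) |>
    left_join(vt, by = c(eqtl_variant = "variant_id")) |>
    left_join(tss, by = "gene_id", suffix = c("", ".g"))
  if (any(abs(planted$pos - planted$tss) > cis_window))
    abort("a planted eQTL variant lies outside its gene's cis window")

  local_seed(rng_seed %||% (cfg$rng_seed + 3000L))
  n <- cfg$n_individuals
  ids <- sim$panel$sample_ids
  dos <- genotype_dosage(sim$panel)
  hap <- sim$panel$haplotypes
  genes <- unique(exons$gene_id)
  true_counts <- matrix(0L, nrow = length(genes), ncol = n,
                        dimnames = list(genes, ids))
  out <- vector("list", length(genes))

  for (gi in seq_along(genes)) {
    g <- genes[gi]
    ex <- exons[exons$gene_id == g, ]
    ex <- ex[order(ex$start), ]
    contig <- ex$contig[1]
    refseq <- sim$reference[[contig]]
    tr <- sim$truth[sim$truth$gene_id == g, ]
    # variants fully inside an exon of this gene
    vend <- vt$pos + nchar(vt$ref_seq) - 1L
    gvars <- vt[vt$contig == contig &
                  purrr::map_lgl(seq_len(nrow(vt)), function(i)
                    any(vt$pos[i] >= ex$start & vend[i] <= ex$end)), ]
    gv_ids <- gvars$variant_id
    sigs_chrom <- if (length(gv_ids))
      apply(hap[, gv_ids, drop = FALSE], 1L, paste0, collapse = "") else
        rep("", 2L * n)
    usig <- unique(sigs_chrom)
    # per (signature, exon): substituted sequence, filled coordinate map,
    # number of eligible read starts
    hapseq <- vector("list", length(usig))
    for (si in seq_along(usig)) {
      alt <- strsplit(usig[si], "", fixed = TRUE)[[1]] == "1"
      per_exon <- purrr::map(seq_len(nrow(ex)), function(e) {
        inex <- gvars$pos >= ex$start[e] & (gvars$pos +
                  nchar(gvars$ref_seq) - 1L) <= ex$end[e]
        sel <- which(inex & alt)
        sub <- substitute_region(substr(refseq, ex$start[e], ex$end[e]),
                                 ex$start[e], gvars$pos[sel],
                                 gvars$ref_seq[sel], gvars$alt_seq[sel])
        list(seq = sub$seq, map = fill_map_forward(sub$map),
             n_elig = max(0L, nchar(sub$seq) - L + 1L))
      })
      hapseq[[si]] <- per_exon
    }
    # flat lookup tables indexed by (signature, exon)
    n_exon <- nrow(ex)
    flat_idx <- function(si, e) (si - 1L) * n_exon + e
    seq_flat <- unlist(purrr::map(hapseq, function(pe)
      purrr::map_chr(pe, "seq")))
    maps <- unlist(purrr::map(hapseq, function(pe) purrr::map(pe, "map")),
                   recursive = FALSE)
    map_flat <- unlist(maps)
    map_off <- c(0L, cumsum(lengths(maps)))[seq_along(maps)]
    elig <- matrix(unlist(purrr::map(hapseq, function(pe)
      purrr::map_int(pe, "n_elig"))), nrow = n_exon)

    # genotype-dependent mean for TRUE_EQTL genes
    mu <- rep(depth, n)
    if (!is.na(tr$eqtl_variant) && tr$effect_size != 1)
      mu <- depth * tr$effect_size^dos[tr$eqtl_variant, ]
    cnt <- rnbinom(n, mu = mu, size = 1 / dispersion)
    true_counts[gi, ] <- cnt
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      n_i <- cnt[i]
      if (n_i == 0L) next
      chrom_sig <- match(sigs_chrom[c(2L * i - 1L, 2L * i)], usig)
      sig_r <- chrom_sig[sample.int(2L, n_i, replace = TRUE)]
      exon_r <- integer(n_i); start_r <- integer(n_i)
      for (si in unique(sig_r)) {
        sel <- which(sig_r == si)
        w <- elig[, si]
        if (sum(w) == 0L) { exon_r[sel] <- NA_integer_; next }
        exon_r[sel] <- sample.int(length(w), length(sel), replace = TRUE,
                                  prob = w)
        start_r[sel] <- floor(runif(length(sel)) *
                                w[exon_r[sel]]) + 1L
      }
      ok <- !is.na(exon_r)
      rows[[i]] <- tibble(
        individual = ids[i], gene_id = g,
        sig = sig_r[ok], exon = exon_r[ok], start = start_r[ok])
    }
    reads_g <- list_rbind(rows[!vapply(rows, is.null, TRUE)])
    if (is.null(reads_g) || nrow(reads_g) == 0L) next
    fi <- flat_idx(reads_g$sig, reads_g$exon)
    reads_g$sequence <- str_sub(seq_flat[fi], reads_g$start,
                                reads_g$start + L - 1L)
    reads_g$true_pos <- map_flat[map_off[fi] + reads_g$start]
    reads_g$true_contig <- contig
    out[[gi]] <- reads_g |> select("individual", "gene_id", "true_contig",
                                   "true_pos", "sequence")
  }

  reads <- list_rbind(out[!vapply(out, is.null, TRUE)])
  reads$read_id <- sprintf("%s:%s:%07d", reads$individual, reads$gene_id,
                           seq_len(nrow(reads)))
  aln <- map_reads(reads[, c("read_id", "sequence")], sim$reference,
                   engine = "builtin", k = cfg$edit_k)
  alignments <- reads |>
    select(-"sequence") |>
    left_join(aln, by = "read_id") |>
    arrange(.data$individual, .data$contig, .data$pos) |>
    select("individual", "read_id", "gene_id", "true_contig", "true_pos",
           "mapped", "contig", "pos", "strand", "mapq", "n_best_hits")
  structure(list(alignments = alignments, true_counts = true_counts,
                 genotypes = dos, exons = exons, truth = sim$truth,
                 config = cfg),
            class = "mb_cohort")
}

#' @export
print.mb_cohort <- function(x, ...) {
  cat("<mb_cohort> ", nrow(x$alignments), " reads; ",
      nrow(x$true_counts), " genes x ", ncol(x$true_counts),
      " individuals; mapped ", round(100 * mean(x$alignments$mapped), 1),
      "%\n", sep = "")
  invisible(x)
}
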