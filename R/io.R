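# Interchange with the field's standard formats. In-memory tibbles are the
# package's working representation; these writers/readers exist so synthetic
# panels and results can round-trip through FASTA/VCF/GTF/BED/SAM tooling.

#' Write / read the reference as FASTA
#'
#' @param reference Named character vector of contig sequences.
#' @param path File path.
#' @return `read_reference_fasta()` returns a named character vector.
#' @export
write_reference_fasta <- function(reference, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), path)
  invisible(path)
}

#' @rdname write_reference_fasta
#' @export
read_reference_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a phased panel as VCF v4.2
#'
#' One record per variant with `AF` in INFO and phased `GT` per individual.
#'
#' @param sim An `mb_sim` (contig lengths come from its reference).
#' @param path Output path (plain text).
#' @export
write_panel_vcf <- function(sim, path) {
  panel <- sim$panel
  vt <- panel$variants
  hap <- panel$haplotypes
  n <- length(panel$sample_ids)
  gt <- vapply(seq_len(n), function(i)
    paste0(hap[2L * i - 1L, ], "|", hap[2L * i, ]), character(nrow(vt)))
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(vt))
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=", names(sim$reference), ",length=",
           nchar(sim$reference), ">"),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t"))
  af <- colMeans(hap)[vt$variant_id]
  body <- paste(vt$contig, vt$pos, vt$variant_id, vt$ref_seq, vt$alt_seq,
                ".", "PASS", sprintf("AF=%.6g", af), "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a phased panel from VCF
#'
#' Uses VariantAnnotation; expects phased single-ALT genotypes.
#'
#' @param path VCF path.
#' @return An `mb_panel`-style list: `variants`, `haplotypes`, `sample_ids`.
#' @export
read_panel_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    abort("read_panel_vcf() needs the VariantAnnotation package")
  v <- VariantAnnotation::readVcf(path, genome = "synthetic")
  rr <- SummarizedExperiment::rowRanges(v)
  gt <- VariantAnnotation::geno(v)$GT
  ref <- as.character(rr$REF)
  alt <- as.character(unlist(rr$ALT))
  a1 <- substr(gt, 1L, 1L) == "1"
  a2 <- substr(gt, 3L, 3L) == "1"
  n_var <- nrow(gt); n_ind <- ncol(gt)
  hap <- matrix(0L, nrow = 2L * n_ind, ncol = n_var)
  hap[seq(1L, 2L * n_ind, 2L), ] <- t(a1 * 1L)
  hap[seq(2L, 2L * n_ind, 2L), ] <- t(a2 * 1L)
  ids <- rownames(gt)
  colnames(hap) <- ids
  af <- colMeans(hap)
  variants <- tibble(
    variant_id = ids,
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref_seq = ref, alt_seq = alt,
    maf = pmin(af, 1 - af),
    vclass = ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNP", "INDEL"),
    planted_bias = FALSE)
  structure(list(variants = variants, haplotypes = hap,
                 sample_ids = colnames(gt)),
            class = "mb_panel")
}

#' Write gene models as GTF
#'
#' @param transcripts Exon table from [make_gene_models()].
#' @param path Output path.
#' @export
write_transcripts_gtf <- function(transcripts, path) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; exon_number "%d";',
                   transcripts$gene_id, transcripts$transcript_id,
                   transcripts$exon_rank)
  lines <- paste(transcripts$contig, "mapbias", "exon", transcripts$start,
                 transcripts$end, ".", transcripts$strand, ".", attrs,
                 sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GTF
#'
#' @param path GTF path.
#' @return Exon tibble in [make_gene_models()] layout.
#' @export
read_transcripts_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    abort("read_transcripts_gtf() needs the rtracklayer package")
  g <- rtracklayer::import(path, format = "gtf")
  g <- g[g$type == "exon"]
  tibble(gene_id = g$gene_id, transcript_id = g$transcript_id,
         contig = as.character(GenomicRanges::seqnames(g)),
         strand = as.character(GenomicRanges::strand(g)),
         exon_rank = as.integer(g$exon_number),
         start = GenomicRanges::start(g), end = GenomicRanges::end(g)) |>
    arrange(.data$gene_id, .data$exon_rank)
}

#' Write biased start sites as BED
#'
#' Single-base intervals, 0-based half-open as BED requires.
#'
#' @param sites Tibble with `contig`, `start` (1-based).
#' @param path Output path.
#' @export
write_sites_bed <- function(sites, path) {
  writeLines(paste(sites$contig, sites$start - 1L, sites$start, sep = "\t"),
             path)
  invisible(path)
}

#' Read biased start sites from BED
#'
#' @param path BED path.
#' @return Tibble with `contig`, `start` (1-based).
#' @export
read_sites_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    abort("read_sites_bed() needs the rtracklayer package")
  g <- rtracklayer::import(path, format = "bed")
  tibble(contig = as.character(GenomicRanges::seqnames(g)),
         start = GenomicRanges::start(g))
}

#' Write alignments as SAM
#'
#' Minimal SAM export of an alignment tibble (sequences are not retained in
#' the tibble, so SEQ/QUAL are `*`; CIGAR is full-length match).
#'
#' @param alignments Alignment tibble.
#' @param reference Named character vector (for `@SQ` lines).
#' @param path Output path.
#' @param read_len Read length for the CIGAR.
#' @export
write_alignments_sam <- function(alignments, reference, path, read_len = 50L) {
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           paste0("@SQ\tSN:", names(reference), "\tLN:", nchar(reference)))
  a <- alignments
  flag <- ifelse(!a$mapped, 4L, ifelse(a$strand %in% "-", 16L, 0L))
  body <- paste(a$read_id, flag,
                ifelse(a$mapped, a$contig, "*"),
                ifelse(a$mapped, a$pos, 0L),
                ifelse(a$mapped, a$mapq, 0L),
                ifelse(a$mapped, paste0(read_len, "M"), "*"),
                "*", 0L, 0L, "*", "*", sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
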