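#' Exon table from gene models
#'
#' @param transcripts Exon tibble from [make_gene_models()].
#' @return Tibble with `exon_id`, `gene_id`, `contig`, `strand`, `start`,
#'   `end`.
#' @export
exon_table <- function(transcripts) {
  transcripts |>
    mutate(exon_id = paste0(.data$gene_id, "_e", .data$exon_rank)) |>
    select("exon_id", "gene_id", "contig", "strand", "start", "end")
}

#' Quantify exon expression from alignments
#'
#' A read increments an exon iff its leftmost aligned base falls inside the
#' exon interval — the same start-site convention used for bias filtering, so
#' filtered reads subtract cleanly from the exon they were counted in. Each
#' read is counted at most once (exons are non-overlapping by construction);
#' reads overlapping no exon are tallied in `attr(, "uncounted")`.
#'
#' @param alignments Alignment tibble (`contig`, `pos`, `mapq`, `mapped`,
#'   optionally `individual`).
#' @param exons Exon table from [exon_table()] (non-overlapping intervals).
#' @param individuals Column order of the output; defaults to the sorted
#'   distinct individuals present.
#' @param min_mapq Minimum mapping quality; the default 1 excludes
#'   multi-mapping reads, as in standard unique-read quantification.
#' @return Integer matrix, exons x individuals, with an `uncounted` attribute
#'   (reads mapping outside all exons, per individual).
#' @export
quantify_exons <- function(alignments, exons, individuals = NULL,
                           min_mapq = 1L) {
  if (!"individual" %in% names(alignments))
    alignments$individual <- "all"
  individuals <- individuals %||% sort(unique(alignments$individual))
  use <- alignments |>
    filter(.data$mapped, .data$mapq >= min_mapq,
           .data$contig %in% unique(exons$contig))
  q <- IRanges::findOverlaps(
    IRanges::IRanges(start = use$pos, width = 1L),
    IRanges::IRanges(start = exons$start, end = exons$end))
  # contig match (single-contig gene sets make this a no-op, but be safe)
  ok <- use$contig[S4Vectors::queryHits(q)] ==
    exons$contig[S4Vectors::subjectHits(q)]
  q <- q[ok]
  counted <- tibble(individual = use$individual[S4Vectors::queryHits(q)],
                    exon_id = exons$exon_id[S4Vectors::subjectHits(q)])
  mat <- matrix(0L, nrow = nrow(exons), ncol = length(individuals),
                dimnames = list(exons$exon_id, individuals))
  if (nrow(counted)) {
    tab <- counted |> count(.data$exon_id, .data$individual)
    mat[cbind(tab$exon_id, tab$individual)] <- tab$n
  }
  n_counted <- table(factor(counted$individual, levels = individuals))
  n_used <- table(factor(use$individual, levels = individuals))
  attr(mat, "uncounted") <- as.integer(n_used - n_counted) |>
    setNames(individuals)
  mat
}

#' Presence-filter and normalize an exon count matrix
#'
#' Keeps exons detected (`> 0` reads) in strictly more than `presence_frac` of
#' individuals, scales each column by that individual's total exon-mapped
#' reads (counts per million), and optionally regresses caller-supplied
#' covariates out of `log2(cpm + 1)`, returning residuals. Downstream
#' association is rank-based, so the normalization scale is irrelevant; what
#' matters is removing per-individual depth.
#'
#' @param counts Integer matrix from [quantify_exons()].
#' @param presence_frac Presence threshold in (0, 1], strict (an exon present
#'   in exactly `presence_frac` of individuals is dropped).
#' @param covariates Optional numeric matrix/data frame (individuals x
#'   covariates) to regress out.
#' @return Numeric matrix of normalized values (kept exons x individuals).
#' @export
filter_and_normalize <- function(counts, presence_frac = 0.9,
                                 covariates = NULL) {
  stopifnot(presence_frac > 0, presence_frac <= 1)
  n <- ncol(counts)
  keep <- rowSums(counts > 0L) > presence_frac * n
  if (!any(keep)) abort("all exons removed by the presence filter")
  depth <- colSums(counts)
  depth[depth == 0] <- 1
  norm <- t(t(counts[keep, , drop = FALSE]) / depth) * 1e6
  if (!is.null(covariates)) {
    x <- as.matrix(covariates)
    stopifnot(nrow(x) == n)
    lx <- log2(norm + 1)
    fit <- lm(t(lx) ~ x)
    norm <- t(resid(fit))
    dimnames(norm) <- dimnames(lx)
  }
  norm
}
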