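#' Remove alignments at biased start sites
#'
#' Drops every read whose leftmost aligned reference position is in the biased
#' start-site set, from each individual regardless of genotype — the reads at
#' those positions are untrustworthy for everyone, not just carriers of the
#' biased allele. Unmapped records are retained.
#'
#' @param alignments Alignment tibble with `contig`, `pos` and a `mapped`
#'   column (as produced by [simulate_rnaseq_cohort()] or [map_reads()]),
#'   coordinate-sorted within each individual. An `individual` column, when
#'   present, scopes the per-individual statistics; a `fragment_id` column is
#'   required for `pair_policy = "fragment"`.
#' @param sites Biased site set: tibble with `contig`, `start` (1-based),
#'   optionally `vclass` (see [biased_sites()]).
#' @param pair_policy `"read"` removes each mate independently on its own
#'   start site; `"fragment"` removes both mates when either matches.
#' @return List of class `mb_filter`: `alignments` (retained, original order)
#'   and `stats` (per individual: `n_input`, `n_removed`, `n_retained`, plus
#'   `removed_snp` / `removed_indel` when `sites` carries `vclass`).
#' @export
filter_alignments <- function(alignments, sites,
                              pair_policy = c("read", "fragment")) {
  pair_policy <- match.arg(pair_policy)
  ind <- if ("individual" %in% names(alignments)) alignments$individual else
    rep("all", nrow(alignments))
  ord_ok <- alignments |>
    mutate(.ind = ind) |>
    group_by(.data$.ind, .data$contig) |>
    summarise(sorted = !is.unsorted(.data$pos, na.rm = TRUE),
              .groups = "drop")
  if (!all(ord_ok$sorted))
    abort("alignments must be coordinate-sorted within each individual")
  if (nrow(sites) == 0L) {
    warn("empty biased-site set: filtering is an identity copy")
    stats <- tibble(individual = unique(ind),
                    n_input = as.integer(table(ind)[unique(ind)]),
                    n_removed = 0L) |>
      mutate(n_retained = .data$n_input)
    return(structure(list(alignments = alignments, stats = stats),
                     class = "mb_filter"))
  }
  sites <- distinct(sites, .data$contig, .data$start, .keep_all = TRUE)
  key_aln <- paste(alignments$contig, alignments$pos)
  key_site <- paste(sites$contig, sites$start)
  hit <- !is.na(alignments$pos) & key_aln %in% key_site
  mapped <- if ("mapped" %in% names(alignments)) alignments$mapped else
    !is.na(alignments$pos)
  remove <- hit & mapped
  if (pair_policy == "fragment") {
    if (!"fragment_id" %in% names(alignments))
      abort("pair_policy = 'fragment' needs a fragment_id column")
    bad_frag <- unique(alignments$fragment_id[remove])
    remove <- remove | (alignments$fragment_id %in% bad_frag & mapped)
  }
  removed_class <- NULL
  if ("vclass" %in% names(sites)) {
    cls <- setNames(sites$vclass, key_site)
    removed_class <- ifelse(remove, cls[key_aln], NA_character_)
  }
  stats <- tibble(individual = ind, removed = remove,
                  vclass = removed_class %||% NA_character_) |>
    group_by(.data$individual) |>
    summarise(n_input = dplyr::n(), n_removed = sum(.data$removed),
              n_retained = .data$n_input - .data$n_removed,
              removed_snp = sum(.data$removed & .data$vclass %in% "SNP"),
              removed_indel = sum(.data$removed & .data$vclass %in% "INDEL"),
              .groups = "drop")
  structure(list(alignments = alignments[!remove, , drop = FALSE],
                 stats = stats),
            class = "mb_filter")
}

#' @export
print.mb_filter <- function(x, ...) {
  cat("<mb_filter> removed ", sum(x$stats$n_removed), " of ",
      sum(x$stats$n_input), " alignments across ", nrow(x$stats),
      " individual(s)\n", sep = "")
  invisible(x)
}
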