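# Low-level sequence helpers shared by the generator and the read simulator.
# Reference coordinates are 1-based and closed throughout, as in VCF/GTF.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Reverse complement of plain character sequences
#'
#' Thin vectorized wrapper around [Biostrings::reverseComplement()].
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Reference positions removed from a haplotype that carries the ALT allele.
# Indels are VCF-padded (ref and alt share their first base), so a deletion
# with alleles ref/alt removes ref positions pos+nchar(alt) .. pos+nchar(ref)-1.
deleted_positions <- function(pos, ref_seq, alt_seq) {
  nr <- nchar(ref_seq)
  na <- nchar(alt_seq)
  if (nr <= na) return(integer(0))
  (pos + na):(pos + nr - 1L)
}

# Substitute ALT alleles into a reference region.
#
# region_seq: reference bases covering [region_start, region_start+n-1].
# vpos/vref/valt: parallel vectors describing the variants to substitute,
#   sorted by position, all with pos >= region_start and footprint inside the
#   region (plain vectors: this runs in tight per-window loops).
#
# Returns list(seq = substituted sequence, map = integer vector giving, for
# each output base, its 1-based reference coordinate (NA for inserted bases)).
substitute_region <- function(region_seq, region_start, vpos, vref, valt) {
  n <- nchar(region_seq)
  region_end <- region_start + n - 1L
  if (!length(vpos)) {
    return(list(seq = region_seq, map = seq.int(region_start, region_end)))
  }
  chunks <- character(0)
  maps <- list()
  cursor <- region_start
  for (i in seq_along(vpos)) {
    pos <- vpos[i]
    if (pos < cursor) next  # overlapping variant already consumed; skip
    ref_len <- nchar(vref[i])
    alt_seq <- valt[i]
    ref_end <- min(pos + ref_len - 1L, region_end)
    if (pos > cursor) {
      chunks <- c(chunks, substr(region_seq, cursor - region_start + 1L,
                                 pos - region_start))
      maps <- c(maps, list(seq.int(cursor, pos - 1L)))
    }
    na <- nchar(alt_seq)
    chunks <- c(chunks, alt_seq)
    amap <- rep(NA_integer_, na)
    n_aligned <- min(na, ref_len)
    if (n_aligned > 0L) amap[seq_len(n_aligned)] <- seq.int(pos, pos + n_aligned - 1L)
    maps <- c(maps, list(amap))
    cursor <- ref_end + 1L
  }
  if (cursor <= region_end) {
    chunks <- c(chunks, substr(region_seq, cursor - region_start + 1L, n))
    maps <- c(maps, list(seq.int(cursor, region_end)))
  }
  list(seq = paste(chunks, collapse = ""), map = unlist(maps))
}

# First aligned reference coordinate at or after each haplotype position.
# Used to project a haplotype start onto the reference.
fill_map_forward <- function(map) {
  if (!anyNA(map)) return(map)
  rev_filled <- rev(cummin(rev(ifelse(is.na(map), .Machine$integer.max, map))))
  rev_filled[rev_filled == .Machine$integer.max] <- NA_integer_
  as.integer(rev_filled)
}
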