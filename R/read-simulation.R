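#' Enumerate candidate read start sites over variants
#'
#' Every reference start `s` such that the read window `[s, s + read_len - 1]`
#' intersects the variant footprint `[pos, pos + nchar(ref_seq) - 1]` and lies
#' inside the contig. A mid-contig SNP therefore has exactly `read_len`
#' windows; windows are truncated at contig edges.
#'
#' @param variants Tibble with at least `variant_id`, `pos`, `ref_seq`.
#' @param read_len Read length in bases.
#' @param contig_len Contig length in bases.
#' @return Tibble `variant_id`, `origin_start`, sorted by start within
#'   variant; zero rows when the contig is shorter than a read.
#' @export
enumerate_read_windows <- function(variants, read_len, contig_len) {
  if (contig_len < read_len)
    return(tibble(variant_id = character(0), origin_start = integer(0)))
  variants |>
    mutate(.from = pmax(1L, .data$pos - as.integer(read_len) + 1L),
           .to = pmin(.data$pos + nchar(.data$ref_seq) - 1L,
                      as.integer(contig_len) - as.integer(read_len) + 1L)) |>
    filter(.data$.from <= .data$.to) |>
    reframe(origin_start = seq.int(.data$.from, .data$.to),
            .by = "variant_id")
}

#' Distinct local haplotypes over a window
#'
#' Restricts every observed panel chromosome to the variants whose footprint
#' intersects the window and returns each distinct restriction once — the
#' "observed haplotype combinations" that read simulation enumerates in equal
#' proportions regardless of population frequency. The all-reference string is
#' always included.
#'
#' @param panel Panel element of an `mb_sim`.
#' @param contig,window_start,window_end Window in 1-based closed reference
#'   coordinates.
#' @return Tibble with `signature` (string over R/A, ordered by variant
#'   position) and `n_hap` (chromosomes carrying it); attribute
#'   `"variant_ids"` gives the window variants in signature order.
#' @export
local_haplotypes <- function(panel, contig, window_start, window_end) {
  vt <- panel$variants
  sel <- vt$contig == contig & vt$pos <= window_end &
    (vt$pos + nchar(vt$ref_seq) - 1L) >= window_start
  ids <- vt$variant_id[sel]
  if (!length(ids)) {
    out <- tibble(signature = "", n_hap = nrow(panel$haplotypes))
    attr(out, "variant_ids") <- character(0)
    return(out)
  }
  sub <- panel$haplotypes[, ids, drop = FALSE]
  sigs <- apply(sub, 1L, function(r) paste(c("R", "A")[r + 1L], collapse = ""))
  tb <- table(sigs)
  all_ref <- strrep("R", length(ids))
  if (!all_ref %in% names(tb)) tb <- c(setNames(0L, all_ref), tb)
  out <- tibble(signature = names(tb), n_hap = as.integer(tb)) |>
    arrange(.data$signature)
  attr(out, "variant_ids") <- ids
  out
}

# Is reference base `s` deleted on a haplotype carrying ALT at these variants?
# (vectorized over the ALT-carrying variants of one window)
site_deleted <- function(s, vpos, vref, valt) {
  any(nchar(vref) > nchar(valt) & s >= vpos + nchar(valt) &
        s <= vpos + nchar(vref) - 1L)
}

#' Enumerate all potential reads overlapping panel variants
#'
#' The core of the bias simulation: for every variant, every read window and
#' every distinct observed local haplotype, build the read from the
#' haplotype-substituted sequence. Three modes:
#'
#' * `"genome_se"` — single-end reads over the genome sequence.
#' * `"transcript_se"` — single-end reads over spliced transcript sequences;
#'   only variants fully overlapping exons are simulated, and reads may span
#'   junctions. `origin_start` records the genomic projection of the read's
#'   first aligned base; `origin_tx_start` the transcript coordinate.
#' * `"genome_pe"` — paired-end: mate 1 as `genome_se`; mate 2 is the reverse
#'   complement of the window starting `inner_insert` bases after mate 1's end
#'   on the same haplotype (haplotypes enumerated jointly over the whole
#'   fragment). Fragments extending past the contig are skipped and counted.
#'
#' Only the forward strand is simulated: end-to-end alignment of a read and
#' its reverse complement is symmetric, so reverse-strand reads carry no extra
#' information. Window starts falling on a base deleted by the haplotype are
#' skipped (no read starts there on that chromosome).
#'
#' @param sim An `mb_sim` (with `transcripts` for transcript mode).
#' @param mode Simulation frame, see above.
#' @param config Simulation config; defaults to `sim$config`.
#' @return Tibble of simulated reads: `read_id`, `focal_variant`, `vclass`,
#'   `origin_contig`, `origin_start`, `hap_signature`, `focal_allele` (R/A),
#'   `sequence`, `frame`, plus mode-specific columns (`transcript_id`,
#'   `origin_tx_start`; `mate_sequence`, `mate_origin_start`). The number of
#'   skipped windows is in `attr(, "skipped")`.
#' @export
build_simulated_reads <- function(sim,
                                  mode = c("genome_se", "transcript_se",
                                           "genome_pe"),
                                  config = sim$config) {
  mode <- match.arg(mode)
  switch(mode,
         genome_se = sim_reads_genome_se(sim, config),
         transcript_se = sim_reads_transcript_se(sim, config),
         genome_pe = sim_reads_genome_pe(sim, config))
}

read_id_str <- function(vid, contig, start, sig, allele, frame, tx = NULL) {
  id <- sprintf("v=%s;c=%s;s=%d;h=%s;a=%s;f=%s", vid, contig, start, sig,
                allele, frame)
  if (!is.null(tx)) id <- paste0(id, ";t=", tx)
  id
}

# Shared inner loop: enumerate (window, haplotype) reads for one variant over
# one coordinate system (genome contig or spliced transcript).
# `seqstr` is the reference-frame sequence, `vars` the variant table in that
# frame (column pos already translated), `starts` the window starts.
enum_variant_reads <- function(seqstr, slen, vars, hap, focal_id, starts, L) {
  o_start <- integer(0); o_sig <- character(0); o_allele <- character(0)
  o_seq <- character(0)
  skipped <- 0L
  vid <- vars$variant_id
  vpos <- vars$pos; vref <- vars$ref_seq; valt <- vars$alt_seq
  vend <- vpos + nchar(vref) - 1L
  hap_chr <- matrix(as.character(hap[, vid, drop = FALSE]), nrow = nrow(hap))
  focal_col <- match(focal_id, vid)
  for (s in starts) {
    wend <- s + L - 1L
    idx <- which(vpos <= wend & vend >= s)
    sigs <- unique(do.call(paste0, lapply(idx, function(j) hap_chr[, j])))
    all_ref <- strrep("0", length(idx))
    if (!all_ref %in% sigs) sigs <- c(all_ref, sigs)
    sigs <- sort(sigs)
    region <- substr(seqstr, s, min(s + 3L * L, slen))
    focal_in <- match(focal_col, idx)
    for (hi in seq_along(sigs)) {
      alt <- strsplit(sigs[hi], "", fixed = TRUE)[[1]] == "1"
      sel <- idx[alt]
      if (site_deleted(s, vpos[sel], vref[sel], valt[sel])) next
      subbed <- substitute_region(region, s, vpos[sel], vref[sel], valt[sel])
      if (nchar(subbed$seq) < L) { skipped <- skipped + 1L; next }
      o_start <- c(o_start, s)
      o_sig <- c(o_sig, chartr("01", "RA", sigs[hi]))
      o_allele <- c(o_allele, if (alt[focal_in]) "A" else "R")
      o_seq <- c(o_seq, substr(subbed$seq, 1L, L))
    }
  }
  res <- tibble(focal_variant = focal_id, origin_start = o_start,
                hap_signature = o_sig, focal_allele = o_allele,
                sequence = o_seq)
  attr(res, "skipped") <- skipped
  res
}

sim_reads_genome_se <- function(sim, config) {
  L <- config$read_len
  vt <- sim$panel$variants
  hap <- sim$panel$haplotypes
  skipped <- 0L
  per_contig <- vector("list", 0)
  for (ctg in unique(vt$contig)) {
    slen <- nchar(sim$reference[[ctg]])
    cv <- vt[vt$contig == ctg, ]
    wins <- enumerate_read_windows(cv, L, slen)
    reads <- vector("list", nrow(cv))
    for (i in seq_len(nrow(cv))) {
      starts <- wins$origin_start[wins$variant_id == cv$variant_id[i]]
      if (!length(starts)) next
      r <- enum_variant_reads(sim$reference[[ctg]], slen, cv, hap,
                              cv$variant_id[i], starts, L)
      skipped <- skipped + attr(r, "skipped")
      r$origin_contig <- ctg
      reads[[i]] <- r
    }
    per_contig[[ctg]] <- list_rbind(reads[!vapply(reads, is.null, TRUE)])
  }
  res <- list_rbind(per_contig) |>
    left_join(vt[, c("variant_id", "vclass")],
              by = c(focal_variant = "variant_id")) |>
    mutate(frame = "G",
           read_id = read_id_str(.data$focal_variant, .data$origin_contig,
                                 .data$origin_start, .data$hap_signature,
                                 .data$focal_allele, "G")) |>
    select("read_id", "focal_variant", "vclass", "origin_contig",
           "origin_start", "hap_signature", "focal_allele", "sequence",
           "frame")
  attr(res, "skipped") <- skipped
  res
}

# Spliced transcript sequence plus per-base genomic coordinates.
transcript_frame <- function(reference, exons) {
  exons <- exons[order(exons$start), ]
  seqs <- str_sub(reference[[exons$contig[1]]], exons$start, exons$end)
  list(seq = paste(seqs, collapse = ""),
       gmap = unlist(purrr::map2(exons$start, exons$end, seq.int)),
       contig = exons$contig[1])
}

sim_reads_transcript_se <- function(sim, config) {
  if (is.null(sim$transcripts)) abort("transcript mode needs gene models")
  L <- config$read_len
  vt <- sim$panel$variants
  hap <- sim$panel$haplotypes
  skipped <- 0L
  out <- list()
  for (tx in unique(sim$transcripts$transcript_id)) {
    exons <- sim$transcripts[sim$transcripts$transcript_id == tx, ]
    fr <- transcript_frame(sim$reference, exons)
    tlen <- nchar(fr$seq)
    # variants fully overlapping exons, translated to transcript coordinates
    cv <- vt[vt$contig == fr$contig, ]
    vend <- cv$pos + nchar(cv$ref_seq) - 1L
    keep <- purrr::map_lgl(seq_len(nrow(cv)), function(i)
      any(cv$pos[i] >= exons$start & vend[i] <= exons$end))
    cv <- cv[keep, ]
    if (!nrow(cv)) next
    cv$gpos <- cv$pos
    cv$pos <- match(cv$gpos, fr$gmap)
    wins <- enumerate_read_windows(cv, L, tlen)
    for (i in seq_len(nrow(cv))) {
      starts <- wins$origin_start[wins$variant_id == cv$variant_id[i]]
      if (!length(starts)) next
      r <- enum_variant_reads(fr$seq, tlen, cv, hap, cv$variant_id[i],
                              starts, L)
      skipped <- skipped + attr(r, "skipped")
      if (!nrow(r)) next
      r$transcript_id <- tx
      r$origin_tx_start <- r$origin_start
      r$origin_start <- fr$gmap[r$origin_tx_start]
      r$origin_contig <- fr$contig
      out[[length(out) + 1L]] <- r
    }
  }
  if (!length(out)) {
    res <- tibble()
    attr(res, "skipped") <- skipped
    return(res)
  }
  res <- list_rbind(out) |>
    left_join(vt[, c("variant_id", "vclass")],
              by = c(focal_variant = "variant_id")) |>
    mutate(frame = "T",
           read_id = read_id_str(.data$focal_variant, .data$origin_contig,
                                 .data$origin_start, .data$hap_signature,
                                 .data$focal_allele, "T",
                                 .data$transcript_id)) |>
    select("read_id", "focal_variant", "vclass", "origin_contig",
           "origin_start", "origin_tx_start", "transcript_id",
           "hap_signature", "focal_allele", "sequence", "frame")
  attr(res, "skipped") <- skipped
  res
}

sim_reads_genome_pe <- function(sim, config) {
  L <- config$read_len
  inner <- config$inner_insert
  span <- 2L * L + inner
  vt <- sim$panel$variants
  hap <- sim$panel$haplotypes
  skipped <- 0L
  out <- list()
  for (ctg in unique(vt$contig)) {
    ctg_seq <- sim$reference[[ctg]]
    slen <- nchar(ctg_seq)
    cv <- vt[vt$contig == ctg, ]
    vid <- cv$variant_id
    vpos <- cv$pos; vref <- cv$ref_seq; valt <- cv$alt_seq
    cvend <- vpos + nchar(vref) - 1L
    hap_chr <- matrix(as.character(hap[, vid, drop = FALSE]),
                      nrow = nrow(hap))
    wins <- enumerate_read_windows(cv, L, slen)
    o_var <- character(0); o_start <- integer(0); o_sig <- character(0)
    o_allele <- character(0); o_seq <- character(0); o_m2seq <- character(0)
    o_m2start <- integer(0)
    m2_start <- L + inner + 1L
    for (i in seq_len(nrow(cv))) {
      starts <- wins$origin_start[wins$variant_id == vid[i]]
      for (s in starts) {
        if (s + span - 1L > slen) { skipped <- skipped + 1L; next }
        fend <- s + span - 1L
        idx <- which(vpos <= fend & cvend >= s)
        sigs <- unique(do.call(paste0, lapply(idx, function(j) hap_chr[, j])))
        all_ref <- strrep("0", length(idx))
        if (!all_ref %in% sigs) sigs <- c(all_ref, sigs)
        sigs <- sort(sigs)
        region <- substr(ctg_seq, s, min(s + span + L, slen))
        focal_in <- match(i, idx)
        for (sg in sigs) {
          alt <- strsplit(sg, "", fixed = TRUE)[[1]] == "1"
          sel <- idx[alt]
          if (site_deleted(s, vpos[sel], vref[sel], valt[sel])) next
          subbed <- substitute_region(region, s, vpos[sel], vref[sel],
                                      valt[sel])
          if (nchar(subbed$seq) < span) { skipped <- skipped + 1L; next }
          gmap <- fill_map_forward(subbed$map)
          o_var <- c(o_var, vid[i])
          o_start <- c(o_start, s)
          o_sig <- c(o_sig, chartr("01", "RA", sg))
          o_allele <- c(o_allele, if (alt[focal_in]) "A" else "R")
          o_seq <- c(o_seq, substr(subbed$seq, 1L, L))
          o_m2seq <- c(o_m2seq, substr(subbed$seq, m2_start,
                                       m2_start + L - 1L))
          o_m2start <- c(o_m2start, gmap[m2_start])
        }
      }
    }
    out[[ctg]] <- tibble(focal_variant = o_var, origin_contig = ctg,
                         origin_start = o_start, hap_signature = o_sig,
                         focal_allele = o_allele, sequence = o_seq,
                         mate_sequence = revcomp(o_m2seq),
                         mate_origin_start = o_m2start)
  }
  res <- list_rbind(out) |>
    left_join(vt[, c("variant_id", "vclass")],
              by = c(focal_variant = "variant_id")) |>
    mutate(frame = "G",
           read_id = read_id_str(.data$focal_variant, .data$origin_contig,
                                 .data$origin_start, .data$hap_signature,
                                 .data$focal_allele, "P")) |>
    select("read_id", "focal_variant", "vclass", "origin_contig",
           "origin_start", "hap_signature", "focal_allele", "sequence",
           "mate_sequence", "mate_origin_start", "frame")
  attr(res, "skipped") <- skipped
  res
}
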