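#' Map reads to a reference
#'
#' Maps each read end-to-end and reports, per read, whether it mapped within
#' edit distance `k`, the leftmost best-hit position, and the number of
#' equally good best hits (ties enumerated exhaustively, never sampled — a
#' multi-hit read gets `mapq = 0`, a unique hit `mapq = 37`).
#'
#' Engines:
#' * `"builtin"` — pigeonhole-seeded banded edit-distance verification
#'   (deterministic, exact for distances up to `k`).
#' * `"exhaustive"` — brute-force scan of every genome position with the same
#'   scoring; algorithmically independent of the seeded engine and used as its
#'   oracle in the test suite.
#' * `"external"` — a shell command template with `{reads}` and `{ref}`
#'   placeholders producing SAM on stdout (e.g. a BWA pipeline); parsed with
#'   Rsamtools. Best-hit counts come from the `X0` tag when present, else are
#'   inferred from `mapq == 0`.
#'
#' @param reads Tibble with `read_id` and `sequence` columns (a bare character
#'   vector also works). All reads in one call must share a length for the
#'   seeded engine.
#' @param reference Named character vector of contig sequences.
#' @param engine See above.
#' @param k Maximum edit distance (default 3 for 50 bp reads).
#' @param both_strands Also try the reverse complement of each read.
#' @param report_hits Attach every hit with distance `<= k` as
#'   `attr(, "hits")` (needed for paired-end resolution and transcript-hit
#'   projection).
#' @param external_cmd Shell command template for `engine = "external"`.
#' @return Tibble: `read_id`, `mapped`, `contig`, `pos`, `strand`, `mapq`,
#'   `n_best_hits`, `best_dist`.
#' @export
map_reads <- function(reads, reference,
                      engine = c("builtin", "exhaustive", "external"),
                      k = 3L, both_strands = TRUE, report_hits = FALSE,
                      external_cmd = NULL) {
  engine <- match.arg(engine)
  if (is.character(reads)) {
    reads <- tibble(read_id = paste0("r", seq_along(reads)), sequence = reads)
  }
  stopifnot(is.character(reference), !is.null(names(reference)))
  if (engine == "external")
    return(map_reads_external(reads, reference, external_cmd))
  fn <- if (engine == "builtin") .cpp_map_reads_seed else .cpp_map_reads_scan
  res <- fn(reads$sequence, unname(reference), as.integer(k), both_strands,
            report_hits)
  out <- as_tibble(res$summary) |>
    mutate(read_id = reads$read_id,
           contig = names(reference)[.data$contig_i], .before = 1) |>
    select("read_id", "mapped", "contig", "pos", "pos_max", "strand", "mapq",
           "n_best_hits", "best_dist")
  if (report_hits) {
    attr(out, "hits") <- as_tibble(res$hits) |>
      mutate(read_id = reads$read_id[.data$read],
             contig = names(reference)[.data$contig_i]) |>
      select("read_id", "strand", "contig", "pos", "dist")
  }
  out
}

map_reads_external <- function(reads, reference, external_cmd) {
  if (is.null(external_cmd))
    abort("engine = 'external' needs an external_cmd template with {reads} and {ref}")
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    abort("engine = 'external' needs the Rsamtools package")
  dir <- tempfile("mapbias_ext")
  dir.create(dir)
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  fq <- file.path(dir, "reads.fq")
  fa <- file.path(dir, "ref.fa")
  sam <- file.path(dir, "out.sam")
  errf <- file.path(dir, "err.txt")
  writeLines(paste0("@", reads$read_id, "\n", reads$sequence, "\n+\n",
                    strrep("I", nchar(reads$sequence))), fq)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(reference), fa)
  cmd <- gsub("{reads}", fq, gsub("{ref}", fa, external_cmd, fixed = TRUE),
              fixed = TRUE)
  status <- system2("/bin/sh", c("-c", shQuote(cmd)), stdout = sam,
                    stderr = errf)
  if (status != 0L)
    abort(paste0("external mapper failed:\n",
                 paste(readLines(errf, warn = FALSE), collapse = "\n")))
  bam <- Rsamtools::asBam(sam, file.path(dir, "out"), overwrite = TRUE,
                          indexDestination = FALSE)
  prm <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq"),
    tag = c("X0", "NM"),
    flag = Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  b <- Rsamtools::scanBam(bam, param = prm)[[1]]
  x0 <- b$tag$X0 %||% rep(NA_integer_, length(b$qname))
  nm <- b$tag$NM %||% rep(NA_integer_, length(b$qname))
  tibble(read_id = b$qname,
         mapped = !bitwAnd(b$flag, 4L),
         contig = as.character(b$rname),
         pos = b$pos,
         strand = ifelse(bitwAnd(b$flag, 16L), "-", "+"),
         mapq = b$mapq,
         n_best_hits = dplyr::coalesce(x0, ifelse(b$mapq == 0L, 2L, 1L)),
         best_dist = nm) |>
    mutate(pos_max = .data$pos, .after = "pos") |>
    mutate(contig = ifelse(.data$mapped, .data$contig, NA_character_),
           pos = ifelse(.data$mapped, .data$pos, NA_integer_),
           n_best_hits = ifelse(.data$mapped, .data$n_best_hits, 0L)) |>
    (\(d) d[match(reads$read_id, d$read_id), ])() |>
    mutate(read_id = reads$read_id)
}

#' Judge per-read mapping correctness
#'
#' A simulated single-end read is mapped *correctly* iff it mapped, has a
#' single best location with `mapq >= 1`, and the recorded origin lies within
#' that location's span `[pos, pos_max]` (extended by `pos_tolerance`, which
#' absorbs aligner left-shift ambiguity around indels). Unmapped, mismapped
#' and multi-mapping reads are all incorrect — each is a way for reads
#' carrying one allele to "not map equally".
#'
#' @param sim_reads Simulated reads from [build_simulated_reads()].
#' @param alignments Output of [map_reads()] for those reads.
#' @param pos_tolerance Extra positional slack around the best location span.
#' @return `sim_reads` with alignment columns and a logical `correct` column.
#' @export
judge_correctness <- function(sim_reads, alignments, pos_tolerance = 0L) {
  sim_reads |>
    left_join(alignments, by = "read_id") |>
    mutate(correct = .data$mapped & .data$n_best_hits == 1L &
             .data$mapq >= 1L &
             .data$contig == .data$origin_contig &
             .data$origin_start >= .data$pos - pos_tolerance &
             .data$origin_start <= .data$pos_max + pos_tolerance) |>
    mutate(correct = dplyr::coalesce(.data$correct, FALSE))
}


#' Judge transcript-frame reads against a joint genome+transcriptome index
#'
#' Transcript-simulated reads are mapped against the genome contigs plus one
#' contig per spliced transcript. Exon-interior reads hit both copies of the
#' same locus, so raw hits are first projected to genomic coordinates
#' (transcript hits via the exon structure) and deduplicated; the read is
#' correct iff exactly one distinct projected best location remains and it
#' equals the recorded genomic origin.
#'
#' @param sim_reads Transcript-frame simulated reads.
#' @param hits The `attr(, "hits")` table from [map_reads()] over the joint
#'   index.
#' @param sim The `mb_sim` providing transcripts and reference names.
#' @param pos_tolerance Positional slack.
#' @return `sim_reads` plus `n_best_hits` (after projection) and `correct`.
#' @export
judge_transcript_reads <- function(sim_reads, hits, sim, pos_tolerance = 0L) {
  frames <- purrr::map(split(sim$transcripts, sim$transcripts$transcript_id),
                       function(ex) transcript_frame(sim$reference, ex))
  is_tx <- hits$contig %in% names(frames)
  gcontig <- hits$contig
  gpos <- hits$pos
  if (any(is_tx)) {
    gcontig[is_tx] <- purrr::map_chr(hits$contig[is_tx],
                                     function(tx) frames[[tx]]$contig)
    gpos[is_tx] <- purrr::map2_int(hits$contig[is_tx], hits$pos[is_tx],
                                   function(tx, p) {
                                     gm <- frames[[tx]]$gmap
                                     if (p >= 1L && p <= length(gm))
                                       gm[p] else NA_integer_
                                   })
  }
  k <- sim$config$edit_k
  proj <- hits |>
    mutate(gcontig = gcontig, gpos = gpos) |>
    filter(!is.na(.data$gpos)) |>
    group_by(.data$read_id) |>
    filter(.data$dist == min(.data$dist)) |>
    distinct(.data$read_id, .data$strand, .data$gcontig, .data$gpos) |>
    arrange(.data$gcontig, .data$strand, .data$gpos, .by_group = TRUE) |>
    mutate(new_cl = dplyr::row_number() == 1L |
             .data$gcontig != dplyr::lag(.data$gcontig) |
             .data$strand != dplyr::lag(.data$strand) |
             .data$gpos - dplyr::lag(.data$gpos) > k) |>
    summarise(n_best_hits = sum(.data$new_cl, na.rm = TRUE),
              gcontig = .data$gcontig[1],
              gpos_min = min(.data$gpos), gpos_max = max(.data$gpos),
              .groups = "drop")
  sim_reads |>
    left_join(proj, by = "read_id") |>
    mutate(n_best_hits = dplyr::coalesce(.data$n_best_hits, 0L),
           mapped = .data$n_best_hits > 0L,
           correct = .data$mapped & .data$n_best_hits == 1L &
             .data$gcontig == .data$origin_contig &
             .data$origin_start >= .data$gpos_min - pos_tolerance &
             .data$origin_start <= .data$gpos_max + pos_tolerance,
           correct = dplyr::coalesce(.data$correct, FALSE))
}

#' Resolve paired-end placements and judge pair correctness
#'
#' Mates are mapped independently (all hits within distance `k` retained); a
#' placement is concordant when both mates land on the same contig in
#' forward/reverse orientation with an inner mate distance within
#' `insert_tolerance` of `inner_insert`. The pair score is the summed edit
#' distance; `n_best_hits` counts concordant placements attaining the minimum.
#' The pair is correct iff that placement is unique and both mates sit at
#' their recorded origins.
#'
#' @param sim_reads Paired-end simulated reads.
#' @param hits1,hits2 Hit tables (`attr(, "hits")`) for mate 1 and mate 2.
#' @param inner_insert Simulated inner mate distance.
#' @param read_len Read length.
#' @param insert_tolerance Allowed deviation of the observed inner distance.
#' @param pos_tolerance Positional slack for origin matching.
#' @param k Edit-distance budget, used to merge shift-equivalent placements of
#'   one locus into a single location.
#' @return `sim_reads` plus `mapped`, `n_best_hits` and `correct`.
#' @export
resolve_pairs <- function(sim_reads, hits1, hits2, inner_insert, read_len,
                          insert_tolerance = 15L, pos_tolerance = 0L, k = 3L) {
  pairs <- inner_join(
    hits1 |> rename(s1 = "strand", p1 = "pos", d1 = "dist"),
    hits2 |> rename(s2 = "strand", p2 = "pos", d2 = "dist"),
    by = c("read_id", "contig"), relationship = "many-to-many") |>
    mutate(gap = ifelse(.data$s1 == "+" & .data$s2 == "-",
                        .data$p2 - (.data$p1 + read_len),
                        ifelse(.data$s1 == "-" & .data$s2 == "+",
                               .data$p1 - (.data$p2 + read_len), NA_real_))) |>
    filter(!is.na(.data$gap),
           abs(.data$gap - inner_insert) <= insert_tolerance) |>
    mutate(score = .data$d1 + .data$d2) |>
    group_by(.data$read_id) |>
    filter(.data$score == min(.data$score)) |>
    arrange(.data$contig, .data$s1, .data$p1, .by_group = TRUE) |>
    mutate(new_cl = dplyr::row_number() == 1L |
             .data$contig != dplyr::lag(.data$contig) |
             .data$s1 != dplyr::lag(.data$s1) |
             .data$p1 - dplyr::lag(.data$p1) > k) |>
    summarise(n_best_hits = sum(.data$new_cl, na.rm = TRUE),
              contig = .data$contig[1],
              p1_min = min(.data$p1), p1_max = max(.data$p1),
              p2_min = min(.data$p2), p2_max = max(.data$p2),
              .groups = "drop")
  sim_reads |>
    left_join(pairs, by = "read_id") |>
    mutate(n_best_hits = dplyr::coalesce(.data$n_best_hits, 0L),
           mapped = .data$n_best_hits > 0L,
           correct = .data$mapped & .data$n_best_hits == 1L &
             .data$contig == .data$origin_contig &
             .data$origin_start >= .data$p1_min - pos_tolerance &
             .data$origin_start <= .data$p1_max + pos_tolerance &
             .data$mate_origin_start >= .data$p2_min - pos_tolerance &
             .data$mate_origin_start <= .data$p2_max + pos_tolerance,
           correct = dplyr::coalesce(.data$correct, FALSE))
}
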