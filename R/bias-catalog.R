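#' Summarize mapping correctness per read start site
#'
#' One record per (focal variant, start site); a site is *biased* when reads
#' from different local haplotypes at that site do not share one correctness
#' value — the start positions "where reads carrying different alleles did not
#' map equally".
#'
#' @param judged Judged reads (from [judge_correctness()] or friends).
#' @return Tibble: `focal_variant`, `contig`, `start`, `n_hap`, `n_correct`,
#'   `biased`.
#' @export
summarize_site_bias <- function(judged) {
  judged |>
    group_by(focal_variant = .data$focal_variant,
             contig = .data$origin_contig, start = .data$origin_start) |>
    summarise(n_hap = dplyr::n(), n_correct = sum(.data$correct),
              biased = .data$n_correct > 0L & .data$n_correct < .data$n_hap,
              .groups = "drop")
}

#' Deduplicated biased start-site set
#'
#' The union over variants of biased start sites, one row per (contig,
#' position) — the filterable artifact analogous to a biased-sites BED track.
#' When several variants share a biased site the site is attributed to the
#' SNP-class variant if any (else INDEL), so filter statistics can be split by
#' variant class.
#'
#' @param sites Site records from [summarize_site_bias()].
#' @param variants Optional variant table supplying `vclass`.
#' @return Tibble: `contig`, `start` (1-based), and `vclass` when available.
#' @export
biased_sites <- function(sites, variants = NULL) {
  out <- sites |> filter(.data$biased)
  if (!is.null(variants) && "vclass" %in% names(variants)) {
    out <- out |>
      left_join(variants[, c("variant_id", "vclass")],
                by = c(focal_variant = "variant_id")) |>
      group_by(.data$contig, .data$start) |>
      summarise(vclass = if (any(.data$vclass == "SNP")) "SNP" else "INDEL",
                .groups = "drop")
  } else {
    out <- out |> distinct(.data$contig, .data$start)
  }
  arrange(out, .data$contig, .data$start)
}

#' Summarize mapping bias per variant
#'
#' Pools all reads overlapping each variant and computes the mapping rate of
#' reference-allele and alternate-allele reads, their difference `delta =
#' rate_ref - rate_alt`, and the reference-allele ratio among correctly mapped
#' reads. A variant is flagged when `|delta|` strictly exceeds
#' `bias_threshold` (default 0.05, the ">5% difference in the mapping rate"
#' rule); `direction` is `"REF"` for reference-favoring bias, `"ALT"` for the
#' secondary-effect direction, `"NONE"` when unflagged.
#'
#' @param judged Judged reads.
#' @param bias_threshold Flagging threshold on `|delta|`, in (0, 1).
#' @return Tibble, one row per variant: counts, rates, `delta`, `ref_ratio`,
#'   `flagged`, `direction` (plus `vclass` when present in `judged`).
#' @export
summarize_variant_bias <- function(judged, bias_threshold = 0.05) {
  stopifnot(bias_threshold > 0, bias_threshold < 1)
  out <- judged |>
    group_by(variant_id = .data$focal_variant) |>
    summarise(
      vclass = if ("vclass" %in% names(judged)) .data$vclass[1] else
        NA_character_,
      n_ref_reads = sum(.data$focal_allele == "R"),
      n_alt_reads = sum(.data$focal_allele == "A"),
      n_ref_correct = sum(.data$correct & .data$focal_allele == "R"),
      n_alt_correct = sum(.data$correct & .data$focal_allele == "A"),
      .groups = "drop")
  if (any(out$n_ref_reads == 0L | out$n_alt_reads == 0L))
    abort("variant with zero simulated reads on one allele (panel must segregate)")
  out |>
    mutate(rate_ref = .data$n_ref_correct / .data$n_ref_reads,
           rate_alt = .data$n_alt_correct / .data$n_alt_reads,
           delta = .data$rate_ref - .data$rate_alt,
           ref_ratio = ifelse(.data$n_ref_correct + .data$n_alt_correct > 0L,
                              .data$n_ref_correct /
                                (.data$n_ref_correct + .data$n_alt_correct),
                              NA_real_),
           # strictly greater than the threshold, robust to float noise
           flagged = abs(.data$delta) > bias_threshold + 1e-12,
           direction = case_when(!.data$flagged ~ "NONE",
                                 .data$delta > 0 ~ "REF",
                                 TRUE ~ "ALT"))
}

#' Compare two bias catalogs
#'
#' Spearman correlation of per-variant reference-allele ratios over the shared
#' variants (overall and stratified by variant class), together with the
#' flagged proportions and the overlap of flagged sets — the catalog-level
#' concordance summaries used to compare mappers, read frames (genome vs
#' transcriptome) and single- vs paired-end simulations.
#'
#' @param cat_a,cat_b Variant bias tables ([summarize_variant_bias()]) or
#'   `mb_bias_catalog` objects.
#' @return Tibble, one row per stratum (`ALL`, `SNP`, `INDEL`): `n_shared`,
#'   `rho`, `pct_flagged_a`, `pct_flagged_b`, `flagged_overlap_a_in_b` (share
#'   of a's flagged variants also flagged in b).
#' @export
compare_catalogs <- function(cat_a, cat_b) {
  va <- if (inherits(cat_a, "mb_bias_catalog")) cat_a$variants else cat_a
  vb <- if (inherits(cat_b, "mb_bias_catalog")) cat_b$variants else cat_b
  shared <- inner_join(va, vb, by = "variant_id", suffix = c("_a", "_b")) |>
    filter(!is.na(.data$ref_ratio_a), !is.na(.data$ref_ratio_b))
  if (nrow(shared) < 2L) abort("catalogs share fewer than 2 comparable variants")
  strata <- list(ALL = shared)
  if ("vclass_a" %in% names(shared)) {
    for (cl in intersect(c("SNP", "INDEL"), unique(shared$vclass_a))) {
      sub <- shared[shared$vclass_a == cl, ]
      if (nrow(sub) >= 2L) strata[[cl]] <- sub
    }
  }
  purrr::imap(strata, function(d, nm) {
    tibble(stratum = nm,
           n_shared = nrow(d),
           rho = suppressWarnings(
             cor(d$ref_ratio_a, d$ref_ratio_b, method = "spearman")),
           pct_flagged_a = mean(d$flagged_a),
           pct_flagged_b = mean(d$flagged_b),
           flagged_overlap_a_in_b = if (any(d$flagged_a))
             mean(d$flagged_b[d$flagged_a]) else NA_real_)
  }) |> list_rbind()
}

#' Build a bias catalog for a synthetic panel
#'
#' End-to-end wrapper: enumerate all potential reads for the requested mode,
#' map them back to the reference with the chosen engine, judge per-read
#' correctness, and aggregate into per-variant and per-site bias records.
#'
#' @param sim An `mb_sim`.
#' @param mode Simulation mode, see [build_simulated_reads()].
#' @param engine Mapping engine, see [map_reads()] (transcript and paired-end
#'   modes use the built-in engines only).
#' @param bias_threshold Variant flagging threshold.
#' @param pos_tolerance Positional slack when judging correctness.
#' @param external_cmd Command template for the external engine.
#' @return An `mb_bias_catalog`: list with `variants`, `sites`,
#'   `biased_sites`, `judged`, `mode`, `bias_threshold`, `n_reads`,
#'   `n_skipped`.
#' @export
build_bias_catalog <- function(sim,
                               mode = c("genome_se", "transcript_se",
                                        "genome_pe"),
                               engine = c("builtin", "exhaustive", "external"),
                               bias_threshold = 0.05, pos_tolerance = 0L,
                               external_cmd = NULL) {
  mode <- match.arg(mode)
  engine <- match.arg(engine)
  cfg <- sim$config
  reads <- build_simulated_reads(sim, mode)
  if (mode == "genome_se") {
    aln <- map_reads(reads, sim$reference, engine, k = cfg$edit_k,
                     external_cmd = external_cmd)
    judged <- judge_correctness(reads, aln, pos_tolerance)
  } else if (mode == "transcript_se") {
    if (engine == "external")
      abort("transcript mode supports the built-in engines only")
    tx_seqs <- purrr::map_chr(
      split(sim$transcripts, sim$transcripts$transcript_id),
      function(ex) transcript_frame(sim$reference, ex)$seq)
    joint <- c(sim$reference, tx_seqs)
    aln <- map_reads(reads, joint, engine, k = cfg$edit_k, report_hits = TRUE)
    judged <- judge_transcript_reads(reads, attr(aln, "hits"), sim,
                                     pos_tolerance)
  } else {
    if (engine == "external")
      abort("paired-end mode supports the built-in engines only")
    aln1 <- map_reads(reads[, c("read_id", "sequence")], sim$reference,
                      engine, k = cfg$edit_k, report_hits = TRUE)
    aln2 <- map_reads(
      reads |> mutate(sequence = .data$mate_sequence) |>
        select("read_id", "sequence"),
      sim$reference, engine, k = cfg$edit_k, report_hits = TRUE)
    judged <- resolve_pairs(reads, attr(aln1, "hits"), attr(aln2, "hits"),
                            cfg$inner_insert, cfg$read_len,
                            pos_tolerance = pos_tolerance, k = cfg$edit_k)
  }
  sites <- summarize_site_bias(judged)
  variants <- summarize_variant_bias(judged, bias_threshold)
  structure(
    list(variants = variants, sites = sites,
         biased_sites = biased_sites(sites, sim$panel$variants),
         judged = judged, mode = mode, bias_threshold = bias_threshold,
         n_reads = nrow(reads), n_skipped = attr(reads, "skipped")),
    class = "mb_bias_catalog")
}

#' @export
print.mb_bias_catalog <- function(x, ...) {
  cat("<mb_bias_catalog> mode=", x$mode, "; ", x$n_reads, " reads over ",
      nrow(x$variants), " variants; ", sum(x$variants$flagged),
      " flagged (|delta| > ", x$bias_threshold, "); ",
      nrow(x$biased_sites), " biased start sites\n", sep = "")
  invisible(x)
}

#' Tidy a bias catalog into its per-variant table
#'
#' @param x An `mb_bias_catalog`.
#' @param ... Unused.
#' @return The per-variant bias tibble.
#' @export
tidy.mb_bias_catalog <- function(x, ...) x$variants

#' One-row summary of a bias catalog
#'
#' @param x An `mb_bias_catalog`.
#' @param ... Unused.
#' @return A one-row tibble with catalog-level counts and proportions.
#' @export
glance.mb_bias_catalog <- function(x, ...) {
  tibble(mode = x$mode, n_reads = x$n_reads, n_variants = nrow(x$variants),
         n_flagged = sum(x$variants$flagged),
         pct_flagged = mean(x$variants$flagged),
         pct_ref_direction = if (any(x$variants$flagged))
           mean(x$variants$direction[x$variants$flagged] == "REF") else
             NA_real_,
         n_biased_sites = nrow(x$biased_sites),
         n_skipped = x$n_skipped)
}
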