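#' Classify per-gene eQTL changes after bias filtering
#'
#' Genes are `COMMON` (significant before and after filtering), `LOST`
#' (significant only before), `GAINED` (only after) or `NEVER`. `dlogp =
#' log10(p_before) - log10(p_after)` on the gene-best nominal P (the empirical
#' P is floored at `1/(n_perm+1)` and cannot express large drops);
#' `large_drop` flags LOST genes whose -log10 P fell by more than
#' `drop_threshold` — the signature of an association that was a clear mapping
#' artifact.
#'
#' @param before,after Called `mb_eqtl_fit`s ([call_eqtl_genes()]); the after
#'   fit must have been called with the before fit's threshold.
#' @param drop_threshold Drop in -log10 nominal P marking a clear false
#'   positive (default 20, the full-scale convention; scale it down for
#'   shallow fixtures).
#' @return An `mb_eqtl_comparison`: list with `genes` (per-gene classes,
#'   `dlogp`, `large_drop`, best exon/variant before and after) and `counts`.
#' @export
classify_eqtl_changes <- function(before, after, drop_threshold = 20) {
  gb <- before$genes
  ga <- after$genes
  if (is.null(gb$significant) || is.null(ga$significant))
    abort("run call_eqtl_genes() on both fits first")
  genes <- inner_join(gb, ga, by = "gene_id", suffix = c("_before", "_after"))
  if (nrow(genes) == 0L) abort("gene sets are disjoint; mismatched inputs?")
  genes <- genes |>
    filter(!is.na(.data$p_empirical_before), !is.na(.data$p_empirical_after)) |>
    mutate(
      class = case_when(
        .data$significant_before & .data$significant_after ~ "COMMON",
        .data$significant_before ~ "LOST",
        .data$significant_after ~ "GAINED",
        TRUE ~ "NEVER"),
      dlogp = log10(pmax(.data$p_nominal_before, 1e-300)) -
        log10(pmax(.data$p_nominal_after, 1e-300)),
      large_drop = .data$class == "LOST" & -.data$dlogp > drop_threshold)
  counts <- genes |> count(.data$class) |>
    tidyr::complete(class = c("COMMON", "LOST", "GAINED", "NEVER"),
                    fill = list(n = 0L))
  structure(list(genes = genes, counts = counts,
                 drop_threshold = drop_threshold),
            class = "mb_eqtl_comparison")
}

#' @export
print.mb_eqtl_comparison <- function(x, ...) {
  cat("<mb_eqtl_comparison> ",
      paste(x$counts$class, x$counts$n, sep = "=", collapse = ", "),
      "; ", sum(x$genes$large_drop), " large drop(s)\n", sep = "")
  invisible(x)
}

#' Per-gene change table
#'
#' @param x An `mb_eqtl_comparison`.
#' @param ... Unused.
#' @return The per-gene classification tibble.
#' @export
tidy.mb_eqtl_comparison <- function(x, ...) x$genes

#' Variant content of best-associated exons, by eQTL change class
#'
#' Tests whether exons whose eQTL signal behaves one way under filtering (e.g.
#' LOST) contain panel variants more often than a comparison class — the
#' expected footprint of mapping-bias-driven associations, since the biased
#' variant must sit inside the quantified exon to distort it.
#'
#' @param comparison An `mb_eqtl_comparison`.
#' @param exons Exon table.
#' @param variants Panel variant table.
#' @param classes Length-2 character: the classes compared.
#' @return List of class `mb_enrichment`: `proportions` (per class: n, share
#'   of best exons containing a variant), `table` (2x2), `fisher_p`
#'   (two-sided).
#' @export
variant_overlap_enrichment <- function(comparison, exons, variants,
                                       classes = c("LOST", "COMMON")) {
  stopifnot(length(classes) == 2L)
  g <- comparison$genes |>
    filter(.data$class %in% classes, !is.na(.data$exon_before))
  if (!all(classes %in% g$class))
    abort("need at least one gene in each compared class")
  ex <- exons[match(g$exon_before, exons$exon_id), ]
  vend <- variants$pos + nchar(variants$ref_seq) - 1L
  has_var <- purrr::map_lgl(seq_len(nrow(ex)), function(i)
    any(variants$contig == ex$contig[i] & variants$pos <= ex$end[i] &
          vend >= ex$start[i]))
  d <- tibble(class = factor(g$class, levels = classes),
              has_variant = has_var)
  tab <- table(d$class, factor(d$has_variant, levels = c(TRUE, FALSE)))
  fisher_p <- if (any(rowSums(tab) == 0L) || any(colSums(tab) == 0L)) {
    warn("degenerate contingency table; Fisher P set to 1")
    1
  } else fisher.test(tab)$p.value
  props <- d |> group_by(.data$class) |>
    summarise(n = dplyr::n(), prop_with_variant = mean(.data$has_variant),
              .groups = "drop")
  structure(list(proportions = props, table = tab, fisher_p = fisher_p),
            class = "mb_enrichment")
}

#' @export
print.mb_enrichment <- function(x, ...) {
  cat("<mb_enrichment>\n")
  print(x$proportions)
  cat("Fisher two-sided P =", signif(x$fisher_p, 3))
  if (!is.null(x$mannwhitney_p))
    cat("; Mann-Whitney P =", signif(x$mannwhitney_p, 3))
  cat("\n")
  invisible(x)
}

#' TSS-distance-matched mapping-bias enrichment of eQTL variants
#'
#' Are best eQTL variants more often mapping-biased than random variants at
#' the same distance from a TSS? Variants are binned by |distance to the
#' nearest TSS| (for a cis-eQTL variant that is almost always its own gene's
#' TSS; using one definition for both sets keeps the matching exact) into
#' `n_bins` equal-occupancy bins; a null set of the same size is drawn from
#' the catalog matching the bin histogram exactly (without replacement where
#' possible). Flagged proportions are compared by two-sided Fisher exact test
#' and the full |delta| bias distributions by two-sided Mann-Whitney.
#'
#' @param eqtl_variants Tibble with `gene_id`, `variant_id` (best variant per
#'   eQTL gene).
#' @param variants Panel variant table (positions).
#' @param tss Gene TSS table ([gene_tss()]).
#' @param catalog Variant bias table ([summarize_variant_bias()]) covering
#'   both sets.
#' @param n_bins Number of equal-occupancy distance bins (>= 5).
#' @param rng_seed Seed for the matched draw.
#' @return List of class `mb_enrichment`: proportions, 2x2 `table`,
#'   `fisher_p`, `mannwhitney_p`, the `matched` null variant ids, and the
#'   per-bin histogram.
#' @export
tss_matched_bias_enrichment <- function(eqtl_variants, variants, tss, catalog,
                                        n_bins = 10L, rng_seed = 1L) {
  if (n_bins < 5L) abort("n_bins must be >= 5")
  cat_tbl <- if (inherits(catalog, "mb_bias_catalog")) catalog$variants else
    catalog
  vpos <- setNames(variants$pos, variants$variant_id)
  vctg <- setNames(variants$contig, variants$variant_id)
  nearest_tss <- function(v)
    min(abs(vpos[[v]] - tss$tss[tss$contig == vctg[[v]]]))
  d_eqtl <- purrr::map_dbl(eqtl_variants$variant_id, nearest_tss)
  if (anyNA(d_eqtl)) abort("eQTL variants missing from the variant table")
  cand <- cat_tbl$variant_id
  d_cand <- purrr::map_dbl(cand, nearest_tss)
  brk <- unique(quantile(d_eqtl, probs = seq(0, 1, length.out = n_bins + 1)))
  bin_eqtl <- cut(d_eqtl, brk, include.lowest = TRUE)
  bin_cand <- cut(d_cand, brk, include.lowest = TRUE)
  matched <- character(0)
  with_seed(rng_seed, {
    for (b in levels(bin_eqtl)) {
      need <- sum(bin_eqtl == b)
      if (!need) next
      pool <- cand[!is.na(bin_cand) & bin_cand == b]
      if (length(pool) >= need) {
        matched <- c(matched, sample(pool, need))
      } else if (length(pool) > 0L) {
        warn(paste0("bin ", b, ": sampling matched nulls with replacement"))
        matched <- c(matched, sample(pool, need, replace = TRUE))
      } else {
        warn(paste0("bin ", b, ": no null candidates; bin skipped"))
      }
    }
  })
  flag <- setNames(cat_tbl$flagged, cat_tbl$variant_id)
  delta <- setNames(abs(cat_tbl$delta), cat_tbl$variant_id)
  f_eqtl <- flag[eqtl_variants$variant_id]
  f_null <- flag[matched]
  tab <- rbind(eqtl = c(sum(f_eqtl), sum(!f_eqtl)),
               matched_null = c(sum(f_null), sum(!f_null)))
  colnames(tab) <- c("flagged", "unflagged")
  fisher_p <- if (any(colSums(tab) == 0L)) 1 else fisher.test(tab)$p.value
  x <- delta[eqtl_variants$variant_id]
  y <- delta[matched]
  mw_p <- if (identical(sort(unname(x)), sort(unname(y)))) 1 else
    suppressWarnings(wilcox.test(x, y)$p.value)
  props <- tibble(set = c("eqtl", "matched_null"),
                  n = c(length(f_eqtl), length(f_null)),
                  prop_flagged = c(mean(f_eqtl), mean(f_null)),
                  mean_abs_delta = c(mean(x), mean(y)))
  structure(list(proportions = props, table = tab, fisher_p = fisher_p,
                 mannwhitney_p = mw_p, matched = matched,
                 bins = table(bin_eqtl)),
            class = "mb_enrichment")
}

#' Before/after eQTL analysis around bias filtering
#'
#' The full downstream pipeline: quantify exons from the cohort alignments,
#' filter reads at the catalog's biased start sites, re-quantify, normalize
#' both matrices identically, map cis-eQTLs on both with the same permutation
#' order, call the unfiltered analysis at `config$fdr` and the filtered one at
#' the *same* realized threshold, and classify per-gene changes.
#'
#' @param cohort An `mb_cohort`.
#' @param catalog An `mb_bias_catalog` (its `biased_sites` drive filtering).
#' @param variants Panel variant table.
#' @param config An [eqtl_config()].
#' @param presence_frac Exon presence threshold for [filter_and_normalize()].
#' @param drop_threshold See [classify_eqtl_changes()].
#' @param min_mapq Quantification mapping-quality floor.
#' @return List: `before`, `after` (`mb_eqtl_fit`s), `comparison`
#'   (`mb_eqtl_comparison`), `filter_stats`, `counts_before`, `counts_after`.
#' @export
eqtl_before_after <- function(cohort, catalog, variants,
                              config = eqtl_config(), presence_frac = 0.9,
                              drop_threshold = 20, min_mapq = 1L) {
  inds <- colnames(cohort$genotypes)
  cb <- quantify_exons(cohort$alignments, cohort$exons, individuals = inds,
                       min_mapq = min_mapq)
  flt <- filter_alignments(cohort$alignments, catalog$biased_sites)
  ca <- quantify_exons(flt$alignments, cohort$exons, individuals = inds,
                       min_mapq = min_mapq)
  eb <- filter_and_normalize(cb, presence_frac)
  ea <- filter_and_normalize(ca, presence_frac)
  fit_b <- map_cis_eqtls(eb, cohort$exons, cohort$genotypes, variants, config)
  fit_a <- map_cis_eqtls(ea, cohort$exons, cohort$genotypes, variants, config)
  fit_b <- call_eqtl_genes(fit_b)
  fit_a <- call_eqtl_genes(fit_a, threshold = fit_b$threshold)
  cmp <- classify_eqtl_changes(fit_b, fit_a, drop_threshold)
  list(before = fit_b, after = fit_a, comparison = cmp,
       filter_stats = flt$stats, counts_before = cb, counts_after = ca)
}
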