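# Rank-transform columns and scale to unit sums of squares so crossprod()
# yields Spearman (midrank) correlations. Constant columns are flagged.
scale_ranks <- function(m) {
  r <- apply(m, 2L, rank)
  if (is.null(dim(r))) r <- matrix(r, ncol = ncol(m))
  r <- sweep(r, 2L, colMeans(r))
  ss <- sqrt(colSums(r^2))
  ok <- ss > 0
  r[, ok] <- sweep(r[, ok, drop = FALSE], 2L, ss[ok], "/")
  list(x = r, ok = ok)
}

row_max <- function(m) {
  out <- m[, 1L]
  for (j in seq_len(ncol(m))[-1L]) out <- pmax(out, m[, j])
  out
}

# Two-sided nominal P for a Spearman rho via the t approximation.
spearman_p <- function(rho, n) {
  d <- dim(rho)
  r <- pmin(1, pmax(-1, as.vector(rho)))
  t <- abs(r) * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-t, df = n - 2)
  dim(p) <- d
  p
}

#' Map cis-eQTLs by Spearman rank correlation with permutation P values
#'
#' For every gene, correlates each quantified exon with the dosage of every
#' cis variant (within `cis_window` of the TSS) using Spearman rank
#' correlation with midrank ties, takes the gene's best association, and
#' converts it to a gene-level empirical P value by permuting individual
#' labels `n_perm` times and recomputing the best statistic. The same
#' permutation order is used for every gene in a run, so analyses before and
#' after bias filtering are strictly comparable.
#'
#' `p_empirical = (1 + #\{perm best >= observed best\}) / (n_perm + 1)` on the
#' |rho| scale (equivalent to the minimum nominal P at fixed n), with floor
#' `1 / (n_perm + 1)`.
#'
#' @param expr Normalized expression matrix (exons x individuals) from
#'   [filter_and_normalize()].
#' @param exons Exon table linking exon ids to genes and coordinates.
#' @param genotypes Dosage matrix (variants x individuals),
#'   [genotype_dosage()].
#' @param variants Variant table with `variant_id`, `contig`, `pos`.
#' @param config An [eqtl_config()].
#' @return An `mb_eqtl_fit`: list with `genes` (per-gene best association:
#'   `gene_id`, `exon`, `variant`, `rho`, `p_nominal`, `p_empirical`,
#'   `n_exons`, `n_variants`), `exon_best` (best variant per exon), `n`,
#'   `config`. Genes with no testable pair get NA P values.
#' @export
map_cis_eqtls <- function(expr, exons, genotypes, variants,
                          config = eqtl_config()) {
  stopifnot(identical(colnames(expr), colnames(genotypes)))
  n <- ncol(expr)
  tss <- gene_tss(exons |> mutate(exon_rank = 1L))
  perm <- with_seed(config$rng_seed,
                    matrix(replicate(config$n_perm, sample.int(n)), nrow = n))
  genes <- unique(exons$gene_id[exons$exon_id %in% rownames(expr)])
  ng <- length(genes)
  # per-gene results accumulated in plain vectors (this loop is hot)
  r_exon <- r_var <- rep(NA_character_, ng)
  r_rho <- r_pnom <- r_pemp <- rep(NA_real_, ng)
  r_nex <- r_nvar <- integer(ng)
  exon_rows <- vector("list", ng)
  exon_of_gene <- split(exons$exon_id, exons$gene_id)
  start_of_exon <- setNames(exons$start, exons$exon_id)
  tss_of <- setNames(tss$tss, tss$gene_id)
  contig_of <- setNames(tss$contig, tss$gene_id)
  expr_names <- rownames(expr)
  geno_names <- rownames(genotypes)
  for (gi in seq_len(ng)) {
    g <- genes[gi]
    eids <- exon_of_gene[[g]]
    eids <- eids[eids %in% expr_names]
    vsel <- variants$contig == contig_of[[g]] &
      abs(variants$pos - tss_of[[g]]) <= config$cis_window
    vids <- variants$variant_id[vsel]
    vids <- vids[vids %in% geno_names]
    vpos <- variants$pos[match(vids, variants$variant_id)]
    r_nex[gi] <- length(eids)
    if (!length(eids) || !length(vids)) next
    E <- scale_ranks(t(expr[eids, , drop = FALSE]))
    G <- scale_ranks(t(genotypes[vids, , drop = FALSE]))
    keep_e <- which(E$ok); keep_v <- which(G$ok)  # drop monomorphic/constant
    if (!length(keep_e) || !length(keep_v)) next
    Ex <- E$x[, keep_e, drop = FALSE]
    Gx <- G$x[, keep_v, drop = FALSE]
    eids <- eids[keep_e]; vids <- vids[keep_v]; vpos <- vpos[keep_v]
    R <- crossprod(Ex, Gx)
    P <- spearman_p(R, n)
    pv <- as.vector(P)
    estart_v <- rep(unname(start_of_exon[eids]), times = length(vids))
    vpos_v <- rep(vpos, each = length(eids))
    best <- order(pv, vpos_v, estart_v)[1L]
    obs <- max(abs(R))
    permstat <- rep(0, config$n_perm)
    for (e in seq_len(ncol(Ex))) {
      pe <- matrix(Ex[, e][perm], nrow = n)
      permstat <- pmax(permstat, row_max(abs(crossprod(pe, Gx))))
    }
    r_exon[gi] <- rep(eids, times = length(vids))[best]
    r_var[gi] <- rep(vids, each = length(eids))[best]
    r_rho[gi] <- R[best]
    r_pnom[gi] <- pv[best]
    r_pemp[gi] <- (1 + sum(permstat >= obs - 1e-12)) / (config$n_perm + 1)
    r_nex[gi] <- length(eids)
    r_nvar[gi] <- length(vids)
    # best variant per exon (rows of P), deterministic tie-break by position
    vord <- order(vpos)
    eb <- apply(P[, vord, drop = FALSE], 1L, which.min)
    exon_rows[[gi]] <- data.frame(
      gene_id = g, exon_id = eids,
      variant = vids[vord][eb],
      rho = R[cbind(seq_along(eids), vord[eb])],
      p_nominal = P[cbind(seq_along(eids), vord[eb])])
  }
  gene_tbl <- tibble(gene_id = genes, exon = r_exon, variant = r_var,
                     rho = r_rho, p_nominal = r_pnom, p_empirical = r_pemp,
                     n_exons = r_nex, n_variants = r_nvar)
  structure(list(genes = gene_tbl,
                 exon_best = as_tibble(dplyr::bind_rows(
                   exon_rows[!vapply(exon_rows, is.null, TRUE)])),
                 n = n, config = config),
            class = "mb_eqtl_fit")
}

#' Call significant eQTL genes at a target FDR
#'
#' Benjamini-Hochberg on the gene-level empirical P values at `fdr`, recording
#' the realized empirical-P threshold. Passing that `threshold` back in (from
#' the unfiltered analysis) reuses it verbatim — the filtered re-analysis is
#' called at the *same* P value threshold, exactly as the before/after
#' comparison requires.
#'
#' @param fit An `mb_eqtl_fit`.
#' @param fdr Target FDR (default from the fit's config).
#' @param threshold Empirical-P threshold to reuse; `NULL` derives it by BH.
#' @return The fit with `genes$significant` filled in and elements `threshold`
#'   and `fdr` set.
#' @export
call_eqtl_genes <- function(fit, fdr = NULL, threshold = NULL) {
  fdr <- fdr %||% fit$config$fdr
  p <- fit$genes$p_empirical
  tested <- !is.na(p)
  if (!any(tested)) abort("no tested genes")
  if (is.null(threshold)) {
    ps <- sort(p[tested])
    m <- length(ps)
    pass <- which(ps <= seq_len(m) / m * fdr)
    threshold <- if (length(pass)) ps[max(pass)] else 0
  }
  fit$genes$significant <- tested & p <= threshold
  fit$threshold <- threshold
  fit$fdr <- fdr
  fit
}

#' @export
print.mb_eqtl_fit <- function(x, ...) {
  cat("<mb_eqtl_fit> ", nrow(x$genes), " genes (",
      sum(!is.na(x$genes$p_empirical)), " tested), n = ", x$n,
      ", n_perm = ", x$config$n_perm, sep = "")
  if (!is.null(x$threshold))
    cat("; ", sum(x$genes$significant), " significant at FDR ", x$fdr,
        " (threshold ", signif(x$threshold, 3), ")", sep = "")
  cat("\n")
  invisible(x)
}

#' Per-gene eQTL results as a tibble
#'
#' @param x An `mb_eqtl_fit`.
#' @param ... Unused.
#' @return The per-gene association tibble.
#' @export
tidy.mb_eqtl_fit <- function(x, ...) x$genes

#' One-row summary of an eQTL fit
#'
#' @param x An `mb_eqtl_fit`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.mb_eqtl_fit <- function(x, ...) {
  tibble(n_genes = nrow(x$genes),
         n_tested = sum(!is.na(x$genes$p_empirical)),
         n_significant = if (!is.null(x$threshold))
           sum(x$genes$significant) else NA_integer_,
         threshold = x$threshold %||% NA_real_,
         n = x$n, n_perm = x$config$n_perm, fdr = x$fdr %||% x$config$fdr)
}
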