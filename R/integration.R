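#' Pair CpG islands with the promoters they overlap
#'
#' A (CGI, gene) pair is emitted whenever the CGI overlaps the gene's
#' promoter by at least 1 bp; a CGI spanning two promoters yields two
#' pairs.
#'
#' @param cgis CpG-island intervals.
#' @param genes Gene-model `data.frame`.
#' @param promoter_length Promoter length in bp passed to
#'   [promoter_of()] (default 2000).
#' @return `data.frame` with columns `cgi_index` (row in `cgis`),
#'   `cgi_chrom`, `cgi_start`, `cgi_end`, `gene_id`.
#' @export
cgi_promoter_pairs <- function(cgis, genes, promoter_length = 2000) {
  prom <- promoter_of(genes, length = promoter_length)
  ov <- GenomicRanges::findOverlaps(.gr(cgis), .gr(prom),
                                    ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
  out <- data.frame(cgi_index = qi,
                    cgi_chrom = cgis$chrom[qi],
                    cgi_start = cgis$start[qi],
                    cgi_end = cgis$end[qi],
                    gene_id = prom$gene_id[si],
                    stringsAsFactors = FALSE)
  out <- out[order(out$cgi_index, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median CGI methylation per region
#'
#' For every CGI and region, the median methylation level over the
#' (depth-filtered) sites falling inside the CGI. Regions without any
#' covered site in a CGI yield `NA`.
#'
#' @param cgis CpG-island intervals.
#' @param region_sites Named list of site tables, one per region
#'   (depth-filtered).
#' @return Numeric matrix, one row per CGI (rownames
#'   `chrom:start-end`), one column per region.
#' @export
cgi_median_methylation <- function(cgis, region_sites) {
  gcgi <- .gr(cgis)
  out <- matrix(NA_real_, nrow = nrow(cgis), ncol = length(region_sites),
                dimnames = list(paste0(cgis$chrom, ":", cgis$start, "-",
                                       cgis$end),
                                names(region_sites)))
  for (r in seq_along(region_sites)) {
    s <- region_sites[[r]]
    beta <- methyl_beta(s)
    ov <- GenomicRanges::findOverlaps(.gr_sites(s), gcgi,
                                      ignore.strand = TRUE)
    if (!length(ov)) next
    med <- tapply(beta[S4Vectors::queryHits(ov)],
                  S4Vectors::subjectHits(ov), median, na.rm = TRUE)
    out[as.integer(names(med)), r] <- med
  }
  out
}

#' Pearson screen of promoter-CGI methylation against expression
#'
#' For each (CGI, gene) pair, computes the Pearson correlation between
#' the per-region median CGI methylation vector and the gene's
#' per-region expression vector, with the two-sided p-value from the
#' t-statistic `r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of
#' freedom. Pairs with an incomplete methylation vector or zero variance
#' in either vector are skipped (counted in the `"skipped"` attribute).
#' Records passing `p <= p_threshold` are retained and signed by the
#' sign of `r`. By default, when a gene appears in several surviving
#' pairs only the smallest-p pair is kept.
#'
#' @param pairs Output of [cgi_promoter_pairs()].
#' @param meth CGI-by-region median methylation matrix from
#'   [cgi_median_methylation()].
#' @param expr Gene-by-region expression matrix (TMM-normalized
#'   expression units, not z-scores).
#' @param p_threshold Significance threshold (default 0.05).
#' @param bh If `TRUE`, adds BH q-values (over all tested pairs) to the
#'   output; the retention rule stays on raw p.
#' @param dedup Keep only the smallest-p pair per gene (default `TRUE`).
#' @return `data.frame` with `gene_id`, CGI coordinates, `n_regions`,
#'   `r`, `p_value`, optional `q_value`, `sign`; attribute `"skipped"`
#'   holds counts of excluded pairs.
#' @export
pearson_screen <- function(pairs, meth, expr, p_threshold = 0.05,
                           bh = FALSE, dedup = TRUE) {
  skipped <- c(missing_region = 0L, zero_variance = 0L, no_expression = 0L)
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    mv <- meth[pairs$cgi_index[i], ]
    gid <- pairs$gene_id[i]
    if (!(gid %in% rownames(expr))) {
      skipped["no_expression"] <- skipped["no_expression"] + 1L
      next
    }
    ev <- expr[gid, ]
    if (anyNA(mv)) {
      skipped["missing_region"] <- skipped["missing_region"] + 1L
      next
    }
    if (sd(mv) == 0 || sd(ev) == 0) {
      skipped["zero_variance"] <- skipped["zero_variance"] + 1L
      next
    }
    n <- length(mv)
    r <- cor(mv, ev)
    p <- if (abs(r) >= 1) 0 else {
      t <- r * sqrt((n - 2) / (1 - r^2))
      2 * pt(-abs(t), df = n - 2)
    }
    rows[[i]] <- data.frame(gene_id = gid,
                            cgi_chrom = pairs$cgi_chrom[i],
                            cgi_start = pairs$cgi_start[i],
                            cgi_end = pairs$cgi_end[i],
                            n_regions = n, r = r, p_value = p,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(gene_id = character(), cgi_chrom = character(),
                      cgi_start = integer(), cgi_end = integer(),
                      n_regions = integer(), r = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  if (bh) out$q_value <- bh_adjust(out$p_value)
  out <- out[out$p_value <= p_threshold, , drop = FALSE]
  if (dedup && nrow(out)) {
    out <- out[order(out$gene_id, out$p_value), , drop = FALSE]
    out <- out[!duplicated(out$gene_id), , drop = FALSE]
  }
  out$sign <- ifelse(out$r > 0, "positive", "negative")
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Categorize correlated genes against BRSG and DMG sets
#'
#' Flags each correlation record by membership in any region's BRSG set
#' and in the DMG output, and tabulates counts by sign x BRSG x DMG.
#'
#' @param records Output of [pearson_screen()].
#' @param brsg_sets Named list of per-region BRSG gene-id vectors (from
#'   [assign_region_clusters()]), or `NULL`.
#' @param dmgs DMG table from [call_dmgs()], or `NULL`.
#' @return List with `records` (input plus `is_brsg`, `is_dmg`) and
#'   `summary` (`data.frame` of counts by `sign`, `is_brsg`, `is_dmg`).
#' @export
categorize_correlations <- function(records, brsg_sets = NULL, dmgs = NULL) {
  brsg_genes <- unique(unlist(brsg_sets, use.names = FALSE))
  dmg_genes <- if (is.null(dmgs)) character() else unique(dmgs$gene_id)
  records$is_brsg <- records$gene_id %in% brsg_genes
  records$is_dmg <- records$gene_id %in% dmg_genes
  summary <- as.data.frame(table(sign = records$sign,
                                 is_brsg = records$is_brsg,
                                 is_dmg = records$is_dmg),
                           stringsAsFactors = FALSE)
  names(summary)[names(summary) == "Freq"] <- "n"
  list(records = records, summary = summary)
}
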