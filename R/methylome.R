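#' Discard sites below a read-depth threshold
#'
#' Sites with combined methylated + unmethylated read count below
#' `min_depth` are removed. The default of 10 reflects the usual WGBS
#' practice of discarding sites with depth < 10 before computing
#' methylation levels.
#'
#' @param sites Site table (see [read_cytosine_report()]).
#' @param min_depth Minimum depth kept (`>= 1`).
#' @return The filtered site table, input order preserved.
#' @export
filter_by_depth <- function(sites, min_depth = 10) {
  stopifnot(min_depth >= 1)
  sites[site_depth(sites) >= min_depth, , drop = FALSE]
}

#' Promoter intervals of gene models
#'
#' The promoter is the fixed-length window immediately upstream of the
#' transcription start site: `[tx_start - length, tx_start)` on the `+`
#' strand and `[tx_end, tx_end + length)` on `-`. Promoters are clipped at
#' position 0, and at the chromosome end when `chrom_lengths` is supplied.
#' A gene whose TSS sits at position 0 on `+` has an empty promoter and is
#' dropped with a warning.
#'
#' @param genes Gene-model `data.frame`.
#' @param length Promoter length in bp (default 2000).
#' @param chrom_lengths Optional named vector of chromosome lengths.
#' @return Interval `data.frame` with a `gene_id` column.
#' @export
promoter_of <- function(genes, length = 2000, chrom_lengths = NULL) {
  stopifnot(length > 0)
  plus <- genes$strand == "+"
  start <- ifelse(plus, genes$tx_start - length, genes$tx_end)
  end   <- ifelse(plus, genes$tx_start, genes$tx_end + length)
  start <- pmax(start, 0L)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[genes$chrom]
    end <- pmin(end, ifelse(is.na(lim), end, lim))
  }
  out <- data.frame(gene_id = genes$gene_id, chrom = genes$chrom,
                    start = as.integer(start), end = as.integer(end),
                    strand = genes$strand, stringsAsFactors = FALSE)
  empty <- out$start >= out$end
  if (any(empty)) {
    warning(sum(empty), " gene(s) with empty promoter after clipping dropped")
    out <- out[!empty, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Quartile bin of a methylation level
#'
#' Bins are half-open: `[0, 0.25)`, `[0.25, 0.5)`, `[0.5, 0.75)` and the
#' closed top bin `[0.75, 1]`.
#'
#' @param beta Methylation levels in `[0, 1]` (NA allowed).
#' @return Factor with levels `b0_25`, `b25_50`, `b50_75`, `b75_100`.
#' @export
methylation_level_bin <- function(beta) {
  cut(beta, breaks = c(-Inf, 0.25, 0.5, 0.75, Inf), right = FALSE,
      labels = c("b0_25", "b25_50", "b50_75", "b75_100"))
}

#' Classify sites by genomic feature and sequence context
#'
#' Each site receives exactly one feature label with priority
#' `promoter > gene_body > intergenic` (gene body = `[tx_start, tx_end)`
#' including introns), a context group (`CpG` vs `non-CpG`, the latter
#' pooling CHG and CHH), and a methylation-level quartile bin (`NA` at
#' zero depth). Sites on chromosomes absent from the annotation are
#' labelled intergenic with a single aggregate warning.
#'
#' @param sites Site table.
#' @param genes Gene-model `data.frame`.
#' @param promoters Optional promoter intervals; derived via
#'   [promoter_of()] when `NULL`.
#' @return The site table with added columns `feature`, `context_group`,
#'   `beta`, `level_bin`.
#' @export
classify_sites <- function(sites, genes, promoters = NULL) {
  if (is.null(promoters)) promoters <- promoter_of(genes)
  gsite <- .gr_sites(sites)
  feature <- rep("intergenic", nrow(sites))
  # suppressWarnings: disjoint seqlevels are expected when a chromosome is
  # absent from the annotation; the aggregate warning below covers it
  if (nrow(genes)) {
    bodies <- data.frame(chrom = genes$chrom, start = genes$tx_start,
                         end = genes$tx_end, strand = ".")
    feature[S4Vectors::queryHits(suppressWarnings(
      GenomicRanges::findOverlaps(gsite, .gr(bodies),
                                  ignore.strand = TRUE)))] <- "gene_body"
  }
  if (nrow(promoters)) {
    feature[S4Vectors::queryHits(suppressWarnings(
      GenomicRanges::findOverlaps(gsite, .gr(promoters),
                                  ignore.strand = TRUE)))] <- "promoter"
  }
  unk <- setdiff(unique(sites$chrom), unique(c(genes$chrom, promoters$chrom)))
  if (length(unk))
    warning("chromosome(s) absent from annotation labelled intergenic: ",
            paste(unk, collapse = ", "))
  out <- sites
  out$feature <- factor(feature,
                        levels = c("promoter", "gene_body", "intergenic"))
  out$context_group <- factor(ifelse(sites$context == "CpG", "CpG", "non-CpG"),
                              levels = c("CpG", "non-CpG"))
  out$beta <- methyl_beta(sites)
  out$level_bin <- methylation_level_bin(out$beta)
  out
}

#' Proportions of methylation-level bins per group
#'
#' Within each group defined by `by`, reports the count and proportion of
#' sites falling into the four methylation-level quartile bins. Within
#' each non-empty group the proportions sum to 1; empty groups are simply
#' absent from the output.
#'
#' @param classified Output of [classify_sites()] (all sites must have
#'   depth > 0).
#' @param by Character vector of grouping columns, a subset of
#'   `c("sample", "feature", "context_group")` (a `sample` column must be
#'   present to group by it).
#' @return `data.frame` with grouping columns, `level_bin`, `count`,
#'   `proportion`.
#' @export
level_bin_proportions <- function(classified,
                                  by = c("feature", "context_group")) {
  if (anyNA(classified$level_bin))
    stop("level_bin_proportions requires sites with depth > 0")
  stopifnot(all(by %in% names(classified)))
  dt <- data.table::as.data.table(classified[, c(by, "level_bin")])
  cnt <- dt[, list(count = .N), by = c(by, "level_bin")]
  cnt[, `:=`(proportion = count / sum(count)), by = by]
  out <- as.data.frame(cnt)
  out[do.call(order, out[c(by, "level_bin")]), , drop = FALSE] ->
    out
  rownames(out) <- NULL
  out
}
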