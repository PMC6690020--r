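#' Vectorized two-sided Fisher's exact test for 2x2 count tables
#'
#' For each table `(n_meth_a, n_unmeth_a; n_meth_b, n_unmeth_b)` the
#' two-sided p-value is the sum of hypergeometric probabilities, over all
#' tables with the same margins, that do not exceed the probability of the
#' observed table (probability-mass rule, with the conventional relative
#' slack of 1e-7 for floating-point ties). Tables with a zero row margin
#' are degenerate: they return p = 1 and are flagged in the `"degenerate"`
#' attribute.
#'
#' @param n_meth_a,n_unmeth_a,n_meth_b,n_unmeth_b Nonnegative integer
#'   vectors (recycled to common length).
#' @return Numeric vector of p-values in `(0, 1]`, with a logical
#'   attribute `"degenerate"` marking zero-margin tables.
#' @export
fisher_exact_2x2 <- function(n_meth_a, n_unmeth_a, n_meth_b, n_unmeth_b) {
  n <- max(length(n_meth_a), length(n_unmeth_a),
           length(n_meth_b), length(n_unmeth_b))
  a <- as.integer(rep_len(n_meth_a, n));   b <- as.integer(rep_len(n_unmeth_a, n))
  cc <- as.integer(rep_len(n_meth_b, n)); d <- as.integer(rep_len(n_unmeth_b, n))
  if (any(c(a, b, cc, d) < 0)) stop("counts must be nonnegative")
  m1 <- a + b; m2 <- cc + d; k <- a + cc
  p <- rep(1, n)
  degen <- m1 == 0L | m2 == 0L
  idx <- which(!degen)
  if (length(idx)) {
    lo <- pmax(0L, k[idx] - m2[idx]); hi <- pmin(k[idx], m1[idx])
    len <- hi - lo + 1L
    tab <- rep.int(seq_along(idx), len)
    x <- sequence(len) - 1L + rep.int(lo, len)
    dv <- dhyper(x, m1[idx][tab], m2[idx][tab], k[idx][tab])
    dobs <- dhyper(a[idx], m1[idx], m2[idx], k[idx])
    keep <- dv <= dobs[tab] * (1 + 1e-7)
    s <- rowsum(dv * keep, tab)           # every group keeps >= 1 term (dobs)
    p[idx[as.integer(rownames(s))]] <- pmin(s[, 1], 1)
  }
  attr(p, "degenerate") <- degen
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `q_(i) = min_{j >= i} m * p_(j) / j` on the
#' sorted p-values, clipped at 1, returned in input order (delegates to
#' [stats::p.adjust()]).
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  p.adjust(p, method = "BH")
}

#' Call differentially methylated sites between two samples
#'
#' Tests the sites present in both samples (matched on chromosome,
#' position and strand; both inputs are expected to be depth-filtered)
#' with [fisher_exact_2x2()], adjusts p-values per pair with
#' [bh_adjust()] over the whole tested universe, and classifies sites
#' with `q <= q_threshold` and `|diff| >= min_abs_diff` as `hyper`
#' (level higher in sample B) or `hypo` (lower in B); everything else
#' is `ns`.
#'
#' @param sites_a,sites_b Site tables for the two samples.
#' @param q_threshold Significance threshold on the q-value (default 0.05).
#' @param min_abs_diff Minimum absolute methylation-level difference
#'   (default 0; 0.25 is a common stricter choice).
#' @return `data.frame` with columns `chrom`, `pos`, `strand`, `context`,
#'   `level_a`, `level_b`, `diff`, `p_value`, `q_value`, `direction`.
#' @export
call_dms <- function(sites_a, sites_b, q_threshold = 0.05,
                     min_abs_diff = 0) {
  da <- data.table::as.data.table(sites_a)
  db <- data.table::as.data.table(sites_b)
  m <- merge(da, db, by = c("chrom", "pos", "strand"),
             suffixes = c("_a", "_b"))
  if (!nrow(m)) {
    warning("no shared sites between the two samples")
    return(data.frame(chrom = character(), pos = integer(),
                      strand = character(), context = character(),
                      level_a = numeric(), level_b = numeric(),
                      diff = numeric(), p_value = numeric(),
                      q_value = numeric(), direction = character(),
                      stringsAsFactors = FALSE))
  }
  level_a <- m$n_meth_a / (m$n_meth_a + m$n_unmeth_a)
  level_b <- m$n_meth_b / (m$n_meth_b + m$n_unmeth_b)
  p <- fisher_exact_2x2(m$n_meth_a, m$n_unmeth_a, m$n_meth_b, m$n_unmeth_b)
  q <- bh_adjust(as.numeric(p))
  d <- level_b - level_a
  dir <- ifelse(q <= q_threshold & abs(d) >= min_abs_diff & d > 0, "hyper",
         ifelse(q <= q_threshold & abs(d) >= min_abs_diff & d < 0, "hypo",
                "ns"))
  out <- data.frame(chrom = m$chrom, pos = m$pos, strand = m$strand,
                    context = m$context_a, level_a = level_a,
                    level_b = level_b, diff = d, p_value = as.numeric(p),
                    q_value = q, direction = dir, stringsAsFactors = FALSE)
  out[order(out$chrom, out$pos, out$strand), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Pairwise DMS count matrix across samples
#'
#' Entry `(i, j)` is the number of significant sites (direction other
#' than `ns`) from [call_dms()] between samples `i` and `j`; the matrix
#' is symmetric with a zero diagonal.
#'
#' @param site_list Named list of site tables, one per sample.
#' @param q_threshold,min_abs_diff Passed to [call_dms()].
#' @return Symmetric integer matrix with sample names as dimnames.
#' @export
dms_count_matrix <- function(site_list, q_threshold = 0.05,
                             min_abs_diff = 0) {
  stopifnot(length(site_list) >= 2)
  nm <- names(site_list)
  if (is.null(nm)) nm <- paste0("S", seq_along(site_list))
  n <- length(site_list)
  m <- matrix(0L, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    dms <- call_dms(site_list[[i]], site_list[[j]],
                    q_threshold = q_threshold, min_abs_diff = min_abs_diff)
    m[i, j] <- m[j, i] <- sum(dms$direction != "ns")
  }
  m
}

#' Call differentially methylated genes (DMGs)
#'
#' A gene is a DMG when its first exon overlaps (by at least 1 bp) a CpG
#' island that contains at least one significant DMS. One record is
#' emitted per qualifying (gene, CGI) pair with the count of supporting
#' DMSs inside the CGI, and the contributing sample pairs when the DMS
#' table carries a `pair` column.
#'
#' @param dms DMS table ([call_dms()] output, possibly pooled over sample
#'   pairs with a `pair` column). Rows with a `direction` column keep only
#'   `direction != "ns"`; otherwise rows with `q_value <= q_threshold`.
#' @param cgis CpG-island intervals.
#' @param genes Gene-model `data.frame`.
#' @param q_threshold Fallback significance threshold (default 0.05).
#' @return `data.frame` with `gene_id`, `cgi_chrom`, `cgi_start`,
#'   `cgi_end`, `supporting_dms_count`, `region_pairs`.
#' @export
call_dmgs <- function(dms, cgis, genes, q_threshold = 0.05) {
  sig <- if ("direction" %in% names(dms)) dms[dms$direction != "ns", ,
                                              drop = FALSE]
         else dms[dms$q_value <= q_threshold, , drop = FALSE]
  empty <- data.frame(gene_id = character(), cgi_chrom = character(),
                      cgi_start = integer(), cgi_end = integer(),
                      supporting_dms_count = integer(),
                      region_pairs = character(), stringsAsFactors = FALSE)
  if (!nrow(sig) || !nrow(cgis) || !nrow(genes)) return(empty)
  fe <- gene_first_exon(genes)
  if (!nrow(fe)) return(empty)
  ov_fe <- GenomicRanges::findOverlaps(.gr(fe), .gr(cgis),
                                       ignore.strand = TRUE)
  if (!length(ov_fe)) return(empty)
  ov_dms <- GenomicRanges::findOverlaps(.gr_sites(sig), .gr(cgis),
                                        ignore.strand = TRUE)
  dms_by_cgi <- split(S4Vectors::queryHits(ov_dms),
                      S4Vectors::subjectHits(ov_dms))
  rows <- lapply(seq_along(ov_fe), function(i) {
    gi <- S4Vectors::queryHits(ov_fe)[i]
    ci <- S4Vectors::subjectHits(ov_fe)[i]
    hits <- dms_by_cgi[[as.character(ci)]]
    if (is.null(hits)) return(NULL)
    pairs <- if ("pair" %in% names(sig))
      paste(sort(unique(sig$pair[hits])), collapse = ",") else ""
    data.frame(gene_id = fe$gene_id[gi], cgi_chrom = cgis$chrom[ci],
               cgi_start = cgis$start[ci], cgi_end = cgis$end[ci],
               supporting_dms_count = length(hits), region_pairs = pairs,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$gene_id, out$cgi_chrom, out$cgi_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
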