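# Independent oracles, kept deliberately separate from the package's
# implementation paths.

# Two-sided Fisher p by direct enumeration of the hypergeometric support
# with log-binomial coefficients (probability-mass rule).
oracle_fisher <- function(a, b, c, d) {
  m1 <- a + b; m2 <- c + d; k <- a + c
  if (m1 == 0 || m2 == 0) return(1)
  lo <- max(0, k - m2); hi <- min(k, m1)
  xs <- lo:hi
  logp <- lchoose(m1, xs) + lchoose(m2, k - xs) - lchoose(m1 + m2, k)
  pr <- exp(logp)
  pobs <- exp(lchoose(m1, a) + lchoose(m2, c) - lchoose(m1 + m2, k))
  min(1, sum(pr[pr <= pobs * (1 + 1e-7)]))
}

# BH step-up by its definition: q_i = min over j with p_(j) >= p_i of
# m * p_(j) / rank_j, clipped at 1 (O(m^2) via outer()).
oracle_bh <- function(p) {
  m <- length(p)
  ps <- sort(p)
  cand <- pmin(m * ps / seq_len(m), 1)
  vapply(p, function(pi) min(cand[ps >= pi - 1e-15]), numeric(1))
}

# exhaustive k-medoids optimum
oracle_pam_cost <- function(d, k) {
  n <- nrow(d)
  sets <- utils::combn(n, k)
  min(apply(sets, 2, function(m)
    sum(apply(d[m, , drop = FALSE], 2, min))))
}

# small handmade site table
make_sites <- function(pos, n_meth, n_unmeth, chrom = "chr1", strand = "+",
                       context = "CpG") {
  data.frame(chrom = chrom, pos = as.integer(pos),
             strand = rep_len(strand, length(pos)),
             context = rep_len(context, length(pos)),
             n_meth = as.integer(n_meth), n_unmeth = as.integer(n_unmeth),
             stringsAsFactors = FALSE)
}

# two-exon gene model builder
make_gene <- function(gene_id, chrom, strand, exon_starts, exon_ends) {
  data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
             tx_start = min(exon_starts), tx_end = max(exon_ends),
             exon_starts = paste(exon_starts, collapse = ","),
             exon_ends = paste(exon_ends, collapse = ","),
             stringsAsFactors = FALSE)
}

# dyad-grouped standard error of a pooled mean (sites within a CpG dyad
# share a latent level, so per-site SEs understate the Monte-Carlo error)
dyad_se <- function(sites) {
  beta <- sites$n_meth / (sites$n_meth + sites$n_unmeth)
  anchor <- ifelse(sites$strand == "+", sites$pos, sites$pos - 1L)
  dm <- tapply(beta, paste(sites$chrom, anchor), mean)
  stats::sd(dm) / sqrt(length(dm))
}
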