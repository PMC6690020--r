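#' Configuration for the synthetic multi-region study generator
#'
#' Captures the study design the generator emulates: a small genome with
#' gene models, promoter CpG islands and intergenic repeat elements; one
#' WGBS methylome per region sharing latent per-site methylation levels
#' except at planted differential sites; and a matched expression matrix
#' with one high-expression gene cluster per region and a set of genes
#' whose expression is coupled to their promoter-CGI methylation.
#'
#' Identical config + seed yields byte-identical outputs.
#'
#' @param seed Integer seed driving every random draw.
#' @param n_chroms,chrom_length Genome size (default 2 x 2 Mbp).
#' @param n_genes Number of genes (default 300; every gene has >= 2
#'   exons).
#' @param n_cgis Number of CpG islands, each overlapping a distinct
#'   gene's promoter and first exon (default 240; must be <= `n_genes`).
#' @param n_repeats Named integer vector of elements per repeat class.
#' @param n_regions Number of regions/samples (default 7).
#' @param n_cpg_sites Total CpG-context cytosines (both strands; default
#'   40000).
#' @param noncpg_fraction Fraction of additional non-CpG cytosines
#'   (default 0.1).
#' @param depth_mean,depth_size Negative-binomial read-depth model
#'   (defaults mean 15, size 5 — deliberately close to the depth-10
#'   discard threshold so the filter is exercised).
#' @param beta_params Named list of `c(shape1, shape2)` Beta parameters
#'   per compartment: `cgi_promoter`, `gene_body`, `intergenic`,
#'   `repeat_inner`, `repeat_flank`.
#' @param noncpg_beta Beta parameters for non-CpG sites.
#' @param n_planted_dms Number of planted differential CpG dyads
#'   (default 200). Both strands of a planted dyad share the shifted
#'   level, mirroring the strand symmetry of CpG methylation, so planted
#'   effects survive dyad merging intact.
#' @param planted_dms_delta Methylation-level shift of planted sites
#'   (default 0.5); the shift direction is chosen away from the nearer
#'   boundary so the full magnitude is realized, and clipped to
#'   `[0.02, 0.98]` with a warning otherwise.
#' @param n_planted_corr_pos,n_planted_corr_neg Genes with planted
#'   positive/negative methylation-expression coupling (defaults 5/3).
#' @param corr_strength Target |Pearson r| of the planted coupling
#'   (default 0.95).
#' @param corr_slope Coupling slope in log2-expression units per
#'   methylation unit (default 4).
#' @param cluster_genes_per_region,cluster_effect_size Planted cluster
#'   size per region and its log2 effect (defaults 25 and 3).
#' @param region_noise_sd Per-region log2 expression noise (default
#'   0.25).
#' @param baseline_mean,baseline_sd Gene baseline log2 expression
#'   (defaults 3 and 1).
#' @param repeat_profile Named list mapping repeat classes to a planted
#'   body shape, `"edge_high"` or `"center_high"`.
#' @param profile_high,profile_low Methylation levels of the high/low
#'   thirds of profiled repeat bodies (defaults 0.9 / 0.6).
#' @param flank_bp Repeat flank width used for spacing and compartments
#'   (default 100).
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 101L,
                       n_chroms = 2L, chrom_length = 2e6,
                       n_genes = 300L, n_cgis = 240L,
                       n_repeats = c(LINE = 60L, SINE = 60L, LTR = 60L,
                                     Simple_repeat = 30L),
                       n_regions = 7L,
                       n_cpg_sites = 40000L,
                       noncpg_fraction = 0.1,
                       depth_mean = 15, depth_size = 5,
                       beta_params = list(cgi_promoter = c(1, 9),
                                          gene_body = c(8, 2),
                                          intergenic = c(8, 2),
                                          repeat_inner = c(8, 2),
                                          repeat_flank = c(8.5, 1.5)),
                       noncpg_beta = c(0.5, 20),
                       n_planted_dms = 200L,
                       planted_dms_delta = 0.5,
                       n_planted_corr_pos = 5L, n_planted_corr_neg = 3L,
                       corr_strength = 0.95, corr_slope = 4,
                       cluster_genes_per_region = 25L,
                       cluster_effect_size = 3,
                       region_noise_sd = 0.25,
                       baseline_mean = 3, baseline_sd = 1,
                       repeat_profile = list(LINE = "edge_high",
                                             SINE = "center_high"),
                       profile_high = 0.9, profile_low = 0.6,
                       flank_bp = 100L) {
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes), n_cgis = as.integer(n_cgis),
              n_repeats = n_repeats, n_regions = as.integer(n_regions),
              n_cpg_sites = as.integer(n_cpg_sites),
              noncpg_fraction = noncpg_fraction,
              depth_mean = depth_mean, depth_size = depth_size,
              beta_params = beta_params, noncpg_beta = noncpg_beta,
              n_planted_dms = as.integer(n_planted_dms),
              planted_dms_delta = planted_dms_delta,
              n_planted_corr_pos = as.integer(n_planted_corr_pos),
              n_planted_corr_neg = as.integer(n_planted_corr_neg),
              corr_strength = corr_strength, corr_slope = corr_slope,
              cluster_genes_per_region = as.integer(cluster_genes_per_region),
              cluster_effect_size = cluster_effect_size,
              region_noise_sd = region_noise_sd,
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              repeat_profile = repeat_profile,
              profile_high = profile_high, profile_low = profile_low,
              flank_bp = as.integer(flank_bp))
  counts <- c(cfg$n_chroms, cfg$n_genes, cfg$n_cgis, cfg$n_repeats,
              cfg$n_regions, cfg$n_cpg_sites, cfg$n_planted_dms,
              cfg$n_planted_corr_pos, cfg$n_planted_corr_neg,
              cfg$cluster_genes_per_region)
  if (any(counts < 0)) stop("sim_config: counts must be >= 0")
  if (any(unlist(cfg$beta_params) <= 0) || any(cfg$noncpg_beta <= 0))
    stop("sim_config: Beta parameters must be > 0")
  if (cfg$n_cgis > cfg$n_genes)
    stop("sim_config: n_cgis must be <= n_genes (one CGI per gene)")
  if (cfg$n_planted_corr_pos + cfg$n_planted_corr_neg > cfg$n_cgis)
    stop("sim_config: planted correlated genes exceed available CGI genes")
  if (cfg$n_regions < 2) stop("sim_config: need >= 2 regions")
  class(cfg) <- "sim_config"
  cfg
}

.region_names <- function(config) paste0("region_", seq_len(config$n_regions))

#' Generate the synthetic genome annotation
#'
#' Lays out non-overlapping multi-exon genes (with room for a 2-kb
#' promoter on the correct side) in the first segment of each
#' chromosome, CpG islands spanning the TSS of a subset of genes (so
#' each CGI overlaps both the promoter and the first exon), and repeat
#' elements of the configured classes placed intergenically with at
#' least `2 * flank_bp` spacing.
#'
#' @param config A [sim_config()].
#' @return List with `genes`, `cgis`, `repeats`, `chrom_lengths`,
#'   `config`.
#' @export
make_annotation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  chroms <- paste0("chr", seq_len(config$n_chroms))
  chrom_lengths <- setNames(rep(config$chrom_length, config$n_chroms),
                            chroms)
  slot <- 8500L
  genes_per_chrom <- ceiling(config$n_genes / config$n_chroms)
  gene_seg_end <- genes_per_chrom * slot + 2000L
  if (gene_seg_end > 0.72 * config$chrom_length)
    stop("make_annotation: chromosome too short for requested genes; need >= ",
         ceiling(gene_seg_end / 0.72), " bp")

  rows <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    ci <- ((g - 1L) %% config$n_chroms) + 1L
    si <- (g - 1L) %/% config$n_chroms          # slot index on that chrom
    slot_start <- si * slot + 1000L
    strand <- sample(c("+", "-"), 1)
    n_ex <- sample(2:4, 1)
    w <- round(runif(n_ex, 150, 500))
    gaps <- if (n_ex > 1) round(runif(n_ex - 1, 200, 800)) else integer()
    anchor <- slot_start + 2000L + sample.int(200L, 1)
    starts <- anchor + cumsum(c(0L, head(w, -1) + gaps))
    ends <- starts + w
    rows[[g]] <- data.frame(
      gene_id = sprintf("G%04d", g), chrom = chroms[ci], strand = strand,
      tx_start = starts[1], tx_end = ends[n_ex],
      exon_starts = paste(starts, collapse = ","),
      exon_ends = paste(ends, collapse = ","), stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)
  validate_gene_models(genes)

  cgi_genes <- sort(sample.int(config$n_genes, config$n_cgis))
  tss <- gene_tss(genes)[cgi_genes, ]
  plus <- tss$strand == "+"
  cgis <- data.frame(chrom = tss$chrom,
                     start = as.integer(ifelse(plus, tss$start - 150L,
                                               tss$start - 249L)),
                     end = as.integer(ifelse(plus, tss$start + 250L,
                                             tss$start + 151L)),
                     strand = ".",
                     name = paste0("CGI_", tss$gene_id),
                     gene_id = tss$gene_id, stringsAsFactors = FALSE)
  validate_intervals(cgis, "cgis")

  subtype_pool <- list(
    LINE = c("L1MA4", "L1MB7", "L2a"),
    SINE = c("AluJo", "AluSx", "MIRc"),
    LTR = c("MLT1A", "ERVL-E"),
    Simple_repeat = c("(TA)n", "(CA)n"),
    Low_complexity = c("A-rich"), Satellite = c("ALR"), DNA = c("MER5A"),
    Other = c("Unknown"))
  family_of <- c(LINE = "L1", SINE = "Alu", LTR = "ERVL-MaLR",
                 Simple_repeat = "Simple_repeat",
                 Low_complexity = "Low_complexity", Satellite = "centr",
                 DNA = "hAT", Other = "Other")
  len_range <- list(LINE = c(1000, 3000), SINE = c(150, 350),
                    LTR = c(300, 800), Simple_repeat = c(60, 150),
                    Low_complexity = c(60, 150), Satellite = c(200, 600),
                    DNA = c(200, 600), Other = c(200, 600))
  rep_rows <- list()
  cursor <- setNames(rep(gene_seg_end + 5L * config$flank_bp,
                         config$n_chroms), chroms)
  classes <- rep(names(config$n_repeats), config$n_repeats)
  if (length(classes)) classes <- sample(classes)   # interleave classes
  spacing <- 2L * config$flank_bp + 50L
  for (i in seq_along(classes)) {
    cls <- classes[i]
    ci <- ((i - 1L) %% config$n_chroms) + 1L
    rng <- len_range[[cls]]
    len <- round(runif(1, rng[1], rng[2]))
    start <- cursor[ci]
    end <- start + len
    if (end + config$flank_bp > config$chrom_length)
      stop("make_annotation: chromosome too short for requested repeats; ",
           "need >= ", end + config$flank_bp, " bp")
    cursor[ci] <- end + spacing
    rep_rows[[i]] <- data.frame(
      chrom = chroms[ci], start = as.integer(start), end = as.integer(end),
      strand = sample(c("+", "-"), 1),
      rep_name = sample(subtype_pool[[cls]], 1),
      rep_class = cls, rep_family = family_of[[cls]],
      stringsAsFactors = FALSE)
  }
  repeats <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), rep_name = character(),
               rep_class = character(), rep_family = character(),
               stringsAsFactors = FALSE)
  list(genes = genes, cgis = cgis, repeats = repeats,
       chrom_lengths = chrom_lengths, config = config)
}

# sample n dyad anchor positions inside an interval set, width-weighted
.sample_positions <- function(iv, n) {
  iv <- iv[iv$end - iv$start >= 3, , drop = FALSE]
  if (!nrow(iv) || n <= 0)
    return(data.frame(chrom = character(), pos = integer()))
  w <- iv$end - iv$start - 1L
  pick <- sample.int(nrow(iv), n, replace = TRUE, prob = w)
  off <- floor(runif(n) * (w[pick] - 1L))
  data.frame(chrom = iv$chrom[pick], pos = iv$start[pick] + as.integer(off),
             stringsAsFactors = FALSE)
}

.complement <- function(occupied, chrom_lengths) {
  genome <- GenomicRanges::GRanges(
    names(chrom_lengths),
    IRanges::IRanges(1L, unname(chrom_lengths)))
  gaps <- GenomicRanges::setdiff(genome, GenomicRanges::reduce(
    .gr(occupied), ignore.strand = TRUE), ignore.strand = TRUE)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gaps)),
             start = GenomicRanges::start(gaps) - 1L,
             end = GenomicRanges::end(gaps), strand = ".",
             stringsAsFactors = FALSE)
}

#' Simulate one WGBS methylome per region
#'
#' CpG dyads are placed in five compartments (promoter CGIs, gene
#' bodies, intergenic space, repeat interiors, repeat flanks) with
#' compartment-specific latent methylation levels drawn from Beta
#' distributions; the latent level of a site is shared across regions
#' except at planted differential sites, where one region of a sampled
#' pair is shifted by `planted_dms_delta`, and in the CGIs of
#' correlation-planted genes, which receive a per-region methylation
#' profile spread over `[0.15, 0.85]`. Read depth is negative-binomial
#' per site and region; methylated counts are binomial in the latent
#' level. Repeat interiors of profiled classes carry positional shapes
#' (edge-high for LINE-like, center-high for SINE-like elements).
#'
#' @param annotation Output of [make_annotation()].
#' @param config The same [sim_config()].
#' @return List with `regions` (named list of per-region site tables),
#'   `truth` (list: `dms` — planted dyads with `pos` the anchor
#'   (plus-strand) cytosine, the position merged sites carry after
#'   [merge_dyads()]; `correlated_cgis`; `site_compartments`) and
#'   `config`.
#' @export
simulate_methylomes <- function(annotation, config = annotation$config) {
  set.seed(config$seed + 2L)
  genes <- annotation$genes; cgis <- annotation$cgis
  repeats <- annotation$repeats
  fl <- config$flank_bp
  n_dyads <- config$n_cpg_sites %/% 2L

  alloc <- c(cgi_promoter = 0.15, gene_body = 0.25, intergenic = 0.25,
             repeat_inner = 0.25, repeat_flank = 0.10)
  if (!nrow(repeats)) {
    alloc["intergenic"] <- alloc[["intergenic"]] + alloc[["repeat_inner"]] +
      alloc[["repeat_flank"]]
    alloc["repeat_inner"] <- alloc["repeat_flank"] <- 0
  }
  if (!nrow(cgis)) {
    alloc["intergenic"] <- alloc[["intergenic"]] + alloc[["cgi_promoter"]]
    alloc["cgi_promoter"] <- 0
  }
  n_per <- round(alloc * n_dyads)

  bodies <- data.frame(chrom = genes$chrom, start = genes$tx_start,
                       end = genes$tx_end, strand = ".")
  flanks <- if (nrow(repeats)) data.frame(
    chrom = rep(repeats$chrom, 2),
    start = c(pmax(repeats$start - fl, 0L), repeats$end),
    end = c(repeats$start, repeats$end + fl), strand = ".") else
    bodies[0, ]
  occupied <- rbind(bodies[, c("chrom", "start", "end", "strand")],
                    promoter_of(genes)[, c("chrom", "start", "end", "strand")],
                    cgis[, c("chrom", "start", "end", "strand")],
                    if (nrow(repeats))
                      repeats[, c("chrom", "start", "end", "strand")],
                    if (nrow(flanks)) flanks)
  interg <- .complement(occupied, annotation$chrom_lengths)

  comp_iv <- list(cgi_promoter = cgis, gene_body = bodies,
                  intergenic = interg, repeat_inner = repeats,
                  repeat_flank = flanks)
  dy <- do.call(rbind, lapply(names(n_per), function(cp) {
    d <- .sample_positions(comp_iv[[cp]], n_per[[cp]])
    if (nrow(d)) d$compartment <- cp
    d
  }))
  # gene-body draws that land inside a CGI belong to the CGI compartment
  if (nrow(cgis)) {
    incgi <- S4Vectors::queryHits(GenomicRanges::findOverlaps(
      .gr_sites(dy), .gr(cgis), ignore.strand = TRUE))
    dy$compartment[incgi] <- "cgi_promoter"
  }
  dy <- dy[!duplicated(paste(dy$chrom, dy$pos)), , drop = FALSE]
  dy <- dy[order(dy$chrom, dy$pos), , drop = FALSE]
  rownames(dy) <- NULL

  # latent beta per dyad
  bp <- config$beta_params
  nd <- nrow(dy)
  beta <- numeric(nd)
  for (cp in names(comp_iv)) {
    sel <- dy$compartment == cp
    if (any(sel))
      beta[sel] <- rbeta(sum(sel), bp[[cp]][1], bp[[cp]][2])
  }
  # positional shapes inside profiled repeat classes
  if (nrow(repeats) && length(config$repeat_profile)) {
    ov <- GenomicRanges::findOverlaps(.gr_sites(dy), .gr(repeats),
                                      ignore.strand = TRUE)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    for (cls in names(config$repeat_profile)) {
      shape <- config$repeat_profile[[cls]]
      in_cls <- repeats$rep_class[sh] == cls
      if (!any(in_cls)) next
      q <- qh[in_cls]; s <- sh[in_cls]
      rel <- (dy$pos[q] - repeats$start[s]) /
        pmax(repeats$end[s] - repeats$start[s], 1L)
      edge <- rel < 1 / 3 | rel >= 2 / 3
      m <- if (shape == "edge_high")
        ifelse(edge, config$profile_high, config$profile_low)
      else ifelse(edge, config$profile_low, config$profile_high)
      conc <- 50
      beta[q] <- rbeta(length(q), m * conc, (1 - m) * conc)
    }
  }

  regions <- .region_names(config)
  beta_mat <- matrix(beta, nrow = nd, ncol = config$n_regions,
                     dimnames = list(NULL, regions))

  # correlation-planted CGIs: per-region methylation profiles
  n_corr <- config$n_planted_corr_pos + config$n_planted_corr_neg
  corr_truth <- NULL
  corr_dyads <- logical(nd)
  if (n_corr > 0 && nrow(cgis)) {
    corr_rows <- sample.int(nrow(cgis), n_corr)
    prof <- matrix(NA_real_, n_corr, config$n_regions,
                   dimnames = list(cgis$gene_id[corr_rows], regions))
    base_prof <- seq(0.15, 0.85, length.out = config$n_regions)
    ovc <- GenomicRanges::findOverlaps(
      .gr_sites(dy), .gr(cgis[corr_rows, , drop = FALSE]),
      ignore.strand = TRUE)
    for (i in seq_len(n_corr)) {
      prof[i, ] <- sample(base_prof)
      q <- S4Vectors::queryHits(ovc)[S4Vectors::subjectHits(ovc) == i]
      if (!length(q)) next
      corr_dyads[q] <- TRUE
      jit <- rnorm(length(q), 0, 0.02)
      for (r in seq_len(config$n_regions))
        beta_mat[q, r] <- pmin(pmax(prof[i, r] + jit, 0.02), 0.98)
    }
    corr_truth <- list(
      cgis = data.frame(gene_id = cgis$gene_id[corr_rows],
                        cgi_chrom = cgis$chrom[corr_rows],
                        cgi_start = cgis$start[corr_rows],
                        cgi_end = cgis$end[corr_rows],
                        stringsAsFactors = FALSE),
      profiles = prof)
  }

  # planted differential dyads (both strands share the shifted level)
  dms_truth <- NULL
  if (config$n_planted_dms > 0) {
    eligible <- which(!corr_dyads)
    if (config$n_planted_dms > length(eligible))
      stop("simulate_methylomes: n_planted_dms exceeds available CpG dyads")
    picked <- sort(sample(eligible, config$n_planted_dms))
    pair_idx <- matrix(sample.int(config$n_regions,
                                  2L * config$n_planted_dms, replace = TRUE),
                       ncol = 2)
    same <- pair_idx[, 1] == pair_idx[, 2]
    while (any(same)) {
      pair_idx[same, 2] <- sample.int(config$n_regions, sum(same),
                                      replace = TRUE)
      same <- pair_idx[, 1] == pair_idx[, 2]
    }
    base <- beta_mat[cbind(picked, pair_idx[, 2])]
    dir <- ifelse(base < 0.5, 1, -1)          # shift away from the boundary
    shifted <- base + dir * config$planted_dms_delta
    clipped <- shifted < 0.02 | shifted > 0.98
    if (any(clipped)) {
      warning(sum(clipped),
              " planted DMS level(s) clipped to [0.02, 0.98]")
      shifted <- pmin(pmax(shifted, 0.02), 0.98)
    }
    beta_mat[cbind(picked, pair_idx[, 2])] <- shifted
    dms_truth <- data.frame(
      chrom = dy$chrom[picked], pos = dy$pos[picked],
      region_a = regions[pair_idx[, 1]], region_b = regions[pair_idx[, 2]],
      direction = ifelse(dir > 0, "hyper", "hypo"),
      beta_base = base, beta_shifted = shifted, stringsAsFactors = FALSE)
  }

  # expand dyads to cytosines: + at pos, - at pos + 1
  cyto <- data.frame(
    chrom = rep(dy$chrom, each = 2),
    pos = as.integer(rep(dy$pos, each = 2) + c(0L, 1L)),
    strand = rep(c("+", "-"), nd),
    context = "CpG",
    compartment = rep(dy$compartment, each = 2),
    stringsAsFactors = FALSE)
  cbeta <- beta_mat[rep(seq_len(nd), each = 2), , drop = FALSE]
  c_corr <- rep(corr_dyads, each = 2)

  # non-CpG cytosines at low methylation
  n_noncpg <- round(config$noncpg_fraction * config$n_cpg_sites)
  if (n_noncpg > 0) {
    np <- .sample_positions(
      data.frame(chrom = names(annotation$chrom_lengths), start = 0L,
                 end = unname(annotation$chrom_lengths), strand = "."),
      n_noncpg)
    np <- np[!duplicated(paste(np$chrom, np$pos)), , drop = FALSE]
    np <- np[!(paste(np$chrom, np$pos) %in%
                 paste(cyto$chrom, cyto$pos)), , drop = FALSE]
    nc <- data.frame(chrom = np$chrom, pos = np$pos,
                     strand = sample(c("+", "-"), nrow(np), replace = TRUE),
                     context = sample(c("CHG", "CHH"), nrow(np),
                                      replace = TRUE),
                     compartment = "noncpg", stringsAsFactors = FALSE)
    ncb <- rbeta(nrow(np), config$noncpg_beta[1], config$noncpg_beta[2])
    cyto <- rbind(cyto, nc)
    cbeta <- rbind(cbeta, matrix(ncb, nrow(np), config$n_regions))
    c_corr <- c(c_corr, rep(FALSE, nrow(np)))
  }
  ncyto <- nrow(cyto)

  out_regions <- setNames(vector("list", config$n_regions), regions)
  for (r in seq_len(config$n_regions)) {
    depth <- rnbinom(ncyto, size = config$depth_size, mu = config$depth_mean)
    n_meth <- rbinom(ncyto, depth, cbeta[, r])
    df <- data.frame(chrom = cyto$chrom, pos = cyto$pos,
                     strand = cyto$strand, context = cyto$context,
                     n_meth = n_meth, n_unmeth = depth - n_meth,
                     stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$pos, df$strand), , drop = FALSE]
    rownames(df) <- NULL
    out_regions[[r]] <- df
  }

  list(regions = out_regions,
       truth = list(dms = dms_truth, correlated_cgis = corr_truth,
                    site_compartments = cyto),
       config = config)
}

#' Simulate the matched expression matrix
#'
#' Baseline log2 expression is normal per gene with independent
#' per-region noise. Cluster-planted genes (disjoint from
#' correlation-planted genes) receive `+cluster_effect_size` in exactly
#' one region, `cluster_genes_per_region` genes per region.
#' Correlation-planted genes follow
#' `log2 expr = a + slope_sign * (CGI methylation profile) + noise`,
#' with the noise variance calibrated so the true correlation magnitude
#' is `corr_strength`. Values are exponentiated to an FPKM-like scale.
#'
#' @param annotation Output of [make_annotation()].
#' @param config The same [sim_config()].
#' @param methylomes Output of [simulate_methylomes()] (supplies the
#'   planted CGI methylation profiles).
#' @return List with `expr` (gene x region matrix), `truth` (list:
#'   `clusters`, `correlated`) and `config`.
#' @export
simulate_expression <- function(annotation, config = annotation$config,
                                methylomes) {
  set.seed(config$seed + 3L)
  gene_ids <- annotation$genes$gene_id
  regions <- .region_names(config)
  n <- length(gene_ids)
  mu <- rnorm(n, config$baseline_mean, config$baseline_sd)
  l <- matrix(mu, n, config$n_regions) +
    matrix(rnorm(n * config$n_regions, 0, config$region_noise_sd),
           n, config$n_regions)
  dimnames(l) <- list(gene_ids, regions)

  corr <- methylomes$truth$correlated_cgis
  corr_genes <- if (is.null(corr)) character() else corr$cgis$gene_id

  n_cluster <- config$cluster_genes_per_region * config$n_regions
  pool <- setdiff(gene_ids, corr_genes)
  if (n_cluster > length(pool))
    stop("simulate_expression: not enough genes for the requested clusters")
  cluster_genes <- sample(pool, n_cluster)
  cluster_region <- rep(regions, each = config$cluster_genes_per_region)
  for (i in seq_len(n_cluster))
    l[cluster_genes[i], cluster_region[i]] <-
      l[cluster_genes[i], cluster_region[i]] + config$cluster_effect_size

  corr_truth <- NULL
  if (length(corr_genes)) {
    sign_vec <- rep(c(1, -1), c(config$n_planted_corr_pos,
                                config$n_planted_corr_neg))
    slopes <- sign_vec * config$corr_slope
    for (i in seq_along(corr_genes)) {
      p <- corr$profiles[i, ]
      s_noise <- abs(slopes[i]) * sd(p) *
        sqrt(1 / config$corr_strength^2 - 1)
      l[corr_genes[i], ] <- mu[match(corr_genes[i], gene_ids)] +
        slopes[i] * (p - mean(p)) + rnorm(config$n_regions, 0, s_noise)
    }
    corr_truth <- data.frame(
      gene_id = corr_genes,
      sign = ifelse(sign_vec > 0, "positive", "negative"),
      slope = slopes,
      corr$cgis[, c("cgi_chrom", "cgi_start", "cgi_end")],
      stringsAsFactors = FALSE)
  }

  expr <- 2^l
  list(expr = expr,
       truth = list(
         clusters = data.frame(gene_id = cluster_genes,
                               region = cluster_region,
                               stringsAsFactors = FALSE),
         correlated = corr_truth),
       config = config)
}

#' Generate a complete synthetic dataset
#'
#' Runs [make_annotation()], [simulate_methylomes()] and
#' [simulate_expression()] and optionally writes every artifact to
#' `out_dir`: `genes.tsv`, `cgis.bed`, `rmsk.tsv`, `expr.tsv`, one
#' `calls_<region>.tsv` cytosine report per region, truth tables under
#' `truth/`, and the resolved configuration (`config.tsv`).
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory, or `NULL` for in-memory only.
#' @return List with `annotation`, `methylomes`, `expression`, `paths`
#'   (when written).
#' @export
simulate_dataset <- function(config = sim_config(), out_dir = NULL) {
  ann <- make_annotation(config)
  met <- simulate_methylomes(ann, config)
  ex <- simulate_expression(ann, config, met)
  paths <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
    p <- list(genes = file.path(out_dir, "genes.tsv"),
              cgis = file.path(out_dir, "cgis.bed"),
              rmsk = file.path(out_dir, "rmsk.tsv"),
              expr = file.path(out_dir, "expr.tsv"),
              config = file.path(out_dir, "config.tsv"))
    write_gene_models(ann$genes, p$genes)
    write_bed(ann$cgis, p$cgis)
    write_rmsk(ann$repeats, p$rmsk)
    write_expression(ex$expr, p$expr)
    p$calls <- setNames(file.path(out_dir,
                                  paste0("calls_", names(met$regions),
                                         ".tsv")),
                        names(met$regions))
    for (r in names(met$regions))
      write_cytosine_report(met$regions[[r]], p$calls[[r]])
    if (!is.null(met$truth$dms))
      data.table::fwrite(met$truth$dms,
                         file.path(out_dir, "truth", "dms.tsv"), sep = "\t")
    if (!is.null(ex$truth$clusters))
      data.table::fwrite(ex$truth$clusters,
                         file.path(out_dir, "truth", "clusters.tsv"),
                         sep = "\t")
    if (!is.null(ex$truth$correlated))
      data.table::fwrite(ex$truth$correlated,
                         file.path(out_dir, "truth", "correlated.tsv"),
                         sep = "\t")
    flat <- unlist(config)
    data.table::fwrite(data.frame(key = names(flat),
                                  value = as.character(flat),
                                  stringsAsFactors = FALSE),
                       p$config, sep = "\t")
    paths <- p
  }
  list(annotation = ann, methylomes = met, expression = ex, paths = paths)
}

#' Simulate a focused correlation-screen study
#'
#' Generates `n_genes` pseudo promoter-CGI methylation vectors over
#' `n_regions` regions and matching expression vectors: planted genes
#' are coupled at true correlation magnitude `corr_strength` with the
#' requested sign, the rest are independent of methylation. Intended
#' for power/size studies of [pearson_screen()].
#'
#' @param n_genes Total genes (default 1000).
#' @param n_pos,n_neg Planted positive/negative genes (defaults 50/50).
#' @param corr_strength True |r| of planted genes (default 0.95).
#' @param n_regions Number of regions (default 7).
#' @param seed Integer seed.
#' @return List with `pairs`, `meth`, `expr` (ready for
#'   [pearson_screen()]) and `truth` (`data.frame` of gene, status).
#' @export
simulate_correlation_study <- function(n_genes = 1000, n_pos = 50,
                                       n_neg = 50, corr_strength = 0.95,
                                       n_regions = 7, seed = 101) {
  set.seed(seed)
  gene_ids <- sprintf("G%04d", seq_len(n_genes))
  meth <- matrix(runif(n_genes * n_regions, 0.1, 0.9), n_genes, n_regions,
                 dimnames = list(gene_ids,
                                 paste0("region_", seq_len(n_regions))))
  status <- rep("null", n_genes)
  status[seq_len(n_pos)] <- "positive"
  status[n_pos + seq_len(n_neg)] <- "negative"
  slope <- ifelse(status == "positive", 4, ifelse(status == "negative",
                                                  -4, 0))
  expr <- matrix(rnorm(n_genes * n_regions, 3, 1), n_genes, n_regions,
                 dimnames = dimnames(meth))
  for (i in which(status != "null")) {
    s_noise <- abs(slope[i]) * sd(meth[i, ]) *
      sqrt(1 / corr_strength^2 - 1)
    expr[i, ] <- 3 + slope[i] * (meth[i, ] - mean(meth[i, ])) +
      rnorm(n_regions, 0, s_noise)
  }
  expr <- 2^expr
  pairs <- data.frame(cgi_index = seq_len(n_genes),
                      cgi_chrom = "chr1",
                      cgi_start = (seq_len(n_genes) - 1L) * 1000L,
                      cgi_end = (seq_len(n_genes) - 1L) * 1000L + 500L,
                      gene_id = gene_ids, stringsAsFactors = FALSE)
  list(pairs = pairs, meth = meth, expr = expr,
       truth = data.frame(gene_id = gene_ids, status = status,
                          stringsAsFactors = FALSE))
}
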