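#' Pipeline configuration
#'
#' Bundles the input paths and thresholds of a full run. Unknown keys
#' are rejected, every threshold is checked against its documented
#' domain, and the resolved configuration (defaults filled in) is
#' written back alongside the outputs by [run_all()].
#'
#' @param calls Named character vector of per-region cytosine-report
#'   paths (names are the region labels).
#' @param genes,cgis,rmsk,expr Paths to the gene-model TSV, CGI BED,
#'   repeat table (UCSC dialect) and expression TSV.
#' @param out_dir Output directory.
#' @param min_depth Site depth cutoff (default 10).
#' @param dms_q DMS q-value threshold (default 0.05).
#' @param dmg_q Stricter q-value threshold used for the reported DMG
#'   set (default 0.01).
#' @param corr_p Correlation-screen p threshold (default 0.05).
#' @param fc Expression fold-change filter (default 4).
#' @param k Number of PAM clusters (default 7).
#' @param flank_bp Repeat flank width (default 100).
#' @param merge_dyads Merge CpG dyad strands before analysis (default
#'   `FALSE`).
#' @param bh_on_screen Add BH q-values to the correlation screen
#'   (default `FALSE`).
#' @param tolerant_io Drop malformed cytosine-report lines instead of
#'   failing (default `FALSE`).
#' @param seed Seed recorded in output headers (the pipeline itself is
#'   deterministic).
#' @return A validated list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(calls, genes, cgis, rmsk, expr, out_dir,
                            min_depth = 10, dms_q = 0.05, dmg_q = 0.01,
                            corr_p = 0.05, fc = 4, k = 7, flank_bp = 100,
                            merge_dyads = FALSE, bh_on_screen = FALSE,
                            tolerant_io = FALSE, seed = 101L) {
  stopifnot(length(calls) >= 2, !is.null(names(calls)),
            min_depth >= 1, dms_q > 0, dms_q <= 1, dmg_q > 0, dmg_q <= 1,
            corr_p > 0, corr_p <= 1, fc > 1, k >= 1, flank_bp >= 1)
  cfg <- list(calls = calls, genes = genes, cgis = cgis, rmsk = rmsk,
              expr = expr, out_dir = out_dir, min_depth = min_depth,
              dms_q = dms_q, dmg_q = dmg_q, corr_p = corr_p, fc = fc,
              k = k, flank_bp = flank_bp, merge_dyads = merge_dyads,
              bh_on_screen = bh_on_screen, tolerant_io = tolerant_io,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

.config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  flat <- unlist(config[setdiff(names(config), "out_dir")])
  writeLines(paste(names(flat), as.character(flat), sep = "="), f)
  unname(tools::md5sum(f))
}

.provenance <- function(config) {
  sprintf("# methexpress %s; config=%s; seed=%d",
          as.character(packageVersion("methexpress")),
          .config_hash(config), config$seed)
}

.write_stage <- function(df, path, header) {
  con <- file(path, "w")
  writeLines(header, con)
  close(con)
  data.table::fwrite(df, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Pre-flight validation of pipeline inputs
#'
#' Reports per-file row counts and chromosome namespaces, and flags
#' namespace mismatches between the methylation calls and each
#' annotation, before any computation.
#'
#' @param config A [pipeline_config()].
#' @return List with `counts` (named row counts), `chromosomes` (named
#'   list of namespaces) and `issues` (character vector; empty when
#'   consistent).
#' @export
validate_inputs <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  issues <- character()
  for (p in c(config$calls, config$genes, config$cgis, config$rmsk,
              config$expr))
    if (!file.exists(p)) issues <- c(issues, paste0("missing file: ", p))
  if (length(issues))
    return(list(counts = NULL, chromosomes = NULL, issues = issues))
  calls1 <- read_cytosine_report(config$calls[[1]],
                                 tolerant = config$tolerant_io)
  genes <- read_gene_models(config$genes)
  cgis <- read_bed(config$cgis)
  rmsk <- read_rmsk(config$rmsk, dialect = "ucsc_table")
  expr <- read_expression(config$expr)
  counts <- c(calls = nrow(calls1), genes = nrow(genes), cgis = nrow(cgis),
              repeats = nrow(rmsk), expression_genes = nrow(expr))
  chroms <- list(calls = sort(unique(calls1$chrom)),
                 genes = sort(unique(genes$chrom)),
                 cgis = sort(unique(cgis$chrom)),
                 repeats = sort(unique(rmsk$chrom)))
  for (nm in c("genes", "cgis", "repeats")) {
    if (!length(intersect(chroms$calls, chroms[[nm]])))
      issues <- c(issues, paste0("chromosome namespace mismatch between ",
                                 "calls and ", nm, " (e.g. '",
                                 chroms$calls[1], "' vs '",
                                 chroms[[nm]][1], "')"))
  }
  if (nrow(expr) == 0) issues <- c(issues, "expression table has zero rows")
  if (!all(names(config$calls) %in% colnames(expr)))
    issues <- c(issues, "expression columns do not cover all call regions")
  list(counts = counts, chromosomes = chroms, issues = issues)
}

#' Run the full integration pipeline
#'
#' Executes, in order: per-region methylome classification and
#' level-bin summaries; pairwise differential methylation with the DMS
#' count matrix and DMG calling (at both `dms_q` and the stricter
#' `dmg_q`); expression normalization, fold-change filtering, PAM
#' clustering and region-cluster assignment; the promoter-CGI
#' methylation/expression correlation screen with BRSG/DMG
#' categorization; and repeat-element statistics (CGI split, inner/outer
#' flank statistics and metaprofiles per class, subtype summary). Every
#' output file starts with a provenance header (package version, config
#' hash, seed) and a run manifest lists each file with its MD5 digest.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results and
#'   `manifest` (`data.frame` of file, md5).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  v <- validate_inputs(config)
  if (length(v$issues))
    stop("pre-flight validation failed:\n  ",
         paste(v$issues, collapse = "\n  "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  hdr <- .provenance(config)
  written <- character()
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    .write_stage(df, p, hdr)
    written <<- c(written, p)
    p
  }

  genes <- read_gene_models(config$genes)
  cgis <- read_bed(config$cgis)
  rmsk <- read_rmsk(config$rmsk, dialect = "ucsc_table")
  expr <- read_expression(config$expr)
  regions <- names(config$calls)

  # stage 1: methylome
  message("[methylome] reading and classifying ", length(regions),
          " region(s)")
  raw <- lapply(config$calls, read_cytosine_report,
                tolerant = config$tolerant_io)
  if (config$merge_dyads) raw <- lapply(raw, merge_dyads)
  filtered <- lapply(raw, filter_by_depth, min_depth = config$min_depth)
  message("[methylome] sites in/out of depth filter: ",
          paste(vapply(raw, nrow, 0L), collapse = "/"), " -> ",
          paste(vapply(filtered, nrow, 0L), collapse = "/"))
  promoters <- promoter_of(genes)
  summaries <- do.call(rbind, lapply(regions, function(r) {
    cls <- classify_sites(filtered[[r]], genes, promoters)
    s <- level_bin_proportions(cls, by = c("feature", "context_group"))
    cbind(sample = r, s)
  }))
  emit(summaries, "methylome_summary.tsv")

  # stage 2: differential
  message("[differential] ", choose(length(regions), 2), " region pair(s)")
  cpg <- lapply(filtered, function(s) s[s$context == "CpG", , drop = FALSE])
  dms_all <- list()
  n <- length(regions)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- call_dms(cpg[[regions[i]]], cpg[[regions[j]]],
                  q_threshold = config$dms_q)
    d$pair <- paste0(regions[i], "|", regions[j])
    dms_all[[d$pair[1]]] <- d
  }
  pooled <- do.call(rbind, dms_all)
  counts <- vapply(dms_all, function(d) sum(d$direction != "ns"), 0L)
  cm <- matrix(0L, n, n, dimnames = list(regions, regions))
  for (nm in names(counts)) {
    ij <- strsplit(nm, "|", fixed = TRUE)[[1]]
    cm[ij[1], ij[2]] <- cm[ij[2], ij[1]] <- counts[[nm]]
  }
  emit(as.data.frame(cbind(region = rownames(cm), as.data.frame(cm))),
       "dms_counts.tsv")
  sig <- pooled[pooled$direction != "ns", , drop = FALSE]
  emit(sig, "dms_significant.tsv")
  dmgs <- call_dmgs(sig, cgis, genes)
  emit(dmgs, "dmgs.tsv")
  sig_strict <- pooled[pooled$q_value <= config$dmg_q &
                         pooled$direction != "ns", , drop = FALSE]
  dmgs_strict <- call_dmgs(sig_strict, cgis, genes,
                           q_threshold = config$dmg_q)
  emit(dmgs_strict, "dmgs_strict.tsv")
  message("[differential] significant sites: ", nrow(sig), "; DMGs: ",
          nrow(dmgs), " (strict: ", nrow(dmgs_strict), ")")

  # stage 3: expression
  expr <- expr[, regions, drop = FALSE]
  norm <- tmm_normalize(expr)
  kept <- fold_change_filter(norm, fc = config$fc)
  message("[expression] fold-change filter kept ", length(kept), "/",
          nrow(norm), " genes")
  z <- log_z_capped(norm[kept, , drop = FALSE])
  pam <- pam_cluster(z, k = config$k)
  rc <- assign_region_clusters(pam, z)
  emit(data.frame(gene_id = names(pam$cluster),
                  cluster = as.integer(pam$cluster),
                  is_medoid = names(pam$cluster) %in% pam$medoids),
       "clusters.tsv")
  emit(data.frame(region = names(rc$region_cluster),
                  cluster = as.integer(rc$region_cluster)),
       "region_clusters.tsv")
  emit(data.frame(gene_id = kept), "filtered_genes.tsv")

  # stage 4: integration
  pairs <- cgi_promoter_pairs(cgis, genes)
  meth <- cgi_median_methylation(cgis, cpg)
  screen <- pearson_screen(pairs, meth, norm, p_threshold = config$corr_p,
                           bh = config$bh_on_screen)
  cat_out <- categorize_correlations(screen, rc$brsg, dmgs)
  message("[integration] ", nrow(pairs), " CGI-promoter pairs; ",
          nrow(screen), " significant at p <= ", config$corr_p)
  emit(cat_out$records, "correlations.tsv")
  emit(cat_out$summary, "correlation_summary.tsv")

  # stage 5: repeats
  split_sets <- split_by_cgi(rmsk, cgis)
  message("[repeats] ", nrow(split_sets$with_cgi), " elements with CGI, ",
          nrow(split_sets$without_cgi), " without")
  io_stats <- do.call(rbind, lapply(split(rmsk, rmsk$rep_class),
                                    function(cl) {
    s <- do.call(rbind, lapply(regions, function(r) {
      cbind(region = r,
            inner_outer_stats(cl, cpg[[r]], flank_bp = config$flank_bp,
                              exclude = rmsk))
    }))
    cbind(rep_class = cl$rep_class[1], s)
  }))
  emit(io_stats, "repeat_inner_outer.tsv")
  profiles <- do.call(rbind, lapply(split(rmsk, rmsk$rep_class),
                                    function(cl) {
    pooled_sites <- do.call(rbind, cpg)
    pr <- metaprofile(cl, pooled_sites, flank_bp = config$flank_bp)
    cbind(rep_class = cl$rep_class[1], pr)
  }))
  emit(profiles, "repeat_metaprofiles.tsv")
  pooled_sites <- do.call(rbind, cpg)
  emit(subtype_summary(rmsk, pooled_sites), "repeat_subtypes.tsv")

  # resolved config + manifest
  flat <- unlist(config[setdiff(names(config), "out_dir")])
  cfg_path <- file.path(config$out_dir, "config_resolved.tsv")
  data.table::fwrite(data.frame(key = names(flat),
                                value = as.character(flat),
                                stringsAsFactors = FALSE),
                     cfg_path, sep = "\t")
  written <- c(written, cfg_path)
  manifest <- data.frame(file = basename(written),
                         md5 = unname(tools::md5sum(written)),
                         stringsAsFactors = FALSE)
  data.table::fwrite(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t")
  invisible(list(dms_counts = cm, dmgs = dmgs, dmgs_strict = dmgs_strict,
                 clusters = pam, region_clusters = rc,
                 correlations = cat_out$records,
                 correlation_summary = cat_out$summary,
                 inner_outer = io_stats, manifest = manifest))
}
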