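# small config keeps the generator fast in unit tests
small_cfg <- function(seed = 11, n_cpg_sites = 6000, ...) {
  sim_config(seed = seed, n_genes = 60, n_cgis = 40,
             n_cpg_sites = n_cpg_sites,
             n_repeats = c(LINE = 10, SINE = 10, LTR = 10),
             n_planted_dms = 40, n_planted_corr_pos = 3,
             n_planted_corr_neg = 2, cluster_genes_per_region = 5, ...)
}

test_that("configuration validation rejects impossible designs", {
  expect_error(sim_config(n_cgis = 400, n_genes = 300), "n_cgis")
  expect_error(sim_config(n_planted_corr_pos = 300, n_cgis = 200,
                          n_genes = 300), "correlated")
  expect_error(sim_config(beta_params = list(cgi_promoter = c(0, 9),
                                             gene_body = c(8, 2),
                                             intergenic = c(8, 2),
                                             repeat_inner = c(8, 2),
                                             repeat_flank = c(9, 1.5))),
               "Beta")
  expect_error(sim_config(n_regions = 1), "regions")
  expect_error(make_annotation(sim_config(chrom_length = 1e5)),
               "too short")
})

test_that("annotation satisfies the generator's structural guarantees", {
  ann <- make_annotation(small_cfg())
  g <- ann$genes
  expect_equal(nrow(g), 60L)
  expect_true(all(lengths(strsplit(g$exon_starts, ",")) >= 2))
  # genes do not overlap within a chromosome
  for (ch in split(g, g$chrom)) {
    ch <- ch[order(ch$tx_start), ]
    expect_true(all(ch$tx_start[-1] >= ch$tx_end[-nrow(ch)]))
  }
  # every CGI overlaps its gene's promoter AND first exon
  fe <- gene_first_exon(g)
  pr <- promoter_of(g)
  for (i in seq_len(nrow(ann$cgis))) {
    cgi <- ann$cgis[i, ]
    fei <- fe[fe$gene_id == cgi$gene_id, ]
    pri <- pr[pr$gene_id == cgi$gene_id, ]
    expect_true(cgi$start < fei$end && cgi$end > fei$start)
    expect_true(cgi$start < pri$end && cgi$end > pri$start)
  }
  # repeats spaced by >= 2 * flank_bp
  r <- ann$repeats
  for (ch in split(r, r$chrom)) {
    ch <- ch[order(ch$start), ]
    if (nrow(ch) > 1)
      expect_true(all(ch$start[-1] - ch$end[-nrow(ch)] >=
                        2 * ann$config$flank_bp))
  }
  # zero repeats still emits a parseable empty table
  cfg0 <- sim_config(n_repeats = c(LINE = 0), n_genes = 60, n_cgis = 10,
                     n_cpg_sites = 2000, n_planted_dms = 0,
                     n_planted_corr_pos = 0, n_planted_corr_neg = 0,
                     cluster_genes_per_region = 2)
  ann0 <- make_annotation(cfg0)
  f <- withr::local_tempfile()
  write_rmsk(ann0$repeats, f)
  expect_equal(nrow(read_rmsk(f, dialect = "ucsc_table")), 0L)
})

test_that("identical config and seed give byte-identical outputs", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  cfg <- small_cfg()
  suppressWarnings(simulate_dataset(cfg, out_dir = d1))
  suppressWarnings(simulate_dataset(cfg, out_dir = d2))
  f <- sort(list.files(d1, recursive = TRUE))
  expect_identical(unname(tools::md5sum(file.path(d1, f))),
                   unname(tools::md5sum(file.path(d2, f))))
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  suppressWarnings(simulate_dataset(small_cfg(seed = 12), out_dir = d3))
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "expr.tsv"))),
    unname(tools::md5sum(file.path(d3, "expr.tsv")))))
})

test_that("compartment methylation tracks the configured Beta means", {
  # no planted effects, so every compartment stays at its configured Beta
  cfg <- sim_config(seed = 11, n_genes = 60, n_cgis = 40,
                    n_cpg_sites = 20000,
                    n_repeats = c(LINE = 10, SINE = 10, LTR = 10),
                    n_planted_dms = 0, n_planted_corr_pos = 0,
                    n_planted_corr_neg = 0, cluster_genes_per_region = 5)
  ds <- suppressWarnings(simulate_dataset(cfg))
  s <- ds$methylomes$regions[[1]]
  comp <- ds$methylomes$truth$site_compartments
  beta <- methyl_beta(s[match(paste(comp$chrom, comp$pos, comp$strand),
                              paste(s$chrom, s$pos, s$strand)), ])
  keep <- site_depth(s)[match(paste(comp$chrom, comp$pos, comp$strand),
                              paste(s$chrom, s$pos, s$strand))] >= 10
  means <- tapply(beta[keep], comp$compartment[keep], mean, na.rm = TRUE)
  bp <- cfg$beta_params
  expect_lt(abs(means[["cgi_promoter"]] - 1 / 10), 0.03)
  expect_lt(abs(means[["gene_body"]] - 8 / 10), 0.03)
  expect_lt(abs(means[["intergenic"]] - 8 / 10), 0.03)
  expect_lt(abs(means[["repeat_flank"]] - 8.5 / 10), 0.03)
  expect_lt(means[["noncpg"]], 0.1)
})

test_that("planted truth refers to entities that exist in the dataset", {
  ds <- suppressWarnings(simulate_dataset(small_cfg()))
  tr <- ds$methylomes$truth
  s <- ds$methylomes$regions[[1]]
  anchors <- paste(s$chrom, s$pos)[s$strand == "+" & s$context == "CpG"]
  expect_true(all(paste(tr$dms$chrom, tr$dms$pos) %in% anchors))
  expect_true(all(tr$dms$region_a != tr$dms$region_b))
  expect_true(all(abs(tr$dms$beta_shifted - tr$dms$beta_base) <=
                    ds$methylomes$config$planted_dms_delta + 1e-9))
  ex <- ds$expression$truth
  expect_true(all(ex$clusters$gene_id %in% rownames(ds$expression$expr)))
  expect_true(all(ex$correlated$gene_id %in% ds$annotation$cgis$gene_id))
  # cluster and correlated sets are disjoint
  expect_equal(length(intersect(ex$clusters$gene_id,
                                ex$correlated$gene_id)), 0L)
})
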