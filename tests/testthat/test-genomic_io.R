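test_that("cytosine report parsing shifts to 0-based and filters context", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t101\t+\t8\t2\tCpG\tCGA",
               "chr1\t102\t-\t0\t0\tCpG\tCGT",
               "chr1\t200\t+\t3\t9\tCHH\tCAT"), f)
  x <- read_cytosine_report(f)
  expect_equal(x$pos, c(100L, 101L, 199L))
  expect_equal(x$n_meth[1], 8L)
  expect_true(is.na(methyl_beta(x)[2]))          # zero depth: beta undefined
  expect_equal(site_depth(x), c(10L, 0L, 12L))
  cpg <- read_cytosine_report(f, context = "CpG")
  expect_equal(nrow(cpg), 2L)
})

test_that("malformed cytosine reports fail loudly unless tolerant", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t101\t+\t8\t2\tCpG\tCGA",
               "chr1\t102\t+\t-3\t2\tCpG\tCGA"), f)
  expect_error(read_cytosine_report(f), "line 2")
  expect_warning(x <- read_cytosine_report(f, tolerant = TRUE), "dropped")
  expect_equal(nrow(x), 1L)
})

test_that("cytosine report round-trips", {
  f <- withr::local_tempfile()
  x <- make_sites(c(10, 20, 30), c(5, 0, 3), c(5, 0, 9),
                  strand = c("+", "-", "+"),
                  context = c("CpG", "CpG", "CHH"))
  write_cytosine_report(x, f)
  expect_equal(read_cytosine_report(f), x)
})

test_that("BED parsing keeps 0-based half-open coordinates and strand", {
  f <- withr::local_tempfile()
  writeLines(c("chr1\t0\t100", "chr2\t5\t10"), f)
  x <- read_bed(f)
  expect_equal(x$start, c(0L, 5L))
  expect_equal(x$strand, c(".", "."))
  writeLines("chr1\t5\t5", f)
  expect_error(read_bed(f), "line 1")
  writeLines("chr1\t0\t10\tr1\t0\t-", f)
  expect_equal(read_bed(f)$strand, "-")
})

test_that("rmsk dialects normalize to identical repeat records", {
  fu <- withr::local_tempfile(); fo <- withr::local_tempfile()
  writeLines(c(paste("genoName", "genoStart", "genoEnd", "strand",
                     "repName", "repClass", "repFamily", sep = "\t"),
               paste("chr1", 1000, 1300, "+", "AluJo", "SINE", "Alu",
                     sep = "\t")), fu)
  writeLines(c("   SW  perc ...", "score div ...", "",
               paste(" 463 11.4 0.0 0.0 chr1 1001 1300 (100) + AluJo",
                     "SINE/Alu 1 300 (0) 1")), fo)
  u <- read_rmsk(fu, dialect = "ucsc_table")
  o <- read_rmsk(fo, dialect = "repeatmasker_out")
  expect_equal(u[, c("chrom", "start", "end", "rep_name", "rep_class")],
               o[, c("chrom", "start", "end", "rep_name", "rep_class")])
  expect_equal(u$start, 1000L)
  expect_error(read_rmsk(fu, dialect = "nope"), "unknown rmsk dialect")
})

test_that("uncertain and unknown repeat classes map into the closed vocabulary", {
  fu <- withr::local_tempfile()
  writeLines(c(paste("genoName", "genoStart", "genoEnd", "strand",
                     "repName", "repClass", "repFamily", sep = "\t"),
               paste("chr1", 0, 100, "+", "X1", "SINE?", "Alu", sep = "\t"),
               paste("chr1", 200, 300, "+", "X2", "Retroposon", "SVA",
                     sep = "\t")), fu)
  expect_warning(x <- read_rmsk(fu, dialect = "ucsc_table"), "Other")
  expect_equal(x$rep_class, c("SINE", "Other"))
})

test_that("expression matrix validation rejects defects with coordinates", {
  f <- withr::local_tempfile()
  writeLines(c("gene_id\tA\tB", "g1\t1\t2", "g2\t0\t4.5"), f)
  m <- read_expression(f)
  expect_equal(dim(m), c(2L, 2L))
  writeLines(c("gene_id\tA\tB", "g1\t1\t2", "g1\t0\t4"), f)
  expect_error(read_expression(f), "duplicate gene id")
  writeLines(c("gene_id\tA\tB", "g1\t1\t2", "g2\t0\t-4"), f)
  expect_error(read_expression(f), "negative")
  writeLines(c("gene_id\tA\tB", "g1\t1\t2", "g2\tx\t4"), f)
  expect_error(read_expression(f), "g2")
})

test_that("gene-model views honour strand for TSS and first exon", {
  g <- rbind(make_gene("gp", "chr1", "+", c(100, 500), c(200, 700)),
             make_gene("gm", "chr1", "-", c(1000, 1500), c(1200, 1800)))
  fe <- gene_first_exon(g)
  expect_equal(fe$start[fe$gene_id == "gp"], 100L)
  expect_equal(fe$start[fe$gene_id == "gm"], 1500L)   # rightmost on minus
  ts <- gene_tss(g)
  expect_equal(ts$start, c(100L, 1799L))
  f <- withr::local_tempfile()
  write_gene_models(g, f)
  expect_equal(read_gene_models(f), g)
})

test_that("dyad merging sums the two strands at the plus-strand anchor", {
  x <- make_sites(c(10, 11, 50), c(3, 4, 1), c(2, 1, 9),
                  strand = c("+", "-", "+"))
  m <- merge_dyads(x)
  expect_equal(nrow(m), 2L)
  expect_equal(m$n_meth[m$pos == 10], 7L)
  expect_equal(m$n_unmeth[m$pos == 10], 3L)
  expect_equal(m$n_meth[m$pos == 50], 1L)    # unpaired site passes through
})
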