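test_that("exact test matches enumeration oracle and fisher.test", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)[1], 1)
  expect_equal(fisher_exact_2x2(10, 0, 0, 10)[1],
               oracle_fisher(10, 0, 0, 10), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(3, 7, 7, 3)[1],
               oracle_fisher(3, 7, 7, 3), tolerance = 1e-9)
  set.seed(42)
  a <- sample(0:25, 200, TRUE); b <- sample(0:25, 200, TRUE)
  cc <- sample(0:25, 200, TRUE); d <- sample(0:25, 200, TRUE)
  keep <- (a + b) > 0 & (cc + d) > 0
  p <- fisher_exact_2x2(a, b, cc, d)
  pf <- mapply(function(a, b, cc, d)
    stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value,
    a, b, cc, d)
  expect_lt(max(abs(p[keep] - pf[keep])), 1e-9)
  expect_true(all(p > 0 & p <= 1))
})

test_that("zero-margin tables return p = 1 with a degenerate flag", {
  p <- fisher_exact_2x2(c(0, 5), c(0, 5), c(3, 0), c(7, 0))
  expect_equal(as.numeric(p), c(1, 1))
  expect_equal(attr(p, "degenerate"), c(TRUE, TRUE))
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "nonnegative")
})

test_that("BH adjustment follows the step-up definition", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(0.5, 10)), rep(0.5, 10))
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:80, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    o <- sample(length(p))
    expect_equal(bh_adjust(p[o]), q[o])             # permutation invariance
    expect_true(!is.unsorted(q[order(p)]))          # monotone in sorted p
  }
})

test_that("DMS calling tests the shared-site universe and mirrors on swap", {
  a <- make_sites(c(10, 20, 30), c(10, 5, 2), c(2, 7, 10))
  b <- make_sites(c(10, 20, 40), c(2, 5, 9), c(10, 7, 3))
  dms <- call_dms(a, b)
  expect_equal(dms$pos, c(10L, 20L))                # site 30/40 not shared
  rev <- call_dms(b, a)
  expect_equal(rev$p_value, dms$p_value)
  expect_equal(rev$q_value, dms$q_value)
  expect_equal(rev$diff, -dms$diff)
  # identical samples: no calls
  self <- call_dms(a, a)
  expect_true(all(self$direction == "ns"))
  expect_true(all(self$diff == 0))
  expect_warning(call_dms(a, make_sites(99, 5, 5)), "no shared sites")
})

test_that("a single extreme site among nulls is called with hand-applied BH", {
  pos <- seq(10, 110, by = 10)
  a <- make_sites(pos, c(rep(5L, 10), 30L), c(rep(5L, 10), 0L))
  b <- make_sites(pos, c(rep(5L, 10), 0L), c(rep(5L, 10), 30L))
  dms <- call_dms(a, b)
  p_extreme <- oracle_fisher(30, 0, 0, 30)
  expect_equal(dms$q_value[11], min(p_extreme * 11, 1))   # m = 11, rank 1
  expect_equal(dms$direction[11], "hypo")                 # lower in b
  expect_equal(sum(dms$direction != "ns"), 1L)
  # orientation flip
  expect_equal(call_dms(b, a)$direction[11], "hyper")
})

test_that("DMS count matrix is symmetric with zero diagonal", {
  a <- make_sites(seq(10, 100, 10), rep(8, 10), rep(2, 10))
  b <- a; b$n_meth[1] <- 0L; b$n_unmeth[1] <- 30L; b$n_meth[2:10] <- 8L
  m <- dms_count_matrix(list(r1 = a, r2 = b, r3 = a))
  expect_equal(dim(m), c(3L, 3L))
  expect_equal(diag(m), c(r1 = 0L, r2 = 0L, r3 = 0L))
  expect_equal(m, t(m))
  expect_equal(m["r1", "r3"], 0L)                   # identical samples
  expect_equal(m["r1", "r2"], m["r2", "r1"])
})

test_that("DMG rule requires first-exon CGI overlap with a contained DMS", {
  genes <- rbind(
    make_gene("hit1", "chr1", "+", c(1000, 2000), c(1300, 2400)),
    make_gene("hit2", "chr1", "-", c(5000, 6000), c(5300, 6500)),
    make_gene("second_exon", "chr1", "+", c(9000, 10000), c(9300, 10400)),
    make_gene("no_dms", "chr1", "+", c(13000, 14000), c(13300, 14400)))
  cgis <- genomic_intervals(
    "chr1",
    c(1100, 6100, 9900, 13100),    # hit1 fe, hit2 fe (rightmost), 2nd exon, no dms
    c(1250, 6450, 10300, 13250))
  dms <- data.frame(chrom = "chr1",
                    pos = c(1150L, 6200L, 10000L),
                    q_value = 0.01, direction = "hyper",
                    stringsAsFactors = FALSE)
  out <- call_dmgs(dms, cgis, genes)
  expect_setequal(out$gene_id, c("hit1", "hit2"))
  # second_exon gene: CGI overlaps exon 2 only -> excluded
  expect_false("second_exon" %in% out$gene_id)
  # two DMSs in one qualifying CGI
  dms2 <- rbind(dms, data.frame(chrom = "chr1", pos = 1200L, q_value = 0.01,
                                direction = "hypo"))
  out2 <- call_dmgs(dms2, cgis, genes)
  expect_equal(out2$supporting_dms_count[out2$gene_id == "hit1"], 2L)
  # non-significant records never support a DMG
  ns <- data.frame(chrom = "chr1", pos = 13150L, q_value = 0.5,
                   direction = "ns", stringsAsFactors = FALSE)
  expect_false("no_dms" %in% call_dmgs(rbind(dms, ns), cgis, genes)$gene_id)
})
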