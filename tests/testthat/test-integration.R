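test_that("CGI-promoter pairing requires >= 1 bp overlap, one pair per gene", {
  # divergent gene pair: promoters [3000,5000) for g+ and [6000,8000) for g-
  genes <- rbind(make_gene("gp", "chr1", "+", c(5000, 5600), c(5400, 5900)),
                 make_gene("gm", "chr1", "-", c(5300, 5700), c(5500, 6000)))
  cgis <- genomic_intervals("chr1",
                            c(4000, 2999, 4900, 10000),
                            c(4500, 3001, 6100, 10500))
  pr <- cgi_promoter_pairs(cgis, genes)
  expect_equal(pr$gene_id[pr$cgi_index == 1], "gp")     # fully inside
  expect_equal(pr$gene_id[pr$cgi_index == 2], "gp")     # 1-bp overlap
  expect_setequal(pr$gene_id[pr$cgi_index == 3], c("gp", "gm"))  # spans both
  expect_false(4 %in% pr$cgi_index)                     # outside everything
  # 1 bp short of the promoter start: no pair
  miss <- cgi_promoter_pairs(genomic_intervals("chr1", 2990, 3000), genes)
  expect_equal(nrow(miss), 0L)
})

test_that("CGI methylation is the per-region median with NA for no coverage", {
  cgis <- genomic_intervals("chr1", c(100, 500), c(200, 600))
  r1 <- make_sites(c(110, 120, 130), c(2, 4, 9), c(8, 6, 1))  # 0.2 0.4 0.9
  r2 <- make_sites(c(110, 120), c(2, 4), c(8, 6))             # 0.2 0.4
  m <- cgi_median_methylation(cgis, list(r1 = r1, r2 = r2))
  expect_equal(m[1, "r1"], 0.4)          # odd-count median
  expect_equal(m[1, "r2"], 0.3)          # even-count midpoint
  expect_true(all(is.na(m[2, ])))        # CGI without covered sites
})

test_that("the Pearson screen signs perfect couplings and matches the t-test", {
  meth <- matrix(seq(0.1, 0.7, 0.1), 3, 7, byrow = TRUE,
                 dimnames = list(NULL, paste0("r", 1:7)))
  meth[3, ] <- 0.5                                       # zero variance
  expr <- rbind(pos = 1 + 2 * meth[1, ],
                neg = 5 - 3 * meth[2, ],
                flat = 2 + 0 * meth[3, ] + rnorm(7))
  pairs <- data.frame(cgi_index = 1:3, cgi_chrom = "chr1",
                      cgi_start = c(0, 100, 200),
                      cgi_end = c(50, 150, 250),
                      gene_id = c("pos", "neg", "flat"),
                      stringsAsFactors = FALSE)
  rec <- pearson_screen(pairs, meth, expr)
  expect_equal(rec$sign[rec$gene_id == "pos"], "positive")
  expect_equal(rec$r[rec$gene_id == "pos"], 1)
  expect_equal(rec$sign[rec$gene_id == "neg"], "negative")
  expect_false("flat" %in% rec$gene_id)
  expect_equal(attr(rec, "skipped")[["zero_variance"]], 1L)
  # p at the n = 7 significance boundary equals the t CDF value
  r_crit <- uniroot(function(r) 2 * pt(-r * sqrt(5 / (1 - r^2)), 5) - 0.05,
                    c(0.5, 0.9))$root
  expect_equal(r_crit, 0.7544918, tolerance = 1e-4)
  set.seed(1)
  mv <- runif(7); ev <- mv + rnorm(7, 0, 0.4)
  ct <- cor.test(mv, ev)
  m1 <- matrix(mv, 1, dimnames = list(NULL, paste0("r", 1:7)))
  e1 <- matrix(ev, 1, dimnames = list("g", paste0("r", 1:7)))
  rec1 <- pearson_screen(pairs[1, ][, ], m1,
                         `rownames<-`(e1, "pos"), p_threshold = 1)
  expect_equal(rec1$p_value, unname(ct$p.value), tolerance = 1e-9)
  expect_equal(rec1$r, unname(ct$estimate), tolerance = 1e-12)
})

test_that("the screen is invariant to affine rescaling of either vector", {
  meth <- matrix(c(0.1, 0.5, 0.2, 0.8, 0.4, 0.6, 0.3), 1,
                 dimnames = list(NULL, paste0("r", 1:7)))
  expr <- matrix(c(2, 6, 1, 9, 5, 7, 3), 1,
                 dimnames = list("g", paste0("r", 1:7)))
  pairs <- data.frame(cgi_index = 1, cgi_chrom = "chr1", cgi_start = 0,
                      cgi_end = 10, gene_id = "g", stringsAsFactors = FALSE)
  r0 <- pearson_screen(pairs, meth, expr, p_threshold = 1)
  r1 <- pearson_screen(pairs, meth * 0.5 + 0.05, expr * 30 + 2,
                       p_threshold = 1)
  expect_equal(r1$r, r0$r, tolerance = 1e-12)
  r2 <- pearson_screen(pairs, meth, -expr, p_threshold = 1)
  expect_equal(r2$r, -r0$r, tolerance = 1e-12)
})

test_that("categorization flags BRSG/DMG membership and tabulates counts", {
  rec <- data.frame(gene_id = c("a", "b", "c"), r = c(0.9, -0.8, 0.85),
                    p_value = 0.01, sign = c("positive", "negative",
                                             "positive"),
                    stringsAsFactors = FALSE)
  out <- categorize_correlations(rec,
                                 brsg_sets = list(r1 = c("a"), r2 = c("b")),
                                 dmgs = data.frame(gene_id = "a"))
  expect_equal(out$records$is_brsg, c(TRUE, TRUE, FALSE))
  expect_equal(out$records$is_dmg, c(TRUE, FALSE, FALSE))
  expect_equal(sum(out$summary$n), 3L)
  both <- out$summary$n[out$summary$sign == "positive" &
                          out$summary$is_brsg == "TRUE" &
                          out$summary$is_dmg == "TRUE"]
  expect_equal(both, 1L)
  none <- categorize_correlations(rec, NULL, NULL)
  expect_false(any(none$records$is_dmg))
})
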