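make_repeats <- function(start, end, strand = "+", rep_name = "L1MA4",
                         rep_class = "LINE", chrom = "chr1") {
  data.frame(chrom = chrom, start = as.integer(start), end = as.integer(end),
             strand = rep_len(strand, length(start)),
             rep_name = rep_len(rep_name, length(start)),
             rep_class = rep_len(rep_class, length(start)),
             rep_family = "fam", stringsAsFactors = FALSE)
}

test_that("CGI split is an exact partition with 1-bp overlap sensitivity", {
  reps <- make_repeats(c(1000, 3000, 5000), c(2000, 4000, 6000))
  cgis <- genomic_intervals("chr1", c(1500, 4000), c(1600, 4100))
  sp <- split_by_cgi(reps, cgis)
  expect_equal(sp$with_cgi$start, 1000L)         # contains a CGI
  expect_equal(sp$without_cgi$start, c(3000L, 5000L))  # 4000 is 1 bp away
  expect_equal(nrow(sp$with_cgi) + nrow(sp$without_cgi), nrow(reps))
})

test_that("per-element summaries report NA for uncovered elements", {
  reps <- make_repeats(c(100, 500), c(200, 600))
  s <- make_sites(c(110, 120, 130), c(10, 9, 8), c(0, 1, 2))
  em <- element_methylation(reps, s)
  expect_equal(em$n_sites, c(3L, 0L))
  expect_equal(em$beta[1], mean(c(1, 0.9, 0.8)))
  expect_true(is.na(em$beta[2]))
  emm <- element_methylation(reps, make_sites(c(110, 120, 130),
                                              c(1, 9, 8), c(9, 1, 2)),
                             stat = "median")
  expect_equal(emm$beta[1], 0.8)
})

test_that("metaprofile bins match a brute-force positional mean", {
  # 5 identical-length plus-strand elements, deterministic beta by offset
  L <- 200
  starts <- seq(1000, 9000, 2000)
  reps <- make_repeats(starts, starts + L)
  pos <- unlist(lapply(starts, function(s) s + seq(0, L - 1, 5)))
  beta <- rep(seq(0, 1, length.out = L / 5), length(starts))
  s <- make_sites(pos, round(beta * 20), 20 - round(beta * 20))
  pr <- metaprofile(reps, s, body_bins = 40, flank_bp = 100,
                    flank_bins = 10)
  body <- pr[pr$bin_kind == "body", ]
  b <- methyl_beta(s)
  off <- (s$pos - reps$start[findInterval(s$pos, reps$start)])
  oracle <- tapply(b, floor(40 * off / L), mean)
  expect_equal(body$mean_beta, as.vector(oracle))
  expect_equal(sum(body$n_sites), length(pos))
  # constant series: LOESS leaves it constant
  s2 <- make_sites(pos, 16, 4)
  pr2 <- metaprofile(reps, s2, body_bins = 40, flank_bp = 100,
                     flank_bins = 10)
  def <- !is.na(pr2$mean_beta)
  expect_true(all(abs(pr2$loess_beta[def] - 0.8) < 1e-6))
})

test_that("reversing element strand reverses the raw bin series", {
  L <- 100
  reps_p <- make_repeats(1000, 1000 + L, strand = "+")
  reps_m <- make_repeats(1000, 1000 + L, strand = "-")
  pos <- 1000 + seq(0, L - 1, 2)
  grad <- seq(0.1, 0.9, length.out = length(pos))
  s <- make_sites(pos, round(grad * 30), 30 - round(grad * 30))
  pp <- metaprofile(reps_p, s, body_bins = 25, flank_bp = 10,
                    flank_bins = 2)
  pm <- metaprofile(reps_m, s, body_bins = 25, flank_bp = 10,
                    flank_bins = 2)
  bp <- pp$mean_beta[pp$bin_kind == "body"]
  bm <- pm$mean_beta[pm$bin_kind == "body"]
  expect_equal(bm, rev(bp))
})

test_that("inner/outer statistics respect masking and chromosome ends", {
  reps <- make_repeats(c(50, 1000), c(150, 1200))
  inner_pos <- c(60, 70, 1100)
  outer_pos <- c(10, 160, 950, 1250)
  s <- make_sites(c(inner_pos, outer_pos), 8, 2)
  st <- inner_outer_stats(reps, s, flank_bp = 100)
  expect_equal(st$n_inner, 3L)
  expect_equal(st$n_outer, 4L)
  expect_equal(st$difference, 0)                     # identical beta
  expect_equal(st$outer_mean - st$inner_mean, st$difference)
  # site inside another annotated repeat is masked from the outer pool
  extra <- make_repeats(940, 960, rep_class = "SINE")
  st2 <- inner_outer_stats(reps, s, flank_bp = 100,
                           exclude = rbind(reps, extra))
  expect_equal(st2$n_outer, 3L)
  # element at the chromosome start: upstream flank truncated, not wrapped
  expect_equal(st$n_inner + st$n_outer, nrow(s))
  empty <- inner_outer_stats(reps[0, ], s)
  expect_true(is.na(empty$inner_mean))
})

test_that("subtypes classify as hypo/hyper/intermediate by median level", {
  reps <- rbind(make_repeats(c(100, 300), c(200, 400), rep_name = "hyperE"),
                make_repeats(c(600, 800), c(700, 900), rep_name = "hypoE"),
                make_repeats(1100, 1200, rep_name = "midE"))
  s <- rbind(make_sites(c(110, 310), 9, 1),      # 0.9
             make_sites(c(610, 810), 1, 9),      # 0.1
             make_sites(1110, 5, 5))             # 0.5
  out <- subtype_summary(reps, s)
  expect_equal(out$classification[out$rep_name == "hyperE"], "hyper")
  expect_equal(out$classification[out$rep_name == "hypoE"], "hypo")
  expect_equal(out$classification[out$rep_name == "midE"], "intermediate")
})
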