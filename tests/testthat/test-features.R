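# gene-centric aggregation and the statistical comparisons

test_that("up-regulated gene selection applies the time-course rule", {
  tbl <- data.frame(gene_id = c("a", "b", "c", "d"),
                    expr_0h = c(10, 10, 10, 10),
                    expr_1h = c(20, 25, 19, 30),
                    expr_4h = c(20, 10, 19, 60))
  # a: x2 then x1 -> in; b: x2.5 then x0.4 -> out; c: x1.9 -> out;
  # d: x3 then further up -> in
  expect_setequal(classify_upregulated_genes(tbl), c("a", "d"))
  # endpoints variant needs significance
  tbl$significant <- c(TRUE, TRUE, TRUE, FALSE)
  expect_setequal(classify_upregulated_genes(tbl, rule = "endpoints"), "a")
  expect_error(classify_upregulated_genes(tbl[, 1:3]), "columns")
})

test_that("gene-body and promoter regions are strand-aware and clipped", {
  plus <- data.frame(chrom = "c1", tss = 10000L, tts = 14000L, strand = "+")
  minus <- data.frame(chrom = "c1", tss = 14000L, tts = 10000L, strand = "-")
  expect_equal(gene_body_region(plus)[, .(start, end)],
               data.table::data.table(start = 9500L, end = 14000L))
  expect_equal(gene_body_region(minus)[, .(start, end)],
               data.table::data.table(start = 10000L, end = 14500L))
  expect_warning(
    clipped <- gene_body_region(data.frame(chrom = "c1", tss = 200L,
                                           tts = 3000L, strand = "+")),
    "clipped")
  expect_equal(clipped$start, 0L)
  expect_equal(promoter_region(data.frame(chrom = "c1", tss = 5000L))[
    , .(start, end)], data.table::data.table(start = 4000L, end = 6000L))
  expect_warning(p2 <- promoter_region(data.frame(chrom = "c1", tss = 500L)),
                 "clipped")
  expect_equal(p2$start, 0L)
  expect_error(promoter_region(plus, flank = 0), "positive")
})

test_that("per-region means weight bins by overlap", {
  flat <- toy_track(rep(3.5, 10))
  expect_equal(per_region_mean(flat, data.frame(chrom = "c1", start = 150,
                                                end = 1450)), 3.5)
  tr <- toy_track(c(0, 2, 5))
  # exactly one bin
  expect_equal(per_region_mean(tr, data.frame(chrom = "c1", start = 200,
                                              end = 400)), 2)
  # half of bin1 + half of bin2, values 0 and 2 -> 1.0
  expect_equal(per_region_mean(tr, data.frame(chrom = "c1", start = 100,
                                              end = 300)), 1.0)
  # empty/absent regions give NA
  expect_true(is.na(per_region_mean(tr, data.frame(chrom = "cX", start = 0,
                                                   end = 100))))
})

test_that("metagene profiles orient by strand and report SEM", {
  flat <- toy_track(rep(2, 50))
  pr <- metagene_profile(flat, data.frame(chrom = "c1", pos = 5000L,
                                          strand = "+"), flank = 1000)
  expect_true(all(pr$mean == 2))
  expect_true(all(pr$sem == 0))
  expect_error(metagene_profile(flat, data.frame(chrom = character(),
                                                 pos = integer())), "empty")
  # two anchors on opposite strands over a mirror-symmetric track give
  # identical oriented rows
  v <- c(1:25, 25:1)
  tr <- toy_track(as.numeric(v), bin_size = 100L)
  anchors <- data.frame(chrom = "c1", pos = c(2450L, 2550L),
                        strand = c("+", "-"))
  pr2 <- metagene_profile(tr, anchors, flank = 2000, step = 100)
  expect_equal(pr2$matrix[1, ], pr2$matrix[2, ])
  # mirror property: reversing strands and coordinates mirrors the profile
  anc_f <- data.frame(chrom = "c1", pos = 1200L, strand = "+")
  anc_r <- data.frame(chrom = "c1", pos = 5000L - 1L - 1200L, strand = "-")
  trv <- toy_track(as.numeric(sample(1:50)), bin_size = 100L)
  trr <- toy_track(rev(trv$values$c1), bin_size = 100L)
  prf <- metagene_profile(trv, anc_f, flank = 500, step = 100)
  prr <- metagene_profile(trr, anc_r, flank = 500, step = 100)
  expect_equal(prf$mean, prr$mean)
})

test_that("phased nucleosome lattice shows up at the repeat length", {
  g <- test_genome()
  sets <- test_titration()
  cl <- g$spec$chrom_lengths
  merged <- fragment_set(
    data.table::rbindlist(lapply(sets, function(s) s$fragments)), list(), cl)
  cov <- coverage_track(merged)
  # anchor on called peaks (true dyads unknown to the caller) and look for
  # lattice periodicity in the averaged profile
  anchors <- data.frame(chrom = "chrT",
                        pos = g$nucleosomes[chrom == "chrT" &
                                              occ_0h > 0.6, dyad],
                        strand = "+")
  pr <- metagene_profile(cov, anchors[seq_len(400), ], flank = 400, step = 1)
  ac <- acf(pr$mean, lag.max = 250, plot = FALSE)$acf[, 1, 1]
  peak_lag <- which.max(ac[150:220]) + 149 - 1
  expect_lt(abs(peak_lag - g$spec$nucleosome_spacing), 10)
})

test_that("group comparison reproduces exact rank-sum enumeration", {
  res <- compare_group_timepoints(c(1, 2, 3), c(11, 12, 13))
  expect_equal(res$statistic, 0)
  expect_equal(res$p.value, 0.1)   # 2 * (1 / C(6,3))
  # symmetry
  expect_equal(compare_group_timepoints(c(11, 12, 13), c(1, 2, 3))$p.value,
               0.1)
  # identical groups
  expect_gt(compare_group_timepoints(c(1, 5, 9, 2), c(1, 5, 9, 2))$p.value,
            0.99)
})

test_that("signed-rank profile comparison honors the stated alternative", {
  a <- toy_track(as.numeric(1:20))
  b <- toy_track(as.numeric(1:20) + 1)
  up <- compare_profiles_signed_rank(a, b, alternative = "increase")
  # all 20 differences positive and tied -> approximate branch, tiny p
  expect_lt(up$p.value, 1e-4)
  # untied all-positive differences: exactly the smallest attainable 2^-20
  set.seed(1)
  b2 <- toy_track(as.numeric(1:20) + runif(20, 0.5, 1.5))
  expect_equal(compare_profiles_signed_rank(a, b2,
                                            alternative = "increase")$p.value,
               2^-20)
  down <- compare_profiles_signed_rank(a, b, alternative = "decrease")
  expect_gt(down$p.value, 0.999)
  expect_warning(tie <- compare_profiles_signed_rank(a, a, alternative = "increase"),
                 "zero")
  expect_equal(tie$p.value, 1)
  # region restriction picks the right bins
  reg <- list(chrom = "c1", start = 400L, end = 1200L)
  sub <- compare_profiles_signed_rank(a, b, reg, "increase")
  expect_equal(sub$n_used, 4L)
})

test_that("rank tests match the reference implementation to 1e-8", {
  set.seed(99)
  for (i in 1:100) {
    x <- rnorm(sample(4:15, 1)); y <- rnorm(sample(4:15, 1))
    alt <- sample(c("two.sided", "greater", "less"), 1)
    expect_equal(mann_whitney_test(x, y, alt)$p.value,
                 wilcox.test(x, y, alternative = alt, exact = TRUE)$p.value,
                 tolerance = 1e-8)
    d <- rnorm(sample(5:20, 1))
    expect_equal(signed_rank_test(d, alt)$p.value,
                 wilcox.test(d, alternative = alt, exact = TRUE)$p.value,
                 tolerance = 1e-8)
  }
  # large-sample branch against the reference's normal approximation
  set.seed(100)
  x <- rnorm(80); y <- rnorm(75, 0.3)
  expect_equal(mann_whitney_test(x, y)$p.value,
               wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-8)
  d <- rnorm(90, 0.1)
  expect_equal(signed_rank_test(d)$p.value,
               wilcox.test(d, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-8)
})

test_that("expression correlation behaves at the extremes and in pipeline", {
  e <- c(5, 1, 9, 3, 7, 2)
  expect_equal(correlate_with_expression(e, e)$rho, 1)
  expect_equal(correlate_with_expression(-e, e)$rho, -1)
  expect_true(is.na(correlate_with_expression(rep(1, 6), e)$rho))
})

test_that("fraction of significant change is calibrated and monotone", {
  set.seed(123)
  nb <- 5000
  mk <- function() toy_track(rnorm(nb))
  t0 <- list(mk(), mk()); t4 <- list(mk(), mk())
  res <- fraction_significant_changes(t0, t4, thresholds = c(0, 0.5, Inf))
  # alpha-level calibration at threshold 0 within 3 binomial SDs
  expect_lt(abs(res$percent[1] - 5), 300 * sqrt(0.05 * 0.95 / nb))
  # monotone non-increasing; infinite threshold -> 0
  expect_true(all(diff(res$percent) <= 0))
  expect_equal(res$percent[3], 0)
  expect_error(fraction_significant_changes(t0[1], t4), "replicates")
  # planted change in 10% of bins at high effect
  shift <- c(rep(20, nb / 10), rep(0, nb - nb / 10))   # high effect: near-full power at df = 2
  t4b <- list(toy_track(rnorm(nb) + shift), toy_track(rnorm(nb) + shift))
  hit <- fraction_significant_changes(t0, t4b, 0)$percent
  expect_lt(abs(hit - (10 + 5 * 0.9)), 1.5)
})

test_that("random site sampling is reproducible and representative", {
  cl <- c(c1 = 5e4L, c2 = 5e4L)
  s1 <- sample_random_sites(500, cl, seed = 11)
  s2 <- sample_random_sites(500, cl, seed = 11)
  expect_identical(s1, s2)
  expect_equal(nrow(sample_random_sites(0, cl)), 0L)
  expect_error(sample_random_sites(1e6, cl), "exceeds")
  expect_true(all(s1$pos >= 1000 & s1$pos < 49000))
  # mean of a track over many random sites approaches the genome mean
  v <- rnorm(500)
  tr <- binned_track(list(c1 = v[1:250], c2 = v[251:500]), 200L, cl)
  pr <- metagene_profile(tr, sample_random_sites(3000, cl, seed = 4),
                         flank = 0, step = 200)
  expect_lt(abs(pr$mean[1] - mean(v)), 4 * sd(v) / sqrt(3000))
})
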