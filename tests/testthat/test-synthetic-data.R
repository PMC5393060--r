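# synthetic world: genome construction, ground truth, forward simulators

test_that("spec validation rejects impossible worlds", {
  expect_error(synthetic_genome_spec(chrom_lengths = c(a = -5L)))
  expect_error(synthetic_genome_spec(gc_mean = 0.7, gc_amplitude = 0.2),
               "GC profile")
})

test_that("empty annotation spec yields a bare nucleosome lattice", {
  g <- build_genome(synthetic_genome_spec(
    chrom_lengths = c(c1 = 2e5L), n_genes = 0L, n_enhancers = 0L,
    accessibility_sd = 0, seed = 7L))
  expect_equal(nrow(g$genes), 0L)
  expect_equal(nrow(g$enhancers), 0L)
  expect_true(all(g$nucleosomes$accessibility == 0))
  # lattice density: ~length/spacing nucleosomes (+-10%)
  expect_lt(abs(nrow(g$nucleosomes) - 2e5 / 180) / (2e5 / 180), 0.1)
  # dyad constraints
  expect_true(all(g$nucleosomes$dyad >= 73 &
                    g$nucleosomes$dyad <= 2e5 - 73))
  expect_true(all(diff(g$nucleosomes$dyad) >= 120))
})

test_that("identical spec+seed gives byte-identical outputs", {
  spec <- synthetic_genome_spec(chrom_lengths = c(c1 = 1e5L), n_genes = 4L,
                                n_enhancers = 2L, seed = 33L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  p1 <- write_genome(build_genome(spec), d1)
  p2 <- write_genome(build_genome(spec), d2)
  for (k in names(p1))
    expect_equal(unname(tools::md5sum(p1[[k]])), unname(tools::md5sum(p2[[k]])),
                 label = k)
  # fragment files too
  g <- build_genome(spec)
  f1 <- file.path(d1, "f.bed"); f2 <- file.path(d2, "f.bed")
  write_fragments_bed(simulate_titration_fragments(g, "0h", 2, 5000, seed = 9L), f1)
  write_fragments_bed(simulate_titration_fragments(g, "0h", 2, 5000, seed = 9L), f2)
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("sequence GC matches the profile within 0.02 in 1-kb windows", {
  g <- test_genome()
  gt <- gc_track(g$sequences, 1000)
  v <- track_values(gt)
  centers <- (seq_along(v) - 1) * 1000 + 500
  target <- maccr:::gc_target(g$spec, centers)
  expect_lt(max(abs(v - target)), 0.02)
})

test_that("genes carry a promoter nucleosome-depleted dip (>= 40%)", {
  g <- test_genome()
  occ <- g$truth[["0h"]]$occupancy
  prom <- per_region_mean(occ, data.frame(chrom = g$genes$chrom,
                                          start = g$genes$tss - 100,
                                          end = g$genes$tss + 100))
  flank <- per_region_mean(occ, data.frame(chrom = g$genes$chrom,
                                           start = g$genes$tss + 500,
                                           end = g$genes$tss + 1000))
  expect_gt(1 - mean(prom, na.rm = TRUE) / mean(flank, na.rm = TRUE), 0.40)
})

test_that("time-course class labels are consistent with their deltas", {
  g <- test_genome()
  eff <- g$effects
  uao <- eff[eff$class_label == "up_access_only"]
  if (nrow(uao)) {
    expect_true(all(uao$occ_mult_1h == 1 & uao$occ_mult_4h == 1))
    expect_true(all(uao$d_acc_1h > 0 & uao$d_acc_4h > 0))
  }
  unch <- eff[eff$class_label == "unchanged"]
  if (nrow(unch))
    expect_true(all(unch$d_acc_1h == 0 & unch$occ_mult_1h == 1))
})

test_that("titration release model behaves as designed", {
  # closed-form kernel: extremes give clean monotone responses
  lv <- 1:4
  expect_true(all(diff(mnase_release(lv, +1)) < 0))
  expect_true(all(diff(mnase_release(lv, -1)) > 0))
  # calibration: rank correlation of accessibility with (level1 - level4)
  set.seed(11)
  a <- runif(1e5, -1, 1)
  expect_gt(cor(a, mnase_release(1, a) - mnase_release(4, a),
                method = "spearman"), 0.9)
})

test_that("per-level counts decrease for accessible and increase for closed regions", {
  # library depth is fixed per level, so the titration response shows up as
  # the RELATIVE share of reads: plant an accessible (+1) half-chromosome
  # and a closed (-1) half and track each half's counts across levels
  g <- build_genome(synthetic_genome_spec(chrom_lengths = c(c1 = 2e5L),
                                          n_genes = 0L, n_enhancers = 0L,
                                          accessibility_sd = 0, seed = 5L))
  acc <- ifelse(g$nucleosomes$dyad < 1e5, 1, -1)
  for (col in c("acc_0h", "acc_1h", "acc_4h"))
    g$nucleosomes[[col]] <- acc
  counts_open <- counts_closed <- numeric(4)
  for (lv in 1:4) {
    fs <- simulate_titration_fragments(g, "0h", lv, 1e5, seed = 40 + lv,
                                       bg_fraction = 0)
    mid <- (fs$fragments$start + fs$fragments$end) %/% 2
    counts_open[lv] <- sum(mid < 1e5)
    counts_closed[lv] <- sum(mid >= 1e5)
  }
  expect_true(all(diff(counts_open) < 0))
  expect_true(all(diff(counts_closed) > 0))
})

test_that("zero depth and bad level are handled", {
  g <- test_genome()
  expect_equal(simulate_titration_fragments(g, "0h", 1, 0)$library_size, 0L)
  expect_error(simulate_titration_fragments(g, "0h", 5, 10), "titration_level")
})

test_that("gc_bias_strength = 0 leaves bin counts uncorrelated with GC", {
  g <- test_genome()
  fs <- simulate_titration_fragments(g, "0h", 2, 1e5, gc_bias_strength = 0,
                                     seed = 77L)
  tr <- bin_frequencies(fs, 200, normalize = FALSE)
  # compare against GC after removing the occupancy signal: use residual
  # correlation over bins of similar expected coverage (background-only
  # genome would be cleaner; accept the small-structure test genome here)
  r <- cor(track_values(tr), track_values(g$gc_bins))
  expect_lt(abs(r), 0.05)
})

test_that("total simulated count always equals requested depth", {
  g <- test_genome()
  for (d in c(0, 1, 1234)) {
    fs <- simulate_titration_fragments(g, "1h", 3, d, seed = 3L)
    expect_equal(fs$library_size, as.integer(d))
  }
})

test_that("fragment lengths: truncated normal core plus ~2% contaminants", {
  g <- test_genome()
  fs <- simulate_titration_fragments(g, "0h", 2, 5e4, seed = 13L)
  len <- fs$fragments$end - fs$fragments$start
  frac_out <- mean(len < 50 | len > 500)
  expect_lt(abs(frac_out - 0.02), 0.005)
  core <- len[len >= 50 & len <= 500]
  expect_lt(abs(mean(core) - 147), 2)
})

test_that("ChIP pair: fold 1 everywhere is indistinguishable from input", {
  g <- build_genome(synthetic_genome_spec(chrom_lengths = c(c1 = 5e5L),
                                          n_genes = 0L, n_enhancers = 0L,
                                          seed = 21L))
  pair <- simulate_chip_pair(g, "H3K27ac", "0h", 1e5, seed = 8L)
  we <- window_enrichment(pair$chip, pair$input, 200)
  # var(z) ~ 2 under the null (input is itself noisy), so the genome-wide
  # max sits near 6-7; the operational property is that nothing reaches
  # the calling threshold
  expect_lt(max(we$z), 10)
  expect_equal(nrow(call_enriched_regions(we)), 0L)
})

test_that("planted enhancer folds flow through to classification", {
  g <- test_genome()
  cls <- classify_enhancers(g$enhancers)
  expect_true(all(cls[g$enhancers$class == "enhancer_up"] == "up_regulated"))
  expect_true(all(cls[g$enhancers$class == "enhancer_constitutive"] ==
                    "constitutive_high"))
})

test_that("ATAC simulator: closed chromatin yields only the floor; depth is linear", {
  g <- build_genome(synthetic_genome_spec(chrom_lengths = c(c1 = 2e5L),
                                          n_genes = 0L, n_enhancers = 0L,
                                          accessibility_sd = 0, seed = 6L))
  for (col in c("acc_0h", "acc_1h", "acc_4h"))
    g$nucleosomes[[col]] <- rep(-1, nrow(g$nucleosomes))
  g$truth <- lapply(setNames(c("0h", "1h", "4h"), c("0h", "1h", "4h")),
                    function(tp) truth_tracks(g, tp))
  fs <- simulate_atac(g, "0h", 5e4, seed = 14L)
  tr <- bin_frequencies(fs, 200, normalize = FALSE)
  v <- track_values(tr)
  # uniform floor only: counts consistent with a flat multinomial
  expect_lt(max(abs(v - mean(v))) / mean(v), 6 / sqrt(mean(v)))
  # doubling depth doubles per-bin expectation
  fs2 <- simulate_atac(g, "0h", 1e5, seed = 15L)
  v2 <- track_values(bin_frequencies(fs2, 200, normalize = FALSE))
  expect_lt(abs(mean(v2) / mean(v) - 2), 0.05)
})

test_that("ATAC counts track the sign of a bimodal accessibility landscape", {
  g <- test_genome()
  fs <- simulate_atac(g, "4h", 1e5, seed = 16L)
  tr <- bin_frequencies(fs, 200, normalize = FALSE)
  acc <- track_values(g$truth[["4h"]]$accessibility)
  v <- track_values(tr)
  open <- which(acc > 0.3); closed <- which(acc < -0.3)
  expect_gt(mean(v[open]), 3 * mean(v[closed]))
})

test_that("expression table reproduces planted classes", {
  g <- test_genome()
  # zero noise: classifier round-trips the planted up set exactly
  e0 <- simulate_expression_table(g, seed = 2L, noise_sd = 0)
  up_planted <- g$genes$gene_id[g$genes$class %in%
                                  c("up_access_only", "up_access_and_occ_loss")]
  expect_setequal(classify_upregulated_genes(e0), up_planted)
  # default noise keeps folds on the right side of the class boundaries
  e1 <- simulate_expression_table(g, seed = 2L)
  up <- e1[e1$class %in% c("up_access_only", "up_access_and_occ_loss")]
  expect_true(all(up$expr_1h / up$expr_0h >= 2))
  unch <- e1[e1$class == "unchanged"]
  expect_true(all(abs(unch$log2fc_0_1) < 0.2 & abs(unch$log2fc_1_4) < 0.2))
  # different seeds: different noise, same labels
  e2 <- simulate_expression_table(g, seed = 3L)
  expect_false(isTRUE(all.equal(e1$expr_1h, e2$expr_1h)))
  expect_identical(e1$class, e2$class)
})
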