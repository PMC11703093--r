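test_that("DP score distribution equals exhaustive enumeration for small widths", {
  for (seed in 1:6) {
    p <- random_pwm(width = sample(3:6, 1), seed = seed)
    th <- score_threshold(p, p_cut = 0.2)
    en <- enum_score_tail(p)
    # tail probability at every DP bin score must match the enumeration
    for (s in sample(th$scores, min(20, length(th$scores)))) {
      dp_tail <- th$tail[match(s, th$scores)]
      en_tail <- sum(en$probs[en$scores >= s - 1e-9])
      expect_equal(dp_tail, en_tail, tolerance = 1e-9)
    }
  }
})

test_that("threshold edge cases behave", {
  p <- random_pwm(4, seed = 31)
  th1 <- score_threshold(p, p_cut = 1)
  expect_equal(th1$threshold, min(th1$scores))   # everything passes

  # degenerate PWM equal to background: all scores 0, no hits downstream
  flat <- pwm(matrix(0.25, 4, 5), pseudocount = 0)
  thf <- suppressWarnings(score_threshold(flat, p_cut = 0.5))
  expect_true(all(abs(thf$scores) < 1e-9))
  expect_warning(score_threshold(flat, p_cut = 0.4), "resolution")
  hits <- scan_pwm(gen_random_seq(1000, seed = 32), flat,
                   suppressWarnings(score_threshold(flat, 0.4)$threshold + 1))
  expect_equal(nrow(hits), 0)

  # p_cut below 1/4^W resolution warns and returns the max score
  strong <- strong_pwm(width = 6, seed = 33)
  expect_warning(score_threshold(strong, p_cut = 1e-9), "resolution")
})

test_that("scanning finds planted consensus sites and respects strand symmetry", {
  p <- strong_pwm(width = 12, seed = 34)
  thr <- score_threshold(p, 1e-6)$threshold
  cons <- pwm_consensus(p)
  s <- paste0(gen_random_seq(500, seed = 35), cons,
              gen_random_seq(300, seed = 36), cons,
              gen_random_seq(200, seed = 37))
  h <- scan_pwm(s, p, thr)
  expect_true(all(c(500, 812) %in% h$start))

  # reverse-complemented sequence: hits mirror with flipped strands
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  h_rc <- scan_pwm(rc, p, thr)
  L <- nchar(s)
  expect_setequal(L - 12 - h$start, h_rc$start)
  expect_equal(nrow(h), nrow(h_rc))

  # windows containing N are skipped
  s_n <- paste0(substr(s, 1, 505), "N", substr(s, 507, L))
  h_n <- scan_pwm(s_n, p, thr)
  expect_false(500 %in% h_n$start)
  expect_true(812 %in% h_n$start)
})

test_that("random-sequence hit counts are consistent with the p-value cutoff", {
  p <- strong_pwm(width = 12, seed = 38)
  p_cut <- 1e-5
  th <- score_threshold(p, p_cut)
  # actual tail at the threshold (<= p_cut by construction)
  actual <- th$tail[match(th$threshold, th$scores)]
  set.seed(39)
  n_rep <- 40; L <- 10000
  hits <- vapply(1:n_rep, function(i)
    nrow(scan_pwm(gen_random_seq(L, gc = 0.5), p, th$threshold)), numeric(1))
  lambda <- 2 * actual * (L - 12 + 1) * n_rep
  expect_lte(sum(hits), qpois(0.999, lambda) + 1)
  expect_gte(sum(hits), qpois(0.001, lambda))
})

test_that("block restriction scales hit counts with coverage", {
  p <- strong_pwm(width = 8, seed = 40, major = 0.97)
  thr <- score_threshold(p, 1e-4)$threshold
  set.seed(41)
  g <- list(g1 = c(chr1 = gen_random_seq(40000, gc = 0.5)))
  full <- count_in_blocks(g, NULL, p, thr)
  whole <- count_in_blocks(g, data.frame(genome = "g1", chrom = "chr1",
                                         start = 0, end = 40000), p, thr)
  expect_equal(full, whole)
  none <- count_in_blocks(g, data.frame(genome = "g1", chrom = "chr1",
                                        start = 0, end = 0)[0, ], p, thr)
  expect_equal(unname(none), 0L)
  half <- count_in_blocks(g, data.frame(genome = "g1", chrom = "chr1",
                                        start = 0, end = 20000), p, thr)
  expect_lte(half, full)
})

test_that("the erosion statistic reproduces printed lineage means", {
  expect_equal(round(erosion_percent(rep(3329, 5), rep(3230, 7)), 2), 2.97)
  expect_error(erosion_percent(c(0, 0), c(1, 2)), "zero")
})

test_that("erosion test is null-centred for identical lineages and seeded", {
  p <- strong_pwm(width = 12, seed = 42)
  er <- gen_eroded_genomes(p = p, n_per_lineage = c(2, 2), erosion_frac = 0,
                           n_instances = 60, base_length = 2e4,
                           neutral_rate = 0, seed = 43)
  res <- erosion_test(er$genomes_a, er$genomes_b, p, er$blocks_a, er$blocks_b,
                      n_perm = 19, seed = 44)
  expect_equal(res$percent_reduction, 0)
  expect_equal(res$observed_diff, 0)
  expect_gt(res$p, 0.5)

  # identical nulls under a fixed seed; invariance to within-lineage order
  res2 <- erosion_test(er$genomes_a, er$genomes_b, p, er$blocks_a, er$blocks_b,
                       n_perm = 19, seed = 44)
  expect_identical(res$null, res2$null)
  res3 <- erosion_test(rev(er$genomes_a), er$genomes_b, p,
                       er$blocks_a, er$blocks_b, n_perm = 19, seed = 44)
  expect_equal(res3$observed_diff, res$observed_diff)
})

test_that("erosion p-values are not systematically small without erosion", {
  # scaled-down calibration: small genomes, few permutations
  p <- strong_pwm(width = 12, seed = 45)
  set.seed(46)
  ps <- vapply(1:10, function(i) {
    er <- gen_eroded_genomes(p = p, n_per_lineage = c(2, 2), erosion_frac = 0,
                             n_instances = 40, base_length = 15000,
                             neutral_rate = 2e-4, seed = 400 + i)
    erosion_test(er$genomes_a, er$genomes_b, p, er$blocks_a, er$blocks_b,
                 n_perm = 19, seed = 500 + i)$p
  }, numeric(1))
  expect_lte(mean(ps <= 0.05), 0.3)
})

test_that("hotspot motif enrichment computes folds and retention", {
  res <- enrichment_at_hotspots(c(rep(1, 10), rep(0, 90)),
                                c(rep(1, 10), rep(0, 90)))
  expect_equal(res$fold, 1)
  expect_false(res$retained)

  res2 <- enrichment_at_hotspots(c(rep(1, 10), rep(0, 90)),
                                 c(rep(1, 5), rep(0, 95)))
  expect_equal(res2$fold, 2)
  expect_true(res2$retained)   # fold 2 and 10% of hotspots carry it

  res3 <- enrichment_at_hotspots(c(rep(1, 4), rep(0, 96)),
                                 c(rep(1, 2), rep(0, 98)))
  expect_false(res3$retained)  # fold 2 but below the 5% carrier rule

  # planted-motif simulation: strong enrichment, small p
  res4 <- enrichment_at_hotspots(c(rep(1, 60), rep(0, 40)), rbinom(400, 1, 0.05))
  expect_true(res4$retained)
  expect_lt(res4$p, 0.05)
})

test_that("GC-matched controls reproduce the hotspot GC histogram bin-for-bin", {
  set.seed(47)
  genome <- c(chr1 = gen_random_seq(2e5, gc = 0.45))
  mask <- build_mask(c(chr1 = 2e5))
  hot_gc <- c(0.40, 0.42, 0.44, 0.45, 0.46, 0.50)
  ctrl <- sample_gc_matched_controls(genome, hot_gc, mask, n_per_target = 3,
                                     width = 500, seed = 48)
  expect_equal(nrow(ctrl), 3 * length(hot_gc))
  expect_equal(as.vector(table(floor(ctrl$gc / 0.025))),
               as.vector(3 * table(floor(hot_gc / 0.025))))
})

test_that("central enrichment is detected by the one-tailed binomial test", {
  expect_equal(centrality_test(numeric(0), 500, 5000)$p, 1)

  set.seed(49)
  centered <- rnorm(50, 0, 80)
  res_c <- centrality_test(centered, 500, 5000)
  expect_lt(res_c$p, 1e-6)

  uniform_ps <- vapply(1:40, function(i)
    centrality_test(runif(60, -2500, 2500), 500, 5000)$p, numeric(1))
  expect_gt(mean(uniform_ps), 0.2)   # roughly uniform, not inflated
  expect_lt(mean(uniform_ps <= 0.05), 0.25)

  dens <- centrality_test(centered, 500, 5000)$density
  expect_equal(dens$pos[which.max(dens$density)], 0, tolerance = 150)
})

test_that("MEME minimal format round-trips PWMs", {
  p <- random_pwm(9, seed = 50)
  f <- withr::local_tempfile(fileext = ".meme")
  write_meme(p, f)
  back <- read_meme(f)
  expect_equal(length(back), 1)
  expect_equal(back[[1]]$mat, p$mat, tolerance = 1e-5)
  expect_equal(back[[1]]$width, p$width)
})
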