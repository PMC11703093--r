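test_that("overlap percentages use the smaller set as denominator", {
  a <- hotspot_set("chr1", seq(0, 615) * 1e4, seq(0, 615) * 1e4 + 2000)
  # 167 of a's hotspots are overlapped; the rest of b lies elsewhere
  b_start <- c(seq(0, 166) * 1e4 + 500, 7e6 + seq_len(1924 - 167) * 1e4)
  b <- hotspot_set("chr1", b_start, b_start + 2000)
  ov <- overlap_sets(a, b)
  expect_equal(ov$n_shared, 167)
  expect_equal(ov$denominator, 616)
  expect_equal(round(ov$percent_shared), 27)
  expect_equal(overlap_sets(b, a)$percent_shared, ov$percent_shared) # symmetric

  expect_equal(overlap_sets(a, a)$percent_shared, 100)
  dis <- hotspot_set("chr1", 1e7 + (1:10) * 1e4, 1e7 + (1:10) * 1e4 + 2000)
  expect_equal(overlap_sets(a, dis)$n_shared, 0)
  expect_error(overlap_sets(a, hotspot_set(character(), numeric(), numeric())),
               "empty")
})

test_that("single-bp overlaps count under the default minimum", {
  a <- hotspot_set("chr1", 1000, 3000)
  b <- hotspot_set("chr1", 2999, 5000)
  expect_equal(overlap_sets(a, b)$n_shared, 1)
  b2 <- hotspot_set("chr1", 3000, 5000)   # abutting, zero overlap
  expect_equal(overlap_sets(a, b2)$n_shared, 0)
})

test_that("genome masks record exclusion reasons that re-derive from inputs", {
  cl <- c(chr1 = 1e6)
  m <- random_map(1000, seed = 91)
  attr(m, "chrom_lengths") <- cl
  div <- data.frame(chrom = "chr1", start = seq(0, 9.9e5, by = 1e4),
                    end = seq(1e4, 1e6, by = 1e4))
  set.seed(92)
  div$value <- rnorm(nrow(div), 0.005, 0.001)
  gaps <- data.frame(chrom = "chr1", start = c(1e5, 3e5, 5e5),
                     end = c(1e5 + 5000, 3e5 + 500, 5e5 + 200))
  hs <- hotspot_set("chr1", 7e5, 702000)
  mask <- build_mask(cl, map = m, diversity = div, gaps = gaps, hs = hs)

  ex <- mask$excluded
  qs <- quantile(div$value, c(0.025, 0.975))
  expect_equal(sum(ex$reason == "diversity"),
               sum(div$value < qs[1] | div$value > qs[2]))
  expect_equal(sum(ex$reason == "extreme_rho"),
               sum(m$rho > quantile(m$rho, 0.999)))
  expect_equal(sum(ex$reason == "gap"), 1)   # only the largest 10% of gaps
  expect_equal(sum(ex$reason == "hotspot"), 1)
  # allowed and excluded tile the genome
  expect_equal(sum(mask$allowed$end - mask$allowed$start) +
                 sum(recfin:::.reduce_intervals(ex)$end -
                       recfin:::.reduce_intervals(ex)$start), 1e6)
})

test_that("uniform tracks and no hotspots leave only gap-derived exclusions", {
  cl <- c(chr1 = 1e5)
  gaps <- data.frame(chrom = "chr1", start = c(1e4, 5e4), end = c(2e4, 5.1e4))
  mask <- build_mask(cl, gaps = gaps)
  expect_true(all(mask$excluded$reason == "gap"))
})

test_that("random placements respect the mask and fixed seeds reproduce", {
  cl <- c(chr1 = 1e6)
  hs <- hotspot_set("chr1", seq(1e5, 9e5, by = 1e5),
                    seq(1e5, 9e5, by = 1e5) + 50000)
  mask <- build_mask(cl, hs = hs)
  set.seed(1)
  for (i in 1:20) {
    sp <- recfin:::.place_random_spots(30, 2000, mask)
    expect_equal(nrow(sp), 30)
    hits <- GenomicRanges::countOverlaps(recfin:::.as_granges(sp),
                                         recfin:::.as_granges(hs))
    expect_true(all(hits == 0))
    expect_true(all(sp$start[-1] >= sp$end[-30] | sp$chrom[-1] != sp$chrom[-30]))
  }

  a <- hotspot_set("chr1", seq(1000, 90000, by = 3000),
                   seq(1000, 90000, by = 3000) + 2000)
  b <- hotspot_set("chr1", seq(2000, 91000, by = 3000),
                   seq(2000, 91000, by = 3000) + 2000)
  m_open <- build_mask(c(chr1 = 1e6))
  r1 <- permutation_null(a, b, m_open, n_perm = 50, seed = 7)
  r2 <- permutation_null(a, b, m_open, n_perm = 50, seed = 7)
  expect_identical(r1$null, r2$null)

  # the fast sorted-interval hit counter agrees with countOverlaps
  set.seed(8)
  for (i in 1:10) {
    x <- recfin:::.place_random_spots(40, 1500, m_open)
    fast <- recfin:::.count_hits_sorted(x, b)
    slow <- sum(GenomicRanges::countOverlaps(recfin:::.as_granges(x),
                                             recfin:::.as_granges(b)) > 0)
    expect_equal(fast, slow)
  }

  # a full-genome mask makes placement impossible
  full <- build_mask(cl, hs = hotspot_set("chr1", 0, 1e6))
  expect_error(permutation_null(a, b, full, n_perm = 5), "allowed space")
})

test_that("null overlap counts match the analytic expectation without a mask", {
  # E[overlaps] = n_a x coverage of b dilated by the spot width / genome length
  cl <- c(chr1 = 1e7)
  mask <- build_mask(cl)
  b_start <- seq(5e4, 9.9e6, by = 5e4)
  b <- hotspot_set("chr1", b_start, b_start + 2000)
  n_a <- 100; width <- 2000
  a <- hotspot_set("chr1", seq(1e4, 2e6, length.out = n_a),
                   seq(1e4, 2e6, length.out = n_a) + width)
  res <- permutation_null(a, b, mask, n_perm = 200, seed = 11, width = width)
  p_hit <- nrow(b) * (2000 + width) / 1e7
  expected <- n_a * p_hit
  se <- sqrt(n_a * p_hit * (1 - p_hit) / 200)
  expect_lt(abs(mean(res$null) - expected), 3 * se + 0.5)
})

test_that("an empty comparison set gives p = 1 and an all-zero null", {
  a <- hotspot_set("chr1", c(1000, 5000), c(3000, 7000))
  res <- permutation_null(a, hotspot_set(character(), numeric(), numeric()),
                          build_mask(c(chr1 = 1e5)), n_perm = 10)
  expect_equal(res$n_shared, 0L)
  expect_equal(res$p, 1)
  expect_true(all(res$null == 0))
})

test_that("hotspot lifting maps contained intervals and drops the rest", {
  lt <- data.frame(chrom = "chr1", start = c(0, 50000),
                   end = c(20000, 80000),
                   dest_chrom = c("c2", "c2"),
                   dest_start = c(100000, 0), dest_end = c(120000, 30000))
  hs <- hotspot_set("chr1", c(1000, 55000, 30000), c(3000, 57000, 32000))
  lf <- lift_hotspots(hs, lt)
  expect_equal(lf$n_dropped, 1)          # 30000-32000 is outside both blocks
  expect_equal(lf$lifted$start, c(5000, 101000))
  expect_equal(lf$lifted$chrom, c("c2", "c2"))

  # round trip back through the inverted table is the identity
  inv <- data.frame(chrom = lt$dest_chrom, start = lt$dest_start,
                    end = lt$dest_end, dest_chrom = lt$chrom,
                    dest_start = lt$start, dest_end = lt$end)
  back <- lift_hotspots(lf$lifted, inv)
  expect_equal(back$n_dropped, 0)
  expect_setequal(back$lifted$start, c(1000, 55000))

  # identity table
  idt <- data.frame(chrom = "chr1", start = 0, end = 1e5,
                    dest_chrom = "chr1", dest_start = 0, dest_end = 1e5)
  expect_equal(lift_hotspots(hs, idt)$lifted$start, sort(hs$start))
})

test_that("rate-class comparison flags shifted classes and rejects degenerate input", {
  m <- random_map(1000, seed = 101)
  iv <- function(starts) data.frame(chrom = "chr1", start = starts,
                                    end = starts + 2000)
  set.seed(102)
  c1 <- iv(sort(sample(seq(0, 4.8e5, by = 2000), 50)))
  c2 <- iv(sort(sample(seq(0, 4.8e5, by = 2000), 50)))
  shifted <- m
  res_null <- compare_rate_classes(m, list(a = c1, b = c2))
  expect_gt(res_null$kruskal_p, 0.001)

  m10 <- m
  for (i in seq_len(nrow(c1))) {
    sel <- m10$start >= c1$start[i] & m10$end <= c1$end[i]
    m10$rho[sel] <- m10$rho[sel] * 10
  }
  res_shift <- compare_rate_classes(m10, list(a = c1, b = c2))
  expect_lt(res_shift$kruskal_p, 0.05)
  expect_true(all(dim(res_shift$pairwise_p) == c(1, 1)))

  expect_error(compare_rate_classes(m, list(a = c1)), "2 classes")
})

test_that("permutation p-values are conservative-to-uniform under the null", {
  # both hotspot sets placed uniformly in allowed space; the fraction of
  # datasets with p <= 0.05 should sit near (at or just below) 5%
  cl <- c(chr1 = 5e6)
  mask <- build_mask(cl)
  set.seed(201)
  ps <- vapply(1:60, function(i) {
    a <- recfin:::.place_random_spots(150, 2000, mask)
    b <- recfin:::.place_random_spots(150, 2000, mask)
    permutation_null(hotspot_set(a$chrom, a$start, a$end),
                     hotspot_set(b$chrom, b$start, b$end),
                     mask, n_perm = 59)$p
  }, numeric(1))
  expect_gte(mean(ps <= 0.05), 0)
  expect_lte(mean(ps <= 0.05), 0.15)
  expect_gt(mean(ps), 0.3)   # not systematically anti-conservative
})
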