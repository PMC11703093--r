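# Fixtures and independent oracles used across the suite. Everything is
# generated in code; no data files.

# a constant-rate map tiling one chromosome
const_map <- function(n = 100, width = 1000, rho = 1, chrom = "chr1") {
  s <- seq(0, by = width, length.out = n)
  rho_map(chrom, s, s + width, rep(rho, n),
          chrom_lengths = setNames(n * width, chrom))
}

# random contiguous inter-SNP map
random_map <- function(n = 200, chrom = "chr1", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cuts <- sort(sample(seq_len(n * 500 - 1), n - 1))
  s <- c(0, cuts); e <- c(cuts, n * 500)
  rho_map(chrom, s, e, rgamma(n, 1),
          chrom_lengths = setNames(n * 500, chrom))
}

# brute-force per-bp expansion of a map (small instances only)
per_bp_rho <- function(map) {
  unlist(lapply(seq_len(nrow(map)), function(i)
    rep(map$rho[i], map$end[i] - map$start[i])))
}

# naive O(n^2) raw hotspot caller used as an oracle:
# literal re-statement of the definition, no prefix sums
naive_raw_hotspots <- function(map, fold = 5, flank = 50000) {
  out <- NULL
  for (chr in unique(map$chrom)) {
    d <- map[map$chrom == chr, ]
    n <- nrow(d)
    fm <- vapply(seq_len(n), function(i) {
      spans <- rbind(c(max(d$start[i] - flank, 0), d$start[i]),
                     c(d$end[i], d$end[i] + flank))
      num <- 0; den <- 0
      for (j in seq_len(n)) {
        if (j == i) next
        for (k in 1:2) {
          ov <- min(d$end[j], spans[k, 2]) - max(d$start[j], spans[k, 1])
          if (ov > 0) { num <- num + d$rho[j] * ov; den <- den + ov }
        }
      }
      if (den > 0) num / den else NA_real_
    }, numeric(1))
    q <- !is.na(fm) & d$rho > 0 & d$rho >= fold * fm
    if (!any(q)) next
    run <- cumsum(c(TRUE, !(q[-n] & d$start[-1] == d$end[-n])))[q]
    for (ii in split(which(q), run[seq_len(sum(q))]))
      out <- rbind(out, data.frame(chrom = chr, start = d$start[ii[1]],
                                   end = d$end[ii[length(ii)]],
                                   peak = max(d$rho[ii])))
  }
  out
}

# enumeration oracle for the PWM score distribution: all 4^W words, scores
# binned exactly as the DP bins them
enum_score_tail <- function(p, bin = 0.01) {
  k <- round(recfin:::.pwm_scores(p) / bin)
  W <- p$width
  words <- as.matrix(expand.grid(rep(list(1:4), W)))
  scores <- numeric(nrow(words))
  probs <- numeric(nrow(words)) + 1
  for (j in seq_len(W)) {
    scores <- scores + k[words[, j], j]
    probs <- probs * p$bkg[words[, j]]
  }
  o <- order(scores)
  list(scores = scores[o] * bin, probs = probs[o])
}

# strong near-consensus PWM of a given width
strong_pwm <- function(width = 12, seed = 1, major = 0.91) {
  set.seed(seed)
  mat <- matrix((1 - major) / 3, 4, width)
  for (j in seq_len(width)) mat[sample(4, 1), j] <- major
  pwm(mat)
}

random_pwm <- function(width, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mat <- matrix(rgamma(4 * width, 1), 4, width)
  pwm(sweep(mat, 2, colSums(mat), "/"))
}

# a perfect C2H2 unit and variants
zf_unit <- function(x = strsplit("QKRTNSGCEKCGKAFSRSDHLTRHQRTH", "")[[1]]) {
  paste(x, collapse = "")
}
zf_unit_sub <- function(pos, aa) {
  x <- strsplit(zf_unit(), "")[[1]]
  x[pos] <- aa
  paste(x, collapse = "")
}
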