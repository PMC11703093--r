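#' Construct a position weight matrix
#'
#' @param mat 4 x W matrix of per-column base probabilities, rows A/C/G/T;
#'   columns must sum to 1.
#' @param bkg background base frequencies (default uniform).
#' @param pseudocount pseudocount mixed into the probabilities before
#'   log-odds (default 0.1): p' = (p + pc * bkg) / (1 + pc).
#' @param name optional motif name.
#' @return a `pwm` object.
#' @export
pwm <- function(mat, bkg = rep(0.25, 4), pseudocount = 0.1, name = "motif") {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 4, all(abs(colSums(mat) - 1) < 1e-9),
            length(bkg) == 4, abs(sum(bkg) - 1) < 1e-9, all(bkg > 0))
  rownames(mat) <- c("A", "C", "G", "T")
  structure(list(mat = mat, bkg = bkg, pseudocount = pseudocount,
                 name = name, width = ncol(mat)), class = "pwm")
}

# log2-odds score matrix (bits), pseudocount applied
.pwm_scores <- function(p) {
  q <- (p$mat + p$pseudocount * p$bkg) / (1 + p$pseudocount)
  log2(q / p$bkg)
}

#' Consensus sequence of a PWM
#' @param p a [pwm()].
#' @return character string of most probable bases.
#' @export
pwm_consensus <- function(p) {
  paste(rownames(p$mat)[apply(p$mat, 2, which.max)], collapse = "")
}

#' Permute the column order of a PWM
#'
#' Shuffling columns preserves base composition and information content: the
#' permuted motif is equally "motif-like" but targets a different word, which
#' is exactly the property the erosion null requires.
#'
#' @param p a [pwm()].
#' @param perm optional explicit permutation of seq_len(width).
#' @return a [pwm()] with reordered columns.
#' @export
pwm_shuffle_columns <- function(p, perm = NULL) {
  if (is.null(perm)) perm <- sample.int(p$width)
  pwm(p$mat[, perm, drop = FALSE], p$bkg, p$pseudocount,
      name = paste0(p$name, "_shuffled"))
}

#' Exact log-odds score distribution and p-value threshold
#'
#' Computes the exact null distribution of the log-odds score under the
#' background model by dynamic programming over scores discretised into
#' `bin`-bit bins (tail probabilities evaluated on the conservative upper bin
#' edge), and returns the smallest score whose tail probability is at most
#' `p_cut`. Because column order does not change the distribution, the same
#' threshold applies to any column permutation of the matrix.
#'
#' @param p a [pwm()].
#' @param p_cut p-value cutoff (default 1e-7, the usual FIMO-style setting).
#' @param bin score discretisation in bits (default 0.01).
#' @return list (threshold in bits, p_cut, scores, tail): `scores` are bin
#'   scores and `tail[i]` = P(score >= scores[i]).
#' @export
score_threshold <- function(p, p_cut = 1e-7, bin = 0.01) {
  stopifnot(p_cut > 0, p_cut <= 1)
  k <- round(.pwm_scores(p) / bin)   # integer bin per base and column
  dist <- 1
  offset <- 0
  for (j in seq_len(p$width)) {
    kmin <- min(k[, j]); kmax <- max(k[, j])
    new <- numeric(length(dist) + (kmax - kmin))
    for (b in 1:4) {
      sh <- k[b, j] - kmin
      new[(1 + sh):(sh + length(dist))] <-
        new[(1 + sh):(sh + length(dist))] + p$bkg[b] * dist
    }
    dist <- new
    offset <- offset + kmin
  }
  scores <- (offset + seq_along(dist) - 1) * bin
  tail_p <- rev(cumsum(rev(dist)))
  ok <- which(tail_p <= p_cut)
  if (!length(ok)) {
    warning("p_cut below the attainable resolution; threshold set to max score")
    thr <- scores[length(scores)]
  } else {
    thr <- scores[min(ok)]
  }
  if (p_cut >= 1) thr <- scores[1]
  list(threshold = thr, p_cut = p_cut, scores = scores, tail = tail_p)
}

# encode a sequence as integers 1..4 (A,C,G,T), NA otherwise
.encode_dna <- function(seq) {
  x <- utf8ToInt(toupper(as.character(seq)))
  out <- rep(NA_integer_, length(x))
  out[x == utf8ToInt("A")] <- 1L
  out[x == utf8ToInt("C")] <- 2L
  out[x == utf8ToInt("G")] <- 3L
  out[x == utf8ToInt("T")] <- 4L
  out
}

#' Scan a sequence with a PWM
#'
#' Scores every window on both strands with the log-odds matrix and reports
#' hits at or above the threshold. Windows containing N (or any non-ACGT
#' base) are skipped. Reverse-strand hits are reported at the forward-strand
#' coordinate of the window's leftmost base.
#'
#' @param seq character string or [Biostrings::DNAString].
#' @param p a [pwm()].
#' @param threshold log-odds threshold in bits (from [score_threshold()]).
#' @param bin score discretisation in bits; must match the value used for the
#'   threshold so that scan scores and the threshold live in the same
#'   discretised score space.
#' @return data.frame (start 0-based, strand, score).
#' @export
scan_pwm <- function(seq, p, threshold, bin = 0.01) {
  x <- .encode_dna(seq)
  W <- p$width
  L <- length(x)
  if (L < W) return(data.frame(start = integer(), strand = character(),
                               score = numeric()))
  smat <- round(.pwm_scores(p) / bin) * bin
  n <- L - W + 1L
  fwd <- numeric(n); rev_ <- numeric(n)
  # reverse strand == forward scan with the reverse-complemented score matrix
  smat_rc <- smat[4:1, W:1, drop = FALSE]
  for (j in seq_len(W)) {
    xi <- x[j:(j + n - 1L)]
    fwd <- fwd + smat[, j][xi]
    rev_ <- rev_ + smat_rc[, j][xi]
  }
  eps <- bin / 2   # guard against accumulated floating error at bin edges
  hf <- which(!is.na(fwd) & fwd >= threshold - eps)
  hr <- which(!is.na(rev_) & rev_ >= threshold - eps)
  out <- data.frame(
    start = c(hf, hr) - 1L,
    strand = rep(c("+", "-"), c(length(hf), length(hr))),
    score = unname(c(fwd[hf], rev_[hr]))
  )
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count PWM hits within collinear blocks, per genome
#'
#' Restricting counts to alignable blocks makes motif counts comparable
#' between assemblies of different sizes. Hits are counted inside each block
#' only (a window straddling a block edge is not counted).
#'
#' @param genomes named list; each genome is a named character vector of
#'   chromosome sequences.
#' @param blocks data.frame (genome, chrom, start, end); NULL counts over the
#'   whole of every genome.
#' @param p a [pwm()].
#' @param threshold log-odds threshold.
#' @return named integer vector of per-genome hit counts.
#' @export
count_in_blocks <- function(genomes, blocks = NULL, p, threshold) {
  vapply(names(genomes), function(g) {
    chroms <- genomes[[g]]
    if (is.null(names(chroms)))
      names(chroms) <- paste0("chr", seq_along(chroms))
    total <- 0L
    for (chr in names(chroms)) {
      b <- if (is.null(blocks)) data.frame(start = 0, end = nchar(chroms[[chr]]))
           else blocks[blocks$genome == g & blocks$chrom == chr, , drop = FALSE]
      if (nrow(b) == 0L) next
      for (i in seq_len(nrow(b))) {
        sub <- substring(chroms[[chr]], b$start[i] + 1, b$end[i])
        total <- total + nrow(scan_pwm(sub, p, threshold))
      }
    }
    as.integer(total)
  }, integer(1))
}

#' Percent reduction in mean motif count between lineages
#'
#' @param counts_a reference-lineage per-genome counts.
#' @param counts_b compared-lineage per-genome counts.
#' @return 100 * (mean_a - mean_b) / mean_a.
#' @export
erosion_percent <- function(counts_a, counts_b) {
  ma <- mean(counts_a)
  if (ma == 0) stop("reference lineage mean count is zero")
  100 * (ma - mean(counts_b)) / ma
}

#' Between-lineage motif erosion test
#'
#' The observed statistic is the between-lineage difference in mean motif
#' counts within collinear blocks (reported alongside the percent reduction
#' relative to the reference lineage). The null distribution rescans every
#' genome with `n_perm` independent column-order permutations of the matrix
#' at the same score threshold, which column shuffling leaves exactly
#' unchanged. The empirical p uses the +1 correction; two-sided by default.
#'
#' @param genomes_a,genomes_b named lists of genomes (named character vectors
#'   of chromosome sequences), at least 2 per lineage.
#' @param p a [pwm()].
#' @param blocks_a,blocks_b collinear-block tables as in [count_in_blocks()].
#' @param p_cut p-value cutoff for the scan threshold.
#' @param n_perm number of matrix permutations (default 100).
#' @param seed optional integer seed.
#' @param alternative "two.sided" (default) or "greater" (erosion in b).
#' @return an `erosion_result` list: counts_a, counts_b, percent_reduction,
#'   observed_diff, null (count differences), p, n_perm.
#' @export
erosion_test <- function(genomes_a, genomes_b, p, blocks_a = NULL,
                         blocks_b = NULL, p_cut = 1e-7, n_perm = 100,
                         seed = NULL, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(length(genomes_a) >= 2, length(genomes_b) >= 2)
  thr <- score_threshold(p, p_cut)$threshold
  counts_a <- count_in_blocks(genomes_a, blocks_a, p, thr)
  counts_b <- count_in_blocks(genomes_b, blocks_b, p, thr)
  obs_diff <- mean(counts_a) - mean(counts_b)
  pct <- erosion_percent(counts_a, counts_b)
  null <- .with_seed(seed, vapply(seq_len(n_perm), function(i) {
    ps <- pwm_shuffle_columns(p)
    na <- count_in_blocks(genomes_a, blocks_a, ps, thr)
    nb <- count_in_blocks(genomes_b, blocks_b, ps, thr)
    mean(na) - mean(nb)
  }, numeric(1)))
  pval <- if (alternative == "two.sided")
    (1 + sum(abs(null) >= abs(obs_diff))) / (1 + n_perm)
  else
    (1 + sum(null >= obs_diff)) / (1 + n_perm)
  structure(list(counts_a = counts_a, counts_b = counts_b,
                 percent_reduction = pct, observed_diff = obs_diff,
                 null = null, p = pval, n_perm = n_perm,
                 alternative = alternative),
            class = "erosion_result")
}

#' Motif enrichment at hotspots versus control sequences
#'
#' Fold = fraction of hotspot sequences with at least one hit over the same
#' fraction in controls; Fisher's exact test on the 2x2 table. A motif is
#' retained as a candidate binding motif when the fold is >= `min_fold` and
#' at least `min_frac` of hotspot sequences carry it.
#'
#' @param hits_in,hits_ctrl per-sequence hit counts (or logical has-hit) for
#'   hotspot and control sequences.
#' @param min_fold,min_frac retention thresholds (default 2 and 0.05).
#' @return list (fold, frac_in, frac_ctrl, p, retained).
#' @export
enrichment_at_hotspots <- function(hits_in, hits_ctrl, min_fold = 2,
                                   min_frac = 0.05) {
  stopifnot(length(hits_in) > 0, length(hits_ctrl) > 0)
  a <- sum(hits_in > 0); b <- length(hits_in) - a
  c_ <- sum(hits_ctrl > 0); d <- length(hits_ctrl) - c_
  frac_in <- a / length(hits_in)
  frac_ctrl <- c_ / length(hits_ctrl)
  fold <- if (frac_ctrl > 0) frac_in / frac_ctrl else Inf
  pv <- fisher.test(matrix(c(a, b, c_, d), 2))$p.value
  list(fold = fold, frac_in = frac_in, frac_ctrl = frac_ctrl, p = pv,
       retained = (fold >= min_fold) && (frac_in >= min_frac))
}

#' Draw GC-matched control intervals from the masked genome
#'
#' Bins the hotspot GC-content distribution (default bin width 0.025) and
#' draws `n_per_target` random width-bp spots from the allowed space for each
#' hotspot in its GC bin, so the control GC histogram matches the hotspot
#' histogram bin-for-bin.
#'
#' @param genome named character vector of chromosome sequences.
#' @param hotspot_gc GC fractions of the hotspot sequences.
#' @param mask a [build_mask()] result.
#' @param n_per_target controls per hotspot (default 10).
#' @param bin_width GC bin width (default 0.025).
#' @param width control interval width in bp (default 2000).
#' @param seed optional integer seed.
#' @param max_draws rejection-sampling cap per batch round.
#' @return data.frame (chrom, start, end, gc).
#' @export
sample_gc_matched_controls <- function(genome, hotspot_gc, mask,
                                       n_per_target = 10, bin_width = 0.025,
                                       width = 2000, seed = NULL,
                                       max_draws = 200) {
  gc_of <- function(df) {
    vapply(seq_len(nrow(df)), function(i) {
      s <- substring(genome[[df$chrom[i]]], df$start[i] + 1, df$end[i])
      x <- .encode_dna(s)
      mean(x %in% c(2L, 3L))
    }, numeric(1))
  }
  bins <- floor(hotspot_gc / bin_width)
  quota <- table(bins) * n_per_target
  .with_seed(seed, {
    got <- NULL
    for (round in seq_len(max_draws)) {
      need_total <- sum(quota)
      if (need_total == 0) break
      cand <- .place_random_spots(max(need_total * 2, 50), width, mask)
      cand$gc <- gc_of(cand)
      cand$bin <- as.character(floor(cand$gc / bin_width))
      for (bn in names(quota)) {
        if (quota[bn] == 0) next
        sel <- which(cand$bin == bn)
        take <- head(sel, quota[bn])
        if (length(take)) {
          got <- rbind(got, cand[take, c("chrom", "start", "end", "gc")])
          quota[bn] <- quota[bn] - length(take)
        }
      }
    }
    if (sum(quota) > 0)
      stop("could not fill GC-matched control quotas; allowed space too small")
    rownames(got) <- NULL
    got
  })
}

#' One-tailed central-enrichment test for motif positions
#'
#' Tests whether hits concentrate in the central window of hotspot-centered
#' sequences: the number of hits within `center_window` of the center is
#' compared with a binomial expectation proportional to the window-length
#' fraction. Also returns a triangular-weighted sliding-window positional
#' density.
#'
#' @param hits hit positions relative to the sequence centers (signed bp).
#' @param center_window central window width in bp.
#' @param total_window total examined width in bp (> center_window).
#' @param density_window sliding window for the smoothed density (default
#'   250 bp, triangular weights).
#' @return list (p, n_center, n_total, expected_frac, density).
#' @export
centrality_test <- function(hits, center_window, total_window,
                            density_window = 250) {
  stopifnot(total_window > center_window)
  hits <- hits[abs(hits) <= total_window / 2]
  n_total <- length(hits)
  n_center <- sum(abs(hits) <= center_window / 2)
  expected <- center_window / total_window
  pv <- if (n_total == 0) 1 else
    binom.test(n_center, n_total, p = expected, alternative = "greater")$p.value
  grid <- seq(-total_window / 2, total_window / 2, by = density_window / 10)
  half <- density_window / 2
  dens <- vapply(grid, function(g) {
    w <- pmax(0, 1 - abs(hits - g) / half)
    sum(w) / half
  }, numeric(1))
  list(p = pv, n_center = n_center, n_total = n_total,
       expected_frac = expected,
       density = data.frame(pos = grid, density = dens))
}
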