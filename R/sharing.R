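#' Hotspot overlap between two sets
#'
#' Counts hotspots of the smaller set that intersect at least one hotspot of
#' the other set by at least `min_bp` bp; the percent shared uses the smaller
#' set's size as denominator, making the statistic symmetric in (a, b). A
#' hotspot overlapping several partners counts once.
#'
#' @param a,b [hotspot_set()]s (or plain chrom/start/end frames) on the same
#'   assembly or pre-lifted coordinates.
#' @param min_bp minimum overlap in bp (default 1).
#' @return list (n_shared, percent_shared, denominator).
#' @export
overlap_sets <- function(a, b, min_bp = 1) {
  if (nrow(a) == 0L || nrow(b) == 0L) stop("empty hotspot set")
  if (nrow(a) <= nrow(b)) { small <- a; big <- b } else { small <- b; big <- a }
  n_shared <- sum(GenomicRanges::countOverlaps(
    .as_granges(small), .as_granges(big), minoverlap = min_bp) > 0)
  list(n_shared = n_shared,
       percent_shared = 100 * n_shared / nrow(small),
       denominator = nrow(small))
}

#' Build a genome mask for permutation analyses
#'
#' Excludes (with reason labels) diversity windows outside the stated
#' quantiles, the intervals carrying the very highest recombination rates, the
#' largest assembly gaps, and the hotspots themselves; the allowed space is
#' the merged complement.
#'
#' @param chrom_lengths named chromosome lengths (bp).
#' @param map optional [rho_map()] used for the extreme-rate exclusion.
#' @param diversity optional windowed diversity track (chrom/start/end/value).
#' @param gaps optional assembly-gap intervals (chrom/start/end).
#' @param hs optional [hotspot_set()] to exclude.
#' @param q_div lower/upper diversity quantiles kept (default 0.025/0.975).
#' @param q_rho_top fraction of highest-rho intervals excluded (default 0.001).
#' @param q_gap_top fraction of largest gaps excluded (default 0.10).
#' @return a `genome_mask` list (excluded with reasons, allowed, chrom_lengths).
#' @export
build_mask <- function(chrom_lengths, map = NULL, diversity = NULL,
                       gaps = NULL, hs = NULL,
                       q_div = c(0.025, 0.975), q_rho_top = 0.001,
                       q_gap_top = 0.10) {
  excl <- list()
  add <- function(df, reason) {
    if (!is.null(df) && nrow(df))
      excl[[length(excl) + 1]] <<- data.frame(df[, c("chrom", "start", "end")],
                                              reason = reason)
  }
  if (!is.null(diversity)) {
    qs <- quantile(diversity$value, q_div, na.rm = TRUE)
    add(diversity[!is.na(diversity$value) &
                    (diversity$value < qs[1] | diversity$value > qs[2]), ],
        "diversity")
  }
  if (!is.null(map)) {
    thr <- quantile(map$rho, 1 - q_rho_top)
    add(map[map$rho > thr, ], "extreme_rho")
  }
  if (!is.null(gaps) && nrow(gaps)) {
    len <- gaps$end - gaps$start
    thr <- quantile(len, 1 - q_gap_top)
    add(gaps[len >= thr, ], "gap")
  }
  if (!is.null(hs)) add(hs, "hotspot")
  excluded <- if (length(excl)) do.call(rbind, excl) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               reason = character())
  merged <- .reduce_intervals(excluded)
  allowed <- .complement_intervals(merged, chrom_lengths)
  structure(list(excluded = .sort_intervals(excluded), allowed = allowed,
                 chrom_lengths = chrom_lengths),
            class = "genome_mask")
}

# Count a-intervals overlapping >= 1 bp of some b interval; both frames must
# be sorted and non-overlapping per chromosome. findInterval-based fast path
# used inside the permutation loop (equivalent to countOverlaps > 0).
.count_hits_sorted <- function(a, b) {
  total <- 0L
  bs <- split(b, b$chrom)
  for (chr in unique(a$chrom)) {
    d <- a[a$chrom == chr, , drop = FALSE]
    bb <- bs[[chr]]
    if (is.null(bb) || nrow(bb) == 0L) next
    n <- nrow(bb)
    j <- findInterval(d$start, bb$start)
    hit <- (j >= 1L & bb$end[pmax(j, 1L)] > d$start) |
           (j < n & bb$start[pmin(j + 1L, n)] < d$end)
    total <- total + sum(hit)
  }
  total
}

# Place n non-overlapping width-bp intervals uniformly in the mask's allowed
# space. Rejection sampling with a retry cap; placements never leave allowed
# segments.
.place_random_spots <- function(n, width, mask, max_rounds = 100) {
  seg <- mask$allowed
  seg <- seg[seg$end - seg$start >= width, , drop = FALSE]
  feas <- seg$end - seg$start - width + 1
  total <- sum(feas)
  if (nrow(seg) == 0L || total < n)
    stop("allowed space cannot hold ", n, " intervals of ", width, " bp")
  placed <- NULL
  for (round in seq_len(max_rounds)) {
    need <- n - NROW(placed)
    if (need <= 0L) break
    u <- runif(need) * total
    j <- findInterval(u, cumsum(feas) - feas, rightmost.closed = FALSE)
    j[j == 0L] <- 1L
    off <- floor(u - (cumsum(feas) - feas)[j])
    cand <- data.frame(chrom = seg$chrom[j], start = seg$start[j] + off)
    cand$end <- cand$start + width
    all <- rbind(placed, cand)
    all <- all[order(all$chrom, all$start), ]
    keep <- !logical(nrow(all))
    sp <- split(seq_len(nrow(all)), all$chrom)
    for (idx in sp) {
      if (length(idx) < 2) next
      e <- all$end[idx]; s <- all$start[idx]
      drop <- c(FALSE, s[-1] < cummax(e[-length(e)]))
      keep[idx[drop]] <- FALSE
    }
    placed <- all[keep, , drop = FALSE]
  }
  if (NROW(placed) < n)
    stop("could not place ", n, " non-overlapping intervals after ",
         max_rounds, " rounds")
  placed[seq_len(n), ]
}

#' Random-placement permutation null for hotspot sharing
#'
#' Replaces set `a` by the same number of width-bp intervals placed uniformly
#' (without mutual overlap) in the mask's allowed space, `n_perm` times, and
#' compares the observed count of a-hotspots overlapping `other` with the
#' null counts. The empirical p uses the +1 correction and is never exactly 0.
#'
#' @param a observed [hotspot_set()] (its size and overlap define the
#'   observed statistic).
#' @param other the comparison hotspot set.
#' @param mask a [build_mask()] result.
#' @param n_perm number of permutations (default 1000; 100 is the light
#'   variant).
#' @param width placed interval width in bp; defaults to the median width of
#'   `a` (2000 for 2-kb hotspots).
#' @param min_bp minimum overlap in bp.
#' @param seed optional integer seed for reproducible placements.
#' @return an `overlap_result` list: n_shared, percent_shared, null counts,
#'   empirical p, n_perm.
#' @export
permutation_null <- function(a, other, mask, n_perm = 1000, width = NULL,
                             min_bp = 1, seed = NULL) {
  if (nrow(other) == 0L) {
    obs <- 0L
    null <- integer(n_perm)
    return(structure(list(n_shared = 0L, percent_shared = 0,
                          null = null, p = 1, n_perm = n_perm),
                     class = "overlap_result"))
  }
  if (is.null(width)) width <- stats::median(a$end - a$start)
  n <- nrow(a)
  other_sorted <- .sort_intervals(other[, c("chrom", "start", "end")])
  gr_other <- .as_granges(other)
  count_hits <- function(df) {
    if (min_bp == 1) return(.count_hits_sorted(df, other_sorted))
    sum(GenomicRanges::countOverlaps(.as_granges(df), gr_other,
                                     minoverlap = min_bp) > 0)
  }
  obs <- count_hits(a)
  null <- .with_seed(seed, vapply(seq_len(n_perm), function(i)
    count_hits(.place_random_spots(n, width, mask)), numeric(1)))
  structure(list(
    n_shared = obs,
    percent_shared = 100 * obs / min(n, nrow(other)),
    null = null,
    p = (1 + sum(null >= obs)) / (1 + n_perm),
    n_perm = n_perm
  ), class = "overlap_result")
}

#' Lift hotspots through a table of homologous blocks
#'
#' Maps intervals fully contained in a source block to the homologous target
#' block at the same offset; intervals not covered are dropped and counted.
#'
#' @param hs a [hotspot_set()] in source coordinates.
#' @param lift_table data.frame with columns chrom/start/end (source) and
#'   dest_chrom/dest_start/dest_end (target), blocks of equal lengths.
#' @return list with `lifted` (hotspot_set in target coordinates) and
#'   `n_dropped`.
#' @export
lift_hotspots <- function(hs, lift_table) {
  stopifnot(all((lift_table$end - lift_table$start) ==
                  (lift_table$dest_end - lift_table$dest_start)))
  gr_q <- .as_granges(hs)
  gr_b <- .as_granges(lift_table)
  ov <- GenomicRanges::findOverlaps(gr_q, gr_b, type = "within")
  qh <- S4Vectors::queryHits(ov); bh <- S4Vectors::subjectHits(ov)
  first <- !duplicated(qh)
  qh <- qh[first]; bh <- bh[first]
  lifted <- data.frame(
    chrom = lift_table$dest_chrom[bh],
    start = lift_table$dest_start[bh] + (hs$start[qh] - lift_table$start[bh]),
    end = lift_table$dest_start[bh] + (hs$end[qh] - lift_table$start[bh]),
    peak = hs$peak[qh], flank_mean = hs$flank_mean[qh], fold = hs$fold[qh]
  )
  list(lifted = hotspot_set(lifted$chrom, lifted$start, lifted$end,
                            lifted$peak, lifted$flank_mean, lifted$fold,
                            caller = attr(hs, "caller")),
       n_dropped = nrow(hs) - length(qh))
}

#' Compare recombination rates between labelled interval classes
#'
#' Computes the bp-weighted mean rate of the map within each interval, then a
#' Kruskal-Wallis omnibus test across classes and pairwise two-sided Wilcoxon
#' post-hoc tests with Benjamini-Hochberg adjustment.
#'
#' @param map a [rho_map()] or windowed map.
#' @param classes named list of interval frames (chrom/start/end), at least 2
#'   classes of at least 2 intervals each.
#' @return list (kruskal_p, pairwise_p matrix, per-class values).
#' @export
compare_rate_classes <- function(map, classes) {
  if (length(classes) < 2) stop("at least 2 classes required")
  track <- data.frame(chrom = map$chrom, start = map$start, end = map$end,
                      value = map$rho)
  track <- track[!is.na(track$value), , drop = FALSE]
  vals <- lapply(classes, function(iv) {
    v <- vapply(seq_len(nrow(iv)), function(i)
      .weighted_mean_over(track, iv[i, , drop = FALSE]), numeric(1))
    v[!is.na(v)]
  })
  if (any(vapply(vals, length, integer(1)) < 2))
    stop("every class needs at least 2 covered intervals")
  x <- unlist(vals, use.names = FALSE)
  g <- factor(rep(names(vals), vapply(vals, length, integer(1))))
  kw <- kruskal.test(x, g)
  pw <- suppressWarnings(pairwise.wilcox.test(x, g, p.adjust.method = "BH",
                                              exact = FALSE))
  list(kruskal_p = kw$p.value, pairwise_p = pw$p.value, values = vals)
}
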