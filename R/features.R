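#' CGI prediction parameters
#'
#' Defaults follow the cpgplot-style parameterisation appropriate for fish
#' genomes, where CpG islands are CpG-rich but carry no elevated GC content:
#' the observed/expected CpG threshold is kept at 0.6 while the minimum GC
#' fraction is 0.
#'
#' @param window sliding window width in bp.
#' @param minlen minimum reported island length in bp.
#' @param minoe minimum averaged observed/expected CpG ratio.
#' @param minpc minimum averaged GC fraction (0 disables the GC constraint).
#' @export
cgi_params <- function(window = 500, minlen = 250, minoe = 0.6, minpc = 0) {
  stopifnot(window >= 1, minlen >= 1, minoe >= 0, minpc >= 0)
  structure(list(window = window, minlen = minlen, minoe = minoe,
                 minpc = minpc), class = "cgi_params")
}

# moving sum of x over windows of length w starting at 1..(n-w+1)
.window_sums <- function(x, w) {
  cs <- c(0, cumsum(x))
  cs[(w + 1):length(cs)] - cs[1:(length(cs) - w)]
}

#' Predict CpG islands from sequence
#'
#' Slides a `window`-bp window stepped by 1 bp; each window's observed/expected
#' CpG ratio is (#CG dinucleotides x window) / (#C x #G) and its GC content is
#' (#C + #G) / window. Every position is then assigned the average of all
#' windows covering it (cpgplot semantics), and maximal runs of positions
#' meeting both thresholds that reach `minlen` are reported as islands.
#' N bases count neither as C/G nor towards CpG dinucleotides.
#'
#' @param seq a character string or [Biostrings::DNAString] over A/C/G/T/N.
#' @param params a [cgi_params()].
#' @param chrom chromosome name attached to the output intervals.
#' @param average per-position averaging over covering windows (TRUE, the
#'   cpgplot dialect) or plain per-window values (FALSE).
#' @return data.frame chrom/start/end (0-based half-open) with mean obs/exp
#'   and GC per island; zero rows when nothing qualifies.
#' @export
predict_cgis <- function(seq, params = cgi_params(), chrom = "chr",
                         average = TRUE) {
  s <- toupper(as.character(seq))
  L <- nchar(s)
  w <- params$window
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      obs_exp = numeric(), gc = numeric())
  if (L < w) {
    warning("sequence shorter than the CGI window; no prediction")
    return(empty)
  }
  ch <- strsplit(s, "")[[1]]
  isC <- ch == "C"; isG <- ch == "G"
  isCG <- c(isC[-L] & isG[-1], FALSE)
  nw <- L - w + 1L
  nC <- .window_sums(isC, w)
  nG <- .window_sums(isG, w)
  # CpG dinucleotide starts fully inside the window: starts i .. i+w-2
  nCG <- .window_sums(isCG, w - 1L)[seq_len(nw)]
  oe <- ifelse(nC * nG > 0, nCG * w / (nC * nG), 0)
  gc <- (nC + nG) / w
  if (average) {
    # position i is covered by windows starting in [i-w+1, i] clipped to [1, nw]
    csoe <- c(0, cumsum(oe)); csgc <- c(0, cumsum(gc))
    i <- seq_len(L)
    lo <- pmax(i - w + 1L, 1L); hi <- pmin(i, nw)
    cnt <- hi - lo + 1L
    pos_oe <- (csoe[hi + 1L] - csoe[lo]) / cnt
    pos_gc <- (csgc[hi + 1L] - csgc[lo]) / cnt
  } else {
    # assign each position its own window's value where defined
    pos_oe <- rep(NA_real_, L); pos_gc <- rep(NA_real_, L)
    pos_oe[seq_len(nw)] <- oe; pos_gc[seq_len(nw)] <- gc
    pos_oe[is.na(pos_oe)] <- oe[nw]; pos_gc[is.na(pos_gc)] <- gc[nw]
  }
  ok <- pos_oe >= params$minoe & pos_gc >= params$minpc
  r <- rle(ok)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= params$minlen
  if (!any(keep)) return(empty)
  data.frame(
    chrom = chrom,
    start = starts[keep] - 1L,
    end = ends[keep],
    obs_exp = vapply(which(keep), function(k)
      mean(pos_oe[starts[k]:ends[k]]), numeric(1)),
    gc = vapply(which(keep), function(k)
      mean(pos_gc[starts[k]:ends[k]]), numeric(1))
  )
}

# absolute distance from each position to the nearest point in `pts` (sorted)
.dist_to_nearest <- function(pos, pts) {
  pts <- sort(pts)
  j <- findInterval(pos, pts)
  left <- ifelse(j >= 1, pos - pts[pmax(j, 1)], Inf)
  right <- ifelse(j < length(pts), pts[pmin(j + 1, length(pts))] - pos, Inf)
  pmin(left, right)
}

#' Recombination fold by distance to the nearest feature point
#'
#' Windows are assigned the distance from their midpoint to the nearest point
#' (e.g. TSS), binned, and bin means are scaled by the mean of the reference
#' bin at `max_dist` so the profile equals 1 far from the feature.
#'
#' @param wmap a windowed map from [smooth_windows()].
#' @param points data.frame chrom/pos (e.g. from [tss_points()]).
#' @param max_dist profile span in bp (default 50000).
#' @param bin distance bin width in bp (default 2000, the map resolution).
#' @return data.frame (dist_lo, dist_hi, mean_rho, fold).
#' @export
fold_by_distance <- function(wmap, points, max_dist = 50000, bin = 2000) {
  if (nrow(points) == 0L) stop("no feature points")
  mid <- (wmap$start + wmap$end) / 2
  d <- rep(Inf, nrow(wmap))
  for (chr in unique(wmap$chrom)) {
    sel <- wmap$chrom == chr
    p <- points$pos[points$chrom == chr]
    if (length(p)) d[sel] <- .dist_to_nearest(mid[sel], p)
  }
  w <- .map_weights(wmap)
  keep <- is.finite(d) & d <= max_dist & !is.na(wmap$rho) & w > 0
  b <- pmin(floor(d[keep] / bin), max_dist / bin - 1)
  num <- tapply(wmap$rho[keep] * w[keep], b, sum)
  den <- tapply(w[keep], b, sum)
  means <- setNames(rep(NA_real_, max_dist / bin),
                    as.character(seq_len(max_dist / bin) - 1))
  means[names(num)] <- num / den
  ref <- means[length(means)]
  if (is.na(ref)) stop("no window at the reference distance (", max_dist, " bp)")
  nb <- length(means)
  data.frame(dist_lo = (seq_len(nb) - 1) * bin, dist_hi = seq_len(nb) * bin,
             mean_rho = as.numeric(means), fold = as.numeric(means) / ref)
}

#' Mean recombination rate per feature class, scaled by the intergenic mean
#'
#' Feature classes may overlap (a CGI can be genic); only intergenic space is
#' exclusive by construction. TSS/TES regions are the 1-kb neighbourhoods of
#' the strand-aware gene ends.
#'
#' @param wmap a windowed map.
#' @param ann a [genome_annotation()].
#' @param tss_flank half-width of the TSS/TES regions in bp (default 1000).
#' @return data.frame (feature, mean_rho, fold).
#' @export
rate_by_feature <- function(wmap, ann, tss_flank = 1000) {
  track <- data.frame(chrom = wmap$chrom, start = wmap$start, end = wmap$end,
                      value = wmap$rho)
  track <- track[!is.na(track$value), , drop = FALSE]
  cl <- ann$chrom_lengths
  pt_iv <- function(p) {
    iv <- data.frame(chrom = p$chrom,
                     start = pmax(p$pos - tss_flank, 0),
                     end = pmin(p$pos + tss_flank, cl[p$chrom]))
    .reduce_intervals(iv)
  }
  classes <- list(
    gene = ann$genes[, c("chrom", "start", "end")],
    te = ann$tes[, c("chrom", "start", "end")],
    cgi = ann$cgis[, c("chrom", "start", "end")],
    tss = pt_iv(tss_points(ann)),
    tes = pt_iv(tes_points(ann)),
    intergenic = ann$intergenic[, c("chrom", "start", "end")]
  )
  classes <- classes[vapply(classes, nrow, integer(1)) > 0]
  means <- vapply(classes, function(iv) .weighted_mean_over(track, iv), numeric(1))
  inter <- means[["intergenic"]]
  if (is.na(inter) || inter <= 0) stop("intergenic mean rate is not positive")
  data.frame(feature = names(means), mean_rho = as.numeric(means),
             fold = as.numeric(means) / inter, row.names = NULL)
}

#' Hotspot density per feature class
#'
#' Counts hotspot midpoints falling in each feature class and divides by the
#' class's total span in Mb.
#'
#' @param hs a [hotspot_set()].
#' @param ann a [genome_annotation()].
#' @param tss_flank half-width of TSS/TES regions in bp.
#' @return data.frame (feature, n, mb, density_per_mb).
#' @export
hotspot_density_by_feature <- function(hs, ann, tss_flank = 1000) {
  cl <- ann$chrom_lengths
  pt_iv <- function(p) .reduce_intervals(data.frame(
    chrom = p$chrom, start = pmax(p$pos - tss_flank, 0),
    end = pmin(p$pos + tss_flank, cl[p$chrom])))
  classes <- list(
    gene = ann$genes[, c("chrom", "start", "end")],
    te = ann$tes[, c("chrom", "start", "end")],
    cgi = ann$cgis[, c("chrom", "start", "end")],
    tss = pt_iv(tss_points(ann)),
    tes = pt_iv(tes_points(ann)),
    intergenic = ann$intergenic[, c("chrom", "start", "end")]
  )
  classes <- classes[vapply(classes, nrow, integer(1)) > 0]
  mids <- data.frame(chrom = hs$chrom, pos = (hs$start + hs$end) / 2)
  out <- lapply(names(classes), function(nm) {
    iv <- classes[[nm]]
    n <- 0L
    for (chr in unique(mids$chrom)) {
      ci <- iv[iv$chrom == chr, , drop = FALSE]
      p <- mids$pos[mids$chrom == chr]
      if (nrow(ci) == 0L || !length(p)) next
      j <- findInterval(p, ci$start)
      n <- n + sum(j > 0 & p < ci$end[pmax(j, 1)])
    }
    mb <- sum(iv$end - iv$start) / 1e6
    data.frame(feature = nm, n = n, mb = mb, density_per_mb = n / mb)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Rank correlation between a windowed map and a covariate track
#'
#' Windows are matched on chrom/start; pairs with either value missing are
#' dropped. Spearman's rank correlation with a two-sided test.
#'
#' @param wmap a windowed map (typically 100-kb windows).
#' @param track a windowed covariate (data.frame chrom/start/end/value, or a
#'   second windowed map whose rho column is used).
#' @return list (rho, p, n).
#' @export
correlate_tracks <- function(wmap, track) {
  val <- if (!is.null(track$value)) track$value else track$rho
  key_a <- paste(wmap$chrom, wmap$start)
  key_b <- paste(track$chrom, track$start)
  j <- match(key_a, key_b)
  x <- wmap$rho; y <- val[j]
  keep <- !is.na(x) & !is.na(y)
  if (sum(keep) < 10) stop("fewer than 10 paired windows")
  ct <- suppressWarnings(cor.test(x[keep], y[keep], method = "spearman"))
  list(rho = unname(ct$estimate), p = ct$p.value, n = sum(keep))
}

#' Covariate profile around hotspot centers
#'
#' Bins the covariate track by distance from the nearest hotspot center (bin
#' width = track window width) out to `span`, and reports the genomic mean as
#' baseline.
#'
#' @param track windowed covariate (chrom/start/end/value or a windowed map).
#' @param hs a [hotspot_set()].
#' @param span profile span in bp; must be a multiple of the track width.
#' @return list with `profile` (data.frame dist_lo, dist_hi, mean) and
#'   `baseline` (genomic mean of the covariate).
#' @export
profile_around_hotspots <- function(track, hs, span = 10000) {
  w <- attr(track, "width")
  if (is.null(w)) w <- stats::median(track$end - track$start)
  if (span %% w != 0) stop("span must be a multiple of the track window width")
  val <- if (!is.null(track$value)) track$value else track$rho
  centers <- (hs$start + hs$end) / 2
  mid <- (track$start + track$end) / 2
  d <- rep(Inf, nrow(track))
  for (chr in unique(track$chrom)) {
    sel <- track$chrom == chr
    p <- centers[hs$chrom == chr]
    if (length(p)) d[sel] <- .dist_to_nearest(mid[sel], p)
  }
  keep <- is.finite(d) & d <= span & !is.na(val)
  b <- pmin(floor(d[keep] / w), span / w - 1)
  means <- tapply(val[keep], b, mean)
  nb <- span / w
  prof <- setNames(rep(NA_real_, nb), as.character(seq_len(nb) - 1))
  prof[names(means)] <- means
  list(profile = data.frame(dist_lo = (seq_len(nb) - 1) * w,
                            dist_hi = seq_len(nb) * w,
                            mean = as.numeric(prof)),
       baseline = mean(val, na.rm = TRUE))
}
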