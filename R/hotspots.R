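#' Construct a hotspot set
#'
#' @param chrom,start,end,peak,flank_mean,fold per-hotspot columns; `fold` is
#'   peak rate over the bp-weighted mean rate of the flanking regions.
#' @param caller `"raw"` (inter-SNP intervals) or `"window2kb"`.
#' @param chrom_lengths optional named chromosome lengths.
#' @return a `hotspot_set` data.frame.
#' @export
hotspot_set <- function(chrom, start, end, peak = NA_real_,
                        flank_mean = NA_real_, fold = NA_real_,
                        caller = "raw", chrom_lengths = NULL) {
  n <- length(chrom)
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end),
                   peak = rep_len(peak, n),
                   flank_mean = rep_len(flank_mean, n),
                   fold = rep_len(fold, n),
                   stringsAsFactors = FALSE)
  df <- .sort_intervals(df)
  .check_intervals(df, "hotspot set")
  structure(df, class = c("hotspot_set", "data.frame"),
            caller = caller, chrom_lengths = chrom_lengths)
}

# bp-weighted mean rate over the two flank spans of each interval, excluding
# the interval itself. Near chromosome ends the available one-sided flank is
# used. Returns NA where no flank bp is covered.
.flank_means <- function(d, flank) {
  ct <- .cum_track(d$start, d$end, d$rho)
  s <- d$start; e <- d$end
  num <- (.mass_at(ct, s) - .mass_at(ct, pmax(s - flank, 0))) +
         (.mass_at(ct, e + flank) - .mass_at(ct, e))
  den <- (.cov_at(ct, s) - .cov_at(ct, pmax(s - flank, 0))) +
         (.cov_at(ct, e + flank) - .cov_at(ct, e))
  ifelse(den > 0, num / den, NA_real_)
}

#' Call hotspots on the raw inter-SNP map
#'
#' An inter-SNP interval qualifies when its rate is at least `fold` times the
#' bp-weighted mean rate of the `flank` bp on each side (the candidate
#' interval itself is excluded from its flank). Maximal runs of contiguous
#' qualifying intervals are merged into one hotspot whose peak is the highest
#' rate in the run.
#'
#' @param map a [rho_map()].
#' @param fold minimum fold over the flanking mean (default 5).
#' @param flank flank span per side in bp (default 50000).
#' @return a [hotspot_set()] with caller tag `"raw"`.
#' @export
call_raw_hotspots <- function(map, fold = 5, flank = 50000) {
  if (nrow(map) == 0L) stop("empty map")
  out <- list()
  any_flank <- FALSE
  for (chr in unique(map$chrom)) {
    d <- map[map$chrom == chr, , drop = FALSE]
    fm <- .flank_means(d, flank)
    if (all(is.na(fm))) next
    any_flank <- TRUE
    q <- !is.na(fm) & d$rho > 0 & d$rho >= fold * fm
    if (!any(q)) next
    # runs of qualifying intervals that are contiguous in coordinates
    n <- nrow(d)
    joined <- c(FALSE, q[-n] & q[-1] & d$start[-1] == d$end[-n])
    run <- cumsum(!joined)[q]
    idx <- which(q)
    out[[chr]] <- do.call(rbind, lapply(split(idx, run), function(ii) {
      peak_i <- ii[which.max(d$rho[ii])]
      data.frame(chrom = chr, start = d$start[ii[1]], end = d$end[ii[length(ii)]],
                 peak = d$rho[peak_i], flank_mean = fm[peak_i],
                 fold = d$rho[peak_i] / fm[peak_i])
    }))
  }
  if (!any_flank)
    stop("flanks uncovered for every interval: chromosomes too short for flank = ", flank)
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      peak = numeric(), flank_mean = numeric(), fold = numeric())
  hotspot_set(res$chrom, res$start, res$end, res$peak, res$flank_mean,
              res$fold, caller = "raw",
              chrom_lengths = attr(map, "chrom_lengths"))
}

#' Call hotspots on a smoothed windowed map
#'
#' Windows qualify as for [call_raw_hotspots()]; within each maximal run of
#' consecutive qualifying windows only the window with the highest rate is
#' retained as a hotspot with the window's own bounds (leftmost window on
#' ties). Windows with no SNP-interval coverage never qualify and break runs.
#'
#' @param wmap a windowed map from [smooth_windows()] (2-kb windows by
#'   convention; any width is accepted).
#' @param fold minimum fold over the flanking mean (default 5).
#' @param flank flank span per side in bp (default 50000).
#' @return a [hotspot_set()] with caller tag `"window<width>"`.
#' @export
call_window_hotspots <- function(wmap, fold = 5, flank = 50000) {
  if (nrow(wmap) == 0L) stop("empty map")
  width <- attr(wmap, "width")
  out <- list()
  for (chr in unique(wmap$chrom)) {
    d0 <- wmap[wmap$chrom == chr, , drop = FALSE]
    cov <- !is.na(d0$rho) & d0$covered > 0
    d <- d0[cov, , drop = FALSE]
    if (nrow(d) == 0L) next
    # flank means over covered windows only, bp-weighted by covered bp:
    # use covered bp as the track weight by rescaling interval extents
    ctd <- data.frame(chrom = chr, start = d$start, end = d$end, rho = d$rho)
    fm <- .flank_means(ctd, flank)
    q <- !is.na(fm) & d$rho > 0 & d$rho >= fold * fm
    qf <- logical(nrow(d0)); qf[cov] <- q
    if (!any(qf)) next
    # runs broken by missing windows or non-qualifiers
    run <- cumsum(c(TRUE, diff(qf) != 0 | !qf[-nrow(d0)]))
    idx <- which(qf)
    runs <- split(idx, cumsum(c(TRUE, diff(idx) != 1L))[seq_along(idx)])
    out[[chr]] <- do.call(rbind, lapply(runs, function(ii) {
      best <- ii[which.max(d0$rho[ii])]   # which.max takes the leftmost tie
      fmi <- fm[match(best, which(cov))]
      data.frame(chrom = chr, start = d0$start[best], end = d0$end[best],
                 peak = d0$rho[best], flank_mean = fmi,
                 fold = d0$rho[best] / fmi)
    }))
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      peak = numeric(), flank_mean = numeric(), fold = numeric())
  hotspot_set(res$chrom, res$start, res$end, res$peak, res$flank_mean,
              res$fold, caller = paste0("window", width),
              chrom_lengths = attr(wmap, "chrom_lengths"))
}

#' Summarize a hotspot set
#'
#' @param hs a [hotspot_set()].
#' @param map the map the hotspots were called on (for the recombination
#'   fraction); may be NULL to skip that statistic.
#' @param genome_len total genome length in bp; defaults to the sum of known
#'   chromosome lengths.
#' @return a `hotspot_summary` list: count, fraction of total recombination
#'   inside hotspots, density per Mb, genome occupancy, width quantiles.
#' @export
summarize_hotspots <- function(hs, map = NULL, genome_len = NULL) {
  if (is.null(genome_len)) {
    cl <- .chrom_lengths(if (is.null(map)) hs else map)
    genome_len <- sum(cl)
  }
  n <- nrow(hs)
  if (n == 0L)
    return(structure(list(count = 0L, recomb_fraction = 0, density_per_mb = 0,
                          occupancy = 0, width_quantiles = NULL),
                     class = "hotspot_summary"))
  widths <- hs$end - hs$start
  frac <- NA_real_
  if (!is.null(map)) {
    tr <- data.frame(chrom = map$chrom, start = map$start, end = map$end,
                     value = map$rho)
    if (!is.null(map$covered)) tr <- tr[!is.na(tr$value), , drop = FALSE]
    total <- sum(tr$value * (tr$end - tr$start))
    inside <- 0
    for (chr in unique(hs$chrom)) {
      t <- tr[tr$chrom == chr, , drop = FALSE]
      if (nrow(t) == 0L) next
      ct <- .cum_track(t$start, t$end, t$value)
      h <- hs[hs$chrom == chr, , drop = FALSE]
      inside <- inside + sum(.mass_at(ct, h$end) - .mass_at(ct, h$start))
    }
    frac <- inside / total
  }
  structure(list(
    count = n,
    recomb_fraction = frac,
    density_per_mb = n / (genome_len / 1e6),
    occupancy = sum(widths) / genome_len,
    width_quantiles = quantile(widths, c(0.05, 0.25, 0.5, 0.75, 0.95))
  ), class = "hotspot_summary")
}

#' @export
print.hotspot_summary <- function(x, ...) {
  cat("Hotspots:", x$count, "\n")
  cat(sprintf("  fraction of recombination: %.3f\n", x$recomb_fraction))
  cat(sprintf("  density: %.2f per Mb\n", x$density_per_mb))
  cat(sprintf("  genome occupancy: %.2f%%\n", 100 * x$occupancy))
  invisible(x)
}

#' Hotspot width distribution
#'
#' Raw-caller hotspots have data-driven widths; most salmonid hotspots are
#' narrower than 2 kb.
#'
#' @param hs a [hotspot_set()] from the raw caller.
#' @param cutoff width cutoff in bp (default 2000).
#' @return list with `quantiles` and `fraction_below`.
#' @export
width_distribution <- function(hs, cutoff = 2000) {
  if (!identical(attr(hs, "caller"), "raw"))
    stop("width_distribution applies to raw-caller hotspots")
  widths <- hs$end - hs$start
  list(quantiles = quantile(widths, c(0.05, 0.25, 0.5, 0.75, 0.95)),
       fraction_below = mean(widths < cutoff))
}

#' Write a hotspot set as BED6 (fold in the score column)
#' @param hs a [hotspot_set()].
#' @param path output path.
#' @export
write_hotspots_bed <- function(hs, path) {
  bed <- data.frame(hs$chrom, as.integer(hs$start), as.integer(hs$end),
                    name = paste0("hs", seq_len(nrow(hs))),
                    score = round(ifelse(is.finite(hs$fold), hs$fold, 0), 3),
                    strand = ".")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a hotspot set from BED
#' @param path BED3+ file; column 5, when present, is taken as the fold.
#' @param caller caller tag to attach.
#' @export
read_hotspots_bed <- function(path, caller = "raw") {
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", "numeric", "numeric", rep(NA, 10))[
                     seq_len(max(utils::count.fields(path, sep = "\t")))])
  fold <- if (ncol(df) >= 5) as.numeric(df[[5]]) else NA_real_
  hotspot_set(df[[1]], df[[2]], df[[3]], fold = fold, caller = caller)
}
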