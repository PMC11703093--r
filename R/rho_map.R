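#' Construct a population recombination map
#'
#' A rho map holds ordered inter-SNP intervals with a per-bp population-scaled
#' recombination rate rho = 4*Ne*r, as inferred by LD-based methods between
#' consecutive SNPs. Coordinates are 0-based half-open.
#'
#' @param chrom,start,end,rho vectors describing the intervals.
#' @param chrom_lengths optional named vector of chromosome lengths (bp).
#' @param sort sort intervals before validation.
#' @return a `rho_map` data.frame with columns chrom/start/end/rho.
#' @export
rho_map <- function(chrom, start, end, rho, chrom_lengths = NULL, sort = TRUE) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), rho = as.numeric(rho),
                   stringsAsFactors = FALSE)
  if (sort) df <- .sort_intervals(df)
  .check_intervals(df, "rho map")
  if (any(!is.finite(df$rho)) || any(df$rho < 0))
    stop("rho map: rho must be finite and non-negative")
  structure(df, class = c("rho_map", "data.frame"),
            chrom_lengths = chrom_lengths)
}

#' Read a recombination map from tab-separated text
#'
#' Expects four columns (chrom, start, end, rho per bp); a header line is
#' detected and skipped. Malformed rows are reported with their line number.
#'
#' @param path file path.
#' @param strict reject unsorted or overlapping input instead of sorting it.
#' @return a [rho_map()].
#' @export
read_rho_map <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(as.numeric(strsplit(first, "\t")[[1]][2])))
  df <- read.table(path, header = has_header, sep = "\t",
                   col.names = c("chrom", "start", "end", "rho"),
                   colClasses = c("character", "numeric", "numeric", "numeric"))
  offset <- if (has_header) 1L else 0L
  bad <- which(df$end <= df$start)
  if (length(bad))
    stop("line ", bad[1] + offset, ": end must exceed start")
  bad <- which(!is.finite(df$rho) | df$rho < 0)
  if (length(bad))
    stop("line ", bad[1] + offset, ": rho must be finite and non-negative")
  if (strict) {
    ord <- order(df$chrom, df$start)
    if (!identical(ord, seq_len(nrow(df))))
      stop("input map is not sorted (strict mode)")
  }
  rho_map(df$chrom, df$start, df$end, df$rho, sort = !strict)
}

#' Write a recombination map as tab-separated text
#' @param map a [rho_map()].
#' @param path output path.
#' @param header write a header line.
#' @export
write_rho_map <- function(map, path, header = FALSE) {
  write.table(map[, c("chrom", "start", "end", "rho")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = header)
  invisible(path)
}

#' Average independent inference runs of the same map
#'
#' All maps must share an identical interval skeleton. The per-interval rho
#' values are arithmetically averaged and the pairwise Spearman rank
#' correlations between runs are reported, the standard convergence check for
#' repeated MCMC-based rate inference.
#'
#' @param maps list of [rho_map()]s on the same skeleton.
#' @return list with `map` (the averaged rho_map) and `spearman` (run-by-run
#'   rank correlation matrix).
#' @export
average_runs <- function(maps) {
  stopifnot(is.list(maps), length(maps) >= 1L)
  skel <- maps[[1]][, c("chrom", "start", "end")]
  for (m in maps[-1])
    if (!identical(m[, c("chrom", "start", "end")], skel))
      stop("maps do not share an identical interval skeleton")
  rho_mat <- vapply(maps, function(m) m$rho, numeric(nrow(skel)))
  avg <- rho_map(skel$chrom, skel$start, skel$end, rowMeans(rho_mat),
                 chrom_lengths = attr(maps[[1]], "chrom_lengths"), sort = FALSE)
  rho_cor <- suppressWarnings(cor(rho_mat, method = "spearman"))
  dimnames(rho_cor) <- list(seq_along(maps), seq_along(maps))
  list(map = avg, spearman = rho_cor)
}

#' Smooth a map into fixed-width windows
#'
#' Each window's rate is the bp-weighted mean of the intersecting inter-SNP
#' intervals; windows with no covered bp are flagged missing (NA), not zero.
#' Tail windows shorter than `width` at chromosome ends are kept and
#' bp-weighted, so the genome-wide total recombination (sum of rho x length)
#' is conserved exactly.
#'
#' @param map a [rho_map()].
#' @param width window width in bp (2000, 100000 and 1e6 are the usual scales).
#' @param chrom_lengths optional named chromosome lengths; defaults to the
#'   map's own attribute or its furthest interval end.
#' @return a `windowed_map` data.frame (chrom/start/end/rho/covered) with a
#'   `width` attribute.
#' @export
smooth_windows <- function(map, width, chrom_lengths = NULL) {
  stopifnot(width > 0)
  cl <- .chrom_lengths(map, chrom_lengths)
  out <- list()
  for (chr in names(cl)) {
    L <- cl[[chr]]
    starts <- (seq_len(ceiling(L / width)) - 1) * width
    ends <- pmin(starts + width, L)
    d <- map[map$chrom == chr, , drop = FALSE]
    if (nrow(d)) {
      ct <- .cum_track(d$start, d$end, d$rho)
      mass <- .mass_at(ct, ends) - .mass_at(ct, starts)
      cov <- .cov_at(ct, ends) - .cov_at(ct, starts)
    } else {
      mass <- cov <- numeric(length(starts))
    }
    rho <- ifelse(cov > 0, mass / cov, NA_real_)
    out[[chr]] <- data.frame(chrom = chr, start = starts, end = ends,
                             rho = rho, covered = cov)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("windowed_map", "data.frame"),
            width = width, chrom_lengths = cl)
}

#' Write a windowed map as BEDGRAPH
#'
#' Missing windows (no SNP coverage) are omitted from the output.
#'
#' @param wmap a windowed map from [smooth_windows()].
#' @param path output path.
#' @export
write_bedgraph <- function(wmap, path) {
  d <- wmap[!is.na(wmap$rho), c("chrom", "start", "end", "rho")]
  d$start <- as.integer(d$start); d$end <- as.integer(d$end)
  write.table(d, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Windowed maps and rho maps expose the same per-interval weight: covered bp
# for windows, interval length otherwise.
.map_weights <- function(map) {
  if (!is.null(map$covered)) map$covered else map$end - map$start
}

#' Genome-wide mean recombination rate
#'
#' The bp-weighted mean rho per bp, i.e. total recombination divided by total
#' covered length.
#'
#' @param map a [rho_map()] or windowed map.
#' @return rho per bp.
#' @export
genome_wide_rate <- function(map) {
  if (nrow(map) == 0L) stop("empty map")
  w <- .map_weights(map)
  keep <- !is.na(map$rho) & w > 0
  sum(map$rho[keep] * w[keep]) / sum(w[keep])
}

#' Landscape heterogeneity (Lorenz-style concentration curve)
#'
#' Intervals are sorted by decreasing rho; the curve relates the cumulative
#' genome fraction (bp-weighted) to the cumulative fraction of total
#' recombination. Highly heterogeneous landscapes rise steeply: in salmonids
#' roughly 90% of recombination falls in the top 20% of the genome.
#'
#' @param map a [rho_map()] or windowed map.
#' @return a `heterogeneity_curve` data.frame (genome_frac, recomb_frac).
#' @export
heterogeneity_curve <- function(map) {
  if (nrow(map) == 0L) stop("empty map")
  w <- .map_weights(map)
  keep <- !is.na(map$rho) & w > 0
  rho <- map$rho[keep]; w <- w[keep]
  if (sum(rho * w) == 0) stop("all-zero map: heterogeneity curve undefined")
  o <- order(rho, decreasing = TRUE)
  gf <- cumsum(w[o]) / sum(w)
  rf <- cumsum(rho[o] * w[o]) / sum(rho * w)
  structure(data.frame(genome_frac = gf, recomb_frac = rf),
            class = c("heterogeneity_curve", "data.frame"))
}

#' Fraction of total recombination in the most recombining genome fraction
#'
#' Linearly interpolates the heterogeneity curve at genome fraction `q`
#' (interval granularity makes exact cuts unattainable otherwise).
#'
#' @param curve a [heterogeneity_curve()] (or a map, converted on the fly).
#' @param q genome fraction, e.g. 0.2 for the top 20%.
#' @return fraction of recombination in [0, 1].
#' @export
fraction_in_top <- function(curve, q = 0.2) {
  stopifnot(q >= 0, q <= 1)
  if (!inherits(curve, "heterogeneity_curve")) curve <- heterogeneity_curve(curve)
  stats::approx(x = c(0, curve$genome_frac), y = c(0, curve$recomb_frac),
                xout = q, ties = "ordered")$y
}

#' Broad-scale chromosomal profile in length percentiles
#'
#' Splits every chromosome into `n_bins` equal-length bins, averages the
#' windowed rates within bins, averages bins across chromosomes, and scales by
#' the genomic mean. Telomere-elevated landscapes produce the characteristic
#' U-shape with terminal bins above 1.
#'
#' @param map a windowed map from [smooth_windows()] (a raw map also works).
#' @param n_bins number of equal-length bins per chromosome (default 30).
#' @return data.frame (bin, frac_lo, frac_hi, scaled_rate).
#' @export
chromosome_percentile_profile <- function(map, n_bins = 30) {
  stopifnot(n_bins >= 2)
  cl <- .chrom_lengths(map)
  gmean <- genome_wide_rate(map)
  w <- .map_weights(map)
  mid <- (map$start + map$end) / 2
  binmat <- matrix(NA_real_, nrow = length(cl), ncol = n_bins)
  for (k in seq_along(cl)) {
    chr <- names(cl)[k]
    sel <- map$chrom == chr & !is.na(map$rho) & w > 0
    if (!any(sel)) next
    b <- pmin(floor(mid[sel] / cl[[chr]] * n_bins) + 1L, n_bins)
    num <- tapply(map$rho[sel] * w[sel], b, sum)
    den <- tapply(w[sel], b, sum)
    binmat[k, as.integer(names(num))] <- num / den
  }
  prof <- colMeans(binmat, na.rm = TRUE) / gmean
  data.frame(bin = seq_len(n_bins),
             frac_lo = (seq_len(n_bins) - 1) / n_bins,
             frac_hi = seq_len(n_bins) / n_bins,
             scaled_rate = prof)
}

#' Mutation to recombination rate ratio
#'
#' Converts a pedigree-based recombination rate in cM/Mb to per-bp Morgans per
#' generation (1 cM/Mb = 1e-8 /bp) and returns mu / r.
#'
#' @param mu per-bp per-generation mutation rate.
#' @param r_cm_per_mb sex-averaged pedigree-based recombination rate (cM/Mb).
#' @return dimensionless mu/r ratio.
#' @export
mu_over_r <- function(mu, r_cm_per_mb) {
  stopifnot(r_cm_per_mb > 0)
  mu / (r_cm_per_mb * 1e-8)
}

#' Effective population size from nucleotide diversity
#'
#' Under neutrality theta = 4*Ne*mu, so Ne = theta / (4*mu).
#'
#' @param theta per-bp nucleotide diversity.
#' @param mu per-bp per-generation mutation rate.
#' @return Ne.
#' @export
estimate_ne <- function(theta, mu) {
  stopifnot(mu > 0)
  theta / (4 * mu)
}
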