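# Internal interval arithmetic shared across modules.
# All coordinates are 0-based half-open; interval frames are data.frames with
# at least chrom/start/end, sorted and non-overlapping within a chromosome.

.check_intervals <- function(df, what = "intervals", allow_empty = TRUE) {
  stopifnot(is.data.frame(df), all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) == 0L) {
    if (!allow_empty) stop(what, " must be non-empty")
    return(invisible(df))
  }
  if (any(df$end <= df$start)) stop(what, ": end must exceed start")
  sp <- split(seq_len(nrow(df)), df$chrom)
  for (idx in sp) {
    s <- df$start[idx]; e <- df$end[idx]
    o <- order(s)
    if (any(s[o][-1] < e[o][-length(o)]))
      stop(what, ": overlapping intervals within a chromosome")
  }
  invisible(df)
}

.sort_intervals <- function(df) {
  df[order(df$chrom, df$start), , drop = FALSE]
}

# Convert an interval frame to GRanges (0-based half-open -> 1-based closed).
.as_granges <- function(df, seqlengths = NULL) {
  if (nrow(df) == 0L)
    return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = as.character(df$chrom),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

.from_granges <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE
  )
}

# Chromosome lengths: explicit attribute wins, otherwise the furthest end seen.
.chrom_lengths <- function(x, chrom_lengths = NULL) {
  if (!is.null(chrom_lengths)) return(chrom_lengths)
  cl <- attr(x, "chrom_lengths")
  if (!is.null(cl)) return(cl)
  df <- if (is.data.frame(x)) x else as.data.frame(x)
  vapply(split(df$end, df$chrom), max, numeric(1))
}

# Prefix-sum evaluator over a sorted, non-overlapping interval frame carrying a
# per-bp value column. mass(x) integrates value*bp over covered positions < x;
# cov(x) counts covered bp < x. Both are vectorised in x.
.cum_track <- function(start, end, value) {
  len <- end - start
  m <- value * len
  list(
    start = start, end = end, value = value, len = len,
    cm0 = cumsum(m) - m,   # mass of intervals strictly before interval j
    cl0 = cumsum(len) - len
  )
}

.mass_at <- function(ct, x) {
  j <- findInterval(x, ct$start)
  out <- numeric(length(x))
  hit <- j > 0L
  jj <- j[hit]
  out[hit] <- ct$cm0[jj] + ct$value[jj] * pmin(x[hit] - ct$start[jj], ct$len[jj])
  out
}

.cov_at <- function(ct, x) {
  j <- findInterval(x, ct$start)
  out <- numeric(length(x))
  hit <- j > 0L
  jj <- j[hit]
  out[hit] <- ct$cl0[jj] + pmin(x[hit] - ct$start[jj], ct$len[jj])
  out
}

# bp-weighted mean of a per-bp track over a set of query intervals (same
# chromosome naming); returns NA when nothing is covered.
.weighted_mean_over <- function(track, queries) {
  .check_intervals(queries, "query intervals")
  num <- 0; den <- 0
  tr <- split(track, track$chrom)
  qs <- split(queries, queries$chrom)
  for (chr in names(qs)) {
    t <- tr[[chr]]
    if (is.null(t) || nrow(t) == 0L) next
    ct <- .cum_track(t$start, t$end, t$value)
    q <- qs[[chr]]
    num <- num + sum(.mass_at(ct, q$end) - .mass_at(ct, q$start))
    den <- den + sum(.cov_at(ct, q$end) - .cov_at(ct, q$start))
  }
  if (den == 0) return(NA_real_)
  num / den
}

# Complement of an interval frame within chromosome bounds.
.complement_intervals <- function(df, chrom_lengths) {
  out <- list()
  for (chr in names(chrom_lengths)) {
    L <- chrom_lengths[[chr]]
    d <- df[df$chrom == chr, , drop = FALSE]
    if (nrow(d) == 0L) {
      out[[chr]] <- data.frame(chrom = chr, start = 0, end = L)
      next
    }
    d <- d[order(d$start), ]
    starts <- c(0, d$end)
    ends <- c(d$start, L)
    keep <- ends > starts
    if (any(keep))
      out[[chr]] <- data.frame(chrom = chr, start = starts[keep], end = ends[keep])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(chrom = character(), start = numeric(), end = numeric())
  rownames(res) <- NULL
  res
}

# Merge overlapping or touching intervals.
.reduce_intervals <- function(df) {
  if (nrow(df) == 0L) return(df[, c("chrom", "start", "end")])
  sp <- split(df, df$chrom)
  out <- lapply(sp, function(d) {
    d <- d[order(d$start), ]
    grp <- cumsum(c(TRUE, d$start[-1] > cummax(d$end[-nrow(d)])))
    data.frame(
      chrom = d$chrom[1],
      start = tapply(d$start, grp, min),
      end = tapply(d$end, grp, max)
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Local, restorable RNG seeding; all generators route their randomness here.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
  }
  force(code)
}
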