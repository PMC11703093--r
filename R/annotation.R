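#' Construct a genome annotation
#'
#' Holds strand-aware genes plus CGI, TE and intergenic interval tracks.
#' The TSS is the gene start on the + strand and the gene end on the - strand
#' (symmetrically for the TES). Intergenic space is the complement of genes
#' and TEs within the chromosome bounds.
#'
#' @param genes data.frame chrom/start/end/strand (and optional id).
#' @param cgis,tes data.frames chrom/start/end (tes may carry a family column).
#' @param chrom_lengths named vector of chromosome lengths (bp), required.
#' @param intergenic optional precomputed intergenic intervals; derived from
#'   genes and TEs when omitted.
#' @return a `genome_annotation` list.
#' @export
genome_annotation <- function(genes, cgis = NULL, tes = NULL,
                              chrom_lengths, intergenic = NULL) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric())
  if (is.null(cgis)) cgis <- empty
  if (is.null(tes)) tes <- empty
  if (is.null(genes$id)) genes$id <- paste0("gene", seq_len(nrow(genes)))
  stopifnot(all(genes$strand %in% c("+", "-")))
  .check_intervals(genes, "genes")
  .check_intervals(cgis, "CGIs")
  .check_intervals(tes, "TEs")
  genes <- .sort_intervals(genes)
  if (is.null(intergenic)) {
    occupied <- .reduce_intervals(rbind(genes[, c("chrom", "start", "end")],
                                        tes[, c("chrom", "start", "end")]))
    intergenic <- .complement_intervals(occupied, chrom_lengths)
  }
  structure(list(genes = genes, cgis = .sort_intervals(cgis),
                 tes = .sort_intervals(tes),
                 intergenic = .sort_intervals(intergenic),
                 chrom_lengths = chrom_lengths),
            class = "genome_annotation")
}

#' Strand-aware transcription start sites
#' @param ann a [genome_annotation()].
#' @return data.frame chrom/pos/strand/id (pos is a 0-based point coordinate).
#' @export
tss_points <- function(ann) {
  g <- ann$genes
  data.frame(chrom = g$chrom,
             pos = ifelse(g$strand == "+", g$start, g$end - 1),
             strand = g$strand, id = g$id)
}

#' Strand-aware transcription end sites
#' @param ann a [genome_annotation()].
#' @return data.frame chrom/pos/strand/id.
#' @export
tes_points <- function(ann) {
  g <- ann$genes
  data.frame(chrom = g$chrom,
             pos = ifelse(g$strand == "+", g$end - 1, g$start),
             strand = g$strand, id = g$id)
}

#' Read gene annotations from GFF3 or BED
#'
#' GFF3 (1-based closed) is converted to the package's 0-based half-open
#' convention on read; BED is taken as-is.
#'
#' @param path file path ending in .gff/.gff3 or .bed.
#' @param chrom_lengths named chromosome lengths.
#' @param feature GFF3 feature type to keep (default "gene").
#' @return a [genome_annotation()] with genes only.
#' @export
read_annotation <- function(path, chrom_lengths, feature = "gene") {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == feature]
    genes <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                        start = GenomicRanges::start(gr) - 1L,
                        end = GenomicRanges::end(gr),
                        strand = as.character(GenomicRanges::strand(gr)))
  } else {
    df <- read.table(path, sep = "\t", header = FALSE)
    genes <- data.frame(chrom = as.character(df[[1]]), start = df[[2]],
                        end = df[[3]],
                        strand = if (ncol(df) >= 6) as.character(df[[6]]) else "+")
  }
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  genome_annotation(genes, chrom_lengths = chrom_lengths)
}

#' Split TSSs by CpG-island overlap
#'
#' A TSS is "in CGI" iff its point position lies within a CGI interval
#' (half-open, so a TSS at the CGI end coordinate is outside).
#'
#' @param ann a [genome_annotation()] with CGIs present or supplied.
#' @param cgis optional CGI intervals overriding the annotation's.
#' @return list with `in_cgi` and `out_cgi` TSS point frames.
#' @export
classify_tss <- function(ann, cgis = NULL) {
  if (is.null(cgis)) cgis <- ann$cgis
  tss <- tss_points(ann)
  if (nrow(cgis) == 0L) return(list(in_cgi = tss[0, ], out_cgi = tss))
  inside <- logical(nrow(tss))
  for (chr in unique(tss$chrom)) {
    ci <- cgis[cgis$chrom == chr, , drop = FALSE]
    ti <- which(tss$chrom == chr)
    if (nrow(ci) == 0L || !length(ti)) next
    j <- findInterval(tss$pos[ti], ci$start)
    inside[ti] <- j > 0 & tss$pos[ti] < ci$end[pmax(j, 1)]
  }
  list(in_cgi = tss[inside, , drop = FALSE],
       out_cgi = tss[!inside, , drop = FALSE])
}
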