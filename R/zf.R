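# PRDM9 zinc-finger array parsing and diversity statistics.
#
# A C2H2 unit is the 28-residue repeat X7-CXXC-X12-HXXXH: cysteines at unit
# positions 8 and 11, histidines at 24 and 28. The four residues contacting
# DNA (alpha-helix positions -1, +2, +3, +6) default to unit positions
# 16/18/19/22; the mapping is exposed because numbering conventions differ.

.ZF_FULL <- "^.{7}C.{2}C.{12}H.{3}H"
.ZF_DEGEN <- "^.{7}C.{2}C.{12}H.{3}[^H]"
.ZF_SHORT <- "^.{7}C.{2}C.{11}H.{3}H"
.AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Default DNA-contact positions within a 28-residue C2H2 unit
#' @export
zf_contact_positions <- function() c(16L, 18L, 19L, 22L)

#' Parse an amino-acid sequence into C2H2 zinc-finger units
#'
#' Greedy left-to-right tiling anchored on the C..C..H..H scaffold. A trailing
#' 28-mer whose final histidine is replaced is emitted with the degenerate
#' flag (such last fingers cannot coordinate the zinc ion); 27-residue units
#' missing one residue are flagged short. Residues that fit no unit are
#' reported as skipped.
#'
#' @param aa_seq amino-acid string over the 20-letter alphabet
#'   (case-insensitive; stop/frameshift characters are rejected).
#' @return data.frame (index, start, seq, width, degenerate, short) plus a
#'   `skipped` attribute with the number of non-conforming residues.
#' @export
parse_zf_array <- function(aa_seq) {
  s <- toupper(as.character(aa_seq))
  if (grepl(paste0("[^", paste(.AA20, collapse = ""), "]"), s))
    stop("sequence contains characters outside the 20-letter amino-acid alphabet")
  L <- nchar(s)
  units <- list()
  i <- 1L
  skipped <- 0L
  while (i + 26L <= L) {
    rest <- substring(s, i, min(i + 27L, L))
    if (nchar(rest) == 28L && grepl(.ZF_FULL, rest)) {
      units[[length(units) + 1L]] <- list(start = i, seq = rest, width = 28L,
                                          degenerate = FALSE, short = FALSE)
      i <- i + 28L
    } else if (grepl(.ZF_SHORT, substring(s, i, i + 26L))) {
      units[[length(units) + 1L]] <- list(start = i,
                                          seq = substring(s, i, i + 26L),
                                          width = 27L,
                                          degenerate = FALSE, short = TRUE)
      i <- i + 27L
    } else if (nchar(rest) == 28L && i + 27L == L && grepl(.ZF_DEGEN, rest)) {
      units[[length(units) + 1L]] <- list(start = i, seq = rest, width = 28L,
                                          degenerate = TRUE, short = FALSE)
      i <- i + 28L
    } else {
      i <- i + 1L
      skipped <- skipped + 1L
    }
  }
  skipped <- skipped + (L - i + 1L)
  if (!length(units)) stop("no C2H2 unit found in sequence")
  df <- do.call(rbind, lapply(seq_along(units), function(k)
    data.frame(index = k, start = units[[k]]$start, seq = units[[k]]$seq,
               width = units[[k]]$width, degenerate = units[[k]]$degenerate,
               short = units[[k]]$short)))
  attr(df, "skipped") <- skipped
  df
}

#' Catalogue zinc-finger array alleles
#'
#' Identical amino-acid arrays collapse into one allele (a single residue
#' difference defines a new allele); frequencies are carrier chromosomes over
#' the total number of observations. Pass one entry per observed chromosome
#' (diploid genotypes therefore contribute two entries).
#'
#' @param arrays character vector of amino-acid array sequences, one per
#'   chromosome observation; names identify carriers.
#' @param species optional species label.
#' @return a `zf_allele_set` list: alleles (allele name -> sequence), units
#'   (allele -> parsed unit frame), counts, freqs, n_obs.
#' @export
catalogue_alleles <- function(arrays, species = NA_character_) {
  stopifnot(length(arrays) >= 1)
  arrays <- toupper(as.character(arrays))
  tab <- sort(table(arrays), decreasing = TRUE)
  seqs <- names(tab)
  names(seqs) <- paste0("allele", seq_along(seqs))
  counts <- as.integer(tab)
  names(counts) <- names(seqs)
  structure(list(
    alleles = seqs,
    units = lapply(seqs, parse_zf_array),
    counts = counts,
    freqs = counts / length(arrays),
    n_obs = length(arrays),
    species = species
  ), class = "zf_allele_set")
}

#' Collect zinc-finger units from an allele set
#'
#' @param aset a [catalogue_alleles()] result.
#' @param unique_only keep one copy of each distinct unit sequence (the
#'   convention for the diversity profile).
#' @param include_degenerate,include_short include flagged units (excluded by
#'   default: degenerate last fingers and 27-mers do not align to the
#'   28-position frame).
#' @return character vector of unit sequences.
#' @export
collect_units <- function(aset, unique_only = TRUE,
                          include_degenerate = FALSE, include_short = FALSE) {
  u <- do.call(rbind, aset$units)
  keep <- (include_degenerate | !u$degenerate) & (include_short | !u$short)
  out <- u$seq[keep]
  if (unique_only) out <- unique(out)
  out
}

#' Per-position amino-acid diversity of zinc-finger units
#'
#' For each of the 28 unit positions, the Gini-Simpson heterozygosity
#' d = 1 - sum(f^2) over the amino-acid frequencies among the supplied units.
#' Units are de-duplicated by default (each distinct finger counted once);
#' set `weights` for a frequency-weighted variant.
#'
#' @param units character vector of 28-residue unit sequences (e.g. from
#'   [collect_units()]); duplicates are removed.
#' @param weights optional per-unit weights (after de-duplication is skipped);
#'   when supplied, units are used as given.
#' @return a `zf_diversity_profile` list: d (length 28), n_units.
#' @export
position_diversity <- function(units, weights = NULL) {
  if (is.null(weights)) units <- unique(units)
  if (length(units) < 2) stop("at least 2 unique units required")
  if (any(nchar(units) != 28))
    stop("all units must be full-length (28 residues)")
  if (is.null(weights)) weights <- rep(1, length(units))
  w <- weights / sum(weights)
  m <- do.call(rbind, strsplit(units, ""))
  d <- vapply(seq_len(28), function(j) {
    f <- tapply(w, m[, j], sum)
    1 - sum(f^2)
  }, numeric(1))
  structure(list(d = d, n_units = length(units)),
            class = "zf_diversity_profile")
}

#' Proportion of amino-acid diversity at DNA-binding residues
#'
#' r = sum of per-position diversity at the contact positions over the sum at
#' all 28 positions. High r marks rapid evolution at DNA-contact residues
#' combined with concerted homogenisation elsewhere in the array, the
#' signature of an active, Red-Queen-driven PRDM9 ZF domain.
#'
#' @param profile a [position_diversity()] result (or a bare length-28
#'   numeric vector of diversities).
#' @param contact_positions 1-based unit indices of the DNA-contact residues.
#' @return r in [0, 1].
#' @export
dna_binding_ratio <- function(profile,
                              contact_positions = zf_contact_positions()) {
  d <- if (inherits(profile, "zf_diversity_profile")) profile$d else profile
  stopifnot(length(d) == 28, all(contact_positions %in% 1:28))
  tot <- sum(d)
  if (tot <= 0) stop("total diversity is zero: ratio undefined")
  sum(d[contact_positions]) / tot
}

#' Read zinc-finger arrays from FASTA (one array per record)
#' @param path FASTA of amino-acid sequences.
#' @return named character vector.
#' @export
read_zf_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  setNames(as.character(ss), names(ss))
}

#' Write zinc-finger arrays to FASTA
#' @param arrays named character vector of amino-acid sequences.
#' @param path output path.
#' @export
write_zf_fasta <- function(arrays, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(arrays), path)
  invisible(path)
}
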