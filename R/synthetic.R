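# Synthetic-data generator: produces inputs with the statistical structure the
# downstream analyses assume, so every stage is testable without population
# resequencing data. All generators take an explicit seed and restore the
# caller's RNG state.

#' Describe a synthetic genome
#'
#' @param chrom_lengths named numeric vector of chromosome lengths in bp.
#' @param gc target GC fraction for generated sequence (0 < gc < 1).
#' @param seed integer seed used by generators that take the spec.
#' @export
synthetic_genome_spec <- function(chrom_lengths, gc = 0.42, seed = 1L) {
  stopifnot(all(chrom_lengths > 0), gc > 0, gc < 1,
            !is.null(names(chrom_lengths)))
  structure(list(chrom_lengths = chrom_lengths, gc = gc, seed = seed),
            class = "synthetic_genome_spec")
}

#' Plan hotspots to embed in a synthetic landscape
#'
#' @param chrom,center,fold vectors: chromosome, center position (bp) and
#'   intensity relative to the local background (>= 1).
#' @param width hotspot width in bp (default 2000, the typical fine scale at
#'   which recombination concentrates).
#' @export
hotspot_plan <- function(chrom, center, fold, width = 2000) {
  df <- data.frame(chrom = as.character(chrom), center = center,
                   width = width, fold = fold)
  stopifnot(all(df$width > 0), all(df$fold >= 1))
  df$start <- df$center - df$width / 2
  df$end <- df$center + df$width / 2
  df
}

# smooth telomere multiplier: cosine ramp from 1 at mid-chromosome to
# `fold` at the ends, over the outer `edge` fraction of the length
.telomere_multiplier <- function(pos, L, fold, edge = 0.2) {
  d <- pmin(pos, L - pos) / L            # distance to nearest end, fraction
  m <- rep(1, length(pos))
  ramp <- d < edge
  m[ramp] <- 1 + (fold - 1) * (1 + cos(pi * d[ramp] / edge)) / 2
  m
}

#' Generate a synthetic inter-SNP recombination landscape
#'
#' SNP positions form a homogeneous Poisson process; each inter-SNP interval
#' draws an iid gamma background rate (mean `background_mean`, shape
#' `background_shape`) multiplied by a positional factor: a cosine ramp
#' rising to `telomere_fold` over the outer 20% of each chromosome
#' (emulating the U-shaped broad-scale elevation seen in salmonid maps) and
#' by each planned hotspot's `fold` inside its interval.
#'
#' @param spec a [synthetic_genome_spec()].
#' @param snp_density per-bp SNP rate (> 0).
#' @param background_mean mean background rho per bp.
#' @param background_shape gamma shape of the background (default 0.2, a
#'   heavy-tailed background whose rate variation spans orders of magnitude,
#'   as in real LD-based maps; 1 gives an exponential background).
#' @param telomere_fold broad-scale elevation at chromosome ends (1 = flat).
#' @param plan optional [hotspot_plan()]; overlapping planned hotspots are
#'   rejected.
#' @param seed integer seed; defaults to the spec's.
#' @return a [rho_map()] with attributes `plan` and `chrom_lengths`.
#' @export
gen_rho_landscape <- function(spec, snp_density, background_mean,
                              background_shape = 0.2, telomere_fold = 1,
                              plan = NULL, seed = spec$seed) {
  if (snp_density <= 0) stop("snp_density must be positive")
  stopifnot(background_mean > 0, background_shape > 0, telomere_fold >= 1)
  if (!is.null(plan) && nrow(plan)) {
    .check_intervals(plan, "planned hotspots")
    cl <- spec$chrom_lengths
    if (any(plan$center < 0 | plan$center > cl[plan$chrom]))
      stop("planned hotspot center outside chromosome")
  }
  .with_seed(seed, {
    out <- list()
    for (chr in names(spec$chrom_lengths)) {
      L <- spec$chrom_lengths[[chr]]
      n_snp <- rpois(1, L * snp_density)
      if (n_snp < 2) next
      pos <- sort(unique(floor(runif(n_snp) * L)))
      if (length(pos) < 2) next
      s <- pos[-length(pos)]; e <- pos[-1]
      mid <- (s + e) / 2
      rho <- rgamma(length(s), shape = background_shape,
                    rate = background_shape / background_mean)
      rho <- rho * .telomere_multiplier(mid, L, telomere_fold)
      if (!is.null(plan) && nrow(plan)) {
        pc <- plan[plan$chrom == chr, , drop = FALSE]
        for (i in seq_len(nrow(pc))) {
          inside <- mid >= pc$start[i] & mid < pc$end[i]
          rho[inside] <- rho[inside] * pc$fold[i]
        }
      }
      out[[chr]] <- data.frame(chrom = chr, start = s, end = e, rho = rho)
    }
    if (!length(out)) stop("no chromosome received at least 2 SNPs")
    df <- do.call(rbind, out)
    m <- rho_map(df$chrom, df$start, df$end, df$rho,
                 chrom_lengths = spec$chrom_lengths)
    attr(m, "plan") <- plan
    m
  })
}

#' Generate a synthetic genome annotation
#'
#' Places `n_genes` non-overlapping genes with random strands, gives a
#' fraction of TSSs an overlapping CGI, and lays down TE intervals covering
#' approximately `te_frac` of the genome (TEs may overlap genes but not each
#' other). Intergenic space is the complement of genes and TEs.
#'
#' @param spec a [synthetic_genome_spec()].
#' @param n_genes number of genes (infeasible counts are rejected).
#' @param cgi_at_tss_frac fraction of TSSs overlapped by a CGI.
#' @param te_frac target TE genome fraction.
#' @param gene_len_range,te_len_range,cgi_width size parameters in bp.
#' @param seed integer seed; defaults to the spec's.
#' @return a [genome_annotation()].
#' @export
gen_annotation <- function(spec, n_genes, cgi_at_tss_frac = 0.5,
                           te_frac = 0.1, gene_len_range = c(1000, 10000),
                           te_len_range = c(200, 5000), cgi_width = 500,
                           seed = spec$seed) {
  stopifnot(cgi_at_tss_frac >= 0, cgi_at_tss_frac <= 1,
            te_frac >= 0, te_frac <= 1)
  cl <- spec$chrom_lengths
  .with_seed(seed, {
    # genes distributed over chromosomes proportionally to length
    chrom_of <- sample(names(cl), n_genes, replace = TRUE, prob = cl / sum(cl))
    lens <- floor(runif(n_genes, gene_len_range[1], gene_len_range[2]))
    place_nonoverlap <- function(lens_chr, L) {
      free <- L - sum(lens_chr)
      if (free < 0) stop("n_genes infeasible for genome size")
      cuts <- sort(runif(length(lens_chr), 0, free))
      starts <- floor(cuts + cumsum(c(0, lens_chr[-length(lens_chr)])))
      data.frame(start = starts, end = starts + lens_chr)
    }
    genes <- do.call(rbind, lapply(names(cl), function(chr) {
      sel <- chrom_of == chr
      if (!any(sel)) return(NULL)
      g <- place_nonoverlap(lens[sel], cl[[chr]])
      g$chrom <- chr
      g
    }))
    genes$strand <- sample(c("+", "-"), nrow(genes), replace = TRUE)
    genes$id <- paste0("gene", seq_len(nrow(genes)))
    genes <- genes[, c("chrom", "start", "end", "strand", "id")]
    # CGIs overlapping a fraction of TSSs
    tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
    pick <- runif(nrow(genes)) < cgi_at_tss_frac
    cgis <- if (any(pick)) .reduce_intervals(data.frame(
      chrom = genes$chrom[pick],
      start = pmax(tss[pick] - floor(cgi_width / 2), 0),
      end = pmin(tss[pick] + ceiling(cgi_width / 2), cl[genes$chrom[pick]])
    )) else NULL
    # TEs to target coverage, non-overlapping among themselves
    tes <- NULL
    if (te_frac > 0) {
      tes <- do.call(rbind, lapply(names(cl), function(chr) {
        target <- te_frac * cl[[chr]]
        lens_te <- c()
        while (sum(lens_te) < target)
          lens_te <- c(lens_te, floor(runif(20, te_len_range[1], te_len_range[2])))
        lens_te <- lens_te[cumsum(lens_te) <= target + te_len_range[2]]
        t <- place_nonoverlap(lens_te, cl[[chr]])
        t$chrom <- chr
        t$family <- sample(c("Tc1-mariner", "LINE", "LTR"), nrow(t),
                           replace = TRUE, prob = c(0.5, 0.3, 0.2))
        t[, c("chrom", "start", "end", "family")]
      }))
    }
    genome_annotation(genes, cgis = cgis, tes = tes, chrom_lengths = cl)
  })
}

#' Generate synthetic PRDM9 zinc-finger alleles
#'
#' Each allele concatenates 28-residue C2H2 units derived from a common
#' consensus, with substitutions concentrated at the DNA-contact positions at
#' rate `contact_variability` and 10x rarer elsewhere (scaffold C/C/H/H
#' residues never mutate). Optionally the final histidine of the last unit is
#' replaced (H -> Y), mirroring the degenerate last finger of real arrays.
#'
#' @param n_alleles number of alleles to draw.
#' @param n_units_range inclusive range of units per allele.
#' @param contact_variability per-position substitution rate at contact
#'   positions.
#' @param seed integer seed.
#' @param contact_positions contact-position indices.
#' @param degenerate_last replace the terminal histidine of each array.
#' @return named character vector of allele array sequences.
#' @export
gen_zf_alleles <- function(n_alleles, n_units_range = c(5, 10),
                           contact_variability = 0.3, seed = 1L,
                           contact_positions = zf_contact_positions(),
                           degenerate_last = FALSE) {
  stopifnot(n_alleles >= 1, contact_variability >= 0, contact_variability <= 1)
  scaffold <- c(8L, 11L, 24L, 28L)
  .with_seed(seed, {
    consensus <- sample(setdiff(.AA20, "H"), 28, replace = TRUE)
    consensus[scaffold] <- c("C", "C", "H", "H")
    bg_positions <- setdiff(seq_len(28), c(scaffold, contact_positions))
    make_unit <- function() {
      u <- consensus
      for (j in contact_positions)
        if (runif(1) < contact_variability)
          u[j] <- sample(setdiff(.AA20, c(u[j], "H", "C")), 1)
      for (j in bg_positions)
        if (runif(1) < contact_variability / 10)
          u[j] <- sample(setdiff(.AA20, c(u[j], "H", "C")), 1)
      paste(u, collapse = "")
    }
    alleles <- vapply(seq_len(n_alleles), function(i) {
      rng <- seq(n_units_range[1], n_units_range[2])
      k <- rng[sample.int(length(rng), 1)]
      arr <- paste(vapply(seq_len(k), function(x) make_unit(), character(1)),
                   collapse = "")
      if (degenerate_last)
        substring(arr, nchar(arr), nchar(arr)) <- "Y"
      arr
    }, character(1))
    names(alleles) <- paste0("allele", seq_len(n_alleles))
    alleles
  })
}

#' Generate a random DNA sequence at a target GC content
#' @param length sequence length in bp.
#' @param gc GC fraction.
#' @param seed optional integer seed.
#' @return character string.
#' @export
gen_random_seq <- function(length, gc = 0.42, seed = NULL) {
  .with_seed(seed, paste(sample(c("A", "C", "G", "T"), length, replace = TRUE,
                                prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                         (1 - gc) / 2)), collapse = ""))
}

#' Generate two genome lineages with partial motif erosion
#'
#' Plants `n_instances` copies of the PWM consensus at random well-separated
#' positions in a base sequence. Lineage A genomes keep all instances;
#' lineage B genomes share a single draw of `erosion_frac` of the instances
#' disrupted by one substitution at the highest-information PWM column (the
#' motif-killing mutation biased gene conversion would fix). Every genome
#' additionally receives independent neutral substitutions outside the
#' planted instances. Collinear blocks cover each genome entirely.
#'
#' @param base named character vector of chromosome sequences (a single
#'   unnamed string is accepted), or NULL to generate one chromosome of
#'   `base_length` bp.
#' @param p a [pwm()] whose consensus is planted.
#' @param n_per_lineage genomes per lineage, c(nA, nB).
#' @param erosion_frac fraction of instances disrupted in lineage B.
#' @param n_instances planted motif copies.
#' @param neutral_rate per-bp substitution rate outside planted instances.
#' @param base_length length of the generated base when `base` is NULL.
#' @param gc GC content of the generated base.
#' @param seed integer seed.
#' @return list: genomes_a, genomes_b (named lists of named chromosome
#'   vectors), blocks_a, blocks_b (data.frames genome/chrom/start/end),
#'   instances (planted positions), disrupted (indices eroded in lineage B).
#' @export
gen_eroded_genomes <- function(base = NULL, p, n_per_lineage = c(5, 5),
                               erosion_frac = 0.03, n_instances = 300,
                               neutral_rate = 1e-4, base_length = 1e5,
                               gc = 0.42, seed = 1L) {
  stopifnot(erosion_frac >= 0, erosion_frac <= 1)
  W <- p$width
  .with_seed(seed, {
    if (is.null(base)) base <- c(chr1 = gen_random_seq(base_length, gc))
    if (is.null(names(base))) names(base) <- paste0("chr", seq_along(base))
    if (all(nchar(base) < W)) stop("PWM wider than any plantable region")
    cons <- strsplit(pwm_consensus(p), "")[[1]]
    # spread instances across chromosomes proportionally to length
    lens <- nchar(base)
    inst_chrom <- sample(names(base), n_instances, replace = TRUE,
                         prob = lens / sum(lens))
    gap <- W + 10
    instances <- do.call(rbind, lapply(names(base), function(chr) {
      k <- sum(inst_chrom == chr)
      if (!k) return(NULL)
      slots <- floor(lens[[chr]] / gap)
      if (slots < k) stop("too many instances for the base sequence")
      at <- sort(sample.int(slots, k) - 1L) * gap
      data.frame(chrom = chr, start = at, end = at + W)
    }))
    base_chars <- lapply(base, function(s) strsplit(s, "")[[1]])
    for (i in seq_len(nrow(instances))) {
      chr <- instances$chrom[i]
      base_chars[[chr]][(instances$start[i] + 1):instances$end[i]] <- cons
    }
    # the motif-killing substitution: worst base at the most informative column
    ic <- apply(p$mat, 2, function(col) sum(col * log2(pmax(col, 1e-12) / 0.25)))
    kill_col <- which.max(ic)
    kill_base <- rownames(p$mat)[which.min(p$mat[, kill_col])]
    n_dis <- round(erosion_frac * n_instances)
    disrupted <- if (n_dis > 0) sort(sample.int(n_instances, n_dis)) else integer()
    in_instance <- lapply(base, function(s) logical(nchar(s)))
    for (i in seq_len(nrow(instances)))
      in_instance[[instances$chrom[i]]][
        (instances$start[i] + 1):instances$end[i]] <- TRUE
    mutate_neutral <- function(chars, chr) {
      n_mut <- rpois(1, length(chars) * neutral_rate)
      if (n_mut == 0) return(chars)
      at <- sample.int(length(chars), n_mut)
      at <- at[!in_instance[[chr]][at]]
      if (length(at))
        chars[at] <- vapply(chars[at], function(b)
          sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      chars
    }
    make_genome <- function(eroded) {
      chars <- base_chars
      if (eroded && length(disrupted)) {
        for (i in disrupted) {
          chr <- instances$chrom[i]
          chars[[chr]][instances$start[i] + kill_col] <- kill_base
        }
      }
      out <- lapply(names(chars), function(chr)
        paste(mutate_neutral(chars[[chr]], chr), collapse = ""))
      setNames(out, names(chars))
    }
    genomes_a <- lapply(seq_len(n_per_lineage[1]), function(i) make_genome(FALSE))
    names(genomes_a) <- paste0("A", seq_len(n_per_lineage[1]))
    genomes_b <- lapply(seq_len(n_per_lineage[2]), function(i) make_genome(TRUE))
    names(genomes_b) <- paste0("B", seq_len(n_per_lineage[2]))
    mk_blocks <- function(gs) do.call(rbind, lapply(names(gs), function(g)
      data.frame(genome = g, chrom = names(base),
                 start = 0, end = as.numeric(lens))))
    list(genomes_a = genomes_a, genomes_b = genomes_b,
         blocks_a = mk_blocks(genomes_a), blocks_b = mk_blocks(genomes_b),
         instances = instances, disrupted = disrupted)
  })
}
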