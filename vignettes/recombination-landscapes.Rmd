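---
title: "Recombination landscapes, PRDM9 zinc-finger diversity and motif erosion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recombination landscapes, PRDM9 zinc-finger diversity and motif erosion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(recfin)
```

## The analysis this package implements

Linkage-disequilibrium (LD) based recombination maps assign every interval
between consecutive SNPs a population-scaled recombination rate
$\rho = 4 N_e r$ per bp, where $N_e$ is the effective population size and $r$
the per-generation recombination rate. In species whose recombination is
directed by PRDM9 — a meiosis-specific zinc-finger (ZF) protein that binds a
DNA motif and marks it for double-strand-break formation — these maps have a
characteristic shape: most recombination concentrates in kilobase-scale
hotspots located away from promoters, hotspot positions turn over rapidly
between populations, the PRDM9 ZF array is hypervariable at its DNA-contact
residues, and the bound motif erodes over generations through biased gene
conversion at the very hotspots it creates (the intra-genomic Red Queen).

`recfin` provides the downstream stages of that analysis as testable,
reusable functions: map summaries and heterogeneity statistics, two hotspot
callers, feature-relative enrichment with a fish-appropriate CpG-island (CGI)
predictor, between-population hotspot sharing with a masked permutation null,
ZF allele cataloguing with a per-position diversity profile, and PWM scanning
with an exact p-value threshold feeding a between-lineage erosion test. A
seeded synthetic-data generator stands in for population resequencing data.

## Landscape statistics

`read_rho_map()` ingests four-column inter-SNP maps (0-based half-open
coordinates everywhere in the package; BED is written as-is and GFF3
converted on read). `smooth_windows()` averages a map into fixed windows
(2 kb, 100 kb and 1 Mb are the conventional scales) with bp-weighted means;
windows without SNP coverage are flagged missing rather than zero, because
zero-filling would bias every downstream feature mean. Tail windows shorter
than the nominal width are kept, so the bp-weighted total recombination
$\sum_i \rho_i \ell_i$ is conserved exactly — the suite asserts this at
relative tolerance 1e-9 across widths.

`heterogeneity_curve()` sorts intervals by decreasing rate and accumulates
genome fraction against recombination fraction; `fraction_in_top(0.2)`
interpolates the curve at 20% of the genome (interval granularity makes an
exact cut unattainable). Because the curve sorts by rate, it is monotone and
concave and majorises the diagonal; all three properties are asserted on
random maps. Whether such a statistic is computed on raw inter-SNP intervals
or on 2-kb windows is a genuine choice: both are exposed. Note that windowing
attenuates concentration for the synthetic generator specifically, because
its background rates are drawn independently per interval (see below), while
real LD maps are locally autocorrelated.

`mu_over_r()` converts a pedigree map rate in cM/Mb to per-bp Morgans with
the fixed factor $10^{-8}$ and returns $\mu / r$; `estimate_ne()` implements
$N_e = \theta / 4\mu$. With the coho-salmon pedigree rate of 2.24 cM/Mb these
reproduce the published ratio bounds 0.09–0.45 across the fish-to-human
mutation-rate range ($2 \times 10^{-9}$ to $1 \times 10^{-8}$).

## Hotspot calling

Both callers implement the same qualification rule: an interval (or 2-kb
window) is hotspot-like when its rate is at least `fold` (default 5) times
the bp-weighted mean rate of the `flank` bp on each side (default 50 kb per
side — the flank wording is ambiguous between per-side and total, so the span
is a parameter). Decisions taken where the definition is silent:

* the candidate interval is excluded from its own flank mean — including it
  would dilute the statistic;
* near chromosome ends the available one-sided flank is used;
* missing windows never qualify and break runs of consecutive windows;
* `call_raw_hotspots()` merges maximal runs of contiguous qualifying
  inter-SNP intervals; `call_window_hotspots()` instead retains only the
  highest-rate window of each run (leftmost on ties), yielding fixed 2-kb
  hotspots.

Flank means are computed with prefix sums, so calling is linear in map size;
a naive $O(n^2)$ re-statement of the definition serves as the test oracle.
`summarize_hotspots()` reports count, density per Mb, genome occupancy and
the fraction of total recombination inside hotspots; at the published density
of 13.6 hotspots/Mb with 2-kb widths the occupancy is 2.7%.

## Features and CGIs

CGIs in teleost fish are CpG-rich but *not* GC-rich, so the predictor scores
only CpG content: sliding 500-bp windows stepped by 1 bp, observed/expected
CpG $= \#CG \cdot w / (\#C \cdot \#G)$ (defined as 0 when a window lacks C or
G; N bases count as neither), each position averaged over all covering
windows (the cpgplot dialect; a plain per-window mode is available), runs of
positions with averaged ratio $\ge 0.6$ reported when at least 250 bp long.
The GC floor defaults to 0.

`fold_by_distance()` profiles windowed rates against distance to the nearest
TSS/TES (2-kb bins out to 50 kb, scaled to the 50-kb bin);
`rate_by_feature()` scales class means by the intergenic mean, with
intergenic defined as the complement of genes and TEs; feature classes may
otherwise overlap. TSS/TES regions are the strand-aware gene ends ±1 kb.
Per-bp brute-force oracles pin both functions on small instances.

## Hotspot sharing

`overlap_sets()` counts hotspots of the smaller set overlapping the other set
by ≥1 bp and reports the percentage on the smaller set's size, making the
statistic symmetric. Significance comes from `permutation_null()`: the same
number of 2-kb spots is placed uniformly, without mutual overlap (rejection
sampling with a bounded retry), in the allowed space of a `build_mask()`
mask excluding extreme-diversity windows (outside the 2.5–97.5% quantiles),
the top 0.1% of rates, the largest 10% of assembly gaps, and the hotspots
themselves. The empirical p-value uses the +1 correction and is never exactly
zero; 1,000 permutations is the default, with 100 as the light variant. Under
a null in which both hotspot sets are themselves random placements, the
p-value distribution is calibrated: over 200 simulated pairs the suite
requires between 2% and 10% of datasets at $p \le 0.05$ (the statistic is
discrete, so slight conservatism is expected).

## PRDM9 ZF diversity

`parse_zf_array()` tiles an amino-acid sequence greedily into 28-residue
C2H2 units matching X7-CXXC-X12-HXXXH; a trailing unit whose final histidine
is replaced is kept but flagged degenerate (it cannot coordinate zinc), and
27-residue units are flagged short. Both are excluded from the 28-position
diversity profile by default. Diversity per position is the Gini–Simpson
index $d_j = 1 - \sum_a f_a^2$ over **unique** units — each distinct finger
counted once, because concerted evolution homogenises repeats within arrays
and carrier-weighted frequencies would conflate allele frequency with finger
diversity; a frequency-weighted mode exists. The headline ratio
$r = \sum_{j \in \text{contact}} d_j / \sum_j d_j$ uses the four DNA-contact
positions (α-helix −1, +2, +3, +6), defaulting to unit indices 16/18/19/22.
The literature numbers C2H2 helices inconsistently (one convention places the
same residues at 17/19/20/23), so the mapping is a parameter; with the
generator and analysis sharing one convention, all synthetic results are
internally consistent, and an active array shows $r$ well above the uniform
baseline $4/28 \approx 0.14$.

## PWM scanning and erosion

`score_threshold()` computes the exact distribution of the log-odds score
under the background model by dynamic programming over scores discretised in
0.01-bit bins, and returns the smallest score whose tail probability is at
most the cutoff (default $10^{-7}$). Scanning compares scores in the same
discretised space — mixing exact scores with binned thresholds can lose hits
at the bin edge. For widths ≤ 6 the DP tail equals exhaustive enumeration of
all $4^W$ words to floating precision, which the suite checks over 50 random
matrices. A pseudocount of 0.1 (mixed with the background) is applied before
log-odds; windows containing N are skipped; both strands are scanned.

`erosion_test()` compares mean motif counts between two genome lineages
inside collinear blocks. The observed headline is the percent reduction
$100(\bar c_A - \bar c_B)/\bar c_A$; the significance test uses the raw
between-lineage difference in mean counts, compared with the same difference
recomputed under column-order permutations of the matrix (default 100).
Column shuffling preserves base composition and information content — the
permuted motif is equally motif-like but targets a different word — and it
leaves the exact score distribution unchanged, so one threshold serves all
permutations. The empirical p is two-sided by default (one-sided available).
With the published lineage means (3,329 vs 3,230) the observed reduction is
2.97%.

Supporting operations: GC-matched control sampling (hotspot GC binned at
0.025 and controls drawn per bin from the masked genome, 10 per hotspot by
default), fold-enrichment of motif carriers at hotspots with Fisher's exact
test and the ≥2-fold / ≥5%-of-hotspots retention rule, and a one-tailed
binomial central-enrichment test with a triangular-weighted 250-bp sliding
positional density.

## The synthetic generator and what passing tests mean

`gen_rho_landscape()` draws SNPs as a homogeneous Poisson process and gives
each inter-SNP interval an iid gamma background rate multiplied by a smooth
positional factor: a cosine ramp rising over the outer 20% of each
chromosome to `telomere_fold` (salmonid maps show 3–6× telomeric elevation;
no functional form is published, so a smooth ramp was chosen), and the
planted `fold` inside each planned ~2-kb hotspot. Generator defaults used as
study conditions elsewhere in the package: SNP spacing ~200 bp, background
gamma shape 0.2 (chosen so that rate variation spans orders of magnitude and
the raw-map concentration statistic sits near the observed ~90% in 20%),
telomere fold 4, hotspot folds 10–20 at ~10 hotspots/Mb. What the generator
does **not** emulate: background autocorrelation (rates are iid between
intervals; real LD maps are locally smooth, so windowed concentration
statistics on synthetic data understate real ones), inference noise of the
LD method itself, and the SNP-density/rate coupling of real data. Passing
recovery tests therefore demonstrates correctness of the callers and tests
under the stated generative model, not end-to-end accuracy of LD-based rate
inference.

`gen_zf_alleles()` concatenates units derived from a consensus with
substitutions at contact positions at the requested rate and 10× rarer
elsewhere; the scaffold C/C/H/H never mutates, and the final histidine can
optionally be replaced (H→Y) to emulate the degenerate last finger.
`gen_eroded_genomes()` plants motif-consensus instances, disrupts a fixed
fraction of them — drawn once, as ancestral erosion would — in one lineage by
substituting the worst base at the most informative column, and adds
independent per-genome neutral substitutions elsewhere.

Problem sizes used by the test suite and the acceptance script (chosen to
exercise each statistic at meaningful resolution): a 20-Mb, 10-chromosome
genome with 200 planted hotspots for caller recovery; 200 simulated set
pairs with 99 permutations each for null calibration; ten 100-kb genomes
with 400 planted instances and 100 matrix permutations for erosion recovery;
100 random maps for the conservation and curve-shape properties.

## Numerical choices and edge cases

* All coordinates 0-based half-open; a TSS exactly at a CGI's end coordinate
  is outside it.
* Window ties in the window caller go to the leftmost window.
* An all-zero map has no heterogeneity curve (explicit error), a zero total
  ZF diversity has no ratio (explicit error, not 0), and a zero reference
  lineage mean has no erosion percent.
* Empirical p-values use the +1 correction throughout.
* Random spot placement rejects after a bounded number of retry rounds
  rather than looping forever on infeasible masks.
* All generators take one explicit seed and restore the caller's RNG state.

## Known limitations

The ZF contact-position index mapping is a convention choice (see above);
the published supplementary allele sequences that would pin it are figure
panels not redistributable here, so the ratio values on real alleles are not
reproduced by the suite. The CGI predictor implements one (cpgplot-style)
averaging dialect; other tools tile windows differently. The erosion null
permutes column order only — row (base) permutations would break strand
symmetry and composition. The generator's iid background is a stand-in for
unmodelled rate autocorrelation.
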