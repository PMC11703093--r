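# recfin

Downstream analysis of fine-scale recombination landscapes in fish
population genomics, for researchers working with LD-based recombination
maps (LDhelmet-style inter-SNP output) in species carrying a full-length
PRDM9.

In PRDM9-driven genomes, meiotic recombination concentrates in ~2-kb
hotspots positioned away from promoters by the DNA-binding zinc-finger (ZF)
array of PRDM9; hotspot locations turn over rapidly between populations
because the bound motif erodes through biased gene conversion, which in turn
selects for new ZF alleles (the intra-genomic Red Queen). `recfin`
implements the statistics used to characterise that regime:

* **Landscapes** — reading/writing per-interval maps of the
  population-scaled rate ρ = 4·N<sub>e</sub>·r per bp, bp-weighted window
  smoothing (2 kb / 100 kb / 1 Mb), genome-wide rates, Lorenz-style
  heterogeneity curves ("X% of recombination in the top 20% of the
  genome"), chromosome-percentile profiles (the telomeric U-shape), and the
  parameter arithmetic N<sub>e</sub> = θ/4μ and μ/r (cM/Mb converted at
  1e-8 per bp).
* **Hotspots** — two callers against the local background: merged runs of
  inter-SNP intervals, or single best 2-kb windows, each ≥5-fold above the
  bp-weighted mean of the 50-kb flanks; summaries (density/Mb, occupancy,
  fraction of recombination, width distribution).
* **Features** — a CpG-island predictor for fish genomes (CpG
  observed/expected ≥ 0.6 with no GC floor, cpgplot-style per-position
  averaging), rate enrichment by distance to TSS/TES and per feature class,
  hotspot density per feature, covariate correlations and profiles.
* **Sharing** — percent of hotspots shared between populations (smaller set
  as denominator), tested against random placement of the same number of
  2-kb spots in a masked genome (excluding extreme diversity, extreme
  rates, large gaps and the hotspots themselves).
* **ZF diversity** — parsing C2H2 arrays (X7-CXXC-X12-HXXXH, 28 residues),
  allele cataloguing, per-position Gini–Simpson diversity over unique
  fingers, and the DNA-binding ratio r = Σ d(contact) / Σ d(all 28).
* **Motif erosion** — PWM scanning at an exact DP-computed p-value threshold
  (FIMO-style, default 1e-7), GC-matched control sampling, enrichment and
  central-enrichment tests, and a between-lineage erosion test whose null
  comes from column-order permutations of the matrix.
* **Synthetic data** — a seeded generator for every input: gamma-background
  inter-SNP maps with telomere elevation and planted hotspots, annotations,
  hypervariable ZF alleles, and genome lineages with a known fraction of
  motif instances disrupted.

## Worked example

```r
library(recfin)

spec <- synthetic_genome_spec(c(chr1 = 2e6, chr2 = 2e6), seed = 7)
plan <- hotspot_plan(c("chr1", "chr1", "chr2"), c(5e5, 1.2e6, 8e5), fold = 15)
map  <- gen_rho_landscape(spec, snp_density = 1/200, background_mean = 0.005,
                          background_shape = 0.2, telomere_fold = 4, plan = plan)

genome_wide_rate(map)
#> [1] 0.008294712
100 * fraction_in_top(heterogeneity_curve(map), 0.2)
#> [1] 86.47334

w2k <- smooth_windows(map, 2000)
hs  <- call_window_hotspots(w2k, fold = 5, flank = 50000)
head(as.data.frame(hs), 3)
#>   chrom  start    end       peak  flank_mean     fold
#> 1  chr1  32000  34000 0.10970154 0.020068036 5.466481
#> 2  chr1  82000  84000 0.09821965 0.018428646 5.329727
#> 3  chr1 182000 184000 0.06951782 0.013700417 5.074139
summarize_hotspots(hs, w2k)
#> Hotspots: 18
#>   fraction of recombination: 0.062
#>   density: 4.50 per Mb
#>   genome occupancy: 0.90%
```

The genome-wide rate recovers the generator's settings (background 0.005/bp
times the telomeric elevation), 86.5% of the recombination sits in the most
recombining fifth of the genome, and all three planted hotspots are among
the 18 calls (the rest are genuine 5-fold excursions of the heavy-tailed
background). The ZF side works the same way:

```r
alleles <- gen_zf_alleles(20, contact_variability = 0.4, seed = 11)
aset    <- catalogue_alleles(alleles)
dna_binding_ratio(position_diversity(collect_units(aset)))
#> [1] 0.596
```

A ratio near 0.6 — far above the uniform baseline 4/28 ≈ 0.14 — is the
signature of diversity concentrated at the four DNA-contact residues, as
seen in active PRDM9 arrays.

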