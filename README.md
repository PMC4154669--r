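# ernascan

Discovery of tissue-specific enhancer RNA (eRNA) transcription from
strand-specific total RNA-seq of two tissues.

Active enhancers are commonly transcribed into short bidirectional
non-coding RNAs whose abundance tracks enhancer activity. Given uniquely
mapped, strand-specific reads from two tissues plus a gene annotation,
`ernascan` finds **tissue-specifically transcribed regions (TSTRs)** —
intergenic regions with significantly higher read density in one tissue —
and characterizes them against the canonical enhancer evidence:
evolutionary constraint (phastCons), CAGE-defined transcription start
sites, p300/H3K27ac ChIP enrichment, and catalogs of in vivo validated
enhancers. It is aimed at regulatory genomicists who want an auditable,
fully testable implementation of this analysis, including a seeded
synthetic-data generator with planted ground truth.

## The statistic at the core

Reads are extended to 200 bp in the 3' direction; a 500 bp window sliding
in 50 bp steps keeps every position with ≥ 10 overlapping reads
(strand-agnostic), merged into maximal regions and filtered against the
annotation. For each region, reads are counted in a 2 kb window around
the peak center in both tissues. With n the window count, N the library
size (unique reads excluding rRNA), p̂ᵢ = nᵢ/Nᵢ and the pooled
p₀ = (n_A + n_B)/(N_A + N_B):

    z = (p̂_A − p̂_B) / sqrt( p₀ (1 − p₀) (1/N_A + 1/N_B) )

A region is a TSTR of the higher-proportion tissue when the two-sided
p = 2Φ(−|z|) < 0.01. Per region the package also computes RPKM, the
tissue-specificity index (s−u)/(s+u) and the strand directionality index
|f−r|/(f+r), plus background calibration (100-iteration random-region
normal fit), Fisher-exact feature enrichment, trimmed-mean strand-split
metaprofiles, ±25 kb z-scaled ChIP heatmaps, and binned correlation of
TSTR specificity with the 1st–5th nearest genes.

## Worked example

```r
library(ernascan)

# a complete synthetic two-tissue world: 2 x 1 Mb genome, genes, rRNA,
# 100 tissue-specific + 100 non-specific planted intergenic loci,
# p300/H3K27ac/phastCons/CAGE tracks and a validated-enhancer catalog
config <- pipeline_config(sim = sim_config(seed = 1), seed = 1)
result <- run_pipeline(config, outdir = "ernascan_out")
print(result)
```

```
ernascan pipeline result
TSTR discovery fit
  candidate intergenic regions: 200
  A-specific TSTRs (p < 0.01): 51
  B-specific TSTRs (p < 0.01): 50
  not tissue-specific: 99
  enhancer concordance: 100%
  conservation: 35% of TSTRs vs 19% of controls (p = 0.00045)
  neighbor correlation (rank 1): R = 0.083
```

Reading this: all 200 planted intergenic loci survive the annotation
filter and are tested; 101 are called tissue-specific at p < 0.01 —
the 100 truly specific loci (5-fold planted difference) plus one false
call among the 100 non-specific loci. Every cataloged enhancer has more
eRNA reads in its annotated activity tissue (concordance 100%), TSTR
windows overlap conserved elements about twice as often as size-matched
random intergenic controls, and the near-zero nearest-gene correlation
reflects that this synthetic world plants no TSTR–gene coupling (that
machinery is tested on coupled fixtures). `ernascan_out/` holds the TSTR
table, volcano and background tables, class summaries, profile and
heatmap matrices, the correlation table, and `report.txt` echoing the
full configuration.

A thin CLI wraps the same functions:

```sh
Rscript inst/scripts/ernascan simulate --seed 1 --outdir fixtures/
Rscript inst/scripts/ernascan run --input fixtures/ --seed 1 --outdir out/
```

## Acceptance script

`scripts/acceptance.R` re-runs the full pipeline from scratch on the
default simulated world under a given seed — fixture generation, read
extension, discovery, filtering, TSTR calling, background calibration,
feature overlap, profiling and correlation — and writes its JSON result
manifest:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
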