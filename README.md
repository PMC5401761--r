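# mosaicAncestry

Dissecting the subspecies origin of a chromosome from a
chromosome-substitution (consomic) mouse strain.

When an inbred host strain carries one chromosome from an outbred donor —
such as the Chinese Kunming (KM) stock, descended from Swiss mice — that
chromosome can be a mosaic of segments derived from the three house-mouse
subspecies (*M. m. domesticus*, *M. m. musculus*, *M. m. castaneus*).
`mosaicAncestry` takes such a chromosome from variant calls to an ancestry
map:

* **Variant filtering** with the strict pileup-caller clauses
  `QUAL > 10 && MQ > 25 && 6 < DP < 199 && DP4[alt-fwd]+DP4[alt-rev] > 2`,
  indel-proximity removal, left-aligned known/novel classification against
  variant catalogs, SNP-density window profiles, and summary percentages.
* **Consequence annotation** of SNPs/indels against gene models under a
  total severity ladder (splice donor/acceptor > stop gained > frameshift >
  ... > intergenic) with strand-aware codon translation, plus a
  disease-gene join.
* **Ancestry painting**: a consensus sequence per strain (SNP alleles
  substituted into the reference; het sites become N), windowed identity

  sim(w) = matches(w) / callable(w)

  in 100 kb blocks and 500 kb / 100 kb sliding windows against one
  wild-derived representative per subspecies. Windows above the
  within-subspecies similarity band (> 99.7%) merge into introgression
  tracts; between-subspecies segments sit near 99.05–99.1%.
* **Topology concordance**: 200 kb loci → p-distance → neighbor-joining →
  outgroup rooting → the focal strain's sister taxon, with bootstrap
  support from column resampling; genome-wide concordance factors are the
  fraction of loci supporting each sister relationship.
* **A synthetic mosaic-chromosome generator** (calibrated divergences,
  exact tract quotas, VCF/BED/GFF3/FASTA emission, ground-truth JSON) that
  makes every stage testable end to end, since the analysis is validated by
  recovering known truth.

## A worked example

```r
library(mosaicAncestry)

cfg <- pipelineConfig(
  params = simulationParams(chromosomeLength = 2e6, nGenes = 10,
                            meanTractLength = 4e5, seed = 3),
  bootstrap = 50, outDir = "run1")
report <- runPipeline(cfg)

round(100 * unlist(report$concordance), 1)
#> FOCAL_WITH_DOM FOCAL_WITH_MUS FOCAL_WITH_CAS     UNRESOLVED
#>             90             10              0              0
report$meanSnpDensity
#> [1] 251.9
round(100 * unlist(report$recovery$truthFractions), 1)
#>  CAS  DOM  MUS
#>  2.6 87.7  9.7
```

Here 90% of the 200 kb loci place the focal chromosome sister to the
domesticus representative and 10% sister to musculus — recovering the
simulated truth (87.7 / 9.7 / 2.6% of sequence; the small castaneus tract
is shorter than a locus and is absorbed). The mean SNP density of ~252 per
100 kb window reflects the mixture of host-like segments (~200/100 kb at
0.2% divergence) and introgressed segments (~920/100 kb at 0.92%).
`run1/` contains the stage outputs as plain files (VCF, BED, GFF3, FASTA,
TSV profiles, bedGraph tracks, JSON report and manifest), and
`report$recovery` holds the confusion of truth donors vs locus labels.

A thin CLI over the same functions is installed at
`inst/scripts/mosaic-pipeline.R` (subcommands `simulate` and `run`).

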