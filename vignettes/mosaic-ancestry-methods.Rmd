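---
title: "Dissecting the subspecies origin of a mosaic chromosome"
author: "mosaicAncestry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting the subspecies origin of a mosaic chromosome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosaicAncestry)
```

## The problem

A chromosome-substitution (consomic) mouse strain carries one chromosome
from a donor stock on an otherwise inbred host background. When the donor
is an outbred stock such as the Chinese Kunming mouse, the substituted
chromosome can itself be a mosaic of segments derived from the three house
mouse subspecies (*M. m. domesticus*, *M. m. musculus*,
*M. m. castaneus*). This package implements the analysis chain used to
dissect such a chromosome from its variant calls:

1. **variants** — strict quality filtering of SNP/indel calls and
   known/novel classification against variant catalogs;
2. **annotate** — a simplified functional-consequence classifier against
   gene models, with Table-style tallies and a disease-gene join;
3. **ancestry** — consensus construction and windowed sequence-similarity
   "painting" of the focal chromosome against one wild-derived
   representative strain per subspecies (WSB-, PWK-, CAST-like);
4. **concordance** — locus-wise neighbor-joining trees with outgroup
   rooting and bootstrap support, summarized as genome-wide concordance
   factors for the focal strain's sister taxon;
5. **simulate** — a synthetic mosaic-chromosome generator with ground
   truth, so every stage can be exercised and validated end to end.

## The similarity model

All sequences share reference coordinates (consensus construction
substitutes SNP alleles and never shifts positions), so similarity is a
direct positional comparison. For a window $w$ and two sequences, with
$C_w$ the callable sites (unmasked, non-N in both) and $M_w$ the matches,

$$\mathrm{sim}(w) = M_w / C_w,$$

undefined when $C_w$ falls below `minCallable` (default 1000; heavily
masked windows give unstable ratios). Block mode (100 kb/100 kb) keeps the
terminal partial window, so a 195.5 Mb chromosome yields exactly 1955
blocks. Sliding mode uses 500 kb windows at 100 kb steps. The two
similarity bands that drive the analysis are:

* between subspecies: ~0.9% divergence, i.e. similarity ≈ 99.05–99.1%;
* within a subspecies: <0.3% divergence, similarity > 99.7%.

Introgression tracts are called from the sliding profile as maximal runs
of windows whose similarity **strictly** exceeds 0.997, merged when
overlapping or adjacent; the reported fraction divides merged tract length
by the full chromosome length (undefined windows can never qualify — they
are excluded from the numerator while the denominator stays the whole
chromosome, a choice the tract fractions are robust to at these mask
levels).

## The concordance model

The chromosome alignment (focal consensus, three subspecies
representatives, and a distant outgroup) is partitioned into loci —
fixed-length 200 kb tiles by default. Per locus, distances are p-distances
over the locus's callable columns (a JC69 correction is available but the
decision problem at <1.5% divergence is insensitive to it), trees are
built by the standard Saitou–Nei neighbor-joining agglomeration, rooted at
the outgroup, and the focal tip's sister clade is read off: exactly one
representative in the sister clade gives the locus label
(`FOCAL_WITH_DOM` / `MUS` / `CAS`); anything else is `UNRESOLVED`.

Support comes from the classical bootstrap: columns are resampled $B$
times and each replicate goes through distance → NJ → classification. For
speed, a locus is collapsed to its distinct pairwise-mismatch site
patterns, so a bootstrap replicate is a multinomial draw over patterns and
one matrix product; this is exact, not an approximation. Replicates with
no mismatching column are star-like and vote `UNRESOLVED`; ties or a
winning frequency below `minSupport` (default 0.5) also yield
`UNRESOLVED`. Genome-wide concordance factors are the label fractions over
classified loci.

Two deliberate methodological substitutions, chosen because they keep the
same five-taxon decision problem deterministic under a seed at desk
scale: (a) Bayesian concordance analysis over gene-tree posteriors is
replaced by bootstrap-vote concordance factors; (b) minimum-description-
length locus partitioning is replaced by fixed-length loci, with an
optional penalized binary-segmentation changepoint mode
(`partitionLoci(mode = "changepoint")`, penalty $c \cdot k \log n$ on
standardized per-bin mismatch profiles).

## What the generator emulates

`simulateHaplotypes()` draws a uniform-random ancestral chromosome and
evolves it by independent-site substitutions with uniform resampling
(Jukes–Cantor-like): only pairwise divergence levels matter downstream, so
a richer substitution model would add parameters without changing any
decision. Under this kernel two substitution layers compose as
$s_{12} = s_1 + s_2 - \tfrac{4}{3}s_1 s_2$, which lets the per-branch
substitution probabilities be solved **exactly** for the divergence
targets rather than hoping small rates add linearly (at outgroup distances
of 0.15 the naive sum is off by more than a realized 3σ band).

The branch scheme places the within-subspecies diversity *inside* each
subspecies: a latent subspecies ancestor, with the visible representative
and any focal-donor haplotype each about half the intra-subspecies
divergence away from it. Consequently the focal chromosome sits at
`divergenceIntra` (default 0.002) from its donor's representative and at
`divergenceInter` (default 0.0092) from the other representatives — both
similarity bands hold simultaneously, which a naive "donor + private
mutations on top" scheme cannot achieve. The reference-like host is itself
a domesticus haplotype, so SNP densities against the reference come out
near 200–250 per 100 kb on domesticus-derived segments and >800 per
100 kb on introgressed ones, reproducing the low/high density classes the
variant summaries use.

Mosaic tracts have exact breakpoints. Tract layout uses a quota scheme:
each donor receives exactly `round(fraction × L)` bases, split into a
number of tracts targeting `meanTractLength` with exponential weights,
then shuffled. Realized donor fractions therefore equal the nominal ones
at every seed — the recovery analyses measure the method's boundary
behavior, not the generator's sampling noise. Defaults follow the headline
composition (87.7% domesticus, 9.7% musculus, 2.6% castaneus on a 20 Mb
chromosome with 2 Mb mean tracts).

Variant emission turns every mismatching callable site into a
homozygous-alternate SNP with synthetic QUAL/MQ/DP/DP4 fields (depth
Poisson around 36.6×, the coverage class of the data being emulated);
3.58% of records are flagged heterozygous (so homozygosity summaries come
out near 96.4%) and a low indel rate (4×10⁻⁴ per callable site) adds
insertion/deletion records that are emitted and filtered but never enter
the consensus. Corruption fractions per filter clause support filter
testing. What the generator does **not** emulate: read-level errors and
coverage waves, alignment artifacts, segmental duplications, SVs,
recombination genealogies within tracts, and reference bias — so green
recovery tests certify the analysis logic under the stated divergence
structure, not robustness to every artifact of real resequencing data.

## Numerical and design choices

* **Filter clauses are strict inequalities** (`QUAL > 10`, `MQ > 25`,
  `6 < DP < 199`, alt-supporting DP4 reads `> 2`), matching the filter
  expression convention they come from; boundary records fail.
* **Proximity filter**: SNPs within 10 bp of an indel and indels within
  3 bp of another indel are removed, symmetrically.
* **Indel normalization**: left-alignment against the reference before
  catalog matching, since dbSNP-style matching is representation
  sensitive; multi-allelic records are split to atomic alleles on read.
* **Percentages** round half-up at the displayed precision (summary
  tables mix one- and two-decimal displays); the consequence-tally
  denominator is total consequence assignments per variant class, not
  distinct variants — the convention under which the published intron
  share of 47.8% arises from its column sum.
* **Splice conventions** (VEP-like): donor/acceptor = first/last 2
  intronic bases; splice region = 1–3 exonic or 3–8 intronic bases from
  the junction. The severity ladder is total, so each
  (variant, transcript) pair gets exactly one category; start-loss is
  checked only on the annotated initiator codon; NMD-flagged transcripts
  always report `NMD_transcript_variant`.
* **Gene models**: the generator writes ATG/stop and recodes in-frame
  internal stops identically across all haplotypes, so translated CDS are
  clean while pairwise divergences are untouched.
* **NJ details**: negative branch lengths are clamped to zero; trees are
  ladderized so equal inputs give identical output; loci whose callable
  columns fall below `minInformative` (default 1000) are skipped with a
  logged reason, as are loci where the outgroup is uncallable (those
  columns are excluded globally by the callable-column rule).
* **Auxiliary caller-specific filter hook** (`varFilterHook`): one
  published filtering step has no reconstructible definition; it is a
  named no-op, default off, so configurations can state it explicitly.

## Problem sizes

The packaged tests exercise 2 Mb chromosomes for module behavior and
20 Mb chromosomes (100 loci × 200 kb, 200 bootstrap replicates) for the
recovery analyses; `scripts/acceptance.R` uses the same 20 Mb
configurations. These sizes give per-window and per-locus callable counts
(~10⁵) at which binomial noise on similarities (~3×10⁻⁴) is far below the
band separations the decisions depend on (>5×10⁻³), so results are stable
across seeds.

## A worked example

```{r example, eval = FALSE}
cfg <- pipelineConfig(
  params = simulationParams(chromosomeLength = 2e6, nGenes = 10,
                            meanTractLength = 4e5, seed = 3),
  bootstrap = 50, outDir = "run1")
report <- runPipeline(cfg)
report$concordance      # locus fractions per topology label
report$tractFractions   # painted high-similarity fraction per strain
report$recovery         # confusion of truth donor vs locus label
```

## Known limitations

* Similarity is strictly positional; structural variation or large
  indels between genomes would require realignment, which is out of
  scope.
* The consequence classifier implements the categories and conventions
  listed above, not a full VEP rule set (no MANE/canonical logic, no
  miRNA-specific categories, no protein-impact scores; externally
  computed deleteriousness scores can be joined onto the call table).
* Bootstrap concordance factors are not posterior concordance factors;
  they agree on well-separated topologies but their uncertainty
  calibration differs.
* With five taxa the topology space is tiny; the implementation is not
  tuned for larger panels.
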