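## Shared small-scale fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

## 2 Mb mosaic simulation with the default divergence structure; used by
## several modules. Mean tract 400 kb keeps a multi-donor mosaic at this
## scale.
smallSim <- function() {
  if (is.null(.fixtures$small)) {
    p <- simulationParams(chromosomeLength = 2e6, nGenes = 20,
                          meanTractLength = 4e5, seed = 42)
    haps <- simulateHaplotypes(p)
    models <- emitGeneModels(p)
    haps <- harmonizeCodingSequence(haps, models)
    mask <- emitMask(p)
    mos <- simulateMosaic(p, haps, mask = mask)
    ref <- maskedSequence(haps@sequences[["REF"]], mask = mask,
                          label = "REF")
    .fixtures$small <- list(p = p, haps = haps, models = models,
                            mask = mask, mos = mos, ref = ref)
  }
  .fixtures$small
}

## masked sequence view of one panel haplotype sharing the run's mask
panelSeq <- function(sim, label) {
  maskedSequence(sim$haps@sequences[[label]], mask = sim$mask,
                 label = label)
}

## one fully populated variant record that passes every filter clause
passingRecord <- function(qual = 50, mq = 50, dp = 30, altF = 14,
                          altR = 14, pos = 100, ref = "A", alt = "G") {
  data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt, qual = qual,
             mq = mq, dp = dp, dp4_rf = 0L, dp4_rr = 0L, dp4_af = altF,
             dp4_ar = altR, genotype = "hom_alt",
             vclass = ifelse(nchar(ref) == nchar(alt), "snp",
                             ifelse(nchar(ref) < nchar(alt), "insertion",
                                    "deletion")),
             stringsAsFactors = FALSE)
}

## random variant table for property-style filter tests
randomRecords <- function(n, seed) {
  withr::with_seed(seed, {
    data.frame(chrom = "chr1", pos = sort(sample.int(1e6, n)),
               ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
               alt = "N", qual = round(stats::runif(n, 0, 60), 1),
               mq = sample(0:60, n, replace = TRUE),
               dp = sample(0:250, n, replace = TRUE),
               dp4_rf = sample(0:20, n, replace = TRUE),
               dp4_rr = sample(0:20, n, replace = TRUE),
               dp4_af = sample(0:10, n, replace = TRUE),
               dp4_ar = sample(0:10, n, replace = TRUE),
               genotype = "hom_alt", vclass = "snp",
               stringsAsFactors = FALSE)
  })
}

## hand-built single-gene models on a short chromosome, for exact
## consequence expectations. Layout (1-based, + strand):
##   exon1 101-160, intron 161-300, exon2 301-400
##   CDS: 121-160 (exon1) + 301-340 (exon2)  -> 80 bases... adjusted to 81
toyGene <- function(strand = "+", biotype = "coding") {
  ex <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(101, 301), c(160, 400)), strand = strand)
  cds <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(c(121, 301), c(160, 341)), strand = strand)
  tx <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 400),
    strand = strand, gene_id = "geneT", tx_id = "txT", biotype = biotype)
  methods::new("GeneModels", transcripts = tx,
               exons = GenomicRanges::GRangesList(txT = ex),
               cds = GenomicRanges::GRangesList(txT = cds))
}

## reference chromosome carrying the toy gene with a known CDS
toyReference <- function(strand = "+") {
  set.seed(7)
  base <- sample(c("A", "C", "G", "T"), 1000, replace = TRUE)
  cdsPlus <- paste0("ATG", strrep("AAACCCGGGTTTACGCAT", 4), "AAATAA")
  stopifnot(nchar(cdsPlus) == 81)
  cdsSeq <- if (strand == "+") cdsPlus
    else as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(cdsPlus)))
  ## cdsSeq is in genomic orientation (reverse-complemented already for the
  ## minus strand), so it lays out over ascending genomic positions
  cdsChars <- strsplit(cdsSeq, "")[[1]]
  base[121:160] <- cdsChars[1:40]
  base[301:341] <- cdsChars[41:81]
  maskedSequence(paste(base, collapse = ""), label = "REF")
}

toyVariant <- function(pos, ref, alt, vclass = NULL) {
  v <- passingRecord(pos = pos, ref = ref, alt = alt)
  if (!is.null(vclass)) v$vclass <- vclass
  v
}
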