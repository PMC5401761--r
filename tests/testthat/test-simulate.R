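test_that("zero divergence gives identical subspecies haplotypes", {
  p <- simulationParams(chromosomeLength = 5e4, divergenceInter = 0,
                        divergenceIntra = 0, divergenceOutgroup = 0.15,
                        nGenes = 0, maskFraction = 0, seed = 1)
  h <- simulateHaplotypes(p)
  s <- as.character(h@sequences)
  expect_identical(s[["DOM"]], s[["MUS"]])
  expect_identical(s[["DOM"]], s[["CAS"]])
  expect_identical(s[["DOM"]], s[["REF"]])
  expect_false(identical(s[["DOM"]], s[["OUT"]]))
})

test_that("realized pairwise divergences hit their targets within 3 sigma", {
  mismatch <- function(h, a, b) {
    ra <- charToRaw(as.character(h@sequences[[a]]))
    rb <- charToRaw(as.character(h@sequences[[b]]))
    mean(ra != rb)
  }
  for (L in c(1e5, 1e6)) {
    p <- simulationParams(chromosomeLength = L, nGenes = 0, seed = 11)
    h <- simulateHaplotypes(p)
    tol <- function(d) 3 * sqrt(d * (1 - d) / L)
    expect_lt(abs(mismatch(h, "DOM", "MUS") - 0.0092), tol(0.0092))
    expect_lt(abs(mismatch(h, "MUS", "CAS") - 0.0092), tol(0.0092))
    expect_lt(abs(mismatch(h, "REF", "DOM") - 0.0020), tol(0.0020))
    expect_lt(abs(mismatch(h, "OUT", "DOM") - 0.15), tol(0.15))
  }
})

test_that("saturating divergence is rejected", {
  expect_error(simulationParams(divergenceOutgroup = 0.8),
               "saturates|\\[0, 1\\)")
  expect_error(simulationParams(divergenceIntra = 0.5,
                                divergenceInter = 0.2), "divergenceIntra")
})

test_that("mosaic truth tracts tile the chromosome with exact donor quotas", {
  sim <- smallSim()
  tr <- truthTracts(sim$mos$truth)
  expect_identical(tr$start[1], 0)
  expect_identical(tr$end[nrow(tr)], sim$p$chromosomeLength)
  expect_true(all(tr$start[-1] == tr$end[-nrow(tr)]))
  fr <- donorFractions(sim$mos$truth)
  expect_lt(abs(fr[["DOM"]] - 0.877), 1e-3)
  expect_lt(abs(fr[["MUS"]] - 0.097), 1e-3)
  expect_lt(abs(fr[["CAS"]] - 0.026), 1e-3)
})

test_that("single-donor mosaic is one whole-chromosome tract", {
  p <- simulationParams(chromosomeLength = 1e5, nGenes = 0,
                        tractFractions = c(DOM = 1),
                        meanTractLength = 2e4, maskFraction = 0, seed = 2)
  h <- simulateHaplotypes(p)
  m <- simulateMosaic(p, h)
  tr <- truthTracts(m$truth)
  expect_identical(nrow(tr), 1L)
  expect_identical(tr$donor, "DOM")
  expect_error(simulateMosaic(simulationParams(chromosomeLength = 1e4,
                                               meanTractLength = 2e4,
                                               nGenes = 0), h),
               "meanTractLength")
})

test_that("mask coverage matches maskFraction and full masking propagates", {
  p <- simulationParams(chromosomeLength = 5e5, maskFraction = 0.3,
                        nGenes = 0, seed = 3)
  mask <- emitMask(p)
  expect_lt(abs(sum(IRanges::width(mask)) / 5e5 - 0.3), 0.01)
  pAll <- simulationParams(chromosomeLength = 5e4, maskFraction = 1,
                           nGenes = 0, meanTractLength = 1e4, seed = 3)
  h <- simulateHaplotypes(pAll)
  m <- simulateMosaic(pAll, h)
  prof <- windowSimilarity(m$focal, panelSeq(list(haps = h,
                                                  mask = maskRanges(m$focal)),
                                             "MUS"),
                           size = 1e4, step = 1e4)
  expect_true(all(is.na(profileWindows(prof)$similarity)))
})

test_that("identical sequences emit no variants", {
  p <- simulationParams(chromosomeLength = 1e4, nGenes = 0,
                        maskFraction = 0, indelRate = 0, seed = 4)
  s <- maskedSequence(strrep("ACGT", 2500), label = "A")
  expect_identical(nrow(emitVariants(s, s, p)), 0L)
})

test_that("emitted SNP count matches the divergence expectation", {
  sim <- smallSim()
  v <- emitVariants(sim$mos$focal, sim$ref, sim$p)
  callable <- sim$p$chromosomeLength - sum(IRanges::width(sim$mask))
  ## focal-vs-REF divergence: intra within DOM tracts, inter elsewhere
  fr <- donorFractions(sim$mos$truth)
  d <- fr[["DOM"]] * 0.002 + (1 - fr[["DOM"]]) * 0.0092
  expected <- d * callable
  expect_lt(abs(sum(v$vclass == "snp") - expected),
            4 * sqrt(expected))
  expect_gt(sum(v$vclass != "snp"), 0)
})

test_that("clause-targeted corruption hits the requested rate", {
  p <- simulationParams(chromosomeLength = 5e5, nGenes = 0,
                        maskFraction = 0, hetFraction = 0, indelRate = 0,
                        meanTractLength = 1e5,
                        corruptFractions = c(depth = 0.1), seed = 5)
  h <- simulateHaplotypes(p)
  m <- simulateMosaic(p, h, mask = IRanges::IRanges())
  v <- emitVariants(m$focal, maskedSequence(h@sequences[["REF"]],
                                            label = "REF"), p)
  bad <- v$dp <= 6 | v$dp >= 199
  expect_lt(abs(mean(bad) - 0.1), 0.02)
})

test_that("gene models have clean structure and translate after harmonize", {
  p <- simulationParams(chromosomeLength = 1e6, nGenes = 50,
                        meanTractLength = 2e5, seed = 3)
  h <- simulateHaplotypes(p)
  g <- emitGeneModels(p)
  tx <- g@transcripts
  expect_identical(length(tx), 50L)
  ## genes non-overlapping
  expect_identical(
    length(IRanges::reduce(IRanges::ranges(tx))), 50L)
  h2 <- harmonizeCodingSequence(h, g)
  refraw <- charToRaw(as.character(h2@sequences[["REF"]]))
  for (txid in tx$tx_id[tx$biotype == "coding"]) {
    cds <- g@cds[[txid]]
    expect_identical(sum(GenomicRanges::width(cds)) %% 3L, 0L)
    sc <- mosaicAncestry:::splicedCds(g, txid, refraw)
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(sc$seq)))
    expect_identical(substr(aa, 1, 1), "M")
    internal <- substr(aa, 1, nchar(aa) - 1)
    expect_false(grepl("*", internal, fixed = TRUE))
  }
})

test_that("same seed gives byte-identical FASTA, VCF, BED and GFF3", {
  run <- function(dir) {
    p <- simulationParams(chromosomeLength = 2e5, nGenes = 5,
                          meanTractLength = 5e4, seed = 9)
    h <- simulateHaplotypes(p)
    g <- emitGeneModels(p)
    h <- harmonizeCodingSequence(h, g)
    mask <- emitMask(p)
    m <- simulateMosaic(p, h, mask = mask)
    ref <- maskedSequence(h@sequences[["REF"]], mask = mask, label = "REF")
    v <- emitVariants(m$focal, ref, p)
    dir.create(dir, showWarnings = FALSE)
    writeFasta(m$focal, file.path(dir, "f.fa"))
    writeVariantVcf(v, file.path(dir, "v.vcf"), p$chromosomeLength)
    writeBed(mask, file.path(dir, "m.bed"))
    writeGeneModelsGff3(g, file.path(dir, "g.gff3"))
    dir
  }
  d1 <- run(tempfile()); d2 <- run(tempfile())
  for (f in c("f.fa", "v.vcf", "m.bed", "g.gff3"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
})

test_that("variant emission round-trips through consensus construction", {
  p <- simulationParams(chromosomeLength = 2e5, nGenes = 0,
                        meanTractLength = 5e4, hetFraction = 0,
                        indelRate = 0, seed = 12)
  h <- simulateHaplotypes(p)
  mask <- emitMask(p)
  m <- simulateMosaic(p, h, mask = mask)
  ref <- maskedSequence(h@sequences[["REF"]], mask = mask, label = "REF")
  v <- emitVariants(m$focal, ref, p)
  cons <- buildConsensus(ref, v, label = "KM")
  ## equality at all callable (unmasked) sites
  keep <- !mosaicAncestry:::maskLogical(mask, length(ref))
  expect_identical(charToRaw(as.character(dnaSeq(cons)))[keep],
                   charToRaw(as.character(dnaSeq(m$focal)))[keep])
})
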