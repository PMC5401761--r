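## Toy gene (+ strand): exon1 101-160, intron 161-300, exon2 301-400,
## CDS 121-160 + 301-341 spelling ATG (AAACCCGGGTTTACGCAT)x4 AAATAA.

test_that("plus-strand codon logic covers every coding category", {
  g <- toyGene("+"); ref <- toyReference("+")
  classify1 <- function(pos, from, to, vclass = NULL) {
    v <- toyVariant(pos, from, to, vclass)
    classifyConsequences(v, g, ref)$category
  }
  expect_identical(classify1(144, "A", "G"), "synonymous_variant") # AAA->AAG
  expect_identical(classify1(127, "C", "T"), "missense_variant")   # CCC->TCC
  expect_identical(classify1(124, "A", "T"), "stop_gained")        # AAA->TAA
  expect_identical(classify1(340, "A", "C"), "stop_lost")          # TAA->TCA
  expect_identical(classify1(340, "A", "G"), "stop_retained_variant") # ->TGA
  expect_identical(classify1(121, "A", "G"), "start_lost")         # ATG->GTG
  expect_identical(classify1(130, "GGG", "G", "deletion"),
                   "frameshift_variant")
  expect_identical(classify1(130, "GGGT", "G", "deletion"),
                   "inframe_deletion")
  expect_identical(classify1(130, "G", "GAT", "insertion"),
                   "frameshift_variant")
  expect_identical(classify1(130, "G", "GATA", "insertion"),
                   "inframe_insertion")
})

test_that("splice, UTR, intron and flank categories follow the conventions", {
  g <- toyGene("+"); ref <- toyReference("+")
  classify1 <- function(pos, alt = NULL) {
    from <- substr(as.character(dnaSeq(ref)), pos, pos)
    to <- if (is.null(alt)) setdiff(c("A", "C", "G", "T"), from)[1] else alt
    v <- toyVariant(pos, from, to)
    classifyConsequences(v, g, ref)$category
  }
  expect_identical(classify1(161), "splice_donor_variant")
  expect_identical(classify1(162), "splice_donor_variant")
  expect_identical(classify1(299), "splice_acceptor_variant")
  expect_identical(classify1(300), "splice_acceptor_variant")
  expect_identical(classify1(165), "splice_region_variant")  # intronic 3-8
  ## CAT -> CAC is synonymous, so the exonic 1-3 splice-region rank wins
  expect_identical(classify1(159, "C"), "splice_region_variant")
  expect_identical(classify1(230), "intron_variant")
  expect_identical(classify1(110), "5_prime_UTR_variant")
  expect_identical(classify1(380), "3_prime_UTR_variant")
  expect_identical(classify1(50), "upstream_gene_variant")
  expect_identical(classify1(450), "downstream_gene_variant")
  ## beyond a short flank the variant is intergenic
  v <- toyVariant(50, substr(as.character(dnaSeq(ref)), 50, 50), "N")
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  expect_identical(classifyConsequences(v, g, ref, flank = 20)$category,
                   "intergenic_variant")
})

test_that("minus-strand transcripts complement codons and flip flanks", {
  g <- toyGene("-"); ref <- toyReference("-")
  classify1 <- function(pos, from, to) {
    classifyConsequences(toyVariant(pos, from, to), g, ref)$category
  }
  refc <- function(pos) substr(as.character(dnaSeq(ref)), pos, pos)
  ## initiator codon sits at genomic 341-339
  expect_identical(classify1(341, refc(341), "C"), "start_lost")
  ## codon3 (CCC) first base is genomic 335 (complemented)
  expect_identical(classify1(335, refc(335), "T"), "missense_variant")
  ## downstream of a minus-strand gene is genomically left
  v <- toyVariant(50, refc(50), setdiff(c("A", "C", "G", "T"),
                                        refc(50))[1])
  expect_identical(classifyConsequences(v, g, ref)$category,
                   "downstream_gene_variant")
  ## splice donor of a minus-strand intron is its genomic right edge
  expect_identical(classify1(300, refc(300), setdiff(c("A", "C", "G", "T"),
                                                     refc(300))[1]),
                   "splice_donor_variant")
})

test_that("NMD and noncoding transcripts get their dedicated categories", {
  ref <- toyReference("+")
  nmd <- toyGene("+", biotype = "nmd")
  v <- toyVariant(127, "C", "T")
  expect_identical(classifyConsequences(v, nmd, ref)$category,
                   "NMD_transcript_variant")
  nc <- toyGene("+", biotype = "noncoding")
  nc@cds <- GenomicRanges::GRangesList()
  expect_identical(classifyConsequences(v, nc, ref)$category,
                   "non_coding_transcript_exon_variant")
  vIntron <- toyVariant(230, substr(as.character(dnaSeq(ref)), 230, 230),
                        "A")
  vIntron$alt <- setdiff(c("A", "C", "G", "T"), vIntron$ref)[1]
  expect_identical(classifyConsequences(vIntron, nc, ref)$category,
                   "non_coding_transcript_variant")
})

test_that("a disagreeing ref allele raises an error naming the position", {
  g <- toyGene("+"); ref <- toyReference("+")
  wrong <- setdiff(c("A", "C", "G", "T"),
                   substr(as.character(dnaSeq(ref)), 126, 126))[1]
  expect_error(classifyConsequences(toyVariant(126, wrong, "T"), g, ref),
               "126")
})

test_that("every variant gets at least one call and counts are conserved", {
  sim <- smallSim()
  v <- emitVariants(sim$mos$focal, sim$ref, sim$p)
  v <- filterVariants(v)
  calls <- classifyConsequences(v, sim$models, sim$ref)
  expect_true(all(seq_len(nrow(v)) %in% calls$variant))
  ## one category per (variant, transcript) pair
  expect_false(anyDuplicated(calls[, c("variant", "tx_id")]) > 0)
  tally <- tallyConsequences(calls)
  expect_identical(sum(tally$snp_count) + sum(tally$indel_count),
                   nrow(calls))
})

test_that("no gene models means everything is intergenic", {
  sim <- smallSim()
  p0 <- sim$p; p0$nGenes <- 0L
  empty <- emitGeneModels(p0)
  v <- emitVariants(sim$mos$focal, sim$ref, sim$p)[1:50, ]
  calls <- classifyConsequences(v, empty, sim$ref)
  expect_true(all(calls$category == "intergenic_variant"))
})

test_that("tally percentages use class-wise call denominators", {
  g <- toyGene("+"); ref <- toyReference("+")
  v <- toyVariant(50, substr(as.character(dnaSeq(ref)), 50, 50), "N")
  v$alt <- setdiff(c("A", "C", "G", "T"), v$ref)[1]
  calls <- classifyConsequences(v, g, ref, flank = 20)
  tally <- tallyConsequences(calls)
  expect_identical(tally$snp_pct[tally$category == "intergenic_variant"],
                   100)
})

test_that("reverse-complementing the chromosome preserves the tallies", {
  gP <- toyGene("+"); refP <- toyReference("+")
  L <- length(refP)
  ## mirror image: reverse-complement sequence, mirrored minus-strand gene
  refM <- maskedSequence(as.character(Biostrings::reverseComplement(
    dnaSeq(refP))), label = "REF")
  mirror <- function(gr) {
    s <- L - GenomicRanges::end(gr) + 1L
    e <- L - GenomicRanges::start(gr) + 1L
    GenomicRanges::GRanges("chr1", IRanges::IRanges(s, e), strand = "-")
  }
  exM <- mirror(gP@exons[["txT"]]); cdsM <- mirror(gP@cds[["txT"]])
  txM <- mirror(gP@transcripts)
  txM$gene_id <- "geneT"; txM$tx_id <- "txT"; txM$biotype <- "coding"
  gM <- methods::new("GeneModels", transcripts = txM,
                     exons = GenomicRanges::GRangesList(txT = exM),
                     cds = GenomicRanges::GRangesList(txT = cdsM))
  positions <- c(124, 127, 144, 159, 161, 165, 230, 299, 110, 380, 50, 450)
  refChar <- as.character(dnaSeq(refP))
  vP <- do.call(rbind, lapply(positions, function(pos) {
    from <- substr(refChar, pos, pos)
    toyVariant(pos, from, setdiff(c("A", "C", "G", "T"), from)[1])
  }))
  refMChar <- as.character(dnaSeq(refM))
  vM <- do.call(rbind, lapply(positions, function(pos) {
    mpos <- L - pos + 1L
    from <- substr(refMChar, mpos, mpos)
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    origFrom <- substr(refChar, pos, pos)
    origTo <- setdiff(c("A", "C", "G", "T"), origFrom)[1]
    toyVariant(mpos, from, comp[[origTo]])
  }))
  vM <- vM[order(vM$pos), ]
  tP <- tallyConsequences(classifyConsequences(vP, gP, refP))
  tM <- tallyConsequences(classifyConsequences(vM, gM, refM))
  expect_identical(tP, tM)
})

test_that("disease join reports distinct genes and phenotypes", {
  dt <- data.frame(gene = c("g1", "g2", "g2", "g9"),
                   phenotype = c("ph1", "ph2", "ph2", "ph9"),
                   omim_id = c("1", "2", "2", "9"),
                   stringsAsFactors = FALSE)
  res <- diseaseJoin(c("g1", "g2", "g3", "g4", "g5"), dt)
  expect_identical(res$nGenes, 2L)
  expect_identical(res$nPhenotypes, 2L)  # duplicate rows collapse
  expect_identical(nrow(res$table), 2L)
  empty <- diseaseJoin(c("g1"), dt[0, ])
  expect_identical(nrow(empty$table), 0L)
  expect_identical(empty$nGenes, 0L)
})
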