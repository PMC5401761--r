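#' @importFrom GenomicRanges GRanges GRangesList start end strand seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols
NULL

## Map spliced (transcript) coordinates to genomic positions for one
## transcript: returns the integer vector of genomic positions in 5'->3'
## transcript order. Exons must be sorted by genomic start.
splicedMap <- function(exonStarts, exonEnds, strand) {
  g <- unlist(mapply(seq, exonStarts, exonEnds, SIMPLIFY = FALSE))
  if (strand == "-") rev(g) else g
}

## Collapse a sorted integer position vector into IRanges of consecutive runs.
positionsToRanges <- function(pos) {
  if (!length(pos)) return(IRanges::IRanges())
  pos <- sort(pos)
  brk <- c(TRUE, diff(pos) != 1L)
  grp <- cumsum(brk)
  IRanges::IRanges(start = tapply(pos, grp, min),
                   end = tapply(pos, grp, max))
}

#' Simulate gene models
#'
#' Places non-overlapping genes (one transcript each) on both strands with
#' multi-exon structure; coding transcripts get a CDS contained in the
#' exons with length divisible by 3, flanked by 5' and 3' UTR. Biotypes are
#' drawn as coding/noncoding/nmd at 80/15/5%.
#'
#' @param params a \code{\link{simulationParams}} list (uses
#'   \code{nGenes}, \code{chromosomeLength}, \code{seed}).
#' @return a \linkS4class{GeneModels} object.
#' @export
emitGeneModels <- function(params) {
  validateParams(params)
  L <- as.integer(params$chromosomeLength)
  n <- params$nGenes
  if (n == 0)
    return(new("GeneModels",
               transcripts = GenomicRanges::GRanges(
                 seqnames = character(), ranges = IRanges::IRanges(),
                 strand = character(), gene_id = character(),
                 tx_id = character(), biotype = character()),
               exons = GenomicRanges::GRangesList(),
               cds = GenomicRanges::GRangesList()))
  slot <- L %/% n
  if (slot < 1500) stop("chromosome too short for nGenes gene models")
  withSeed(params$seed + 3L, {
    txRows <- vector("list", n)
    exL <- cdsL <- stats::setNames(vector("list", n), paste0("tx", seq_len(n)))
    for (i in seq_len(n)) {
      nEx <- sample(2:6, 1)
      repeat {
        exLen <- sample(90:240, nEx, replace = TRUE)
        inLen <- sample(80:2000, max(1, nEx - 1), replace = TRUE)
        span <- sum(exLen) + sum(inLen)
        if (span <= slot - 200) break
        nEx <- max(2L, nEx - 1L)
      }
      gStart <- (i - 1L) * slot + sample.int(slot - span - 100L, 1)
      exStart <- gStart + cumsum(c(0L, exLen[-nEx] + inLen))
      exEnd <- exStart + exLen - 1L
      strand <- sample(c("+", "-"), 1)
      biotype <- sample(c("coding", "noncoding", "nmd"), 1,
                        prob = c(0.8, 0.15, 0.05))
      txId <- paste0("tx", i)
      exL[[txId]] <- GenomicRanges::GRanges(params$chromName,
        IRanges::IRanges(exStart, exEnd), strand = strand)
      if (biotype != "noncoding") {
        E <- sum(exLen)
        utr5 <- sample(20:max(21, min(150, E %/% 4)), 1)
        utr3 <- sample(20:max(21, min(150, E %/% 4)), 1)
        cdsLen <- (E - utr5 - utr3) %/% 3 * 3
        if (cdsLen < 60) { utr5 <- utr3 <- 20; cdsLen <- (E - 40) %/% 3 * 3 }
        map <- splicedMap(exStart, exEnd, strand)
        cdsPos <- map[(utr5 + 1):(utr5 + cdsLen)]
        cdsL[[txId]] <- GenomicRanges::GRanges(params$chromName,
          positionsToRanges(cdsPos), strand = strand)
      }
      txRows[[i]] <- data.frame(start = gStart, end = gEnd <- max(exEnd),
                                strand = strand, gene_id = paste0("gene", i),
                                tx_id = txId, biotype = biotype,
                                stringsAsFactors = FALSE)
    }
    tx <- do.call(rbind, txRows)
    transcripts <- GenomicRanges::GRanges(params$chromName,
      IRanges::IRanges(tx$start, tx$end), strand = tx$strand,
      gene_id = tx$gene_id, tx_id = tx$tx_id, biotype = tx$biotype)
    cdsL <- cdsL[!vapply(cdsL, is.null, TRUE)]
    new("GeneModels", transcripts = transcripts,
        exons = GenomicRanges::GRangesList(exL),
        cds = GenomicRanges::GRangesList(cdsL))
  })
}

## Spliced CDS of a transcript as a character string read 5'->3'.
splicedCds <- function(models, txId, rawSeq) {
  cds <- models@cds[[txId]]
  if (is.null(cds) || !length(cds)) return(NULL)
  cds <- cds[order(GenomicRanges::start(cds))]
  strand <- as.character(GenomicRanges::strand(cds))[1]
  map <- splicedMap(GenomicRanges::start(cds), GenomicRanges::end(cds),
                    strand)
  s <- rawToChar(rawSeq[map])
  if (strand == "-")
    s <- as.character(Biostrings::complement(Biostrings::DNAString(s)))
  list(seq = s, map = map, strand = strand)
}

#' Harmonize coding sequence across a haplotype panel
#'
#' Rewrites every coding transcript so its CDS starts with ATG, ends with a
#' stop codon, and contains no internal stop, applying identical edits to
#' all visible haplotypes and latent ancestors (so pairwise divergences are
#' unchanged at the edited sites). Run after \code{\link{emitGeneModels}}
#' when translated gene models are needed downstream.
#'
#' @param haps a \linkS4class{HaplotypeSet}.
#' @param models a \linkS4class{GeneModels}.
#' @return the edited HaplotypeSet.
#' @export
harmonizeCodingSequence <- function(haps, models) {
  seqs <- lapply(seq_along(haps@sequences), function(i)
    dnaToRaw(haps@sequences[[i]]))
  names(seqs) <- names(haps@sequences)
  ancs <- lapply(seq_along(haps@ancestors), function(i)
    dnaToRaw(haps@ancestors[[i]]))
  names(ancs) <- names(haps@ancestors)
  ref <- seqs$REF
  coding <- models@transcripts$tx_id[models@transcripts$biotype == "coding"]
  edits <- integer(0); letters <- character(0)
  for (txId in coding) {
    sc <- splicedCds(models, txId, ref)
    if (is.null(sc)) next
    cdsSeq <- strsplit(sc$seq, "")[[1]]
    nC <- length(cdsSeq) %/% 3
    txEdit <- integer(0)
    put <- function(codonIdx, codon) {
      idx <- (codonIdx - 1L) * 3L + 1:3
      cdsSeq[idx] <<- strsplit(codon, "")[[1]]
      txEdit <<- c(txEdit, idx)
    }
    if (paste(cdsSeq[1:3], collapse = "") != "ATG") put(1L, "ATG")
    for (ci in 2:(nC - 1)) {
      codon <- paste(cdsSeq[(ci - 1) * 3 + 1:3], collapse = "")
      if (codon %in% c("TAA", "TAG", "TGA"))
        put(ci, sub("^T", "C", codon))
    }
    last <- paste(cdsSeq[(nC - 1) * 3 + 1:3], collapse = "")
    if (!last %in% c("TAA", "TAG", "TGA")) put(nC, "TAA")
    if (length(txEdit)) {
      let <- cdsSeq[txEdit]  # coding-strand orientation
      if (sc$strand == "-")
        let <- strsplit(as.character(Biostrings::complement(
          Biostrings::DNAString(paste(let, collapse = "")))), "")[[1]]
      edits <- c(edits, sc$map[txEdit])
      letters <- c(letters, let)
    }
  }
  if (length(edits)) {
    lr <- charToRaw(paste(letters, collapse = ""))
    applyEdits <- function(r) { r[edits] <- lr; r }
    seqs <- lapply(seqs, applyEdits)
    ancs <- lapply(ancs, applyEdits)
  }
  new("HaplotypeSet",
      sequences = Biostrings::DNAStringSet(vapply(seqs, rawToChar, "")),
      ancestors = Biostrings::DNAStringSet(vapply(ancs, rawToChar, "")),
      params = haps@params, branchRates = haps@branchRates)
}
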