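## Consequence categories ordered by severity (most severe first). The
## ladder is total: every (variant, transcript) pair gets exactly one
## category, the most severe that applies.
consequenceLadder <- function() c(
  "splice_acceptor_variant", "splice_donor_variant", "stop_gained",
  "frameshift_variant", "stop_lost", "start_lost", "missense_variant",
  "inframe_insertion", "inframe_deletion", "splice_region_variant",
  "synonymous_variant", "stop_retained_variant", "coding_sequence_variant",
  "5_prime_UTR_variant", "3_prime_UTR_variant",
  "non_coding_transcript_exon_variant", "intron_variant",
  "NMD_transcript_variant", "non_coding_transcript_variant",
  "upstream_gene_variant", "downstream_gene_variant", "intergenic_variant")

severityRank <- function(cat) match(cat, consequenceLadder())

## classify one variant against one overlapping coding/noncoding transcript;
## returns the most severe applicable category.
classifyOne <- function(pos, ref, alt, vclass, txStrand, biotype,
                        exons, cdsInfo, refRaw) {
  if (biotype == "nmd") return("NMD_transcript_variant")
  exStart <- GenomicRanges::start(exons); exEnd <- GenomicRanges::end(exons)
  nEx <- length(exStart)
  vEnd <- pos + nchar(ref) - 1L
  inExon <- any(pos <= exEnd & vEnd >= exStart)
  cand <- character(0)
  ## splice logic on internal junctions, in transcription order:
  ## donor = first 2 intronic bases after an exon (5' side of the intron),
  ## acceptor = last 2 intronic bases before the next exon; splice_region =
  ## 1-3 exonic or 3-8 intronic bases from the junction.
  if (nEx > 1) {
    for (i in seq_len(nEx - 1)) {
      intronL <- exEnd[i] + 1L; intronR <- exStart[i + 1] - 1L
      ## genomic-left junction side (end of exon i)
      leftDonor <- txStrand == "+"
      if (any(pos <= intronL + 1L & vEnd >= intronL))
        cand <- c(cand, if (leftDonor) "splice_donor_variant"
                        else "splice_acceptor_variant")
      if (any(pos <= intronR & vEnd >= intronR - 1L))
        cand <- c(cand, if (leftDonor) "splice_acceptor_variant"
                        else "splice_donor_variant")
      if (any(pos <= intronL + 7L & vEnd >= intronL + 2L) ||
          any(pos <= intronR - 2L & vEnd >= intronR - 7L) ||
          any(pos <= exEnd[i] & vEnd >= exEnd[i] - 2L) ||
          any(pos <= exStart[i + 1] + 2L & vEnd >= exStart[i + 1]))
        cand <- c(cand, "splice_region_variant")
    }
  }
  if (!inExon) {
    intronic <- if (biotype == "coding") "intron_variant"
                else "non_coding_transcript_variant"
    cand <- c(cand, intronic)
    return(consequenceLadder()[min(severityRank(cand))])
  }
  if (biotype == "noncoding") {
    cand <- c(cand, "non_coding_transcript_exon_variant")
    return(consequenceLadder()[min(severityRank(cand))])
  }
  ## coding transcript, exonic variant
  map <- cdsInfo$map
  inCds <- pos %in% map || (vclass != "snp" && any((pos:vEnd) %in% map))
  if (!inCds) {
    ## UTR side from the spliced coordinate relative to the CDS
    tmap <- cdsInfo$txMap     # genomic positions in transcript order
    tpos <- match(pos, tmap)
    if (is.na(tpos)) tpos <- match(vEnd, tmap)
    if (is.na(tpos)) {
      cand <- c(cand, "coding_sequence_variant")
    } else {
      cand <- c(cand, if (tpos < cdsInfo$cdsFirstTx) "5_prime_UTR_variant"
                      else "3_prime_UTR_variant")
    }
    return(consequenceLadder()[min(severityRank(cand))])
  }
  if (vclass != "snp") {
    shift <- abs(nchar(alt) - nchar(ref))
    cand <- c(cand, if (shift %% 3 != 0) "frameshift_variant"
                    else if (vclass == "insertion") "inframe_insertion"
                    else "inframe_deletion")
    return(consequenceLadder()[min(severityRank(cand))])
  }
  ## SNP in CDS: strand-aware codon translation
  cdsIdx <- match(pos, map)
  ci <- (cdsIdx - 1L) %/% 3L
  codonPos <- map[(ci * 3L + 1L):(ci * 3L + 3L)]
  refCodon <- rawToChar(refRaw[codonPos])
  altBase <- alt
  if (txStrand == "-") {
    refCodon <- as.character(Biostrings::complement(
      Biostrings::DNAString(refCodon)))
    altBase <- as.character(Biostrings::complement(
      Biostrings::DNAString(altBase)))
  }
  off <- cdsIdx - (ci * 3L)
  altCodon <- refCodon
  substr(altCodon, off, off) <- altBase
  gc <- Biostrings::GENETIC_CODE
  refAA <- gc[[refCodon]]; altAA <- gc[[altCodon]]
  cds <- if (ci == 0L && altCodon != "ATG") "start_lost"
    else if (refAA != "*" && altAA == "*") "stop_gained"
    else if (refAA == "*" && altAA != "*") "stop_lost"
    else if (refAA == "*" && altAA == "*") "stop_retained_variant"
    else if (refAA == altAA) "synonymous_variant"
    else "missense_variant"
  cand <- c(cand, cds)
  consequenceLadder()[min(severityRank(cand))]
}

#' Assign functional consequences to variants
#'
#' Each variant receives one most-severe category per transcript it
#' overlaps (transcript span extended by \code{flank} bases for
#' upstream/downstream calls); variants with no transcript within the flank
#' are intergenic. Codon interpretation is strand-aware under the standard
#' genetic code; NMD-flagged transcripts report \code{NMD_transcript_variant}
#' for any overlapping variant; start-loss is checked only on the annotated
#' initiator codon.
#'
#' @param v variant data.frame (see \code{\link{emitVariants}}).
#' @param models a \linkS4class{GeneModels}.
#' @param refseq the reference \linkS4class{MaskedSequence} (or DNAString);
#'   variant ref alleles are checked against it.
#' @param flank upstream/downstream distance in bases (default 5000).
#' @return data.frame with columns variant (row index into \code{v}), pos,
#'   vclass, tx_id (NA for intergenic), gene_id, category.
#' @export
classifyConsequences <- function(v, models, refseq, flank = 5000) {
  if (is(refseq, "MaskedSequence")) refseq <- dnaSeq(refseq)
  refRaw <- dnaToRaw(refseq)
  n <- nrow(v)
  if (!n) return(data.frame(variant = integer(), pos = integer(),
                            vclass = character(), tx_id = character(),
                            gene_id = character(), category = character(),
                            stringsAsFactors = FALSE))
  ## ref-allele consistency check (first base for indels, full for SNPs)
  chk <- substr(v$ref, 1, 1) != rawToChar(refRaw[v$pos], multiple = TRUE)
  chk[v$vclass == "snp"] <- v$ref[v$vclass == "snp"] !=
    rawToChar(refRaw[v$pos[v$vclass == "snp"]], multiple = TRUE)
  if (any(chk))
    stop("variant ref allele disagrees with reference at position ",
         v$pos[which(chk)[1]])
  tx <- models@transcripts
  vr <- GenomicRanges::GRanges(v$chrom,
    IRanges::IRanges(v$pos, width = pmax(1L, nchar(v$ref))))
  txFlank <- GenomicRanges::GRanges(GenomicRanges::seqnames(tx),
    IRanges::IRanges(pmax(1L, GenomicRanges::start(tx) - flank),
                     GenomicRanges::end(tx) + flank))
  ov <- GenomicRanges::findOverlaps(vr, txFlank, ignore.strand = TRUE)
  qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
  ## per-transcript cached CDS maps
  cdsCache <- new.env(parent = emptyenv())
  txInfo <- function(j) {
    txId <- tx$tx_id[j]
    if (!is.null(cdsCache[[txId]])) return(cdsCache[[txId]])
    ex <- models@exons[[txId]]
    ex <- ex[order(GenomicRanges::start(ex))]
    strand <- as.character(GenomicRanges::strand(tx))[j]
    txMap <- splicedMap(GenomicRanges::start(ex), GenomicRanges::end(ex),
                        strand)
    cdsGr <- models@cds[[txId]]
    if (!is.null(cdsGr)) cdsGr <- cdsGr[order(GenomicRanges::start(cdsGr))]
    map <- if (!is.null(cdsGr) && length(cdsGr))
      splicedMap(GenomicRanges::start(cdsGr), GenomicRanges::end(cdsGr),
                 strand) else integer(0)
    info <- list(exons = ex, strand = strand, txMap = txMap, map = map,
                 cdsFirstTx = if (length(map)) match(map[1], txMap)
                              else NA_integer_)
    cdsCache[[txId]] <- info
    info
  }
  out <- vector("list", length(qh) + n)
  k <- 0L
  for (h in seq_along(qh)) {
    i <- qh[h]; j <- sh[h]
    info <- txInfo(j)
    vEnd <- v$pos[i] + nchar(v$ref[i]) - 1L
    if (vEnd < GenomicRanges::start(tx)[j] ||
        v$pos[i] > GenomicRanges::end(tx)[j]) {
      beforeTx <- vEnd < GenomicRanges::start(tx)[j]
      categ <- if (xor(beforeTx, info$strand == "-"))
        "upstream_gene_variant" else "downstream_gene_variant"
    } else {
      categ <- classifyOne(v$pos[i], v$ref[i], v$alt[i], v$vclass[i],
                           info$strand, tx$biotype[j], info$exons, info,
                           refRaw)
    }
    k <- k + 1L
    out[[k]] <- data.frame(variant = i, pos = v$pos[i], vclass = v$vclass[i],
                           tx_id = tx$tx_id[j], gene_id = tx$gene_id[j],
                           category = categ, stringsAsFactors = FALSE)
  }
  ## intergenic: no transcript within flank
  hitVar <- unique(qh)
  for (i in setdiff(seq_len(n), hitVar)) {
    k <- k + 1L
    out[[k]] <- data.frame(variant = i, pos = v$pos[i], vclass = v$vclass[i],
                           tx_id = NA_character_, gene_id = NA_character_,
                           category = "intergenic_variant",
                           stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out[seq_len(k)])
  calls <- calls[order(calls$variant, calls$tx_id), , drop = FALSE]
  rownames(calls) <- NULL
  calls
}

#' Tally consequence calls per category and variant class
#'
#' One count per ladder category per variant class (SNP vs indel); the
#' percentage denominator is the total number of consequence assignments of
#' that class (not distinct variants), rounded half-up at one decimal --
#' the convention under which an intron share of 47.8% arises from the
#' published SNP column.
#'
#' @param calls data.frame from \code{\link{classifyConsequences}}.
#' @return data.frame category, snp_count, snp_pct, indel_count, indel_pct.
#' @export
tallyConsequences <- function(calls) {
  cats <- consequenceLadder()
  isSnp <- calls$vclass == "snp"
  cnt <- function(sel) {
    tab <- table(factor(calls$category[sel], levels = cats))
    as.integer(tab)
  }
  snp <- cnt(isSnp); ind <- cnt(!isSnp)
  data.frame(category = cats,
             snp_count = snp,
             snp_pct = if (sum(snp)) percentHalfUp(snp, sum(snp), 1) else NA,
             indel_count = ind,
             indel_pct = if (sum(ind)) percentHalfUp(ind, sum(ind), 1) else NA,
             stringsAsFactors = FALSE)
}

#' Join a gene list against a disease-phenotype table
#'
#' Inner join on gene id; one row per (gene, phenotype) pair, duplicates
#' collapsed. Reports distinct gene and phenotype counts.
#'
#' @param genes character vector of gene ids.
#' @param diseaseTable data.frame with columns gene, phenotype, omim_id.
#' @return list with \code{table} (joined rows) and counts
#'   \code{nGenes}, \code{nPhenotypes}.
#' @export
diseaseJoin <- function(genes, diseaseTable) {
  stopifnot(all(c("gene", "phenotype") %in% names(diseaseTable)))
  hit <- diseaseTable[diseaseTable$gene %in% genes, , drop = FALSE]
  hit <- unique(hit[, intersect(c("gene", "phenotype", "omim_id"),
                                names(hit)), drop = FALSE])
  rownames(hit) <- NULL
  list(table = hit,
       nGenes = length(unique(hit$gene)),
       nPhenotypes = length(unique(hit$phenotype)))
}
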