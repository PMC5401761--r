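#' Write a variant table as VCF v4.2
#'
#' Emits 1-based positions with INFO keys DP, MQ, DP4 and FORMAT GT for a
#' single sample, the layout produced by pileup-based callers.
#'
#' @param v variant data.frame as returned by \code{\link{emitVariants}}.
#' @param path output path.
#' @param contigLength contig length for the header.
#' @param sampleName sample column name.
#' @return the path, invisibly.
#' @export
writeVariantVcf <- function(v, path, contigLength = NA, sampleName = "focal") {
  chrom <- if (nrow(v)) v$chrom[1] else "chr1"
  hdr <- c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s%s>", chrom,
            if (is.na(contigLength)) "" else sprintf(",length=%d",
                                                     as.integer(contigLength))),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Integer,Description=\"RMS mapping quality\">",
    paste0("##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"Ref-forward,",
           " ref-reverse, alt-forward, alt-reverse read counts\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sampleName, sep = "\t"))
  lines <- hdr
  if (nrow(v)) {
    gt <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1")[v$genotype]
    info <- sprintf("DP=%d;MQ=%d;DP4=%d,%d,%d,%d", v$dp, as.integer(v$mq),
                    v$dp4_rf, v$dp4_rr, v$dp4_af, v$dp4_ar)
    filt <- if ("filter" %in% names(v)) v$filter else "."
    lines <- c(lines, paste(v$chrom, v$pos, ".", v$ref, v$alt,
                            format(v$qual, trim = TRUE), filt, info,
                            "GT", gt, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF into the package's variant table
#'
#' Parses with \pkg{vcfR}; multi-allelic records are split into bi-allelic
#' records (INFO fields duplicated) and the variant class is derived from
#' allele lengths.
#'
#' @param path VCF path.
#' @return variant data.frame (see \code{\link{emitVariants}} for columns).
#' @export
readVariantVcf <- function(path) {
  vc <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vc@fix, stringsAsFactors = FALSE)
  if (!nrow(fix)) return(emptyVariantFrame())
  dp <- as.integer(vcfR::extract.info(vc, "DP"))
  mq <- as.numeric(vcfR::extract.info(vc, "MQ"))
  dp4 <- vcfR::extract.info(vc, "DP4")
  dp4m <- matrix(NA_integer_, nrow(fix), 4)
  ok <- !is.na(dp4)
  if (any(ok))
    dp4m[ok, ] <- t(vapply(strsplit(dp4[ok], ","),
                           function(x) as.integer(x[1:4]), integer(4)))
  gtRaw <- if (ncol(vc@gt) >= 2) vcfR::extract.gt(vc, "GT")[, 1] else
    rep(NA_character_, nrow(fix))
  genotype <- rep("hom_alt", nrow(fix))
  genotype[gtRaw %in% c("0/1", "0|1", "1/0", "1|0")] <- "het"
  genotype[gtRaw %in% c("0/0", "0|0")] <- "hom_ref"
  v <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                  ref = fix$REF, alt = fix$ALT,
                  qual = as.numeric(fix$QUAL), mq = mq, dp = dp,
                  dp4_rf = dp4m[, 1], dp4_rr = dp4m[, 2],
                  dp4_af = dp4m[, 3], dp4_ar = dp4m[, 4],
                  genotype = genotype, stringsAsFactors = FALSE)
  ## split multi-allelic ALT into bi-allelic rows
  alts <- strsplit(v$alt, ",", fixed = TRUE)
  n <- lengths(alts)
  if (any(n > 1)) {
    v <- v[rep(seq_len(nrow(v)), n), , drop = FALSE]
    v$alt <- unlist(alts)
    rownames(v) <- NULL
  }
  v$vclass <- ifelse(nchar(v$ref) == nchar(v$alt), "snp",
                     ifelse(nchar(v$ref) < nchar(v$alt), "insertion",
                            "deletion"))
  v <- v[order(v$pos), , drop = FALSE]
  rownames(v) <- NULL
  v[, variantColumns()]
}

#' Write masked intervals or tracts as BED (0-based half-open)
#'
#' @param x an IRanges (1-based closed; converted), or a data.frame with
#'   0-based half-open start/end columns (written as is, extra columns
#'   appended).
#' @param path output path.
#' @param chrom chromosome name.
#' @return the path, invisibly.
#' @export
writeBed <- function(x, path, chrom = "chr1") {
  if (is(x, "IRanges"))
    df <- data.frame(start = IRanges::start(x) - 1L, end = IRanges::end(x))
  else df <- x
  extra <- setdiff(names(df), c("start", "end"))
  out <- cbind(chrom = chrom, df[, c("start", "end"), drop = FALSE],
               df[, extra, drop = FALSE])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED3 file as an IRanges (1-based closed)
#'
#' @param path BED path.
#' @return IRanges.
#' @export
readBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  IRanges::ranges(gr)
}

#' Write gene models as GFF3
#'
#' @param models a \linkS4class{GeneModels}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGeneModelsGff3 <- function(models, path) {
  tx <- models@transcripts
  feats <- list()
  genes <- tx
  genes$type <- "gene"
  genes$ID <- tx$gene_id
  genes$Parent <- NA_character_
  mrna <- tx
  mrna$type <- "mRNA"
  mrna$ID <- tx$tx_id
  mrna$Parent <- tx$gene_id
  rows <- list(genes, mrna)
  for (i in seq_along(tx)) {
    txId <- tx$tx_id[i]
    ex <- models@exons[[txId]]
    ex$type <- "exon"
    ex$ID <- paste0(txId, ".exon", seq_along(ex))
    ex$Parent <- txId
    ex$gene_id <- tx$gene_id[i]; ex$tx_id <- txId
    ex$biotype <- tx$biotype[i]
    rows <- c(rows, list(ex))
    cds <- models@cds[[txId]]
    if (!is.null(cds) && length(cds)) {
      cds$type <- "CDS"
      w <- GenomicRanges::width(cds)
      ord <- if (as.character(GenomicRanges::strand(cds))[1] == "-")
        rev(seq_along(cds)) else seq_along(cds)
      before <- cumsum(c(0L, w[ord][-length(w)]))
      cds$phase[ord] <- as.integer((3L - before %% 3L) %% 3L)
      cds$ID <- paste0(txId, ".cds", seq_along(cds))
      cds$Parent <- txId
      cds$gene_id <- tx$gene_id[i]; cds$tx_id <- txId
      cds$biotype <- tx$biotype[i]
      rows <- c(rows, list(cds))
    }
  }
  all <- suppressWarnings(do.call(c, rows))
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Expects the layout written by \code{\link{writeGeneModelsGff3}}:
#' gene/mRNA/exon/CDS features with ID/Parent links and a biotype attribute
#' on exon/CDS rows.
#'
#' @param path GFF3 path.
#' @return a \linkS4class{GeneModels}.
#' @export
readGeneModelsGff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mrna <- gr[gr$type == "mRNA"]
  ex <- gr[gr$type == "exon"]
  cds <- gr[gr$type == "CDS"]
  txIds <- as.character(mrna$ID)
  parent <- function(g) vapply(g$Parent, function(p) p[[1]], "")
  exL <- split(ex, factor(parent(ex), levels = txIds))
  cdsParents <- parent(cds)
  biot <- vapply(txIds, function(t) {
    b <- ex$biotype[parent(ex) == t][1]
    if (is.na(b) || is.null(b)) "coding" else b
  }, "")
  tx <- GenomicRanges::GRanges(GenomicRanges::seqnames(mrna),
                               IRanges::ranges(mrna),
                               strand = GenomicRanges::strand(mrna),
                               gene_id = parent(mrna), tx_id = txIds,
                               biotype = unname(biot))
  byStart <- function(g) g[order(GenomicRanges::start(g))]
  exClean <- GenomicRanges::GRangesList(lapply(exL, function(g) {
    S4Vectors::mcols(g) <- NULL
    byStart(g)
  }))
  cdsL <- lapply(txIds[txIds %in% cdsParents], function(t) {
    g <- cds[cdsParents == t]
    S4Vectors::mcols(g) <- NULL
    byStart(g)
  })
  names(cdsL) <- txIds[txIds %in% cdsParents]
  new("GeneModels", transcripts = tx,
      exons = exClean, cds = GenomicRanges::GRangesList(cdsL))
}

#' Write one or more sequences as wrapped FASTA
#'
#' @param seqs a named list of \linkS4class{MaskedSequence} /
#'   DNAString objects, or a DNAStringSet.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeFasta <- function(seqs, path) {
  if (is(seqs, "MaskedSequence")) seqs <- stats::setNames(list(seqs),
                                                          seqLabel(seqs))
  if (is.list(seqs)) {
    chr <- vapply(seqs, function(s)
      as.character(if (is(s, "MaskedSequence")) dnaSeq(s) else s), "")
    seqs <- Biostrings::DNAStringSet(chr)
  }
  Biostrings::writeXStringSet(seqs, path, width = 60)
  invisible(path)
}

#' Write ground-truth tracts and parameters as JSON
#'
#' @param truth a \linkS4class{MosaicTruth}.
#' @param params the \code{\link{simulationParams}} used.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeTruthJson <- function(truth, params, path) {
  jsonlite::write_json(list(chrom_length = truth@chromLength,
                            tracts = truthTracts(truth),
                            params = unclass(params)),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
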