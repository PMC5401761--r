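#' Quality-filter parameters
#'
#' The four depth/quality clauses are strict inequalities:
#' QUAL > 10, MQ > 25, 6 < DP < 199, alt-supporting reads
#' (DP4 alt-forward + alt-reverse) > 2. \code{snpGap}/\code{indelGap}
#' drive the proximity filter (SNPs within \code{snpGap} bases of an indel
#' removed; indels within \code{indelGap} of another indel removed).
#' \code{varFilterHook} is a named no-op hook for an auxiliary
#' caller-specific filtering step whose intent is not reconstructible;
#' it defaults to off and currently passes records through unchanged.
#'
#' @param minQual,minMq,minDp,maxDp,minAltReads strict clause bounds.
#' @param snpGap,indelGap proximity distances in bases.
#' @param varFilterHook logical, default FALSE.
#' @return a list of class \code{filterParams}.
#' @export
filterParams <- function(minQual = 10, minMq = 25, minDp = 6, maxDp = 199,
                         minAltReads = 2, snpGap = 10, indelGap = 3,
                         varFilterHook = FALSE) {
  p <- list(minQual = minQual, minMq = minMq, minDp = minDp, maxDp = maxDp,
            minAltReads = minAltReads, snpGap = snpGap, indelGap = indelGap,
            varFilterHook = varFilterHook)
  if (any(unlist(p[1:7]) < 0)) stop("filter thresholds must be non-negative")
  class(p) <- "filterParams"
  p
}

## Vectorized clause evaluation; returns "PASS" or the first failing clause
## name in the order the filter expression states them. Missing fields fail
## with the clause that needed them.
filterReasons <- function(v, p) {
  if (any(!is.na(v$dp) & v$dp < 0)) stop("malformed record: negative depth")
  if (any(!is.na(v$dp4_af) & (v$dp4_af < 0 | v$dp4_ar < 0 |
                              v$dp4_rf < 0 | v$dp4_rr < 0)))
    stop("malformed record: negative DP4 count")
  altReads <- v$dp4_af + v$dp4_ar
  reason <- rep("PASS", nrow(v))
  fail <- function(bad, name) {
    bad <- is.na(bad) | bad
    reason[reason == "PASS" & bad] <<- name
  }
  fail(!(v$qual > p$minQual), "qual")
  fail(!(v$mq > p$minMq), "mq")
  fail(!(v$dp > p$minDp & v$dp < p$maxDp), "depth")
  fail(!(altReads > p$minAltReads), "alt_reads")
  reason
}

#' Does one variant record pass the quality filter?
#'
#' @param v a one-row variant data.frame (see \code{\link{emitVariants}}).
#' @param p a \code{\link{filterParams}} list.
#' @return TRUE, or the name of the first failing clause (one of
#'   "qual", "mq", "depth", "alt_reads").
#' @export
passesQuality <- function(v, p = filterParams()) {
  r <- filterReasons(v[1, , drop = FALSE], p)
  if (r == "PASS") TRUE else r
}

#' Quality-filter a variant table
#'
#' Applies the strict QUAL/MQ/DP/DP4 clauses and annotates each record with
#' a \code{filter} column ("PASS" or the first failing clause).
#'
#' @param v variant data.frame.
#' @param p a \code{\link{filterParams}} list.
#' @param keep if TRUE (default) return only passing records; otherwise
#'   return all records with the \code{filter} column.
#' @return filtered variant data.frame.
#' @export
filterVariants <- function(v, p = filterParams(), keep = TRUE) {
  if (!nrow(v)) { v$filter <- character(0); return(v) }
  v$filter <- filterReasons(v, p)
  if (keep) v <- v[v$filter == "PASS", , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Remove variants near indels
#'
#' SNPs within \code{snpGap} bases of any indel are removed; indels within
#' \code{indelGap} bases of another indel are removed (both members of a
#' close pair). Distances are between POS coordinates; removal is symmetric
#' in scan order.
#'
#' @param v variant data.frame sorted by position.
#' @param p a \code{\link{filterParams}} list.
#' @return the surviving subset.
#' @export
proximityFilter <- function(v, p = filterParams()) {
  if (!nrow(v)) return(v)
  if (is.unsorted(v$pos)) stop("records must be sorted by position")
  isIndel <- v$vclass != "snp"
  ipos <- v$pos[isIndel]
  drop <- rep(FALSE, nrow(v))
  if (length(ipos)) {
    near <- function(pos, centers, gap) {
      if (!length(centers)) return(rep(FALSE, length(pos)))
      ir <- IRanges::IRanges(centers - gap, centers + gap)
      pq <- IRanges::IRanges(pos, width = 1L)
      IRanges::countOverlaps(pq, ir) > 0
    }
    drop[!isIndel] <- near(v$pos[!isIndel], ipos, p$snpGap)
    if (length(ipos) > 1) {
      d <- diff(ipos)
      close <- d <= p$indelGap
      bad <- unique(c(which(close), which(close) + 1L))
      drop[which(isIndel)[bad]] <- TRUE
    }
  }
  out <- v[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Left-align and trim an indel representation
#'
#' Canonicalizes an (pos, ref, alt) allele pair against the reference
#' sequence: shared suffix bases are trimmed (extending left through the
#' reference when an allele would empty), then shared prefix bases beyond
#' the anchor are trimmed. dbSNP-style matching is representation-sensitive,
#' so catalogs and queries are normalized the same way.
#'
#' @param pos 1-based position.
#' @param ref,alt allele strings.
#' @param refseq the reference \linkS4class{MaskedSequence} (or DNAString);
#'   needed to extend left.
#' @return list(pos, ref, alt).
#' @export
leftAlignIndel <- function(pos, ref, alt, refseq = NULL) {
  if (!is.null(refseq) && is(refseq, "MaskedSequence")) refseq <- dnaSeq(refseq)
  repeat {
    ## trim identical last base while both alleles keep >=1 base
    while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1, nchar(ref) - 1)
      alt <- substr(alt, 1, nchar(alt) - 1)
    }
    ## if alleles still share their last base with exactly one base left in
    ## one of them, extend left with the reference base and retry
    if (nchar(ref) >= 1 && nchar(alt) >= 1 &&
        substr(ref, nchar(ref), nchar(ref)) ==
        substr(alt, nchar(alt), nchar(alt)) &&
        (nchar(ref) == 1 || nchar(alt) == 1) && nchar(ref) != nchar(alt) &&
        !is.null(refseq) && pos > 1) {
      prev <- as.character(Biostrings::subseq(refseq, pos - 1, pos - 1))
      ref <- paste0(prev, substr(ref, 1, nchar(ref) - 1))
      alt <- paste0(prev, substr(alt, 1, nchar(alt) - 1))
      pos <- pos - 1
    } else break
  }
  ## trim identical leading bases beyond the anchor
  while (nchar(ref) > 1 && nchar(alt) > 1 &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos <- pos + 1
  }
  list(pos = pos, ref = ref, alt = alt)
}

normalizedKeys <- function(v, refseq = NULL) {
  key <- character(nrow(v))
  isSnp <- v$vclass == "snp"
  key[isSnp] <- paste(v$chrom[isSnp], v$pos[isSnp], v$ref[isSnp],
                      v$alt[isSnp], sep = ":")
  for (i in which(!isSnp)) {
    la <- leftAlignIndel(v$pos[i], v$ref[i], v$alt[i], refseq)
    key[i] <- paste(v$chrom[i], la$pos, la$ref, la$alt, sep = ":")
  }
  key
}

#' Classify variants as known or novel against catalogs
#'
#' A variant is known iff its normalized (chrom, pos, ref, alt) key --
#' indels left-aligned first -- occurs in at least one catalog.
#'
#' @param v variant data.frame.
#' @param catalogs list of variant data.frames (same columns, or at least
#'   chrom/pos/ref/alt/vclass).
#' @param refseq reference sequence for indel normalization (optional).
#' @return character vector "known"/"novel", one per record.
#' @export
classifyKnown <- function(v, catalogs, refseq = NULL) {
  if (!nrow(v)) return(character(0))
  catKeys <- unlist(lapply(catalogs, function(cc) {
    if (is.null(cc$vclass))
      cc$vclass <- ifelse(nchar(cc$ref) == nchar(cc$alt), "snp", "indel")
    normalizedKeys(cc, refseq)
  }))
  ifelse(normalizedKeys(v, refseq) %in% catKeys, "known", "novel")
}

#' SNP density over tiling windows
#'
#' Windows tile [0, chromLength) half-open; the terminal partial window is
#' kept. Density classes follow the reported scheme: low = 0--5 SNPs per
#' window, high = >= 800 per window, mid otherwise.
#'
#' @param pos 1-based SNP positions.
#' @param chromLength chromosome length.
#' @param window window size in bases (default 100 kb).
#' @param lowMax,highMin class bounds.
#' @return list with \code{windows} (data.frame start, end 0-based
#'   half-open, count, class), \code{meanDensity} (mean count per window),
#'   and \code{classFractions}.
#' @export
densityProfile <- function(pos, chromLength, window = 1e5,
                           lowMax = 5, highMin = 800) {
  if (length(pos) && (min(pos) < 1 || max(pos) > chromLength))
    stop("SNP position outside [1, chromLength]")
  nw <- ceiling(chromLength / window)
  idx <- (pos - 1) %/% window + 1
  counts <- tabulate(idx, nbins = nw)
  start <- (seq_len(nw) - 1) * window
  end <- pmin(start + window, chromLength)
  cls <- ifelse(counts <= lowMax, "low",
                ifelse(counts >= highMin, "high", "mid"))
  stopifnot(sum(counts) == length(pos))
  list(windows = data.frame(start = start, end = end, count = counts,
                            class = cls, stringsAsFactors = FALSE),
       meanDensity = mean(counts),
       classFractions = c(low = mean(cls == "low"),
                          mid = mean(cls == "mid"),
                          high = mean(cls == "high")))
}

#' Summarize a variant set
#'
#' Counts SNPs/indels, homozygous/heterozygous sites and known/novel calls,
#' with percentages rounded half-up at one and two decimals (the two
#' conventions summary tables mix).
#'
#' @param v variant data.frame; if a \code{known} column (values
#'   known/novel) is present, novelty is summarized too.
#' @return a list of counts and percentages.
#' @export
summarizeVariants <- function(v) {
  isSnp <- v$vclass == "snp"
  out <- list(nRecords = nrow(v),
              nSnps = sum(isSnp),
              nIndels = sum(!isSnp),
              nHom = sum(v$genotype == "hom_alt"),
              nHet = sum(v$genotype == "het"))
  out$pctHom <- if (nrow(v)) percentHalfUp(out$nHom, nrow(v), 2) else NA
  if (!is.null(v$known)) {
    out$nNovelSnps <- sum(isSnp & v$known == "novel")
    out$nNovelIndels <- sum(!isSnp & v$known == "novel")
    out$pctNovelSnps <- if (out$nSnps)
      percentHalfUp(out$nNovelSnps, out$nSnps, 1) else NA
    out$pctNovelIndels <- if (out$nIndels)
      percentHalfUp(out$nNovelIndels, out$nIndels, 1) else NA
    out$nNovel <- out$nNovelSnps + out$nNovelIndels
    out$pctNovel <- if (nrow(v)) percentHalfUp(out$nNovel, nrow(v), 1) else NA
  }
  out
}
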