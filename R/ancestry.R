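#' Build a strain consensus sequence from SNP calls
#'
#' Substitutes each homozygous-alternate SNP allele into the reference;
#' heterozygous sites become N (the base cannot be phased into a haploid
#' consensus); indels are ignored, so coordinates stay reference-aligned.
#' The consensus inherits the reference mask plus an optional strain mask.
#'
#' @param reference a \linkS4class{MaskedSequence}.
#' @param snps variant data.frame (filtered; unique positions).
#' @param strainMask optional IRanges of additional masked intervals.
#' @param label consensus label (default the reference label).
#' @return a \linkS4class{MaskedSequence}.
#' @export
buildConsensus <- function(reference, snps, strainMask = NULL,
                           label = seqLabel(reference)) {
  s <- snps[snps$vclass == "snp", , drop = FALSE]
  seq <- dnaSeq(reference)
  if (nrow(s)) {
    if (anyDuplicated(s$pos)) stop("SNP positions must be unique")
    refAt <- rawToChar(dnaToRaw(seq)[s$pos], multiple = TRUE)
    bad <- refAt != s$ref
    if (any(bad))
      stop("SNP ref allele disagrees with reference at position ",
           s$pos[which(bad)[1]])
    letters <- ifelse(s$genotype == "het", "N", s$alt)
    seq <- Biostrings::replaceLetterAt(seq, s$pos,
                                       paste(letters, collapse = ""))
  }
  mask <- maskRanges(reference)
  if (!is.null(strainMask)) mask <- IRanges::reduce(c(mask, strainMask))
  maskedSequence(seq, mask = mask, label = label)
}

#' Windowed sequence similarity between two masked sequences
#'
#' Direct positional comparison (no realignment): per window, callable
#' sites are those unmasked and non-N in both sequences; similarity =
#' matches / callable, undefined (NA) below \code{minCallable} callable
#' sites. Block mode uses size == step (e.g. 100 kb/100 kb: a 195.5 Mb
#' chromosome gives 1955 blocks, terminal partial window retained); sliding
#' mode uses step < size (e.g. 500 kb/100 kb) with size a multiple of step.
#'
#' @param a,b \linkS4class{MaskedSequence}s of equal length.
#' @param size,step window size and step in bases.
#' @param minCallable minimum callable sites for a defined similarity.
#' @return a \linkS4class{SimilarityProfile} (windows labelled with
#'   \code{b}'s label).
#' @export
windowSimilarity <- function(a, b, size = 1e5, step = size,
                             minCallable = 1000) {
  if (length(a) != length(b)) stop("sequences have unequal lengths")
  if (step > size) stop("step must not exceed window size")
  if (size %% step != 0) stop("window size must be a multiple of step")
  L <- length(a)
  ra <- dnaToRaw(dnaSeq(a)); rb <- dnaToRaw(dnaSeq(b))
  callable <- !maskLogical(maskRanges(a), L) &
    !maskLogical(maskRanges(b), L) & ra != .rawN & rb != .rawN
  nbins <- as.integer(ceiling(L / step))
  idxC <- which(callable)
  binC <- tabulate((idxC - 1L) %/% as.integer(step) + 1L, nbins)
  idxM <- idxC[ra[idxC] == rb[idxC]]
  binM <- tabulate((idxM - 1L) %/% as.integer(step) + 1L, nbins)
  m <- as.integer(size / step)
  csC <- c(0, cumsum(binC)); csM <- c(0, cumsum(binM))
  k <- seq_len(nbins)
  hi <- pmin(k + m - 1L, nbins)
  callableW <- as.integer(csC[hi + 1L] - csC[k])
  matchesW <- as.integer(csM[hi + 1L] - csM[k])
  start <- as.integer((k - 1L) * step)
  end <- as.integer(pmin(start + size, L))
  sim <- ifelse(callableW >= minCallable, matchesW / pmax(callableW, 1L), NA)
  new("SimilarityProfile", comparison = seqLabel(b), windowSize = size,
      step = step, minCallable = minCallable, chromLength = as.numeric(L),
      windows = data.frame(start = start, end = end, callable = callableW,
                           matches = matchesW, similarity = sim))
}

#' Histogram of window similarities with peak detection
#'
#' Bins the defined window similarities and reports local maxima whose
#' count reaches \code{prominence} times the tallest bin, together with the
#' fraction of windows in each peak's basin (basins split at the minimum
#' between adjacent peaks). A bimodal profile against a partially
#' introgressed strain shows one peak near the between-subspecies band and
#' one above the within-subspecies threshold.
#'
#' @param profile a \linkS4class{SimilarityProfile}.
#' @param binWidth histogram bin width on the similarity scale.
#' @param prominence minimum peak height as a fraction of the maximum bin.
#' @return list with \code{histogram} (data.frame mid, count) and
#'   \code{peaks} (data.frame similarity, count, basinFraction).
#' @export
similarityHistogram <- function(profile, binWidth = 5e-4,
                                prominence = 0.05) {
  s <- profileWindows(profile)$similarity
  s <- s[!is.na(s)]
  if (!length(s))
    return(list(histogram = data.frame(mid = numeric(), count = integer()),
                peaks = data.frame(similarity = numeric(), count = integer(),
                                   basinFraction = numeric())))
  lo <- floor(min(s) / binWidth) * binWidth
  breaks <- seq(lo, 1 + binWidth, by = binWidth)
  bin <- findInterval(s, breaks, rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  mid <- breaks[-length(breaks)] + binWidth / 2
  padded <- c(-1L, counts, -1L)
  isPeak <- counts > padded[seq_along(counts)] &
    counts > padded[seq_along(counts) + 2L] &
    counts >= prominence * max(counts)
  pk <- which(isPeak)
  basin <- numeric(length(pk))
  if (length(pk)) {
    bounds <- c(0L, vapply(seq_len(length(pk) - 1), function(i) {
      seg <- pk[i]:pk[i + 1]
      seg[which.min(counts[seg])]
    }, integer(1)), length(counts))
    for (i in seq_along(pk))
      basin[i] <- sum(counts[(bounds[i] + 1L):bounds[i + 1L]]) / length(s)
  }
  list(histogram = data.frame(mid = mid, count = counts),
       peaks = data.frame(similarity = mid[pk], count = counts[pk],
                          basinFraction = basin))
}

#' Call high-similarity introgression tracts from a sliding profile
#'
#' Windows whose similarity strictly exceeds \code{threshold} are marked;
#' overlapping or adjacent marked windows are merged into tracts. The
#' reported chromosome fraction uses the full chromosome length as the
#' denominator; undefined windows never qualify.
#'
#' @param profile a sliding \linkS4class{SimilarityProfile}.
#' @param threshold similarity threshold in (0, 1), strict (default 0.997,
#'   the >99.7% within-subspecies band).
#' @return list with \code{tracts} (data.frame start, end 0-based half-open,
#'   meanSimilarity, donor) and \code{fraction} (merged tract length /
#'   chromosome length).
#' @export
callTracts <- function(profile, threshold = 0.997) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0, 1)")
  w <- profileWindows(profile)
  hit <- !is.na(w$similarity) & w$similarity > threshold
  if (!any(hit))
    return(list(tracts = data.frame(start = numeric(), end = numeric(),
                                    meanSimilarity = numeric(),
                                    donor = character()),
                fraction = 0))
  ir <- IRanges::reduce(IRanges::IRanges(w$start[hit] + 1L, w$end[hit]))
  tr <- data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
  tr$meanSimilarity <- vapply(seq_len(nrow(tr)), function(i) {
    sel <- hit & w$start >= tr$start[i] & w$end <= tr$end[i]
    mean(w$similarity[sel])
  }, numeric(1))
  tr$donor <- profile@comparison
  list(tracts = tr, fraction = sum(tr$end - tr$start) / profile@chromLength)
}
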