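#' @import methods
#' @importClassesFrom Biostrings DNAString DNAStringSet
#' @importClassesFrom IRanges IRanges
NULL

#' MaskedSequence: a chromosome plus excluded intervals
#'
#' Holds one chromosome-scale DNA sequence together with the intervals that
#' are excluded from all similarity arithmetic (repeat mask, ambiguous
#' regions). Masked intervals are stored as 1-based closed \code{IRanges};
#' BED output converts to 0-based half-open. A site is \emph{callable} in a
#' pairwise comparison when it is unmasked and non-N in both sequences.
#'
#' @slot label strain/taxon label.
#' @slot seq a \link[Biostrings]{DNAString}.
#' @slot mask an \link[IRanges]{IRanges} of masked intervals (reduced,
#'   within the sequence).
#' @export
setClass("MaskedSequence",
  representation(label = "character", seq = "DNAString", mask = "IRanges"))

setValidity("MaskedSequence", function(object) {
  L <- length(object@seq)
  m <- object@mask
  if (length(m) && (min(IRanges::start(m)) < 1 || max(IRanges::end(m)) > L))
    return("masked intervals fall outside the sequence")
  if (length(object@label) != 1) return("label must be a single string")
  TRUE
})

#' Construct a MaskedSequence
#'
#' @param seq a DNAString or character scalar over A/C/G/T/N.
#' @param mask an IRanges of masked intervals (1-based closed); intervals are
#'   reduced (merged) on construction.
#' @param label strain label.
#' @return a \linkS4class{MaskedSequence}.
#' @export
maskedSequence <- function(seq, mask = IRanges::IRanges(), label = "seq") {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  new("MaskedSequence", label = label, seq = seq, mask = IRanges::reduce(mask))
}

#' @describeIn maskedSequence the DNA sequence slot.
#' @param x a MaskedSequence.
#' @export
dnaSeq <- function(x) x@seq

#' @describeIn maskedSequence the masked intervals (1-based closed IRanges).
#' @export
maskRanges <- function(x) x@mask

#' @describeIn maskedSequence the strain label.
#' @export
seqLabel <- function(x) x@label

setMethod("length", "MaskedSequence", function(x) length(x@seq))

setMethod("show", "MaskedSequence", function(object) {
  cat("MaskedSequence '", object@label, "': ", length(object@seq), " bp, ",
      sum(IRanges::width(object@mask)), " bp masked in ",
      length(object@mask), " intervals\n", sep = "")
})

#' HaplotypeSet: simulated strain haplotypes sharing one coordinate system
#'
#' The five visible haplotypes are the reference-like host (\code{REF}), one
#' representative per subspecies (\code{DOM}, \code{MUS}, \code{CAS}) and a
#' distant outgroup (\code{OUT}). The latent per-subspecies ancestral
#' sequences, from which mosaic tract donors are drawn, are kept in
#' \code{ancestors} so that focal tracts sit at the within-subspecies
#' divergence from their representative while keeping the between-subspecies
#' divergence to every other representative.
#'
#' @slot sequences DNAStringSet named REF, DOM, MUS, CAS, OUT.
#' @slot ancestors DNAStringSet named DOM, MUS, CAS (latent subspecies
#'   ancestors; not part of the visible strain panel).
#' @slot params the \code{simulationParams} list used.
#' @slot branchRates named numeric: per-branch substitution probabilities
#'   (tip, anc, out) solved from the divergence targets.
#' @export
setClass("HaplotypeSet",
  representation(sequences = "DNAStringSet", ancestors = "DNAStringSet",
                 params = "list", branchRates = "numeric"))

setValidity("HaplotypeSet", function(object) {
  need <- c("REF", "DOM", "MUS", "CAS", "OUT")
  if (!all(need %in% names(object@sequences)))
    return("sequences must be named REF, DOM, MUS, CAS, OUT")
  if (length(unique(Biostrings::width(object@sequences))) != 1)
    return("all haplotypes must have equal length")
  TRUE
})

#' @describeIn simulateHaplotypes extract one haplotype as a MaskedSequence
#'   (no mask).
#' @param haps a HaplotypeSet.
#' @param label which haplotype.
#' @export
haplotype <- function(haps, label) {
  maskedSequence(haps@sequences[[label]], label = label)
}

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet: ", length(object@sequences), " haplotypes of ",
      Biostrings::width(object@sequences)[1], " bp (",
      paste(names(object@sequences), collapse = ", "), ")\n", sep = "")
})

#' MosaicTruth: ground-truth donor tracts of a simulated chromosome
#'
#' Tracts tile the chromosome exactly; coordinates are 0-based half-open
#' (BED convention) so they can be written out unchanged.
#'
#' @slot tracts data.frame with columns start, end (0-based half-open) and
#'   donor.
#' @slot chromLength chromosome length in bases.
#' @export
setClass("MosaicTruth",
  representation(tracts = "data.frame", chromLength = "numeric"))

setValidity("MosaicTruth", function(object) {
  tr <- object@tracts
  if (!all(c("start", "end", "donor") %in% names(tr)))
    return("tracts needs columns start, end, donor")
  if (nrow(tr)) {
    if (tr$start[1] != 0) return("first tract must start at 0")
    if (tr$end[nrow(tr)] != object@chromLength)
      return("last tract must end at chromLength")
    if (nrow(tr) > 1 && any(tr$start[-1] != tr$end[-nrow(tr)]))
      return("tracts must tile the chromosome without gaps or overlap")
  }
  TRUE
})

#' @describeIn simulateMosaic the tract table (start, end 0-based half-open,
#'   donor).
#' @param truth a MosaicTruth.
#' @export
truthTracts <- function(truth) truth@tracts

#' @describeIn simulateMosaic realized fraction of the chromosome per donor.
#' @export
donorFractions <- function(truth) {
  tr <- truth@tracts
  tapply((tr$end - tr$start) / truth@chromLength, tr$donor, sum)
}

setMethod("show", "MosaicTruth", function(object) {
  fr <- donorFractions(object)
  cat("MosaicTruth: ", nrow(object@tracts), " tracts over ",
      object@chromLength, " bp; donor fractions: ",
      paste(sprintf("%s=%.3f", names(fr), fr), collapse = ", "), "\n",
      sep = "")
})

#' SimilarityProfile: windowed identity of the focal chromosome vs one strain
#'
#' @slot comparison label of the comparison strain.
#' @slot windowSize,step window grid in bases (block mode: size == step;
#'   sliding mode: step < size, size a multiple of step).
#' @slot minCallable windows with fewer callable sites have similarity NA.
#' @slot chromLength chromosome length.
#' @slot windows data.frame with start, end (0-based half-open), callable,
#'   matches, similarity (NA when undefined).
#' @export
setClass("SimilarityProfile",
  representation(comparison = "character", windowSize = "numeric",
                 step = "numeric", minCallable = "numeric",
                 chromLength = "numeric", windows = "data.frame"))

setValidity("SimilarityProfile", function(object) {
  w <- object@windows
  if (!all(c("start", "end", "callable", "matches", "similarity") %in% names(w)))
    return("windows needs start, end, callable, matches, similarity")
  s <- w$similarity[!is.na(w$similarity)]
  if (length(s) && (min(s) < 0 || max(s) > 1))
    return("similarity must lie in [0, 1]")
  TRUE
})

#' @describeIn windowSimilarity the per-window table.
#' @param profile a SimilarityProfile.
#' @export
profileWindows <- function(profile) profile@windows

setMethod("show", "SimilarityProfile", function(object) {
  w <- object@windows
  ok <- !is.na(w$similarity)
  cat("SimilarityProfile vs ", object@comparison, ": ", nrow(w),
      " windows (", object@windowSize, "/", object@step, " bp), ",
      sum(ok), " defined, median similarity ",
      if (any(ok)) sprintf("%.4f", stats::median(w$similarity[ok])) else "NA",
      "\n", sep = "")
})

#' GeneModels: transcript structures for consequence annotation
#'
#' @slot transcripts GRanges with mcols gene_id, tx_id, biotype
#'   (coding/noncoding/nmd).
#' @slot exons GRangesList keyed by tx_id.
#' @slot cds GRangesList keyed by tx_id (empty for noncoding transcripts).
#' @export
setClass("GeneModels",
  representation(transcripts = "GRanges", exons = "GRangesList",
                 cds = "GRangesList"))

setValidity("GeneModels", function(object) {
  tx <- object@transcripts
  if (!all(c("gene_id", "tx_id", "biotype") %in%
           names(S4Vectors::mcols(tx))))
    return("transcripts need mcols gene_id, tx_id, biotype")
  if (!all(tx$tx_id %in% names(object@exons)))
    return("every transcript needs exons")
  TRUE
})

#' ChromAlignment: a chromosome-scale positional alignment of the taxon panel
#'
#' Sequences share reference coordinates (consensus construction preserves
#' them), so columns are positions; a column is callable when no taxon has N
#' there and the position is unmasked.
#'
#' @slot seqs DNAStringSet over the taxa (equal widths).
#' @slot focal label of the focal strain.
#' @slot reps named character: labels of the subspecies representatives
#'   (names DOM, MUS, CAS).
#' @slot outgroup label of the outgroup taxon.
#' @slot mask IRanges of masked columns (1-based closed).
#' @export
setClass("ChromAlignment",
  representation(seqs = "DNAStringSet", focal = "character",
                 reps = "character", outgroup = "character",
                 mask = "IRanges"))

setValidity("ChromAlignment", function(object) {
  if (length(unique(Biostrings::width(object@seqs))) != 1)
    return("aligned sequences must have equal length")
  need <- c(object@focal, object@reps, object@outgroup)
  if (!all(need %in% names(object@seqs)))
    return("focal, representative and outgroup labels must name sequences")
  TRUE
})

setMethod("show", "ChromAlignment", function(object) {
  cat("ChromAlignment: ", length(object@seqs), " taxa x ",
      Biostrings::width(object@seqs)[1], " bp (focal ", object@focal,
      ", outgroup ", object@outgroup, ")\n", sep = "")
})

setMethod("show", "GeneModels", function(object) {
  cat("GeneModels: ", length(unique(object@transcripts$gene_id)), " genes, ",
      length(object@transcripts), " transcripts (",
      sum(object@transcripts$biotype == "coding"), " coding)\n", sep = "")
})
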