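#' Parameters for the synthetic mosaic-chromosome generator
#'
#' Defaults emulate the divergence structure of the house-mouse subspecies
#' panel the analysis assumes: between-subspecies divergence ~0.92%
#' (similarity band 99.05--99.1%), within-subspecies divergence 0.2%
#' (similarity band >99.7%), and a distant outgroup at 15%. The focal
#' chromosome is a mosaic of subspecies-derived tracts with sharp
#' breakpoints; its per-donor length fractions default to 87.7% domesticus,
#' 9.7% musculus and 2.6% castaneus.
#'
#' @param chromosomeLength chromosome length in bases.
#' @param divergenceInter expected pairwise mismatch fraction between
#'   subspecies representatives (and between the focal chromosome and a
#'   representative of a different subspecies).
#' @param divergenceIntra expected mismatch fraction between two haplotypes
#'   of the same subspecies (focal tract vs its donor's representative).
#' @param divergenceOutgroup expected mismatch fraction outgroup vs ingroup.
#' @param tractFractions named numeric (names among DOM, MUS, CAS) summing
#'   to 1: fraction of chromosome length per donor subspecies.
#' @param meanTractLength target mean tract length in bases.
#' @param maskFraction fraction of sites masked (repeat-mask emulation).
#' @param meanMaskLength mean masked-interval length in bases.
#' @param nGenes number of gene models to simulate.
#' @param hetFraction fraction of emitted variant records flagged
#'   heterozygous (consensus turns those sites into N).
#' @param indelRate per-callable-site indel rate for emission.
#' @param depthMean mean sequencing depth for synthetic DP fields.
#' @param corruptFractions named numeric over clauses qual, mq, depth,
#'   alt_reads: fraction of emitted records corrupted to fail that clause.
#' @param chromName chromosome name used in VCF/BED/GFF3 output.
#' @param seed integer seed; every generator operation derives its stream
#'   from it, so equal seeds give byte-identical outputs.
#' @return a validated list of class \code{simulationParams}.
#' @export
simulationParams <- function(chromosomeLength = 2e7,
                             divergenceInter = 0.0092,
                             divergenceIntra = 0.0020,
                             divergenceOutgroup = 0.15,
                             tractFractions = c(DOM = 0.877, MUS = 0.097,
                                                CAS = 0.026),
                             meanTractLength = 2e6,
                             maskFraction = 0.1,
                             meanMaskLength = 500,
                             nGenes = 100,
                             hetFraction = 0.0358,
                             indelRate = 4e-4,
                             depthMean = 36.6,
                             corruptFractions = c(qual = 0, mq = 0,
                                                  depth = 0, alt_reads = 0),
                             chromName = "chr1",
                             seed = 1L) {
  p <- list(chromosomeLength = as.numeric(chromosomeLength),
            divergenceInter = divergenceInter,
            divergenceIntra = divergenceIntra,
            divergenceOutgroup = divergenceOutgroup,
            tractFractions = tractFractions,
            meanTractLength = as.numeric(meanTractLength),
            maskFraction = maskFraction,
            meanMaskLength = meanMaskLength,
            nGenes = as.integer(nGenes),
            hetFraction = hetFraction,
            indelRate = indelRate,
            depthMean = depthMean,
            corruptFractions = corruptFractions,
            chromName = chromName,
            seed = as.integer(seed))
  class(p) <- "simulationParams"
  validateParams(p)
  p
}

validateParams <- function(p) {
  divs <- c(p$divergenceIntra, p$divergenceInter, p$divergenceOutgroup)
  if (any(divs < 0) || any(divs >= 1))
    stop("divergences must lie in [0, 1)")
  if (any(divs >= 0.75))
    stop("divergence >= 0.75 saturates under uniform resampling")
  if (!(p$divergenceIntra <= p$divergenceInter &&
        p$divergenceInter <= p$divergenceOutgroup))
    stop("require divergenceIntra <= divergenceInter <= divergenceOutgroup")
  if (p$chromosomeLength <= 0) stop("chromosomeLength must be positive")
  tf <- p$tractFractions
  if (is.null(names(tf)) || !all(names(tf) %in% c("DOM", "MUS", "CAS")))
    stop("tractFractions must be named with donors among DOM, MUS, CAS")
  if (abs(sum(tf) - 1) > 1e-6) stop("tractFractions must sum to 1")
  if (p$maskFraction < 0 || p$maskFraction > 1)
    stop("maskFraction must lie in [0, 1]")
  invisible(p)
}

## Apply one substitution layer to a raw DNA vector: each site mutates with
## probability rate, resampling uniformly among the three other bases.
mutateRaw <- function(r, rate) {
  if (rate <= 0) return(r)
  L <- length(r)
  n <- stats::rbinom(1L, L, rate)
  if (n == 0L) return(r)
  pos <- sample.int(L, n)
  cur <- match(r[pos], .baseRaw)
  new <- (cur - 1L + sample.int(3L, n, replace = TRUE)) %% 4L + 1L
  r[pos] <- .baseRaw[new]
  r
}

randomRawSeq <- function(L) .baseRaw[sample.int(4L, L, replace = TRUE)]

## Branch substitution probabilities that realize the pairwise divergence
## targets exactly in expectation (see the methods vignette):
##   tip:  rep and focal donor each sit at `tip` from the subspecies ancestor
##   anc:  each subspecies ancestor from the root
##   out:  the outgroup from the root, targeting outgroup-vs-ingroup-tip
branchRates <- function(inter, intra, outgroup) {
  tip <- solveEqualBranches(intra)
  a2 <- (inter - intra) / (1 - (4 / 3) * intra)
  anc <- solveEqualBranches(a2)
  path <- composeDivergence(anc, tip)
  out <- solveResidualBranch(outgroup, path)
  c(tip = tip, anc = anc, out = out)
}

#' Simulate the strain haplotype panel
#'
#' Draws a uniform-random ancestral chromosome and evolves it along a
#' star-with-outgroup branch scheme under independent-site uniform
#' resampling. Branch substitution probabilities are solved so that expected
#' pairwise mismatch fractions equal the targets: representative pairs of
#' different subspecies at \code{divergenceInter}; any haplotype vs its own
#' subspecies representative (including the reference-like host, itself a
#' domesticus haplotype) at \code{divergenceIntra}; outgroup vs any ingroup
#' tip at \code{divergenceOutgroup}.
#'
#' @param params a \code{\link{simulationParams}} list.
#' @return a \linkS4class{HaplotypeSet} with visible haplotypes REF, DOM,
#'   MUS, CAS, OUT and latent subspecies ancestors.
#' @export
simulateHaplotypes <- function(params) {
  validateParams(params)
  L <- as.integer(params$chromosomeLength)
  rates <- branchRates(params$divergenceInter, params$divergenceIntra,
                       params$divergenceOutgroup)
  withSeed(params$seed, {
    root <- randomRawSeq(L)
    ancs <- list(DOM = mutateRaw(root, rates["anc"]),
                 MUS = mutateRaw(root, rates["anc"]),
                 CAS = mutateRaw(root, rates["anc"]))
    seqs <- list(REF = mutateRaw(ancs$DOM, rates["tip"]),
                 DOM = mutateRaw(ancs$DOM, rates["tip"]),
                 MUS = mutateRaw(ancs$MUS, rates["tip"]),
                 CAS = mutateRaw(ancs$CAS, rates["tip"]),
                 OUT = mutateRaw(root, rates["out"]))
    new("HaplotypeSet",
        sequences = Biostrings::DNAStringSet(vapply(seqs, rawToChar, "")),
        ancestors = Biostrings::DNAStringSet(vapply(ancs, rawToChar, "")),
        params = unclass(params), branchRates = rates)
  })
}

## Quota tract layout: per-donor total length is exact (round(frac*L)), the
## per-donor tract count targets meanTractLength, individual lengths get
## exponential weights, and tract order is a random shuffle. Realized donor
## fractions therefore match tractFractions up to integer rounding.
layoutTracts <- function(L, fractions, meanLen) {
  fractions <- fractions[fractions > 0]
  totals <- round(fractions * L)
  totals[which.max(totals)] <- totals[which.max(totals)] + (L - sum(totals))
  pieces <- list()
  for (d in names(totals)) {
    tot <- totals[[d]]
    n <- max(1L, as.integer(round(tot / meanLen)))
    w <- stats::rexp(n)
    len <- floor(tot * w / sum(w))
    len[n] <- len[n] + (tot - sum(len))
    len <- len[len > 0]
    pieces[[d]] <- data.frame(donor = d, len = len)
  }
  tr <- do.call(rbind, pieces)
  tr <- tr[sample.int(nrow(tr)), , drop = FALSE]
  end <- cumsum(tr$len)
  out <- data.frame(start = c(0, end[-length(end)]), end = end,
                    donor = tr$donor, stringsAsFactors = FALSE)
  ## merge adjacent tracts from the same donor
  keep <- c(TRUE, out$donor[-1] != out$donor[-nrow(out)])
  grp <- cumsum(keep)
  data.frame(start = tapply(out$start, grp, min),
             end = tapply(out$end, grp, max),
             donor = out$donor[keep], row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Simulate the focal mosaic chromosome
#'
#' Tract lengths follow an exponential-weight scheme around
#' \code{meanTractLength}; per-donor total lengths equal
#' \code{tractFractions} exactly (up to base rounding), so recovery tests
#' see the nominal fractions at every seed. Within each tract the focal
#' sequence is drawn from the donor subspecies' latent ancestor plus fresh
#' private tip mutations, placing it at \code{divergenceIntra} from the
#' donor's representative and at \code{divergenceInter} from every other
#' representative. Breakpoints are exact.
#'
#' @param params a \code{\link{simulationParams}} list.
#' @param haps the \linkS4class{HaplotypeSet} from
#'   \code{\link{simulateHaplotypes}}.
#' @param mask optional IRanges mask to attach to the focal sequence
#'   (default: \code{\link{emitMask}(params)}).
#' @return list with elements \code{focal} (a
#'   \linkS4class{MaskedSequence} labelled KM) and \code{truth}
#'   (a \linkS4class{MosaicTruth}).
#' @export
simulateMosaic <- function(params, haps, mask = NULL) {
  validateParams(params)
  L <- as.integer(params$chromosomeLength)
  if (params$meanTractLength > L)
    stop("meanTractLength exceeds chromosomeLength")
  if (is.null(mask)) mask <- emitMask(params)
  withSeed(params$seed + 1L, {
    tr <- layoutTracts(L, params$tractFractions, params$meanTractLength)
    focal <- raw(L)
    ancRaw <- lapply(seq_along(haps@ancestors), function(i)
      dnaToRaw(haps@ancestors[[i]]))
    names(ancRaw) <- names(haps@ancestors)
    for (i in seq_len(nrow(tr))) {
      idx <- (tr$start[i] + 1L):tr$end[i]
      focal[idx] <- ancRaw[[tr$donor[i]]][idx]
    }
    focal <- mutateRaw(focal, haps@branchRates["tip"])
    list(focal = maskedSequence(rawToChar(focal), mask = mask, label = "KM"),
         truth = new("MosaicTruth", tracts = tr, chromLength = as.numeric(L)))
  })
}

#' Simulate a repeat-mask interval set
#'
#' Masked intervals have exponential lengths around \code{meanMaskLength}
#' and are placed uniformly; generation proceeds until the merged coverage
#' reaches \code{maskFraction} of the chromosome exactly (the final interval
#' is trimmed), so realized coverage equals the target.
#'
#' @param params a \code{\link{simulationParams}} list.
#' @return an \link[IRanges]{IRanges} of masked intervals (1-based closed).
#' @export
emitMask <- function(params) {
  validateParams(params)
  L <- as.integer(params$chromosomeLength)
  target <- round(params$maskFraction * L)
  if (target <= 0) return(IRanges::IRanges())
  if (target >= L) return(IRanges::IRanges(1L, L))
  withSeed(params$seed + 2L, {
    acc <- IRanges::IRanges()
    while (sum(IRanges::width(acc)) < target) {
      need <- target - sum(IRanges::width(acc))
      n <- max(10L, ceiling(1.3 * need / params$meanMaskLength))
      w <- pmax(1L, round(stats::rexp(n, 1 / params$meanMaskLength)))
      s <- sample.int(L, n, replace = TRUE)
      add <- IRanges::IRanges(s, width = pmin(w, L - s + 1L))
      acc <- IRanges::reduce(c(acc, add))
    }
    ## drop a random subset of intervals (and trim one) so coverage is
    ## exact without spatial bias
    ord <- sample.int(length(acc))
    cum <- cumsum(IRanges::width(acc)[ord])
    k <- which(cum >= target)[1]
    keep <- ord[seq_len(k)]
    excess <- cum[k] - target
    acc <- acc[sort(keep)]   # reduce() output is position-sorted
    if (excess > 0) {
      at <- which(sort(keep) == ord[k])
      IRanges::end(acc)[at] <- IRanges::end(acc)[at] - excess
    }
    acc
  })
}

#' Emit SNP/indel records for the focal chromosome against the reference
#'
#' Every mismatching callable (unmasked, non-N in both) site becomes a
#' homozygous-alternate SNP record with synthetic QUAL/MQ/DP/DP4 fields; a
#' configurable fraction of records is flagged heterozygous, and optional
#' low-rate indels are emitted (not applied to any sequence). Fractions of
#' records can be corrupted to fail individual filter clauses, for filter
#' testing. Applying the emitted homozygous SNPs back onto the reference
#' reproduces the focal sequence at callable sites.
#'
#' @param focal,reference \linkS4class{MaskedSequence}s of equal length.
#' @param params a \code{\link{simulationParams}} list (field distributions,
#'   het/indel/corruption rates, chromosome name, seed).
#' @return a data.frame of variant records with columns chrom, pos (1-based),
#'   ref, alt, qual, mq, dp, dp4_rf, dp4_rr, dp4_af, dp4_ar, genotype
#'   (hom_alt/het), vclass (snp/insertion/deletion), sorted by position.
#' @export
emitVariants <- function(focal, reference, params) {
  if (length(focal) != length(reference))
    stop("focal and reference lengths differ")
  L <- length(focal)
  fr <- dnaToRaw(dnaSeq(focal)); rr <- dnaToRaw(dnaSeq(reference))
  callable <- !maskLogical(maskRanges(focal), L) &
    !maskLogical(maskRanges(reference), L) &
    fr != .rawN & rr != .rawN
  pos <- which(fr != rr & callable)
  withSeed(params$seed + 4L, {
    snps <- if (length(pos))
      data.frame(chrom = params$chromName, pos = pos,
                 ref = strsplit(rawToChar(rr[pos]), "")[[1]],
                 alt = strsplit(rawToChar(fr[pos]), "")[[1]],
                 vclass = "snp", stringsAsFactors = FALSE)
    else emptyVariantFrame(params$chromName)[, c("chrom", "pos", "ref",
                                                 "alt", "vclass")]
    ## indels: placed at callable non-SNP sites, alleles from ref context
    nInd <- stats::rbinom(1L, max(0L, sum(callable) - length(pos)),
                          params$indelRate)
    if (nInd > 0) {
      avail <- which(callable)
      avail <- avail[avail > 1L & avail < L - 4L]
      avail <- setdiff(avail, pos)
      ipos <- sort(sample(avail, min(nInd, length(avail))))
      isIns <- stats::runif(length(ipos)) < 0.5
      ilen <- sample.int(3L, length(ipos), replace = TRUE)
      refA <- altA <- character(length(ipos))
      for (i in seq_along(ipos)) {
        p <- ipos[i]
        anchor <- rawToChar(rr[p])
        if (isIns[i]) {
          refA[i] <- anchor
          altA[i] <- paste0(anchor, rawToChar(
            .baseRaw[sample.int(4L, ilen[i], replace = TRUE)]))
        } else {
          refA[i] <- rawToChar(rr[p:(p + ilen[i])])
          altA[i] <- anchor
        }
      }
      indels <- data.frame(chrom = params$chromName, pos = ipos, ref = refA,
                           alt = altA,
                           vclass = ifelse(isIns, "insertion", "deletion"),
                           stringsAsFactors = FALSE)
      snps <- rbind(snps, indels)
    }
    v <- snps[order(snps$pos), , drop = FALSE]
    n <- nrow(v)
    v$qual <- round(stats::runif(n, 30, 200), 1)
    v$mq <- pmin(60, pmax(26, round(stats::rnorm(n, 50, 2))))
    v$dp <- pmin(198L, pmax(7L, stats::rpois(n, params$depthMean)))
    het <- stats::runif(n) < params$hetFraction
    altReads <- ifelse(het, pmax(3L, stats::rbinom(n, v$dp, 0.5)), v$dp)
    refReads <- v$dp - altReads
    v$dp4_rf <- stats::rbinom(n, refReads, 0.5)
    v$dp4_rr <- refReads - v$dp4_rf
    v$dp4_af <- stats::rbinom(n, altReads, 0.5)
    v$dp4_ar <- altReads - v$dp4_af
    v$genotype <- ifelse(het, "het", "hom_alt")
    ## clause-targeted corruption for filter testing
    cf <- params$corruptFractions
    pool <- seq_len(n)
    for (clause in names(cf)) {
      k <- round(cf[[clause]] * n)
      if (k <= 0 || !length(pool)) next
      idx <- sample(pool, min(k, length(pool)))
      pool <- setdiff(pool, idx)
      switch(clause,
        qual = { v$qual[idx] <- round(stats::runif(length(idx), 0, 10), 1) },
        mq = { v$mq[idx] <- sample(0:25, length(idx), replace = TRUE) },
        depth = {
          lo <- stats::runif(length(idx)) < 0.5
          v$dp[idx] <- ifelse(lo, sample(0:6, length(idx), replace = TRUE),
                              sample(199:240, length(idx), replace = TRUE))
        },
        alt_reads = {
          a <- sample(0:2, length(idx), replace = TRUE)
          v$dp4_af[idx] <- pmin(a, 1L)
          v$dp4_ar[idx] <- a - v$dp4_af[idx]
        },
        stop("unknown corruption clause: ", clause))
    }
    rownames(v) <- NULL
    v[, variantColumns()]
  })
}

variantColumns <- function() c("chrom", "pos", "ref", "alt", "qual", "mq",
                               "dp", "dp4_rf", "dp4_rr", "dp4_af", "dp4_ar",
                               "genotype", "vclass")

emptyVariantFrame <- function(chrom = "chr1") {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), qual = numeric(), mq = numeric(),
             dp = integer(), dp4_rf = integer(), dp4_rr = integer(),
             dp4_af = integer(), dp4_ar = integer(), genotype = character(),
             vclass = character(), stringsAsFactors = FALSE)
}
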