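#' Assemble a chromosome alignment from masked sequences
#'
#' @param focal the focal strain's \linkS4class{MaskedSequence}.
#' @param dom,mus,cas subspecies representative sequences.
#' @param out outgroup sequence.
#' @return a \linkS4class{ChromAlignment}; the mask is the union of all
#'   input masks.
#' @export
chromAlignment <- function(focal, dom, mus, cas, out) {
  inputs <- list(focal, dom, mus, cas, out)
  labels <- vapply(inputs, seqLabel, "")
  seqs <- Biostrings::DNAStringSet(vapply(inputs, function(s)
    as.character(dnaSeq(s)), ""))
  names(seqs) <- labels
  mask <- IRanges::reduce(do.call(c, lapply(inputs, maskRanges)))
  new("ChromAlignment", seqs = seqs, focal = labels[1],
      reps = c(DOM = labels[2], MUS = labels[3], CAS = labels[4]),
      outgroup = labels[5], mask = mask)
}

alignmentCallable <- function(aln) {
  L <- Biostrings::width(aln@seqs)[1]
  ok <- !maskLogical(aln@mask, L)
  for (i in seq_along(aln@seqs))
    ok <- ok & dnaToRaw(aln@seqs[[i]]) != .rawN
  ok
}

taxonPairs <- function(taxa) {
  idx <- utils::combn(length(taxa), 2)
  list(i = idx[1, ], j = idx[2, ],
       names = paste(taxa[idx[1, ]], taxa[idx[2, ]], sep = "-"))
}

#' Partition the alignment into loci
#'
#' Fixed mode tiles the chromosome into contiguous equal-length loci
#' (terminal partial locus kept). Changepoint mode places boundaries by
#' penalized binary segmentation on binned focal-vs-representative mismatch
#' profiles (penalty \code{penaltyC * k * log(n)} on the standardized
#' residual sum of squares, k = number of profiles). Loci with fewer than
#' \code{minInformative} callable columns are dropped with a logged reason.
#'
#' @param aln a \linkS4class{ChromAlignment}.
#' @param mode "fixed" or "changepoint".
#' @param locusLength fixed-mode locus length in bases (>= 1000).
#' @param minInformative minimum callable columns per locus.
#' @param cpBin changepoint-mode bin width in bases.
#' @param penaltyC changepoint penalty constant.
#' @return data.frame with start, end (0-based half-open), callable, kept
#'   (logical), reason (NA or "too_few_callable").
#' @export
partitionLoci <- function(aln, mode = c("fixed", "changepoint"),
                          locusLength = 2e5, minInformative = 1000,
                          cpBin = 1e4, penaltyC = 4) {
  mode <- match.arg(mode)
  if (locusLength < 1000) stop("locusLength must be at least 1000")
  L <- Biostrings::width(aln@seqs)[1]
  callable <- alignmentCallable(aln)
  if (mode == "fixed") {
    start <- seq(0, L - 1, by = locusLength)
    end <- pmin(start + locusLength, L)
  } else {
    nb <- ceiling(L / cpBin)
    binOf <- function(pos) (pos - 1) %/% cpBin + 1
    fr <- dnaToRaw(aln@seqs[[aln@focal]])
    prof <- sapply(aln@reps, function(r) {
      rr <- dnaToRaw(aln@seqs[[r]])
      mis <- which(callable & fr != rr)
      tabulate(binOf(mis), nb) / pmax(tabulate(binOf(which(callable)), nb), 1)
    })
    cp <- binarySegment(scale(prof), penaltyC * ncol(prof) *
                          log(nrow(prof)))
    bounds <- c(0, sort(cp) * cpBin, L)
    bounds[length(bounds)] <- L
    start <- bounds[-length(bounds)]
    end <- bounds[-1]
  }
  csC <- c(0, cumsum(callable))
  nCall <- csC[end + 1] - csC[start + 1]
  kept <- nCall >= minInformative
  data.frame(start = start, end = end, callable = nCall, kept = kept,
             reason = ifelse(kept, NA_character_, "too_few_callable"),
             stringsAsFactors = FALSE)
}

## Recursive binary segmentation on a (bins x k) matrix; returns changepoint
## bin indices (boundary AFTER that bin). Gain = reduction in RSS from
## splitting a segment at its best point; accept while gain > penalty.
binarySegment <- function(x, penalty) {
  x <- as.matrix(x)
  segRss <- function(lo, hi) {
    xs <- x[lo:hi, , drop = FALSE]
    sum(scale(xs, scale = FALSE)^2)
  }
  bestSplit <- function(lo, hi) {
    if (hi - lo < 3) return(NULL)
    whole <- segRss(lo, hi)
    gains <- vapply((lo + 1):(hi - 1), function(s)
      whole - segRss(lo, s) - segRss(s + 1, hi), numeric(1))
    k <- which.max(gains)
    list(at = lo + k, gain = gains[k])
  }
  out <- integer(0)
  recurse <- function(lo, hi) {
    sp <- bestSplit(lo, hi)
    if (is.null(sp) || sp$gain <= penalty) return()
    out <<- c(out, sp$at)
    recurse(lo, sp$at)
    recurse(sp$at + 1, hi)
  }
  recurse(1, nrow(x))
  sort(out)
}

## Precompute the per-taxon raw sequences and the callable-column vector
## once per alignment; locus extraction then only slices.
alignmentContext <- function(aln) {
  taxa <- c(aln@focal, unname(aln@reps), aln@outgroup)
  raws <- lapply(taxa, function(t) dnaToRaw(aln@seqs[[t]]))
  names(raws) <- taxa
  L <- Biostrings::width(aln@seqs)[1]
  callable <- !maskLogical(aln@mask, L)
  for (r in raws) callable <- callable & r != .rawN
  list(taxa = taxa, raws = raws, callable = callable)
}

#' Site-pattern summary of one locus
#'
#' Collapses the locus's callable columns into unique pairwise-mismatch
#' patterns with counts; all distance computation (including bootstrap
#' resampling) then reduces to multinomial draws over patterns and one
#' matrix product.
#'
#' @param aln a \linkS4class{ChromAlignment}.
#' @param start,end locus interval, 0-based half-open.
#' @param ctx optional precomputed context (internal; lets a caller reuse
#'   the raw sequences and callable vector across many loci).
#' @return list with \code{mis} (pairs x patterns 0/1 matrix),
#'   \code{counts} (pattern multiplicities), \code{n} (callable columns),
#'   \code{taxa}, \code{pairs}.
#' @export
locusPatterns <- function(aln, start, end, ctx = NULL) {
  if (is.null(ctx)) ctx <- alignmentContext(aln)
  taxa <- ctx$taxa
  idx <- (start + 1):end
  callable <- ctx$callable[idx]
  raws <- lapply(ctx$raws, function(r) r[idx][callable])
  pr <- taxonPairs(taxa)
  nP <- length(pr$i)
  n <- sum(callable)
  if (n == 0)
    return(list(mis = matrix(0L, nP, 0), counts = integer(0), n = 0L,
                taxa = taxa, pairs = pr$names))
  code <- integer(n)
  misList <- vector("list", nP)
  for (p in seq_len(nP)) {
    m <- raws[[pr$i[p]]] != raws[[pr$j[p]]]
    misList[[p]] <- m
    code <- code * 2L + m
  }
  uc <- sort(unique(code))
  pat <- match(code, uc)
  counts <- tabulate(pat, length(uc))
  mis <- matrix(0L, nP, length(uc),
                dimnames = list(pr$names, NULL))
  for (p in seq_len(nP))
    mis[p, ] <- as.integer(bitwAnd(uc %/% 2L^(nP - p), 1L))
  list(mis = mis, counts = counts, n = as.integer(n), taxa = taxa,
       pairs = pr$names)
}

#' Pairwise distance matrix of a locus
#'
#' p-distance = mismatches / callable columns (pairwise deletion happens
#' globally: a column with any N or mask is excluded for all pairs); jc69
#' applies the substitution correction -(3/4) log(1 - (4/3) p).
#'
#' @param pat a \code{\link{locusPatterns}} list (or a ChromAlignment
#'   together with \code{start}/\code{end}).
#' @param model "p" or "jc69".
#' @param start,end locus interval when \code{pat} is a ChromAlignment.
#' @return symmetric distance matrix with zero diagonal.
#' @export
distanceMatrix <- function(pat, model = c("p", "jc69"), start = NULL,
                           end = NULL) {
  model <- match.arg(model)
  if (is(pat, "ChromAlignment")) pat <- locusPatterns(pat, start, end)
  if (pat$n == 0) stop("locus has no callable columns")
  mism <- as.vector(pat$mis %*% pat$counts)
  p <- mism / pat$n
  if (model == "jc69") {
    if (any(p >= 0.75))
      stop("p-distance >= 0.75: jc69 correction undefined")
    p <- -(3 / 4) * log(1 - (4 / 3) * p)
  }
  k <- length(pat$taxa)
  d <- matrix(0, k, k, dimnames = list(pat$taxa, pat$taxa))
  pr <- taxonPairs(pat$taxa)
  d[cbind(pr$i, pr$j)] <- p
  d[cbind(pr$j, pr$i)] <- p
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}); negative branch
#' lengths are clamped to zero and the tree is ladderized so equal inputs
#' give identical output.
#'
#' @param d symmetric numeric matrix with taxon dimnames.
#' @return an \link[ape]{ape} \code{phylo} tree (unrooted).
#' @export
njTree <- function(d) {
  if (any(is.na(d)) || any(!is.finite(d))) stop("distance matrix has NA/NaN")
  if (!isSymmetric(unname(d))) stop("distance matrix must be symmetric")
  if (nrow(d) < 3) stop("need at least 3 taxa")
  tr <- ape::nj(d)
  tr$edge.length[tr$edge.length < 0] <- 0
  ape::ladderize(tr)
}

descTips <- function(tree, node) {
  nTip <- length(tree$tip.label)
  if (node <= nTip) return(node)
  kids <- tree$edge[tree$edge[, 1] == node, 2]
  unlist(lapply(kids, descTips, tree = tree))
}

#' Classify the focal strain's sister taxon in a rooted tree
#'
#' Roots at the outgroup and inspects the focal tip's sister clade: if it
#' holds exactly one subspecies representative, the locus supports that
#' topology; a sister clade with several representatives (or the outgroup)
#' is UNRESOLVED.
#'
#' @param tree a \code{phylo} tree containing the focal, representative and
#'   outgroup tips.
#' @param focal,reps,outgroup taxon labels (\code{reps} named DOM/MUS/CAS).
#' @return one of FOCAL_WITH_DOM, FOCAL_WITH_MUS, FOCAL_WITH_CAS,
#'   UNRESOLVED.
#' @export
classifyTopology <- function(tree, focal = "KM",
                             reps = c(DOM = "DOM", MUS = "MUS",
                                      CAS = "CAS"),
                             outgroup = "OUT") {
  tr <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  fi <- match(focal, tr$tip.label)
  parent <- tr$edge[tr$edge[, 2] == fi, 1]
  sibs <- setdiff(tr$edge[tr$edge[, 1] == parent, 2], fi)
  sisterTips <- tr$tip.label[unlist(lapply(sibs, descTips, tree = tr))]
  sisterTips <- setdiff(sisterTips, focal)
  hit <- names(reps)[match(sisterTips, reps)]
  if (length(sisterTips) == 1 && !is.na(hit[1]))
    paste0("FOCAL_WITH_", hit[1]) else "UNRESOLVED"
}

topologyLabels <- function() c("FOCAL_WITH_DOM", "FOCAL_WITH_MUS",
                               "FOCAL_WITH_CAS", "UNRESOLVED")

#' Bootstrap topology support for one locus
#'
#' Resamples callable columns (as multinomial draws over site patterns) B
#' times; each replicate goes through distance, neighbor-joining, outgroup
#' rooting and sister-taxon classification. Support is the frequency of
#' each label; the locus call is the argmax when it reaches
#' \code{minSupport} (ties or a sub-threshold maximum give UNRESOLVED).
#' Replicates without any mismatching column are star-like and vote
#' UNRESOLVED.
#'
#' @param pat a \code{\link{locusPatterns}} list.
#' @param B bootstrap replicates (>= 1).
#' @param seed integer seed for the resampling stream.
#' @param minSupport minimum winning frequency (default 0.5).
#' @param model distance model passed to \code{\link{distanceMatrix}}.
#' @return list with \code{support} (named frequencies summing to 1) and
#'   \code{call}.
#' @export
bootstrapSupport <- function(pat, B = 1000, seed = 1, minSupport = 0.5,
                             model = "p") {
  if (B < 1) stop("B must be at least 1")
  if (pat$n == 0) stop("locus has no callable columns")
  labels <- topologyLabels()
  votes <- stats::setNames(numeric(length(labels)), labels)
  k <- length(pat$taxa)
  pr <- taxonPairs(pat$taxa)
  reps <- stats::setNames(pat$taxa[2:4], c("DOM", "MUS", "CAS"))
  withSeed(seed, {
    draws <- stats::rmultinom(B, pat$n, pat$counts)
    cache <- new.env(parent = emptyenv())
    for (b in seq_len(B)) {
      mism <- as.vector(pat$mis %*% draws[, b])
      key <- paste(mism, collapse = ",")
      lab <- cache[[key]]
      if (is.null(lab)) {
        if (all(mism == 0)) lab <- "UNRESOLVED"
        else {
          p <- mism / pat$n
          if (model == "jc69") p <- -(3 / 4) * log(1 - (4 / 3) * p)
          d <- matrix(0, k, k, dimnames = list(pat$taxa, pat$taxa))
          d[cbind(pr$i, pr$j)] <- p; d[cbind(pr$j, pr$i)] <- p
          lab <- classifyTopology(njTree(d), focal = pat$taxa[1],
                                  reps = reps, outgroup = pat$taxa[5])
        }
        cache[[key]] <- lab
      }
      votes[lab] <- votes[lab] + 1
    }
  })
  support <- votes / B
  best <- which(support == max(support))
  call <- if (length(best) > 1 || support[best] < minSupport)
    "UNRESOLVED" else labels[best]
  list(support = support, call = call)
}

#' Locus-wise topology concordance over a chromosome alignment
#'
#' Partitions the alignment, runs per-locus bootstrap topology calls, and
#' returns the call track.
#'
#' @param aln a \linkS4class{ChromAlignment}.
#' @param loci optional locus table from \code{\link{partitionLoci}}
#'   (default: fixed 200 kb loci).
#' @param B bootstrap replicates per locus.
#' @param seed integer seed; locus b gets stream \code{seed + b}.
#' @param minSupport minimum winning bootstrap frequency.
#' @param model distance model.
#' @param locusLength fixed-locus length when \code{loci} is NULL.
#' @return data.frame start, end, callable, label, support (winning
#'   frequency); skipped loci carry label NA.
#' @export
topologyCalls <- function(aln, loci = NULL, B = 1000, seed = 1,
                          minSupport = 0.5, model = "p",
                          locusLength = 2e5) {
  if (is.null(loci)) loci <- partitionLoci(aln, "fixed", locusLength)
  ctx <- alignmentContext(aln)
  out <- loci[, c("start", "end", "callable")]
  out$label <- NA_character_
  out$support <- NA_real_
  for (i in which(loci$kept)) {
    pat <- locusPatterns(aln, loci$start[i], loci$end[i], ctx = ctx)
    bs <- bootstrapSupport(pat, B = B, seed = seed + i,
                           minSupport = minSupport, model = model)
    out$label[i] <- bs$call
    out$support[i] <- max(bs$support)
  }
  out
}

#' Summarize genome-wide concordance factors
#'
#' Fractions of classified loci per topology label (UNRESOLVED included;
#' fractions sum to 1). When introgression tracts are supplied, reports the
#' fraction of FOCAL_WITH_MUS loci overlapping a called MUS tract -- the
#' consistency check between the similarity painting and the tree-based
#' concordance.
#'
#' @param calls data.frame from \code{\link{topologyCalls}}.
#' @param tracts optional tract data.frame (start, end 0-based half-open)
#'   from \code{\link{callTracts}} against the MUS representative.
#' @return list with \code{fractions}, \code{nLoci}, \code{track} and
#'   optionally \code{musTractAgreement}.
#' @export
concordanceSummary <- function(calls, tracts = NULL) {
  done <- calls[!is.na(calls$label), , drop = FALSE]
  if (!nrow(done)) stop("no classified loci to summarize")
  labels <- topologyLabels()
  fr <- stats::setNames(as.vector(table(factor(done$label,
                                               levels = labels))) /
                          nrow(done), labels)
  out <- list(fractions = fr, nLoci = nrow(done), track = done)
  if (!is.null(tracts) && nrow(tracts)) {
    mus <- done[done$label == "FOCAL_WITH_MUS", , drop = FALSE]
    if (nrow(mus)) {
      ovl <- vapply(seq_len(nrow(mus)), function(i)
        any(tracts$start < mus$end[i] & tracts$end > mus$start[i]), TRUE)
      out$musTractAgreement <- mean(ovl)
    }
  }
  out
}
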