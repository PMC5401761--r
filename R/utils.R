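#' Round half away from zero at a fixed number of decimals
#'
#' Reported percentages follow the print convention of rounding halves up
#' (e.g. 6.45 -> 6.5 at one decimal), not base R's round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places to keep.
#' @return numeric vector rounded half-up.
#' @export
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5 + 1e-9) / m
}

#' Percentage of a count over a denominator, rounded half-up
#'
#' @param num numerator count.
#' @param den denominator count.
#' @param digits decimal places (default 1, matching typical summary tables).
#' @return percentage on the 0--100 scale.
#' @export
percentHalfUp <- function(num, den, digits = 1) {
  stopifnot(den > 0)
  roundHalfUp(100 * num / den, digits)
}

## Composition of two independent uniform-resampling substitution layers:
## if a site differs with prob a after layer 1 and b after layer 2, the
## composed mismatch probability is a + b - (4/3)ab (Jukes-Cantor-like kernel
## M(s) = (1-s)I + (s/3)(J-I), which is closed under multiplication).
composeDivergence <- function(a, b) a + b - (4 / 3) * a * b

## Solve f(s, s) = d for the per-branch substitution probability of two
## equal sibling branches whose tips must show pairwise mismatch d.
solveEqualBranches <- function(d) {
  if (d < 0 || d >= 0.75)
    stop("pairwise divergence must be in [0, 0.75) (saturation under uniform resampling)")
  if (d == 0) return(0)
  (2 - sqrt(4 - (16 / 3) * d)) * 3 / 8
}

## Solve f(x, c) = d for the remaining branch given a known partial path c.
solveResidualBranch <- function(d, c) {
  if (d < 0 || d >= 0.75)
    stop("pairwise divergence must be in [0, 0.75) (saturation under uniform resampling)")
  x <- (d - c) / (1 - (4 / 3) * c)
  if (x < 0) stop("target divergence smaller than the already-accumulated path")
  x
}

## Evaluate an expression with a temporary RNG seed, restoring global state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(seed))
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

## Raw byte codes for plain character DNA (upper case).
.rawA <- charToRaw("A"); .rawC <- charToRaw("C")
.rawG <- charToRaw("G"); .rawT <- charToRaw("T"); .rawN <- charToRaw("N")
.baseRaw <- charToRaw("ACGT")

## character sequence <-> raw vector helpers (sequences held as DNAString)
dnaToRaw <- function(dna) charToRaw(as.character(dna))
rawToDna <- function(r) Biostrings::DNAString(rawToChar(r))

## logical per-base mask vector from an IRanges (1-based closed)
maskLogical <- function(mask, L) {
  if (!length(mask)) return(rep(FALSE, L))
  as.vector(IRanges::coverage(mask, width = L) > 0)
}
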