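#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib milkmiR, .registration = TRUE
NULL

#' TagSet: unique small-RNA tags with per-library counts
#'
#' A collapsed representation of two small-RNA libraries: every unique read
#' sequence (after adapter trimming) becomes one tag carrying its read count
#' in each library.  The two libraries are the two compared conditions
#' (by default named \code{HH} and \code{LL}, the high- and low-milk-fat
#' cell libraries of the motivating design).
#'
#' @slot sequence character vector of uppercase DNA tag sequences (U is
#'   converted to T on input).
#' @slot countHH integer read counts in the first (HH) library.
#' @slot countLL integer read counts in the second (LL) library.
#' @slot metadata list of bookkeeping values (e.g. reads removed by a
#'   length filter).
#'
#' @exportClass TagSet
setClass("TagSet",
  representation(
    sequence = "character",
    countHH  = "integer",
    countLL  = "integer",
    metadata = "list"
  ),
  prototype(
    sequence = character(0),
    countHH  = integer(0),
    countLL  = integer(0),
    metadata = list()
  )
)

setValidity("TagSet", function(object) {
  msg <- character(0)
  n <- length(object@sequence)
  if (length(object@countHH) != n || length(object@countLL) != n)
    msg <- c(msg, "sequence and count slots must have equal length")
  if (n > 0) {
    if (any(grepl("[^ACGT]", object@sequence)))
      msg <- c(msg, "tag sequences must be uppercase DNA (ACGT)")
    if (any(object@countHH < 0) || any(object@countLL < 0))
      msg <- c(msg, "counts must be non-negative")
    if (any(object@countHH + object@countLL < 1))
      msg <- c(msg, "every tag must carry at least one read")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a TagSet
#'
#' @param sequence character vector of tag sequences (DNA or RNA; uppercased,
#'   U converted to T).
#' @param countHH,countLL read counts per library, recycled to the length of
#'   \code{sequence}.
#' @param metadata optional list of bookkeeping values.
#' @return A \linkS4class{TagSet}.
#' @examples
#' TagSet(c("ACGTACGTACGTACGTACGTAC", "TTTTACGTACGTACGTACGTAC"), c(3L, 1L), c(2L, 0L))
#' @export
TagSet <- function(sequence = character(0), countHH = integer(0),
                   countLL = integer(0), metadata = list()) {
  sequence <- toupper(as.character(sequence))
  sequence <- gsub("U", "T", sequence, fixed = TRUE)
  n <- length(sequence)
  new("TagSet",
    sequence = sequence,
    countHH  = as.integer(rep_len(countHH, n)),
    countLL  = as.integer(rep_len(countLL, n)),
    metadata = metadata)
}

#' MireapParams: the ten novel-miRNA prediction constraints
#'
#' Parameter object holding the ten hairpin-prediction constraints applied
#' to folded precursor candidates: mature-arm length bounds, star-arm
#' (duplex partner, the "reference" arm) length bounds, minimal read depth
#' at the Drosha/Dicer 5' cut site, maximal genomic copy number of the
#' mature sequence, maximal precursor folding free energy, maximal spacing
#' between the mature and star arms, minimal paired bases in the
#' miRNA/miRNA* duplex, and maximal duplex bulge.  Defaults are the standard
#' Mireap settings for animal small-RNA libraries.
#'
#' @slot minMatureLen minimal mature miRNA length (nt), default 18.
#' @slot maxMatureLen maximal mature miRNA length (nt), default 26.
#' @slot minStarLen minimal star-arm length (nt), default 20.
#' @slot maxStarLen maximal star-arm length (nt), default 24.
#' @slot minCutDepth minimal read depth at the mature 5' cut site, default 3.
#' @slot maxCopyNumber maximal genomic loci of the mature sequence, default 20.
#' @slot maxFreeEnergy maximal precursor free energy (kcal/mol); folding
#'   energies are negative, so the default -18 requires dG <= -18.
#' @slot maxDuplexSpace maximal spacing between mature and star arms (nt),
#'   default 35.
#' @slot minDuplexPairs minimal paired bases between miRNA and miRNA*,
#'   default 14.
#' @slot maxDuplexBulge maximal bulge in the duplex (nt), default 4.
#'
#' @exportClass MireapParams
setClass("MireapParams",
  representation(
    minMatureLen   = "numeric",
    maxMatureLen   = "numeric",
    minStarLen     = "numeric",
    maxStarLen     = "numeric",
    minCutDepth    = "numeric",
    maxCopyNumber  = "numeric",
    maxFreeEnergy  = "numeric",
    maxDuplexSpace = "numeric",
    minDuplexPairs = "numeric",
    maxDuplexBulge = "numeric"
  ),
  prototype(
    minMatureLen   = 18,
    maxMatureLen   = 26,
    minStarLen     = 20,
    maxStarLen     = 24,
    minCutDepth    = 3,
    maxCopyNumber  = 20,
    maxFreeEnergy  = -18,
    maxDuplexSpace = 35,
    minDuplexPairs = 14,
    maxDuplexBulge = 4
  )
)

setValidity("MireapParams", function(object) {
  msg <- character(0)
  if (object@minMatureLen > object@maxMatureLen)
    msg <- c(msg, "minMatureLen must be <= maxMatureLen")
  if (object@minStarLen > object@maxStarLen)
    msg <- c(msg, "minStarLen must be <= maxStarLen")
  if (object@minCutDepth < 1)
    msg <- c(msg, "minCutDepth must be >= 1")
  if (object@maxFreeEnergy > 0)
    msg <- c(msg, "maxFreeEnergy is an upper bound on a folding energy and must be <= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a MireapParams object
#'
#' @param ... named overrides of any \linkS4class{MireapParams} slot, e.g.
#'   \code{mireapParams(minDuplexPairs = 12)}.
#' @return A \linkS4class{MireapParams} with the defaults except for the
#'   supplied overrides.
#' @examples
#' mireapParams()
#' mireapParams(maxFreeEnergy = -25)
#' @export
mireapParams <- function(...) {
  args <- list(...)
  bad <- setdiff(names(args), slotNames("MireapParams"))
  if (length(bad))
    stop("unknown MireapParams field(s): ", paste(bad, collapse = ", "))
  do.call(new, c(list(Class = "MireapParams"), args))
}
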